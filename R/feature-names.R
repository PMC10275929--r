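#' Names of the 23 physiological window features
#'
#' The feature inventory extracted on every 0.5-s window: 15 electrodermal
#' features derived from the tonic (SCL) and phasic (SCR) skin-conductance
#' components, 7 cardiac features derived from the instantaneous heart rate
#' and the inter-beat-interval series, and 1 respiratory feature.
#'
#' @param group `"all"` (default) or one of `"gsr"`, `"scl"`, `"scr"`,
#'   `"cardiac"`, `"respiratory"`, `"cardiorespiratory"` to select a
#'   physiologically defined subset.
#' @return Character vector of feature names.
#' @examples
#' feature_names()
#' feature_names("cardiac")
#' @export
feature_names <- function(group = c("all", "gsr", "scl", "scr", "cardiac",
                                    "respiratory", "cardiorespiratory")) {
  group <- match.arg(group)
  scl <- c("SCL_mean", "SCL_std", "SCL_min", "SCL_max", "SCL_max_minus_min",
           "SCL_dot", "SCL_ddot")
  scr <- c("SCR_mean", "SCR_std", "SCR_min", "SCR_max", "SCR_max_minus_min",
           "N_peaks", "PA_mean", "PA_std")
  cardiac <- c("HR_mean", "HR_std", "HR_min", "HR_max", "HR_max_minus_min",
               "sDNN_mean", "rMSSD_mean")
  resp <- "RR_mean"
  switch(group,
    all = c(scl, scr, cardiac, resp),
    gsr = c(scl, scr),
    scl = scl,
    scr = scr,
    cardiac = cardiac,
    respiratory = resp,
    cardiorespiratory = c(cardiac, resp)
  )
}

#' The five affective quadrant labels
#'
#' High/Low Arousal x High/Low Valence quadrants of the valence-arousal
#' plane plus the central Neutral box.
#'
#' @return Character vector `c("HAHV", "HALV", "LALV", "LAHV", "N")`.
#' @export
quadrant_levels <- function() c("HAHV", "HALV", "LALV", "LAHV", "N")

# population standard deviation (divide by n); NA-free inputs assumed
pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

stopf <- function(...) abort(sprintf(...))
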