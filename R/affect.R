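#' Rescale a 1-9 affect rating to the centred -4..4 range
#'
#' Both picture-database ratings and self-assessment ratings live on a
#' 1-9 scale; subtracting 5 centres them so the neutral region sits at
#' the origin of the valence-arousal plane.
#'
#' @param raw Numeric rating(s) in `[1, 9]`.
#' @return `raw - 5`, in `[-4, 4]`.
#' @examples
#' rescale_rating(c(1, 5, 9)) # -4 0 4
#' @export
rescale_rating <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw < 1 | raw > 9))
    abort("ratings must lie in [1, 9]")
  raw - 5
}

#' Assign valence-arousal points to affective quadrants
#'
#' The plane is partitioned into the four Russell quadrants plus a closed
#' central neutral box of half-width 1 on both axes (|valence| <= 1 and
#' |arousal| <= 1), i.e. 6.25% of the [-4, 4]^2 plane. Outside the box,
#' axis boundaries resolve by sign convention: valence > 0 is
#' high-valence, arousal > 0 is high-arousal.
#'
#' @param valence,arousal Rescaled coordinates in `[-4, 4]` (recycled).
#' @param neutral_halfwidth Half-width of the neutral box (default 1).
#' @return Character vector over [quadrant_levels()].
#' @examples
#' assign_quadrant(c(2, -2, 0.5), c(3, 1.5, -0.5)) # HAHV HALV N
#' @export
assign_quadrant <- function(valence, arousal, neutral_halfwidth = 1) {
  if (any(abs(valence) > 4 + 1e-9) || any(abs(arousal) > 4 + 1e-9))
    abort("rescaled coordinates must lie in [-4, 4]")
  n <- pmax(length(valence), length(arousal))
  v <- rep_len(valence, n); a <- rep_len(arousal, n)
  out <- ifelse(abs(v) <= neutral_halfwidth & abs(a) <= neutral_halfwidth, "N",
         ifelse(v > 0 & a > 0, "HAHV",
         ifelse(v <= 0 & a > 0, "HALV",
         ifelse(v <= 0 & a <= 0, "LALV", "LAHV"))))
  out
}

#' The four classification problems on the valence-arousal plane
#'
#' `HL_VALENCE` and `HL_AROUSAL` are binary problems over the four
#' Russell quadrants (neutral images are excluded), `FOUR_CLASS`
#' discriminates the four quadrants, and `FIVE_CLASS` adds the neutral
#' class.
#'
#' @param id Problem identifier; with no argument, all four ids.
#' @return For `affect_problems()`, the character vector of ids; for
#'   `problem_class_map()`, a named character vector mapping each
#'   quadrant to its class label, with `NA` for excluded quadrants.
#' @export
affect_problems <- function() {
  c("HL_VALENCE", "HL_AROUSAL", "FOUR_CLASS", "FIVE_CLASS")
}

#' @rdname affect_problems
#' @export
problem_class_map <- function(id = affect_problems()) {
  id <- match.arg(id)
  q <- quadrant_levels()
  switch(id,
    HL_VALENCE = c(HAHV = "high", HALV = "low", LALV = "low",
                   LAHV = "high", N = NA),
    HL_AROUSAL = c(HAHV = "high", HALV = "high", LALV = "low",
                   LAHV = "low", N = NA),
    FOUR_CLASS = c(HAHV = "HAHV", HALV = "HALV", LALV = "LALV",
                   LAHV = "LAHV", N = NA),
    FIVE_CLASS = stats::setNames(q, q)
  )
}

#' Attach a problem's class labels to a window feature table
#'
#' Maps the `quadrant` column through the problem's class map and drops
#' windows of excluded quadrants.
#'
#' @param features Window feature tibble from [extract_features()].
#' @param problem One of [affect_problems()].
#' @return The tibble with a `class_label` column, excluded rows removed.
#' @export
label_windows <- function(features, problem = affect_problems()) {
  problem <- match.arg(problem)
  map <- problem_class_map(problem)
  out <- features
  out$class_label <- unname(map[out$quadrant])
  out[!is.na(out$class_label), ]
}

opposite_quadrant <- c(HAHV = "LALV", HALV = "LAHV",
                       LALV = "HAHV", LAHV = "HALV", N = NA)

#' Filter images whose self-assessment contradicts the database rating
#'
#' An image is excluded when the participant's self-assessed quadrant is
#' the diagonal opposite of the database quadrant (both axes' signs
#' flipped, neither point neutral) -- complete inconsistency. Single-axis
#' disagreements and neutral self-reports are kept. Images without a
#' self-report are kept with a warning.
#'
#' @param events Stimulus-event tibble (see [recording()]).
#' @param self_reports Self-report tibble.
#' @return List with `kept` (character image ids) and `exclusions`
#'   (tibble of excluded ids with both quadrants).
#' @export
consistency_filter <- function(events, self_reports) {
  iaps_q <- assign_quadrant(rescale_rating(events$iaps_valence_raw),
                            rescale_rating(events$iaps_arousal_raw))
  idx <- match(events$image_id, self_reports$image_id)
  missing <- is.na(idx)
  if (any(missing))
    warn(sprintf("no self-report for image(s) %s; kept",
                 paste(events$image_id[missing], collapse = ", ")))
  sam_q <- rep(NA_character_, nrow(events))
  has <- !missing
  sam_q[has] <- assign_quadrant(
    rescale_rating(self_reports$sam_valence[idx[has]]),
    rescale_rating(self_reports$sam_arousal[idx[has]]))
  excluded <- has & !is.na(sam_q) &
    sam_q == unname(opposite_quadrant[iaps_q]) & iaps_q != "N"
  excluded[is.na(excluded)] <- FALSE
  list(
    kept = events$image_id[!excluded],
    exclusions = tibble(image_id = events$image_id[excluded],
                        iaps_quadrant = iaps_q[excluded],
                        sam_quadrant = sam_q[excluded])
  )
}

#' Leave-one-image-per-class-out split
#'
#' For each class of the problem, one image id is drawn (seeded) and all
#' of its windows form the test set; every other window trains the
#' model. Train and test never share an image.
#'
#' @param windows Labeled window tibble from [label_windows()] (must have
#'   `image_id` and `class_label` columns).
#' @param seed Integer seed making the draw reproducible.
#' @return List with `train`, `test` (tibbles) and `test_images`.
#' @export
loio_split <- function(windows, seed = 1) {
  if (!all(c("image_id", "class_label") %in% names(windows)))
    abort("`windows` must carry image_id and class_label (see label_windows)")
  by_class <- split(windows$image_id, windows$class_label)
  test_images <- withr::with_seed(seed, {
    vapply(sort(names(by_class)), function(cl) {
      imgs <- sort(unique(by_class[[cl]]))
      if (length(imgs) < 2L)
        stopf("class '%s' has %d image(s); need >= 2 for a held-out split",
              cl, length(imgs))
      sample(imgs, 1L)
    }, character(1))
  })
  in_test <- windows$image_id %in% test_images
  list(train = windows[!in_test, ], test = windows[in_test, ],
       test_images = unname(test_images))
}
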