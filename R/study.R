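#' Configuration of a full study run
#'
#' Collects every tunable of the end-to-end pipeline with the defaults
#' used throughout: 0.5-s windows on a 36.5 Hz grid, ReliefF with k = 5,
#' all four problems and algorithms, and both the full 23-feature set
#' and the selected optimal set.
#'
#' @param seed Master seed for cohort simulation and held-out splits.
#' @param n_subjects Cohort size.
#' @param images_per_cluster Images per protocol cluster (5 = full
#'   session).
#' @param effects Generator effect tibble.
#' @param relieff_k Neighbour count for the per-participant ReliefF.
#' @param problems Subset of [affect_problems()] to evaluate.
#' @param algorithms Subset of `c("KNN","SVM_CUBIC","SVM_GAUSSIAN","LDA")`.
#' @param feature_sets `"all"`, `"optimal"` or both.
#' @param window_s Analysis window length (s).
#' @param sync_rate_hz Shared grid rate (Hz).
#' @param knn_k,svm_cost Classifier hyperparameters.
#' @param ablation Also run the per-sensor ablation (KNN over all /
#'   cardiorespiratory / GSR-only / optimal feature sets).
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, n_subjects = 20, images_per_cluster = 5,
                         effects = default_effect_spec(), relieff_k = 5,
                         problems = affect_problems(),
                         algorithms = c("KNN", "SVM_CUBIC", "SVM_GAUSSIAN",
                                        "LDA"),
                         feature_sets = c("all", "optimal"),
                         window_s = 0.5, sync_rate_hz = 36.5,
                         knn_k = 5, svm_cost = 1, ablation = TRUE) {
  structure(list(seed = seed, n_subjects = n_subjects,
                 images_per_cluster = images_per_cluster, effects = effects,
                 relieff_k = relieff_k, problems = problems,
                 algorithms = algorithms, feature_sets = feature_sets,
                 window_s = window_s, sync_rate_hz = sync_rate_hz,
                 knn_k = knn_k, svm_cost = svm_cost, ablation = ablation),
            class = "study_config")
}

#' Extract labeled, consistency-filtered windows from a cohort
#'
#' Preprocesses every recording, extracts the 23 features on 0.5-s
#' windows tiled over the image presentations, and drops images whose
#' self-assessment is diagonally inconsistent with the database rating.
#'
#' @param cohort List of recordings, e.g. from [simulate_cohort()].
#' @param config A [study_config()].
#' @return List with `features` (one tibble over all participants) and
#'   `exclusions` (per-participant consistency-filter log).
#' @export
cohort_features <- function(cohort, config = study_config()) {
  feats <- list(); excl <- list()
  for (id in names(cohort)) {
    rec <- cohort[[id]]
    prep <- preprocess_recording(rec, sync_rate_hz = config$sync_rate_hz)
    fx <- extract_features(prep, window_s = config$window_s)
    cf <- consistency_filter(rec$events, rec$self_reports)
    feats[[id]] <- fx[fx$image_id %in% cf$kept, ]
    if (nrow(cf$exclusions))
      excl[[id]] <- mutate(cf$exclusions, participant_id = id)
  }
  list(features = bind_rows(feats), exclusions = bind_rows(excl))
}

split_seeds <- function(seed, ids) {
  stats::setNames(withr::with_seed(seed,
    sample.int(.Machine$integer.max, length(ids))), ids)
}

#' Per-participant ReliefF weights and the cohort optimal set
#'
#' For each participant, a leave-one-image-per-class-out split of the
#' five-class windows is drawn and ReliefF is fit on the training
#' windows only (the held-out images never influence ranges or
#' weights); the cross-participant median-positive rule then defines
#' the optimal set.
#'
#' @param features Labeled window tibble over participants.
#' @param config A [study_config()].
#' @return List with `weights` (long tibble) and `optimal_set`.
#' @export
select_features <- function(features, config = study_config()) {
  ids <- unique(features$participant_id)
  seeds <- split_seeds(config$seed, ids)
  weights <- lapply(ids, function(id) {
    d <- label_windows(features[features$participant_id == id, ],
                       "FIVE_CLASS")
    sp <- loio_split(d, seed = seeds[[id]])
    tidy(relieff(sp$train, k = config$relieff_k))
  })
  long <- bind_rows(weights)
  list(weights = long, optimal_set = optimal_feature_set(long))
}

#' Run the full study on a (possibly simulated) cohort
#'
#' Reproduces the study design end to end: preprocessing and feature
#' extraction per participant, consistency filtering, per-participant
#' ReliefF on training windows, the cross-participant optimal feature
#' set, then per participant x problem x algorithm x feature-set
#' training and held-out evaluation, pairwise ANOVA comparison of the
#' algorithms with Bonferroni correction, and (optionally) the
#' per-sensor ablation with KNN.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built cohort; simulated from `config`
#'   when `NULL`.
#' @return An `affect_study` object; see [tidy()], [glance()] and
#'   [autoplot()] methods, and [report_study()] for on-disk output.
#' @export
run_study <- function(config = study_config(), cohort = NULL) {
  if (is.null(cohort))
    cohort <- simulate_cohort(config$n_subjects, seed = config$seed,
                              effects = config$effects,
                              images_per_cluster = config$images_per_cluster)
  cf <- cohort_features(cohort, config)
  features <- cf$features
  sel <- select_features(features, config)
  fsets <- list(all = feature_names(),
                optimal = sel$optimal_set$features,
                cardiorespiratory = feature_names("cardiorespiratory"),
                gsr = feature_names("gsr"))

  ids <- unique(features$participant_id)
  seeds <- split_seeds(config$seed, ids)
  cells <- list()
  for (id in ids) {
    pf <- features[features$participant_id == id, ]
    for (problem in config$problems) {
      d <- label_windows(pf, problem)
      sp <- loio_split(d, seed = seeds[[id]])
      want <- config$feature_sets
      if (config$ablation)
        want <- unique(c(want, "cardiorespiratory", "gsr"))
      for (fs in want) {
        algs <- if (fs %in% config$feature_sets) config$algorithms else "KNN"
        for (alg in algs) {
          model <- fit_affect_model(sp$train, alg, features = fsets[[fs]],
                                    knn_k = config$knn_k,
                                    svm_cost = config$svm_cost)
          ev <- evaluate_model(model, sp$test, problem = problem,
                               feature_set = fs)
          cells[[length(cells) + 1L]] <-
            mutate(glance(ev), participant_id = id)
        }
      }
    }
  }
  results <- if (length(cells)) bind_rows(cells)
             else tibble(problem = character(), algorithm = character(),
                         feature_set = character(), accuracy = numeric(),
                         f_score = numeric(), n = integer(),
                         participant_id = character())

  comparisons <- list()
  if (length(config$algorithms) >= 2 && length(ids) >= 2) {
    for (problem in config$problems) {
      for (fs in config$feature_sets) {
        sub <- results[results$problem == problem &
                         results$feature_set == fs &
                         results$algorithm %in% config$algorithms, ]
        comparisons[[paste(problem, fs, sep = "/")]] <- compare_models(sub)
      }
    }
  }

  ablation <- NULL
  if (config$ablation && nrow(results)) {
    ab <- results[results$algorithm == "KNN", ]
    ablation <- ab %>%
      group_by(.data$problem, .data$feature_set) %>%
      summarise(mean_accuracy = mean(.data$accuracy),
                sd_accuracy = sd(.data$accuracy), .groups = "drop")
  }

  structure(
    list(config = config, features = features, weights = sel$weights,
         optimal_set = sel$optimal_set, results = results,
         comparisons = comparisons, ablation = ablation,
         exclusions = cf$exclusions),
    class = "affect_study"
  )
}

#' @export
print.affect_study <- function(x, ...) {
  cat(sprintf("<affect_study> %d participants, %d evaluation cells\n",
              length(unique(x$results$participant_id)), nrow(x$results)))
  print(x$optimal_set)
  invisible(x)
}

#' @method tidy affect_study
#' @export
tidy.affect_study <- function(x, ...) x$results

#' @method glance affect_study
#' @export
glance.affect_study <- function(x, ...) {
  x$results %>%
    filter(.data$feature_set %in% c("all", "optimal")) %>%
    group_by(.data$problem, .data$algorithm, .data$feature_set) %>%
    summarise(mean_accuracy = mean(.data$accuracy),
              mean_f_score = mean(.data$f_score), .groups = "drop")
}

#' Write study tables to a directory
#'
#' Writes `results.csv` (accuracy/F-score per participant x problem x
#' algorithm x feature set), `weights.csv` (per-participant ReliefF
#' weights, the boxplot data), `optimal_set.json`, `comparisons.csv` and
#' `ablation.csv`, plus a `summary.md`. Every CSV starts with a
#' `# seed=<n>` comment line.
#'
#' @param study An `affect_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
report_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- sprintf("# seed=%d", study$config$seed)
  put <- function(df, name) {
    f <- file.path(dir, name)
    writeLines(seed_line, f)
    readr::write_csv(df, f, append = TRUE, col_names = TRUE)
  }
  put(study$results, "results.csv")
  put(study$weights, "weights.csv")
  if (length(study$comparisons)) {
    comp <- bind_rows(lapply(names(study$comparisons), function(nm)
      mutate(tidy(study$comparisons[[nm]]), cell = nm)))
    put(comp, "comparisons.csv")
  }
  if (!is.null(study$ablation)) put(study$ablation, "ablation.csv")
  jsonlite::write_json(
    list(seed = study$config$seed,
         features = study$optimal_set$features,
         medians = study$optimal_set$medians),
    file.path(dir, "optimal_set.json"), auto_unbox = TRUE, digits = NA)

  gl <- glance(study)
  md <- c(sprintf("# Study summary (seed %d)", study$config$seed), "",
          sprintf("- participants: %d",
                  length(unique(study$results$participant_id))),
          sprintf("- optimal feature set (%d features): %s",
                  length(study$optimal_set$features),
                  paste(study$optimal_set$features, collapse = ", ")), "")
  if (nrow(gl)) {
    md <- c(md, "| problem | algorithm | feature set | accuracy | F-score |",
            "|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %.3f | %.3f |", gl$problem,
                    gl$algorithm, gl$feature_set, gl$mean_accuracy,
                    gl$mean_f_score))
  } else {
    md <- c(md, "No evaluations were run (empty problem list).")
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
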