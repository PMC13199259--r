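# Default per-feature generating distributions: ranges follow the published
# descriptive statistics of the standard CTG feature table; five informative
# features get class-separated locations matching the clinical directions
# (pathological traces: low histogram Mean, few accelerations, high abnormal
# short/long-term variability, more prolonged decelerations).
default_feature_table <- function() {
  tibble::tribble(
    ~feature,   ~min, ~max,  ~loc_normal, ~loc_suspect, ~loc_pathological, ~scale, ~informative,
    "LB",        106,  160,       133.30,       133.30,            133.30,   9.84, FALSE,
    "AC",          0, 0.02,        0.004,       0.0015,            0.0005,  0.002, TRUE,
    "FM",          0, 0.48,         0.01,         0.01,              0.01,   0.05, FALSE,
    "UC",          0, 0.01,        0.004,        0.004,             0.004,  0.003, FALSE,
    "DL",          0, 0.01,        0.002,        0.002,             0.002,  0.002, FALSE,
    "DS",          0, 0.001,      0.0003,       0.0003,            0.0003, 0.0003, FALSE,
    "DP",          0, 0.01,       0.0002,       0.0008,             0.003, 0.0015, TRUE,
    "ASTV",       12,   87,           40,           60,                70,     12, TRUE,
    "MSTV",        0,    7,         1.34,         1.34,              1.34,   0.89, FALSE,
    "ALTV",        0,   91,            5,           20,                45,     12, TRUE,
    "MLTV",        0,   50,         8.21,         8.21,              8.21,   5.70, FALSE,
    "Width",       3,  180,        70.45,        70.45,             70.45,  38.96, FALSE,
    "Min",        50,  159,        93.58,        93.58,             93.58,  29.56, FALSE,
    "Max",       122,  238,       164.03,       164.03,            164.03,  17.94, FALSE,
    "Nmax",        0,   18,         4.07,         4.07,              4.07,   2.95, FALSE,
    "Nzeros",      0,   10,         0.32,         0.32,              0.32,   0.71, FALSE,
    "Mode",       60,  187,       137.45,       137.45,            137.45,  16.38, FALSE,
    "Mean",       73,  182,          135,          120,                95,     12, TRUE,
    "Median",     77,  186,       138.09,       138.09,            138.09,  14.47, FALSE,
    "Variance",    0,  269,        18.81,        18.81,             18.81,  28.98, FALSE,
    "Tendency",   -1,    1,         0.32,         0.32,              0.32,   0.61, FALSE
  )
}

#' Specification of a synthetic CTG-like dataset
#'
#' Defines class proportions and class-conditional truncated-normal feature
#' distributions for generating CTG-like feature tables with a known ground
#' truth. The defaults emulate the standard CTG table: 21 features, class
#' proportions 77.8% normal / 14.2% suspect / 8.0% pathological, and five
#' planted informative features (`Mean`, `AC`, `ASTV`, `ALTV`, `DP`) whose
#' class-conditional locations follow the clinical direction claims — e.g.
#' the heart-rate histogram `Mean` concentrates near 135 bpm for normal
#' traces and near 95 bpm for pathological ones. All other features are
#' class-independent noise with realistic location/scale/range. Features are
#' sampled independently (no correlation structure).
#'
#' @param n_samples Number of rows to generate.
#' @param class_proportions Length-3 probabilities (normal, suspect,
#'   pathological) summing to 1.
#' @param features Optional replacement for the per-feature tibble (columns
#'   `feature`, `min`, `max`, `loc_normal`, `loc_suspect`,
#'   `loc_pathological`, `scale`, `informative`).
#' @param seed Integer seed.
#' @return Object of class `"ctg_synthetic_spec"`.
#' @export
ctg_synthetic_spec <- function(n_samples = 2126,
                               class_proportions = c(0.778, 0.142, 0.080),
                               features = default_feature_table(),
                               seed = 1) {
  if (length(class_proportions) != 3 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    abort_bad_arg("class_proportions must be 3 non-negative numbers summing to 1")
  }
  needed <- c("feature", "min", "max", "loc_normal", "loc_suspect",
              "loc_pathological", "scale", "informative")
  if (!all(needed %in% names(features))) {
    abort_bad_arg("features table is missing required columns")
  }
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions,
                 features = features, seed = as.integer(seed)),
            class = "ctg_synthetic_spec")
}

#' @export
print.ctg_synthetic_spec <- function(x, ...) {
  cat(sprintf("<ctg_synthetic_spec> n = %d, proportions %.1f/%.1f/%.1f%%, informative: %s\n",
              x$n_samples, 100 * x$class_proportions[1],
              100 * x$class_proportions[2], 100 * x$class_proportions[3],
              paste(x$features$feature[x$features$informative], collapse = ", ")))
  invisible(x)
}

# Exact truncated-normal sampling by inverse-CDF, vectorised and seeded
# through the calling RNG stream.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) return(rep(min(max(mean, lower), upper), n))
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic CTG-like feature table
#'
#' Draws class labels from the spec's proportions and every feature from its
#' class-conditional truncated-normal distribution, producing a table in the
#' standard 21-features-plus-NSP layout that the rest of the pipeline
#' consumes. Fully deterministic under the spec's (or the override) seed.
#'
#' @param spec A [ctg_synthetic_spec()].
#' @param n Optional row-count override.
#' @param seed Optional seed override.
#' @return Tibble with the feature columns and an integer `NSP` label in
#'   `{0, 1, 2}`. The spec is attached as attribute `"spec"`.
#' @export
#' @examples
#' d <- simulate_ctg(ctg_synthetic_spec(n_samples = 200), seed = 7)
#' table(d$NSP)
simulate_ctg <- function(spec = ctg_synthetic_spec(), n = NULL, seed = NULL) {
  n <- as.integer(n %||% spec$n_samples)
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  labels <- sample(0:2, n, replace = TRUE, prob = spec$class_proportions)
  ft <- spec$features
  loc_cols <- c("loc_normal", "loc_suspect", "loc_pathological")
  out <- matrix(0, n, nrow(ft))
  colnames(out) <- ft$feature
  for (f in seq_len(nrow(ft))) {
    for (cl in 0:2) {
      idx <- which(labels == cl)
      if (length(idx) == 0) next
      out[idx, f] <- rtruncnorm(length(idx),
                                mean = ft[[loc_cols[cl + 1L]]][f],
                                sd = ft$scale[f],
                                lower = ft$min[f], upper = ft$max[f])
    }
  }
  res <- tibble::as_tibble(as.data.frame(out))
  res$NSP <- as.integer(labels)
  attr(res, "spec") <- spec
  res
}

#' End-to-end recovery report on synthetic data
#'
#' Given a pipeline run on a generated table with planted informative
#' features, reports whether the model and its attribution recover the
#' ground truth: the held-out test accuracy, and how many of the planted
#' features appear in the attribution top ranks for the pathological class.
#'
#' @param run A `"plectabm_run"` from [run_pipeline()] (with attribution
#'   enabled), or a list with `$metrics` and `$attribution`.
#' @param informative_features Character vector of planted features;
#'   defaults to the spec default set.
#' @param class_index Class whose ranking is inspected (default 2,
#'   pathological).
#' @param top_n Size of the inspected top of the ranking.
#' @param accuracy_min,min_planted Thresholds reported as met/not met.
#' @return Object of class `"recovery_report"` (a list): `test_accuracy`,
#'   `top_features`, `n_planted_in_top`, `accuracy_ok`, `planted_ok`,
#'   `criteria_met`.
#' @export
recovery_check <- function(run,
                           informative_features = c("Mean", "AC", "ASTV",
                                                    "ALTV", "DP"),
                           class_index = 2, top_n = 5,
                           accuracy_min = 0.90, min_planted = 2) {
  if (is.null(run$metrics) || is.null(run$attribution)) {
    abort_bad_arg("run must carry $metrics and $attribution")
  }
  acc <- run$metrics$accuracy
  ranking <- feature_ranking(run$attribution, class_index = class_index)
  top <- ranking$feature[seq_len(min(top_n, nrow(ranking)))]
  n_planted <- sum(top %in% informative_features)
  structure(list(test_accuracy = acc, top_features = top,
                 n_planted_in_top = n_planted,
                 accuracy_ok = acc >= accuracy_min,
                 planted_ok = n_planted >= min_planted,
                 criteria_met = acc >= accuracy_min && n_planted >= min_planted),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> test accuracy %.4f (%s); planted in top-%d: %d (%s)\n",
              x$test_accuracy, if (x$accuracy_ok) "ok" else "below threshold",
              length(x$top_features), x$n_planted_in_top,
              if (x$planted_ok) "ok" else "below threshold"))
  cat("  top features:", paste(x$top_features, collapse = ", "), "\n")
  invisible(x)
}
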