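#' Assemble an outcome-level labeled dataset
#'
#' Joins a whole-session feature table (one row per proband) with one outcome
#' scale's scores by proband id.
#'
#' @param features Feature table from [cohort_features()] /
#'   [simulate_study()] at `level = "outcome"`.
#' @param scores Score matrix (probands x scales) with proband ids as row
#'   names, e.g. `al_outcomes$scores`.
#' @param scale Outcome scale name (a column of `scores`).
#' @return An `al_dataset`.
#' @export
outcome_dataset <- function(features, scores, scale) {
  if (!scale %in% colnames(scores)) {
    stop("outcome_dataset: unknown scale ", scale, call. = FALSE)
  }
  x <- feature_matrix(features)
  y <- scores[features$proband_id, scale]
  labeled_dataset(x, y, features$proband_id, 0L)
}

#' Assemble a process-level labeled dataset
#'
#' Joins a per-sample feature table (13 rows per proband) with one slider
#' scale's experience-sample values. Invalid samples keep `NA` labels; the
#' cross-validation drivers exclude them from training and evaluation.
#'
#' @param features Feature table at `level = "process"`.
#' @param sliders Named list (proband id -> alarms x 5 slider matrix), e.g.
#'   `simulate_study(..., level = "process")$labels`.
#' @param scale Slider scale, one of `ESM_SCALES`.
#' @return An `al_dataset`.
#' @export
process_dataset <- function(features, sliders, scale) {
  scale <- match.arg(scale, ESM_SCALES)
  y <- mapply(function(pb, k) sliders[[pb]][k, scale],
              features$proband_id, features$sample_index)
  labeled_dataset(feature_matrix(features), unname(y),
                  features$proband_id, features$sample_index)
}

# Strip the metadata columns off a feature table.
feature_matrix <- function(features) {
  meta <- c("proband_id", "sample_index", "coverage", "flagged")
  as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
}

#' Per-feature Pearson correlations with a label, sorted by magnitude
#'
#' @param features Feature table (or plain feature matrix).
#' @param y Label vector, one per row.
#' @return data.frame `feature`, `r`, sorted by decreasing `|r|` (constant
#'   features get `NA` and sort last).
#' @export
feature_label_correlations <- function(features, y) {
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  ok <- !is.na(y)
  r <- suppressWarnings(as.numeric(stats::cor(x[ok, , drop = FALSE], y[ok])))
  out <- data.frame(feature = colnames(x), r = r, stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$feature, na.last = TRUE), , drop = FALSE]
}

#' Is a feature derived from the left temporal electrode?
#'
#' True for T7 band-power features, T7 ratio indices (`bla_T7`, `nasa_T7`)
#' and the temporal laterality index (`lateral_T_*`, computed as T7 - T8).
#'
#' @param name Character vector of feature names.
#' @return Logical vector.
#' @export
is_t7_derived <- function(name) {
  grepl("^T7_", name) | grepl("^(bla|nasa)_T7_", name) | grepl("^lateral_T_", name)
}

#' Did the model beat the baseline significantly?
#'
#' `TRUE` when the paired comparison has `p < alpha` and the model's mean
#' absolute error is below the baseline's.
#'
#' @param result An `al_cv_result`.
#' @param alpha Significance level (default 0.05).
#' @return Logical scalar.
#' @export
significant_improvement <- function(result, alpha = 0.05) {
  p <- result$comparison$p
  !is.na(p) && p < alpha &&
    result$metrics["model", "mae"] < result$metrics["baseline", "mae"]
}

#' End-to-end outcome-level experiment on a synthetic cohort
#'
#' Simulates a cohort under `cfg`, extracts whole-session EEG features, runs
#' leave-one-out cross-validation for one outcome scale, and summarizes the
#' top feature-label correlations — the full pipeline the planted-effect and
#' null-calibration checks exercise.
#'
#' @param cfg An `al_generator_config`.
#' @param scale Outcome scale (default `"intrinsic_motivation"`).
#' @param spec An `al_model_spec` (default: ridge seeded from `cfg$seed`).
#' @param top Number of top-correlation features to report (default 10).
#' @return List with `cv` (`al_cv_result`), `top_correlations` (data.frame),
#'   `t7_top_share` (fraction of the top features that are T7-derived) and
#'   `significant` (logical).
#' @export
run_outcome_experiment <- function(cfg, scale = "intrinsic_motivation",
                                   spec = NULL, top = 10L) {
  if (is.null(spec)) spec <- model_spec("ridge", seed = cfg$seed)
  sim <- simulate_study(cfg, sensor = "eeg", level = "outcome")
  ds <- outcome_dataset(sim$features, sim$labels, scale)
  cv <- loo_cv(ds, spec)
  cors <- feature_label_correlations(sim$features, ds$y)
  top_tab <- utils::head(cors, top)
  list(cv = cv,
       top_correlations = top_tab,
       t7_top_share = mean(is_t7_derived(top_tab$feature)),
       significant = significant_improvement(cv))
}

#' Read a generator config from a YAML file
#'
#' Scalar fields of the YAML map onto [generator_config()] arguments; named
#' vectors (`band_baseline`, `slider_load`) and the `outcome_scales` table
#' are converted from YAML maps/lists.
#'
#' @param path YAML file.
#' @return An `al_generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$band_baseline)) raw$band_baseline <- unlist(raw$band_baseline)
  if (!is.null(raw$slider_load)) raw$slider_load <- unlist(raw$slider_load)
  if (!is.null(raw$outcome_scales)) {
    raw$outcome_scales <- do.call(rbind, lapply(raw$outcome_scales, as.data.frame))
  }
  do.call(generator_config, raw)
}
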