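#' Mean-of-others baseline for leave-one-out prediction
#'
#' Predicts each proband's outcome value as the mean of all other probands'
#' values: `yhat_i = mean(y[-i])`. This sensor-free baseline is the
#' sensibility floor any model must beat. Because `yhat_i` is a strictly
#' decreasing affine function of `y_i`, its label-prediction correlation is
#' exactly -1 for every non-constant `y`, and its RMSE equals
#' `n/(n-1) * population-sd(y)`.
#'
#' @param y Numeric outcome vector, length >= 2.
#' @return Numeric vector of leave-one-out predictions.
#' @examples
#' loo_baseline(c(1, 2, 3))  # 2.5 2.0 1.5
#' @export
loo_baseline <- function(y) {
  n <- length(y)
  if (n < 2L) stop("loo_baseline: need >= 2 values", call. = FALSE)
  (sum(y) - y) / (n - 1)
}

#' Mean-of-others baseline for leave-one-proband-out prediction
#'
#' For each held-out proband, predicts all of their samples with one constant:
#' the grand mean of every other proband's valid (non-missing) samples.
#'
#' @param Y Numeric matrix, probands x samples (typically n x 13); `NA` for
#'   invalid samples.
#' @return Numeric vector, one constant prediction per proband (`NA` rows of
#'   all-missing probands are excluded from every mean, with a warning).
#' @export
lopo_baseline <- function(Y) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2L) stop("lopo_baseline: need >= 2 probands", call. = FALSE)
  all_missing <- rowSums(!is.na(Y)) == 0L
  if (any(all_missing)) {
    warning("lopo_baseline: proband(s) with all-missing labels excluded: ",
            paste(which(all_missing), collapse = ", "))
  }
  tot <- sum(Y, na.rm = TRUE)
  cnt <- sum(!is.na(Y))
  row_tot <- rowSums(Y, na.rm = TRUE)
  row_cnt <- rowSums(!is.na(Y))
  (tot - row_tot) / (cnt - row_cnt)
}

#' Prediction error metrics: RMSE, MAE and label-prediction correlation
#'
#' @param pred,true Equal-length numeric vectors (missing pairs dropped).
#' @return Named numeric vector `(rmse, mae, lpc)`; `lpc` is the Pearson
#'   correlation between predictions and true values, `NA` when either side
#'   is constant or fewer than 2 pairs remain.
#' @export
metrics <- function(pred, true) {
  ok <- !is.na(pred) & !is.na(true)
  pred <- pred[ok]; true <- true[ok]
  if (!length(pred)) return(c(rmse = NA_real_, mae = NA_real_, lpc = NA_real_))
  e <- pred - true
  lpc <- if (length(pred) >= 2L && stats::sd(pred) > 0 && stats::sd(true) > 0) {
    stats::cor(pred, true)
  } else NA_real_
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), lpc = lpc)
}

#' Compare per-fold model errors to baseline errors
#'
#' Paired two-sided Student's t-test on the per-fold error differences
#' `baseline - model` (positive mean difference = model better), with the
#' paired effect size `d = mean(diff) / sd(diff)`. Zero-variance differences
#' are flagged: `p` is `NA` and `d` is 0.
#'
#' @param model_errors,baseline_errors Paired per-fold absolute-error vectors
#'   of equal length.
#' @return Named list `(t, p, d, flag)`.
#' @export
compare_to_baseline <- function(model_errors, baseline_errors) {
  if (length(model_errors) != length(baseline_errors)) {
    stop("compare_to_baseline: error vectors must be paired (equal length)",
         call. = FALSE)
  }
  d <- baseline_errors - model_errors
  d <- d[!is.na(d)]
  if (length(d) < 2L || stats::sd(d) == 0) {
    return(list(t = if (length(d) && all(d == 0)) 0 else NA_real_,
                p = if (length(d) && all(d == 0)) 1 else NA_real_,
                d = 0, flag = "zero-variance differences"))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = mean(d) / stats::sd(d), flag = NULL)
}

#' Cronbach's alpha scale reliability
#'
#' `alpha = k/(k-1) * (1 - sum(var(item_j)) / var(sum of items))` with sample
#' (n-1) variances.
#'
#' @param items Numeric matrix, probands x items; >= 2 items, >= 3 probands,
#'   no missing values.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  if (!is.matrix(items)) items <- as.matrix(items)
  if (ncol(items) < 2L) stop("cronbach_alpha: need >= 2 items", call. = FALSE)
  if (nrow(items) < 3L) stop("cronbach_alpha: need >= 3 probands", call. = FALSE)
  if (anyNA(items)) stop("cronbach_alpha: missing values not supported", call. = FALSE)
  k <- ncol(items)
  vt <- stats::var(rowSums(items))
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / vt)
}

# ---- cross-validation drivers ----------------------------------------------

new_cv_result <- function(predictions, method_metrics, comparison, importance,
                          scheme) {
  structure(list(predictions = predictions, metrics = method_metrics,
                 comparison = comparison, importance = importance,
                 scheme = scheme),
            class = "al_cv_result")
}

#' @export
print.al_cv_result <- function(x, ...) {
  cat(sprintf("<al_cv_result> %s\n", x$scheme))
  print(round(x$metrics, 4))
  if (!is.null(x$comparison$p)) {
    cat(sprintf("model vs baseline: t = %.3f, p = %.4f, d = %.3f\n",
                x$comparison$t, x$comparison$p, x$comparison$d))
  }
  invisible(x)
}

#' Leave-one-out cross-validation against the mean-of-others baseline
#'
#' For each proband i: hyperparameters are tuned on the remaining rows by
#' grouped threefold CV ([tune()]), the model is refit on those rows (after
#' optional recursive feature elimination) and row i is predicted. Metrics
#' (RMSE, MAE, LPC) are computed on the pooled prediction vector; the paired
#' per-proband absolute errors of model and baseline feed the t-test /
#' effect-size comparison. Feature importances are averaged over folds.
#'
#' @param data An `al_dataset` with one row per proband (`sample == 0`).
#' @param spec An `al_model_spec`.
#' @return An `al_cv_result`.
#' @export
loo_cv <- function(data, spec) {
  stopifnot(inherits(data, "al_dataset"), inherits(spec, "al_model_spec"))
  if (any(data$sample != 0L)) {
    stop("loo_cv: expects outcome-level data (sample_index 0)", call. = FALSE)
  }
  n <- nrow(data$x)
  if (n < 5L) stop("loo_cv: insufficient data (need >= 5 probands)", call. = FALSE)
  preds <- numeric(n)
  imp <- matrix(0, nrow = n, ncol = ncol(data$x),
                dimnames = list(NULL, colnames(data$x)))
  for (i in seq_len(n)) {
    tr <- ds_subset(data, setdiff(seq_len(n), i))
    fill <- impute_columns(tr$x)
    tr <- labeled_dataset(fill$x, tr$y, tr$proband, tr$sample)
    sp <- spec
    sp$seed <- child_seed(spec$seed, i)
    cols <- if (spec$rfe) rfecv(sp, tr) else colnames(tr$x)
    tr_sel <- labeled_dataset(tr$x[, cols, drop = FALSE], tr$y, tr$proband, tr$sample)
    tuned <- tune(sp, tr_sel)
    sp$best <- tuned$best
    fit <- fit_model(sp, tr_sel$x, tr_sel$y)
    newx <- impute_columns(data$x[i, cols, drop = FALSE], fill$center[cols])$x
    preds[i] <- predict(fit, newx)
    imp[i, cols] <- model_weights(fit)
  }
  base <- loo_baseline(data$y)
  m_model <- metrics(preds, data$y)
  m_base <- metrics(base, data$y)
  cmp <- compare_to_baseline(abs(preds - data$y), abs(base - data$y))
  new_cv_result(
    predictions = data.frame(proband_id = data$proband, fold = seq_len(n),
                             y = data$y, pred = preds, baseline = base,
                             stringsAsFactors = FALSE),
    method_metrics = rbind(model = m_model, baseline = m_base),
    comparison = cmp,
    importance = sort(colMeans(imp), decreasing = TRUE),
    scheme = "LOO")
}

#' Leave-one-proband-out cross-validation for process measures
#'
#' For each proband: the model is tuned (grouped threefold CV) and fit on all
#' other probands' rows, then predicts the held-out proband's samples.
#' Per-proband metrics are averaged over probands (`lpc_pooled` over the
#' pooled prediction vector is also reported); the per-proband mean absolute
#' errors of model and baseline feed the paired comparison. Missing labels
#' (invalid answers) are excluded from training, from the baseline mean and
#' from the metrics.
#'
#' @param data An `al_dataset` with up to 13 rows per proband (label `NA` for
#'   invalid samples allowed).
#' @param spec An `al_model_spec`.
#' @return An `al_cv_result`.
#' @export
lopo_cv <- function(data, spec) {
  stopifnot(inherits(data, "al_dataset"), inherits(spec, "al_model_spec"))
  probands <- unique(data$proband)
  n <- length(probands)
  if (n < 5L) stop("lopo_cv: insufficient data (need >= 5 probands)", call. = FALSE)
  labelled <- !is.na(data$y)
  per_pb <- vector("list", n)
  imp <- matrix(0, nrow = n, ncol = ncol(data$x),
                dimnames = list(NULL, colnames(data$x)))
  for (k in seq_len(n)) {
    pb <- probands[k]
    tr_idx <- which(data$proband != pb & labelled)
    te_idx <- which(data$proband == pb & labelled)
    if (!length(te_idx)) next
    tr <- ds_subset(data, tr_idx)
    fill <- impute_columns(tr$x)
    tr <- labeled_dataset(fill$x, tr$y, tr$proband, tr$sample)
    sp <- spec
    sp$seed <- child_seed(spec$seed, k)
    cols <- if (spec$rfe) rfecv(sp, tr) else colnames(tr$x)
    tr_sel <- labeled_dataset(tr$x[, cols, drop = FALSE], tr$y, tr$proband, tr$sample)
    tuned <- tune(sp, tr_sel)
    sp$best <- tuned$best
    fit <- fit_model(sp, tr_sel$x, tr_sel$y)
    newx <- impute_columns(data$x[te_idx, cols, drop = FALSE], fill$center[cols])$x
    pr <- predict(fit, newx)
    base_pred <- mean(data$y[setdiff(which(labelled), te_idx)])
    per_pb[[k]] <- data.frame(proband_id = pb, fold = k,
                              sample_index = data$sample[te_idx],
                              y = data$y[te_idx], pred = pr,
                              baseline = base_pred, stringsAsFactors = FALSE)
    imp[k, cols] <- model_weights(fit)
  }
  all_pred <- do.call(rbind, per_pb)
  by_pb <- split(all_pred, all_pred$fold)
  m_model <- rowMeans(vapply(by_pb, function(d) metrics(d$pred, d$y), numeric(3)),
                      na.rm = TRUE)
  m_base <- rowMeans(vapply(by_pb, function(d) metrics(d$baseline, d$y), numeric(3)),
                     na.rm = TRUE)
  pooled <- c(lpc_pooled_model = unname(metrics(all_pred$pred, all_pred$y)["lpc"]),
              lpc_pooled_baseline = unname(metrics(all_pred$baseline, all_pred$y)["lpc"]))
  mae_model <- vapply(by_pb, function(d) mean(abs(d$pred - d$y)), numeric(1))
  mae_base <- vapply(by_pb, function(d) mean(abs(d$baseline - d$y)), numeric(1))
  cmp <- compare_to_baseline(mae_model, mae_base)
  res <- new_cv_result(
    predictions = all_pred,
    method_metrics = rbind(model = m_model, baseline = m_base),
    comparison = cmp,
    importance = sort(colMeans(imp), decreasing = TRUE),
    scheme = "LOPO")
  res$pooled_lpc <- pooled
  res
}

#' Result tables in the study's reporting layout
#'
#' One table per target scale with method rows (e.g. Ridge, Boosting,
#' Baseline) and columns RMSE, MAE, r, p, d. A `+` marks a method whose error
#' is below the baseline's; a `*` marks a significant paired difference
#' (p < 0.05). Written as TSV, one file per target.
#'
#' @param results Named list (target scale -> named list of `al_cv_result`
#'   per method; the baseline row is derived from the first result).
#' @param dir Output directory for `<target>.tsv` files (`NULL` = don't
#'   write).
#' @return Named list of data.frames (invisibly written as TSV if `dir`
#'   given).
#' @export
report <- function(results, dir = NULL) {
  fmt_row <- function(method, met, cmp, base_met) {
    mark <- function(x, bx) paste0(formatC(x, digits = 4, format = "g"),
                                   if (!is.na(x) && !is.na(bx) && x < bx) "+" else "",
                                   if (!is.null(cmp) && !is.na(cmp$p) && cmp$p < 0.05) "*" else "")
    data.frame(method = method,
               RMSE = mark(met["rmse"], base_met["rmse"]),
               MAE = mark(met["mae"], base_met["mae"]),
               r = formatC(met["lpc"], digits = 4, format = "g"),
               p = if (is.null(cmp) || is.na(cmp$p)) "" else formatC(cmp$p, digits = 3, format = "g"),
               d = if (is.null(cmp)) "" else formatC(cmp$d, digits = 2, format = "g"),
               stringsAsFactors = FALSE)
  }
  tables <- lapply(names(results), function(target) {
    methods <- results[[target]]
    base_met <- methods[[1L]]$metrics["baseline", ]
    rows <- lapply(names(methods), function(m) {
      r <- methods[[m]]
      fmt_row(m, r$metrics["model", ], r$comparison, base_met)
    })
    rows <- c(rows, list(fmt_row("Baseline", base_met, NULL, base_met)))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })
  names(tables) <- names(results)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (target in names(tables)) {
      data.table::fwrite(tables[[target]],
                         file.path(dir, paste0(target, ".tsv")), sep = "\t")
    }
  }
  tables
}

#' Feature-importance table (mean over CV folds), sorted descending
#' @param result An `al_cv_result`.
#' @param top Number of rows (default all non-zero).
#' @return data.frame with `feature` and `weight`.
#' @export
importance_table <- function(result, top = NULL) {
  imp <- result$importance
  if (is.null(top)) top <- sum(imp > 0)
  imp <- utils::head(imp, max(top, 1L))
  data.frame(feature = names(imp), weight = unname(imp), stringsAsFactors = FALSE)
}
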