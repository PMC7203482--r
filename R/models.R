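#' Labeled dataset
#'
#' Feature/label rows of the learning problem: one row per proband (outcome
#' level, `sample = 0`) or per proband-sample pair (process level). The
#' proband id is the grouping key every cross-validation split respects.
#'
#' @param x Numeric feature matrix with column names.
#' @param y Numeric label vector, `nrow(x)` long.
#' @param proband Proband id per row.
#' @param sample Sample index per row (default 0 = outcome level).
#' @return Object of class `al_dataset`: list with `x`, `y`, `proband`,
#'   `sample`.
#' @export
labeled_dataset <- function(x, y, proband, sample = 0L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) stop("labeled_dataset: `x` needs column names", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("labeled_dataset: duplicate feature names", call. = FALSE)
  n <- nrow(x)
  if (length(y) != n) stop("labeled_dataset: length(y) != nrow(x)", call. = FALSE)
  proband <- as.character(proband)
  if (length(proband) == 1L) proband <- rep(proband, n)
  if (length(sample) == 1L) sample <- rep(as.integer(sample), n)
  if (length(proband) != n || length(sample) != n) {
    stop("labeled_dataset: `proband`/`sample` must match nrow(x)", call. = FALSE)
  }
  if (anyDuplicated(paste(proband, sample))) {
    stop("labeled_dataset: duplicated (proband, sample) keys", call. = FALSE)
  }
  structure(list(x = x, y = as.numeric(y), proband = proband,
                 sample = as.integer(sample)),
            class = "al_dataset")
}

# Train-mean imputation of missing feature values (e.g. tendency features
# whose 30 s end-window was fully masked). Statistics come from the training
# rows only and are frozen for the held-out rows.
impute_columns <- function(X, center = NULL) {
  if (is.null(center)) {
    center <- colMeans(X, na.rm = TRUE)
    center[!is.finite(center)] <- 0
  }
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- center[nas[, 2L]]
  list(x = X, center = center)
}

ds_subset <- function(data, idx) {
  labeled_dataset(data$x[idx, , drop = FALSE], data$y[idx],
                  data$proband[idx], data$sample[idx])
}

#' Model specification
#'
#' @param family `"ridge"` or `"boosting"`.
#' @param search Named list of hyperparameter ranges overriding the defaults
#'   (ridge: `log10_lambda` in `[-4, 6]`; boosting: `max_depth` 2-8, `eta`
#'   0.01-0.3, `nrounds` 50-500, `subsample` 0.5-1).
#' @param budget Tuning budget: number of candidates evaluated (default 50).
#' @param rfe Run recursive feature elimination on each training set
#'   (default `FALSE`).
#' @param seed Integer seed for the tuning search and the boosting fit.
#' @return Object of class `al_model_spec`.
#' @export
model_spec <- function(family = c("ridge", "boosting"), search = list(),
                       budget = 50L, rfe = FALSE, seed = 1L) {
  family <- match.arg(family)
  defaults <- if (family == "ridge") {
    list(log10_lambda = c(-4, 6))
  } else {
    list(max_depth = c(2L, 8L), eta = c(0.01, 0.3),
         nrounds = c(50L, 500L), subsample = c(0.5, 1))
  }
  defaults[names(search)] <- search
  bounds <- unlist(defaults, use.names = FALSE)
  if (any(!is.finite(bounds))) stop("model_spec: search bounds must be finite", call. = FALSE)
  structure(list(family = family, search = defaults, budget = as.integer(budget),
                 rfe = isTRUE(rfe), seed = as.integer(seed)),
            class = "al_model_spec")
}

# ---- ridge -----------------------------------------------------------------

#' Closed-form l2-regularized linear regression
#'
#' Minimizes `||y - Xw - b||^2 + lambda * ||w||^2` with an unpenalized
#' intercept. Features are standardized to mean 0 / sd 1 on the training rows
#' (constant columns map to 0) and the statistics are frozen into the fit for
#' prediction, so predictions are invariant to affine rescaling of the raw
#' features. Solved in the primal (`p <= n`) or dual (`p > n`) normal
#' equations, whichever is smaller.
#'
#' @param X Numeric feature matrix (n x p) with column names.
#' @param y Numeric response vector.
#' @param lambda Ridge penalty, >= 0 (unique solution for lambda > 0).
#' @return Object of class `al_ridge` with elements `w` (weights on the
#'   standardized scale), `intercept`, `center`, `scale`, `lambda`.
#' @export
fit_ridge <- function(X, y, lambda) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("fit_ridge: non-finite values in the inputs", call. = FALSE)
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("fit_ridge: `lambda` must be a single non-negative number", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  Xc <- X - matrix(ctr, n, p, byrow = TRUE)
  scl <- sqrt(colSums(Xc^2) / max(1L, n - 1L))
  scl[!is.finite(scl) | scl == 0] <- Inf   # constant columns -> standardized 0
  Z <- Xc / matrix(scl, n, p, byrow = TRUE)
  ybar <- mean(y)
  yc <- y - ybar
  w <- if (p <= n) {
    A <- crossprod(Z)
    diag(A) <- diag(A) + lambda
    as.numeric(solve(A, crossprod(Z, yc)))
  } else {
    K <- tcrossprod(Z)
    diag(K) <- diag(K) + lambda
    as.numeric(crossprod(Z, solve(K, yc)))
  }
  structure(list(w = stats::setNames(w, colnames(X)), intercept = ybar,
                 center = ctr, scale = scl, lambda = lambda),
            class = "al_ridge")
}

#' @export
predict.al_ridge <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  Z <- sweep(sweep(newdata[, names(object$w), drop = FALSE], 2L, object$center, "-"),
             2L, object$scale, "/")
  as.numeric(Z %*% object$w) + object$intercept
}

# ---- boosting --------------------------------------------------------------

#' Gradient-boosted tree regression (XGBoost backend)
#'
#' Thin deterministic wrapper: single-threaded, seeded, squared-error
#' objective. The fit exposes per-feature importance weights for
#' feature-importance reporting and recursive feature elimination.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Numeric response.
#' @param params Named list with `max_depth`, `eta`, `nrounds`, `subsample`
#'   (missing entries fall back to depth 4, eta 0.1, 100 rounds, subsample 1).
#' @param seed Integer seed (same seed, same data => bit-identical model).
#' @param importance Extract per-feature importance after fitting (default
#'   `TRUE`; inner CV loops skip it, it is only needed for reporting and
#'   feature elimination).
#' @return Object of class `al_boosting` with the fitted booster and
#'   `importance` (named gain per feature; features never used score 0).
#' @export
fit_boosting <- function(X, y, params = list(), seed = 1L, importance = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  p <- list(max_depth = 4L, eta = 0.1, nrounds = 100L, subsample = 1)
  p[names(params)] <- params
  dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = as.integer(p$max_depth),
                  eta = p$eta, subsample = p$subsample, seed = as.integer(seed),
                  nthread = 1),
    data = dtr, nrounds = as.integer(p$nrounds), verbose = 0)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (importance) {
    it <- tryCatch(xgboost::xgb.importance(model = booster), error = function(e) NULL)
    if (!is.null(it) && nrow(it)) imp[it$Feature] <- it$Gain
  }
  structure(list(booster = booster, importance = imp, params = p, seed = seed),
            class = "al_boosting")
}

#' @export
predict.al_boosting <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  as.numeric(stats::predict(object$booster,
                            xgboost::xgb.DMatrix(newdata, nthread = 1)))
}

fit_model <- function(spec, X, y, importance = TRUE) {
  if (spec$family == "ridge") {
    fit_ridge(X, y, lambda = 10^spec$best$log10_lambda)
  } else {
    fit_boosting(X, y, params = spec$best, seed = spec$seed,
                 importance = importance)
  }
}

# Absolute feature weights used for importance ranking / RFE.
model_weights <- function(fit) {
  if (inherits(fit, "al_ridge")) abs(fit$w) else fit$importance
}

# ---- tuning ----------------------------------------------------------------

# Proband-grouped k-fold assignment: probands shuffled deterministically from
# `seed`, dealt round-robin into folds.
group_folds <- function(proband, k = 3L, seed = 1L) {
  groups <- unique(proband)
  rng <- rng_stream(seed)
  ord <- groups[order(rng$unif(length(groups)))]
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
  unname(fold_of_group[proband])
}

sample_candidates <- function(spec, budget, rng) {
  lapply(seq_len(budget), function(i) {
    cand <- lapply(spec$search, function(rg) {
      v <- rg[1] + rng$unif(1) * (rg[2] - rg[1])
      if (is.integer(rg)) as.integer(round(v)) else v
    })
    cand
  })
}

#' Seeded random-search hyperparameter tuning with grouped threefold CV
#'
#' Samples `budget` candidates uniformly from the spec's search space and
#' scores each by mean RMSE over a threefold cross-validation of the training
#' data, with folds grouped by proband so no proband's rows ever appear in
#' both the training and the validation side of an inner split. Returns the
#' candidate with the lowest mean CV RMSE, the full evaluation log, and the
#' fold assignment used.
#'
#' @param spec An `al_model_spec`.
#' @param train An `al_dataset`.
#' @param budget Number of candidates (default `spec$budget`).
#' @return List with `best` (named hyperparameter list), `log` (data.frame of
#'   candidates and scores) and `folds` (inner fold id per training row).
#' @export
tune <- function(spec, train, budget = spec$budget) {
  stopifnot(inherits(spec, "al_model_spec"), inherits(train, "al_dataset"))
  if (budget < 1L) stop("tune: budget must be >= 1", call. = FALSE)
  n <- nrow(train$x)
  if (n < 6L) stop("tune: need >= 6 training rows", call. = FALSE)
  folds <- group_folds(train$proband, k = 3L, seed = spec$seed)
  rng <- rng_stream(spec$seed + 1L)
  cands <- sample_candidates(spec, budget, rng)
  scores <- vapply(cands, function(cand) {
    sp <- spec; sp$best <- cand
    errs <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; va <- folds == f
      if (!any(va) || sum(tr) < 2L) return(NA_real_)
      fit <- fit_model(sp, train$x[tr, , drop = FALSE], train$y[tr],
                       importance = FALSE)
      pr <- predict(fit, train$x[va, , drop = FALSE])
      sqrt(mean((pr - train$y[va])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.min(scores)
  log <- data.frame(candidate = seq_along(cands),
                    do.call(rbind, lapply(cands, function(cc) unlist(cc))),
                    cv_rmse = scores)
  list(best = cands[[best_i]], log = log, folds = folds)
}

# ---- recursive feature elimination -----------------------------------------

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Starting from all features, repeatedly fits the model on the current set,
#' scores it by grouped threefold CV RMSE, and drops the 10% of features with
#' the smallest absolute weight/importance (ties broken by name order: later
#' names are dropped first), down to a single feature. Returns the feature
#' subset with the best CV RMSE; subsets scoring within a relative tolerance
#' `tie_tol` of each other count as tied and the smaller one wins (exact
#' duplicate features, for instance, produce such floating-point ties). With
#' fewer than 2 features the input is returned unchanged.
#'
#' @param spec An `al_model_spec` carrying fixed hyperparameters in
#'   `spec$best` (defaults used otherwise).
#' @param train An `al_dataset`.
#' @param step Fraction of remaining features dropped per iteration
#'   (default 0.1).
#' @param tie_tol Relative CV-RMSE tolerance for score ties (default 1e-6).
#' @return Character vector of selected feature names (non-empty).
#' @export
rfecv <- function(spec, train, step = 0.1, tie_tol = 1e-6) {
  stopifnot(inherits(spec, "al_model_spec"), inherits(train, "al_dataset"))
  feats <- colnames(train$x)
  if (length(feats) < 2L) return(feats)
  if (is.null(spec$best)) {
    spec$best <- if (spec$family == "ridge") list(log10_lambda = 0) else list()
  }
  folds <- group_folds(train$proband, k = 3L, seed = spec$seed)
  cv_rmse <- function(cols) {
    errs <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; va <- folds == f
      fit <- fit_model(spec, train$x[tr, cols, drop = FALSE], train$y[tr],
                       importance = FALSE)
      pr <- predict(fit, train$x[va, cols, drop = FALSE])
      sqrt(mean((pr - train$y[va])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  current <- feats
  best_set <- NULL
  best_score <- Inf
  while (length(current) >= 1L) {
    score <- cv_rmse(current)
    tol <- tie_tol * max(best_score, .Machine$double.eps)
    better <- score < best_score - tol ||
      (abs(score - best_score) <= tol && length(current) < length(best_set))
    if (is.null(best_set) || better) {
      best_set <- current
      best_score <- score
    }
    if (length(current) == 1L) break
    fit <- fit_model(spec, train$x[, current, drop = FALSE], train$y)
    w <- model_weights(fit)[current]
    n_drop <- max(1L, floor(step * length(current)))
    ord <- order(w, -rank(current), decreasing = FALSE)  # low weight first; name-order ties
    drop <- current[ord[seq_len(n_drop)]]
    current <- setdiff(current, drop)
  }
  sort(best_set)
}
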