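rand_problem <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.numeric(X %*% rnorm(p) + rnorm(n, 0, 0.5))
  list(X = X, y = y)
}

test_that("ridge at lambda 0 reproduces ordinary least squares", {
  pr <- rand_problem(seed = 41)
  fit <- fit_ridge(pr$X, pr$y, 0)
  ols <- lm(pr$y ~ scale(pr$X))
  expect_equal(unname(fit$w), unname(coef(ols)[-1]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("huge lambda shrinks weights to zero and predictions to mean(y)", {
  pr <- rand_problem(seed = 43)
  fit <- fit_ridge(pr$X, pr$y, 1e12)
  expect_lt(max(abs(fit$w)), 1e-9)
  expect_equal(predict(fit, pr$X), rep(mean(pr$y), 20), tolerance = 1e-8)
})

test_that("closed-form ridge matches the numeric minimizer of the penalized loss", {
  for (seed in 1:20) {
    pr <- rand_problem(seed = seed)
    lam <- 10^runif(1, -2, 2)
    fit <- fit_ridge(pr$X, pr$y, lam)
    oracle <- ridge_bfgs_oracle(pr$X, pr$y, lam)
    expect_lt(max(abs(c(fit$w, fit$intercept) - c(oracle$w, oracle$intercept))),
              1e-6)
  }
})

test_that("primal and dual ridge solutions coincide", {
  set.seed(47)
  X <- matrix(rnorm(12 * 30), 12, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- rnorm(12)
  dual <- fit_ridge(X, y, 2)                        # p > n path
  A <- crossprod(scale(X)); diag(A) <- diag(A) + 2
  w_primal <- solve(A, crossprod(scale(X), y - mean(y)))
  expect_equal(unname(dual$w), as.numeric(w_primal), tolerance = 1e-8)
})

test_that("ridge predictions are invariant to affine rescaling of raw features", {
  pr <- rand_problem(seed = 53)
  fit1 <- fit_ridge(pr$X, pr$y, 3)
  X2 <- sweep(sweep(pr$X, 2, c(10, 0.1, 5, 2, 100), "*"), 2, c(1, -3, 0, 7, 2), "+")
  fit2 <- fit_ridge(X2, pr$y, 3)
  expect_equal(predict(fit1, pr$X), predict(fit2, X2), tolerance = 1e-8)
})

test_that("constant feature columns are neutralized, non-finite inputs rejected", {
  pr <- rand_problem(seed = 59)
  Xc <- cbind(pr$X, const = 1)
  fit <- fit_ridge(Xc, pr$y, 1)
  expect_equal(unname(fit$w["const"]), 0)
  Xb <- pr$X; Xb[1, 1] <- NA
  expect_error(fit_ridge(Xb, pr$y, 1), "non-finite")
  expect_error(fit_ridge(pr$X, pr$y, -1), "non-negative")
})

test_that("boosting is deterministic, fits constants, and has capacity for steps", {
  pr <- rand_problem(n = 60, seed = 61)
  m1 <- fit_boosting(pr$X, pr$y, list(subsample = 0.7), seed = 9)
  m2 <- fit_boosting(pr$X, pr$y, list(subsample = 0.7), seed = 9)
  expect_identical(predict(m1, pr$X), predict(m2, pr$X))
  yc <- rep(4.2, 60)
  mc <- fit_boosting(pr$X, yc, list(nrounds = 20), seed = 1)
  expect_equal(predict(mc, pr$X), yc, tolerance = 1e-6)
  # single-feature step function is learnable to near zero training error
  step_y <- ifelse(pr$X[, 1] > 0, 5, -5)
  ms <- fit_boosting(pr$X, step_y, list(max_depth = 3, eta = 0.3, nrounds = 300),
                     seed = 2)
  expect_lt(sqrt(mean((predict(ms, pr$X) - step_y)^2)), 0.01)
  expect_gt(ms$importance["f1"], 0.9)
})

test_that("tuning returns the best candidate by grouped threefold CV RMSE", {
  pr <- rand_problem(n = 60, seed = 67)
  ds <- labeled_dataset(pr$X, pr$y, paste0("p", 1:60))
  one <- model_spec("ridge", search = list(log10_lambda = c(0, 0)), seed = 1)
  expect_equal(tune(one, ds, budget = 5)$best$log10_lambda, 0)
  # strongly informative linear data: small lambda must beat huge lambda
  score_at <- function(ll) {
    sp <- model_spec("ridge", search = list(log10_lambda = c(ll, ll)), seed = 1)
    tune(sp, ds, budget = 1)$log$cv_rmse
  }
  expect_lt(score_at(-2), score_at(6))
  grid <- model_spec("ridge", seed = 1)
  best <- tune(grid, ds, budget = 30)$best
  expect_lt(best$log10_lambda, 2)
  expect_error(tune(grid, ds, budget = 0), "budget")
  small <- labeled_dataset(pr$X[1:4, ], pr$y[1:4], paste0("p", 1:4))
  expect_error(tune(grid, small), ">= 6")
})

test_that("tuning folds never mix a proband across train and validation", {
  pr <- rand_problem(n = 39, seed = 71)
  probands <- rep(paste0("p", 1:13), each = 3)
  ds <- labeled_dataset(pr$X, pr$y, probands, sample = rep(1:3, 13))
  tu <- tune(model_spec("ridge", seed = 3), ds, budget = 2)
  folds <- tu$folds
  expect_length(folds, 39L)
  expect_setequal(unique(folds), 1:3)
  # every proband's rows sit in exactly one fold
  per_pb <- tapply(folds, probands, function(f) length(unique(f)))
  expect_true(all(per_pb == 1))
})

test_that("tuning search is reproducible from the spec seed and logged", {
  pr <- rand_problem(n = 30, seed = 73)
  ds <- labeled_dataset(pr$X, pr$y, paste0("p", 1:30))
  sp <- model_spec("ridge", seed = 11)
  t1 <- tune(sp, ds, budget = 8)
  t2 <- tune(sp, ds, budget = 8)
  expect_identical(t1$log, t2$log)
  expect_equal(nrow(t1$log), 8L)
  expect_true(all(is.finite(t1$log$cv_rmse)))
})

test_that("RFECV recovers a planted support among noise features", {
  kept <- sapply(1:10, function(seed) {
    set.seed(seed)
    n <- 60
    X <- matrix(rnorm(n * 55), n, 55,
                dimnames = list(NULL, c(sprintf("inf%d", 1:5),
                                        sprintf("noise%02d", 1:50))))
    y <- as.numeric(X[, 1:5] %*% c(3, -3, 2.5, 2, -2) + rnorm(n, 0, 0.5))
    ds <- labeled_dataset(X, y, paste0("p", 1:n))
    sel <- rfecv(model_spec("ridge", seed = seed), ds)
    sum(grepl("^inf", sel))
  })
  expect_gte(median(kept), 4)
})

test_that("RFECV tie-breaking and degenerate inputs", {
  set.seed(79)
  base <- rnorm(30)
  X <- matrix(base, 30, 4)
  colnames(X) <- c("a", "b", "c", "d")
  y <- base * 2 + rnorm(30, 0, 0.1)
  ds <- labeled_dataset(X, y, paste0("p", 1:30))
  # with a negligible penalty, duplicate subsets predict identically:
  # the score tie resolves to a single feature, kept by name order
  sp <- model_spec("ridge", seed = 1)
  sp$best <- list(log10_lambda = -8)
  sel <- rfecv(sp, ds, step = 0.25)
  expect_length(sel, 1L)
  expect_equal(sel, "a")
  one <- labeled_dataset(X[, 1, drop = FALSE], y, paste0("p", 1:30))
  expect_identical(rfecv(model_spec("ridge", seed = 1), one), "a")
})
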