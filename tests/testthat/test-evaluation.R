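test_that("LOO baseline predicts the mean of the other probands", {
  expect_equal(loo_baseline(c(1, 2, 3)), c(2.5, 2.0, 1.5))
  expect_equal(loo_baseline(rep(4, 6)), rep(4, 6))
  expect_error(loo_baseline(5), ">= 2")
})

test_that("LOO baseline LPC is exactly -1 for any non-constant labels", {
  set.seed(83)
  for (i in 1:100) {
    y <- rnorm(sample(3:40, 1))
    expect_equal(cor(loo_baseline(y), y), -1, tolerance = 1e-12)
  }
  # constant labels: correlation undefined, reported missing
  expect_true(is.na(metrics(loo_baseline(rep(2, 5)), rep(2, 5))["lpc"]))
})

test_that("LOO baseline RMSE equals n/(n-1) times the population sd", {
  set.seed(89)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    rmse <- metrics(loo_baseline(y), y)["rmse"]
    pop_sd <- sqrt(mean((y - mean(y))^2))
    expect_equal(unname(rmse), n / (n - 1) * pop_sd, tolerance = 1e-12)
  }
})

test_that("LOPO baseline is the grand mean of the other probands' samples", {
  Y <- rbind(rnorm(13), rep(4, 13))
  expect_equal(lopo_baseline(Y)[1], 4)
  Yc <- matrix(2.5, 4, 13)
  expect_equal(lopo_baseline(Yc), rep(2.5, 4))
  set.seed(97)
  Y3 <- matrix(rnorm(39), 3, 13)
  brute <- sapply(1:3, function(i) mean(Y3[-i, ]))
  expect_equal(lopo_baseline(Y3), brute)
  # missing entries excluded from the mean
  Y3[1, 4] <- NA
  brute2 <- sapply(1:3, function(i) mean(Y3[-i, ], na.rm = TRUE))
  expect_equal(lopo_baseline(Y3), brute2)
  Yall <- Y3; Yall[2, ] <- NA
  expect_warning(lopo_baseline(Yall), "all-missing")
})

test_that("metrics follow their definitions", {
  expect_equal(unname(metrics(1:5, 1:5)), c(0, 0, 1))
  expect_equal(unname(metrics(2:6, 1:5)), c(1, 1, 1))
  m <- metrics(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unname(m), c(sqrt(0.5), 0.5, 0))
  expect_true(is.na(metrics(rep(1, 4), 1:4)["lpc"]))
})

test_that("baseline comparison is a paired t-test with d = mean/sd of diffs", {
  same <- compare_to_baseline(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
  # constant non-zero differences: zero-variance flag path
  flg <- compare_to_baseline(c(1, 1, 1, 1), c(2, 2, 2, 2))
  expect_true(is.na(flg$p))
  expect_equal(flg$d, 0)
  expect_match(flg$flag, "zero-variance")
  # diffs (1, 2, 3): t = 2/(1/sqrt(3)), p from t_2
  cmp <- compare_to_baseline(c(0, 0, 0), c(1, 2, 3))
  expect_equal(cmp$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(cmp$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(cmp$p, 0.0742, tolerance = 1e-3)
  expect_equal(cmp$d, 2, tolerance = 1e-12)
  expect_error(compare_to_baseline(1:3, 1:4), "paired")
})

test_that("Cronbach's alpha matches closed forms", {
  set.seed(101)
  base <- rnorm(50)
  ident <- matrix(base, 50, 4)
  expect_equal(cronbach_alpha(ident), 1)
  # two items with exact sample correlation 0.5 and unit variance:
  # Spearman-Brown gives alpha = 2*0.5/1.5 = 2/3
  v1 <- as.numeric(scale(rnorm(100)))
  w <- as.numeric(scale(residuals(lm(rnorm(100) ~ v1))))
  v2 <- 0.5 * v1 + sqrt(0.75) * w
  expect_equal(cor(v1, v2), 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(v1, v2)), 2 / 3, tolerance = 1e-10)
  # independent items: alpha near zero
  set.seed(103)
  ind <- matrix(rnorm(10000 * 5), ncol = 5)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 10, 1)), ">= 2 items")
  expect_error(cronbach_alpha(matrix(1, 2, 3)), ">= 3 probands")
})

make_outcome_ds <- function(n = 30, p = 4, signal = TRUE, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- if (signal) as.numeric(X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.05)) else rnorm(n)
  labeled_dataset(X, y, paste0("p", seq_len(n)))
}

test_that("LOO CV recovers a deterministic linear signal with high LPC", {
  ds <- make_outcome_ds(n = 30, signal = TRUE, seed = 107)
  cv <- loo_cv(ds, model_spec("ridge", seed = 1, budget = 20))
  expect_gte(cv$metrics["model", "lpc"], 0.95)
  expect_lt(cv$metrics["model", "rmse"], cv$metrics["baseline", "rmse"])
  expect_equal(nrow(cv$predictions), 30L)
  # stored predictions re-aggregate to the reported metrics bit-exactly
  expect_identical(unname(cv$metrics["model", ]),
                   unname(metrics(cv$predictions$pred, cv$predictions$y)))
  expect_identical(unname(cv$metrics["baseline", ]),
                   unname(metrics(cv$predictions$baseline, cv$predictions$y)))
})

test_that("LOO CV on pure-noise labels rarely beats the baseline", {
  sig <- sapply(1:20, function(s) {
    ds <- make_outcome_ds(n = 20, signal = FALSE, seed = 200 + s)
    cv <- loo_cv(ds, model_spec("ridge", seed = s, budget = 10))
    significant_improvement(cv)
  })
  expect_lte(sum(sig), 2)
})

test_that("LOO CV input contract", {
  ds <- make_outcome_ds(n = 3)
  expect_error(loo_cv(ds, model_spec("ridge")), "insufficient")
  proc <- labeled_dataset(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b"))),
                          rnorm(10), rep("p1", 10), 1:10)
  expect_error(loo_cv(proc, model_spec("ridge")), "outcome-level")
})

make_process_ds <- function(n_pb = 8, shared = TRUE, seed = 1) {
  set.seed(seed)
  rows <- n_pb * 13
  X <- matrix(rnorm(rows * 3), rows, 3, dimnames = list(NULL, c("a", "b", "c")))
  pb <- rep(paste0("p", seq_len(n_pb)), each = 13)
  y <- if (shared) {
    as.numeric(2 * X[, 1] + rnorm(rows, 0, 0.2))
  } else {
    rep(rnorm(n_pb, 0, 2), each = 13) + rnorm(rows, 0, 0.1)
  }
  labeled_dataset(X, y, pb, rep(1:13, n_pb))
}

test_that("LOPO CV beats the baseline when probands share a signal", {
  ds <- make_process_ds(shared = TRUE, seed = 109)
  cv <- lopo_cv(ds, model_spec("ridge", seed = 2, budget = 10))
  expect_lt(cv$metrics["model", "rmse"], cv$metrics["baseline", "rmse"])
  expect_true(significant_improvement(cv))
  expect_equal(nrow(cv$predictions), 8 * 13)
})

test_that("LOPO CV cannot predict proband-specific offsets above baseline", {
  ds <- make_process_ds(shared = FALSE, seed = 113)
  cv <- lopo_cv(ds, model_spec("ridge", seed = 3, budget = 10))
  expect_false(significant_improvement(cv))
})

test_that("LOPO predictions for a proband are independent of their labels", {
  ds <- make_process_ds(shared = TRUE, seed = 127)
  cv1 <- lopo_cv(ds, model_spec("ridge", seed = 4, budget = 5))
  ds2 <- ds
  ds2$y[ds2$proband == "p3"] <- ds2$y[ds2$proband == "p3"] + 100
  cv2 <- lopo_cv(ds2, model_spec("ridge", seed = 4, budget = 5))
  p3 <- cv1$predictions$proband_id == "p3"
  expect_identical(cv1$predictions$pred[p3], cv2$predictions$pred[p3])
  # the baseline for p3 is also untouched by p3's labels
  expect_identical(cv1$predictions$baseline[p3], cv2$predictions$baseline[p3])
})

test_that("LOPO handles missing labels by excluding those samples", {
  ds <- make_process_ds(shared = TRUE, seed = 131)
  ds$y[c(3, 17, 40)] <- NA
  cv <- lopo_cv(ds, model_spec("ridge", seed = 5, budget = 5))
  expect_equal(nrow(cv$predictions), 8 * 13 - 3)
  expect_false(anyNA(cv$predictions$pred))
})

test_that("report tables carry the below-baseline and significance markers", {
  ds <- make_outcome_ds(n = 30, signal = TRUE, seed = 137)
  cv <- loo_cv(ds, model_spec("ridge", seed = 1, budget = 10))
  dir <- withr::local_tempdir()
  tabs <- report(list(demo_scale = list(Ridge = cv)), dir = dir)
  tab <- tabs$demo_scale
  expect_equal(tab$method, c("Ridge", "Baseline"))
  expect_match(tab$RMSE[1], "\\+")   # model beat the baseline
  expect_match(tab$RMSE[1], "\\*")   # significantly
  expect_false(grepl("[+*]", tab$RMSE[2]))
  rt <- data.table::fread(file.path(dir, "demo_scale.tsv"))
  expect_equal(rt$method, tab$method)
  expect_equal(rt$RMSE, tab$RMSE)
  expect_length(report(list()), 0L)
  it <- importance_table(cv, top = 3)
  expect_equal(names(it), c("feature", "weight"))
  expect_equal(order(it$weight, decreasing = TRUE), 1:3)
})
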