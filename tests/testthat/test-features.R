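test_that("summary features of a constant stream are (c, c, 0, c, c, 0, 0)", {
  ts <- timeseries(0:269, rep(7, 270), 1)
  f <- summary_features(make_segment(ts, 0, 270))
  expect_equal(unname(f), c(7, 7, 0, 7, 7, 0, 0))
})

test_that("tendency of a linear ramp is first-median minus last-median", {
  ts <- timeseries(0:269, 0:269, 1)
  f <- summary_features(make_segment(ts, 0, 270))
  expect_equal(unname(f["tendency"]), median(0:29) - median(240:269))  # -240
  expect_equal(unname(f["tendency"]), -240)
})

test_that("maxmin and median follow direct arithmetic", {
  ts <- timeseries(c(0, 100, 200), c(1, 2, 100), 1)
  f <- summary_features(make_segment(ts, 0, 270))
  expect_equal(unname(f["maxmin"]), 99)
  expect_equal(unname(f["median"]), 2)
  expect_gte(f["maxmin"], 0)
})

test_that("empty segments and empty tendency windows yield NA features", {
  empty <- make_segment(timeseries(numeric(0), numeric(0), 1), 0, 270)
  expect_true(all(is.na(summary_features(empty))))
  # samples only in the middle: both 30 s end-windows empty
  mid <- timeseries(100:150, rnorm(51), 1)
  f <- summary_features(make_segment(mid, 0, 270))
  expect_true(is.na(f["tendency"]))
  expect_false(anyNA(f[setdiff(names(f), "tendency")]))
})

test_that("ratio index series follow their defining identities", {
  bp <- make_flat_bp(levels = c(theta = 1, alpha = 2, beta_low = 2,
                                beta_high = 4, gamma = 1))
  expect_equal(bla_series(bp, "T7")$v, rep(1, 80))       # beta_low == alpha
  expect_equal(nasa_series(bp, "T7")$v, rep(2, 80))      # (2+4)/(1+2)
  bp2 <- make_flat_bp(levels = c(theta = 3, alpha = 3, beta_low = 3,
                                 beta_high = 3, gamma = 3))
  expect_equal(nasa_series(bp2, "Pz")$v, rep(1, 80))     # scale invariance
  expect_equal(bla_series(bp2, "Pz")$v, rep(1, 80))
  bp3 <- make_flat_bp(levels = c(theta = 1, alpha = 1, beta_low = 3,
                                 beta_high = 3, gamma = 1))
  expect_equal(nasa_series(bp3, "AF3")$v, rep(3, 80))    # (3+3)/(1+1)
})

test_that("zero alpha power is floored to keep BLA finite", {
  bp <- make_flat_bp(levels = c(theta = 1, alpha = 0, beta_low = 1,
                                beta_high = 1, gamma = 1))
  s <- bla_series(bp, "T7", eps = 1e-12)
  expect_true(all(is.finite(s$v)))
  expect_equal(s$v[1], 1e12)
  expect_equal(attr(s, "n_floored"), 80L)
})

test_that("laterality series are left-minus-right and antisymmetric", {
  bp <- make_flat_bp(site_offset = c(AF3 = 0.5, AF4 = 0, T7 = 1, T8 = 0, Pz = 0))
  expect_equal(lateral_series(bp, "T", "alpha")$v, rep(1, 80))
  expect_equal(lateral_series(bp, "AF", "gamma")$v, rep(0.5, 80))
  swapped <- make_flat_bp(site_offset = c(AF3 = 0, AF4 = 0.5, T7 = 0, T8 = 1, Pz = 0))
  expect_equal(lateral_series(swapped, "T", "alpha")$v,
               -lateral_series(bp, "T", "alpha")$v)
  sym <- make_flat_bp()
  expect_equal(lateral_series(sym, "T", "theta")$v, rep(0, 80))
})

test_that("an EEG segment yields exactly 315 uniquely parseable features", {
  set.seed(23)
  bp <- make_flat_bp()
  bp$power <- bp$power * exp(matrix(rnorm(length(bp$power), 0, 0.2),
                                    nrow(bp$power)))
  fv <- eeg_feature_vector(make_bp_segment(bp))
  expect_length(fv, 315L)
  expect_equal(anyDuplicated(names(fv)), 0L)
  parsed <- lapply(names(fv), parse_feature_name)
  streams <- vapply(parsed, `[[`, character(1), "stream")
  stats_ <- vapply(parsed, `[[`, character(1), "stat")
  expect_setequal(unique(streams), eeg_stream_names())
  expect_equal(paste(streams, stats_, sep = "_"), names(fv))
  # the field's reported feature names are all present
  expect_true(all(c("T7_GAMMA_median", "nasa_AF4_median",
                    "lateral_T_BETA_HIGH_median", "bla_T7_min") %in% names(fv)))
})

test_that("all-constant streams zero the dispersion features", {
  fv <- eeg_feature_vector(make_bp_segment(make_flat_bp()))
  disp <- fv[grepl("_(std|maxmin|tendency)$", names(fv))]
  expect_equal(unname(disp), rep(0, length(disp)))
})

test_that("doubling all band power doubles site-band means, leaves ratios fixed", {
  set.seed(29)
  bp <- make_flat_bp()
  bp$power <- bp$power * exp(matrix(rnorm(length(bp$power), 0, 0.2), nrow(bp$power)))
  bp2 <- bp; bp2$power <- 2 * bp$power
  f1 <- eeg_feature_vector(make_bp_segment(bp))
  f2 <- eeg_feature_vector(make_bp_segment(bp2))
  site_means <- grepl("^(AF3|AF4|T7|T8|Pz)_.*_mean$", names(f1))
  expect_equal(f2[site_means], 2 * f1[site_means])
  ratios <- grepl("^(bla|nasa)_", names(f1))
  expect_equal(f2[ratios], f1[ratios])
})

test_that("features are invariant to timestamp translation", {
  set.seed(31)
  v <- rnorm(270)
  ts1 <- timeseries(0:269, v, 1)
  ts2 <- timeseries(500:769, v, 1)
  f1 <- summary_features(make_segment(ts1, 0, 270))
  f2 <- summary_features(make_segment(ts2, 500, 770))
  expect_equal(f1, f2)
})

test_that("an EDA segment yields exactly 7 GSR-prefixed features", {
  ts <- timeseries(0:269, 0:269 + 100, 5)
  fv <- eda_feature_vector(make_segment(ts, 0, 270))
  expect_length(fv, 7L)
  expect_true(all(grepl("^GSR_", names(fv))))
  expect_equal(unname(fv["GSR_tendency"]), -240)
})

test_that("feature tables have 13 process rows or 1 outcome row per proband", {
  sess <- make_session(session_length = 1080, interval = 270, seed = 37)
  proc <- session_features(sess, "eda", "process")
  expect_equal(nrow(proc), 4L)       # 1080/270 alarms
  expect_equal(proc$sample_index, 1:4)
  outc <- session_features(sess, "eeg", "outcome")
  expect_equal(nrow(outc), 1L)
  expect_equal(outc$sample_index, 0L)
  expect_equal(ncol(outc), 4L + 315L)
  tab <- cohort_features(list(sess, make_session("p02", 1080, seed = 38)),
                         "eda", "process")
  expect_equal(table(tab$proband_id), table(c(rep("p01", 4), rep("p02", 4))))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, p)
  rt <- read_feature_table(p)
  expect_equal(rt$GSR_mean, tab$GSR_mean)
})
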