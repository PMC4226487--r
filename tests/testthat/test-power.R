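test_that("replicates are classified by the target-window rule", {
  grid <- seq(0, 180000, by = 1000)
  thr <- structure(list(statistic = "clr", cutoff = 5, alpha_level = 0.05,
                        n_null_replicates = 100, method = "max"),
                   class = "threshold_set")
  mk <- function(sig_at) {
    stat <- rep(0, length(grid))
    stat[match(sig_at, grid)] <- 10
    structure(list(grid_positions = grid, statistic = stat,
                   arg_alpha = NULL, max_value = max(stat),
                   max_position = grid[which.max(stat)],
                   statistic_name = "clr", L = 180000),
              class = c("sweep_scan", "scan_result"))
  }
  # single significant point exactly at the target
  cls <- classify_replicate(mk(90000), thr, 90000, 10000)
  expect_true(cls$is_tp); expect_false(cls$is_fp)
  # nothing significant
  cls <- classify_replicate(mk(numeric(0)), thr, 90000, 10000)
  expect_false(cls$is_tp); expect_false(cls$is_fp)
  # significant at target - 4 kb and target + 40 kb: both TP and FP
  cls <- classify_replicate(mk(c(86000, 130000)), thr, 90000, 10000)
  expect_true(cls$is_tp); expect_true(cls$is_fp)
  # window edge: 5 kb away is inside a 10 kb window, 6 kb is not
  expect_true(classify_replicate(mk(95000), thr, 90000, 10000)$is_tp)
  expect_false(classify_replicate(mk(96000), thr, 90000, 10000)$is_tp)
})

test_that("the cutoff is the right order statistic and converges with more nulls", {
  x <- c(1:99, 1000)
  expect_equal(sweeppower:::order_stat_quantile(x, 0.95), 95)
  expect_equal(sweeppower:::order_stat_quantile(rep(2, 10), 0.95), 2)
  # quantile consistency under resampling
  set.seed(1)
  big <- rexp(4000)
  q1 <- sweeppower:::order_stat_quantile(big[1:500], 0.95)
  q2 <- sweeppower:::order_stat_quantile(big[1:2000], 0.95)
  q_true <- qexp(0.95)
  expect_lt(abs(q2 - q_true), abs(q1 - q_true) + 0.05)
})

test_that("calibration gives the advertised null rejection rate", {
  p <- preset_model("florida")
  st <- study_config(n_replicates = 0, n_null_replicates = 60, seed = 17,
                     grid_spacing_bp = 4000)
  thr <- calibrate_threshold(p$demography, p$region, st, "clr")
  fresh <- simulate_replicates(60, 555, function(s) {
    simulate_neutral_sample(p$demography, p$region, s)
  })
  rej <- vapply(fresh, function(h) {
    sc <- sweeppower:::scan_or_null(h, "clr", st)
    !is.null(sc) && any(sc$statistic > thr$cutoff, na.rm = TRUE)
  }, logical(1))
  # binomial error around alpha = 0.05 with 60 replicates
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("degenerate null samples warn and give an exact quantile", {
  grid <- seq(0, 1000, 100)
  p <- preset_model("florida")
  st <- study_config(n_replicates = 0, n_null_replicates = 25, seed = 1,
                     grid_spacing_bp = 30000)
  # omega on Florida-scale data is frequently undefined (too few sites),
  # which exercises the degenerate path deterministically at small L
  reg_small <- region_config(L = 2000, n = 6)
  expect_warning(
    thr <- calibrate_threshold(p$demography, reg_small, st, "omega"),
    "degenerate|missing|4"
  )
  expect_s3_class(thr, "threshold_set")
})

test_that("a zero-replicate study exits cleanly with an empty table", {
  st <- study_config(n_replicates = 0, n_null_replicates = 20, seed = 1)
  pt <- run_power_study(list(), st)
  expect_s3_class(pt, "power_table")
  expect_equal(nrow(pt), 0L)
  expect_equal(nrow(rejection_curves(pt)), 0L)
})

test_that("power studies are reproducible bit-for-bit from the master seed", {
  p <- preset_model("florida-table2")
  cells <- list(a = list(demography = p$demography, region = p$region,
                         sweep = sweep_model(0.01, 0.1)))
  st <- study_config(n_replicates = 6, n_null_replicates = 20, seed = 33,
                     grid_spacing_bp = 5000)
  pt1 <- run_power_study(cells, st, statistics = "clr")
  pt2 <- run_power_study(cells, st, statistics = "clr")
  expect_identical(as.data.frame(pt1), as.data.frame(pt2))
  expect_identical(rejection_curves(pt1), rejection_curves(pt2))
  expect_named(pt1, c("cell", "N_anc", "f", "s", "tau", "statistic",
                      "tp_pct", "fp_pct", "n_replicates", "n_failed",
                      "cutoff"))
})
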