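test_that("background pooling is idempotent and pools counts", {
  m <- matrix(c(1, 0, 0, 0,
                0, 0, 1, 0), nrow = 4)
  h <- make_h(m, c(100, 200))
  b <- background_spectrum(h)
  expect_equal(sum(b$counts), 1)
  expect_equal(b$counts, c(1, 0, 0))
  # pooling an identical region leaves the normalized spectrum unchanged
  b2 <- background_spectrum(h, extra = list(h))
  expect_equal(b2$counts, b$counts)
  # focal 2 singletons + extra 2 doubletons at n = 4
  md <- matrix(c(1, 1, 0, 0,
                 0, 1, 1, 0), nrow = 4)
  b3 <- background_spectrum(h, extra = list(make_h(md, c(10, 20))))
  expect_equal(b3$counts, c(0.5, 0.5, 0))
})

test_that("spectrum projection is hypergeometric and conserves mass", {
  allsing <- structure(list(counts = c(4, 0, 0), n = 4, normalized = FALSE),
                       class = "site_sfs")
  pr <- downsample_spectrum(allsing, 2)
  expect_equal(unname(pr), c(0.5, 0.5, 0))
  # m = n is the identity on the polymorphic classes
  b <- structure(list(counts = c(3, 2, 1), n = 4, normalized = FALSE),
                 class = "site_sfs")
  expect_equal(unname(downsample_spectrum(b, 4)), c(0, 0.5, 1 / 3, 1 / 6, 0))
  for (m in 1:4) expect_equal(sum(downsample_spectrum(b, m)), 1)
  expect_error(downsample_spectrum(b, 5), "m")
})

test_that("sweep-site probabilities match exhaustive enumeration", {
  for (n in c(4, 6)) {
    counts <- c(5, seq_len(n - 2))
    b <- structure(list(counts = counts, n = n, normalized = FALSE),
                   class = "site_sfs")
    for (ad in c(0.05, 0.5, 3)) {
      ours <- sweep_site_probability(b, d = ad, alpha = 1, k = 1:(n - 1))
      oracle <- enum_sweep_site(counts, n, 1, ad)
      expect_equal(ours, oracle, tolerance = 1e-12)
      expect_equal(sum(ours), 1, tolerance = 1e-12)
    }
  }
})

test_that("distant sites recover the background spectrum", {
  b <- structure(list(counts = c(3, 2, 1), n = 4, normalized = FALSE),
                 class = "site_sfs")
  expect_equal(sweep_site_probability(b, d = 50, alpha = 1, k = 1:3),
               c(3, 2, 1) / 6, tolerance = 1e-10)
})

test_that("near-zero escape concentrates mass at the spectrum edges", {
  b <- structure(list(counts = c(1, 1, 1, 1, 1), n = 6, normalized = FALSE),
                 class = "site_sfs")
  p <- sweep_site_probability(b, d = 0.02, alpha = 1, k = 1:5)
  expect_gt(p[1] + p[5], 0.9)
  expect_error(sweep_site_probability(b, 1, 1, k = 0), "k")
})

test_that("the likelihood ratio vanishes when the data equal the background", {
  # all-singleton data with an all-singleton background: the sweep model
  # can never beat the null
  set.seed(4)
  n <- 10
  m <- diag(1L, n)[, 1:8]
  h <- make_h(m, sort(sample(1:999, 8)), L = 1000)
  sc <- clr_scan(h, grid_spacing_bp = 100)
  expect_true(all(sc$statistic <= 1e-8))
  expect_true(all(sc$statistic >= 0))
})

test_that("the likelihood-ratio profile is non-negative and translation invariant", {
  p <- preset_model("florida")
  h <- simulate_neutral_sample(p$demography, p$region, seed = 21)
  grid <- seq(0, 180000, by = 5000)
  alphas <- exp(seq(log(1e-11), log(1e-2), length.out = 40))
  sc <- clr_scan(h, grid = grid, alpha_grid = alphas)
  expect_true(all(sc$statistic >= -1e-9))
  # shift every position (and the grid) by a constant
  shift <- 12345
  h2 <- haplotype_matrix(h$alleles, h$positions + shift, h$L + shift)
  b <- background_spectrum(h)
  sc2 <- clr_scan(h2, background = b, grid = grid + shift, alpha_grid = alphas)
  expect_equal(sc$statistic, sc2$statistic, tolerance = 1e-9)
})

test_that("a strong recent sweep is localized near the selected site", {
  dem <- demographic_model(5e4, 0.1, 1, d = 0.3, t_r = 0.005)
  reg <- region_config()
  sw <- sweep_model(0.1, 0.01, 90000)
  hits <- vapply(1:10, function(i) {
    h <- simulate_sweep_sample(dem, sw, reg, seed = i)
    sc <- clr_scan(h, grid_spacing_bp = 2000)
    abs(sc$max_position - 90000) <= 10000
  }, logical(1))
  expect_gte(sum(hits), 6)  # majority, against a ~11% random expectation
})
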