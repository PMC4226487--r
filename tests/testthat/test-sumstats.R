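test_that("the unfolded SFS counts derived alleles directly", {
  m <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0), nrow = 4)
  h <- make_h(m, c(100, 200))
  expect_equal(site_sfs(h)$counts, c(0, 2, 0))
  # empty matrix gives the zero vector
  h0 <- make_h(matrix(integer(0), nrow = 4, ncol = 0), numeric(0))
  expect_equal(site_sfs(h0)$counts, c(0, 0, 0))
})

test_that("SFS counts always sum to the number of segregating sites", {
  for (seed in 1:8) {
    h <- random_h(n = 7, S = 12, seed = seed)
    expect_equal(sum(site_sfs(h)$counts), n_sites(h))
  }
})

test_that("per-site diversity equals the brute-force pairwise average", {
  # hand example: 4 haplotypes, 2 sites at derived count 2, L = 1000
  m <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0), nrow = 4)
  h <- make_h(m, c(100, 200))
  expect_equal(nuc_div(h), (4 / 6 + 4 / 6) / 1000)
  expect_equal(nuc_div(h), 1.333e-3, tolerance = 1e-3)
  # exhaustive oracle over random matrices
  for (seed in 1:10) {
    h <- random_h(n = sample(4:8, 1), S = sample(3:15, 1), seed = seed)
    expect_equal(nuc_div(h), brute_pi(h))
  }
  # no sites, no diversity
  expect_equal(nuc_div(make_h(matrix(integer(0), 4, 0), numeric(0))), 0)
})

test_that("Tajima's D matches the textbook constants and sign convention", {
  # n = 4, all singletons: evaluate against an independent inline oracle
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  h <- make_h(m, c(10, 20, 30))
  pi_region <- brute_pi(h) * h$L
  expect_equal(tajimas_d(h), textbook_tajima(4, 3, pi_region))
  # undefined when S = 0, not zero
  expect_true(is.na(tajimas_d(make_h(matrix(integer(0), 4, 0), numeric(0)))))
  # sign agrees with pi_region - theta_W on arbitrary inputs
  for (seed in 1:10) {
    h <- random_h(n = 6, S = 10, seed = 100 + seed)
    num <- brute_pi(h) * h$L - n_sites(h) / sum(1 / (1:5))
    expect_equal(sign(tajimas_d(h)), sign(num))
  }
})

test_that("r2 comes from the 2x2 haplotype table and ignores allele labels", {
  # perfectly associated pair
  m <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(r2_matrix(make_h(m, c(1, 2)))$r2[1, 2], 1)
  # independent pair: haplotype counts {10, 01, 11, 00}
  m2 <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 0))
  expect_equal(r2_matrix(make_h(m2, c(1, 2)))$r2[1, 2], 0)
  # swapping allele labels at one site leaves r2 unchanged
  for (seed in 1:6) {
    h <- random_h(n = 8, S = 6, seed = 200 + seed)
    r <- r2_matrix(h)$r2
    m3 <- h$alleles
    m3[, 2] <- 1L - m3[, 2]
    r_swap <- r2_matrix(make_h(m3, h$positions, h$L))$r2
    expect_equal(r, r_swap, tolerance = 1e-12)
  }
})

test_that("LD decay marks empty distance bins as missing, not zero", {
  m <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 1, 0))
  h <- make_h(m, c(100, 200, 9000), L = 10000)
  dec <- ld_decay(r2_matrix(h), bin_width = 1000)
  expect_true(any(dec$n_pairs == 0))
  expect_true(all(is.na(dec$median_r2[dec$n_pairs == 0])))
  expect_true(all(!is.na(dec$median_r2[dec$n_pairs > 0])))
})

test_that("replicate summary tables carry one row per replicate", {
  p <- preset_model("florida")
  reps <- simulate_replicates(3, 5, function(s) {
    simulate_neutral_sample(p$demography, p$region, s)
  })
  tab <- replicate_sumstats(reps)
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("replicate", "S", "pi", "theta_w", "D"))
  expect_equal(tab$S[1], n_sites(reps[[1]]))
})
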