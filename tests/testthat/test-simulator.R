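test_that("neutral equilibrium pairwise diversity matches 4 N mu (n = 2)", {
  m <- equilibrium_model(2482)
  reg <- region_config(L = 20000, n = 2)
  pis <- vapply(1:2000, function(i) {
    nuc_div(simulate_neutral_sample(m, reg, seed = i))
  }, numeric(1))
  theory <- 4 * 2482 * 3.7e-8
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theory), 3 * se)
})

test_that("neutral equilibrium segregating sites match Watterson's formula", {
  # theta_region * a_{n-1} with the Gulf Coast theta over 180 kb
  m <- equilibrium_model(2482)
  reg <- region_config()
  S <- vapply(1:300, function(i) {
    n_sites(simulate_neutral_sample(m, reg, seed = 5000 + i))
  }, numeric(1))
  theory <- 4 * 2482 * 3.7e-8 * 180000 * sum(1 / (1:39))
  expect_equal(theory, 281.2, tolerance = 1e-3)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - theory), 3 * se)
})

test_that("bottleneck models skew the spectrum towards rare alleles", {
  p <- preset_model("florida")
  D <- vapply(1:30, function(i) {
    tajimas_d(simulate_neutral_sample(p$demography, p$region, seed = 80 + i))
  }, numeric(1))
  expect_lt(mean(D, na.rm = TRUE), 0)
})

test_that("segregating-site distribution matches an independent coalescent simulator", {
  # cross-validation oracle: msprime under the identical demography
  script <- c(
    "import msprime, sys, json",
    "N, f, c, d, tr = 2482.0, 0.001, 0.413, 1.225, 0.01",
    "dem = msprime.Demography()",
    "dem.add_population(name='p', initial_size=c*N)",
    "dem.add_population_parameters_change(time=tr*2*N, initial_size=f*N, population='p')",
    "dem.add_population_parameters_change(time=d*2*N, initial_size=N, population='p')",
    "S = []",
    "reps = msprime.sim_ancestry(samples={'p': 20}, demography=dem, sequence_length=180000,",
    "    recombination_rate=5.6e-7, num_replicates=300, random_seed=77)",
    "for ts in reps:",
    "    mts = msprime.sim_mutations(ts, rate=3.7e-8, model=msprime.BinaryMutationModel(), discrete_genome=False)",
    "    S.append(mts.num_sites)",
    "print(json.dumps(S))")
  pyfile <- tempfile(fileext = ".py")
  writeLines(script, pyfile)
  out <- suppressWarnings(system2("python", pyfile, stdout = TRUE, stderr = FALSE))
  expect_gt(length(out), 0)
  S_oracle <- as.numeric(strsplit(gsub("\\[|\\]|\\s", "", out), ",")[[1]])
  expect_equal(length(S_oracle), 300L)
  p <- preset_model("florida")
  S_ours <- vapply(1:300, function(i) {
    n_sites(simulate_neutral_sample(p$demography, p$region, seed = i))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(S_ours, S_oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("a vanishing selection coefficient degenerates to the neutral model", {
  p <- preset_model("florida")
  sw <- sweep_model(0.001, 0.1)
  S_sweep <- vapply(1:150, function(i) {
    n_sites(simulate_sweep_sample(p$demography, sw, p$region, seed = 300 + i))
  }, numeric(1))
  S_null <- vapply(1:150, function(i) {
    n_sites(simulate_neutral_sample(p$demography, p$region, seed = 700 + i))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(S_sweep, S_null))
  expect_gt(ks$p.value, 0.01)
})

test_that("hitchhiking strips diversity around the selected site", {
  dem <- demographic_model(1e4, 0.1, 1, d = 0.2, t_r = 0.005)
  reg <- region_config(L = 60000, n = 40)
  sw <- sweep_model(0.5, 0.01, 30000)
  pi_near <- function(h) {
    sel <- abs(h$positions - 30000) <= 1000
    n <- n_chromosomes(h)
    k <- colSums(h$alleles[, sel, drop = FALSE])
    sum(2 * k * (n - k) / (n * (n - 1))) / 2000
  }
  ps <- vapply(1:100, function(i) {
    pi_near(simulate_sweep_sample(dem, sw, reg, seed = i))
  }, numeric(1))
  pn <- vapply(1:100, function(i) {
    pi_near(simulate_neutral_sample(dem, reg, seed = 2000 + i))
  }, numeric(1))
  expect_lt(mean(ps), 0.1 * mean(pn))
})

test_that("every simulated sample satisfies the container invariants", {
  set.seed(99)
  for (case in 1:12) {
    n <- sample(c(4, 10, 40, 70), 1)
    L <- sample(c(5000, 50000), 1)
    m <- equilibrium_model(sample(c(500, 5000), 1))
    h <- simulate_neutral_sample(m, region_config(L = L, n = n),
                                 seed = 1e4 + case)
    if (n_sites(h) > 0) {
      k <- colSums(h$alleles)
      expect_true(all(k >= 1 & k <= n - 1))
      expect_true(all(diff(h$positions) > 0))
      expect_true(all(h$positions >= 0 & h$positions < L))
    }
    expect_equal(nrow(h$alleles), n)
  }
})

test_that("simulation replicates are reproducible from their seed", {
  p <- preset_model("florida")
  h1 <- simulate_neutral_sample(p$demography, p$region, seed = 123)
  h2 <- simulate_neutral_sample(p$demography, p$region, seed = 123)
  h3 <- simulate_neutral_sample(p$demography, p$region, seed = 124)
  expect_identical(h1$alleles, h2$alleles)
  expect_identical(h1$positions, h2$positions)
  expect_false(identical(h1$positions, h3$positions))
})
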