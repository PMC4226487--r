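# Shared helpers for the test suite. Fixtures are built in code.

# quick haplotype container from a matrix
make_h <- function(mat, pos, L = 1000) {
  haplotype_matrix(mat, pos, L)
}

# constant-size model expressed through the bottleneck parameterization
equilibrium_model <- function(N) {
  demographic_model(N, f = 1, c_recovery = 1, d = 10, t_r = 0.01)
}

# brute-force average pairwise difference per site (exhaustive oracle)
brute_pi <- function(h) {
  m <- h$alleles
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / choose(n, 2) / h$L
}

# random small haplotype matrix guaranteed polymorphic columns
random_h <- function(n = 6, S = 5, L = 1000, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), nrow = n)
    k <- colSums(m)
    keep <- k >= 1 & k <= n - 1
    if (sum(keep) >= 2) {
      m <- m[, keep, drop = FALSE]
      pos <- sort(sample(seq_len(L) - 1, ncol(m)))
      return(haplotype_matrix(m, pos, L))
    }
    seed <- seed + 1000
    set.seed(seed)
  }
}

# first-principles enumeration of the sweep-site sampling distribution
enum_sweep_site <- function(counts, n, alpha, d) {
  p <- counts / sum(counts)
  bf <- c(0, p, 0)  # classes 0..n
  pe <- 1 - exp(-alpha * d)
  mass <- rep(0, n + 1)
  for (e in 0:n) {
    we <- dbinom(e, n, pe)
    if (e == n) {
      mass <- mass + we * bf
      next
    }
    m <- e + 1
    Bm <- rep(0, m + 1)
    for (j in 0:n) {
      if (bf[j + 1] == 0) next
      for (jp in max(0, m - (n - j)):min(m, j)) {
        Bm[jp + 1] <- Bm[jp + 1] +
          bf[j + 1] * choose(j, jp) * choose(n - j, m - jp) / choose(n, m)
      }
    }
    for (jp in 0:m) {
      if (Bm[jp + 1] == 0) next
      psw <- jp / m
      if (jp >= 1) {
        k <- (jp - 1) + (n - e)
        mass[k + 1] <- mass[k + 1] + we * Bm[jp + 1] * psw
      }
      if (jp <= m - 1) {
        mass[jp + 1] <- mass[jp + 1] + we * Bm[jp + 1] * (1 - psw)
      }
    }
  }
  mass[2:n] / (1 - mass[1] - mass[n + 1])
}

# independent textbook evaluation of Tajima's D for a given (n, S, pi_region)
textbook_tajima <- function(n, S, pi_region) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_region - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}
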