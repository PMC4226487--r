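#' Background site frequency spectrum
#'
#' Pools the focal region's spectrum with any extra neutral regions (the
#' larger-background experiment) and normalizes it; this is the null model
#' of the composite-likelihood-ratio scan.
#'
#' @param h Focal [haplotype_matrix()].
#' @param extra Optional list of additional [haplotype_matrix()] objects
#'   simulated under the same demography.
#' @return A normalized [site_sfs()].
#' @export
background_spectrum <- function(h, extra = list()) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- n_chromosomes(h)
  counts <- site_sfs(h)$counts
  for (e in extra) {
    stopifnot(inherits(e, "haplotype_matrix"))
    if (n_chromosomes(e) != n) abort("extra regions must share the sample size")
    counts <- counts + site_sfs(e)$counts
  }
  if (sum(counts) == 0) abort("cannot build a background spectrum from zero segregating sites")
  structure(list(counts = counts / sum(counts), n = n, normalized = TRUE),
            class = "site_sfs")
}

#' Hypergeometric projection of a spectrum to a smaller sample
#'
#' Projects a background spectrum on `n` chromosomes down to `m` by
#' hypergeometric sampling without replacement:
#' `P(k of m | j of n) = C(j,k) C(n-j, m-k) / C(n,m)`. The monomorphic
#' classes `k = 0` and `k = m` produced by the projection are retained,
#' because the sweep-site mixture needs them.
#'
#' @param b A [site_sfs()] (counts or proportions over `1..n-1`).
#' @param m Target sample size, `1 <= m <= n`.
#' @return A named numeric vector of probabilities over `k = 0..m`,
#'   summing to 1.
#' @export
#' @examples
#' b <- structure(list(counts = c(4, 0, 0), n = 4, normalized = FALSE),
#'                class = "site_sfs")
#' downsample_spectrum(b, 2)  # all-singleton spectrum: P(0) = P(1) = 1/2
downsample_spectrum <- function(b, m) {
  stopifnot(inherits(b, "site_sfs"))
  n <- b$n
  if (m < 1 || m > n) abort("`m` must satisfy 1 <= m <= n")
  p <- b$counts / sum(b$counts)
  out <- numeric(m + 1)
  for (j in seq_len(n - 1)) {
    if (p[j] == 0) next
    k <- max(0, m - (n - j)):min(m, j)
    out[k + 1] <- out[k + 1] +
      p[j] * exp(lchoose(j, k) + lchoose(n - j, m - k) - lchoose(n, m))
  }
  setNames(out, 0:m)
}

#' Sweep-distorted site probabilities
#'
#' The per-site sampling distribution of the composite-likelihood sweep
#' model: each of the `n` lineages escapes the sweep independently with
#' probability `p_e = 1 - exp(-alpha * d)`; the non-escaping lineages
#' collapse onto the single swept ancestor; the ancestral configuration of
#' `e` escapees plus the swept ancestor is drawn from the background
#' spectrum projected to `e + 1`, the swept ancestor's allele being copied
#' to all `n - e` collapsed lineages; the result is conditioned on
#' polymorphism. As `alpha * d` grows, the background spectrum is recovered.
#'
#' @param b Background [site_sfs()] on `n` chromosomes.
#' @param d Distance from the putative sweep site, base pairs (>= 0).
#' @param alpha Sweep intensity per base pair (>= 0).
#' @param k Observed derived count(s), each in `1..n-1`.
#' @param n Sample size (defaults to the spectrum's).
#' @return Probability (vectorized over `k`).
#' @export
sweep_site_probability <- function(b, d, alpha, k, n = NULL) {
  stopifnot(inherits(b, "site_sfs"))
  if (is.null(n)) n <- b$n
  if (n != b$n) abort("`n` must match the background spectrum")
  if (d < 0 || alpha < 0) abort("`d` and `alpha` must be non-negative")
  if (any(k < 1 | k > n - 1)) abort("`k` must lie in [1, n-1]")
  p <- b$counts / sum(b$counts)
  dist <- .cpp_sweep_site_distribution(p, as.integer(n), alpha, d)
  dist[k]
}

#' Composite-likelihood-ratio sweep scan
#'
#' At each test position `X` on a physical grid, the composite likelihood of
#' the sweep model (each site's distribution distorted according to its
#' distance from `X`, maximized over the sweep-intensity nuisance parameter
#' `alpha` on a logarithmic grid that always includes the null `alpha =
#' Inf`) is contrasted with the composite likelihood of the background
#' spectrum itself:
#' `Lambda(X) = 2 (ln CL_sweep(alpha_hat) - ln CL_background)`.
#' Including the null in the `alpha` grid makes the statistic non-negative.
#'
#' @param h A [haplotype_matrix()].
#' @param background Optional [background_spectrum()]; defaults to the
#'   spectrum of `h` itself (the single-locus convention).
#' @param grid_spacing_bp Test-grid spacing in base pairs.
#' @param grid Optional explicit grid of test positions (overrides
#'   `grid_spacing_bp`).
#' @param alpha_grid Finite sweep intensities to search; the default is 40
#'   logarithmic steps from an intensity giving escape probability `1e-6`
#'   at half the region length up to `1e-2` per bp.
#' @return An object of class `sweep_scan` (also `scan_result`): list with
#'   `grid_positions`, `statistic`, `arg_alpha`, `max_value`,
#'   `max_position`, `statistic_name`.
#' @export
#' @examples
#' p <- preset_model("florida")
#' h <- simulate_neutral_sample(p$demography, p$region, seed = 3)
#' sc <- clr_scan(h, grid_spacing_bp = 20000)
#' glance(sc)
clr_scan <- function(h, background = NULL, grid_spacing_bp = 1000,
                     grid = NULL, alpha_grid = NULL) {
  stopifnot(inherits(h, "haplotype_matrix"))
  if (n_sites(h) < 1) abort("the scan needs at least one segregating site")
  n <- n_chromosomes(h)
  if (is.null(background)) background <- background_spectrum(h)
  stopifnot(inherits(background, "site_sfs"))
  if (background$n != n) abort("background spectrum sample size must match the data")
  if (is.null(grid)) grid <- seq(0, h$L, by = grid_spacing_bp)
  if (is.null(alpha_grid)) {
    a_min <- -log1p(-1e-6) / (h$L / 2)
    alpha_grid <- exp(seq(log(a_min), log(1e-2), length.out = 40))
  }
  b <- background$counts / sum(background$counts)
  k <- colSums(h$alleles)
  res <- .cpp_clr_scan(h$positions, as.integer(k), b, as.integer(n),
                       grid, alpha_grid)
  new_scan_result(grid, res$statistic, res$arg_alpha, "clr", h$L)
}

# shared scan-result constructor
new_scan_result <- function(grid, statistic, arg_alpha, name, L) {
  finite_or_inf <- ifelse(is.na(statistic), -Inf, statistic)
  imax <- which.max(finite_or_inf)
  structure(
    list(grid_positions = as.numeric(grid),
         statistic = as.numeric(statistic),
         arg_alpha = arg_alpha,
         max_value = statistic[imax],
         max_position = grid[imax],
         statistic_name = name,
         L = L),
    class = c("sweep_scan", "scan_result")
  )
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("%s scan over %d grid positions: max = %s at %g bp\n",
              toupper(x$statistic_name), length(x$grid_positions),
              format(x$max_value, digits = 4), x$max_position))
  invisible(x)
}

#' @export
tidy.sweep_scan <- function(x, ...) {
  out <- tibble(position = x$grid_positions, statistic = x$statistic)
  if (!is.null(x$arg_alpha)) out$arg_alpha <- x$arg_alpha
  out
}

#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(statistic = x$statistic_name, max_value = x$max_value,
         max_position = x$max_position,
         n_grid = length(x$grid_positions))
}
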