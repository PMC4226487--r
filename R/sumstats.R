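#' Unfolded site frequency spectrum
#'
#' Counts of polymorphic sites by derived-allele count `j = 1..n-1`.
#' Ancestral states are known by construction in simulated data, so the
#' spectrum is unfolded; [fold_sfs()] is available for minor-allele folding
#' but is not used by the scan pipeline.
#'
#' @param h A [haplotype_matrix()].
#' @param normalized If `TRUE`, counts are scaled to proportions summing
#'   to 1 (when any site exists).
#' @return An object of class `site_sfs`: list with `counts` (length
#'   `n - 1`), `n`, `normalized`.
#' @export
#' @examples
#' m <- matrix(c(1,1,0,0, 0,1,1,0), nrow = 4)
#' h <- haplotype_matrix(m, c(100, 200), 1000)
#' site_sfs(h)$counts
site_sfs <- function(h, normalized = FALSE) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- n_chromosomes(h)
  k <- colSums(h$alleles)
  counts <- tabulate(k, nbins = n - 1)
  if (normalized && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(counts = as.numeric(counts), n = n,
                 normalized = normalized),
            class = "site_sfs")
}

#' @export
print.site_sfs <- function(x, ...) {
  cat(sprintf("%s SFS, n = %d, %s sites\n",
              if (x$normalized) "Normalized unfolded" else "Unfolded",
              x$n, format(sum(x$counts))))
  invisible(x)
}

#' @export
tidy.site_sfs <- function(x, ...) {
  tibble(derived_count = seq_len(x$n - 1), value = x$counts)
}

#' Fold a site frequency spectrum
#'
#' @param sfs A [site_sfs()].
#' @return A numeric vector of minor-allele-count classes `1..floor(n/2)`.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "site_sfs"))
  n <- sfs$n
  half <- floor(n / 2)
  out <- numeric(half)
  for (j in seq_len(n - 1)) {
    m <- min(j, n - j)
    out[m] <- out[m] + sfs$counts[j]
  }
  out
}

#' Pairwise nucleotide diversity per site
#'
#' `sum_sites 2 k (n - k) / (n (n - 1)) / L`, the average number of pairwise
#' differences per base pair.
#'
#' @param h A [haplotype_matrix()].
#' @return Per-site diversity (0 when there are no segregating sites).
#' @export
nuc_div <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- n_chromosomes(h)
  if (n < 2) abort("diversity needs at least 2 chromosomes")
  if (n_sites(h) == 0) return(0)
  k <- colSums(h$alleles)
  sum(2 * k * (n - k) / (n * (n - 1))) / h$L
}

#' Tajima's D
#'
#' The standard normalization of the difference between mean pairwise
#' differences and the Watterson estimate over the region. Undefined
#' (returned as `NA`) when there are no segregating sites.
#'
#' @param h A [haplotype_matrix()].
#' @return The D statistic, or `NA_real_` if `S = 0`.
#' @export
tajimas_d <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- n_chromosomes(h)
  S <- n_sites(h)
  if (S == 0) return(NA_real_)
  k <- colSums(h$alleles)
  pi_region <- sum(2 * k * (n - k) / (n * (n - 1)))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_region - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Watterson's theta per site
#'
#' @param h A [haplotype_matrix()].
#' @return `S / (a_{n-1} * L)`.
#' @export
theta_watterson <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- n_chromosomes(h)
  n_sites(h) / (sum(1 / seq_len(n - 1)) * h$L)
}

#' Pairwise linkage disequilibrium matrix
#'
#' Squared allelic correlation `r^2` between every pair of segregating
#' sites, from phased haplotype counts.
#'
#' @param h A [haplotype_matrix()].
#' @return An object of class `ld_matrix`: list with `r2` (S x S symmetric,
#'   unit diagonal) and `positions`.
#' @export
r2_matrix <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  if (n_sites(h) < 2) abort("LD needs at least 2 segregating sites")
  r2 <- suppressWarnings(cor(h$alleles))^2
  # monomorphic columns are excluded upstream, so cor is well defined
  diag(r2) <- 1
  structure(list(r2 = r2, positions = h$positions), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("r^2 matrix over %d sites\n", length(x$positions)))
  invisible(x)
}

#' Linkage-disequilibrium decay with physical distance
#'
#' Bins all site pairs by physical distance and reports the per-bin median,
#' mean and 95th percentile of `r^2`. Bins containing no pairs are kept in
#' the output with `NA` summaries (marked empty, not zero).
#'
#' @param ld An [r2_matrix()] result.
#' @param bin_width Bin width in base pairs.
#' @param max_distance Largest pair distance retained (defaults to the full
#'   span of the positions).
#' @return A tibble with one row per distance bin: `bin_mid`, `n_pairs`,
#'   `median_r2`, `mean_r2`, `q95_r2`.
#' @export
ld_decay <- function(ld, bin_width = 5000, max_distance = NULL) {
  stopifnot(inherits(ld, "ld_matrix"))
  S <- length(ld$positions)
  ut <- upper.tri(ld$r2)
  dmat <- abs(outer(ld$positions, ld$positions, "-"))
  d <- dmat[ut]
  v <- ld$r2[ut]
  if (is.null(max_distance)) max_distance <- max(d)
  breaks <- seq(0, max_distance + bin_width, by = bin_width)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tibble(
    bin_mid = head(breaks, -1) + bin_width / 2,
    n_pairs = as.integer(table(factor(bin, levels = levels(bin))))
  ) %>%
    mutate(
      median_r2 = as.numeric(tapply(v, factor(bin, levels = levels(bin)), median)),
      mean_r2 = as.numeric(tapply(v, factor(bin, levels = levels(bin)), mean)),
      q95_r2 = as.numeric(tapply(v, factor(bin, levels = levels(bin)),
                                 quantile, probs = 0.95))
    )
}

#' Per-replicate summary-statistic table
#'
#' One row per replicate with segregating sites, per-site diversity,
#' Watterson's theta and Tajima's D; the tab-separated export format of the
#' statistics interface.
#'
#' @param replicates A list of [haplotype_matrix()] objects.
#' @return A tibble with columns `replicate`, `S`, `pi`, `theta_w`, `D`.
#' @export
replicate_sumstats <- function(replicates) {
  purrr::map_dfr(seq_along(replicates), function(i) {
    h <- replicates[[i]]
    tibble(replicate = i, S = n_sites(h), pi = nuc_div(h),
           theta_w = theta_watterson(h), D = tajimas_d(h))
  })
}
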