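#' Omega statistic for one window and split
#'
#' The ratio of average within-block linkage disequilibrium (left and right
#' of a putative sweep site) to average cross-block LD:
#' `omega = [ (C(l,2) + C(S-l,2))^-1 (sum r2 left + sum r2 right) ] /
#'          [ (l (S-l))^-1 sum r2 across ]`.
#' A completed sweep leaves elevated LD on each flank but reduced LD across
#' the swept site, inflating omega there. Zero cross-block LD returns
#' `Inf` (reported as exceeding any finite threshold).
#'
#' @param ld An [r2_matrix()].
#' @param window_site_indices Indices (into `ld$positions`) of the window's
#'   sites, in order; at least 4.
#' @param ell Split index: sites `1..ell` form the left block,
#'   `ell+1..S_w` the right; `2 <= ell <= S_w - 2`.
#' @return The omega value (possibly `Inf`).
#' @export
#' @examples
#' # four sites, perfect LD within each flank, none across
#' m <- cbind(c(1,1,0,0), c(1,1,0,0), c(1,0,1,0), c(1,0,1,0))
#' h <- haplotype_matrix(m, c(1, 2, 10, 11), 20)
#' omega_at_split(r2_matrix(h), 1:4, 2)
omega_at_split <- function(ld, window_site_indices, ell) {
  stopifnot(inherits(ld, "ld_matrix"))
  idx <- window_site_indices
  Sw <- length(idx)
  if (Sw < 4) abort("omega needs at least 4 sites in the window")
  if (ell < 2 || ell > Sw - 2) abort("`ell` must satisfy 2 <= ell <= S_w - 2")
  left <- idx[seq_len(ell)]
  right <- idx[(ell + 1):Sw]
  sub <- function(i, j) ld$r2[i, j, drop = FALSE]
  sum_within <- function(i) {
    m <- sub(i, i)
    sum(m[upper.tri(m)])
  }
  w <- sum_within(left) + sum_within(right)
  npairs_w <- choose(ell, 2) + choose(Sw - ell, 2)
  across <- sum(sub(left, right))
  if (across <= 0) {
    return(if (w > 0) Inf else NA_real_)
  }
  (w / npairs_w) / (across / (ell * (Sw - ell)))
}

#' Omega-maximum sweep scan
#'
#' For each position on a physical grid, sites within `half_window` base
#' pairs on each side (nearest first, at most `max_side` per side) are split
#' at the position; omega is maximized over the number of sites retained on
#' each flank (every admissible window extent). The profile's maximum is
#' the region-wide `omega_max`.
#'
#' @param h A [haplotype_matrix()] with at least 4 segregating sites.
#' @param grid_spacing_bp Test-grid spacing in base pairs.
#' @param grid Optional explicit grid (overrides `grid_spacing_bp`).
#' @param half_window Maximum physical distance (bp) of a used site from
#'   the test position.
#' @param max_side Maximum number of sites per flank.
#' @param ld Optional precomputed [r2_matrix()].
#' @return A `sweep_scan` object (see [clr_scan()]); positions with fewer
#'   than 2 usable sites on either flank carry `NA`.
#' @export
#' @examples
#' p <- preset_model("nebraska")
#' h <- simulate_neutral_sample(p$demography, p$region, seed = 5)
#' sc <- omega_max_scan(h, grid_spacing_bp = 20000)
#' glance(sc)
omega_max_scan <- function(h, grid_spacing_bp = 1000, grid = NULL,
                           half_window = 25000, max_side = 50, ld = NULL) {
  stopifnot(inherits(h, "haplotype_matrix"))
  if (n_sites(h) < 4) {
    warn("fewer than 4 segregating sites: omega profile is all missing")
    if (is.null(grid)) grid <- seq(0, h$L, by = grid_spacing_bp)
    return(new_scan_result(grid, rep(NA_real_, length(grid)), NULL,
                           "omega", h$L))
  }
  if (is.null(ld)) ld <- r2_matrix(h)
  if (is.null(grid)) grid <- seq(0, h$L, by = grid_spacing_bp)
  stat <- .cpp_omega_scan(ld$r2, ld$positions, grid, half_window,
                          as.integer(max_side), 2L)
  if (all(is.na(stat))) {
    warn("no grid position had 2 usable sites on each flank")
  }
  new_scan_result(grid, stat, NULL, "omega", h$L)
}
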