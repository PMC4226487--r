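#' Calibrate a neutral significance threshold
#'
#' Simulates neutral replicates under the same demography, scans each one,
#' and takes the empirical `(1 - alpha_level)` quantile (the corresponding
#' order statistic) of the per-replicate maximum statistic as the cutoff.
#' When `target_theta_w` is supplied, the mutation rate of the null
#' simulations is first rescaled so that their expected Watterson's theta
#' matches it (estimated from a small pilot set), mirroring the practice of
#' fitting theta to the scanned data.
#'
#' With `method = "pooled"`, the cutoff is instead the quantile of all
#' per-position null statistic values pooled across replicates (a pointwise
#' threshold).
#'
#' @param model A [demographic_model()].
#' @param region A [region_config()].
#' @param study A [study_config()] (uses `n_null_replicates`, `alpha_level`,
#'   `grid_spacing_bp`, `seed`).
#' @param statistic `"clr"` or `"omega"`.
#' @param target_theta_w Optional per-site Watterson's theta to match.
#' @param method `"max"` (per-replicate maxima, the default) or `"pooled"`.
#' @param counter_offset Seed-counter offset separating this stream from
#'   the sweep replicates.
#' @param ... Passed to the scan ([clr_scan()] or [omega_max_scan()]).
#' @return An object of class `threshold_set`.
#' @export
calibrate_threshold <- function(model, region, study,
                                statistic = c("clr", "omega"),
                                target_theta_w = NULL,
                                method = c("max", "pooled"),
                                counter_offset = 2e6, ...) {
  statistic <- match.arg(statistic)
  calibrate_thresholds(model, region, study, statistics = statistic,
                       target_theta_w = target_theta_w, method = method,
                       counter_offset = counter_offset, ...)[[statistic]]
}

#' @rdname calibrate_threshold
#' @param statistics For `calibrate_thresholds`: the statistics to
#'   calibrate from one shared null-simulation set.
#' @export
calibrate_thresholds <- function(model, region, study,
                                 statistics = c("clr", "omega"),
                                 target_theta_w = NULL,
                                 method = c("max", "pooled"),
                                 counter_offset = 2e6, ...) {
  statistics <- match.arg(statistics, c("clr", "omega"), several.ok = TRUE)
  method <- match.arg(method)
  if (study$n_null_replicates < 20 && method == "max") {
    warn("fewer than 20 null replicates gives a very noisy tail quantile")
  }
  mu_use <- region$mu
  if (!is.null(target_theta_w)) {
    n_pilot <- min(30L, study$n_null_replicates)
    pilot <- simulate_replicates(
      n_pilot, study$seed,
      function(s) simulate_neutral_sample(model, region, s),
      counter_offset = counter_offset + 5e5
    )
    pilot_theta <- mean(purrr::map_dbl(pilot, theta_watterson))
    if (pilot_theta > 0) {
      mu_use <- region$mu * target_theta_w / pilot_theta
    } else {
      warn("pilot null replicates had no segregating sites; theta not fitted")
    }
  }
  nulls <- simulate_replicates(
    study$n_null_replicates, study$seed,
    function(s) simulate_neutral_sample(model, region, s, mu = mu_use),
    counter_offset = counter_offset
  )
  out <- list()
  for (statistic in statistics) {
    scans <- purrr::map(nulls, function(h) {
      scan_or_null(h, statistic, study, ...)
    })
    values <- if (method == "max") {
      purrr::map_dbl(scans, function(sc) {
        if (is.null(sc)) return(-Inf)
        m <- sc$max_value
        if (is.na(m)) -Inf else m
      })
    } else {
      unlist(purrr::map(scans, function(sc) {
        if (is.null(sc)) return(numeric(0))
        sc$statistic[!is.na(sc$statistic)]
      }))
    }
    cutoff <- order_stat_quantile(values, 1 - study$alpha_level)
    if (length(unique(values)) == 1) {
      warn("degenerate null sample: all calibration values identical")
    }
    out[[statistic]] <- structure(
      list(statistic = statistic, cutoff = cutoff,
           alpha_level = study$alpha_level,
           n_null_replicates = study$n_null_replicates,
           method = method, mu_used = mu_use,
           model = unclass(model)),
      class = "threshold_set"
    )
  }
  out
}

# scan wrapper tolerating replicates with too few sites
scan_or_null <- function(h, statistic, study, ...) {
  grid <- seq(0, h$L, by = study$grid_spacing_bp)
  if (statistic == "clr") {
    if (n_sites(h) < 1) return(NULL)
    clr_scan(h, grid = grid, ...)
  } else {
    if (n_sites(h) < 4) return(NULL)
    suppressWarnings(omega_max_scan(h, grid = grid, ...))
  }
}

# empirical quantile as an order statistic (inverse ECDF)
order_stat_quantile <- function(x, p) {
  x <- sort(x)  # Inf sorts last; NA removed upstream
  if (length(x) == 0) return(Inf)
  x[max(1L, ceiling(p * length(x)))]
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("%s threshold (%s method): cutoff %s at alpha = %g from %d null replicates\n",
              toupper(x$statistic), x$method, format(x$cutoff, digits = 4),
              x$alpha_level, x$n_null_replicates))
  invisible(x)
}

#' @export
tidy.threshold_set <- function(x, ...) {
  tibble(statistic = x$statistic, cutoff = x$cutoff,
         alpha_level = x$alpha_level,
         n_null_replicates = x$n_null_replicates, method = x$method)
}

#' Classify one scanned replicate as true/false positive
#'
#' A replicate is a true positive when some grid position with statistic
#' above the cutoff lies within the window of width `tp_window_bp` centred
#' on the selected site, and a false positive when some such position lies
#' outside it; one replicate can be both.
#'
#' @param scan A `sweep_scan` (from [clr_scan()] or [omega_max_scan()]).
#' @param threshold A [calibrate_threshold()] result.
#' @param x_sel Selected-site position, base pairs.
#' @param tp_window_bp Full window width, base pairs.
#' @return A tibble with logical columns `is_tp` and `is_fp`.
#' @export
classify_replicate <- function(scan, threshold, x_sel, tp_window_bp = 10000) {
  stopifnot(inherits(threshold, "threshold_set"))
  if (is.null(scan)) return(tibble(is_tp = FALSE, is_fp = FALSE))
  stopifnot(inherits(scan, "sweep_scan"))
  sig <- !is.na(scan$statistic) & scan$statistic > threshold$cutoff
  inside <- abs(scan$grid_positions - x_sel) <= tp_window_bp / 2
  tibble(is_tp = any(sig & inside), is_fp = any(sig & !inside))
}

#' Approximate physical extent of a sweep footprint
#'
#' The classical hitchhiking approximation `0.01 * s / r` base pairs for
#' the width of the region dragged by a sweep with selection coefficient
#' `s` under per-site recombination rate `r`; the basis of the 10 kb
#' true-positive window.
#'
#' @param s Selection coefficient.
#' @param r Per-site recombination rate (> 0).
#' @return Width in base pairs.
#' @export
#' @examples
#' expected_sweep_width(0.1, 5.6e-7)  # ~1786 bp
expected_sweep_width <- function(s, r) {
  if (!is.numeric(r) || r <= 0) abort("`r` must be positive (division by zero)")
  if (!is.numeric(s) || s <= 0) abort("`s` must be positive")
  0.01 * s / r
}

#' Run a Monte-Carlo power study
#'
#' For each cell of a parameter grid: simulate sweep replicates, calibrate
#' the neutral threshold for each statistic (with theta fitted to the sweep
#' replicates), scan, classify, and tabulate true- and false-positive
#' percentages. Also computes localization curves: the fraction of
#' replicates with a significant point within a window of varying width
#' around the target.
#'
#' @param cells Named list; each element is a list with components
#'   `demography`, `region`, `sweep`.
#' @param study A [study_config()].
#' @param statistics Character subset of `c("clr", "omega")`.
#' @param fp_mode `"sweep"`: false positives are counted on the sweep
#'   replicates, outside the target window (the definition used for the
#'   power tables); `"neutral"`: on a matched fresh neutral replicate set.
#' @param theta_fit Fit the null mutation rate to the sweep replicates'
#'   Watterson theta (see [calibrate_threshold()]).
#' @param threshold_method `"max"` or `"pooled"`.
#' @param curve_windows_bp Window widths (bp) for the localization curves.
#' @param ... Scan options passed through.
#' @return A tibble of class `power_table` with one row per cell and
#'   statistic: `cell`, `N_anc`, `f`, `s`, `tau`, `statistic`, `tp_pct`,
#'   `fp_pct`, `n_replicates`, `n_failed`, `cutoff`. The localization
#'   curves are in `attr(, "curves")`.
#' @export
run_power_study <- function(cells, study, statistics = c("clr", "omega"),
                            fp_mode = c("sweep", "neutral"),
                            theta_fit = TRUE,
                            threshold_method = c("max", "pooled"),
                            curve_windows_bp = c(2e3, 5e3, 1e4, 2e4, 4e4,
                                                 8e4, 16e4),
                            ...) {
  fp_mode <- match.arg(fp_mode)
  threshold_method <- match.arg(threshold_method)
  if (study$n_replicates == 0) {
    out <- tibble(cell = character(0), N_anc = numeric(0), f = numeric(0),
                  s = numeric(0), tau = numeric(0), statistic = character(0),
                  tp_pct = numeric(0), fp_pct = numeric(0),
                  n_replicates = integer(0), n_failed = integer(0),
                  cutoff = numeric(0))
    class(out) <- c("power_table", class(out))
    attr(out, "curves") <- tibble(cell = character(0),
                                  statistic = character(0),
                                  window_bp = numeric(0),
                                  fraction = numeric(0))
    return(out)
  }
  rows <- list()
  curves <- list()
  for (cell_name in names(cells)) {
    cell <- cells[[cell_name]]
    dem <- cell$demography
    region <- cell$region
    sweep <- cell$sweep
    reps <- vector("list", study$n_replicates)
    for (i in seq_len(study$n_replicates)) {
      sd <- derive_seed(study$seed, i - 1)
      reps[[i]] <- tryCatch(
        simulate_sweep_sample(dem, sweep, region, sd),
        error = function(e) {
          warn(paste0("cell ", cell_name, " replicate ", i, " failed: ",
                      conditionMessage(e)))
          NULL
        })
    }
    ok <- !purrr::map_lgl(reps, is.null)
    target_theta <- if (theta_fit && any(ok)) {
      mean(purrr::map_dbl(reps[ok], theta_watterson))
    } else NULL
    extra_bg <- study$extra_neutral_regions
    thrs <- calibrate_thresholds(dem, region, study, statistics,
                                 target_theta_w = target_theta,
                                 method = threshold_method, ...)
    for (stat in statistics) {
      thr <- thrs[[stat]]
      scans <- purrr::map(reps, function(h) {
        if (is.null(h)) return(NULL)
        extras <- list()
        if (stat == "clr" && extra_bg > 0) {
          extras <- simulate_replicates(
            extra_bg, derive_seed(study$seed, 3.5e6 + h$metadata$seed %||% 0),
            function(s) simulate_neutral_sample(dem, region, s))
          return(scan_or_null_bg(h, stat, study, extras, ...))
        }
        scan_or_null(h, stat, study, ...)
      })
      cls <- purrr::map_dfr(scans, classify_replicate, threshold = thr,
                            x_sel = sweep$x_sel,
                            tp_window_bp = study$tp_window_bp)
      fp_pct <- if (fp_mode == "sweep") {
        100 * mean(cls$is_fp)
      } else {
        neutral <- simulate_replicates(
          study$n_replicates, study$seed,
          function(s) simulate_neutral_sample(dem, region, s),
          counter_offset = 4e6)
        nscans <- purrr::map(neutral, scan_or_null, statistic = stat,
                             study = study, ...)
        ncls <- purrr::map_dfr(nscans, classify_replicate, threshold = thr,
                               x_sel = sweep$x_sel,
                               tp_window_bp = study$tp_window_bp)
        100 * mean(ncls$is_fp | ncls$is_tp)
      }
      rows[[length(rows) + 1]] <- tibble(
        cell = cell_name, N_anc = dem$N_anc, f = dem$f,
        s = sweep$s, tau = sweep$tau, statistic = stat,
        tp_pct = 100 * mean(cls$is_tp), fp_pct = fp_pct,
        n_replicates = study$n_replicates, n_failed = sum(!ok),
        cutoff = thr$cutoff)
      for (w in curve_windows_bp) {
        frac <- mean(purrr::map_lgl(scans, function(sc) {
          if (is.null(sc)) return(FALSE)
          sig <- !is.na(sc$statistic) & sc$statistic > thr$cutoff
          any(sig & abs(sc$grid_positions - sweep$x_sel) <= w / 2)
        }))
        curves[[length(curves) + 1]] <- tibble(
          cell = cell_name, statistic = stat, window_bp = w,
          fraction = frac)
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("power_table", class(out))
  attr(out, "curves") <- bind_rows(curves)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scan with an explicit extra-region background (larger-background option)
scan_or_null_bg <- function(h, statistic, study, extras, ...) {
  if (statistic != "clr" || n_sites(h) < 1) {
    return(scan_or_null(h, statistic, study, ...))
  }
  grid <- seq(0, h$L, by = study$grid_spacing_bp)
  clr_scan(h, background = background_spectrum(h, extras), grid = grid, ...)
}

#' Localization curves of a power table
#'
#' @param x A [run_power_study()] result.
#' @return The tibble of fraction-rejecting-versus-window-width curves.
#' @export
rejection_curves <- function(x) {
  stopifnot(inherits(x, "power_table"))
  attr(x, "curves")
}
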