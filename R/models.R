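#' Piecewise-constant demographic model with a recent bottleneck
#'
#' Describes a population that diverged from an ancestral population of
#' `N_anc` diploids at time `d`, was immediately reduced to `f * N_anc`
#' (the bottleneck phase), and recovered to `c_recovery * N_anc` at time
#' `t_r`. All times are in units of `2 * N_anc` generations before sampling,
#' so the size history backward in time is: `c_recovery * N_anc` on
#' `[0, t_r)`, `f * N_anc` on `[t_r, d)`, and `N_anc` before `d`.
#'
#' @param N_anc Ancestral diploid effective population size (>= 2).
#' @param f Bottleneck severity: ratio of bottleneck-phase size to `N_anc`,
#'   in (0, 1].
#' @param c_recovery Ratio of contemporary to ancestral size. Values > 1
#'   (an overshooting recovery) are accepted with a warning.
#' @param d Divergence / bottleneck-onset time, in `2 * N_anc` generations.
#' @param t_r Recovery time, in `2 * N_anc` generations; `0 <= t_r < d`.
#'
#' @return An object of class `demographic_model`.
#' @seealso [preset_model()], [region_config()], [sweep_model()]
#' @export
#' @examples
#' demographic_model(N_anc = 2482, f = 0.001, c_recovery = 0.413,
#'                   d = 1.225, t_r = 0.01)
demographic_model <- function(N_anc, f, c_recovery, d, t_r) {
  if (!is.numeric(N_anc) || N_anc < 2) {
    abort("`N_anc` must be a number >= 2 (diploid individuals)")
  }
  if (!is.numeric(f) || f <= 0 || f > 1) {
    abort("`f` (bottleneck severity) must be in (0, 1]")
  }
  if (!is.numeric(c_recovery) || c_recovery <= 0) {
    abort("`c_recovery` must be positive")
  }
  if (c_recovery > 1) {
    warn("`c_recovery` > 1: contemporary size exceeds the ancestral size")
  }
  if (!is.numeric(d) || !is.numeric(t_r) || t_r < 0 || t_r >= d) {
    abort("times must satisfy 0 <= t_r < d (units of 2*N_anc generations)")
  }
  structure(
    list(N_anc = as.numeric(N_anc), f = as.numeric(f),
         c_recovery = as.numeric(c_recovery), d = as.numeric(d),
         t_r = as.numeric(t_r)),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model (times in 2*N_anc generations before sampling)\n")
  cat(sprintf("  N_anc = %g diploids; bottleneck f = %g from d = %g to t_r = %g; recovery c = %g\n",
              x$N_anc, x$f, x$d, x$t_r, x$c_recovery))
  invisible(x)
}

#' Hard-sweep model
#'
#' A single de novo beneficial mutation at physical position `x_sel`, with
#' selection coefficient `s`, that reached fixation `tau` time units
#' (`2 * N_anc` generations) before sampling. The sweep runs inside the
#' bottleneck phase of its paired [demographic_model()].
#'
#' @param s Selection coefficient per generation (> 0).
#' @param tau Fixation time of the beneficial allele, in `2 * N_anc`
#'   generations before sampling.
#' @param x_sel Physical position of the selected site in base pairs.
#'
#' @return An object of class `sweep_model`.
#' @export
#' @examples
#' sweep_model(s = 0.01, tau = 0.1, x_sel = 90000)
sweep_model <- function(s, tau, x_sel = 90000) {
  if (!is.numeric(s) || s <= 0) abort("`s` must be positive")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive")
  if (!is.numeric(x_sel) || x_sel < 0) abort("`x_sel` must be non-negative")
  structure(list(s = as.numeric(s), tau = as.numeric(tau),
                 x_sel = as.numeric(x_sel)),
            class = "sweep_model")
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(sprintf("Hard sweep: s = %g, fixed tau = %g x 2N generations ago, at %g bp\n",
              x$s, x$tau, x$x_sel))
  invisible(x)
}

#' Simulated-region configuration
#'
#' @param L Region length in base pairs.
#' @param n Sample size in chromosomes (2 to 128).
#' @param mu Per-site per-generation mutation rate.
#' @param r Per-site per-generation recombination rate.
#'
#' @return An object of class `region_config`.
#' @export
#' @examples
#' region_config()  # the 180 kb, n = 40 mouse-locus defaults
region_config <- function(L = 180000, n = 40, mu = 3.7e-8, r = 5.6e-7) {
  if (!is.numeric(L) || L <= 0) abort("`L` must be positive")
  if (!is.numeric(n) || n < 2 || n > 128) abort("`n` must be in [2, 128] chromosomes")
  if (!is.numeric(mu) || mu < 0 || !is.numeric(r) || r < 0) {
    abort("`mu` and `r` must be non-negative")
  }
  structure(list(L = as.numeric(L), n = as.integer(n),
                 mu = as.numeric(mu), r = as.numeric(r)),
            class = "region_config")
}

#' Study configuration for power experiments
#'
#' @param n_replicates Number of sweep replicates per parameter combination.
#' @param n_null_replicates Number of neutral replicates for threshold
#'   calibration.
#' @param seed Master integer seed; per-replicate seeds are derived by a
#'   counter scheme (see [derive_seed()]).
#' @param grid_spacing_bp Spacing of the scan grid in base pairs.
#' @param tp_window_bp Width of the true-positive window centred on the
#'   selected site, in base pairs.
#' @param alpha_level Tail probability for the neutral significance cutoff.
#' @param extra_neutral_regions Number of additional neutral regions of the
#'   same length pooled into the background spectrum.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_replicates = 100, n_null_replicates = 1000,
                         seed = 1L, grid_spacing_bp = 1000,
                         tp_window_bp = 10000, alpha_level = 0.05,
                         extra_neutral_regions = 0) {
  if (n_replicates < 0) abort("`n_replicates` must be >= 0")
  if (n_null_replicates < 1) abort("`n_null_replicates` must be >= 1")
  if (alpha_level <= 0 || alpha_level >= 1) abort("`alpha_level` must be in (0, 1)")
  if (tp_window_bp <= 0) abort("`tp_window_bp` must be positive")
  structure(list(n_replicates = as.integer(n_replicates),
                 n_null_replicates = as.integer(n_null_replicates),
                 seed = as.integer(seed),
                 grid_spacing_bp = as.numeric(grid_spacing_bp),
                 tp_window_bp = as.numeric(tp_window_bp),
                 alpha_level = as.numeric(alpha_level),
                 extra_neutral_regions = as.integer(extra_neutral_regions)),
            class = "study_config")
}

#' Preset demographic models for the two mouse populations
#'
#' `"florida"` and `"nebraska"` carry the estimated parameters of the Gulf
#' Coast beach-mouse and Sand Hills deer-mouse histories; `"florida-table2"`
#' and `"nebraska-table2"` are the rounded variants used in the power study
#' (ancestral sizes 2500 and 50000, recovery at 0.1 rather than 0.01).
#' The `nebraska-table2` divergence time is set to 0.5 so that sweeps fixing
#' up to `tau = 0.3` complete inside the bottleneck phase; the estimated
#' divergence of 0.067 is older than neither of the studied fixation times
#' and cannot host them.
#'
#' @param name One of `"florida"`, `"nebraska"`, `"florida-table2"`,
#'   `"nebraska-table2"`.
#'
#' @return A list with components `demography` ([demographic_model()]) and
#'   `region` ([region_config()]).
#' @export
#' @examples
#' preset_model("florida")$demography
preset_model <- function(name) {
  presets <- list(
    "florida" = list(N_anc = 2482, f = 0.001, c_recovery = 0.413,
                     d = 1.225, t_r = 0.01),
    "nebraska" = list(N_anc = 53080, f = 0.004, c_recovery = 0.662,
                      d = 0.067, t_r = 0.01),
    "florida-table2" = list(N_anc = 2500, f = 0.001, c_recovery = 0.413,
                            d = 1.225, t_r = 0.1),
    "nebraska-table2" = list(N_anc = 50000, f = 0.004, c_recovery = 0.662,
                             d = 0.5, t_r = 0.1)
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets)) {
    abort(paste0("unknown preset '", paste(name, collapse = ","),
                 "'; valid presets: ",
                 paste(names(presets), collapse = ", ")))
  }
  p <- presets[[name]]
  list(
    demography = demographic_model(p$N_anc, p$f, p$c_recovery, p$d, p$t_r),
    region = region_config()
  )
}

#' Expected pairwise diversity of the ancestral population
#'
#' The population-scaled mutation rate per site, `4 * N_anc * mu`, which is
#' the expected pairwise nucleotide diversity of the ancestral population at
#' equilibrium.
#'
#' @param model A [demographic_model()].
#' @param region A [region_config()].
#' @return The dimensionless rate `4 * N_anc * mu`.
#' @export
#' @examples
#' p <- preset_model("florida")
#' theta_per_site(p$demography, p$region)  # ~3.67e-4
theta_per_site <- function(model, region) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(region, "region_config"))
  4 * model$N_anc * region$mu
}

#' Time-unit conversions
#'
#' Model times are in units of `2 * N_anc` generations. `time_to_generations`
#' converts to raw generations; `time_to_ms_units` converts to the `ms`
#' convention of `4 * N` generations (divide by 2);
#' `generations_to_time` inverts the first.
#'
#' @param t Time in `2 * N_anc` generations (or raw generations for
#'   `generations_to_time`).
#' @param model A [demographic_model()] supplying `N_anc`.
#' @return A numeric time in the target unit.
#' @export
time_to_generations <- function(t, model) {
  stopifnot(inherits(model, "demographic_model"))
  t * 2 * model$N_anc
}

#' @rdname time_to_generations
#' @export
generations_to_time <- function(t, model) {
  stopifnot(inherits(model, "demographic_model"))
  t / (2 * model$N_anc)
}

#' @rdname time_to_generations
#' @export
time_to_ms_units <- function(t) t / 2

#' Derive a per-replicate seed from a master seed
#'
#' A fixed counter scheme (`(master * 69069 + counter * 1234567) mod
#' (2^31 - 1)`, kept strictly positive) so that replicate streams are
#' reproducible and non-overlapping in practice.
#'
#' @param master Master integer seed.
#' @param counter Replicate counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 69069 +
                as.numeric(counter) * 1234567) %% 2147483647 + 1)
}

#' Write and read plain-text model configurations
#'
#' Serializes demographic, sweep, region and study configurations as
#' `key = value` lines; [read_model_config()] restores them. Round-tripping
#' any preset yields identical field values.
#'
#' @param config A named list whose elements are any of
#'   [demographic_model()], [sweep_model()], [region_config()],
#'   [study_config()].
#' @param path File to write to / read from.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns the restored list.
#' @export
write_model_config <- function(config, path) {
  classes <- c(demography = "demographic_model", sweep = "sweep_model",
               region = "region_config", study = "study_config")
  lines <- character(0)
  for (nm in names(config)) {
    obj <- config[[nm]]
    cls <- class(obj)[1]
    lines <- c(lines, paste0("[", nm, ":", cls, "]"))
    for (fld in names(obj)) {
      lines <- c(lines, sprintf("%s = %.17g", fld, as.numeric(obj[[fld]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  current <- NULL
  cls <- NULL
  fields <- list()
  flush <- function(out, current, cls, fields) {
    if (is.null(current)) return(out)
    maker <- switch(cls,
      demographic_model = function(f) demographic_model(f$N_anc, f$f, f$c_recovery, f$d, f$t_r),
      sweep_model = function(f) sweep_model(f$s, f$tau, f$x_sel),
      region_config = function(f) region_config(f$L, f$n, f$mu, f$r),
      study_config = function(f) study_config(f$n_replicates, f$n_null_replicates,
                                              f$seed, f$grid_spacing_bp,
                                              f$tp_window_bp, f$alpha_level,
                                              f$extra_neutral_regions),
      abort(paste0("unknown config section class '", cls, "'")))
    out[[current]] <- maker(fields)
    out
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      out <- flush(out, current, cls, fields)
      hdr <- strsplit(gsub("^\\[|\\]$", "", ln), ":", fixed = TRUE)[[1]]
      current <- hdr[1]
      cls <- hdr[2]
      fields <- list()
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      fields[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    }
  }
  flush(out, current, cls, fields)
}
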