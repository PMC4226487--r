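#' Haplotype sample container
#'
#' An `n x S` binary matrix of phased haplotypes (0 = ancestral, 1 = derived)
#' with strictly increasing physical positions in `[0, L)`. This is the
#' exchange object every statistic consumes; [read_ms()] and [write_ms()]
#' translate it to and from Hudson `ms` text.
#'
#' Monomorphic columns are dropped on construction so that every retained
#' column has derived count in `[1, n - 1]`.
#'
#' @param alleles Integer/numeric matrix of 0/1 with `n` rows (haplotypes).
#' @param positions Numeric vector of physical positions, one per column.
#' @param L Region length in base pairs.
#' @param metadata Optional named list recording provenance (model, seed).
#'
#' @return An object of class `haplotype_matrix` with elements `alleles`,
#'   `positions`, `L`, `metadata`.
#' @export
haplotype_matrix <- function(alleles, positions, L, metadata = list()) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L))) abort("`alleles` must be a 0/1 matrix")
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles)) {
    abort("`positions` must have one entry per column of `alleles`")
  }
  if (any(positions < 0 | positions >= L)) {
    abort("positions must lie in [0, L)")
  }
  o <- order(positions)
  positions <- positions[o]
  alleles <- alleles[, o, drop = FALSE]
  # nudge measure-zero collisions upward by the smallest increment
  if (ncol(alleles) > 1) {
    for (j in 2:length(positions)) {
      if (positions[j] <= positions[j - 1]) {
        positions[j] <- positions[j - 1] +
          max(.Machine$double.eps * positions[j - 1], 1e-9)
      }
    }
  }
  n <- nrow(alleles)
  k <- colSums(alleles)
  keep <- k >= 1 & k <= n - 1
  structure(
    list(alleles = alleles[, keep, drop = FALSE],
         positions = positions[keep], L = as.numeric(L),
         metadata = metadata),
    class = "haplotype_matrix"
  )
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("Haplotype sample: %d chromosomes, %d segregating sites, %g bp region\n",
              nrow(x$alleles), ncol(x$alleles), x$L))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Number of segregating sites
#' @param h A [haplotype_matrix()].
#' @return Integer count of polymorphic columns.
#' @export
n_sites <- function(h) ncol(h$alleles)

#' Sample size in chromosomes
#' @param h A [haplotype_matrix()].
#' @return Integer number of haplotypes.
#' @export
n_chromosomes <- function(h) nrow(h$alleles)

# internal: epoch description in generations / chromosome counts
epochs_from_model <- function(model) {
  N2 <- 2 * model$N_anc
  list(
    end = c(model$t_r * N2, model$d * N2, Inf),
    size = c(model$c_recovery * N2, model$f * N2, N2)
  )
}

#' Beneficial-allele frequency trajectory conditioned on fixation
#'
#' Generates the frequency path of the beneficial allele through the
#' bottleneck-phase population of size `N_b = f * N_anc`. The default
#' stochastic mode runs a per-generation Wright-Fisher walk with selection,
#' rejection-conditioned on fixation, which is essential when `N_b` is a
#' handful of individuals and drift dominates. The deterministic logistic
#' mode is available (and selected by `"auto"`) when `2 * N_b * s > 100`.
#'
#' The path is laid onto the timeline so that fixation occurs exactly at
#' `sweep$tau`; the implied origin must predate neither the divergence `d`
#' nor follow it.
#'
#' @param model A [demographic_model()].
#' @param sweep A [sweep_model()].
#' @param seed Optional integer seed.
#' @param mode `"auto"`, `"stochastic"` or `"deterministic"`.
#'
#' @return An object of class `trajectory_path`: list with `times`
#'   (increasing, `2 * N_anc` generations before sampling, starting at
#'   `tau`), `freqs` (frequency at each time; 1 at fixation, `1/(2 N_b)` at
#'   the origin), `origin_time`, `fixation_time`.
#' @export
#' @examples
#' p <- preset_model("nebraska-table2")
#' tr <- simulate_trajectory(p$demography, sweep_model(0.1, 0.1), seed = 1)
#' range(tr$freqs)
simulate_trajectory <- function(model, sweep, seed = NULL,
                                mode = c("auto", "stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "demographic_model"), inherits(sweep, "sweep_model"))
  N2b <- round(2 * model$N_anc * model$f)
  if (N2b < 2) {
    abort("bottleneck population has fewer than one diploid individual (N_b < 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (mode == "auto") {
    mode <- if (N2b * sweep$s > 100) "deterministic" else "stochastic"
  }
  freqs_back <- if (mode == "deterministic") {
    .cpp_trajectory_logistic(N2b, sweep$s)
  } else {
    .cpp_trajectory_wf(N2b, sweep$s)
  }
  N2 <- 2 * model$N_anc
  g <- length(freqs_back)
  times <- sweep$tau + (0:g) / N2
  origin_time <- sweep$tau + g / N2
  if (origin_time > model$d) {
    abort(paste0("the sweep needs ", g, " generations and would originate at ",
                 signif(origin_time, 4), " x 2N, before the divergence d = ",
                 model$d, "; raise s or shorten tau"))
  }
  structure(
    list(times = times, freqs = c(1, as.numeric(freqs_back)),
         origin_time = origin_time, fixation_time = sweep$tau,
         mode = mode, N2b = N2b),
    class = "trajectory_path"
  )
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat(sprintf("Conditioned trajectory (%s): fixation at %g, origin at %g x 2N generations; %d generations\n",
              x$mode, x$fixation_time, x$origin_time, length(x$freqs) - 1))
  invisible(x)
}

# internal common simulation driver
simulate_sample_internal <- function(model, region, seed, traj_back = numeric(0),
                                     tau = NA_real_, x_sel = NA_real_,
                                     mu = NULL, metadata = list()) {
  ep <- epochs_from_model(model)
  N2 <- 2 * model$N_anc
  if (!is.null(seed)) set.seed(seed)
  mu_use <- if (is.null(mu)) region$mu else mu
  res <- .cpp_simulate(region$n, region$L, mu_use, region$r,
                       ep$end, ep$size,
                       if (length(traj_back)) tau * N2 else -1,
                       traj_back,
                       if (is.na(x_sel)) 0 else x_sel,
                       max(2L, as.integer(round(N2 * model$f))))
  haplotype_matrix(res$alleles, res$positions, region$L, metadata = metadata)
}

#' Simulate a neutral bottleneck sample
#'
#' Backward-in-time coalescent with recombination under the piecewise-
#' constant demography of `model`; infinite-sites mutations with continuous
#' uniform positions.
#'
#' @param model A [demographic_model()].
#' @param region A [region_config()].
#' @param seed Integer seed (required for reproducibility).
#' @param mu Optional mutation-rate override (used by the
#'   theta-fitting step of [calibrate_threshold()]).
#'
#' @return A [haplotype_matrix()].
#' @export
#' @examples
#' p <- preset_model("florida")
#' h <- simulate_neutral_sample(p$demography, p$region, seed = 7)
#' n_sites(h)
simulate_neutral_sample <- function(model, region, seed, mu = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(region, "region_config"))
  simulate_sample_internal(
    model, region, seed, mu = mu,
    metadata = list(kind = "neutral", model = unclass(model), seed = seed)
  )
}

#' Simulate a sample that experienced a hard selective sweep
#'
#' Structured coalescent with recombination: during the sweep phase lineages
#' are labelled by background (linked to the beneficial allele or not);
#' coalescence within the beneficial background happens in a subpopulation
#' of size `2 N_b x(t)` chromosomes and within the wild-type background in
#' `2 N_b (1 - x(t))`, with `x(t)` the conditioned allele-frequency
#' trajectory; recombination between a lineage's material and the selected
#' site moves it between backgrounds with probability `x(t)`. Outside the
#' sweep phase the process is the neutral coalescent under the piecewise
#' demography.
#'
#' The sweep must fix inside the bottleneck phase: `t_r <= tau < d`.
#'
#' @param model A [demographic_model()].
#' @param sweep A [sweep_model()].
#' @param region A [region_config()].
#' @param seed Integer seed.
#' @param trajectory Optional precomputed [simulate_trajectory()] result;
#'   by default a fresh conditioned trajectory is drawn from `seed`.
#' @param mu Optional mutation-rate override.
#'
#' @return A [haplotype_matrix()].
#' @export
#' @examples
#' p <- preset_model("florida-table2")
#' h <- simulate_sweep_sample(p$demography, sweep_model(0.01, 0.1),
#'                            p$region, seed = 11)
simulate_sweep_sample <- function(model, sweep, region, seed,
                                  trajectory = NULL, mu = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(sweep, "sweep_model"),
            inherits(region, "region_config"))
  if (sweep$x_sel > region$L) abort("`x_sel` must lie within the region")
  if (sweep$tau < model$t_r || sweep$tau >= model$d) {
    abort("the sweep must fix inside the bottleneck phase: t_r <= tau < d")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trajectory)) {
    trajectory <- simulate_trajectory(model, sweep)
  }
  if (trajectory$origin_time > model$d) {
    abort("sweep trajectory originates before the divergence; raise s or shorten tau")
  }
  # backward path excluding the fixed state
  traj_back <- trajectory$freqs[-1]
  simulate_sample_internal(
    model, region, seed = NULL, traj_back = traj_back,
    tau = sweep$tau, x_sel = sweep$x_sel, mu = mu,
    metadata = list(kind = "sweep", model = unclass(model),
                    sweep = unclass(sweep), seed = seed,
                    trajectory_generations = length(traj_back))
  )
  # seed was consumed above, so trajectory and genealogy share one stream
}

#' Simulate many replicates
#'
#' Convenience wrapper deriving one seed per replicate from a master seed
#' (see [derive_seed()]) and returning a list of [haplotype_matrix()]
#' objects.
#'
#' @param n_replicates Number of replicates.
#' @param master_seed Master seed.
#' @param simulate_fn Function of a single integer seed returning a
#'   [haplotype_matrix()].
#' @param counter_offset Offset added to the replicate counter, so that
#'   disjoint replicate sets can be drawn from one master seed.
#' @return A list of [haplotype_matrix()] objects.
#' @export
simulate_replicates <- function(n_replicates, master_seed, simulate_fn,
                                counter_offset = 0) {
  lapply(seq_len(n_replicates), function(i) {
    simulate_fn(derive_seed(master_seed, counter_offset + i - 1))
  })
}
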