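#' Write haplotype samples in Hudson `ms` text format
#'
#' Emits the classical coalescent-simulator dialect: a command-echo line, a
#' seeds line, then for each replicate a blank line, `//`, `segsites: S`, a
#' `positions:` line with positions as fractions of the region length
#' (8 decimal places), and `n` rows of 0/1 characters. Replicates with no
#' segregating sites carry no positions line.
#'
#' @param replicates A [haplotype_matrix()] or list of them (all with the
#'   same sample size).
#' @param file Optional path; when `NULL` the lines are returned.
#' @param header Command echo recorded on the first line.
#' @param seeds Integer vector written on the seeds line.
#' @return The character vector of lines, invisibly when writing to a file.
#' @export
#' @examples
#' h <- haplotype_matrix(matrix(c(1, 0), 2), 90000, 180000)
#' cat(write_ms(h), sep = "\n")
write_ms <- function(replicates, file = NULL, header = NULL, seeds = NULL) {
  if (inherits(replicates, "haplotype_matrix")) replicates <- list(replicates)
  ns <- vapply(replicates, n_chromosomes, integer(1))
  if (length(unique(ns)) > 1) {
    abort("all replicates must have the same number of chromosomes")
  }
  if (is.null(header)) {
    header <- sprintf("sweeppower %d %d", ns[1], length(replicates))
  }
  if (is.null(seeds)) {
    seeds <- vapply(replicates,
                    function(h) as.integer(h$metadata$seed %||% 0L),
                    integer(1))[1]
  }
  lines <- c(header, paste(seeds, collapse = " "))
  for (h in replicates) {
    lines <- c(lines, "", "//", sprintf("segsites: %d", n_sites(h)))
    if (n_sites(h) > 0) {
      lines <- c(lines,
                 paste("positions:",
                       paste(sprintf("%.8f", h$positions / h$L),
                             collapse = " ")),
                 apply(h$alleles, 1, paste, collapse = ""))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read Hudson `ms`-format text
#'
#' Parses the dialect written by [write_ms()] (and by `ms`-compatible
#' simulators): positions are rescaled from fractions of the region to base
#' pairs by multiplying by `L`. Malformed input (position count differing
#' from `segsites`, ragged or non-binary haplotype rows) raises an error
#' naming the offending line.
#'
#' @param input A file path or a character vector of lines.
#' @param L Region length in base pairs.
#' @return A list of [haplotype_matrix()] objects.
#' @export
read_ms <- function(input, L) {
  lines <- if (length(input) == 1 && file.exists(input)) {
    readLines(input)
  } else {
    as.character(input)
  }
  reps <- list()
  i <- 1
  n_lines <- length(lines)
  # skip header and seed lines: everything before the first "//"
  while (i <= n_lines && !startsWith(trimws(lines[i]), "//")) i <- i + 1
  while (i <= n_lines) {
    if (!startsWith(trimws(lines[i]), "//")) { i <- i + 1; next }
    i <- i + 1
    while (i <= n_lines && !nzchar(trimws(lines[i]))) i <- i + 1
    if (i > n_lines || !grepl("^segsites:", trimws(lines[i]))) {
      abort(paste0("line ", i, ": expected 'segsites:' after '//'"))
    }
    S <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", trimws(lines[i]))))
    if (is.na(S)) abort(paste0("line ", i, ": unparseable segsites count"))
    i <- i + 1
    positions <- numeric(0)
    if (S > 0) {
      if (i > n_lines || !grepl("^positions:", trimws(lines[i]))) {
        abort(paste0("line ", i, ": expected 'positions:' line"))
      }
      positions <- suppressWarnings(as.numeric(strsplit(
        sub("^positions:\\s*", "", trimws(lines[i])), "\\s+")[[1]]))
      if (anyNA(positions) || length(positions) != S) {
        abort(paste0("line ", i, ": expected ", S,
                     " numeric positions, found ", length(positions)))
      }
      i <- i + 1
    }
    rows <- character(0)
    while (i <= n_lines && grepl("^[01]+$", trimws(lines[i]))) {
      rows <- c(rows, trimws(lines[i]))
      i <- i + 1
    }
    if (S > 0) {
      if (length(rows) == 0) abort(paste0("line ", i, ": no haplotype rows"))
      widths <- nchar(rows)
      if (length(unique(widths)) != 1 || widths[1] != S) {
        abort(paste0("line ", i - length(rows),
                     ": ragged haplotype rows or width != segsites"))
      }
      mat <- do.call(rbind, lapply(rows, function(r) {
        as.integer(strsplit(r, "")[[1]])
      }))
      reps[[length(reps) + 1]] <- haplotype_matrix(mat, positions * L, L)
    } else {
      # a zero-site replicate: sample size is unknowable from the text; use 2
      reps[[length(reps) + 1]] <- haplotype_matrix(
        matrix(integer(0), nrow = max(2, length(rows)), ncol = 0),
        numeric(0), L)
    }
    while (i <= n_lines && !startsWith(trimws(lines[i]), "//")) i <- i + 1
  }
  if (length(reps) > 1) {
    ns <- vapply(reps, n_chromosomes, integer(1))
    pos_ns <- ns[vapply(reps, n_sites, integer(1)) > 0]
    if (length(unique(pos_ns)) > 1) {
      abort("replicates disagree on the number of chromosomes")
    }
  }
  reps
}
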