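# Small accounting helpers for read- and locus-level bookkeeping of a
# RAD-seq study: retention fractions along the filtering cascade, the
# fraction of the genome resequenced by recovered sites, and survivor
# arithmetic for the locus filters.

#' Read-accounting table
#'
#' Given read counts after each successive treatment step (raw,
#' pre-processed, aligned, ...), reports each step's retention relative to
#' the previous step and to the raw input.
#'
#' @param counts named numeric vector of read counts in pipeline order.
#' @return data.frame with `step`, `n`, `frac_of_previous`,
#'   `frac_of_total`.
#' @export
read_accounting <- function(counts) {
  stopifnot(length(counts) >= 1L, all(counts >= 0))
  data.frame(step = names(counts), n = as.numeric(counts),
             frac_of_previous = c(1, counts[-1L] /
                                    counts[-length(counts)]),
             frac_of_total = as.numeric(counts) / counts[[1L]],
             row.names = NULL)
}

#' Fraction of the genome resequenced by recovered RAD loci
#'
#' Each recovered restriction site contributes two read-length stretches
#' (one RAD locus upstream and one downstream of the cut).
#'
#' @param n_sites recovered restriction-site count.
#' @param read_bases bases covered by one read (default 75).
#' @param genome_size reference genome size in bp.
#' @return The resequenced fraction (0-1).
#' @export
resequenced_fraction <- function(n_sites, read_bases = 75L, genome_size) {
  stopifnot(n_sites >= 0, read_bases > 0, genome_size > 0)
  n_sites * 2 * read_bases / genome_size
}

#' Locus-filter survivor arithmetic
#'
#' Sequentially subtracts filter removals from the total discovered locus
#' count (e.g. organellar loci, missing-rate casualties, MAF casualties)
#' and reports the survivors after each step.
#'
#' @param total discovered locus count.
#' @param removed named numeric vector of removal counts in filter order.
#' @return data.frame with `step`, `removed`, `remaining`; the last row's
#'   `remaining` is the final panel size.
#' @export
locus_accounting <- function(total, removed) {
  stopifnot(total >= 0, all(removed >= 0))
  remaining <- total - cumsum(as.numeric(removed))
  if (any(remaining < 0)) stop("removals exceed the locus total")
  data.frame(step = names(removed), removed = as.numeric(removed),
             remaining = remaining, row.names = NULL)
}

#' Mean markers per chromosome
#'
#' @param total marker count.
#' @param assembled_fraction fraction of markers on assembled chromosomes.
#' @param n_chromosomes chromosome count.
#' @return Mean markers per chromosome.
#' @export
mean_per_chromosome <- function(total, assembled_fraction, n_chromosomes) {
  stopifnot(total >= 0, assembled_fraction >= 0, assembled_fraction <= 1,
            n_chromosomes >= 1)
  total * assembled_fraction / n_chromosomes
}
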