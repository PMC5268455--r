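# End-to-end driver: simulated reads -> pre-processing -> colour-space
# alignment -> base evidence -> Bayesian calls -> merged variant set.

#' Run the discovery pipeline on a simulated library
#'
#' Chains [preprocess_reads()], [build_index()] / [align_reads()],
#' [collect_evidence()], [call_samples()] and [merge_samples()] over a
#' simulated population and library, keeping the intermediate products for
#' inspection.
#'
#' @param pop a [simulate_population()] result.
#' @param lib a [simulate_library()] result for that population.
#' @param params a [genotyper_params()].
#' @param min_identity alignment identity threshold (default 0.90).
#' @param mapq_call minimum mapping quality for genotyping evidence
#'   (default 17).
#' @param k seed length for the alignment index.
#' @param max_start_errors pre-processing start-error tolerance.
#' @return A list of class `rad_pipeline`: `preprocess` (summary),
#'   `index`, `alignment` (accepted table + summary), `evidence`,
#'   `calls`, `variants` (a `variant_set`), `gm` (a [genotype_matrix()]
#'   with subpopulation labels).
#' @export
rad_pipeline <- function(pop, lib, params = genotyper_params(),
                         min_identity = 0.90, mapq_call = 17L, k = 16L,
                         max_start_errors = 1L) {
  stopifnot(inherits(pop, "rad_population"), inherits(lib, "rad_library"))
  enzyme <- pop$reference$enzyme
  raw <- lib$reads[!lib$reads$truncated, , drop = FALSE]
  pre <- preprocess_reads(raw, enzyme = enzyme,
                          read_length = nchar(raw$colors[1L]),
                          max_start_errors = max_start_errors)
  kept <- pre$reads
  kept$sample <- raw$sample[match(kept$id, raw$id)]
  index <- build_index(pop$reference, k = k)
  aln <- align_reads(kept, index, min_identity = min_identity)
  ev <- collect_evidence(aln, kept, index, mapq_min = mapq_call)
  calls <- call_samples(ev, pop$reference$genome, params)
  vs <- merge_samples(calls, samples = pop$samples$sample,
                      min_depth = params$min_depth)
  gm <- variant_set_to_gm(vs, subpop = pop$samples)
  structure(list(preprocess = pre["summary"], index = index,
                 alignment = aln, evidence = ev, calls = calls,
                 variants = vs, gm = gm),
            class = "rad_pipeline")
}

#' @export
print.rad_pipeline <- function(x, ...) {
  cat(sprintf("<rad_pipeline: %d aligned reads, %d variant sites>\n",
              nrow(x$alignment$alignments), nrow(x$variants$sites)))
  invisible(x)
}

#' Compare called genotypes with simulator truth
#'
#' Matches called variant positions against the simulator's truth loci
#' and computes genotype concordance, optionally excluding loci flanking
#' restriction sites whose presence is polymorphic (null-allele loci) and
#' calls below a depth threshold.
#'
#' @param pipe a [rad_pipeline()] result.
#' @param pop the [simulate_population()] that produced it.
#' @param exclude_null_alleles drop loci at RE-polymorphic sites
#'   (default TRUE).
#' @param min_depth only compare calls with depth at or above this
#'   (default 10).
#' @return A list: `rate`, `n_compared`, `n_mismatch`, `n_loci_shared`,
#'   plus `called_not_truth` and `truth_not_called` position counts.
#' @export
pipeline_concordance <- function(pipe, pop, exclude_null_alleles = TRUE,
                                 min_depth = 10L) {
  truth_loci <- pop$truth$loci
  keep <- rep(TRUE, nrow(truth_loci))
  if (exclude_null_alleles) {
    poly_sites <- pop$truth$sites$site_id[pop$truth$site_polymorphic]
    keep <- !(truth_loci$site_id %in% poly_sites)
  }
  tkey <- paste(truth_loci$contig, truth_loci$pos)
  ckey <- paste(pipe$variants$sites$contig, pipe$variants$sites$pos)
  shared <- intersect(tkey[keep], ckey)
  called <- pipe$variants$geno[, match(shared, ckey), drop = FALSE]
  dp <- pipe$variants$dp[, match(shared, ckey), drop = FALSE]
  called[dp < min_depth] <- NA_integer_
  truth <- pop$truth$geno[match(rownames(called), pop$samples$sample),
                          match(shared, tkey), drop = FALSE]
  cmp <- !is.na(called) & !is.na(truth)
  list(rate = if (any(cmp)) 1 - sum(called != truth, na.rm = TRUE) /
         sum(cmp) else NA_real_,
       n_compared = sum(cmp),
       n_mismatch = sum(cmp & called != truth),
       n_loci_shared = length(shared),
       called_not_truth = sum(!ckey %in% tkey),
       truth_not_called = sum(!tkey[keep] %in% ckey))
}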