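# SNP annotation against GFF3 gene models: genomic feature classes
# (CDS > UTR > intron > intergenic) and synonymous / nonsynonymous coding
# effects via strand-aware codon translation.

#' Read gene models from a GFF3 file
#'
#' Loads gene, mRNA, CDS and UTR features; intron intervals are implied by
#' the gene span minus the annotated features.
#'
#' @param path GFF3 path.
#' @return A list of class `gene_models`: `genes`, `cds`, `utr`
#'   (GRanges; `cds` carries `Parent` ids and phase), indexed per contig.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path)
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  cds <- gff[type == "CDS"]
  utr <- gff[type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  parent <- function(x) {
    vapply(as.list(x$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, "")
  }
  if (length(cds)) cds$parent <- parent(cds)
  structure(list(genes = genes, cds = cds, utr = utr), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models: %d genes, %d CDS segments, %d UTRs>\n",
              length(x$genes), length(x$cds), length(x$utr)))
  invisible(x)
}

#' Classify SNP positions by genomic feature
#'
#' Each site receives exactly one class with precedence CDS over UTR over
#' intron (any other position inside a gene) over intergenic. Sites on
#' contigs absent from the annotation are intergenic (with a warning).
#'
#' @param sites data.frame with `contig` and `pos` (1-based).
#' @param models a [read_gene_models()] result.
#' @return Character vector of classes (`"CDS"`, `"UTR"`, `"intron"`,
#'   `"intergenic"`), one per site.
#' @export
classify_snps <- function(sites, models) {
  stopifnot(inherits(models, "gene_models"))
  known <- unique(as.character(GenomicRanges::seqnames(models$genes)))
  if (!all(sites$contig %in% known)) {
    warning("site(s) on contigs absent from the annotation are intergenic")
  }
  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos, sites$pos))
  cls <- rep("intergenic", nrow(sites))
  hit <- function(subject) {
    # seqlevel mismatches are already reported above; overlap counting
    # should not warn again per feature type
    suppressWarnings(
      GenomicRanges::countOverlaps(gr, subject, ignore.strand = TRUE) > 0L)
  }
  cls[hit(models$genes)] <- "intron"
  if (length(models$utr)) cls[hit(models$utr)] <- "UTR"
  if (length(models$cds)) cls[hit(models$cds)] <- "CDS"
  cls
}

#' Coding effect of a SNP
#'
#' For a site inside a CDS, rebuilds the transcript's coding sequence from
#' the reference, substitutes the alternate allele, and translates the
#' affected codon on the coding strand; an amino-acid change (including a
#' gained or lost stop) is nonsynonymous. Broken models (coding length not
#' a multiple of 3, or a reference mismatch) are flagged and excluded.
#'
#' @param contig,pos site position (1-based).
#' @param ref,alt reference and alternate alleles (top strand).
#' @param models a [read_gene_models()] result.
#' @param genome named character vector of contig sequences.
#' @return A list: `effect` (`"synonymous"`, `"nonsynonymous"`, or `NA`
#'   when not in a valid codon), `codon_ref`, `codon_alt`, `aa_ref`,
#'   `aa_alt`, `transcript`.
#' @export
coding_effect <- function(contig, pos, ref, alt, models, genome) {
  stopifnot(inherits(models, "gene_models"))
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(gr, models$cds, ignore.strand = TRUE)
  if (!length(ov)) {
    return(list(effect = NA_character_, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA, transcript = NA_character_))
  }
  cds_hit <- models$cds[S4Vectors::subjectHits(ov)[1L]]
  tx <- cds_hit$parent
  segs <- models$cds[models$cds$parent == tx]
  segs <- segs[order(GenomicRanges::start(segs))]
  strand <- as.character(GenomicRanges::strand(segs))[1L]
  seq_parts <- substring(genome[[contig]], GenomicRanges::start(segs),
                         GenomicRanges::end(segs))
  coding <- paste(seq_parts, collapse = "")
  offs <- cumsum(c(0L, GenomicRanges::width(segs)))
  seg_i <- which(GenomicRanges::start(segs) <= pos &
                   GenomicRanges::end(segs) >= pos)[1L]
  cpos_plus <- offs[seg_i] + (pos - GenomicRanges::start(segs)[seg_i]) + 1L
  n <- nchar(coding)
  if (n %% 3L != 0L ||
      toupper(substring(coding, cpos_plus, cpos_plus)) != toupper(ref)) {
    return(list(effect = NA_character_, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA, transcript = tx))
  }
  if (strand == "-") {
    coding <- .revcomp(coding)
    cpos <- n - cpos_plus + 1L
    alt_c <- .complement[[toupper(alt)]]
  } else {
    cpos <- cpos_plus
    alt_c <- toupper(alt)
  }
  codon_i <- (cpos - 1L) %/% 3L
  codon_ref <- substring(coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- cpos - codon_i * 3L
  codon_alt <- codon_ref
  substring(codon_alt, within, within) <- alt_c
  aa <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  }
  aa_ref <- aa(codon_ref)
  aa_alt <- aa(codon_alt)
  list(effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
       codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt, transcript = tx)
}

#' Annotate a variant table
#'
#' Adds a feature class to every site and a coding effect to CDS sites,
#' plus a per-class summary table.
#'
#' @param sites data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param models a [read_gene_models()] result.
#' @param genome named character vector of contig sequences.
#' @return A list: `table` (input plus `class` and `effect` columns) and
#'   `summary` (per-class counts; CDS split by effect).
#' @export
annotate_variants <- function(sites, models, genome) {
  cls <- classify_snps(sites, models)
  effect <- rep(NA_character_, nrow(sites))
  for (i in which(cls == "CDS")) {
    effect[i] <- coding_effect(sites$contig[i], sites$pos[i], sites$ref[i],
                               sites$alt[i], models, genome)$effect
  }
  tab <- cbind(sites, class = cls, effect = effect,
               stringsAsFactors = FALSE)
  summ <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(summ) <- c("class", "n")
  eff <- as.data.frame(table(effect = effect[cls == "CDS"],
                             useNA = "no"), stringsAsFactors = FALSE)
  names(eff) <- c("class", "n")
  list(table = tab, summary = rbind(summ, eff))
}
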