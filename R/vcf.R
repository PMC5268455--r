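# VCF v4.2 output for merged call sets and genotype-matrix import/export.

.gt_string <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a merged call set as VCF v4.2
#'
#' Emits biallelic SNP records with GT:DP:GQ fields; missing genotypes are
#' `./.`.
#'
#' @param vs a [merge_samples()] result (class `variant_set`).
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, contig_lengths = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=radsolid",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of called samples\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(vs$geno)), collapse = "\t"))
  n_sites <- nrow(vs$sites)
  cols <- vapply(seq_len(n_sites), function(j) {
    gt <- vs$geno[, j]
    fld <- ifelse(is.na(gt), "./.",
                  paste0(.gt_string[as.character(gt)], ":", vs$dp[, j], ":",
                         ifelse(is.na(vs$gq[, j]), 0L, vs$gq[, j])))
    paste(fld, collapse = "\t")
  }, "")
  body <- paste(vs$sites$contig, vs$sites$pos, ".", vs$sites$ref,
                vs$sites$alt, ".", "PASS",
                paste0("NS=", colSums(!is.na(vs$geno))), "GT:DP:GQ",
                cols, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Biallelic SNP records are converted to 0/1/2 alternate-allele dosages;
#' any other genotype becomes missing.
#'
#' @param path VCF path (plain text or gzipped).
#' @param subpop optional data.frame (`sample`, `subpop`).
#' @return A [genotype_matrix()].
#' @export
read_vcf_gm <- function(path, subpop = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- data.frame(sample = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(subpop)) {
    samples$subpop <- subpop$subpop[match(samples$sample, subpop$sample)]
  }
  genotype_matrix(t(code),
                  data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE),
                  samples)
}

#' Export a genotype matrix as TSV
#'
#' Long-format table with one row per locus: metadata columns then one
#' dosage column per sample (`NA` for missing).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gm_tsv <- function(gm, path) {
  out <- cbind(gm$loci, as.data.frame(t(gm$geno)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read subpopulation labels from a two-column sample table
#'
#' @param path TSV/whitespace table with columns `sample` and `subpop`
#'   (header optional when exactly two columns).
#' @return data.frame with `sample` and `subpop`.
#' @export
read_subpop_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "subpop") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) != 2L) stop("expected a two-column sample table")
    names(df) <- c("sample", "subpop")
  }
  df
}
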