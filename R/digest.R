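# In-silico restriction digestion: enzyme definitions, recognition-site
# scanning, fragment accounting and multi-enzyme comparison.

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence on the top strand (ACGT).
#' @param cut_offset bases after the recognition start at which the top
#'   strand is cleaved (BamHI cuts just after the first G, offset 1).
#' @return An object of class `restriction_enzyme` with fields `name`,
#'   `recognition`, `cut_offset` and the derived `sticky_end`
#'   (`recognition` after the cut).
#' @export
#' @examples
#' bamhi()
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  .seq_codes(recognition)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset >= nchar(recognition)) {
    stop("cut_offset must lie inside the recognition sequence")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset,
                 sticky_end = substring(recognition, cut_offset + 1L)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme %s: %s, cut after %d, sticky end %s>\n",
              x$name, x$recognition, x$cut_offset, x$sticky_end))
  invisible(x)
}

#' BamHI (G^GATCC)
#'
#' The default enzyme: six-base recognition site GGATCC cleaved just after
#' the first guanine, leaving the GATCC overhang with which RAD reads begin.
#'
#' @return A [restriction_enzyme()].
#' @export
bamhi <- function() restriction_enzyme("BamHI", "GGATCC", 1L)

#' Colour-space signatures of an enzyme's read start
#'
#' `enzyme_start_signature()` encodes the sticky end from the primer base
#' (the signature raw reads are expected to begin with, `"12320"` for BamHI
#' with a T primer); `enzyme_site_signature()` encodes the full recognition
#' sequence (the signature planted onto retained reads, `"102320"`).
#'
#' @param enzyme a [restriction_enzyme()].
#' @param primer primer base.
#' @return A colour string.
#' @export
enzyme_start_signature <- function(enzyme, primer = "T") {
  cs_encode(primer, enzyme$sticky_end)
}

#' @rdname enzyme_start_signature
#' @export
enzyme_site_signature <- function(enzyme, primer = "T") {
  cs_encode(primer, enzyme$recognition)
}

#' Find restriction recognition sites in a sequence
#'
#' Scans the top strand for exact occurrences of the recognition sequence
#' (overlapping occurrences included). Windows containing N never match.
#' Palindromic recognition sequences such as GGATCC are reported once per
#' position.
#'
#' @param seq nucleotide string (ACGTN).
#' @param enzyme a [restriction_enzyme()].
#' @return Integer vector of 0-based start positions, strictly increasing.
#' @export
find_sites <- function(seq, enzyme = bamhi()) {
  if (nchar(seq) < nchar(enzyme$recognition)) return(integer(0))
  m <- Biostrings::matchPattern(enzyme$recognition,
                                Biostrings::DNAString(seq), fixed = TRUE)
  as.integer(Biostrings::start(m)) - 1L
}

#' Cut a sequence into restriction fragments
#'
#' Applies the enzyme's top-strand cut (`site + cut_offset`) at every
#' recognition site. Fragments concatenate back to the input; every
#' fragment after the first begins with the enzyme's sticky-end sequence.
#'
#' @inheritParams find_sites
#' @return Character vector of fragment sequences in genomic order.
#' @export
fragments <- function(seq, enzyme = bamhi()) {
  sites <- find_sites(seq, enzyme)
  if (!length(sites)) return(seq)
  cuts <- sites + enzyme$cut_offset          # 0-based cut points
  starts <- c(0L, cuts)
  ends <- c(cuts, nchar(seq))
  substring(seq, starts + 1L, ends)
}

#' Read a multi-contig FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Build a restriction-site catalog for a genome
#'
#' Scans every contig with [find_sites()] and derives the fragment
#' intervals. The mean inter-site distance is computed over consecutive
#' same-contig site pairs only (distances never span contigs).
#'
#' @param genome named character vector of contig sequences, or a FASTA
#'   path.
#' @param enzyme a [restriction_enzyme()].
#' @param organellar character vector of contig names to label as
#'   organellar; all others are nuclear.
#' @return An object of class `re_catalog`: list with `sites` (data.table
#'   `contig`, `pos0`), `fragments` (data.table `contig`, `start0`, `end0`,
#'   0-based half-open), `contig_len`, `contig_class`, `enzyme`, `n_sites`
#'   and `mean_spacing`.
#' @export
digest_catalog <- function(genome, enzyme = bamhi(),
                           organellar = character(0)) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (!length(genome) || is.null(names(genome))) {
    stop("genome must be a non-empty named character vector or FASTA path")
  }
  contig <- pos0 <- NULL # data.table NSE
  site_list <- lapply(genome, find_sites, enzyme = enzyme)
  sites <- data.table::data.table(
    contig = rep(names(genome), lengths(site_list)),
    pos0 = as.integer(unlist(site_list, use.names = FALSE)))
  frag <- data.table::rbindlist(lapply(names(genome), function(ct) {
    cuts <- site_list[[ct]] + enzyme$cut_offset
    data.table::data.table(contig = ct,
                           start0 = as.integer(c(0L, cuts)),
                           end0 = as.integer(c(cuts, nchar(genome[[ct]]))))
  }))
  gaps <- unlist(lapply(site_list, function(p) if (length(p) > 1L) diff(p)),
                 use.names = FALSE)
  cls <- ifelse(names(genome) %in% organellar, "organellar", "nuclear")
  names(cls) <- names(genome)
  structure(list(sites = sites, fragments = frag,
                 contig_len = vapply(genome, nchar, integer(1)),
                 contig_class = cls, enzyme = enzyme,
                 n_sites = nrow(sites),
                 mean_spacing = if (length(gaps)) mean(gaps) else NA_real_),
            class = "re_catalog")
}

#' @export
print.re_catalog <- function(x, ...) {
  cat(sprintf(paste0("<re_catalog: %s, %d contig(s), %d sites, ",
                     "mean spacing %.1f bp>\n"),
              x$enzyme$name, length(x$contig_len), x$n_sites,
              x$mean_spacing))
  invisible(x)
}

#' Export catalog sites as BED intervals
#'
#' @param catalog an [digest_catalog()] result.
#' @param path output BED path (0-based half-open site intervals).
#' @return `path`, invisibly.
#' @export
catalog_to_bed <- function(catalog, path) {
  w <- nchar(catalog$enzyme$recognition)
  writeLines(sprintf("%s\t%d\t%d\t%s", catalog$sites$contig,
                     catalog$sites$pos0, catalog$sites$pos0 + w,
                     catalog$enzyme$name), path)
  invisible(path)
}

#' Compare candidate enzymes by recovered-site counts
#'
#' For each enzyme, catalogs the genome and simulates per-site read depth
#' (Poisson with mean `coverage` per site), then counts the sites whose
#' depth meets each threshold. Counts are monotone non-increasing across
#' increasing thresholds.
#'
#' @param genome named character vector of contig sequences.
#' @param enzymes list of [restriction_enzyme()] objects.
#' @param thresholds positive integer depth thresholds (default
#'   `c(4, 8, 16, 24)`).
#' @param coverage mean simulated reads per site.
#' @param seed integer seed for the simulated depths.
#' @return data.frame with columns `enzyme`, `n_sites`, `threshold`,
#'   `recovered`.
#' @export
compare_enzymes <- function(genome, enzymes, thresholds = c(4L, 8L, 16L, 24L),
                            coverage = 16, seed = 1L) {
  stopifnot(length(enzymes) >= 1L, all(thresholds > 0))
  set.seed(seed)
  out <- lapply(enzymes, function(enz) {
    cat_ <- digest_catalog(genome, enz)
    depth <- stats::rpois(cat_$n_sites, coverage)
    data.frame(enzyme = enz$name, n_sites = cat_$n_sites,
               threshold = as.integer(thresholds),
               recovered = vapply(thresholds,
                                  function(t) sum(depth >= t), integer(1)))
  })
  do.call(rbind, out)
}
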