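# SOLiD two-base colour-space encoding and restriction-site-anchored read
# pre-processing.
#
# The colour code maps each ordered base pair to one of four colours:
#   0 = {AA, CC, GG, TT}, 1 = {AC, CA, GT, TG},
#   2 = {AG, GA, CT, TC}, 3 = {AT, TA, CG, GC}.
# Numerically this is the XOR of the 2-bit base codes A=0, C=1, G=2, T=3,
# which makes the mapping symmetric and, for a fixed first base, bijective
# in the second base.

.base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
.code_base <- c("A", "C", "G", "T")

.seq_codes <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- .base_code[ch]
  if (anyNA(codes)) {
    bad <- unique(ch[is.na(codes)])
    stop("invalid nucleotide(s) in sequence: ", paste(bad, collapse = ", "),
         " (ambiguity codes are rejected)")
  }
  unname(codes)
}

.primer_code <- function(primer) {
  if (!is.character(primer) || length(primer) != 1L || nchar(primer) != 1L ||
      is.na(.base_code[toupper(primer)])) {
    stop("primer must be a single nucleotide (A, C, G or T)")
  }
  unname(.base_code[[toupper(primer)]])
}

.color_codes <- function(colors) {
  ch <- strsplit(colors, "", fixed = TRUE)[[1L]]
  codes <- match(ch, c("0", "1", "2", "3")) - 1L
  if (anyNA(codes)) stop("invalid colour symbol(s): colours must be in 0-3")
  codes
}

#' Encode a nucleotide sequence in SOLiD colour space
#'
#' Each colour encodes the transition between two adjacent bases, starting
#' from a known primer base, using the standard SOLiD two-base code
#' (0 = identical bases, 1 = A/C or G/T transition, 2 = A/G or C/T,
#' 3 = A/T or C/G). For example `cs_encode("T", "GATCC")` is `"12320"`, the
#' colour-space signature with which BamHI RAD reads begin.
#'
#' @param primer single primer nucleotide (A, C, G or T).
#' @param seq non-empty nucleotide string over ACGT.
#' @return A string of colour digits, one per base of `seq`.
#' @seealso [cs_decode()]
#' @export
#' @examples
#' cs_encode("T", "GATCC")   # "12320"
#' cs_encode("T", "GGATCC")  # "102320"
cs_encode <- function(primer, seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L) {
    stop("seq must be a single non-empty string")
  }
  pc <- .primer_code(primer)
  codes <- .seq_codes(seq)
  cols <- bitwXor(c(pc, codes[-length(codes)]), codes)
  paste(cols, collapse = "")
}

#' Decode a SOLiD colour string back to nucleotides
#'
#' Inverse of [cs_encode()]: starting from the primer base, each colour
#' determines the next base, so `cs_decode(p, cs_encode(p, s))` returns `s`.
#'
#' @param primer single primer nucleotide.
#' @param colors string of colour digits 0-3.
#' @return The decoded nucleotide string, same length as `colors`.
#' @export
#' @examples
#' cs_decode("T", "12320")  # "GATCC"
cs_decode <- function(primer, colors) {
  if (!is.character(colors) || length(colors) != 1L || nchar(colors) < 1L) {
    stop("colors must be a single non-empty string")
  }
  pc <- .primer_code(primer)
  cols <- .color_codes(colors)
  codes <- Reduce(bitwXor, cols, accumulate = TRUE, init = pc)[-1L]
  paste(.code_base[codes + 1L], collapse = "")
}

#' Construct a SOLiD colour-space read
#'
#' @param id read identifier.
#' @param primer single primer nucleotide (SOLiD fragment reads use T).
#' @param colors non-empty string of colour digits 0-3.
#' @param quals optional integer vector of Phred-like colour qualities, one
#'   per colour.
#' @return An object of class `color_read`.
#' @export
color_read <- function(id, primer, colors, quals = NULL) {
  .primer_code(primer)
  .color_codes(colors)
  if (!is.null(quals)) {
    quals <- as.integer(quals)
    if (length(quals) != nchar(colors)) {
      stop("quals must have one entry per colour")
    }
  }
  structure(list(id = as.character(id), primer = toupper(primer),
                 colors = colors, quals = quals),
            class = "color_read")
}

#' @export
print.color_read <- function(x, ...) {
  cat(sprintf("<color_read %s: %s%s (%d colours%s)>\n", x$id, x$primer,
              x$colors, nchar(x$colors),
              if (is.null(x$quals)) "" else ", with qualities"))
  invisible(x)
}

# Hamming distance between the first nchar(signature) colours of each read
# and the signature; vectorised over reads.
.start_mismatches <- function(colors, signature) {
  ns <- nchar(signature)
  short <- nchar(colors) < ns
  if (any(short)) {
    stop(sum(short), " read(s) shorter than the start signature (",
         ns, " colours)")
  }
  sig <- strsplit(signature, "", fixed = TRUE)[[1L]]
  mism <- integer(length(colors))
  for (i in seq_len(ns)) {
    mism <- mism + (substring(colors, i, i) != sig[i])
  }
  mism
}

#' Count colour mismatches against the expected read start signature
#'
#' RAD reads are expected to begin with the colour-space signature of the
#' sticky end released by the restriction cut (for BamHI with a T primer,
#' `"12320"`). This returns the Hamming distance between the first
#' `nchar(signature)` colours of the read and that signature.
#'
#' @param read a [color_read()] object, or a character vector of colour
#'   strings.
#' @param signature colour-space start signature (default the BamHI sticky
#'   end `encode(T, "GATCC") = "12320"`).
#' @return Integer mismatch count(s).
#' @export
classify_start <- function(read, signature = "12320") {
  colors <- if (inherits(read, "color_read")) read$colors else read
  .start_mismatches(colors, signature)
}

#' Pre-process colour-space RAD reads at the restriction-site anchor
#'
#' Reads whose first colours differ from the sticky-end start signature at
#' more than `max_start_errors` positions are discarded; the rest have their
#' start replaced by the full restriction-site colour signature (the
#' recognition sequence encoded from the primer), which lengthens each kept
#' read by `nchar(recognition) - nchar(sticky end)` colours (75 to 76 for
#' BamHI). Reads with zero start mismatches are labelled `"exact"`, reads
#' with tolerated mismatches `"repaired"`.
#'
#' @param reads a [color_read()], a character vector of colour strings, or a
#'   data.frame with columns `id` and `colors` (e.g. from [read_csfasta()]).
#' @param enzyme a [restriction_enzyme()]; default [bamhi()].
#' @param primer primer base used to derive the signatures.
#' @param read_length expected raw read length in colours; reads of any
#'   other length raise an error. `NULL` skips the check.
#' @param max_start_errors maximum tolerated colour mismatches over the
#'   start signature (default 1).
#' @return A list with elements `reads` (data.frame of retained reads:
#'   `id`, `colors`, `status`, `mismatches`), `discarded` (ids), and
#'   `summary` (counts and fractions of exact / repaired / discarded).
#' @export
preprocess_reads <- function(reads, enzyme = bamhi(), primer = "T",
                             read_length = 75L, max_start_errors = 1L) {
  if (inherits(reads, "color_read")) {
    reads <- data.frame(id = reads$id, colors = reads$colors,
                        stringsAsFactors = FALSE)
  } else if (is.character(reads)) {
    reads <- data.frame(id = as.character(seq_along(reads)), colors = reads,
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("id", "colors") %in% names(reads)))
  if (!is.null(read_length) && nrow(reads) &&
      any(nchar(reads$colors) != read_length)) {
    stop("all raw reads must be ", read_length, " colours long")
  }
  start_sig <- enzyme_start_signature(enzyme, primer)
  site_sig <- enzyme_site_signature(enzyme, primer)

  mism <- if (nrow(reads)) .start_mismatches(reads$colors, start_sig)
          else integer(0)
  keep <- mism <= max_start_errors
  status <- ifelse(mism == 0L, "exact", "repaired")[keep]
  kept <- reads[keep, , drop = FALSE]
  if (nrow(kept)) {
    kept$colors <- paste0(site_sig,
                          substring(kept$colors, nchar(start_sig) + 1L))
  }
  kept$status <- status
  kept$mismatches <- mism[keep]
  rownames(kept) <- NULL

  n <- nrow(reads)
  counts <- c(exact = sum(mism == 0L & keep),
              repaired = sum(mism > 0L & keep),
              discarded = sum(!keep))
  list(reads = kept,
       discarded = reads$id[!keep],
       summary = data.frame(status = names(counts),
                            n = as.integer(counts),
                            fraction = if (n) as.numeric(counts) / n
                                       else rep(NA_real_, 3L)))
}

#' Pre-process a single colour read
#'
#' Single-read convenience wrapper around [preprocess_reads()].
#'
#' @inheritParams preprocess_reads
#' @param read a [color_read()].
#' @return A list with `status` (`"exact"`, `"repaired"` or `"discarded"`),
#'   `read` (the repaired [color_read()], or `NULL` when discarded) and
#'   `mismatches`.
#' @export
preprocess_read <- function(read, enzyme = bamhi(), primer = "T",
                            read_length = 75L, max_start_errors = 1L) {
  stopifnot(inherits(read, "color_read"))
  res <- preprocess_reads(read, enzyme = enzyme, primer = primer,
                          read_length = read_length,
                          max_start_errors = max_start_errors)
  if (nrow(res$reads)) {
    list(status = res$reads$status[1L],
         read = color_read(res$reads$id[1L], primer, res$reads$colors[1L]),
         mismatches = res$reads$mismatches[1L])
  } else {
    list(status = "discarded", read = NULL,
         mismatches = .start_mismatches(read$colors,
                                        enzyme_start_signature(enzyme, primer)))
  }
}

#' Read colour-space reads from a csfasta-style file
#'
#' The dialect is one header line (`>id`) followed by one line holding the
#' primer base immediately followed by the colour digits (e.g.
#' `T12320...`). An optional parallel quality file holds, per read, a
#' header line and one line of space-separated integer qualities.
#'
#' @param path csfasta file path.
#' @param qual_path optional quality file path.
#' @return A data.frame with columns `id`, `primer`, `colors` and, when
#'   qualities are supplied, a list column `quals`.
#' @export
read_csfasta <- function(path, qual_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- startsWith(lines, ">")
  if (!any(hdr) || any(diff(which(hdr)) != 2L)) {
    stop("malformed csfasta: expected alternating header and read lines")
  }
  ids <- sub("^>", "", lines[hdr])
  seqs <- lines[!hdr]
  out <- data.frame(id = ids,
                    primer = substring(seqs, 1L, 1L),
                    colors = substring(seqs, 2L),
                    stringsAsFactors = FALSE)
  if (!is.null(qual_path)) {
    qlines <- readLines(qual_path)
    qlines <- qlines[nzchar(qlines) & !startsWith(qlines, "#")]
    qhdr <- startsWith(qlines, ">")
    qids <- sub("^>", "", qlines[qhdr])
    if (!identical(qids, ids)) stop("quality file ids do not match reads")
    out$quals <- lapply(strsplit(qlines[!qhdr], "[[:space:]]+"), as.integer)
  }
  out
}

#' Write colour-space reads to a csfasta-style file
#'
#' @param reads data.frame with columns `id`, `primer`, `colors` and
#'   optionally a list column `quals`.
#' @param path output csfasta path.
#' @param qual_path optional output quality file path (requires `quals`).
#' @return `path`, invisibly.
#' @export
write_csfasta <- function(reads, path, qual_path = NULL) {
  stopifnot(all(c("id", "primer", "colors") %in% names(reads)))
  writeLines(paste0(">", reads$id, "\n", reads$primer, reads$colors), path)
  if (!is.null(qual_path)) {
    if (is.null(reads$quals)) stop("no quals column to write")
    writeLines(paste0(">", reads$id, "\n",
                      vapply(reads$quals, paste, "", collapse = " ")),
               qual_path)
  }
  invisible(path)
}
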