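# Site-anchored colour-space alignment. The reference is converted to
# colour space on both strands; candidate placements are retrieved by
# exact k-colour seed lookup (packed 2-bit integers), which covers every
# catalogued restriction site as well as novel (gained) sites. Comparison
# happens entirely in colour space; bases are only inferred afterwards by
# the two-adjacent-colour consistency rule, which distinguishes true
# substitutions (two consistent adjacent colour changes) from isolated
# sequencing errors.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  paste(.complement[ch], collapse = "")
}

# pack k consecutive colour codes (0-3) starting at each index into one
# number; exact for k <= 26 in doubles
.pack_kmers <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  val <- numeric(n)
  mult <- 1
  for (j in seq_len(k)) {
    val <- val + codes[j:(j + n - 1L)] * mult
    mult <- mult * 4
  }
  val
}

#' Build a colour-space alignment index
#'
#' Converts every contig (both strands) to colour space and hashes all
#' k-colour words so that reads can retrieve candidate placements by exact
#' seed lookup. Every restriction site in the catalog is retrievable this
#' way, as are novel site positions absent from the catalog (e.g. gained
#' sites).
#'
#' @param genome named character vector of contig sequences, or a
#'   `rad_reference` from [simulate_reference()].
#' @param catalog optional [digest_catalog()] (taken from the reference
#'   when one is supplied); carried for site annotation of alignments.
#' @param k seed length in colours, between 8 and 24 (default 16).
#' @param primer primer base of the reads.
#' @return An object of class `cs_index`.
#' @export
build_index <- function(genome, catalog = NULL, k = 16L, primer = "T") {
  if (inherits(genome, "rad_reference")) {
    if (is.null(catalog)) catalog <- genome$catalog
    genome <- genome$genome
  }
  stopifnot(k >= 8L, k <= 24L)
  contigs <- lapply(names(genome), function(ct) {
    fwd <- .seq_codes(genome[[ct]])
    rev_ <- .seq_codes(.revcomp(genome[[ct]]))
    list(name = ct, n = length(fwd),
         codes_f = fwd, codes_r = rev_,
         colors_f = bitwXor(fwd[-length(fwd)], fwd[-1L]),
         colors_r = bitwXor(rev_[-length(rev_)], rev_[-1L]))
  })
  names(contigs) <- names(genome)
  kmer <- contig <- strand <- i <- NULL
  tabs <- lapply(seq_along(contigs), function(ci) {
    cc <- contigs[[ci]]
    data.table::rbindlist(list(
      data.table::data.table(kmer = .pack_kmers(cc$colors_f, k),
                             contig = ci, strand = 1L,
                             i = seq_along(.pack_kmers(cc$colors_f, k))),
      data.table::data.table(kmer = .pack_kmers(cc$colors_r, k),
                             contig = ci, strand = 2L,
                             i = seq_along(.pack_kmers(cc$colors_r, k)))))
  })
  kmers <- data.table::rbindlist(tabs)
  data.table::setkey(kmers, kmer)
  structure(list(contigs = contigs, kmers = kmers, k = k,
                 primer = toupper(primer),
                 primer_code = .primer_code(primer),
                 catalog = catalog),
            class = "cs_index")
}

#' @export
print.cs_index <- function(x, ...) {
  cat(sprintf("<cs_index: %d contig(s), k=%d, %s kmers>\n",
              length(x$contigs), x$k,
              format(nrow(x$kmers), big.mark = ",")))
  invisible(x)
}

# reads' colour strings (equal length) to an integer matrix
.color_matrix <- function(colors) {
  L <- nchar(colors[1L])
  if (any(nchar(colors) != L)) stop("reads must have equal length")
  m <- matrix(utf8ToInt(paste(colors, collapse = "")) - 48L,
              ncol = L, byrow = TRUE)
  if (any(m < 0L | m > 3L)) stop("invalid colour symbols in reads")
  m
}

#' Align pre-processed colour reads
#'
#' For each read, candidate placements are the exact matches of k-colour
#' seeds taken downstream of the restriction-site signature. At each
#' candidate the read's colours are compared with the reference colours;
#' identity is the fraction of matching colours. A read is kept only when
#' its best placement is strictly better than the second best (unique) and
#' its identity reaches `min_identity`; mapping quality is
#' `min(60, 4 * (best_matches - second_best_matches))` and 0 for ties.
#'
#' @param reads data.frame with columns `id` and `colors` (pre-processed,
#'   equal length), optionally `sample`.
#' @param index a [build_index()] result.
#' @param min_identity minimum colour identity (default 0.90).
#' @param seed_offsets 1-based colour offsets of the lookup seeds; the
#'   defaults start just after the 6-colour site signature.
#' @return A list with `alignments` (data.table: `id`, `sample`, `contig`,
#'   `strand` "+"/"-", `placement` 1-based first covered base on the
#'   aligned strand, `site_pos0` 0-based recognition-site start in
#'   original coordinates, `side` "down"/"up", `matches`, `mismatches`,
#'   `identity`, `mapq`, `unique`) and `summary` (counts of aligned /
#'   rejected reads by reason).
#' @export
align_reads <- function(reads, index, min_identity = 0.90,
                        seed_offsets = NULL) {
  stopifnot(inherits(index, "cs_index"),
            all(c("id", "colors") %in% names(reads)))
  k <- index$k
  n_reads <- nrow(reads)
  if (!n_reads) stop("no reads to align")
  M <- .color_matrix(reads$colors)
  L <- ncol(M)
  motif_len <- if (!is.null(index$catalog))
    nchar(index$catalog$enzyme$recognition) else 6L
  if (is.null(seed_offsets)) {
    seed_offsets <- motif_len + 1L + (0:2) * k
    seed_offsets <- seed_offsets[seed_offsets + k - 1L <= L]
  }
  if (!length(seed_offsets)) stop("read length too short for seeding")

  kmer <- read <- contig <- strand <- placement <- NULL
  cand_list <- lapply(seed_offsets, function(s) {
    # read colour j (j >= 2) aligns to strand colour p + j - 2, so a seed
    # at read offset s matching table index i implies placement p = i-s+2
    val <- numeric(n_reads)
    mult <- 1
    for (j in seq_len(k)) {
      val <- val + M[, s + j - 1L] * mult
      mult <- mult * 4
    }
    hits <- index$kmers[data.table::data.table(kmer = val, read = seq_len(n_reads)),
                        on = "kmer", nomatch = NULL,
                        .(read, contig, strand, i)]
    hits[, placement := i - s + 2L][, i := NULL]
    hits
  })
  cand <- unique(data.table::rbindlist(cand_list))
  # placements must leave room for the full read
  nvec <- vapply(index$contigs, `[[`, integer(1), "n")
  cand <- cand[placement >= 1L & placement + L - 1L <= nvec[contig]]

  out <- data.table::data.table(
    id = reads$id,
    sample = if ("sample" %in% names(reads)) reads$sample else NA_character_,
    contig = NA_character_, strand = NA_character_,
    placement = NA_integer_, site_pos0 = NA_integer_,
    side = NA_character_, matches = NA_integer_, mismatches = NA_integer_,
    identity = NA_real_, mapq = NA_integer_, unique = NA,
    status = "no_candidate")

  if (nrow(cand)) {
    cand[, matches := 0L]
    data.table::setkey(cand, contig, strand, placement)
    grp <- cand[, .(n = .N), by = .(contig, strand, placement)]
    pc <- index$primer_code
    for (g in seq_len(nrow(grp))) {
      cc <- index$contigs[[grp$contig[g]]]
      codes <- if (grp$strand[g] == 1L) cc$codes_f else cc$codes_r
      cols <- if (grp$strand[g] == 1L) cc$colors_f else cc$colors_r
      p <- grp$placement[g]
      tpl <- cols[p:(p + L - 2L)]
      fc <- bitwXor(pc, codes[p])
      rows <- cand[.(grp$contig[g], grp$strand[g], p), which = TRUE]
      X <- M[cand$read[rows], , drop = FALSE]
      mm <- as.integer(X[, 1L] != fc) +
        rowSums(X[, -1L, drop = FALSE] !=
                  matrix(tpl, nrow(X), L - 1L, byrow = TRUE))
      data.table::set(cand, rows, "matches", as.integer(L - mm))
    }
    data.table::setorder(cand, read, -matches)
    best <- cand[!duplicated(read)]
    rest <- cand[duplicated(read)]
    second <- rest[!duplicated(read)]
    sec_matches <- integer(n_reads)
    sec_matches[second$read] <- second$matches
    r <- best$read
    uniq <- best$matches > sec_matches[r]
    mapq_v <- ifelse(uniq, pmin(60L, 4L * (best$matches - sec_matches[r])),
                     0L)
    ident <- best$matches / L
    ctg_names <- names(index$contigs)
    n_ctg <- nvec[best$contig]
    fwd <- best$strand == 1L
    site0 <- ifelse(fwd, best$placement - 1L,
                    n_ctg - best$placement - motif_len + 1L)
    out[r, `:=`(contig = ctg_names[best$contig],
                strand = ifelse(fwd, "+", "-"),
                placement = best$placement,
                site_pos0 = as.integer(site0),
                side = ifelse(fwd, "down", "up"),
                matches = best$matches,
                mismatches = as.integer(L - best$matches),
                identity = ident,
                mapq = as.integer(mapq_v),
                unique = uniq,
                status = ifelse(!uniq, "not_unique",
                                ifelse(ident < min_identity,
                                       "low_identity", "aligned")))]
  }
  status <- NULL
  summary <- out[, .(n = .N), by = status]
  list(alignments = out[status == "aligned"][, status := NULL][],
       rejected = out[status != "aligned",
                      .(id, sample, reason = status)],
       summary = summary[])
}

#' Alignment accounting by mapping-quality tier
#'
#' Splits accepted alignments into unique MapQ > `mapq_report` and unique
#' MapQ <= `mapq_report` tiers, per sample, alongside rejected read
#' counts.
#'
#' @param aln an [align_reads()] result.
#' @param mapq_report reporting threshold (default 10).
#' @return data.frame per sample with `high_mapq`, `low_mapq`, `rejected`.
#' @export
alignment_stats <- function(aln, mapq_report = 10L) {
  sample <- mapq <- NULL
  hi <- aln$alignments[, .(high_mapq = sum(mapq > mapq_report),
                           low_mapq = sum(mapq <= mapq_report)),
                       by = sample]
  rej <- aln$rejected[, .(rejected = .N), by = sample]
  out <- merge(hi, rej, by = "sample", all = TRUE)
  for (cl in c("high_mapq", "low_mapq", "rejected")) {
    out[[cl]][is.na(out[[cl]])] <- 0L
  }
  as.data.frame(out)
}

#' Infer per-position base evidence from aligned colour reads
#'
#' Applies the two-base-encoding substitution rule to every accepted
#' alignment: a run of exactly two adjacent colour mismatches whose implied
#' base change is self-consistent yields one alternate-base observation at
#' that reference position; isolated mismatches (and longer inconsistent
#' runs) are treated as sequencing errors whose affected base positions
#' yield no observation; all other covered positions support the reference
#' base.
#'
#' @param aln an [align_reads()] result (or its `alignments` table).
#' @param reads the read table that was aligned (columns `id`, `colors`).
#' @param index the [build_index()] used.
#' @param mapq_min minimum mapping quality for a read to contribute
#'   evidence (default 17, the genotyping cut).
#' @return A list of class `base_evidence`: `alt_obs` (data.table `sample`,
#'   `contig`, `pos` 1-based original coordinates, `base`), `excluded`
#'   (same shape, error-affected positions), `coverage` (data.table
#'   `sample`, `contig`, `start`, `end` 1-based inclusive intervals, one
#'   per read).
#' @export
collect_evidence <- function(aln, reads, index, mapq_min = 17L) {
  alignments <- if (is.data.frame(aln)) aln else aln$alignments
  alignments <- alignments[alignments$mapq > mapq_min, ]
  if (!nrow(alignments)) stop("no alignments above the mapping-quality cut")
  M <- .color_matrix(reads$colors)
  L <- ncol(M)
  ridx <- match(alignments$id, reads$id)
  stopifnot(!anyNA(ridx))
  pc <- index$primer_code
  ctg_idx <- match(alignments$contig, names(index$contigs))
  nvec <- vapply(index$contigs, `[[`, integer(1), "n")

  # coverage intervals in original 1-based coordinates
  fwd <- alignments$strand == "+"
  cov_start <- ifelse(fwd, alignments$placement,
                      nvec[ctg_idx] - alignments$placement - L + 2L)
  coverage <- data.table::data.table(
    sample = alignments$sample, contig = alignments$contig,
    start = as.integer(cov_start), end = as.integer(cov_start + L - 1L))

  alt_list <- list()
  excl_list <- list()
  with_mm <- which(alignments$mismatches > 0L)
  for (a in with_mm) {
    cc <- index$contigs[[ctg_idx[a]]]
    codes <- if (fwd[a]) cc$codes_f else cc$codes_r
    cols <- if (fwd[a]) cc$colors_f else cc$colors_r
    p <- alignments$placement[a]
    rc <- M[ridx[a], ]
    mism <- which(c(rc[1L] != bitwXor(pc, codes[p]),
                    rc[-1L] != cols[p:(p + L - 2L)]))
    runs <- split(mism, cumsum(c(1L, diff(mism) != 1L)))
    bad_bases <- integer(0)
    for (run in runs) {
      is_snp <- FALSE
      if (length(run) == 2L) {
        j <- run[1L]                       # read base index of the change
        q <- p + j - 1L                    # strand base position (1-based)
        prev_code <- if (j == 1L) pc else codes[q - 1L]
        alt_a <- bitwXor(prev_code, rc[j])
        alt_b <- bitwXor(codes[q + 1L], rc[j + 1L])
        if (alt_a == alt_b && alt_a != codes[q]) {
          is_snp <- TRUE
          if (fwd[a]) {
            pos <- q
            base <- .code_base[alt_a + 1L]
          } else {
            pos <- nvec[ctg_idx[a]] - q + 1L
            base <- .complement[[.code_base[alt_a + 1L]]]
          }
          alt_list[[length(alt_list) + 1L]] <- data.table::data.table(
            sample = alignments$sample[a], contig = alignments$contig[a],
            pos = as.integer(pos), base = base)
        }
      }
      if (!is_snp) {
        bb <- (min(run) - 1L):max(run)
        bad_bases <- c(bad_bases, bb[bb >= 1L & bb <= L])
      }
    }
    if (length(bad_bases)) {
      q <- p + unique(bad_bases) - 1L
      pos <- if (fwd[a]) q else nvec[ctg_idx[a]] - q + 1L
      excl_list[[length(excl_list) + 1L]] <- data.table::data.table(
        sample = alignments$sample[a], contig = alignments$contig[a],
        pos = as.integer(pos))
    }
  }
  empty <- data.table::data.table(sample = character(0),
                                  contig = character(0), pos = integer(0))
  structure(list(
    alt_obs = if (length(alt_list)) data.table::rbindlist(alt_list)
              else data.table::copy(empty)[, base := character(0)][],
    excluded = if (length(excl_list)) data.table::rbindlist(excl_list)
               else empty,
    coverage = coverage),
    class = "base_evidence")
}
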