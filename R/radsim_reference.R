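# Synthetic reference genomes with planted restriction sites and
# near-miss motifs (single-base-away gain candidates).

#' Simulate a reference genome with planted restriction sites
#'
#' Generates random contigs, removes every spurious occurrence of the
#' enzyme's recognition motif, then plants recognition sites at
#' approximately the requested density together with "near-miss" motifs
#' (the recognition sequence with its last base substituted) that serve as
#' candidate positions for restriction-site gain mutations in
#' [simulate_population()]. Planted features keep a minimum separation so
#' that every RAD locus has room for full-length reads.
#'
#' @param n_contigs number of contigs.
#' @param lengths contig length(s) in bp, recycled to `n_contigs`.
#' @param site_density planted recognition sites per bp (default one per
#'   8 kb).
#' @param gain_density near-miss gain-candidate motifs per bp (default 7%
#'   of `site_density`).
#' @param enzyme a [restriction_enzyme()].
#' @param organellar names of contigs to label organellar (e.g. a small
#'   plastid-like contig); labels flow into the site catalog.
#' @param min_separation minimum distance in bp between planted features.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A list of class `rad_reference`: `genome` (named character
#'   vector), `catalog` (the [digest_catalog()] of the emitted genome),
#'   `gain_candidates` (data.table `contig`, `pos0`, `ref_base`,
#'   `gain_base`, `offset` of the substituted motif base) and `enzyme`.
#' @export
simulate_reference <- function(n_contigs = 1L, lengths = 1e6,
                               site_density = 1 / 8000,
                               gain_density = site_density * 0.07,
                               enzyme = bamhi(), organellar = character(0),
                               min_separation = 200L, seed = 1L) {
  stopifnot(n_contigs >= 1L, all(lengths > 0))
  lengths <- as.integer(rep_len(lengths, n_contigs))
  motif_len <- nchar(enzyme$recognition)
  if ((site_density + gain_density) * min_separation > 0.5) {
    stop("site density too high for the requested minimum separation")
  }
  set.seed(seed)
  motif <- strsplit(enzyme$recognition, "")[[1L]]
  # near-miss motif: last base replaced, so a single substitution restores it
  off <- motif_len - 1L
  gain_base <- motif[off + 1L]
  nearmiss <- motif
  nearmiss[off + 1L] <- setdiff(c("A", "C", "G", "T"), gain_base)[1L]

  genome <- character(n_contigs)
  names(genome) <- paste0("chr", seq_len(n_contigs))
  if (length(organellar)) {
    stopifnot(all(organellar %in% names(genome) | organellar %in%
                    paste0("chr", seq_len(n_contigs))))
  }
  gains <- vector("list", n_contigs)
  for (ci in seq_len(n_contigs)) {
    len <- lengths[ci]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # destroy spurious recognition motifs (scan-and-mutate until clean)
    repeat {
      hits <- find_sites(paste(bases, collapse = ""), enzyme)
      if (!length(hits)) break
      mid <- hits + (motif_len %/% 2L) + 1L
      bases[mid] <- vapply(bases[mid],
                           function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1L), "")
    }
    n_sites <- max(0L, round(len * site_density))
    n_gain <- max(0L, round(len * gain_density))
    pos <- .plant_positions(len - motif_len, n_sites + n_gain,
                            min_separation)
    if (length(pos) < n_sites + n_gain) {
      stop("could not plant the requested feature density on contig ",
           names(genome)[ci])
    }
    take_gain <- sample(length(pos), n_gain)
    site_pos <- if (n_gain) pos[-take_gain] else pos
    gain_pos <- pos[take_gain]
    for (p in site_pos) bases[(p + 1L):(p + motif_len)] <- motif
    for (p in gain_pos) bases[(p + 1L):(p + motif_len)] <- nearmiss
    genome[ci] <- paste(bases, collapse = "")
    gains[[ci]] <- data.table::data.table(
      contig = names(genome)[ci],
      pos0 = as.integer(sort(gain_pos)),
      ref_base = nearmiss[off + 1L], gain_base = gain_base,
      offset = off)
  }
  structure(list(genome = genome,
                 catalog = digest_catalog(genome, enzyme,
                                          organellar = organellar),
                 gain_candidates = data.table::rbindlist(gains),
                 enzyme = enzyme),
            class = "rad_reference")
}

# sample n 0-based positions in [min_separation, max_pos -
# min_separation], pairwise separated by >= min_separation and uniform
# over the contig
.plant_positions <- function(max_pos, n, min_separation) {
  if (n == 0L) return(integer(0))
  span <- max_pos - 2L * min_separation
  if (span < n) return(integer(0))
  for (mult in c(2L, 4L, 8L)) {
    cand <- sort(sample.int(span, min(n * mult, span)) + min_separation)
    ok <- integer(0)
    last <- -min_separation
    for (p in cand) {
      if (p - last >= min_separation) {
        ok <- c(ok, p)
        last <- p
      }
    }
    if (length(ok) == n) return(ok)
    if (length(ok) > n) return(sort(ok[sample.int(length(ok), n)]))
  }
  ok
}

#' @export
print.rad_reference <- function(x, ...) {
  cat(sprintf("<rad_reference: %d contig(s), %d bp, %d sites, %d gain candidates>\n",
              length(x$genome), sum(nchar(x$genome)), x$catalog$n_sites,
              nrow(x$gain_candidates)))
  invisible(x)
}
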