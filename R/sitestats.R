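# Restriction-site recovery accounting, depth-bias diagnostics and SNP
# density summaries.

#' Tabulate recovered restriction sites against the catalog
#'
#' Anchors accepted alignments at their restriction-site positions,
#' declares a site recovered when its total alignment count reaches
#' `min_alignments`, and partitions recovered sites into predicted /
#' unpredicted (present / absent in the in-silico digestion catalog)
#' crossed with nuclear / organellar contig class.
#'
#' @param alignments accepted-alignment table from [align_reads()] (needs
#'   `contig`, `site_pos0`, `side`, `sample`).
#' @param catalog a [digest_catalog()].
#' @param min_alignments recovery depth threshold (default 10).
#' @return A list of class `site_recovery`: `sites` (data.table per
#'   recovered site: `contig`, `pos0`, `predicted`, `class`, `n_align`),
#'   `counts` (data.frame of the four classes plus `total`), and `shares`
#'   (predicted / unpredicted fractions).
#' @export
classify_sites <- function(alignments, catalog, min_alignments = 10L) {
  contig <- site_pos0 <- pos0 <- predicted <- cls <- NULL
  tab <- data.table::as.data.table(alignments)[
    , .(n_align = .N), by = .(contig, pos0 = site_pos0)]
  tab <- tab[tab$n_align >= min_alignments]
  key <- paste(catalog$sites$contig, catalog$sites$pos0)
  tab[, predicted := paste(contig, pos0) %in% key]
  tab[, cls := unname(catalog$contig_class[contig])]
  counts <- data.frame(
    predicted = sum(tab$predicted & tab$cls == "nuclear"),
    unpredicted = sum(!tab$predicted & tab$cls == "nuclear"),
    organellar_predicted = sum(tab$predicted & tab$cls == "organellar"),
    organellar_unpredicted = sum(!tab$predicted & tab$cls == "organellar"))
  counts$total <- sum(unlist(counts))
  structure(list(sites = tab[], counts = counts,
                 shares = site_class_shares(
                   counts$predicted, counts$unpredicted,
                   counts$organellar_predicted,
                   counts$organellar_unpredicted)),
            class = "site_recovery")
}

#' Predicted / unpredicted shares from classification counts
#'
#' Pure accounting on a four-way site classification (nuclear and
#' organellar, predicted and unpredicted): total and the fraction of
#' recovered sites that were predicted by the in-silico digestion.
#'
#' @param predicted,unpredicted nuclear site counts.
#' @param organellar_predicted,organellar_unpredicted organellar counts.
#' @return A list: `total`, `predicted_share`, `unpredicted_share`.
#' @export
site_class_shares <- function(predicted, unpredicted,
                              organellar_predicted = 0,
                              organellar_unpredicted = 0) {
  total <- predicted + unpredicted + organellar_predicted +
    organellar_unpredicted
  list(total = total,
       predicted_share = (predicted + organellar_predicted) / total,
       unpredicted_share = (unpredicted + organellar_unpredicted) / total)
}

#' Flag sites with one-sided read-depth asymmetry
#'
#' A site is flagged when more than `sample_frac` of the samples have
#' depth above `depth_min` at exactly one of the two flanking RAD loci
#' (always the same side).
#'
#' @param up,down integer matrices (sites x samples) of per-side locus
#'   depths.
#' @param depth_min per-locus depth defining "high depth" (default 10,
#'   exceeded strictly).
#' @param sample_frac fraction of samples that must be one-sided
#'   (default 0.8, exceeded strictly).
#' @return Logical vector, one flag per site.
#' @export
depth_asymmetry <- function(up, down, depth_min = 10L, sample_frac = 0.8) {
  stopifnot(all(dim(up) == dim(down)))
  up_only <- rowMeans(up > depth_min & down <= depth_min)
  down_only <- rowMeans(down > depth_min & up <= depth_min)
  up_only > sample_frac | down_only > sample_frac
}

#' Correlation between locus depth and restriction-fragment length
#'
#' Pearson correlation between RAD-locus read depth and
#' `log10(restriction fragment length)`, overall and stratified at a
#' fragment-length boundary (default 10 kb).
#'
#' @param depth numeric vector of per-locus read depths.
#' @param fraglen matching vector of flanking restriction-fragment lengths
#'   (bp); the fragment on the side the locus reads into.
#' @param boundary stratification boundary in bp.
#' @return data.frame with one row per stratum (`all`, `short`, `long`):
#'   `n`, `r`, `p_value`; degenerate strata (fewer than 3 loci or zero
#'   variance) report `NA`.
#' @export
depth_fraglen_correlation <- function(depth, fraglen, boundary = 1e4) {
  stopifnot(length(depth) == length(fraglen), all(fraglen > 0))
  strata <- list(all = rep(TRUE, length(depth)),
                 short = fraglen < boundary,
                 long = fraglen >= boundary)
  out <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    x <- depth[sel]
    y <- log10(fraglen[sel])
    if (sum(sel) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(stratum = nm, n = sum(sel), r = NA_real_,
                        p_value = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(stratum = nm, n = sum(sel), r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' SNP density in genomic windows
#'
#' Counts SNPs in non-overlapping windows tiling each contig (the final
#' partial window is kept), reports per-contig totals, and the Pearson
#' correlation between contig length and SNP count.
#'
#' @param sites data.frame with `contig` and `pos` (1-based, sorted within
#'   contig), e.g. a `variant_set`'s `sites`.
#' @param contig_lengths named vector of contig lengths (bp).
#' @param window window size in bp (default 500 kb).
#' @return A list: `bins` (data.frame `contig`, `start`, `end`, `n`),
#'   `per_contig` (`contig`, `length`, `n`), `size_correlation` (list
#'   `r`, `p_value`; `NA` with fewer than 3 contigs), `mean_per_bin`.
#' @export
snp_density <- function(sites, contig_lengths, window = 5e5) {
  stopifnot(all(sites$contig %in% names(contig_lengths)))
  for (ct in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ct]
    if (is.unsorted(p)) stop("sites must be position-sorted within contig")
  }
  bins <- do.call(rbind, lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- seq(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    p <- sites$pos[sites$contig == ct]
    n <- tabulate(findInterval(p, starts), nbins = length(starts))
    data.frame(contig = ct, start = starts, end = ends, n = n)
  }))
  per_contig <- data.frame(
    contig = names(contig_lengths),
    length = as.integer(contig_lengths),
    n = as.integer(table(factor(sites$contig,
                                levels = names(contig_lengths)))))
  size_cor <- list(r = NA_real_, p_value = NA_real_)
  if (nrow(per_contig) >= 3L && stats::sd(per_contig$length) > 0 &&
      stats::sd(per_contig$n) > 0) {
    ct <- stats::cor.test(per_contig$length, per_contig$n)
    size_cor <- list(r = unname(ct$estimate), p_value = ct$p.value)
  }
  list(bins = bins, per_contig = per_contig, size_correlation = size_cor,
       mean_per_bin = mean(bins$n))
}
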