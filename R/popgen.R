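# Genotype-matrix container, filtering, LD-kNNi imputation, diversity
# statistics, LD decay, MAF spectra and call-set concordance.

#' Construct a genotype matrix
#'
#' Samples-by-loci diploid dosage matrix with entries 0/1/2 (copies of the
#' alternate allele) or `NA` for missing, plus locus and sample metadata.
#'
#' @param geno integer matrix, samples in rows, loci in columns.
#' @param loci data.frame with at least `contig` and `pos` (1-based),
#'   usually also `ref` and `alt`; positions must be sorted within contig.
#' @param samples data.frame with at least `sample`, optionally `subpop`
#'   (`"cultivated"` / `"wild"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(loci),
            all(c("contig", "pos") %in% names(loci)),
            "sample" %in% names(samples))
  if (any(!is.na(geno) & (geno < 0L | geno > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  ord <- order(loci$contig, loci$pos)
  if (is.unsorted(ord)) {
    geno <- geno[, ord, drop = FALSE]
    loci <- loci[ord, , drop = FALSE]
  }
  rownames(geno) <- samples$sample
  structure(list(geno = geno, loci = as.data.frame(loci),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d samples x %d loci, %.1f%% missing>\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

.subpop_idx <- function(gm, subpop) {
  if (is.null(gm$samples$subpop)) stop("genotype matrix has no subpop labels")
  which(gm$samples$subpop == subpop)
}

.gm_subset <- function(gm, samples = NULL, loci = NULL) {
  g <- gm$geno
  s <- gm$samples
  l <- gm$loci
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  if (!is.null(loci)) {
    g <- g[, loci, drop = FALSE]
    l <- l[loci, , drop = FALSE]
  }
  genotype_matrix(g, l, s)
}

#' Filter samples and loci by missing rate
#'
#' Samples are removed first (missing rate above `sample_miss`), then loci
#' whose missing rate, computed on the retained samples, exceeds
#' `snp_miss`.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_miss maximum tolerated per-sample missing rate (strictly
#'   greater is removed; default 0.5).
#' @param snp_miss maximum tolerated per-locus missing rate (default 0.2).
#' @return The filtered [genotype_matrix()] with attribute `report`, a
#'   data.frame of removal counts per step.
#' @export
filter_matrix <- function(gm, sample_miss = 0.5, snp_miss = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$geno) > 0)
  smiss <- rowMeans(is.na(gm$geno))
  keep_s <- smiss <= sample_miss
  if (!any(keep_s)) stop("all samples removed by the missing-rate filter")
  g2 <- gm$geno[keep_s, , drop = FALSE]
  lmiss <- colMeans(is.na(g2))
  keep_l <- lmiss <= snp_miss
  out <- .gm_subset(gm, samples = which(keep_s), loci = which(keep_l))
  attr(out, "report") <- data.frame(
    step = c("samples_removed", "loci_removed"),
    n = c(sum(!keep_s), sum(!keep_l)))
  out
}

#' Remove loci by minor allele frequency
#'
#' MAF is computed from allele counts over non-missing genotypes. Loci with
#' MAF strictly lower than `maf_min` are removed (a locus at exactly the
#' threshold is retained); monomorphic loci have MAF 0 and are removed.
#'
#' @inheritParams filter_matrix
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return The filtered [genotype_matrix()] with attribute `report`.
#' @export
maf_filter <- function(gm, maf_min = 0.05) {
  maf <- .maf(gm$geno)
  keep <- !is.na(maf) & maf >= maf_min
  out <- .gm_subset(gm, loci = which(keep))
  attr(out, "report") <- data.frame(step = "maf_removed", n = sum(!keep))
  out
}

# per-locus minor allele frequency over non-missing genotypes
.maf <- function(geno) {
  n <- colSums(!is.na(geno))
  p <- colSums(geno, na.rm = TRUE) / (2 * n)
  pmin(p, 1 - p)
}

#' LD-kNNi genotype imputation
#'
#' Imputes each missing genotype from the `k` nearest samples, with sample
#' distances computed over the `l` loci in highest LD (squared genotype
#' correlation) with the target locus: the distance between two samples is
#' the mean absolute dosage difference over the selected loci at which both
#' are observed, and the imputed genotype maximises the sum of `1/(d+eps)`
#' weights among the neighbours carrying it (ties resolved towards the
#' smaller dosage). Observed entries are never altered.
#'
#' @inheritParams filter_matrix
#' @param k number of nearest neighbour samples (default 5).
#' @param l number of highest-LD proxy loci (default 20).
#' @param eps small constant guarding the inverse-distance weights.
#' @return A complete [genotype_matrix()] (no missing entries).
#' @export
impute_ldknni <- function(gm, k = 5L, l = 20L, eps = 1e-9) {
  g <- gm$geno
  n_s <- nrow(g)
  n_l <- ncol(g)
  stopifnot(n_s >= k + 1L, n_l >= l + 1L)
  if (any(colSums(!is.na(g)) == 0L)) {
    stop("loci with all entries missing cannot be imputed")
  }
  miss_loci <- which(colSums(is.na(g)) > 0L)
  if (!length(miss_loci)) return(gm)
  gd <- g
  storage.mode(gd) <- "double"
  out <- g
  for (j in miss_loci) {
    r2 <- suppressWarnings(
      stats::cor(gd[, j], gd, use = "pairwise.complete.obs"))^2
    r2[j] <- NA
    r2[is.na(r2)] <- -Inf
    proxies <- order(r2, decreasing = TRUE)[seq_len(l)]
    sub <- gd[, proxies, drop = FALSE]
    obs_at_j <- which(!is.na(g[, j]))
    for (s in which(is.na(g[, j]))) {
      diffs <- abs(sweep(sub[obs_at_j, , drop = FALSE], 2L, sub[s, ]))
      d <- rowMeans(diffs, na.rm = TRUE)
      d[is.nan(d)] <- Inf
      nb <- obs_at_j[order(d)[seq_len(min(k, length(obs_at_j)))]]
      w <- 1 / (d[match(nb, obs_at_j)] + eps)
      score <- vapply(0:2, function(gt) sum(w[g[nb, j] == gt]), numeric(1))
      out[s, j] <- (0:2)[which.max(score)]
    }
  }
  gm$geno <- out
  gm
}

#' Per-subpopulation diversity statistics
#'
#' For each subpopulation: per-locus observed heterozygosity (fraction of
#' heterozygotes) and unbiased expected heterozygosity
#' `(2n/(2n-1)) * 2pq`; multilocus `H_O` and `H_E` are means over loci and
#' `F_IS = 1 - mean(H_O)/mean(H_E)` (ratio of multilocus averages;
#' `per_locus_fis = TRUE` averages the per-locus `1 - Ho/He` instead).
#' Private alleles (`PA`) count the loci at which some allele is present in
#' the subpopulation and absent from the other.
#'
#' @inheritParams filter_matrix
#' @param subpops subpopulation labels to evaluate (default all present).
#' @param unbiased use the sample-size-corrected expected heterozygosity
#'   (default) or the naive `2pq`.
#' @param per_locus_fis average per-locus Fis instead of the multilocus
#'   ratio of averages.
#' @return data.frame with one row per subpopulation: `subpop`, `n`,
#'   `n_loci`, `Ho`, `He`, `Fis`, `PA`.
#' @export
diversity <- function(gm, subpops = unique(gm$samples$subpop),
                      unbiased = TRUE, per_locus_fis = FALSE) {
  stopifnot(length(subpops) >= 1L)
  present <- lapply(subpops, function(sp) {
    idx <- .subpop_idx(gm, sp)
    if (length(idx) < 2L) stop("subpopulation ", sp, " has fewer than 2 samples")
    g <- gm$geno[idx, , drop = FALSE]
    n <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    list(idx = idx, g = g, n = n,
         has_ref = alt < 2L * n, has_alt = alt > 0L)
  })
  names(present) <- subpops
  out <- lapply(seq_along(subpops), function(i) {
    pp <- present[[i]]
    g <- pp$g
    n <- pp$n
    ok <- n >= 2L
    p <- colSums(g, na.rm = TRUE)[ok] / (2 * n[ok])
    ho <- colSums(g == 1L, na.rm = TRUE)[ok] / n[ok]
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * (2 * n[ok]) / (2 * n[ok] - 1)
    fis <- if (per_locus_fis) {
      mean(1 - ho[he > 0] / he[he > 0])
    } else {
      1 - mean(ho) / mean(he)
    }
    pa <- 0L
    others <- present[setdiff(seq_along(subpops), i)]
    if (length(others)) {
      o_ref <- Reduce(`|`, lapply(others, `[[`, "has_ref"))
      o_alt <- Reduce(`|`, lapply(others, `[[`, "has_alt"))
      pa <- sum((pp$has_ref & !o_ref) | (pp$has_alt & !o_alt))
    }
    data.frame(subpop = subpops[i], n = length(pp$idx), n_loci = sum(ok),
               Ho = mean(ho), He = mean(he), Fis = fis, PA = pa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay
#'
#' Computes `r^2` (squared Pearson correlation of 0/1/2 dosages over
#' samples with both genotypes observed) for all same-contig locus pairs up
#' to `max_dist` apart, then summarises the decay as the median `r^2` in
#' sequential half-open distance bins. The reported `dist_below` is the
#' midpoint of the first bin whose median falls below `r2_threshold`.
#'
#' @inheritParams filter_matrix
#' @param subpop optional subpopulation label restricting the samples.
#' @param bin distance bin width in bp (default 10 kb).
#' @param maf_min pairs are restricted to loci with within-panel MAF at or
#'   above this (default 0.05).
#' @param max_dist maximum pair distance in bp (default 500 kb).
#' @param r2_threshold decay threshold (default 0.2).
#' @return A list of class `ld_result`: `pairs` (data.table `dist`, `r2`),
#'   `curve` (data.table `bin_start`, `bin_mid`, `n`, `median_r2`; empty
#'   bins have `NA` medians) and `dist_below`.
#' @export
ld_decay <- function(gm, subpop = NULL, bin = 1e4, maf_min = 0.05,
                     max_dist = 5e5, r2_threshold = 0.2) {
  idx <- if (is.null(subpop)) seq_len(nrow(gm$geno)) else
    .subpop_idx(gm, subpop)
  g <- gm$geno[idx, , drop = FALSE]
  maf <- .maf(g)
  keep <- !is.na(maf) & maf >= maf_min
  g <- g[, keep, drop = FALSE]
  loci <- gm$loci[keep, , drop = FALSE]
  storage.mode(g) <- "double"
  pair_list <- list()
  for (ct in unique(loci$contig)) {
    li <- which(loci$contig == ct)
    if (length(li) < 2L) next
    cc <- suppressWarnings(
      stats::cor(g[, li, drop = FALSE], use = "pairwise.complete.obs"))
    dd <- abs(outer(loci$pos[li], loci$pos[li], "-"))
    ut <- upper.tri(cc)
    sel <- ut & dd > 0 & dd <= max_dist & !is.na(cc)
    pair_list[[ct]] <- data.table::data.table(dist = dd[sel],
                                              r2 = cc[sel]^2)
  }
  pairs <- data.table::rbindlist(pair_list)
  n_bins <- ceiling(max_dist / bin)
  starts <- (seq_len(n_bins) - 1) * bin
  dist <- r2 <- NULL
  med <- pairs[, .(n = .N, median_r2 = stats::median(r2)),
               by = .(bin_start = floor(dist / bin) * bin)]
  curve <- data.table::data.table(bin_start = starts)
  curve <- merge(curve, med, by = "bin_start", all.x = TRUE)
  curve[, bin_mid := bin_start + bin / 2]
  curve[is.na(n), n := 0L]
  below <- which(!is.na(curve$median_r2) &
                   curve$median_r2 < r2_threshold)
  structure(list(pairs = pairs, curve = curve[],
                 dist_below = if (length(below)) curve$bin_mid[min(below)]
                              else NA_real_,
                 r2_threshold = r2_threshold),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result: %d pairs, median r2 first below %.2f at %s bp>\n",
              nrow(x$pairs), x$r2_threshold,
              format(x$dist_below, big.mark = ",")))
  invisible(x)
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of within-subpopulation MAF in bins of `binwidth` (default
#' 0.05), over all loci of the matrix including those monomorphic in the
#' subpopulation (MAF 0). The count of loci with MAF below 0.1 is reported
#' alongside.
#'
#' @inheritParams ld_decay
#' @param binwidth histogram bin width.
#' @return A list: `spectrum` (data.frame `bin_start`, `bin_end`, `n`),
#'   `n_below_0.1`, `n_loci`.
#' @export
maf_spectrum <- function(gm, subpop = NULL, binwidth = 0.05) {
  idx <- if (is.null(subpop)) seq_len(nrow(gm$geno)) else
    .subpop_idx(gm, subpop)
  maf <- .maf(gm$geno[idx, , drop = FALSE])
  maf <- maf[!is.na(maf)]
  edges <- seq(0, 0.5, by = binwidth)
  bin <- pmin(findInterval(maf, edges), length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  list(spectrum = data.frame(bin_start = edges[-length(edges)],
                             bin_end = edges[-1L], n = counts),
       n_below_0.1 = sum(maf < 0.1), n_loci = length(maf))
}

#' Genotype concordance between two call sets
#'
#' Compares genotypes over the shared loci and samples of two genotype
#' matrices; entries missing in either set are excluded from both numerator
#' and denominator.
#'
#' @param a,b [genotype_matrix()] objects.
#' @return A list: `rate` (fitted-genotype fraction), `n_compared`,
#'   `n_mismatch`, and `per_locus` (data.frame with per-locus compared and
#'   mismatch counts).
#' @export
concordance <- function(a, b) {
  key_a <- paste(a$loci$contig, a$loci$pos)
  key_b <- paste(b$loci$contig, b$loci$pos)
  loci <- intersect(key_a, key_b)
  smp <- intersect(a$samples$sample, b$samples$sample)
  if (!length(loci) || !length(smp)) {
    stop("no shared loci and samples to compare")
  }
  ga <- a$geno[match(smp, a$samples$sample), match(loci, key_a),
               drop = FALSE]
  gb <- b$geno[match(smp, b$samples$sample), match(loci, key_b),
               drop = FALSE]
  cmp <- !is.na(ga) & !is.na(gb)
  if (!any(cmp)) stop("zero comparable genotype pairs")
  mism <- cmp & (ga != gb)
  list(rate = 1 - sum(mism) / sum(cmp),
       n_compared = sum(cmp), n_mismatch = sum(mism),
       per_locus = data.frame(locus = loci,
                              compared = colSums(cmp),
                              mismatches = colSums(mism),
                              row.names = NULL))
}
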