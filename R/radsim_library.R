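# RAD library and SOLiD sequencing simulator: for every restriction site
# surviving on a haplotype, biotin capture yields an upstream and a
# downstream read stack starting exactly at the cut with the sticky-end
# sequence; reads are colour-encoded with independent per-colour errors.

#' Parameters of the library and sequencing model
#'
#' @param read_length raw read length in colours (default 75).
#' @param shear_range random-shear fragment size range in bp (default
#'   150-350); reads are truncated and flagged if a restriction fragment is
#'   shorter than a read.
#' @param depth_mean expected reads per RAD locus per sample, split evenly
#'   between the haplotypes carrying the site.
#' @param sample_cv coefficient of variation of the per-sample depth
#'   multiplier (gamma-distributed library-size effect).
#' @param error_rate independent per-colour error probability (default
#'   0.01).
#' @param shear_bias when `TRUE`, locus depth scales with the logarithm of
#'   the flanking restriction-fragment length (the shearing-step bias);
#'   when `FALSE`, depth is independent of fragment length.
#' @return A list of class `library_model`.
#' @export
library_model <- function(read_length = 75L, shear_range = c(150L, 350L),
                          depth_mean = 12, sample_cv = 0.2,
                          error_rate = 0.01, shear_bias = FALSE) {
  stopifnot(read_length >= 20L, length(shear_range) == 2L,
            all(shear_range > 0), shear_range[1] <= shear_range[2],
            depth_mean > 0, sample_cv >= 0,
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 shear_range = as.integer(shear_range),
                 depth_mean = depth_mean, sample_cv = sample_cv,
                 error_rate = error_rate, shear_bias = shear_bias),
            class = "library_model")
}

# restriction-fragment length flanking each site on each side, from the
# predicted catalog cuts (contig ends close the terminal fragments)
.site_fraglen <- function(sites, catalog) {
  enz <- catalog$enzyme
  out <- matrix(NA_real_, nrow(sites), 2L,
                dimnames = list(NULL, c("up", "down")))
  for (ct in unique(sites$contig)) {
    cuts <- sort(catalog$sites$pos0[catalog$sites$contig == ct] +
                   enz$cut_offset)
    clen <- catalog$contig_len[[ct]]
    bounds <- c(0L, cuts, clen)
    six <- which(sites$contig == ct)
    cut_here <- sites$pos0[six] + enz$cut_offset
    iv <- findInterval(cut_here, bounds, left.open = TRUE)
    # a predicted site's own cut is a fragment boundary: its downstream
    # fragment runs to the next cut, not to itself
    nxt <- iv + 1L + (bounds[iv + 1L] == cut_here)
    out[six, "up"] <- cut_here - bounds[iv]
    out[six, "down"] <- bounds[nxt] - cut_here
  }
  out
}

#' Simulate colour-space RAD reads for a germplasm panel
#'
#' For each sample, haplotype and restriction site present on that
#' haplotype, generates downstream (top-strand) and upstream
#' (bottom-strand) read stacks starting at the cut with the sticky-end
#' sequence, applies the sample's variant alleles, encodes in colour space
#' from the T primer and plants independent per-colour errors.
#'
#' @param pop a [simulate_population()] result.
#' @param library a [library_model()].
#' @param seed integer seed.
#' @return A list of class `rad_library`: `reads` (data.frame `id`,
#'   `sample`, `primer`, `colors`, `truncated`) and `provenance`
#'   (data.table `id`, `sample`, `site_id`, `side`, `hap`), plus the
#'   per-locus expected-depth table `depth_model`.
#' @export
simulate_library <- function(pop, library = library_model(), seed = 1L) {
  stopifnot(inherits(pop, "rad_population"),
            inherits(library, "library_model"))
  set.seed(seed)
  enzyme <- pop$reference$enzyme
  genome <- pop$reference$genome
  motif_len <- nchar(enzyme$recognition)
  rl <- library$read_length
  sticky_len <- nchar(enzyme$sticky_end)
  sites <- pop$truth$sites
  loci <- pop$truth$loci
  pres <- pop$truth$site_presence
  n_samples <- nrow(pop$samples)
  fraglen <- .site_fraglen(sites, pop$reference$catalog)
  bias <- matrix(1, nrow(sites), 2L, dimnames = list(NULL, c("up", "down")))
  if (library$shear_bias) {
    lg <- log10(pmax(fraglen, 100))
    bias[] <- lg / mean(lg)
  }
  sample_mult <- if (library$sample_cv > 0) {
    shp <- 1 / library$sample_cv^2
    stats::rgamma(n_samples, shape = shp, rate = shp)
  } else rep(1, n_samples)

  loci_by_site <- split(seq_len(nrow(loci)), loci$site_id)
  read_rows <- list()
  color_rows <- list()
  n_out <- 0L
  for (r in seq_len(nrow(sites))) {
    ct <- sites$contig[r]
    p0 <- sites$pos0[r]                 # 0-based recognition start
    clen <- nchar(genome[[ct]])
    lix <- loci_by_site[[as.character(sites$site_id[r])]]
    lpos0 <- loci$pos0[lix]
    lalt <- loci$alt[lix]
    for (side in c("down", "up")) {
      # raw read window in 0-based original coordinates; the downstream
      # read runs top-strand from the top cut, the upstream read runs
      # bottom-strand from the bottom cut (both begin with the sticky end)
      if (side == "down") {
        w0 <- p0 + enzyme$cut_offset
        w1 <- w0 + rl - 1L
      } else {
        w1 <- p0 + motif_len - 1L - enzyme$cut_offset
        w0 <- w1 - rl + 1L
      }
      trunc_lo <- max(w0, 0L)
      trunc_hi <- min(w1, clen - 1L)
      truncated <- trunc_lo != w0 || trunc_hi != w1
      win <- strsplit(substring(genome[[ct]], trunc_lo + 1L, trunc_hi + 1L),
                      "", fixed = TRUE)[[1L]]
      in_win <- which(lpos0 >= trunc_lo & lpos0 <= trunc_hi)
      hap_cache <- new.env(parent = emptyenv())
      for (smp in seq_len(n_samples)) {
        for (hap in 1:2) {
          if (!pres[r, smp, hap]) next
          lam <- library$depth_mean / 2 * bias[r, side] * sample_mult[smp]
          depth <- stats::rpois(1L, lam)
          if (depth == 0L) next
          hmat <- if (hap == 1L) pop$truth$h1 else pop$truth$h2
          alle <- hmat[smp, lix[in_win]]
          key <- paste(c("k", alle), collapse = "")
          cached <- get0(key, envir = hap_cache)
          if (is.null(cached)) {
            wb <- win
            subs <- in_win[alle == 1L]
            if (length(subs)) {
              wb[lpos0[subs] - trunc_lo + 1L] <- lalt[subs]
            }
            if (side == "down") {
              codes <- .base_code[wb]
            } else {
              codes <- .base_code[.complement[rev(wb)]]
            }
            cached <- bitwXor(c(.base_code[["T"]],
                                codes[-length(codes)]), codes)
            assign(key, cached, envir = hap_cache)
          }
          read_rows[[length(read_rows) + 1L]] <- data.table::data.table(
            sample = pop$samples$sample[smp], site_id = sites$site_id[r],
            side = side, hap = hap, n = depth, truncated = truncated)
          color_rows[[length(color_rows) + 1L]] <-
            matrix(rep(cached, depth), nrow = depth, byrow = TRUE)
          n_out <- n_out + depth
        }
      }
    }
  }
  if (!n_out) stop("no reads generated")
  prov <- data.table::rbindlist(read_rows)
  n <- NULL
  prov <- prov[rep(seq_len(nrow(prov)), prov$n)][, n := NULL]
  prov[, id := sprintf("r%07d", seq_len(.N))]
  cm <- do.call(rbind, color_rows)
  if (library$error_rate > 0) {
    err <- which(stats::runif(length(cm)) < library$error_rate)
    if (length(err)) {
      cm[err] <- (cm[err] + sample(1:3, length(err), replace = TRUE)) %% 4L
    }
  }
  colors <- do.call(paste0, as.data.frame(cm))
  reads <- data.frame(id = prov$id, sample = prov$sample, primer = "T",
                      colors = colors, truncated = prov$truncated,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads,
                 provenance = prov[, .(id, sample, site_id, side, hap,
                                       truncated)],
                 depth_model = list(fraglen = fraglen, bias = bias,
                                    sample_mult = sample_mult)),
            class = "rad_library")
}

#' @export
print.rad_library <- function(x, ...) {
  cat(sprintf("<rad_library: %d reads, %d samples>\n", nrow(x$reads),
              length(unique(x$reads$sample))))
  invisible(x)
}

#' Write simulated reads as per-sample csfasta files
#'
#' @param lib a [simulate_library()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(lib$reads, lib$reads$sample), function(df) {
    path <- file.path(dir, paste0(df$sample[1L], ".csfasta"))
    write_csfasta(df, path)
    path
  }, "")
  invisible(paths)
}
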