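# Bayesian diploid genotype calling from per-position base evidence and
# multi-sample merging.

#' Genotyper parameters
#'
#' @param error_rate per-base sequencing error probability `e`
#'   (0 < e < 0.5; default 0.01).
#' @param theta heterozygosity prior (0 < theta < 0.1; default 0.001);
#'   genotype priors are `(1 - 3 theta / 2, theta, theta / 2)` for
#'   hom-ref, het and hom-alt.
#' @param min_depth minimum per-sample read depth for a call to enter the
#'   multi-sample merge (default 10).
#' @return A list of class `genotyper_params`.
#' @export
genotyper_params <- function(error_rate = 0.01, theta = 0.001,
                             min_depth = 10L) {
  stopifnot(error_rate > 0, error_rate < 0.5, theta > 0, theta < 0.1,
            min_depth >= 1L)
  structure(list(error_rate = error_rate, theta = theta,
                 min_depth = as.integer(min_depth)),
            class = "genotyper_params")
}

#' Diploid genotype likelihoods
#'
#' For each observed base `b` and genotype `{a1, a2}`,
#' `P(b | a1, a2) = P(b|a1)/2 + P(b|a2)/2` with `P(b|a) = 1 - e` when
#' `b = a` and `e/3` otherwise; the likelihood is the product over the
#' observations. Returned for hom-ref, het and hom-alt.
#'
#' @param obs character vector of observed bases (A/C/G/T); other symbols
#'   are skipped with a warning.
#' @param ref,alt reference and alternate alleles.
#' @param e per-base error rate.
#' @return Numeric length-3 likelihood vector
#'   (`c(hom_ref, het, hom_alt)`), normalised to sum 1.
#' @export
genotype_likelihoods <- function(obs, ref, alt, e = 0.01) {
  bad <- !obs %in% c("A", "C", "G", "T")
  if (any(bad)) {
    warning(sum(bad), " non-ACGT observation(s) skipped")
    obs <- obs[!bad]
  }
  if (!length(obs)) stop("no usable observations")
  counts <- c(ref = sum(obs == ref), alt = sum(obs == alt),
              other = sum(obs != ref & obs != alt))
  .likelihoods_from_counts(counts[["ref"]], counts[["alt"]],
                           counts[["other"]], e)
}

# log-space product likelihood from (n_ref, n_alt, n_other) counts
.likelihoods_from_counts <- function(n_ref, n_alt, n_other, e) {
  p_match <- 1 - e
  p_mis <- e / 3
  p_het <- p_match / 2 + p_mis / 2
  ll <- c(n_ref * log(p_match) + n_alt * log(p_mis),
          (n_ref + n_alt) * log(p_het),
          n_ref * log(p_mis) + n_alt * log(p_match)) +
    n_other * log(p_mis)
  lik <- exp(ll - max(ll))
  lik / sum(lik)
}

#' Call a diploid genotype from likelihoods
#'
#' Combines the likelihood triple with the prior
#' `(1 - 3 theta/2, theta, theta/2)` and returns the
#' maximum-posterior genotype; an exact posterior tie (or an all-zero
#' likelihood) yields a missing call.
#'
#' @param lik numeric length-3 likelihoods for (hom-ref, het, hom-alt).
#' @param theta heterozygosity prior.
#' @return A list: `genotype` (0, 1, 2 dosage or `NA`), `gq`
#'   (Phred-scaled posterior gap, capped at 99), `posterior` (normalised
#'   triple), `pl` (Phred-scaled likelihoods, minimum 0).
#' @export
call_genotype <- function(lik, theta = 0.001) {
  stopifnot(length(lik) == 3L, all(is.finite(lik)), all(lik >= 0))
  prior <- c(1 - 1.5 * theta, theta, theta / 2)
  post <- prior * lik
  if (sum(post) == 0) {
    return(list(genotype = NA_integer_, gq = 0L,
                posterior = rep(NA_real_, 3L), pl = rep(0L, 3L)))
  }
  post <- post / sum(post)
  ord <- order(post, decreasing = TRUE)
  if (post[ord[1L]] == post[ord[2L]]) {
    return(list(genotype = NA_integer_, gq = 0L, posterior = post,
                pl = .to_pl(lik)))
  }
  gq <- min(99L, as.integer(round(10 * (log10(post[ord[1L]]) -
                                          log10(max(post[ord[2L]],
                                                    1e-300))))))
  list(genotype = ord[1L] - 1L, gq = gq, posterior = post,
       pl = .to_pl(lik))
}

.to_pl <- function(lik) {
  lik <- pmax(lik, 1e-300)
  as.integer(round(-10 * (log10(lik) - log10(max(lik)))))
}

#' Call genotypes for all samples from base evidence
#'
#' Builds per-sample calls at every position with at least one
#' alternate-base observation: per position, the alternate allele is the
#' most frequently observed non-reference base across samples (positions
#' whose samples support two different alternate bases are dropped with a
#' warning, keeping records biallelic), likelihoods come from per-sample
#' (ref, alt, other) counts, and genotypes are maximum-posterior calls.
#'
#' @param evidence a [collect_evidence()] result.
#' @param genome named character vector of contig sequences (reference).
#' @param params a [genotyper_params()].
#' @return data.table of sample calls: `contig`, `pos` (1-based), `ref`,
#'   `alt`, `sample`, `gt` dosage, `dp`, `gq`, `pl1-pl3`.
#' @export
call_samples <- function(evidence, genome, params = genotyper_params()) {
  stopifnot(inherits(evidence, "base_evidence"))
  alt_obs <- evidence$alt_obs
  if (!nrow(alt_obs)) stop("no alternate-base evidence to genotype")
  contig <- pos <- base <- sample_ <- NULL
  # consensus alternate allele per position
  site_alt <- alt_obs[, .(n = .N), by = .(contig, pos, base)]
  data.table::setorder(site_alt, contig, pos, -n)
  multi <- unique(site_alt[duplicated(paste(contig, pos)),
                           .(contig, pos)])
  if (nrow(multi)) {
    warning(nrow(multi), " multi-allelic position(s) dropped")
    site_alt <- site_alt[!multi, on = c("contig", "pos")]
  }
  sites <- site_alt[!duplicated(paste(contig, pos)), .(contig, pos, base)]
  data.table::setnames(sites, "base", "alt")
  sites[, ref := substring(genome[contig], pos, pos)]
  sites <- sites[ref != alt]

  samples <- sort(unique(evidence$coverage$sample))
  # depth at candidate positions per sample from coverage intervals
  cov <- evidence$coverage
  depth_tab <- data.table::rbindlist(lapply(samples, function(s) {
    out <- list()
    for (ct in unique(sites$contig)) {
      pos_v <- sites$pos[sites$contig == ct]
      iv <- cov[cov$sample == s & cov$contig == ct]
      if (!nrow(iv)) {
        dp <- rep(0L, length(pos_v))
      } else {
        dp <- findInterval(pos_v, sort(iv$start)) -
          findInterval(pos_v - 1L, sort(iv$end))
      }
      out[[ct]] <- data.table::data.table(sample = s, contig = ct,
                                          pos = pos_v,
                                          dp = as.integer(dp))
    }
    data.table::rbindlist(out)
  }))

  n_alt_tab <- alt_obs[sites, on = c("contig", "pos"),
                       nomatch = NULL][base == alt,
                                       .(n_alt = .N),
                                       by = .(sample, contig, pos)]
  n_oth_tab <- alt_obs[sites, on = c("contig", "pos"),
                       nomatch = NULL][base != alt,
                                       .(n_other_alt = .N),
                                       by = .(sample, contig, pos)]
  excl_tab <- evidence$excluded[, .(n_excl = .N),
                                by = .(sample, contig, pos)]
  tab <- merge(depth_tab, n_alt_tab, by = c("sample", "contig", "pos"),
               all.x = TRUE)
  tab <- merge(tab, n_oth_tab, by = c("sample", "contig", "pos"),
               all.x = TRUE)
  tab <- merge(tab, excl_tab, by = c("sample", "contig", "pos"),
               all.x = TRUE)
  for (cl in c("n_alt", "n_other_alt", "n_excl")) {
    tab[[cl]][is.na(tab[[cl]])] <- 0L
  }
  tab <- merge(tab, sites, by = c("contig", "pos"))
  n_ref <- dp <- n_alt <- n_other_alt <- n_excl <- NULL
  tab[, n_ref := pmax(dp - n_alt - n_other_alt - n_excl, 0L)]
  tab <- tab[dp > 0L]

  res <- tab[, {
    calls <- mapply(function(nr, na, no) {
      lik <- .likelihoods_from_counts(nr, na, no, params$error_rate)
      cg <- call_genotype(lik, params$theta)
      c(cg$genotype, cg$gq, cg$pl)
    }, n_ref, n_alt, n_other_alt)
    .(sample = sample, ref = ref, alt = alt, gt = as.integer(calls[1L, ]),
      dp = dp, gq = as.integer(calls[2L, ]),
      pl1 = as.integer(calls[3L, ]), pl2 = as.integer(calls[4L, ]),
      pl3 = as.integer(calls[5L, ]))
  }, by = .(contig, pos)]
  data.table::setorder(res, contig, pos, sample)
  res[]
}

#' Merge per-sample calls into a multi-sample variant table
#'
#' A position is emitted when at least one sample has a non-reference call
#' with depth at or above `min_depth`; samples below `min_depth` at an
#' emitted position are set to missing. Positions with inconsistent
#' reference alleles raise an error.
#'
#' @param calls a [call_samples()] table (or a compatible data.frame).
#' @param samples character vector fixing the sample columns (defaults to
#'   the samples present).
#' @param min_depth merge depth threshold (default 10).
#' @return A list of class `variant_set`: `sites` (data.frame `contig`,
#'   `pos`, `ref`, `alt`), `geno` (samples x sites dosage matrix with
#'   `NA` for missing), `dp`, `gq` (matching matrices).
#' @export
merge_samples <- function(calls, samples = NULL, min_depth = 10L) {
  calls <- data.table::as.data.table(calls)
  contig <- pos <- ref <- NULL
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  nref <- calls[, .(n = data.table::uniqueN(ref)), by = .(contig, pos)]
  if (any(nref$n > 1L)) {
    stop("inconsistent reference alleles across samples")
  }
  emit <- calls[calls$gt %in% c(1L, 2L) & calls$dp >= min_depth,
                unique(.SD), .SDcols = c("contig", "pos")]
  if (!nrow(emit)) stop("no position passes the merge rule")
  kept <- calls[emit, on = c("contig", "pos")]
  key <- paste(kept$contig, kept$pos)
  ukey <- unique(key)
  sites <- kept[!duplicated(key), .(contig, pos, ref, alt)]
  data.table::setorder(sites, contig, pos)
  ukey <- paste(sites$contig, sites$pos)
  mk <- function(field, default) {
    m <- matrix(default, length(samples), nrow(sites),
                dimnames = list(samples, NULL))
    m[cbind(match(kept$sample, samples), match(key, ukey))] <- kept[[field]]
    m
  }
  geno <- mk("gt", NA_integer_)
  dp <- mk("dp", 0L)
  gq <- mk("gq", NA_integer_)
  geno[dp < min_depth] <- NA_integer_
  structure(list(sites = as.data.frame(sites), geno = geno, dp = dp,
                 gq = gq, min_depth = as.integer(min_depth)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set: %d sites x %d samples>\n", nrow(x$sites),
              nrow(x$geno)))
  invisible(x)
}

#' Convert a variant set to a genotype matrix
#'
#' @param vs a [merge_samples()] result.
#' @param subpop optional data.frame (`sample`, `subpop`) with
#'   subpopulation labels.
#' @return A [genotype_matrix()].
#' @export
variant_set_to_gm <- function(vs, subpop = NULL) {
  samples <- data.frame(sample = rownames(vs$geno),
                        stringsAsFactors = FALSE)
  if (!is.null(subpop)) {
    samples$subpop <- subpop$subpop[match(samples$sample, subpop$sample)]
  }
  genotype_matrix(vs$geno,
                  data.frame(contig = vs$sites$contig, pos = vs$sites$pos,
                             ref = vs$sites$ref, alt = vs$sites$alt,
                             stringsAsFactors = FALSE),
                  samples)
}
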