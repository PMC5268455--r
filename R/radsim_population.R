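# Two-subpopulation diploid germplasm simulator.
#
# Model: cultivated and wild founder haplotypes are related by windowed
# two-population structured coalescents (independent local genealogies
# refreshed along the genome) carrying infinite-sites variants, one per
# locus, whose carriers are the leaves under the branch the mutation fell
# on. The wild population has a small relative effective size, so its
# lineages coalesce rapidly before joining the ancestral pool: wild
# variation is a drifted subset of the shared ancestral variation, with
# few wild-private mutations, reduced wild heterozygosity and stronger
# wild LD. Individuals are recombinant founder mosaics; wild homologous
# haplotypes share identity-by-descent blocks with stationary probability
# F, producing the configured excess homozygosity.

#' Parameters of the two-subpopulation germplasm model
#'
#' @param n_cultivated,n_wild diploid sample counts (defaults 51 and 44).
#' @param founders_cultivated,founders_wild founder-haplotype pool sizes
#'   per subpopulation (cultivated must exceed wild).
#' @param mutation_rate per-bp probability that a position inside a RAD
#'   window carries a segregating variant (used by
#'   [simulate_population()]).
#' @param recombination expected founder-switch events per megabase along a
#'   haplotype mosaic (the panel's accumulated recombination history).
#' @param f_cultivated,f_wild inbreeding coefficients: stationary
#'   probability that homologous haplotype blocks are identical by descent.
#' @param re_loss_rate per-site probability that a recognition site carries
#'   a segregating disrupting mutation (null-allele source).
#' @param private_cultivated,private_wild fractions of loci that are novel
#'   mutations private to one subpopulation (single-founder carriers).
#' @param alpha_cultivated,alpha_wild Dirichlet concentration of founder
#'   contribution weights; large = even contributions, small = drift.
#' @param genealogy_persistence distance scale (bp) over which neighbouring
#'   loci share the same branch of the founder genealogy; controls the
#'   founder-level LD block length.
#' @param ascertainment exponent of the discovery-ascertainment weight
#'   `(c (K - c))^ascertainment` applied when placing variants on
#'   genealogy branches with `c` carriers; positive values favour
#'   intermediate-frequency variants, as SNP discovery in a sequenced
#'   panel does.
#' @param split_time time (coalescent units of the ancestral population)
#'   since the wild and cultivated founder lineages shared one ancestral
#'   pool.
#' @param ne_wild relative effective size of the wild population
#'   (cultivated and ancestral sizes are 1); small values bottleneck the
#'   wild lineages.
#' @param tree_span distance scale (bp) over which the local founder
#'   genealogy turns over.
#' @return A list of class `population_model`.
#' @export
population_model <- function(n_cultivated = 51L, n_wild = 44L,
                             founders_cultivated = 24L, founders_wild = 16L,
                             mutation_rate = 0.004, recombination = 40,
                             f_cultivated = 0, f_wild = 0.02,
                             re_loss_rate = 0.04,
                             private_cultivated = 0.02,
                             private_wild = 5e-4,
                             alpha_cultivated = 20, alpha_wild = 1.5,
                             genealogy_persistence = 1e3,
                             ascertainment = 1,
                             split_time = 0.3, ne_wild = 0.2,
                             tree_span = 1e5) {
  stopifnot(n_cultivated >= 2L, n_wild >= 2L,
            founders_cultivated >= 2L, founders_wild >= 2L,
            founders_cultivated > founders_wild,
            mutation_rate >= 0, mutation_rate <= 1,
            recombination >= 0,
            f_cultivated >= 0, f_cultivated <= 1, f_wild >= 0, f_wild <= 1,
            re_loss_rate >= 0, re_loss_rate <= 1,
            private_cultivated >= 0, private_wild >= 0,
            private_cultivated + private_wild < 1,
            split_time > 0, ne_wild > 0, tree_span > 0,
            genealogy_persistence > 0)
  structure(as.list(environment()), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(paste0("<population_model: %d cultivated (K=%d), %d wild ",
                     "(K=%d), F_wild=%.3f>\n"),
              x$n_cultivated, x$founders_cultivated, x$n_wild,
              x$founders_wild, x$f_wild))
  invisible(x)
}

# Two-population structured Kingman coalescent on k_c cultivated plus k_w
# wild founder lineages: within-population coalescence (the wild rate is
# inflated by its small relative effective size ne_wild) until split_time,
# then panmictic ancestral coalescence. Returns the non-root branches as a
# logical membership matrix (branch x leaf; wild leaves are the last k_w
# columns) and branch lengths.
.structured_branches <- function(k_c, k_w, split_time, ne_wild,
                                 ne_cultivated = 1, ne_ancestral = 1) {
  k <- k_c + k_w
  active <- as.list(seq_len(k))
  pop <- rep(1:2, c(k_c, k_w))
  alen <- numeric(k)
  leafsets <- vector("list", 2L * (k - 1L))
  lens <- numeric(2L * (k - 1L))
  nb <- 0L
  merge_pair <- function(i, j) {
    for (b in c(i, j)) {
      nb <<- nb + 1L
      leafsets[[nb]] <<- active[[b]]
      lens[nb] <<- alen[b]
    }
    active[[i]] <<- c(active[[i]], active[[j]])
    active[[j]] <<- NULL
    pop <<- pop[-j]
    alen[i] <<- 0
    alen <<- alen[-j]
  }
  t <- 0
  repeat {
    nc <- sum(pop == 1L)
    nw <- sum(pop == 2L)
    rc <- nc * (nc - 1) / 2 / ne_cultivated
    rw <- nw * (nw - 1) / 2 / ne_wild
    if (rc + rw <= 0) break
    dt <- stats::rexp(1L, rc + rw)
    if (t + dt >= split_time) break
    t <- t + dt
    alen <- alen + dt
    p <- if (stats::runif(1L) < rc / (rc + rw)) 1L else 2L
    idx <- which(pop == p)
    pair <- sample(idx, 2L)
    merge_pair(min(pair), max(pair))
  }
  alen <- alen + (split_time - t)
  while (length(active) > 1L) {
    nk <- length(active)
    dt <- stats::rexp(1L, nk * (nk - 1) / 2 / ne_ancestral)
    alen <- alen + dt
    pair <- sample.int(nk, 2L)
    merge_pair(min(pair), max(pair))
  }
  memb <- matrix(FALSE, nb, k)
  for (b in seq_len(nb)) memb[b, leafsets[[b]]] <- TRUE
  list(membership = memb, lengths = lens[seq_len(nb)])
}

.rdirichlet <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Assign founder alleles for the loci (sorted within contig; needs contig
# and pos columns). The genome is tiled by genealogy windows (independent
# structured-coalescent trees, refreshed over distance tree_span, the way
# local genealogies turn over along real chromosomes); within a window the
# branch carrying each variant follows a Markov chain, persisting over
# distance d with probability exp(-d / genealogy_persistence), which sets
# the founder-level LD block length. Branch choice is weighted by
# genealogical length times a discovery-ascertainment factor
# (c (k - c))^ascertainment favouring intermediate-frequency variants, as
# SNP discovery in a sequenced panel does. Returns carrier matrices for
# the cultivated (K_c x n) and wild (K_w x n) founder pools plus the locus
# class ("shared", "private_cultivated", "private_wild").
.founder_alleles <- function(model, loci) {
  n_loci <- nrow(loci)
  k_c <- model$founders_cultivated
  k_w <- model$founders_wild
  cls <- sample(c("shared", "private_cultivated", "private_wild"), n_loci,
                replace = TRUE,
                prob = c(1 - model$private_cultivated - model$private_wild,
                         model$private_cultivated, model$private_wild))
  a_all <- matrix(FALSE, k_c + k_w, n_loci)
  for (ix in split(seq_len(n_loci), loci$contig)) {
    gap <- diff(loci$pos[ix])
    new_tree <- c(TRUE, stats::runif(length(gap)) >=
                    exp(-gap / model$tree_span))
    fresh <- c(TRUE, stats::runif(length(gap)) >=
                 exp(-gap / model$genealogy_persistence)) | new_tree
    win <- cumsum(new_tree)
    for (w in seq_len(max(win))) {
      wix <- which(win == w)
      tree <- .structured_branches(k_c, k_w, model$split_time,
                                   model$ne_wild)
      # ascertainment counts cultivated carriers only: shared variants are
      # those segregating in the deeply sampled cultivated pool, so
      # wild-private alleles arise solely from the explicit private_wild
      # class below
      carriers <- rowSums(tree$membership[, seq_len(k_c), drop = FALSE])
      bweight <- tree$lengths *
        (carriers * (k_c - carriers))^model$ascertainment
      nf <- sum(fresh[wix])
      draws <- sample.int(length(bweight), nf, replace = TRUE,
                          prob = bweight)
      b <- draws[cumsum(fresh[wix])]
      a_all[, ix[wix]] <- t(tree$membership[b, , drop = FALSE])
    }
  }
  a_c <- a_all[seq_len(k_c), , drop = FALSE]
  a_w <- a_all[k_c + seq_len(k_w), , drop = FALSE]
  pc <- which(cls == "private_cultivated")
  if (length(pc)) {
    a_c[, pc] <- FALSE
    a_w[, pc] <- FALSE
    a_c[cbind(sample.int(k_c, length(pc), TRUE), pc)] <- TRUE
  }
  pw <- which(cls == "private_wild")
  if (length(pw)) {
    a_c[, pw] <- FALSE
    a_w[, pw] <- FALSE
    a_w[cbind(sample.int(k_w, length(pw), TRUE), pw)] <- TRUE
  }
  list(cultivated = a_c, wild = a_w, class = cls)
}

# Founder-identity path along one contig's sorted positions: Markov mosaic
# with switch probability 1 - exp(-rate_per_bp * distance).
.mosaic_path <- function(pos, k, weights, rate_per_bp) {
  n <- length(pos)
  sw <- c(TRUE, stats::runif(n - 1L) < 1 - exp(-rate_per_bp * diff(pos)))
  seg <- cumsum(sw)
  sample.int(k, max(seg), replace = TRUE, prob = weights)[seg]
}

# One subpopulation's haplotype allele matrices over loci (sorted within
# contig). alleles: K x n_loci logical founder carriers.
.sim_subpop_haplotypes <- function(n_ind, alleles, weights, f, loci,
                                   rate_per_bp) {
  n_loci <- ncol(alleles)
  k <- nrow(alleles)
  h1 <- matrix(0L, n_ind, n_loci)
  h2 <- matrix(0L, n_ind, n_loci)
  idx <- seq_len(n_loci)
  by_contig <- split(idx, loci$contig)
  for (ind in seq_len(n_ind)) {
    p1 <- integer(n_loci)
    p2 <- integer(n_loci)
    for (ix in by_contig) {
      pos <- loci$pos[ix]
      p1[ix] <- .mosaic_path(pos, k, weights, rate_per_bp)
      p2x <- .mosaic_path(pos, k, weights, rate_per_bp)
      if (f > 0) {
        ibd_seg <- cumsum(c(TRUE, stats::runif(length(pos) - 1L) <
                              1 - exp(-rate_per_bp * diff(pos))))
        ibd <- (stats::runif(max(ibd_seg)) < f)[ibd_seg]
        p2x[ibd] <- p1[ix][ibd]
      }
      p2[ix] <- p2x
    }
    h1[ind, ] <- alleles[cbind(p1, idx)]
    h2[ind, ] <- alleles[cbind(p2, idx)]
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate a genotype panel from the two-subpopulation model
#'
#' Generates founder alleles and recombinant mosaic individuals directly at
#' `n_loci` marker positions placed uniformly on synthetic chromosomes,
#' without sequences or reads. This is the lightweight generator used for
#' population-genetics parameter-recovery studies; [simulate_population()]
#' runs the same machinery against a simulated reference genome.
#'
#' @param model a [population_model()].
#' @param n_loci number of candidate loci (loci monomorphic across the
#'   combined panel are dropped unless `drop_monomorphic = FALSE`).
#' @param chrom_lengths chromosome length(s) in bp over which positions are
#'   placed.
#' @param seed integer seed.
#' @param drop_monomorphic drop loci with no variation in the sampled
#'   panel, mimicking SNP discovery.
#' @return A [genotype_matrix()] with subpopulation labels
#'   (`cultivated` / `wild`) and attribute `truth` holding the founder
#'   allele matrices, locus classes and haplotype matrices.
#' @export
simulate_genotype_panel <- function(model, n_loci = 5000L,
                                    chrom_lengths = 2e6, seed = 1L,
                                    drop_monomorphic = TRUE) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)
  chrom_lengths <- as.numeric(chrom_lengths)
  n_chr <- length(chrom_lengths)
  per_chr <- as.integer(round(n_loci * chrom_lengths / sum(chrom_lengths)))
  per_chr[n_chr] <- n_loci - sum(per_chr[-n_chr])
  loci <- data.table::rbindlist(lapply(seq_len(n_chr), function(ci) {
    data.table::data.table(
      contig = sprintf("chr%d", ci),
      pos = sort(sample.int(chrom_lengths[ci], per_chr[ci])))
  }))
  fa <- .founder_alleles(model, loci)
  rate <- model$recombination / 1e6
  cult <- .sim_subpop_haplotypes(model$n_cultivated, fa$cultivated,
                                 .rdirichlet(model$founders_cultivated,
                                             model$alpha_cultivated),
                                 model$f_cultivated, loci, rate)
  wild <- .sim_subpop_haplotypes(model$n_wild, fa$wild,
                                 .rdirichlet(nrow(fa$wild),
                                             model$alpha_wild),
                                 model$f_wild, loci, rate)
  h1 <- rbind(cult$h1, wild$h1)
  h2 <- rbind(cult$h2, wild$h2)
  geno <- h1 + h2
  samples <- data.frame(
    sample = c(sprintf("C%02d", seq_len(model$n_cultivated)),
               sprintf("W%02d", seq_len(model$n_wild))),
    subpop = rep(c("cultivated", "wild"),
                 c(model$n_cultivated, model$n_wild)),
    stringsAsFactors = FALSE)
  loci_df <- data.frame(contig = loci$contig, pos = loci$pos,
                        ref = "A", alt = "G", class = fa$class,
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, n_loci)
  if (drop_monomorphic) {
    cs <- colSums(geno)
    keep <- cs > 0L & cs < 2L * nrow(geno)
  }
  gm <- genotype_matrix(geno[, keep, drop = FALSE],
                        loci_df[keep, , drop = FALSE], samples)
  attr(gm, "truth") <- list(founder_alleles = fa,
                            h1 = h1[, keep, drop = FALSE],
                            h2 = h2[, keep, drop = FALSE])
  gm
}

#' Simulate the germplasm panel against a reference genome
#'
#' Places segregating variants inside the RAD windows of a simulated
#' reference (within read range of each restriction cut, on both sides),
#' including recognition-site disrupting mutations (null-allele source) and
#' site-gain mutations at the reference's near-miss candidates, then builds
#' diploid individuals as recombinant founder mosaics (see
#' [population_model()]).
#'
#' @param reference a [simulate_reference()] result.
#' @param model a [population_model()].
#' @param read_bases bases covered by a pre-processed read (76 for 75-colour
#'   SOLiD reads); regular variants are kept at least 2 bases clear of the
#'   far read end so every allele is observable from colour pairs.
#' @param gain_rate probability that a near-miss candidate segregates as a
#'   site-gain mutation (default 1: all candidates segregate).
#' @param seed integer seed.
#' @return A list of class `rad_population`: `truth` (list with `loci`
#'   data.table (`contig`, `pos` 1-based, `pos0`, `ref`, `alt`, `class`,
#'   `site_id`, `side`), genotype matrix `geno`, haplotype allele matrices
#'   `h1`/`h2`, `site_presence` array sites x samples x 2 haplotypes,
#'   `site_polymorphic` flag, `samples`), plus `reference`, `model` and the
#'   per-sample subpopulation table.
#' @export
simulate_population <- function(reference, model = population_model(),
                                read_bases = 76L, gain_rate = 1,
                                seed = 1L) {
  stopifnot(inherits(reference, "rad_reference"),
            inherits(model, "population_model"))
  set.seed(seed)
  enzyme <- reference$enzyme
  motif_len <- nchar(enzyme$recognition)
  sites <- data.table::copy(reference$catalog$sites)
  sites[, `:=`(site_id = seq_len(.N), predicted = TRUE)]
  gains <- data.table::copy(reference$gain_candidates)
  if (nrow(gains)) {
    gains <- gains[stats::runif(.N) < gain_rate]
  }
  if (nrow(gains)) {
    gains[, site_id := max(sites$site_id) + seq_len(.N)]
  }
  all_sites <- data.table::rbindlist(list(
    sites[, .(contig, pos0, site_id, predicted)],
    if (nrow(gains)) gains[, .(contig, pos0, site_id, predicted = FALSE)]),
    use.names = TRUE)
  data.table::setkey(all_sites, contig, pos0)

  genome <- reference$genome
  # candidate variant positions: recognition bases (loss loci) handled
  # separately; regular SNPs sit in the flanks covered by reads
  loci_list <- list()
  for (r in seq_len(nrow(all_sites))) {
    s <- all_sites[r]
    clen <- nchar(genome[[s$contig]])
    down <- (s$pos0 + motif_len):(s$pos0 + read_bases - 2L)
    up <- (s$pos0 - 1L):(s$pos0 + motif_len - 1L - read_bases + 2L)
    down <- down[down >= 0L & down < clen]
    up <- up[up >= 0L & up < clen]
    flank <- c(sort(up), down)
    take <- flank[stats::runif(length(flank)) < model$mutation_rate]
    if (length(take)) {
      loci_list[[length(loci_list) + 1L]] <- data.table::data.table(
        contig = s$contig, pos0 = take, class = "snp",
        site_id = s$site_id,
        side = ifelse(take < s$pos0, "up", "down"))
    }
    if (s$predicted && stats::runif(1L) < model$re_loss_rate) {
      lp <- s$pos0 + sample.int(motif_len, 1L) - 1L
      loci_list[[length(loci_list) + 1L]] <- data.table::data.table(
        contig = s$contig, pos0 = lp, class = "loss", site_id = s$site_id,
        side = "site")
    }
    if (!s$predicted) {
      g <- gains[site_id == s$site_id]
      loci_list[[length(loci_list) + 1L]] <- data.table::data.table(
        contig = s$contig, pos0 = g$pos0 + g$offset, class = "gain",
        site_id = s$site_id, side = "site")
    }
  }
  loci <- data.table::rbindlist(loci_list)
  if (!nrow(loci)) {
    loci <- data.table::data.table(contig = character(0),
                                   pos0 = integer(0),
                                   class = character(0),
                                   site_id = integer(0),
                                   side = character(0))
  }
  loci <- loci[!duplicated(loci, by = c("contig", "pos0"))]
  data.table::setkey(loci, contig, pos0)
  # substitutions closer than 3 bp interleave their colour-pair signatures
  # and would be unreadable from two-base encoding; keep loci separated
  keep3 <- unlist(lapply(split(loci$pos0, loci$contig), function(p) {
    k <- rep(TRUE, length(p))
    last <- -10L
    for (i in seq_along(p)) {
      if (p[i] - last <= 2L) k[i] <- FALSE else last <- p[i]
    }
    k
  }), use.names = FALSE)
  if (length(keep3)) loci <- loci[keep3]
  loci[, pos := pos0 + 1L]
  loci[, ref := substring(genome[contig], pos, pos)]
  bases <- c("A", "C", "G", "T")
  loci[, alt := vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")]
  if (nrow(gains)) {
    gkey <- loci$class == "gain"
    gb <- gains$gain_base[match(loci$site_id[gkey], gains$site_id)]
    loci$alt[gkey] <- gb
  }

  n_loci <- nrow(loci)
  fa <- .founder_alleles(model, loci)
  rate <- model$recombination / 1e6
  cult <- .sim_subpop_haplotypes(model$n_cultivated, fa$cultivated,
                                 .rdirichlet(model$founders_cultivated,
                                             model$alpha_cultivated),
                                 model$f_cultivated, loci, rate)
  wild <- .sim_subpop_haplotypes(model$n_wild, fa$wild,
                                 .rdirichlet(nrow(fa$wild),
                                             model$alpha_wild),
                                 model$f_wild, loci, rate)
  h1 <- rbind(cult$h1, wild$h1)
  h2 <- rbind(cult$h2, wild$h2)
  # drop variants absent from the sampled panel (undiscoverable)
  carried <- colSums(h1 + h2) > 0L
  loci <- loci[carried]
  h1 <- h1[, carried, drop = FALSE]
  h2 <- h2[, carried, drop = FALSE]
  n_loci <- nrow(loci)
  n_samples <- nrow(h1)
  samples <- data.frame(
    sample = c(sprintf("C%02d", seq_len(model$n_cultivated)),
               sprintf("W%02d", seq_len(model$n_wild))),
    subpop = rep(c("cultivated", "wild"),
                 c(model$n_cultivated, model$n_wild)),
    stringsAsFactors = FALSE)

  # per-haplotype site presence: predicted sites lost by "loss" carriers,
  # unpredicted sites present only in "gain" carriers
  n_sites <- nrow(all_sites)
  pres <- array(TRUE, dim = c(n_sites, n_samples, 2L))
  site_row <- match(loci$site_id, all_sites$site_id)
  for (l in which(loci$class == "loss")) {
    r <- site_row[l]
    pres[r, , 1L][h1[, l] == 1L] <- FALSE
    pres[r, , 2L][h2[, l] == 1L] <- FALSE
  }
  gain_rows <- match(all_sites$site_id[!all_sites$predicted],
                     all_sites$site_id)
  pres[gain_rows, , ] <- FALSE
  for (l in which(loci$class == "gain")) {
    r <- site_row[l]
    pres[r, , 1L][h1[, l] == 1L] <- TRUE
    pres[r, , 2L][h2[, l] == 1L] <- TRUE
  }
  site_poly <- vapply(seq_len(n_sites), function(r) {
    p <- pres[r, , ]
    any(p) && !all(p)
  }, logical(1))

  structure(list(
    truth = list(loci = loci, geno = h1 + h2, h1 = h1, h2 = h2,
                 sites = all_sites, site_presence = pres,
                 site_polymorphic = site_poly, samples = samples),
    reference = reference, model = model, samples = samples),
    class = "rad_population")
}

#' @export
print.rad_population <- function(x, ...) {
  cat(sprintf("<rad_population: %d samples, %d truth loci, %d sites (%d unpredicted)>\n",
              nrow(x$samples), nrow(x$truth$loci), nrow(x$truth$sites),
              sum(!x$truth$sites$predicted)))
  invisible(x)
}
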