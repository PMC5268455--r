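test_that("missing-rate filtering removes samples first, then loci", {
  g <- matrix(0L, 4, 6)
  g[1, 1:4] <- NA_integer_          # sample 1: 4/6 missing -> removed
  g[2, 5] <- NA_integer_
  g[3, 5] <- NA_integer_            # locus 5: 2/3 missing after removal
  gm <- toy_gm(g)
  out <- filter_matrix(gm)
  rep_ <- attr(out, "report")
  expect_identical(dim(out), c(3L, 5L))
  expect_identical(rep_$n, c(1L, 1L))
  # no missing data: identity
  clean <- toy_gm(matrix(1L, 3, 4))
  expect_identical(dim(filter_matrix(clean)), c(3L, 4L))
  all_na <- toy_gm(matrix(NA_integer_, 2, 2))
  expect_error(filter_matrix(all_na), "all samples")
})

test_that("MAF filtering uses strict less-than and drops monomorphic loci", {
  # 45 diploids, one heterozygote: MAF = 1/90 < 0.05 -> removed
  g1 <- matrix(0L, 45, 1)
  g1[1, 1] <- 1L
  expect_identical(ncol(maf_filter(toy_gm(g1))$geno), 0L)
  # MAF exactly 0.05 is retained: 1 het in 10 diploids = 0.05
  g2 <- matrix(0L, 10, 1)
  g2[1, 1] <- 1L
  expect_identical(ncol(maf_filter(toy_gm(g2))$geno), 1L)
  # monomorphic locus removed
  g3 <- cbind(rep(2L, 10), c(rep(0L, 5), rep(2L, 5)))
  out <- maf_filter(toy_gm(g3))
  expect_identical(ncol(out$geno), 1L)
})

test_that("imputation honours the LD-kNNi rules", {
  set.seed(41)
  # no missing entries: identity
  g <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  gm <- toy_gm(g)
  expect_identical(impute_ldknni(gm, k = 3, l = 5)$geno, gm$geno)
  # a duplicated locus in perfect LD dictates the imputed value
  base <- matrix(sample(0:2, 30 * 24, replace = TRUE), 30, 24)
  base[, 2] <- base[, 1]
  gm2 <- toy_gm(base)
  truth <- gm2$geno[5, 1]
  gm2$geno[5, 1] <- NA_integer_
  imp <- impute_ldknni(gm2, k = 5, l = 1)
  expect_identical(imp$geno[5, 1], truth)
  # observed entries are never altered and nothing stays missing
  gm3 <- toy_gm(base)
  mask <- cbind(sample(30, 12, TRUE), sample(24, 12, TRUE))
  obs_keep <- gm3$geno
  gm3$geno[mask] <- NA_integer_
  out <- impute_ldknni(gm3)
  expect_false(anyNA(out$geno))
  seen <- !is.na(gm3$geno)
  expect_identical(out$geno[seen], gm3$geno[seen])
  all_miss <- base
  all_miss[, 5] <- NA_integer_
  expect_error(impute_ldknni(toy_gm(all_miss)), "all entries missing")
})

test_that("LD-kNNi beats the modal-genotype baseline on simulated data", {
  gm <- simulate_genotype_panel(population_model(), n_loci = 700,
                                chrom_lengths = 6e5, seed = 42)
  gmf <- maf_filter(gm, 0.1)
  g <- gmf$geno
  set.seed(43)
  mask <- which(matrix(runif(length(g)) < 0.1, nrow(g)) & !is.na(g),
                arr.ind = TRUE)
  truth <- g[mask]
  gmf$geno[mask] <- NA_integer_
  imp <- impute_ldknni(gmf)
  acc_knni <- mean(imp$geno[mask] == truth)
  modal <- apply(gmf$geno, 2, function(x) {
    tx <- table(x)
    as.integer(names(tx)[which.max(tx)])
  })
  acc_modal <- mean(modal[mask[, 2]] == truth)
  expect_gt(acc_knni, acc_modal)
})

test_that("diversity statistics match hand arithmetic", {
  # an all-heterozygote locus in 10 samples
  gm <- toy_gm(matrix(1L, 10, 1), subpop = rep("cultivated", 10))
  d <- diversity(gm, "cultivated")
  expect_equal(d$Ho, 1)
  expect_equal(d$He, (20 / 19) * 0.5)
  expect_lt(1 - d$Ho / d$He, 0)          # per-locus Fis negative
  # He equals the brute-force unbiased estimator on random matrices
  set.seed(44)
  g <- matrix(sample(0:2, 25 * 40, replace = TRUE), 25, 40)
  gm2 <- toy_gm(g, subpop = rep("cultivated", 25))
  d2 <- diversity(gm2, "cultivated")
  expect_equal(d2$He, mean(apply(g, 2, he_brute)), tolerance = 1e-12)
  expect_equal(d2$Ho, mean(colMeans(g == 1L)), tolerance = 1e-12)
  expect_equal(d2$Fis, 1 - d2$Ho / d2$He, tolerance = 1e-12)
  # per-locus averaging mode
  d2l <- diversity(gm2, "cultivated", per_locus_fis = TRUE)
  ho <- colMeans(g == 1L)
  he <- apply(g, 2, he_brute)
  expect_equal(d2l$Fis, mean(1 - ho[he > 0] / he[he > 0]),
               tolerance = 1e-12)
  expect_error(diversity(toy_gm(matrix(0L, 2, 2),
                                subpop = c("cultivated", "wild")),
                         "wild"), "fewer than 2")
})

test_that("a Hardy-Weinberg population has Fis near zero", {
  set.seed(45)
  n <- 40
  p <- runif(5000, 0.1, 0.9)
  g <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  gm <- toy_gm(g, subpop = rep("wild", n))
  expect_lt(abs(diversity(gm, "wild")$Fis), 0.02)
})

test_that("private alleles follow the presence/absence definition", {
  g <- rbind(c(1L, 0L, 2L),
             c(0L, 0L, 2L),
             c(0L, 1L, 2L),
             c(0L, 1L, 2L))
  gm <- toy_gm(g, subpop = c("cultivated", "cultivated", "wild", "wild"))
  d <- diversity(gm)
  # locus 1 alt only in cultivated; locus 2 alt only in wild; locus 3
  # monomorphic alt in both
  expect_identical(d$PA[d$subpop == "cultivated"], 1L)
  expect_identical(d$PA[d$subpop == "wild"], 1L)
})

test_that("r-squared matches brute force and behaves at the null", {
  set.seed(50)
  g <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  g[, 2] <- g[, 1]
  gm <- toy_gm(g, positions = seq(1000, by = 2000, length.out = 10))
  ld <- ld_decay(gm, maf_min = 0, max_dist = 1e5)
  pair12 <- ld$pairs[ld$pairs$dist == 2000, ]
  expect_true(any(abs(pair12$r2 - 1) < 1e-12))
  # all pair r2 match the longhand Pearson square
  set.seed(46)
  g2 <- matrix(sample(0:2, 50 * 8, replace = TRUE), 50, 8)
  gm2 <- toy_gm(g2, positions = seq(1e3, by = 1e3, length.out = 8))
  ld2 <- ld_decay(gm2, maf_min = 0, max_dist = 1e5, bin = 1e3)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      d <- (j - i) * 1e3
      expected <- pearson_brute(g2[, i], g2[, j])^2
      hit <- ld2$pairs[abs(ld2$pairs$dist - d) < 1 &
                         abs(ld2$pairs$r2 - expected) < 1e-12, ]
      expect_gte(nrow(hit), 1L)
    }
  }
  # independent loci: mean r2 is near 1/n
  set.seed(47)
  n <- 100
  g3 <- vapply(runif(300, 0.2, 0.8), function(p) rbinom(n, 2, p),
               integer(n))
  gm3 <- toy_gm(g3, positions = seq(1e3, by = 1e3, length.out = 300))
  ld3 <- ld_decay(gm3, maf_min = 0.05, max_dist = 3e5)
  expect_lt(abs(mean(ld3$pairs$r2) - 1 / n), 3 / n)
})

test_that("the decay curve bins pairs and finds the crossing distance", {
  set.seed(48)
  pos <- sort(sample.int(5e5, 120))
  g <- vapply(seq_along(pos), function(i) rbinom(30, 2, 0.5), integer(30))
  gm <- toy_gm(g, positions = pos)
  ld <- ld_decay(gm, bin = 1e4, max_dist = 2e5)
  expect_identical(nrow(ld$curve), 20L)
  expect_true(all(diff(ld$curve$bin_start) == 1e4))
  expect_true(all(ld$pairs$r2 >= 0 & ld$pairs$r2 <= 1))
  # random genotypes: the curve starts below 0.2 already
  expect_identical(ld$dist_below, ld$curve$bin_mid[1L])
})

test_that("concordance counts fitted genotypes and excludes missing", {
  set.seed(49)
  g <- matrix(sample(0:2, 7 * 148, replace = TRUE), 7, 148)
  a <- toy_gm(g, positions = seq_len(148) * 500L)
  expect_equal(concordance(a, a)$rate, 1)
  # plant 145 mismatches across the 1036 comparisons
  b <- toy_gm(g, positions = seq_len(148) * 500L)
  flat <- which(!is.na(g))
  flip <- sample(flat, 145)
  b$geno[flip] <- (b$geno[flip] + 1L) %% 3L
  cc <- concordance(a, b)
  expect_identical(cc$n_compared, 7L * 148L)
  expect_equal(cc$rate, (1036 - 145) / 1036)
  expect_equal(sum(cc$per_locus$mismatches), 145)
  # all-missing comparison errors
  c_ <- toy_gm(matrix(NA_integer_, 7, 148),
               positions = seq_len(148) * 500L)
  expect_error(concordance(a, c_), "zero comparable")
})

test_that("the MAF spectrum conserves counts and reports the rare tail", {
  g <- cbind(rep(1L, 20),                        # MAF 0.5
             c(rep(0L, 19), 1L),                 # MAF 0.025
             rep(2L, 20))                        # monomorphic, MAF 0
  gm <- toy_gm(g, subpop = rep("wild", 20))
  sp <- maf_spectrum(gm, "wild")
  expect_identical(sum(sp$spectrum$n), 3L)
  expect_identical(sp$n_below_0.1, 2L)
  expect_identical(sp$spectrum$n[sp$spectrum$bin_start == 0.45], 1L)
})
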