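test_that("reference simulation is deterministic and self-consistent", {
  ref1 <- simulate_reference(n_contigs = 1, lengths = 1e5,
                             site_density = 1 / 8000, seed = 7)
  ref2 <- simulate_reference(n_contigs = 1, lengths = 1e5,
                             site_density = 1 / 8000, seed = 7)
  expect_identical(ref1$genome, ref2$genome)
  expect_gt(ref1$catalog$n_sites, 6)
  expect_lt(ref1$catalog$n_sites, 20)
  # re-scanning the emitted FASTA reproduces the catalog
  rescanned <- digest_catalog(ref1$genome)
  expect_identical(ref1$catalog$sites, rescanned$sites)
  # zero density gives an empty catalog
  ref0 <- simulate_reference(lengths = 5e4, site_density = 0,
                             gain_density = 0, seed = 1)
  expect_identical(ref0$catalog$n_sites, 0L)
  expect_error(simulate_reference(lengths = 1e4, site_density = 0.01,
                                  seed = 1), "density")
})

test_that("population truth respects the window and null-allele rules", {
  sim <- small_sim()
  pop <- sim$pop
  loci <- pop$truth$loci
  sites <- pop$truth$sites
  # every truth variant lies within read range of its site
  d <- loci$pos0 - sites$pos0[match(loci$site_id, sites$site_id)]
  expect_true(all(d >= -70 & d <= 74))
  expect_true(all(c("snp", "loss", "gain") %in% loci$class |
                    all(loci$class %in% c("snp", "loss", "gain"))))
  # loss carriers lose the site, gain carriers create it
  pres <- pop$truth$site_presence
  for (l in which(loci$class == "loss")) {
    r <- match(loci$site_id[l], sites$site_id)
    expect_true(all(pres[r, , 1][pop$truth$h1[, l] == 1L] == FALSE))
    expect_true(all(pres[r, , 1][pop$truth$h1[, l] == 0L] == TRUE))
  }
  gain_rows <- which(!sites$predicted)
  for (r in gain_rows) {
    l <- which(loci$class == "gain" & loci$site_id == sites$site_id[r])
    if (length(l)) {
      expect_identical(pres[r, , 1], pop$truth$h1[, l] == 1L)
    } else {
      expect_true(all(!pres[r, , ]))
    }
  }
  # zero loss rate leaves no disrupted predicted site in truth
  ref <- simulate_reference(lengths = 2e5, gain_density = 0, seed = 21)
  pop0 <- simulate_population(ref, population_model(
    n_cultivated = 6L, n_wild = 4L, re_loss_rate = 0), seed = 22)
  expect_identical(sum(pop0$truth$loci$class == "loss"), 0L)
  expect_true(all(pop0$truth$site_presence))
})

test_that("library reads start at the cut and are error-free when told so", {
  sim <- small_sim()
  res <- preprocess_reads(sim$lib$reads, read_length = 75L)
  expect_identical(unique(res$reads$status), "exact")
  expect_identical(nrow(res$reads), nrow(sim$lib$reads))
  # every read has provenance
  expect_setequal(sim$lib$reads$id, sim$lib$provenance$id)
  # a site absent on both haplotypes yields no reads for that sample
  pres <- sim$pop$truth$site_presence
  prov <- sim$lib$provenance
  absent <- which(!pres[, , 1] & !pres[, , 2], arr.ind = TRUE)
  if (nrow(absent)) {
    for (i in seq_len(min(5, nrow(absent)))) {
      sid <- sim$pop$truth$sites$site_id[absent[i, 1]]
      smp <- sim$pop$samples$sample[absent[i, 2]]
      expect_identical(nrow(prov[prov$site_id == sid &
                                   prov$sample == smp, ]), 0L)
    }
  }
})

test_that("read counts track the depth model within three standard deviations", {
  ref <- simulate_reference(lengths = 3e5, seed = 31)
  pop <- simulate_population(ref, population_model(n_cultivated = 5L,
                                                   n_wild = 4L),
                             seed = 32)
  lm0 <- library_model(error_rate = 0, depth_mean = 10, sample_cv = 0)
  lib <- simulate_library(pop, lm0, seed = 33)
  pres <- pop$truth$site_presence
  # expected reads: depth_mean/2 per present haplotype per side
  expected <- sum(pres) * 2 * lm0$depth_mean / 2
  expect_lt(abs(nrow(lib$reads) - expected), 3 * sqrt(expected))
})

test_that("shear bias induces a depth / log fragment-length correlation", {
  ref <- simulate_reference(lengths = 1e6, site_density = 1 / 4000,
                            gain_density = 0, seed = 41)
  pop <- simulate_population(ref, population_model(n_cultivated = 4L,
                                                   n_wild = 3L,
                                                   re_loss_rate = 0),
                             seed = 42)
  depth_by_locus <- function(lib) {
    prov <- lib$provenance
    tab <- table(paste(prov$site_id, prov$side))
    key <- expand.grid(side = c("up", "down"),
                       site = pop$truth$sites$site_id)
    n <- as.integer(tab[paste(key$site, key$side)])
    n[is.na(n)] <- 0L
    n
  }
  fraglen <- as.vector(t(radsolid:::.site_fraglen(pop$truth$sites,
                                                  ref$catalog)))
  biased <- simulate_library(pop, library_model(error_rate = 0,
                                                shear_bias = TRUE,
                                                sample_cv = 0), seed = 43)
  flat <- simulate_library(pop, library_model(error_rate = 0,
                                              shear_bias = FALSE,
                                              sample_cv = 0), seed = 43)
  r_biased <- depth_fraglen_correlation(depth_by_locus(biased), fraglen)
  r_flat <- depth_fraglen_correlation(depth_by_locus(flat), fraglen)
  expect_gt(r_biased$r[r_biased$stratum == "all"], 0)
  expect_lt(r_biased$p_value[r_biased$stratum == "all"], 0.01)
  expect_lt(abs(r_flat$r[r_flat$stratum == "all"]), 0.1)
})

test_that("a symmetric model with F = 0 shows no heterozygosity contrast", {
  m <- population_model(n_cultivated = 30L, n_wild = 29L,
                        founders_cultivated = 24L, founders_wild = 23L,
                        f_wild = 0, ne_wild = 1, split_time = 1e-4,
                        private_cultivated = 0, private_wild = 0)
  gm <- simulate_genotype_panel(m, n_loci = 3000, seed = 51)
  d <- diversity(gm)
  expect_lt(abs(d$Ho[1] - d$Ho[2]), 0.05)
})
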