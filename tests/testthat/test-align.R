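test_that("error-free reads align to their provenance site", {
  sim <- small_sim()
  pre <- preprocess_reads(sim$lib$reads, read_length = 75L)
  kept <- pre$reads
  kept$sample <- sim$lib$reads$sample[match(kept$id, sim$lib$reads$id)]
  idx <- build_index(sim$ref)
  aln <- align_reads(kept, idx)
  expect_identical(nrow(aln$rejected), 0L)
  # reads carrying sample variants differ from the reference by two
  # colours per substitution; all reads stay near-perfect and unique
  expect_true(all(aln$alignments$identity >= 1 - 6 / 76))
  expect_true(all(aln$alignments$unique))
  prov <- sim$lib$provenance
  m <- merge(aln$alignments, prov, by = "id")
  sites <- sim$pop$truth$sites
  expect_identical(m$site_pos0,
                   sites$pos0[match(m$site_id, sites$site_id)])
  expect_identical(m$side.x, m$side.y)
})

test_that("a variant-free panel aligns every read with identity exactly 1", {
  ref <- simulate_reference(lengths = 2e5, gain_density = 0, seed = 95)
  pop <- simulate_population(ref, population_model(
    n_cultivated = 4L, n_wild = 3L, mutation_rate = 0, re_loss_rate = 0,
    private_cultivated = 0, private_wild = 0), seed = 96)
  lib <- simulate_library(pop, library_model(error_rate = 0), seed = 97)
  pre <- preprocess_reads(lib$reads, read_length = 75L)
  pre$reads$sample <- "s"
  aln <- align_reads(pre$reads, build_index(ref))
  expect_true(all(aln$alignments$identity == 1))
  expect_true(all(aln$alignments$mapq == 60L))
})

test_that("identity sits exactly at the mismatch arithmetic boundary", {
  sim <- small_sim()
  pre <- preprocess_reads(sim$lib$reads[1:50, ], read_length = 75L)
  idx <- build_index(sim$ref)
  plant <- function(colors, k) {
    v <- strsplit(colors, "")[[1L]]
    at <- sample(56:76, k)   # past every lookup seed
    v[at] <- as.character((as.integer(v[at]) + 1L) %% 4L)
    paste(v, collapse = "")
  }
  set.seed(5)
  r7 <- data.frame(id = "m7", colors = plant(pre$reads$colors[1L], 7L))
  r8 <- data.frame(id = "m8", colors = plant(pre$reads$colors[1L], 8L))
  a7 <- align_reads(r7, idx)
  a8 <- align_reads(r8, idx)
  # 69/76 = 0.9079 passes, 68/76 = 0.8947 fails the 0.90 cut
  expect_identical(nrow(a7$alignments), 1L)
  expect_equal(a7$alignments$identity, 69 / 76)
  expect_identical(nrow(a8$alignments), 0L)
  expect_identical(a8$rejected$reason, "low_identity")
})

test_that("reads from a duplicated region are dropped as non-unique", {
  set.seed(6)
  flank <- function(n) random_dna(n, c("A", "C", "T"))  # no spurious sites
  block <- paste0(flank(300), "GGATCC", flank(300))
  genome <- c(chr1 = paste0(flank(200), block, flank(150), block,
                            flank(200)))
  idx <- build_index(genome, digest_catalog(genome))
  site <- find_sites(genome[[1]])[1]
  bases <- substring(genome[[1]], site + 1, site + 76)
  read <- data.frame(id = "dup",
                     colors = cs_encode("T", bases))
  a <- align_reads(read, idx)
  expect_identical(nrow(a$alignments), 0L)
  expect_identical(a$rejected$reason, "not_unique")
})

test_that("retained fraction is monotone in the identity threshold", {
  sim <- small_sim()
  set.seed(8)
  noisy <- simulate_library(sim$pop, library_model(error_rate = 0.02),
                            seed = 94)
  pre <- preprocess_reads(noisy$reads, read_length = 75L)
  kept <- pre$reads[1:400, ]
  idx <- build_index(sim$ref)
  kept$sample <- "s"
  n_kept <- vapply(c(0.85, 0.9, 0.95, 1.0), function(thr)
    nrow(align_reads(kept, idx, min_identity = thr)$alignments),
    integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("every single-base substitution is recovered as one consistent observation", {
  set.seed(12)
  genome <- c(chr1 = paste0(random_dna(150, c("A", "C", "T")), "GGATCC",
                            random_dna(150, c("A", "C", "T"))))
  catalog <- digest_catalog(genome)
  idx <- build_index(genome, catalog)
  site0 <- catalog$sites$pos0
  ref_bases <- substring(genome[[1]], site0 + 1, site0 + 76)
  for (i in 8:29) {   # substitution positions within the read, past the motif
    for (b in setdiff(c("A", "C", "G", "T"), substring(ref_bases, i, i))) {
      mut <- ref_bases
      substring(mut, i, i) <- b
      read <- data.frame(id = "x", sample = "s",
                         colors = cs_encode("T", mut))
      aln <- align_reads(read, idx)
      ev <- collect_evidence(aln, read, idx)
      expect_identical(nrow(ev$alt_obs), 1L)
      expect_identical(ev$alt_obs$pos, site0 + i)
      expect_identical(ev$alt_obs$base, b)
    }
  }
})

test_that("isolated colour mismatches yield no base observation", {
  set.seed(13)
  genome <- c(chr1 = paste0(random_dna(150, c("A", "C", "T")), "GGATCC",
                            random_dna(150, c("A", "C", "T"))))
  catalog <- digest_catalog(genome)
  idx <- build_index(genome, catalog)
  site0 <- catalog$sites$pos0
  clean <- cs_encode("T", substring(genome[[1]], site0 + 1, site0 + 76))
  v <- strsplit(clean, "")[[1L]]
  v[40] <- as.character((as.integer(v[40]) + 2L) %% 4L)
  read <- data.frame(id = "e", sample = "s",
                     colors = paste(v, collapse = ""))
  aln <- align_reads(read, idx)
  ev <- collect_evidence(aln, read, idx)
  expect_identical(nrow(ev$alt_obs), 0L)
  expect_identical(nrow(ev$excluded), 2L)   # bases flanking the bad colour
})

test_that("upstream reads cover the expected original-coordinate window", {
  sim <- small_sim()
  pre <- preprocess_reads(sim$lib$reads, read_length = 75L)
  kept <- pre$reads
  kept$sample <- sim$lib$reads$sample[match(kept$id, sim$lib$reads$id)]
  idx <- build_index(sim$ref)
  up_ids <- sim$lib$provenance$id[sim$lib$provenance$side == "up"]
  ups <- kept[kept$id %in% up_ids[1:50], ]
  aln <- align_reads(ups, idx)
  ev <- collect_evidence(aln, ups, idx)
  # coverage rows parallel the alignment table; an upstream read spans
  # [site0 - 69, site0 + 6] in 1-based original coordinates
  s0 <- aln$alignments$site_pos0
  expect_identical(ev$coverage$start, as.integer(s0 - 69L))
  expect_identical(ev$coverage$end, as.integer(s0 + 6L))
})

test_that("alignment statistics split by the reporting MapQ tier", {
  aln <- list(
    alignments = data.table::data.table(
      sample = c("a", "a", "b"), mapq = c(60L, 4L, 60L)),
    rejected = data.table::data.table(sample = c("a", "b", "b"),
                                      reason = "low_identity"))
  st <- alignment_stats(aln)
  expect_identical(st$high_mapq[st$sample == "a"], 1L)
  expect_identical(st$low_mapq[st$sample == "a"], 1L)
  expect_identical(st$rejected[st$sample == "b"], 2L)
})
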