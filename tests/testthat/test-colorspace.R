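test_that("encoding matches the two-base colour code on worked examples", {
  expect_identical(cs_encode("T", "GATCC"), "12320")
  expect_identical(cs_encode("T", "GGATCC"), "102320")
  expect_identical(cs_encode("A", "AAAA"), "0000")
  expect_identical(cs_decode("T", "12320"), "GATCC")
  expect_identical(cs_decode("T", "102320"), "GGATCC")
  expect_error(cs_encode("T", "GANCC"), "invalid")
  expect_error(cs_decode("T", "12 0"), "invalid")
  expect_error(cs_encode("N", "ACGT"), "primer")
})

test_that("encode and decode are mutual inverses (exhaustive and random)", {
  bases <- c("A", "C", "G", "T")
  mers <- apply(expand.grid(bases, bases, bases, bases), 1L, paste,
                collapse = "")
  for (p in bases) {
    expect_identical(vapply(mers, function(s) cs_decode(p, cs_encode(p, s)),
                            "", USE.NAMES = FALSE), mers)
  }
  set.seed(1)
  for (i in 1:20) {
    s <- random_dna(sample(30:200, 1))
    p <- sample(bases, 1)
    expect_identical(cs_decode(p, cs_encode(p, s)), s)
  }
})

test_that("the colour code is symmetric and bijective in the second base", {
  bases <- c("A", "C", "G", "T")
  first_color <- function(x, y) substring(cs_encode(x, y), 1L, 1L)
  for (x in bases) {
    for (y in bases) {
      expect_identical(first_color(x, y), first_color(y, x))
    }
    expect_setequal(vapply(bases, function(y) first_color(x, y), ""),
                    c("0", "1", "2", "3"))
  }
})

test_that("a single substitution changes two adjacent colours (one at the end)", {
  set.seed(7)
  s <- random_dna(20)
  ref_cols <- strsplit(cs_encode("T", s), "")[[1L]]
  for (i in 1:20) {
    for (b in setdiff(c("A", "C", "G", "T"), substring(s, i, i))) {
      mut <- s
      substring(mut, i, i) <- b
      diff_at <- which(strsplit(cs_encode("T", mut), "")[[1L]] != ref_cols)
      if (i < 20) {
        expect_identical(diff_at, c(i, i + 1L))
      } else {
        expect_identical(diff_at, 20L)
      }
    }
  }
})

test_that("start classification is the Hamming distance to the signature", {
  expect_identical(classify_start(paste0("12320", strrep("0", 70))), 0L)
  expect_identical(classify_start(paste0("02320", strrep("0", 70))), 1L)
  expect_identical(classify_start("3030303"), 4L)
  expect_error(classify_start("123"), "shorter")
  r <- color_read("x", "T", paste0("12300", strrep("2", 70)))
  expect_identical(classify_start(r), 1L)
})

test_that("pre-processing repairs the start and partitions the batch", {
  ok <- paste0("12320", strrep("1", 70))
  one <- paste0("12321", strrep("1", 70))
  two <- paste0("00320", strrep("1", 70))
  res <- preprocess_reads(c(ok, one, two))
  expect_identical(res$summary$n, c(1L, 1L, 1L))
  expect_identical(res$reads$status, c("exact", "repaired"))
  expect_true(all(nchar(res$reads$colors) == 76L))
  expect_true(all(startsWith(res$reads$colors, "102320")))
  # repaired + exact + discarded partition the batch, nothing in two bins
  expect_identical(sum(res$summary$n), 3L)
  expect_identical(length(res$discarded), 1L)
  expect_false(any(res$discarded %in% res$reads$id))
  # planted error counts are recovered by the retained count
  set.seed(11)
  n <- 300
  planted <- sample(0:2, n, replace = TRUE)
  reads <- vapply(planted, function(k) {
    cols <- strsplit(paste0("12320", strrep("0", 70)), "")[[1L]]
    if (k > 0) {
      at <- sample(1:5, k)
      cols[at] <- as.character((as.integer(cols[at]) + 1L) %% 4L)
    }
    paste(cols, collapse = "")
  }, "")
  res <- preprocess_reads(reads)
  expect_identical(nrow(res$reads), sum(planted <= 1L))
  expect_identical(res$summary$n[res$summary$status == "discarded"],
                   sum(planted == 2L))
})

test_that("single-read pre-processing mirrors the batch result", {
  r <- color_read("a", "T", paste0("12220", strrep("3", 70)))
  out <- preprocess_read(r)
  expect_identical(out$status, "repaired")
  expect_identical(out$mismatches, 1L)
  expect_identical(nchar(out$read$colors), 76L)
  bad <- color_read("b", "T", paste0("00000", strrep("3", 70)))
  expect_identical(preprocess_read(bad)$status, "discarded")
})

test_that("csfasta round trip preserves reads and qualities", {
  reads <- data.frame(id = c("r1", "r2"), primer = "T",
                      colors = c("12320", "00123"),
                      stringsAsFactors = FALSE)
  reads$quals <- list(c(20L, 20L, 9L, 30L, 30L), c(5L, 5L, 5L, 5L, 5L))
  f <- tempfile(fileext = ".csfasta")
  q <- tempfile(fileext = ".qual")
  write_csfasta(reads, f, q)
  back <- read_csfasta(f, q)
  expect_identical(back$id, reads$id)
  expect_identical(back$primer, c("T", "T"))
  expect_identical(back$colors, reads$colors)
  expect_identical(back$quals, reads$quals)
})

test_that("the signatures derive from the enzyme definition", {
  expect_identical(enzyme_start_signature(bamhi()), "12320")
  expect_identical(enzyme_site_signature(bamhi()), "102320")
  ecorv <- restriction_enzyme("EcoRV", "GATATC", 3L)
  expect_identical(ecorv$sticky_end, "ATC")
  expect_identical(enzyme_start_signature(ecorv), cs_encode("T", "ATC"))
  res <- preprocess_reads(paste0(cs_encode("T", "ATC"), strrep("0", 72)),
                          enzyme = ecorv)
  expect_true(startsWith(res$reads$colors, cs_encode("T", "GATATC")))
})
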