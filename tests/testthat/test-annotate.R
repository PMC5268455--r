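# A small planted annotation: one plus-strand gene with two CDS exons and
# UTRs, one minus-strand single-CDS gene, written as GFF3 at test time.

make_annotation <- function() {
  # plus-strand gene g1 on chrA: 5'UTR 101-130, CDS 131-190 + 241-279
  # (60 + 39 = 99 bases = 33 codons), intron 191-240, 3'UTR 280-300
  # minus-strand gene g2 on chrA: CDS 501-560 (60 bases, 20 codons)
  set.seed(61)
  n <- 800
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  # plant known codons at the start of g1's CDS: GGA TTC ...
  bases[131:136] <- c("G", "G", "A", "T", "T", "C")
  # g2 is minus strand: plant top-strand TCC at 558-560 so the coding
  # strand (revcomp) starts with GGA
  bases[555:560] <- c("G", "A", "A", "T", "C", "C")
  genome <- c(chrA = paste(bases, collapse = ""))
  gff <- c(
    "##gff-version 3",
    "chrA\ttest\tgene\t101\t300\t.\t+\t.\tID=g1",
    "chrA\ttest\tmRNA\t101\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrA\ttest\tfive_prime_UTR\t101\t130\t.\t+\t.\tParent=g1.t1",
    "chrA\ttest\tCDS\t131\t190\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chrA\ttest\tCDS\t241\t279\t.\t+\t0\tID=c2;Parent=g1.t1",
    "chrA\ttest\tthree_prime_UTR\t280\t300\t.\t+\t.\tParent=g1.t1",
    "chrA\ttest\tgene\t501\t560\t.\t-\t.\tID=g2",
    "chrA\ttest\tmRNA\t501\t560\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chrA\ttest\tCDS\t501\t560\t.\t-\t0\tID=c3;Parent=g2.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  list(genome = genome, path = path)
}

test_that("feature classification follows CDS > UTR > intron > intergenic", {
  ann <- make_annotation()
  models <- read_gene_models(ann$path)
  sites <- data.frame(
    contig = "chrA",
    pos = c(50L,    # intergenic
            110L,   # 5' UTR
            150L,   # CDS exon 1
            200L,   # intron
            260L,   # CDS exon 2
            290L,   # 3' UTR
            530L,   # minus-strand CDS
            700L))  # intergenic
  cls <- classify_snps(sites, models)
  expect_identical(cls, c("intergenic", "UTR", "CDS", "intron", "CDS",
                          "UTR", "CDS", "intergenic"))
  # exactly one class per site, so counts always sum to the input size
  expect_identical(length(cls), nrow(sites))
  expect_warning(classify_snps(data.frame(contig = "chrZ", pos = 1L),
                               models), "absent")
})

test_that("coding effects follow the genetic code on both strands", {
  ann <- make_annotation()
  models <- read_gene_models(ann$path)
  # g1 starts GGA (Gly): third base A->G is synonymous (GGA -> GGG)
  syn <- coding_effect("chrA", 133L, "A", "G", models, ann$genome)
  expect_identical(syn$effect, "synonymous")
  expect_identical(syn$codon_ref, "GGA")
  expect_identical(syn$codon_alt, "GGG")
  # first base G->A is nonsynonymous (GGA -> AGA, Gly -> Arg)
  nsy <- coding_effect("chrA", 131L, "G", "A", models, ann$genome)
  expect_identical(nsy$effect, "nonsynonymous")
  expect_identical(nsy$aa_ref, "G")
  expect_identical(nsy$aa_alt, "R")
  # minus strand: g2's first codon reads GGA from the reverse complement
  # (top 560..558); top-strand 559 C->T complements to coding G->A, so the
  # codon becomes GAA by hand: nonsynonymous (Gly -> Glu)
  mns <- coding_effect("chrA", 559L, "C", "T", models, ann$genome)
  expect_identical(mns$codon_ref, "GGA")
  expect_identical(mns$codon_alt, "GAA")
  expect_identical(mns$effect, "nonsynonymous")
  # a reference mismatch is flagged, not guessed
  bad <- coding_effect("chrA", 131L, "T", "A", models, ann$genome)
  expect_true(is.na(bad$effect))
})

test_that("variant annotation summarises classes and effects", {
  ann <- make_annotation()
  models <- read_gene_models(ann$path)
  sites <- data.frame(contig = "chrA",
                      pos = c(150L, 133L, 131L, 50L, 200L),
                      ref = c("T", "A", "G", "A", "A"),
                      alt = c("G", "G", "A", "C", "C"),
                      stringsAsFactors = FALSE)
  sites$ref <- substring(ann$genome[["chrA"]], sites$pos, sites$pos)
  out <- annotate_variants(sites, models, ann$genome)
  expect_identical(nrow(out$table), 5L)
  expect_identical(sum(out$summary$n[out$summary$class %in%
                                       c("CDS", "UTR", "intron",
                                         "intergenic")]), 5L)
  expect_identical(out$table$class[4], "intergenic")
  expect_true(is.na(out$table$effect[4]))
})
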