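# radsolid

RAD-seq discovery analysis in SOLiD colour space: simulation, alignment,
genotyping and population genetics for a cultivated-vs-wild germplasm
panel.

Restriction-site associated DNA sequencing (RAD-seq) digests genomic DNA
with a rare-cutting enzyme (here BamHI, G^GATCC) and sequences short
fragments flanking every recognition site, so that tens of thousands of
loci are genotyped at high depth across many individuals. When the reads
come from a SOLiD instrument they arrive in two-base colour space: each
symbol 0–3 encodes the transition between adjacent bases, anchored by a
known primer base, and every genuine read must begin with the colour
signature of the enzyme's sticky end (`T` + `12320` for `GATCC`).
radsolid implements the complete workflow for such data — and, because
studies of this design rarely deposit raw reads, a first-class simulator
that generates reference genomes, a two-subpopulation diploid panel and
colour-space read libraries with full ground truth.

The package is aimed at method developers and population geneticists who
want a tested, reproducible re-implementation of this workflow to study
its behaviour: restriction-site recovery, null alleles caused by
polymorphic cut sites, depth biases, and the downstream diversity and
linkage-disequilibrium (LD) contrasts between a domesticated and a wild
gene pool.

## What is implemented

* **Digestion** — `restriction_enzyme()`, `find_sites()`, `fragments()`,
  `digest_catalog()`, `compare_enzymes()`: in-silico digestion, site
  catalogs with fragment intervals, multi-enzyme recovery comparison.
* **Colour space** — `cs_encode()` / `cs_decode()` (the 4×4 two-base
  code), `classify_start()` and `preprocess_reads()`: reads with more
  than one colour error over the sticky-end signature are discarded, the
  rest have their start replaced by the full-site signature
  (`T102320`, 75 → 76 colours); csfasta reader/writer.
* **Simulator** — `simulate_reference()` (planted sites plus "near-miss"
  motifs that can mutate into unpredicted sites),
  `population_model()` / `simulate_population()` /
  `simulate_genotype_panel()` (windowed structured-coalescent founder
  genealogies, recombinant founder-mosaic individuals,
  identity-by-descent inbreeding blocks, restriction-site gain/loss
  variants), `simulate_library()` (site-anchored read stacks, per-colour
  errors, optional shear bias).
* **Alignment** — `build_index()` / `align_reads()`: seed-indexed
  colour-space alignment, unique-best placement, identity ≥ 0.90,
  MapQ = min(60, 4·(best − second-best matches)); `collect_evidence()`
  converts consistent adjacent colour-mismatch pairs into base
  observations.
* **Genotyping** — `genotype_likelihoods()` (P(b|a1,a2) =
  ½P(b|a1) + ½P(b|a2), P(b|a) = 1−e or e/3), `call_genotype()` (prior
  (1−3θ/2, θ, θ/2), maximum posterior), `merge_samples()` (sites emitted
  on ≥ 1 non-reference call at depth ≥ 10), VCF v4.2 output.
* **Site statistics** — `classify_sites()` (predicted/unpredicted ×
  nuclear/organellar), `depth_asymmetry()`, `depth_fraglen_correlation()`,
  `snp_density()` (500-kb tiling windows, chromosome-size correlation).
* **Population genetics** — `filter_matrix()` (sample missing rate
  > 0.5, locus > 0.2), `impute_ldknni()` (LD-k-nearest-neighbour
  imputation, k = 5, l = 20), `maf_filter()` (MAF < 0.05),
  `diversity()` (H_O; unbiased H_E = (2n/(2n−1))·2pq;
  F_IS = 1 − mean(H_O)/mean(H_E); private alleles), `ld_decay()`
  (genotype r², median per 10-kb bin, 0.2-crossing distance),
  `maf_spectrum()`, `concordance()`.
* **Annotation** — `read_gene_models()`, `classify_snps()`
  (CDS > UTR > intron > intergenic), `coding_effect()`
  (strand-aware codon translation, synonymous vs nonsynonymous).

## Worked example

```r
library(radsolid)

ref  <- simulate_reference(n_contigs = 1, lengths = 5e5, seed = 11)
pop  <- simulate_population(ref, population_model(n_cultivated = 12L,
                                                  n_wild = 10L), seed = 12)
lib  <- simulate_library(pop, library_model(error_rate = 0.01,
                                            depth_mean = 18), seed = 13)
pipe <- rad_pipeline(pop, lib)
pipe$preprocess$summary
#>      status     n     fraction
#> 1     exact 48920 0.9511773055
#> 2  repaired  2463 0.0478894052
#> 3 discarded    48 0.0009332893
pipeline_concordance(pipe, pop)$rate      # 0.999 over 673 comparisons
classify_sites(pipe$alignment$alignments, ref$catalog)$counts
#>   predicted unpredicted organellar_predicted organellar_unpredicted total
#> 1        62           3                    0                      0    65
```

95% of the simulated reads start with a clean `12320` signature at the
1% per-colour error rate, 4.8% are repaired, and 0.1% are discarded;
called genotypes agree with the simulator truth at 99.9% of deep
comparisons, and the three recovered sites absent from the reference
catalog are the simulated site-gain mutations.

The germplasm contrasts, on a panel at the default model:

```r
gm  <- simulate_genotype_panel(population_model(), n_loci = 4000,
                               chrom_lengths = 2e6, seed = 21)
pa  <- diversity(gm)$PA                   # 3622 cultivated, 1 wild
gmf <- maf_filter(filter_matrix(gm))
diversity(gmf)
#>       subpop  n n_loci     Ho     He     Fis   PA
#> 1 cultivated 51   3221 0.3747 0.3771 0.00647 2853
#> 2       wild 44   3221 0.0219 0.0239 0.08616    0
ld_decay(gmf, "cultivated")$dist_below    # 15000 bp
ld_decay(gmf, "wild")$dist_below          # 25000 bp
```

The cultivated subpopulation is more heterozygous, holds essentially all
private alleles, and its median r² decays below 0.2 at a shorter
distance than the wild subpopulation's — the qualitative fingerprint of
a diverse domesticated gene pool against a bottlenecked wild relict.
The methods vignette (`vignettes/rad-colorspace-methods.Rmd`) documents
the underlying models, defaults and limitations.

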