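---
title: "Models and methods behind radsolid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radsolid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsolid)
```

# Scope

radsolid implements a complete discovery workflow for restriction-site
associated DNA sequencing (RAD-seq) performed in SOLiD two-base colour
space: in-silico digestion, library and sequencing simulation with ground
truth, restriction-site-anchored read pre-processing, colour-space
alignment, Bayesian diploid genotype calling, restriction-site recovery
accounting, and population-genetics analysis of a germplasm panel split
into a cultivated and a wild subpopulation. This vignette documents the
models, the tunable parameters, and the design decisions, so that results
produced with the package can be interpreted correctly.

# Colour space and the read-start filter

SOLiD reads encode transitions between adjacent bases rather than bases:
colour 0 joins identical bases, colour 1 joins A/C or G/T, colour 2 joins
A/G or C/T, and colour 3 joins A/T or C/G. Numerically this is the XOR of
2-bit base codes, which makes the code symmetric and, for a fixed first
base, bijective — the properties the whole pipeline relies on. A read is
anchored by a known primer base (T for fragment libraries), so
`cs_encode("T", "GATCC")` yields `"12320"`: the colour signature of the
BamHI sticky end with which every genuine RAD read must begin.

The pre-processing filter counts colour mismatches over that 5-colour
start signature. Reads with more than one mismatch are discarded; the
rest have their start replaced by the 6-colour signature of the complete
recognition site (`"102320"`), which both repairs likely sequencing
errors in the anchor and restores the full site for alignment — a
repaired 75-colour read becomes 76 colours. The signatures are derived
from the enzyme definition (`restriction_enzyme()`), not hard-coded, so
any enzyme with a defined cut offset is supported. Base qualities are
carried by the csfasta reader but deliberately ignored by this filter,
which is purely positional.

A property worth noting: a single base substitution alters exactly two
adjacent colours (one when it falls on the last base), and the two
altered colours jointly determine the substituted base. The aligner's
evidence extraction uses this to separate true substitutions (consistent
adjacent colour pairs) from sequencing errors (isolated mismatches),
which is why colour-space alignment is performed on colours and bases
are only inferred after placement.

# In-silico digestion

`find_sites()` scans the top strand for exact motif occurrences
(overlapping hits included; windows containing N never match — a
conservative choice). BamHI's recognition sequence is palindromic, so one
catalog entry represents both strands and yields two RAD loci, one read
stack running downstream on the top strand and one upstream on the
bottom strand, both starting at the cut with the sticky-end sequence.
Coordinates are 0-based half-open internally; VCF output is 1-based.
Fragment accounting applies the cut at `site + cut_offset`; fragments
always concatenate back to the input, a property the tests enforce.

`compare_enzymes()` ranks candidate enzymes by the number of sites whose
simulated per-site read depth (Poisson with a common mean) reaches each
coverage threshold; with a fixed per-site depth this isolates the motif
frequency as the driver of recovery, which is the quantity of interest
when choosing an enzyme.

# The synthetic germplasm model

No public raw data accompany the study design this package addresses, so
the simulator is a first-class component: it defines the conditions under
which every statistical claim is tested.

## Founder genealogies

Founder haplotypes for the two subpopulations are related by a
two-population structured Kingman coalescent: within-population
coalescence at rates inversely proportional to the population's relative
effective size until `split_time`, then panmictic ancestral coalescence.
The wild population's small `ne_wild` (default 0.2 against 1 for the
cultivated and ancestral populations) makes wild lineages coalesce
rapidly, so in every genealogy most wild founders descend from a handful
of ancestral lineages. This single mechanism produces, at once, the
reduced wild heterozygosity, the excess of wild loci with low minor
allele frequency, the stronger and longer-ranged wild linkage
disequilibrium, and the near-absence of wild private alleles — the four
qualitative contrasts between a domesticated panel and a bottlenecked
wild relict.

Local genealogies turn over along the genome (an independent tree every
`tree_span` bp, default 100 kb), and within a tree the branch carrying
each variant follows a Markov chain whose persistence distance
(`genealogy_persistence`, default 1 kb) sets the founder-level LD block
length. Branch choice is weighted by genealogical length times a
discovery-ascertainment factor `(c(K - c))^ascertainment` computed on
cultivated carrier counts: discovered SNP panels are depleted of rare
variants, and counting cultivated carriers only encodes the assumption
that wild variation is a drifted subset of the shared ancestral
variation. Wild-private alleles therefore arise only from the explicit
`private_wild` fraction (default 5e-4), and cultivated-private alleles
both from `private_cultivated` singletons and, in much larger numbers,
from ancestral variants that the wild bottleneck lost.

## Individuals

Individuals are recombinant founder mosaics: the founder identity along a
haplotype switches at `recombination` expected events per megabase
(default 40). The rate is expressed per megabase of mosaic rather than
per gamete because a panel of unpedigreed accessions accumulates an
unknown number of historical meioses; the mosaic block length is the
identifiable quantity. Founder contributions are Dirichlet-weighted
(`alpha_cultivated = 20`: nearly even; `alpha_wild = 1.5`: drifted).
Inbreeding is modelled as identity-by-descent blocks: along wild
homologous chromosomes, blocks are copies of each other with stationary
probability `f_wild` (default 0.02), so the realised deficit of
heterozygotes matches the configured F and is recoverable from the
genotypes (the tests demand recovery within ±0.05 at F of 0 and 0.2 with
5,000 loci on eight 2-Mb chromosomes and 40 samples).

Defaults were fixed once, with the published diversity table, the MAF
spectra and the LD-decay contrast of a cultivated/wild grapevine panel as
tuning goals for the qualitative behaviour, and then frozen. The
cultivated side lands near the published values (multilocus observed
heterozygosity about 0.4, inbreeding coefficient near 0); the wild side
deliberately exaggerates the bottleneck (observed heterozygosity well
below the published 0.31) because the directional contrasts — which are
what the acceptance checks assert — must hold robustly at any seed, and a
milder bottleneck makes them flip in an appreciable fraction of runs.
Users studying absolute wild diversity should raise `ne_wild`.

## Variants at restriction sites

`simulate_population()` places variants only within read range of a cut
(at most 74 bases downstream or 69 upstream, leaving the terminal base
free so every allele is observable from a colour pair; substitutions
closer than 3 bp are thinned because interleaved colour signatures are
unreadable). Recognition sites additionally segregate: a disrupting
substitution inside the motif (`re_loss_rate` per site) removes the site
from carrier haplotypes — the null-allele mechanism that biases flanking
genotypes toward homozygosity — and "near-miss" motifs planted by
`simulate_reference()` (motif with the last base substituted) are
converted to genuine sites on carrier haplotypes, producing the
"unpredicted" recovered sites absent from the reference catalog. The
default near-miss density is 7% of the site density, so the predicted
share of recovered sites sits near 93%.

## Library and sequencing

Each surviving site on each haplotype emits an upstream and a downstream
read stack starting exactly at the cut (Poisson depth, mean
`depth_mean / 2` per haplotype so that a null allele halves locus depth),
a gamma per-sample library-size multiplier with coefficient of variation
`sample_cv`, and independent per-colour errors at `error_rate` (default
0.01). With `shear_bias = TRUE` the locus depth scales with the
logarithm of the flanking restriction-fragment length, reproducing the
shearing-step bias diagnostic; with the default `FALSE` the
depth/fragment-length correlation is structurally absent. The simulator
does not model PCR duplicates, adapter dimers, instrument-specific error
spectra (the published 75/11/14 start-classification split is an
instrument property, not a model target), base-quality learning, or
organellar copy-number amplification — so passing tests demonstrate the
pipeline's correctness under the stated error model, not robustness to
every artefact of real libraries.

# Alignment

The reference is colour-encoded on both strands and every k-colour word
(k = 16, packed into 2-bit integers) is hashed. Candidates for a read are
the exact matches of three staggered seeds taken after the 6-colour site
signature; this retrieves every catalogued site and any novel (gained)
site, and a read whose seeds are all disrupted by errors is reported
unaligned. At each candidate the colours are compared directly: identity
is the matching fraction, a read is kept only if its best placement is
strictly better than the second best (ties are dropped, never broken at
random) and identity reaches 0.90 — on a 76-colour read, 7 mismatches
(identity 0.9079) pass and 8 (0.8947) fail. Mapping quality is
`min(60, 4 * (best - second best matches))`, an artifact-defined proxy
for the placement gap: 60 for a single perfect candidate, 0 for a tie.
Two thresholds are exposed because they serve different purposes:
MapQ > 10 delimits the reporting tier in alignment accounting, and
MapQ > 17 gates the evidence used for genotyping.

# Genotyping

Per observed base b and genotype {a1, a2},
P(b | a1, a2) = P(b|a1)/2 + P(b|a2)/2 with P(b|a) = 1 − e for a match and
e/3 otherwise; the likelihood is the product over the read stack. The
prior is the conventional diploid split (1 − 3θ/2, θ, θ/2) with
θ = 0.001, and the call is the maximum-posterior genotype; an exact
posterior tie is reported missing rather than broken arbitrarily. GQ is
the Phred-scaled posterior gap capped at 99. Multi-sample merging emits a
position only when at least one sample has a non-reference call at depth
≥ 10; shallower samples are missing at emitted sites; positions whose
samples support different alternate bases are dropped with a warning,
keeping the output biallelic. The error-rate parameter should match the
data: the end-to-end zero-error check runs the caller at e = 1e-4,
because a mismatched error prior turns strong allelic-sampling imbalance
(9:1 at depth 10) into confident wrong homozygous calls — exactly the
behaviour the parameter is meant to control.

# Site recovery and density diagnostics

A site is recovered when it attracts at least 10 alignments; recovered
sites are partitioned into predicted/unpredicted crossed with
nuclear/organellar, and the partition must sum to the total — an
invariant under test. Depth asymmetry flags sites where more than 80% of
samples are deep (> 10 reads) on exactly one flank. SNP density uses
non-overlapping windows tiling each contig (the published bin arithmetic
— 985 bins of 500 kb over a ~492 Mb genome — implies tiling rather than
stepped sliding windows, and that is what is implemented); the final
partial window is kept, and bin counts must sum to the per-contig totals.
The fragment length attributed to a RAD locus is that of the restriction
fragment on the side the locus reads into.

# Population genetics

Filtering follows the fixed order: samples with missing rate > 0.5, then
loci with missing rate > 0.2 (computed on retained samples), then
LD-kNNi imputation, then removal of loci with MAF strictly below 0.05 (a
locus at exactly 0.05 is retained). Imputation ranks candidate proxy loci
by squared genotype correlation with the target locus, measures sample
distances as mean absolute dosage difference over the top-20 proxies at
mutually observed entries, and scores each genotype among the 5 nearest
observed neighbours by summed inverse distance (ε = 1e-9 guards zeros;
score ties resolve to the smaller dosage). Observed entries are never
altered.

Expected heterozygosity uses the sample-size-corrected estimator
(2n/(2n−1))·2pq by default (the naive 2pq sits behind
`unbiased = FALSE`), and F_IS = 1 − mean(H_O)/mean(H_E) is the ratio of
multilocus averages; per-locus averaging is available via
`per_locus_fis = TRUE` since published tables rarely state which
convention they used. Private alleles count loci at which some allele is
present in one subpopulation and absent in the other. LD is the squared
Pearson correlation of 0/1/2 dosages (genotype r², not haplotype-EM r²),
pairs are restricted to the same contig within 500 kb, the decay curve is
the median r² in half-open 10-kb bins, and the reported crossing distance
is the midpoint of the first bin whose median falls below 0.2 — a
convention chosen for determinism; only curves from the same convention
should be compared. Concordance between call sets excludes entries
missing in either set from numerator and denominator alike.

# Annotation

Feature classes follow the precedence CDS > UTR > intron (any other
genic position) > intergenic, so every site receives exactly one class.
Coding effects rebuild the transcript's coding sequence from the ordered
CDS intervals, reverse-complementing for minus-strand models, translate
the reference and alternate codons with the standard genetic code, and
call any amino-acid change — including a gained or lost stop —
nonsynonymous. Models whose coding length is not a multiple of three, or
where the reference base disagrees with the genome, are flagged and
excluded rather than guessed.

# Problem sizes and limitations

The test suite and the acceptance script run, by design, at reduced
scale: reference simulations of 1 Mb with one site per 8 kb (about 125
sites), 20-sample end-to-end runs at depth 24, and genotype panels of
4,000–5,000 loci for the diversity, LD and imputation studies — sizes at
which every stochastic assertion was verified to be stable across seeds.
Known limitations: no gapped alignment (RAD reads are anchored and
short; indels are out of scope), no methylation-sensitive digestion, no
multi-allelic records, a single global per-colour error rate, and a wild
population model tuned for directional robustness rather than absolute
diversity levels.
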