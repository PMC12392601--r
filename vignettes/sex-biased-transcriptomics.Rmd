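---
title: "Methods: sex-biased transcriptome analysis in SexBiasTx"
author: "SexBiasTx maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SexBiasTx)
```

# Scope and design

SexBiasTx implements a complete analysis chain for sex differences in bulk
preimplantation-embryo RNA-seq — sexing statistics, differential
expression, X dosage compensation, skipped-exon splicing, protein-domain
disruption and isoform classification — together with a seeded simulator
that generates every input with known ground truth. The simulator is
first-class code, not a test fixture: it defines the statistical structure
(effect types, noise model, design sizes) under which the analysis stages
are validated, and all calibration and power claims in the test suite refer
to those conditions.

The package deliberately substitutes self-contained statistical models for
two heavyweight external engines. Differential expression uses a
negative-binomial GLM with moment dispersion rather than a shrinkage
framework, and differential splicing uses a binomial-logit likelihood-ratio
test rather than a junction-count mixed model. Both stand-ins are
documented below with their assumptions and the situations in which the
full engines would differ.

# Embryo sexing and sex-ratio statistics

Sex is called from a duplex PCR: an autosomal control amplicon and a
Y-specific amplicon. Both present → male; autosomal only → female; no
autosomal control → undetermined, whatever the Y lane shows, because a
failed control makes a missing Y band uninformative. Undetermined embryos
are excluded from all ratio statistics.

The stage-wise test is the Pearson goodness-of-fit chi-square against a
1:1 expectation, df = 1, with **no Yates continuity correction**. Both
choices are forced by back-calculation from the five published stage
results the test reproduces: for 8 males vs 4 females the uncorrected
statistic gives p = 0.248 (printed "0.25") whereas the corrected one gives
0.386, and only a 1:1 null reproduces all five printed p-values. The test
is applied per day × stage stratum; `stageSexRatios()` wraps the per-stratum
loop.

A second, independent sexing check uses expression: a sample is male iff
its mean TPM over Y-linked genes exceeds a threshold (default 1 TPM).
On simulated data with zero leakage the two routes agree exactly.

# Differential expression

`computeTPM()` divides counts by feature length in kb and rescales each
sample to one million; all-zero samples yield flagged all-zero columns.

`differentialExpression()` fits, per gene, a negative-binomial GLM of
counts on sex (female = reference, so positive log2FC = male-biased) plus
an optional batch factor such as collection week, with log size factors as
offsets. Size factors are median-of-ratios. Dispersion is per-gene
method-of-moments on normalized counts, pooled within sexes, floored at
1e-8 and capped at 10; there is **no shrinkage across genes**. Inference is
a Wald test on the sex coefficient with Benjamini–Hochberg FDR.

Choices worth stating explicitly:

* The DEG rule is |FC| > 1.5 **and** FDR < 0.1, both strict. The fold
  change is the raw model estimate, not a shrunken one; with moment
  dispersions and 5–6 replicates per group the raw estimate is the less
  surprising default, and the threshold test uses a 1e-8 guard so a fold
  change numerically equal to 1.5 is never flagged.
* All-zero genes are excluded before fitting and reported in an attribute.
* Against a shrinkage-based reference implementation on simulated data the
  per-gene log2FC estimates correlate above 0.95 and agree in sign on all
  spiked genes (this is asserted in the test suite); per-gene p-values
  differ more, which is why published DEG *counts* are not treated as
  reproduction targets anywhere in the package.

Gene-group enrichment is the two-sided Fisher exact test on the 2×2 table
of DEG × group membership, significant at p < 0.01. The background
universe defaults to all annotated genes and is configurable to expressed
genes only; the choice changes the table margins, and the tests pin the
implementation to an exhaustive hypergeometric enumeration oracle rather
than to any particular universe. The 2^−ΔΔCt utility aggregates reference
genes by the arithmetic mean of their Ct values (equivalently the geometric
mean of linear quantities), the common convention when two reference genes
are used.

# X:autosome dosage compensation

The estimand is the ratio of the median expression of X-linked genes to
the median of autosomal genes, per sex, where per-gene expression is the
**mean TPM across the group's samples** (gene-level pooling first, then
medians — the convention of the X:A literature this statistic comes from).
Y-linked genes never enter either stratum. Categories: expressed
(mean TPM > 1, strict), DEG, and non-DEG (non-DEG additionally requires
expression, so silent genes cannot drag the medians); each category has a
paralog-excluded variant, since paralog-rich X regions can inflate
apparent X expression through multi-mapping. An X:A near 1 indicates
complete compensatory upregulation of the single active X; near 0.5, none.

The confidence interval is a **percentile bootstrap stratified by
chromosome class**: genes are resampled with replacement within the X
stratum and within the autosome stratum independently, the ratio is
recomputed per replicate (default 1000), and the 2.5/97.5 percentiles are
reported. Two readings of "stratified by the group variables" are
possible — within chromosome strata or within sex groups; resampling genes
within chromosome strata is the one that matches the estimand (the
resampling unit is the gene, and sex enters only through which samples are
averaged), so it is the default. Percentile intervals (rather than BCa)
are the simplest interval consistent with a ratio-of-medians estimator;
on null data (X and autosome drawn identically, 500 genes each) their
empirical coverage of 1 sits a few points below the nominal 95%, which the
acceptance checks account for by testing coverage against a ~95% band
rather than an exact count.

DEG density along the X uses 0-based half-open 1-Mb windows with
start-coordinate assignment — an unambiguous rule under which window counts
always sum to the number of genes — and flags runs of empty windows.

# Skipped-exon splicing

PSI for a skipped-exon event is the effective-length-normalized inclusion
fraction PSI = (I/l_I)/(I/l_I + S/l_S). In junction-count mode an
inclusion read can come from either flanking junction while a skipping
read has a single junction, so l_I = 2 and l_S = 1; the simulator
allocates junction reads with exactly this weighting, which makes
estimator consistency a testable property (the estimate converges on the
generating PSI as junction depth grows). A sample with I = S = 0 has
undefined PSI and is omitted from group means.

The differential test is a per-event likelihood-ratio test comparing a
binomial-logit model with a sex term against an intercept-only model
(1 df). It treats replicates as binomial draws and therefore ignores
between-replicate overdispersion; a beta-binomial variant
(`method = "betabinomial"`) absorbs it at some cost in power and speed.
On data generated under the binomial model the default test is
FDR-calibrated (the suite checks ≤ 2× nominal at 1000 null events) — on
real data with extra-binomial variation the beta-binomial option is the
safer choice.

Significance combines four filters, boundary semantics exactly as stated:
group-mean junction count ≥ 10 in **both** groups; an informativeness
filter on PSI; FDR ≤ 0.01; |ΔPSI| ≥ 0.05 (ΔPSI = male − female). The
informativeness filter deserves a note: the natural-language rule
"filter out events with average PSI ranging 0.05–0.95 in both groups"
is self-contradictory for a differential analysis — read literally it
discards every informative event and keeps only near-constitutive ones.
The default (`psiRangeMode = "standard"`) implements the standard intent:
an event is removed when its group-average PSI falls *outside* (0.05,
0.95) in both groups, i.e. near-constitutive inclusion or exclusion
everywhere. The literal reading remains available behind
`psiRangeMode = "literal"` for comparison.

Only skipped-exon events are modeled end to end; the rMATS-like TSV
reader/writer preserves the other event classes' records but no statistics
are attached to them.

# Protein domains and coordinate lift-over

CDS translation concatenates the CDS intervals in transcription order
(reverse-complementing on the minus strand), requires frame (length
divisible by 3, enforced at annotation construction), drops a trailing
stop and rejects internal stops.

Domain-hit filtering keeps a hit iff score > 10, domain E-value < 0.01,
sequence E-value < 1e-5, accuracy ≥ 0.8 and coverage ≥ 0.9 — strict versus
inclusive exactly as written, which the tests pin at each boundary.
"Coverage" is coverage of the **domain model** (aligned model span /
model length), the hmmer reading of "proportion of the domain aligned",
not coverage of the protein. Hits with any missing metric are rejected
with reason `incomplete`.

The lift-over maps amino acid *k* to spliced-CDS nucleotides 3k−2…3k and
those through the exon structure to genomic intervals; a codon split by an
intron owns all three of its bases wherever they fall, so a domain
spanning a junction lifts to multiple intervals whose widths always sum to
3× the amino-acid span. Internally all coordinates are 1-based closed
IRanges (the Bioconductor convention; GTF I/O is 1-based inclusive as
usual), and the test suite verifies the genomic↔protein map is a per-base
bijection on both strands against an enumeration oracle built by hand.

A filtered domain is called **disrupted** when any of its genomic
intervals overlaps a significant skipped exon by ≥ 1 bp on the same
chromosome — the skipped exon itself, not the whole event region; callers
wanting the wider region can pass those intervals instead, since the
overlap rule only sees intervals.

# Isoform classification and integration

Intron chains are compared with the reference annotation per chromosome
and strand. Gene-overlap categories are resolved first: no same-strand
overlapping gene → `antisense` (opposite-strand gene present) or
`intergenic`; a chain spanning two or more same-strand genes with disjoint
spans → `fusion`. Within a gene, `FSM` requires the exact reference intron
chain (checked before `ISM`); `ISM` a consecutive sub-chain (the
5′-degradation pattern — arbitrary subsets do not qualify); `NIC` all
splice sites known but the junction set novel; `NNC` at least one novel
splice site. Mono-exonic chains are `FSM` when contained in a mono-exonic
reference transcript, `genic_genomic` within a gene, `intergenic`
otherwise. Splice-site identity is exact coordinate match by default;
a `wobble` window (in bases) is available but defaults to 0 because exact
matching is what makes the classifier property-testable. Where a chain
overlaps a gene only on the opposite strand and also has novel sites,
antisense wins — gene-overlap precedence is applied uniformly.

The sex-biased isoform test is a per-isoform Wilcoxon rank-sum test on
size-factor-normalized counts with BH q-values (q < 0.05), a distribution-
free stand-in for inferential-replicate methods; it is exactly the tool
for the isoform-switch pattern in which one isoform rises and another
falls while the gene total stays flat, and the suite contains that
scenario. `integrateGeneSets()` partitions DEG / splicing / isoform gene
sets into the seven exclusive membership patterns; the partition is
verified against brute-force membership enumeration.

# The simulator: what it emulates, and what it does not

`simulationConfig()` defaults encode the study conditions the package is
validated under: a five-stratum blastocyst cohort (Day 7
expanded/hatched; Day 8 non-expanded/expanded/hatched; 444 embryos
collected, sexing failure 32/444) with stage-wise male fractions matching
the observed male-biased progression, and an 11-sample RNA-seq design of
6 female and 5 male pooled replicates at ~1e6 expected reads. The
`maleStageAdvantage` knob scales the per-stratum male log-odds (0 = exact
1:1 null). The toy genome has 5 autosomes plus X and Y (40 genes per
chromosome, Y one-fifth), random multi-exon structures on both strands,
in-frame CDS with designed codons written into the random chromosome
sequences, an XIST-like female-only lncRNA on X, and sampled gene flags
(paralog 0.2, TF 0.1, TF-cofactor 0.05, escapee 0.15).

Counts are negative binomial (dispersion 0.05) with mean = library size ×
relative abundance × effect factor: Y genes silent in females and the
XIST-like gene silent in males (a configurable leak rate, default 0),
X genes scaled 1.3 in females and 1.0 in males (partial compensatory
upregulation — the magnitude of autosomal male effects is a free
parameter, since no canonical value exists), and 10% of autosomal coding
genes spiked at |log2FC| = 2 with random sign. Junction counts are
Poisson totals with binomial allocation under the same effective-length
weighting the PSI estimator inverts (15% of events differential at
ΔPSI 0.3, depth 200). Domain hits are constructed to fail each filter
criterion exactly once at its boundary and to sit inside or outside
skipped exons with known disruption labels. Isoform chains cover all
eight categories by construction.

All draws flow from one root seed through named substreams (cohort,
annotation, sequences, counts, SE events, domain hits, isoform chains), so
each generator is reproducible in isolation and truth tables always refer
to generated feature ids.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: read-level artifacts (mapping ambiguity,
positional bias, GC effects), gene–gene correlation, overdispersion beyond
NB at the gene level or beyond binomial at the junction level (unless the
beta-binomial path is exercised), realistic sequence composition, and
library-preparation batch structure beyond a label. Calibration statements
are therefore statements about the model classes, not about any particular
dataset.

# Numerical choices and problem sizes

Tolerances and guards: BH is used for all FDR control; the DEG
fold-change comparison carries a 1e-8 guard against ties at the
threshold; dispersions are floored at 1e-8 and capped at 10; LRT
statistics are floored at 0; degenerate inputs (all-zero genes, all-zero
junction rows, empty strata, missing hit metrics) are excluded with
reports rather than silently dropped, and empty strata are errors that
name the stratum.

The validation suite runs at deliberately desk-scale sizes chosen as the
smallest that make the statistical assertions stable: 2–3 autosomes ×
20–60 genes for pipeline tests, 1000 events/genes for null-calibration
checks, 20 seeded replicates for power and recovery rates, 100 runs for
bootstrap coverage, and 1000 bootstrap replicates per interval (the
method default). `scripts/acceptance.R` re-runs the same battery from a
single command-line seed.

# Known limitations

* The DE stand-in's moment dispersions are noisy with 5–6 replicates;
  shrinkage frameworks will be better powered at low counts.
* The binomial splicing test is anticonservative under real
  overdispersion; use the beta-binomial option there.
* Percentile bootstrap intervals on ratio-of-medians undercover slightly
  at stratum sizes of a few hundred genes.
* The classifier's exact splice-site matching treats any 1-bp wobble as
  novel unless `wobble` is raised; long-read callers with soft junction
  correction may need a nonzero window.
* XCI escapees are an annotation input; the package does not infer escape
  from data, and pseudoautosomal coordinates are not modeled.
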