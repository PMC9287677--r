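---
title: "Methods: dissecting a miRNA regulatory axis with miraxis"
author: "miraxis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a miRNA regulatory axis with miraxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miraxis)
```

# Overview

When a microRNA is lost in a disease state, its signature appears at
several independent layers of transcriptomic data: its target genes are
de-repressed, the complementary seed sequence is over-represented in the
3' UTRs of genes that respond to restoring the miRNA, its loss replicates
across independent patient cohorts, and — when the miRNA is intronic — the
transcription of its host gene tells us whether the loss is transcriptional
or a biogenesis (processing) defect. `miraxis` implements each of these
inference layers as a small, testable statistical procedure, together with
a synthetic-data generator that plants known effects so every claim the
package makes can be validated against ground truth.

The five analysis layers are:

1. **Positional seed-word enrichment** (`seedScan`): exact hypergeometric
   tests of 7mer site words along miRNA positions 1–15, BH-corrected.
2. **Target de-repression** (`cdfShift`): two-sample Kolmogorov–Smirnov
   comparison of fold-change CDFs.
3. **Permutation GSEA** (`gseaPermutation`, `gseaCollection`): weighted
   running-sum enrichment with gene-label permutation p-values.
4. **Cross-dataset consensus** (`harmonizeDeTables`, `consensusFilter`):
   vote-counting retention of miRNAs significant in at least *m* of *K*
   datasets, with direction-consistency flags.
5. **pri-miRNA inference** (`buildIntronSet`, `countIntronicReads`,
   `priFoldChange`, `correlateMatureVsPri`, `classifyRegulation`):
   intron-contained read counting as a proxy for primary-transcript
   abundance of intronic miRNAs.

# Seed-word enrichment

For a mature miRNA sequence $s$ (RNA, 5'→3') the scan enumerates the
words $s_{p..p+k-1}$ for start positions $p = 1..15$ and $k = 7$. Each
word's putative binding site in a 3' UTR is its DNA reverse complement
(A–T, C–G, G–C, U–A): a miRNA word cannot base-pair with a UTR occurrence
of itself, so the complement is the canonical convention; a
`matchLiteral` flag exposes the alternative literal reading. For each
position the test is exact hypergeometric on gene-level *presence/absence*
(multiplicity in a UTR is ignored, and `N` never matches):

$$P = \sum_{x \ge x_{obs}} \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}}$$

with $N$ the universe size, $K$ the universe genes containing the site,
$n$ the query size and $x_{obs}$ the query genes containing the site.
Presence/absence (rather than occurrence counts) is used because the
hypergeometric's population/draw framing is over genes. BH correction is
applied across the 15 positions of one scan — the natural test family —
and per miRNA when several miRNAs are scanned. Because it is ambiguous
whether such scans are conventionally reported on raw or adjusted
p-values, both columns are always emitted and the `significant` flag uses
the adjusted one (default threshold 0.01).

The default query set mirrors common differential-expression practice:
adjusted p < 0.05 and log2 fold change < −0.5, applied one-sided to
downregulated genes; the default universe is every gene that has both a
DE measurement and a UTR sequence. Whether a study's universe was "all
expressed genes" or "all genes with an annotated UTR" is rarely stated,
so both choices remain explicit arguments.

# Target de-repression as a CDF shift

`cdfShift` compares the log2 fold-change distributions of a target set
and a background with the two-sample, two-sided KS test. The p-value is
exact when $\min(n, m) \le 25$ and there are no ties, asymptotic
otherwise. The KS statistic is unsigned, so the direction of the shift is
reported separately as the difference of medians; sidedness is left
two-sided because the direction of de-repression is a conclusion, not an
assumption.

# Permutation GSEA

Genes are ranked from most up- to most downregulated (ties broken
lexicographically so the order is total and deterministic; ranking metric
`log2fc` by default, `signed_logp` = $\mathrm{sign}(\mathrm{lfc})\cdot
-\log_{10} p$ offered). The running sum rises by
$|r_i|^w / \sum_{hits} |r_j|^w$ at gene-set hits and falls by $1/(N-m)$
at misses; the enrichment score (ES) is the extremum of largest
magnitude. Weight $w = 1$ is the default (the classic weighted
statistic); $w = 0$ gives the analytically tractable unweighted case used
by the exactness tests. Numerical tie between the positive and negative
extremum resolves to the positive one, with a $10^{-12}$ tolerance so
that the choice cannot flip on last-bit rounding.

The null is **gene-label permutation**: random same-size sets of ranked
genes. Phenotype permutation is degenerate in designs with 2–3 samples
per arm, which is the regime this package targets, so gene-label
permutation is the deliberate design choice. With $n_s$ same-sign
permutation scores, $p = (1 + \#\{|ES_{perm}| \ge |ES|,
\text{same sign}\}) / (1 + n_s)$ — never zero, and valid by construction.
NES divides ES by the mean same-sign permutation magnitude and is
reported as missing when fewer than 10 same-sign permutations exist,
rather than returning an unstable value. Collections are BH-corrected
across sets; zero-overlap sets are skipped and listed.

# Cross-dataset consensus

Independent DE tables are outer-joined on the miRNA identifier. Three
states are kept distinct throughout: *missing* (not measured in that
dataset), *measured but not significant*, and *significant*. Each
dataset's significance criterion uses its adjusted p-value when present
and falls back to the raw p-value otherwise (microarray-era tables often
lack adjusted values); the criterion used is recorded per dataset. A
miRNA is *retained* when significant (criterion < 0.05, |lfc| > 0.5) in
at least `minDatasets` (default 3) datasets. The `all_down` flag is
operationalized strictly: significant *and* down in every dataset in
which the miRNA was measured; `requireAllDatasets = TRUE` additionally
demands measurement in every dataset. Raising `minDatasets` can only
shrink the retained set (a tested monotonicity invariant).

The bundled `deContrast` (median-of-ratios size factors, Welch t on
log2(CPM + 0.5), BH) exists to close the loop on synthetic counts; real
data are expected to arrive as externally produced DE tables.

# pri-miRNA inference from intronic reads

For an intronic miRNA, the unspliced primary transcript of its host gene
is the pri-miRNA; intron-contained reads proxy its abundance. The intron
set of a host gene is its span minus the merged exons of **every** gene
overlapping that span, so a neighbour's exonic signal is never counted as
intronic. A read counts only when *fully contained* in one intronic
interval: any overlap with an exon or junction disqualifies it, because
junction reads are ambiguous between spliced and unspliced molecules. (A
containment rule is stricter than a minimum-overlap rule; it was chosen
because the quantity of interest is the unspliced molecule.)

Fold changes are computed with size factors from **total intronic
counts** per sample — not whole-library totals — so global changes in
exonic amplitude cannot masquerade as pri-miRNA changes. This carries an
identifiability assumption worth stating plainly: like any
ratio-normalization, it assumes most host genes are unperturbed. If every
host gene changed by the same factor, that factor would be absorbed into
the size factors and the fold changes would read as null. The package's
simulations therefore plant effects sparsely (a few hosts among many),
which is also the biologically realistic regime. Genes with fewer than
`minCount = 20` total intronic reads across the contrast are flagged
low-coverage and excluded from fold-change reporting, reflecting the
deep-coverage requirement of intron-based quantification.

Mature-vs-pri concordance is summarized by both Spearman's $\rho$ and
Pearson's $r$ (the conventional choice of statistic for such scatter
analyses varies, so both are reported), and per-miRNA calls follow
`classifyRegulation`: *transcriptional* when the mature change is
substantial (|lfc| ≥ 0.5), same-signed, and the pri change carries at
least half its magnitude; *post_transcriptional* when the pri change is
proportionally small; *discordant* when both are substantial but
opposite-signed; *unchanged* otherwise.

# The synthetic-data generator

Every generator returns a `SimTruth` recording exactly what was planted;
recovery tests consume the truth object only.

* **UTR sets** (`simulateUtrSet`): i.i.d. per-base background at a stated
  GC content (default 0.45, typical of human 3' UTRs); target genes carry
  the DNA reverse complement of miRNA seed positions 2–8 at recorded,
  non-overlapping offsets, so the expected minimum-p scan position is 2.
  No higher-order sequence composition is modelled — adequate for
  word-count nulls, but real UTRs have dinucleotide structure and
  conserved elements, so null calibration on synthetic data is a
  necessary, not sufficient, check for real data.
* **Counts** (`simulateCounts`): negative binomial with a single shared
  dispersion (default 0.05, moderate bulk-RNA-seq variability);
  per-feature dispersion is deliberately out of scope.
* **Multi-dataset DE** (`simulateMultiDatasetDe`): six datasets by
  default; planted miRNAs are significant with the stated direction in
  exactly their planned number of datasets, nulls everywhere else (null
  lfc sd 0.15, uniform p). The same noise model is used for all datasets;
  real cohorts span platforms with heterogeneous noise, which this
  deliberately simplifies.
* **Host-gene experiments** (`simulateHostGeneExperiment`): reads are
  emitted as genomic intervals, not sequences, since the pri-miRNA stage
  needs only positions. The *transcriptional* regime scales intronic and
  mature levels together by $2^{\mathrm{priLog2fc}}$; the *processing*
  regime scales mature levels only. Defaults echo magnitudes typical of
  the motivating biology: −1.32 (a 60% reduction) and −0.51 (a 30%
  reduction). Exonic reads start uniformly inside exons and may overhang
  junctions, exercising the containment rule; intronic reads are placed
  fully inside introns, uniformly over feasible placements, with
  Poisson-distributed per-gene totals around the requested depth
  (default 500 intronic reads per gene per sample, the deep-coverage
  regime intron-based inference needs).

# Numerical and reproducibility choices

* Coordinates are held internally as `GRanges` (1-based, closed), the
  native Bioconductor convention; GTF (1-based inclusive) and BED
  (0-based half-open) are converted only at the I/O boundary by
  `rtracklayer`, so there is a single place to audit off-by-one errors.
* miRNAs stay RNA and UTRs stay DNA; U↔T conversion happens only inside
  `seedSiteWord`, explicitly.
* All stochastic functions take an explicit integer seed and isolate the
  RNG with `withr::with_seed`; identical parameters and seed give
  bit-identical output (a tested contract).
* Tables are written at full double precision (`%.17g`) so
  write-then-read is the identity.
* Degenerate inputs fail loudly and by name: alphabet violations name the
  record, schema violations list the missing columns, inconsistent
  hypergeometric counts, empty query sets and unknown genes are errors,
  not warnings.
* Pseudocounts (0.5) stabilize log fold changes at low counts; Welch
  rows with zero pooled variance get p = 1 when means agree and p = 0
  otherwise.

# Validation scale

The test suite validates each statistic against an independent oracle:
exhaustive enumeration for the hypergeometric tail (all instances with
universe ≤ 12), the literal double-loop definition for BH (1,000 random
vectors), label-assignment enumeration and a brute-force ECDF supremum
for KS, a naive running-sum walk and the external `fgsea` statistic for
the ES, explicit set algebra for the consensus rule, and per-base
membership for intron subtraction. Statistical recovery runs at sizes
chosen to keep the full suite under a few minutes on one CPU while
leaving comfortable statistical margins: 300-gene UTR sets with 30%
targets (20 replicates), 200 null scans, 200-gene null rankings for GSEA
calibration (200 trials), a planted set against 50 null sets (10
replicates, 1,000 permutations), 20-host panels with effects planted in
2 hosts for fold-change recovery (20 replicates per regime), and
80-host/miRNA panels for the concordance correlations (10 replicates per
scenario). These sizes are the package's own choices and are documented
here so they can be scaled up freely.

# Known limitations

* The i.i.d. UTR background understates the clumpiness of real UTR
  sequence; passing null-calibration tests here does not guarantee
  calibration on real genomes.
* `deContrast` is a minimal plumbing DE method; it makes no attempt at
  dispersion shrinkage and should not replace a dedicated DE tool on
  real data.
* Intronic size-factor normalization assumes sparse perturbation of host
  genes (see above).
* The scenario classifier uses fixed thresholds (|lfc| ≥ 0.5,
  concordance fraction 0.5); borderline effects near the threshold are
  genuinely ambiguous and will be called `unchanged` or split between
  classes.
* No site-type taxonomy (8mer/7mer-m8/7mer-A1), conservation weighting,
  or context scoring is implemented; the seed scan is a pure positional
  word-count statistic.
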