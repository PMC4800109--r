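---
title: "Profiling colorectal cancers with inactive Wnt signaling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling colorectal cancers with inactive Wnt signaling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcprofiler)
```

# The scientific problem

Nearly all colorectal cancers activate beta-catenin/TCF regulated
transcription through APC or CTNNB1 mutations. The rare tumors that do not
— modelled in vitro by the RKO cell line, and identified in tissue by
membranous rather than nuclear beta-catenin staining — appear to follow a
distinct carcinogenic route in which structural chromosomal instability,
promoter hypermethylation and loss of heterozygosity (LOH) interact.
`crcprofiler` implements the computational layer of that profiling
workflow: cytogenetic instability indices from metaphase karyotypes and
CGH results, MS-MLPA methylation calling with cohort-derived thresholds,
Bethesda-panel MSI classification and LOH calling, differential expression
with centroid-linkage clustering, and the association statistics that tie
hypermethylation burden to beta-catenin status. A seeded synthetic-cohort
generator stands in for the patient material, which is not publicly
available, and carries known ground truth so every stage can be validated
by recovery tests.

# Karyotype model

`parse_iscn()` reads an ISCN-style karyotype string: a modal chromosome
count with an optional observed range (`47 (44~49)`; tilde, en-dash and
hyphen all accepted, since published karyotypes mix them), a sex
complement, and a comma-separated aberration list. The supported token
dialect is deliberately narrow — `del`, `dup`, `der` (with an optional
`t(...)` translocation), `iso`, `add`, and bare whole-chromosome `+N`/`-N`
— because that covers every printed form the package targets without
building a full ISCN grammar. Unrecognised tokens are preserved verbatim
with kind `other` and a warning; they are never dropped, so serialization
with `format_iscn()` round-trips the input. Whole-chromosome tokens get
their own kind `num` rather than being lumped into `other`, which keeps
"no `other` tokens on the supported corpus" a meaningful parser health
check and lets structural counting exclude numerical events cleanly.

Arm-level shorthand such as `del(5q)` keeps the arm letter in `band_spec`.
An empty band field would make `del(5p)` and `del(5q)` the same structural
identity in recurrence counting; retaining the arm preserves the
distinction at no cost to round-tripping.

## Centromere accounting

`centromere_counts()` starts from the baseline complement (two per
autosome; sex chromosomes as given by the metaphase's own sex complement,
so `45,X` against an `XX` baseline shows one X centromere). A
gain-prefixed structural aberration (`+der(8)t(8;8)`) adds one centromere
of the chromosome named by its outer argument — a derivative chromosome
carries exactly one centromere, of the `der()` chromosome, whether its
material is normal or rearranged. A non-prefixed structural aberration
replaces a normal homolog and leaves the count unchanged. Bare `+N`/`-N`
adjust whole chromosomes; a count falling below zero is an error.

`check_metaphase()` compares the declared chromosome count with the sum of
derived centromere counts. Published clone descriptions are sometimes
arithmetically inconsistent — a printed modal count that the listed gains
cannot produce from the baseline. Because the underlying per-metaphase
data are generally unpublished, the check *reports* the discrepancy and
never attempts to resolve it; all indices are computed from the derived
centromere counts, which are internally consistent.

# Instability indices

Three indices summarise a metaphase set, with a fourth from CGH:

* **Aneuploid index** (`aneuploid_index()`): for each centromere class the
  modal count across metaphases is the "consistent" state; the index is
  the sum of absolute deviations of these modal counts from the expected
  baseline. Ties in the mode are broken toward the expected count: a
  50/50 split between two and three copies is cell-to-cell variability,
  not a consistent trisomy. A consistent tetrasomy contributes 2
  (deviation-weighted); `cap_at_one = TRUE` switches to event counting.
* **Centromere-number variability** (`centromere_variability()`): per
  centromere class, the percentage of metaphases deviating from the modal
  count, averaged unweighted over the classes present in the baseline —
  24 for a male baseline, 23 for a female one, since an absent Y has no
  centromere class to vary.
* **Rearranged-chromosome count** (`rearranged_count()`): distinct
  structural identities (kind + primary chromosome + partners + band)
  present in at least `min_recurrence` metaphases (default 2), excluding
  numerical events.
* **CGH changes** (`parse_cgh()`): each comma-separated region within an
  `enh`/`dim`/`amp` group is one copy-number change, so `enh(20)` counts
  one change — the convention that reproduces published totals.

`classify_instability()` compares a report against shipped reference
ranges for classical MSI and MSS colorectal cancer cell lines
(`inst/extdata/reference_ranges.tsv`). The numeric axis (aneuploid index,
centromere variability) and the structural axis (rearranged count, CGH
changes) are classified separately: each index votes for the class whose
range contains it (inside both or neither is an "intermediate" vote), and
an axis takes a class only when its non-intermediate votes agree. A
distance-to-range table accompanies every call so borderline values can be
audited.

`expand_clone()` rebuilds a metaphase set from a published main clone plus
recurrent extra rearrangements. Extras are assigned to the lowest-index
metaphases first — a deterministic rule chosen for reproducible golden
tests; since every implemented statistic is invariant to *which*
metaphases carry an extra (only *how many* matters), the choice cannot
affect results.

Mutation frequency tables (`tabulate_mutation_frequency()`) report
whole-percent frequencies truncated toward zero, the convention of
whole-percent tabulation in clinical reports (17/33 prints 51).

# MS-MLPA methylation

The methylation dosage ratio is computed as the ratio of ratios

$$D_m = \frac{T_{dig}/R_{dig}}{T_{undig}/R_{undig}}$$

where $T$ is the target-probe peak and $R$ summarises the reference probes
of the same reaction. This is standard MS-MLPA practice; the reference
summary is the mean by default with a median switch (`ref_summary`),
since reference-probe robustness is the only genuinely open choice in the
formula. Zero undigested target or zero reference signal is an assay
failure and an error; $D_m$ slightly above 1 is kept but flagged.

Calling proceeds on two thresholds with distinct roles:

* the **technical detection threshold**, 0.15 for all loci
  (`call_methylated()`): below it MS-MLPA signal corresponds to bisulfite
  T/T (no methylation), above it to C/T or C/C. A value of exactly 0.15
  is called unmethylated — the bounding evidence covers only values
  strictly below and strictly above, so the boundary is assigned to the
  conservative side and documented.
* the **hypermethylation threshold**, per locus, equal to the mean plus
  one sample standard deviation (n − 1 denominator, as the normals are a
  sample) of normal-mucosa $D_m$ (`fit_thresholds()`). Hypermethylation
  requires only exceeding this normal-derived threshold; the technical
  threshold plays no additional role in the burden, because the
  hypermethylation cut-off already sits where it is needed relative to
  normal background.

The **burden** of a tumor (`hypermethylation_burden()`) is the number of
panel loci (7: CMTM3, DGKI, OPCML, KLK10, EPCAM, and two DLC1 promoter
probes) exceeding their thresholds; loci missing for a tumor reduce the
denominator and are reported rather than imputed.
`burden_vs_catenin()` compares mean burden between membranous and nuclear
beta-catenin tumors in the pooled sporadic series by one-way ANOVA (with
two groups, F is exactly the squared pooled t). For paired tumor–normal
comparisons the package gates on a Shapiro–Wilk test of the paired
differences at alpha 0.05 — the literature names both the paired t and the
Wilcoxon signed-rank test without a selection rule, so the package makes
the gate explicit and logs the decision per locus.

# MSI and LOH

`msi_classify()` applies the Bethesda rule: MSI-H if two or more of the
five markers are unstable, or if BAT25 or BAT26 is unstable alone.
`call_loh()` is non-informative for homozygous germline genotypes and
excludes tumors with novel alleles at the marker (instability confounds
allele ratios). Otherwise the allele ratio
$r = (T_1/T_2)/(N_1/N_2)$ (alleles ordered by size) calls LOH when
$r \le 0.5$ or $r \ge 2.0$ — at least a 50% relative loss of one allele's
signal, the common capillary-electrophoresis convention; the bounds are
configurable and boundary values count as LOH. `loh_frequency()` reports
LOH/informative fractions per marker, flags markers above 50%, and
compares beta-catenin groups by Fisher exact test. LOH analysis is
meaningful only in microsatellite-stable tumors; restricting input to MSS
cases is a cohort-level filter left to the caller, and the synthetic
cohort generates MSS-like data.

# Differential expression and clustering

`differential_expression()` runs an unpaired t-test per probe on log2
values — pooled-variance by default, since plain "unpaired t-test" in the
microarray-software tradition means the equal-variance test, with a Welch
switch — followed by Benjamini–Hochberg correction across all probes.
A probe is selected when its absolute linear fold change
($2^{\bar{x}_A - \bar{x}_B}$) reaches 2.0 and its adjusted p is below
0.05. Probes with zero variance in both classes are given p = 1 when the
means agree and the smallest representable double (flagged) when they do
not, avoiding silent division failure. `collapse_probes()` keeps the
probe with the largest absolute log2 fold change per gene symbol;
symbol-less probes stay as probe-level records and are counted separately.

`hcluster()` implements agglomerative clustering with euclidean distance
and *size-weighted centroid linkage*: inter-cluster distance is the
distance between centroids, and the merged centroid is the size-weighted
mean of the two (equivalently, the exact mean of all member samples).
Internally the Lance–Williams update on squared distances is used; the
test suite checks the merge sequence against a naive implementation that
recomputes explicit centroids at every step. Ties are broken toward the
pair containing the lowest original sample index, a deterministic
convention. Centroid linkage can produce height inversions; cuts are
therefore taken by merge order (`cut_clusters()`), which is well defined
regardless.

# Shared statistics

`fisher_exact()`, `anova_oneway()`, `independent_t()`, `paired_t()` and
`wilcoxon_signed_rank()` are thin validated surfaces over the classical
tests (two-tailed throughout, alpha 0.05). The two-tailed Fisher p is the
probability-mass convention: the sum over tables at fixed margins with
point probability not exceeding the observed table's. The signed-rank
test uses the exact null for up to 25 non-zero differences and the normal
approximation with continuity correction above. The test suite verifies
these against independent enumeration oracles: full-margin hypergeometric
enumeration for Fisher, and complete $2^n$ sign-flip enumeration for the
signed-rank test.

# The synthetic cohorts: what they emulate, and what they do not

The generators produce every input the pipeline consumes, at the scale of
the modelled study, with ground truth attached:

* `gen_metaphases()` — default 20 metaphases; clonal events in every
  metaphase, plus per-metaphase random whole-chromosome mis-segregation
  (probability per metaphase) and Poisson-distributed one-off deletions
  with unique band labels, so random structural noise is non-recurrent by
  construction.
* `gen_methylation_cohort()` — 110 normal mucosa samples and tumor groups
  of 27 Lynch, 33 sporadic-MSI and 40 sporadic-MSS cancers, a 50/50
  membranous/nuclear split, and planted mean burdens per group and
  beta-catenin class defaulting to the reported pattern (3.4/3.5/3.8
  membranous vs 3.1/2.7/2.9 nuclear). Normal $D_m$ is normal-distributed
  and truncated at 0 (dosage ratios are non-negative). Each tumor locus
  is hypermethylated with probability `burden_mean / 7`;
  planted-hypermethylated loci draw well above the true threshold
  $\mu + \sigma$, and background loci draw from the lower bulk of the
  normal distribution (below $\mu + 0.5\sigma$), so the planted
  exceedance probability is exact with respect to a fitted threshold and
  burden recovery can be asserted exactly. The implied burden is
  binomial, SD $\approx$ 1.3 at the planted means — close to, though
  slightly below, the ~1.5 typical of real cohorts; burden correlation
  between loci within a tumor (a CIMP-like phenotype) is *not* modelled.
* `gen_marker_cohort()` — 12 nuclear and 10 membranous beta-catenin MSS
  tumors over the Bethesda panel plus 31 dinucleotide markers with
  synthetic names (`D<chr>S9<nnn>`), heterozygosity 0.7, configurable
  per-group LOH probability, and a 5% instability rate producing
  excluded-unstable calls. Stutter, allele dropout and tissue
  heterogeneity are not modelled; LOH shifts one allele to ~30% signal,
  well past the 0.5 ratio bound.
* `gen_expression()` — 10,000 probes, baseline N(7, 1), within-class SD
  0.5, 200 planted probes shifted 2 log2 units (4-fold, half up and half
  down) in the target-line class; the clustering scenario adds normals
  with their own planted probe set so three groups are mutually
  separable. Probe-level correlation and intensity-dependent variance of
  real arrays are not modelled.

Passing recovery tests on these cohorts therefore demonstrates that the
*computations* are correct at realistic scale and effect sizes — not that
real tissue satisfies the generating assumptions (independence across
loci and probes, Gaussian noise, clean peak heights).

# Validation scale and numerical choices

The test suite validates, among others: all three instability indices
against naive brute-force tallies on 200 simulated metaphase populations;
threshold recovery within 1% of $\mu + \sigma$ averaged over 100
simulated cohorts of 110 normals; the membranous-vs-nuclear burden ANOVA
(planted 3.6 vs 2.8, n = 40 per group) rejecting in the majority of 500
replicates with type-I error near 0.05 under the matching null; DE
recovery of planted 4-fold probes at mean sensitivity at least 90% and
FDR at most 5% over 20 cohorts of 10,000 probes (6 vs 6 samples); Fisher
vs full enumeration on 500 random tables; signed-rank vs sign-flip
enumeration at n up to 10; and centroid merges vs naive recomputation on
up to 6 samples. These sizes keep the whole battery at a few minutes on a
single core while staying at the scale of the modelled study.

Numerical conventions worth knowing: modal-count ties break toward the
expected count, then the nearer, then the smaller candidate; squared
distances in the Lance–Williams update are clipped at zero before the
square root; the burden comparison uses strict `>` against thresholds on
both the technical and hypermethylation scales; and all generators draw
from R's RNG so a single `set.seed()` (or the `seed` argument / pipeline
seed) makes any run reproducible.

# Known limitations

* The ISCN dialect excludes ring/marker/double-minute chromosomes and
  band-level breakpoint arithmetic; such tokens survive as kind `other`
  and are excluded from structural identity counting.
* Published karyotypes can be internally inconsistent; the package
  reports the discrepancy (`check_metaphase()`) and computes indices from
  derived centromere counts, which may then not be comparable to values
  derived from unpublished raw metaphase data.
* The LOH ratio bounds (0.5/2.0) are a field convention, not a calibrated
  quantity; they are configurable per run.
* `hypermethylation_frequency()` tests pairwise groups without
  multiplicity correction across loci, matching the descriptive use of
  these comparisons; callers needing family-wise control should adjust
  the returned p-values.
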