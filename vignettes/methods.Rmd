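---
title: "Models and methods in DevoProteomics"
author: "DevoProteomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in DevoProteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DevoProteomics)
```

# Scope

DevoProteomics implements the quantitative core of a comparative
developmental multi-omics analysis for embryonic time courses sampled at a
handful of ordered stages (the default conventions follow an eight-stage
ascidian series from unfertilized egg to hatched larva, compared against a
vertebrate series):

1. **Absolute quantification** of a deep single-sample proteome from
   spike-in standards, plus a stoichiometry test for annotated protein
   complexes.
2. **Within-species profile analytics**: normalization, clustering,
   per-gene RNA--protein correlation, fold changes and stage-transition
   ranking.
3. **Orthology** by reciprocal best alignment hits.
4. **Cross-species stage correspondence**: stage-by-stage similarity of
   ortholog expression, best-match traces, divergence curves, and a
   permutation test that classifies the divergence profile as
   hourglass-shaped (mid-development most conserved), inverse-hourglass
   (mid-development most divergent), or flat.
5. **In-silico proteolysis** to quantify how sequence polymorphism between
   animal batches propagates to the peptide level.
6. A **synthetic-data generator** that produces inputs with the
   statistical structure these analyses assume, so the full pipeline runs
   and is testable without any external download.

Raw spectra processing, read alignment, reference-database assembly, GO
enrichment and PCA visualization are outside the package's scope; the
package consumes expression matrices, FASTA files, tabular alignment hits
and membership/annotation lists.

# Absolute quantification

## The standard curve

Spike-in standards of known, staggered amounts (a UPS2-style mixture)
share one log-linear relation between amount and MS1 signal:

$$\log_{10}(\text{signal}) = a \cdot \log_{10}(\text{amount}) + b.$$

`fitStandardCurve()` estimates $(a, b)$ with the **Theil--Sen estimator**:
the slope is the median of all pairwise slopes over standards with
distinct amounts, and the intercept the median of $y_i - a x_i$. The
median-of-slopes construction has a 29% breakdown point, which matters
because low-amount standards sit near the detection limit and can be
grossly mis-measured; a single standard corrupted by three orders of
magnitude moves the fitted slope by less than 10% (this is a tested
property). Standards reported with zero signal are treated as undetected
and excluded, with the exclusion count kept on the returned
`StandardCurve`.

## From signal to concentration

`estimateConcentrations()` inverts the curve per protein,
$c_{\mathrm{raw}} = 10^{(\log_{10} s - b)/a}$, optionally after summing
isoform signals per gene (a `max` collapse is available), then rescales
all concentrations by one global factor so their molar sum equals a
configured total --- default **2 mM**, a standard figure for total
cellular protein. Entities below the concentration cutoff (default
**0.01 µM**) are removed *after* scaling. Because the inverse transform is
monotone, concentration ranks always mirror signal ranks, and the molar
sum before the cutoff equals the configured total to relative $10^{-9}$
(tested).

Both the total and the cutoff are plain parameters rather than constants:
a 10 nM floor is close to, or above, the medians reported for regulatory
protein classes in deep embryo proteomes, so analyses that care about
scarce regulators (transcription factors, signaling molecules) will want
to lower it. The package deliberately does not hard-wire one "correct"
combination.

## Complex stoichiometry

`complexStoichiometryTest()` asks whether the subunits of an annotated
complex occupy a concentration stratum distinct from the bulk proteome.
For every complex with at least three detected subunits it runs a
one-factor analysis of variance on $\log_{10}$ concentrations across
groups (each qualifying complex, plus all remaining proteins as one
background group) followed by Tukey honest-significant-difference
comparisons of each complex against the background; the Tukey-adjusted
p-value is reported per complex. Proteins annotated to several complexes
stay with the first; qualification is judged after that resolution.

This is a *mean-based* test: it detects complexes whose subunit
concentrations sit away from the bulk average, which is the situation for
the abundant molecular machines (ribosome-, chaperonin-,
replication-machinery-class complexes) that dominate complex catalogs in
deep single-cell-type proteomes. It does **not** detect a complex whose
subunits are tight around the bulk mean --- low dispersion alone carries no
mean signal. A dispersion-sensitive test (e.g. an F-test per complex)
would, but the mean-based ANOVA/Tukey procedure is the field's convention
for this figure type and is what the package implements. The synthetic
complex generator consequently places complex means 1.5--3 orders of
magnitude above the background median (parameter `complexOffsetRange`),
emulating those machines; with the default within-complex spread of 0.1
log units against a background of 1.0 log units, the test flags essentially
all planted complexes at $p < 0.01$ while complexes assembled by randomly
sampling the background are flagged at well below the nominal rate (both
tested).

# Within-species dynamics

**Median normalization** (`medianNormalize()`) rescales each stage column
so its median equals the grand median (the median of column medians) ---
the standard first step for multiplexed proteome time courses where total
signal per channel is arbitrary. **Sum-to-one scaling** (`sumToOne()`)
then converts each protein's trajectory into a compositional profile so
that dynamics, not absolute levels, are compared across entities, datasets
and species. Sum-to-one scaling is idempotent and leaves missing stages
missing.

**K-means clustering** (`kmeansProfiles()`) groups complete profiles by
Euclidean distance, running Lloyd iterations from `nRestarts = 100` random
initializations (uniform sample of $k$ distinct entities each) and keeping
the run with the lowest total within-cluster sum of squares. An empty
cluster is re-seeded from the point farthest from its assigned centroid.
The whole procedure is deterministic given `seed`, and cluster labels are
relabelled by descending cluster size so output is stable. The default
$k = 8$ for within-species protein dynamics and $k = 5$ for cross-species
ortholog co-clustering (`coClusterOrthologs()`, which clusters the
concatenation of the two sum-to-one profiles of each ortholog pair) are
defaults, not constants; on data with well-separated temporal programs the
implementation reaches the same optimum as `stats::kmeans` (tested), but
it is written in-package because the restart and empty-cluster policy must
be reproducible bit-for-bit.

**RNA--protein correlation** (`rnaProteinCorrelation()`) computes one
Pearson $r$ per gene between its mRNA and protein trajectories over
shared, mutually non-missing stages (at least three), and summarizes the
distribution by its median. Profiles can be supplied raw, median
normalized, or sum-to-one; the demo uses sum-to-one profiles. One subtle
property of compositional profiles deserves note: two *independent*
peaked compositions are slightly anti-correlated (where one peaks, the
other is usually below its mean), so the null median $r$ on sum-to-one
profiles is slightly negative rather than exactly zero. On unconstrained
profiles the estimator is centred on zero (tested at $n = 2000$ pairs).

**Stage-transition ranking** (`stageTransitionRanking()`) orders entities
by $|\log_2((s_{t+1} + \varepsilon)/(s_t + \varepsilon))|$ per consecutive
stage pair, with $\varepsilon$ set to half the smallest positive value in
the matrix so zero-containing profiles remain rankable; ties break by
entity id. **`aggregateIsoformTpm()`** sums transcript TPM per gene
(conserving stage totals), and **`expressedFlags()`** applies the
inclusive TPM $\ge 2$ detection threshold, with missing values counted as
not expressed.

# Orthology

`bestHits()` reduces a 12-column tabular alignment file to one best
subject per query: hits above the e-value ceiling (default 0.01) are
discarded, then the lowest e-value wins, ties resolved by the highest bit
score, and any residual tie by first occurrence in file order (logged, so
order-dependence is visible). `reciprocalBestHits()` keeps a pair exactly
when each member is the other's best hit; the result is one-to-one by
construction and sorted by query id. This replicates single-best-target
alignment logically, so results do not depend on an aligner's internal
reporting quirks; users with real proteomes would produce the input with
a protein aligner configured for distant homology (BLOSUM45-class matrix,
permissive e-value, one target sequence) and feed the tabular output in.
`collapseToGeneLevel()` projects protein pairs through isoform-to-gene
maps and drops any gene pair that would break one-to-one-ness, logging the
count.

# Cross-species stage correspondence

`quantileNormalize()` implements the standard procedure (each column's
sorted values replaced by the cross-column mean of sorted values; tied
values receive the mean of the reference values their average rank spans)
and is cross-checked in the test suite against `limma`'s implementation.

`stageSimilarity()` computes, for every pair of stages $(s, t)$ of the two
species, the similarity between the vector of species-A ortholog values at
$s$ and the species-B partner values at $t$ over all mapped pairs
non-missing in both --- Pearson, Spearman (average ranks for ties) or
cosine, on sum-to-one profiles in linear space. Zero-variance stage
vectors make correlation entries undefined; these are recorded as missing
rather than invented. `bestMatchTrace()` takes the per-row argmax (ties
toward the earlier stage, logged), and `divergenceCurve()` reports
$1 - \max_t \mathrm{sim}(s, t)$ per species-A stage. For Pearson this can
exceed 1; it is deliberately not clamped, since clamping would hide
anti-correlated stage pairs.

## The hourglass statistic

Stages are partitioned into early / mid / late classes
(`stageClasses()`); by default the normalized stage index is split at
tertiles, which for an eight-stage series places stages 4--5 ---
gastrulation and neurulation in the ascidian convention --- in the mid
class. The shape statistic is

$$H = \bar d_{\text{mid}} - \tfrac{1}{2}\left(\bar d_{\text{early}} +
\bar d_{\text{late}}\right),$$

with $d$ the per-stage divergence. $H > 0$ means divergence peaks at
mid-development (inverse hourglass), $H < 0$ that mid-development is the
conserved waist (hourglass). Significance comes from permuting the
stage-class labels (`nPermutations = 1000`, two-sided, add-one
correction); curves with permutation $p \ge 0.05$ are called flat. The
statistic and its null are an *operationalization defined by this
package*: the pattern is usually judged visually in the literature, and no
community-standard test exists.

Two numerical caveats are worth knowing. First, with 8 stages and class
sizes 3/2/3 there are only $\binom{8}{2} = 28$ distinct mid-class
assignments (with equal-sized early/late classes the statistic depends
only on which stages are labelled mid), so the smallest achievable
two-sided p-value is about $1/28 \approx 0.036$ --- close below the 0.05
flat threshold. Shape calls on series this short are therefore inherently
binary: a clean mid-stage extreme is detectable, a graded one is not.
Second, because the test is two-sided, a shape is only called when the
observed mid-class is *uniquely* extreme; divergence profiles whose flanks
are as extreme as their middle (in either direction) are correctly left
as flat.

`sharedExpressionFraction()` complements the divergence curve at the
transcriptome level: per stage class, the fraction of orthologs expressed
(TPM $\ge 2$ at one or more stages of the class) in *both* species. Under
independent expression at marginal rate $p$ in each species the fraction
concentrates at $p^2$, which the test suite verifies analytically.

# In-silico proteolysis

`digestProtein()` applies protease rules positionally: trypsin cleaves
C-terminal to K or R except before P; LysC cleaves after K including
before P. With $m$ allowed missed cleavages every union of up to $m + 1$
consecutive fully-cleaved fragments is emitted; length filters apply last.
With $m = 0$ and no filters, concatenating a protein's peptides in order
reconstructs the protein --- an invariant the suite checks on 10,000
random sequences. `snpRobustnessReport()` restricts two sequence-database
batches to shared identifiers, digests both, and reports shared and unique
peptide fractions over the union of distinct peptide strings (set
semantics, since observed peptide lists are reported without
multiplicity). For a per-residue substitution rate $\rho$ and typical
peptide length $L$, a peptide survives unchanged with probability
$u = (1 - \rho)^L$, giving an expected union-based shared fraction near
$u / (2 - u)$; the suite checks the report against this closed form.

# The synthetic-data generator

The generator exists so that every downstream analysis has an input whose
ground truth is known. All generators take an integer `seed`, route their
randomness through one RNG stream, restore the caller's RNG state, and are
bit-reproducible.

* `simulateSpikeIn()` draws standards log-spaced over the dynamic range
  and sample proteins log-uniform over the same range (default 8 orders of
  magnitude, the depth of modern egg proteomes), then applies the signal
  law with log-normal noise (default 0.2 log units) --- measurement error
  in MS1 intensities is multiplicative, so a Normal model in log space is
  the natural choice.
* `simulateTwoSpeciesSeries()` gives each ortholog pair a shared latent
  temporal program drawn from a stationary Gaussian process over
  normalized stage time (squared-exponential covariance, length scale 0.2,
  amplitude 0.4 log units, i.e. few-fold relative dynamics). A stationary
  process is used deliberately: every stage then carries the same marginal
  variance, so no stage is artificially information-poor. Stage-dependent
  divergence is injected by replacing a fraction $w(t)$ of the species-B
  profile with an independent program, where $w$ follows a clamped
  quadratic window $q(t) = \max(0,\, 1 - 16(t - \tfrac12)^2)$ centred on
  mid-development for the inverse-hourglass shape, its complement
  $1 - q(t)$ for the hourglass shape, and a constant $\tfrac12$ for flat;
  `effectSize` scales the window and `effectSize = 0` makes all shapes
  indistinguishable from flat. The window is concentrated on the mid
  stages on purpose: the shape labels assert that *mid-development* is the
  extreme period, so the generator makes the mid stages --- not their
  flanks --- the extremes. A shared per-ortholog abundance baseline
  (1 log-unit spread) is added to both species; it cancels under
  sum-to-one scaling, as intended.
* `simulateSnpBatches()` plants independent single-residue substitutions
  at a configurable rate (default $10^{-3}$, the scale of protein-level
  polymorphism between wild animal batches in highly polymorphic marine
  invertebrates).
* `simulateHitTables()` plants each true ortholog pair as the best hit in
  both directions (e-values $\le 10^{-50}$) and adds decoys that are
  strictly worse ($\ge 10^{-40}$, lower bit scores), so reciprocal
  best-hit recovery of the planted map is guaranteed and decoy count only
  stresses the bookkeeping.
* `simulateComplexData()` draws background proteins log-normally around a
  22 nM-style bulk median and complex subunits tightly around
  complex-specific means offset 1.5--3 orders above the bulk (see the
  stoichiometry section for why the offsets are there).

What the generator does **not** emulate: peptide-level sampling noise and
shared-peptide inference, missing-not-at-random dropout of low-abundance
proteins, multiplexed-channel interference, compositional artifacts of
ratio-based quantification, batch effects between time courses, and
lineage-specific gene loss (the ortholog map is exactly one-to-one).
Passing tests on synthetic data therefore demonstrate the correctness and
statistical calibration of the *procedures*, not the biological
conclusions one would draw from real data.

# Numerical choices and degenerate inputs

* Theil--Sen: pairs with equal amounts contribute no slope; fewer than two
  usable standards or all-identical amounts are errors, not NaNs.
* Scaling: all-zero profiles are dropped (logged) rather than producing
  NaN compositions; all-zero stage columns make median normalization
  impossible and are an error naming the stage.
* K-means: incomplete profiles are excluded (logged); `k` larger than the
  number of complete entities is an error; ties in nearest-centroid
  assignment go to the lowest cluster index.
* Quantile normalization: tied column values receive the interpolated mean
  of the reference values their average rank spans; a single-column matrix
  is returned unchanged with a warning.
* Similarity: entries are missing (never fabricated) when a stage vector
  has zero variance or fewer than three complete pairs.
* Digestion: invalid residues are an error naming the first offending
  position; the residue alphabet is the 20 canonical amino acids plus X
  and U (selenoproteins occur in chordate proteomes).
* All dropped/excluded counts are emitted as messages so the pipeline log
  records them.

# The demonstration pipeline

`runPipeline()` executes the whole chain --- simulate, write inputs to
disk, re-read them through the package's validating readers, quantify,
test stoichiometry, normalize, cluster, resolve orthology, compute
similarity/trace/divergence, classify the shape, and run the digestion
report --- from a single YAML config with explicit seeds
(`inst/extdata/demo_config.yaml`). Config validation fails before any
computation on unknown keys or invalid values; a rerun with the same
config reproduces identical numeric outputs, and the run directory
contains the resolved config and a per-stage log. The demo sizes (500
sample proteins, 300 ortholog pairs, 8 stages per species, 100 k-means
restarts, 1000 permutations, 300 sequences) keep a full run well under a
minute on one CPU while leaving every statistical behaviour measurable;
the same sizes are used by `scripts/acceptance.R`, which recomputes the
package's headline quantities from scratch and writes them as JSON.

# Known limitations

* The hourglass test's resolution is bounded by the number of stages; with
  short series, only concentrated mid-development signals are callable.
* The stoichiometry test inherits the mean-based convention; it is blind
  to dispersion-only structure (discussed above).
* The quantile-normalization reference is the plain column-sorted mean;
  no variant handling for missing values beyond complete-case filtering.
* Orthology consumes precomputed alignment tables; it does not run an
  aligner, and many-to-many ortholog groups are out of scope.
* Absolute concentrations depend on the configured total (2 mM default)
  and cutoff; these interact (a high cutoff raises every reported median),
  so reported medians are only comparable under identical settings.
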