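---
title: "Paralog divergence, WGD dating and sex-chromosome regions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog divergence, WGD dating and sex-chromosome regions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupfate)
```

`dupfate` analyses the fate of duplicated genes in a plant genome: how old
the duplications are (synonymous divergence), whether the copies evolved
under purifying, neutral or positive selection, whether their expression
programs diverged, and — for a young sex chromosome — which parts of a
Y contig are male-specific, still pseudoautosomal, or repetitive.  This
vignette documents the models, the parameter choices, the numerical
details, and what the synthetic-data generators do and do not emulate.

## Codon divergence: NG86 with Jukes–Cantor correction

All divergence statistics operate on a *codon alignment*: gap-free codon
columns with per-sequence source coordinates.  Columns containing a gap,
an `N` (any ambiguity is normalized to `N` at load), or a stop codon in
any sequence are excluded at construction and tallied.  Protein-guided
alignments are back-translated codon by codon, with every codon checked
against its amino-acid row so a frameshifted or mislabeled CDS fails
loudly rather than silently shifting the frame.

Site counting follows the Nei–Gojobori convention: at each codon position
the synonymous site fraction is the fraction of the three
single-nucleotide neighbours encoding the same amino acid, with
stop-creating neighbours excluded from the denominator; the three
fractions sum with their complements to exactly 3 sites per codon.  Site
totals are averaged across the two sequences.  Differences are counted by
pathway averaging: codons differing at $k$ positions are connected by
$k!$ substitution orderings; each step is classified synonymous or
nonsynonymous, pathways passing through a stop codon are excluded, and
the per-class counts are averaged over the remaining pathways.  In the
degenerate case where *every* pathway crosses a stop, all pathways are
averaged — preferring a defined, slightly conservative count over an
undefined one for a handful of diverged codon pairs.

The raw proportions $p_S = s_d/S$ and $p_N = n_d/N$ are corrected for
multiple hits with Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$,
which is monotone on $[0, 3/4)$ and undefined beyond.  Estimates with
either proportion at or above 0.74 are flagged *saturated* and excluded
from downstream distributions by default; $\omega = d_N/d_S$ is defined
only when $d_S > 0$ and the estimate is unsaturated.  The whole machinery
is table-driven (61 sense codons, precomputed site and pathway tables)
and is checked in the test suite against an independent character-level
enumeration oracle to machine precision.

**Known limitation.**  NG86 weighting assumes no transition/transversion
bias.  When sequences evolve with $\kappa > 1$, synonymous changes (mostly
third-position transitions) are produced faster than the unweighted site
counts anticipate, so dS is mildly overestimated and $\omega$ mildly
underestimated — about 10% downward at $\kappa = 2$ for $\omega$ near 0.1.
The neutral-calibration test therefore runs at $\kappa = 1$, where the
estimator's assumptions hold exactly; the recovery checks at $\kappa = 2$
bound the residual bias instead of pretending it away.

## 4DTv

A column contributes a fourfold-degenerate site when both codons share
the same two first bases and that prefix encodes one amino acid whatever
the third base; the 4DTv rate is the fraction of those sites whose third
bases differ by a transversion.  The rate is reported uncorrected: the
statistic is used here as a relative, saturation-resistant clock for peak
detection, where a monotone correction would not move the mode.

## WGD detection and dating

The paralog-age distribution is a Gaussian kernel density (Silverman's
rule-of-thumb bandwidth) over the unsaturated pair dS values clipped to
$[0, 3]$, evaluated on a fixed grid of step 0.005.  The mode is the grid
argmax within a search range, default $[0.2, 2.0]$: the lower bound skips
the spike of very recent small-scale duplicates near 0, which otherwise
dominates the density.  A histogram cross-check (bin 0.05) gives the same
mode on the synthetic mixtures; the KDE is preferred because the mode
does not quantize to bin edges.  WGD-derived pairs are flagged inside a
*closed* dS window, default $[0.5, 0.9]$ — the endpoint convention is a
package choice, stated because counts at the boundary differ between
conventions.  Events are dated as $T = d_S/(2r)$ with
$r = 2.81\times10^{-9}$ synonymous substitutions per site per year:
pairwise divergence accumulates along both lineages, hence the factor 2,
which is exposed in `date_event(lineages = )` for users who prefer the
single-lineage convention.

## Selection screens

The sliding-window profile walks the *retained alignment columns* in
150 bp windows advanced by 30 bp from the start codon, stopping when the
window would pass the alignment end; alignments shorter than one window
yield a single flagged, truncated window.  Windows are in post-exclusion
alignment coordinates: dropped columns do not stretch windows, so a
window always contains exactly 50 codon columns.

Branch-specific profiles use a three-sequence alignment with a designated
outgroup and a parsimony rule per column: when the two ingroup codons
differ and exactly one of them equals the outgroup codon, the change is
assigned to the other ingroup's branch (pathway-averaged if multi-base);
columns where all three differ, or where the outgroup matches neither,
are skipped and tallied as ambiguous.  Branch dS/dN use the branch
sequence's own site counts over the assignable columns, so the two
branches are each measured against their own codon composition.

The neutrality screen is a two-sided exact binomial test of the
nonsynonymous difference count against $p_0 = N/(N+S)$, the neutral
expectation that each difference is nonsynonymous in proportion to the
nonsynonymous share of sites (two-sided by small-probability summation).
It is a *counts-based substitute* for a codon-model likelihood-ratio
test — cheap, assumption-light, and clearly labelled as such in output
tables; it has no site-level resolution and inherits the NG86 bias noted
above.  Its measured type-I error at $\alpha = 0.05$ on neutral
simulations at the package's standard scale (300 codons, dS 0.3,
$\kappa = 2$) is about 5%.

## Pair catalog

Genes flagged as transposable elements (an input annotation, not
recomputed) and "repetitive" genes with more than 5 distinct within-genome
homologs at the hit threshold ($e \le 10^{-20}$) are excluded, with a
per-gene reason report.  The homolog count uses distinct non-self
subjects, not HSPs, and the boundary is strictly greater than 5.
Families are single-linkage connected components of the filtered hit
graph — a deterministic, dependency-free stand-in for Markov clustering
that preserves the property actually used downstream (family
co-membership); family ids are ordered by each family's smallest member
so output is invariant to input row order.

## Expression divergence

Profiles are compared across the ordered sample series — by design 16
datapoints, 8 developmental stages × 2 sexes spanning an annual
flower-development cycle — with Pearson correlation; a pair is called
divergent when $r^2 < 0.3$.  The test is sign-blind on purpose: an
anticorrelated pair tracks the same program.  Pairs with a zero-variance
profile have no defined correlation and are excluded from reported
denominators.  Sex bias per development phase ("developing" vs "mature"
is a required sample annotation, not inferred) is a two-sided 2×2 Fisher
exact test on *pooled read counts* (rows paralogs, columns sexes) — an
exact test needs counts, not RPKM.  Fold bias compares the two paralogs'
$\log_{10}$((male + 1)/(female + 1)) pooled ratios against a 5-fold
cutoff.  Raw p-values at $\alpha = 0.01$ are reported without
multiple-testing correction, mirroring common practice for this screen;
users scanning many pairs should treat the flags as a ranking.  Note that
with deep pooled counts the Fisher screen detects any biological
male/female variability, not only planted shifts — a property of exact
tests at large n, documented rather than hidden.

## Y-region classification

Depth tracks (1-based samtools-depth-like input, zero-filled at
unreported positions — a stated package choice) are summarized in
non-overlapping 500 bp windows: mean male depth, mean female depth,
female read fraction $F/(M+F)$, and a repetitive flag when the mean of
the two depths exceeds twice the expected single-copy depth (default 20).
The 500 bp window balances resolution against Poisson noise: at depth 20
the window mean has a standard error of 0.2, so class boundaries are
sharp to one window.  Window classes: repetitive by the flag;
male-specific when the female fraction is below 0.05 (a concrete
threshold for "female coverage ≈ 0") with male depth at least half the
expected; PAR-like *candidate* when the female fraction exceeds 0.30;
undetermined otherwise.  Consecutive same-class windows merge, and PAR
candidates become PAR-like only when the merged run exceeds 3,000 bp
(strictly), otherwise reverting to undetermined.  The classification is
deterministic and idempotent, and the female fraction is scale-invariant
(the repetitive flag is not, since it references the expected depth).

X–Y divergence decay uses the same pairwise dS estimator on per-gene X/Y
alignments, gene-midpoint distance to the anchor coordinate, per-species
interspecific baselines computed identically, and a Spearman rank
correlation (average ranks on ties; undefined when either variable is
constant; reports under 4 genes are marked insufficient).  Genes whose
X–Y dS exceeds every interspecific baseline are flagged: recombination
arrest at that position predates the speciations the baselines represent.

## Synthetic data: what is emulated, and what is not

The simulators exist so every stage can be tested against known truth
without any external data.

**Codon pairs and triples.**  Sequences evolve on the 61 sense codons
under a symmetric mutation-selection process: single-nucleotide changes
at rate $\kappa$ (transitions) or 1 (transversions), multiplied by
$\omega$ when nonsynonymous, zero into stops.  This realizes any target
(dS, ω) pair and is far simpler to calibrate than a full
codon-frequency model; it does not emulate codon usage bias or indels
(alignments are generated gap-free).  Endpoints are sampled exactly from
the matrix exponential of the rate matrix (eigendecomposition of the
symmetric generator), not by discretized stepping.  The divergence time
is calibrated by bisection so the *expected NG86-estimated* dS over the
actual ancestral codon composition equals the target, to well within 1%;
targets at or beyond the estimator's saturation regime are rejected.
Calibrating on the estimated scale makes recovery checks meaningful:
dS recovery tests the estimator + simulator loop, while ω recovery
honestly exposes the NG86 κ-bias discussed above.  Per-codon-range ω
windows support the sliding-window and branch screens; triples radiate
from one ancestor with the outgroup branch calibrated separately.

**Pair sets.**  WGD pairs draw true dS from a lognormal burst (median
0.69, σ 0.08 — a tight paleopolyploidy peak) over an exponential
small-scale-duplication background (mean 0.15, matching the
recent-duplicate spike near 0); genes are 300 codons, ω 0.2, κ 2 by
default.  The emitted hit table is exact (one hit per true pair), so
catalog recovery is an identity check; it does not emulate spurious
similarity hits.

**Expression.**  Conserved pairs share one latent log-profile across the
16 samples (sd 1.3 on the natural-log scale — order-of-magnitude seasonal
swings) plus small independent noise (sd 0.15); divergent pairs draw
independent profiles.  Counts are negative binomial (dispersion 0.1)
around the profile means, base level ~300 counts.  This realizes a
conserved $r^2$ near 0.75–0.8 and an independent-profile $r^2$ near
1/15 ≈ 0.067, comfortably separated by the 0.3 rule; the planted
divergent count is exact, so recovery error comes only from
misclassification (about −1.5 percentage points net at n = 1311, from
the ~5% of independent heavy-tailed profiles that correlate spuriously
at 16 samples).  Planted sex bias multiplies one paralog's male means by
an odds factor.  Real data differ in library-size variation,
correlated pair structure and annotation noise, so passing tests bound
algorithmic behaviour, not real-data performance.

**Depth tracks.**  Per-position Poisson draws (or exact expectations in
the noiseless variant) at class-specific rates: male-specific (20, 0),
PAR-like (20, 20 at the default 0.5 female fraction), repetitive
(80, 80), background (20, 20).  Mapping artefacts, GC bias and gradual
repeat boundaries are not emulated; the noiseless variant must be
recovered exactly, the Poisson variant to ≥95% base accuracy.

## Problem sizes and reproducibility

Every generator is a pure function of its arguments including the seed,
and the pipeline fans one global seed out to fixed per-stage offsets so
partial reruns reproduce full runs.  The standard scales used by the test
suite and the acceptance script — 5,000 pairs of 300-codon genes for mode
recovery, 10 replicates of 10,000 codons for ω/dS recovery, 1,311 pairs
for the expression fraction, 1,000 replicates for the type-I bound —
were chosen so Monte-Carlo error is a small fraction of each check's
tolerance.
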