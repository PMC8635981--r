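---
title: "Methods: modelling the evolution of sex-biased gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the evolution of sex-biased gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgevol)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the package's tests demonstrate. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Study design and the fixture tree

The analyses assume the design the synthetic generator emulates: ten
dioecious species arranged in five sister-species pairs plus one
hermaphrodite outgroup, with six replicated leaf transcriptomes per sex and
species (five females in two species) and a single outgroup sample. Sister
pairs matter twice: delta-x needs a sister species for every focal species,
and cherries make the ancestral-state question non-trivial at shallow depth.

The fixture tree (`default_fixture_tree()`) is parametric because no
numerical branch lengths are available to copy: it is an ultrametric 11-tip
tree with tip depth 0.0265 and ingroup-crown tip depth 0.0185 (expected
substitutions per site), so the maximum ingroup patristic distance is 0.037
and every ingroup-to-outgroup distance is 0.053 — matching the divergence
summaries the design targets (up to ~3.7% at synonymous sites within the
genus, ~5.3% to the outgroup). Cherry depths are staggered between 0.003 and
0.005 so sister pairs are not artificially interchangeable.

## The synthetic-data generator

Per gene $g$: a root mean $r_g \sim \mathcal{N}(5, 2^2)$ (log2 expression
units) and a Brownian-motion rate $\sigma^2_g \sim
\mathrm{LogNormal}(\log 30, 1)$ (log2-expression variance per unit branch
length). Tip values are multivariate normal with covariance
$\sigma^2_g \cdot$ shared-path-length matrix; both sexes of a species start
as identical copies. These scales were chosen once so that sister species
differ by about 0.5 log2 units (SD) and ingroup-to-outgroup comparisons by
about 1.6 — substantial but not saturating interspecific divergence relative
to the root spread of 2.

Sex bias is injected additively into one sex's column of one species per
selected gene (default incidence 4% of genes, the ~650/16,194 ratio of the
emulated study; effect $|{\log_2 \mathrm{FC}}| = 1 + \mathrm{Exp}(1)$, so
every true effect is at least twofold). Three switches shape regimes the
analyses care about:

* `sbg_rate_quantile` recruits SBGs only from genes above a BM-rate
  quantile — the "fast genes become biased" world in which the
  ancestral-rate property is expected to hold;
* `p_shared` / `p_divergent` add a second biased species with the same or
  the opposite direction — exercising the turnover categories;
* `sbg_disp_factor` multiplies the NB dispersion of true SBGs — the world
  in which sex-biased shifts carry more within-species variance and are
  therefore depleted of high delta-x.

Counts are negative-binomial: sample $s$, gene $g$ has mean
$\mathrm{lib}_s \cdot \ell_g 2^{\mu_{gs}} / \sum_{g'} \ell_{g'}
2^{\mu_{g's}}$ with a single global dispersion $\phi = 0.05$ by default
($\phi = 0$ gives Poisson). A single global $\phi$ is the simplest model
consistent with the exact-test machinery; a per-gene vector can be supplied.
Library sizes are lognormal around $2 \times 10^6$ reads — small enough to
keep the default test matrix fast, large enough that the expression filter
and fold-change estimates behave as with realistic depth.

Codon alignments evolve only third positions of fourfold-degenerate codons
under Jukes–Cantor at the branch-length rate, with first/second positions
frozen; every simulated codon therefore stays synonymous and the raw
fourfold p-distance tracks the tree's patristic distances (up to JC
saturation, about 2% relative at these depths — visible as 3.6% rather than
3.7% at the deepest ingroup pair).

What the generator does *not* emulate: assembly and mapping artifacts,
orthogroup mis-assignment, isoform mixtures, contamination, GC or length
biases, and any correlation between sequence and expression evolution beyond
the shared tree. Passing tests therefore demonstrate internal correctness
and statistical calibration of the pipeline, not robustness to those
real-data pathologies.

## Normalization and SBG calling

Normalization follows the standard TMM/TPM pipeline (edgeR's
`calcNormFactors`): doubly-trimmed (30% log-ratio, 5% abundance) weighted
mean of gene-wise log ratios against an upper-quartile-chosen reference,
factors rescaled to geometric mean 1. Analysis matrices are
$\log_2(\mathrm{TMM\text{-}TPM} + 1)$: plain TPM (columns sum to $10^6$)
divided by the sample's TMM factor. Whether "TMM-normalized TPM" scales the
library size or the TPM itself is not derivable from the phrase; we divide
TPM by the factor (equivalent to an effective-library-size denominator) and
keep the choice in one function, `normalized_expression()`.

The expression filter is per species and deliberately uses raw library
sizes, reading the rule literally: CPM above `10 reads / min(library size)`
in at least 3 samples, so sex-limited genes (all-zero in one sex) pass.

Differential expression is edgeR's classic exact-test route — qCML common +
tag-wise dispersions (shrinkage prior 10 df) and the conditional exact test
on quantile-equalized pseudo-counts — because that is the method named for
the analysis; the package wraps it rather than re-deriving it, and the test
suite pins the contract with independent oracles: at $\phi = 0$ and equal
libraries the p-value equals the conditional binomial two-tail exactly
(e.g. group sums 0 vs 10 give $2/1024$), null p-values are uniform, and
power/FDR behave on generator truth. Fold-changes use edgeR's proportional
prior count (0.125), so sex-limited genes get large but finite log2FC and
can clear the twofold rule. Classification applies BH per species over the
expressed genes only; `male_biased` requires $q \le 0.05$ *and*
$\log_2\mathrm{FC} \ge 1$ (male minus female sign convention, used
consistently downstream).

## Ancestral states, gains, and turnover

The 3-state Mk model is equal-rates (the default of the reconstruction tool
named for this analysis), with a uniform root prior; the single rate $q$ is
optimized on $\log q \in [\log 10^{-8}, \log 10^{3}]$ (bound hits are
flagged). Marginal node probabilities come from the standard inside–outside
two pass, equivalent to re-rooting at each node — true marginals, not the
scaled conditionals some implementations report; the brute-force enumeration
oracle in the tests pins both the likelihood and the marginals. The ML state
is the argmax, with exact ties resolved to "unbiased". A species in which
the gene is not expressed contributes an ambiguous tip (all three partial
likelihoods 1), not a forced "unbiased" — a flag switches to the stricter
interpretation.

Gains are branches whose parent ML state is unbiased and whose child state
is biased; losses the reverse. History categories: biased in one species →
uniquely biased at the tip; same direction in ≥ 2 species with exactly one
ancestral gain and no tip gains → shared, single ancestral gain; same
direction with ≥ 2 independent gains → shared, repeated; opposite directions
anywhere → divergent.

The overlap permutation redraws each species' male- and female-biased
labels within that species' expressed genes (not the global gene universe —
bias is undefined where a gene is not expressed; a global mode would only
dilute the null), keeping counts intact. Genes whose classified history is a
single ancestral gain are excluded from the comparison — the exclusion count
is data-driven rather than fixed. The ancestral-vs-tip distinction cannot be
recomputed inside the null (a permuted label set has no reconstruction), so
the null collapses categories to unique/shared/divergent. p-values use the
+1 correction, reporting the achievable Monte-Carlo floor honestly; the
upper tail is tested for shared and divergent counts and the lower tail for
unique counts (which are depleted exactly when sharing is enriched), with
the tail used reported alongside.

## Rates of expression evolution

The per-gene rate measure is the mean absolute standardized PIC of
species-mean log2 expression (sexes averaged), computed after pruning the
gene's sex-biased species from the tree (degree-2 nodes removed by summing
branch lengths; genes left with fewer than 3 tips are reported NA with a
reason). Under Brownian motion standardized contrasts are
$\mathcal{N}(0, \sigma^2)$, so the measure estimates
$\sigma\sqrt{2/\pi}$ — the closed form the tests check to 2%. Group
differences are tested by a label-permutation mean test (sign flips when
paired), written directly since the published permutation-test package is
a trivial primitive.

Expression distances are $1 - r$ over genes, per species pair, excluding
from each pair the genes biased in either member (a stricter
drop-everywhere mode exists). Unbiased-gene distances use the mean of the
sexes; SBG distances are computed separately from male and from female
columns; the outgroup contributes its single hermaphrodite profile to all
modes. Distances are regressed on fourfold-degenerate sequence divergence
over all $\binom{11}{2} = 55$ pairs, with the Mantel test (joint
row/column permutation) for significance.

The noise-matched null asks whether the SBG slope merely reflects noisy
genes: each SBG is replaced by an unbiased gene whose mean within-group
(species × sex) coefficient of variation of counts lies within 95%–105% of
the SBG's (multiplicative bounds on the CV itself; the alternative reading —
bounds on a CV ratio — is equivalent here). If an SBG has no match the
window widens in 5% steps and the widening count is reported. Within a
replicate, matches are drawn without replacement while possible, falling
back to reuse only when a replicate exhausts a match set. The CV is computed
on raw counts within species × sex, so it captures replicate noise rather
than interspecific signal — which is exactly why the null separates the
fast-evolution hypothesis from the noise artifact.

Clustering of species × sex mean profiles uses complete linkage on
$1 - r$ (the default of the usual heatmap tooling; no linkage is otherwise
specified), and the "groups by species, not by sex" statement is made
computable: every species' two sexes must be cophenetically closer to each
other than to any other row.

## Delta-x and adaptive shifts

For each gene, focal species, and sex: divergence is the absolute difference
between focal and sister mean log2 expression; polymorphism is the sample SD
(denominator $n-1$) over the focal replicates of that sex;
$\Delta x$ = divergence/SD, with SD = 0 mapping to $\infty$ (classified
high) when divergence is positive and to 0 otherwise. Shifts require a
1.5-fold difference of means interpreted on the log2 scale
($|\Delta| \ge \log_2 1.5$), the scale on which delta-x itself is defined;
a linear-scale option exists. Both boundaries are inclusive (`>= 1.5`-fold,
`>= 5.0`), the threshold note in the shift-count table taking precedence
over the looser prose ("greater than"); a flag restores strict inequality.
"Sex-biased" for a shift means the gene is biased in the focal species in
either direction (a direction-matched mode is provided), and every species
is focal once per pair — both choices are needed so each record uses its own
within-species SD. The 2×2 tables (high/low delta-x × biased/unbiased, per
sex, shifts only) are tested with Yates-corrected chi-squared
(`min(0.5, |O - E|)` capping, i.e. base R's `chisq.test(correct = TRUE)`,
cross-checked in the tests against the raw formula).

## Numerical choices and degenerate inputs

* BM simulation adds a $10^{-12}$ ridge before the Cholesky factor
  (ultrametric trees give exactly singular corner cases).
* Mk partial likelihoods are rescaled per node when they underflow; with
  11 tips this never triggers but keeps the code safe for larger trees.
* All permutation p-values use the $(k+1)/(n+1)$ correction and never
  report 0.
* All-zero genes in the exact test get $p = 1$, $\log_2\mathrm{FC} = 0$;
  all-zero samples are an error naming the sample; a constant distance
  matrix is an error (undefined correlation).
* Fourfold-site masking is pairwise-strict: the two sequences must agree on
  an unambiguous fourfold prefix, so a non-synonymous change at positions
  1–2 removes the codon for that pair rather than contaminating the
  synonymous distance.

## Problem sizes used by the tests

The suite and the acceptance script run scaled-down studies chosen as the
smallest sizes at which each statistical property is sharp: 1,200–2,000
genes for pipeline-level properties (the full 16,194 is supported), 20,000
genes for the folded-normal PIC closed form, 50,000 genes for BM-covariance
recovery on a 4-tip tree, 1,000 noise-matched replicates, and 10,000
permutations where a $10^{-4}$ p-value floor is needed. The acceptance
script completes in well under a minute on one CPU.

## Known limitations

* Exact numerical parity with any specific external DE tool's defaults is
  promised only where the tests pin it (the $\phi = 0$ closed form and
  calibration); other tools' prior counts or trended dispersions will differ
  in the third decimal of fold-changes.
* PGLS assumes pure Brownian residual covariance (no λ or other
  transformations), matching the bare method named for the
  dimorphism-vs-SBGE regressions.
* The delta-x statistic is a heuristic indicator of directional selection,
  not a model fit; no Ornstein–Uhlenbeck machinery is implied.
* dN/dS values for the paired omega comparison are external inputs to the
  permutation test; no codon-model estimation is performed here.
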