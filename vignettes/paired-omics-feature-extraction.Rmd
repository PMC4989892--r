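---
title: "Paired expression–methylation feature extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired expression–methylation feature extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcafe)
```

## The analysis problem

The package targets panels in which the same cell lines are profiled on
two array platforms — mRNA expression and promoter methylation — across
several unordered categories (parental tumour lines, reprogrammed
derivatives, re-differentiated derivatives, controls) with a few
replicates each.  Two features of such designs drive the method:

1. there is no natural ordering or contrast among the categories, so
   supervised ranking along a chosen comparison is arbitrary; and
2. the biologically interesting coordinated signal (probes whose
   expression and promoter methylation change together during
   reprogramming) is typically *not* the leading variance component of
   either platform, which is dominated by platform- and batch-private
   structure.

The answer implemented here is unsupervised on both counts: principal
components are computed per modality, the informative component *pair*
is identified by the coincidence of sample loadings across modalities,
and probes are then selected as outliers along the paired components.

## Model and procedure

### Feature-embedding PCA

For a probes × samples matrix $x_{ij}$, each sample column is centered
by its mean over probes and the probe scores on component $k$ are

$$x_{ik} = \sum_j c_{jk}\,\bigl(x_{ij} - \langle x_{i'j}\rangle_{i'}\bigr),$$

where the loadings $c_{jk}$ are the orthonormal sample-space axes of the
centered matrix, ordered by decreasing variance.  This embeds *features*
rather than samples: with tens of thousands of probes and two dozen
samples, the sample space is the small one, and probe scores inherit an
interpretable axis per component.  Computation uses the singular value
decomposition of the centered $I \times J$ matrix (never an $I \times I$
covariance), which is exact and fast at these shapes.

Deliberately, **only per-sample centering** is performed: no per-probe
centering, no variance scaling, no log transform.  Raw array units are
analysed as distributed, and probe scores therefore retain intensity
information — a probe with large raw dynamic range can be a large-score
outlier, which is the intended notion of "outlier" here.

### Identifying the coincident component pair

Loadings of the first $K$ components per modality (default $K = 5$) are
standardized over samples,

$$\Delta c_{jk} = \frac{c_{jk} - \langle c_{jk}\rangle_j}
  {\bigl\langle (c_{jk} - \langle c_{jk}\rangle_j)^2 \bigr\rangle_j^{1/2}},$$

and all correlations $\rho_{kk'} = \langle \Delta c_{jk}\,\Delta
c_{jk'}\rangle_j$ over the joint $2K$ label set (methylation labels are
tagged `M`) feed a UPGMA clustering with distance $-|\rho_{kk'}|$.  The
absolute value matters: promoter methylation is often *anti*-correlated
with expression, and the sign of any PCA axis is arbitrary anyway, so
coincidence is judged on magnitude while the signed $\rho$ is reported.
Sibling leaf pairs with one member per modality, ordered by merge
distance, are the candidate coincident pairs.  "Clustered together" is
operationalized as *sibling leaves*; a mutual-nearest-neighbour variant
(`method = "mutual_nn"`) is available as a sensitivity check and agrees
on clear-cut pairings.

Note that a tree over $2K$ leaves always contains several sibling pairs,
so incidental cross-modality siblings among the uninformative components
are expected; what identifies the informative pair is its position at
the *smallest* merge distance (largest $|\rho|$), and the pipeline
orders candidates accordingly.

### Directional outlier selection

For a chosen pair, the top $N$ probes by score are taken along each
component in both directions (largest and smallest $x_{ik}$), and the
union over the four direction combinations of cross-modality
intersections is selected.  This union is identical to the intersection
of the two modality-wise larger∪smaller unions — an identity the test
suite verifies on random instances — so the selection does not depend on
the sign convention, while per-direction subsets (which do) are also
reported.  $N$ defaults to 300, the study-scale convention for
`I` in the tens of thousands; for synthetic data with `n_planted`
planted probes, `N = 2 * n_planted` is the natural scale.

### Categorical-regression feature extraction

Independently of PCA, each probe is fitted with
$x_{ij} = a_{i0} + \sum_l a_{il}\,\delta_{jl}$ over the $L$ cell-line
categories.  The reported P-value is the overall model F-test
(between-category over within-category mean square on $L-1$ and $J-L$
degrees of freedom) — identical to a one-way ANOVA, and identical to the
summary F of a linear model on a single factor.  The computation is
vectorized over probes and cross-checked against per-probe `lm()` fits
in the tests.  Selection takes the $N$ smallest P-values per modality
and intersects the modalities; because selection is by rank,
multiple-testing adjustment would be order-preserving and is not
applied.

### Stability and reporting

Leave-one-out stability drops each sample in turn from both modalities,
recomputes both decompositions, and relabels each reduced-sample
component with the full-sample label whose loadings (restricted to the
shared $J-1$ samples, both standardized) correlate most in absolute
value — a greedy assignment, strongest correlation first, each label
used once, hence a bijection.  The UPGMA tree is rebuilt under the new
labels and a subset counts as conserved when the tracked pair(s) are
again cross-modality siblings.  By default *all* tracked pairs must be
conserved (`require_all = TRUE`); requiring any single pair is available
because either convention is defensible when two pairs are tracked.

The gene report unions the methods' gene sets (methods are tracked
per component, e.g. `pca_fe_pc3`, `pca_fe_pc4`, `catreg`, since
selection is per component) and attaches a per-gene expression–
methylation Pearson correlation with the exact two-sided t-based P-value
($t = r\sqrt{J-2}/\sqrt{1-r^2}$, $J-2$ df) and a flag for $r < 0$,
$P < 0.05$ (raw P).  For genes with several probes the most significant
expression–methylation probe pair is reported (`reduce = "best_probe"`);
averaging probes first (`reduce = "mean"`) is provided because neither
reduction is canonical, and the choice is recorded in the output.

Two-group comparisons (`compare_groups()`) default to the Welch t-test;
the pooled-variance flavor is provided since published panel comparisons
frequently leave the variance assumption unstated, and the two coincide
exactly for balanced groups with equal sample variances.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `K` | 5 | components per modality entering the pairing; matches tracking the first five components in the stability analysis — enough to reach past the leading nuisance structure, few enough that the $2K$-leaf tree stays readable |
| `top_n` | 300 | probes per direction (PCA) and per modality (regression); study-scale convention, configurable |
| `n_pairs` | 2 | coincident pairs carried into selection; outputs are labelled per component rather than merged |
| `flavor` | `welch` | two-group test variance assumption |
| `reduce` | `best_probe` | probe→gene reduction for correlations |
| `require_all` | `TRUE` | leave-one-out conservation needs every tracked pair |

## The synthetic generator

`generate_paired_omics()` draws, per modality,
$$x^{(m)}_{ij} = \mu^{(m)}_{i,c(j)} + \textstyle\sum_f w^{(m)}_{if}
s^{(m)}_{fj} + w^{(m)}_{i,\mathrm{sh}}\, s_{\mathrm{sh},j} +
\varepsilon^{(m)}_{ij}$$
with Gaussian factor scores and noise.  The shared factor's sample
scores $s_{\mathrm{sh},j}$ are common to both modalities; nuisance
factor scores are modality-private.  Defaults (8 categories × 3
replicates, $I = 5000$ probes, nuisance score variances 9 and 4, shared
factor variance 1, 50 planted probes with loading magnitude 4 and a
50/50 cross-modality sign mix, unit noise, category offsets with sd 0.5)
are chosen so the shared factor sits near the third component of each
modality — below the two nuisance factors and above the category and
noise floor — mirroring the situation the method is designed for, where
the coincident pair is not the leading one.  Sign-mixed planted loadings
exercise all four directional combinations.

What the generator does *not* emulate: intensity-dependent array noise,
beta-value distributions bounded in [0, 1], probe GC effects,
missingness patterns, or differing probe universes between platforms.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the stated factor model, not robustness to array-
specific artefacts.

## Numerical choices and conventions

* **Sign convention.** Each loading column is flipped so its
  largest-magnitude element is positive.  Directional top-$N$ sets
  depend on this; the union across directions does not.
* **Standardization divisor.** $\Delta c$ uses the population (divisor
  $J$) standard deviation.  Correlations are invariant to the divisor,
  so this is cosmetic and is covered by a test.
* **Tie-breaks.** Probe rankings break score ties by probe identifier;
  UPGMA breaks equal-distance merges by the lexicographically smallest
  pair of cluster representatives.  Both make results deterministic.
* **Degenerate inputs.** A fully constant probe gets $P = 1$ (no
  signal); a probe with zero within-category but nonzero
  between-category variance gets $P = 0$ with a `perfect_separation`
  flag and a warning; a constant matrix or constant loading column is a
  hard error; both-constant two-group comparisons get $P = 1$ (equal
  means) or $P = 0$ (unequal), flagged.
* **Missing values.** Probes with any missing value are dropped at
  construction, with a reported count; the decompositions assume
  complete rows.
* **Round trips.** The writers emit 17 significant digits so that
  re-reading reproduces doubles bit-exactly.
* **F vs permutation P-values.** The tests compare the model F P-values
  with permutation nulls.  The permutation distribution *conditional on
  one dataset* deviates from the exact F distribution by $O(1/\sqrt{J})$
  (about 0.01 at $J = 24$), so per-dataset agreement is asserted at that
  order, while calibration (uniformity of P under the global null) is
  asserted tightly at 10,000 probes.

## Problem sizes in the test suite

Simulation-backed tests run at $I$ between 800 and 2000 probes (20 seeds
for pairing recovery, 10 for leave-one-out stability), with the
study-scale configuration ($I = 5000$, 20 seeds; null calibration at
$I = 10{,}000$) exercised in the end-to-end validation tests and the
acceptance script.  These sizes were chosen so the full suite completes
in well under a minute while keeping the planted-recovery operating
point (score separation of planted vs background probes) identical to
the default configuration.

## Known limitations

* Selection happens at probe level and probe universes may differ
  between platforms; cross-modality intersection of *probes* (PCA and
  regression FE) therefore requires a shared universe, as in the
  synthetic data.  With differing universes, intersect at gene level
  after `map_probes_to_genes()`.
* UPGMA with $-|\rho|$ distances is the only linkage offered; no
  bootstrap confidence on the tree is computed.
* The categorical model fits category means only — no covariates,
  nesting, or specific contrasts.
* `P = 0` for perfect separation is a reporting convention, not a
  statement that the null is impossible.
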