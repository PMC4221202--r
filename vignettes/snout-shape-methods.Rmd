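---
title: "Methods: outline shape, discrimination and phylogenetic signal in snoutmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline shape, discrimination and phylogenetic signal in snoutmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoutmorph)
```

# The analysis in outline

snoutmorph studies pure shape variation in two-dimensional outlines — the
motivating case is the ventral profile of the ruminant premaxilla — and
asks whether two a-priori ecological groups (browsers and grazers)
occupy distinguishable regions of shape space, how reliably specimens
can be assigned to a group from shape alone, and how much of the shape
structure is attributable to phylogeny or body size rather than ecology.

The pipeline is: equal arc-length semilandmarks → generalized Procrustes
superimposition → covariance PCA (or phylogenetic PCA) → two-group
canonical variates analysis with a randomized log-likelihood-ratio test →
classification and unknown projection → axis shape models → phylogenetic
signal statistics.

# Semilandmarks

`resample_outline()` places `p` points at equal arc-length intervals
along the digitised polyline, interpolating linearly between vertices.
Outlines are treated as **open** curves by default: the profile starts at
a fixed homologous landmark (for snouts, where the maxilla–premaxilla
suture meets the left lateral margin), sweeps the ventral profile, and
ends at the contralateral counterpart; both endpoints are retained at
arc positions $kL/(p-1)$. A closed-contour mode ($kL/p$) exists for
fully circumscribing outlines. The default `p = 100` (hence 200 shape
variables) is a digitising resolution at which the piecewise-linear
representation of a smooth profile is faithful; resampling an already
uniformly spaced `p`-point outline is an exact no-op, so the reader
accepts either raw digitised outlines or pre-resampled ones.

Two deliberate restrictions: **no semilandmark sliding** (sliding
optimises points against the very consensus being estimated and is a
known source of artefactual covariance in outline data), and **linear
rather than spline interpolation** (at `p = 100` the difference is below
digitising noise, and the linear rule is deterministic and checkable
against a brute-force arc-length table, which the test suite does).

# Procrustes superimposition

`gpa()` implements classical generalized least-squares superimposition
into shape space: each configuration is centred, scaled **once** to unit
centroid size, rotated to an initial reference (the first specimen), and
then the consensus is iterated — mean, re-centre, rescale to unit size,
rotate every specimen to the mean — until the *partial Procrustes
distance* between successive consensus shapes falls below `tolerance`
(default $10^{-4}$).

Numerical choices:

* **Proper rotations only.** The 2-D orthogonal Procrustes problem is
  solved by SVD with the determinant constrained to +1. Specimens are
  all digitised in the same view; allowing reflections would fabricate
  left/right inversions.
* **Convergence metric.** "Distance between successive means" is
  measured as the partial Procrustes distance between consecutive
  consensus shapes, consistent with the distance used everywhere else.
  The tolerance could alternatively be read as a summed coordinate
  displacement; at these magnitudes the two differ only in scaling and
  both stop the iteration at visually identical consensi.
* **No tangent projection.** PCA acts on the superimposed coordinates
  directly. At the shape ranges involved (all specimens within a small
  neighbourhood of the consensus after alignment) the curvature of shape
  space is negligible relative to digitising noise; the full-rank score
  round-trip test (reconstruction to $10^{-8}$) would detect any
  inconsistency introduced here.
* **Degenerate inputs** — coincident points (zero centroid size),
  mismatched landmark counts, rank-0 configurations — raise immediate
  errors rather than propagating NaNs.

# Ordination

`pca_fit()` eigendecomposes the sample covariance (divisor $n-1$) of the
flattened aligned coordinates via SVD of the centred data matrix.
Retaining all axes preserves pairwise Euclidean distances exactly, which
is what makes the downstream CVA a rotation of the Procrustes geometry
rather than a new metric. Eigenvector sign is fixed by making the
largest-magnitude loading positive, so ordinations are reproducible
across linear-algebra backends.

By default the ordination is fitted on the **known** (browser + grazer)
specimens only, with unknowns projected afterwards; superimposition, by
contrast, includes all specimens jointly. This mirrors the logic of the
study design: the shape space is defined by the specimens whose ecology
is trusted, while every specimen should share one common alignment.

`phylo_pca_fit()` substitutes the evolutionary covariance
$E = (X-1\hat a')' C^{-1} (X-1\hat a')/(n-1)$, with $C$ the
Brownian-motion shared-path-length matrix and $\hat a$ the GLS root
state. Plain Brownian motion (no λ optimisation) is used for $C$ — the
simplest phylogenetically controlled counterpart, and the one whose
star-tree special case provably collapses to ordinary PCA (a test
asserts this). Singular $C$ (duplicate zero-length tips) is reported
with advice rather than silently regularised.

Three PC axes are retained for discrimination by default
(configurable): in both the motivating study design and the synthetic
generator the leading three axes carry the overwhelming majority of
shape variance, and keeping $k$ small relative to $n$ is exactly what
the randomization tests below are designed to validate.

# Canonical variates analysis and the φ statistic

With $W$ and $B$ the pooled within- and between-group SSCP matrices of
the retained scores, the single discriminant axis for two groups is the
leading eigenvector of $W^{-1}B$ — computed in closed form as
$W^{-1}(\bar x_1 - \bar x_2)$, to which it is proportional — scaled so
the pooled within-group variance of the projected scores is 1.
Distances along the axis are then Mahalanobis distances, and
nearest-centroid classification needs no further weighting. No prior
probabilities enter the assignment; ties (exactly equidistant points) go
to the alphabetically first group and are flagged.

Group distinctiveness is summarised by Wilks'
$\Lambda = \det W / \det(W+B)$ and the log-likelihood-ratio index

$$\varphi = -\left(n - 1 - \tfrac{k+g}{2}\right) \ln \Lambda,$$

Bartlett's chi-squared-calibrated form with $g = 2$, referred to
$\chi^2_k$. The unscaled variant $-n \ln\Lambda$ is available
(`phi_form = "unscaled"`) because the literature on this index is not
unanimous about the multiplier; the Bartlett form is the default since
it is the one with a known null calibration, which the test suite
verifies empirically (the χ² decision and the Monte Carlo decision agree
on ≥ 90 % of datasets spanning the critical region).

Two randomization nulls guard against the hyper-dimensionality critique
of CVA on landmark data (many variables, modest $n$):

* **Monte Carlo**: every score column is redrawn iid normal with the
  pooled (group-blind) mean and variance of that column; group sizes are
  retained as labels.
* **Bootstrap**: rows are resampled with replacement from the pooled
  observed scores and the first $n_1$ are labelled group 1 — a random
  agglomeration with the observed sample sizes that destroys the group
  structure by construction (a permutation variant is available via
  `permute = TRUE`; resampling with replacement is the default reading
  of "bootstrapping").

Both use $R = 1000$ replicates by default and report
$p = \#\{\varphi_r \ge \varphi_{obs}\}/R$ alongside the conservative
$(\#+1)/(R+1)$. The type-I behaviour of the Monte Carlo test is checked
in the acceptance suite by 500 outer null trials at $n = 60$, $k = 3$
with 199 inner replicates per trial — at $R = 199$ the rejection rule
$p < 0.05$ is exact (it fires iff at most 9 replicates reach the
observed φ), so the outer rejection rate estimates the true size
without granularity bias, at a fifth of the cost of $R = 1000$.

The jackknife refits the CVA $n$ times with one specimen held out; the
confusion matrix object reports the exact fraction (not only the
percentage), because leave-one-out percentages with near-identical
denominators are otherwise easy to misread.

# Shape models

`model_pc_axis()` and `model_cv_axis()` back-project five positions per
axis — the observed score extremes, zero, and the two medial
interpolants — into landmark space. Extremes come from the observed
score range rather than ±k·SD: the models are meant to illustrate the
data's own span, not a parametric envelope. A CV position $c$ maps to
the PC-space point $\bar s + c\,v/(v'v)$ (the right inverse of the
discriminant projection, so re-projecting a model recovers its position
exactly), then through the eigenvectors to coordinates. Strobe plots
are written as SVG by a small deterministic writer — one polyline per
model, colour-graded along the axis — so golden-file tests are
byte-stable and the structure is assertable with an XML parser.

# Phylogenetic signal

`blomberg_k()` implements the ratio statistic
$K = \frac{MSE_0/MSE}{(\mathrm{tr}\,C - n/(1'C^{-1}1))/(n-1)}$ with the
GLS mean; $K = 1$ exactly on a star tree, and $E(K) = 1$ under Brownian
motion on the true tree (both are tested, the latter by simulation).
The permutation p-value uses **K itself** as the statistic over tip
permutations (999 by default, seeded). Some established
implementations permute a contrast-variance statistic instead; the two
orderings differ slightly, and K-as-statistic is the more direct
reading of "significance of K". Point estimates are cross-checked
against `picante::Kcalc` and `phytools::phylosig` in the tests.

`pagel_lambda()` profiles the multivariate-normal likelihood over
$\lambda \in [0,1]$ (off-diagonal elements of $C$ scaled by λ, GLS mean,
ML-profiled rate), with the interval ends checked explicitly since the
optimiser never evaluates them. λ > 1 is not explored: it can break
positive-definiteness and is rarely interpretable. The reported p-value
is a likelihood-ratio test against λ = 0 — the hypothesis "no
phylogenetic structure", which is the relevant null when asking whether
a phylogenetically controlled reanalysis is needed; testing against
λ = 1 is available via `against = 1`.

`independent_contrasts()` is a direct implementation of Felsenstein's
pruning recursion (contrast $(x_a-x_b)/\sqrt{v_a+v_b}$,
precision-weighted node value, branch lengthening $v_av_b/(v_a+v_b)$),
validated against a hand-computed table and `ape::pic`. Contrast signs
are arbitrary, so `contrast_correlation()` positivises the x contrasts
(flipping y in tandem) before Spearman or Kendall rank correlation.

Body mass enters as $\log_{10}$ grams, transformed **before** any
analysis; `mass_residuals()` regresses the shape score on log mass (not
mass on score) — residualising the shape variable is the direction that
keeps "phylogenetic signal in the scores" meaningful downstream.

# The synthetic study generator

`generate_study()` emulates the structure of a two-guild outline study,
not ruminant anatomy: two analytic end-member templates (a wide, short,
distally concave "blunt" form and a narrow, elongate, distally convex
"pointed" form with mid-margin compression) are blended by a parameter
$s \in [0,1]$; specimens draw $s$ from their guild's truncated normal
(defaults: browser mean 0.8, grazer mean 0.2, sd 0.1 — overlapping
tails, matching the observation that real guilds form a continuum), get
iid coordinate noise (1 % of outline scale), and are then rotated,
scaled and translated at random so the superimposition stage has real
work to do. Unknowns draw their guild uniformly; body mass is
log-linear in $s$ (slope −1.5: more pointed, typically smaller) with
lognormal noise around a 100 kg baseline; the phylogeny is a Yule tree
**independent of guild**, so phylogenetic signal in guild-driven shape
is absent by construction.

What the generator deliberately does **not** emulate: phylogenetically
autocorrelated shape (real snout shape carries strong signal; simulated
shape is tree-independent), asymmetry and digitising warp, multiple
specimens per species, and the actual morphospace geometry of real
premaxillae. Passing tests therefore demonstrate that the machinery
recovers known structure under realistic nuisance variation — they do
not certify effect sizes on real data. The generator records every true
parameter so recovery tests can assert against the truth.

All stochastic functions take explicit seeds; `generate_study()` and
`run_pipeline()` derive per-stage sub-seeds deterministically from one
master seed (a fixed affine map modulo $2^{31}-1$), so enlarging one
stage's replicate count does not disturb another stage's stream.

# Problem sizes used in the tests

The test and acceptance suites run at deliberately modest sizes chosen
to exercise every code path with comfortable statistical power: GPA
oracle comparisons on 3 specimens × 5 landmarks; the type-I simulation
at 500 × 199 replicates; signal recovery at 200 Brownian simulations on
a 32-tip Yule tree; end-to-end runs at 60 known + 20 unknown specimens
with 100 semilandmarks. These are the package's reference conditions
for its own correctness claims.

# Known limitations

* Two groups only; the CVA is specialised to the single-discriminant
  case and will refuse more groups.
* 2-D outlines only; no missing-landmark estimation.
* The phylogenetic PCA assumes plain Brownian motion for $C$; λ- or
  OU-transformed covariances are not offered for the ordination.
* The bootstrap/Monte Carlo nulls treat retained PC scores as the data;
  uncertainty in the superimposition and in axis retention is not
  propagated.
* `reconcile()` matches names only up to trimming, underscore/space
  unification and case; it performs no taxonomic synonym resolution.
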