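---
title: "Models, methods and design choices in morphoclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods and design choices in morphoclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoclass)
```

# Overview

`morphoclass` reimplements, on synthetic data, a complete neuroanatomic
case–control classification study: regional morphometry and connectivity
feature tables for a diagnosis × sex design, PCA reduction, SMO-trained
SVM classification (binary and one-vs-one four-class), repeated
cross-validation, an a posteriori univariate screen, and classical MDS
embedding. This vignette records the models, the parameters that matter,
and the design decisions made where the underlying protocol was
ambiguous — in the package's own words, as the package's own choices.

# The synthetic cohort model

`generate_cohort()` draws a four-cell cohort (ASD-M, ASD-F, TD-M, TD-F;
study-scale default 55/55/43/40 = 193 subjects). Ages are uniform on
[8, 18] years, matching a pediatric cohort; sites (default 4) are
assigned uniformly at random (round-robin available); total intracranial
volume (TICV) is log-normal with mean 1.45 × 10⁶ mm³ and SD 1.4 × 10⁵ mm³
— a realistic pediatric head-size distribution that is strictly positive
by construction.

`generate_feature_table()` implements a linear-additive Gaussian model
per (region, measure) cell:

$$ v = \mu_m + \sigma_m\,(\beta_{dx}\mathbf{1}[\mathrm{ASD}]
   + \beta_{sex}\mathbf{1}[F] + \beta_{int}\mathbf{1}[\mathrm{ASD}]\mathbf{1}[F]
   + \beta_{age}\,\mathrm{age} + s_{site}) + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma_m^2) $$

with per-measure baselines and noise SDs chosen at physiologically
plausible scales (thickness 2.5 ± 0.15 mm; area 700 ± 70 mm²; volume
1800 ± 200 mm³; curvature 0.12 ± 0.02; CD 0.5 ± 0.08 in arbitrary
normalized units). Effect coefficients are expressed in units of the
per-measure noise SD so a "1-SD effect" means the same thing for every
measure. Area and volume are additionally scaled by
$\mathrm{TICV}/\overline{\mathrm{TICV}}$, so the TICV-normalization stage
has a real confound to remove. Setting every coefficient to zero is the
null configuration. Design choices, deliberate and fixed:

* the model is linear-additive Gaussian — the simplest structure
  consistent with the pipeline's linear residualization and t/ANOVA
  screens;
* TICV enters multiplicatively only where it is physically meaningful
  (area, volume), while the normalization stage still defaults to
  dividing *all* measures (the literal protocol), configurable to
  `c("area", "volume")`;
* site effects are additive main-effect shifts only — the screen
  regresses site out as a main effect, so simulating site × diagnosis
  interactions would add untested structure;
* the affected-region set is the first `ceiling(fraction × R)` regions,
  deterministically, so tests can name the affected features.

What the generator does **not** emulate: the correlated covariance
structure of real regional descriptors (real thickness/area/volume are
strongly collinear), scanner- and sequence-specific noise, motion
artifacts, or registration error. A green test therefore establishes
that the *pipeline machinery* is correct under its stated statistical
assumptions — not that the published clinical accuracies are
reproducible. The published headline accuracies (93.26 ± 4.21 %
two-group, etc.) were computed on restricted multi-site clinical data
and are deliberately outside the acceptance surface.

The region count is a free parameter (default 165, the parcel count of
the study's atlas — 74 gyral/sulcal parcels per hemisphere plus the
brain stem gives 149, and the protocol's own number 165 is used as
printed; the discrepancy is not resolvable from the text, so the
generator simply treats it as configurable).

# Connectivity density

Toy geometry (`generate_toy_brain()`) is a subdivided-icosahedron sphere
(smallest subdivision reaching the requested vertex count), streamlines
as straight polylines between random vertex pairs carrying per-point FA
samples in [0.2, 0.8], and an azimuthal-sector parcellation. FA is
stored per polyline point rather than on a voxel grid: the mean-FA
contract only needs the traversed values.

The per-subject connectivity stage:

1. **Turning-angle filter** (`filter_streamlines()`): retain a
   streamline iff its maximum turning angle between consecutive segments
   is ≤ 60°. The protocol's literal phrasing ("below 60 degrees …
   discarded") would discard *straight* streamlines, contradicting all
   tractography practice; the literal behavior remains available via
   `literal = TRUE`.
2. **Endpoint snapping** (`build_connectivity_matrix()`): each endpoint
   maps to the nearest vertex within `snap_radius` (default 2 mm — the
   association rule is not specified by the protocol, so nearest-vertex
   with a configurable radius is used); failures and self-loops are
   dropped and counted. The matrix is symmetric, non-negative, and
   zero-diagonal.
3. **Geodesic neighborhoods** (`geodesic_neighborhood()`): shortest
   paths along mesh edges (Dijkstra, Euclidean edge weights) rather than
   exact polyhedral geodesics — standard, testable, and within
   discretization error at ~1 mm edge lengths.
4. **CD** (`compute_vertex_metrics()`): for vertex $v$,
   $\mathrm{CD}(v) = n_{\mathrm{cross}}(v) / A(v) / T$ where
   $n_{\mathrm{cross}}$ counts streamlines with *exactly one* endpoint in
   the 5 mm neighborhood ("linking it to the rest of the brain" implies
   crossing the neighborhood boundary; both-endpoints-inside streamlines
   are excluded), $A(v)$ is the neighborhood area (sum of member vertex
   areas, each one third of incident triangle area — the protocol does
   not define "area of the vertex neighborhood"), and $T$ is the total
   retained streamline count. Whether $T$ should instead be the number
   of distinct connected vertex pairs is unclear from the text;
   `denominator = "pairs"` provides the alternative. CD is invariant
   under duplication of the entire streamline set (numerator and $T$
   both double), which the tests verify to 1e-12.
5. **Smoothing** (`smooth_vertex_map()`): normalized geodesic Gaussian,
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, truncated at $3\sigma$;
   the output is a convex combination of inputs, so constants are
   preserved and values stay within the input range. Cross-subject
   spherical averaging is out of scope; smoothing is per subject.

# Preprocessing and PCA

Standardization uses the $n-1$ sample-SD convention throughout
(consistent with R's `sd()` and the numerical examples in the tests;
a `{1, 3}` column standardizes to $\pm 1/\sqrt 2$). Zero-variance
columns are centered, given scale 1, and flagged rather than producing
NaNs.

PCA (`fit_pca()`) is computed by SVD of the standardized (default) or
merely centered data; eigenvalues of the sample covariance are
$d_i^2/(n-1)$. PCA on standardized features (correlation PCA) is the
default because the five measures mix units (mm, mm², mm³,
dimensionless); raw-covariance PCA is available via `scale. = FALSE`.
The retained count $k$ is the smallest number of leading components
whose cumulative explained-variance fraction reaches the threshold
(default 0.95). Inside cross-validation the model is refitted on each
training fold and applied to the held-out fold (`pca_scope = "fold"`),
because fitting on all data leaks information into the held-out fold;
`pca_scope = "global"` mirrors the whole-sample protocol literally.
Residualization of age and site happens by default only in the a
posteriori screen (the protocol mentions it only there), but
`residualize_covariates()` can equally be applied before classification.

# The SVM

`train_binary_svm()` minimizes the soft-margin dual
$\tfrac12\alpha^\top Q\alpha - \mathbf 1^\top\alpha$ subject to
$0 \le \alpha_i \le C_i$ and $y^\top\alpha = 0$, with
$Q_{ij} = y_i y_j k(x_i, x_j)$, by sequential minimal optimization with
maximal-violating-pair working-set selection: convergence is declared
when $m(\alpha) - M(\alpha) \le$ `tol`, the standard KKT-violation gap.
The algorithm is fully deterministic (ties by lowest index). The bias is
the mean of $y_i - f_0(x_i)$ over free support vectors, or the midpoint
of the final KKT interval when none are free. Numerical choices: dual
variables within 1e-12 of a bound count as bounded; a vanishing
second-derivative along the working pair ($h \le$ 1e-12) takes the
full box-constrained step.

Per-class box constraints (`class_box_constraints()`): with class sizes
$N_1, N_2$ and $N = N_1 + N_2$, the default **balanced** scheme assigns
$C_{\mathrm{class}} = N / (2 N_{\mathrm{class}})$, so the smaller class
receives the larger constraint and the total constraint mass is equal
across classes — this is what "taking the unbalanced design into
account" requires. The printed study configuration assigns the two
values the other way around (majority class gets the larger constraint),
which defeats that purpose; it is preserved verbatim behind
`scheme = "literal"`.

Mode defaults (`svm_config()`), following the printed study values:

| parameter | two-group | four-group |
|---|---|---|
| kernel | linear | polynomial, degree 2, offset 1 |
| KKT tolerance | 0.001 | $2^{-0.77} \approx 0.586$ |
| penalty scale | 1 | $2^{-16}$ |
| γ (RBF variance parameter) | — | 0.25 |

Two open interpretation points, resolved as follows. (1) The two-group
description mentions both an RBF scaling factor of 1 and a linear
kernel; the linear kernel is the default (`kernel_spec("rbf", sigma = 1)`
is available). (2) The four-group "penalty parameter $2^{-16}$" is
interpreted as a multiplicative scale on the pairwise box constraints —
the most natural reading of a misclassification-cost parameter. This
makes the pairwise duals strongly box-constrained; empirically the
resulting decision functions still classify 10-SD-separated clusters
perfectly (the Gram-matrix magnitudes keep the quadratic term of the
dual active), and the loose four-group tolerance $2^{-0.77}$ makes
training fast, consistent with its description as a deliberately
relaxed optimization threshold. γ is stored and applied as the RBF
variance parameter ($\gamma = 1/(2\sigma^2)$) when an RBF kernel is
selected; the polynomial kernel's unstated offset is fixed at 1.

`train_ovo()` builds one binary model per unordered class pair (6 for
four classes), each trained only on that pair's subjects with pairwise
recomputed class constraints. `predict_ovo()` takes the majority vote;
ties are broken by the largest sum of absolute decision values over the
models that voted for each tied class, then by class level order — the
protocol is silent, and this rule is deterministic and scale-aware.

The SMO optimum is verified in the tests against an independent dense
QP solver (`quadprog`) with ridge stabilization and an exact
active-set polish: across 50 random instances (n ≤ 30, all three
kernels, per-class constraints) the dual objectives agree to better
than 1e-7 relative.

# Cross-validation and scenarios

`make_cv_folds()` partitions $n$ subjects into $k$ folds with sizes
$\lfloor n/k \rfloor$ or $\lceil n/k \rceil$ (193 subjects → 3 folds of
20 and 7 of 19). Folds are unstratified by default (the protocol says
only "random"); stratification by the class label is a flag.
`run_repeated_cv()` draws a fresh partition per repetition (seed =
base + repetition), refits preprocessing and classifier inside each
training fold, and records each subject's single out-of-fold prediction.
The accuracy SD across repetitions uses the $n-1$ convention; a single
repetition reports SD 0 with a degeneracy flag.

A "classification scenario" is operationalized as the exact vector of
out-of-fold predicted labels; `most_frequent_scenario()` returns the
modal vector, ties broken by earliest repetition. Confusion summaries
store standard-convention counts (FN = ASD classified TD, FP = TD
classified ASD); the study's tables print these two labels swapped —
with the printed counts, only sensitivity = TP/(TP + printed-"FP") and
specificity = TN/(TN + printed-"FN") reproduce the printed 97.17 % and
91.67 % (and the four-group totals 106 + 4 = 110, 77 + 6 = 83 confirm
the same reading) — so a `paper_labels` rendering is attached while the
stored counts stay conventional. Percentages use half-up rounding to
two decimals, matching the printed conversions (103/193 → 53.37 %).
The printed two-group counts total 190 rather than 193; the ratio
arithmetic is reproduced as-is and the 3-subject discrepancy is not
modeled.

# A posteriori screen

Per feature, after OLS residualization of age and site (intercept +
age + S−1 site dummies; rank-deficient designs drop columns with a
warning): Welch's $t$ with Satterthwaite df between diagnoses, and a
one-way fixed-effects ANOVA across the four cells — one-way because the
printed df pair F(3, 189) at n = 193 is the one-way df, despite the
text's "unequal variances" phrasing; Welch-ANOVA and the factorial
two-way interaction test are available via `method`. Benjamini–Hochberg
runs separately within each test family across all features (the family
definition is not stated in the protocol; per-test-kind across features
is the conventional choice). Degenerate inputs (zero variance
everywhere) return $p = 1$ with a flag instead of NaN. The χ² test for
sex composition defaults to no continuity correction; the printed
χ² = 0.13 is not recoverable from the printed group compositions under
either convention (Pearson gives ≈ 0.066), so it is not a test target.

One calibration subtlety: the generator's TICV scaling makes raw
area/volume columns products of a Gaussian and a log-normal, for which
Welch's test at small n is measurably conservative (≈ 0.037 empirical
size at nominal 0.05, n = 40). The null-calibration tests therefore
check the TICV-normalized features — the analysis-ready form the screen
actually consumes — where the Gaussian null is exact and the empirical
size falls inside the binomial 99 % band.

# Classical MDS

`classical_mds()` implements Torgerson scaling: square the Euclidean
dissimilarities, double-center ($B = -\tfrac12 J D^{(2)} J$),
eigendecompose, and scale eigenvectors by $\sqrt{\lambda}$. The
configuration's Gram matrix is the double-centered $B$ — eigendecomposing
a raw cross-product of non-centered data would not yield a
distance-preserving embedding. Negative-eigenvalue dimensions (possible
only for non-Euclidean input) are dropped with a warning. Reflection
ambiguity is fixed by making each eigenvector's first nonzero loading
positive, so outputs are reproducible. MDS is run on standardized
features by default (whether the original analysis used raw features,
standardized features or PC scores is unstated; standardized features
match the SVM preprocessing and avoid unit dominance).

# Scale of the shipped tests

Test and demo configurations are deliberately smaller than the study
protocol (tens of subjects, ≤ 20 repetitions, 42–2562-vertex meshes) so
the default suite runs in about a minute; the stages themselves are the
study-scale code paths, and the study-scale parameters (193 subjects,
165 regions, 500 repetitions, 10 folds) are plain arguments.

# Known limitations

* Independent features: no attempt to mimic the real covariance
  structure across 825 descriptors, so PCA retention counts on synthetic
  data (≈ 0.95 · d components for isotropic input) do not mirror the
  ~63 components observed on clinical data.
* The four-group classifier cannot beat ~50 % accuracy unless sex or
  interaction effects are injected — by design, not by defect.
* Geodesics are graph shortest paths; on coarse meshes they overestimate
  surface distance (path-length discretization), which slightly shrinks
  neighborhoods relative to exact geodesics.
* No probability calibration, shrinking heuristics, nested tuning,
  permutation tests, or spatial cluster correction.
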