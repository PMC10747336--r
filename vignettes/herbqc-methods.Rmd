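---
title: "Methods behind herbqc: fingerprints, comprehensive scores, response surfaces and exact-mass annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind herbqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbqc)
```

herbqc implements the computational core of a standard-decoction
development workflow for multi-herb formulas: screening raw-herb batches
by chromatographic fingerprint, ranking their quality chemometrically,
optimizing the water-extraction process on a Box–Behnken design, and
annotating LC–MS constituents and plasma metabolites by exact-mass
arithmetic. This vignette records the models, the parameters that matter,
and the design choices made where the methodology left room.

## 1. Fingerprint alignment and similarity

A batch fingerprint is a peak table: retention times (minutes) and areas.
`match_peaks()` pools the peaks of all batches, sorts by retention time,
and starts a new consensus group wherever the gap between consecutive
pooled retention times exceeds the window half-width (single-linkage with
a threshold). The consensus retention time is the median of the members;
a batch missing from a group contributes area 0; a *common peak* has
nonzero area in every batch.

Parameters:

* `window` (minutes, default **0.1**): the standard matching window for
  HPLC fingerprint work. Generated peaks are spaced 1.5 min apart, so the
  window is never the binding constraint in simulation.
* Because consensus retention times of distinct groups are separated by
  more than the window, re-matching the consensus output is a no-op;
  that idempotence is asserted in the tests.

Gap-based single linkage was chosen over fixed binning because it is
deterministic and order-independent after sorting, and ties resolve
toward the earlier consensus time. If one sample contributes two peaks to
a group (possible only when its own peaks sit closer than the window),
their areas are summed.

Similarity against the median reference fingerprint uses the congruence
(cosine) coefficient $\sum x y / (\lVert x \rVert \lVert y \rVert)$:
scale-invariant (dilution-robust), symmetric, and 1 exactly for
positively proportional profiles. Whether the upstream evaluation
software uses plain cosine or mean-centered correlation is not public;
cosine is the default and `method = "correlation"` is exposed. Published
intragroup similarity ranges cannot be recomputed without the raw
chromatograms, so the tests assert the metric's properties, not those
numbers.

## 2. Chemometric ranking

`autoscale()` standardizes each common-peak column to mean 0, sd 1
(n−1). A zero-variance column is an error that names the column — in
real data that means a peak with identical area everywhere, which is
almost always an upstream processing artifact. The one legitimate
degenerate case, *all batches identical* (zero-noise single-origin
simulation), is handled in `run_quality()`: the ranking is trivially all
zeros in stable id order and all samples form one cluster.

`pca_fingerprint()` eigendecomposes the correlation matrix. The
correlation (not covariance) matrix is used because the retention
threshold "eigenvalue > 0.99" is only meaningful on unit-trace-per-
variable scaling; peak areas also span orders of magnitude, which would
otherwise let one peak dominate. Scores are the standardized data times
the loadings. Each loading vector is oriented so its largest-magnitude
element is positive; without a convention the sign is
backend-arbitrary, and the comprehensive score would inherit that
arbitrariness.

The comprehensive score of batch $i$ is
$\sum_k w_k \, t_{ik}$ over retained components, with
$w_k = c_k / \sum_{j \le K} c_j$ and $c_k$ the variance contribution.
The exact weighting behind published comprehensive-score tables is
unstated; renormalizing over the retained components is the default
(weights sum to 1, so the score is a proper weighted average), and raw
contributions are available via `weights = "contribution"`. Ranking ties
break by sample id for determinism. Published per-batch scores are not
reproducible without the raw area matrices; the tests instead assert
trace conservation, score orthogonality, equivalence with a brute-force
weighted-sum oracle, and recovery of generator ground truth.

`hca()` defaults to Ward linkage (`ward.D2`) on Euclidean distances of
the autoscaled data — the de-facto standard for fingerprint clustering;
the original analysis software's settings are unreported.

## 3. Box–Behnken response-surface optimization

The three-factor design has 12 edge midpoints plus `n_center = 5` center
replicates (17 runs). The factors map to coded units via
$x = (X - \text{center})/\text{step}$, with defaults center (8, 45, 30)
and step (1, 15, 10) — first liquid–solid ratio (mL/g), first and second
extraction times (min).

Per-response desirability is the linear rescale
$d_i = (Y_i - Y_{\min})/(Y_{\max} - Y_{\min})$ (maximize direction), and
the overall desirability is the geometric mean — zero whenever any
response hits its floor, which is why two of the packaged 17 runs have
OD exactly 0.000. Bounds default to the observed per-response min/max
over the design; supplied bounds clip to [0, 1]. Note the packaged OD
column is *not* reproducible from the packaged responses under observed
bounds (the original bounds/weights are unstated), so the OD column is
treated as given input for the regression, and the desirability code
path is validated on its own terms.

`fit_quadratic()` is OLS on the ten-term coded model matrix. Regression
is done in coded units because the published coefficient magnitudes are
only consistent with that scale; actual-unit predictions go through the
factor specs. On this design the columns are orthogonal enough that the
intercept equals the center-point mean and each linear coefficient
equals its ±1 contrast over 8 — both asserted against the OLS solution
at 1e−10.

ANOVA partitions: model vs residual, residual into lack-of-fit and pure
error (pure error from the exact replicate runs, i.e. the centers);
per-term F tests come from coefficient t-statistics, which coincide with
type-III tests on this design. A saturated (interpolating) fit is
flagged and its F statistics reported as `Inf` rather than a 0/0.

`optimize_quadratic()` enumerates all 27 ways of fixing each coordinate
at −1/+1 or leaving it free, solves each reduced stationary-point system
analytically, keeps feasible candidates, and takes the maximum; a
51-per-axis grid is evaluated as a safeguard. For a quadratic on a box
this enumeration *is* the global optimum (the maximum lies at a
stationary point of some face), so the result is deterministic and
derivative-free polish is unnecessary.

## 4. Exact-mass annotation

Monoisotopic atomic masses are frozen package constants (C 12 exactly,
H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117,
Cl 34.96885268), chosen over a live lookup so results cannot drift with
a dependency version. All charged-species arithmetic carries the
electron mass: protonation adds 1.0072765 Da, deprotonation subtracts
it, the formate adduct is the composite +HCOOH−H⁻, and the chloride
adduct adds m(Cl) + m(e) — the electron term is what makes the published
[M+Cl]⁻ value at 933.4620 reproduce exactly.

The biotransformation library covers the phase-I/II reactions seen for
flavonoids: glucuronidation (+C6H8O6), sulfation (+SO3), demethylation
(−CH2), hydroxylation (+O), hydrogenation (+H2), deglycosylation
(−C6H10O5). `annotate_features()` enumerates parent × modification
multiset (size ≤ `max_depth`, default 3 — triple modifications do occur
in plasma) × mode-matching adduct, rejects combinations that drive any
element count negative, keeps candidates within `tol_ppm` (default 10;
published errors stay under 5 ppm), and ranks by |ppm|, then fewer
modifications, then parent name. |ppm| is rounded to 1e−4 ppm before
ranking so combinations with analytically identical masses — equal ion
formulas reached by different arithmetic — tie exactly and fall through
to the structural tie-breaks.

`fragment_ladder()` subtracts an ordered series of neutral losses
(glycoside residues, CH3, CO, CH3OH) from the precursor formula and
reports the adduct m/z at each step; `match_fragments()` assigns
observed MS² peaks to ladder steps greedily by |ppm|.

## 5. Synthetic generators: what they emulate, and what they don't

`make_fingerprints()` draws, per origin, an archetype area vector
(lognormal shape × origin amplitude) and produces batches as archetype ×
lognormal noise with a stated coefficient of variation, Gaussian
retention-time jitter, and Bernoulli peak dropout applied *before*
alignment so common-peak detection is exercised. Defaults (3 origins ×
5 batches = 15 batches, 11 peaks, jitter sd 0.01 min, area CV 5%,
dropout 0) mirror a 15-batch single-herb fingerprint study with the
matching window an order of magnitude wider than the jitter.
Multiplicative lognormal noise keeps areas positive, as chromatographic
areas are. The generator does not simulate raw traces, baselines,
co-elution or detector saturation — so passing tests demonstrate the
pipeline's algebra and alignment logic, not robustness to raw-signal
artifacts.

`make_bbd_responses()` evaluates a true quadratic surface at the coded
design points and adds Gaussian noise. Noiseless responses are recovered
exactly by the fit (interpolation); across 200 noisy replicates the
linear-coefficient estimate is unbiased within Monte-Carlo error, using
the closed-form $\mathrm{var}(\hat b_1) = \sigma^2/8$ on this design.

`make_feature_set()` samples parent × modification × adduct combinations
and perturbs the theoretical m/z by Gaussian ppm noise. Two
identifiability filters are part of the design: (i) where several
combinations share one exact ion mass — identical ion formulas, or a
formate adduct isobaric with the deprotonated CH2O2-shifted formula —
only the combination the annotator ranks first at that mass serves as a
truth label, making zero-noise recovery exact by construction; (ii)
candidates closer than 20 ppm (twice the default search tolerance) to
another candidate mass in the same mode are excluded, so the recovery
benchmark measures noise tolerance rather than inherent isobaric
ambiguity. Real plasma data contain exactly such ambiguities; on real
data the annotator returns the full ranked candidate list rather than a
single truth.

All generators are deterministic under a fixed seed; each consumes its
own seed (or derives draws from one `set.seed()` call) so modules stay
decoupled.

## 6. Problem sizes and numerical tolerances

The test suite runs the 17-run design fits, 15-batch fingerprint sets,
a 1000-feature annotation benchmark and a 200-replicate coefficient
Monte-Carlo — sizes chosen to match the study conditions (the design and
tables are fixed by the workflow) while keeping the full suite fast.
Numerical assertions use 1e−10 for linear-algebra identities on
well-conditioned 17×10 systems, 1e−12 for direct arithmetic oracles,
1e−8 for score orthogonality (accumulated rounding over eigenvector
products), and the domain tolerances ±0.0005 Da and ±0.02 ppm for
published mass values at their printed precision.

## 7. Known limitations

* No raw-signal processing anywhere: peak picking, baseline correction,
  isotope-pattern scoring and spectral-library search are out of scope.
* The similarity metric and PCA weighting reproduce the *procedure*, not
  the published per-batch numbers, which require unpublished raw data.
* The desirability bounds behind the packaged OD column are unknown;
  the column is input, not a reproduction target.
* Adducts are limited to the four species observed in this workflow;
  the formula grammar has no parentheses, isotopes or charges.
* `hca()` exposes the four standard linkages only; no bootstrap support
  values on the dendrogram.
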