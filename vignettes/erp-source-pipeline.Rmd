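---
title: "Methods: mass-univariate ERP statistics and BMA-LORETA source reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-univariate ERP statistics and BMA-LORETA source reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpsource)
```

## Overview

`erpsource` implements the analysis chain of a 2x2 repeated-measures ERP
experiment — two tasks (intra-domain face-feature matching vs cross-domain
face-occupation matching) crossed with two target types (match vs mismatch) —
from scalp statistics through distributed source reconstruction to
second-level group inference.  Because no recorded EEG accompanies the
package, a synthetic-study generator plants dipolar component sources in a
labelled source space and emulates the acquisition, so every stage can be
exercised and tested end-to-end.

## Forward model

The volume conductor is three concentric spheres (brain, skull, scalp) with
piecewise-constant conductivity.  The potential of a current dipole in the
innermost shell is expanded in Legendre series; for each degree the five
interface conditions (continuity of potential and of radial current density
at the two internal interfaces, zero radial current at the scalp) are solved
for the layer coefficients, and the series is truncated at `n_terms` degrees
(default 60; for sources at 90% of the brain radius the tail term is below
1e-6 of the sum, and a warning fires when the geometric tail exceeds 1e-4).
The solver works in radii scaled by the scalp radius, which keeps the
per-degree linear systems well conditioned at high degree.

Defaults: radii 0.08 / 0.085 / 0.092 m (standard adult values) and
conductivities 0.33, 0.022 and 0.013 S/m assigned to brain, scalp and skull
respectively.  That triple — with scalp more resistive than brain and only
~1.7x the skull — follows the source study's printed assignment; the
constructor takes arbitrary values, so the common convention (scalp equal to
brain at 0.33 S/m, skull 40-80x smaller) is a one-argument change.  The
units are read as S/m: the printed unit "Ohm/m" is neither a conductivity
nor a resistivity unit, and 0.33 S/m is the standard brain value.

The 60-channel extended 10/20 montage is generated from the scheme's arc
geometry: the outer ring lies 72 degrees from the vertex sampled every 18
degrees of azimuth, each coronal row runs from its midline site to its ring
site along a great circle, and intermediate electrodes sit at quarter
fractions of that arc.  The reference is the nose tip, placed on the front
midline 20 degrees below the equator; the reference potential is subtracted
from every channel, so predicted potentials vanish there identically.

The source space is a Fibonacci lattice on a shell at 90% of the brain
radius, partitioned into spherical-Voronoi compartments whose seeds are
drawn (seeded) among the generators, guaranteeing non-empty, contiguous
patches; a symmetric 6-nearest-neighbour graph approximates the mesh
topology of a triangulated cortical surface.  Generators carry free
3-component moments.

The forward solution was verified two ways: against an independently coded
single-sphere analytic series in the equal-conductivity limit (relative
error ~1e-5 at the default truncation, asserted below 1e-3 in the tests),
and via physical invariants (linearity, reference nulling, skull-conductivity
attenuation, the 1/length^2 geometric scaling law).

## Synthetic studies

`generate_study("paper_like")` emulates 28 participants, 40 trials per
condition, 60 channels and 256-sample epochs at 250 Hz beginning 200 ms
before stimulus onset (latency grid -200, -196, ..., 820 ms).  Components:
N170 in both tasks but from distinct compartments, P200 and N250 only in the
intra-domain task, and an N400-like 330-440 ms mismatch effect whose source
compartment differs between tasks.  Planted compartments are the six most
posterior-superior ones — the emulated components arise in posterior
visual/occipitotemporal cortex, and this also guarantees electrode coverage.
Dipole moments (2-6 nA.m) were chosen once so that scalp peaks fall in the
physiological few-microvolt range given the lead-field gains (~0.3-1.8
uV per nA.m for posterior compartments); the mismatch-dominant pattern is
5 nA.m (mismatch) vs 2 nA.m (match).

Sensor noise is Gaussian, spatially correlated with an exponential decay
over inter-electrode great-circle angle (length 30 degrees, mimicking volume
conduction), temporally white, with single-trial sd 10 uV.  Between-subject
variability is a multiplicative component gain 1 + N(0, 0.2) floored at 0.1.
Artifacts occur with probability 0.1 per trial as a 120-180 uV square pulse
on a random frontal channel, exercising the +/-100 uV rejection rule.
Averaging equalises kept-trial counts across conditions per subject (seeded
subsampling), removes a linear trend per channel and zeroes the baseline
mean; the enforced minimum is 24 kept trials of 40, scaled proportionally
(60%) for reduced trial counts, and a subject falling below it is
re-simulated under a shifted substream so a study always delivers its full
sample.

What the generator does *not* emulate: ocular artifacts and their
correction, filtering chains, temporally correlated (1/f) background EEG,
trial-to-trial latency jitter, and realistic cortical geometry.  Passing
tests therefore demonstrate the correctness and calibration of the
*methods*, not performance on real recordings — in particular, window-mean
features average away white noise faster than they would 1/f noise.

## Sensor statistics

At every electrode and time point a two-way within-subject ANOVA is fitted.
For a 2x2 within design each effect is a single-df contrast across the four
condition means — (+,+,-,-)/2 for TASK, (+,-,+,-)/2 for MATCH, (+,-,-,+)/2
for the interaction — so `F = n mean(d)^2 / var(d)` with df (1, n-1), which
is exactly the squared paired t; no sphericity correction exists to apply.
Zero-variance points are degenerate and report p = 1 with a warning rather
than NaN (conservative).  Multiplicity over the 60 x 256 grid is controlled
by Benjamini-Hochberg FDR at q = 0.05 (the standard neuroimaging choice for
a p-map; under the positively correlated noise here BH remains valid, and
the realized false-discovery proportion under global-null simulations is
asserted <= 0.07).  Post hoc paired-t maps are computed only at points
retained by the corresponding main effect and BH-corrected jointly across
the two within-factor comparisons and all retained points.  For display,
two-sided p-values map to unsigned Z via `qnorm(1 - p/2)`, with signs copied
from the post hoc t maps; a one-sided mapping `qnorm(1 - p)` is available by
flag.  The behavioural discrimination index `d' = 0.6 log[(pH(1-pF))/(pF(1-pH))]`
is implemented with configurable log base (default 10): the formula's
lineage is ambiguous and published group values cannot be reproduced from
group mean probabilities under any base, so the function evaluates the
printed formula and leaves aggregation to the caller.

## Inverse problem: LORETA within compartments, averaged by evidence

Per subject, the feature inverted for the late mismatch effect is the
channel-wise mean of the mismatch-condition ERP over 330-440 ms (the
"mismatch ERPs" reading; a mismatch-minus-match variant is a config switch).
Early components use subject-specific peak features: the extremum of the
posterior-channel mean within 130-200 ms (N170, negative), 180-250 ms
(P200, positive) or 230-310 ms (N250, negative) — windows are package
defaults exposed in the specs, since no numeric definitions exist to
inherit.  Subjects without an interior extremum of the required polarity are
excluded with a warning.

An anatomical-constraint model `M` restricts support to a compartment
subset.  Under `M`, the solution minimises
`beta ||v - K_M j||^2 + alpha ||L~ j||^2`, where `L~` is the graph Laplacian
of the subset (applied identically to each moment component) augmented with
a trace-scaled ridge `eps = 1e-8 mean(diag(L'L))` that removes its constant
null space.  This is the posterior mean of a Gaussian linear model, computed
through the SVD of the whitened gain `K_M (L'L + eps I)^{-1/2}`, which also
yields the marginal likelihood in closed form.  The hyperparameters
(alpha, beta) maximise the evidence: a 25-point log-grid over 10^-6..10^6
per parameter, then Nelder-Mead refinement on the log scale (relative
tolerance 1e-12).  The SVD is data-independent and shared across subjects
and conditions, which makes per-subject inversion cheap.

Models are enumerated exhaustively up to `max_size = 2` compartments (cap
1000 models): exact and oracle-verifiable at this scale, in place of the
stochastic model search used with realistic atlases.  Posterior model
probabilities are softmax weights of the log evidences under a uniform
model prior (computed after subtracting the maximum, so underflow is
impossible); models whose posterior odds against the best fall below the
Occam window (default 1/20, the conventional odds bound) are pruned and the
weights renormalised — the best model is always retained, so `occam = 0`
(keep all) and `occam = Inf` (best only) bracket every intermediate setting.
The averaged primary current density is the weighted sum of zero-padded
per-model solutions; the inverse-solution map is its per-generator norm.
Scale covariance holds by construction: scaling the data by c rescales the
optimal precisions by 1/c^2 and the solution by c, leaving model weights
unchanged.

## Second-level group analysis

Inverse-solution maps mix exact zeros with positive magnitudes whose scale
varies across subjects, so group analysis operates on binarized maps.
Exact zeros are inactive by definition; the log-magnitudes of positive
generators are fitted with a two-component Gaussian mixture by EM
(deterministic quantile-based initialisation at the 80th percentile,
lower-mean component = null, convergence at 1e-10 relative log-likelihood,
at most 500 iterations; non-convergence or degenerate spread falls back to
an all-inactive map with a warning).  The local FDR at a value is the
posterior null probability, and a generator is active when lfdr < 0.2
(Efron's conventional reporting level; no published cutoff exists to
inherit).  The two-Gaussian EM stands in for the spline-based empirical-null
fit of the local-FDR literature: it is deterministic, has few parameters and
is adequate for a unimodal null, but it is a deliberate simplification.
Everything downstream is invariant to any positive rescaling of a subject's
map because only shifts of the log-magnitudes are involved.

The conjunction map is the per-voxel proportion of subjects active (values
on the 1/n grid).  Between tasks, each subject's binary maps are subtracted
(-1/0/1), the group map is the signed per-voxel mean, and significance comes
from a sign-flip permutation test: each subject's pair is exchanged with
probability 1/2 per iteration (the exchangeability group of a paired
design), two-sided p-values use the add-one estimator
`(1 + #{|perm| >= |obs|})/(n_iter + 1)` (never exactly zero), and BH-FDR at
q = 0.05 is applied across voxels.  The default is 10,000 iterations;
calibration tests use 1000.  Note that with 28 ternary differences the
permutation p-values are *discrete*, with a sizeable atom at p = 1 wherever
the observed statistic sits at the null mode; they are super-uniform
(valid/conservative), which the tests assert directly, but no continuous
uniformity check can pass on them.  Cluster tables summarise suprathreshold
voxels per compartment (size, mean |value|, SD), with signed difference maps
split by direction; within-condition conjunctions are tabulated
unthresholded at a 0.5 proportion cutoff.

## Pipeline, seeding and problem sizes

`run_pipeline()` chains the stages under a single validated config; a global
seed is expanded into per-stage substreams by a fixed offset scheme (stage
index appended to the seed; per-subject recordings use a subject offset), so
stages rerun standalone reproduce the pipeline bit for bit, and output
manifests record MD5 hashes plus the fully resolved config.

Problem sizes used by the test-suite and the acceptance script are the
package's choices for a thorough-but-quick desk study: the full 28-subject
paper-like study for sensor statistics and recovery checks; 500 generators
in 12 compartments with model size <= 2 (78 models) for inversion; null
studies with 8 trials and 64 samples for the FDR-calibration replicates
(the false-discovery proportion is size-free); directly constructed
exchangeable binary maps for permutation calibration; 1000 permutation
iterations in calibration and end-to-end checks.

## Known limitations

* Spherical geometry end to end: no realistic BEM/FEM conductor, no
  anatomical atlas; compartments are synthetic Voronoi patches.
* The evidence optimisation assumes isotropic sensor noise.
* The EM mixture binarization can be conservative when the active fraction
  is very small, and requires at least 50 positive magnitudes.
* Exhaustive model enumeration is exponential in compartment count; the cap
  forces small model sizes rather than falling back to stochastic search.
* Discrete permutation p-values make the FDR threshold conservative for
  small samples.
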