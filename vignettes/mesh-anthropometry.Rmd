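---
title: "Mesh-based anthropometry and comparative error statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based anthropometry and comparative error statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(anthropix)
```

## The scientific problem

Forensic identification often hinges on basic physical attributes — above
all a person's height and weight — estimated from a single photograph.
Three very different kinds of estimators compete at this task:

* **AI (mesh anthropometry).** A parametric 3D body model is fit to the
  image, given a metric scale, and measured directly: height as a
  geometric distance, weight as an enclosed volume times an average body
  density.
* **Humans.** Expert photogrammetrists with scene reference measurements,
  or untrained raters who simply look at the picture. Many raters can be
  pooled into a "crowd" consensus.
* **A baseline.** Predicting the gender-specific population-average
  height and weight for every image, regardless of content. Any estimator
  worth deploying must beat it.

This package implements the measurement chain of the first estimator, the
baseline, and the nonparametric statistics used to compare all of them —
together with a synthetic-data layer (cohorts, poses, body meshes, rating
sessions) so that the entire comparison runs end-to-end, reproducibly,
with no external data.

Because the synthetic layer replaces photographs, model fits and real
raters, the package cannot reproduce empirical claims about how well AI
or humans estimate attributes from *real images*. What it does support is
(a) exact validation of every computational step of the chain, and (b)
recomputation of the quantities that follow from stated population
parameters alone — chiefly the baseline's irreducible error.

## The measurement chain

Given a watertight, neutral-pose triangulated body mesh with eight named
landmarks (four eye corners, the head apex, three sole points):

1. **Pupil centers.** Body meshes have no pupils; each pupil is the
   midpoint of the inner and outer corners of that eye.
2. **Metric scale from the IPD.** Monocular reconstructions carry no
   reliable absolute scale, but the adult inter-pupillary distance is
   tightly distributed: 6.17 ± 0.36 cm for women and 6.40 ± 0.34 cm for
   men. Every vertex is multiplied by
   `s = ipd_mean(gender) / ipd_measured`, after which the mesh is in
   centimetres. Since `s` absorbs any uniform pre-scaling, the chain is
   invariant to the arbitrary units the mesh arrives in.
3. **Height.** The perpendicular distance from the head apex to the plane
   through the three sole landmarks. The perpendicular reading (rather
   than a vertical-coordinate difference) is the unique rotation-invariant
   interpretation of "distance from the top of the head to a plane through
   the feet", and makes the measurement independent of how the mesh is
   oriented in space.
4. **Weight.** The enclosed volume, converted to mass at an average body
   density of 1023 kg/m³ (the density corresponding to a gender-agnostic
   average body fat of 34%). Volume is the divergence-theorem sum of
   signed tetrahedra spanned by each face and the origin — exact for
   watertight, consistently outward-wound triangulations, `O(faces)`, and
   translation-invariant.

```{r measure}
mesh <- generate_body_mesh(176.1, 78.4, "male")
measure(mesh, "male")
```

Two deliberate contracts are worth stating. *Units are explicit*: meshes
carry a `units` field (`"raw"` or `"cm"`) and every operation refuses
unit-mismatched input instead of guessing. *The apex is a landmark, not an
argmax*: taking the farthest vertex from the foot plane would silently
depend on pose and orientation; the named landmark keeps the contract
testable (a `fallback_apex` flag provides the argmax as a convenience).
Reposing a posed mesh into the neutral pose is out of scope — it requires
a rigged body model — so the chain requires neutral-pose input.

## The synthetic generator

`generate_body_mesh()` builds the body as a single closed surface of
revolution about the vertical axis with an anthropomorphic radius profile,
capped by a flat sole disk and a head-apex point. A lathe was chosen over
a union of head/torso/limb primitives because a boolean union of
primitives is not watertight without a CSG engine, while the lathe is
watertight by construction and preserves everything the chain measures.
The target quantities are hit exactly, not approximately:

* *Height* — the apex sits at `z = height`, the soles on `z = 0`.
* *Volume* — radial coordinates are scaled by
  `k = sqrt(V_target / V_template)`; scaling `(x, y)` is an affine map
  with determinant `k²`, so the discrete mesh volume lands on
  `weight / density` to machine precision. Radial scales outside
  `[0.15, 3]` are rejected as anatomically infeasible (for example a
  0.001 kg body at 170 cm).
* *IPD* — the four eye-corner landmarks are dedicated annotation vertices
  appended after the triangulated surface (no face references them), so
  they can be placed exactly: the pupil midpoints are separated by the
  subject's IPD without perturbing the closed surface or its volume.
  Watertightness is an edge/face property and is unaffected.

The mesh is emitted in arbitrary raw units (by default metre-like,
100 cm per unit, with the true scale recorded) so the measurement chain
must recover the metric scale itself.

With `ipd_jitter_sd > 0` each subject's true IPD is drawn around the
gendered mean; because the chain scales by the *population* mean, this is
precisely the error source of IPD-based metric scaling: all linear
measurements inherit a relative error of `ipd_mean / ipd_true`, and weight
its cube. The default jitter in `run_config()` (0.25 cm) produces AI
height errors of a few percent, the realistic regime for this scaling
strategy; jitter-free meshes make the AI channel exact, which is the
configuration used to validate the chain itself.

The cohort generator draws gendered heights and weights from normal
distributions (defaults: 33 women at 161.1 ± 5.3 cm and 60.9 ± 11.4 kg,
25 men at 176.1 ± 8.3 cm and 78.4 ± 12.9 kg — a university-style cohort
whose weights run well below the US adult averages of 78.7/90.8 kg).
Non-positive draws are rejection-resampled rather than truncated; at
these parameters the rejection probability is negligible, so the stated
means are preserved. The study design enumerates 8 + 6 no-reference
studio poses, 1 reference pose and 2 + 3 in-the-wild poses per
participant (812/58/290 images for 58 participants).

Rating sessions emulate a crowd-sourcing platform: each rater sees one
set of images in which every participant appears once, plus four catch
trials with displayed answers. Rater estimates are truth plus additive
Gaussian bias/noise per attribute (a multiplicative lognormal option
exists); the distribution shape of real raters is unknown, so these
defaults are plumbing for the statistics, not a claim about human
behaviour. Catch trials are modelled as pass/fail flags — their only
analytical role is the exclusion rule, under which a session failing
*any* catch trial is voided entirely, and incomplete sessions are
likewise dropped. A session that is both is counted once, in the
catch-failed bucket, which keeps the bucket arithmetic additive
(e.g. 325 − 65 − 24 = 236 valid sessions in the deterministic-assignment
mode).

## The comparative statistics

Per-image error statistics come in two flavours for a pool of raters
`j` rating image `i` with truth `h_i`:

* individual: `median_j |ĥ_ij − h_i|` — the typical lone rater;
* crowd: `|median_j(ĥ_ij) − h_i|` — the pooled consensus.

Reported summaries take the per-image statistic first and the median
across images second, uniformly for all groups (for one-estimate-per-image
groups the two readings coincide). A percent error divides by the
image's true value *before* the across-image median — the only reading
that is well-defined per image. One wording ambiguity is worth
flagging: "median individual error" could also pool all image–rater
errors into one median; the per-image-first reading is the default and
the pooled alternative is available via
`individual_accuracy(..., pooling = "pooled")`, without endorsement.
Medians are used throughout because rater responses are not normally
distributed within or across images; even-length medians are the
midpoint of the two central order statistics.

Uncertainty on every reported median is a percentile bootstrap
(default 1000 iterations, 95% level) resampling *images* with
replacement — images are the unit of analysis. The bootstrap is seeded,
and samples are put in canonical image order first, so summaries are
deterministic and invariant to input row order. Degenerate inputs
(fewer than two images) yield a zero-width interval with a warning.

Group comparison follows the standard nonparametric recipe on the
complete-case per-image error matrix (images × groups):

* a **Friedman omnibus** on within-image ranks (average ranks for ties,
  tie-corrected statistic, chi-square approximation with k − 1 degrees of
  freedom). The chi-square p is accurate at the matrix sizes the pipeline
  produces (dozens of images); for very small instances the test suite
  validates it against a within-row permutation oracle instead of exact
  tables. A matrix with no rank information at all (identical columns) is
  defined as "no group effect" (statistic 0, p 1).
* **all-pairs two-sided Wilcoxon signed-rank tests** on paired per-image
  error differences, with the classic drop-zeros convention, the exact
  null for n ≤ 25 untied differences and the tie-corrected normal
  approximation otherwise. Significance uses a Bonferroni-corrected
  threshold `alpha / n_pairs` — 0.05/10 = 0.005 for five groups — plus a
  ten-fold stricter flag. Absolute differences at or below 1e-9 are
  treated as ties: the chain's geometric predicates operate at that
  epsilon (on unit-IPD-normalised coordinates, chosen to be scale-free),
  and floating-point dust from an exact channel must not register as a
  systematic difference.

Both tests are delegated to the standard `stats` implementations behind
this module's surface; the test suite checks them against independent
enumeration (all `2^n` sign assignments) and permutation (10,000
within-row shuffles) oracles.

The baseline's error needs no simulation at all in the large-cohort
limit: against a constant prediction `b`, a Normal(μ, σ) population has
absolute error distributed as a folded normal, whose median solves
`P(|X| < m) = 1/2`; a two-gender cohort is the corresponding mixture
(`baseline_error_theory()`). The simulated counterpart
(`baseline_error_simulated()`) repeats finite cohorts and averages the
cohort-level pooled medians:

```{r baseline}
baseline_error_theory("height")
baseline_error_theory("weight")
baseline_error_simulated("height", n_cohorts = 100, seed = 1)
```

The height baseline is strikingly good (~4.3 cm) while the weight
baseline is terrible (~16 kg): gendered adult heights have low variance,
and this cohort's weights sit far from the US averages. This asymmetry
is structural, not an artefact of simulation. Note also that any single
n = 58 cohort's median error scatters around these population values
with a spread of 1–2 kg for weight, so a one-off empirical cohort can
legitimately sit noticeably above or below them.

## The pipeline

`run_pipeline()` composes everything: cohort → design → per-image meshes
→ AI measurements → non-expert sessions (with exclusion) → expert pass
over the in-the-wild images → baseline → per-setting summaries → omnibus
and pairwise tests on the in-the-wild complete-case set across the five
groups (ai, expert, crowd, individual, baseline). A master seed derives
per-stage seeds through a documented multiplicative scheme
(`stage_seed()`), so stages are individually reproducible and re-running
a config reproduces byte-identical CSVs; the manifest lists every output
file with its MD5 hash. `render_report()` formats the summaries as a
Markdown median-error table and upper-triangular significance star
matrices.

```{r pipeline}
cfg <- run_config(seed = 11,
                  cohort = cohort_params(n_female = 5, n_male = 4),
                  n_boot = 200, n_sessions = 30, session_counts = c(6, 2),
                  mesh_resolution = 16)
res <- run_pipeline(cfg)
res$session_report
subset(res$summaries, setting == "wild" & attribute == "height")
res$friedman
```

The package's functions are the interface; a thin command-line wrapper
(`inst/scripts/anthropix-cli.R`) exposes `measure` and `run-all` for
shell use.

## Numerical choices and problem sizes

* Geometric predicates (collinearity, degenerate IPD) use an absolute
  epsilon of 1e-9 on normalised coordinates; the same epsilon defines
  Wilcoxon ties, as above.
* Mesh resolution defaults to 48 rings (32 in the pipeline, where one
  mesh is generated per image); the measured quantities are exact by
  construction at any resolution ≥ 8, so resolution only shapes surface
  smoothness.
* Default example and test runs use reduced problem sizes — cohorts of a
  handful of participants, a few hundred bootstrap iterations — chosen so
  a complete validation pass stays interactive while leaving every
  statistical check well-powered; the full-study configuration
  (58 participants, 1160 images, 325 sessions, 1000 bootstrap iterations)
  is the `run_config()` default and runs in a few minutes.

## Known limitations

* The lathe body is radially symmetric: it preserves measurable
  anthropometry but not body shape; nothing here validates model *fitting*
  to images.
* Simulated raters are Gaussian (or lognormal) around truth; real crowds
  show skew, rounding to unit preferences, and image-difficulty effects
  none of which are modelled. Passing tests validate the statistics
  pipeline, not human behaviour.
* Gender is binary `{female, male}` exactly as in the published IPD and
  population-norm constants the chain depends on.
* The Friedman p-value relies on the chi-square approximation; below
  roughly 8 images it should be read qualitatively (the suite bounds its
  error against a permutation null at those sizes).
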