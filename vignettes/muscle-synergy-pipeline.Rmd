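---
title: "Muscle synergy extraction and shared-synergy analysis with musyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy extraction and shared-synergy analysis with musyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musyn)
```

## The model

A common account of motor control holds that the central nervous system
does not command every muscle independently but recruits a small set of
*muscle synergies*: fixed non-negative weightings over muscles, each driven
by a single time-varying activation. In matrix form, a participant's
envelope matrix $E$ (muscles $\times$ timepoints) is approximated by

$$E \approx W C, \qquad W \ge 0,\; C \ge 0,$$

where the columns of $W$ ($m \times k$) are the synergy vectors and the
rows of $C$ ($k \times n$) the activation coefficients. `musyn` implements
this model for multi-channel surface EMG recorded over repeated trials of
several motor tasks (the motivating application is 16 lower-limb muscles
during three kinds of skateboard jump), together with the downstream
questions the decomposition is used to answer:

* How many synergies does a task need (`select_nos()`, `nosoa()`)?
* How variable are synergies across participants
  (`pairwise_interparticipant()`, `coefficient_of_variation()`)?
* Can one participant's (or task's) factors reconstruct another's data
  better than chance (`cross_participant_study()`,
  `cross_task_reconstruction()`, `randomized_null()`)?
* Which synergies are shared between tasks (`shared_oa()`, `shared_ind()`)?

## Preprocessing

`emg_envelope()` applies the standard movement-science chain: a 4th-order
Butterworth band-pass (10–400 Hz) applied forward and backward (zero phase,
effective order 8), demeaning, full-wave rectification, and a 4th-order
zero-lag Butterworth low-pass at 6 Hz. Two details are deliberate choices
rather than forced by convention:

* *Order of demeaning.* Demeaning is applied after the band-pass. The
  band-pass already removes DC, so the step is near-idempotent; applying it
  in this order keeps the chain faithful to the usual published ordering
  (filtered, demeaned, rectified, low-passed).
* *Non-negativity.* A low-pass filter can undershoot below zero near sharp
  envelope flanks; the envelope is clipped at zero because downstream NMF
  requires non-negative input. The clipped mass is negligible for realistic
  envelopes.

`time_normalize()` maps the analysed phase (delimited by per-trial event
samples, e.g. the takeoff between the lowest and highest pelvis position)
onto 100 uniformly spaced points by linear interpolation. Linear
interpolation is the least-assumption choice and has a known error bound
(grid spacing squared over 8 times the maximum curvature), which the test
suite verifies on analytic signals.

`assemble_envelopes()` concatenates each task's trial envelopes
(6 trials $\times$ 100 points $= 600$ columns) and divides every muscle row
by that muscle's maximum over *all* of the participant's tasks. This
cross-task amplitude normalisation means one task's matrix may peak below 1
— by design, so that between-task amplitude differences survive
normalisation. A muscle that is zero everywhere makes the division
undefined and is reported by name instead of silently propagating NaN.

## Factorisation and model selection

`nmf()` minimises $\|E - WC\|_F^2$ under non-negativity. Because the
problem is non-convex and the attained optimum depends on the random
initialisation, the factorisation is repeated 50 times (uniform random
initial factors, each restart seeded deterministically from the caller's
seed) and the restart with the highest tVAF is kept, where

$$\mathrm{tVAF} = 100\left(1 - \frac{\|E - WC\|_F^2}{\|E\|_F^2}\right)$$

with the *uncentred* total sum of squares, the convention of the synergy
literature. Synergy vectors are then rescaled to unit maximum and the
matching activation rows multiplied by the same factors, leaving the
product unchanged.

Three solvers are provided. The default, `method = "hals"`, is exact block
coordinate descent at component granularity: each synergy's weight column
and activation row is replaced by its exact non-negative least-squares
minimiser given all other components. It was chosen as the default because
its per-sweep cost is $O(mnk)$, which keeps the full study protocol (k = 1
to 15, 50 restarts each, per participant and task) affordable, and its
solution quality on this problem class matches the slower alternatives; the
cross-implementation test against an independent NMF implementation
verifies the attained residual. `method = "anls"` solves whole columns and
rows by an exact active-set NNLS each sweep (the classical alternating
non-negative least squares family), and `method = "mu"` provides
multiplicative updates. All three decrease the residual monotonically,
which the test suite asserts on every stored residual trace. Iteration
stops when the relative residual change falls below `tol` (default 1e-6) or
after `max_iter` sweeps (default 500); non-convergence is reported through
a flag, not an error, because the best iterate is still a valid (if
conservative) decomposition.

When `k` exceeds the effective rank of the data a component can converge to
all zeros. Such dead components are replaced by a tiny fixed ramp
(so the unit-maximum normalisation stays defined) with a zero activation
row, and their indices are reported in the result.

`tvaf_curve()` runs `nmf()` for $k = 1, \dots, m-1$. A curve point can
occasionally fall below its predecessor (a local-minimum artifact); the
point is re-run once with fresh restarts and, if still lower, clamped to
the previous value and flagged. The selection rule assumes a non-decreasing
curve, so clamping is preferable to letting a solver artifact leak into
model selection.

`select_nos()` applies two criteria *conjunctively at the same k*: tVAF
must exceed 90% (strict), and the gain from one additional synergy must be
at most 1 percentage point (the increment criterion is vacuous at the last
k). The conjunctive reading is the only one that produces a single
well-defined value when the criteria first hold at different k, and it
reproduces the worked examples in the test suite. If no k satisfies both,
the largest candidate is returned with `criteria_met = FALSE` rather than
an error, since downstream summaries still need a value. `nosoa()` rounds
the grand mean of all NoS values half-up; the tie rule is recorded because
means landing exactly on .5 are possible with small cohorts.
`coefficient_of_variation()` uses the sample (n−1) standard deviation,
consistent with the small cohorts it summarises.

## Similarity

Three similarity measures serve different comparisons:

* `cos_sim()` for non-negative synergy vectors (threshold 0.8);
* `pearson_r()` with the analytic two-tailed critical value
  `critical_r(n, alpha)` $= t_{1-\alpha/2,\,n-2} / \sqrt{t^2 + n - 2}$.
  For 16 muscles at $\alpha = 0.01$ this is 0.623. Here $n$ is the number
  of muscles, i.e. the number of paired observations when two weight
  vectors are correlated;
* `xcorr_rmax()` for activation waveforms (threshold 0.9): the maximum
  Pearson correlation over integer lags, ties resolved towards the smallest
  absolute lag (negative first). The default lag window is ±10% of one
  trial block (±10 samples). The window is bounded because the compared
  waveforms are concatenations of trials: unbounded lags would align
  sample points across trial boundaries, which is physiologically
  meaningless. Whether to correlate concatenated (600-point) or
  trial-averaged (100-point) waveforms is not settled in the literature;
  the package operates on whatever rows it is handed, and the pipeline
  passes concatenated rows with the bounded window.

`reorder_to_reference()` aligns synergy order across participants by
greedy cosine matching: the globally most similar (reference, other) pair
is fixed first, removed, and so on. Greedy matching is the procedure
described in the synergy-reordering literature; the test suite checks it
against the exhaustive assignment optimum on structured synergy-like
instances (within 5% of the optimal total similarity), and ties are broken
by the lowest reference index for determinism.

## Reconstruction and the randomized null

`reconstruct_C()` fixes a synergy-vector matrix and refits activations by
exact per-column NNLS (active-set on the Gram matrix, written in C++);
`reconstruct_W()` is the transposed problem. Columns are independent given
a fixed design, so the per-column solve is jointly exact. The resulting
tVAF$_{rec}$ can never exceed the target's own jointly fitted tVAF (the
own decomposition minimises the same objective over both factors), an
invariant the tests assert to solver tolerance.

`randomized_null()` replaces each real source by a seeded uniform random
matrix of the same dimensions (unit-maximum columns when standing in for
W). Each random matrix is preordered against the corresponding real source
by greedy cosine matching before use, mirroring the preordering applied to
real inputs, and one random source is drawn per real source so the
tVAF$_{rand}$ averages are directly comparable to the tVAF$_{rec}$
averages. Uniform entries are the minimal-assumption non-negative choice;
the distribution of the null is fully determined by the seed.

## Shared synergies

`count_shared()` correlates all synergy-vector pairs between two tasks and
accepts pairs greedily by descending r while r exceeds the critical value,
removing both members after each acceptance. Matching is one-to-one — a
synergy cannot be "shared" with two different partners — which is what
makes the count and the relative measure

$$\%n_{shared} = 100\,\frac{n_{shared}}{k_1 + k_2 - n_{shared}}$$

well defined (the denominator is the size of the union of the two synergy
sets). The threshold defaults to `critical_r(muscles, 0.01)` rather than a
hard-coded 0.623 so other montages work unchanged.

`shared_oa()` compares all tasks at the common rank NoSoA; `shared_ind()`
at each task's own NoS. A synergy is flagged as shared through *all* tasks
when the pairwise matchings are transitively consistent: its partner in
task B and its partner in task C must themselves be matched to each other.
Transitive consistency is the strictest reading of "consistent across all
tasks" and avoids counting chains that contradict each other.

## The synthetic-data generator

`generate_dataset()` produces raw EMG-like signals whose analysed phase,
once envelope-processed, approximates a known factorisation. The defaults
mirror the motivating study: 7 participants × 3 tasks × 6 trials, 16
muscles at 1000 Hz, phase between samples 200 and 700 (leaving ample filter
warm-up), 4 synergies per task with one shared across all tasks.

Design choices, in the order they act:

* *Synergy vectors*: a few dominant muscles over a small positive floor,
  drawn with rejection so distinct synergies stay mutually dissimilar
  (pairwise r < 0.5). Shared synergies reuse the same pool vector across
  tasks; participants perturb each pool vector once (log-normal
  multiplicative noise, SD 0.25, then unit-maximum renormalisation), and
  that perturbed vector is reused wherever the synergy appears, so a shared
  synergy stays shared within a participant.
* *Activations*: one Gaussian burst per synergy on the 100-point phase
  (SD 7 points). The all-task-shared synergy bursts in the first third of
  the phase, emulating a propulsive "jump" module; task-specific synergies
  spread over the remainder. Per-trial variation enters through burst
  centre jitter (SD 2 points) and amplitude variability (CV 0.1).
* *Envelope noise*: additive Gaussian noise with SD expressed as a fraction
  of each muscle's peak envelope (default 0.05), clipped at zero. The
  trial-to-trial envelope variability of real skateboard EMG is not
  characterised anywhere, so this is an honest free parameter, not a fitted
  value.
* *Raw signals*: white noise band-passed to 20–380 Hz, scaled to unit RMS,
  and amplitude-modulated by the envelope interpolated onto the phase
  window, plus a small baseline (1% of peak) elsewhere. This gives the
  10–400 Hz band-pass and rectification stages realistic work, and makes
  envelope extraction a genuine estimation step rather than an identity.

What the generator does *not* emulate: motion artefacts and electrode
noise below 20 Hz, signal cross-talk between adjacent muscles, fatigue
drift across trials, and any biomechanics of an actual jump. Passing
recovery tests on this generator therefore demonstrates that the pipeline
is correct and well-conditioned under the model's own assumptions — not
that real skateboard EMG contains four synergies.

## Worked example

A small study (2 participants × 3 tasks) end to end:

```{r example, eval = FALSE}
cfg <- synthetic_config(participants = 2, tasks = 3, trials_per_task = 6)
ds <- generate_dataset(cfg, seed = 42)
env <- process_dataset(ds)

curve <- tvaf_curve(env$P1$T1, restarts = 50, seed = 1)
select_nos(curve)$nos
#> [1] 4

decs <- setNames(lapply(names(env$P1), function(t)
  nmf(env$P1[[t]], k = 4, restarts = 50, seed = 1)), names(env$P1))
shared_oa(decs)$pairs[, c("task1", "task2", "n_shared", "pct_shared")]
```

The full pipeline, including reconstruction nulls and tidy result tables
on disk, is one call: `run_pipeline(pipeline_config(manifest, outdir))`.

## Problem sizes, tolerances and limitations

The package's own validation runs at deliberately chosen problem sizes:
envelope matrices of 16 × 600 (the study's native size) for recovery and
reconstruction simulations, 10 seeds for recovery scoring, 20 seeds for
the reconstruction-ordering sign test, and reduced designs (6 muscles, 2–4
trials) for structural and pipeline tests where the size is irrelevant to
the property under test.

Numerical conventions worth knowing:

* NMF convergence is declared at relative residual change < 1e-6; restart
  selection compares tVAF, so exact ties (measure zero) resolve to the
  earlier restart.
* tVAF is not clamped: pathological factors can produce negative values,
  and hiding that would mask bugs.
* `xcorr_rmax` skips lags whose overlap has zero variance and errors only
  when every lag is degenerate.
* Greedy matching is deterministic (ties by lowest index), so all results
  are exactly reproducible from the recorded seeds.

Known limitations: the NoS criteria inherit the arbitrariness of the 90% /
1% thresholds (they are parameters, not constants); greedy matching can in
principle be below the optimal assignment (bounded in practice, see above);
and the generator's noise model is additive on envelopes rather than
physiological. The statistical comparison of tVAF vs tVAF$_{rec}$ vs
tVAF$_{rand}$ across a cohort (repeated-measures ANOVA or Friedman tests)
is intentionally out of scope: the package emits the tidy per-participant
tables those tests consume.
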