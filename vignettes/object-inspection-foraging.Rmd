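---
title: "Object-inspection foraging: model, solver, and behavioral pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-inspection foraging: model, solver, and behavioral pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchforage)
```

## The scientific problem

Primates respond slowly to low-value targets even when slowness only costs
them reward. During visual search in environments whose richness varies,
this reward-related bias grows: searches lengthen when the target is
unrewarded *and* when the surrounding environment has a high probability of
containing reward, with the extra time spent actively inspecting the
never-rewarded environmental objects. `patchforage` provides the two
halves needed to study this quantitatively:

1. a normative model — an object-inspection extension of the classic
   patch-leaving problem — whose optimal policy shows the same two biases,
   and
2. a behavioral pipeline — saccade detection, gaze-window decomposition,
   and the associated statistics — together with a synthetic session
   generator that stands in for animal data and records its ground truth.

## The foraging model

An agent repeatedly enters a patch drawn uniformly from `n_envs`
environments. Each patch contains `n_objects` objects ranked best to
worst; object `i` of environment `env` yields reward with probability

$$p(env, i) = p_{\max}(env)\, 2^{-\tau(env)(i-1)},$$

and a successful reward has integer size 1..5 drawn from the environment's
size distribution (uniform by default). Foraging has two phases: an
*inspection* phase, in which the agent pays `t_inspect` = 0.5 s per object
to reveal its outcome (best object first), and a *consumption* phase, in
which it consumes any number of the revealed rewards in descending order at
`t_consume` = 1.25 s each, then pays `t_travel` = 8 s to reach a fresh
patch. Rewards decay with the time elapsed since patch entry,
$r(1-k)^{t}$ with `k` = 0.275 per second (half value lost in ~2.2 s), so
dallying is costly.

A state is (environment, number inspected, sorted multiset of revealed
sizes, zeros included); with the defaults this gives
$5\sum_{n=0}^{9}\binom{n+5}{5} = 25{,}025$ states. The value of consuming
the $i$ best revealed rewards from state $s$, normalized over a horizon
`T_max` = 23.75 s (the longest possible patch visit), is

$$V(s,\mathrm{consume}) = \max_i \frac{\sum_{j\le i} r_j (1-k)^{N t_i + j t_c}
  + R_{\mathrm{global}}\,(T_{\max} - N t_i - i t_c - t_t)}{T_{\max}},$$

and the value of inspecting is the transition-probability-weighted value of
the successor states. Because the opportunity cost $R_{\mathrm{global}}$ is
itself a property of the policy, `optimize_policy()` iterates: solve the
dynamic program at the current rate, then re-evaluate the true rate of the
resulting policy by exact forward propagation of state probabilities (no
sampling), until the policy is stable and the rate moves by less than
`tol` (default 1e-6 reward/s), capped at `max_iter` = 40. At the fixed
point the mean fresh-patch value equals the global rate — a renewal-theory
identity the test suite checks to 1e-9 — and the fixed point maximizes
reward per second: for any policy $\pi$,
$E_\pi[R] - R^*E_\pi[T] \le 0$, so $E_\pi[R]/E_\pi[T] \le R^*$.

```{r solve}
cfg <- foraging_config()
res <- optimize_policy(cfg)
res
```

### Decision thresholds

Within each (environment, inspections-so-far) slice, the optimal policy is
exactly separable by the consumption value: it consumes above a threshold
and inspects below it. `extract_thresholds()` verifies this separability
(erroring otherwise) and returns the per-slice curves; thresholds rise with
environment richness — the rich-environment bias — and fall with the
number of objects already inspected. Slices where only one action occurs
are reported as `lower`/`upper` boundary values rather than exact
thresholds. The separability check uses an absolute tolerance of 1e-12 and
considers only reachable states: the state space enumerates every size
multiset, and in configurations whose size distribution has zero-probability
sizes (e.g. the null variant E) the unreachable states carry arbitrary
actions.

### Information-restricted policies

`observable_spec()` restricts what a policy may condition on. Four cases
are conventional: P1 sees only the number inspected, P2 adds the
environment, P3 sees the revealed rewards but not the environment, and P4
sees everything. Restricted policies are solved as a POMDP: states sharing
an observable signature receive a single action and a single
consumption-count plan, chosen to maximize the belief-weighted value, where
the belief is the exact posterior given the signature (a Poisson-binomial
marginalization over which of the first $n$ objects rewarded, times size
likelihoods). Two modelling choices are deliberate:

* *Everything* the restricted policy decides — including how many rewards
  to consume — conditions only on its observables; hidden components are
  marginalized. This is the strict reading of restricted observability and
  it reproduces the reward-blind policies' cap of two inspections.
* The belief's sufficient statistic is the count of nonzero rewards (plus
  sizes where distributions differ), because the state's sorted multiset
  has already discarded the index-to-outcome mapping; the posterior is
  exact given the information the state retains.

Ties between inspecting and consuming resolve to consuming (terminating the
patch); any consistent rule is value-equivalent.

### Model variants

`environment_variants()` packages six worlds that differ in *how*
environments are rich: via the best object's reward probability (A, the
reference), via the decay rate (B), via the reward-size distribution with
decaying (C1) or constant (C2) reward probability, all three combined at a
third of their extent (D), and a null world with identical environments
and a fixed reward size (E). Only variant A's numbers are fully pinned
down; B-D involve free choices, stored as editable presets:

* B: `p_max` = 0.9 everywhere, `tau` = 0.7·2^(2..-2) (richer environments
  decay more slowly, log-spaced).
* C1/C2: size distributions tilted as $w_m \propto e^{\beta(m-3)}$ with
  $\beta$ spanning ±0.8 (C1) or ±1 (C2). For C2 the constant reward
  probability is set to 0.2: with a rank-constant probability the policy's
  no-reward inspection counts saturate at all nine objects for generous
  probabilities, hiding the graded environment effect; 0.2 keeps the probe
  off that ceiling.
* D: each manipulation at one third of its extent around its centre.

In the search-task probe (`search_task_probe()`), outcomes are forced
rather than sampled — the first "target" object reveals a size-3 reward or
nothing and all later objects reveal nothing — because the question is how
the policy behaves *conditional* on those outcomes, and forcing is the
deterministic equivalent of conditioning. The probe always inspects the
first object, mirroring the task where the target is always found. A
mid-range reward of size 3 serves both descriptions of the probe reward
("average size" and "size 3") since it is the median of 1..5.

## The behavioral pipeline

`detect_saccades()` implements velocity-threshold detection: interpolate to
1-ms spacing, differentiate, smooth with a 15-ms moving mean, threshold at
0.025°/ms, and drop movements under 1° of amplitude (within-object
micro-movements). `classify_initial_saccade()` calls a first saccade
"direct" when it lands within 1.5° of the target centre.

The task geometry is fixed: twelve environmental fractals in three
four-fractal rings (6° eccentricity rotated −22.5°, 15° at +22.5°, 17.5°
at −22.5°), four target locations at 12° eccentricity canted at
40/130/220/310°, and a central start position. Analysis runs on a 100×100
grid over a 61°×61° square (bin edge 0.61°); each object's gaze window is
its 77 nearest bins, approximately a 3°-radius disc. At these printed
eccentricities the target windows and their nearest middle-ring fractal
sit ~5.1° apart, so their ~3°-radius windows can share bins; sample
assignment therefore applies a fixed priority — target > start >
environmental > other — with the target first because target fixation
defines trial completion. Invalid (blink) samples count as "other", and
trials with blinks during the initial target foveation should be excluded
from direct-saccade analyses upstream.

`assign_gaze_components()` partitions every millisecond of the search
period (array onset to the start of the successful terminal fixation) into
the four components, which sum to the search duration exactly.
`remaining_search_duration()` measures persistence after a broken direct
fixation, starting at the first sample outside the 1.5° target zone — the
minimum-dwell criterion for "leaving" the target is not specified by
convention, so the first-sample rule is used and documented here.

Statistics follow standard practice: ROC area as the midrank Mann-Whitney
U over $n_a n_b$ (half credit for ties), Spearman correlations with
two-sided permutation p-values computed as
$(1+\#\{|\rho_{perm}|\ge|\rho_{obs}|\})/(n_{perm}+1)$ (never zero),
percentile bootstrap intervals with the trial as the resampling unit (no
session-level clustering — a documented limitation), condition-variance
decomposition over the eight target-value × environment-probability cells
(component percentages may sum above 100 when components covary), an OLS
fit with main effects of p(reward) and reward value, and the reward-rate
ratio (RRR): the achieved post-array reward rate divided by the rate
implied by substituting no-reward-trial behavior (mean correct search
duration and error rate) with reward-trial behavior.

## The synthetic generator

`generate_session()` emulates the task: ~25% single-fractal trials, five
environments with reward probabilities 0/25/50/75/100%, a 5-s search limit
with a 0.75-s hold, 1-2 s inter-trial intervals, and condition repeats
after search errors. Search durations are truncated log-normal — positive
and right-skewed, matching the qualitative shape of real search-duration
distributions; the family itself is a modelling choice — with a negative
target-value effect and a positive environment-probability effect on the
log scale. The default effect sizes (`beta_value` = −0.68,
`beta_prob` = 0.55, `sigma_log` = 0.45) were set so that the pooled
reward/no-reward ROC area is ≈0.73, echoing the discriminability scale of
the search task; this is a calibration aid, not a claim of equivalence.
The non-environmental components (start ≈ 0.18 s, target ≈ 0.12 s,
other ≈ 0.08 s) are roughly condition-independent, so the injected effects
land almost entirely in the environmental-gaze component.

Gaze traces are schematic: smooth knot-interpolated fixational jitter
(SD 0.15°, 50-ms knots, keeping fixational velocity far below the
detection threshold) and constant-velocity saccades of duration
20 + 2·amplitude ms, which always exceed the 0.025°/ms threshold. Only
detectability is modelled, not main-sequence kinematics. Saccadic flight
time is paid out of the "other" budget, and flights can clip gaze windows
en route — exactly as in real data — so recovered component durations
match the ground truth to within a few tens of milliseconds rather than
exactly, while the partition property (components sum to the search
duration) holds exactly by construction. Non-direct trials foveate 2.5°
off the target centre (inside the gaze window, outside the direct zone).

What passing round-trip tests on these sessions shows is that the pipeline
recovers the *structure the generator injects* — effect signs and
approximate magnitudes, direct-saccade fractions, component allocations —
at realistic trial counts. It does not show that the pipeline handles
everything real data contains: no smooth pursuit, no real blink artefacts,
no main-sequence variability, no session-level heterogeneity.

## Numerical choices and problem sizes

* Rate-iteration tolerance 1e-6 reward/s with a 40-iteration cap; the
  reference configuration converges in 4 iterations.
* Threshold separability tolerance 1e-12 (absolute, on normalized rates).
* Brute-force oracles in the tests enumerate all deterministic policies on
  worlds up to 2 environments × 3 objects × binary sizes, and Monte-Carlo
  cross-checks use 20,000 simulated patches compared at three standard
  errors of the ratio estimator.
* Round-trip acceptance testing uses 100 sessions of 2,000 trials
  (trial-table level) and 100 null sessions of 600 trials for p-value
  calibration; gaze-level checks run on smaller sessions since rendering
  millisecond traces dominates runtime.

## Known limitations

* The exact feature sets of the two reward-blind policies are assigned as
  P1 = {n inspected} and P2 = {environment, n inspected}; the convention
  only fixes that neither sees the revealed rewards.
* `evaluate_global_rate()` requires the policy to cover every reachable
  state; it does not attempt repair of partial policies.
* The RRR bootstrap resamples trials, ignoring any session-level
  clustering.
* The generator's single-fractal trials are simplified (no environment
  effect on their durations by default, minimal gaze plans).
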