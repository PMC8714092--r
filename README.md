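# patchforage

Optimal foraging with costly object inspection, and the behavioral
analysis of reward-guided visual search.

## The problem

In instrumental tasks, primates respond slowly to low-value targets even
when slowness only reduces their reward rate. During visual search in
environments of varying richness the bias grows: search durations fall
with the target's reward value but *rise* with the environment's
probability of containing reward, and the extra time goes into actively
inspecting the never-rewarded objects that make up the environment. Is
this strategy irrational, or optimal for a world the laboratory task only
approximates?

`patchforage` addresses the question from both ends:

* **A normative model.** The classic patch-leaving problem is extended so
  that rewards are hidden and probabilistic: an agent must spend
  `t_inspect` seconds per object to reveal its outcome (best object
  first), may then consume any number of the revealed rewards in
  descending order at `t_consume` each, and pays `t_travel` to reach a
  fresh patch. Object `i` of environment `env` rewards with probability
  `p_max(env) · 2^(−τ(env)(i−1))`, reward sizes are 1–5, and value decays
  with delay as `r(1−k)^t` (`k` = 0.275/s, half value in ~2.2 s). The
  optimal policy is found by dynamic programming over all 25,025 states
  together with an iterative fixed point on the global reward rate
  `R_global`, which enters the consumption value as the opportunity cost
  of time. Information-restricted (POMDP) policies — blind to the
  environment and/or the revealed rewards — are solved under exact
  Bayesian beliefs.
* **A behavioral pipeline.** Velocity-threshold saccade detection
  (0.025°/ms on 15-ms-smoothed 1-ms-interpolated traces, 1° amplitude
  floor), gaze-window decomposition of the search period into
  environmental/target/start/other components on a 100×100 grid with
  77-bin object windows, ROC discriminability, permutation-tested Spearman
  correlations, bootstrap CIs, condition-variance decomposition, OLS
  reward-effect fits, and the reward-rate ratio (RRR).
* **A synthetic session generator** that emulates the search task (five
  environments with reward probabilities 0–100%, ~25% single-fractal
  trials, 5-s search limit, condition repeats after errors) with injected,
  recorded effects, for parameter-recovery testing.

## Worked example

```r
library(patchforage)

cfg <- foraging_config()          # 5 environments x 9 objects, reference defaults
res <- optimize_policy(cfg)       # DP + global-reward-rate fixed point
res
#> <solver_result>
#>   observables: n_inspected, env, revealed
#>   r_global = 0.117511 reward/s after 4 iteration(s)
```

The optimal policy is exactly threshold-separable: after one inspection it
consumes only if the consumption value exceeds a per-environment
threshold, and the threshold rises with environment richness — the
rich-environment persistence bias:

```r
subset(extract_thresholds(cfg, res), n_inspected == 1)
#>    env n_inspected threshold  kind
#>      1           1 0.0843540 exact
#>      2           1 0.1052460 exact
#>      3           1 0.1292303 exact
#>      4           1 0.1532147 exact
#>      5           1 0.1771990 exact
```

Probing the policy with search-task-like forced outcomes (first object
reveals a size-3 reward or nothing; all later objects reveal nothing)
reproduces both monkey-like biases — more inspection after a no-reward
target, and more inspection in richer environments, with the steeper
slope on no-reward trials:

```r
xtabs(n_inspected ~ condition + env, search_task_probe(cfg, res))
#>            env
#> condition   1 2 3 4 5
#>   no_reward 2 4 4 5 5
#>   reward    1 1 1 2 2
```

On the behavioral side, a synthetic 2,000-trial session analyzed end to
end recovers the injected structure:

```r
ses <- generate_session(generator_params(), seed = 42)
analyze_trials(ses$trials, n_perm = 2000, seed = 1)
#>           statistic             stratum   estimate       p    n
#>            roc_area reward_vs_no_reward  0.747          NA 1381
#>        spearman_rho              reward  0.290     0.0005   679
#>        spearman_rho           no_reward  0.302     0.0005   702
#>    ols_coef_preward               total  0.280         NA  1381
#>     ols_coef_reward               total -0.349         NA  1381
#>   reward_rate_ratio              search  0.838         NA  1528
```

Search durations discriminate reward from no-reward targets (ROC 0.75),
correlate positively with environment reward probability within both
target values (rho ≈ +0.3, permutation p < 0.001), carry a negative
target-value and positive probability effect in the OLS fit, and the
reward-related bias costs the synthetic subject ~16% of its achievable
reward rate (RRR 0.84 < 1).

See the vignette (`vignettes/object-inspection-foraging.Rmd`) for the
model's equations, the POMDP restriction, the preset model variants, and
every numerical choice.

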