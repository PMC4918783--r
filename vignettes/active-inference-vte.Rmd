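---
title: "Modelling vicarious trial and error with active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vicarious trial and error with active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteforage)
```

## The phenomenon and the model

Rodents at maze junctions sometimes pause and orient toward one arm and then
the other before committing — vicarious trial and error (VTE) — while
hippocampal place cells sweep forward along the candidate paths. VTE is
frequent early in learning, disappears with familiarity, and returns when
reward contingencies change. `vteforage` reproduces this dynamic with a
discrete partially observed Markov decision process solved by active
inference, in which a forward sweep is an explicit *covert action* available
to the planner.

Hidden states factor into a location and a **context** (which arm is baited).
The agent knows the task's contingencies but not the context, which it must
infer from probabilistic cues:

* the baited arm emits the reward cue with probability 0.75 (otherwise the
  neutral cue); non-baited arms emit the neutral cue;
* each real arm has an *imaginary* counterpart. "Visiting" it is covert: the
  animal stays put, pays a small utility cost, and retrieves a mnemonic cue
  that is context-congruent with probability 0.85.

Beliefs are categorical distributions over hidden states, updated by exact
recursive Bayesian filtering: predict through the executed control's
transition matrix, then condition on the observed outcome. For this discrete
family the exact filter is the fixed point of the free-energy minimisation
that defines the scheme, so filtering is both exact and what a converged
variational update would return; the one-step free-energy functional is kept
in the package (`free_energy()`) as a testable oracle of that equivalence.

Policies are fixed-length control sequences (horizon 3 or 4), scored from the
current belief by expected free energy: at each future step the predicted
state distribution is propagated (without conditioning on future outcomes)
and contributes

* **extrinsic value** — the expected log prior preference of predicted
  outcomes, where preferences are the softmax of outcome utilities, and
* **epistemic value** — the expected information gain about hidden states,
  equivalently the mutual information between states and outcomes under the
  predicted joint.

Actions are sampled from the per-step control marginal of the softmax policy
posterior `P(π) ∝ exp(γ Q(π))`, restricted to feasible controls (an absorbing
arm only permits its own control), and the whole policy set is re-scored at
every step, so a plan can be abandoned mid-trial. Between trials the context
posterior is carried over through a volatility kernel: with probability `v`
the context is assumed to have switched, uniformly among the alternatives.
It is this volatility prior that keeps beliefs revisable and lets VTE return
after a reversal.

Two consequences of this arithmetic are worth keeping in mind when reading
results. First, reward sites are absorbing and re-emit their outcome at every
remaining step, so arriving one step later forfeits one expected consumption
— an implicit temporal discount. Second, when the expected value of
committing is negative (an uncertain choice between a +2 and a −2 arm),
spending a step on a cheap covert action is value-*positive* independently of
its information content. Deliberation under uncertainty is therefore driven
by both information gain and the implicit option value of not committing;
both disappear once the context is known, which is exactly the
deliberative-to-habitual transition the model is built to capture.

## Tasks

`build_two_arm_tmaze()` (two contexts, 10 states, 14 policies of length 3:
two direct, four one-sweep, eight two-sweep), `build_three_arm_radial()`
(three contexts, 21 states, 48 policies of length 4 with up to three distinct
ordered sweeps), `build_double_tmaze()` and `build_plentiful_tmaze()` are
validated generative models addressable as `sim1`–`sim4`; `validate_model()`
checks column stochasticity, location-determinism of outcomes, absorbing-state
closure and within-trial context conservation.

The double T-maze deserves its own notes, because several design choices were
genuinely open:

* **Layout.** 11 locations: home (the easy decision point), two costly
  decision points, two shared absorbing final arms, and six imaginary
  locations (two per decision point); 4 contexts crossing which side is open
  with which final arm is rewarded. A context-dependent barrier is encoded in
  the transitions: moving toward the blocked side leaves the animal in place,
  so a blocked path is discovered through a failed move — which is how the
  agent can detect a context change mid-trial.
* **Policy grammar.** Policy counts are not structurally forced here, so the
  set is built from five classes (32 policies, horizon 4): direct plans, one
  easy-point sweep, one costly-point sweep, a *probe* plan (try one side,
  then the other — the natural recovery plan when a path turns out blocked),
  and a probe followed by a costly-point sweep. No policy contains two
  sweeps: one-sweep plans are never pitted against two-sweep plans, and each
  decision point hosts at most one sweep. During development we found that
  allowing easy+costly two-sweep policies lets the sixteen such plans pool
  softmax mass on the step-1 easy sweep and turns the easy decision point
  into a procrastination device, inverting the empirically expected
  costly ≫ easy asymmetry; restricting to single-sweep plans and adding the
  probe classes restores it, and the probe tails are precisely what allows a
  same-trial costly sweep after the trial-21 block.
* **Transit cost.** Home and the costly decision points carry a utility of
  −0.5 per step. The task's defining feature is that a wrong costly choice
  wastes time; without a time cost on transit states, policy tails stranded
  at home score zero and dominate any uncertain commitment, and the agent
  dithers instead of acting. The value (−0.5) sits between the sweep cost and
  the wrong-arm loss.
* **Easy-point cues.** Both easy imaginary locations emit the same
  partition cue (yellow for left-open contexts, black for right-open, 0.85
  reliable): an easy sweep tells the agent which side is open but nothing
  about the final arm, mirroring the limited span of a forward sweep from the
  first junction.

In the plentiful-reward task, preferences are over outcomes, and the reward
cue is shared between the "baited arm" contexts and the "usual reward" arm of
the both-rewarded contexts, so one utility must serve both: `U(red) = c`
(usual reward), `U(dark red) = c + diff` (high reward), wrong-arm neutral
−2. At the default `c = 2`, `diff = 2` the first two contexts are exactly the
±2 T-maze and the high reward is twice the usual one; in the reward-grid
variant, where `c` is swept, the first two contexts scale with it (they lie
more than ten trials before the probed trial and have negligible influence
there).

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `reward_reliability` | P(reward cue at baited arm) | 0.75 | task definition |
| `context_cue_reliability` | P(congruent mnemonic cue) | 0.85 | task definition |
| `gamma` | policy precision (inverse temperature, dimensionless) | 4 (sims 1/2/4), 7 (sim 3), 8 (grid) | calibrated, see below |
| `volatility` | agent's per-trial context-change prior | 0.1 | calibrated |
| `imaginary_cost` | utility per sweep outcome | −0.1 (sims 1/2/4), −0.15 (sim 3, grid) | calibrated; intermediate between the arm utilities |
| `transit_cost` (sim 3) | utility per transit step | −0.5 | see above |
| utilities | reward +2, wrong-arm −2, neutral elsewhere 0 | — | gain/loss coding of the choice |

Precision, volatility and the sweep cost are free parameters of the scheme;
their defaults were calibrated once, by a coarse search, to place each
experiment in its intended regime, and then frozen. A single precision cannot
serve all four experiments: the plentiful-reward task needs a soft enough
softmax for deliberation to be visible at all early on (its four-context
prior includes both-rewarded contexts, which props up direct policies'
extrinsic value), while the reward-grid variant needs a sharp softmax so that
sweeps are genuinely extinguished above the usual-reward threshold rather
than leaking through as selection noise. Treating precision as a
per-experiment constant is consistent with its role as a fixed confidence
parameter rather than a learned quantity. The volatility default (0.1) is of
the order of the true change rate of the schedules (one change per ten
trials).

## What the simulations emulate — and what they do not

The generative process is the generative model with the true context clamped
and scheduled: contingencies are assumed known (no learning of likelihoods or
transitions), transitions are deterministic given the action, and all
stochasticity is in cue emission and in the agent's own action sampling.
Context reversals follow the published schedules (trial 11; trials 11/21;
trials 11/21/31 through the left-left → left-right → right-left → right-right
sequence; trials 10/20/30). The environment never reveals the context except
through sampled cues.

Passing tests on these simulations therefore show that the *scheme* produces
the documented behavioural signatures under its own assumptions. They do not
show anything about real rodent data: there is no trial-to-trial learning of
the model itself, no within-trial time course of a sweep (a sweep is one
discrete step), no neural quantities, and the exact heights of VTE curves
depend on the calibrated parameters — only the ordinal patterns (decline,
reinstatement, costly ≫ easy, extinction under plenty, the grid threshold)
are stable claims.

## Metrics

`compute_metrics()` aggregates per trial across runs: **performance** is the
fraction of runs whose trial *ends* on a reward-cue outcome, which puts its
ceiling at the reward reliability (0.75) — with a normalised-utility variant
(`performance_utility`) for the plentiful task whose two phases have
different ceilings; **uncertainty** is the Shannon entropy of the trial-start
context belief normalised by `ln K`; **vte_fraction** is the fraction of runs
executing at least one covert sweep (split easy/costly where the task tags
decision points); the sweep histogram reports 0/1/2-or-more sweeps; and the
belief heatmap is the mean end-of-trial context posterior. A VTE event is
counted on *executed* actions, not on evaluated policies.

## Numerical choices

Probabilities inside logarithms are floored at 1e−16, which leaves exact
zeros contributing exactly zero to entropy terms; epistemic value is computed
as the state–outcome mutual information through a sparse triplet view of the
likelihood (each state emits at most a few cues), and is clipped at its
theoretical floor of zero; the policy softmax is computed in log space with
the maximum subtracted. Structurally impossible outcomes carry utility 0 —
they shift the preference normaliser uniformly, which cancels across policies
because all policies share one horizon. Run `r` of an experiment is seeded
`base_seed + r`, so experiments are reproducible bit-for-bit and runs are
independent; identical seeds and configuration reproduce identical results.

## Simulation scales

The reference experiments average 1000 runs (10,000 per grid cell for the
reward grid). The test suite exercises the same protocols at 200 runs per
simulation and 60 runs per probed grid cell, sizes at which every asserted
ordinal pattern is stable across seeds; statistical tolerances in the
calibration checks follow the binomial standard error at 10,000 draws
(±2 percentage points).

## Known limitations

* Likelihoods and transitions are assumed known; learning them, and with
  them the emergence of sweeps themselves, is out of scope.
* Policy precision is fixed per experiment; no precision dynamics.
* The reward-grid threshold for sweep extinction falls between a usual
  reward of 1 and 1.5 under this calibration; its exact location trades off
  against the other experiments through the shared cost and precision
  parameters.
* The easy/costly double T-maze models two decision points; deeper mazes
  would need longer horizons and a richer policy grammar.
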