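---
title: "Equitable outreach planning for a digital diabetes program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equitable outreach planning for a digital diabetes program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermab)
```

## The planning problem

A digital type-2-diabetes program supports a cohort of patients through an
app and periodic outreach interventions (for example a coach call). The
program has a monthly intervention capacity `B` that is much smaller than the
cohort size `N`, so each month it must decide *which* patients to contact.
Contacting a patient keeps them engaged and, with a delay, improves their
chance of reaching the clinical target HbA1c < 8; not contacting them risks
permanent dropout. `ermab` casts this as a restless multi-armed bandit: each
patient is an independent Markov decision process that evolves whether or not
it is acted on, and the planner chooses at most `B` arms per month.

Utility-maximizing index policies are known to concentrate resources on the
"most promising" patients, which can systematically starve demographic
groups. The package therefore also implements two *equitable* planners that
allocate the budget across predefined groups before selecting patients within
each group: a maximin (water-filling) rule and a maximum-Nash-welfare rule.

## Patient model

Each patient occupies a state $(s_E, s_C, s_M)$:

* **Engagement** $s_E \in \{\text{Engaged}, \text{Maintenance},
  \text{Dropout}\}$. Engaged means the patient responded to an intervention
  this month; Maintenance means active in the app without responding;
  Dropout is absorbing (the patient has left the program).
* **Clinical** $s_C \in \{\text{HbA1c} \ge 8, \text{HbA1c} < 8\}$, a
  binary discretization of glycated hemoglobin at the program's target
  threshold.
* **Memory** $s_M = [m_0, m_1]$, the engagement states one and two months
  back. Because HbA1c summarizes roughly three months of blood glucose, the
  clinical benefit of engagement acts with a delay: the one-month clinical
  transition conditions on $m_1$, so an intervention response shows up in
  the clinical chain three months later.

The joint space has $3 \times 2 \times 9 = 54$ states, indexed
lexicographically by $(s_E, s_C, m_0, m_1)$ (`enumerate_states()`), and the
joint kernel is the product of three factors (`build_transition_kernel()`):

* **Engagement.** Under an intervention the patient first risks dropout
  with probability `p_I_MtoD`, then responds — moving to Engaged — with
  probability `p_I_EtoE` (from Engaged) or `p_I_MtoE` (from Maintenance),
  and otherwise falls to Maintenance. Under self-care the patient drops out
  with probability `p_U_MtoD` and otherwise moves to Maintenance. Two
  structural choices deserve a note. First, the dropout-then-respond
  composition is the simplest factorization that uses exactly the four named
  engagement parameters while keeping rows stochastic and preserving the
  orderings (response easier from Engaged, dropout rarer under
  intervention). Second, self-care from Engaged reuses the Maintenance
  dropout rate `p_U_MtoD`: Engaged status is *defined* by responding to an
  intervention, so it cannot persist under self-care, and no separate
  self-care rate for Engaged patients exists in the sources the cohort
  tables are built from.
* **Clinical.** From HbA1c ≥ 8 the patient improves with the background
  monthly probability `p_improve_bg`, multiplied by `1 + boost` (capped at
  1) when $m_1$ is Engaged. From HbA1c < 8 the patient relapses with
  `p_relapse_bg` regardless of engagement history — the published summary
  statistics make the healthy state "sticky" (≈0.5% monthly relapse), and
  that is the only reading of the two printed clinical rates consistent
  with stickiness. The boost is applied to improvement only; nothing in the
  underlying statistics supports an engagement effect on relapse.
* **Memory.** Deterministic shift: $m_0' = s_E$, $m_1' = m_0$.

**Rewards.** $R(s) = \alpha\,r_E(s_E) + (1-\alpha)\,r_C(s_C)$ with
$r_E = 1\{s_E \ne \text{Dropout}\}$ and $r_C = 1\{s_C = \text{HbA1c} < 8\}$.
Maintenance counts as engaged for reward purposes: the program's engagement
outcome of record is "still in the program", and the twelve-month engagement
analyses count E and M together. $\alpha$ is the planner's weight on
engagement; all policies default to $\alpha = 0$ (clinical-only).

## Partial observability and beliefs

Engagement (hence memory) is always observable. HbA1c is observed with a
probability that depends on the *next* engagement state: always for Engaged,
with probability `q_obs_maint` for Maintenance, never for Dropout. The
planner therefore works with a belief state
$(s_E, s_M, b, k)$ where $b$ is the probability that the patient currently
has HbA1c < 8 and $k$ counts months since the last observation
(`belief_patient_state()`, `belief_propagate()`).

Beliefs are propagated *exactly* rather than on a discretized grid. The
reachable belief set over a finite horizon is small because an Engaged month
always produces an observation: any observation-free stretch evolves in
Maintenance/Dropout, where the belief follows a single affine map after at
most two history-dependent steps. The planning core enumerates the reachable
belief graph explicitly and reuses it across all charge evaluations.

## Planning

**Finite-horizon DP.** `finite_horizon_dp()` runs backward induction on the
belief MDP with a per-action charge $\lambda$:
$V^t(s) = \max_a \big[-\lambda\,1\{a = I\} + \sum_{s'} P(s'\mid s,a)\,
(R(s') + V^{t+1}(s'))\big]$, with $V^H \equiv 0$. Rewards accrue on the
successor state. This convention makes the final month's state
reward-bearing (what the twelve-month outcome measures) and gives the
Whittle index a clean closed form at the last decision epoch — the index
equals the one-step expected reward gain of acting — which the test suite
exploits as an oracle. The alternative (reward on the pre-decision state)
differs only by the constant $R(s^0)$ and by making the final action
vacuous.

**Whittle index (Opt).** `whittle_index()` finds the charge at which acting
and not acting are equally valuable, by bisection to `1e-4` on a bracket
expanded adaptively from $[-1, 2]$. The advantage $Q_I - Q_U$ is
non-increasing in $\lambda$ on every tested instance; if no sign change is
found in the expanded bracket the nearest endpoint is returned with a
warning. A dropped-out arm's index is exactly 0 (acting changes nothing).
`opt_policy()` acts on the top-`B` indices, breaking ties uniformly at
random from the experiment's policy RNG stream so runs are reproducible.

**Group Lagrangian.** For a group $g$ with per-round budget $b_g$ and $T$
remaining months, `lagrangian_group_value()` computes
$L_g(b_g) = \min_{\lambda \ge 0}\,[\lambda\,b_g\,T + \sum_{n \in g}
V_n^\lambda]$ by golden-section search on $[0, 2]$ to `1e-4`. The minimand
is convex piecewise-linear, and any $\lambda \ge 0$ gives an upper bound on
the exact budget-constrained group value (verified against brute-force
policy enumeration on tiny instances in the tests). Inside the simulator the
allocators instead evaluate $\sum_n V_n^\lambda$ once per group-month on a
fixed 33-point grid (quadratically spaced on $[0, 2]$, dense near 0 where
charges fall) and take the discrete Legendre transform over the grid; this
makes $L_g(b)$ available for every $b$ at once at negligible extra cost and
keeps the upper-bound property, at the price of a slightly looser minimum
than the golden-section op.

**Equitable allocators.** `mmr_allocate()` water-fills: each of the `B`
units goes to the group with the smallest current $L_g(b_g)$, ties to the
lowest group id, groups at their size cap skipped. `mnw_allocate()` greedily
maximizes the marginal increase of $\log(L_g(b_g)/|g|)$ — per-capita values
implement the equalized-groups correction so that a large group is not
favored merely for containing more arms; when any value is non-positive all
values are shifted by a common constant so the smallest becomes `1e-6`
before taking logs. Within a group, `within_group_actions()` acts on the
$b_g$ arms with the largest advantage $Q_I - Q_U$ under the group's
$\lambda^*$; arms with non-positive advantage are skipped and the unused
units lapse — forcing interventions onto arms that cannot benefit (for
example Dropout) would only waste budget. Budgets and charges are re-solved
every month from the current beliefs, matching the monthly decision epoch.

**Baselines.** `baseline_high_risk_random()` intervenes uniformly on
"high-risk" patients — not Dropout, belief of HbA1c < 8 below one half
(under partial observability the current clinical state is only available
as a belief, and Dropout patients are excluded because their clinical state
is unobservable and they cannot respond). `baseline_high_risk_round_robin()`
prioritizes high-risk patients by months since their last intervention.
`no_action` provides the standard-care lower bound.

## The synthetic cohort

`canonical_group_table()` encodes six demographic groups (three age bands ×
two genders) with relative sizes 0.175, 0.15, 0.2, 0.15, 0.125, 0.2 and
means taken from published claims and program statistics: background
improvement 7.5%/month and relapse 0.5%/month with about one percentage
point of spread across groups; self-care dropout near 10%/month with about
four points of spread; engagement boost 25%/50%/75% by age band; response
probabilities 99% (Engaged) and mean 75% (Maintenance); 3% dropout under
intervention; 30% monthly observation probability in Maintenance. Only the
group *means and spreads* are published, so the per-group offsets are chosen
symmetric and evenly spaced — reproducing the stated mean and range without
inventing further structure — and the Maintenance response rate carries the
same offsets as the dropout rate, mirroring the statement that its group
variation follows the dropout statistics. `counterexample_group_table()`
makes group 0 "unmovable" (boost 0.01, response probabilities 0.02): the
stress case in which maximin allocation sinks the whole budget into a group
whose outcomes cannot improve.

`sample_cohort()` gives every patient an individual profile by drawing each
probability parameter from a Normal centred on the group mean with
$\sigma = 0.05$, clipped to $[0, 1]$; the boost multiplier is a derived
effect rather than a probability and stays at the group value. Clipping and
the pairwise restoration of the orderings (`p_I_EtoE >= p_I_MtoE`,
`p_I_MtoD <= p_U_MtoD`) necessarily shift the means of parameters close to a
boundary: most visibly, a Normal(0.005, 0.05) relapse rate clipped at zero
has mean ≈ 0.023, so the jittered cohort relapses faster and plateaus at a
lower healthy fraction than the group means alone would suggest. This is a
direct consequence of the stated jitter model, and the capacity analyses
below inherit it; the test suite therefore checks the simulator's chains on
a σ = 0 cohort where the closed forms are exact. Patients enter in five
equal random waves over months 1–5, all at state (Engaged, HbA1c ≥ 8,
[M, M]) with a collapsed belief of 0, and twelve-month outcomes are read at
each patient's twelfth month after entry, which requires `H >= 17`.

What the generator does *not* emulate: comorbidities, continuous HbA1c,
re-enrollment after dropout, seasonal or secular trends, and correlation
between a patient's parameters (draws are independent). Passing tests
therefore show that the planner behaves correctly *under this model*, not
that the effect sizes transfer to a real program.

## Randomness and reproducibility

Every simulation seed is expanded into named substreams (cohort,
enrollment, transitions, observations, policy tie-breaks), so a
configuration plus seed is bit-reproducible and different policies face
identical cohorts — common random numbers for paired comparisons. Twelve-
month summaries are computed on the true latent states, not beliefs: the
simulation reports actual outcomes, while beliefs are what the planner acts
on.

## Problem sizes used by the checks

The packaged checks run at the full cohort scale (N = 300, H = 18): the
directional equity comparisons use 50 seeds, and `scripts/acceptance.R`
averages its quantitative summaries over 10 seeds per cell across the
budget grid {0, 15, 30, 45, 60, 75, 100, 150} — enough replication that the
Monte-Carlo standard error of a healthy-count mean is a few patients.
Oracle comparisons (exhaustive policy enumeration, closed-form indices) run
on deliberately tiny instances (≤ 2 arms, horizon ≤ 4) where exact
computation is feasible.

## Numerical choices, edge cases, limitations

* Boosted improvement probabilities are capped at 1; kernel construction
  validates every factor probability.
* Bisection/golden-section tolerances are `1e-4` on the charge; reward
  magnitudes are O(1) per month, so this is far below decision-relevant
  differences.
* Ties: group allocation ties break to the lowest group id
  (deterministic); arm-selection ties break uniformly at random from the
  seeded policy stream; the round-robin baseline breaks ties by patient id.
* Degenerate inputs: zero budget returns empty selections everywhere; a
  group with no enrolled arms is excluded from allocation; `months_unobserved`
  caps at the horizon; zero-mean Gini input returns 0 by convention.
* The full budget is available from month 1 even while the cohort is still
  enrolling; unused budget lapses (it is not banked).
* The Lagrangian grid evaluation trades a slightly loose $L_g$ for a large
  constant-factor speedup; allocation decisions compare groups at identical
  grids, so the looseness is shared.
* Known limitations: binary clinical state; a single absorbing dropout
  state with no re-engagement; per-patient parameters are static over the
  horizon; the Whittle policy assumes (but does not verify) indexability —
  the implementation falls back to a bracketed endpoint with a warning on
  non-indexable edges.
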