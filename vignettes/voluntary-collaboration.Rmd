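---
title: "Modeling collaboration under voluntary participation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling collaboration under voluntary participation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volpgg)
```

## The game and the belief-based decision model

`volpgg` studies collaboration as a one-shot threshold public goods game
with an outside individual option. Groups of $n$ members (default $n = 5$)
each hold an endowment of $e$ points (default 10). Group members choose to
cooperate (C, investing the endowment) or defect (D, keeping it); if at
least $q$ members cooperate, every member receives the group reward $R$
(default 30). Under *voluntary* participation a third action is available
before groups form: leave (L), which pays a sure $e + s$ (default
$10 + 10 = 20$) regardless of everyone else. Under *mandatory*
participation, leaving is unavailable. The threshold $q \in \{2, 4, 5\}$
tunes the free-riding temptation: at $q = n$ a player's own defection
guarantees failure, so the game is pure coordination.

A player holds a subjective belief $\gamma \in [0, 1]$ that any given other
member cooperates. Writing $\Gamma_k = \sum_{j=k}^{n-1} \binom{n-1}{j}
\gamma^j (1-\gamma)^{n-1-j}$ for the probability that at least $k$ of the
others cooperate, expected total payoffs are

$$E[\pi \mid C] = R\,\Gamma_{q-1}, \qquad
  E[\pi \mid D] = e + R\,\Gamma_{q}, \qquad
  E[\pi \mid L] = e + s .$$

`expected_payoffs()` implements these; `best_response()` takes the argmax.
Under mandatory play, defection wins in two separate belief regions — *fear*
(low $\gamma$: cooperation looks futile) and *greed* (high $\gamma$: success
looks assured without one's own contribution); `best_response_regions()`
recovers the partition. The probability of being *pivotal* (exactly $q - 1$
others cooperating) is `pivotal_probability()`.

**Tie-breaking.** At exact payoff indifference the best response is taken in
the fixed order C ≻ L ≻ D. Indifference is measure-zero under any continuous
belief distribution, so this convention only pins interval boundaries down
reproducibly; choosing the prosocial action keeps boundary behaviour
conservative with respect to the package's central claims (it never
manufactures defection).

## Population predictions

Population heterogeneity in beliefs is modeled as
$\gamma \sim \mathrm{Beta}(\alpha, \beta)$ (`beta_belief()`, or
`beta_belief_mc()` parameterized by mean $\mu$ and concentration $\nu$ with
$\alpha = \mu\nu$, $\beta = (1-\mu)\nu$). The share choosing action $x$ is
$r_x = \int_0^1 I\{\text{best response is } x \mid \gamma\}\,
\phi(\gamma)\,d\gamma$. Because the best response is piecewise constant,
`action_shares()` evaluates this *analytically*: region boundaries are
found by bisection (absolute tolerance $10^{-10}$ after a 10,001-point
scan) and each region's share is a difference of Beta distribution
functions. Quadrature over the indicator is never needed; Monte-Carlo
integration is retained in the test suite purely as an independent oracle.

Downstream quantities:

* within-group cooperation rate $p_{\mathrm{coop}} = r_C / (r_C + r_D)$
  (`cooperation_rate()`; `NA` when everyone leaves — undefined rates are
  flags, not errors, throughout the package);
* effective cooperation rate under loner externality $\rho$:
  $p_{\mathrm{coop}}(\rho) = r_C / (r_C + r_D + \rho\, r_L)$
  (`effective_cooperation_rate()`). $\rho = 0$ is flexible group formation
  (loners excluded); $\rho = 1$ makes loners equivalent to defectors, as
  when group boundaries are fixed in advance;
* group success rate
  $p_{\mathrm{success}} = \sum_{k=q}^{n} \binom{n}{k}
  p_{\mathrm{coop}}^k (1 - p_{\mathrm{coop}})^{n-k}$
  (`group_success_rate()`);
* normalized efficiency (`expected_efficiency()`): mean expected payoff
  divided by the per-capita payoff of the most efficient feasible group
  (exactly $q$ cooperators), $(qR + (n-q)(e+R))/n$, i.e. $40 - 2q$ points
  under the defaults.

**Efficiency approximation.** Member payoffs are evaluated under the
independent-composition approximation: each opt-in's co-members cooperate
i.i.d. with probability $p_{\mathrm{coop}}$ — the same approximation the
success-rate formula makes. The exact finite-population alternative
(random assignment without replacement) is available through the session
engine and is used as a cross-check in the tests; for realistic population
sizes the two agree to within Monte-Carlo error. Whether one computes
efficiency analytically or from realized random groups is a genuinely open
choice; the analytic route is the default because it is deterministic and
mirrors the treatment of $p_{\mathrm{success}}$.

## Equilibrium analysis

`find_symmetric_equilibria()` searches for self-reproducing beliefs: a
fixed point $\gamma^*$ of the consistency map that sends $\gamma$ to the
within-group cooperation probability implied by best-response play (1 where
the best response is C, 0 where D, undefined where L since no group forms).
The scan uses a 10,001-point grid with bisection refinement to $10^{-8}$.
Because the map is a step function, interior fixed points are indifference
points sustained by mixing; they are reported with a stability annotation
(attracting when the map crosses the diagonal downward). The package's key
equilibrium property: under mandatory play the all-defect point
$\gamma^* = 0$ always survives, while under voluntary play with default
payoffs it is eliminated — a group of defectors earns $e < e + s$, so
pessimists leave rather than defect.

A note on the fixed-point self-consistency check: for *pure* fixed points
the map reproduces $\gamma^*$ exactly, and the tests assert this. For
*mixed* fixed points a discontinuous map cannot literally satisfy
$T(\gamma^*) = \gamma^*$; the meaningful property, and the one tested, is
that $\gamma^*$ lies at exact expected-payoff indifference, where the
set-valued best response contains the mixture.

## When voluntary participation helps — and when it does not

Sweeping $p_{\mathrm{coop}}$ over Beta parameters (`sweep_beta()`, default
grid $\mu \in \{0.05, \dots, 0.95\}$ in steps of 0.05,
$\nu \in \{1, 2, 5, 10, 20\}$ — the grid is this package's choice) shows
that voluntary participation raises the predicted within-group cooperation
rate over most of the grid, and *always* at $q = 5$: there defection is
strictly dominated by leaving, so $r_D = 0$ and $p_{\mathrm{coop}} = 1$
whenever anyone cooperates.

The advantage is not universal, however, and the package deliberately
reports this. At $q = 2$ (and, marginally, at very optimistic beliefs for
$q = 4$) the outside option also filters out *reluctant cooperators* —
players with $E[\pi|D] < E[\pi|C] < e + s$ who cooperate when forced but
prefer to leave when free. When little belief mass lies in the fear region,
removing them lowers $p_{\mathrm{coop}}$: with uniform Beta(1,1) beliefs at
$q = 2$, the model gives 0.290 under mandatory and 0.229 under voluntary
participation ($\Delta = -0.061$; about 30% of the default grid cells at
$q \in \{2, 4\}$ behave this way, worst case $\approx -0.07$). This is a
property of the pure self-selection model with fixed beliefs; the optimism
(belief-updating) mechanism works in the opposite direction and is modeled
separately in the cohort generator.

## The synthetic cohort generator

`generate_cohort()` emulates the within-subject experimental structure so
that every downstream stage is testable without external data: ~30
participants per session (default 191 in 6 sessions), a 2 (regime) × 3
(threshold) design with regime blocks ordered voluntary-first for a random
half of the cohort and thresholds shuffled within block, beliefs elicited
as integer counts of 30 others per action, a confidence rating, and an
action. `generate_externality_cohort()` produces the three-level
$\rho \in \{0, 0.5, 1\}$ design (threshold 4, default 182 participants),
where each participant's decision is evaluated against the effective
cooperation rate implied by their own counts.

Generative structure, and the defaults (all synthetic stand-ins, not
estimates from any dataset):

* latent beliefs per condition are Beta with mean 0.6 and concentration 5
  for the main design — moderate optimism with substantial heterogeneity,
  a typical elicited-belief profile for one-shot social dilemmas. For the
  externality design the means fall with $\rho$ (0.7, 0.5, 0.35) and the
  believed leaver share rises (0.3, 0.55, 0.7): loners weigh more, so
  players expect fewer effective cooperators;
* within-participant stability via a shared latent Gaussian quantile
  (correlation 0.7 across conditions) — individual differences persist
  across conditions, which the change analyses require;
* the mandatory→voluntary *optimism shift*: an additive logit-scale shift
  $\delta = 0.8$ applied to a random half of participants
  (`shift_fraction = 0.5`). This is the generator's handle on the
  belief-updating mechanism; belief formation itself is intentionally not
  modeled;
* actions by softmax over expected payoffs with temperature
  $\lambda = 2$ points; $\lambda = 0$ nests the exact best response. A
  softmax (rather than ε-uniform noise) preserves payoff ordering;
* elicited counts are multinomial draws of 30 from the participant's
  implied action-share expectations (own $\gamma$ for within-group
  cooperativeness, the analytic leaver share of the condition's belief
  distribution for L), so counts carry realistic integer noise;
* confidence ratings are random fill (Beta(5, 2) rescaled), modeled no
  further.

What the generator does *not* emulate: real participants' deviation from
payoff-maximizing play. Under the default moderate-optimism beliefs the
best-response core makes $q = 2$ defection mostly greedy, so default
synthetic cohorts show a *negative* voluntary–mandatory cooperation gap at
$q = 2$ even though human cohorts show a positive one; the generator
reproduces the mechanisms (self-selection of pessimists out of groups,
optimism shifts accompanying cooperative switches, near-complete
cooperation in voluntary $q = 5$ groups, loner shares rising with $\rho$),
not the experimental point estimates. Passing tests therefore certify the
pipeline's correctness on data with known structure, not behavioural
realism at every threshold.

## Session mechanics and incentives

`assign_groups()` implements group formation: opt-ins enter the pool,
each leaver enters independently with probability $\rho$, the pool is
shuffled, groups of $n$ are formed, and the remainder (pool size mod $n$)
goes to the individual option. Remainder selection is uniform at random
(the shuffle), a choice this package makes; remainder participants receive
the individual-option payoff of 20 regardless of their chosen action.
Included leavers occupy seats, contribute nothing, and keep the loner
payoff. `realize_outcomes()` scores groups against $q$ counting only C
actions.

The two experimental incentives: `estimation_bonus()` applies the accuracy
formula $v = 800 - \tfrac{80}{6}\sum_x \lvert e_x/30 - \hat p_x \rvert$ JPY
verbatim, where $\hat p_x$ is the realized action proportion among the
other participants; `points_bonus()` pays $20 \times \pi$ JPY. The accuracy
formula's floor for a single condition is $800 - \tfrac{80}{6}\cdot 2
\approx 773.3$ (the L1 distance between probability vectors is at most 2);
a 0 bonus is reachable only through the points branch. The formula is
implemented as printed; the tension with a nominal 0–800 range is
documented, not resolved.

## The statistical pipeline

* **Belief conversion** (`elicited_belief_to_gamma()`): mandatory counts
  convert as $e_C/30$; voluntary main-design counts as
  $e_C/(e_C + e_D)$ — the cooperativeness of those expected to opt in,
  which is the quantity the decision problem turns on; externality rows as
  $e_C/(e_C + e_D + \rho e_L)$. The voluntary conversion is the natural
  rule but is a package choice: elicitation-to-$\gamma$ mapping for
  voluntary conditions is underdetermined by the experimental description.
* **Bootstrap** (`bootstrap_ci()`): participants are the resampling unit;
  all of a participant's rows move together and each draw counts as a new
  participant. One stream drives all statistics jointly. Percentile 95%
  intervals; resamples where a statistic is undefined are excluded from
  that statistic's percentiles and counted in `n_undefined` (an edge the
  procedure description leaves open). Resampling is numerically invariant
  to row order because participant ids are sorted first.
* **Regressions** (`fit_random_intercept_logit()`): logistic mixed models
  with a participant random intercept via `lme4`, Wald summaries, and
  surfaced convergence/separation diagnostics. Coefficient point values are
  estimation-backend-dependent; the package's guarantees are sign and CI
  recovery on synthetic data, which the tests assert. The primary
  significance convention is a 95% CI excluding 0.
* **ROC comparison** (`roc_compare()`): midrank AUC for predicting
  cooperation among opt-ins from raw beliefs versus pivotal probabilities.
  AUC depends only on ranks, so at $q = n$ — where the pivotal probability
  $\gamma^{n-1}$ is strictly increasing in $\gamma$ — the two AUCs coincide
  exactly; the comparison is informative only at lower thresholds.
* **Change classification** (`belief_action_change()`): pairs each
  participant's regimes at equal threshold; D→C is a positive change,
  C→D negative; belief changes are reported for non-loners.

## Numerical choices and problem sizes

Boundary bisection tolerance $10^{-10}$; equilibrium tolerance $10^{-8}$;
share sums verified to $10^{-9}$. The test suite validates expected payoffs
against brute-force enumeration of all $2^{n-1}$ co-player profiles (to
$10^{-12}$), action shares against Monte-Carlo integration at $10^5$–$10^6$
belief draws (3 standard errors), the session engine against the analytic
success rate at $10^5$ agents, bootstrap coverage at 500 replications of
$B = 250$ on 200 participants (±3 percentage points around the nominal
95%), and regression recovery at 5,000 observations — sizes chosen to make
sampling error small relative to the tolerances while keeping the suite
quick to run.

## Known limitations

* One-shot play only; no repeated-game strategies, no replicator dynamics.
* Other-regarding preferences (fairness, efficiency concerns) are out of
  scope; payoff maximization given beliefs is the behavioural core.
* Belief formation is not modeled; the generator's optimism shift is a
  free knob, not a theory.
* Asymmetric equilibria are not searched; the consistency map is symmetric.
* The generator's defaults reproduce mechanisms and the high-threshold
  pattern, not low-threshold experimental levels (see above).
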