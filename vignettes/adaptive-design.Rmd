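---
title: "The adaptive design: model, allocation rule, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adaptive design: model, allocation rule, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesrar)
```

`bayesrar` implements a Bayesian response-adaptive randomization design for
multi-arm trials with a categorical longitudinal endpoint. This vignette is
the package's own account of the statistical machinery: the outcome model
and its priors, how incomplete patients enter an interim analysis, the
allocation and stopping rules, what the virtual-trial simulator does and
does not emulate, and the numerical and design choices made where more than
one defensible option existed.

## Outcome model

Each patient is assessed at weeks 4, 8 and 12 and classified into exactly
one of three categories: `quit` (off study drug, for lack of efficacy or
side effects), `eff` (on drug, pain reduced by at least 50% from baseline)
or `noeff` (on drug, smaller reduction). Two modeling commitments follow
from the clinical setting:

* **The 50% boundary is inclusive.** A follow-up score of exactly half of
  baseline counts as efficacious. `classify_outcome()` treats the scores as
  real numbers and is invariant to rescaling the pain instrument.
* **Quitting is absorbing.** Once a patient quits, all later visits are
  `quit`. `validate_records()` treats a violation as a hard error, while a
  *gap* (a later visit entered before an earlier one) is only a warning:
  multisite data entry is asynchronous and late entries are queried, not
  rejected.

The primary endpoint is the week-12 category. For arm $a$ it is multinomial
with probabilities $\theta_a = (\theta_{a1}, \theta_{a2}, \theta_{a3})$
(quit, eff, noeff) under a Dirichlet$(1/3, 1/3, 1/3)$ prior — uniform over
the simplex in total prior mass 1, so 80 burn-in patients dominate it
immediately. Each arm is scored by the utility
$$U_a = w\,\theta_{a2} + (1 - \theta_{a1}), \qquad w = 0.75,$$
a clinician-elicited trade-off between efficacy and tolerability: an arm
that keeps everyone on drug and helps them all scores $1.75$; an arm
everyone abandons scores $0$. The weight $w$ is configurable
(`utility_weight`) with the elicited default.

## Interim analyses with incomplete patients

At an interim analysis, patients divide into those with a final (week-12)
outcome, those with only interim visits, and those with no post-baseline
visit yet. The last group is excluded — it carries no outcome information.
The middle group enters through conditional transition models: for each arm
and each interim week, two Dirichlet–multinomial models predict the
week-12 category given an on-drug interim outcome, with priors

* Dirichlet$(1, 7, 2)$ given interim efficacy (a priori 10% quit, 70%
  efficacious, 20% not at week 12), and
* Dirichlet$(1, 2, 7)$ given interim no-efficacy,

each carrying a prior sample size of 10 — weakly informative, updated by
every patient observed on drug at that interim visit *and* at week 12.
Patients who quit at an interim need no model: their final category is
`quit` with certainty.

`posterior_summary()` then uses **multiple imputation**, with
$m$ = `m_imputations` (default 20) completions. Each completion imputes
every missing final outcome (a Dirichlet draw from the matching transition
model, then a category draw), applies the conjugate update, and draws
`n_draws`$/m$ probability triples per arm; utility draws are pooled across
completions. Three choices here were genuinely open:

* *Imputation scheme.* A full joint sampler over missing outcomes and
  $\theta$ would also be defensible; multiple imputation with pooled draws
  is simpler, embarrassingly parallel, and propagates imputation
  uncertainty into the posterior variance (the pooled variance includes the
  between-completion component). With zero incomplete patients every
  completion is identical and the summary is invariant to $m$.
* *Conditioning visit.* When weeks 4 and 8 are both observed on drug, the
  week-8 model is used — the latest information dominates.
* *Eligibility.* Patients with no observed visit are excluded rather than
  entered as prior-only pseudo-observations; `n_enrolled` therefore counts
  analyzable patients, and it is this $n_a$ that enters the allocation
  rule below.

From the pooled draws the summary reports, per arm: $P_a^{\max}$ (the
fraction of draw indices at which the arm attains the maximal utility, with
exact ties split uniformly at random), the posterior mean of $U_a$, and the
posterior variance $V(U_a)$. Closed-form Dirichlet moments of $U_a$ and a
dense grid integration of the two-arm $P(U_1 > U_2)$ serve as independent
oracles in the test suite.

## Allocation and stopping rules

The randomization vector is proportional to the information measure
$$I_a = \sqrt{P_a^{\max}\, V(U_a) / (n_a + 1)},$$
zeroed on loser arms and normalized. The $1/(n_a+1)$ factor makes the rule
*information-seeking*: among arms with equal posterior standing, the one
with the higher standard error (fewer patients) receives more. Decision
rules, both read literally as inclusive comparisons:

* **Success** when the leading arm's $P_a^{\max} \ge 0.925$, evaluated at
  interims and at end of trial;
* **Loser** when an arm's $P_a^{\max} \le 0.01$; loser status is permanent
  and the arm's allocation probability is exactly 0 thereafter.

If every open arm has zero information (degenerate posteriors) the open
arms share equal probability; if every arm is a loser the allocation is
undefined and the package raises an explicit error rather than guessing —
the same policy as for an exhausted allocation table.

## Allocation-table lifecycle

The initial table has `burn_in_n` = 80 slots, exactly balanced (20 per arm)
in uniformly random order, plus `burn_in_spare` = 20 buffer slots. The
buffer keeps sites enrolling while an adapted table is prepared; the
composition of the buffer is not dictated by the design, and `bayesrar`
balances it (5 per arm) to preserve the burn-in's equal-allocation intent.
Each adaptation deletes all unassigned slots and appends `block_size`
(default 100) new slots drawn *independently* per slot with probabilities
$q$ — sampled, not forced to exact proportions, matching how a sampling
function generates such tables. Assigned slots are never touched and slot
numbering continues across adaptations, so an audit can reconstruct the
full history. Patients take the first unassigned slot (`assign_next()`),
optionally within a stratum label; stratification defaults off.

## The virtual-trial simulator

`run_trial()` wires the engine to a generative truth (`scenario_truth()`):
per arm, a week-4 category triple and conditional next-visit triples given
an on-drug efficacious / non-efficacious state, with quit absorbing and the
same transition triples reused for the 8-to-12-week step unless overridden.
The implied 12-week marginal is available in closed form
(`twelve_week_marginal()`) and anchors the generator's tests. Simulated
pain scores are synthesized to be consistent with each category so records
round-trip through the classifier.

Simulation mechanics, with the reasoning behind each choice:

* **Accrual** is deterministic at `accrual_rate` patients/week (default 4,
  i.e. 400 patients in roughly two years across ~40 sites), with a Poisson
  arrival option. The rate is a scenario input, not an estimate.
* **Interim clock**: the first interim fires at the calendar week of the
  80th enrollment and repeats every 13 weeks, anchored there. Each interim
  sees exactly the data a same-day extract would contain: a week-$w$ visit
  is visible only if `enrollment_week` $+ w \le$ analysis week
  (`mask_records()`).
* **Table swap** is instantaneous by default; `swap_lag_weeks` delays the
  adapted table's activation, with in-between patients drawing from the old
  table — the situation the 20-slot buffer exists for.
* **End of trial**: if no early stop occurs, enrollment caps at `max_n` =
  400, every patient is followed to week 12, and the success rule is
  applied once more on complete data (no imputation needed). Interim
  analyses scheduled after enrollment completes are subsumed by this final
  full-data analysis.

`operating_characteristics()` aggregates replicate trials into winner-rate
(type I error under a null, power under an effect scenario) with its
Monte-Carlo standard error, early-stop rate, sample-size and duration
moments, per-arm allocation shares, and loser rates.

### The null scenario

No canonical null rates exist for this population, so the package ships an
explicit assumption (`null_scenario()`): week-4 probabilities
$(0.30, 0.25, 0.45)$ for quit/eff/noeff in all four arms, and transition
triples equal to the elicited conditional prior means, $(0.1, 0.7, 0.2)$
after an efficacious visit and $(0.1, 0.2, 0.7)$ after a non-efficacious
one. Choosing the prior means makes the generative process exactly the one
the design's longitudinal model is calibrated to, so the null measures the
stopping rules rather than prior-data conflict. Under this null the
acceptance script estimates a winner-declaration rate of about 5–7% over
500 replicates — consistent with the design's intended ~5% type I error.

### What the generator does not emulate

Synthetic patients have no site effects, no consent refusal, no missed
visits other than drug-quit, no data-entry lag (beyond the optional swap
lag) and no measurement error in the pain scores. Passing tests therefore
demonstrate the *design engine's* correctness and its operating
characteristics under clean longitudinal data — not robustness to the
messiness of real multisite capture.

## Numerical choices

* `n_draws` = 10,000 utility draws per summary (Monte-Carlo SE on
  $P_a^{\max}$ about 0.005 near 0.5, 0.003 near 0.925), split over
  $m$ = 20 completions; oracle-comparison tests raise this to 100,000.
* Ties in the per-draw argmax are split uniformly at random; they have
  probability zero for continuous posteriors but matter for degenerate
  concentrations.
* Utility inputs are checked against the simplex with tolerance
  $|\Sigma\theta - 1| \le 10^{-9}$.
* Dirichlet draws use normalized gamma variates; every stochastic function
  takes an explicit seed, summaries record the seed used, and identical
  inputs plus seeds reproduce byte-identical tables, reports and manifests
  (manifests timestamp the wall clock; the timestamp is an explicit
  argument so archival reruns can be reproduced exactly).
* Test and acceptance problem sizes: 500 replicate null trials for the
  type I error estimate (Monte-Carlo SE about 1 percentage point), 40–60
  replicates for the qualitative power/allocation properties, 100,000-draw
  oracle comparisons. These sizes were chosen so the whole suite documents
  the design's behavior at desk scale.

## Known limitations

* The conditional transition models are per-arm and per-visit but share no
  strength across arms; with very uneven allocation the lagging arms'
  models stay close to their priors.
* The utility's posterior variance drives exploration, so the allocation
  rule is deliberately conservative: even with a clearly best arm, its
  mean allocation share across a trial tends to sit well below what a
  greedy (probability-proportional) rule would give, because the burn-in
  allocates equally and $1/(n_a+1)$ keeps pulling allocation toward
  under-sampled competitors until they are formally declared losers.
* No covariate adjustment, site stratification of the model, or
  frequentist interim testing is provided; these are outside the design.
* All-arms-loser configurations and exhausted tables raise errors by
  design; callers orchestrating a real trial must decide the operational
  response (the design itself does not define one).
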