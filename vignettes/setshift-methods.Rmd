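---
title: "Simulating and scoring the attentional set-shifting task"
author: "setshiftr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring the attentional set-shifting task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setshiftr)
```

## The task

The attentional set-shifting task (ASST) presents a rat with two digging
cups that differ along two dimensions — odor and digging medium — only one
of which predicts the food reward. Seven stages run in fixed order: a
simple discrimination (SD, one dimension only), a compound discrimination
(CD, the irrelevant dimension is introduced), its reversal (CDR), an
intradimensional shift to fresh exemplars (ID) and its reversal (IDR), the
extradimensional shift (ED, fresh exemplars *and* the previously
irrelevant dimension becomes relevant), and its reversal (EDR). Each stage
runs until six consecutive correct trials. A subject that has formed an
*attentional set* — a learned bias to the relevant dimension — solves ID
faster than CD and pays a cost at ED; that asymmetry is the task's
headline measure of cognitive flexibility.

Schedules are counterbalanced exactly as the paradigm prescribes: three
exemplar pairs rotate over the three stage blocks by a cyclic latin square
(`latin_square_assignment()`); half of the subjects shift odor-to-medium
(series 1), half medium-to-odor (series 2); within a stage the two
cross-pairings of relevant and irrelevant exemplars alternate
pseudorandomly with no more than two consecutive repeats, and the baited
side obeys the same run-length rule independently. `validate_schedule()`
re-checks every one of these contracts on any trial table.

## Scoring

`trials_to_criterion()` returns the index of the trial completing the
first run of six correct responses; errors and mean first-dig latency are
totalled over trials 1..T. Correctness is always defined by the first dig,
exploratory trials (1–4) included — an exploratory error counts and breaks
a correct run, it just does not terminate the trial for the animal.

`classify_errors()` implements the block-of-four taxonomy. Each error is
first tagged old-rule-consistent or not; trials are then partitioned into
consecutive blocks of four from trial 1 (the last block may be short).
While the subject is still in the perseveration phase, a block with three
or more errors of any type marks its old-rule-consistent errors
*perseverative*; the first block with two or fewer errors switches the
phase, and that block's and all later old-rule-consistent errors are
*regressive*; errors consistent with no previously rewarded rule are
*never-reinforced*. Reading "all subsequent" as including the triggering
block is a deliberate choice: a calm block is itself evidence that
disengagement has begun. Because a short terminal block can never reach
three errors, a two-trial tail can never be perseverative.

Old-rule consistency is not defined by the source procedure for a
two-choice compound task, so the package fixes it by stage role:

* **Reversals (CDR/IDR/EDR)** — every error chooses the previously correct
  exemplar, so all errors are old-rule-consistent and never-reinforced is
  structurally zero.
* **Acquisitions (SD/CD/ID)** — no previously rewarded competing rule
  exists; every error is never-reinforced.
* **ED** — all exemplars are new, so the old rule is anchored: the
  previous-dimension exemplar contained in the cup chosen on the stage's
  first error becomes the anchor, and later errors are old-rule-consistent
  iff their cup contains it. This keeps the intended meaning (following
  the old dimension) while being deterministic and testable.

A brute-force re-implementation of these three paragraphs lives in the
test helpers and agrees with `classify_errors()` on every one of thousands
of random sequences.

## The synthetic agent

No behavioral model is inherited from the source procedure; the package's
generator is its own design, chosen as the simplest learner that produces
the four phenomena the task is about: set formation, perseveration,
lapse-driven regression, and impulsive short latencies.

The agent holds a value $V_e \in [0,1]$ for every exemplar (0.5 =
uninformative) and attention weights $w_{odor} + w_{medium} = 1$.

**Choice.** With probability `lapse` the response is uniformly random.
Otherwise the agent attends a single dimension — odor with probability
$w_{odor}$ — and chooses between the cups by a softmax with inverse
temperature $\beta$ over the attended dimension's exemplar values. The
marginal choice probability is therefore
$\lambda/2 + (1-\lambda)\sum_d w_d\,\sigma(\beta\,\Delta V_d)$.
Attending the irrelevant dimension is close to a coin flip, so dimensional
attention — not exemplar knowledge — is what separates the shift stages.
An additive attention-weighted cup score was tried first and rejected: a
misallocated attention weight barely changes choice once any value
difference exists, so the CD and ED costs (and with them the set-formation
contrasts) collapse to a trial or two.

**Learning.** The chosen cup's exemplar values move toward the outcome by
`learning_rate`. Attention drifts toward the dimension whose on-offer
exemplar pair is better differentiated, $|V_{chosen} - V_{unchosen}|$,
with step $0.4\,(1-\text{perseveration})$ scaled by the differentiation
margin. The margin grading matters: the irrelevant dimension's values
wobble around the overall reward rate, and an ungraded step lets that
noise yank attention back and forth. `perseveration` is the inertia of
this re-allocation — the mechanism of perseverative responding after a
rule change — and the spontaneously hypertensive preset is nearly inert
(0.99) while controls re-allocate readily (0.73).

**Stage transitions.** Belief is never reset (carry-over is what makes
reversals and shifts hard), but two things happen at a stage boundary:
learned values relax toward 0.5 by `stage_forgetting` (memory decay across
the inter-stage interval — without it the compound discrimination would be
trivially solved by values carried from SD, and no ID-vs-CD contrast could
exist), and a dimension appearing for the *first time* captures attention
(`novelty_attention` sets a floor on its weight). New exemplars within
familiar dimensions do not capture attention, which is precisely why a
formed set survives the ID transition but handicaps the agent at CD and
ED.

**Latency.** First-dig latency is lognormal:
$\log t \sim N(\mu - \delta(s-1) + [\text{novel}]\log g,\ \sigma)$ with
per-stage decline $\delta$ and a novelty gain $g$ in stages introducing
new exemplars (SD, CD, ID, ED) — reproducing both the gradual decline
across the session and the elevation at novel stages.

### Presets and calibration

| parameter | SHR | WKY | SD | what it encodes |
|---|---|---|---|---|
| learning_rate | 0.18 | 0.55 | 0.55 | slow value learning in the ADHD model |
| perseveration | 0.99 | 0.73 | 0.73 | attentional rigidity |
| lapse | 0.16 | 0.008 | 0.008 | impulsive/random responding |
| inverse_temperature | 3.5 | 12 | 12 | choice determinism |
| novelty_attention | 0.55 | 0.97 | 0.97 | capture by a brand-new dimension |
| latency_mu (log s) | 2.71 | 3.82 | 3.26 | response speed |

WKY and SD share the learning profile and differ only in speed — the two
control strains are behaviorally indistinguishable on this task, and the
package keeps them so. `latency_mu`, `stage_decay` (0.08/stage) and
`novelty_latency_gain` (1.35) are calibrated so an 8-subject cohort's
grand-mean latency over all trials lands on the published strain means
(≈ 14.7, 46.4, 26.9 s); the behavioral parameters are calibrated so that
controls show ID &lt; CD and ID &lt; ED (paired t, p &lt; .05) in ≥ 95% of
8-subject cohorts while the SHR preset's ID-vs-ED comparison rejects at
roughly the nominal rate, and so that SHR cohorts make more trials,
more perseverative and more regressive errors at every stage. These are
the recovery properties the generator exists to provide; they are asserted
at full strength in `tests/testthat/test-acceptance.R` and the presets are
not meant to be tuned per analysis.

Methylphenidate is a static parameter transform (`apply_treatment()`): no
pharmacokinetics, just the after-effect of a fixed dosing regimen. Both
doses raise `latency_mu` and lower `lapse`; the 2.5 mg/kg dose releases
perseveration strongly (−0.55) while 5 mg/kg barely does (−0.08) — the
inverted-U by which the lower dose restores set-shifting and the higher
dose mainly slows responding. Whether the latency increase reflects
reduced impulsivity or sedation is deliberately left open; the transform
only commits to the observable profile.

### What the generator does and does not emulate

It reproduces the *statistical structure* of the published strain and
treatment profiles: latency orderings and magnitudes, trials-to-criterion
orderings, set-formation contrasts, error-subtype patterns, and the
decline/novelty shape of latency. It does not model animals' physiology
(blood pressure, hunger state, circadian phase), habituation (agents start
naive but task-competent), within-session drug dynamics, or refusal
behavior (a `refuse_prob` hook exists, default 0). Passing recovery tests
therefore validates the pipeline's algorithms and power characteristics on
data with the right structure — not any claim about real rat neurobiology.

## The statistical battery

`mixed_rm_anova()` computes the balanced two-way mixed design (one
between-subjects factor, one within-subjects factor) by direct
sum-of-squares decomposition; the partition is asserted against the total
to 1e-8 in tests, and the F table, epsilons and Mauchly test are verified
against an independent multivariate-model implementation (`car::Anova`) to
1e-6. Sphericity handling follows the conventional recipe: Mauchly's test
at α = .05 gates any correction; when violated, Greenhouse–Geisser scaling
is used for large violations (ε_GG &lt; .75) and Huynh–Feldt (capped at 1)
for small ones. The Huynh–Feldt value uses the error-df form
$\tilde\varepsilon = ((f+1)(k-1)\hat\varepsilon - 2)/((k-1)(f -
(k-1)\hat\varepsilon))$ with $f = N - g$, which reduces to the classic
formula for a single group. Unbalanced designs are rejected outright —
the experiments this battery serves are balanced by design, and silent
Type-III guesswork helps nobody.

Post-hoc stage comparisons are one-way ANOVAs with Fisher's LSD (pairwise
t on the pooled error term, unadjusted — that is what LSD is; a `holm`
switch exists for users who want protection). Set-formation comparisons
are two-sided paired t-tests (CD vs ID, ID vs ED) and the SD-vs-ED
association is a Pearson correlation. All tests are two-sided.

## Numerical and design choices

* **Determinism.** Every stochastic entry point takes a seed;
  `simulate_cohort()` derives per-subject seeds from the master seed, so
  cohorts are byte-reproducible and every output file records the seed and
  a config hash.
* **Run-length generation** uses a per-trial feasibility state machine
  (forced alternation after two repeats) rather than rejection sampling —
  with two symbols a feasible extension always exists, and the guard for
  the impossible case remains.
* **max_trials_per_stage** defaults to 150: no cap is inherent to the
  procedure, but an unbounded session is untestable; capped stages are
  flagged incomplete and later stages still run.
* **Latency aggregation**: the per-strain "mean latency" averages over all
  trials (not over stage means); with very unequal stage lengths the two
  differ, and trial-weighting matches how the per-trial record is kept.
* **Ties** in the attention drift (equal differentiation in both
  dimensions) leave attention unchanged; degenerate statistical inputs
  (zero variance, &lt; 3 within levels, &lt; 2 per group) raise errors
  rather than returning NaNs, except the 2-level sphericity case which
  legitimately returns ε = 1 with a flag.
* **Problem sizes in tests**: the recovery properties are asserted with
  200 replicate cohorts per preset, the ANOVA type-I rate with 2,000 null
  simulations, the classifier equivalence with 1,000 random sequences, and
  the schedule constraints with 10,000 generated stages — large enough for
  tight binomial intervals while keeping the suite comfortably fast.

## Limitations

The agent is a minimal ordinal-structure generator, not a fitted cognitive
model: its parameters are calibrated to group-level summary statistics,
and no claim is made that individual simulated trial sequences are
distributionally indistinguishable from real rats (real data show
autocorrelated motivation drifts, position biases and session-termination
behavior the generator omits). The ED old-rule anchor is one principled
resolution of an under-specified scoring rule; alternative anchors would
reclassify a small number of ED errors between the perseverative and
never-reinforced bins. The statistics module covers exactly the battery
this task family uses — it is not a general ANOVA replacement.
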