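---
title: "Measuring subjective values of emotion-regulation strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subjective values of emotion-regulation strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadsv)
```

## The measurement problem

People differ in which emotion-regulation (ER) strategy — distraction,
distancing, or expressive suppression — they find effortful and which they
find useful, so there is no objective difficulty ordering that a classic
cognitive-effort discounting design could anchor on.  The Cognitive and
Affective Discounting (CAD) paradigm solves this by first letting the
decision-maker reveal, for each of the three strategy pairings, which
strategy they prefer at equal money ("1 € for A or 1 € for B", three
presentations, majority wins).  The winner becomes the *flexible* strategy
and starts at 1 €; the loser is anchored at a *fixed* 2 €.  Six consecutive
choices follow.  After each of the first five, the flexible offer is lowered
(if chosen) or raised (if the 2 € option was chosen) by a halving step:
0.50, 0.25, 0.125, 0.0625, 0.03125 €.  The staircase is therefore a bisection
search that brackets the decision-maker's indifference point $m^\*$ — the
flexible amount at which both options are equally attractive.

The subjective value (SV) of the fixed strategy is the normalized
indifference amount: after the sixth (logged) choice, 0.02 € is subtracted
from the last displayed flexible value if the flexible strategy was chosen
again, or added if the fixed strategy was chosen, and the result is divided
by 2 €.  The flexible strategy's SV is set to 1.  Per-strategy SVs are the
mean over the two pairings each strategy appears in, so a consistent
decision-maker has exactly one strategy at SV 1 and the attainable range per
pairing is $[0.005, 0.995]$.

## Numerical contract of the titration

Two printed endpoints pin the arithmetic down: a chooser who always takes
the fixed 2 € ends with the flexible strategy displayed at 1.97 €, and a
chooser who always keeps the flexible strategy ends at 0.03 €.  Summing
*rounded* adjustments cannot produce these endpoints (it gives 1.96 or
1.99), so the engine keeps the internal offer exact — every value is a
multiple of $2^{-5}$ €, which binary floating point represents without
error — and rounds only the *displayed* value, half away from zero, to two
decimals ($1.96875 \to 1.97$, $0.03125 \to 0.03$, $1.875 \to 1.88$).  SV
arithmetic operates on the displayed value in integer cents,
$(100\,v \pm 2)/200$, so the published minimum of 0.005 is exact.

Tie-breaks are deterministic and documented: at an exact utility tie the
agent keeps the flexible (lower-priced) option; at equal money the
canonically (alphabetically) first strategy wins.  Pair order and side
assignment come from one seeded generator per session, and a session replays
bit-exactly from `(agent, seed)`.

Because the staircase is a five-step bisection plus the 0.02 € analysis
adjustment, the per-pairing SV can deviate from $m^\*/2$ by at most 0.03;
the test suite verifies this bound exhaustively over every cent on
$(0, 2)$.

## Simulated decision agents

An agent values an offer as *displayed money + strategy utility* (euro
scale).  With inverse temperature $\beta$ the probability of choosing the
left option is $\mathrm{logit}^{-1}(\beta\,\Delta)$ where $\Delta$ is the
value difference; $\beta = \infty$ gives the deterministic argmax and
$\beta = 0$ a fair coin.  A lapse rate $\lambda$ mixes in a uniform random
choice with probability $\lambda$, applied as an independent mixture after
the logistic rule — the usual psychometric convention.  For a deterministic
agent the indifference point against the 2 € anchor is
$m^\* = 2 + u_\text{fixed} - u_\text{flexible}$, and `expected_sv()` gives
the closed-loop prediction of the aggregated SVs by running the staircase
arithmetic analytically.  A preference-matrix parametrization
(`cyclic_agent()`) produces intransitive choosers, whose profiles contain
no SV of 1 — the "inconsistent response pattern" the paradigm can reveal.

## The synthetic study generator

`generate_study()` emulates the structure the downstream statistics assume:
120 participants, five blocks (neutral viewing, negative viewing, three
regulation strategies) of 20 trials, retrospective block ratings of
arousal, effort and (for regulation blocks) utility, trial-level corrugator
and levator EMG summaries, questionnaire scores, and a final strategy
choice.  Key choices:

* **Slider scale.** The original slider range is not stated; condition
  means reach ~229, so ratings live on a continuous 0–300 scale
  (configurable).  Default means/SDs are the published condition values.
* **Truncation by resampling.** Out-of-range draws are redrawn, not
  clipped.  Because resampling shifts the mean, the generator solves for
  the pre-truncation location (integrating the truncated-normal mean over
  the subject-effect distribution) so that realized cohort means match the
  configured targets.
* **Subject effects.** Each rating dimension splits its variance between a
  subject level and a block level (`rating_subject_share`, default 0.5).
* **SV structure.** Per-participant SV targets for the two non-preferred
  strategies follow an explicit random-intercept model on the SV scale:
  $t_{ps} = \mu + b_p + w^\top x^{c}_{ps} + e_{ps}$, with $x^c$ the
  within-participant-centered ratings and EMG block means, and weights
  defaulting to the published per-unit associations (effort negative,
  utility positive, corrugator positive, arousal ~0).  The targets are
  inverted to agent utilities ($u_1 - u_2 = 4(1 - t_2)$,
  $u_1 + u_2 - 2u_3 = 4(1 - t_3)$, clamped to the representable staircase
  range) and every agent is run through the full titration engine — the
  study table carries the engine-produced SVs, never the targets, so there
  is no shortcut path around the paradigm.
* **Subject-intercept SD.** The default 0.146 was derived by simulating
  the generator: because the preferred strategy is structurally pinned at
  SV 1 and the staircase quantizes, the realized subject share of
  trial-level SV variance is smaller than the raw $\tau^2$ share; 0.146
  makes it average the configured 0.19.
* **Choice agreement.** The sampled actual choice equals the predicted
  (highest-SV) strategy with probability 0.8 by default — a rate that
  produces a predicted-vs-actual association of the magnitude typical for
  this paradigm; the raw agreement rate itself is not published.

What the generator does *not* emulate: real normative picture ratings
(the set partitioner works on synthetic valence/arousal draws), response
times, serial dependencies across trials, or trait/state SV dynamics.
Passing recovery tests therefore shows that the pipeline recovers the
planted structure under Gaussian block/trial noise — not that real data
meet these assumptions.

## Stimulus-set partitioning

`partition_stimuli()` splits 100 rated pictures into five sets of 20 with
comparable mean valence and arousal, minimizing the summed variance of the
set means with an evolutionary search: permutation encoding, tournament
selection (size 3), swap mutation (one guaranteed swap plus a geometric
number of extras), and elitism (2), which makes the best objective
non-increasing across generations.  Defaults (population 60, 150
generations) match set mean valence within 0.1 rating units on synthetic
norms.

## Facial EMG preprocessing

The chain is: 20 Hz high-pass and 300 Hz low-pass Butterworth filters
(order 8), a 50 Hz notch, full-wave rectification, integration, per-trial
averaging over the 6 s picture window, baseline correction by the mean of
the 2 s pre-onset window, and decimation of the processed trace to 100 Hz.
The filter family and phase handling are not specified in the measurement
protocol, so the package uses zero-phase forward–backward application and a
second-order IIR notch with quality factor 30; "integration" is a 100 ms
moving average of the rectified signal (configurable).  The order of
operations — filter, rectify, smooth, window averages, baseline subtraction
— makes the corrected pre-onset mean exactly zero by construction.  Raw and
processed data are distinct types; re-processing a processed table is
rejected.

The synthetic EMG generator drives a band-limited Gaussian noise carrier
(unit SD) with a per-sample amplitude envelope; since the rectified mean of
Gaussian noise of SD $\sigma$ is $\sigma\sqrt{2/\pi}$, condition amplitude
deltas are scaled by $\sqrt{\pi/2}$ so that recovered baseline-corrected
activities equal the configured deltas in mV.  One known bias: the sharp
burst edges interact with the high-pass filter, depressing 6 s window means
by under 1 %; the closed-form recovery test uses a carrier band away from
the filter edges (80–180 Hz) and a short smoothing window to isolate the
closed form.

## Statistical pipeline

* **Within-cluster centering** subtracts each participant's own mean from
  level-1 predictors (exactly, idempotently) before mixed-model fitting.
* **The SV multilevel model** is a random-intercept model fitted by REML
  (`lmerTest`), `sv ~ effort + arousal + utility + corrugator + levator +
  (1 | subject)`, with Satterthwaite degrees of freedom (the reported
  fractional dfs imply such an approximation; the method is recorded in the
  output).  Level-2 covariates (self-control, NFC) can be appended, grand-
  mean centered.  The intraclass correlation comes from the intercept-only
  model; marginal and conditional $R^2$ follow the fixed/random variance
  decomposition, and the local effect size is
  $f^2 = (R^2_{full} - R^2_{reduced})/(1 - R^2_{full})$ on the *marginal*
  $R^2$ (the raw $\Delta R^2$ is reported alongside, since the original
  computation could have used either).
* **Granularity.** The reported residual df (~5,619) implies trial-level
  rows with block ratings broadcast to trials; that is the default, and it
  is what the recovery checks (coefficient signs, ICC target) use.  Note
  that broadcasting repeats each rating 20 times, so null-hypothesis
  t-tests at trial level are anti-conservative (pseudoreplication); the
  condition-level mode (`collapse_to_condition_level()`, 3 rows per
  participant) is the calibrated granularity and is what the package's
  null-simulation tests use.
* **rmANOVA** is the one-factor within-subject decomposition with
  Greenhouse–Geisser-corrected dfs (epsilon from the condition covariance
  matrix), Mauchly's sphericity test, generalized and partial eta squared,
  and pairwise paired-t post-hoc contrasts.  Both Tukey and Bonferroni
  adjustments are available; Tukey is the default (the reporting
  convention), Bonferroni matches the pre-registered plan.  A flat outcome
  reports $F = 0$; an implementation-independent cross-check against
  `car::Anova`'s multivariate route is part of the test suite.
* **Choice prediction** uses a Pearson $\chi^2$ on the 3×3 predicted-vs-
  actual table, computed as the explicit $\sum (O - E)^2/E$ so strategy
  levels absent from both margins remain structural zeros (df stays 4).
* **The choice regression** defaults to a proportional-odds model over the
  canonical strategy order — mirroring the original analysis — but choice
  is nominally scaled, so a multinomial mode is provided and is the one
  whose own-SV coefficient signs are checked in simulation.  Separation and
  degenerate predictors raise a flag instead of an error.  McFadden's
  pseudo-$R^2$ is reported.
* **The flexibility regression** predicts the FlexER score from each
  participant's ordered-SV intercept (mean SV) and slope
  ($(\text{lowest} - \text{highest})/2 \le 0$), by OLS with confidence
  intervals.
* **Bayes factors are out of scope**; the analysis bundle carries an
  explicit note.

## Problem sizes used by the test suite

Exhaustive checks run over all 199 cent-grid indifference points and a
500-agent deterministic sweep.  Mixed-model recovery runs 100 generated
studies at $n = 120$ (trial granularity); null-calibration checks use 24
replicates at $n = 40$ and condition granularity; the temperature-RMSE
ladder uses 60-agent cohorts at three $\beta$ values.  These sizes were
chosen to make the Monte-Carlo bounds sharp (binomial error well inside the
asserted margins) while keeping a full run quick on one CPU.

## Known limitations

* Rank ties in SV profiles are broken by the canonical strategy order; the
  original analysis never faced one (119 of 120 participants had a unique
  SV of 1), so this is a convention, not an inference.
* The generator's rating model is Gaussian with a single subject factor
  per dimension; real slider data are often skewed and heteroscedastic.
* The EMG synthesizer uses stationary noise bursts; real EMG has
  non-Gaussian amplitude structure and artifacts, and the chain performs no
  artifact rejection beyond window-bound checks.
* The trial-level MLM inherits the pseudoreplication of its design; see
  the granularity note above.
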