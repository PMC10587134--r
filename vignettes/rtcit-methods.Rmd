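---
title: "Models and methods behind rtcit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtcit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcit)
```

`rtcit` implements the analysis chain of a two-condition reaction-time
Concealed Information Test (RT-CIT) cohort study: trial-level simulation,
preregistered exclusions, per-participant scoring, default Bayes factors
with a sequential sampling plan, and a simulated-naive ROC analysis. This
vignette is the package's own account of those methods — the model
assumptions, the tunable parameters, the numerical choices, and what the
simulation-based validation does and does not establish.

## The task being simulated

Under the multiple probes protocol, two semantic categories (names and
cities) are intermixed within every block. Each category contributes one
probe (a personally significant item), one target (requires the alternative
button), and four irrelevants. A block presents each of these 12 items 6
times (72 trials); a session has 4 blocks (288 trials). Two consecutive
presentations of the same item never occur, and a response must arrive
within 1500 ms.

The generator reproduces this structure exactly; item order is drawn one
trial at a time, uniformly over the items still owed repetitions in the
block but excluding the immediately preceding item (also across block
boundaries). The rare dead end — only the preceding item remains — restarts
the block's draw. We chose this sequential scheme over
rejection-reshuffling whole blocks because a uniform 72-slot shuffle with
12 items of multiplicity 6 avoids adjacent repeats with probability of
roughly `exp(-5)`, i.e. rejection would discard ~150 shuffles per block.
The sequential draw is not exactly uniform over admissible sequences
(orders that exhaust an item early are slightly favoured), which is
immaterial here: the analysis never uses item order beyond the no-repeat
constraint.

## The RT model

Trial RT is

```
rt = baseline_i + shift(stimulus type) + e,   e ~ Normal(0, trial_sd_ms)
```

truncated by redrawing into the response window (0, 1500] and recorded to
0.1 ms. Participant baselines are `Normal(baseline_mean_ms,
baseline_sd_ms)`; the probe shift is the participant's true RT-CIT effect,
drawn once per participant from `Normal(probe_effect_mean_ms,
probe_effect_sd_ms)` (exactly 0 for naive participants); targets get a
constant `target_shift_ms`. A plain normal rather than an ex-Gaussian is
deliberate: every downstream statistic uses only per-participant means and
SDs, which the normal reproduces with far fewer knobs. Misses (no response
within the window) occur with `miss_rate`; wrong presses with a
per-stimulus-type probability, independent of RT.

Defaults are calibrated to a large two-condition online validation cohort
(analysed n = 292): conflict-condition effects 35.84 ms (between-participant
SD 34.14) on a 472.88 (43.96) ms irrelevant baseline; no-conflict effects
23.40 (32.04) on 487.85 (55.28). Parameters that the study's summary tables
cannot identify were fixed once at field-typical values:

| parameter | default | rationale |
|---|---|---|
| `trial_sd_ms` | 100 ms | within-subject RT SD of ~20% of a ~500 ms mean, typical of speeded binary classification |
| `target_shift_ms` | 60 ms | targets require the rarer alternative press and run slower |
| `error_rate_by_type` | 0.05 / 0.04 / 0.15 | probe/irrelevant errors of a few percent; target errors substantially higher |
| `miss_rate` | 0.02 | deadline feedback keeps misses rare |

Two consequences of the model are worth flagging. First,
`probe_effect_sd_ms` is the spread of *true* effects; an observed cohort's
effect SD additionally contains trial-sampling noise (about
`trial_sd_ms * sqrt(1/n_probe + 1/n_irrelevant)` ≈ 17 ms at the default
trial counts), so observed SDs exceed 34.14 by design. Second, the two
probe categories share one true effect per participant, so the generator
does not emulate the empirically larger names-than-cities effect; the
per-stratum report rows differ only by sampling noise. Simulated cohorts
also contain none of the slow drifts, speed–accuracy trade-offs, or
RT-skewness of real data — passing tests on them validates the *pipeline's
arithmetic and bookkeeping*, not the behavioural realism of any single
simulated participant.

`n_contaminated` participants are engineered to fail quality control
deterministically (they always respond to probes and always press the wrong
button), so exclusion bookkeeping can be tested exactly rather than
probabilistically.

## Exclusions and scoring

Trial filters remove wrong presses, presses under 150 ms, presses above
800 ms, and misses. "Under" and "above" are read strictly: RTs of exactly
150 or 800 ms are retained. Participant-level QC runs on *unfiltered*
trials: a wrong-press rate of at least 0.5 for any stimulus type excludes
(boundary included), as do incomplete sessions (fewer than 288 presented
trials; partial blocks are not salvaged) and repeat participation (all
sessions of a duplicated id are dropped, not just the later ones — on a
flat trial table a duplicate manifests as more than 288 rows for one id).
Misses sit in the denominator of the error rate but are not errors by
default (`misses_as_errors` flips this; the criterion's wording does not
settle it, and "errors" most naturally means wrong presses).

The RT-CIT effect is the mean filtered probe RT minus the mean filtered
irrelevant RT; dCIT divides it by the sample SD (n − 1) of the filtered
irrelevant RTs, pooled across both categories and all blocks — the score's
definition names no stratification, and pooling uses all ~180 retained
irrelevant trials. dCIT requires at least one probe trial, two irrelevant
trials and non-zero irrelevant variance; degenerate participants raise an
error naming the participant and the deficient stimulus type. Target trials
enter QC only, never the scores.

## Effect sizes and confidence intervals

All estimators work from group summaries (mean, SD, n), so published tables
can be re-analysed without raw data. The within-condition d is `mean/sd`
with the large-sample CI `d ± z * sqrt(1/n + d²/(2n))`; the mean-effect CI
is `mean ± z * sd/sqrt(n)`. Normal (z = 1.96) rather than t critical values
are the default because they reproduce conventionally reported
summary-table CIs at these sample sizes — for the calibration cohort's
conflict row the z interval is [29.99; 41.69] where the t interval would be
[29.94; 41.74] — and a `critical = "t"` flag provides the exact-t
alternative. The between-condition contrast is the pooled-variance
Student's t (the standard frequentist companion of a default Bayesian
independent-samples t test), with Welch behind a flag; the between-groups
d standardises by the pooled SD.

## Default Bayes factors

The JZS Bayes factor places a zero-centred Cauchy prior with scale
`sqrt(2)/2` on the standardised effect δ and evaluates

```
BF10 = ∫ dt(t; df, δ√N) Cauchy(δ; 0, r) dδ  /  dt(t; df, 0)
```

with `N = n` (one sample) or `n1·n2/(n1+n2)` (two samples). The scale
0.707 is the conventional "medium" default of the standard Bayes-factor
software. The integral is evaluated by adaptive quadrature at relative
tolerance 1e-6, *split at the maximum-likelihood effect* `t/√N`: for large
t the integrand is a narrow spike there, and quadrature over a single
infinite interval can miss it entirely. The infinite tails use the
quadrature's built-in change of variables. The returned object carries the
absolute-error estimate; `bf10 * bf01 = 1` holds to numerical tolerance,
and the implementation agrees with an independent default-Bayes-factor
implementation to at least four significant digits on a 13-point grid
(frozen in the test suite).

The sequential plan stops at the first cumulative-batch BF10 above 5 or
below 0.2, and declares `inconclusive_max_n` at 300 recruited participants.
One deliberate extension: a trajectory that ends uncrossed *before* the
maximum is reported as `continue`, not `inconclusive_max_n` — collapsing
the two would misreport an unfinished experiment as a completed one.
"BF < 0.2" is taken at face value as a threshold on BF10.
`sequential_operating_characteristics()` simulates the plan at the
participant-summary level (observed effects drawn directly from each
condition's configured normal; at that level the configured SD plays the
role of the observed spread), which makes a few hundred simulated
experiments cheap.

## Detection efficiency

Because a cohort study of knowledgeable participants contains no naive
ones, the naive dCIT distribution is constructed, not observed: mean 0 (a
probe holds no special meaning for a naive examinee) and SD from the
sampling-variance approximation of a standardised mean difference,

```
Var = (N−1)/(N−3) · (4/N) · (1 + δ²/8),   δ = 0,
```

with N the per-condition knowledgeable sample size. The expression is a
*variance*; the implementation takes its square root for the null SD
(`literal = TRUE` preserves the un-rooted reading for sensitivity
analysis — treated as an SD directly it would be ~0.03 rather than ~0.18 at
N = 131, collapsing the null and inflating every AUC). Naive scores are
drawn from `Normal(0, sd)`.

The AUC is the Mann–Whitney estimator (ties count 1/2), computed via
midranks and verified in the tests against exhaustive pair counting. The
bootstrap repeats the whole construction 100 times; by default each
replicate resamples the knowledgeable dCITs with replacement *and* redraws
the simulated naive sample, so the replicate spread reflects both sources
of uncertainty. A `naive_only` scheme (fixed knowledgeable sample) is
provided because the procedure's description is compatible with either. The
CI is the 2.5/97.5 percentile interval of the replicates (normal
approximation behind a flag). Two AUCs from independent cohorts are
compared with `Z = (A1 − A2)/sqrt(SE1² + SE2²)` using Hanley–McNeil (1982)
standard errors, `Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`. With the calibration
cohort's AUCs (0.84 at n = 131 vs 0.74 at n = 161) this yields Z ≈ 2.70;
the published comparison for those AUCs reports Z = 3.68, which is not
recoverable from the Hanley–McNeil SEs (nor from bootstrap-SD-based SEs,
which give Z ≈ 6); the SE inputs behind that figure are unknown, so the
package reports its own Z and documents the discrepancy here. Orientation:
knowledgeable is the positive class, higher dCIT means more evidence of
knowledge.

## Pipeline determinism and degenerate inputs

`run_pipeline()` derives one sub-seed per stochastic stage (generation, one
per condition's bootstrap, ROC export) from the master seed, so stages can
be rerun independently and a rerun of the whole pipeline is bit-identical.
Results are invariant to trial-log row order (grouping is by participant
id, never position). Every rendered number is recomputable from the
serialized artifacts (trial log, participant summaries, AUC replicates,
JSON results). Report rendering rounds half away from zero at two decimals;
internal computation never rounds. Degenerate inputs fail loudly with the
offending participant, row, or report cell named: RTs outside (0, 1500],
unknown enum values, a stimulus type with no trials, zero irrelevant
variance, an empty report stratum.

## Validation scale and limitations

The test suite exercises the full protocol invariants on small cohorts, the
summary-statistic estimators against hand and brute-force computation, and
the Bayes factors against the frozen reference grid. The two Monte-Carlo
checks run at the calibration cohort's size: chance-level AUC for
null-drawn knowledgeable scores (12 cohorts of n = 131, 30 bootstrap
replicates each), and parameter recovery — 100 seeded cohorts of
131 + 161 participants, each bootstrapped with 100 replicates, requiring
the conflict condition to out-classify the no-conflict condition in at
least 95% of runs. At the default calibration the expected mean AUCs are
roughly 0.80 and 0.72 (slightly below the published 0.84/0.74, because the
configured between-participant SD is the *true*-effect spread; see the RT
model section), with per-cohort SEs near 0.03, so the ordering check sits
comfortably above its threshold without being tautological.

Known limitations: no ex-Gaussian RT option, no per-category effect
heterogeneity, error and miss processes independent of RT, ratings tables
are consumed but never simulated by the generator, and the Bayes factors
are two-sided defaults only (no directional or informed priors) — matching
the analyses the pipeline is built to reproduce.
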