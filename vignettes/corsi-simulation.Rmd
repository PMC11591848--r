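---
title: "Simulating and analysing the computerized Corsi block-tapping test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the computerized Corsi block-tapping test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsiblocks)
```

## The task model

The computerized Corsi block-tapping test (CBT) presents sequences of
blocks highlighted one at a time on a fixed board (here a 20 x 15 cm
window with ten blocks; each block highlights for 1 s with 0.5 s between
blocks). The participant clicks the blocks back in order. Sequences start
at two blocks; three trials are administered at every length, and the
participant advances one block whenever at least one of the three trials
is reproduced fully correctly. The session ends at the first failed
length, or after the ten-block level is passed.

`run_session()` implements this state machine. Two deliberate choices:

* **All three trials are always administered** before the pass decision —
  "one out of three attempts" implies three attempts are given, and the
  terminal-level average needs all three trials.
* **The engine never sleeps and takes a respondent callback** rather than
  presenting stimuli: the package simulates sessions, it does not run
  human participants. The timing fields are carried as metadata so a
  session log fully describes the protocol it came from.

Sequences are fresh uniform draws of distinct blocks at every trial; the
protocol does not specify whether trials at a level may share content, so
independence is the simplest defensible choice. Block positions on the
default board are arbitrary (the classical task never standardised them);
the board is configurable, and validation only enforces containment and
non-overlap.

## Scoring

One *item credit* per serial position recalled in the correct order and
location, counted over the overlap of target and response; extra clicks
earn nothing and void full correctness; a correct block in a wrong
position earns nothing. With `L` the last level administered (including a
failed final level) and `avLevelScore` the mean credit over the trials at
`L`,

$$\mathrm{FinalResult} = L - 1 + \mathrm{avLevelScore}/L \in [L-1,\, L].$$

**The averaging divisor.** Two readings of the terminal-level average are
in circulation: divide the summed credits by the number of trials, or by
"the number of blocks presented". At a terminal level of 3 with 3 trials
the readings coincide (the canonical worked example, credits (2,2,1),
gives 1.67 either way). Only the trial-count reading keeps
`avLevelScore` in `[0, L]` — and hence the final score inside
`[L-1, L]` — at every level, so it is the default;
`score_session(divisor = "sequence_length")` retains the other reading.

Scores are kept at full precision internally and rounded half-up to two
decimals only when printed (so 5/3 reports as 1.67 and the worked final
score as 2.56). `classify_performance()` splits scores at 7 by default;
"good performance" has no canonical definition, and 7 matches the usual
binning of CBT final scores (under 7 / 7–8 / over 8). It is configurable
everywhere it is used.

## The synthetic cohort generator

`cohort_spec()` + `simulate_study()` generate a two-group study
(musicians / non-musicians) in which every downstream stage is testable.
Each participant carries a latent span `s` and recalls each item of a
length-`k` sequence independently with probability

$$p(k) = (1 - \mathrm{lapse}) \cdot \mathrm{logistic}\!\big((s - k)/\tau\big),$$

a soft threshold at the span (sharpness `tau`, in blocks) with a small
lapse rate. A missed position is replaced by a uniformly chosen wrong,
not-yet-used block, so responses keep the target's length and errors stay
positionally independent. This is the simplest mechanism whose induced
final-score distribution is continuous over `[1, 10]` and calibrable to
two group means; it is a generative stand-in, not a cognitive model.

Latent spans follow
`base_span + delta_group·musician + delta_sex·male + beta_age·(age - 24.1) + N(0, span_sd[group])`.

**Default study conditions.** The defaults emulate the reference design:
31 musicians and 29 non-musicians; truncated-normal ages (musicians 23.6
± 3.6 on 19–35, non-musicians 24.6 ± 6.2 on 18–40); about half of each
group male; musician years of music reading lognormal (mean ≈ 8.25,
SD ≈ 5.25, clipped 1–25, uncorrelated with span — matching the null
experience–score association); `beta_age = 0` (the null age effect).

**Calibration.** With `tau = 0.4` and `lapse = 0.01` fixed, the four span
parameters were fitted once by iterated simulation at n = 20 000/group so
that simulated final scores reproduce the target group moments — means
7.04 (musicians) and 6.30 (non-musicians), SDs 0.78 and 1.10, and a
male−female difference of ≈ 0.72: `base_span = 6.49`,
`delta_group = 0.76`, `delta_sex = 0.75`, `span_sd = 0.66 / 1.04`. The
latent values sit above the observed means because sessions truncate:
failing a level early costs score, so the span-to-score mapping has a
bias of about −0.55. A per-group span SD is needed because the two target
SDs differ while the within-session noise is common.

**Metacognition.** Each participant perceives their span with Gaussian
noise (`meta_sigma`) and claims "good" visuospatial ability when the
perceived span reaches `meta_reference = 7.2`; labels are overridden to
"normal" / "unable" with probabilities 11.8% / 2.6% (the interview
categories excluded from inference). Musician noise (0.4) is far below
non-musician noise (3.5), calibrated so claim-good accuracy runs ≈ 0.70
for musicians vs ≈ 0.33 for non-musicians — reproducing the
metacompetence asymmetry in direction and roughly in magnitude — while
keeping the share of claim-good participants near 60%.

**What the generator does not emulate:** serial-position effects,
chunking strategies, practice and proactive-interference effects,
correlations between experience and span, or any response-time
structure. Passing tests therefore validate the pipeline's statistics
under a plausible data-generating process, not these aspects of real CBT
data.

## The analysis pipeline

`run_full_analysis()` runs, in order: the exclusion filter ("normal" /
"unable" self-assessments are dropped from inference, mirroring the
interview design), sample matching checks (Student t on age,
Mann-Whitney on sex), assumption checks (Levene on the outcome,
covariate–factor independence for age, homogeneity of regression slopes
for age), the ANCOVA of score on group with sex and age, correlations,
the metacompetence table with chi-square, and the experience-split
one-way ANOVA (≤ 7 vs ≥ 8 years by default).

Numerical and design choices:

* **Partial (Type-III-equivalent) F tests.** Each ANCOVA term is tested
  by comparing the full OLS fit against the fit without that term; with
  one factor and continuous covariates this is standard and
  order-invariant. `eta_p_sq = SS_term / (SS_term + SS_residual)`.
  Degenerate designs are handled explicitly: collinear columns raise an
  error naming them, and a constant outcome yields F = 0 rather than a
  0/0 artefact.
* **Levene centring** defaults to the group mean (classic Levene);
  `center = "median"` gives Brown–Forsythe.
* **The slopes check** uses `score ~ group * covariate` (one covariate at
  a time), the form under which its denominator df at n = 60 is 56.
* **Mann–Whitney** uses exhaustive enumeration of group assignments for
  combined n ≤ 10 (exact even under ties, via the symmetric-deviation
  permutation p) and a tie-corrected, continuity-corrected normal
  approximation otherwise.
* **Chi-square** is a generic r×c Pearson test from the product of
  margins with an upper-tail p. The report applies it to the
  group × (claim × performance) table (df = 3); published analyses of
  such "multiple response" tables differ in how cells are constructed
  (a df of 4 implies a 2×5 layout whose definition is not recoverable),
  so the table builder is generic and the construction documented.
* **Metacompetence percentages** default to the claim-good denominator:
  the four cells (group × performance among claim-good participants) sum
  to 100%. `denominator = "all"` switches to the full filtered sample.
* **p-values** always come from distribution functions, never tables;
  two-sided everywhere except chi-square. No multiple-testing correction
  is applied, matching the analysis design the pipeline mirrors.
* **Rounding** of reported values is half-up at print time only.

## Simulation-based validation

Because a study's raw data are rarely available, the package validates
its inferential machinery by simulation (`power_analysis()` and the test
suite):

* Under a null cohort (`delta_group = 0`, n = 30/group), the ANCOVA
  group-term rejection rate at α = 0.05 is checked to land in
  0.05 ± 0.02 over 1000 replicates.
* Under the calibrated effect spec at n = 10 000/group, the simulated
  group means and SDs are checked to land within ±0.15 of their targets.
* The metacompetence direction (musician claim-good accuracy above
  non-musician) is checked to hold in ≥ 95% of 200 study-size
  replicates.

Problem sizes (1000 null replicates at n = 60; one 20 000-participant
calibration study; 200 study-size replicates) were chosen to keep
Monte-Carlo error well below the tolerances while the whole suite runs
in a few minutes on one core.

## Known limitations

* The respondent model's independence assumptions (across items, trials
  and levels) understate the trial-to-trial correlation of real
  participants; within-session score noise is therefore, if anything,
  optimistic.
* The span-to-score calibration is specific to the default protocol
  (start at 2, three trials, pass on one); changing the protocol requires
  recalibrating `cohort_spec()`'s span parameters.
* `meta_reference` is shared between groups; group-specific claim
  thresholds (e.g. differential overconfidence) can only be mimicked via
  `meta_sigma`.
* The exact-vs-approximate switch in `mann_whitney()` is at combined
  n = 10; between 10 and ~20 the normal approximation is adequate but
  not exact (checked to within 0.02 of enumeration at n = 8 + 8).
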