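---
title: "Scanpath networks and standardized weighted degree centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanpath networks and standardized weighted degree centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazenet)
library(dplyr)
```

## The problem

Most eye-tracking studies of face perception summarize gaze with *fixation
time*: the share of viewing time spent inside each predefined area of
interest (AOI) — left eye, right eye, nose, mouth, outer facial features.
Fixation time says nothing about *how* the viewer moves between features.
Two children can both spend 20% of their time on the mouth while one shuttles
constantly between mouth and eyes and the other parks there once. gazenet
implements a complementary, network-based description of scanning: the
saccadic transitions between AOIs are counted into a per-participant
transition matrix, the matrix is read as a weighted undirected graph over
the five AOIs, and each AOI's importance as a scanning *anchor* is scored by
a standardized weighted degree centrality. The package also carries the
classical fixation-time metrics and the group-level inferential layer, so
a full case-control comparison (here framed as ASD vs. typically developing
preschoolers viewing emotional faces) runs end to end.

## Pipeline and models

### Fixation detection (I-VT)

Raw gaze arrives as a 60 Hz binocular sample stream. The two eyes are
combined by averaging the valid eyes per sample (mean of both, a single
valid eye, or invalid — the combination rule is a convention and is
configurable). Angular velocity is a two-point backward difference between
consecutive valid samples, converted from pixels through the screen
geometry (defaults: 1024×768 on a 34.5×25.9 cm panel at 60 cm, about 31
px/degree). A sample belongs to a candidate fixation when it is valid and
slower than the **35 deg/s** threshold; maximal candidate runs lasting at
least **100 ms** become fixations, with the centroid of member samples as
position. These thresholds are the standard I-VT settings for remote
tracking of young children and are the package defaults
(`detection_config()`).

Numerical choices worth stating:

* A sample with undefined velocity (trial start, or the first valid sample
  after tracking loss) never breaks a run — otherwise no fixation could
  ever start.
* Invalid samples split candidate runs. Optional short-gap interpolation
  (`max_gap_interpolation_ms`, off by default) bridges brief tracking loss
  linearly. Published pipelines for infant data often smooth and
  interpolate more aggressively; we expose plain I-VT with explicit
  options rather than a fixed preprocessing cascade, so results on real
  recordings may differ slightly from pipelines that smooth.
* A fixation's duration is counted as one nominal sample period per member
  sample, and the minimum-duration cut allows 1 µs of floating-point slack
  so a fixation of exactly 100 ms at 60 Hz (6 frames) is kept.
* Pixel-to-degree conversion uses the small-angle planar approximation;
  the exact arctangent is available (`exact = TRUE`) and differs by well
  under 1% at the ~20 degree stimulus sizes involved.

### AOIs and labeling

AOIs are closed rectangles in stimulus pixel coordinates, five per
stimulus. The four internal-feature AOIs are expanded by **1 degree of
visual angle per side** (clipped to the stimulus) to absorb the
calibration offsets typical of preschool recordings. Where the expansion
makes AOIs overlap — the two eye regions, usually — a fixation in the
overlap goes to the nearer AOI centre, with ties broken in the canonical
order (left eye, right eye, nose, mouth, outer). The `outer` AOI is the
face bounding rectangle tested *after* the internal AOIs, which
approximates the non-rectangular "face minus features" region without
polygon support. Points inside no rectangle are `outside`.

Throughout the package **left eye means the eye on the viewer's left**
(the face's own right eye). This is stated here prominently because
lateral-bias results flip meaning if the convention is misread.

### Fixation-time metrics

Per trial, the time in each label is divided by the trial's total fixation
time on the stimulus (all six labels, including `outside`) and expressed in
percent; per-participant values are the equal-weight mean over trials with
any fixation time. Whether to average per-trial percentages or pool
milliseconds across the twelve faces is genuinely ambiguous in practice;
both are implemented (`method = "per_trial"` is the default, `"pooled"` the
alternative) and differ only when trials have unequal fixation totals. The
left/right eye ratio is `left / (left + right)`; 0.50 is no bias, and the
form is forced by that reference value and the 0–1 range. Participants
with no eye-region time have an undefined ratio and are excluded from
ratio analyses with a logged reason.

### Transition networks and centrality

A *transition* is a saccade from one face AOI directly to a different face
AOI. Within each trial, every consecutive fixation pair with two distinct
AOI labels increments the (departure, arrival) cell; same-AOI pairs and
pairs involving `outside` count nothing, and pairs never span trial
boundaries. The strict reading — an AOI→outside→AOI excursion is *not* a
transition — is the default; `bridge_outside = TRUE` optionally bridges a
single intervening outside fixation. All twelve trials accumulate into one
5×5 matrix per participant.

Direction is then discarded: the weighted undirected adjacency has
`w[i,j] = counts[i,j] + counts[j,i]`. For node *i*,

* degree centrality `C_D(i)` = number of other AOIs with a nonzero link,
* strength `w(i)` = total transitions involving the AOI,
* **standardized weighted degree centrality**

  $$C_D^w(i) = \frac{C_D(i)}{\max C_D}\cdot\frac{w(i)}{\max w}\cdot 100,$$

  with the maxima taken within the same participant's network.

`C_D^w` weighs breadth (how many features an AOI exchanges gaze with) and
volume (how often) equally, needs no tuning parameter, and is standardized
within participant so values are comparable across people; it ranges from
0 to 100 and the node attaining both maxima scores exactly 100. On a
five-node network plain degree saturates quickly (most AOIs connect to
most others), which is exactly why the weighted, standardized form is the
headline measure. In a degenerate network with no transitions at all,
every `C_D^w` is defined as 0 and the participant is flagged
(`empty_network`), rather than erroring, so cohort pipelines run to
completion on low-data participants. The formula is printed against an
undirected binarized adjacency; the worked example (node 1 connected to
2, 4, 5 giving degree 3) fixes that interpretation.

### Group statistics

The inferential layer mirrors a case-control analysis with developmental
covariates:

* **ANCOVA**: `outcome ~ group + vma + nvma` with optional group×covariate
  interactions, sum-to-zero group coding. With interactions in the model
  the group main effect uses Type III sums of squares (the only
  decomposition under which it stays meaningful); Type II is available.
  Partial eta squared is `SS_group / (SS_group + SS_resid)`. With 41
  participants the two variants give the denominator dfs 35 and 37 — both
  variants are computed side by side in `analyze_cohort()` so either
  convention can be matched.
* **One-sample t** on the ratio against 0.50, two-sided, with
  `d = (mean − 0.50)/sd`.
* **Pearson correlations** between an AOI's fixation-time percentage and
  its `C_D^w`, per group, compared between groups by the **Fisher r-to-z**
  statistic `z = (atanh r1 − atanh r2)/√(1/(n1−3)+1/(n2−3))`. Both one-
  and two-sided p-values are reported: directional hypotheses about
  correlation differences are sometimes reported one-sided, and showing
  both avoids ambiguity.
* **No multiple-comparison correction** is applied anywhere; the report
  states this. With compositional fixation-time outcomes (more time on one
  AOI forces less on others) familywise corrections are ill-calibrated,
  and the package treats the correction policy as the analyst's decision
  to state, not the software's to impose.

## The synthetic cohort generator

No individual-level data ship with the package; every stage is instead
exercised by a generator whose defaults emulate the paradigm's study
conditions: two groups of 20 and 21, twelve 3500 ms trials per participant
at 60 Hz, five face AOIs. Its pieces:

* **Scanpaths** are a first-order Markov chain over the five AOIs plus
  `outside`. Defaults: repeat probability 0.5, outside probability 0.05,
  otherwise uniform movement. With a ~2000 ms per-trial fixation budget
  and log-normal durations (median ≈ 250 ms, floored at the 100 ms
  detection minimum — shorter events would never be observed), this yields
  roughly 8 fixations and 3 between-AOI transitions per trial, i.e. about
  2.0 s of fixation time and 30–38 transitions per participant over twelve
  trials, matching the data-quality figures such paradigms report for
  preschoolers. The remaining trial time is saccades and tracking loss.
* **Anchoring** multiplies inbound transition probabilities into the
  anchor AOI by `1/(1−s)` and shrinks the anchor's repeat/outside mass by
  `1−s`, then renormalizes rows. The control group's default anchor is the
  left eye at `s = 0.3`; the case group has none. This is the generator's
  operationalization of a feature that organizes exploration — a modeling
  device, not a claim about mechanism.
* **Lateral bias** multiplies inbound probability into the left eye by a
  factor and divides the right eye's by it. The defaults (0.96 case, 1.25
  control, on top of the control anchor) were calibrated once so the group
  mean left/right ratios land at the reference values of roughly 0.48 and
  0.64; per-participant spread (SD ≈ 0.11–0.14) is narrower than real
  cohorts (≈ 0.19–0.26) because the generator omits between-child
  heterogeneity in scanning style.
* **Covariates** (chronological, verbal and non-verbal mental age in
  months) are drawn from per-group normal distributions with the reported
  group means and SDs, floored at 6 months; sex is Bernoulli with the
  reported group ratios.
* **Raw gaze rendering** inverts detection for round-trip tests: each
  planned fixation is placed at a point inside its AOI (central half of
  the rectangle, so that the accuracy error stays within the 1 degree
  expansion) plus a per-fixation Gaussian *accuracy* offset (default
  0.3 degrees, inside the 0.4–0.6 degree accuracy band quoted for remote
  trackers) and a small per-sample *precision* jitter (0.02 degrees).
  Splitting tracker noise into a slowly-varying offset and a tiny jitter
  matters: putting 0.3 degrees of white noise on every sample would
  produce apparent velocities far above 35 deg/s and shred every fixation,
  which is not how tracker error behaves. Between fixations the renderer
  emits straight-line saccade samples easing into the landing point when
  the implied per-step speed clears 1.5× the velocity threshold, and
  tracking loss otherwise, so consecutive fixations always separate.
  Planned `outer` fixations are placed in the lower band of the face
  rectangle, which the default layout keeps clear of internal features.
  Fixation onsets are snapped to the sample grid so a 100 ms plan occupies
  exactly six frames.

Everything is a pure function of (design, seed).

### What passing tests do and do not show

The generator produces clean Markov scanpaths with stationary per-group
structure. Real recordings have drift, smooth pursuit, blinks correlated
with events, AOI-dependent fixation durations, and children who quit
mid-session. Recovery results on synthetic cohorts therefore validate the
*pipeline arithmetic* — detection, labeling, counting, the centrality
formula, the statistics — not the behavioral model; they show the
machinery finds an injected anchor of strength 0.3 at n = 20/21 with high
probability, and keeps its type-I error near the nominal 5% on null
cohorts, under the stated noise model.

## Problem sizes and defaults used in validation

The shipped validation suite uses: exhaustive enumeration of all 1024
binary edge supports and all 4096 weight assignments (weights 0–3) on a
fixed six-edge support, plus 2000 random denser networks, against a
brute-force centrality oracle; 10,000 random networks for the 0–100 range
property; 1000 rendered trials for round-trip detection (target ≥ 99%
exact recovery); 200 anchored replicates for contrast recovery (target
≥ 95% correct direction) and 1000 null replicates for type-I error
(target 5% ± 2%). The acceptance script recomputes the same quantities at
somewhat smaller replicate counts. Full enumeration of all weight
assignments on all ten edges (4^10 ≈ 10^6 networks) adds nothing beyond
the stratified enumeration above and is omitted.

## Known limitations

* Rectangles only; no polygonal or landmark-derived AOIs.
* The `outer` region is a precedence rule, not a true set difference.
* Plain I-VT; no saccade metrics, smooth-pursuit handling or
  microsaccades.
* Betweenness and closeness centrality are deliberately out of scope;
  the five-node networks here are too small for them to add much.
* The supplementary-data reader takes an explicit column map because
  individual-data workbooks have no standard layout; it guesses nothing.

## A short worked run

```{r example, eval = FALSE}
co <- generate_cohort(cohort_design(), seed = 1, render = TRUE)
res <- analyze_cohort(co$gaze, default_aoi_set(), co$metadata)
res$tables$centrality
cat(make_report(res))
autoplot(res) # group means of C_D^w by AOI
```
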