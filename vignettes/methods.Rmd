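---
title: "Methods: quantification, pharmacology and synthetic data for dorsal horn recordings in the MIA model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, pharmacology and synthetic data for dorsal horn recordings in the MIA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsalhorn)
```

This vignette documents the measurement model the package implements, every
parameter with its units and default, the resolution of the underspecified
corners of the protocol, and what the synthetic generator does and does not
emulate. Quantitative claims about the package's behaviour are made only
where a test in `tests/testthat/` or `scripts/acceptance.R` computes them.

# The measurement model

## Electrical-train quantification

A wide-dynamic-range (WDR) dorsal horn neurone is recorded during a
transcutaneous electrical train: `n_pulses = 16` pulses of
`pulse_width = 2` ms at `frequency = 0.5` Hz, delivered at
`intensity_multiple = 3` times the neurone's C-fibre threshold. Every spike
is assigned a latency relative to the *nearest preceding pulse onset* and
classified into half-open latency bands (ms):

* Aβ `[0, 20)` — fast myelinated afferent volley;
* Aδ `[20, 90)` — thinly myelinated;
* C `[90, 350)` — unmyelinated nociceptor drive;
* postdischarge `[350, 800)` — afterdischarge reflecting network
  excitability.

Two conventions had to be fixed where the protocol literature prints shared
band edges without assignment:

* **Half-open edges.** A spike at exactly 20 ms is Aδ, at exactly 90 ms is
  C, at exactly 350 ms is postdischarge; each spike falls in exactly one
  band and a spike ≥ 800 ms after its reference pulse is not counted.
* **Latency origin.** Latency is measured from pulse *onset*, not from the
  end of the 2 ms pulse. The 2 ms offset is far smaller than any band width
  and a fixed shift would cancel in every within-neurone contrast; onsets
  are also what the event schema records.

From the per-pulse C-band counts `C_i` the two derived measures are

$$\mathrm{input} = C_1 \times n, \qquad
  \mathrm{windup} = \sum_{i=1}^{n} C_i - \mathrm{input},$$

i.e. the response the train would evoke with no activity-dependent
potentiation, and the excess actually evoked. Wind-up may legitimately be
negative (a first pulse that happens to fire strongly). Whether
afterdischarge counts belong in wind-up is genuinely ambiguous ("evoked by
C-fibre activity" can be read either way); the package defaults to the
literal C-band-only reading and exposes `include_postdischarge = TRUE` for
the inclusive convention. The identity
`input + windup = c_total` (respectively `c_total + pd_total`) holds under
both conventions and is enforced over 1000 random spike trains in the
acceptance suite.

Natural stimuli (brush; von Frey 2, 8, 26, 60 g; heat 40, 45, 48 °C) are
applied for `duration_s = 10` s and quantified as the spike count in
`[onset, onset + 10 s)`.

## Pharmacological timecourse

A neurone enters analysis only if three consecutive predrug trials are
stable: per-measure variation `100·(max − min)/mean` below
`c_threshold = 10` % for the C-band count and `other_threshold = 20` % for
the other directly evoked measures. Two resolutions are worth recording:

* Wind-up is excluded from the screen: it is a *difference* of tracked
  quantities and its relative variation is ill-behaved near zero. "All
  other parameters" is read as the directly evoked responses.
* An alternative `rule = "max_dev"` (maximum deviation from the mean rather
  than the range) is provided; the range rule is the default.

Baselines are the arithmetic means of the stable trials. The drug effect for
a measure at a dose is the *maximum absolute change* from baseline over the
post-dose test minutes (spinal: 10, 30, 50 min per dose; systemic: 30,
60 min), reported signed — "maximum percentage change" is interpreted as
maximal absolute deviation with its sign, not maximal inhibition, so
facilitation is representable. Ties go to the earliest minute. A zero
baseline makes the percentage undefined; the raw change is then reported and
flagged (`pct_defined = FALSE`). Group tables give mean ± SEM of the raw
response at the maximal-change minute per dose, next to the mean baseline.

## Behavioural endpoints

* **50% paw withdrawal threshold (PWT).** Dixon up–down staircase on the
  filament ladder 0.4, 0.6, 1, 2, 4, 6, 8, 15 g (start 2 g, cutoff 15 g),
  terminating four presentations after the first response change. The
  estimate is $10^{X_f + k\delta}$ g with $X_f$ the final log10 force and
  $\delta$ the mean log-step of the ladder. The classical pattern table for
  $k$ is delegated to secondary literature that could not be transcribed
  faithfully offline, so $k$ is instead computed by probit maximum
  likelihood with the psychometric spread fixed at $\delta$ — exactly the
  normal-response-model assumption those tables were derived from. This
  handles every response pattern (including boundary-clamped ones)
  uniformly. All-negative sessions return the 15 g cutoff exactly;
  all-positive sessions return 0.4 g exactly. The acceptance suite checks
  that a deterministic step responder with threshold anywhere in
  [0.4, 15] g is recovered to within one filament step.
* **Acetone (cooling) withdrawal frequency**: withdrawals out of 5
  applications, ×100.
* **Weight-bearing**: each hind limb's load is the mean of three positive
  readings (g); the ipsilateral percentage is `100·ipsi/(ipsi + contra)`.

## Statistical battery

Standard tests are *called*, not re-implemented, wherever an installed
routine provides the exact contract: Kruskal-Wallis wraps
`stats::kruskal.test` (tie-corrected H against χ²), repeated-measures ANOVA
wraps `stats::aov` with `Error()` strata, paired contrasts wrap
`stats::t.test` with Bonferroni multiplication. Two pieces are authored
here because no installed routine covers them:

* **Exact Mann-Whitney U with ties** — full enumeration of rank splits
  (`stats::wilcox.test` refuses exact p-values under ties). Auto mode uses
  enumeration for total n ≤ 14 and the tie-corrected,
  continuity-corrected normal approximation above. Tests verify the exact
  mode against an independent enumeration oracle for every split with total
  n ≤ 10 and the approximation against `wilcox.test`.
* **Dunn's posttest** — pooled-midrank z with tie term `T/(12(N−1))` and
  Bonferroni adjustment, verified against a from-first-principles
  computation in the tests.

Numerical/statistical choices worth flagging:

* No sphericity correction is applied in the RM-ANOVA; every result row
  carries the caveat. With the small cohort sizes here (≤ 7 per group) a
  Greenhouse-Geisser estimate would itself be unstable.
* The baseline MIA-versus-sham comparison across stimulus intensities uses
  the mixed-design form (group as between-subject factor); the protocol
  wording does not state whether the original battery was mixed or
  fully-within, so both forms are exposed (`design = "mixed"` /
  `"two_way"`).
* Degenerate inputs are defined, not errors: all-tied Kruskal-Wallis gives
  H = 0, p = 1; a zero-variance paired contrast gives t = 0, p = 1; a
  zero-variance ANOVA table is flagged `degenerate` with p = NA.
* The exact Mann-Whitney test at n = 6 vs 7 is discrete: its attainable
  two-sided levels jump from 0.03497 to 0.05128, so its true size at
  nominal 0.05 is 0.03497, not 0.05. The null-calibration acceptance test
  computes that attainable size analytically and checks the empirical
  rejection rate (2000 null replicates) against a binomial 99% band around
  it — a band around 0.05 itself is unattainable for any correct exact
  test at these sample sizes — plus an upper guard at the nominal level so
  anticonservatism would still fail.

# The synthetic generator

The generator exists so every pipeline stage is testable without animal
data. Its defaults *are* the study conditions: spinal cohorts of 7 MIA and
6 sham neurones (systemic: 5 and 6), doses 10/50/100 µg with tests at
10/30/50 min, behavioural arms of 5 animals.

## Structure

Per neurone, per pulse `i`, band counts are Poisson with means

$$\lambda_{A\beta}, \lambda_{A\delta} \;(\text{non-potentiating}), \qquad
  \lambda_{C,i} = \mu_C\,(1 - \phi)\,g\,\big(1 + w\,(1 - e^{-(i-1)/\tau})\big),$$

postdischarge sharing the C-band wind-up factor. Spike latencies are drawn
uniformly within each band's window. Natural responses use rate functions
monotone in intensity (constant brush; linear in von Frey force; logistic
in temperature). The drug enters as binomial thinning
$\phi = f_{max}\, d^h/(d^h + ED_{50}^h)\, s_{group}$ — state-dependence is
the contrast $s_{sham} = 0.1\, s_{MIA}$, a real but small sham effect
rather than an exact null.

Defaults (units; rationale):

| parameter | default | meaning |
|---|---|---|
| `mu_abeta`, `mu_adelta` | 8, 6 spikes/pulse | stable afferent volley |
| `mu_c`, `mu_pd` | 12, 4 spikes/pulse | C/afterdischarge drive |
| `windup_gain` `w`, `windup_tau` | 0.8, 4 pulses | saturating potentiation |
| `mia_gain` | 1.2 | MIA sensitisation multiplier on all rates |
| `neurone_cv` | 0.15 | lognormal between-neurone heterogeneity |
| `trial_gain_cv` | 0.15 | lognormal post-dose trial excitability gain |
| `f_max`, `ed50`, `hill` | 0.7, 30 µg, 1.5 | Hill inhibition |
| `s_mia`, `s_sham` | 1, 0.1 | state factors |

No baseline firing magnitudes were available in numerical form to anchor
the rate defaults; they are free parameters chosen to give realistic count
scales (tens to a few hundred spikes per train) and are documented as such.

Two generator decisions deserve explanation:

* **Stable baselines by construction.** Real labs screen neurones and keep
  the stable ones; the generator emulates the *selected* population rather
  than the selection process. Baseline trials therefore use deterministic
  rounding of the expected counts times a small common trial factor
  (±2% uniform, `baseline_jitter = 0.02`) instead of full Poisson draws,
  which provably keeps every measure's trial-to-trial variation below the
  screen thresholds. Post-dose trials are fully stochastic.
* **Shared trial gain.** Pure Poisson variation around the mean makes
  post-dose trial noise unrealistically small (≈ √N), which is
  incompatible with the generator's own stated sham-null structure: the
  genuine-but-small sham inhibition (6% of counts at the top dose) would
  be detectable nearly always. Evoked responses in this preparation drift
  between trials through common-mode excitability changes, so each
  post-dose trial draws one lognormal gain (`trial_gain_cv = 0.15`,
  i.e. ~15% trial-to-trial CV, within the 10–20% range typical for evoked
  counts) applied to all measures of that trial. This was calibrated to
  the generator's specified invariant (sham arm statistically quiet, MIA
  arm reliably detected), not to any acceptance threshold.

The behavioural generator gives each animal a latent log10 threshold
(sham mean 12 g, MIA mean 1.4 g, SD 0.12 log units), a logistic
psychometric (spread 0.06 log units) sampled by the same up–down code used
for real data, Bernoulli acetone withdrawals (per-trial probability 0.8 MIA
/ 0.04 sham), and triplicate weight-bearing readings around a mean
ipsilateral fraction (0.40 MIA / 0.50 sham, total hind load 150 g). Drug
moves MIA thresholds and acetone probabilities toward the sham values by
the inhibited fraction; weight-bearing is deliberately left uncorrected —
the readout the drug is expected *not* to normalise.

## What is emulated, and what is not

Emulated: cohort layout and dose ladders, selection-screened stable
baselines, wind-up kinetics, intensity-graded natural responses,
state-dependent inhibition, staircase-sampled behavioural thresholds,
deterministic seeding (identical seeds give byte-identical output files).

Not emulated: spike waveforms and sorting artefacts, within-train latency
dynamics (latencies are uniform within bands; only counts carry signal),
receptive-field geometry, anaesthetic depth drift, cumulative-dosing
carry-over (each dose's inhibition is computed from the dose alone),
between-day behavioural learning, and animal attrition.

# Reproducibility and problem sizes

All randomness flows from a single mandatory master seed
(`cohort_config(seed = ...)`); file writers format times to fixed 6-decimal
precision so identical data give byte-identical files, and every output
directory receives a JSON manifest (package version, seed, configuration and
its md5). The test suite's stochastic blocks use fixed seeds with problem
sizes chosen to keep total runtime in minutes: 1000 random trains for the
conservation suite, 2000 null replicates for calibration, a 120-point
threshold grid for staircase recovery, and 50 master seeds (13 neurones,
~1400 recordings each) for the state-dependent recovery criterion.

# Limitations

* The probit-ML `k` replaces the classical bundled pattern table; estimates
  agree with the tabulated method's model assumptions but are not
  digit-for-digit reproductions of the historical tables.
* RM-ANOVA p-values are uncorrected for sphericity violations.
* The exact Mann-Whitney enumerator is O(C(N, n₁)) and is auto-selected
  only up to N = 14; above that the tie-corrected normal approximation is
  used.
* The generator's rate parameters are plausibility-chosen, not fitted to
  data; absolute effect sizes in synthetic cohorts should not be read as
  quantitative predictions — only the contrast structure (MIA vs sham,
  dose ordering, drug-insensitive weight-bearing) is designed to be
  faithful.
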