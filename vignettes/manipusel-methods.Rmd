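---
title: "Measuring and selecting on host manipulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and selecting on host manipulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(manipusel)
library(dplyr)
```

`manipusel` implements the measurement-and-selection analysis used in
experimental evolution of resistance to parasite host manipulation in
copepods (*Macrocyclops albidus* infected by the cestode *Schistocephalus
solidus*). This vignette explains the models behind each stage, the
parameters that matter, and the design choices made where the procedure was
genuinely open.

## The behavioural assay and the tracker

A drop-plate assay simulates a predator attack; the copepod's activity is
the proportion of time it spends moving afterwards. Frames are sampled every
`interval_s = 2` s for `window_s = 90` s starting `offset_s = 10` s after
the drop (the first 10 s are excluded as startle reaction). The default
sequence is therefore 46 frames and 45 inter-frame intervals; whether the
endpoint frame is included is a protocol ambiguity, so `n_frames` is
configurable and 46 is only the default.

Detection (`detect_position()`) is deliberately simple and deterministic:
polarity correction so the animal is bright, Otsu thresholding, largest
connected component, intensity-weighted centroid. Two numerical guards
matter in practice:

* **Small-object guard.** A copepod covers well under 1% of the frame, and
  Otsu's between-class criterion will happily split the *background noise
  mode* when the foreground class is nearly empty. The threshold is floored
  at `median + 4 * MAD` of the corrected frame. On noise-free frames the MAD
  is zero and the guard is inert; on pure-background frames it leaves no
  component of at least `min_area = 5` px and detection fails loudly, which
  is the desired behaviour.
* **Missingness is not stillness.** An interval adjacent to a failed
  detection, or spanning a dropped frame, is *missing*, not "not moving";
  the activity statistic is the proportion of moving intervals among
  observed intervals only (`activity_score()`).

Movement is called per interval when the Euclidean displacement is at least
`threshold_px = 5` px, roughly one copepod body length. The comparison is
inclusive — "at least" read literally — and the metric is configurable to
Chebyshev, since the original tracking program's conventions are not
documented; both choices are isolated behind `call_movement()`.

## The manipulation score

Infection by *S. solidus* first suppresses host activity while the parasite
is not yet infective (recordings on days 6, 7, 8 post-infection) and then
enhances it once infective (days 13, 14, 15). The per-host **manipulation
score** is

$$ s = \bar A_{\text{post}} - \bar A_{\text{pre}}, $$

the difference of the two stage means (`score_table()`). The direction of
subtraction makes infected hosts score positive and is recorded in the
output metadata. Uninfected hosts are scored identically and act as the
no-manipulation reference; using a within-host difference also prevents
selection from acting on overall activity level directly, because any
constant host effect cancels. By default a host must have all six days
(selection used day-15 survivors with complete schedules); a relaxed mode
averages whatever days are present.

## Truncation selection

All infected day-15 survivors of a replicate form the selection pool.
In the founding generation, a random quarter (rounded down) becomes the
control line; the remaining pool is ranked by score, the top third becomes
the susceptible line, the bottom third the resistant line, and the middle
band is discarded. Rounding is conservative — thirds of size
`floor(r / 3)`, remainder to the discarded middle — and boundary ties break
by copepod id under a fixed seed; the source procedure states neither.

From then on each line × replicate breeds from at most ten individuals: the
ten most extreme scores (susceptible and resistant) or ten drawn uniformly
(control). Replicates correspond to parasite families and never mix.

The **selection differential** is `mean(selected) - mean(pool)`. Two
reference pools are meaningful: in the founding generation the three lines
are carved out of one common replicate pool, and the realized strength of
selection is measured against that whole pool; afterwards each line's pool
*is* its whole population. `select_generation(reference = )` implements the
founding case. Cross-replicate aggregation defaults to pooling individuals,
with per-replicate values always reported, because it is not documented
which of the two the published differentials use.

## Mixed models and repeatability

Activity and score tables are analysed with Gaussian linear mixed models
(`fit_mixed()`, backed by lme4) fitted by **maximum likelihood**, not REML,
so that likelihood-ratio tests across fixed-effect structures are coherent.
Activities are proportions; they are modelled on the proportion scale (as
in the source analysis), with an empirical-logit option available but off
by default. `lrt_compare()` reports `chi2 = 2\,\Delta\ell`, its
degrees of freedom, the upper-tail chi-square p value and
`delta_aic = AIC(reduced) - AIC(full)`; for ML fits the identity
`delta_aic = chi2 - 2\,df` holds and is tested.

Repeatability of repeated measurements is the intraclass ratio

$$ R = \frac{\sigma^2_{id}}{\sigma^2_{id} + \sigma^2_{res}} $$

from an intercept-only model with a host random effect
(`repeatability()`). The standard error comes from a seeded parametric
bootstrap (simulate from the fit, refit, recompute), and the p value from an
LRT against $\sigma^2_{id} = 0$ using the boundary-corrected
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture, the standard null for a
variance component on its boundary.

Note that $R$ from an intercept-only fit is *not* the id-variance share of
a model with infection and stage fixed effects: in an intercept-only fit
the between-host variance absorbs infection effects, which is why a
behavioural repeatability near 0.7 coexists with a small id intercept
variance (about 0.003 against a residual of about 0.023) once those fixed
effects are in the model. The package's tests exercise both readings.

Group summaries for response-over-generations figures use seeded
nonparametric bootstrap percentile intervals
(`selection_response_summary()`, 2000 resamples, 95%), a pragmatic choice
where the original interval method is unstated.

## The synthetic-data generator

The generator exists so that every stage has ground truth. It emulates:

* **Trajectories** (`generate_trajectory()`): per-interval Bernoulli
  movement (probability `p_move`) with step `step_px >= threshold` and
  sub-threshold jitter `jitter_px < threshold`, reflected at the arena
  walls with a margin so rendered blobs stay in frame. Movement flags are
  *defined from the realized positions*, so truth is exactly recomputable
  from the emitted coordinates; a persistent (Markov) movement state is
  deliberately not modelled — the simplest model with exactly controllable
  true activity wins here.
* **Frames** (`render_frames()`): a disc with edge-coverage anti-aliasing
  on constant background plus optional Gaussian pixel noise; with zero
  noise the rendered centroid matches the true position to within 0.5 px.
* **Cohorts** (`generate_cohort()`): activity =
  `clamp01(baseline + replicate + individual + stage x infection +
  drift_per_day * day + residual)` with variance components defaulting to
  the study-scale values (id 0.0031, replicate 0.0004, residual 0.0231) and
  stage effects `effect_suppression = -0.2`, `effect_enhancement = +0.1`.
  The habituation drift observed in uninfected hosts has no published
  magnitude; the default (`0.002` per day) is deliberately small — chosen,
  together with `baseline = 0.5`, so that clamping to the proportion scale
  touches fewer than 1% of draws. Clamping on the raw proportion scale
  (rather than simulating on the logit scale) matches the measured scale
  but introduces a slight boundary bias; keep effects modest if you care.
* **Heritability** (`generate_experiment()`): selection acts on the score,
  and a per-host *activity intercept cancels exactly* in a post-minus-pre
  score — so the generator carries a separate latent manipulation-amplitude
  trait `m ~ N(0, trait_sd^2)`, expressed in infected hosts as `-m/2`
  during suppression and `+m/2` during enhancement (score gain `+m`).
  `trait_sd = 0.07` makes the total score SD about 0.14, the scale implied
  by the study's residual variance and the spread of its printed control
  differentials. Offspring follow the breeder's-equation regression
  `pop_mean + h2 (midparent - pop_mean) + segregation noise`, where
  `pop_mean` is the mean of the population the parents were selected from:
  the common replicate pool in the founding generation, afterwards the
  line × replicate population — so transmitted gains persist while each
  round of selection regresses at slope `h2`. With `h2 = 0` offspring are
  independent of parental selection; with `h2 = 1` and no segregation noise
  they reproduce the selected-parent mean. Segregation noise defaults to
  `trait_sd / sqrt(2)` (half the additive variance, the infinitesimal-model
  convention).

Seeding is counter-based throughout: one master seed, per-copepod and
per-frame substreams, so generating a subset never shifts the draws of the
rest.

### What the generator does *not* emulate

Real drop-plate footage has uneven illumination, reflections at well
edges, molting and debris, occasional double occupancy, and animals whose
appearance changes with orientation; the renderer draws a disc. Real
mortality censors hosts non-randomly; the generator models complete
schedules and lets the scoring layer handle missingness injected by tests.
Real inheritance involves mate pairing, maternal effects and unequal family
sizes; the generator's infinitesimal recursion has none of these. Passing
tests therefore demonstrate that the *analysis* is correct and calibrated
under the stated statistical structure — not that the tracker would be
robust on arbitrary field video.

## A worked run

```{r example, eval = FALSE}
ex <- generate_experiment(cohort_params(n_per_cell = 200, h2 = 0.5,
                                        seed = 1),
                          n_generations = 4)
ex$outcomes |> filter(generation == "F0")
plot_selection_response(ex)

rec <- ex$records |> filter(generation == "F0", day <= 8)
repeatability(rec, nboot = 200, seed = 1)
```

## Problem sizes and numerical choices

The package's own checks run at deliberate scales: tracker exactness on 100
noise-free 46-frame sequences; selection arithmetic against exhaustive
subset enumeration on gridded pools up to size 12; the regime-sign pattern
on 50 replicate experiments at 200 hosts per line × status; repeatability
recovery on 500 × 3 designs over 20 seeds; LRT calibration on 1000 null
simulations. Degenerate inputs fail loudly and specifically: empty pools
name their line × replicate, detection failures carry their frame index,
all-missing interval sets refuse to produce an activity, and singular
designs are refused rather than silently reduced.

Two calibration notes from those runs. First, a pooled control-line
differential has standard deviation around 0.022–0.025 under the default
variance structure (30 breeders drawn from 600), so individual control
differentials a little beyond ±0.05 are expected occasionally — matching
the spread of the published control values. Second, variance components for
a random factor with very few levels (the study has three replicates) are
not precisely estimable from any single experiment; recovery checks
therefore use many synthetic replicates, and real-data replicate variances
should be read as order-of-magnitude.

## Known limitations

* The detector is single-target; two animals in a well will be merged or
  mis-tracked (the largest blob wins).
* Gaussian models on proportions are adequate away from the boundaries but
  the package does not model boundary inflation; the logit option is a
  mitigation, not a cure.
* The published dataset's column layout is not bundled; `load_dryad_adapter()`
  requires an explicit mapping and refuses to guess.
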