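---
title: "Lick microstructure and sucrose preference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lick microstructure and sucrose preference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickspt)
```

## The measurement problem

The two-bottle sucrose preference test (SPT) is the workhorse assay for
anhedonia-like behavior in rodents: a mouse chooses freely overnight
between water and a dilute (1–2%) sucrose solution, and preference is the
percentage of total intake taken from the sucrose bottle,

$$\mathrm{preference} = 100 \cdot \frac{S}{S + W}.$$

Weighing bottles gives one number per night. Contact lickometry gives the
same number *plus* the complete temporal structure of drinking: when the
mouse licks a bottle, a junction potential (~400 mV) closes a circuit and
is digitized as a positive voltage deflection, so every individual lick is
timestamped. `lickspt` implements the full analysis chain from those
voltage traces to per-mouse preference, microstructure, and memory
metrics, together with a generative simulator of mouse-nights that lets
every stage be validated against known ground truth without animal data.

## Detection: from voltage to lick trains

A lick is detected as a local maximum of the trace with **topographic
prominence** above 80 mV and **width at half-prominence** between 15 and
80 ms; the lick time is the peak sample time. Prominence (the height of a
peak above the higher of the two lowest points separating it from higher
terrain) makes detection robust to slow baseline drift without any
filtering; the width band rejects both electrical spikes and slow
artifacts. Detected events closer than 50 ms apart are double peaks — a
single tongue contact bouncing — and are removed by a greedy
left-to-right scan that keeps a lick only if it falls at least 50 ms
after the last *kept* lick (the first lick is always kept). This
kept-anchor convention is deterministic and independent of peak
amplitudes; the scan is idempotent and never increases the lick count.
An optional running-median detrend (off by default) is exposed for
recordings with baseline wander; the default assumes, as the detection
rule itself does, that prominence already absorbs slow drift.

No installed peak finder computes topographic prominence and
half-prominence width, so `detect_licks()` implements them directly; the
implementation is tested against a brute-force $O(n^2)$ oracle that walks
outward from every local maximum sample by sample.

## Microstructure: ILI classes and bouts

Mouse licking is rhythmic at roughly 8 Hz. The interlick-interval (ILI)
histogram accordingly separates into three groups, interpreted as
uninterrupted rhythmic licking and the "miss" of one or two licks:

* **burst** — ILI < 180 ms (the large majority, >90%),
* **cluster** — 180–320 ms (one missed lick),
* **pause** — 320–1000 ms (two missed licks).

Intervals of 1 s or more separate **lick bouts**, defined as four or more
consecutive licks with all internal ILIs < 1 s. Binning is half-open
`[a, b)` everywhere — the verbal boundaries ("<180", "180–320", ">320")
leave membership of the boundary values ambiguous, and a fixed convention
makes every test exact: an ILI of exactly 180 ms is a cluster, and an ILI
of exactly 1.000 s splits a bout. Intrabout lick frequency is
$(n-1)/\mathrm{duration}$ — an $n$-lick bout spans $n-1$ intervals — and
session-level licks/bout and intrabout frequency are unweighted means
over bouts. The fraction ">90% in the burst group" is reported as a
fraction of within-bout *ILIs*; whether the corresponding verbal claim
concerns ILIs or the licks carrying them is ambiguous, and the ILI
reading is the one the classifier computes (for rhythmic licking the two
differ by at most one count per run).

## Preference, memory, and windows

Beyond preference, two event-level metrics read out reward-location
memory:

* **quick switches** — transitions between bottles with < 60 s (strict)
  between the last lick at one bottle and the first at the other,
  tallied by direction; an excess of water→sucrose switches indicates
  error correction;
* **returns after a pause** — on the merged two-bottle timeline, every
  gap > 5 min (strict) defines a return, attributed to the bottle of the
  first lick after the gap; preferential returns to sucrose indicate
  memory of its location. The interval before the session's first lick
  is not a pause (a return presupposes a previous visit). A per-bottle
  variant (pause evaluated within each bottle's own train) is available
  behind a flag; the merged-timeline reading is primary because a
  "pause from drinking" most naturally means no drinking at either
  bottle.

Windowed analyses (first 2 h and last 2 h of the dark phase, half-open)
recompute all counts on clipped trains; memory emergence within a night
appears as a higher sucrose-return fraction late than early. Windows are
attached only when the dark phase spans at least 2 h.

Night averaging aligns bottles by **content**, not side — the sucrose
bottle switches sides between nights by design — and the final preference
is the unweighted arithmetic mean of per-night preferences (not a pooled
volume ratio). After chronic stress, mice below 70% final preference are
classified susceptible, others resilient; exactly 70.0% is assigned
resilient as a documented tie-break, since the defining inequalities are
strict on both sides.

## Quality control

A working lickometer yields a tight linear relation between volume
consumed and licks recorded, so all bottle-session points (one per bottle
per session) are pooled into a least-squares fit of volume on licks and
the $R^2$ is reported; on clean cohorts it exceeds 0.8 comfortably.
Session exclusion, done visually in practice, needs an automated
surrogate here. A first candidate — classical studentized residuals of
the OLS fit — turns out to be the wrong tool under this error model:
weighing noise is multiplicative, so raw-scale residuals scale with
volume, and the large sucrose volumes are systematically over-flagged
(most clean small cohorts acquire a false flag). `qc_cohort()` therefore
judges outliers on the ratio scale: residuals
$\log(\mathrm{volume}/\mathrm{expected})$ against a robust proportional
reference (the median per-lick volume, immune to the outlier itself),
robustly studentized by median/MAD, flagged at $|z| > 3$. Classical
studentized residuals are still computed and reported alongside.

Flag semantics follow the failure modes of the hardware: a positive
ratio residual (volume excess per lick) is labeled `leak`, a negative
one (lick excess or volume deficit) `connection`, sessions below a
minimum lick count (default 50) `low_signal`, and unknown volumes
`manual`. A leak and a dropped connection can produce the same positive
signature — volume high relative to recorded licks — so the labels
describe the signature, not a certain cause; precedence for a session's
primary reason is leak > connection > low_signal.

## The generative simulator

No generative model of SPT drinking accompanies the analysis it
validates, so the simulator is this package's own construction,
constrained by the qualitative structure the metrics are meant to
detect. A session is drawn as follows:

1. **Bout initiation** is an inhomogeneous Poisson process (sampled by
   thinning) under a circadian envelope: Gaussian bumps about 1 h and
   9 h after dark onset with a trough between, a small dark-phase
   baseline, and near-zero intensity after lights-on. This is the
   simplest intensity reproducing the observed two-spike overnight
   raster. Default rate: 10 bouts/h at unit envelope, ~65 bouts/night.
2. **Bottle choice**: ordinarily Bernoulli with
   $p = \rho/(1+\rho)$ where $\rho$ is the sucrose/water bout-rate
   ratio (default 3). If the bout follows a >5-min drinking-free gap it
   is a *return*, and the choice instead uses the location-memory
   probability `p_return_sucrose` (default 0.8), optionally ramped
   linearly across the night to emulate within-night learning — the
   minimal time-varying model given that memory measurably emerges only
   late in the night.
3. **Bout size**: $4 + \mathrm{NegBin}$ (means 15 water / 30 sucrose,
   dispersion 3), encoding the 4-lick bout floor and overdispersed
   sizes.
4. **Within-bout ILIs**: a base interval $\sim N(120, 20^2)$ ms,
   multiplied by exactly 2 (probability `p_skip1` = 0.04, a cluster) or
   3 (`p_skip2` = 0.01, a pause) — the direct encoding of the
   missed-lick interpretation. Base draws are truncated so each mixture
   component maps exactly onto its classification group and never
   violates the 50 ms floor; the expected within-bout class fractions
   are therefore exactly $(1-s_1-s_2,\; s_1,\; s_2)$.
5. **Error probes**: with probability `p_error_switch` (default 0.1) a
   sucrose-intended bout is preceded by a 1–3-lick water probe 5–30 s
   earlier — the substrate of water→sucrose quick switches. Probes are
   *not* inserted on return bouts: a probe would become the first lick
   after the pause and re-attribute the return, making
   `p_return_sucrose` unidentifiable from return counts. With that
   choice, measured returns equal the generator's memory draws exactly,
   and the probability is recoverable to ±0.05 from ~50 pauses/night.
6. **Volumes**: 0.002 mL per lick times lognormal noise with 10% CV
   (weighing error scales with amount and keeps volumes positive).
7. **Voltage rendering** (optional): one Gaussian pulse per lick
   (~400 mV, FWHM 18–45 ms), additive noise, and double-peak echoes
   38–44 ms after the main pulse at a configurable rate — inside the
   <50 ms exclusion window with margin for detection jitter, so the
   cleaning filter restores exact counts.

Condition presets encode the qualitative group differences: `naive`
(defaults above), `acute` (fewer but larger bouts, front-loaded
envelope, weakened returns), `chronic_susceptible` ($\rho = 1.5$,
sucrose bouts barely larger than water, returns near chance — final
preference ~60%, below the 70% cutoff by construction) and
`chronic_resilient` (near-naive, ~83%).

The inter-bout gap distribution is not empirically constrained; it falls
out of the thinned Poisson process plus a 1.5 s refractory after each
bout (which guarantees generated bouts are identifiable by the 1 s
criterion). This is a modeling choice, flagged as such. Other realities
the simulator does not attempt: drinking-independent cage activity,
bottle-side biases, lick-amplitude physiology, slow electrode drift, and
any coupling between stress and circadian phase beyond the acute
front-loading preset.

```{r example}
s <- simulate_session(sim_config(seed = 42))
s
classify_ilis(c(compute_ilis(s$water), compute_ilis(s$sucrose)))
segment_bouts(s$sucrose)
```

## What passing tests do and do not show

Because the simulator is built from the same definitions the metrics
implement, end-to-end tests demonstrate *internal consistency* — the
pipeline recovers the parameters and class fractions it was told to
generate, detection inverts rendering, QC catches injected artifacts —
not fidelity to any real cohort. Real-animal effect sizes (group
differences under stress, sex effects) depend on the animals and are out
of scope; the presets only reproduce directions of effects, calibrated
by construction.

## Numerical conventions and problem sizes

All windows and bins are half-open; all thresholds are strict
inequalities as stated (`<50 ms`, `<60 s`, `>5 min`, `<1000 ms`,
`<70%` / `>70%` with the 70.0 tie-break). Session time is seconds from
recording start; lights-off anchors travel in metadata. Determinism:
every stochastic routine takes an integer seed, cohort sessions use
consecutive seeds in mouse-major order, and the RNG state of the caller
is restored afterwards.

Validation problem sizes were chosen so the whole suite runs in a few
minutes on one core: property tests use 1,000 random trains per
operation; the detection round trip uses 20 seeds of 500 licks at
2 kHz; parameter recovery uses 50 sessions (with
`p_return = \rho/(1+\rho)` for the bout-ratio estimate, the
homogeneous-choice condition under which every bout is informative
about $\rho$); the learning-ramp check uses a 12 h stationary scenario
at 12 bouts/h — near the rate that maximizes the number of >5-min-pause
returns per 2 h window — over 50 seeds.

## Known limitations

* Exclusion reasons are signature-based; a leak and a lost connection
  are not distinguishable from the volume–lick fit alone.
* The QC reference line is proportional (no intercept); real lickometers
  with a constant per-session dead volume would need the intercept term,
  at some cost in robustness at small cohort sizes.
* Detection assumes positive-going pulses from a voltage-mode contact
  lickometer; other sensor dialects are out of scope.
* With heavy trace noise the detected peak time jitters by a few
  milliseconds; the ±1-sample timing guarantee holds for noise-free
  pulses only.
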