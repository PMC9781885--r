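---
title: "Minute-by-minute intensity zones from metabolic power events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minute-by-minute intensity zones from metabolic power events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpezones)
```

## The problem

Conventional soccer load monitoring summarises a whole match with a handful
of aggregate GPS metrics — total distance, high-speed-running distance,
sprint counts. These collapse 90 minutes of strongly non-stationary effort
into single numbers and depend on vendor-specific speed thresholds. An
energy-expenditure view avoids the threshold problem: wearable providers
estimate *metabolic power* (W/kg) from speed and acceleration, detect
*metabolic power events* (MPEs) — short phases where estimated power
exceeds what oxygen uptake can supply — and report aggregate energetic
metrics over fixed 5-minute windows (GM-5MIN).

`mpezones` rebuilds game intensity at one-minute resolution from these two
streams, clusters the minutes into low / middle / high intensity zones,
quantifies how much more between-game variability those zones expose than
whole-game speed-band metrics, and tracks a player's capability to shift
into and sustain high intensity with a Markov-chain index.

## The feature model

Every played minute of every player is described by 25 features in three
blocks:

* **GM-5MIN-PRIOR** (12): the provider's 5-minute aggregates over the
  5 minutes preceding the minute — distance, MPE count, anaerobic energy,
  average metabolic power, average MPE time / recovery time / recovery
  power, walking / running / general energy, plus two cumulative fields
  (total MPE count and total energy since kickoff).
* **MPE-PRIOR** (9): event-stream aggregates over the preceding 3 and
  5 minutes — MPE energy, counts, recovery times and average recovery
  times, plus cumulative recovery time.
* **MPE-CURRENT** (4): the observed minute itself — MPE energy, event
  count, recovery time and average recovery time.

Event energy is average power times duration,
$E_{\mathrm{MPE}} = P_{\mathrm{avg}} \cdot t$ (J/kg). A window containing
$N$ events has $N+1$ recovery periods, so its average recovery time is

$$t_{\mathrm{avg\,recovery}} = \frac{t_{\mathrm{recovery}}}{N + 1},$$

which makes a fully rested minute average exactly 60 s — the signature of
the low-intensity zone — and gives 42/(4+1) = 8.4 s for a minute holding
four events totalling 18 s of work.

Alignment choices that the provider format forces on us:

* Minutes are half-open $[60m, 60(m+1))$; an event belongs to the minute
  containing its start (events are short, median ≈ 5.8 s).
* "Work" inside a window is the union overlap of event intervals with the
  window, so boundary-straddling events contribute only their overlap and
  duplicated vendor rows cannot double-count.
* The preceding 5 minutes of an arbitrary minute straddle at most two
  fixed provider windows; extensive fields (distances, energies, counts)
  take the time-weighted sum, intensive fields (averages) the
  time-weighted mean. This is the unbiased reconstruction when activity is
  uniform within a window, which is the best available assumption.
* Minutes whose preceding 5 minutes have no provider data (the first five
  minutes of the game, and of a substitute's participation) are flagged
  `excluded`. Second-half opening minutes are *not* flagged: their prior
  windows exist (the halftime lull) and the 200 m distance rule removes
  them from training, which matches how the method's own account
  attributes the exclusion.

## Denoising, reduction, clustering

Per feature, values above the corpus-level 99.5th-percentile ceiling are
clipped to it. The ceiling uses the type-1 (order statistic) quantile so
that clipping is exactly idempotent. Features are then min-max normalised
with bounds fit on training rows only; PCA keeps the smallest component
count reaching 92% explained variance by default (a fixed
`n_components = 7` override reproduces the reference configuration, whose
seven components carried 92.8% on the original club data); K-means
(k-means++ seeding, Lloyd iterations, 10 restarts, tolerance 1e-6) is run
for $k \in \{2, \dots, 15\}$ and $k$ is chosen by the farthest point from
the chord through the first and last WCSS values — an automated elbow with
ties broken to the smallest $k$.

Rows excluded from training (no prior coverage, or preceding-5-min
distance below 200 m — halftime recovery and half openings) are assigned
`unclassified` rather than forced into a zone, because they would inflate
the low-intensity cluster with artefacts of the schedule rather than of
effort.

With $k = 3$ the clusters are labelled semantically: the cluster with the
lowest mean observed-minute event count is **low** (no MPE activity); of
the remaining two, the one with the greater mean preceding-5-min general
energy is **high**, the other **middle**. This mirrors the empirical
cluster profiles: the low zone is an *active recovery* state that tends to
follow heavy expenditure, so prior energy separates high from middle while
current activity separates low from both.

## What the synthetic generator emulates — and what it does not

Real match exports are proprietary, so the package ships a generator whose
world is stated once and then frozen:

* **Event durations**: log-normal truncated at 20 s, with parameters
  solved numerically so the truncated distribution has median 5.8 s and
  mean 6.5 s (the empirical SD ≈ 3.3 s then emerges; the reference corpus
  reports 3.35 s).
* **Energy split**: background (non-MPE) power is rescaled so MPE energy
  is 30% of total energy in expectation at corpus level, matching the
  provider's reported share; the remaining 70% flows through the 5-minute
  aggregates.
* **Hidden regimes**: a first-order, three-state Markov chain at 1-minute
  resolution drives event rate (0.1 / 2.0 / 5.5 per min), event power,
  background power, distance per minute (50 / 105 / 160 m) and speed-band
  shares. The stationary mix is ≈ 27% low / 46% middle / 26% high.
* **Schedule**: 45-min halves separated by a 15-min halftime lull
  (near-zero distance, forcing the 200 m exclusion), kickoff-continuous
  clock, substitutions with partial provider windows, Poisson goal times.
* **Game-to-game variation**: a per-game log-normal multiplier on
  transition probabilities into the high regime makes intensity mixes
  vary strongly between games, qualitatively like the large between-game
  CVs of cluster fractions observed on real data; an optional
  `high_decay` parameter emulates fatigue by shrinking transitions into
  the high regime linearly over the game.

**Deliberate departures from realism.** The default regime process is
*more persistent and more separated* than real match intensity: mean dwell
times are ≈ 25–35 minutes and per-regime event rates differ by ≥ 1.5
events/min, whereas real cluster profiles show per-minute event counts of
roughly 0 / 1.8 / 2. This is intentional. Since 21 of the 25 features
describe the preceding 3–5 minutes, the current-minute regime is only
recoverable by clustering when regimes persist well beyond the 5-minute
aggregation window; the defaults are an *identifiability-first validation
world* in which the pipeline's correctness (elbow at $k = 3$, adjusted
Rand index ≥ 0.7 against ground truth) can be verified mechanically. A
green recovery test therefore establishes that the pipeline recovers
structure that is present — not that real games contain structure this
clean, nor that real analyses will reach these agreement levels. The
generator also does not simulate raw GPS trajectories, tactics, opponent
quality or scoreline feedback on effort.

The CV-comparison scenario (`sim_config_cv_scenario()`) is likewise a
designed world: regime mixes vary strongly between games while speed-band
shares are nearly regime-independent, so whole-game band fractions barely
move. Under it, cluster-fraction CVs must exceed the speed-band-proxy CVs
in every zone — the qualitative claim made against conventional metrics.
The reference headline CVs (45.91/30.66/24.41% vs 21.32/16.82/19.12%)
derive from one club's private data and are not reproduction targets.

## Markov fitness index

Transitions are counted only between temporally adjacent classified
minutes; halftime, substitutions and unclassified minutes break the chain.
Counts are Laplace-smoothed (α = 0.5 by default) before row
normalisation. The fitness score is a documented **proxy**:
$\pi_{\mathrm{high}} + 0.5\,P(\mathrm{middle} \to \mathrm{high})$, clipped
to $[0, 1]$, where $\pi$ is the stationary distribution — a monotone
measure of the propensity to reach and sustain high intensity. The exact
index defined in the original appendix is not available in the source
text; the proxy is isolated behind a single pluggable `score_fn` argument
so a reader with that appendix can substitute the exact definition. If
smoothing still leaves a reducible chain, the fallback score is the
fraction of transitions entering the high state, with a warning.

## Numerical choices and degenerate inputs

* Duration calibration: Nelder-Mead on (meanlog, log sdlog), squared
  error on the truncated median and mean, tolerance 1e-14; an error is
  raised if the residual exceeds 1e-8.
* K-means: empty clusters are re-seeded at the point farthest from its
  centroid; restarts use seeds derived deterministically from the master
  seed, recorded in `training_meta`.
* Constant features min-max-map to 0 with a warning rather than erroring,
  so degenerate corpora (e.g. a player with no events) remain processable.
* A 0.5 s tolerance absorbs vendor rounding between `duration_s` and
  `end_s − start_s`.
* Unseen values outside the training min-max bounds are *not* clipped at
  transform time (the ceiling already bounds training influence), so
  assignment of out-of-range minutes degrades continuously.
* CVs use the population SD; at 60–80 games the difference from the
  sample SD is below 1%, and the per-game fraction triples are explicitly
  normalised to sum to 1.

## Known limitations

* The GM-5MIN-PRIOR reconstruction assumes within-window uniformity; a
  provider exporting 1-minute aggregates would make it exact.
* Cluster labels are only comparable across corpora fitted with the same
  model; the package deliberately refuses to compare MFit points across
  different fitted models.
* The elbow rule inherits the weaknesses of WCSS elbows: on data without
  clear cluster structure the chord criterion can select neighbouring k;
  the fitted `training_meta$wcss` is stored so the curve can be inspected.
* Positions are carried in the metadata and a per-position aggregation is
  available in the analysis layer, but no position-specific modelling is
  attempted.
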