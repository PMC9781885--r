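# mpezones

Minute-by-minute intensity zones for soccer from metabolic-power wearable
data.

## What it does, and for whom

Strength-and-conditioning staff usually monitor match load with whole-game
GPS aggregates (total distance, high-speed running above a threshold).
Those numbers average away the structure of the game: a match can look
"average" while hiding a furious first half and a flat second. `mpezones`
is for sports scientists and performance analysts who want load described
*as the game unfolds*, using energy-based metrics that do not depend on
vendor speed thresholds.

The package consumes two provider-level streams per player per match —

* an **MPE stream**: one row per *metabolic power event* (a short
  high-intensity phase where estimated metabolic power exceeds what
  oxygen uptake can supply), with start/end time, duration, max speed and
  average power, and
* **GM-5MIN**: energetic aggregates over fixed 5-minute windows
  (distance, MPE count, anaerobic energy, average metabolic power,
  walking/running/general energy, recovery metrics) —

and builds, for every played minute, a 25-feature record combining the
preceding 5-minute aggregates (GM-5MIN-PRIOR), event-stream aggregates
over the preceding 3 and 5 minutes (MPE-PRIOR), and the observed minute
itself (MPE-CURRENT). Event energy follows

> E_MPE = P_avg · t  (J/kg),

and average recovery time in a window with N events and total recovery
time t_recovery is

> t_avg_recovery = t_recovery / (N + 1),

so a fully rested minute averages exactly 60 s (and a 60 s frame with
4 events totalling 18 s of work averages 42/(4+1) = 8.4 s).

After ceiling denoising at the corpus 99.5th percentile, min-max
normalisation, PCA (components kept to reach 92% variance) and K-means
over k = 2…15 with an automated WCSS elbow, each minute is assigned to a
**low / middle / high** intensity zone (or `unclassified` for minutes
without 5 prior minutes of play, including the halftime lull caught by a
200 m minimum-distance rule). On top of the assignments the package
computes per-player timelines with goal annotations, 5-minute interval
distributions, a per-game load summary compared against whole-game
speed-band proxies via the coefficient of variation, and a Markov-chain
fitness index (stationary high-state occupancy plus half the
middle→high transition probability) for tracking players across training
cycles.

Because real exports are proprietary, a regime-switching simulator
generates full corpora (MPE stream + consistent 5-minute aggregates +
game totals + metadata) with known per-minute ground truth, calibrated to
published corpus statistics (event duration median 5.8 s / mean 6.5 s,
truncation at 20 s, MPE energy ≈ 30% of total energy).

## Worked example

```r
library(mpezones)

cfg     <- sim_config(n_games = 6, players_per_game = 8, seed = 42)
corpus  <- simulate_corpus(cfg)
feats   <- build_minute_table(corpus$events, corpus$windows, corpus$meta)
model   <- fit_intensity_model(feats, seed = 17)
print(model)
#> <intensity_model> k = 3, 4 PCA components (92.6% variance), 3881 training minutes
#> labels: 1=middle, 2=high, 3=low

a <- assign_intensity(model, feats)
table(a$label)
#>         high          low       middle unclassified
#>          965         1040         1876          439

summaries <- lapply(unique(corpus$totals$game_id),
                    function(g) summarize_game(a, corpus$totals, g))
cv_report(summaries)
#>     group  method       mean         sd cv_percent n_games
#> 1:   high cluster 0.24880973 0.09980373  40.112472       6
#> 2:   high   proxy 0.07352801 0.01648501  22.420036       6
#> 3: middle cluster 0.48307682 0.11147097  23.075206       6
#> 4: middle   proxy 0.66437163 0.01391428   2.094351       6
#> 5:    low cluster 0.26811345 0.03973471  14.820112       6
#> 6:    low   proxy 0.26210036 0.02901053  11.068480       6
```

The elbow lands on three zones and the PCA keeps 4 components for 92.6%
of the variance of this synthetic corpus. Per game, the share of team
minutes per zone (`cluster`) varies far more between games than the
whole-game speed-band shares (`proxy`) — e.g. CV 40.1% vs 22.4% for the
high zone — which is the point of the minute-level view: conventional
aggregates barely distinguish games that demanded very different
high-intensity loads. Fitness tracking:

```r
a[, window := game_id]      # one tracking window per game
head(track_mfit(a), 3)
#>    player_id window      mfit n_transitions
#> 1:  g001_p01   g001 0.5679235            61
#> 2:  g001_p02   g001 0.4122807            81
#> 3:  g001_p03   g001 0.6469761            79
```

Higher `mfit` means the player reaches and sustains the high-intensity
state more readily in that window.

A command-line interface wrapping the same stages (simulate /
build-features / cluster / analyze / mfit / pipeline) ships in
`inst/cli/mpezones.R`; `run_pipeline()` (YAML or JSON config) executes
everything and writes a reproducibility manifest.

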