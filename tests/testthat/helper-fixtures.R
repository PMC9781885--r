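# Shared fixtures. Simulated corpora are cached per test run; everything is
# generated in code under fixed seeds chosen before the suite was frozen.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_cfg <- function(seed = 42L, ...) {
  sim_config(n_games = 2L, players_per_game = 3L, n_substitutions = 1L,
             seed = seed, ...)
}

tiny_corpus <- function() cached("tiny_corpus", simulate_corpus(tiny_cfg()))

tiny_features <- function() cached("tiny_features", {
  co <- tiny_corpus()
  build_minute_table(co$events, co$windows, co$meta)
})

# acceptance-scale default corpus (20 games x 10 starters)
accept_corpus <- function() cached("accept_corpus",
                                   simulate_corpus(sim_config(seed = 1L)))

accept_fit <- function() cached("accept_fit", {
  co <- accept_corpus()
  feats <- build_minute_table(co$events, co$windows, co$meta)
  model <- fit_intensity_model(feats, seed = 17L)
  list(features = feats, model = model,
       assignments = assign_intensity(model, feats))
})

# independent brute-force re-scan of the event list for prior-window
# counts/energies (events attributed by start time)
naive_prior <- function(ev, minute, width_min) {
  lo <- minute * 60 - width_min * 60
  hi <- minute * 60
  sel <- ev$start_s >= lo & ev$start_s < hi
  list(count = sum(sel), energy = sum(ev$energy_jkg[sel]))
}

# independent transition-count oracle: explicit loop over an assignment table
naive_transition_counts <- function(assignments) {
  states <- c("low", "middle", "high")
  counts <- matrix(0, 3, 3, dimnames = list(states, states))
  a <- assignments[order(assignments$game_id, assignments$player_id,
                         assignments$minute), ]
  for (i in seq_len(nrow(a) - 1)) {
    same <- a$game_id[i] == a$game_id[i + 1] &&
      a$player_id[i] == a$player_id[i + 1]
    if (same && a$minute[i + 1] == a$minute[i] + 1 &&
        a$label[i] %in% states && a$label[i + 1] %in% states)
      counts[a$label[i], a$label[i + 1]] <- counts[a$label[i], a$label[i + 1]] + 1
  }
  counts
}

regime_label <- function(regime) c("low", "middle", "high")[regime + 1L]
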