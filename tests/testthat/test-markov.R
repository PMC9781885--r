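seq_assign <- function(labels, minutes = seq_along(labels) - 1L,
                       game = "g1", player = "p1") {
  data.table::data.table(game_id = game, player_id = player,
                         minute = minutes, label = labels)
}

test_that("transitions are counted between adjacent classified minutes only", {
  tm <- fit_transitions(seq_assign(c("low", "low", "high", "middle")), alpha = 0)
  expect_equal(tm$counts["low", "low"], 1)
  expect_equal(tm$counts["low", "high"], 1)
  expect_equal(tm$counts["high", "middle"], 1)
  expect_equal(tm$n_transitions, 3)

  # unclassified minutes and gaps break the chain
  tm2 <- fit_transitions(seq_assign(c("low", "unclassified", "high", "high")),
                         alpha = 0)
  expect_equal(tm2$n_transitions, 1)
  tm3 <- fit_transitions(seq_assign(c("low", "low", "high"),
                                    minutes = c(0L, 1L, 44L)), alpha = 0)
  expect_equal(tm3$n_transitions, 1)
  expect_error(fit_transitions(seq_assign(c("low", "unclassified", "low"))),
               "no valid transitions")

  # smoothing keeps rows stochastic
  tm4 <- fit_transitions(seq_assign(c("low", "low", "high", "middle")), alpha = 0.5)
  expect_equal(rowSums(tm4$probs), c(low = 1, middle = 1, high = 1))
})

test_that("stationary distribution is the chain's fixed point", {
  perm <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE)
  expect_equal(unname(stationary_distribution(perm)), rep(1 / 3, 3))

  P <- default_regime_transition()
  pi_s <- stationary_distribution(P)
  expect_equal(unname(pi_s %*% P), unname(t(pi_s)), tolerance = 1e-9)
  # independent oracle: long-run power iteration
  Pn <- P
  for (i in 1:1000) Pn <- Pn %*% P
  expect_equal(unname(pi_s), unname(Pn[1, ]), tolerance = 1e-9)

  red <- matrix(c(1, 0, 0, 0.5, 0.5, 0, 0, 0, 1), 3, byrow = TRUE,
                dimnames = list(c("low", "middle", "high"), NULL))
  expect_error(stationary_distribution(red), "reducible")
})

test_that("mfit proxy is bounded and tracks high-state occupancy", {
  never_high <- fit_transitions(
    seq_assign(rep(c("low", "middle"), 30)), alpha = 0.1)
  m1 <- mfit_index(never_high)
  expect_lt(m1$mfit, 0.05)

  absorbed <- fit_transitions(
    seq_assign(c("middle", rep("high", 80))), alpha = 0.01)
  expect_gt(mfit_index(absorbed)$mfit, 0.9)

  # monotone in the generator's high-state dwell across >= 5 settings
  dwell <- c(0.05, 0.15, 0.3, 0.5, 0.7)
  scores <- vapply(dwell, function(h) {
    P <- matrix(c(0.8, 0.2 - h / 10, h / 10,
                  0.2, 0.8 - h / 2, h / 2,
                  0.1, 1 - h - 0.1, h), 3, byrow = TRUE,
                dimnames = list(c("low", "middle", "high"),
                                c("low", "middle", "high")))
    tm <- structure(list(player_id = "p", counts = P * 100, probs = P,
                         n_transitions = 300, alpha = 0),
                    class = "transition_model")
    mfit_index(tm)$mfit
  }, numeric(1))
  expect_equal(order(scores), seq_along(scores)) # rank correlation 1
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("estimated transitions converge to the generator on long chains", {
  cfg <- sim_config(n_games = 6L, players_per_game = 10L,
                    game_intensity_sd = 0, seed = 31L)
  co <- simulate_corpus(cfg)
  tr <- data.table::copy(co$truth)
  tr[, "label" := regime_label(tr$regime)]
  tm <- fit_transitions(tr[, c("game_id", "player_id", "minute", "label")],
                        alpha = 0.5)
  expect_gte(tm$n_transitions, 5000)
  expect_lt(max(abs(tm$probs - cfg$regime_transition)), 0.05)
  # oracle: explicit-loop transition counting
  expect_equal(unname(tm$counts),
               unname(naive_transition_counts(as.data.frame(
                 tr[, c("game_id", "player_id", "minute", "label")]))))
})

test_that("track_mfit produces one chronological point per player-window", {
  a <- seq_assign(rep(c("low", "middle", "high"), 20))
  a[, "window" := rep(c("w1", "w2"), each = 30)]
  pts <- track_mfit(a)
  expect_equal(nrow(pts), 2L)
  expect_equal(pts$window, c("w1", "w2"))
  expect_equal(pts$mfit[1], pts$mfit[2]) # identical data, identical score
  single <- track_mfit(a[a$window == "w1", ])
  expect_equal(nrow(single), 1L)
  expect_error(track_mfit(a[, -"window"]), class = "mpezones_schema_error")

  # simulated fitness decline across windows
  mk <- function(h_stay, seed) {
    P <- matrix(c(0.85, 0.13, 0.02, 0.10, 0.85, 0.05,
                  0.05, 1 - h_stay - 0.05, h_stay), 3, byrow = TRUE)
    cfg <- sim_config(n_games = 2L, players_per_game = 2L,
                      regime_transition = P, game_intensity_sd = 0,
                      n_substitutions = 0L, seed = seed)
    co <- simulate_corpus(cfg)
    tr <- data.table::copy(co$truth)
    tr[, "label" := regime_label(tr$regime)]
    tr[, "player_id" := "same"] # pool players into one athlete per window
    tr
  }
  stays <- c(0.9, 0.75, 0.55, 0.35)
  pts <- lapply(seq_along(stays), function(i) {
    w <- mk(stays[i], seed = 100 + i)
    w[, "window" := sprintf("w%d", i)]
    track_mfit(w[, c("game_id", "player_id", "minute", "label", "window")])
  })
  scores <- vapply(pts, function(p) p$mfit[1], numeric(1))
  expect_true(all(diff(scores) < 0))
})
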