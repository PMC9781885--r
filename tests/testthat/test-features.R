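test_that("energy and average-recovery primitives follow their formulas", {
  expect_equal(mpe_energy(10.0, 5.8), 58.0)
  expect_equal(mpe_energy(0, 12), 0)
  expect_equal(mpe_energy(7.5, 4.0), 30.0)
  expect_error(mpe_energy(-1, 5), class = "mpezones_validation_error")

  expect_equal(avg_recovery_time(42, 4), 8.4)
  expect_equal(avg_recovery_time(60, 0), 60)
  expect_equal(avg_recovery_time(0, 3), 0)
})

test_that("window_recovery accounts work and recovery in a 60 s frame", {
  # 4 events totalling 18 s of work inside one minute
  ev <- data.frame(start_s = c(5, 20, 35, 50), end_s = c(9, 25, 39.5, 54.5))
  wr <- window_recovery(ev, 0, 60)
  expect_equal(wr$work_s, 18)
  expect_equal(wr$recovery_s, 42)
  expect_equal(wr$n_events, 4L)

  wr0 <- window_recovery(ev[0, ], 0, 60)
  expect_equal(wr0$recovery_s, 60)
  expect_equal(wr0$n_events, 0L)

  span <- data.frame(start_s = -5, end_s = 70)
  wrs <- window_recovery(span, 0, 60)
  expect_equal(wrs$recovery_s, 0)
  expect_equal(wrs$n_events, 0L) # starts before the window
  wrs2 <- window_recovery(data.frame(start_s = 0, end_s = 70), 0, 60)
  expect_equal(wrs2$n_events, 1L)
  expect_equal(wrs2$recovery_s, 0)

  # overlapping events are merged, boundary events clipped
  ov <- data.frame(start_s = c(10, 12, 55), end_s = c(20, 18, 65))
  expect_equal(window_recovery(ov, 0, 60)$work_s, 10 + 5)
})

test_that("a fully played simulated game yields >= 85 usable minutes per player", {
  co <- tiny_corpus()
  g <- co$games[[1]]
  full <- g$meta$lineup$player_id[g$meta$lineup$on_s == 0 &
                                    g$meta$lineup$off_s == g$meta$game_end_s]
  feats <- build_minute_table(g$events, g$windows, g$meta)
  for (p in full) {
    f <- feats[feats$player_id == p, ]
    expect_equal(nrow(f), 90L) # played minutes only; halftime absent
    expect_gte(sum(!f$excluded), 85L)
    expect_true(all(f$excluded[f$minute < 5]))
  }
  # substitutes: first five minutes after entry lack coverage
  # substitutes: minutes whose prior 5 min lack any provider window are
  # excluded (at least the first three after entry; a partial window can
  # cover the tail of the entry span)
  sub <- g$meta$lineup[g$meta$lineup$on_s > 0, ]
  if (nrow(sub)) {
    f <- feats[feats$player_id == sub$player_id[1], ]
    on_min <- sub$on_s[1] / 60
    expect_true(all(f$excluded[f$minute < on_min + 3]))
    expect_false(all(f$excluded))
  }
})

test_that("a player with no MPEs carries zero event features and full recovery", {
  co <- tiny_corpus()
  g <- co$games[[1]]
  p <- g$meta$lineup$player_id[1]
  ev <- g$events[g$events$player_id != p, ] # strip this player's events
  wi <- data.table::copy(g$windows)
  own <- wi$player_id == p
  wi[own, c("mpe_count", "avg_mpe_time_s", "anaerobic_energy_jkg") := list(0L, 0, 0)]
  wi[own, "avg_mpe_recovery_time_s" := wi$time_played_s[own] / 1]
  feats <- build_minute_table(ev, wi, g$meta)
  f <- feats[feats$player_id == p, ]
  expect_true(all(f$cur_event_count == 0))
  expect_true(all(f$cur_mpe_energy_jkg == 0))
  expect_true(all(f$mpe_energy_3min == 0 & f$mpe_energy_5min == 0))
  expect_true(all(f$cur_avg_recovery_time_s == 60))
  expect_true(all(f$avg_recovery_time_3min == f$recovery_time_3min))
  expect_true(all(f$avg_recovery_time_5min == f$recovery_time_5min))
})

test_that("built features agree with independent oracles and invariants", {
  co <- tiny_corpus()
  feats <- tiny_features()
  for (gi in seq_along(co$games)) {
    g <- co$games[[gi]]
    for (p in unique(g$truth$player_id)) {
      ev <- as.data.frame(g$events[g$events$player_id == p, ])
      f <- as.data.frame(feats[feats$game_id == g$meta$game_id &
                                 feats$player_id == p, ])
      # brute-force re-scan of prior windows (counts and energies)
      for (i in seq_len(nrow(f))) {
        o3 <- naive_prior(ev, f$minute[i], 3)
        o5 <- naive_prior(ev, f$minute[i], 5)
        expect_equal(f$mpe_count_3min[i], o3$count)
        expect_equal(f$mpe_energy_3min[i], o3$energy, tolerance = 1e-9)
        expect_equal(f$mpe_count_5min[i], o5$count)
        expect_equal(f$mpe_energy_5min[i], o5$energy, tolerance = 1e-9)
      }
      # Eq. 2 holds exactly at every window length
      expect_equal(f$cur_avg_recovery_time_s,
                   f$cur_recovery_time_s / (f$cur_event_count + 1))
      expect_equal(f$avg_recovery_time_3min,
                   f$recovery_time_3min / (f$mpe_count_3min + 1))
      # work/recovery conservation per fully played minute
      mins <- f$minute
      work <- vapply(mins, function(m) window_recovery(ev, m * 60, 60)$work_s,
                     numeric(1))
      expect_equal(f$cur_recovery_time_s + work, rep(60, nrow(f)),
                   tolerance = 1e-9)
      # cumulative features are nondecreasing
      expect_true(all(diff(f$total_mpe_count) >= 0))
      expect_true(all(diff(f$total_energy_jkg) >= -1e-9))
      expect_true(all(diff(f$total_recovery_time_s) >= -1e-9))
    }
  }
})

test_that("cumulative energy matches an independent sum over the windows", {
  co <- tiny_corpus()
  feats <- tiny_features()
  g <- co$games[[1]]
  p <- g$meta$lineup$player_id[g$meta$lineup$on_s == 0][1]
  f <- feats[feats$player_id == p & feats$game_id == g$meta$game_id, ]
  wi <- as.data.frame(g$windows[g$windows$player_id == p, ])
  last <- f[nrow(f), ]
  t_end <- last$minute * 60
  oracle <- sum(wi$general_energy_jkg[wi$window_start_s + 300 <= t_end]) +
    sum(wi$general_energy_jkg[wi$window_start_s < t_end &
                                wi$window_start_s + 300 > t_end] *
          (t_end - wi$window_start_s[wi$window_start_s < t_end &
                                       wi$window_start_s + 300 > t_end]) / 300)
  expect_equal(last$total_energy_jkg, oracle, tolerance = 1e-9)
})

test_that("apply_ceiling clips at the corpus quantile and is idempotent", {
  feats <- tiny_features()
  one <- data.table::copy(feats)
  one[, "distance_m" := as.numeric(seq_len(nrow(one)))]
  res <- apply_ceiling(one, 0.995)
  # brute-force oracle: smallest observed value covering 99.5% of the data
  n <- nrow(one)
  thr <- sort(seq_len(n))[ceiling(0.995 * n)]
  expect_equal(res$thresholds[["distance_m"]], thr)
  expect_true(all(res$table$distance_m <= thr))
  expect_equal(sum(res$table$distance_m == thr),
               sum(seq_len(nrow(one)) >= thr))

  const <- data.table::copy(feats)
  const[, "mpe_count" := 3]
  expect_equal(apply_ceiling(const)$table$mpe_count, rep(3, nrow(const)))

  twice <- apply_ceiling(res$table, 0.995)
  expect_equal(as.data.frame(apply_ceiling(twice$table, 0.995)$table),
               as.data.frame(twice$table), tolerance = 1e-12)
})
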