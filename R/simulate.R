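## Regime-switching synthetic game generator.
##
## A hidden three-state (low/middle/high) first-order Markov chain at 1-min
## resolution drives, per player: the Poisson rate of metabolic power
## events, event power, background (non-MPE) metabolic power, distance per
## minute and its speed-band split. Five-minute provider aggregates and
## whole-game totals are derived from the same minute stream, so every
## downstream stage has exact ground truth.

#' Simulation configuration
#'
#' Defaults describe a realistic professional game corpus: event durations
#' follow a log-normal truncated at 20 s calibrated to median 5.8 s and
#' mean 6.5 s; MPE energy is ~30\% of total energy in expectation; regimes
#' are persistent (mean dwell ~5-7 min) with stationary mix of roughly
#' 20\% low / 50\% middle / 30\% high; per-game intensity multipliers make
#' the regime mix vary strongly between games.
#'
#' @param n_games number of games in the corpus.
#' @param players_per_game starters per game (substitutes extra, see
#'   \code{n_substitutions}).
#' @param regime_transition 3x3 row-stochastic matrix over (low, middle,
#'   high) minute regimes.
#' @param regime_params data.frame with one row per regime and columns
#'   \code{mpe_rate} (events/min), \code{power_mean}, \code{power_sd}
#'   (W/kg of an event), \code{bg_power_mean} (W/kg of non-MPE activity,
#'   rescaled internally to hit the energy-share target),
#'   \code{dist_mean}, \code{dist_sd} (m/min), \code{walk_share},
#'   \code{above20_share} (fractions of minute distance).
#' @param duration_target named vector (median, mean) of the MPE duration
#'   distribution in seconds; log-normal parameters are solved numerically.
#' @param duration_trunc_s upper truncation of event durations (s).
#' @param mpe_energy_share_target corpus-level fraction of total energy
#'   spent in MPEs.
#' @param game_intensity_sd sdlog of the per-game log-normal multiplier on
#'   transition probabilities into the high regime (0 disables
#'   game-to-game mix variation).
#' @param high_decay fraction by which the probability of transitioning
#'   into the high regime decays linearly from kickoff to the final
#'   minute (0 = homogeneous chain; >0 emulates fatigue).
#' @param n_substitutions substitution pairs per game.
#' @param seed master seed; per-game seeds are derived from it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_games = 20L,
                       players_per_game = 10L,
                       regime_transition = default_regime_transition(),
                       regime_params = default_regime_params(),
                       duration_target = c(median = 5.8, mean = 6.5),
                       duration_trunc_s = 20,
                       mpe_energy_share_target = 0.30,
                       game_intensity_sd = 0.4,
                       high_decay = 0,
                       n_substitutions = 2L,
                       seed = 1L) {
  P <- as.matrix(regime_transition)
  if (!all(dim(P) == c(3L, 3L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    abort("regime_transition must be a 3x3 row-stochastic matrix",
          class = "mpezones_config_error")
  rp <- as.data.frame(regime_params)
  need <- c("mpe_rate", "power_mean", "power_sd", "bg_power_mean",
            "dist_mean", "dist_sd", "walk_share", "above20_share")
  check_cols(rp, need, "regime_params")
  if (nrow(rp) != 3L) abort("regime_params needs 3 rows (low/middle/high)",
                            class = "mpezones_config_error")
  if (any(rp$mpe_rate < 0)) abort("mpe_rate must be >= 0",
                                  class = "mpezones_config_error")
  if (!(mpe_energy_share_target > 0 && mpe_energy_share_target < 1))
    abort("mpe_energy_share_target must be in (0,1)",
          class = "mpezones_config_error")
  dd <- calibrate_duration_lognormal(duration_target[["median"]],
                                     duration_target[["mean"]],
                                     duration_trunc_s)
  structure(list(n_games = as.integer(n_games),
                 players_per_game = as.integer(players_per_game),
                 regime_transition = P,
                 regime_params = rp,
                 duration_dist = dd,
                 duration_trunc_s = duration_trunc_s,
                 mpe_energy_share_target = mpe_energy_share_target,
                 game_intensity_sd = game_intensity_sd,
                 high_decay = high_decay,
                 n_substitutions = as.integer(n_substitutions),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_regime_transition <- function() {
  matrix(c(0.970, 0.025, 0.005,
           0.015, 0.965, 0.020,
           0.005, 0.035, 0.960),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("low", "middle", "high"), c("low", "middle", "high")))
}

#' @rdname sim_config
#' @export
default_regime_params <- function() {
  data.frame(regime = c("low", "middle", "high"),
             mpe_rate = c(0.1, 2.0, 5.5),
             power_mean = c(12, 18, 26),
             power_sd = c(2, 2, 2.5),
             bg_power_mean = c(4.5, 9, 13.5),
             dist_mean = c(50, 105, 160),
             dist_sd = c(4, 5, 6),
             walk_share = c(0.65, 0.28, 0.10),
             above20_share = c(0.00, 0.03, 0.15))
}

#' Scenario configuration for the load-variability comparison
#'
#' A designed corpus in which game-to-game intensity mixes vary strongly
#' (large per-game multiplier spread) while speed-band shares are nearly
#' identical across regimes, so whole-game speed-band fractions barely
#' move between games. Under this world, cluster-based load fractions
#' must show larger between-game CVs than the speed-band proxies in every
#' zone — the qualitative claim the framework makes against conventional
#' whole-game metrics.
#'
#' @param seed master seed.
#' @param n_games games in the corpus.
#' @return a [sim_config()].
#' @export
sim_config_cv_scenario <- function(seed = 2L, n_games = 20L) {
  rp <- default_regime_params()
  rp$walk_share <- c(0.36, 0.34, 0.32)
  rp$above20_share <- c(0.06, 0.07, 0.08)
  sim_config(n_games = n_games, players_per_game = 10L,
             regime_params = rp, game_intensity_sd = 0.8, seed = seed)
}

## Solve log-normal (meanlog, sdlog) so that, after truncation at trunc_s,
## the distribution has the requested median and mean.
calibrate_duration_lognormal <- function(med, mn, trunc_s) {
  if (!(med > 0 && mn > med && trunc_s > mn))
    abort("invalid duration targets (need 0 < median < mean < truncation)",
          class = "mpezones_config_error")
  trunc_stats <- function(mu, sig) {
    z <- (log(trunc_s) - mu) / sig
    denom <- pnorm(z)
    m <- exp(mu + sig^2 / 2) * pnorm(z - sig) / denom
    q <- exp(mu + sig * qnorm(0.5 * denom))
    c(mean = m, median = q)
  }
  obj <- function(par) {
    s <- trunc_stats(par[1], exp(par[2]))
    (s["mean"] - mn)^2 + (s["median"] - med)^2
  }
  fit <- stats::optim(c(log(med), log(0.5)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8)
    abort("duration distribution calibration failed to converge",
          class = "mpezones_config_error")
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

#' Sample metabolic-power-event durations
#'
#' Draws i.i.d. durations from the configured log-normal truncated at
#' \code{cfg$duration_trunc_s} (20 s by default) via inverse-CDF sampling.
#'
#' @param n number of draws (>= 1).
#' @param cfg a [sim_config()].
#' @param seed optional seed for this draw.
#' @return numeric vector of durations in (0, truncation].
#' @export
sample_mpe_duration <- function(n, cfg = sim_config(), seed = NULL) {
  if (n < 1) abort("n must be >= 1", class = "mpezones_config_error")
  dd <- cfg$duration_dist
  pmax_u <- stats::plnorm(cfg$duration_trunc_s, dd$meanlog, dd$sdlog)
  with_seed(seed, {
    u <- runif(n, 0, pmax_u)
    stats::qlnorm(u, dd$meanlog, dd$sdlog)
  })
}

## expected MPE / background energy per played minute under the stationary
## regime mix; used to rescale background power toward the share target
energy_share_scale <- function(cfg) {
  pi_s <- stationary_distribution(cfg$regime_transition)
  dd <- cfg$duration_dist
  z <- (log(cfg$duration_trunc_s) - dd$meanlog) / dd$sdlog
  mean_dur <- exp(dd$meanlog + dd$sdlog^2 / 2) * pnorm(z - dd$sdlog) / pnorm(z)
  rp <- cfg$regime_params
  mpe_per_min <- sum(pi_s * rp$mpe_rate * rp$power_mean * mean_dur)
  bg_per_min <- sum(pi_s * rp$bg_power_mean * 60)
  target_bg <- mpe_per_min * (1 - cfg$mpe_energy_share_target) /
    cfg$mpe_energy_share_target
  target_bg / bg_per_min
}

## game clock layout (seconds since kickoff, continuous through halftime)
HALF1_END_S <- 2700L
HALF2_START_S <- 3600L
GAME_END_S <- 6300L

minute_is_played <- function(minute) {
  sec <- minute * 60
  (sec < HALF1_END_S) | (sec >= HALF2_START_S & sec < GAME_END_S)
}

sample_positions <- function(n) {
  sample(POSITIONS, n, replace = TRUE, prob = c(11, 7, 8, 3, 9) / 38)
}

#' Simulate one game
#'
#' @param cfg a [sim_config()].
#' @param game_id identifier for the game.
#' @param seed seed for this game (defaults to cfg$seed).
#' @return object of class \code{sim_game}: list with \code{events},
#'   \code{windows}, \code{totals} (validated tables), \code{meta}
#'   (\code{game_meta}), \code{truth} (game_id, player_id, minute, regime
#'   in 0/1/2 = low/middle/high) and the internal \code{minute_stream}.
#' @export
simulate_game <- function(cfg = sim_config(), game_id = "g1", seed = cfg$seed) {
  with_seed(seed, simulate_game_impl(cfg, game_id))
}

simulate_game_impl <- function(cfg, game_id) {
  rp <- cfg$regime_params
  P <- cfg$regime_transition
  bg_scale <- energy_share_scale(cfg)
  pi_s <- stationary_distribution(P)

  ## per-game multiplier on transitions into the high regime
  g_mult <- if (cfg$game_intensity_sd > 0)
    stats::rlnorm(1, -cfg$game_intensity_sd^2 / 2, cfg$game_intensity_sd)
  else 1

  ## lineup: starters play the whole game except substitution pairs
  n <- cfg$players_per_game
  starters <- sprintf("%s_p%02d", game_id, seq_len(n))
  on_s <- rep(0L, n)
  off_s <- rep(GAME_END_S, n)
  pos <- sample_positions(n)
  n_sub <- min(cfg$n_substitutions, n)
  if (n_sub > 0) {
    out_idx <- sample(seq_len(n), n_sub)
    sub_min <- sample(65:95, n_sub, replace = TRUE) # game minute incl. halftime gap
    off_s[out_idx] <- sub_min * 60L
    subs <- sprintf("%s_s%02d", game_id, seq_len(n_sub))
    on_s <- c(on_s, sub_min * 60L)
    off_s <- c(off_s, rep(GAME_END_S, n_sub))
    starters <- c(starters, subs)
    pos <- c(pos, sample_positions(n_sub))
  }
  lineup <- data.frame(player_id = starters, position = pos,
                       on_s = as.integer(on_s), off_s = as.integer(off_s))

  n_goals <- rpois(1, 2.7)
  goals <- if (n_goals > 0) {
    gm <- sort(sample(c(1:44, 61:104), n_goals))
    data.frame(minute = gm, side = sample(c("for", "against"), n_goals, replace = TRUE))
  } else data.frame(minute = numeric(), side = character())
  meta <- game_meta(game_id, "2021-01-01T15:00:00Z", HALF1_END_S, HALF2_START_S,
                    GAME_END_S, goals, lineup)

  all_minutes <- 0:(GAME_END_S / 60 - 1)
  played_flag <- minute_is_played(all_minutes)
  n_played_total <- sum(played_flag)

  events_list <- vector("list", nrow(lineup))
  stream_list <- vector("list", nrow(lineup))

  for (pi_idx in seq_len(nrow(lineup))) {
    pl <- lineup$player_id[pi_idx]
    p_on <- lineup$on_s[pi_idx]; p_off <- lineup$off_s[pi_idx]
    active <- all_minutes * 60 >= p_on & all_minutes * 60 + 60 <= p_off
    nm <- length(all_minutes)
    regime <- rep(NA_integer_, nm)
    dist <- numeric(nm); walk_m <- numeric(nm); above20_m <- numeric(nm)
    bg_energy <- numeric(nm); mpe_e <- numeric(nm); n_ev <- integer(nm)
    ev_rows <- list()
    state <- sample.int(3L, 1, prob = pi_s)
    played_rank <- 0L
    prev_end <- -Inf # a player cannot start an MPE during an ongoing one
    for (m in all_minutes) {
      i <- m + 1L
      if (!active[i]) next
      if (!played_flag[i]) {
        ## halftime: on the pitch area, near-zero activity
        dist[i] <- runif(1, 1, 4)
        walk_m[i] <- dist[i]
        bg_energy[i] <- runif(1, 1, 2) * 60 * 0.02
        regime[i] <- NA_integer_
        next
      }
      ## restart the chain from the stationary mix at the second-half kickoff
      if (m * 60 == HALF2_START_S || m * 60 == p_on)
        state <- sample.int(3L, 1, prob = pi_s)
      else {
        prow <- P[state, ]
        decay_frac <- played_rank / max(1, n_played_total - 1)
        prow[3] <- prow[3] * g_mult * (1 - cfg$high_decay * decay_frac)
        prow <- prow / sum(prow)
        state <- sample.int(3L, 1, prob = prow)
      }
      played_rank <- played_rank + 1L
      regime[i] <- state
      r <- rp[state, ]
      dist[i] <- max(10, rnorm(1, r$dist_mean, r$dist_sd))
      walk_m[i] <- r$walk_share * dist[i]
      above20_m[i] <- r$above20_share * dist[i]
      bg_p <- max(0.5, rnorm(1, r$bg_power_mean * bg_scale,
                             0.1 * r$bg_power_mean * bg_scale))
      bg_energy[i] <- bg_p * 60
      k <- rpois(1, r$mpe_rate)
      if (k > 0) {
        starts <- sort(runif(k, 0, 60))
        durs <- sample_mpe_duration(k, cfg)
        keep <- logical(k)
        for (j in seq_len(k)) {
          s0 <- max(starts[j], prev_end + 0.2 - m * 60)
          if (s0 >= 59.5) next
          starts[j] <- s0
          half_end <- if (m * 60 < HALF1_END_S) HALF1_END_S else GAME_END_S
          durs[j] <- min(durs[j], half_end - (m * 60 + s0))
          if (durs[j] < 0.5) next
          keep[j] <- TRUE
          prev_end <- m * 60 + s0 + durs[j] # absolute clock
        }
        if (any(keep)) {
          s_abs <- m * 60 + starts[keep]
          d <- durs[keep]
          pw <- pmax(5, rnorm(sum(keep), r$power_mean, r$power_sd))
          ev_rows[[length(ev_rows) + 1L]] <- data.table(
            start_s = s_abs, end_s = s_abs + d, duration_s = d,
            max_speed_kmh = pmin(36, 14 + 0.45 * pw + rnorm(sum(keep), 0, 2)),
            avg_power_wkg = pw, energy_jkg = pw * d)
          mpe_e[i] <- sum(pw * d)
          n_ev[i] <- sum(keep)
        }
      }
    }
    ev <- if (length(ev_rows)) rbindlist(ev_rows) else
      data.table(start_s = numeric(), end_s = numeric(), duration_s = numeric(),
                 max_speed_kmh = numeric(), avg_power_wkg = numeric(),
                 energy_jkg = numeric())
    ev[, `:=`(game_id = game_id, player_id = pl)]
    events_list[[pi_idx]] <- ev
    stream_list[[pi_idx]] <- data.table(
      game_id = game_id, player_id = pl, minute = all_minutes,
      active = active, played = active & played_flag, regime = regime - 1L,
      distance_m = dist, walk_m = walk_m, above20_m = above20_m,
      run_m = pmax(0, dist - walk_m - above20_m),
      bg_energy_jkg = bg_energy, mpe_energy_jkg = mpe_e, n_events = n_ev)
  }

  events <- rbindlist(events_list)
  events <- as_mpe_events(events)
  stream <- rbindlist(stream_list)
  stream <- stream[stream$active]

  windows <- aggregate_windows(events, stream)
  totals <- stream[stream$played,
                   list(total_distance_m = sum(distance_m),
                        walk_distance_m = sum(walk_m),
                        run_below20_m = sum(run_m),
                        above20_m = sum(above20_m)),
                   by = c("game_id", "player_id")]
  totals <- as_game_totals(totals)
  truth <- stream[stream$played, c("game_id", "player_id", "minute", "regime")]
  setorderv(truth, c("game_id", "player_id", "minute"))

  structure(list(events = events, windows = windows, totals = totals,
                 meta = meta, truth = truth, minute_stream = stream),
            class = "sim_game")
}

## derive provider 5-min windows exactly from the simulated minute stream
aggregate_windows <- function(events, stream) {
  st <- copy(stream)
  st[, "win" := (st$minute %/% 5L) * 300L]
  key_cols <- c("game_id", "player_id", "win")
  agg <- st[, list(time_played_s = 60 * .N,
                   distance_m = sum(distance_m),
                   walk_distance_m = sum(walk_m),
                   running_distance_m = sum(run_m) + sum(above20_m),
                   bg_energy = sum(bg_energy_jkg),
                   mpe_energy = sum(mpe_energy_jkg)),
            by = key_cols]
  setnames(agg, "win", "window_start_s")

  ## event-derived fields per window, via the shared work/recovery primitive
  ev_split <- split(as.data.frame(events), list(events$game_id, events$player_id),
                    drop = TRUE, sep = "\r")
  n <- nrow(agg)
  mpe_count <- integer(n); avg_t <- numeric(n); rec <- numeric(n)
  for (i in seq_len(n)) {
    key <- paste(agg$game_id[i], agg$player_id[i], sep = "\r")
    ev <- ev_split[[key]]
    ws <- agg$window_start_s[i]
    wr <- window_recovery(ev, ws, 300, played_s = agg$time_played_s[i])
    mpe_count[i] <- wr$n_events
    rec[i] <- wr$recovery_s
    if (wr$n_events > 0) {
      sel <- ev$start_s >= ws & ev$start_s < ws + 300
      avg_t[i] <- mean(ev$duration_s[sel])
    }
  }
  agg[, `:=`(mpe_count = mpe_count,
             avg_mpe_time_s = avg_t,
             avg_mpe_recovery_time_s = avg_recovery_time(rec, mpe_count),
             avg_mpe_recovery_power_wkg = agg$bg_energy / pmax(1, rec),
             anaerobic_energy_jkg = 0.8 * agg$mpe_energy,
             general_energy_jkg = agg$bg_energy + agg$mpe_energy,
             avg_metabolic_power_wkg = (agg$bg_energy + agg$mpe_energy) /
               pmax(60, agg$time_played_s))]
  ## background energy split between walking and non-walking locomotion
  share_walk <- ifelse(agg$distance_m > 0, agg$walk_distance_m / agg$distance_m, 1)
  agg[, `:=`(walk_energy_jkg = agg$bg_energy * share_walk * 0.75,
             running_energy_jkg = agg$bg_energy * (1 - share_walk * 0.75))]
  agg[, c("bg_energy", "mpe_energy") := NULL]
  as_five_min(agg)
}

#' Simulate a corpus of games
#'
#' @param cfg a [sim_config()]; \code{cfg$n_games} games are generated with
#'   per-game seeds derived from \code{cfg$seed}.
#' @return object of class \code{sim_corpus}: list of \code{sim_game}s plus
#'   pooled \code{events}, \code{windows}, \code{totals}, \code{truth}
#'   tables and a named list \code{meta}.
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  games <- lapply(seq_len(cfg$n_games), function(i)
    simulate_game(cfg, game_id = sprintf("g%03d", i),
                  seed = derive_seed(cfg$seed, i)))
  metas <- lapply(games, `[[`, "meta")
  names(metas) <- vapply(metas, function(m) m$game_id, character(1))
  structure(list(games = games,
                 events = rbindlist(lapply(games, `[[`, "events")),
                 windows = rbindlist(lapply(games, `[[`, "windows")),
                 totals = rbindlist(lapply(games, `[[`, "totals")),
                 truth = rbindlist(lapply(games, `[[`, "truth")),
                 meta = metas),
            class = "sim_corpus")
}

#' Write a simulated corpus to a directory
#'
#' Emits \code{mpe.csv}, \code{gm5.csv}, \code{game_totals.csv},
#' \code{game_meta.json} and \code{truth.csv}.
#'
#' @param corpus a \code{sim_corpus}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mpe(corpus$events, file.path(dir, "mpe.csv"))
  write_five_min(corpus$windows, file.path(dir, "gm5.csv"))
  write_game_totals(corpus$totals, file.path(dir, "game_totals.csv"))
  write_game_meta(corpus$meta, file.path(dir, "game_meta.json"))
  write_csv_utf8(corpus$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
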