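## Per-minute feature construction: merge GM-5MIN-PRIOR (provider 5-min
## aggregates covering the 5 min before the observed minute), MPE-PRIOR
## (event-stream aggregates over the preceding 3 and 5 min) and
## MPE-CURRENT (the observed minute itself), plus cumulative load fields.

#' Names of the 25 clustering features, in canonical order
#'
#' Twelve GM-5MIN-PRIOR fields, nine MPE-PRIOR fields and four MPE-CURRENT
#' fields. \code{cur_} prefixes mark observed-minute fields.
#'
#' @return character vector of length 25.
#' @export
minute_feature_names <- function() {
  c(# GM-5MIN-PRIOR (12)
    "distance_m", "mpe_count", "anaerobic_energy_jkg",
    "avg_metabolic_power_wkg", "avg_mpe_time_s", "avg_mpe_recovery_time_s",
    "avg_mpe_recovery_power_wkg", "walk_energy_jkg", "running_energy_jkg",
    "general_energy_jkg", "total_mpe_count", "total_energy_jkg",
    # MPE-PRIOR (9)
    "mpe_energy_3min", "mpe_energy_5min", "mpe_count_3min", "mpe_count_5min",
    "recovery_time_3min", "recovery_time_5min",
    "avg_recovery_time_3min", "avg_recovery_time_5min", "total_recovery_time_s",
    # MPE-CURRENT (4)
    "cur_mpe_energy_jkg", "cur_event_count", "cur_avg_recovery_time_s",
    "cur_recovery_time_s")
}

GM5_EXTENSIVE <- c("distance_m", "mpe_count", "anaerobic_energy_jkg",
                   "walk_energy_jkg", "running_energy_jkg", "general_energy_jkg")
GM5_INTENSIVE <- c("avg_metabolic_power_wkg", "avg_mpe_time_s",
                   "avg_mpe_recovery_time_s", "avg_mpe_recovery_power_wkg")

#' Build the per-minute feature table
#'
#' Emits one row per player per played minute (halftime and off-pitch
#' minutes are not rows). Minute windows are half-open
#' \code{[60 m, 60 (m+1))}; an event belongs to the minute containing its
#' start. The "preceding 5 min" of an arbitrary minute straddles at most
#' two provider windows: extensive fields take the time-weighted sum of
#' the overlapped windows, intensive fields the time-weighted average.
#' Minutes whose preceding 5 min lack provider data (the first 5 min of
#' the game and of a substitute's participation) carry
#' \code{excluded = TRUE}; second-half opening minutes are retained here
#' and fall to the low-distance exclusion during training instead.
#'
#' @param events validated MPE table (see [as_mpe_events()]).
#' @param windows validated GM-5MIN table (see [as_five_min()]).
#' @param meta a \code{game_meta}, or a named list of them for a corpus.
#' @return \code{data.table} with \code{game_id, player_id, minute}, the 25
#'   features of [minute_feature_names()] and \code{excluded}.
#' @export
build_minute_table <- function(events, windows, meta) {
  if (inherits(meta, "game_meta")) meta <- stats::setNames(list(meta), meta$game_id)
  events <- as_mpe_events(events)
  windows <- as_five_min(windows)
  keys <- unique(as.data.frame(windows[, c("game_id", "player_id")]))
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    gid <- keys$game_id[i]; pid <- keys$player_id[i]
    m <- meta[[as.character(gid)]]
    if (is.null(m))
      abort("build_minute_table: no metadata for game %s", gid,
            class = "mpezones_schema_error")
    ev <- events[events$game_id == gid & events$player_id == pid]
    wi <- windows[windows$game_id == gid & windows$player_id == pid]
    out[[i]] <- build_player_minutes(ev, wi, m, gid, pid)
  }
  res <- rbindlist(out)
  setorderv(res, c("game_id", "player_id", "minute"))
  n_ex <- sum(res$excluded)
  if (n_ex > 0)
    message(sprintf("build_minute_table: %d of %d minutes lack full prior 5-min coverage; flagged excluded", n_ex, nrow(res)))
  res[]
}

build_player_minutes <- function(ev, wi, meta, gid, pid) {
  lu <- meta$lineup[meta$lineup$player_id == pid, ]
  if (nrow(lu) == 0)
    abort("player %s not in lineup of game %s", pid, gid,
          class = "mpezones_schema_error")
  on_s <- lu$on_s[1]; off_s <- lu$off_s[1]
  nm <- meta$game_end_s %/% 60L
  all_min <- 0:(nm - 1L)
  sec <- all_min * 60
  played <- (sec >= on_s) & (sec + 60 <= off_s) &
    ((sec + 60 <= meta$half1_end_s) |
       (sec >= meta$half2_start_s & sec + 60 <= meta$game_end_s))

  ## minute-level event aggregates (count/energy by start minute; work by
  ## within-minute union overlap)
  n_ev <- integer(nm); e_ev <- numeric(nm); work <- numeric(nm)
  if (nrow(ev)) {
    sm <- pmin(nm - 1L, ev$start_s %/% 60L)
    tab <- tapply(rep(1L, length(sm)), factor(sm, levels = all_min), sum)
    n_ev <- as.integer(ifelse(is.na(tab), 0L, tab))
    etab <- tapply(ev$energy_jkg, factor(sm, levels = all_min), sum)
    e_ev <- as.numeric(ifelse(is.na(etab), 0, etab))
    ## union-merge event intervals so overlapping vendor rows are not
    ## double-counted, then distribute work across the minutes spanned
    o <- order(ev$start_s)
    ms <- ev$start_s[o]; me <- ev$end_s[o]
    merged_s <- ms[1]; merged_e <- me[1]
    if (length(ms) > 1) for (j in 2:length(ms)) {
      last <- length(merged_e)
      if (ms[j] <= merged_e[last]) merged_e[last] <- max(merged_e[last], me[j])
      else { merged_s <- c(merged_s, ms[j]); merged_e <- c(merged_e, me[j]) }
    }
    for (j in seq_along(merged_s)) {
      lo_m <- as.integer(merged_s[j] %/% 60L)
      hi_m <- as.integer(min(nm - 1, (merged_e[j] - 1e-9) %/% 60L))
      for (mm in lo_m:hi_m)
        work[mm + 1L] <- work[mm + 1L] +
          (min(merged_e[j], (mm + 1) * 60) - max(merged_s[j], mm * 60))
    }
  }
  played_s_min <- ifelse(played, 60, 0)
  recovery_min <- pmax(0, played_s_min - work)

  ## rolling MPE-PRIOR sums over the preceding 3 and 5 minutes
  roll <- function(x, w) {
    cs <- cumsum(c(0, x))
    lo <- pmax(0L, all_min - w)
    cs[all_min + 1L] - cs[lo + 1L]
  }
  cnt3 <- roll(n_ev, 3L); cnt5 <- roll(n_ev, 5L)
  en3 <- roll(e_ev, 3L); en5 <- roll(e_ev, 5L)
  rec3 <- roll(recovery_min, 3L); rec5 <- roll(recovery_min, 5L)

  ## cumulative fields: up to the start of the observed minute
  tot_cnt <- cumsum(c(0L, n_ev))[all_min + 1L]
  tot_rec <- cumsum(c(0, recovery_min))[all_min + 1L]

  ## GM-5MIN-PRIOR: time-weighted combination of the <=2 provider windows
  ## overlapping [60m - 300, 60m)
  wmap <- new.env(parent = emptyenv())
  if (nrow(wi)) for (j in seq_len(nrow(wi)))
    assign(as.character(wi$window_start_s[j]), j, envir = wmap)
  get_win <- function(ws) {
    j <- mget(as.character(ws), envir = wmap, ifnotfound = NA)[[1]]
    if (is.na(j)) NULL else wi[j]
  }
  gm5_cols <- c(GM5_EXTENSIVE, GM5_INTENSIVE)
  gm5 <- matrix(NA_real_, nm, length(gm5_cols),
                dimnames = list(NULL, gm5_cols))
  tot_energy <- numeric(nm)
  covered <- logical(nm)

  ## cumulative general energy from windows, fraction-weighted at the edge
  cum_gen_at <- function(t) {
    if (!nrow(wi)) return(0)
    full <- wi$window_start_s + 300 <= t
    part <- wi$window_start_s < t & !full
    sum(wi$general_energy_jkg[full]) +
      sum(wi$general_energy_jkg[part] *
            (t - wi$window_start_s[part]) / 300)
  }

  for (m in all_min) {
    i <- m + 1L
    if (!played[i]) next
    t0 <- m * 60 - 300
    if (t0 < 0) next # first 5 min of the game: no prior coverage
    off <- (m * 60) %% 300
    w0s <- if (off == 0) m * 60 - 300 else ((m * 60 - 300) %/% 300) * 300
    wA <- get_win(w0s)
    wB <- if (off == 0) NULL else get_win(w0s + 300)
    if (is.null(wA) || (off != 0 && is.null(wB))) next # provider gap
    if (off == 0) {
      for (cn in gm5_cols) gm5[i, cn] <- wA[[cn]]
    } else {
      wa <- (300 - off) / 300; wb <- off / 300
      for (cn in GM5_EXTENSIVE) gm5[i, cn] <- wa * wA[[cn]] + wb * wB[[cn]]
      for (cn in GM5_INTENSIVE) gm5[i, cn] <- wa * wA[[cn]] + wb * wB[[cn]]
    }
    covered[i] <- TRUE
    tot_energy[i] <- cum_gen_at(m * 60)
  }

  sel <- which(played)
  dt <- data.table(game_id = gid, player_id = pid, minute = all_min[sel])
  for (cn in gm5_cols) dt[, (cn) := gm5[sel, cn]]
  dt[, `:=`(total_mpe_count = tot_cnt[sel],
            total_energy_jkg = tot_energy[sel],
            mpe_energy_3min = en3[sel], mpe_energy_5min = en5[sel],
            mpe_count_3min = cnt3[sel], mpe_count_5min = cnt5[sel],
            recovery_time_3min = rec3[sel], recovery_time_5min = rec5[sel],
            avg_recovery_time_3min = avg_recovery_time(rec3[sel], cnt3[sel]),
            avg_recovery_time_5min = avg_recovery_time(rec5[sel], cnt5[sel]),
            total_recovery_time_s = tot_rec[sel],
            cur_mpe_energy_jkg = e_ev[sel],
            cur_event_count = n_ev[sel],
            cur_recovery_time_s = recovery_min[sel],
            cur_avg_recovery_time_s = avg_recovery_time(recovery_min[sel], n_ev[sel]),
            excluded = !covered[sel])]
  ## uncovered minutes carry zeros rather than NA in the GM-5MIN block so
  ## the table stays numeric; they are flagged excluded and never trained on
  for (cn in gm5_cols) {
    nas <- is.na(dt[[cn]])
    if (any(nas)) dt[nas, (cn) := 0]
  }
  setcolorder(dt, c("game_id", "player_id", "minute", minute_feature_names(),
                    "excluded"))
  dt
}

#' Winsorise features at a high ceiling quantile
#'
#' Per feature, values above the corpus-level quantile (default the 99.5th
#' percentile) are set to that quantile, denoising extreme provider
#' values. Idempotent; the \code{excluded} flag and key columns are
#' untouched.
#'
#' @param table minute-feature table.
#' @param quantile ceiling quantile in (0, 1].
#' @param thresholds optional named vector of precomputed ceilings (used
#'   when applying a fitted model to new data).
#' @return list with \code{table} (clipped copy) and \code{thresholds}.
#' @export
apply_ceiling <- function(table, quantile = 0.995, thresholds = NULL) {
  if (!nrow(table)) abort("apply_ceiling: empty table")
  if (is.null(thresholds)) {
    if (!(quantile > 0 && quantile <= 1))
      abort("ceiling quantile must be in (0,1]", class = "mpezones_config_error")
    ## type-1 (order statistic) quantile: the threshold is an observed
    ## value, so clipping is exactly idempotent
    thresholds <- vapply(minute_feature_names(), function(cn)
      stats::quantile(table[[cn]], quantile, na.rm = TRUE, names = FALSE,
                      type = 1),
      numeric(1))
  }
  out <- as.data.table(copy(table))
  for (cn in minute_feature_names())
    out[, (cn) := pmin(out[[cn]], thresholds[[cn]])]
  list(table = out[], thresholds = thresholds)
}
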