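## Domain tables and CSV/JSON readers-writers.
##
## The vendor export format is proprietary, so the package defines its own
## plain-text dialects: UTF-8, comma separator, header row, "." decimal.
## All times are seconds since first-half kickoff, continuous through
## halftime (halftime minutes exist but are not "played").

MPE_COLS <- c("game_id", "player_id", "start_s", "end_s", "duration_s",
              "max_speed_kmh", "avg_power_wkg", "energy_jkg")

GM5_COLS <- c("game_id", "player_id", "window_start_s", "time_played_s",
              "distance_m", "mpe_count", "anaerobic_energy_jkg",
              "avg_metabolic_power_wkg", "avg_mpe_time_s",
              "avg_mpe_recovery_time_s", "avg_mpe_recovery_power_wkg",
              "walk_distance_m", "running_distance_m", "walk_energy_jkg",
              "running_energy_jkg", "general_energy_jkg")

TOTALS_COLS <- c("game_id", "player_id", "total_distance_m", "walk_distance_m",
                 "run_below20_m", "above20_m")

POSITIONS <- c("CB", "WB", "MF", "WF", "FW")

## vendor rounding tolerance between duration_s and end_s - start_s
DURATION_TOL_S <- 0.5

check_cols <- function(df, cols, what, optional = character()) {
  missing <- setdiff(setdiff(cols, optional), names(df))
  if (length(missing))
    abort("%s: missing column(s): %s", what, paste(missing, collapse = ", "),
          class = "mpezones_schema_error")
  invisible(df)
}

## row numbers reported to the user are 1-based data rows (header excluded)
bad_rows <- function(cond, what, msg) {
  idx <- which(cond)
  if (length(idx))
    abort("%s: %s at row(s) %s", what, msg,
          paste(head(idx, 5L), collapse = ", "),
          class = "mpezones_validation_error")
  invisible(NULL)
}

#' Validate a table of metabolic power events
#'
#' An MPE row records one detected high-intensity event: start/end time in
#' seconds since kickoff, duration, maximal speed and average metabolic
#' power. Event energy (J/kg) is the product of average power and duration;
#' it is computed when absent.
#'
#' @param df data.frame with columns
#'   \code{game_id, player_id, start_s, end_s, duration_s, max_speed_kmh,
#'   avg_power_wkg} and optionally \code{energy_jkg}.
#' @return a \code{data.table} sorted by (game_id, player_id, start_s) with
#'   \code{energy_jkg} filled in.
#' @export
as_mpe_events <- function(df) {
  check_cols(df, MPE_COLS, "mpe", optional = "energy_jkg")
  dt <- as.data.table(df)
  bad_rows(!is.finite(dt$start_s) | dt$start_s < 0, "mpe", "negative or missing start_s")
  bad_rows(dt$end_s <= dt$start_s, "mpe", "end_s <= start_s")
  bad_rows(abs(dt$duration_s - (dt$end_s - dt$start_s)) > DURATION_TOL_S,
           "mpe", sprintf("duration_s inconsistent with end_s - start_s (> %.1f s)", DURATION_TOL_S))
  bad_rows(dt$avg_power_wkg < 0, "mpe", "negative avg_power_wkg")
  if (!"energy_jkg" %in% names(dt) || all(is.na(dt$energy_jkg)))
    dt[, "energy_jkg" := dt$avg_power_wkg * dt$duration_s]
  else {
    na <- is.na(dt$energy_jkg)
    if (any(na)) dt[na, "energy_jkg" := dt$avg_power_wkg[na] * dt$duration_s[na]]
  }
  setorderv(dt, c("game_id", "player_id", "start_s"))
  setcolorder(dt, MPE_COLS)
  dt[]
}

#' Validate a table of 5-minute aggregate windows (GM-5MIN)
#'
#' One row per player per fixed 5-minute window: distance, MPE count,
#' anaerobic energy, average metabolic power, average MPE time / recovery
#' time / recovery power, walking and running distance and energy, and total
#' (general) energy. \code{window_start_s} must be a multiple of 300.
#'
#' @param df data.frame with the GM-5MIN columns.
#' @return a sorted \code{data.table}.
#' @export
as_five_min <- function(df) {
  check_cols(df, GM5_COLS, "gm5")
  dt <- as.data.table(df)
  bad_rows(dt$window_start_s %% 300 != 0, "gm5", "window_start_s not a multiple of 300")
  num_cols <- setdiff(GM5_COLS, c("game_id", "player_id"))
  for (cn in num_cols) bad_rows(dt[[cn]] < 0, "gm5", sprintf("negative %s", cn))
  bad_rows(dt$walk_distance_m + dt$running_distance_m > dt$distance_m + 1e-6,
           "gm5", "walk + running distance exceeds total distance")
  bad_rows(dt$general_energy_jkg < dt$walk_energy_jkg + dt$running_energy_jkg - 1e-6,
           "gm5", "general energy below walk + running energy")
  setorderv(dt, c("game_id", "player_id", "window_start_s"))
  setcolorder(dt, GM5_COLS)
  dt[]
}

#' Validate a table of whole-game totals (GM-GAME)
#'
#' Conventional whole-game load metrics used as the comparison baseline:
#' total distance, walking distance, running distance below 20 km/h
#' (walking excluded) and distance above 20 km/h.
#'
#' @param df data.frame with the GM-GAME columns.
#' @return a sorted \code{data.table}.
#' @export
as_game_totals <- function(df) {
  check_cols(df, TOTALS_COLS, "game_totals")
  dt <- as.data.table(df)
  num_cols <- setdiff(TOTALS_COLS, c("game_id", "player_id"))
  for (cn in num_cols) bad_rows(dt[[cn]] < 0, "game_totals", sprintf("negative %s", cn))
  bad_rows(dt$walk_distance_m + dt$run_below20_m + dt$above20_m >
             dt$total_distance_m + 1e-3,
           "game_totals", "speed-band distances exceed total distance")
  setorderv(dt, c("game_id", "player_id"))
  dt[]
}

#' Construct game metadata
#'
#' Half boundaries (seconds since kickoff, continuous through halftime),
#' goal events and the lineup (playing position and on/off times per player).
#'
#' @param game_id identifier.
#' @param kickoff_utc timestamp string.
#' @param half1_end_s,half2_start_s,game_end_s half boundaries in seconds.
#' @param goals data.frame with columns \code{minute}, \code{side}
#'   (\code{"for"} or \code{"against"}); may have zero rows.
#' @param lineup data.frame with columns \code{player_id}, \code{position}
#'   (one of CB, WB, MF, WF, FW), \code{on_s}, \code{off_s}.
#' @return object of class \code{game_meta}.
#' @export
game_meta <- function(game_id, kickoff_utc, half1_end_s, half2_start_s,
                      game_end_s, goals, lineup) {
  if (!(half1_end_s < half2_start_s && half2_start_s < game_end_s))
    abort("game_meta %s: half boundaries must satisfy half1_end < half2_start < game_end",
          game_id, class = "mpezones_validation_error")
  goals <- as.data.frame(goals)
  if (nrow(goals)) {
    check_cols(goals, c("minute", "side"), "goals")
    in_half1 <- goals$minute < half1_end_s / 60
    in_half2 <- goals$minute >= half2_start_s / 60 & goals$minute < game_end_s / 60
    if (any(!(in_half1 | in_half2)))
      abort("game_meta %s: goal minute outside play", game_id,
            class = "mpezones_validation_error")
  }
  lineup <- as.data.frame(lineup)
  check_cols(lineup, c("player_id", "position", "on_s", "off_s"), "lineup")
  if (any(!lineup$position %in% POSITIONS))
    abort("game_meta %s: unknown position (expected %s)", game_id,
          paste(POSITIONS, collapse = "/"), class = "mpezones_validation_error")
  structure(list(game_id = game_id, kickoff_utc = kickoff_utc,
                 half1_end_s = half1_end_s, half2_start_s = half2_start_s,
                 game_end_s = game_end_s, goals = goals, lineup = lineup),
            class = "game_meta")
}

#' @export
print.game_meta <- function(x, ...) {
  cat(sprintf("<game_meta %s> kickoff %s, halves [0,%d) / [%d,%d), %d goals, %d players\n",
              x$game_id, x$kickoff_utc, x$half1_end_s, x$half2_start_s,
              x$game_end_s, nrow(x$goals), nrow(x$lineup)))
  invisible(x)
}

read_table_checked <- function(path, what) {
  if (!file.exists(path))
    abort("%s: file not found: %s", what, path, class = "mpezones_io_error")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) abort("%s: cannot parse %s: %s", what, path, conditionMessage(e),
                              class = "mpezones_io_error"))
  df
}

#' Read a metabolic-power-event CSV
#'
#' @param path CSV with columns \code{game_id,player_id,start_s,end_s,
#'   duration_s,max_speed_kmh,avg_power_wkg[,energy_jkg]}.
#' @return validated \code{data.table} of events (see [as_mpe_events()]).
#' @export
read_mpe <- function(path) as_mpe_events(read_table_checked(path, "mpe"))

#' Read a GM-5MIN aggregate CSV
#' @param path CSV with one column per GM-5MIN field.
#' @return validated \code{data.table} of windows (see [as_five_min()]).
#' @export
read_five_min <- function(path) as_five_min(read_table_checked(path, "gm5"))

#' Read a whole-game totals CSV
#' @param path CSV with GM-GAME columns.
#' @return validated \code{data.table} (see [as_game_totals()]).
#' @export
read_game_totals <- function(path) as_game_totals(read_table_checked(path, "game_totals"))

write_csv_utf8 <- function(df, path) {
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = FALSE),
    error = function(e) abort("cannot write %s: %s", path, conditionMessage(e),
                              class = "mpezones_io_error"))
  invisible(path)
}

#' @rdname read_mpe
#' @param df validated table.
#' @export
write_mpe <- function(df, path) write_csv_utf8(as_mpe_events(df), path)

#' @rdname read_five_min
#' @param df validated table.
#' @export
write_five_min <- function(df, path) write_csv_utf8(as_five_min(df), path)

#' @rdname read_game_totals
#' @param df validated table.
#' @export
write_game_totals <- function(df, path) write_csv_utf8(as_game_totals(df), path)

#' Read or write corpus game metadata (JSON)
#'
#' The metadata file holds a JSON array of games; each entry carries the
#' half boundaries, goals and the lineup.
#'
#' @param path JSON file path.
#' @return named list of \code{game_meta} objects keyed by game_id.
#' @export
read_game_meta <- function(path) {
  if (!file.exists(path))
    abort("game_meta: file not found: %s", path, class = "mpezones_io_error")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  games <- if (is.data.frame(raw)) split(raw, seq_len(nrow(raw))) else raw
  metas <- lapply(games, function(g) {
    g <- as.list(g)
    goals <- g$goals
    if (is.list(goals) && !is.data.frame(goals)) goals <- goals[[1]] %||% goals
    if (is.null(goals) || (is.data.frame(goals) && !nrow(goals)) || !length(goals))
      goals <- data.frame(minute = numeric(), side = character())
    lineup <- g$lineup
    if (is.list(lineup) && !is.data.frame(lineup)) lineup <- lineup[[1]] %||% lineup
    game_meta(g$game_id, g$kickoff_utc, g$half1_end_s, g$half2_start_s,
              g$game_end_s, goals, as.data.frame(lineup))
  })
  names(metas) <- vapply(metas, function(m) as.character(m$game_id), character(1))
  metas
}

#' @rdname read_game_meta
#' @param metas list of \code{game_meta} objects (or a single one).
#' @export
write_game_meta <- function(metas, path) {
  if (inherits(metas, "game_meta")) metas <- list(metas)
  payload <- lapply(metas, function(m) {
    list(game_id = m$game_id, kickoff_utc = m$kickoff_utc,
         half1_end_s = m$half1_end_s, half2_start_s = m$half2_start_s,
         game_end_s = m$game_end_s, goals = m$goals, lineup = m$lineup)
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read or write the per-minute feature table
#'
#' Lossless round-trip of the 25-feature table built by
#' [build_minute_table()], including the exclusion flag.
#'
#' @param path CSV file path.
#' @return \code{data.table} with key columns, 25 features and
#'   \code{excluded} flag.
#' @export
read_minute_features <- function(path) {
  df <- read_table_checked(path, "minute_features")
  check_cols(df, c("game_id", "player_id", "minute", minute_feature_names(), "excluded"),
             "minute_features")
  dt <- as.data.table(df)
  dt[, "excluded" := as.logical(dt$excluded)]
  setorderv(dt, c("game_id", "player_id", "minute"))
  dt[]
}

#' @rdname read_minute_features
#' @param df feature table.
#' @export
write_minute_features <- function(df, path) {
  check_cols(df, c("game_id", "player_id", "minute", minute_feature_names(), "excluded"),
             "minute_features")
  write_csv_utf8(df, path)
}
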