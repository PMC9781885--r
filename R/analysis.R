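## Game-level analytics: per-player timelines, 5-min interval
## distributions, and coefficient-of-variation comparison of cluster-based
## load shares against conventional whole-game speed-band shares.

#' Per-player intensity timeline
#'
#' One label per played minute for a player in a game, with goal minutes
#' annotated and halftime left as an explicit gap (no rows).
#'
#' @param assignments output of [assign_intensity()].
#' @param meta the game's \code{game_meta}.
#' @param player_id player to extract.
#' @param game_id game to extract (defaults to meta's game).
#' @return \code{data.table} with \code{minute, label, goal}
#'   (\code{NA}, \code{"for"} or \code{"against"}).
#' @export
timeline <- function(assignments, meta, player_id, game_id = meta$game_id) {
  sel <- assignments$game_id == game_id & assignments$player_id == player_id
  if (!any(sel)) abort("timeline: player %s not found in game %s",
                       player_id, game_id)
  tl <- as.data.table(assignments[sel, c("minute", "label")])
  setorderv(tl, "minute")
  tl[, "goal" := NA_character_]
  if (nrow(meta$goals)) {
    gm <- floor(meta$goals$minute)
    hit <- match(gm, tl$minute)
    ok <- !is.na(hit)
    if (any(ok)) tl[hit[ok], "goal" := meta$goals$side[ok]]
  }
  tl[]
}

#' Intensity distribution over game intervals
#'
#' Pools classified minutes over players/games into \code{bin_min}-minute
#' bins of the game clock and counts labels per bin; unclassified minutes
#' are tracked in their own column.
#'
#' @param assignments output of [assign_intensity()].
#' @param bin_min bin width in minutes (default 5).
#' @return \code{data.table}: \code{bin_start_min, low, middle, high,
#'   unclassified}.
#' @export
interval_distribution <- function(assignments, bin_min = 5) {
  if (!nrow(assignments)) abort("interval_distribution: empty assignments")
  a <- as.data.table(assignments)
  a[, "bin" := (a$minute %/% bin_min) * bin_min]
  counts <- dcast(a[, .N, by = c("bin", "label")], bin ~ label, value.var = "N",
                  fill = 0L)
  for (cn in c("low", "middle", "high", "unclassified"))
    if (!cn %in% names(counts)) counts[, (cn) := 0L]
  setnames(counts, "bin", "bin_start_min")
  setorderv(counts, "bin_start_min")
  counts[, c("bin_start_min", "low", "middle", "high", "unclassified"),
         with = FALSE]
}

#' Per-game load summary: cluster shares vs speed-band proxy shares
#'
#' Cluster fractions are the team's classified minutes in each zone
#' divided by all classified minutes. Proxy fractions map whole-game
#' speed bands onto zones — above 20 km/h to high, running below 20 km/h
#' to middle, walking to low — pooled over the team's distances and
#' normalised to sum to one.
#'
#' @param assignments output of [assign_intensity()].
#' @param totals validated GM-GAME totals table.
#' @param game_id game to summarise.
#' @return list of class \code{game_load_summary} with \code{game_id},
#'   \code{cluster_fractions} and \code{proxy_fractions} (named high /
#'   middle / low, each summing to 1).
#' @export
summarize_game <- function(assignments, totals, game_id) {
  keep_a <- assignments$game_id == game_id & assignments$label != "unclassified"
  a <- as.data.frame(assignments)[keep_a, ]
  if (!nrow(a)) abort("summarize_game: no classified minutes for game %s", game_id)
  tt <- as.data.frame(totals)[totals$game_id == game_id, ]
  if (!nrow(tt)) abort("summarize_game: no totals for game %s", game_id)
  n <- nrow(a)
  cf <- c(high = sum(a$label == "high") / n,
          middle = sum(a$label == "middle") / n,
          low = sum(a$label == "low") / n)
  d <- c(high = sum(tt$above20_m), middle = sum(tt$run_below20_m),
         low = sum(tt$walk_distance_m))
  pf <- d / sum(d)
  structure(list(game_id = game_id, cluster_fractions = cf,
                 proxy_fractions = pf, n_classified = n),
            class = "game_load_summary")
}

#' Between-game variability report (coefficient of variation)
#'
#' For each zone and method, the CV in percent (100 x population SD /
#' mean) of the per-game fraction across games. A zone with zero mean is
#' reported as \code{NA}.
#'
#' @param summaries list of \code{game_load_summary} objects (>= 2 games).
#' @return \code{data.table} with \code{group, method, mean, sd,
#'   cv_percent, n_games}.
#' @export
cv_report <- function(summaries) {
  if (length(summaries) < 2) abort("cv_report: need at least 2 games")
  grab <- function(field, grp) vapply(summaries, function(s) s[[field]][[grp]],
                                      numeric(1))
  rows <- list()
  for (grp in c("high", "middle", "low"))
    for (method in c("cluster", "proxy")) {
      x <- grab(if (method == "cluster") "cluster_fractions" else "proxy_fractions",
                grp)
      mu <- mean(x); s <- pop_sd(x)
      rows[[length(rows) + 1L]] <- data.table(
        group = grp, method = method, mean = mu, sd = s,
        cv_percent = if (mu > 0) 100 * s / mu else NA_real_,
        n_games = length(x))
    }
  rbindlist(rows)
}
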