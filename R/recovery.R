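## Energetic primitives shared by the feature builder and the simulator.

#' Energy expenditure of a metabolic power event
#'
#' An MPE's energy (J/kg) is the product of its average metabolic power
#' (W/kg) and its duration (s).
#'
#' @param avg_power_wkg average metabolic power, W/kg (>= 0).
#' @param duration_s event duration, s (>= 0).
#' @return energy in J/kg; vectorised.
#' @export
#' @examples
#' mpe_energy(10, 5.8) # 58
mpe_energy <- function(avg_power_wkg, duration_s) {
  if (any(avg_power_wkg < 0, na.rm = TRUE) || any(duration_s < 0, na.rm = TRUE))
    abort("mpe_energy: inputs must be nonnegative", class = "mpezones_validation_error")
  avg_power_wkg * duration_s
}

#' Average recovery time in a window
#'
#' A window containing N events is split into N + 1 recovery periods
#' (before, between and after the events), so the average recovery time is
#' total recovery time divided by N + 1. A fully rested 60 s minute
#' (0 events) therefore averages 60 s.
#'
#' @param recovery_s total recovery seconds in the window (>= 0).
#' @param n_events number of events in the window (>= 0).
#' @return average recovery time, s; vectorised.
#' @export
#' @examples
#' avg_recovery_time(42, 4) # 8.4
#' avg_recovery_time(60, 0) # 60
avg_recovery_time <- function(recovery_s, n_events) {
  recovery_s / (n_events + 1)
}

## union length of a set of intervals clipped to [lo, hi); events are
## merged first so overlapping events are not double counted
interval_union_overlap <- function(start, end, lo, hi) {
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  keep <- e > s
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  total + (cur_e - cur_s)
}

#' Work and recovery accounting for a time window
#'
#' Counts the events starting inside the window, measures "work" as the
#' within-window overlap of the event intervals (events straddling the
#' boundary contribute only their overlap; overlapping events are merged),
#' and returns the remaining time as recovery, floored at zero.
#'
#' @param events data.frame/table with \code{start_s}, \code{end_s}.
#' @param win_start_s window start, seconds since kickoff.
#' @param win_len_s window length in seconds (typically 60, 180 or 300).
#' @param played_s seconds actually played inside the window
#'   (default \code{win_len_s}).
#' @return list with \code{recovery_s}, \code{n_events}, \code{work_s}.
#' @export
#' @examples
#' ev <- data.frame(start_s = c(5, 20, 35, 50), end_s = c(9, 25, 39.5, 54.5))
#' window_recovery(ev, 0, 60) # 42 s recovery, 4 events
window_recovery <- function(events, win_start_s, win_len_s, played_s = win_len_s) {
  win_end_s <- win_start_s + win_len_s
  if (is.null(events) || nrow(events) == 0) {
    work <- 0
    n <- 0L
  } else {
    n <- sum(events$start_s >= win_start_s & events$start_s < win_end_s)
    work <- interval_union_overlap(events$start_s, events$end_s, win_start_s, win_end_s)
  }
  rec <- max(0, min(played_s, win_len_s) - work)
  list(recovery_s = rec, n_events = as.integer(n), work_s = work)
}
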