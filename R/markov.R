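## Markov-chain analysis of intensity shifts and a fitness-tracking index.
##
## Transitions are counted only between temporally adjacent classified
## minutes of the same player-game; halftime, substitutions and
## unclassified minutes break the chain.

INTENSITY_STATES <- c("low", "middle", "high")

#' Estimate a player's intensity-transition model
#'
#' Counts transitions between consecutive classified minutes and returns
#' the Laplace-smoothed row-normalised 3x3 transition matrix over
#' (low, middle, high).
#'
#' @param assignments assignment table (\code{game_id, player_id, minute,
#'   label}) for one player (or pooled rows to be treated as one chain per
#'   player-game).
#' @param alpha Laplace smoothing added to every count (default 0.5).
#' @return object of class \code{transition_model}: \code{counts},
#'   \code{probs}, \code{n_transitions}, \code{alpha}, \code{player_id}.
#' @export
fit_transitions <- function(assignments, alpha = 0.5) {
  a <- as.data.table(assignments)
  setorderv(a, c("game_id", "player_id", "minute"))
  counts <- matrix(0, 3, 3, dimnames = list(INTENSITY_STATES, INTENSITY_STATES))
  keys <- paste(a$game_id, a$player_id, sep = "\r")
  lab <- a$label
  mins <- a$minute
  n <- nrow(a)
  if (n >= 2) {
    i <- seq_len(n - 1)
    ok <- keys[i] == keys[i + 1] & mins[i + 1] == mins[i] + 1 &
      lab[i] %in% INTENSITY_STATES & lab[i + 1] %in% INTENSITY_STATES
    if (any(ok)) {
      from <- factor(lab[i][ok], levels = INTENSITY_STATES)
      to <- factor(lab[i + 1][ok], levels = INTENSITY_STATES)
      counts <- unclass(table(from, to))
      dimnames(counts) <- list(INTENSITY_STATES, INTENSITY_STATES)
    }
  }
  n_trans <- sum(counts)
  if (n_trans == 0)
    abort("fit_transitions: no valid transitions (need >= 2 consecutive classified minutes)")
  sm <- counts + alpha
  probs <- sm / rowSums(sm)
  structure(list(player_id = unique(a$player_id),
                 counts = counts, probs = probs,
                 n_transitions = n_trans, alpha = alpha),
            class = "transition_model")
}

#' Stationary distribution of a transition matrix
#'
#' Left fixed point of a row-stochastic matrix, normalised to sum to 1.
#' Errors if the chain is reducible, naming the closed (absorbing) class.
#'
#' @param probs 3x3 (or n x n) row-stochastic matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(probs) {
  P <- as.matrix(probs)
  n <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8))
    abort("stationary_distribution: rows must sum to 1")
  ## reachability closure to detect reducibility
  R <- (P > 0) | diag(n) > 0
  for (i in seq_len(n)) R <- (R %*% R) > 0
  if (!all(R)) {
    ## the reachable set of the state with the smallest reach is closed
    i0 <- which.min(rowSums(R))
    states <- rownames(P) %||% as.character(seq_len(n))
    abort("stationary_distribution: chain is reducible (closed class: %s)",
          paste(states[which(R[i0, ])], collapse = ","))
  }
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_s <- as.numeric(qr.solve(A, b))
  pi_s <- pmax(pi_s, 0)
  stats::setNames(pi_s / sum(pi_s), rownames(P))
}

#' Markov fitness index (MFit-style proxy)
#'
#' A bounded score of the player's propensity to reach and sustain the
#' high-intensity state: the stationary probability of "high" plus half
#' the probability of shifting middle -> high, clipped to [0, 1]. The
#' formula is pluggable via \code{score_fn} so an alternative definition
#' can be substituted without touching the rest of the pipeline. If the
#' smoothed chain is reducible the fallback score is the fraction of
#' observed transitions entering "high".
#'
#' @param model a \code{transition_model}.
#' @param score_fn optional function(probs, stationary) -> numeric.
#' @return list of class \code{mfit_point}: \code{player_id, mfit,
#'   n_transitions}.
#' @export
mfit_index <- function(model, score_fn = NULL) {
  score <- tryCatch({
    pi_s <- stationary_distribution(model$probs)
    if (is.null(score_fn))
      unname(pi_s["high"] + 0.5 * model$probs["middle", "high"])
    else score_fn(model$probs, pi_s)
  }, mpezones_error = function(e) {
    warning("mfit_index: reducible chain; falling back to count-based score")
    sum(model$counts[, "high"]) / sum(model$counts)
  })
  structure(list(player_id = model$player_id,
                 mfit = min(1, max(0, score)),
                 n_transitions = model$n_transitions),
            class = "mfit_point")
}

#' Track the fitness index across time windows
#'
#' Fits one transition model and MFit score per (player, window), for
#' following players across meso-/macro-cycles. Scores are comparable
#' across windows only when produced under the same fitted intensity
#' model.
#'
#' @param assignments assignment table with an additional \code{window}
#'   column (e.g. week or month id, sortable chronologically).
#' @param alpha Laplace smoothing for each fit.
#' @param score_fn optional custom score (see [mfit_index()]).
#' @return \code{data.table}: \code{player_id, window, mfit,
#'   n_transitions}, ordered by (player, window).
#' @export
track_mfit <- function(assignments, alpha = 0.5, score_fn = NULL) {
  if (!"window" %in% names(assignments))
    abort("track_mfit: assignments need a 'window' column",
          class = "mpezones_schema_error")
  a <- as.data.table(assignments)
  groups <- unique(a[, c("player_id", "window"), with = FALSE])
  setorderv(groups, c("player_id", "window"))
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- a[a$player_id == groups$player_id[i] & a$window == groups$window[i]]
    pt <- mfit_index(fit_transitions(sub, alpha), score_fn)
    rows[[i]] <- data.table(player_id = groups$player_id[i],
                            window = groups$window[i],
                            mfit = pt$mfit, n_transitions = pt$n_transitions)
  }
  rbindlist(rows)
}
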