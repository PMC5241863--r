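#' Strategies consistent with one game of observed play
#'
#' Tests, for each of the eleven strategies, whether replaying that strategy
#' against the opponent's *observed* actions reproduces the player's own
#' actions exactly. Because distinct strategies can be observationally
#' equivalent for a given opponent (e.g. every threshold above the
#' opponent's first defection looks identical under grim retaliation), any
#' number of indicators can be 1; identity is resolved over time by the
#' EWMA in [infer_strategies()]. When no strategy is consistent the play is
#' flagged `OTHER`.
#'
#' A forgiving variant of `Tx` — defect at round `x`, then, if the partner
#' cooperated at round `x`, resume cooperating for a round or two before
#' defecting again — is coded as consistent with `Tx`: a deviation is
#' tolerated when the only mismatches are resumed cooperation in rounds
#' `x + 1 ... x + forgive` (starting at `x + 1`) while the partner
#' cooperated at round `x`.
#'
#' @param own,opp character vectors of length `H`, the player's and the
#'   partner's actions (`"C"`/`"D"`) in round order.
#' @param H number of rounds.
#' @param forgive maximum number of rounds of resumed cooperation tolerated
#'   for the forgiving threshold variant (default 2; 0 disables it).
#' @return named integer vector of 0/1 indicators over
#'   `c(strategy_labels(H), "OTHER")`.
#' @examples
#' consistent_strategies(rep("D", 10), rep("C", 10))  # only T1
#' consistent_strategies(rep("C", 10), rep("C", 10))  # only CC
#' @export
consistent_strategies <- function(own, opp, H = length(own), forgive = 2) {
  stopifnot(length(own) == H, length(opp) == H)
  check_actions(own, "own action")
  check_actions(opp, "opponent action")
  drop(strategy_indicators(matrix(own, 1), matrix(opp, 1), H, forgive))
}

# Vectorised indicator computation over n player-games.
# own, opp: n x H character matrices. Returns n x (H + 2) 0/1 matrix with
# columns strategy_labels(H) then "OTHER".
strategy_indicators <- function(own, opp, H = ncol(own), forgive = 2) {
  n <- nrow(own)
  ownC <- own == "C"
  oppD <- opp == "D"
  # opp defected strictly before round r
  Lstrict <- 1 * outer(seq_len(H), seq_len(H), `<`)
  odb <- (oppD %*% Lstrict) > 0
  labs <- c(strategy_labels(H), "OTHER")
  ind <- matrix(0L, n, H + 2L, dimnames = list(NULL, labs))
  rr <- matrix(seq_len(H), n, H, byrow = TRUE)
  for (x in seq_len(H + 1L)) {           # x = H + 1 is CC
    expC <- (rr < x) & !odb
    mism <- ownC != expC
    n_mis <- rowSums(mism)
    ok <- n_mis == 0L
    if (x <= H && x < H && forgive > 0) {
      win <- seq.int(x + 1L, min(x + forgive, H))
      in_win <- rowSums(mism[, win, drop = FALSE])
      tol <- !ok & n_mis == in_win & mism[, x + 1L] & !oppD[, x]
      ok <- ok | tol
    }
    ind[, x] <- as.integer(ok)
  }
  ind[, H + 2L] <- as.integer(
    rowSums(ind[, seq_len(H + 1L), drop = FALSE]) == 0L)
  ind
}

#' EWMA weight recursion over per-game indicators
#'
#' Updates the exponentially weighted moving average of strategy-consistency
#' indicators: `w(j) = indicator(j) + gamma * w(j - 1)`, applied
#' independently per strategy (including the `OTHER` flag). With `gamma = 0`
#' the weights reduce to the current game's indicator; a constant indicator
#' converges geometrically to `1 / (1 - gamma)`.
#'
#' @param prev numeric vector of previous weights (all zero before the first
#'   game).
#' @param ind 0/1 indicator vector from [consistent_strategies()].
#' @param gamma discount rate for past behaviour in `[0, 1]`; the default
#'   0.818 approximates a moving average with a period of 10 games.
#' @return updated weight vector.
#' @export
update_weights <- function(prev, ind, gamma = 0.818) {
  if (gamma < 0 || gamma > 1) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(prev) == length(ind))
  ind + gamma * prev
}

# Column priority for argmax tie-breaking over c(T1..TH, CC, OTHER):
# known strategies beat OTHER, Tx beats CC, and among tied Tx the largest
# (most cooperative) threshold wins.
assignment_priority <- function(H) c(rev(seq_len(H)), H + 1L, H + 2L)

#' Assign a unique strategy from EWMA weights
#'
#' The assigned strategy is the argmax of the weight vector, with ties
#' broken in favour of a known strategy over `OTHER`, a threshold strategy
#' over `CC`, and the largest threshold among tied `Tx`. All-zero weights
#' (no game observed yet) yield `OTHER`.
#'
#' @param w named numeric weight vector over `c(strategy_labels(H),
#'   "OTHER")`.
#' @param H number of rounds.
#' @return a single strategy label.
#' @export
assign_strategy <- function(w, H = length(w) - 2L) {
  stopifnot(length(w) == H + 2L)
  if (max(w) <= 0) return("OTHER")
  prio <- assignment_priority(H)
  labs <- c(strategy_labels(H), "OTHER")
  labs[prio[which.max(w[prio])]]
}

#' Infer per-game strategies from a game log
#'
#' For every player and every game in a long-format [game log][read_game_log],
#' computes the consistency indicators of [consistent_strategies()], runs
#' the EWMA recursion of [update_weights()] over the player's games in
#' chronological order, and assigns a unique strategy per game by
#' [assign_strategy()].
#'
#' @param log a game-log data frame (columns `session`, `day`, `game`,
#'   `round`, `player`, `partner`, `action`).
#' @param gamma EWMA discount (default 0.818).
#' @param forgive forgiving-variant tolerance, see
#'   [consistent_strategies()].
#' @param indicator `"all"` marks every consistent strategy (default);
#'   `"single"` marks only the highest-priority consistent strategy.
#' @param missing how the recursion treats games a player did not play:
#'   `"carry"` (default) skips them, leaving weights unchanged; `"decay"`
#'   discounts weights by `gamma` per missed game.
#' @return a data.frame with one row per player-game: `session`, `player`,
#'   `day`, `game`, `game_global` (`(day - 1) * games_per_day + game`) and
#'   the assigned `strategy` label.
#' @export
infer_strategies <- function(log, gamma = 0.818, forgive = 2,
                             indicator = c("all", "single"),
                             missing = c("carry", "decay")) {
  indicator <- match.arg(indicator)
  missing <- match.arg(missing)
  log <- validate_game_log(log)
  H <- max(log$round)
  G <- max(log$game)

  key_self <- paste(log$session, log$day, log$game, log$round, log$player)
  key_opp <- paste(log$session, log$day, log$game, log$round, log$partner)
  opp_action <- log$action[match(key_opp, key_self)]

  ord <- order(log$player, log$day, log$game, log$round)
  pl <- log$player[ord]
  gg <- (log$day[ord] - 1L) * G + log$game[ord]
  own_m <- matrix(log$action[ord], ncol = H, byrow = TRUE)
  opp_m <- matrix(opp_action[ord], ncol = H, byrow = TRUE)
  take <- seq(1L, length(pl), by = H)  # one row per player-game
  player <- pl[take]
  game_global <- gg[take]
  session <- log$session[ord][take]
  day <- log$day[ord][take]
  game <- log$game[ord][take]

  ind <- strategy_indicators(own_m, opp_m, H, forgive)
  if (indicator == "single") {
    prio <- assignment_priority(H)
    known <- ind[, seq_len(H + 1L), drop = FALSE]
    pick <- apply(known[, prio[seq_len(H + 1L)], drop = FALSE], 1,
                  function(z) if (any(z == 1L)) which.max(z) else NA_integer_)
    single <- matrix(0L, nrow(ind), ncol(ind), dimnames = dimnames(ind))
    hit <- !is.na(pick)
    single[cbind(which(hit), prio[pick[hit]])] <- 1L
    single[, H + 2L] <- ind[, H + 2L]
    ind <- single
  }

  n <- nrow(ind)
  W <- matrix(0, n, H + 2L)
  w <- numeric(H + 2L)
  prev_player <- ""
  prev_g <- 0L
  for (i in seq_len(n)) {
    if (player[i] != prev_player) {
      w <- numeric(H + 2L)
      prev_g <- game_global[i] - 1L
    } else if (missing == "decay" && game_global[i] - prev_g > 1L) {
      w <- w * gamma^(game_global[i] - prev_g - 1L)
    }
    w <- ind[i, ] + gamma * w
    W[i, ] <- w
    prev_player <- player[i]
    prev_g <- game_global[i]
  }

  prio <- assignment_priority(H)
  labs <- c(strategy_labels(H), "OTHER")
  pick <- prio[max.col(W[, prio, drop = FALSE], ties.method = "first")]
  strategy <- labs[pick]
  strategy[rowSums(W) == 0] <- "OTHER"

  out <- data.frame(session = session, player = player, day = day,
                    game = game, game_global = game_global,
                    strategy = strategy, stringsAsFactors = FALSE)
  out[order(out$player, out$game_global), , drop = FALSE]
}

#' Classify resilient cooperators
#'
#' A player is a resilient cooperator when the assigned strategy is `CC` in
#' at least `threshold` (default 80%) of their non-missing games during the
#' stable phase of the experiment (default days 7-20).
#'
#' @param assignments output of [infer_strategies()].
#' @param stable_days integer vector of days forming the stable phase.
#' @param threshold minimum fraction of stable-phase games assigned `CC`.
#' @return a data.frame with one row per player: `player`, `n_games`
#'   (non-missing stable-phase games), `cc_fraction` and logical
#'   `resilient` (`NA` for players with no stable-phase games, who cannot
#'   be classified).
#' @export
classify_resilient <- function(assignments, stable_days = 7:20,
                               threshold = 0.8) {
  stopifnot(is.data.frame(assignments),
            all(c("player", "day", "strategy") %in% names(assignments)))
  if (!length(stable_days)) {
    stop("stable_days must be nonempty", call. = FALSE)
  }
  players <- unique(assignments$player)
  stable <- assignments[assignments$day %in% stable_days, , drop = FALSE]
  n_games <- tapply(stable$strategy, stable$player, length)
  cc <- tapply(stable$strategy == "CC", stable$player, mean)
  n <- as.integer(n_games[players])
  n[is.na(n)] <- 0L
  frac <- as.numeric(cc[players])
  data.frame(player = players, n_games = n, cc_fraction = frac,
             resilient = ifelse(n > 0L, frac >= threshold, NA),
             stringsAsFactors = FALSE, row.names = NULL)
}
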