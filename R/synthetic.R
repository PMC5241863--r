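#' Configuration for the synthetic experiment generator
#'
#' Describes an experiment-shaped study: one or more sessions of players
#' who meet in uniformly random within-session pairings for `games_per_day`
#' ten-round games on each of `days` consecutive days. A planted fraction
#' `alpha` of each session's players are resilient cooperators who always
#' play `CC`; the rest are "rational" players whose first-defection
#' threshold drifts earlier across the first week and then plateaus
#' (`rational_mode = "scripted"`), or who learn by smoothed fictitious play
#' (`rational_mode = "learning"`, driven by [run_simulation()]).
#'
#' Under the scripted schedule the target threshold on day `d` is
#' `max(plateau_threshold, start_threshold - decrement * (d - 1))`, with
#' `decrement` defaulting to the value that reaches the plateau exactly on
#' `plateau_day`. Fractional targets are realised by stochastic rounding,
#' and an integer jitter of +/-1 (probability `jitter_prob`) spreads the
#' realised thresholds. Each intended action is flipped independently with
#' probability `noise`.
#'
#' @param n_players integer vector, players per session (each even).
#' @param alpha planted resilient fraction; `round(alpha * n)` players per
#'   session are resilient.
#' @param days,games_per_day,H experiment layout (defaults 20, 20, 10).
#' @param rational_mode `"scripted"` (default) or `"learning"`.
#' @param start_threshold scripted starting threshold (`H + 1` = start at
#'   `CC`).
#' @param plateau_day day from which the scripted threshold stays at
#'   `plateau_threshold`; defaults to day 7, capped at the final day for
#'   shorter experiments.
#' @param plateau_threshold scripted asymptotic threshold (1..`H`).
#' @param decrement per-day threshold decrement; `NULL` derives it from the
#'   start, plateau and plateau day.
#' @param jitter_prob probability of a +/-1 jitter on the realised
#'   threshold.
#' @param noise per-action flip probability in `[0, 1]`.
#' @param dropout_prob per-player probability of leaving the experiment at
#'   a uniformly random day (scripted mode only).
#' @param seed integer seed.
#' @param payoffs a [payoff_matrix()].
#' @param sim optional [sim_config()] template for `"learning"` mode
#'   (its `N`, `alpha`, `n_games` and `seed` are overridden per session).
#' @return a `pd_synth_config` list.
#' @export
synth_config <- function(n_players = c(48, 46), alpha = 0.4, days = 20,
                         games_per_day = 20, H = 10,
                         rational_mode = c("scripted", "learning"),
                         start_threshold = NULL, plateau_day = NULL,
                         plateau_threshold = 9, decrement = NULL,
                         jitter_prob = 0.2, noise = 0, dropout_prob = 0,
                         seed = NULL, payoffs = payoff_matrix(),
                         sim = NULL) {
  rational_mode <- match.arg(rational_mode)
  stopifnot(length(n_players) >= 1, all(n_players >= 2),
            alpha >= 0, alpha <= 1, days >= 1, games_per_day >= 1, H >= 1,
            noise >= 0, noise <= 1, dropout_prob >= 0, dropout_prob <= 1,
            jitter_prob >= 0, jitter_prob <= 1)
  if (any(n_players %% 2 != 0)) {
    stop("each session must have an even number of players", call. = FALSE)
  }
  if (is.null(start_threshold)) start_threshold <- H + 1
  if (is.null(plateau_day)) plateau_day <- min(7, days)
  stopifnot(plateau_day >= 1, plateau_day <= days,
            plateau_threshold >= 1, plateau_threshold <= H,
            start_threshold >= plateau_threshold,
            start_threshold <= H + 1)
  if (is.null(decrement)) {
    decrement <- if (plateau_day > 1) {
      (start_threshold - plateau_threshold) / (plateau_day - 1)
    } else 0
  }
  if (rational_mode == "learning" && dropout_prob > 0) {
    stop("dropouts are only supported in scripted mode", call. = FALSE)
  }
  structure(
    list(n_players = as.integer(n_players), alpha = alpha,
         days = as.integer(days), games_per_day = as.integer(games_per_day),
         H = as.integer(H), rational_mode = rational_mode,
         start_threshold = start_threshold,
         plateau_day = as.integer(plateau_day),
         plateau_threshold = as.integer(plateau_threshold),
         decrement = decrement, jitter_prob = jitter_prob, noise = noise,
         dropout_prob = dropout_prob, seed = seed, payoffs = payoffs,
         sim = sim),
    class = "pd_synth_config"
  )
}

#' Default synthetic experiment
#'
#' The study conditions the generator emulates: two sessions of 48 and 46
#' players, a 40% planted fraction of resilient cooperators, 20 days of 20
#' ten-round games, rational thresholds drifting from `CC` down to a
#' plateau of `T9` reached on day 7, and a 2% action-noise rate.
#'
#' @param seed integer seed.
#' @return a `pd_synth_config`.
#' @export
default_experiment_config <- function(seed = NULL) {
  synth_config(n_players = c(48, 46), alpha = 0.4, days = 20,
               games_per_day = 20, H = 10, rational_mode = "scripted",
               plateau_day = 7, plateau_threshold = 9, noise = 0.02,
               seed = seed)
}

# Scripted target threshold on a given day (possibly fractional).
scripted_target <- function(cfg, day) {
  ifelse(day >= cfg$plateau_day, cfg$plateau_threshold,
         pmax(cfg$plateau_threshold,
              cfg$start_threshold - cfg$decrement * (day - 1)))
}

# Realise integer thresholds for n draws at target t: stochastic rounding
# of the fractional part plus +/-1 jitter with probability jitter_prob,
# clipped to [1, H + 1].
realize_thresholds <- function(t, n, jitter_prob, H) {
  x <- floor(t) + (stats::runif(n) < (t - floor(t)))
  u <- stats::runif(n)
  x <- x + ifelse(u < jitter_prob / 2, -1L,
                  ifelse(u < jitter_prob, 1L, 0L))
  pmin(pmax(x, 1L), H + 1L)
}

# Simulate observed actions for paired threshold vectors e1, e2 under grim
# retaliation with per-action noise; returns list of two n x H action
# matrices.
noisy_playout <- function(e1, e2, H, noise) {
  n <- length(e1)
  A1 <- matrix("D", n, H)
  A2 <- matrix("D", n, H)
  seen_d1 <- rep(FALSE, n)  # player 1 has observed a defection by player 2
  seen_d2 <- rep(FALSE, n)
  for (r in seq_len(H)) {
    a1 <- (r < e1) & !seen_d1
    a2 <- (r < e2) & !seen_d2
    if (noise > 0) {
      a1 <- xor(a1, stats::runif(n) < noise)
      a2 <- xor(a2, stats::runif(n) < noise)
    }
    A1[, r] <- ifelse(a1, "C", "D")
    A2[, r] <- ifelse(a2, "C", "D")
    seen_d1 <- seen_d1 | !a2
    seen_d2 <- seen_d2 | !a1
  }
  list(A1, A2)
}

#' Generate a synthetic experiment with ground truth
#'
#' Produces a long-format game log with the structure of the virtual-lab
#' experiment plus a ground-truth sidecar (planted player types, true
#' per-game strategies and the planted change point), fully determined by
#' the configuration and seed.
#'
#' @param cfg a [synth_config()].
#' @return a list with
#'   \describe{
#'     \item{log}{game-log data.frame (`session`, `day`, `game`, `round`,
#'       `player`, `partner`, `action`).}
#'     \item{truth}{list: `players` (data.frame `player`, `session`,
#'       `type`), `strategies` (data.frame `session`, `player`, `day`,
#'       `game`, `strategy` — the intended strategy before noise),
#'       `change_point` (the plateau day).}
#'   }
#' @examples
#' xp <- generate_experiment(synth_config(n_players = 10, days = 3,
#'                                        games_per_day = 2, seed = 1))
#' head(xp$log)
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "pd_synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$H
  sessions <- seq_along(cfg$n_players)
  players_df <- list()
  pair_rows <- list()
  truth_rows <- list()

  for (s in sessions) {
    n <- cfg$n_players[s]
    ids <- sprintf("s%d_p%02d", s, seq_len(n))
    n_res <- round(cfg$alpha * n)
    type <- rep("rational", n)
    type[sample.int(n, n_res)] <- "resilient"
    names(type) <- ids
    players_df[[s]] <- data.frame(player = ids, session = s, type = type,
                                  stringsAsFactors = FALSE, row.names = NULL)

    exit_day <- rep(Inf, n)
    if (cfg$dropout_prob > 0 && cfg$days > 1) {
      drops <- stats::runif(n) < cfg$dropout_prob
      exit_day[drops] <- sample(2:cfg$days, sum(drops), replace = TRUE)
    }

    learned <- NULL
    if (cfg$rational_mode == "learning") {
      sim_cfg <- if (is.null(cfg$sim)) sim_config() else cfg$sim
      sim_cfg$N <- as.integer(n)
      sim_cfg$alpha <- n_res / n
      sim_cfg$H <- H
      sim_cfg$n_games <- cfg$days * cfg$games_per_day
      sim_cfg$payoffs <- cfg$payoffs
      sim_cfg$seed <- NULL  # inherit the generator's RNG stream
      # run_simulation assigns resilient type to the first agents; map ids
      res_first <- c(ids[type == "resilient"], ids[type == "rational"])
      learned <- list(res = run_simulation(sim_cfg), ids = res_first)
    }

    for (d in seq_len(cfg$days)) {
      active <- ids[exit_day > d]
      tgt <- scripted_target(cfg, d)
      for (g in seq_len(cfg$games_per_day)) {
        cur <- active
        if (length(cur) %% 2 == 1) cur <- sample(cur, length(cur) - 1L)
        if (length(cur) < 2) next
        perm <- sample(cur)
        p1 <- perm[seq(1L, length(perm), 2L)]
        p2 <- perm[seq(2L, length(perm), 2L)]
        e <- rep(NA_integer_, length(cur))
        names(e) <- perm
        if (cfg$rational_mode == "scripted") {
          rat <- type[perm] == "rational"
          e[!rat] <- H + 1L
          e[rat] <- realize_thresholds(tgt, sum(rat), cfg$jitter_prob, H)
        } else {
          j <- (d - 1L) * cfg$games_per_day + g
          thr <- strategy_threshold(strategy_labels(H), H)
          e_all <- thr[learned$res$strategies[, j]]
          names(e_all) <- learned$ids
          e[perm] <- e_all[perm]
        }
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          session = s, day = d, game = g, p1 = p1, p2 = p2,
          e1 = unname(e[p1]), e2 = unname(e[p2]),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          session = s, player = perm, day = d, game = g,
          strategy = ifelse(e[perm] > H, "CC", paste0("T", e[perm])),
          stringsAsFactors = FALSE)
      }
    }
  }

  pairs <- do.call(rbind, pair_rows)
  acts <- noisy_playout(pairs$e1, pairs$e2, H, cfg$noise)
  np <- nrow(pairs)
  long <- function(pl, pt, A) data.frame(
    session = rep(pairs$session, each = H),
    day = rep(pairs$day, each = H),
    game = rep(pairs$game, each = H),
    round = rep(seq_len(H), np),
    player = rep(pl, each = H),
    partner = rep(pt, each = H),
    action = as.vector(t(A)),
    stringsAsFactors = FALSE)
  log <- rbind(long(pairs$p1, pairs$p2, acts[[1]]),
               long(pairs$p2, pairs$p1, acts[[2]]))
  log <- log[order(log$session, log$day, log$game, log$player, log$round), ,
             drop = FALSE]
  rownames(log) <- NULL

  truth <- list(players = do.call(rbind, players_df),
                strategies = do.call(rbind, truth_rows),
                change_point = cfg$plateau_day)
  list(log = log, truth = truth)
}
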