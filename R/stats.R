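#' Cooperation rate over a selection of a game log
#'
#' Fraction of cooperative decisions among all individual decisions in the
#' selected subset of the log. Sessions are pooled unless filtered.
#'
#' @param log a game-log data frame.
#' @param rounds,days,games,sessions optional filters; `NULL` keeps all.
#' @return cooperation rate in `[0, 1]`.
#' @export
cooperation_rate <- function(log, rounds = NULL, days = NULL, games = NULL,
                             sessions = NULL) {
  keep <- rep(TRUE, nrow(log))
  if (!is.null(rounds)) keep <- keep & log$round %in% rounds
  if (!is.null(days)) keep <- keep & log$day %in% days
  if (!is.null(games)) keep <- keep & log$game %in% games
  if (!is.null(sessions)) keep <- keep & log$session %in% sessions
  if (!any(keep)) {
    stop("cooperation rate is undefined on an empty selection", call. = FALSE)
  }
  mean(log$action[keep] == "C")
}

#' Game restart effect
#'
#' Within a day, cooperation typically jumps between the last round of one
#' game and the first round of the next. The game restart effect is the
#' mean, over adjacent game pairs `j`, `j + 1`, of
#' `coop(round 1, game j + 1) - coop(round H, game j)`.
#'
#' @param log a game-log data frame.
#' @param day a single day, or `NULL` to average over all days.
#' @return a list with `mean` (the effect) and `diffs`, a data.frame of the
#'   per-day per-boundary differences.
#' @export
game_restart_effect <- function(log, day = NULL) {
  H <- max(log$round)
  days <- if (is.null(day)) sort(unique(log$day)) else day
  out <- list()
  for (d in days) {
    sub <- log[log$day == d, , drop = FALSE]
    gs <- sort(unique(sub$game))
    if (length(gs) < 2) {
      stop("the game restart effect needs at least two games in day ", d,
           call. = FALSE)
    }
    first_c <- tapply(sub$action[sub$round == 1] == "C",
                      sub$game[sub$round == 1], mean)
    last_c <- tapply(sub$action[sub$round == H] == "C",
                     sub$game[sub$round == H], mean)
    j <- gs[-length(gs)]
    out[[length(out) + 1L]] <- data.frame(
      day = d, game = j,
      diff = as.numeric(first_c[as.character(j + 1L)]) -
        as.numeric(last_c[as.character(j)]))
  }
  diffs <- do.call(rbind, out)
  list(mean = mean(diffs$diff), diffs = diffs)
}

#' Session restart effect
#'
#' Cooperation in the late rounds tends to jump back up between the last
#' game of one day and the first game of the next. For each day boundary
#' and each requested round `r`, computes
#' `coop(round r, first game of day d + 1) - coop(round r, last game of day
#' d)`.
#'
#' @param log a game-log data frame.
#' @param rounds rounds to evaluate (default 9 and 10).
#' @return a list with `diffs` (data.frame: `boundary` = day `d`, `round`,
#'   `diff`) and `summary` (per-round mean and quartiles). A single-day log
#'   yields an empty result with a warning.
#' @export
session_restart_effect <- function(log, rounds = c(9, 10)) {
  days <- sort(unique(log$day))
  if (length(days) < 2) {
    warning("session restart effect needs at least two days; returning an ",
            "empty result")
    return(list(diffs = data.frame(boundary = integer(), round = integer(),
                                   diff = numeric()),
                summary = NULL))
  }
  rows <- list()
  for (i in seq_len(length(days) - 1L)) {
    d <- days[i]; d2 <- days[i + 1L]
    last_g <- max(log$game[log$day == d])
    first_g <- min(log$game[log$day == d2])
    for (r in rounds) {
      a <- log$action[log$day == d2 & log$game == first_g & log$round == r]
      b <- log$action[log$day == d & log$game == last_g & log$round == r]
      rows[[length(rows) + 1L]] <- data.frame(
        boundary = d, round = r, diff = mean(a == "C") - mean(b == "C"))
    }
  }
  diffs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(diffs$diff, diffs$round), function(z) {
    q <- stats::quantile(z, c(0.25, 0.5, 0.75))
    data.frame(mean = mean(z), q25 = q[1], median = q[2], q75 = q[3])
  }))
  summ$round <- as.integer(rownames(summ))
  rownames(summ) <- NULL
  list(diffs = diffs, summary = summ[, c("round", "mean", "q25", "median",
                                         "q75")])
}

#' Per-game rounds of first defection in a log
#'
#' One row per game (a `session`/`day`/`game`/player-pair combination) with
#' its round of first defection; fully cooperative games get `H + 1`
#' ([rd_none()]).
#'
#' @param log a game-log data frame.
#' @return data.frame with columns `session`, `day`, `game`, `pair`, `rd`.
#' @export
game_rd <- function(log) {
  H <- max(log$round)
  pair <- paste(pmin(log$player, log$partner),
                pmax(log$player, log$partner))
  key <- paste(log$session, log$day, log$game, pair, sep = "\r")
  first <- !duplicated(key)
  d_round <- ifelse(log$action == "D", log$round, H + 1L)
  rd <- tapply(d_round, key, min)
  out <- data.frame(session = log$session[first], day = log$day[first],
                    game = log$game[first], pair = pair[first],
                    rd = as.integer(rd[key[first]]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$session, out$day, out$game, out$pair), , drop = FALSE]
}

#' Distribution of the round of first defection
#'
#' Tallies per-game first-defection rounds into bins `1 ... H` plus the `C`
#' bin for games in which neither player defected.
#'
#' @param log a game-log data frame.
#' @param day a single day, or `NULL` for all days pooled.
#' @return named integer vector of counts over `c(1:H, "C")`.
#' @export
rd_distribution <- function(log, day = NULL) {
  H <- max(log$round)
  rd <- game_rd(log)
  if (!is.null(day)) rd <- rd[rd$day %in% day, , drop = FALSE]
  counts <- tabulate(rd$rd, nbins = H + 1L)
  names(counts) <- c(seq_len(H), "C")
  counts
}

#' Two-sample Kolmogorov-Smirnov test on first-defection rounds
#'
#' The D statistic is the maximum absolute gap between the two empirical
#' CDFs over the discrete support (fully cooperative games encoded as
#' `H + 1`). The default p-value is the standard asymptotic two-sample
#' approximation; since the support is discrete, a permutation p-value is
#' available for exactness on small samples.
#'
#' @param x,y numeric samples of first-defection rounds.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm permutations for `p_method = "permutation"`.
#' @return list with `statistic` (D) and `p_value`.
#' @export
two_sample_ks <- function(x, y, p_method = c("asymptotic", "permutation"),
                          n_perm = 2000) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  D <- unname(kt$statistic)
  if (p_method == "asymptotic") {
    p <- kt$p.value
  } else {
    pool <- c(x, y)
    n <- length(x)
    exceed <- replicate(n_perm, {
      idx <- sample.int(length(pool), n)
      suppressWarnings(
        stats::ks.test(pool[idx], pool[-idx], exact = FALSE)$statistic) >=
        D - 1e-12
    })
    p <- (1 + sum(exceed)) / (n_perm + 1)
  }
  list(statistic = D, p_value = p)
}

# Pooled per-day samples of rd, C bin encoded as H + 1 and included or
# dropped according to include_c.
daily_rd_samples <- function(log, include_c = TRUE) {
  H <- max(log$round)
  rd <- game_rd(log)
  if (!include_c) rd <- rd[rd$rd <= H, , drop = FALSE]
  split(rd$rd, rd$day)
}

#' Detect the onset of the steady state
#'
#' Tests whether the distribution of the round of first defection changes
#' between successive days, pooling all games of a day (sessions pooled;
#' games treated as independent).
#'
#' Under the default rule (`"first"`) the onset is the earlier day of the
#' first non-significant adjacent pair, floored at day 2: behaviour
#' changed significantly into every earlier day and stops changing
#' detectably from the onset day on. The strict rule (`"all"`) instead
#' reports the first day after which every remaining adjacent pair is
#' non-significant; with many stable days it is vulnerable to single
#' false-positive tests (roughly a `level` chance per boundary), which can
#' push the detected onset far past the true change point. Under either
#' rule, behaviour that keeps changing through the final day leaves the
#' onset undefined (`NA`).
#'
#' @param log a game-log data frame spanning at least 3 days.
#' @param test `"ks"` (two-sample Kolmogorov-Smirnov, default) or `"mw"`
#'   (Mann-Whitney U as a robustness variant).
#' @param level significance level (default 0.05).
#' @param rule `"first"` (default) or `"all"`, see Details.
#' @param include_c include fully cooperative games (as `H + 1`) in the
#'   samples (default) or drop them.
#' @param p_method p-value method for the KS test, see [two_sample_ks()].
#' @return a `pd_steady_state` list: `tests` (data.frame with `day`,
#'   `statistic`, `p_value` for each comparison of day `d - 1` vs `d`),
#'   `onset`, `test`, `rule` and `level`.
#' @export
steady_state_onset <- function(log, test = c("ks", "mw"), level = 0.05,
                               include_c = TRUE, rule = c("first", "all"),
                               p_method = "asymptotic") {
  test <- match.arg(test)
  rule <- match.arg(rule)
  samples <- daily_rd_samples(log, include_c)
  days <- as.integer(names(samples))
  if (length(days) < 3) {
    stop("steady-state detection needs at least 3 days", call. = FALSE)
  }
  res <- lapply(seq_along(days)[-1], function(i) {
    x <- samples[[i - 1]]
    y <- samples[[i]]
    if (test == "ks") {
      r <- two_sample_ks(x, y, p_method = p_method)
      data.frame(day = days[i], statistic = r$statistic,
                 p_value = r$p_value)
    } else {
      r <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      data.frame(day = days[i], statistic = unname(r$statistic),
                 p_value = r$p.value)
    }
  })
  tests <- do.call(rbind, res)
  sig <- tests$p_value < level
  onset <- NA_integer_
  if (rule == "first") {
    hit <- which(!sig)
    if (length(hit)) onset <- max(2L, tests$day[hit[1L]] - 1L)
  } else {
    # onset d: every comparison strictly after day d is non-significant
    for (d in days[-length(days)][-1]) {   # candidates 2 ... D - 1
      if (!any(sig[tests$day > d])) {
        onset <- d
        break
      }
    }
  }
  structure(list(tests = tests, onset = onset, test = test, rule = rule,
                 level = level),
            class = "pd_steady_state")
}

#' @export
print.pd_steady_state <- function(x, ...) {
  cat(sprintf("adjacent-day %s tests on round of first defection\n",
              toupper(x$test)))
  print(x$tests, digits = 3)
  cat(sprintf("steady-state onset (level %.2f): %s\n", x$level,
              ifelse(is.na(x$onset), "undefined (never stable)", x$onset)))
  invisible(x)
}

#' Fraction of conditional cooperators implied by random pairing
#'
#' A game without any defection requires both randomly paired players to be
#' conditional cooperators, so under independent random pairing the
#' frequency of fully cooperative games is the square of the conditional-
#' cooperator fraction. This inverts that relation: e.g. a 16% rate of
#' no-defection games implies a 40% fraction of conditional cooperators.
#'
#' @param no_defection_game_rate observed fraction of games with no
#'   defection, in `[0, 1]`.
#' @return implied conditional-cooperator fraction, `sqrt(rate)`.
#' @export
implied_cc_fraction <- function(no_defection_game_rate) {
  if (any(no_defection_game_rate < 0 | no_defection_game_rate > 1)) {
    stop("the no-defection game rate must lie in [0, 1]", call. = FALSE)
  }
  sqrt(no_defection_game_rate)
}
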