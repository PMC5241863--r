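#' Configuration for the smoothed fictitious play simulation
#'
#' Builds a validated configuration for [run_simulation()]. The population
#' contains `round(alpha * N)` resilient cooperators, who play `CC` in every
#' game and never update, and `N - round(alpha * N)` rational learners. Each
#' game, every rational agent normalises its belief counts over the eleven
#' strategies, computes expected utilities against that belief, and samples
#' a strategy from a softmax; agents are then paired uniformly at random and
#' each agent's count for its opponent's strategy is incremented by one.
#'
#' @param N population size (even).
#' @param alpha fraction of resilient cooperators in `[0, 1]`.
#' @param H rounds per game.
#' @param n_games number of games to simulate.
#' @param beta softmax randomness; `beta -> 0` is deterministic best reply,
#'   `beta -> Inf` uniform choice.
#' @param prior initial per-strategy pseudo-counts (length `H + 1`, order of
#'   [strategy_labels()]). The default places a single pseudo-count on `CC`:
#'   agents start out believing others conditionally cooperate. Use
#'   `rep(1/(H+1), H+1)` for a uniform prior.
#' @param u_scale utility normalisation divisor applied before the softmax,
#'   so that choice probabilities are `P(s) proportional to
#'   exp((u(s)/u_scale)/beta)`. The default 1 uses raw expected utilities in
#'   points per game, the standard logit-choice form with `beta` as a
#'   temperature in payoff units; it reproduces the documented limits
#'   (complete unravelling without resilient cooperators, none in the
#'   all-resilient limit) and leaves the dynamics insensitive to `beta`
#'   across `[0.001, 0.1]`. Setting `u_scale` to the maximum game payoff
#'   `T * H` instead gives a markedly noisier choice rule at the same
#'   `beta`.
#' @param seed integer seed; every source of randomness in the run flows
#'   from it.
#' @param r_inf_window fraction of final games used by [estimate_r_inf()].
#' @param payoffs a [payoff_matrix()].
#' @param belief_update `"true"` increments the count of the opponent's
#'   actually sampled strategy; `"censored"` splits the increment equally
#'   over all strategies consistent with the opponent's observed actions.
#'
#' @return a `pd_sim_config` list.
#' @export
sim_config <- function(N = 100, alpha = 0, H = 10, n_games = 2000,
                       beta = 0.005, prior = NULL, u_scale = 1,
                       seed = NULL, r_inf_window = 0.25,
                       payoffs = payoff_matrix(),
                       belief_update = c("true", "censored")) {
  belief_update <- match.arg(belief_update)
  stopifnot(N >= 2, H >= 1, n_games >= 1, beta > 0,
            alpha >= 0, alpha <= 1, r_inf_window > 0, r_inf_window <= 1)
  if (N %% 2 != 0) stop("N must be even so all agents can be paired",
                        call. = FALSE)
  n_strat <- H + 1L
  if (is.null(prior)) {
    prior <- c(rep(0, H), 1)  # one pseudo-count on CC
  }
  if (length(prior) != n_strat || any(prior < 0) || sum(prior) <= 0) {
    stop("prior must be ", n_strat, " nonnegative pseudo-counts with a ",
         "positive sum", call. = FALSE)
  }
  stopifnot(u_scale > 0)
  structure(
    list(N = as.integer(N), alpha = alpha, H = as.integer(H),
         n_games = as.integer(n_games), beta = beta, prior = prior,
         u_scale = u_scale, seed = seed, r_inf_window = r_inf_window,
         payoffs = payoffs, belief_update = belief_update),
    class = "pd_sim_config"
  )
}

#' Expected utility of each strategy under a belief
#'
#' Normalises the belief counts `pi` to a probability vector and returns
#' `u(s) = sum_t pihat(t) * U[s, t]` for every strategy `s`.
#'
#' @param pi nonnegative belief counts over the strategies (length `H + 1`).
#' @param U the payoff table from [strategy_payoff_table()].
#' @return named numeric vector of expected utilities, in points per game.
#' @export
expected_utilities <- function(pi, U) {
  if (length(pi) != nrow(U)) {
    stop("belief vector length must match the payoff table", call. = FALSE)
  }
  if (any(pi < 0) || sum(pi) <= 0) {
    stop("belief counts must be nonnegative with a positive sum ",
         "(is the prior misconfigured?)", call. = FALSE)
  }
  u <- as.vector(U %*% (pi / sum(pi)))
  names(u) <- rownames(U)
  u
}

#' Softmax choice probabilities and sampling
#'
#' `softmax_probs()` returns `P(s) proportional to exp((u(s)/u_scale)/beta)`,
#' computed stably by shifting by the maximum before exponentiation.
#' `softmax_choice()` samples one strategy index from those probabilities.
#'
#' @param u numeric vector of utilities.
#' @param beta softmax randomness (> 0).
#' @param u_scale utility normalisation divisor.
#' @return `softmax_probs()`: a probability vector; `softmax_choice()`: a
#'   single integer index into `u`.
#' @export
softmax_probs <- function(u, beta, u_scale = 1) {
  stopifnot(beta > 0, u_scale > 0)
  z <- u / u_scale / beta
  z <- exp(z - max(z))
  z / sum(z)
}

#' @rdname softmax_probs
#' @export
softmax_choice <- function(u, beta, u_scale = 1) {
  p <- softmax_probs(u, beta, u_scale)
  sample.int(length(u), 1L, prob = p)
}

# Strategies consistent with an opponent's observed actions, as first-
# defection rounds. Both players' observed play is summarised by the round
# of their own first defection (H + 1 = never). A threshold f reproduces the
# opponent's observed sequence iff min(f, m_self + 1) == m_opp; so:
#   m_opp <= m_self : only f = m_opp
#   m_opp == m_self + 1 (pure retaliation): any f >= m_opp
# Returns a list of integer vectors of consistent thresholds.
consistent_thresholds <- function(m_opp, m_self, H) {
  mapply(function(mo, ms) {
    if (mo <= ms) mo else seq.int(mo, H + 1L)
  }, m_opp, m_self, SIMPLIFY = FALSE)
}

# One simulation game, vectorised over the population.
# beliefs: N x (H+1) counts; resilient: logical N; thr: effective threshold
# of each strategy index; U: payoff table; Mtri: upper-triangular ones for
# row-wise cumsum via matmul.
sim_step <- function(beliefs, resilient, thr, U, beta, u_scale, Mtri,
                     censored = FALSE) {
  N <- nrow(beliefs)
  H <- length(thr) - 1L
  u <- (beliefs / rowSums(beliefs)) %*% t(U)  # u[i, s]; U[s,t] so t(U) maps
  u <- u / u_scale / beta
  u <- exp(u - u[cbind(seq_len(N), max.col(u, ties.method = "first"))])
  p <- u / rowSums(u)
  cs <- p %*% Mtri
  s <- 1L + as.integer(rowSums(cs < stats::runif(N)))
  s[s > ncol(beliefs)] <- ncol(beliefs)  # numeric guard
  s[resilient] <- ncol(beliefs)          # CC
  perm <- sample.int(N)
  a <- perm[seq(1L, N, by = 2L)]
  b <- perm[seq(2L, N, by = 2L)]
  ea <- thr[s[a]]
  eb <- thr[s[b]]
  rd <- pmin(ea, eb)  # = H + 1 iff both CC (no defection)
  opp <- integer(N)
  opp[a] <- s[b]
  opp[b] <- s[a]
  if (!censored) {
    idx <- cbind(seq_len(N), opp)
    beliefs[idx] <- beliefs[idx] + 1
  } else {
    # first-defection round of each agent's own observed play
    m_self <- integer(N)
    m_self[a] <- ifelse(ea <= eb, ea, pmin(eb + 1L, H + 1L))
    m_self[b] <- ifelse(eb <= ea, eb, pmin(ea + 1L, H + 1L))
    m_opp <- integer(N)
    m_opp[a] <- m_self[b]
    m_opp[b] <- m_self[a]
    cons <- consistent_thresholds(m_opp, m_self, H)
    for (i in seq_len(N)) {
      k <- cons[[i]]
      beliefs[i, k] <- beliefs[i, k] + 1 / length(k)
    }
  }
  list(strategy = s, pair_a = a, pair_b = b, rd = rd, beliefs = beliefs)
}

#' Advance a simulation population by one game
#'
#' Pairs the population uniformly at random, lets resilient agents play `CC`
#' and rational agents sample a strategy by softmax from beliefs formed
#' before the game, plays every pairing, and increments each agent's belief
#' count for its opponent's strategy. Exposed mainly for inspection and
#' testing; [run_simulation()] drives the same engine.
#'
#' @param state a population state as returned by [sim_state()] or a
#'   previous `step_game()` call.
#' @return the updated state, with `last` holding the game's strategies,
#'   pairings and per-pair first-defection rounds.
#' @export
step_game <- function(state) {
  stopifnot(inherits(state, "pd_sim_state"))
  res <- sim_step(state$beliefs, state$resilient, state$thr, state$U,
                  state$beta, state$u_scale, state$Mtri,
                  state$censored)
  state$beliefs <- res$beliefs
  state$last <- res[c("strategy", "pair_a", "pair_b", "rd")]
  state
}

#' @rdname step_game
#' @param cfg a [sim_config()].
#' @return `sim_state()` returns a fresh `pd_sim_state` for `cfg` (beliefs at
#'   the prior, resilient types assigned to the first `round(alpha * N)`
#'   agent ids).
#' @export
sim_state <- function(cfg) {
  stopifnot(inherits(cfg, "pd_sim_config"))
  n_strat <- cfg$H + 1L
  n_res <- round(cfg$alpha * cfg$N)
  state <- list(
    beliefs = matrix(cfg$prior, cfg$N, n_strat, byrow = TRUE,
                     dimnames = list(NULL, strategy_labels(cfg$H))),
    resilient = seq_len(cfg$N) <= n_res,
    thr = strategy_threshold(strategy_labels(cfg$H), cfg$H),
    U = strategy_payoff_table(cfg$H, cfg$payoffs),
    beta = cfg$beta, u_scale = cfg$u_scale,
    Mtri = upper.tri(diag(n_strat), diag = TRUE) * 1,
    censored = cfg$belief_update == "censored",
    H = cfg$H
  )
  class(state) <- "pd_sim_state"
  state
}

#' Run the smoothed fictitious play simulation
#'
#' Simulates `cfg$n_games` games and records, per game, every agent's chosen
#' strategy, the random pairing, and each pairing's round of first defection
#' (`H + 1` for fully cooperative games). Identical configurations with the
#' same seed produce bit-identical results.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `pd_sim`: a list with
#'   \describe{
#'     \item{strategies}{`N x n_games` integer matrix of strategy indices
#'       (1..H = `T1`..`TH`, `H + 1` = `CC`).}
#'     \item{pair_a, pair_b}{`(N/2) x n_games` matrices of paired agent ids.}
#'     \item{rd}{`(N/2) x n_games` matrix of per-pairing first-defection
#'       rounds.}
#'     \item{pair_rational}{logical matrix: does the pairing contain at
#'       least one rational agent.}
#'     \item{resilient}{logical vector of agent types.}
#'     \item{beliefs}{final belief counts.}
#'     \item{cfg}{the configuration.}
#'   }
#' @examples
#' res <- run_simulation(sim_config(N = 20, alpha = 0.5, n_games = 200,
#'                                  seed = 1))
#' estimate_r_inf(res)
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "pd_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- sim_state(cfg)
  N <- cfg$N
  J <- cfg$n_games
  n_pairs <- N %/% 2L
  strategies <- matrix(NA_integer_, N, J)
  pair_a <- matrix(NA_integer_, n_pairs, J)
  pair_b <- matrix(NA_integer_, n_pairs, J)
  rd <- matrix(NA_integer_, n_pairs, J)
  beliefs <- state$beliefs
  for (j in seq_len(J)) {
    stp <- sim_step(beliefs, state$resilient, state$thr, state$U,
                    state$beta, state$u_scale, state$Mtri, state$censored)
    beliefs <- stp$beliefs
    strategies[, j] <- stp$strategy
    pair_a[, j] <- stp$pair_a
    pair_b[, j] <- stp$pair_b
    rd[, j] <- stp$rd
  }
  pair_rational <- !(matrix(state$resilient[pair_a], n_pairs, J) &
                       matrix(state$resilient[pair_b], n_pairs, J))
  structure(
    list(strategies = strategies, pair_a = pair_a, pair_b = pair_b,
         rd = rd, pair_rational = pair_rational,
         resilient = state$resilient, beliefs = beliefs, cfg = cfg),
    class = "pd_sim"
  )
}

#' @export
print.pd_sim <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "smoothed fictitious play run: N = %d (alpha = %g), %d games, beta = %g\n",
    cfg$N, cfg$alpha, cfg$n_games, cfg$beta))
  if (any(!x$resilient)) {
    cat(sprintf("  r_inf (final %d%% of games): %.3f\n",
                round(100 * cfg$r_inf_window), estimate_r_inf(x)))
  }
  invisible(x)
}

#' Asymptotic round of first defection
#'
#' Estimates `r_inf`, the asymptotic mean round of first defection among
#' rational players, as the average of per-pairing `rd` values (C games
#' count as `H + 1`) over the final `window` fraction of games, restricted
#' to pairings that contain at least one rational agent.
#'
#' @param res a `pd_sim` from [run_simulation()].
#' @param window fraction of final games to average over; defaults to the
#'   configuration's `r_inf_window`. The window must contain at least 50
#'   games.
#' @return numeric `r_inf` in `[1, H + 1]`.
#' @export
estimate_r_inf <- function(res, window = NULL) {
  stopifnot(inherits(res, "pd_sim"))
  if (is.null(window)) window <- res$cfg$r_inf_window
  if (all(res$resilient)) {
    stop("r_inf is undefined when the population has no rational agents ",
         "(alpha = 1)", call. = FALSE)
  }
  J <- res$cfg$n_games
  n_win <- floor(window * J)
  if (n_win < 50) {
    stop("the estimation window must contain at least 50 games; run more ",
         "games or widen the window", call. = FALSE)
  }
  idx <- seq.int(J - n_win + 1L, J)
  vals <- res$rd[, idx][res$pair_rational[, idx]]
  mean(vals)
}

#' Sweep the resilient fraction and locate the critical mass
#'
#' Runs the simulation at each value of `alphas`, `reps` times with distinct
#' seeds, estimates `r_inf` for every run, and reports the per-alpha mean
#' and standard deviation. The critical fraction `alpha_star` is estimated
#' as the largest grid value whose mean `r_inf` stays at the complete-
#' unravelling floor, i.e. `mean r_inf <= 1 + eps_transition`.
#'
#' @param alphas numeric grid of resilient fractions in `[0, 1)`.
#' @param reps independent runs per grid value.
#' @param cfg a [sim_config()] supplying all other parameters; its `seed`
#'   seeds the whole sweep.
#' @param eps_transition tolerance above the `r_inf = 1` floor used to
#'   separate the unravelled plateau from the rising branch.
#' @return a `pd_sweep` object: list with `curve` (data.frame of `alpha`,
#'   `r_inf_mean`, `r_inf_sd`, `reps`), `alpha_star`, `r_inf` (reps x alphas
#'   matrix of raw estimates) and the inputs.
#' @export
sweep_alpha <- function(alphas, reps = 10, cfg = sim_config(),
                        eps_transition = 0.5) {
  stopifnot(reps >= 1, all(alphas >= 0), all(alphas < 1))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(alphas) * reps),
                  reps, length(alphas))
  r <- matrix(NA_real_, reps, length(alphas),
              dimnames = list(NULL, alphas))
  for (i in seq_along(alphas)) {
    for (k in seq_len(reps)) {
      cfg_ik <- cfg
      cfg_ik$alpha <- alphas[i]
      cfg_ik$seed <- seeds[k, i]
      r[k, i] <- estimate_r_inf(run_simulation(cfg_ik))
    }
  }
  means <- colMeans(r)
  floor_alphas <- alphas[means <= 1 + eps_transition]
  structure(
    list(curve = data.frame(alpha = alphas, r_inf_mean = means,
                            r_inf_sd = apply(r, 2, stats::sd),
                            reps = reps, row.names = NULL),
         alpha_star = if (length(floor_alphas)) max(floor_alphas)
                      else NA_real_,
         r_inf = r, eps_transition = eps_transition, cfg = cfg),
    class = "pd_sweep"
  )
}

#' @export
print.pd_sweep <- function(x, ...) {
  cat("r_inf(alpha) sweep,", x$curve$reps[1], "runs per point\n")
  print(x$curve, digits = 3)
  cat(sprintf("estimated critical fraction alpha_star = %s\n",
              format(x$alpha_star)))
  invisible(x)
}

#' Cooperation rate by round in a simulation
#'
#' Fraction of cooperative decisions in round `round` across all pairings in
#' the selected games, computed from the recorded strategy thresholds: in a
#' pairing with thresholds `e1`, `e2`, a player cooperates in round `r` iff
#' `r <` their own threshold and `r <=` the opponent's (grim retaliation
#' starts one round after the opponent's first defection).
#'
#' @param res a `pd_sim`.
#' @param round round index in `1 ... H`.
#' @param games integer vector of game indices (default all).
#' @return cooperation rate in `[0, 1]`.
#' @export
sim_cooperation_rate <- function(res, round, games = NULL) {
  stopifnot(inherits(res, "pd_sim"), round >= 1, round <= res$cfg$H)
  if (is.null(games)) games <- seq_len(res$cfg$n_games)
  thr <- strategy_threshold(strategy_labels(res$cfg$H), res$cfg$H)
  sa <- res$strategies[cbind(as.vector(res$pair_a[, games, drop = FALSE]),
                             rep(games, each = nrow(res$pair_a)))]
  sb <- res$strategies[cbind(as.vector(res$pair_b[, games, drop = FALSE]),
                             rep(games, each = nrow(res$pair_b)))]
  e1 <- thr[sa]
  e2 <- thr[sb]
  c1 <- (round < e1) & (round <= e2)
  c2 <- (round < e2) & (round <= e1)
  mean(c(c1, c2))
}
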