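# Independent oracles and fixture builders used across the suite.

# Brute-force two-sample ECDF gap over the pooled support.
oracle_ks_D <- function(x, y) {
  support <- sort(unique(c(x, y)))
  Fx <- vapply(support, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(support, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}

# Exact-match strategy enumeration, written independently of the package:
# strategy with threshold x (H + 1 = CC) replayed against the opponent's
# observed actions, one round at a time.
oracle_consistent <- function(own, opp, H = length(own)) {
  labs <- c(paste0("T", seq_len(H)), "CC")
  thr <- c(seq_len(H), H + 1L)
  ok <- logical(H + 1L)
  for (k in seq_along(thr)) {
    seen_d <- FALSE
    sim <- character(H)
    for (r in seq_len(H)) {
      sim[r] <- if (r < thr[k] && !seen_d) "C" else "D"
      if (opp[r] == "D") seen_d <- TRUE
    }
    ok[k] <- all(sim == own)
  }
  stats::setNames(as.integer(ok), labs)
}

# Build a long-format log from explicit per-pair action matrices.
# pairs: data.frame(session, day, game, p1, p2); a1, a2: n x H matrices.
build_log <- function(pairs, a1, a2) {
  H <- ncol(a1)
  n <- nrow(pairs)
  long <- function(pl, pt, A) data.frame(
    session = rep(pairs$session, each = H),
    day = rep(pairs$day, each = H),
    game = rep(pairs$game, each = H),
    round = rep(seq_len(H), n),
    player = rep(pl, each = H),
    partner = rep(pt, each = H),
    action = as.vector(t(A)),
    stringsAsFactors = FALSE)
  rbind(long(pairs$p1, pairs$p2, a1), long(pairs$p2, pairs$p1, a2))
}

# One-day log in which every game is the deterministic playout of the given
# strategy pair.
playout_log <- function(s1, s2, n_games = 1, day = 1, session = 1, H = 10) {
  p <- play_game(s1, s2, H = H)
  pairs <- data.frame(session = session, day = day, game = seq_len(n_games),
                      p1 = "a", p2 = "b", stringsAsFactors = FALSE)
  build_log(pairs,
            matrix(rep(p$actions[1, ], n_games), n_games, H, byrow = TRUE),
            matrix(rep(p$actions[2, ], n_games), n_games, H, byrow = TRUE))
}
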