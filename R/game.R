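#' Play one finitely repeated game between two pure strategies
#'
#' Deterministically plays out an `H`-round Prisoner's Dilemma between two
#' strategies from the threshold/grim set. Player `i` cooperates in round
#' `r` iff `r` is below their effective threshold *and* the opponent has not
#' defected in any earlier round (grim retaliation); otherwise they defect.
#'
#' @param s1,s2 strategy labels (see [strategy_labels()]).
#' @param H number of rounds (default 10).
#' @param M a [payoff_matrix()].
#'
#' @return An object of class `pd_playout`: a list with
#'   \describe{
#'     \item{actions}{`2 x H` character matrix of actions, rows = players.}
#'     \item{payoffs}{`2 x H` numeric matrix of per-round payoffs.}
#'     \item{total}{numeric length-2 vector of total payoffs.}
#'     \item{rd}{round of first defection by either player; `H + 1`
#'       (see [rd_none()]) if the game is fully cooperative.}
#'     \item{H, strategies}{the inputs.}
#'   }
#' @examples
#' p <- play_game("T8", "CC")
#' p$total  # 48 42
#' first_defection_round(p)  # 8
#' @export
play_game <- function(s1, s2, H = 10, M = payoff_matrix()) {
  stopifnot(length(s1) == 1L, length(s2) == 1L, H >= 1)
  e1 <- strategy_threshold(s1, H)
  e2 <- strategy_threshold(s2, H)
  a1 <- character(H)
  a2 <- character(H)
  opp1_defected <- FALSE  # has player 2 defected so far (as seen by player 1)
  opp2_defected <- FALSE
  for (r in seq_len(H)) {
    a1[r] <- if (r < e1 && !opp1_defected) "C" else "D"
    a2[r] <- if (r < e2 && !opp2_defected) "C" else "D"
    opp1_defected <- opp1_defected || a2[r] == "D"
    opp2_defected <- opp2_defected || a1[r] == "D"
  }
  pay <- round_payoff(a1, a2, M)
  if (H == 1L) pay <- matrix(pay, nrow = 1L)
  actions <- rbind(a1, a2)
  rownames(actions) <- c("p1", "p2")
  payoffs <- t(pay)
  rownames(payoffs) <- c("p1", "p2")
  d <- which(actions[1, ] == "D" | actions[2, ] == "D")
  structure(
    list(actions = actions, payoffs = payoffs,
         total = rowSums(payoffs),
         rd = if (length(d)) d[1L] else rd_none(H),
         H = H, strategies = c(s1, s2)),
    class = "pd_playout"
  )
}

#' @export
print.pd_playout <- function(x, ...) {
  cat(sprintf("%d-round PD playout: %s vs %s\n", x$H,
              x$strategies[1], x$strategies[2]))
  print(x$actions)
  cat(sprintf("totals: %g / %g;  first defection: %s\n",
              x$total[1], x$total[2],
              if (x$rd > x$H) "none (C)" else x$rd))
  invisible(x)
}

#' Round of first defection
#'
#' The smallest round index in which either player defected, or `H + 1`
#' ([rd_none()]) when the game was fully cooperative — the "C" bin of the
#' first-defection histogram.
#'
#' @param p a `pd_playout` from [play_game()].
#' @return integer round index in `1 ... H + 1`.
#' @export
first_defection_round <- function(p) {
  stopifnot(inherits(p, "pd_playout"))
  p$rd
}

#' Closed-form strategy-vs-strategy payoff table
#'
#' Total payoffs to the row player over an `H`-round game for every ordered
#' pair of the `H + 1` strategies. With `a = min(e(s), e(t))` and
#' `b = max(e(s), e(t))` the effective thresholds of the pair:
#' if `a = b = H + 1` both earn `R * H`; if `a = b <= H` each earns
#' `(a-1) R + (H-a+1) P`; if `a < b` the earlier defector earns
#' `(a-1) R + T + (H-a) P` and the later one `(a-1) R + S + (H-a) P`.
#' The closed form agrees exactly with the round-by-round playout of
#' [play_game()] on every pair.
#'
#' @param H number of rounds.
#' @param M a [payoff_matrix()].
#' @return an `(H+1) x (H+1)` numeric matrix `U` with
#'   `U[s, t]` = total payoff to a player using strategy `s` against an
#'   opponent using `t`; dimnames are the strategy labels.
#' @examples
#' U <- strategy_payoff_table()
#' U["T10", "CC"]  # 52
#' U["CC", "T10"]  # 46
#' @export
strategy_payoff_table <- function(H = 10, M = payoff_matrix()) {
  stopifnot(H >= 1)
  labs <- strategy_labels(H)
  e <- strategy_threshold(labs, H)
  n <- length(labs)
  es <- matrix(e, n, n)        # row player's threshold
  et <- matrix(e, n, n, byrow = TRUE)
  a <- pmin(es, et)
  U <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  both_cc <- es == H + 1L & et == H + 1L
  tie <- es == et & !both_cc
  first <- es < et   # row player defects first
  later <- es > et
  U[both_cc] <- M$R * H
  U[tie] <- (a[tie] - 1) * M$R + (H - a[tie] + 1) * M$P
  U[first] <- (a[first] - 1) * M$R + M$T + (H - a[first]) * M$P
  U[later] <- (a[later] - 1) * M$R + M$S + (H - a[later]) * M$P
  U
}
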