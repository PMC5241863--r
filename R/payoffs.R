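#' One-round Prisoner's Dilemma payoff matrix
#'
#' Constructs the per-round payoff structure of a two-player Prisoner's
#' Dilemma from the four canonical values: temptation `T` (defect against a
#' cooperator), reward `R` (mutual cooperation), punishment `P` (mutual
#' defection) and sucker `S` (cooperate against a defector). The constructor
#' enforces the PD ordering `T > R > P > S` and the efficiency condition
#' `2R > T + S`, and derives the normalised gain from defecting one round
#' early, `g = (T - R) / (R - P)`, and the normalised loss from being
#' defected on, `l = (P - S) / (R - P)`.
#'
#' The default matrix (7, 5, 3, 1) gives `g = l = 1`: defecting exactly one
#' round before a conditional cooperator neither gains nor loses points in
#' total over the game.
#'
#' @param T temptation payoff (points per round).
#' @param R reward payoff.
#' @param P punishment payoff.
#' @param S sucker payoff.
#'
#' @return An object of class `pd_payoff`: a list with elements `T`, `R`,
#'   `P`, `S` and the derived normalisations `g` and `l`.
#' @examples
#' M <- payoff_matrix()
#' M$g  # 1
#' round_payoff("D", "C", M)  # c(7, 1)
#' @export
payoff_matrix <- function(T = 7, R = 5, P = 3, S = 1) {
  vals <- c(T = T, R = R, P = P, S = S)
  if (!all(is.finite(vals))) {
    stop("payoff values must be finite numbers", call. = FALSE)
  }
  if (!(T > R && R > P && P > S)) {
    stop("payoffs must satisfy the PD ordering T > R > P > S, got (",
         paste(vals, collapse = ", "), ")", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("payoffs must satisfy 2R > T + S so that mutual cooperation ",
         "beats alternating exploitation", call. = FALSE)
  }
  structure(
    list(T = T, R = R, P = P, S = S,
         g = (T - R) / (R - P),
         l = (P - S) / (R - P)),
    class = "pd_payoff"
  )
}

#' @export
print.pd_payoff <- function(x, ...) {
  cat("Prisoner's Dilemma payoff matrix (per round)\n")
  cat(sprintf("  T = %g, R = %g, P = %g, S = %g\n", x$T, x$R, x$P, x$S))
  cat(sprintf("  g = (T-R)/(R-P) = %g,  l = (P-S)/(R-P) = %g\n", x$g, x$l))
  invisible(x)
}

# Validate a vector of action symbols; returns it unchanged.
check_actions <- function(a, what = "action") {
  if (!all(a %in% c("C", "D"))) {
    bad <- unique(a[!a %in% c("C", "D")])
    stop("invalid ", what, " symbol(s): ", paste(bad, collapse = ", "),
         " (must be \"C\" or \"D\")", call. = FALSE)
  }
  a
}

#' Payoffs for a single round
#'
#' Looks up the one-round payoff pair for the two players' actions.
#' Vectorised over `a1` and `a2`.
#'
#' @param a1,a2 actions of player 1 and player 2, `"C"` or `"D"`.
#' @param M a [payoff_matrix()].
#'
#' @return For scalar input, a numeric vector of length 2 (points to player
#'   1, points to player 2); for vector input, a 2-column matrix.
#' @export
round_payoff <- function(a1, a2, M = payoff_matrix()) {
  check_actions(a1)
  check_actions(a2)
  if (length(a1) != length(a2)) {
    stop("a1 and a2 must have equal length", call. = FALSE)
  }
  p1 <- ifelse(a1 == "C",
               ifelse(a2 == "C", M$R, M$S),
               ifelse(a2 == "C", M$T, M$P))
  p2 <- ifelse(a2 == "C",
               ifelse(a1 == "C", M$R, M$S),
               ifelse(a1 == "C", M$T, M$P))
  if (length(a1) == 1L) c(p1, p2) else cbind(p1 = p1, p2 = p2)
}
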