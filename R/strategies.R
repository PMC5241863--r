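#' The eleven pure strategies of the ten-round game
#'
#' The strategy set consists of the ten threshold strategies `T1` ... `TH`
#' and full conditional cooperation `CC` (grim trigger). A player using
#' threshold strategy `Tx` cooperates conditionally up to round `x - 1` and
#' defects unilaterally from round `x` onward; `T1` is unconditional
#' defection (ALLD). `CC` cooperates until the partner defects and then
#' defects for the rest of the game. All strategies retaliate in grim
#' fashion: a single observed defection by the partner triggers permanent
#' defection.
#'
#' Strategies are represented by their labels (`"T1"` ... `"T10"`, `"CC"`)
#' and, internally, by their *effective threshold*: the first round in which
#' the strategy defects unilaterally. For `Tx` this is `x`; for `CC` it is
#' `H + 1` (never defects first).
#'
#' @param H number of rounds per game.
#' @return `strategy_labels()` returns the character vector of the `H + 1`
#'   strategy labels in canonical order (`T1` ... `TH`, `CC`).
#' @examples
#' strategy_labels()
#' strategy_threshold(c("T1", "T8", "CC"))
#' @export
strategy_labels <- function(H = 10) {
  stopifnot(H >= 1)
  c(paste0("T", seq_len(H)), "CC")
}

#' @rdname strategy_labels
#' @param s character vector of strategy labels.
#' @return `strategy_threshold()` returns the integer effective threshold of
#'   each label: `x` for `Tx`, `H + 1` for `CC`.
#' @export
strategy_threshold <- function(s, H = 10) {
  labs <- strategy_labels(H)
  idx <- match(s, labs)
  if (anyNA(idx)) {
    stop("unknown strategy label(s): ",
         paste(unique(s[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  ifelse(idx > H, H + 1L, idx)
}

#' No-defection code for the round of first defection
#'
#' Games in which neither player ever defects have no round of first
#' defection; throughout the package this "C bin" is encoded as the numeric
#' value `H + 1` wherever a number is required (histograms, two-sample
#' tests, asymptotic averages).
#'
#' @param H number of rounds per game.
#' @return the integer `H + 1`.
#' @export
rd_none <- function(H = 10) H + 1L
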