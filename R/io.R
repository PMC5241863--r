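#' Validate a long-format game log
#'
#' Checks the schema of a long-format behavioural game log: one row per
#' player per round, with columns `session`, `day`, `game`, `round`,
#' `player`, `partner`, `action` (and optionally `payoff`). Every row must
#' have a mirror row for the partner in the same session/day/game/round,
#' actions must be `"C"`/`"D"`, and stored payoffs (when present) must
#' match the payoff matrix applied to the recorded actions.
#'
#' @param log a data.frame.
#' @param payoffs a [payoff_matrix()] used to check any `payoff` column.
#' @return the validated log (indices coerced to integer), invisibly usable
#'   downstream.
#' @export
validate_game_log <- function(log, payoffs = payoff_matrix()) {
  required <- c("session", "day", "game", "round", "player", "partner",
                "action")
  miss <- setdiff(required, names(log))
  if (length(miss)) {
    stop("game log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  log <- as.data.frame(log)
  for (col in c("day", "game", "round")) {
    v <- log[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 1) ||
        any(v != as.integer(v))) {
      stop("column '", col, "' must contain positive integers",
           call. = FALSE)
    }
    log[[col]] <- as.integer(v)
  }
  bad <- which(!log$action %in% c("C", "D"))
  if (length(bad)) {
    stop("invalid action symbol(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "",
         " (must be \"C\" or \"D\")", call. = FALSE)
  }
  if (any(log$player == log$partner)) {
    bad <- which(log$player == log$partner)
    stop("player paired with itself in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key_self <- paste(log$session, log$day, log$game, log$round, log$player,
                    log$partner)
  key_mirror <- paste(log$session, log$day, log$game, log$round,
                      log$partner, log$player)
  m <- match(key_mirror, key_self)
  if (anyNA(m)) {
    bad <- which(is.na(m))
    stop("unpairable row(s) (no mirror row for the partner): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  if ("payoff" %in% names(log)) {
    opp_action <- log$action[m]
    expected <- round_payoff(log$action, opp_action, payoffs)[, 1]
    bad <- which(abs(log$payoff - expected) > 1e-9)
    if (length(bad)) {
      stop("stored payoffs inconsistent with actions under the (",
           payoffs$T, ", ", payoffs$R, ", ", payoffs$P, ", ", payoffs$S,
           ") per-round payoff matrix in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    }
  }
  log
}

#' Column dialect for external game logs
#'
#' Describes how an external file maps onto the package's log schema: a
#' named mapping from internal column names to the file's column names and
#' the symbols used for cooperation and defection. Deposited datasets with
#' different layouts are adapted by configuring a dialect rather than by
#' editing code.
#'
#' @param columns named character vector; names are internal columns
#'   (`session`, `day`, `game`, `round`, `player`, `partner`, `action`,
#'   optionally `payoff`), values the file's column names. Internal names
#'   absent from the mapping are assumed identical in the file.
#' @param cooperate,defect the file's action symbols.
#' @return a `pd_log_dialect` list.
#' @export
log_dialect <- function(columns = character(), cooperate = "C",
                        defect = "D") {
  structure(list(columns = columns, cooperate = cooperate, defect = defect),
            class = "pd_log_dialect")
}

#' Read and write game logs
#'
#' Logs are stored as CSV (default) or JSON-lines (`.jsonl`). A write
#' followed by a read restores an identical log; reading validates the
#' schema via [validate_game_log()].
#'
#' @param path file path; format chosen by extension (`.jsonl` for
#'   JSON-lines, anything else CSV).
#' @param dialect an optional [log_dialect()] for external files.
#' @param payoffs payoff matrix used to check any stored payoff column.
#' @return `read_game_log()` returns a validated log data.frame.
#' @export
read_game_log <- function(path, dialect = NULL, payoffs = payoff_matrix()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.jsonl$", path)) {
    log <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    log <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(dialect)) {
    stopifnot(inherits(dialect, "pd_log_dialect"))
    for (internal in names(dialect$columns)) {
      ext <- dialect$columns[[internal]]
      if (!ext %in% names(log)) {
        stop("dialect maps '", internal, "' to missing file column '",
             ext, "'", call. = FALSE)
      }
      names(log)[names(log) == ext] <- internal
    }
    log$action <- ifelse(log$action == dialect$cooperate, "C",
                         ifelse(log$action == dialect$defect, "D",
                                as.character(log$action)))
  }
  validate_game_log(log, payoffs)
}

#' @rdname read_game_log
#' @param log a game-log data frame.
#' @export
write_game_log <- function(log, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(log, con, verbose = FALSE)
  } else {
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON configuration into a list; convenience wrappers
#' turn it into a simulation or synthetic-experiment configuration
#' (list entries must match the constructor's argument names; a `payoffs`
#' entry may give the four values `T`, `R`, `P`, `S`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_payoffs <- function(lst) {
  if (!is.null(lst$payoffs)) {
    lst$payoffs <- do.call(payoff_matrix, as.list(lst$payoffs))
  }
  lst
}

#' @rdname read_config
#' @return `read_sim_config()`: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lst <- config_payoffs(read_config(path))
  # YAML 1.1 parses an unquoted key `N` as the boolean FALSE; map it back,
  # since N (population size) is a legitimate parameter name here
  names(lst)[names(lst) == "FALSE"] <- "N"
  do.call(sim_config, lst)
}

#' @rdname read_config
#' @return `read_synth_config()`: a [synth_config()].
#' @export
read_synth_config <- function(path) {
  do.call(synth_config, config_payoffs(read_config(path)))
}

#' Write a summary object as JSON
#'
#' @param x a list of summary quantities.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
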