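test_that("cooperation rate counts individual cooperative decisions", {
  log <- playout_log("T8", "CC")
  # rounds 1-7 mutual C (14), round 8 one C, rounds 9-10 none: 15/20
  expect_equal(cooperation_rate(log), 15 / 20)
  expect_equal(cooperation_rate(log, rounds = 1), 1)
  expect_equal(cooperation_rate(log, rounds = 9:10), 0)
  expect_error(cooperation_rate(log, days = 99), "empty selection")
  all_c <- playout_log("CC", "CC")
  expect_equal(cooperation_rate(all_c), 1)
})

test_that("game restart effect is the round-10 to round-1 jump", {
  # constant full cooperation: no jump
  expect_equal(game_restart_effect(playout_log("CC", "CC", n_games = 5))$mean,
               0)
  # round 10 always defect, round 1 always cooperate: maximal jump
  log <- playout_log("T8", "T9", n_games = 4)
  expect_equal(game_restart_effect(log)$mean, 1)
  expect_error(game_restart_effect(playout_log("CC", "CC", n_games = 1)),
               "at least two games")
})

test_that("session restart effect compares day boundaries round by round", {
  # time-homogeneous play: zero differences
  log <- rbind(playout_log("T9", "CC", n_games = 3, day = 1),
               playout_log("T9", "CC", n_games = 3, day = 2))
  eff <- session_restart_effect(log)
  expect_true(all(eff$diffs$diff == 0))
  expect_equal(eff$summary$mean, c(0, 0))
  # planted reset: day 2 starts one threshold later than day 1 ended
  log2 <- rbind(playout_log("T9", "T9", n_games = 3, day = 1),
                playout_log("T10", "T10", n_games = 3, day = 2))
  eff2 <- session_restart_effect(log2, rounds = 9)
  expect_equal(eff2$diffs$diff, 1)  # round 9: 0% -> 100% cooperation
  # a single-day log yields an empty result with a warning
  expect_warning(out <- session_restart_effect(playout_log("CC", "CC", 3)),
                 "at least two days")
  expect_equal(nrow(out$diffs), 0)
})

test_that("first-defection distributions conserve game counts", {
  log2 <- playout_log("T5", "CC", n_games = 6)
  log2$player <- paste0(log2$player, "2")   # a second, distinct pair
  log2$partner <- paste0(log2$partner, "2")
  log <- rbind(playout_log("CC", "CC", n_games = 4), log2)
  d <- rd_distribution(log, day = 1)
  expect_equal(sum(d), 10)
  expect_equal(unname(d["C"]), 4)
  expect_equal(unname(d["5"]), 6)
  all_cc <- rd_distribution(playout_log("CC", "CC", n_games = 7))
  expect_equal(unname(all_cc["C"]), 7)
  expect_equal(sum(all_cc), 7)
})

test_that("the KS statistic equals the discrete ECDF gap", {
  r <- two_sample_ks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(two_sample_ks(rep(1, 5), rep(10, 5))$statistic, 1)
  expect_equal(two_sample_ks(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  # brute-force oracle agreement on small tied samples
  set.seed(7)
  for (k in 1:50) {
    x <- sample(1:11, sample(5:20, 1), replace = TRUE)
    y <- sample(1:11, sample(5:20, 1), replace = TRUE)
    expect_equal(two_sample_ks(x, y)$statistic, oracle_ks_D(x, y))
  }
  # permutation p broadly agrees with the asymptotic p away from ties
  set.seed(8)
  x <- sample(1:11, 200, replace = TRUE)
  y <- sample(1:11, 200, replace = TRUE)
  pa <- two_sample_ks(x, y)$p_value
  pp <- two_sample_ks(x, y, p_method = "permutation", n_perm = 500)$p_value
  expect_lt(abs(pa - pp), 0.25)
})

test_that("steady-state onset recovers planted change points", {
  # stationary play from day 1: onset at the earliest possible day
  stat_cfg <- synth_config(n_players = 20, alpha = 0.3, days = 6,
                           games_per_day = 10, plateau_day = 1,
                           plateau_threshold = 9, noise = 0, seed = 5)
  ss <- steady_state_onset(generate_experiment(stat_cfg)$log)
  expect_equal(ss$onset, 2)
  # drift through day 7, then plateau
  xp <- generate_experiment(default_experiment_config(seed = 12))
  ss <- steady_state_onset(xp$log)
  expect_lte(abs(ss$onset - 7), 1)
  expect_true(all(ss$tests$p_value[ss$tests$day <= 7] < 0.05))
  # Mann-Whitney robustness variant finds a similar onset
  ss_mw <- steady_state_onset(xp$log, test = "mw")
  expect_lte(abs(ss_mw$onset - 7), 2)
  # monotone drift on every day: never stable
  drift_cfg <- synth_config(n_players = 30, alpha = 0, days = 10,
                            games_per_day = 12, start_threshold = 11,
                            plateau_day = 10, plateau_threshold = 1,
                            noise = 0, seed = 6)
  ss <- steady_state_onset(generate_experiment(drift_cfg)$log)
  expect_true(is.na(ss$onset))
})

test_that("random pairing converts no-defection rates to cooperator fractions", {
  expect_equal(implied_cc_fraction(0.16), 0.4)
  expect_equal(implied_cc_fraction(0), 0)
  expect_equal(implied_cc_fraction(1), 1)
  expect_equal(implied_cc_fraction(0.25), 0.5)
  expect_error(implied_cc_fraction(1.2), "\\[0, 1\\]")
})
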