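test_that("consistency indicators identify exactly-matching strategies", {
  # unconditional defection can only be T1
  ind <- consistent_strategies(rep("D", 10), rep("C", 10))
  expect_equal(unname(ind[c("T1", "CC", "OTHER")]), c(1L, 0L, 0L))
  expect_equal(sum(ind), 1L)

  # mutual full cooperation can only be grim trigger
  ind <- consistent_strategies(rep("C", 10), rep("C", 10))
  expect_equal(sum(ind), 1L)
  expect_equal(unname(ind["CC"]), 1L)

  # retaliation after the opponent's round-5 defection is observationally
  # equivalent for every threshold above the defection round
  own <- c(rep("C", 5), rep("D", 5))
  opp <- c(rep("C", 4), rep("D", 6))
  ind <- consistent_strategies(own, opp)
  expect_equal(sort(names(ind[ind == 1L])),
               sort(c("CC", "T6", "T7", "T8", "T9", "T10")))
})

test_that("indicators agree with a round-by-round enumeration oracle", {
  set.seed(42)
  for (k in 1:200) {
    own <- sample(c("C", "D"), 10, replace = TRUE)
    opp <- sample(c("C", "D"), 10, replace = TRUE)
    ind <- consistent_strategies(own, opp, forgive = 0)
    expect_equal(ind[1:11], oracle_consistent(own, opp))
    expect_equal(unname(ind["OTHER"]), as.integer(sum(ind[1:11]) == 0L))
  }
})

test_that("every strategy is consistent with its own playouts", {
  labs <- strategy_labels()
  for (s in labs) for (t in labs) {
    p <- play_game(s, t)
    ind <- consistent_strategies(p$actions[1, ], p$actions[2, ])
    expect_equal(unname(ind[s]), 1L)
    expect_equal(unname(ind["OTHER"]), 0L)
  }
})

test_that("the forgiving threshold variant is coded as the threshold strategy", {
  # defect at 4, resume cooperating for one round while the partner still
  # cooperates, then defect again
  own <- c("C", "C", "C", "D", "C", rep("D", 5))
  opp <- rep("C", 10)
  ind <- consistent_strategies(own, opp)
  expect_equal(unname(ind["T4"]), 1L)
  expect_equal(unname(ind["OTHER"]), 0L)
  # two resumed rounds tolerated, three are not
  own2 <- c("C", "C", "C", "D", "C", "C", rep("D", 4))
  expect_equal(unname(consistent_strategies(own2, opp)["T4"]), 1L)
  own3 <- c("C", "C", "C", "D", "C", "C", "C", rep("D", 3))
  ind3 <- consistent_strategies(own3, opp)
  expect_equal(unname(ind3["T4"]), 0L)
  expect_equal(unname(ind3["OTHER"]), 1L)
  # tolerance only applies when the partner cooperated at the threshold
  oppd <- c("C", "C", "C", "D", rep("C", 6))
  expect_equal(unname(consistent_strategies(own, oppd)["T4"]), 0L)
  # and disabling it removes the tolerance
  expect_equal(unname(consistent_strategies(own, opp, forgive = 0)["T4"]),
               0L)
})

test_that("EWMA weights follow the discounted recursion exactly", {
  expect_error(update_weights(0, 1, gamma = 1.2), "\\[0, 1\\]")
  # gamma = 0 reduces to the current indicator
  expect_equal(update_weights(c(3, 7), c(1, 0), gamma = 0), c(1, 0))
  # constant indicator: geometric series (1 - g^j) / (1 - g)
  g <- 0.818
  w <- 0
  for (j in 1:40) w <- update_weights(w, 1, g)
  expect_equal(w, (1 - g^40) / (1 - g))
  expect_equal((1 - g^40) / (1 - g), 5.4945, tolerance = 1e-3)
  expect_lt(w, 1 / (1 - g))  # geometric-series bound
  # single indicator at j = 1 decays as g^(j-1)
  w <- update_weights(0, 1, g)
  w <- update_weights(w, 0, g)
  w <- update_weights(w, 0, g)
  expect_equal(w, 0.818^2)
  expect_equal(w, 0.669124)
})

test_that("strategy assignment breaks ties as specified", {
  labs <- c(strategy_labels(), "OTHER")
  w <- stats::setNames(rep(0, 12), labs)
  w[c("CC", "T9")] <- 2
  expect_equal(assign_strategy(w), "T9")       # threshold beats grim
  w[] <- 0; w[c("OTHER", "T3")] <- 1.5
  expect_equal(assign_strategy(w), "T3")       # known beats unidentified
  w[] <- 0; w[c("T4", "T8")] <- 1
  expect_equal(assign_strategy(w), "T8")       # most cooperative threshold
  w[] <- 0
  expect_equal(assign_strategy(w), "OTHER")    # nothing observed yet
})

test_that("resilient classification applies the 80% stable-phase rule", {
  mk <- function(player, n_cc, n_tot) data.frame(
    player = player, day = rep(7:20, length.out = n_tot),
    strategy = c(rep("CC", n_cc), rep("T9", n_tot - n_cc)))
  asg <- rbind(mk("a", 100, 100), mk("b", 79, 100), mk("c", 80, 100))
  cls <- classify_resilient(asg, stable_days = 7:20)
  expect_equal(cls$resilient[match(c("a", "b", "c"), cls$player)],
               c(TRUE, FALSE, TRUE))
  # games outside the stable phase are ignored
  pre <- data.frame(player = "a", day = 1, strategy = "T1")
  expect_true(classify_resilient(rbind(asg, pre))$resilient[1])
  # a player with no stable-phase games cannot be classified
  only_pre <- rbind(asg, data.frame(player = "z", day = 2, strategy = "CC"))
  cls <- classify_resilient(only_pre)
  expect_true(is.na(cls$resilient[cls$player == "z"]))
})

test_that("noiseless synthetic play is recovered without OTHER assignments", {
  xp <- generate_experiment(synth_config(n_players = 20, alpha = 0.4,
                                         days = 10, games_per_day = 6,
                                         noise = 0, seed = 21))
  asg <- infer_strategies(xp$log)
  expect_equal(mean(asg$strategy == "OTHER"), 0)
  cls <- classify_resilient(asg, stable_days = 7:10)
  truth <- xp$truth$players
  acc <- mean(cls$resilient[match(truth$player, cls$player)] ==
                (truth$type == "resilient"))
  expect_gte(acc, 0.95)
})

test_that("the OTHER fraction grows with action noise", {
  frac <- vapply(c(0, 0.05, 0.2), function(eps) {
    xp <- generate_experiment(synth_config(n_players = 16, alpha = 0.4,
                                           days = 6, games_per_day = 5,
                                           plateau_day = 4, noise = eps,
                                           seed = 31))
    mean(infer_strategies(xp$log)$strategy == "OTHER")
  }, numeric(1))
  expect_equal(frac[1], 0)
  expect_true(all(diff(frac) > 0))
})

test_that("missing games carry weights forward or decay them as configured", {
  # one player, observed in games 1 and 4 of the same day layout
  H <- 10
  p <- play_game("T3", "CC")
  pairs <- data.frame(session = 1, day = 1, game = c(1, 4),
                      p1 = "a", p2 = "b")
  log <- build_log(pairs,
                   matrix(rep(p$actions[1, ], 2), 2, H, byrow = TRUE),
                   matrix(rep(p$actions[2, ], 2), 2, H, byrow = TRUE))
  g <- 0.818
  carry <- infer_strategies(log, gamma = g)
  expect_equal(nrow(carry[carry$player == "a", ]), 2)
  # under carry, game 4's weight for T3 is 1 + g * 1; under decay the old
  # weight shrinks by g^2 extra, but the assignment is unchanged here
  decay <- infer_strategies(log, gamma = g, missing = "decay")
  expect_equal(carry$strategy, decay$strategy)
})
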