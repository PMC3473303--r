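baseline <- baseline_scenario()

test_that("per-arm expectations match hand-computed baseline values and degenerate cases", {
  arms <- per_arm_expectations(baseline$payoffs, baseline$probs)
  expect_equal(arms[["eu_exp"]], 46.517, tolerance = 1e-12)
  expect_equal(arms[["eu_std"]], 56.489, tolerance = 1e-12)
  expect_equal(arms[["ev_exp"]], 70.81, tolerance = 1e-12)
  expect_equal(arms[["ev_std"]], 59.34, tolerance = 1e-12)

  # certain experimental success collapses to u1
  sure <- modified_baseline(e = 1)
  expect_identical(per_arm_expectations(sure$payoffs, sure$probs)[["eu_exp"]],
                   sure$payoffs$u1)
  # constant payoffs are invariant to e
  flat <- scenario(game_payoffs(7, 7, 7, 7, 7, 7, 7, 7),
                   game_probabilities(0.37, 0.5, 0.5, 0.5),
                   psych_params(0, 0))
  expect_equal(per_arm_expectations(flat$payoffs, flat$probs)[["eu_exp"]], 7)
})

test_that("strategy expected values reproduce the published baseline numbers", {
  expect_equal(ev_honor(baseline), 65.075, tolerance = 1e-12)
  expect_equal(ev_abuse(baseline), 66.3614, tolerance = 1e-9)
  expect_equal(ev_no_trust(baseline), 50.4948, tolerance = 1e-9)
  expect_equal(as.numeric(ev_trust(baseline)), 45.0157, tolerance = 1e-9)
})

test_that("strategy values collapse correctly in degenerate corners", {
  arms <- per_arm_expectations(baseline$payoffs, baseline$probs)
  # all patients randomized to the experimental arm
  expect_equal(ev_honor(modified_baseline(r = 1)), arms[["ev_exp"]])
  # identical researcher arms make honoring r-invariant
  for (r in c(0, 0.3, 1)) {
    expect_equal(ev_honor(modified_baseline(v1 = 60, v2 = 60, v3 = 60,
                                            v4 = 60, r = r)), 60)
  }
  # no guilt, or zero researcher-patient gap, removes the abuse penalty
  expect_equal(ev_abuse(modified_baseline(guilt = 0)), arms[["ev_exp"]])
  gap0 <- modified_baseline(v2 = 16.3)
  expect_equal(ev_abuse(gap0),
               per_arm_expectations(gap0$payoffs, gap0$probs)[["ev_exp"]])
  # no regret, or certain standard success, simplifies no-trust
  expect_equal(ev_no_trust(modified_baseline(regret = 0)), arms[["eu_std"]])
  expect_equal(ev_no_trust(modified_baseline(s = 1)), baseline$payoffs$u3)
  # p = 1 gives the conditional-on-honor value; p = 0, R = 0 gives eu_exp
  evs <- expected_values(baseline)
  expect_equal(as.numeric(ev_trust(modified_baseline(p = 1))),
               evs$trust_given_honor)
  expect_equal(as.numeric(ev_trust(modified_baseline(p = 0, regret = 0))),
               arms[["eu_exp"]])
})

test_that("ev_trust is affine in p with the conditional values at its ends", {
  set.seed(401)
  for (i in 1:20) {
    sc <- random_scenario()
    f <- function(p) {
      sc$probs$p <- p
      expected_values(sc)$ev_trust
    }
    evs <- expected_values(sc)
    expect_equal(f(0), evs$trust_given_abuse, tolerance = 1e-12)
    expect_equal(f(1), evs$trust_given_honor, tolerance = 1e-12)
    # affine: midpoint equals mean of endpoints
    expect_equal(f(0.5), (f(0) + f(1)) / 2, tolerance = 1e-9)
  }
})

test_that("guilt lowers only the abuse value and regret lowers no-trust and abused-trust", {
  g_grid <- seq(0, 1, by = 0.1)
  abuse_vals <- vapply(g_grid,
                       function(g) ev_abuse(modified_baseline(guilt = g)),
                       numeric(1))
  expect_true(all(diff(abuse_vals) < 0))
  honor_vals <- vapply(g_grid,
                       function(g) ev_honor(modified_baseline(guilt = g)),
                       numeric(1))
  expect_true(all(diff(honor_vals) == 0))

  r_grid <- seq(0, 1, by = 0.1)
  nt_vals <- vapply(r_grid,
                    function(r) ev_no_trust(modified_baseline(regret = r)),
                    numeric(1))
  expect_true(all(diff(nt_vals) < 0))
  abused <- vapply(r_grid, function(r) {
    expected_values(modified_baseline(regret = r))$trust_given_abuse
  }, numeric(1))
  expect_true(all(diff(abused) < 0))
})

test_that("adding a constant to all utilities shifts every strategy value by it", {
  set.seed(402)
  for (i in 1:20) {
    sc <- random_scenario()
    shift <- 13.7
    pay <- unclass(sc$payoffs)
    shifted <- scenario(do.call(game_payoffs, lapply(pay, `+`, shift)),
                        sc$probs, sc$psych)
    a <- expected_values(sc)
    b <- expected_values(shifted)
    for (field in c("ev_trust", "ev_no_trust", "ev_honor", "ev_abuse")) {
      expect_equal(b[[field]], a[[field]] + shift, tolerance = 1e-9)
    }
  }
})

test_that("equipoise randomization follows s/(s+e), is exact at e = s, and matches a root-finding oracle", {
  expect_identical(equipoise_randomization(0.5, 0.5), 0.5)
  expect_identical(equipoise_randomization(0.123, 0.123), 0.5)
  expect_equal(equipoise_randomization(0.8, 0.2), 0.2)
  expect_error(equipoise_randomization(0, 0), "undefined")
  expect_error(equipoise_randomization(1.5, 0.2), "'e'")

  # oracle: with unit success utility and zero failure utility, the
  # randomization that equalizes expected benefit drawn from each arm
  # solves r*e - (1-r)*s = 0
  set.seed(403)
  for (i in 1:25) {
    e <- runif(1, 0.05, 1)
    s <- runif(1, 0.05, 1)
    root <- uniroot(function(r) r * e - (1 - r) * s, c(0, 1),
                    tol = 1e-12)$root
    expect_equal(equipoise_randomization(e, s), root, tolerance = 1e-8)
  }
})

test_that("solve_game picks the larger expected value with ties toward cooperation", {
  base <- solve_game(baseline_scenario())
  expect_identical(base$patient_choice, "no_trust")
  expect_identical(base$researcher_choice, "abuse")

  # certain, honored experimental success makes trusting dominant
  sure <- modified_baseline(e = 1, r = 1, p = 1)
  expect_identical(solve_game(sure)$patient_choice, "trust")

  # exact ties cooperate: a flat tree gives equal EVs everywhere
  flat <- scenario(game_payoffs(50, 50, 50, 50, 50, 50, 50, 50),
                   game_probabilities(0.3, 0.6, 0.5, 0.5),
                   psych_params(0, 0))
  tied <- solve_game(flat)
  expect_identical(tied$patient_choice, "trust")
  expect_identical(tied$researcher_choice, "honor")
})

test_that("closed forms agree with the brute-force tree oracle on random scenarios", {
  set.seed(404)
  for (i in 1:300) {
    sc <- random_scenario()
    closed <- expected_values(sc)
    oracle <- evaluate_tree_bruteforce(sc)
    for (field in c("ev_trust", "ev_no_trust", "ev_honor", "ev_abuse",
                    "eu_exp", "eu_std", "ev_exp", "ev_std",
                    "trust_given_honor", "trust_given_abuse")) {
      expect_lt(abs(closed[[field]] - oracle[[field]]), 1e-9)
    }
  }
})

test_that("the brute-force tree is exact in analytically known cases", {
  # no regret or guilt: plain probability-weighted sums
  sc <- modified_baseline(regret = 0, guilt = 0)
  oracle <- evaluate_tree_bruteforce(sc)
  arms <- per_arm_expectations(sc$payoffs, sc$probs)
  expect_equal(oracle$ev_abuse, arms[["ev_exp"]])
  expect_equal(oracle$ev_no_trust, arms[["eu_std"]])
  # constant tree: every strategy value equals the constant
  flat <- scenario(game_payoffs(42, 42, 42, 42, 42, 42, 42, 42),
                   game_probabilities(0.2, 0.9, 0.4, 0.7),
                   psych_params(0.5, 0.5))
  o <- evaluate_tree_bruteforce(flat)
  for (field in c("ev_trust", "ev_no_trust", "ev_honor", "ev_abuse")) {
    expect_equal(o[[field]], 42)
  }
})
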