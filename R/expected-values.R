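#' Per-arm expected utilities
#'
#' The building blocks of every strategy value: the expected utility of each
#' treatment arm to each player,
#' \deqn{E_U[Exp] = e u_1 + (1-e) u_2, \quad E_U[Std] = s u_3 + (1-s) u_4,}
#' and analogously \eqn{E_V[Exp]}, \eqn{E_V[Std]} with the researcher's
#' utilities.
#'
#' @param payoffs A [game_payoffs()] object.
#' @param probs A [game_probabilities()] object.
#' @return Named numeric vector `c(eu_exp, eu_std, ev_exp, ev_std)`.
#' @examples
#' sc <- baseline_scenario()
#' per_arm_expectations(sc$payoffs, sc$probs)
#' @export
per_arm_expectations <- function(payoffs, probs) {
  stopifnot(inherits(payoffs, "game_payoffs"),
            inherits(probs, "game_probabilities"))
  e <- probs$e; s <- probs$s
  c(eu_exp = e * payoffs$u1 + (1 - e) * payoffs$u2,
    eu_std = s * payoffs$u3 + (1 - s) * payoffs$u4,
    ev_exp = e * payoffs$v1 + (1 - e) * payoffs$v2,
    ev_std = s * payoffs$v3 + (1 - s) * payoffs$v4)
}

# Vectorised closed-form engine: all strategy values from raw parameter
# vectors. Shared by expected_values(), sweep_2d() and run_monte_carlo();
# solve_game()'s independent check is the tree enumeration oracle.
ev_engine <- function(u1, u2, u3, u4, v1, v2, v3, v4, e, s, r, p,
                      regret, guilt, regret_abuse = regret) {
  eu_exp <- e * u1 + (1 - e) * u2
  eu_std <- s * u3 + (1 - s) * u4
  ev_exp <- e * v1 + (1 - e) * v2
  ev_std <- s * v3 + (1 - s) * v4
  trust_given_honor <- r * eu_exp + (1 - r) * eu_std
  trust_given_abuse <- eu_exp - (1 - e) * regret_abuse * (u3 - u2)
  list(
    eu_exp = eu_exp, eu_std = eu_std, ev_exp = ev_exp, ev_std = ev_std,
    trust_given_honor = trust_given_honor,
    trust_given_abuse = trust_given_abuse,
    ev_trust = p * trust_given_honor + (1 - p) * trust_given_abuse,
    ev_no_trust = eu_std - (1 - s) * regret * (u1 - u4),
    ev_honor = r * ev_exp + (1 - r) * ev_std,
    ev_abuse = ev_exp - (1 - e) * guilt * (v2 - u2)
  )
}

ev_engine_scenario <- function(sc) {
  v <- as.list(scenario_values(sc))
  do.call(ev_engine, v[c("u1", "u2", "u3", "u4", "v1", "v2", "v3", "v4",
                         "e", "s", "r", "p", "regret", "guilt",
                         "regret_abuse")])
}

#' All strategy expected values for a scenario
#'
#' Computes the four strategy values (patient trust/no-trust, researcher
#' honor/abuse), the per-arm expectations behind them, and the patient's
#' conditional values given the researcher honors or abuses.
#'
#' @param sc A `trust_scenario`.
#' @return An object of class `expected_values`: a list with elements
#'   `ev_trust`, `ev_no_trust`, `ev_honor`, `ev_abuse`, `eu_exp`, `eu_std`,
#'   `ev_exp`, `ev_std`, `trust_given_honor`, `trust_given_abuse`.
#' @examples
#' expected_values(baseline_scenario())
#' @export
expected_values <- function(sc) {
  stopifnot(inherits(sc, "trust_scenario"))
  structure(ev_engine_scenario(sc), class = "expected_values")
}

#' @export
print.expected_values <- function(x, ...) {
  cat("Expected values (trust game)\n")
  cat(sprintf("  patient:    E[Trust] = %.3f, E[No Trust] = %.3f\n",
              x$ev_trust, x$ev_no_trust))
  cat(sprintf("              E[Trust | Honor] = %.3f, E[Trust | Abuse] = %.3f\n",
              x$trust_given_honor, x$trust_given_abuse))
  cat(sprintf("  researcher: E[Honor] = %.3f, E[Abuse] = %.3f\n",
              x$ev_honor, x$ev_abuse))
  cat(sprintf("  per-arm:    E_U[Exp] = %.3f, E_U[Std] = %.3f, E_V[Exp] = %.3f, E_V[Std] = %.3f\n",
              x$eu_exp, x$eu_std, x$ev_exp, x$ev_std))
  invisible(x)
}

#' Researcher's expected utility of honoring trust
#'
#' Honoring means enrolling the patient in the trial:
#' \deqn{E[Honor] = r E_V[Exp] + (1-r) E_V[Std].}
#'
#' @param sc A `trust_scenario`.
#' @return A single number.
#' @export
ev_honor <- function(sc) expected_values(sc)$ev_honor

#' Researcher's expected utility of abusing trust
#'
#' Abusing means giving the unproven experimental treatment outside the
#' trial; guilt is felt only when that treatment fails:
#' \deqn{E[Abuse] = E_V[Exp] - (1-e)\,G\,(v_2 - u_2).}
#'
#' @param sc A `trust_scenario`.
#' @return A single number.
#' @export
ev_abuse <- function(sc) expected_values(sc)$ev_abuse

#' Patient's expected utility of not trusting
#'
#' Not trusting means taking the standard treatment; regret is felt when it
#' fails and the experimental treatment would, in retrospect, have been best:
#' \deqn{E[NoTrust] = E_U[Std] - (1-s)\,R\,(u_1 - u_4).}
#'
#' @param sc A `trust_scenario`.
#' @return A single number.
#' @export
ev_no_trust <- function(sc) expected_values(sc)$ev_no_trust

#' Patient's expected utility of trusting
#'
#' With probability `p` the researcher honors trust (randomized trial);
#' otherwise the patient receives the experimental treatment outside the
#' trial and regrets on its failure:
#' \deqn{E[Trust] = p\,[r E_U[Exp] + (1-r) E_U[Std]]
#'   + (1-p)\,[E_U[Exp] - (1-e)\,R\,(u_3 - u_2)].}
#' The two conditional values are attached as attribute `conditionals`
#' (also available from [expected_values()]).
#'
#' @param sc A `trust_scenario`.
#' @return A single number with attribute `conditionals`, a named vector
#'   `c(honor =, abuse =)`.
#' @export
ev_trust <- function(sc) {
  evs <- expected_values(sc)
  structure(evs$ev_trust,
            conditionals = c(honor = evs$trust_given_honor,
                             abuse = evs$trust_given_abuse))
}

#' Equipoise randomization probability
#'
#' In the symmetric equipoise model (success utility 100, failure 0, for
#' both players, no regret or guilt) the randomization probability at which
#' offering and accepting randomization is rational is
#' \deqn{r = \frac{s}{s + e},}
#' which equals 1/2 whenever the two arms are in genuine equipoise
#' (`e == s`).
#'
#' @param e Probability of experimental-treatment success.
#' @param s Probability of standard-treatment success.
#' @return The indifference randomization probability.
#' @examples
#' equipoise_randomization(0.5, 0.5)   # 0.5
#' equipoise_randomization(0.8, 0.2)   # 0.2
#' @export
equipoise_randomization <- function(e, s) {
  for (nm in c("e", "s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("probability '", nm, "' must be a single number in [0, 1]",
           call. = FALSE)
    }
  }
  if (e + s == 0) {
    stop("equipoise randomization is undefined when e = s = 0", call. = FALSE)
  }
  if (e == s) return(0.5)
  s / (s + e)
}

#' Solve the trust game
#'
#' Evaluates all strategy expected values and returns each player's best
#' response. Ties resolve toward cooperation: the patient trusts when
#' `E[Trust] >= E[No Trust]` and the researcher honors when
#' `E[Honor] >= E[Abuse]`. The game is single-play; no state is carried
#' between calls.
#'
#' @param sc A `trust_scenario`.
#' @return An object of class `strategy_profile` with elements
#'   `patient_choice` (`"trust"`/`"no_trust"`), `researcher_choice`
#'   (`"honor"`/`"abuse"`) and `evs` (the [expected_values()]).
#' @examples
#' solve_game(baseline_scenario())
#' @export
solve_game <- function(sc) {
  evs <- expected_values(sc)
  structure(
    list(
      patient_choice = if (evs$ev_trust >= evs$ev_no_trust) "trust"
                       else "no_trust",
      researcher_choice = if (evs$ev_honor >= evs$ev_abuse) "honor"
                          else "abuse",
      evs = evs,
      label = sc$label
    ),
    class = "strategy_profile"
  )
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat("Trust-game solution:", x$label, "\n")
  cat(sprintf("  patient:    %-8s (E[Trust] = %.3f vs E[No Trust] = %.3f)\n",
              toupper(x$patient_choice), x$evs$ev_trust, x$evs$ev_no_trust))
  cat(sprintf("  researcher: %-8s (E[Honor] = %.3f vs E[Abuse] = %.3f)\n",
              toupper(x$researcher_choice), x$evs$ev_honor, x$evs$ev_abuse))
  invisible(x)
}

#' Brute-force tree evaluation (oracle)
#'
#' Independently recomputes the four strategy expected values by enumerating
#' every leaf of the decision tree, multiplying path probabilities by the
#' regret/guilt-adjusted leaf payoffs, and summing per strategy. Exists as a
#' cross-check for the closed-form expressions; the two routes agree to
#' floating-point accuracy.
#'
#' @param sc A `trust_scenario`.
#' @return An `expected_values` object (per-arm intermediates included).
#' @export
evaluate_tree_bruteforce <- function(sc) {
  stopifnot(inherits(sc, "trust_scenario"))
  u1 <- sc$payoffs$u1; u2 <- sc$payoffs$u2
  u3 <- sc$payoffs$u3; u4 <- sc$payoffs$u4
  v1 <- sc$payoffs$v1; v2 <- sc$payoffs$v2
  v3 <- sc$payoffs$v3; v4 <- sc$payoffs$v4
  e <- sc$probs$e; s <- sc$probs$s; r <- sc$probs$r; p <- sc$probs$p
  R <- sc$psych$regret; Ra <- sc$psych$regret_abuse; G <- sc$psych$guilt

  leaf_sum <- function(leaves) {
    sum(vapply(leaves, function(l) l$prob * l$pay, numeric(1)))
  }

  # Patient, "do not trust": standard treatment; regret on its failure
  # relative to the best retrospective action (experimental success, u1).
  no_trust_leaves <- list(
    list(prob = s,     pay = u3),
    list(prob = 1 - s, pay = u4 - R * (u1 - u4))
  )
  # Patient, "trust | honor": enrolled in the trial, randomized.
  trust_honor_leaves <- list(
    list(prob = r * e,             pay = u1),
    list(prob = r * (1 - e),       pay = u2),
    list(prob = (1 - r) * s,       pay = u3),
    list(prob = (1 - r) * (1 - s), pay = u4)
  )
  # Patient, "trust | abuse": experimental treatment outside the trial;
  # regret on failure relative to the standard treatment's success (u3).
  trust_abuse_leaves <- list(
    list(prob = e,     pay = u1),
    list(prob = 1 - e, pay = u2 - Ra * (u3 - u2))
  )
  # Researcher, "honor": the randomized trial from the researcher's side.
  honor_leaves <- list(
    list(prob = r * e,             pay = v1),
    list(prob = r * (1 - e),       pay = v2),
    list(prob = (1 - r) * s,       pay = v3),
    list(prob = (1 - r) * (1 - s), pay = v4)
  )
  # Researcher, "abuse": experimental treatment off-trial; guilt on its
  # failure, scaled by the researcher-patient utility gap.
  abuse_leaves <- list(
    list(prob = e,     pay = v1),
    list(prob = 1 - e, pay = v2 - G * (v2 - u2))
  )

  t_h <- leaf_sum(trust_honor_leaves)
  t_a <- leaf_sum(trust_abuse_leaves)
  structure(
    list(
      eu_exp = leaf_sum(list(list(prob = e, pay = u1),
                             list(prob = 1 - e, pay = u2))),
      eu_std = leaf_sum(list(list(prob = s, pay = u3),
                             list(prob = 1 - s, pay = u4))),
      ev_exp = leaf_sum(list(list(prob = e, pay = v1),
                             list(prob = 1 - e, pay = v2))),
      ev_std = leaf_sum(list(list(prob = s, pay = v3),
                             list(prob = 1 - s, pay = v4))),
      trust_given_honor = t_h,
      trust_given_abuse = t_a,
      ev_trust = p * t_h + (1 - p) * t_a,
      ev_no_trust = leaf_sum(no_trust_leaves),
      ev_honor = leaf_sum(honor_leaves),
      ev_abuse = leaf_sum(abuse_leaves)
    ),
    class = "expected_values"
  )
}
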