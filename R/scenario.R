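#' Patient and researcher payoffs for the trial trust game
#'
#' The eight utilities of the trust game, on a common (by default 0--100)
#' scale. The patient's utilities `u1`--`u4` and the researcher's `v1`--`v4`
#' refer, in order, to: success of the experimental treatment, failure of the
#' experimental treatment, success of the standard treatment, failure of the
#' standard treatment.
#'
#' Validation enforces the model's ordering assumptions: success beats
#' failure for each arm and each player (`u1 >= u3 >= u2`, `u3 >= u4`;
#' `v1 >= v2`, `v1 >= v3`, `v3 >= v4`), and `v2 >= u2` because society still
#' gains knowledge from a failed experimental treatment inside a trial.
#' Negative utilities are rejected unless `allow_negative = TRUE` (any common
#' finite scale is acceptable to the algebra; the default mirrors the 0--100
#' elicitation convention).
#'
#' @param u1,u2,u3,u4 Patient utilities (experimental success/failure,
#'   standard success/failure).
#' @param v1,v2,v3,v4 Researcher utilities, same outcome order.
#' @param allow_negative Accept negative utilities? Default `FALSE`.
#' @return An object of class `game_payoffs`.
#' @examples
#' game_payoffs(90, 16.3, 84, 16.9, 95, 54, 70, 44)
#' @export
game_payoffs <- function(u1, u2, u3, u4, v1, v2, v3, v4,
                         allow_negative = FALSE) {
  vals <- c(u1 = u1, u2 = u2, u3 = u3, u4 = u4,
            v1 = v1, v2 = v2, v3 = v3, v4 = v4)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        !is.finite(vals[[nm]])) {
      stop("payoff '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (!allow_negative && vals[[nm]] < 0) {
      stop("payoff '", nm, "' is negative; set allow_negative = TRUE to ",
           "use a scale that admits negative utilities", call. = FALSE)
    }
  }
  ord <- payoff_order_violations(u1, u2, u3, u4, v1, v2, v3, v4)
  if (length(ord)) {
    stop("payoff ordering violated: ", paste(ord, collapse = "; "),
         call. = FALSE)
  }
  structure(as.list(vals), class = "game_payoffs")
}

# Names of the ordering assumptions violated by a draw; vectorised inputs
# return the union over elements (used by the Monte Carlo strict mode).
payoff_order_violations <- function(u1, u2, u3, u4, v1, v2, v3, v4) {
  checks <- list(
    "u1 >= u3" = u1 >= u3,
    "u3 >= u2" = u3 >= u2,
    "u3 >= u4" = u3 >= u4,
    "v1 >= v2" = v1 >= v2,
    "v1 >= v3" = v1 >= v3,
    "v3 >= v4" = v3 >= v4,
    "v2 >= u2" = v2 >= u2
  )
  names(checks)[!vapply(checks, all, logical(1))]
}

#' Probabilities of the trial trust game
#'
#' @param e Probability the experimental treatment succeeds.
#' @param s Probability the standard treatment succeeds.
#' @param r Probability of randomization to the experimental arm.
#' @param p Probability the researcher honors the patient's trust.
#' @return An object of class `game_probabilities`.
#' @examples
#' game_probabilities(e = 0.41, s = 0.59, r = 0.5, p = 0.5)
#' @export
game_probabilities <- function(e, s, r, p) {
  vals <- c(e = e, s = s, r = r, p = p)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("probability '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    if (v < 0 || v > 1) {
      stop("probability '", nm, "' = ", format(v),
           " is outside [0, 1]", call. = FALSE)
    }
  }
  structure(as.list(vals), class = "game_probabilities")
}

#' Regret and guilt fractions
#'
#' Regret reduces the patient's payoff on failure branches by a fraction of
#' the utility lost relative to the retrospectively best action; guilt
#' reduces the researcher's payoff on the experimental-failure branch under
#' abuse by a fraction of the researcher-patient utility gap.
#'
#' The model uses a single regret fraction for both the no-trust and the
#' abused-trust scenarios; the two plausibly differ, so a separate
#' `regret_abuse` is accepted and defaults to `regret`.
#'
#' @param regret Regret fraction in \[0, 1\] (no-trust branch).
#' @param guilt Guilt fraction in \[0, 1\].
#' @param regret_abuse Regret fraction applied on the abused-trust branch;
#'   defaults to `regret`.
#' @return An object of class `psych_params`.
#' @export
psych_params <- function(regret, guilt, regret_abuse = regret) {
  vals <- c(regret = regret, guilt = guilt, regret_abuse = regret_abuse)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("psych parameter '", nm, "' must be a single number in [0, 1]",
           call. = FALSE)
    }
  }
  structure(as.list(vals), class = "psych_params")
}

#' Assemble a trust-game scenario
#'
#' @param payoffs A [game_payoffs()] object.
#' @param probs A [game_probabilities()] object.
#' @param psych A [psych_params()] object.
#' @param label Free-text label carried through results.
#' @return An object of class `trust_scenario`.
#' @seealso [baseline_scenario()] for the published baseline.
#' @export
scenario <- function(payoffs, probs, psych, label = "scenario") {
  stopifnot(inherits(payoffs, "game_payoffs"),
            inherits(probs, "game_probabilities"),
            inherits(psych, "psych_params"))
  structure(list(payoffs = payoffs, probs = probs, psych = psych,
                 label = as.character(label)[1]),
            class = "trust_scenario")
}

#' The published baseline scenario
#'
#' Elicited utilities and literature-derived probabilities: patient utilities
#' (90, 16.3, 84, 16.9), researcher utilities (95, 54, 70, 44), experimental
#' success 0.41, standard success 0.59, randomization 0.5, honoring 0.5,
#' regret and guilt fractions 0.2.
#'
#' @return A `trust_scenario`.
#' @examples
#' solve_game(baseline_scenario())
#' @export
baseline_scenario <- function() {
  scenario(
    payoffs = game_payoffs(u1 = 90, u2 = 16.3, u3 = 84, u4 = 16.9,
                           v1 = 95, v2 = 54, v3 = 70, v4 = 44),
    probs = game_probabilities(e = 0.41, s = 0.59, r = 0.5, p = 0.5),
    psych = psych_params(regret = 0.2, guilt = 0.2),
    label = "table1_baseline"
  )
}

#' @export
print.trust_scenario <- function(x, ...) {
  cat("Trust-game scenario:", x$label, "\n")
  cat(sprintf("  patient utilities    U = (%g, %g, %g, %g)\n",
              x$payoffs$u1, x$payoffs$u2, x$payoffs$u3, x$payoffs$u4))
  cat(sprintf("  researcher utilities V = (%g, %g, %g, %g)\n",
              x$payoffs$v1, x$payoffs$v2, x$payoffs$v3, x$payoffs$v4))
  cat(sprintf("  probabilities        e = %g, s = %g, r = %g, p = %g\n",
              x$probs$e, x$probs$s, x$probs$r, x$probs$p))
  cat(sprintf("  psych                regret = %g (abuse branch %g), guilt = %g\n",
              x$psych$regret, x$psych$regret_abuse, x$psych$guilt))
  invisible(x)
}

# Flatten a scenario into the named numeric vector used by the vectorised
# engine and by serialization.
scenario_values <- function(sc) {
  c(unlist(sc$payoffs), unlist(sc$probs),
    regret = sc$psych$regret, regret_abuse = sc$psych$regret_abuse,
    guilt = sc$psych$guilt)
}

#' Read a scenario from a YAML configuration file
#'
#' The file has three sections: `payoffs` (`u1`..`u4`, `v1`..`v4`),
#' `probabilities` (`e`, `s`, `r`, `p`) and `psych` (`regret`, `guilt`,
#' optional `regret_abuse`), plus an optional `label`. Utilities are on the
#' 0--100 scale unless `allow_negative` relaxes validation. The special path
#' `"builtin:table1_baseline"` resolves to the bundled baseline file.
#'
#' @param path Path to a YAML file, or `"builtin:table1_baseline"`.
#' @param allow_negative Passed to [game_payoffs()].
#' @return A `trust_scenario`.
#' @export
read_scenario <- function(path, allow_negative = FALSE) {
  path <- resolve_config_path(path)
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  required <- list(
    payoffs = c("u1", "u2", "u3", "u4", "v1", "v2", "v3", "v4"),
    probabilities = c("e", "s", "r", "p"),
    psych = c("regret", "guilt")
  )
  for (sec in names(required)) {
    if (is.null(cfg[[sec]])) {
      stop("scenario file is missing section '", sec, "'", call. = FALSE)
    }
    for (key in required[[sec]]) {
      if (is.null(cfg[[sec]][[key]])) {
        stop("scenario file is missing required key: ", sec, "$", key,
             call. = FALSE)
      }
    }
  }
  pay <- cfg$payoffs
  prob <- cfg$probabilities
  psy <- cfg$psych
  scenario(
    payoffs = game_payoffs(pay$u1, pay$u2, pay$u3, pay$u4,
                           pay$v1, pay$v2, pay$v3, pay$v4,
                           allow_negative = allow_negative),
    probs = game_probabilities(prob$e, prob$s, prob$r, prob$p),
    psych = psych_params(psy$regret, psy$guilt,
                         regret_abuse = if (is.null(psy$regret_abuse))
                           psy$regret else psy$regret_abuse),
    label = if (is.null(cfg$label)) basename(path) else cfg$label
  )
}

#' Write a scenario to a YAML configuration file
#'
#' @param sc A `trust_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "trust_scenario"))
  cfg <- list(
    label = sc$label,
    payoffs = sc$payoffs[c("u1", "u2", "u3", "u4", "v1", "v2", "v3", "v4")],
    probabilities = sc$probs[c("e", "s", "r", "p")],
    psych = sc$psych[c("regret", "guilt", "regret_abuse")]
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

resolve_config_path <- function(path) {
  if (identical(path, "builtin:table1_baseline")) {
    return(system.file("extdata", "table1_baseline.yaml",
                       package = "trustgame", mustWork = TRUE))
  }
  path
}
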