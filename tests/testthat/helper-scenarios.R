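# Draw a random scenario satisfying every payoff ordering; relies on the
# caller having seeded the RNG.
random_scenario <- function() {
  u2 <- runif(1, 0, 50)
  u4 <- runif(1, 0, 50)
  u3 <- runif(1, max(u2, u4), 100)
  u1 <- runif(1, u3, 100)
  v4 <- runif(1, 0, 80)
  v3 <- runif(1, v4, 100)
  v2 <- runif(1, u2, 100)
  v1 <- runif(1, max(v2, v3), 100)
  scenario(
    payoffs = game_payoffs(u1, u2, u3, u4, v1, v2, v3, v4),
    probs = game_probabilities(runif(1), runif(1), runif(1), runif(1)),
    psych = psych_params(runif(1), runif(1), regret_abuse = runif(1)),
    label = "random"
  )
}

scenario_values_public <- function(sc) {
  c(unlist(sc$payoffs), unlist(sc$probs), unlist(sc$psych))
}

# Convenience: baseline with selected parameters replaced.
modified_baseline <- function(...) {
  mods <- list(...)
  sc <- baseline_scenario()
  pay <- unclass(sc$payoffs)
  prob <- unclass(sc$probs)
  psy <- unclass(sc$psych)
  for (nm in names(mods)) {
    if (nm %in% names(pay)) pay[[nm]] <- mods[[nm]]
    else if (nm %in% names(prob)) prob[[nm]] <- mods[[nm]]
    else if (nm %in% names(psy)) psy[[nm]] <- mods[[nm]]
    else stop("unknown parameter: ", nm)
  }
  if (!"regret_abuse" %in% names(mods) && "regret" %in% names(mods)) {
    psy$regret_abuse <- psy$regret
  }
  scenario(
    payoffs = do.call(game_payoffs, pay),
    probs = do.call(game_probabilities, prob),
    psych = do.call(psych_params, psy),
    label = "modified_baseline"
  )
}
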