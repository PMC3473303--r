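#' @title Threshold results
#' @description Constructor for the object returned by the threshold
#'   solvers. `direction` is one of `"at_least"` (the player's cooperative
#'   strategy dominates when the variable is at or above the threshold),
#'   `"less_than"` (dominates below it), `"always"` or `"never"` (no
#'   threshold exists; cooperation dominates everywhere or nowhere).
#'   `threshold` is clamped to \[0, 1\]; the unclamped solution is kept in
#'   `threshold_raw`.
#' @keywords internal
threshold_result <- function(variable, direction, threshold = NA_real_,
                             threshold_raw = NA_real_, scenario = NULL) {
  stopifnot(variable %in% c("r", "p"),
            direction %in% c("at_least", "less_than", "always", "never"))
  structure(
    list(variable = variable, direction = direction,
         threshold = threshold, threshold_raw = threshold_raw,
         scenario = scenario),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  lab <- c(r = "randomization probability r",
           p = "honoring probability p")[[x$variable]]
  who <- if (x$variable == "r") "researcher honors" else "patient trusts"
  if (x$direction %in% c("always", "never")) {
    cat(sprintf("Threshold on %s: %s (%s %s)\n", lab, toupper(x$direction),
                who, if (x$direction == "always") "for every value"
                     else "for no value"))
  } else {
    cmp <- if (x$direction == "at_least") ">=" else "<"
    cat(sprintf("Threshold on %s: %s when %s %s %.4f (%.0f%%)\n",
                lab, who, x$variable, cmp, x$threshold,
                100 * round(x$threshold, 2)))
    if (!identical(x$threshold, x$threshold_raw)) {
      cat(sprintf("  (unclamped solution %.4f)\n", x$threshold_raw))
    }
  }
  invisible(x)
}

clamp01 <- function(x) min(max(x, 0), 1)

#' Randomization threshold for the researcher to honor trust
#'
#' Solves `E[Honor] >= E[Abuse]` for the randomization probability `r`. The
#' critical value is
#' \deqn{r^* = 1 - \frac{(1-e)\,G\,(v_2-u_2)}{E_V[Exp]-E_V[Std]}.}
#' When the experimental arm looks better to the researcher
#' (`ev_exp > ev_std`) honoring dominates for `r >= r*`; when it looks
#' worse, for `r < r*`. When the two arms are exactly equal the inequality
#' is independent of `r`: honoring weakly dominates whenever the guilt term
#' is nonnegative (always, under the payoff orderings), reported as
#' `"always"`.
#'
#' @param sc A `trust_scenario`.
#' @return A `threshold_result` on variable `"r"`.
#' @examples
#' researcher_randomization_threshold(baseline_scenario())  # ~0.61
#' @export
researcher_randomization_threshold <- function(sc) {
  evs <- expected_values(sc)
  gap <- evs$ev_exp - evs$ev_std
  guilt_term <- (1 - sc$probs$e) * sc$psych$guilt *
    (sc$payoffs$v2 - sc$payoffs$u2)
  if (gap == 0) {
    return(threshold_result("r",
                            if (guilt_term >= 0) "always" else "never",
                            scenario = sc))
  }
  t_raw <- 1 - guilt_term / gap
  threshold_result("r",
                   direction = if (gap > 0) "at_least" else "less_than",
                   threshold = clamp01(t_raw), threshold_raw = t_raw,
                   scenario = sc)
}

#' Honoring-probability threshold for the patient to trust
#'
#' `E[Trust] - E[No Trust]` is affine in `p`:
#' \deqn{f(p) = p\,\big[(1-r)(E_U[Std]-E_U[Exp]) + (1-e)R(u_3-u_2)\big]
#'   - \big(E[NoTrust] - E[Trust\,|\,Abuse]\big).}
#' With positive slope the patient trusts for `p >= p*` where
#' `p* = gap/slope`; with negative slope, for `p < p*`; with zero slope the
#' decision is independent of `p` and is reported as `"always"` or
#' `"never"` by the sign of the constant comparison.
#'
#' @param sc A `trust_scenario`.
#' @return A `threshold_result` on variable `"p"`.
#' @examples
#' patient_trust_threshold(baseline_scenario())  # ~0.92
#' @export
patient_trust_threshold <- function(sc) {
  evs <- expected_values(sc)
  slope <- (1 - sc$probs$r) * (evs$eu_std - evs$eu_exp) +
    (1 - sc$probs$e) * sc$psych$regret_abuse *
      (sc$payoffs$u3 - sc$payoffs$u2)
  gap <- evs$ev_no_trust - evs$trust_given_abuse
  if (slope == 0) {
    return(threshold_result("p", if (gap <= 0) "always" else "never",
                            scenario = sc))
  }
  t_raw <- gap / slope
  threshold_result("p",
                   direction = if (slope > 0) "at_least" else "less_than",
                   threshold = clamp01(t_raw), threshold_raw = t_raw,
                   scenario = sc)
}
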