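#' Serialize results to JSON
#'
#' Stable, machine-readable JSON for the main result objects. Numbers are
#' written at full precision; field names match the list structure of the
#' object.
#'
#' @param x A `strategy_profile`, `expected_values`, `threshold_result` or
#'   `mc_result`.
#' @param pretty Pretty-print? Default `TRUE`.
#' @param ... Unused.
#' @return A JSON string (class `json`).
#' @export
as_json <- function(x, pretty = TRUE, ...) UseMethod("as_json")

json_of <- function(lst, pretty) {
  jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = pretty,
                   null = "null")
}

evs_list <- function(evs) {
  lapply(unclass(evs), as.numeric)
}

#' @export
as_json.expected_values <- function(x, pretty = TRUE, ...) {
  json_of(evs_list(x), pretty)
}

#' @export
as_json.strategy_profile <- function(x, pretty = TRUE, ...) {
  json_of(list(label = x$label,
               patient_choice = x$patient_choice,
               researcher_choice = x$researcher_choice,
               expected_values = evs_list(x$evs)),
          pretty)
}

#' @export
as_json.threshold_result <- function(x, pretty = TRUE, ...) {
  json_of(list(variable = x$variable,
               direction = x$direction,
               threshold = if (is.na(x$threshold)) NULL else x$threshold,
               threshold_raw = if (is.na(x$threshold_raw)) NULL
                               else x$threshold_raw,
               threshold_percent = if (is.na(x$threshold)) NULL
                                   else round(100 * x$threshold)),
          pretty)
}

#' @export
as_json.mc_result <- function(x, pretty = TRUE, ...) {
  cfg <- lapply(x$config$distributions, function(d) {
    c(list(kind = d$kind), d$params)
  })
  json_of(list(
    n_trials = x$n_trials,
    seed = if (is.null(x$seed)) NULL else x$seed,
    counts = list(
      honor_trust = x$counts["honor", "trust"],
      honor_no_trust = x$counts["honor", "no_trust"],
      abuse_trust = x$counts["abuse", "trust"],
      abuse_no_trust = x$counts["abuse", "no_trust"]
    ),
    proportions = list(
      honor_trust = x$proportions["honor", "trust"],
      honor_no_trust = x$proportions["honor", "no_trust"],
      abuse_trust = x$proportions["abuse", "trust"],
      abuse_no_trust = x$proportions["abuse", "no_trust"]
    ),
    marginals = list(
      honor = as.numeric(x$row_marginals[["honor"]]),
      abuse = as.numeric(x$row_marginals[["abuse"]]),
      trust = as.numeric(x$col_marginals[["trust"]]),
      no_trust = as.numeric(x$col_marginals[["no_trust"]])
    ),
    config = list(distributions = cfg,
                  enforce_payoff_invariants =
                    x$config$enforce_payoff_invariants)
  ), pretty)
}
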