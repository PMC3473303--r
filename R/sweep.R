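# Parameters a sweep may vary, and how each maps into the engine. "regret"
# moves both regret fields together, matching the single-R simplification.
sweep_variables <- c("e", "s", "r", "p", "regret", "guilt")

#' Two-way sensitivity sweep over strategy regions
#'
#' Varies two probabilities (or psych fractions) of a base scenario over a
#' grid and records each player's best strategy and all four strategy
#' expected values at every grid point — the strategy-region maps of the
#' model. The default 101-point axes resolve features at the
#' one-percentage-point scale of the reported thresholds.
#'
#' @param base A `trust_scenario` giving every parameter not swept.
#' @param x_variable,y_variable Names among
#'   `"e", "s", "r", "p", "regret", "guilt"`.
#' @param x_range,y_range Length-2 numeric ranges within \[0, 1\].
#' @param n_steps Number of grid points per axis (>= 2).
#' @return An object of class `strategy_region_grid`: a list with
#'   `x_variable`, `y_variable`, `x_values`, `y_values` and `grid`, a
#'   long-format data frame with one row per cell (columns `x_variable`,
#'   `y_variable`, `x`, `y`, `patient_choice`, `researcher_choice`,
#'   `ev_trust`, `ev_no_trust`, `ev_honor`, `ev_abuse`).
#' @examples
#' g <- sweep_2d(baseline_scenario(), "e", c(0, 1), "s", c(0, 1), n_steps = 21)
#' head(as.data.frame(g))
#' @export
sweep_2d <- function(base, x_variable, x_range = c(0, 1),
                     y_variable, y_range = c(0, 1), n_steps = 101) {
  stopifnot(inherits(base, "trust_scenario"))
  for (v in c(x_variable, y_variable)) {
    if (!v %in% sweep_variables) {
      stop("unknown sweep variable '", v, "'; valid variables: ",
           paste(sweep_variables, collapse = ", "), call. = FALSE)
    }
  }
  if (x_variable == y_variable) {
    stop("x_variable and y_variable must differ", call. = FALSE)
  }
  for (rg in list(x_range, y_range)) {
    if (length(rg) != 2L || any(!is.finite(rg)) || any(rg < 0) ||
        any(rg > 1) || rg[1] > rg[2]) {
      stop("sweep ranges must be ordered pairs within [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(n_steps) || n_steps < 2) {
    stop("n_steps must be at least 2", call. = FALSE)
  }

  x_values <- seq(x_range[1], x_range[2], length.out = n_steps)
  y_values <- seq(y_range[1], y_range[2], length.out = n_steps)
  cells <- expand.grid(x = x_values, y = y_values, KEEP.OUT.ATTRS = FALSE)

  pars <- as.list(scenario_values(base))
  pars <- pars[c("u1", "u2", "u3", "u4", "v1", "v2", "v3", "v4",
                 "e", "s", "r", "p", "regret", "guilt", "regret_abuse")]
  assign_var <- function(pars, var, val) {
    if (var == "regret") {
      pars$regret <- val
      pars$regret_abuse <- val
    } else {
      pars[[var]] <- val
    }
    pars
  }
  pars <- assign_var(pars, x_variable, cells$x)
  pars <- assign_var(pars, y_variable, cells$y)
  evs <- do.call(ev_engine, pars)

  grid <- data.frame(
    x_variable = x_variable, y_variable = y_variable,
    x = cells$x, y = cells$y,
    patient_choice = ifelse(evs$ev_trust >= evs$ev_no_trust,
                            "trust", "no_trust"),
    researcher_choice = ifelse(evs$ev_honor >= evs$ev_abuse,
                               "honor", "abuse"),
    ev_trust = evs$ev_trust, ev_no_trust = evs$ev_no_trust,
    ev_honor = evs$ev_honor, ev_abuse = evs$ev_abuse,
    stringsAsFactors = FALSE
  )
  structure(
    list(x_variable = x_variable, y_variable = y_variable,
         x_values = x_values, y_values = y_values,
         grid = grid, base = base),
    class = "strategy_region_grid"
  )
}

#' @export
as.data.frame.strategy_region_grid <- function(x, ...) x$grid

#' @export
print.strategy_region_grid <- function(x, ...) {
  cat(sprintf("Strategy-region grid: %s x %s (%d x %d cells)\n",
              x$x_variable, x$y_variable,
              length(x$x_values), length(x$y_values)))
  tab <- table(patient = x$grid$patient_choice,
               researcher = x$grid$researcher_choice)
  print(tab)
  invisible(x)
}

#' Plot a strategy-region grid
#'
#' Renders the joint strategy regions as a tile map (requires ggplot2).
#'
#' @param x A `strategy_region_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.strategy_region_grid <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting a strategy_region_grid requires the ggplot2 package",
         call. = FALSE)
  }
  df <- x$grid
  df$strategy <- paste(df$patient_choice, df$researcher_choice, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = strategy)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = x$x_variable, y = x$y_variable,
                  fill = "patient / researcher") +
    ggplot2::theme_minimal()
}

#' Write a sweep grid to CSV
#'
#' @param x A `strategy_region_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "strategy_region_grid"))
  utils::write.csv(x$grid, path, row.names = FALSE)
  invisible(path)
}
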