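# Drug-combination scoring by Bliss independence on viability grids
# normalised to vehicle.

#' Surviving fraction relative to vehicle
#'
#' Divides a signal (colony count, luminescence, ...) by the mean of the
#' vehicle (solvent-only) signals. Values above 1 are permitted here; they
#' are clamped only when converted to effects.
#'
#' @param signal numeric signal(s).
#' @param vehicle_signals non-empty numeric vector of vehicle signals with
#'   positive mean.
#' @return Surviving fraction(s).
#' @export
surviving_fraction <- function(signal, vehicle_signals) {
  if (length(vehicle_signals) == 0L)
    validation_error("vehicle_signals must be non-empty")
  m <- mean(vehicle_signals)
  if (!is.finite(m) || m <= 0)
    validation_error("mean vehicle signal must be positive")
  signal / m
}

#' Bliss independence excess for one dose pair
#'
#' The Bliss null expects a combination effect of
#' `E_A + E_B - E_A * E_B` from the two monotherapy effects; the excess is
#' the observed combination effect minus this expectation. Positive excess
#' indicates supra-additivity (synergy).
#'
#' @param effect_a,effect_b monotherapy effects (fraction killed), in \[0, 1\].
#' @param effect_ab observed combination effect, in \[0, 1\].
#' @return Excess over Bliss, in \[-1, 1\].
#' @export
bliss_excess <- function(effect_a, effect_b, effect_ab) {
  vals <- c(effect_a, effect_b, effect_ab)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    validation_error("effects must lie in [0, 1]")
  effect_ab - (effect_a + effect_b - effect_a * effect_b)
}

# Shared builder: long-format (dose_a, dose_b, replicate, signal) rows,
# including vehicle rows at (0, 0), into a replicate-averaged grid.
as_viability_grid <- function(long) {
  need <- c("dose_a", "dose_b", "replicate", "signal")
  missing <- setdiff(need, names(long))
  if (length(missing))
    format_error(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  doses_a <- sort(unique(long$dose_a))
  doses_b <- sort(unique(long$dose_b))
  if (!0 %in% doses_a || !0 %in% doses_b)
    validation_error("grid must include dose 0 for both drugs (vehicle and monotherapies)")
  vehicle <- long$signal[long$dose_a == 0 & long$dose_b == 0]
  if (!length(vehicle))
    validation_error("no vehicle (0, 0) measurements present")
  long$viability <- surviving_fraction(long$signal, vehicle)
  cells <- expand.grid(dose_a = doses_a, dose_b = doses_b)
  vmean <- vsd <- matrix(NA_real_, length(doses_a), length(doses_b),
                         dimnames = list(format(doses_a), format(doses_b)))
  for (r in seq_len(nrow(cells))) {
    sel <- long$dose_a == cells$dose_a[r] & long$dose_b == cells$dose_b[r]
    if (!any(sel))
      validation_error(sprintf(
        "missing measurements at dose pair (%g, %g)",
        cells$dose_a[r], cells$dose_b[r]))
    i <- match(cells$dose_a[r], doses_a)
    j <- match(cells$dose_b[r], doses_b)
    vmean[i, j] <- mean(long$viability[sel])
    vsd[i, j] <- stats::sd(long$viability[sel])
  }
  vmean[1, 1] <- 1   # vehicle cell is 1 by construction of the normalisation
  effect <- pmin(pmax(1 - vmean, 0), 1)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 viability = long[c("dose_a", "dose_b", "replicate",
                                    "signal", "viability")],
                 viability_mean = vmean, viability_sd = vsd,
                 effect = effect),
            class = "viability_grid")
}

#' Read a dose-pair viability grid from long-format delimited text
#'
#' Expected columns: `dose_a`, `dose_b`, `replicate`, `signal`. Rows with
#' both doses 0 are the vehicle; every dose pair on the grid must be
#' measured, including the monotherapy margins. Signals are normalised to
#' the mean vehicle signal and converted to effects `1 - viability`, clamped
#' to \[0, 1\].
#'
#' @param path file path.
#' @return An object of class `viability_grid` holding the replicate-level
#'   data, the mean/s.d. viability matrices and the clamped effect matrix.
#' @export
read_viability_grid <- function(path) {
  df <- read_delim_auto(path)
  for (col in c("dose_a", "dose_b", "signal"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  as_viability_grid(df)
}

#' @export
print.viability_grid <- function(x, ...) {
  cat(sprintf("<viability_grid> %d x %d doses, %d measurements\n",
              length(x$doses_a), length(x$doses_b), nrow(x$viability)))
  invisible(x)
}

#' Score a viability grid by Bliss independence
#'
#' Builds the per-cell expected effect from the replicate-mean monotherapy
#' effects (the dose-0 margins), subtracts it from the observed combination
#' effect, and summarises the mean excess over all cells where both doses
#' are positive. Excess is identically 0 along the margins.
#'
#' @param grid a `viability_grid`.
#' @return Object of class `bliss_result`: matrices `expected_effect` and
#'   `excess`, scalar `mean_excess`, and the input `grid`.
#' @export
bliss_grid <- function(grid) {
  stopifnot(inherits(grid, "viability_grid"))
  ea <- grid$effect[, 1]    # drug A alone (dose_b = 0)
  eb <- grid$effect[1, ]    # drug B alone (dose_a = 0)
  expected <- outer(ea, eb, function(a, b) a + b - a * b)
  excess <- grid$effect - expected
  combo <- outer(grid$doses_a > 0, grid$doses_b > 0, `&`)
  structure(list(expected_effect = expected, excess = excess,
                 mean_excess = mean(excess[combo]), grid = grid),
            class = "bliss_result")
}

bliss_long <- function(x) {
  grid <- x$grid
  cells <- expand.grid(dose_a = grid$doses_a, dose_b = grid$doses_b)
  i <- match(cells$dose_a, grid$doses_a)
  j <- match(cells$dose_b, grid$doses_b)
  idx <- cbind(i, j)
  out <- data.frame(dose_a = cells$dose_a, dose_b = cells$dose_b,
                    effect = grid$effect[idx],
                    expected_effect = x$expected_effect[idx],
                    excess = x$excess[idx])
  out[order(out$dose_a, out$dose_b), , drop = FALSE]
}

#' @export
print.bliss_result <- function(x, ...) {
  cat(sprintf("<bliss_result> mean excess over combination cells: %+.4f\n",
              x$mean_excess))
  cat("  excess matrix (rows = drug A doses, cols = drug B doses):\n")
  print(round(x$excess, 4))
  invisible(x)
}
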