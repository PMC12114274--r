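#' One-parameter dose-response model
#'
#' Normalized response of the inhibitor-vs-normalized-response model
#' `Y = 100 / (1 + X / IC50)`: 100% at zero dose, 50% at `dose == ic50`,
#' strictly decreasing in dose.
#'
#' @param dose concentration(s) in uM, `>= 0`.
#' @param ic50 half-maximal concentration in uM, `> 0`.
#' @return normalized response in percent.
#' @export
predict_response <- function(dose, ic50) {
  if (!is.numeric(ic50) || length(ic50) != 1 || !is.finite(ic50) || ic50 <= 0)
    stop("ic50 must be a single positive number")
  if (any(dose < 0)) stop("doses must be non-negative")
  100 / (1 + dose / ic50)
}

#' Fit the one-parameter dose-response model
#'
#' Least-squares estimate of IC50 in `Y = 100/(1 + X/IC50)`. The single
#' parameter is log-parameterized to enforce positivity and found by a
#' deterministic multi-start: a fixed grid over log10(IC50) spanning three
#' decades beyond the dosed range picks the best bracket, then golden
#' section refines it. Responses are percent of the drug-free current; a
#' few points outside [-10, 110] are tolerated as measurement noise (a
#' warning is issued, values are retained).
#'
#' @param doses concentrations in uM; at least two distinct positive
#'   doses are required.
#' @param responses normalized responses in percent, one per dose.
#' @return a `DoseResponseFit`: `ic50` (uM), `residual_sum_squares`,
#'   `doses`, `responses`, `fitted`.
#' @export
fit_ic50 <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("doses and responses differ in length")
  if (any(doses < 0)) stop("doses must be non-negative")
  pos <- unique(doses[doses > 0])
  if (length(pos) < 2) stop("need at least two distinct positive doses")
  if (length(unique(responses)) == 1)
    stop("all responses equal: IC50 is not identifiable")
  if (any(responses < -10 | responses > 110))
    warning("response(s) outside [-10, 110]; retained as-is")

  ss <- function(l) sum((responses - 100 / (1 + doses / 10^l))^2)
  lo <- log10(min(pos)) - 3
  hi <- log10(max(doses)) + 3
  grid <- seq(lo, hi, length.out = 121)
  g_ss <- vapply(grid, ss, numeric(1))
  i <- which.min(g_ss)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(ss, bracket, tol = 1e-12)
  structure(list(ic50 = 10^opt$minimum,
                 residual_sum_squares = opt$objective,
                 doses = doses, responses = responses,
                 fitted = 100 / (1 + doses / 10^opt$minimum)),
            class = "DoseResponseFit")
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf("DoseResponseFit: IC50 = %.4g uM (RSS = %.4g over %d doses)\n",
              x$ic50, x$residual_sum_squares, length(x$doses)))
  invisible(x)
}

#' Summarize a group of measurements as mean +/- SEM
#'
#' @param replicates numeric measurements (e.g. percent inhibition
#'   replicates, or cyst cross-sectional areas in um^2).
#' @param group group label.
#' @param units measurement units (default `"%"`).
#' @return a `GroupSummary`: `group`, `n`, `mean`, `sem`
#'   (sample sd / sqrt(n); 0 with a warning when n = 1), `units`.
#' @export
summarize_inhibition <- function(replicates, group = "group", units = "%") {
  n <- length(replicates)
  if (n == 0) stop("empty replicate list")
  sem <- if (n == 1) {
    warning("single replicate: SEM set to 0 by convention")
    0
  } else {
    stats::sd(replicates) / sqrt(n)
  }
  group_summary(group, n, mean(replicates), sem, units)
}

#' Construct a group summary from printed statistics
#'
#' For summaries reported directly as mean +/- SEM (e.g. published cyst
#' areas) rather than from raw replicates.
#'
#' @param group group label.
#' @param n number of measurements.
#' @param mean group mean.
#' @param sem standard error of the mean, `>= 0`.
#' @param units measurement units.
#' @return a `GroupSummary`.
#' @export
group_summary <- function(group, n = NA_integer_, mean, sem = NA_real_,
                          units = "%") {
  if (!is.na(sem) && sem < 0) stop("sem must be non-negative")
  structure(list(group = group, n = n, mean = mean, sem = sem, units = units),
            class = "GroupSummary")
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g %s (n = %s)\n",
              x$group, x$mean, x$sem, x$units,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' Percent reduction of a treated group mean versus control
#'
#' `100 * (control - treated) / control`, e.g. the shrinkage of the mean
#' cyst cross-sectional area under treatment relative to vehicle.
#'
#' @param control,treated `GroupSummary` objects or bare numeric means;
#'   the control mean must be positive.
#' @return percent reduction (negative when the treated mean exceeds the
#'   control mean).
#' @export
percent_reduction <- function(control, treated) {
  m <- function(x) if (inherits(x, "GroupSummary")) x$mean else as.numeric(x)
  c0 <- m(control); t0 <- m(treated)
  if (!is.finite(c0) || c0 <= 0) stop("control mean must be positive")
  100 * (c0 - t0) / c0
}
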