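# mg/dL per mmol/L of glucose; applied only inside Clarke scoring, which
# is defined on the mg/dL scale.  All other glucose quantities in the
# package are mmol/L.
MGDL_PER_MMOL <- 18.0182

check_pair <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have the same length", call. = FALSE)
  if (length(y) == 0L)
    stop("need at least one observation", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    stop("non-finite values in y or yhat", call. = FALSE)
}

#' Mean absolute error
#'
#' `MAE = mean(|yhat - y|)`, in the units of `y` (mmol/L for glucose).
#'
#' @param y Reference values.
#' @param yhat Estimated values (same length).
#' @return A nonnegative scalar.
#' @export
mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(yhat - y))
}

#' Root mean squared error
#'
#' `RMSE = sqrt(mean((yhat - y)^2))`; always >= [mae()].
#'
#' @inheritParams mae
#' @return A nonnegative scalar.
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((yhat - y)^2))
}

#' Mean absolute relative difference
#'
#' `MARD = mean(|yhat - y| / y)`, returned as a dimensionless *fraction*
#' (e.g. 0.15, not 15%); the standard accuracy figure for glucose
#' monitors.  Scale-invariant: rescaling both arguments by the same
#' positive constant leaves it unchanged.
#'
#' @inheritParams mae
#' @return A nonnegative scalar fraction.
#' @export
mard <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y <= 0))
    stop("mard requires all reference values > 0", call. = FALSE)
  mean(abs(yhat - y) / y)
}

#' Clarke error grid region of (reference, estimate) pairs
#'
#' Assigns each pair to one of the five clinical-risk regions A--E of the
#' Clarke error grid.  The boundaries are evaluated in mg/dL (mmol/L
#' inputs are converted by 18.0182 mg/dL per mmol/L) using the canonical
#' published rules, applied in this precedence order:
#' \itemize{
#'   \item A: both values below 70, or the estimate within 20% of the
#'     reference;
#'   \item E: reference >= 180 with estimate <= 70, or reference <= 70
#'     with estimate >= 180;
#'   \item C: 70 <= reference <= 290 with estimate >= reference + 110, or
#'     130 <= reference <= 180 with estimate <= (7/5) reference - 182;
#'   \item D: reference >= 240 with 70 <= estimate <= 180, or
#'     reference <= 175/3 with 70 <= estimate <= 180, or
#'     175/3 <= reference <= 70 with estimate >= (6/5) reference;
#'   \item B: everything else.
#' }
#' Every positive pair maps to exactly one region, and the diagonal
#' (estimate = reference) is always region A.
#'
#' @param y_ref,y_est Reference and estimated glucose (vectors, positive).
#' @param unit `"mmol/L"` (default) or `"mg/dL"`.
#' @return A factor with levels `A`--`E`, one per pair.
#' @export
clarke_region <- function(y_ref, y_est, unit = c("mmol/L", "mg/dL")) {
  unit <- match.arg(unit)
  check_pair(y_ref, y_est)
  if (any(y_ref <= 0) || any(y_est <= 0))
    stop("glucose values must be positive", call. = FALSE)
  if (unit == "mmol/L") {
    y_ref <- y_ref * MGDL_PER_MMOL
    y_est <- y_est * MGDL_PER_MMOL
  }
  n <- length(y_ref)
  reg <- character(n)
  is_a <- (y_ref < 70 & y_est < 70) | abs(y_est - y_ref) <= 0.2 * y_ref
  is_e <- (y_ref >= 180 & y_est <= 70) | (y_ref <= 70 & y_est >= 180)
  is_c <- (y_ref >= 70 & y_ref <= 290 & y_est >= y_ref + 110) |
    (y_ref >= 130 & y_ref <= 180 & y_est <= (7 / 5) * y_ref - 182)
  is_d <- (y_ref >= 240 & y_est >= 70 & y_est <= 180) |
    (y_ref <= 175 / 3 & y_est >= 70 & y_est <= 180) |
    (y_ref >= 175 / 3 & y_ref <= 70 & y_est >= (6 / 5) * y_ref)
  reg[] <- "B"
  reg[is_d] <- "D"
  reg[is_c] <- "C"
  reg[is_e] <- "E"
  reg[is_a] <- "A"
  factor(reg, levels = c("A", "B", "C", "D", "E"))
}

#' Clarke error grid summary
#'
#' Tallies region counts and percentages over a set of pairs; the
#' percentages sum to 100.
#'
#' @inheritParams clarke_region
#' @return List with `counts` and `pct` (named numeric vectors over
#'   A--E) and `points` (data frame of pairs in mg/dL with their region,
#'   suitable for plotting the grid).
#' @export
clarke_summary <- function(y_ref, y_est, unit = c("mmol/L", "mg/dL")) {
  unit <- match.arg(unit)
  reg <- clarke_region(y_ref, y_est, unit)
  counts <- table(reg)
  scale <- if (unit == "mmol/L") MGDL_PER_MMOL else 1
  list(counts = stats::setNames(as.numeric(counts), names(counts)),
       pct = stats::setNames(100 * as.numeric(counts) / length(reg),
                             names(counts)),
       points = data.frame(ref_mgdl = y_ref * scale,
                           est_mgdl = y_est * scale,
                           region = reg))
}

#' Full evaluation report
#'
#' MAE, RMSE and MARD of the estimates together with the Clarke error grid
#' tally.
#'
#' @inheritParams clarke_region
#' @param y,yhat Reference and estimated glucose.
#' @return An object of class `"metrics_report"`: list with `mae`, `rmse`,
#'   `mard`, `clarke_counts`, `clarke_pct` and `n`.
#' @export
metrics_report <- function(y, yhat, unit = c("mmol/L", "mg/dL")) {
  unit <- match.arg(unit)
  cs <- clarke_summary(y, yhat, unit)
  structure(list(mae = mae(y, yhat), rmse = rmse(y, yhat),
                 mard = mard(y, yhat),
                 clarke_counts = cs$counts, clarke_pct = cs$pct,
                 n = length(y), unit = unit),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d (%s)\n", x$n, x$unit))
  cat(sprintf("  MAE  = %.4f\n  RMSE = %.4f\n  MARD = %.4f\n",
              x$mae, x$rmse, x$mard))
  cat("  Clarke regions (%):",
      paste(sprintf("%s %.2f", names(x$clarke_pct), x$clarke_pct),
            collapse = ", "), "\n")
  invisible(x)
}
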