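#' Descriptive statistics
#'
#' Mean, standard deviation (n-1 denominator), coefficient of variation
#' (`100 * SD / mean`), median, minimum and maximum.  For a single value the
#' SD is reported as 0 and flagged.
#'
#' @param values numeric vector, length >= 1.
#' @return A list of class `describe_stats` with fields `mean, sd,
#'   cv_percent, median, min, max, n` and attribute `"single_value"` when
#'   n = 1.
#' @export
describe_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("need at least one value")
  single <- length(values) == 1L
  s <- if (single) 0 else sd(values)
  m <- mean(values)
  out <- structure(list(
    mean = m, sd = s,
    cv_percent = if (m != 0) 100 * s / m else NA_real_,
    median = median(values), min = min(values), max = max(values),
    n = length(values)), class = "describe_stats")
  if (single) attr(out, "single_value") <- TRUE
  out
}

#' @export
print.describe_stats <- function(x, ...) {
  cat(sprintf("mean %.4g, SD %.4g, CV %.4g%%, median %.4g, range [%.4g, %.4g], n = %d\n",
              x$mean, x$sd, x$cv_percent, x$median, x$min, x$max, x$n))
  invisible(x)
}

#' Fit a power law y = a * x^b
#'
#' Nonlinear least squares on the original scale, initialized from the
#' log-log linear fit.  R-squared is reported on the original scale (and,
#' for reference, on the log scale); the p-value is the two-sided t-test of
#' the log-log slope.  A constant response is returned as a degenerate fit
#' (`b = 0`, `r_squared = 0`) with a flag rather than an error.
#'
#' @param x,y positive numeric vectors, length >= 3.
#' @return An object of class `power_law_fit` with fields `a, b, r_squared,
#'   r_squared_log, p_value, n, residuals, fitted, degenerate`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit requires positive data")
  lx <- log(x); ly <- log(y)
  if (sd(ly) < 1e-14 || sd(lx) < 1e-14) {
    fit <- structure(list(a = exp(mean(ly)), b = 0, r_squared = 0,
                          r_squared_log = 0, p_value = NA_real_,
                          n = length(x), residuals = y - exp(mean(ly)),
                          fitted = rep(exp(mean(ly)), length(x)),
                          degenerate = TRUE), class = "power_law_fit")
    return(fit)
  }
  ll <- lm(ly ~ lx)
  # fit on geometrically normalized data: makes the estimate exactly
  # scale-equivariant (a scales with y, b invariant) and well-conditioned
  gm <- exp(mean(ly))
  yn <- exp(ly - mean(ly))
  start <- list(a = exp(coef(ll)[[1]]) / gm, b = coef(ll)[[2]])
  powmod <- function(x, a, b) { # analytic Jacobian for tight convergence
    v <- a * x^b
    attr(v, "gradient") <- cbind(a = x^b, b = v * log(x))
    v
  }
  nl <- tryCatch(
    nls(yn ~ powmod(x, a, b), start = start,
        control = stats::nls.control(maxiter = 500, tol = 1e-9,
                                     scaleOffset = 1, minFactor = 1e-12)),
    error = function(e) stop("power-law fit did not converge from (a = ",
                             format(start$a * gm), ", b = ", format(start$b),
                             "): ", conditionMessage(e)))
  a <- coef(nl)[["a"]] * gm; b <- coef(nl)[["b"]]
  fitted <- a * x^b
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  r2l <- summary(ll)$r.squared
  p <- summary(ll)$coefficients[2, 4]
  se <- summary(nl)$coefficients[, "Std. Error"]
  se["a"] <- se["a"] * gm
  structure(list(a = a, b = b, r_squared = r2, r_squared_log = r2l,
                 p_value = p, n = length(x),
                 se = setNames(as.numeric(se), c("a", "b")),
                 residuals = y - fitted, fitted = fitted,
                 degenerate = FALSE), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g  (R^2 = %.4f, p = %.3g, n = %d)%s\n",
              x$a, x$b, x$r_squared, x$p_value, x$n,
              if (x$degenerate) "  [degenerate: constant response]" else ""))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
residuals.power_law_fit <- function(object, ...) object$residuals

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  x <- if (missing(newdata)) object$fitted / object$a else
    if (is.list(newdata)) newdata$x else newdata
  if (missing(newdata)) return(object$fitted)
  object$a * x^object$b
}

#' Fit the one-parameter surface-fraction model
#'
#' Least squares for `BS/TV = K * BV/TV * (1 - BV/TV)`; with
#' `w = x * (1 - x)` the closed-form solution is
#' `K = sum(w * y) / sum(w^2)`.
#'
#' @param bv_tv volume fractions in (0, 1) (endpoints contribute zero
#'   prediction and are allowed).
#' @param bs_tv surface densities (1/mm).
#' @return An object of class `surface_model_fit` with fields `K`,
#'   `r_squared`, `n`, `residuals`, `fitted`.
#' @export
fit_surface_model <- function(bv_tv, bs_tv) {
  if (length(bv_tv) != length(bs_tv)) stop("lengths differ")
  if (length(bv_tv) < 2) stop("need at least 2 observations")
  if (any(bv_tv < 0 | bv_tv > 1)) stop("`bv_tv` must lie in [0, 1]")
  w <- bv_tv * (1 - bv_tv)
  if (all(w == 0)) stop("regressor x(1-x) is identically zero")
  K <- sum(w * bs_tv) / sum(w^2)
  fitted <- K * w
  r2 <- 1 - sum((bs_tv - fitted)^2) / sum((bs_tv - mean(bs_tv))^2)
  structure(list(K = K, r_squared = r2, n = length(bv_tv),
                 residuals = bs_tv - fitted, fitted = fitted),
            class = "surface_model_fit")
}

#' @export
print.surface_model_fit <- function(x, ...) {
  cat(sprintf("<surface_model_fit> BS/TV = %.4g * x(1-x)  (R^2 = %.4f, n = %d)\n",
              x$K, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.surface_model_fit <- function(object, ...) c(K = object$K)

#' @export
residuals.surface_model_fit <- function(object, ...) object$residuals

#' @export
predict.surface_model_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  x <- if (is.list(newdata)) newdata$bv_tv else newdata
  object$K * x * (1 - x)
}

#' Grouped descriptive statistics of a cohort table
#'
#' Per-group [describe_stats()] of one or more numeric columns, e.g. the
#' orientation angle gamma by anatomic region or Tb.Th. by vertebral level.
#'
#' @param table a data.frame (e.g. a cohort table from [run_cohort()]).
#' @param by grouping column name (e.g. `"level"`, `"region"`).
#' @param cols numeric columns to summarize; defaults to all numeric
#'   columns.
#' @return A data.frame with one row per group x column: group, column, n,
#'   mean, sd, cv_percent, median, min, max.
#' @export
group_summaries <- function(table, by, cols = NULL) {
  if (!by %in% names(table)) stop("unknown grouping column: ", by)
  if (is.null(cols))
    cols <- names(table)[vapply(table, is.numeric, logical(1))]
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) stop("unknown columns: ",
                                 paste(missing_cols, collapse = ", "))
  groups <- split(table, table[[by]])
  rows <- list()
  for (g in names(groups)) for (cl in cols) {
    v <- groups[[g]][[cl]]
    v <- v[is.finite(v)]
    if (!length(v)) next
    s <- describe_stats(v)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, column = cl, n = s$n, mean = s$mean, sd = s$sd,
      cv_percent = s$cv_percent, median = s$median, min = s$min, max = s$max,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "by") <- by
  out
}
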