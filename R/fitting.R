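#' Read / write a cumulative onset-count table
#'
#' Delimited-text format with header `age_months,cumulative_count`: ages
#' strictly increasing, counts nonnegative and nondecreasing (each row is
#' the cumulative number of individuals diagnosed by that age).
#'
#' @param path file path.
#' @return `read_onset_counts`: a validated data frame with columns
#'   `age_months` and `cumulative_count`.
#' @export
read_onset_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_months", "cumulative_count")
  if (!all(need %in% names(df))) {
    stop("onset-count file ", path, " must have header '",
         paste(need, collapse = ","), "' (line 1)")
  }
  validate_onset_counts(df[need])
}

#' @rdname read_onset_counts
#' @param data onset-count data frame.
#' @export
write_onset_counts <- function(data, path) {
  data <- validate_onset_counts(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_onset_counts <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("age_months", "cumulative_count") %in% names(data))) {
    stop("expected a data frame with columns 'age_months' and ",
         "'cumulative_count'")
  }
  if (nrow(data) == 0L) stop("onset-count table is empty")
  a <- data$age_months
  n <- data$cumulative_count
  if (!is.numeric(a) || !is.numeric(n) || anyNA(a) || anyNA(n)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(a))) |
                 !is.finite(suppressWarnings(as.numeric(n))))[1]
    stop("non-numeric or missing value in onset-count table (data row ",
         bad, ")")
  }
  if (any(a < 0)) stop("ages must be nonnegative")
  if (any(diff(a) <= 0)) {
    stop("ages must be strictly increasing (violated at data row ",
         which(diff(a) <= 0)[1] + 1L, ")")
  }
  if (any(n < 0)) stop("counts must be nonnegative")
  if (any(diff(n) < 0)) {
    stop("cumulative counts must be nondecreasing (violated at data row ",
         which(diff(n) < 0)[1] + 1L, ")")
  }
  data.frame(age_months = as.numeric(a), cumulative_count = as.numeric(n))
}

#' Fit the multimutation onset model to cumulative diagnosis counts
#'
#' Fits `N(t) = N_b * P_s(t)` — the susceptible pool size times the
#' multimutation prevalence — to an observed cumulative
#' age-of-first-diagnosis table by unweighted nonlinear least squares.
#' The integer exponent `m1` is scanned exhaustively over `m1_range`;
#' inside each `m1` the continuous parameters `(N_b, k1, k2)` are
#' optimized by Levenberg-Marquardt ([minpack.lm::nlsLM()]), started from
#' data-driven heuristics (early-age slope for `k1`, late-age tail for
#' `k2`, the last count inflated toward saturation for `N_b`) with a
#' fixed three-point multi-start fallback. Deterministic given the data.
#'
#' Cumulative counts are serially correlated, so the unweighted objective
#' is not a likelihood; it matches the conventional curve-fitting
#' procedure for this model.
#'
#' @param data onset-count data frame (see [read_onset_counts()]); at
#'   least 5 rows, counts not all equal.
#' @param m1_range integer candidates for `m1`; default `1:40`.
#' @return an object of class `fit_result`: a list with elements
#'   `params` ([model_params()] with `r = 1`), `n_b`, `sse`, `r2`,
#'   `converged`, `m1_grid` (per-`m1` best SSE trace), and `data`.
#' @export
#' @examples
#' p <- param_library("asd_male")
#' ages <- seq(6, 180, by = 6)
#' tab <- data.frame(age_months = ages,
#'                   cumulative_count = cumulative_count(ages, 200, p))
#' fit <- fit_onset_curve(tab)
#' fit$params$m1  # 17
fit_onset_curve <- function(data, m1_range = 1:40) {
  data <- validate_onset_counts(data)
  if (nrow(data) < 5L) stop("need at least 5 rows to fit")
  if (length(unique(data$cumulative_count)) == 1L) {
    stop("degenerate data: all cumulative counts are equal")
  }
  m1_range <- sort(unique(as.integer(m1_range)))
  if (any(m1_range < 1L)) stop("'m1_range' must contain positive integers")

  t <- data$age_months
  y <- data$cumulative_count
  grid <- data.frame(m1 = m1_range, sse = NA_real_, converged = FALSE)
  best <- NULL

  for (i in seq_along(m1_range)) {
    m1 <- m1_range[i]
    fit <- fit_one_m1(t, y, m1)
    if (!is.null(fit)) {
      grid$sse[i] <- fit$sse
      grid$converged[i] <- TRUE
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  }
  if (is.null(best)) {
    stop("no m1 in the grid converged; per-m1 diagnostics: ",
         paste(sprintf("m1=%d:%s", grid$m1,
                       ifelse(grid$converged, "ok", "failed")),
               collapse = " "))
  }
  tss <- sum((y - mean(y))^2)
  structure(
    list(params = model_params(best$k1, best$k2, best$m1, r = 1),
         n_b = best$nb, sse = best$sse,
         r2 = 1 - best$sse / tss,
         converged = TRUE, m1_grid = grid, data = data),
    class = "fit_result"
  )
}

# one Levenberg-Marquardt fit at fixed integer exponent; NULL on failure
fit_one_m1 <- function(t, y, m1) {
  nb0 <- max(y) / 0.95
  t_half <- t[which(y >= max(y) / 2)[1]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t)
  k1_0 <- -log(1 - 0.5^(1 / m1)) / t_half
  k2_0 <- max(-log(max(1 - max(y) / nb0, 1e-8)) / max(t), 1e-6)
  starts <- list(c(1, 1), c(0.5, 2), c(2, 0.5))
  best <- NULL
  for (s in starts) {
    st <- list(nb = nb0, k1 = k1_0 * s[1], k2 = k2_0 * s[2])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ nb * (1 - exp(-k1 * t))^m1 * (1 - exp(-k2 * t)),
        start = st,
        lower = c(nb = max(y) * 1e-3, k1 = 1e-9, k2 = 1e-9),
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = 1e-10, ptol = 1e-10, maxfev = 10000))),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(nb = unname(co["nb"]), k1 = unname(co["k1"]),
                   k2 = unname(co["k2"]), m1 = m1, sse = sse)
    }
  }
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Multimutation onset-curve fit\n")
  cat(sprintf("  N_b = %.4g, k1 = %.6g /mo, k2 = %.6g /mo, m1 = %d\n",
              x$n_b, x$params$k1, x$params$k2, x$params$m1))
  cat(sprintf("  SSE = %.6g, R^2 = %.6f, converged: %s\n",
              x$sse, x$r2, x$converged))
  invisible(x)
}

#' Fit the biological clock rate for a cohort with fixed intrinsic shape
#'
#' Keeps the intrinsic shape `(k1, k2, m1)` of a reference fit and lets
#' only the clock rate `r` vary. Two input modes:
#' \describe{
#'   \item{median age (scalar)}{delegates to [clock_rate_for_median()]:
#'     `r = reference median / target median` by the time-scaling law.}
#'   \item{onset-count table (data frame)}{minimizes least squares over
#'     `r`, with the pool size `N_b` concentrated out by linear least
#'     squares at each candidate `r`.}
#' }
#'
#' @param x a positive median onset age in months, or an onset-count data
#'   frame (see [read_onset_counts()]).
#' @param shape a [model_params()] object supplying `k1`, `k2`, `m1`.
#' @return dimensionless clock rate `r`.
#' @export
fit_clock_rate <- function(x, shape) {
  stopifnot(inherits(shape, "model_params"))
  if (is.numeric(x) && length(x) == 1L) {
    return(clock_rate_for_median(x, shape))
  }
  data <- validate_onset_counts(x)
  t <- data$age_months
  y <- data$cumulative_count
  sse_r <- function(logr) {
    ps <- susceptible_prevalence(t, with_clock_rate(shape, exp(logr)))
    nb <- sum(ps * y) / sum(ps^2)
    sum((nb * ps - y)^2)
  }
  opt <- stats::optimize(sse_r, interval = log(c(1e-3, 1e3)), tol = 1e-12)
  exp(opt$minimum)
}

#' Goodness of fit diagnostics
#'
#' Recomputes residuals of a [fit_onset_curve()] result from scratch
#' against an onset-count table with matching ages.
#'
#' @param fit a `fit_result`.
#' @param data onset-count data frame with the same ages as the fit; by
#'   default the data stored in the fit.
#' @return a list with `sse`, `r2`, and a `residuals` data frame
#'   (`age_months`, `observed`, `fitted`, `residual`).
#' @export
goodness_of_fit <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "fit_result"))
  data <- validate_onset_counts(data)
  if (nrow(data) != nrow(fit$data) ||
      any(data$age_months != fit$data$age_months)) {
    stop("ages in 'data' do not match the ages the model was fitted to")
  }
  pred <- cumulative_count(data$age_months, fit$n_b, fit$params)
  res <- data$cumulative_count - pred
  sse <- sum(res^2)
  tss <- sum((data$cumulative_count - mean(data$cumulative_count))^2)
  list(sse = sse,
       r2 = if (tss > 0) 1 - sse / tss else NA_real_,
       residuals = data.frame(age_months = data$age_months,
                              observed = data$cumulative_count,
                              fitted = pred, residual = res))
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  rec <- list(n_b = fit$n_b, k1_per_month = fit$params$k1,
              k2_per_month = fit$params$k2, m1 = fit$params$m1,
              r = fit$params$r, sse = fit$sse, r2 = fit$r2,
              converged = fit$converged,
              m1_grid = fit$m1_grid)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "columns")
  invisible(path)
}
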