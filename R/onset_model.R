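#' Susceptible prevalence P_s(t)
#'
#' Probability that a susceptible individual has developed the disorder by
#' age `t` months under the multimutation model:
#' \deqn{P_s(t; r) = (1 - e^{-k_1 r t})^{m_1} (1 - e^{-k_2 r t}).}
#' This is a proper CDF on ages: zero at birth, nondecreasing, with limit
#' one. The clock rate enters only through the product `r * t`, so
#' `P_s(t; r) = P_s(r t; 1)` exactly (time-scaling law).
#'
#' @param t age(s) in months, nonnegative; vectorized.
#' @param p a [model_params()] object.
#' @return prevalence value(s) in `[0, 1]`.
#' @export
#' @examples
#' susceptible_prevalence(c(33, 124), param_library("asd_female"))
susceptible_prevalence <- function(t, p) {
  stopifnot(inherits(p, "model_params"), is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) stop("'t' must be nonnegative")
  s <- p$r * t
  (1 - exp(-p$k1 * s))^p$m1 * (1 - exp(-p$k2 * s))
}

#' Incidence-rate density IR_s(t) = dP_s/dt
#'
#' Analytic derivative of [susceptible_prevalence()]: the density of onset
#' ages among susceptibles, per month. Nonnegative and integrating to one
#' over all ages.
#'
#' @inheritParams susceptible_prevalence
#' @return density value(s), per month.
#' @export
incidence_rate <- function(t, p) {
  stopifnot(inherits(p, "model_params"), is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) stop("'t' must be nonnegative")
  s <- p$r * t
  e1 <- exp(-p$k1 * s)
  e2 <- exp(-p$k2 * s)
  a <- 1 - e1
  # m1 >= 1 so a^(m1-1) is finite at t = 0 (0^0 = 1 handled by R)
  p$r * (p$m1 * p$k1 * e1 * a^(p$m1 - 1L) * (1 - e2) + a^p$m1 * p$k2 * e2)
}

#' Age at which the incidence-rate density peaks
#'
#' Argmax of [incidence_rate()] over age, located by golden-section search
#' on the analytic density. Unique for the published parameter ranges.
#'
#' @param p a [model_params()] object.
#' @param upper optional upper search bound in months; defaults to the
#'   99.9th onset percentile.
#' @return peak age in months.
#' @export
#' @examples
#' peak_incidence_age(param_library("asd_female"))
peak_incidence_age <- function(p, upper = NULL) {
  stopifnot(inherits(p, "model_params"))
  if (is.null(upper)) upper <- onset_quantile(0.999, p)
  stats::optimize(function(t) incidence_rate(t, p),
                  interval = c(0, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

#' Onset-age quantile (inverse of P_s)
#'
#' Solves `P_s(t) = q` for `t`. The bracket `[0, t_hi]` is found by
#' doubling `t_hi` until `P_s(t_hi) > q`; the root is then polished by
#' safeguarded Newton iteration (bisection fallback) to
#' `|P_s(t) - q| < 1e-10`. Vectorized over `q`.
#'
#' @param q probability value(s) strictly inside `(0, 1)`.
#' @param p a [model_params()] object.
#' @return age(s) in months with `susceptible_prevalence(age, p) == q` to
#'   within `1e-10`.
#' @export
#' @examples
#' onset_quantile(0.5, param_library("asd_female"))  # median onset, ~33.3
onset_quantile <- function(q, p) {
  stopifnot(inherits(p, "model_params"), is.numeric(q))
  if (any(q <= 0 | q >= 1)) stop("'q' must lie strictly inside (0, 1)")
  hi <- 1
  while (susceptible_prevalence(hi, p) <= max(q)) hi <- hi * 2
  lo <- rep(0, length(q))
  up <- rep(hi, length(q))
  # interpolated start on a log-spaced grid, then safeguarded Newton
  grid_t <- c(0, exp(seq(log(1e-3), log(hi), length.out = 256L)))
  grid_p <- susceptible_prevalence(grid_t, p)
  t <- stats::approx(grid_p, grid_t, xout = q, ties = "ordered")$y
  t[is.na(t)] <- hi / 2
  for (iter in seq_len(100L)) {
    f <- susceptible_prevalence(t, p) - q
    done <- abs(f) < 1e-10
    if (all(done)) break
    lo[f < 0] <- t[f < 0]
    up[f > 0] <- t[f > 0]
    d <- incidence_rate(t, p)
    step <- ifelse(d > 0, f / d, 0)
    t_new <- t - step
    bad <- !done & (t_new <= lo | t_new >= up | !is.finite(t_new))
    t_new[bad] <- (lo[bad] + up[bad]) / 2
    t[!done] <- t_new[!done]
  }
  f <- susceptible_prevalence(t, p) - q
  if (any(abs(f) >= 1e-10)) {
    # rare stragglers: fall back to uniroot per element
    idx <- which(abs(f) >= 1e-10)
    for (i in idx) {
      t[i] <- stats::uniroot(function(x) susceptible_prevalence(x, p) - q[i],
                             lower = lo[i], upper = up[i],
                             tol = .Machine$double.eps^0.9)$root
    }
  }
  t
}

#' Expected cumulative diagnosis count
#'
#' Expected number of diagnosed individuals by age `t` in a susceptible
#' pool of size `n_b`: `N(t) = n_b * P_s(t)`. This is the model function
#' fitted to cumulative age-of-first-diagnosis data.
#'
#' @inheritParams susceptible_prevalence
#' @param n_b susceptible pool size, positive.
#' @return expected count(s).
#' @export
cumulative_count <- function(t, n_b, p) {
  stopifnot(is.numeric(n_b), length(n_b) == 1L)
  if (!is.finite(n_b) || n_b <= 0) stop("'n_b' must be positive")
  n_b * susceptible_prevalence(t, p)
}
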