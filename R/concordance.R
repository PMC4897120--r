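#' Twin-pair state probabilities
#'
#' For a pair of susceptible identical twins whose onsets are independent
#' draws from the onset distribution, the probability that by age `t` both
#' are affected, exactly one is affected, or neither is affected:
#' \deqn{P_{ss} = P_s^2,\quad P_{sx} = 2 P_s (1 - P_s),\quad
#'       P_{xx} = (1 - P_s)^2.}
#' The three probabilities sum to one at every age.
#'
#' @param t age(s) in months, nonnegative; vectorized.
#' @param p a [model_params()] object.
#' @return a data frame with columns `age`, `p_ss`, `p_sx`, `p_xx`.
#' @export
#' @examples
#' twin_state_probabilities(40, param_library("asd_female"))
twin_state_probabilities <- function(t, p) {
  ps <- susceptible_prevalence(t, p)
  data.frame(age = t, p_ss = ps^2, p_sx = 2 * ps * (1 - ps),
             p_xx = (1 - ps)^2)
}

#' Monozygote pairwise concordance curve
#'
#' Among susceptible identical-twin pairs with at least one affected
#' member by age `t` (the pairwise convention), the fraction with both
#' affected:
#' \deqn{C_M(t) = \frac{P_{ss}}{P_{ss} + P_{sx}} = \frac{P_s(t)}{2 - P_s(t)}.}
#' Monotone nondecreasing, zero at birth, saturating at 100%.
#'
#' @inheritParams twin_state_probabilities
#' @return concordance value(s) in `[0, 1]`.
#' @export
mz_concordance <- function(t, p) {
  ps <- susceptible_prevalence(t, p)
  ps / (2 - ps)
}

#' Invert an observed MZ concordance to a prevalence
#'
#' Inverse of the pairwise concordance map `c = p/(2 - p)`:
#' \deqn{P_s = \frac{2c}{1 + c}.}
#' An observed concordance of 41/60 maps to a susceptible prevalence of
#' 82/101.
#'
#' @param c observed pairwise MZ concordance in `[0, 1)`; vectorized.
#' @return implied prevalence value(s) in `[0, 1)`.
#' @export
#' @examples
#' prevalence_from_mz_concordance(41 / 60)  # 82/101 = 0.812
prevalence_from_mz_concordance <- function(c) {
  stopifnot(is.numeric(c))
  if (any(c < 0 | c >= 1)) stop("'c' must lie in [0, 1)")
  2 * c / (1 + c)
}

#' Effective cohort age from an observed MZ concordance
#'
#' The age-cohort reading of a registry snapshot: treat the cohort as
#' having a single effective age, invert the observed concordance to a
#' prevalence via [prevalence_from_mz_concordance()], then invert the
#' prevalence through the onset model.
#'
#' @param c observed pairwise MZ concordance, strictly inside `(0, 1)`.
#' @param p a [model_params()] object.
#' @return effective cohort age in months.
#' @export
#' @examples
#' age_for_observed_mz_concordance(41 / 60, param_library("asd_female"))
age_for_observed_mz_concordance <- function(c, p) {
  if (any(c <= 0 | c >= 1)) stop("'c' must lie strictly inside (0, 1)")
  onset_quantile(prevalence_from_mz_concordance(c), p)
}

#' Dizygote pairwise concordance curve
#'
#' The fraternal co-twin of a susceptible index twin is itself susceptible
#' with probability `s_inher`; susceptible twins have independent onsets.
#' Under the same pairwise convention as [mz_concordance()],
#' \deqn{C_D(t) = \frac{s\, P_s(t)}{1 + s\,(1 - P_s(t))}.}
#' Monotone in `t`, saturating at `s_inher` (not at 100%) — the
#' characteristic signature separating dizygote from monozygote pairs.
#'
#' @inheritParams twin_state_probabilities
#' @param s_inher inherited-susceptibility probability in `[0, 1]`.
#' @return concordance value(s) in `[0, s_inher]`.
#' @export
dz_concordance <- function(t, s_inher, p) {
  stopifnot(is.numeric(s_inher), length(s_inher) == 1L)
  if (s_inher < 0 || s_inher > 1) stop("'s_inher' must lie in [0, 1]")
  ps <- susceptible_prevalence(t, p)
  s_inher * ps / (1 + s_inher * (1 - ps))
}

#' Estimate inherited susceptibility from observed DZ concordance
#'
#' Two estimators of `S_inher`, the probability that the fraternal
#' co-twin of a susceptible index twin is also susceptible:
#' \describe{
#'   \item{`"saturation"`}{assigns `s = c_d_obs` directly, treating the
#'     observed cohort as old enough that the dizygote curve has
#'     saturated. This is the conventional assignment (49/260 gives
#'     0.188) and the default.}
#'   \item{`"model-inverse"`}{solves the dizygote concordance formula for
#'     `s` at the prevalence `p_s_obs` prevailing at observation:
#'     `s = c / (p - c (1 - p))`. Requires `p_s_obs`; errors if no
#'     solution lies in `[0, 1]`.}
#' }
#'
#' @param c_d_obs observed pairwise DZ concordance in `[0, 1)`.
#' @param p_s_obs susceptible prevalence at the effective observation age,
#'   in `(0, 1]`; required for mode `"model-inverse"`.
#' @param mode `"saturation"` (default) or `"model-inverse"`.
#' @return estimated `s_inher` in `[0, 1]`.
#' @export
#' @examples
#' s_inher_from_observed(49 / 260)                      # 0.188
#' s_inher_from_observed(0.188, p_s_obs = 0.812,
#'                       mode = "model-inverse")        # ~0.242
s_inher_from_observed <- function(c_d_obs, p_s_obs = NULL,
                                  mode = c("saturation", "model-inverse")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(c_d_obs), length(c_d_obs) == 1L)
  if (c_d_obs < 0 || c_d_obs >= 1) stop("'c_d_obs' must lie in [0, 1)")
  if (mode == "saturation") return(c_d_obs)
  if (is.null(p_s_obs)) stop("mode 'model-inverse' requires 'p_s_obs'")
  stopifnot(is.numeric(p_s_obs), length(p_s_obs) == 1L)
  if (p_s_obs <= 0 || p_s_obs > 1) stop("'p_s_obs' must lie in (0, 1]")
  denom <- p_s_obs - c_d_obs * (1 - p_s_obs)
  if (denom <= 0) stop("no inherited susceptibility in [0, 1] reproduces ",
                       "this concordance at the given prevalence")
  s <- c_d_obs / denom
  if (s > 1 + 1e-12) stop("no inherited susceptibility in [0, 1] reproduces ",
                          "this concordance at the given prevalence")
  min(s, 1)
}

#' Expected MZ concordance over a discrete cohort age distribution
#'
#' The expected pairwise concordance of a cohort whose members have ages
#' `t_i` with multiplicities `n_i`:
#' \deqn{\langle C_M \rangle = \frac{\sum_i C_M(t_i)\, n_i}{\sum_i n_i}.}
#'
#' @param ages cohort ages in months; nonempty.
#' @param p a [model_params()] object.
#' @param counts multiplicities, recycled to `length(ages)`; default 1.
#' @return expected concordance in `[0, 1]`.
#' @export
expected_mz_concordance_discrete <- function(ages, p, counts = 1) {
  if (length(ages) == 0L) stop("'ages' must be nonempty")
  counts <- rep_len(counts, length(ages))
  if (any(counts <= 0)) stop("'counts' must be positive")
  sum(mz_concordance(ages, p) * counts) / sum(counts)
}

#' Expected MZ concordance when cohort ages follow the onset distribution
#'
#' If the cohort's age distribution equals the onset distribution itself
#' (one twin of each pair observed as it develops the disorder), truncated
#' at a maximum age `t_o`, the expected pairwise concordance has the
#' closed form
#' \deqn{\langle C_M \rangle = -1 - \frac{2}{P_s(t_o)}
#'       \ln\!\Big(1 - \frac{P_s(t_o)}{2}\Big),}
#' which at `t_o = Inf` reduces to `2 ln 2 - 1 = 0.38629` — independent of
#' the onset CDF's exact shape, since the integral depends on the age
#' distribution only through the substitution `u = P_s(t)`.
#'
#' @param t_o upper truncation age in months, positive; may be `Inf`.
#' @param p a [model_params()] object.
#' @param method `"closed_form"` (default) or `"quadrature"` (adaptive
#'   integration of `u/(2 - u)` over `[0, P_s(t_o)]`, tolerance 1e-10;
#'   the consistency cross-check).
#' @return expected concordance in `[0, 1]`.
#' @export
#' @examples
#' expected_mz_concordance_onset_weighted(Inf, param_library("asd_female"))
expected_mz_concordance_onset_weighted <- function(t_o, p,
    method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(is.numeric(t_o), length(t_o) == 1L)
  if (!(t_o > 0)) stop("'t_o' must be positive")
  u_o <- if (is.infinite(t_o)) 1 else susceptible_prevalence(t_o, p)
  if (u_o == 0) return(0)
  if (method == "closed_form") {
    -1 - (2 / u_o) * log(1 - u_o / 2)
  } else {
    stats::integrate(function(u) u / (2 - u), 0, u_o,
                     rel.tol = 1e-10, abs.tol = 0)$value / u_o
  }
}

#' Clock rate reproducing a target median onset age
#'
#' By the time-scaling law `P_s(t; r) = P_s(r t; 1)`, a cohort whose
#' median onset age is `target_median` months shares the reference
#' cohort's intrinsic parameters with clock rate
#' `r = median(r = 1) / target_median`. `r < 1` means a slower mutation
#' clock (later onset).
#'
#' @param target_median observed median onset age in months, positive.
#' @param p a [model_params()] object supplying the intrinsic shape
#'   (`k1`, `k2`, `m1`); its own `r` is ignored (reference clock `r = 1`).
#' @return dimensionless clock rate.
#' @export
#' @examples
#' clock_rate_for_median(55, param_library("asd_male"))  # ~0.613
clock_rate_for_median <- function(target_median, p) {
  stopifnot(is.numeric(target_median), length(target_median) == 1L)
  if (!(target_median > 0)) stop("'target_median' must be positive")
  ref <- onset_quantile(0.5, with_clock_rate(p, 1))
  ref / target_median
}
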