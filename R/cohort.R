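#' Configuration for a synthetic twin cohort
#'
#' Describes a simulated registry cohort of twin pairs under the
#' multimutation model's assumptions: monozygote (MZ) pairs are both
#' susceptible; in dizygote (DZ) pairs twin A is the susceptible index
#' twin and twin B is susceptible with probability `s_inher`; susceptible
#' twins have independent onset ages drawn from the onset distribution.
#' A pair is *diagnosed* at its observation age if onset has occurred by
#' then; registry ascertainment keeps pairs with at least one diagnosis.
#' `reporting_bias` models the registry's tendency to under-report
#' concordant pairs (both-diagnosed pairs are retained with this
#' probability; 1 = no bias).
#'
#' @param n_pairs number of pairs, at least 1.
#' @param params a [model_params()] object.
#' @param fraction_mz fraction of pairs that are monozygote, in `[0, 1]`;
#'   the MZ count is `round(n_pairs * fraction_mz)`.
#' @param s_inher inherited-susceptibility probability for DZ co-twins.
#' @param observation_age either a single age in months (the age-cohort
#'   idealization: every pair observed at the same age), a vector of ages
#'   recycled to `n_pairs`, or a data frame with columns `age` and
#'   `count` from which per-pair observation ages are sampled.
#' @param reporting_bias probability that a concordant (both-diagnosed)
#'   pair is retained; default 1.
#' @param seed integer seed recorded in the config and used by
#'   [generate_twin_cohort()]; `NULL` leaves the RNG state alone.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs, params, fraction_mz = 1,
                          s_inher = 0.188, observation_age = 60,
                          reporting_bias = 1, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1 ||
      n_pairs != round(n_pairs)) stop("'n_pairs' must be a positive integer")
  for (nm in c("fraction_mz", "s_inher", "reporting_bias")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("'", nm, "' must be a probability in [0, 1]")
    }
  }
  if (is.data.frame(observation_age)) {
    if (!all(c("age", "count") %in% names(observation_age)) ||
        any(observation_age$count <= 0) || any(observation_age$age < 0)) {
      stop("'observation_age' data frame needs nonnegative 'age' and ",
           "positive 'count' columns")
    }
    observation_age$age <- as.numeric(observation_age$age)
    observation_age$count <- as.numeric(observation_age$count)
  } else if (!is.numeric(observation_age) || any(observation_age < 0)) {
    stop("'observation_age' must be nonnegative")
  } else {
    observation_age <- as.numeric(observation_age)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_pairs = as.integer(n_pairs), params = params,
                 fraction_mz = fraction_mz, s_inher = s_inher,
                 observation_age = observation_age,
                 reporting_bias = reporting_bias, seed = seed),
            class = "cohort_config")
}

#' Sample onset ages from the model's onset distribution
#'
#' Inverse-transform sampling: draws `u` uniform on (0, 1) and returns
#' [onset_quantile()] of `u`, giving i.i.d. ages distributed as the
#' susceptible-prevalence CDF.
#'
#' @param n number of draws.
#' @param p a [model_params()] object.
#' @return numeric vector of onset ages in months.
#' @export
#' @examples
#' set.seed(1)
#' median(sample_onset_age(1000, param_library("asd_female")))
sample_onset_age <- function(n, p) {
  if (n == 0L) return(numeric(0))
  onset_quantile(stats::runif(n), p)
}

#' Simulate a cumulative onset-count table
#'
#' Draws onset ages for `n_b` susceptible individuals and tabulates the
#' cumulative number diagnosed by each requested age — binomial noise
#' around `N(t) = n_b * P_s(t)`. Used as the fitting test bed.
#'
#' @param n_b susceptible pool size.
#' @param ages evaluation ages in months, strictly increasing.
#' @param p a [model_params()] object.
#' @return an onset-count data frame (`age_months`, `cumulative_count`).
#' @export
simulate_onset_counts <- function(n_b, ages, p) {
  onsets <- sample_onset_age(n_b, p)
  data.frame(age_months = ages,
             cumulative_count = vapply(ages,
               function(a) sum(onsets <= a), numeric(1)))
}

#' Generate a synthetic twin cohort
#'
#' Draws a cohort of twin pairs per a [cohort_config()]: susceptibility
#' by zygosity, independent onset ages for susceptible twins
#' (non-susceptible twins never have onset, recorded as `NA`), diagnosis
#' flags at the observation age, and optional thinning of concordant
#' pairs by `reporting_bias`. Fully reproducible: the same config and
#' seed give an identical table.
#'
#' @param cfg a [cohort_config()].
#' @return a data frame with one row per retained pair: `pair_id`,
#'   `zygosity` (`"MZ"`/`"DZ"`), `a_susceptible`, `b_susceptible`,
#'   `a_onset_months`, `b_onset_months` (`NA` = never),
#'   `observation_age_months`, `a_diagnosed`, `b_diagnosed`. The config
#'   is attached as attribute `"config"`.
#' @export
generate_twin_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_pairs
  n_mz <- round(n * cfg$fraction_mz)
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n - n_mz))

  a_susc <- rep(TRUE, n)  # twin A is the (index) susceptible twin
  b_susc <- ifelse(zyg == "MZ", TRUE, stats::runif(n) < cfg$s_inher)

  a_onset <- sample_onset_age(n, cfg$params)
  b_onset <- rep(NA_real_, n)
  b_onset[b_susc] <- sample_onset_age(sum(b_susc), cfg$params)

  obs <- cfg$observation_age
  obs_age <- if (is.data.frame(obs)) {
    sample(obs$age, n, replace = TRUE, prob = obs$count)
  } else {
    rep_len(obs, n)
  }

  pairs <- data.frame(
    pair_id = seq_len(n), zygosity = zyg,
    a_susceptible = a_susc, b_susceptible = b_susc,
    a_onset_months = a_onset, b_onset_months = b_onset,
    observation_age_months = obs_age)
  pairs <- add_diagnosis_flags(pairs)

  if (cfg$reporting_bias < 1) {
    conc <- pairs$a_diagnosed & pairs$b_diagnosed
    drop <- conc & stats::runif(n) >= cfg$reporting_bias
    pairs <- pairs[!drop, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "config") <- cfg
  pairs
}

# diagnosed means susceptible with onset at or before the observation age
add_diagnosis_flags <- function(pairs) {
  pairs$a_diagnosed <- pairs$a_susceptible &
    !is.na(pairs$a_onset_months) &
    pairs$a_onset_months <= pairs$observation_age_months
  pairs$b_diagnosed <- pairs$b_susceptible &
    !is.na(pairs$b_onset_months) &
    pairs$b_onset_months <= pairs$observation_age_months
  pairs
}

#' Registry ascertainment
#'
#' Keeps exactly the pairs with at least one twin diagnosed by the
#' observation age, preserving order.
#'
#' @param pairs a twin-pair data frame from [generate_twin_cohort()].
#' @return the ascertained subset.
#' @export
ascertain_pairs <- function(pairs) {
  keep <- pairs$a_diagnosed | pairs$b_diagnosed
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical pairwise concordance
#'
#' Counts concordant (both diagnosed), discordant (exactly one
#' diagnosed), and unaffected pairs, and reports the pairwise concordance
#' rate: concordant over pairs with at least one diagnosis. Intended for
#' already-ascertained input (where unaffected = 0, so the rate is
#' concordant / total), but unaffected pairs are counted and excluded
#' from the denominator rather than silently miscounted.
#'
#' @param pairs a twin-pair data frame.
#' @param by_zygosity if `TRUE`, one summary row per zygosity.
#' @return a data frame with columns `zygosity`, `n_pairs`,
#'   `n_concordant`, `n_discordant`, `n_unaffected`, `rate`. Empty input
#'   gives zero counts and an `NA` rate.
#' @export
empirical_concordance <- function(pairs, by_zygosity = FALSE) {
  one <- function(df, label) {
    nc <- sum(df$a_diagnosed & df$b_diagnosed)
    nd <- sum(xor(df$a_diagnosed, df$b_diagnosed))
    nu <- sum(!df$a_diagnosed & !df$b_diagnosed)
    data.frame(zygosity = label, n_pairs = nrow(df), n_concordant = nc,
               n_discordant = nd, n_unaffected = nu,
               rate = if (nc + nd > 0) nc / (nc + nd) else NA_real_)
  }
  if (!by_zygosity) return(one(pairs, "all"))
  out <- do.call(rbind, lapply(sort(unique(pairs$zygosity)), function(z) {
    one(pairs[pairs$zygosity == z, , drop = FALSE], z)
  }))
  if (is.null(out)) out <- one(pairs[0, , drop = FALSE], "all")
  rownames(out) <- NULL
  out
}

#' Longitudinal concordance trajectory of one cohort
#'
#' Generates a single cohort and re-evaluates diagnosis flags,
#' ascertainment, and pairwise concordance at each requested observation
#' age — the proposed longitudinal test: the MZ column must climb to
#' 100% once every observation age passes the onset distribution's upper
#' reach, while the DZ column saturates at `s_inher`. Re-evaluation is
#' deterministic on the generated cohort (the `reporting_bias` thinning,
#' a one-time registry-inclusion effect, is applied at generation only).
#'
#' @param cfg a [cohort_config()]; its `observation_age` is ignored in
#'   favor of `ages`.
#' @param ages increasing vector of observation ages in months.
#' @return a data frame with one row per age: `age`, `c_m`, `c_d`
#'   (empirical pairwise concordance per zygosity, `NA` when no pair of
#'   that zygosity is ascertained), and ascertained pair counts
#'   `n_mz_ascertained`, `n_dz_ascertained`.
#' @export
concordance_trajectory <- function(cfg, ages) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (any(diff(ages) <= 0)) stop("'ages' must be strictly increasing")
  pairs <- generate_twin_cohort(cfg)
  rows <- lapply(ages, function(a) {
    pairs$observation_age_months <- a
    asc <- ascertain_pairs(add_diagnosis_flags(pairs))
    cs <- empirical_concordance(asc, by_zygosity = TRUE)
    get_rate <- function(z) {
      i <- match(z, cs$zygosity)
      if (is.na(i)) c(NA_real_, 0) else c(cs$rate[i], cs$n_pairs[i])
    }
    mz <- get_rate("MZ"); dz <- get_rate("DZ")
    data.frame(age = a, c_m = mz[1], c_d = dz[1],
               n_mz_ascertained = mz[2], n_dz_ascertained = dz[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
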