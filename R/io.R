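#' Read / write a twin-pair table
#'
#' Comma-separated text with header
#' `pair_id,zygosity,a_susceptible,b_susceptible,a_onset_months,b_onset_months,observation_age_months`;
#' `NA` marks a twin that never has onset. Diagnosis flags are derived
#' columns (onset at or before observation age) and are recomputed on
#' read rather than stored.
#'
#' @param pairs a twin-pair data frame from [generate_twin_cohort()].
#' @param path file path.
#' @return `read_twin_cohort`: the twin-pair data frame with diagnosis
#'   flags recomputed; `write_twin_cohort`: `path`, invisibly.
#' @export
write_twin_cohort <- function(pairs, path) {
  cols <- c("pair_id", "zygosity", "a_susceptible", "b_susceptible",
            "a_onset_months", "b_onset_months", "observation_age_months")
  stopifnot(all(cols %in% names(pairs)))
  utils::write.csv(pairs[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_twin_cohort
#' @export
read_twin_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("pair_id", "zygosity", "a_susceptible", "b_susceptible",
            "a_onset_months", "b_onset_months", "observation_age_months")
  if (!all(cols %in% names(df))) {
    stop("twin-pair file ", path, " must have header '",
         paste(cols, collapse = ","), "' (line 1)")
  }
  if (!all(df$zygosity %in% c("MZ", "DZ"))) {
    stop("field 'zygosity' must be 'MZ' or 'DZ' (data row ",
         which(!df$zygosity %in% c("MZ", "DZ"))[1], ")")
  }
  add_diagnosis_flags(df[cols])
}

#' Write / read a cohort configuration as JSON
#'
#' @param cfg a [cohort_config()].
#' @param path file path.
#' @return `read_cohort_config`: a `cohort_config`;
#'   `write_cohort_config`: `path`, invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  rec <- list(
    n_pairs = cfg$n_pairs, fraction_mz = cfg$fraction_mz,
    s_inher = cfg$s_inher, observation_age = cfg$observation_age,
    reporting_bias = cfg$reporting_bias, seed = cfg$seed,
    params = list(name = cfg$params$name, k1_per_month = cfg$params$k1,
                  k2_per_month = cfg$params$k2, m1 = cfg$params$m1,
                  r = cfg$params$r))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_pairs", "params", "observation_age")) {
    if (is.null(rec[[f]])) stop("cohort config missing field '", f, "'")
  }
  p <- rec$params
  for (f in c("k1_per_month", "k2_per_month", "m1")) {
    if (is.null(p[[f]])) stop("cohort config missing field 'params.", f, "'")
  }
  obs <- rec$observation_age
  if (is.list(obs)) obs <- as.data.frame(obs)
  cohort_config(
    n_pairs = rec$n_pairs,
    params = model_params(p$k1_per_month, p$k2_per_month, p$m1,
                          r = if (is.null(p$r)) 1 else p$r,
                          name = if (is.null(p$name) || is.na(p$name)) NULL
                                 else p$name),
    fraction_mz = if (is.null(rec$fraction_mz)) 1 else rec$fraction_mz,
    s_inher = if (is.null(rec$s_inher)) 0 else rec$s_inher,
    observation_age = obs,
    reporting_bias = if (is.null(rec$reporting_bias)) 1
                     else rec$reporting_bias,
    seed = rec$seed)
}

#' Model curves over an age grid
#'
#' Tabulates every analytic curve of the model at the requested ages:
#' prevalence, incidence density, the twin-pair state probabilities, and
#' the monozygote (and, given `s_inher`, dizygote) concordance curves.
#'
#' @param p a [model_params()] object.
#' @param ages evaluation ages in months.
#' @param s_inher optional inherited-susceptibility probability; adds the
#'   dizygote concordance column `c_d`.
#' @return a data frame with columns `age`, `p_s`, `ir_s`, `p_ss`,
#'   `p_sx`, `p_xx`, `c_m`, and optionally `c_d`.
#' @export
#' @examples
#' predict_curves(param_library("asd_female"), ages = c(40, 55, 123))
predict_curves <- function(p, ages, s_inher = NULL) {
  states <- twin_state_probabilities(ages, p)
  out <- data.frame(age = ages,
                    p_s = susceptible_prevalence(ages, p),
                    ir_s = incidence_rate(ages, p),
                    p_ss = states$p_ss, p_sx = states$p_sx,
                    p_xx = states$p_xx,
                    c_m = mz_concordance(ages, p))
  if (!is.null(s_inher)) out$c_d <- dz_concordance(ages, s_inher, p)
  out
}

#' Write a run manifest
#'
#' Records package version, seed, and a configuration echo alongside a
#' run's outputs, so every results directory is self-describing. Content
#' is deterministic (no timestamps), keeping fixed-seed reruns
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param config a named list (or `cohort_config`) echoed verbatim.
#' @param seed the run seed, if any.
#' @return path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, config = list(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(config, "cohort_config")) {
    config <- list(n_pairs = config$n_pairs,
                   fraction_mz = config$fraction_mz,
                   s_inher = config$s_inher,
                   observation_age = config$observation_age,
                   reporting_bias = config$reporting_bias,
                   seed = config$seed,
                   params = unclass(config$params))
  }
  man <- list(package = "mmtwin",
              version = as.character(utils::packageVersion("mmtwin")),
              seed = seed, config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
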