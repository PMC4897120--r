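#' Intrinsic onset-model parameters
#'
#' Bundle the parameters of the multimutation onset model: `m1` mutation
#' steps acquired at rate `k1` (in any order) plus one final step at rate
#' `k2`, all scaled by a dimensionless biological clock rate `r`. The
#' implied susceptible-prevalence function is
#' \deqn{P_s(t; r) = (1 - e^{-k_1 r t})^{m_1} (1 - e^{-k_2 r t}).}
#' Rates are per month; ages everywhere in this package are months since
#' birth.
#'
#' @param k1 rate per month of each of the `m1` interchangeable mutation
#'   steps; positive.
#' @param k2 rate per month of the single remaining mutation step; positive.
#' @param m1 number of `k1`-type steps; positive integer. The total
#'   mutation count of the model is `m = m1 + 1`.
#' @param r dimensionless biological clock rate; `r < 1` slows the
#'   mutation clock, `r > 1` speeds it up. Default 1.
#' @param name optional label carried through printing and serialization.
#' @return an object of class `model_params`.
#' @seealso [param_library()] for the published parameter sets,
#'   [susceptible_prevalence()] for the prevalence function.
#' @export
#' @examples
#' p <- model_params(k1 = 0.12532, k2 = 0.031716, m1 = 17)
#' susceptible_prevalence(40, p)
model_params <- function(k1, k2, m1, r = 1, name = NULL) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(m1), length(m1) == 1L, is.finite(m1),
            is.numeric(r), length(r) == 1L, is.finite(r))
  if (k1 <= 0) stop("'k1' must be positive")
  if (k2 <= 0) stop("'k2' must be positive")
  if (m1 < 1 || m1 != round(m1)) stop("'m1' must be a positive integer")
  if (r <= 0) stop("'r' must be positive")
  structure(
    list(k1 = as.numeric(k1), k2 = as.numeric(k2), m1 = as.integer(m1),
         r = as.numeric(r),
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  nm <- if (is.na(x$name)) "" else paste0(" [", x$name, "]")
  cat(sprintf("Multimutation onset-model parameters%s\n", nm))
  cat(sprintf("  k1 = %g /month, k2 = %g /month, m1 = %d (m = %d), r = %g\n",
              x$k1, x$k2, x$m1, mutation_count(x), x$r))
  invisible(x)
}

#' Total mutation count of a parameter set
#'
#' The model requires `m = m1 + 1` mutations in all: `m1` interchangeable
#' steps plus one final step. Published parameter tables report `m`; the
#' exponent in the prevalence function is `m1`.
#'
#' @param p a [model_params()] object.
#' @return integer `m1 + 1`.
#' @export
mutation_count <- function(p) {
  stopifnot(inherits(p, "model_params"))
  p$m1 + 1L
}

#' Replace the clock rate of a parameter set
#'
#' @param p a [model_params()] object.
#' @param r new positive clock rate.
#' @return a `model_params` object with `r` replaced.
#' @export
with_clock_rate <- function(p, r) {
  stopifnot(inherits(p, "model_params"))
  model_params(p$k1, p$k2, p$m1, r = r, name = p$name)
}

#' Published parameter sets
#'
#' Load the intrinsic parameter sets fitted to cumulative
#' age-of-first-diagnosis data: `asd_male` and `asd_female` (2014 IAN
#' registry fits, rates per month) and `schizophrenia` (rates per year in
#' the source table, converted to per-month on load). The male and female
#' ASD sets are practically identical; which set reproduces which printed
#' illustrative value is documented in the package vignette.
#'
#' @param name one of `"asd_male"`, `"asd_female"`, `"schizophrenia"`, or
#'   `NULL` to return the whole library as a named list.
#' @param file optional path to a JSON parameter library; defaults to the
#'   copy shipped with the package.
#' @return a `model_params` object, or a named list of them.
#' @export
#' @examples
#' param_library("asd_female")
param_library <- function(name = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "param_library.json", package = "mmtwin")
  }
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  lib <- lapply(raw, function(rec) {
    unit <- if (is.null(rec$time_unit)) "month" else rec$time_unit
    conv <- switch(unit, month = 1, year = 1 / 12,
                   stop("unknown time unit: ", unit))
    model_params(k1 = rec$k1 * conv, k2 = rec$k2 * conv, m1 = rec$m1,
                 r = if (is.null(rec$r)) 1 else rec$r, name = rec$name)
  })
  names(lib) <- vapply(raw, function(rec) rec$name, character(1))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  }
  lib[[name]]
}

#' Serialize a parameter set to JSON
#'
#' Writes `{name, k1_per_month, k2_per_month, m1, r}`, readable back with
#' [read_model_params()].
#'
#' @param p a [model_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  rec <- list(name = p$name, k1_per_month = p$k1, k2_per_month = p$k2,
              m1 = p$m1, r = p$r)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(k1 = rec$k1_per_month, k2 = rec$k2_per_month, m1 = rec$m1,
               r = if (is.null(rec$r)) 1 else rec$r,
               name = if (is.null(rec$name)) NULL else rec$name)
}
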