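#' Allometric body-size estimation from skull measurements
#'
#' Four regression equations estimate total body length and body mass of
#' a baleen whale from skull measurements (all measurements in mm,
#' logarithms base 10):
#'
#' 1. `log10(total body length) = 0.92 * (log10(bizygomatic width) - 1.64) + 2.67`
#'    (length in mm);
#' 2. `body mass = 4.924e-6 * occipital_breadth^3.858` (mass in kg);
#' 3. `log10(body mass) = 3.08 * log10(skeletal length) - 4.84`
#'    (mass in kg, skeletal length in cm), inverted here to obtain a
#'    length from a mass;
#' 4. `supraoccipital length = 0.3937 * condylobasal length - 62.803`,
#'    inverted to obtain the condylobasal (skull) length, which is then
#'    multiplied by 3 and 4 (skull length being roughly 25-30% of total
#'    body length in balaenids) to bracket total length.
#'
#' Because equations 1-3 were calibrated outside Balaenidae they
#' overestimate; published practice applies multiplicative reductions
#' (fractions of the raw value) which these functions expose as
#' `corrections`.
#'
#' @name body_size
NULL

.body_estimate <- function(method, raw, corrected = NULL, factors = NULL,
                           units, extra = list()) {
  structure(c(list(method = method, raw = raw, corrected = corrected,
                   correction_factors = factors, units = units), extra),
            class = "body_size_estimate")
}

#' @export
print.body_size_estimate <- function(x, ...) {
  cat(sprintf("%s: raw %.2f %s", x$method, x$raw, x$units))
  if (length(x$corrected))
    cat(" | corrected:", paste(sprintf("%.2f", x$corrected), collapse = ", "),
        x$units)
  cat("\n")
  invisible(x)
}

#' @rdname body_size
#' @param bzw bizygomatic width (mm).
#' @param corrections reduction fractions applied multiplicatively as
#'   `raw * (1 - f)`; default `c(0.37, 0.47)`, the deviation range of
#'   the regression from intact specimens.
#' @return a `"body_size_estimate"`: `method`, `raw` (m or t),
#'   `corrected`, `correction_factors`, `units`.
#' @examples
#' length_from_bizygomatic(1660)         # ~13.3 m raw; ~8.4 and ~7 m corrected
#' mass_from_occipital_breadth(353)      # ~33 t
#' length_from_mass(33290)               # ~11 m raw
#' condylobasal_from_supraoccipital(560) # ~1.6 m skull; 4.7-6.3 m body
#' @export
length_from_bizygomatic <- function(bzw, corrections = c(0.37, 0.47)) {
  if (!is.numeric(bzw) || bzw <= 0)
    stop("domain error: bizygomatic width must be positive")
  if (length(corrections) && any(corrections < 0 | corrections >= 1))
    stop("correction fractions must lie in [0, 1)")
  raw_mm <- 10^(0.92 * (log10(bzw) - 1.64) + 2.67)
  raw_m <- raw_mm / 1000
  .body_estimate("eq1_bizygomatic", raw_m,
                 corrected = raw_m * (1 - corrections),
                 factors = corrections, units = "m")
}

#' @rdname body_size
#' @param ob occipital breadth (mm).
#' @export
mass_from_occipital_breadth <- function(ob) {
  if (!is.numeric(ob) || ob <= 0)
    stop("domain error: occipital breadth must be positive")
  mass_kg <- 4.924e-6 * ob^3.858
  .body_estimate("eq2_occipital_mass", mass_kg / 1000, units = "t",
                 extra = list(mass_kg = mass_kg))
}

#' @rdname body_size
#' @param mass body mass in kg (e.g. `mass_from_occipital_breadth(...)$mass_kg`).
#' @param correction single reduction fraction, default 0.40.
#' @export
length_from_mass <- function(mass, correction = 0.40) {
  if (!is.numeric(mass) || mass <= 0)
    stop("domain error: mass must be positive (kg)")
  len_cm <- 10^((log10(mass) + 4.84) / 3.08)
  raw_m <- len_cm / 100
  .body_estimate("eq3_mass_to_length", raw_m,
                 corrected = raw_m * (1 - correction),
                 factors = correction, units = "m",
                 extra = list(corrected_mass_t = mass * (1 - correction) / 1000))
}

#' @rdname body_size
#' @param sol supraoccipital length (mm); must exceed 62.803 mm for the
#'   inverse to be positive.
#' @param multipliers total-length bracket multipliers for the skull
#'   length, default `c(3, 4)`.
#' @export
condylobasal_from_supraoccipital <- function(sol, multipliers = c(3, 4)) {
  if (!is.numeric(sol) || sol <= 62.803)
    stop("domain error: supraoccipital length must exceed 62.803 mm")
  cbl_mm <- (sol + 62.803) / 0.3937
  cbl_m <- cbl_mm / 1000
  .body_estimate("eq4_supraoccipital", cbl_m, units = "m",
                 extra = list(condylobasal_mm = cbl_mm,
                              body_length_bracket_m = cbl_m * multipliers,
                              multipliers = multipliers))
}

#' Consensus of several body-size estimates
#'
#' Pools the corrected (or, failing that, raw or bracket) length values
#' of the supplied estimates into a min-max consensus range, and carries
#' the corrected mass when one is present.  The result is independent of
#' the order of the estimates.
#'
#' @param estimates list of `"body_size_estimate"` objects.
#' @return a list of class `"body_size_consensus"`: `length_range_m`,
#'   `mass_t` (corrected mass or `NA`), `provenance` (per-method values
#'   pooled).
#' @export
consensus_size <- function(estimates) {
  if (!length(estimates)) stop("input error: no estimates supplied")
  lengths <- list(); mass_t <- NA_real_
  for (est in estimates) {
    stopifnot(inherits(est, "body_size_estimate"))
    if (est$units == "m") {
      vals <- if (length(est$corrected)) est$corrected
              else if (!is.null(est$body_length_bracket_m))
                est$body_length_bracket_m
              else est$raw
      lengths[[est$method]] <- vals
    }
    if (!is.null(est$corrected_mass_t)) mass_t <- est$corrected_mass_t
    if (est$units == "t" && is.na(mass_t)) mass_t <- est$raw
  }
  if (!length(lengths)) stop("input error: no length estimates supplied")
  rng <- range(unlist(lengths))
  structure(list(length_range_m = rng, mass_t = mass_t,
                 provenance = lengths[order(names(lengths))]),
            class = "body_size_consensus")
}

#' @export
print.body_size_consensus <- function(x, ...) {
  cat(sprintf("consensus body length: %.1f - %.1f m", x$length_range_m[1L],
              x$length_range_m[2L]))
  if (!is.na(x$mass_t)) cat(sprintf("; body mass ~ %.1f t", x$mass_t))
  cat("\n")
  invisible(x)
}

#' Full body-size protocol from a set of skull measurements
#'
#' Runs every equation for which a measurement is available and returns
#' the estimates plus their consensus.
#'
#' @param bizygomatic_mm,occipital_breadth_mm,supraoccipital_mm skull
#'   measurements (mm); any may be `NULL`.
#' @param eq1_corrections,eq3_correction,eq4_multipliers tuning as in
#'   the individual functions.
#' @return list with `estimates` (list of `"body_size_estimate"`) and
#'   `consensus`.
#' @export
estimate_body_size <- function(bizygomatic_mm = NULL,
                               occipital_breadth_mm = NULL,
                               supraoccipital_mm = NULL,
                               eq1_corrections = c(0.37, 0.47),
                               eq3_correction = 0.40,
                               eq4_multipliers = c(3, 4)) {
  ests <- list()
  if (!is.null(bizygomatic_mm))
    ests <- c(ests, list(length_from_bizygomatic(bizygomatic_mm,
                                                 eq1_corrections)))
  if (!is.null(occipital_breadth_mm)) {
    m2 <- mass_from_occipital_breadth(occipital_breadth_mm)
    ests <- c(ests, list(m2, length_from_mass(m2$mass_kg, eq3_correction)))
  }
  if (!is.null(supraoccipital_mm))
    ests <- c(ests, list(condylobasal_from_supraoccipital(supraoccipital_mm,
                                                          eq4_multipliers)))
  if (!length(ests)) stop("input error: no measurements supplied")
  list(estimates = ests, consensus = consensus_size(ests))
}
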