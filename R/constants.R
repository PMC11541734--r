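# Model constants and parameter containers.

.gppattrib_env <- new.env(parent = emptyenv())

#' Photosynthesis model parameters
#'
#' Container for the constants of the optimality-based light-use-efficiency
#' model: the intrinsic quantum yield, the unit-cost ratio of the least-cost
#' hypothesis, and the Jmax-limitation cost parameter.
#'
#' @param phi0 Intrinsic quantum yield of photosynthesis
#'   (mol C mol^-1 photons). The theoretical ceiling is 0.125 (one CO2 per
#'   eight photons); the default 0.05 is a realised canopy-scale value.
#' @param beta Unit-cost ratio of carboxylation to transpiration capacity
#'   (unitless) governing the optimal ci/ca ratio. Default 146.
#' @param cstar Cost parameter for the Jmax limitation of electron-transport
#'   limited assimilation (unitless). Default 0.41.
#' @param mc_mass Molar mass of carbon (g mol^-1).
#' @param o2_frac Atmospheric O2 mole fraction (unitless).
#' @param phi0_tdep Logical; if `TRUE`, `phi0` is modulated by a quadratic
#'   temperature response (normalised to 1 at 25 degC). Default `FALSE`
#'   (fixed quantum yield).
#' @return An object of class `photo_params`.
#' @examples
#' p <- photo_params()
#' p$phi0
#' @export
photo_params <- function(phi0 = 0.05, beta = 146, cstar = 0.41,
                         mc_mass = 12.0107, o2_frac = 0.20946,
                         phi0_tdep = FALSE) {
  stopifnot(is.numeric(phi0), length(phi0) == 1L, is.finite(phi0),
            phi0 > 0, phi0 <= 0.125,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(cstar), length(cstar) == 1L, cstar > 0, cstar < 1,
            is.numeric(mc_mass), mc_mass > 0,
            is.numeric(o2_frac), o2_frac > 0, o2_frac < 1,
            is.logical(phi0_tdep), length(phi0_tdep) == 1L)
  structure(list(phi0 = phi0, beta = beta, cstar = cstar,
                 mc_mass = mc_mass, o2_frac = o2_frac,
                 phi0_tdep = phi0_tdep),
            class = "photo_params")
}

#' Kinetic constants table
#'
#' Reference values (25 degC, standard pressure) and activation energies of
#' the leaf biochemical temperature responses, read from the versioned JSON
#' configuration shipped with the package (`inst/extdata/kinetics.json`).
#' A different constants file can be supplied to explore alternative
#' parameterisations.
#'
#' @param path Optional path to a JSON constants file; by default the
#'   packaged table is used (and cached for the session).
#' @return A named list of constants.
#' @export
kinetic_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.gppattrib_env$kin)) {
      path <- system.file("extdata", "kinetics.json", package = "gppattrib")
      .gppattrib_env$kin <- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    return(.gppattrib_env$kin)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# quadratic temperature modulation of the quantum yield, normalised to 25 degC
phi0_at <- function(params, tc) {
  if (!isTRUE(params$phi0_tdep)) return(rep(params$phi0, length(tc)))
  q <- function(x) pmax(0, 0.352 + 0.022 * x - 3.4e-4 * x^2)
  params$phi0 * q(tc) / q(25)
}

#' Convert GPP units
#'
#' `gc_m2_to_mgc_ha()` converts gC m^-2 yr^-1 to MgC ha^-1 yr^-1 (exact
#' factor 0.01); `mgc_ha_to_gc_m2()` is its inverse.
#'
#' @param x Numeric flux values.
#' @return Converted numeric values.
#' @examples
#' gc_m2_to_mgc_ha(4000)  # 40
#' @export
gc_m2_to_mgc_ha <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 0.01
}

#' @rdname gc_m2_to_mgc_ha
#' @export
mgc_ha_to_gc_m2 <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 100
}

#' Days in a calendar month
#'
#' Gregorian month lengths, leap-year aware. Used to convert monthly photon
#' totals (mol m^-2 month^-1) into mean photon flux densities
#' (umol m^-2 s^-1).
#'
#' @param year Calendar year(s).
#' @param month Month number(s), 1-12.
#' @return Integer day counts.
#' @export
days_in_month <- function(year, month) {
  stopifnot(all(month %in% 1:12))
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  out <- base[month]
  out[month == 2 & leap] <- 29L
  out
}

# mean absorbed photon flux (umol m-2 s-1) over a month, from a monthly
# photon total (mol m-2 month-1) and the absorbed fraction
mean_iabs_umol <- function(fapar, ppfd_mol_month, year, month) {
  fapar * ppfd_mol_month * 1e6 / (86400 * days_in_month(year, month))
}
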