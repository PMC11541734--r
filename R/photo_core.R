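# FvCB leaf biochemistry, temperature kinetics, and the optimality-based
# prediction of chi, LUE and Vcmax. All functions are vectorised over their
# forcing inputs.

#' Arrhenius temperature scaling
#'
#' Scales a biochemical rate from a reference temperature to a target
#' temperature with the Arrhenius equation
#' \deqn{r(T) = r_{ref} \exp[(H_a/R)(1/T_{ref} - 1/T)]}
#' with temperatures in kelvin and the activation energy \eqn{H_a} in
#' J mol^-1.
#'
#' @param rate_ref Rate at the reference temperature.
#' @param dha Activation energy (J mol^-1).
#' @param tc Target temperature (degC).
#' @param tc_ref Reference temperature (degC), default 25.
#' @return The scaled rate.
#' @examples
#' arrhenius_scale(50, 65330, 25)        # identity at the reference point
#' arrhenius_scale(1, 79430, 35)         # ~2.8-fold increase over 10 degC
#' @export
arrhenius_scale <- function(rate_ref, dha, tc, tc_ref = 25) {
  if (!all(is.finite(rate_ref)) || !all(is.finite(dha)) ||
      !all(is.finite(tc)) || !all(is.finite(tc_ref))) {
    stop("arrhenius_scale(): all inputs must be finite")
  }
  k <- kinetic_constants()
  rate_ref * exp(dha / k$rgas_j_mol_k *
                   (1 / (tc_ref + 273.15) - 1 / (tc + 273.15)))
}

#' Relative viscosity of water
#'
#' Dynamic viscosity of pure water relative to its value at 25 degC, from
#' the Vogel correlation \eqn{\eta(T) = A\,10^{B/(T - C)}}. By construction
#' `eta_star(25)` is exactly 1; viscosity decreases monotonically with
#' temperature. The pressure dependence of liquid-water viscosity is
#' negligible over the surface-pressure range and is not modelled.
#'
#' @param tc Temperature (degC).
#' @return Unitless relative viscosity.
#' @export
eta_star <- function(tc) {
  stopifnot(all(is.finite(tc)))
  visc <- function(x) 2.414e-5 * 10^(247.8 / (x + 273.15 - 140))
  visc(tc) / visc(25)
}

#' Leaf biochemical kinetics at given conditions
#'
#' Photorespiratory compensation point Gammastar, Michaelis constants for
#' CO2 (Kc) and O2 (Ko), the effective Michaelis-Menten coefficient
#' K = Kc (1 + pO2/Ko), and the relative water viscosity, all at the given
#' temperature and pressure. Gammastar scales linearly with pressure
#' relative to the reference pressure; Kc and Ko are treated as
#' pressure-independent.
#'
#' @param tc Air/leaf temperature (degC).
#' @param patm Atmospheric pressure (Pa), default standard pressure.
#' @param params A [photo_params()] object (supplies the O2 mole fraction).
#' @return A list with vectors `gammastar`, `kc`, `ko`, `kmm` (all Pa) and
#'   `eta_star` (unitless).
#' @examples
#' k <- leaf_kinetics(25)
#' k$gammastar  # the 25 degC reference constant
#' @export
leaf_kinetics <- function(tc, patm = 101325, params = photo_params()) {
  stopifnot(all(is.finite(tc)), all(is.finite(patm)), all(patm > 0),
            all(tc > -10), all(tc < 60))
  k <- kinetic_constants()
  gammastar <- k$gammastar25_pa * (patm / k$reference_pressure_pa) *
    arrhenius_scale(1, k$dha_gammastar_j_mol, tc)
  kc <- arrhenius_scale(k$kc25_pa, k$dha_kc_j_mol, tc)
  ko <- arrhenius_scale(k$ko25_pa, k$dha_ko_j_mol, tc)
  po2 <- params$o2_frac * patm
  list(gammastar = gammastar, kc = kc, ko = ko,
       kmm = kc * (1 + po2 / ko), eta_star = eta_star(tc))
}

check_forcing <- function(forcing) {
  need <- c("tc", "vpd", "co2", "patm")
  miss <- setdiff(need, names(forcing))
  if (length(miss) > 0) {
    stop("forcing is missing field(s): ", paste(miss, collapse = ", "))
  }
  with(forcing, {
    stopifnot(all(is.finite(tc)), all(is.finite(vpd)), all(is.finite(co2)),
              all(is.finite(patm)),
              all(vpd >= 0), all(co2 > 0), all(patm > 0),
              all(tc > -10), all(tc < 60))
  })
  invisible(forcing)
}

#' Optimal ci/ca ratio from the least-cost hypothesis
#'
#' Predicts the ratio chi of leaf-internal to ambient CO2 partial pressure
#' that balances the unit costs of maintaining carboxylation and
#' transpiration capacity:
#' \deqn{\xi = \sqrt{\beta (K + \Gamma^*) / (1.6 \eta^*)}}
#' \deqn{\chi = \Gamma^*/c_a + (1 - \Gamma^*/c_a)\,\xi / (\xi + \sqrt{D})}
#' with D the vapour pressure deficit in Pa. At D = 0, chi = 1 exactly.
#'
#' @param forcing A list or data frame with fields `tc` (degC), `vpd` (Pa),
#'   `co2` (umol mol^-1) and `patm` (Pa); vectors allowed.
#' @param params A [photo_params()] object.
#' @return A data frame with columns `chi` (unitless), `ci` (Pa), `ca` (Pa).
#' @examples
#' chi_optimal(list(tc = 25, vpd = 1000, co2 = 400, patm = 101325))
#' @export
chi_optimal <- function(forcing, params = photo_params()) {
  check_forcing(forcing)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  ca <- forcing$co2 * forcing$patm * 1e-6
  if (any(ca <= kin$gammastar)) {
    stop("invalid forcing: ambient CO2 partial pressure at or below ",
         "the photorespiratory compensation point")
  }
  xi <- sqrt(params$beta * (kin$kmm + kin$gammastar) / (1.6 * kin$eta_star))
  chi <- kin$gammastar / ca +
    (1 - kin$gammastar / ca) * xi / (xi + sqrt(forcing$vpd))
  chi[forcing$vpd == 0] <- 1  # the Gammastar terms cancel exactly
  data.frame(chi = chi, ci = chi * ca, ca = ca)
}

#' CO2 limitation factors
#'
#' The CO2 limitation factors of electron-transport-limited and
#' Rubisco-limited assimilation:
#' mj = (ci - Gammastar)/(ci + 2 Gammastar) and
#' mc = (ci - Gammastar)/(ci + K). Sub-compensation values (ci below
#' Gammastar) are clamped to zero so that cold or dry records contribute
#' zero assimilation rather than an error.
#'
#' @param ci Leaf-internal CO2 partial pressure (Pa).
#' @param kin A kinetics list from [leaf_kinetics()].
#' @return A list with vectors `mj` and `mc`, both in \[0, 1).
#' @export
limitation_factors <- function(ci, kin) {
  stopifnot(all(is.finite(ci)), all(ci >= 0))
  list(mj = pmax(0, (ci - kin$gammastar) / (ci + 2 * kin$gammastar)),
       mc = pmax(0, (ci - kin$gammastar) / (ci + kin$kmm)))
}

#' Jmax limitation factor
#'
#' Adjusts the electron-transport limitation factor mj for the cost of
#' maintaining Jmax: \eqn{m' = m_j \sqrt{1 - (c^*/m_j)^{2/3}}} for
#' mj > cstar, and 0 otherwise (degenerate low-light/low-ci conditions).
#'
#' @param mj CO2 limitation factor of electron-transport-limited
#'   assimilation (unitless, >= 0).
#' @param cstar Cost parameter, default 0.41.
#' @return mprime, with 0 <= mprime <= mj.
#' @export
jmax_limitation <- function(mj, cstar = 0.41) {
  stopifnot(all(is.finite(mj)), all(mj >= 0), cstar > 0, cstar < 1)
  out <- rep(0, length(mj))
  ok <- mj > cstar
  out[ok] <- mj[ok] * sqrt(1 - (cstar / mj[ok])^(2 / 3))
  out
}

#' Optimality-based light use efficiency
#'
#' LUE = phi0 * mprime * Mc (gC per mol absorbed photons), with mprime from
#' the chain [chi_optimal()] -> [limitation_factors()] ->
#' [jmax_limitation()].
#'
#' @inheritParams chi_optimal
#' @return Light use efficiency (gC mol^-1 photons), vectorised.
#' @examples
#' lue_optimal(list(tc = 25, vpd = 1000, co2 = 400, patm = 101325))
#' @export
lue_optimal <- function(forcing, params = photo_params()) {
  cc <- chi_optimal(forcing, params)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  lim <- limitation_factors(cc$ci, kin)
  mprime <- jmax_limitation(lim$mj, params$cstar)
  phi0_at(params, forcing$tc) * mprime * params$mc_mass
}

#' Full optimality prediction for one or more forcing records
#'
#' Convenience wrapper returning chi, ci, the limitation factors, the
#' Jmax-limitation-adjusted factor, LUE, and (when an absorbed photon flux
#' is supplied) the optimal Vcmax.
#'
#' @inheritParams chi_optimal
#' @param iabs Optional absorbed PPFD (umol m^-2 s^-1) for the Vcmax
#'   prediction.
#' @param vcmax_method Passed to [vcmax_optimal()].
#' @return A data frame with columns `chi`, `ci`, `mj`, `mc`, `mprime`,
#'   `lue` and, if `iabs` is given, `vcmax_opt`.
#' @export
optimality_prediction <- function(forcing, params = photo_params(),
                                  iabs = NULL,
                                  vcmax_method = c("simple", "jmax_limited")) {
  cc <- chi_optimal(forcing, params)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  lim <- limitation_factors(cc$ci, kin)
  mprime <- jmax_limitation(lim$mj, params$cstar)
  out <- data.frame(chi = cc$chi, ci = cc$ci, mj = lim$mj, mc = lim$mc,
                    mprime = mprime,
                    lue = phi0_at(params, forcing$tc) * mprime *
                      params$mc_mass)
  if (!is.null(iabs)) {
    out$vcmax_opt <- vcmax_optimal(forcing, params, iabs,
                                   method = match.arg(vcmax_method))
  }
  out
}

#' Gross primary productivity from the light-use-efficiency identity
#'
#' GPP = fAPAR * LUE * PPFD. Units follow the inputs: with PPFD in
#' mol m^-2 period^-1 and LUE in gC mol^-1, GPP is in gC m^-2 period^-1.
#' Annual GPP is the sum of monthly values.
#'
#' @param fapar Fraction of absorbed photosynthetically active radiation,
#'   in \[0, 1\].
#' @param lue Light use efficiency (gC mol^-1 photons).
#' @param ppfd Photosynthetic photon flux density (mol m^-2 period^-1).
#' @return GPP (gC m^-2 period^-1).
#' @examples
#' gpp(0.95, 0.35, 1000)  # 332.5 gC m-2 yr-1
#' @export
gpp <- function(fapar, lue, ppfd) {
  stopifnot(all(is.finite(fapar)), all(is.finite(lue)), all(is.finite(ppfd)),
            all(lue >= 0), all(ppfd >= 0))
  if (any(fapar < 0 | fapar > 1)) {
    stop("fapar must lie in [0, 1]")
  }
  fapar * lue * ppfd
}

#' Optimality-predicted maximum carboxylation rate
#'
#' Vcmax implied by the coordination of the Rubisco- and electron-transport
#' limited rates at the prevailing absorbed light: with `method = "simple"`
#' (default) Vcmax = phi0 * Iabs * mj / mc, so that Ac equals the
#' unlimited electron-transport rate; with `method = "jmax_limited"`
#' Vcmax = phi0 * Iabs * mprime / mc, consistent with the
#' Jmax-limitation-adjusted LUE.
#'
#' @inheritParams chi_optimal
#' @param iabs Absorbed PPFD (umol m^-2 s^-1).
#' @param method `"simple"` or `"jmax_limited"` (see Details).
#' @return Vcmax (umol m^-2 s^-1).
#' @export
vcmax_optimal <- function(forcing, params = photo_params(), iabs,
                          method = c("simple", "jmax_limited")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(iabs)), all(iabs >= 0))
  cc <- chi_optimal(forcing, params)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  lim <- limitation_factors(cc$ci, kin)
  if (any(lim$mc == 0)) {
    stop("sub-compensation conditions: Rubisco limitation factor is zero")
  }
  fac <- if (method == "simple") lim$mj else
    jmax_limitation(lim$mj, params$cstar)
  phi0_at(params, forcing$tc) * iabs * fac / lim$mc
}

#' Jmax implied by the optimality limitation factor
#'
#' The maximum electron transport rate at which the saturating
#' electron-transport function reproduces the Jmax-limitation-adjusted
#' assimilation: Jmax = 4 phi0 Iabs / sqrt(u/(1-u)) with
#' u = (cstar/mj)^(2/3). Returns 0 where mj <= cstar.
#'
#' @inheritParams vcmax_optimal
#' @return Jmax (umol m^-2 s^-1).
#' @export
jmax_implied <- function(forcing, params = photo_params(), iabs) {
  stopifnot(all(is.finite(iabs)), all(iabs >= 0))
  cc <- chi_optimal(forcing, params)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  lim <- limitation_factors(cc$ci, kin)
  u <- (params$cstar / lim$mj)^(2 / 3)
  phi0 <- rep_len(phi0_at(params, forcing$tc), length(lim$mj))
  iabs <- rep_len(iabs, length(lim$mj))
  out <- rep(0, length(lim$mj))
  ok <- lim$mj > params$cstar
  out[ok] <- 4 * phi0[ok] * iabs[ok] / sqrt(u[ok] / (1 - u[ok]))
  out
}

#' Rubisco-limited assimilation
#'
#' Ac = Vcmax (ci - Gammastar)/(ci + K), gross by default; a dark
#' respiration rate may be subtracted via `rd`.
#'
#' @param vcmax Maximum carboxylation rate (umol m^-2 s^-1).
#' @param ci Leaf-internal CO2 partial pressure (Pa).
#' @param kin A kinetics list from [leaf_kinetics()].
#' @param rd Dark respiration to subtract (umol m^-2 s^-1), default 0.
#' @return Assimilation rate (umol m^-2 s^-1).
#' @export
assimilation_ac <- function(vcmax, ci, kin, rd = 0) {
  stopifnot(all(is.finite(vcmax)), all(vcmax >= 0), all(is.finite(ci)),
            all(ci >= 0))
  vcmax * pmax(0, ci - kin$gammastar) / (ci + kin$kmm) - rd
}

#' Electron-transport-limited assimilation
#'
#' Electron transport follows the saturating form
#' \deqn{J = 4\phi_0 I_{abs} / \sqrt{1 + (4\phi_0 I_{abs}/J_{max})^2}}
#' and AJ = (J/4) mj. This same form is used for the trait inversion
#' ([invert_jmax()]) so that forward and inverse calculations are exactly
#' consistent. `jmax = Inf` gives the unlimited rate phi0 * Iabs * mj.
#'
#' @param jmax Maximum electron transport rate (umol m^-2 s^-1); must be
#'   positive (may be `Inf`).
#' @param phi0 Intrinsic quantum yield (mol C mol^-1 photons).
#' @param iabs Absorbed PPFD (umol m^-2 s^-1).
#' @param ci Leaf-internal CO2 partial pressure (Pa).
#' @param kin A kinetics list from [leaf_kinetics()].
#' @param rd Dark respiration to subtract (umol m^-2 s^-1), default 0.
#' @return Assimilation rate (umol m^-2 s^-1).
#' @export
assimilation_aj <- function(jmax, phi0, iabs, ci, kin, rd = 0) {
  stopifnot(all(phi0 > 0), all(is.finite(iabs)), all(iabs >= 0),
            all(is.finite(ci)), all(ci >= 0))
  if (any(!(jmax > 0))) {
    stop("invalid trait: jmax must be positive")
  }
  n <- max(length(jmax), length(phi0), length(iabs), length(ci))
  x <- rep_len(4 * phi0 * iabs, n)
  jmax <- rep_len(jmax, n)
  j <- ifelse(is.infinite(jmax), x, x / sqrt(1 + (x / jmax)^2))
  mj <- pmax(0, ci - kin$gammastar) / (ci + 2 * kin$gammastar)
  (j / 4) * mj - rd
}
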