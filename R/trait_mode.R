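# Conversion of two-point field gas-exchange measurements (Asat at 400 ppm
# CO2, Amax at 2000 ppm CO2 and saturating light) into Vcmax and Jmax,
# aggregation to community-weighted means, and the trait-based LUE.

#' Invert Vcmax from light-saturated assimilation
#'
#' Assuming assimilation at 400 umol mol^-1 CO2 and saturating light is
#' Rubisco-limited, Vcmax = (Asat + Rd)(ci + K)/(ci - Gammastar). The
#' chamber ci is taken as a fixed fraction of ambient ca (default 0.7;
#' measured ci columns, when available, should be preferred). Dark
#' respiration follows the policy Rd = `rd_frac` * Vcmax, which enters the
#' inversion implicitly: Vcmax = Asat / (mc - rd_frac).
#'
#' @param asat Net assimilation at 400 umol mol^-1 CO2 (umol m^-2 s^-1).
#' @param tleaf Leaf/block temperature during measurement (degC).
#' @param co2_meas Chamber CO2 mole fraction (umol mol^-1), default 400.
#' @param patm Pressure (Pa).
#' @param ci_frac ci/ca during the measurement, default 0.7.
#' @param ci Optional measured ci (Pa); overrides `ci_frac` where finite.
#' @param rd_frac Dark respiration as a fraction of Vcmax, default 0.015
#'   (set 0 to ignore respiration).
#' @param params A [photo_params()] object.
#' @return A list with vectors `vcmax`, `rd` (umol m^-2 s^-1), `ci` (Pa)
#'   and `mc` (unitless).
#' @export
invert_vcmax <- function(asat, tleaf, co2_meas = 400, patm = 101325,
                         ci_frac = 0.7, ci = NULL, rd_frac = 0.015,
                         params = photo_params()) {
  stopifnot(all(is.finite(asat)), all(asat > 0), all(is.finite(tleaf)),
            rd_frac >= 0, ci_frac > 0, ci_frac <= 1)
  kin <- leaf_kinetics(tleaf, patm, params)
  ca <- co2_meas * patm * 1e-6
  ci_use <- rep_len(ci_frac * ca, length(asat))
  if (!is.null(ci)) {
    ok <- is.finite(ci)
    ci_use[ok] <- ci[ok]
  }
  if (any(ci_use <= kin$gammastar)) {
    stop("invalid record: chamber ci at or below the compensation point")
  }
  mc <- (ci_use - kin$gammastar) / (ci_use + kin$kmm)
  if (any(mc <= rd_frac)) {
    stop("invalid record: limitation factor does not exceed the ",
         "respiration fraction")
  }
  vcmax <- asat / (mc - rd_frac)
  list(vcmax = vcmax, rd = rd_frac * vcmax, ci = ci_use, mc = mc)
}

#' Invert Jmax from CO2- and light-saturated assimilation
#'
#' At 2000 umol mol^-1 CO2 and saturating light, assimilation is
#' electron-transport limited: AJ = (J/4) mj = Amax + Rd is solved for the
#' electron transport rate J, and Jmax is recovered by inverting the same
#' saturating J(Iabs, Jmax) form used in [assimilation_aj()]. Records
#' whose required J reaches the light-limited asymptote 4 phi0 Iabs have
#' no solution and are returned as `NA` with `flagged = TRUE`.
#'
#' @param amax Net assimilation at 2000 umol mol^-1 CO2 (umol m^-2 s^-1).
#' @param rd Dark respiration (umol m^-2 s^-1), typically from
#'   [invert_vcmax()].
#' @param tleaf Leaf/block temperature (degC).
#' @param co2_meas Chamber CO2 (umol mol^-1), default 2000.
#' @param ppfd_meas Chamber PPFD (umol m^-2 s^-1), default 2000.
#' @param patm Pressure (Pa).
#' @param ci_frac ci/ca at saturating CO2, default 0.9 (stomatal
#'   limitation weakens at high CO2).
#' @param ci Optional measured ci (Pa); overrides `ci_frac` where finite.
#' @param params A [photo_params()] object.
#' @return A list with vectors `jmax` (`NA` where flagged), `j`, `mj` and
#'   logical `flagged`.
#' @export
invert_jmax <- function(amax, rd, tleaf, co2_meas = 2000, ppfd_meas = 2000,
                        patm = 101325, ci_frac = 0.9, ci = NULL,
                        params = photo_params()) {
  stopifnot(all(is.finite(amax)), all(is.finite(rd)), all(rd >= 0),
            all(is.finite(tleaf)), all(ppfd_meas > 0))
  kin <- leaf_kinetics(tleaf, patm, params)
  ca <- co2_meas * patm * 1e-6
  ci_use <- rep_len(ci_frac * ca, length(amax))
  if (!is.null(ci)) {
    ok <- is.finite(ci)
    ci_use[ok] <- ci[ok]
  }
  if (any(ci_use <= kin$gammastar)) {
    stop("invalid record: chamber ci at or below the compensation point")
  }
  mj <- (ci_use - kin$gammastar) / (ci_use + 2 * kin$gammastar)
  agross <- amax + rd
  j <- 4 * agross / mj
  jsat <- rep_len(4 * phi0_at(params, tleaf) * ppfd_meas, length(amax))
  flagged <- !(j > 0) | j >= jsat
  jmax <- rep(NA_real_, length(amax))
  ok <- !flagged
  jmax[ok] <- jsat[ok] / sqrt((jsat[ok] / j[ok])^2 - 1)
  list(jmax = jmax, j = j, mj = mj, flagged = flagged)
}

#' Normalise photosynthetic rates between temperatures
#'
#' Applies [arrhenius_scale()] with trait-specific activation energies
#' (from the constants table) to the `vcmax`, `jmax` and `rd` columns of a
#' trait table. The 25 degC round trip is exact.
#'
#' @param traits A data frame with any of the columns `vcmax`, `jmax`,
#'   `rd`.
#' @param tc_from Temperature the rates are currently at (degC).
#' @param tc_to Target temperature (degC).
#' @return The trait table with rates rescaled.
#' @export
normalize_to_temperature <- function(traits, tc_from, tc_to) {
  k <- kinetic_constants()
  dha <- c(vcmax = k$dha_vcmax_j_mol, jmax = k$dha_jmax_j_mol,
           rd = k$dha_rd_j_mol)
  for (col in intersect(names(dha), names(traits))) {
    traits[[col]] <- arrhenius_scale(traits[[col]], dha[[col]],
                                     tc_to, tc_from)
  }
  traits
}

#' Derive a trait table from gas-exchange records
#'
#' Runs [invert_vcmax()] and [invert_jmax()] on every record of a
#' gas-exchange table, normalises the recovered rates to 25 degC and to
#' the site growth temperature, and flags unusable records
#' (Amax < Asat, non-positive rates, or no Jmax solution). A post-hoc
#' consistency check flags records whose fitted traits imply Ac > AJ at
#' the Asat measurement conditions (the Rubisco-limitation assumption
#' would then be violated).
#'
#' @param gasex Data frame with columns `species`, `plot`, `asat`, `amax`,
#'   `tleaf`, `ppfd_meas`, `leaf_class`, `basal_area_frac` (optional
#'   measured-ci columns `ci_sat`, `ci_max` in Pa are honoured).
#' @param tgrowth Site growth temperature (degC): the mean daytime
#'   temperature of the forcing series.
#' @param patm Pressure (Pa).
#' @param ci_frac_sat,ci_frac_max ci/ca assumed at 400 and 2000 umol
#'   mol^-1 CO2.
#' @param rd_frac Respiration policy passed to [invert_vcmax()].
#' @param params A [photo_params()] object.
#' @return A data frame with per-record `vcmax_gt`, `jmax_gt` (at growth
#'   temperature), `vcmax25`, `jmax25`, `rd25`, `basal_area_frac`,
#'   `leaf_class` and a character `flag` ("" when clean). The number of
#'   flagged records is attached as attribute `n_flagged`.
#' @export
derive_traits <- function(gasex, tgrowth, patm = 101325,
                          ci_frac_sat = 0.7, ci_frac_max = 0.9,
                          rd_frac = 0.015, params = photo_params()) {
  need <- c("species", "plot", "asat", "amax", "tleaf", "ppfd_meas",
            "leaf_class", "basal_area_frac")
  miss <- setdiff(need, names(gasex))
  if (length(miss) > 0) {
    stop("gas-exchange table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(gasex)
  flag <- rep("", n)
  bad <- !is.finite(gasex$asat) | !is.finite(gasex$amax) |
    gasex$asat <= 0 | gasex$amax < gasex$asat
  flag[bad] <- "invalid_gas_exchange"

  vcmax <- jmax <- rd <- rep(NA_real_, n)
  ok <- !bad
  if (any(ok)) {
    vc <- invert_vcmax(gasex$asat[ok], gasex$tleaf[ok], patm = patm,
                       ci_frac = ci_frac_sat,
                       ci = if ("ci_sat" %in% names(gasex))
                         gasex$ci_sat[ok] else NULL,
                       rd_frac = rd_frac, params = params)
    jm <- invert_jmax(gasex$amax[ok], vc$rd, gasex$tleaf[ok],
                      ppfd_meas = gasex$ppfd_meas[ok], patm = patm,
                      ci_frac = ci_frac_max,
                      ci = if ("ci_max" %in% names(gasex))
                        gasex$ci_max[ok] else NULL,
                      params = params)
    vcmax[ok] <- vc$vcmax
    rd[ok] <- vc$rd
    jmax[ok] <- jm$jmax
    idx <- which(ok)
    flag[idx[jm$flagged]] <- "jmax_no_solution"
    # post-hoc: Asat should be Rubisco-limited (Ac <= AJ at 400 ppm)
    kin <- leaf_kinetics(gasex$tleaf[ok], patm, params)
    ac <- assimilation_ac(vc$vcmax, vc$ci, kin)
    aj <- rep(Inf, sum(ok))
    has_j <- !jm$flagged
    if (any(has_j)) {
      kin_sub <- lapply(kin, function(x) rep_len(x, sum(ok))[has_j])
      aj[has_j] <- assimilation_aj(jm$jmax[has_j],
                                   phi0_at(params,
                                           gasex$tleaf[ok][has_j]),
                                   gasex$ppfd_meas[ok][has_j],
                                   vc$ci[has_j], kin_sub)
    }
    not_rubisco <- flag[idx] == "" & ac > aj * (1 + 1e-9)
    flag[idx[not_rubisco]] <- "asat_not_rubisco_limited"
  }

  k <- kinetic_constants()
  scale_na <- function(x, dha, tc_to, tc_from) {
    out <- rep(NA_real_, length(x))
    i <- is.finite(x)
    if (any(i)) {
      out[i] <- arrhenius_scale(x[i], dha, rep_len(tc_to, length(x))[i],
                                rep_len(tc_from, length(x))[i])
    }
    out
  }
  vcmax25 <- scale_na(vcmax, k$dha_vcmax_j_mol, 25, gasex$tleaf)
  jmax25 <- scale_na(jmax, k$dha_jmax_j_mol, 25, gasex$tleaf)
  rd25 <- scale_na(rd, k$dha_rd_j_mol, 25, gasex$tleaf)
  out <- data.frame(
    species = gasex$species, plot = gasex$plot,
    leaf_class = gasex$leaf_class,
    basal_area_frac = gasex$basal_area_frac,
    vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25,
    vcmax_gt = scale_na(vcmax25, k$dha_vcmax_j_mol, tgrowth, 25),
    jmax_gt = scale_na(jmax25, k$dha_jmax_j_mol, tgrowth, 25),
    rd_gt = scale_na(rd25, k$dha_rd_j_mol, tgrowth, 25),
    flag = flag,
    stringsAsFactors = FALSE
  )
  attr(out, "n_flagged") <- sum(flag != "")
  attr(out, "tgrowth") <- tgrowth
  out
}

#' Community-weighted mean traits
#'
#' Basal-area-weighted arithmetic mean of the per-species rates, using sun
#' leaves only. Weights cover the sampled fraction of plot basal area
#' (~80% in the underlying field protocol) and are renormalised to sum to
#' one over the retained records; flagged records are excluded.
#'
#' @param traits A trait table from [derive_traits()].
#' @param sun_only Keep only `leaf_class == "sun"` records (default
#'   `TRUE`).
#' @return A list of class `trait_cwm` with the weighted means `vcmax25`,
#'   `jmax25`, `rd25`, `vcmax_gt`, `jmax_gt`, `rd_gt`, plus `n_used` and
#'   `n_excluded`.
#' @export
community_weighted_mean <- function(traits, sun_only = TRUE) {
  keep <- traits$flag == ""
  if (sun_only) keep <- keep & traits$leaf_class == "sun"
  used <- traits[keep, , drop = FALSE]
  w <- used$basal_area_frac
  if (nrow(used) == 0 || !any(is.finite(w)) || sum(w) <= 0) {
    stop("community_weighted_mean(): no usable records with positive weight")
  }
  w <- w / sum(w)
  wm <- function(x) sum(w * x)
  structure(list(vcmax25 = wm(used$vcmax25), jmax25 = wm(used$jmax25),
                 rd25 = wm(used$rd25), vcmax_gt = wm(used$vcmax_gt),
                 jmax_gt = wm(used$jmax_gt), rd_gt = wm(used$rd_gt),
                 tgrowth = attr(traits, "tgrowth"),
                 n_used = nrow(used), n_excluded = nrow(traits) - nrow(used)),
            class = "trait_cwm")
}

#' Light use efficiency from measured traits
#'
#' LUE of the big-leaf canopy when Vcmax and Jmax are prescribed (from
#' field measurements) instead of optimality-predicted: gross assimilation
#' min(Ac, AJ) at the canopy absorbed light, divided by the absorbed
#' photon flux, times the molar mass of carbon. The ci/ca ratio is still
#' taken from the least-cost prediction ([chi_optimal()]), so that the
#' trait-based and optimality LUE paths coincide exactly when the supplied
#' traits are the optimality-implied ones.
#'
#' @param vcmax,jmax Canopy photosynthetic capacity at the operating
#'   temperature (umol m^-2 s^-1). `jmax = Inf` disables the
#'   electron-transport ceiling.
#' @inheritParams chi_optimal
#' @param iabs Absorbed PPFD (umol m^-2 s^-1).
#' @return LUE (gC mol^-1 photons), vectorised over forcing records.
#' @export
lue_from_traits <- function(vcmax, jmax, forcing, params = photo_params(),
                            iabs) {
  stopifnot(all(is.finite(vcmax)), all(vcmax >= 0),
            all(is.finite(iabs)), all(iabs >= 0))
  cc <- chi_optimal(forcing, params)
  kin <- leaf_kinetics(forcing$tc, forcing$patm, params)
  n <- length(cc$ci)
  vcmax <- rep_len(vcmax, n); jmax <- rep_len(jmax, n)
  iabs <- rep_len(iabs, n)
  ac <- assimilation_ac(vcmax, cc$ci, kin)
  aj <- assimilation_aj(jmax, phi0_at(params, forcing$tc), iabs, cc$ci, kin)
  a <- pmax(0, pmin(ac, aj))
  ifelse(iabs > 0, a / iabs * params$mc_mass, 0)
}
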