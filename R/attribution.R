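# The factorial experiment engine: GPP experiments that swap LUE, fAPAR
# and PPFD sources; a lookup-table LUE product emulator; the discrepancy
# decomposition ledger; composite-PFT GPP; and forcing-bias reporting.

.experiment_table <- list(
  Pmodel_null = list(lue_source = "optimality",
                     fapar_source = "satellite_filtered",
                     ppfd_source = "product"),
  Pmodel_P    = list(lue_source = "optimality",
                     fapar_source = "satellite_filtered",
                     ppfd_source = "field"),
  Pmodel_Pf   = list(lue_source = "optimality",
                     fapar_source = "field",
                     ppfd_source = "field"),
  Pmodel_PfL  = list(lue_source = "traits",
                     fapar_source = "field",
                     ppfd_source = "field"),
  product     = list(lue_source = "lookup",
                     fapar_source = "satellite_filtered",
                     ppfd_source = "product")
)

#' Define a GPP experiment
#'
#' An experiment binds the three inputs of the light-use-efficiency
#' identity to sources. The canonical factorial designs are built in:
#' `Pmodel_PfL` (trait LUE, field fAPAR, field PPFD), `Pmodel_Pf`
#' (optimality LUE, field fAPAR, field PPFD), `Pmodel_P` (optimality LUE,
#' filtered satellite fAPAR, field PPFD), `Pmodel_null` (optimality LUE,
#' filtered satellite fAPAR, product PPFD) and `product` (lookup-table
#' LUE, filtered satellite fAPAR, product PPFD). A `"custom"` experiment
#' may bind sources freely.
#'
#' @param name Experiment name (one of the canonical names, or
#'   `"custom"`).
#' @param lue_source,fapar_source,ppfd_source Bindings for a custom
#'   experiment: `lue_source` in optimality/traits/lookup, `fapar_source`
#'   in field/satellite_filtered, `ppfd_source` in field/product.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(name, lue_source = NULL, fapar_source = NULL,
                            ppfd_source = NULL) {
  if (name %in% names(.experiment_table)) {
    spec <- .experiment_table[[name]]
    # canonical names imply fixed bindings; reject contradictions
    for (f in c("lue_source", "fapar_source", "ppfd_source")) {
      given <- get(f)
      if (!is.null(given) && given != spec[[f]]) {
        stop("experiment '", name, "' fixes ", f, " = '", spec[[f]],
             "'; got '", given, "'")
      }
    }
  } else if (name == "custom") {
    spec <- list(lue_source = match.arg(lue_source,
                                        c("optimality", "traits", "lookup")),
                 fapar_source = match.arg(fapar_source,
                                          c("field", "satellite_filtered")),
                 ppfd_source = match.arg(ppfd_source, c("field", "product")))
  } else {
    stop("unknown experiment name '", name, "'; use one of ",
         paste(names(.experiment_table), collapse = ", "), " or 'custom'")
  }
  structure(c(list(name = name), spec), class = "experiment_spec")
}

#' Biome parameters for the lookup-table LUE emulator
#'
#' Parameter set of a prescribed-LUE satellite-product algorithm: a
#' biome-specific maximum light use efficiency reduced by linear ramp
#' functions of minimum temperature and vapour pressure deficit. Defaults
#' follow the published evergreen-broadleaf-forest row of the MOD17
#' biome-properties lookup table.
#'
#' @param emax_gc_mj Maximum LUE (gC per MJ absorbed PAR), default 1.268.
#' @param tmin_ramp Two temperatures (degC): full stress at and below the
#'   first, no stress at and above the second. Default c(-8, 9.09).
#' @param vpd_ramp Two VPD values (Pa): no stress at and below the first,
#'   full stress at and above the second. Default c(800, 3100).
#' @param par_mol_per_mj Photon content of PAR (mol photons per MJ),
#'   default 4.6, used to express the LUE in gC per mol photons.
#' @return A list of class `biome_params`; element `emax_gc_mol` carries
#'   the converted maximum LUE.
#' @export
biome_params <- function(emax_gc_mj = 1.268, tmin_ramp = c(-8, 9.09),
                         vpd_ramp = c(800, 3100), par_mol_per_mj = 4.6) {
  stopifnot(emax_gc_mj > 0, length(tmin_ramp) == 2,
            length(vpd_ramp) == 2, par_mol_per_mj > 0)
  if (!(tmin_ramp[1] < tmin_ramp[2]) || !(vpd_ramp[1] < vpd_ramp[2])) {
    stop("malformed ramp bounds: lower bound must be below upper bound")
  }
  structure(list(emax_gc_mj = emax_gc_mj,
                 emax_gc_mol = emax_gc_mj / par_mol_per_mj,
                 tmin_ramp = tmin_ramp, vpd_ramp = vpd_ramp,
                 par_mol_per_mj = par_mol_per_mj),
            class = "biome_params")
}

#' Lookup-table light use efficiency
#'
#' LUE = emax * ramp(Tmin) * ramp(VPD), with linear ramps clamped to
#' \[0, 1\]: the temperature scalar rises from 0 to 1 across `tmin_ramp`,
#' the VPD scalar falls from 1 to 0 across `vpd_ramp`.
#'
#' @param tc Temperature (degC) entering the minimum-temperature ramp.
#' @param vpd Vapour pressure deficit (Pa).
#' @param biome A [biome_params()] object.
#' @return LUE (gC mol^-1 photons).
#' @export
lookup_lue <- function(tc, vpd, biome = biome_params()) {
  stopifnot(all(is.finite(tc)), all(is.finite(vpd)))
  ramp01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))
  s_t <- ramp01(tc, biome$tmin_ramp[1], biome$tmin_ramp[2])
  s_v <- 1 - ramp01(vpd, biome$vpd_ramp[1], biome$vpd_ramp[2])
  biome$emax_gc_mol * s_t * s_v
}

impute_climatology <- function(clim12, what) {
  ok <- is.finite(clim12)
  if (!any(ok)) {
    stop("configuration error: fAPAR climatology for binding '", what,
         "' has no data in any month")
  }
  clim12[!ok] <- mean(clim12[ok])
  clim12
}

#' Run a GPP experiment
#'
#' Computes monthly GPP = fAPAR * LUE * PPFD with the input sources bound
#' by the experiment spec, sums to calendar-year totals, and averages the
#' annual sums over the forcing years. All experiments share this single
#' code path; only the bound inputs differ. Months whose fAPAR
#' climatology is missing receive the annual mean of the available months
#' (the count is reported).
#'
#' @param spec An [experiment_spec()].
#' @param inputs A list with elements `forcing` (data frame: `year`,
#'   `month`, `tc`, `vpd`, `co2`, `patm`, `ppfd`, and `ppfd_product` when
#'   a product PPFD binding is used), `fapar_field` and/or
#'   `fapar_satellite` (12-vector climatologies), `traits` (a
#'   [community_weighted_mean()] result or list with `vcmax25`, `jmax25`)
#'   when trait LUE is bound, and `biome` (a [biome_params()]) when
#'   lookup LUE is bound.
#' @param params A [photo_params()] object.
#' @return A list of class `gpp_experiment`: `gpp` (mean annual GPP,
#'   MgC ha^-1 yr^-1), `annual` (named per-year vector, MgC ha^-1 yr^-1),
#'   `monthly` (data frame with the bound inputs and monthly GPP in
#'   gC m^-2 month^-1), and `spec`.
#' @export
run_experiment <- function(spec, inputs, params = photo_params()) {
  stopifnot(inherits(spec, "experiment_spec"))
  forcing <- inputs$forcing
  if (is.null(forcing)) {
    stop("configuration error: experiment '", spec$name,
         "' requires input binding 'forcing'")
  }
  check_forcing(forcing)
  stopifnot(all(c("year", "month", "ppfd") %in% names(forcing)),
            all(forcing$ppfd >= 0))

  fap_clim <- switch(spec$fapar_source,
                     field = inputs$fapar_field,
                     satellite_filtered = inputs$fapar_satellite)
  if (is.null(fap_clim)) {
    stop("configuration error: experiment '", spec$name,
         "' requires input binding 'fapar_", spec$fapar_source, "'")
  }
  stopifnot(length(fap_clim) == 12)
  fap_clim <- impute_climatology(fap_clim, spec$fapar_source)
  fap <- fap_clim[forcing$month]

  ppfd <- switch(spec$ppfd_source,
                 field = forcing$ppfd,
                 product = forcing$ppfd_product)
  if (is.null(ppfd)) {
    stop("configuration error: experiment '", spec$name,
         "' requires input binding 'ppfd_product' in the forcing table")
  }

  lue_m <- switch(
    spec$lue_source,
    optimality = lue_optimal(forcing, params),
    traits = {
      traits <- inputs$traits
      if (is.null(traits)) {
        stop("configuration error: experiment '", spec$name,
             "' requires input binding 'traits'")
      }
      k <- kinetic_constants()
      vc <- arrhenius_scale(traits$vcmax25, k$dha_vcmax_j_mol, forcing$tc)
      jm <- arrhenius_scale(traits$jmax25, k$dha_jmax_j_mol, forcing$tc)
      iabs <- mean_iabs_umol(fap, ppfd, forcing$year, forcing$month)
      lue_from_traits(vc, jm, forcing, params, iabs)
    },
    lookup = {
      biome <- inputs$biome
      if (is.null(biome)) {
        stop("configuration error: experiment '", spec$name,
             "' requires input binding 'biome'")
      }
      lookup_lue(forcing$tc, forcing$vpd, biome)
    })

  g_month <- gpp(fap, lue_m, ppfd)  # gC m-2 month-1
  annual_gc <- tapply(g_month, forcing$year, sum)
  annual <- gc_m2_to_mgc_ha(as.numeric(annual_gc))
  names(annual) <- names(annual_gc)
  structure(list(gpp = mean(annual), annual = annual,
                 monthly = data.frame(year = forcing$year,
                                      month = forcing$month,
                                      fapar = fap, lue = lue_m,
                                      ppfd = ppfd, gpp = g_month),
                 spec = spec),
            class = "gpp_experiment")
}

#' Decompose the GPP data-model discrepancy
#'
#' Splits the gap between biometric GPP and a product GPP into four
#' telescoping terms: unresolved (biometric - Pmodel_PfL), traits
#' (Pmodel_PfL - Pmodel_Pf), fAPAR (Pmodel_Pf - Pmodel_P) and
#' trait-optimisation (Pmodel_P - product). The terms sum to
#' biometric - product exactly; each is also expressed as a percentage of
#' biometric GPP.
#'
#' @param biometric,pfl,pf,p,product Site annual GPP values
#'   (MgC ha^-1 yr^-1) from the field measurement, the three Pmodel
#'   experiments and the product (lookup emulator or an externally
#'   supplied site scalar).
#' @param product_source Label recording where the product value came
#'   from (`"lookup_emulator"` or `"external"`).
#' @return An object of class `attribution_ledger`: a data frame with
#'   columns `term`, `gpp` and `pct_of_biometric`, with the five inputs,
#'   the total and the product source attached as attributes.
#' @examples
#' decompose_discrepancy(40, 32, 28, 20, 15)  # terms 8, 4, 8, 5
#' @export
decompose_discrepancy <- function(biometric, pfl, pf, p, product,
                                  product_source = "lookup_emulator") {
  vals <- c(biometric = biometric, pfl = pfl, pf = pf, p = p,
            product = product)
  stopifnot(all(is.finite(vals)))
  terms <- c(unresolved = biometric - pfl,
             traits = pfl - pf,
             fapar = pf - p,
             optimisation = p - product)
  out <- data.frame(term = names(terms), gpp = as.numeric(terms),
                    pct_of_biometric = 100 * as.numeric(terms) / biometric,
                    stringsAsFactors = FALSE)
  structure(out, class = c("attribution_ledger", "data.frame"),
            inputs = vals, total = biometric - product,
            product_source = product_source)
}

#' @export
print.attribution_ledger <- function(x, ...) {
  cat("GPP data-model discrepancy ledger (MgC ha^-1 yr^-1)\n")
  inp <- attr(x, "inputs")
  cat(sprintf("  biometric %.2f | PfL %.2f | Pf %.2f | P %.2f | product %.2f (%s)\n",
              inp["biometric"], inp["pfl"], inp["pf"], inp["p"],
              inp["product"], attr(x, "product_source")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("  total discrepancy: %.3f\n", attr(x, "total")))
  invisible(x)
}

#' Gridcell and forest-only GPP from per-PFT values
#'
#' `composite_gpp()` is the cover-weighted gridcell total
#' sum(fraction * GPP); `forest_only_gpp()` is the cover-weighted mean
#' over the forest PFTs - the GPP the gridcell would have if it were
#' entirely forest. Cover fractions must be non-negative and sum to at
#' most 1 (the residual is bare ground).
#'
#' @param fractions Per-PFT land-cover fractions.
#' @param gpp_per_pft Per-PFT GPP (any consistent unit).
#' @param is_forest Logical vector marking forest PFTs.
#' @return A single GPP value.
#' @examples
#' composite_gpp(c(0.5, 0.5), c(20, 10))          # 15
#' forest_only_gpp(c(0.5, 0.5), c(20, 10), c(TRUE, FALSE))  # 20
#' @export
composite_gpp <- function(fractions, gpp_per_pft) {
  stopifnot(length(fractions) == length(gpp_per_pft),
            all(is.finite(fractions)), all(is.finite(gpp_per_pft)))
  if (any(fractions < 0)) stop("land-cover fractions must be non-negative")
  if (sum(fractions) > 1 + 1e-9) {
    stop("land-cover fractions must sum to at most 1")
  }
  sum(fractions * gpp_per_pft)
}

#' @rdname composite_gpp
#' @export
forest_only_gpp <- function(fractions, gpp_per_pft, is_forest) {
  stopifnot(length(is_forest) == length(fractions), is.logical(is_forest))
  if (any(fractions < 0)) stop("land-cover fractions must be non-negative")
  f <- fractions[is_forest]
  if (sum(f) <= 0) stop("no forest cover in the gridcell")
  sum(f * gpp_per_pft[is_forest]) / sum(f)
}

#' Compare two forcing series and their GPP impact
#'
#' For each shared climate variable, reports the mean bias and RMSE of
#' series `b` relative to series `a` and the monthly-mean profile of
#' both, plus a GPP-sensitivity column: annual optimality-model GPP
#' recomputed with that single variable swapped from `b` into `a`.
#'
#' @param a,b Forcing data frames aligned on (`year`, `month`), e.g.
#'   field measurements and a reanalysis product.
#' @param vars Variables to compare (subset of the forcing columns).
#' @param fapar A 12-vector fAPAR climatology used for the sensitivity
#'   runs (default 1, i.e. per unit of absorbed fraction).
#' @param params A [photo_params()] object.
#' @return A list with `stats` (variable, bias, rmse,
#'   gpp_base, gpp_swapped, gpp_delta) and `monthly` (variable, month,
#'   mean_a, mean_b).
#' @export
forcing_bias_report <- function(a, b, vars = c("tc", "vpd", "ppfd"),
                                fapar = rep(1, 12),
                                params = photo_params()) {
  key_a <- paste(a$year, a$month); key_b <- paste(b$year, b$month)
  if (length(key_a) != length(key_b) || any(key_a != key_b)) {
    stop("forcing series are misaligned: (year, month) keys differ")
  }
  miss <- setdiff(vars, intersect(names(a), names(b)))
  if (length(miss) > 0) {
    stop("variable(s) absent from both series: ", paste(miss, collapse = ", "))
  }
  annual_gpp <- function(forc) {
    lue_m <- lue_optimal(forc, params)
    g <- gpp(fapar[forc$month], lue_m, forc$ppfd)
    mean(gc_m2_to_mgc_ha(as.numeric(tapply(g, forc$year, sum))))
  }
  base <- annual_gpp(a)
  stats <- list(); monthly <- list()
  for (v in vars) {
    d <- b[[v]] - a[[v]]
    swapped <- a
    swapped[[v]] <- b[[v]]
    g_sw <- annual_gpp(swapped)
    stats[[v]] <- data.frame(variable = v, bias = mean(d),
                             rmse = sqrt(mean(d^2)),
                             gpp_base = base, gpp_swapped = g_sw,
                             gpp_delta = g_sw - base)
    monthly[[v]] <- data.frame(
      variable = v, month = 1:12,
      mean_a = as.numeric(tapply(a[[v]], factor(a$month, levels = 1:12),
                                 mean)),
      mean_b = as.numeric(tapply(b[[v]], factor(b$month, levels = 1:12),
                                 mean)))
  }
  out_stats <- do.call(rbind, stats); rownames(out_stats) <- NULL
  out_monthly <- do.call(rbind, monthly); rownames(out_monthly) <- NULL
  list(stats = out_stats, monthly = out_monthly)
}
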