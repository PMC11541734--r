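# Handling of fAPAR series from in-situ (hemispherical photography) and
# satellite sources: QC-flag cloud filtering, monthly climatologies,
# annual means, and the filtering-induced bias.

.cloud_states <- c("00", "01", "10", "11")  # clear / significant / mixed / unset

#' Cloud-filtering policy for satellite fAPAR
#'
#' Named sets of retained two-bit cloud-QC states:
#' `"all"` keeps every state, `"exclude_significant"` removes
#' significant-cloud retrievals (keeping clear, mixed-cloud and unset
#' records - the filter applied to the satellite product in practice),
#' and `"clear_only"` keeps clear-sky retrievals only. The retained sets
#' are nested: clear_only < exclude_significant < all.
#'
#' @param name One of `"exclude_significant"` (default), `"clear_only"`,
#'   `"all"`.
#' @return A list of class `fapar_policy` with elements `name` and
#'   `allowed`.
#' @export
fapar_policy <- function(name = c("exclude_significant", "clear_only",
                                  "all")) {
  name <- match.arg(name)
  allowed <- switch(name,
                    all = .cloud_states,
                    exclude_significant = c("00", "10", "11"),
                    clear_only = "00")
  structure(list(name = name, allowed = allowed), class = "fapar_policy")
}

check_fapar_obs <- function(obs) {
  need <- c("site", "date", "value", "source", "cloud_state")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) {
    stop("fAPAR table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(obs$cloud_state %in% .cloud_states)) {
    stop("cloud_state must be one of: ", paste(.cloud_states, collapse = ", "))
  }
  if (any(!is.finite(obs$value) | obs$value < 0 | obs$value > 1)) {
    stop("fAPAR values must lie in [0, 1]")
  }
  invisible(obs)
}

obs_year <- function(obs) as.integer(substr(obs$date, 1, 4))
obs_month <- function(obs) as.integer(substr(obs$date, 6, 7))

#' Filter fAPAR observations by cloud state
#'
#' Subsets an observation table to the cloud states retained by a policy.
#' The number of removed records per calendar month is attached as
#' attribute `n_removed_by_month`.
#'
#' @param obs Observation data frame with columns `site`, `date`
#'   (ISO `yyyy-mm` or `yyyy-mm-dd`), `value`, `source`, `cloud_state`.
#' @param policy A [fapar_policy()].
#' @return The filtered data frame.
#' @export
filter_fapar <- function(obs, policy = fapar_policy()) {
  check_fapar_obs(obs)
  keep <- obs$cloud_state %in% policy$allowed
  removed <- table(factor(obs_month(obs)[!keep], levels = 1:12))
  out <- obs[keep, , drop = FALSE]
  attr(out, "n_removed_by_month") <- as.integer(removed)
  out
}

#' Monthly fAPAR climatology
#'
#' Mean fAPAR per calendar month across the requested years. Months with
#' no surviving observation are reported as `NA` - never silently
#' imputed.
#'
#' @param obs Observation data frame (typically already filtered).
#' @param years Optional year range to retain (vector of years).
#' @return A data frame with columns `month` (1-12), `fapar` (`NA` when
#'   missing) and `n` (observation count).
#' @export
monthly_climatology <- function(obs, years = NULL) {
  check_fapar_obs(obs)
  yr <- obs_year(obs)
  if (!is.null(years)) obs <- obs[yr %in% years, , drop = FALSE]
  m <- obs_month(obs)
  means <- tapply(obs$value, factor(m, levels = 1:12), mean)
  n <- tapply(obs$value, factor(m, levels = 1:12), length)
  data.frame(month = 1:12, fapar = as.numeric(means),
             n = ifelse(is.na(n), 0L, as.integer(n)))
}

#' Annual mean fAPAR from a climatology
#'
#' Mean over the available months; missing months are counted and
#' reported, not gap-filled (gap-filling would discard most of the rainy
#' season at cloudy sites, which is exactly the bias this function is
#' used to expose).
#'
#' @param clim A climatology from [monthly_climatology()].
#' @return A list with `mean`, `n_months` (months available) and
#'   `missing` (month numbers with no data).
#' @export
annual_mean_fapar <- function(clim) {
  ok <- is.finite(clim$fapar)
  if (!any(ok)) stop("annual_mean_fapar(): all months are missing")
  list(mean = mean(clim$fapar[ok]), n_months = sum(ok),
       missing = clim$month[!ok])
}

#' In-situ versus satellite fAPAR bias report
#'
#' Percent bias of the (cloud-filtered) satellite annual-mean fAPAR
#' relative to the in-situ series, per site and averaged over sites with
#' equal weight, plus the monthly climatology profiles of both sources.
#'
#' @param insitu,satellite Observation data frames covering overlapping
#'   periods (may contain several sites).
#' @param policy Cloud filter applied to the satellite series.
#' @param years Optional year range.
#' @return A list with `site_bias` (data frame: site, insitu_mean,
#'   satellite_mean, bias_pct, n_missing_sat), `mean_bias_pct`, and
#'   `monthly` (long data frame of both profiles).
#' @export
fapar_bias_report <- function(insitu, satellite, policy = fapar_policy(),
                              years = NULL) {
  check_fapar_obs(insitu); check_fapar_obs(satellite)
  sites <- sort(unique(insitu$site))
  if (!any(sites %in% satellite$site)) {
    stop("fapar_bias_report(): no overlapping sites between series")
  }
  sat_f <- filter_fapar(satellite, policy)
  rows <- list(); monthly <- list()
  for (s in intersect(sites, unique(satellite$site))) {
    ci <- monthly_climatology(insitu[insitu$site == s, ], years)
    cs <- monthly_climatology(sat_f[sat_f$site == s, ], years)
    ai <- annual_mean_fapar(ci); as_ <- annual_mean_fapar(cs)
    rows[[s]] <- data.frame(
      site = s, insitu_mean = ai$mean, satellite_mean = as_$mean,
      bias_pct = 100 * (ai$mean - as_$mean) / ai$mean,
      n_missing_sat = length(as_$missing))
    monthly[[s]] <- data.frame(site = s, month = 1:12,
                               insitu = ci$fapar, satellite = cs$fapar)
  }
  site_bias <- do.call(rbind, rows)
  rownames(site_bias) <- NULL
  list(site_bias = site_bias,
       mean_bias_pct = mean(site_bias$bias_pct),
       monthly = do.call(rbind, monthly))
}
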