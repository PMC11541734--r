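# Carbon-isotope derivation of the ci/ca ratio from leaf delta13C, for
# comparison with the optimality-predicted chi.

#' Photosynthetic carbon isotope discrimination
#'
#' Discrimination against 13C during photosynthesis, from the leaf and
#' atmospheric isotope ratios (both permil vs VPDB):
#' \deqn{\Delta^{13}C = (\delta_{air} - \delta_{leaf}) /
#'   (1 + \delta_{leaf}/1000)}
#'
#' @param delta_leaf Leaf delta13C (permil).
#' @param delta_air Atmospheric delta13C (permil), default -8 (a modern
#'   tropospheric value; a year-resolved series can be supplied instead).
#' @return Discrimination Delta13C (permil).
#' @examples
#' isotope_discrimination(-28, -8)  # ~20.58 permil
#' @export
isotope_discrimination <- function(delta_leaf, delta_air = -8) {
  stopifnot(all(is.finite(delta_leaf)), all(is.finite(delta_air)))
  if (any(delta_leaf <= -1000)) {
    stop("delta_leaf of -1000 permil or below is undefined")
  }
  (delta_air - delta_leaf) / (1 + delta_leaf / 1000)
}

#' ci/ca from isotope discrimination
#'
#' The simple (mesophyll-implicit) discrimination model
#' Delta13C = a + (b - a) * chi inverted for chi, with a the diffusive and
#' b the carboxylation fractionation. Values falling outside (0, 1) are
#' clamped and flagged rather than dropped.
#'
#' @param big_delta Discrimination Delta13C (permil).
#' @param a Diffusive fractionation (permil), default 4.4.
#' @param b Carboxylation fractionation (permil), default 27.
#' @return A data frame with columns `chi` (clamped to \[0, 1\]),
#'   `chi_raw` and logical `flagged`.
#' @examples
#' chi_from_discrimination(20.576)  # chi ~ 0.716
#' @export
chi_from_discrimination <- function(big_delta, a = 4.4, b = 27) {
  stopifnot(all(is.finite(big_delta)), is.finite(a), is.finite(b))
  if (b <= a) stop("carboxylation fractionation b must exceed a")
  raw <- (big_delta - a) / (b - a)
  data.frame(chi = pmin(1, pmax(0, raw)), chi_raw = raw,
             flagged = raw < 0 | raw > 1)
}

#' Derive ci/ca for an isotope table
#'
#' Convenience wrapper joining [isotope_discrimination()] and
#' [chi_from_discrimination()] over a per-species isotope table.
#'
#' @param iso Data frame with columns `species`, `plot`, `delta13c_leaf`
#'   and optionally `delta13c_air`.
#' @inheritParams chi_from_discrimination
#' @param delta_air Atmospheric delta13C used where the table has no
#'   `delta13c_air` column.
#' @return The input table with `big_delta`, `chi_isotope` and `flagged`
#'   columns appended.
#' @export
derive_chi_isotope <- function(iso, a = 4.4, b = 27, delta_air = -8) {
  need <- c("species", "plot", "delta13c_leaf")
  miss <- setdiff(need, names(iso))
  if (length(miss) > 0) {
    stop("isotope table is missing column(s): ", paste(miss, collapse = ", "))
  }
  air <- if ("delta13c_air" %in% names(iso)) iso$delta13c_air else delta_air
  iso$big_delta <- isotope_discrimination(iso$delta13c_leaf, air)
  cf <- chi_from_discrimination(iso$big_delta, a, b)
  iso$chi_isotope <- cf$chi
  iso$flagged <- cf$flagged
  iso
}
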