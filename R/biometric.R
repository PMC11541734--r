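# Bottom-up biometric GPP: summing independently measured components with
# error propagation, and aggregating plots to site means.

#' Sum GPP components with error propagation
#'
#' Plot GPP is the sum of its measured components (canopy productivity,
#' stem respiration, fine-root productivity, ...); the uncertainty is
#' propagated in quadrature assuming independent component errors,
#' sigma = sqrt(sum sigma_i^2). An optional covariance matrix generalises
#' the propagation to correlated components.
#'
#' @param values Component values (MgC ha^-1 yr^-1).
#' @param sigmas Component measurement uncertainties (same units,
#'   all >= 0).
#' @param covariance Optional component covariance matrix; its diagonal
#'   must equal `sigmas^2`.
#' @return A list with `gpp` and `sigma`.
#' @examples
#' sum_components(c(10, 5, 3), c(1, 1, 1))  # gpp 18, sigma sqrt(3)
#' @export
sum_components <- function(values, sigmas, covariance = NULL) {
  stopifnot(length(values) >= 1, length(values) == length(sigmas),
            all(is.finite(values)), all(is.finite(sigmas)),
            all(sigmas >= 0))
  if (is.null(covariance)) {
    sigma <- sqrt(sum(sigmas^2))
  } else {
    stopifnot(is.matrix(covariance),
              nrow(covariance) == length(values),
              ncol(covariance) == length(values))
    if (max(abs(diag(covariance) - sigmas^2)) > 1e-8 * max(1, sigmas^2)) {
      stop("covariance diagonal must equal sigmas^2")
    }
    sigma <- sqrt(sum(covariance))
  }
  list(gpp = sum(values), sigma = sigma)
}

#' Plot-level GPP from a component table
#'
#' Applies [sum_components()] within each (site, plot) group of a long
#' component table.
#'
#' @param components Data frame with columns `site`, `plot`, `component`,
#'   `value`, `sigma`.
#' @return A data frame with one row per plot: `site`, `plot`, `gpp`,
#'   `sigma`.
#' @export
plot_gpp <- function(components) {
  need <- c("site", "plot", "component", "value", "sigma")
  miss <- setdiff(need, names(components))
  if (length(miss) > 0) {
    stop("component table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  key <- interaction(components$site, components$plot, drop = TRUE)
  rows <- lapply(split(components, key), function(d) {
    s <- sum_components(d$value, d$sigma)
    data.frame(site = d$site[1], plot = d$plot[1],
               gpp = s$gpp, sigma = s$sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$plot), , drop = FALSE]
}

#' Site-mean biometric GPP
#'
#' Unweighted mean of plot GPP per site. The reported uncertainty is the
#' mean of the plot-level propagated measurement errors - deliberately a
#' measurement uncertainty, not a spatial standard error, matching the
#' field convention for these plot networks.
#'
#' @param plots A data frame from [plot_gpp()] (columns `site`, `plot`,
#'   `gpp`, `sigma`).
#' @return A data frame with one row per site: `site`, `gpp`, `sigma`,
#'   `n_plots`.
#' @export
site_mean_gpp <- function(plots) {
  stopifnot(nrow(plots) >= 1,
            all(c("site", "gpp", "sigma") %in% names(plots)))
  rows <- lapply(split(plots, plots$site), function(d) {
    data.frame(site = d$site[1], gpp = mean(d$gpp),
               sigma = mean(d$sigma), n_plots = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
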