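# Gas-exchange inversion, trait aggregation and the trait-based LUE.

test_that("Vcmax inversion round-trips a forward-simulated Asat", {
  p <- photo_params()
  kin <- leaf_kinetics(30, 101325, p)
  ci <- 0.7 * 400 * 101325 * 1e-6
  mc <- (ci - kin$gammastar) / (ci + kin$kmm)
  vc_true <- 30  # the field magnitude at these forests
  asat <- vc_true * (mc - 0.015)
  inv <- invert_vcmax(asat, tleaf = 30)
  expect_equal(inv$vcmax, 30, tolerance = 1e-9)
  expect_equal(inv$rd, 0.015 * 30, tolerance = 1e-9)
})

test_that("Vcmax inversion is monotone in Asat and reduces to Asat in the ideal limit", {
  asat <- seq(2, 20, by = 2)
  out <- invert_vcmax(asat, tleaf = 30)$vcmax
  expect_true(all(diff(out) > 0))
  # rd = 0 and mc -> 1 (huge ci) gives vcmax = asat
  inv <- invert_vcmax(10, tleaf = 25, rd_frac = 0, ci = 1e9)
  expect_equal(inv$vcmax, 10, tolerance = 1e-6)
})

test_that("Jmax inversion round-trips and flags the light-limited asymptote", {
  p <- photo_params()
  kin <- leaf_kinetics(30, 101325, p)
  ci <- 0.9 * 2000 * 101325 * 1e-6
  jm_true <- 50
  rd <- 0.5
  amax <- assimilation_aj(jm_true, phi0_at(p, 30), 2000, ci, kin, rd = rd)
  inv <- invert_jmax(amax, rd = rd, tleaf = 30)
  expect_false(inv$flagged)
  expect_equal(inv$jmax, 50, tolerance = 1e-9)
  # an Amax at/beyond the asymptote 4 phi0 Iabs has no Jmax solution
  mj <- (ci - kin$gammastar) / (ci + 2 * kin$gammastar)
  amax_asym <- (4 * 0.05 * 2000 / 4) * mj  # J = jsat exactly
  inv2 <- invert_jmax(amax_asym, rd = 0, tleaf = 30)
  expect_true(inv2$flagged)
  expect_true(is.na(inv2$jmax))
  # monotone below the asymptote
  am <- seq(5, 15, by = 1)
  expect_true(all(diff(invert_jmax(am, rd = 0, tleaf = 30)$jmax) > 0))
})

test_that("forward-inverse round trips hold over a plausible trait/temperature grid", {
  p <- photo_params()
  vc_grid <- seq(10, 200, length.out = 20)
  tl_grid <- seq(20, 35, length.out = 20)
  g <- expand.grid(vc = vc_grid, tl = tl_grid)
  kin <- leaf_kinetics(g$tl, 101325, p)
  ci_s <- 0.7 * 400 * 101325 * 1e-6
  mc <- (ci_s - kin$gammastar) / (ci_s + kin$kmm)
  asat <- g$vc * (mc - 0.015)
  vc_rec <- invert_vcmax(asat, tleaf = g$tl)$vcmax
  expect_lt(max(abs(vc_rec - g$vc) / g$vc), 1e-6)

  jm <- 1.8 * g$vc
  rd <- 0.015 * g$vc
  ci_m <- 0.9 * 2000 * 101325 * 1e-6
  amax <- assimilation_aj(jm, phi0_at(p, g$tl), 2000, ci_m, kin, rd = rd)
  inv <- invert_jmax(amax, rd = rd, tleaf = g$tl)
  expect_false(any(inv$flagged))
  expect_lt(max(abs(inv$jmax - jm) / jm), 1e-6)
})

test_that("temperature normalisation round-trips exactly", {
  tr <- data.frame(vcmax = 40, jmax = 70, rd = 0.6)
  back <- normalize_to_temperature(normalize_to_temperature(tr, 30, 25),
                                   25, 30)
  expect_equal(back$vcmax, 40, tolerance = 1e-12)
  expect_equal(back$jmax, 70, tolerance = 1e-12)
  same <- normalize_to_temperature(tr, 28, 28)
  expect_equal(same$vcmax, tr$vcmax)
})

make_gasex <- function(vc25, w, leaf_class = "sun") {
  p <- photo_params()
  k <- kinetic_constants()
  vc30 <- arrhenius_scale(vc25, k$dha_vcmax_j_mol, 30)
  jm30 <- arrhenius_scale(1.8 * vc25, k$dha_jmax_j_mol, 30)
  kin <- leaf_kinetics(30, 101325, p)
  ci_s <- 0.7 * 400 * 101325 * 1e-6
  mc <- (ci_s - kin$gammastar) / (ci_s + kin$kmm)
  rd <- 0.015 * vc30
  data.frame(site = "S1", species = sprintf("sp%d", seq_along(vc25)),
             plot = "P1",
             asat = vc30 * (mc - 0.015),
             amax = assimilation_aj(jm30, phi0_at(p, 30), 2000,
                                    0.9 * 2000 * 101325 * 1e-6, kin,
                                    rd = rd),
             tleaf = 30, ppfd_meas = 2000, leaf_class = leaf_class,
             basal_area_frac = w, stringsAsFactors = FALSE)
}

test_that("community-weighted mean: identity, arithmetic mean, renormalisation", {
  g1 <- make_gasex(40, 1)
  tr1 <- derive_traits(g1, tgrowth = 26)
  cwm1 <- community_weighted_mean(tr1)
  expect_equal(cwm1$vcmax25, 40, tolerance = 1e-6)

  g2 <- make_gasex(c(20, 40), c(0.5, 0.5))
  cwm2 <- community_weighted_mean(derive_traits(g2, tgrowth = 26))
  expect_equal(cwm2$vcmax25, 30, tolerance = 1e-6)

  # weights covering 80% of basal area are renormalised
  g3 <- make_gasex(c(30, 50, 70), 0.8 * c(0.5, 0.25, 0.25))
  cwm3 <- community_weighted_mean(derive_traits(g3, tgrowth = 26))
  expect_equal(cwm3$vcmax25, 0.5 * 30 + 0.25 * 50 + 0.25 * 70,
               tolerance = 1e-6)
})

test_that("CWM is invariant to splitting a species row and uses sun leaves only", {
  g <- make_gasex(c(30, 60), c(0.4, 0.4))
  g_split <- make_gasex(c(30, 60, 60), c(0.4, 0.2, 0.2))
  cwm_a <- community_weighted_mean(derive_traits(g, tgrowth = 26))
  cwm_b <- community_weighted_mean(derive_traits(g_split, tgrowth = 26))
  expect_equal(cwm_a$vcmax25, cwm_b$vcmax25, tolerance = 1e-9)

  shade <- make_gasex(100, 0.5, leaf_class = "shade")
  both <- rbind(make_gasex(30, 0.5), shade)
  cwm <- community_weighted_mean(derive_traits(both, tgrowth = 26))
  expect_equal(cwm$vcmax25, 30, tolerance = 1e-6)  # shade row ignored
  expect_error(community_weighted_mean(derive_traits(shade, tgrowth = 26)),
               "no usable")
})

test_that("invalid gas-exchange records are flagged and excluded", {
  g <- make_gasex(c(30, 40), c(0.5, 0.5))
  g$amax[2] <- 0.5 * g$asat[2]  # Amax < Asat: measurement noise artefact
  tr <- derive_traits(g, tgrowth = 26)
  expect_identical(attr(tr, "n_flagged"), 1L)
  expect_identical(tr$flag[2], "invalid_gas_exchange")
  cwm <- community_weighted_mean(tr)
  expect_equal(cwm$vcmax25, 30, tolerance = 1e-6)
})

test_that("trait LUE is capped by the optimality ceiling and vanishes with Vcmax", {
  f <- standard_forcing()
  p <- photo_params()
  # enormous capacity: LUE converges to phi0 * mj * Mc, never above
  lue_big <- lue_from_traits(1e6, 1e6, f, p, iabs = 800)
  cc <- chi_optimal(f, p)
  kin <- leaf_kinetics(f$tc, f$patm, p)
  mj <- limitation_factors(cc$ci, kin)$mj
  expect_equal(lue_big, p$phi0 * mj * p$mc_mass, tolerance = 1e-4)
  expect_true(lue_big <= p$phi0 * mj * p$mc_mass + 1e-12)
  expect_equal(lue_from_traits(0, 100, f, p, iabs = 800), 0)
})

test_that("the two LUE paths coincide at optimality-implied traits", {
  p <- photo_params()
  f <- random_forcing(50, seed = 3)
  iabs <- runif(50, 100, 1500)
  vc <- vcmax_optimal(f, p, iabs, method = "jmax_limited")
  jm <- jmax_implied(f, p, iabs)
  ok <- jm > 0
  lue_tr <- lue_from_traits(vc[ok], jm[ok],
                            lapply(f, `[`, ok), p, iabs[ok])
  lue_op <- lue_optimal(lapply(f, `[`, ok), p)
  expect_lt(max(abs(lue_tr - lue_op) / lue_op), 1e-6)
})
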