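# Leaf biochemistry, temperature kinetics and the optimality chain.

test_that("Arrhenius scaling: identity at reference, monotone, matches hand arithmetic", {
  expect_equal(arrhenius_scale(50, 65330, 25, 25), 50)
  # monotone increasing in temperature for positive activation energy
  tt <- seq(10, 40, by = 5)
  out <- arrhenius_scale(1, 65330, tt)
  expect_true(all(diff(out) > 0))
  # frozen hand evaluation of exp((79430/8.3145) * (1/298.15 - 1/308.15))
  expect_equal(arrhenius_scale(1, 79430, 35, 25), 2.82866223993,
               tolerance = 1e-9)
  expect_error(arrhenius_scale(NA, 65330, 25), "finite")
})

test_that("kinetics hit their 25 degC reference constants exactly", {
  k <- leaf_kinetics(25, 101325)
  expect_identical(k$gammastar, 4.332)
  expect_identical(k$kc, 39.97)
  expect_identical(k$ko, 27480)
  expect_identical(k$eta_star, 1)
  expect_true(k$kmm > k$kc)  # any positive O2 partial pressure
})

test_that("kinetics at 30 degC match an independent scalar evaluation", {
  # frozen values from direct evaluation of the Bernacchi Arrhenius forms
  k <- leaf_kinetics(30, 101325)
  expect_equal(k$gammastar, 5.57184480633, tolerance = 1e-9)
  expect_equal(k$kc, 67.80297779729, tolerance = 1e-9)
  expect_equal(k$ko, 35005.59686604, tolerance = 1e-9)
  expect_equal(k$kmm, 108.91122811481, tolerance = 1e-9)
})

test_that("Gammastar scales linearly with pressure; viscosity falls with warmth", {
  k1 <- leaf_kinetics(25, 101325)
  k2 <- leaf_kinetics(25, 90000)
  expect_equal(k2$gammastar / k1$gammastar, 90000 / 101325)
  tt <- seq(5, 45, by = 5)
  expect_true(all(diff(eta_star(tt)) < 0))
})

test_that("optimal chi is 1 at zero VPD and decreases with VPD", {
  f0 <- list(tc = 25, vpd = 0, co2 = 400, patm = 101325)
  expect_equal(chi_optimal(f0)$chi, 1)
  vpds <- seq(0, 4000, by = 250)
  f <- list(tc = rep(25, length(vpds)), vpd = vpds,
            co2 = rep(400, length(vpds)), patm = rep(101325, length(vpds)))
  chis <- chi_optimal(f)$chi
  expect_true(all(diff(chis) < 0))
  # chi stays within (Gammastar/ca, 1]
  ca <- 400 * 101325 * 1e-6
  expect_true(all(chis > 4.332 / ca & chis <= 1))
})

test_that("chi under standard conditions matches the closed-form value", {
  # frozen: xi = sqrt(146*(K25+Gammastar25)/1.6), chi at vpd = 1000 Pa
  out <- chi_optimal(standard_forcing())
  expect_equal(out$chi, 0.753218212819, tolerance = 1e-9)
  expect_equal(out$ci, 30.5279341656, tolerance = 1e-8)
})

test_that("chi_optimal rejects forcing with ca at or below Gammastar", {
  bad <- list(tc = 25, vpd = 500, co2 = 40, patm = 101325)
  expect_error(chi_optimal(bad), "compensation")
})

test_that("limitation factors: compensation point, limits and the 4*Gammastar identity", {
  kin <- leaf_kinetics(25, 101325)
  at <- function(ci) limitation_factors(ci, kin)
  expect_equal(at(kin$gammastar)$mj, 0)
  expect_equal(at(kin$gammastar)$mc, 0)
  expect_equal(at(4 * kin$gammastar)$mj, 0.5)
  big <- at(1e9)
  expect_equal(big$mj, 1, tolerance = 1e-6)
  expect_equal(big$mc, 1, tolerance = 1e-6)
  # sub-compensation ci clamps to zero instead of going negative
  expect_equal(at(0.5 * kin$gammastar)$mj, 0)
})

test_that("Jmax limitation factor: boundary, limit and hand-computed value", {
  expect_equal(jmax_limitation(0.41, 0.41), 0)
  expect_equal(jmax_limitation(0.3, 0.41), 0)
  # cstar -> 0 recovers mj
  expect_equal(jmax_limitation(0.7, 1e-12), 0.7, tolerance = 1e-6)
  # frozen: 0.7 * sqrt(1 - (0.41/0.7)^(2/3))
  expect_equal(jmax_limitation(0.7, 0.41), 0.383379176601, tolerance = 1e-9)
  mj <- seq(0, 1, by = 0.05)
  expect_true(all(jmax_limitation(mj) <= mj + 1e-15))
})

test_that("optimality LUE: zero below the cost threshold, linear in phi0, standard fixture", {
  # extreme dryness pushes mj below cstar -> zero LUE
  dry <- list(tc = 25, vpd = 1e6, co2 = 60, patm = 101325)
  expect_equal(lue_optimal(dry), 0)
  f <- standard_forcing()
  expect_equal(lue_optimal(f, photo_params(phi0 = 0.1)),
               2 * lue_optimal(f, photo_params(phi0 = 0.05)))
  # frozen: phi0 * mprime * Mc under standard conditions
  expect_equal(lue_optimal(f), 0.211665023257, tolerance = 1e-9)
})

test_that("GPP identity: annihilation, linearity, arithmetic product, additivity", {
  expect_equal(gpp(0, 0.3, 1000), 0)
  expect_equal(gpp(0.9, 0.3, 2000), 2 * gpp(0.9, 0.3, 1000))
  expect_equal(gpp(0.95, 0.35, 1000), 332.5)
  # splitting a month in two half-months with the same rates is neutral
  expect_equal(gpp(0.8, 0.25, 500) + gpp(0.8, 0.25, 500),
               gpp(0.8, 0.25, 1000))
  expect_error(gpp(1.2, 0.3, 1000), "\\[0, 1\\]")
})

test_that("optimal Vcmax is linear in absorbed light and coordinates Ac with AJ", {
  f <- standard_forcing()
  expect_equal(vcmax_optimal(f, iabs = 0), 0)
  v1 <- vcmax_optimal(f, iabs = 500)
  expect_equal(vcmax_optimal(f, iabs = 1000), 2 * v1)

  # coordination as an algebraic identity, both variants
  p <- photo_params()
  cc <- chi_optimal(f, p)
  kin <- leaf_kinetics(f$tc, f$patm, p)
  iabs <- 800
  # simple variant pairs with the unlimited electron-transport rate
  ac_s <- assimilation_ac(vcmax_optimal(f, p, iabs, "simple"), cc$ci, kin)
  aj_s <- assimilation_aj(Inf, p$phi0, iabs, cc$ci, kin)
  expect_equal(ac_s, aj_s, tolerance = 1e-9)
  # Jmax-limited variant pairs with the implied Jmax
  ac_j <- assimilation_ac(vcmax_optimal(f, p, iabs, "jmax_limited"),
                          cc$ci, kin)
  aj_j <- assimilation_aj(jmax_implied(f, p, iabs), p$phi0, iabs,
                          cc$ci, kin)
  expect_equal(ac_j, aj_j, tolerance = 1e-9)
})

test_that("Rubisco-limited assimilation: zero at compensation, linear, factor identity", {
  kin <- leaf_kinetics(25, 101325)
  expect_equal(assimilation_ac(30, kin$gammastar, kin), 0)
  expect_equal(assimilation_ac(60, 50, kin), 2 * assimilation_ac(30, 50, kin))
  # ci chosen so that mc = 0.5: ci = 2*Gammastar + kmm
  ci_half <- 2 * kin$gammastar + kin$kmm
  expect_equal(assimilation_ac(30, ci_half, kin), 15, tolerance = 1e-12)
})

test_that("electron transport saturates at Jmax and is quantum-limited at low light", {
  kin <- leaf_kinetics(25, 101325)
  ci <- 100
  mj <- (ci - kin$gammastar) / (ci + 2 * kin$gammastar)
  # iabs -> infinity: J -> jmax
  aj_hi <- assimilation_aj(100, 0.05, 1e9, ci, kin)
  expect_equal(aj_hi, 100 / 4 * mj, tolerance = 1e-6)
  # iabs -> 0: J / (4 phi0 iabs) -> 1
  aj_lo <- assimilation_aj(100, 0.05, 1e-6, ci, kin)
  expect_equal(aj_lo / (0.05 * 1e-6 * mj), 1, tolerance = 1e-6)
  # frozen hand arithmetic at the chamber conditions (2000 umol m-2 s-1)
  j <- 4 * 0.05 * 2000 / sqrt(1 + (4 * 0.05 * 2000 / 100)^2)
  expect_equal(j, 97.0142500145, tolerance = 1e-9)
  expect_equal(assimilation_aj(100, 0.05, 2000, ci, kin),
               j / 4 * mj, tolerance = 1e-12)
  expect_error(assimilation_aj(0, 0.05, 2000, ci, kin), "jmax")
})

test_that("temperature-dependent quantum yield mode is normalised at 25 degC", {
  p_fix <- photo_params()
  p_td <- photo_params(phi0_tdep = TRUE)
  f25 <- standard_forcing()
  expect_equal(lue_optimal(f25, p_td), lue_optimal(f25, p_fix))
  f30 <- list(tc = 30, vpd = 1000, co2 = 400, patm = 101325)
  expect_false(isTRUE(all.equal(lue_optimal(f30, p_td),
                                lue_optimal(f30, p_fix))))
})
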