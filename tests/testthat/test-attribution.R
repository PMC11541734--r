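# The factorial experiment engine, the lookup LUE emulator, the ledger
# decomposition, composite-PFT GPP and forcing comparisons.

synth_inputs <- function(seed = 3) {
  b <- generate_site(default_templates()$semi_deciduous, seed = seed,
                     noise = 0)
  list(forcing = b$forcing, fapar_field = b$truth$fapar,
       fapar_satellite = b$truth$fapar * (1 - b$sat_bias),
       traits = b$truth$cwm, biome = biome_params())
}

test_that("canonical experiment specs fix their bindings", {
  s <- experiment_spec("Pmodel_PfL")
  expect_identical(s$lue_source, "traits")
  expect_identical(s$fapar_source, "field")
  expect_identical(s$ppfd_source, "field")
  expect_error(experiment_spec("Pmodel_PfL", lue_source = "optimality"),
               "fixes")
  expect_error(experiment_spec("nonsense"), "unknown experiment")
  cust <- experiment_spec("custom", "optimality", "field", "product")
  expect_identical(cust$ppfd_source, "product")
})

test_that("identical bindings give identical GPP; equal fAPAR sources collapse Pf and P", {
  inp <- synth_inputs()
  g1 <- run_experiment(experiment_spec("Pmodel_Pf"), inp)
  g2 <- run_experiment(experiment_spec("custom", "optimality", "field",
                                       "field"), inp)
  expect_identical(g1$gpp, g2$gpp)
  inp_same <- inp
  inp_same$fapar_satellite <- inp$fapar_field
  gp <- run_experiment(experiment_spec("Pmodel_P"), inp_same)
  expect_equal(gp$gpp, g1$gpp, tolerance = 1e-12)
})

test_that("missing bindings raise configuration errors naming the binding", {
  inp <- synth_inputs()
  no_traits <- inp; no_traits$traits <- NULL
  expect_error(run_experiment(experiment_spec("Pmodel_PfL"), no_traits),
               "traits")
  no_sat <- inp; no_sat$fapar_satellite <- NULL
  expect_error(run_experiment(experiment_spec("Pmodel_P"), no_sat),
               "fapar_satellite")
  no_prod <- inp; no_prod$forcing$ppfd_product <- NULL
  expect_error(run_experiment(experiment_spec("Pmodel_null"), no_prod),
               "ppfd_product")
})

test_that("annual GPP equals an independent spreadsheet-style recomputation", {
  inp <- synth_inputs()
  res <- run_experiment(experiment_spec("Pmodel_Pf"), inp)
  # chain the arithmetic by hand: per-month fapar * lue * ppfd, summed
  # per year, averaged, converted with the exact 0.01 factor
  f <- inp$forcing
  lue_m <- lue_optimal(f)
  gm <- inp$fapar_field[f$month] * lue_m * f$ppfd
  annual <- tapply(gm, f$year, sum) * 0.01
  expect_equal(res$gpp, mean(annual), tolerance = 1e-12)
  expect_equal(as.numeric(res$annual), as.numeric(annual),
               tolerance = 1e-12)
})

test_that("lookup LUE: ramp endpoints and a mid-ramp hand value", {
  bio <- biome_params()
  expect_equal(lookup_lue(-10, 500, bio), 0)        # below the Tmin ramp
  expect_equal(lookup_lue(25, 500, bio),
               bio$emax_gc_mol)                     # VPD below lower bound
  expect_equal(lookup_lue(25, 5000, bio), 0)        # VPD above upper bound
  # mid-ramp: VPD 1950 Pa is halfway between 800 and 3100
  expect_equal(lookup_lue(25, 1950, bio), bio$emax_gc_mol * 0.5,
               tolerance = 1e-12)
  # temperature mid-ramp
  tmid <- mean(bio$tmin_ramp)
  expect_equal(lookup_lue(tmid, 500, bio), bio$emax_gc_mol * 0.5,
               tolerance = 1e-12)
  expect_error(biome_params(vpd_ramp = c(3100, 800)), "malformed ramp")
})

test_that("the ledger reproduces the worked arithmetic example", {
  led <- decompose_discrepancy(40, 32, 28, 20, 15)
  expect_equal(led$gpp, c(8, 4, 8, 5))
  expect_equal(attr(led, "total"), 25)
  expect_equal(led$pct_of_biometric, 100 * c(8, 4, 8, 5) / 40)
  zero <- decompose_discrepancy(30, 30, 30, 30, 30)
  expect_equal(zero$gpp, rep(0, 4))
})

test_that("the ledger telescopes to machine precision for random quintuples", {
  set.seed(42)
  for (i in 1:200) {
    v <- runif(5, 0, 60)
    led <- decompose_discrepancy(v[1], v[2], v[3], v[4], v[5])
    expect_lt(abs(sum(led$gpp) - (v[1] - v[5])), 1e-12)
  }
})

test_that("swapping one input binding moves only its own ledger term", {
  inp <- synth_inputs()
  run <- function(inputs) {
    g <- function(nm) run_experiment(experiment_spec(nm), inputs)$gpp
    decompose_discrepancy(40, g("Pmodel_PfL"), g("Pmodel_Pf"),
                          g("Pmodel_P"), g("product"))
  }
  base <- run(inp)
  # perturb only the satellite fAPAR: the traits term must not move
  inp2 <- inp
  inp2$fapar_satellite <- inp$fapar_satellite * 0.9
  led2 <- run(inp2)
  expect_equal(led2$gpp[led2$term == "traits"],
               base$gpp[base$term == "traits"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(led2$gpp[led2$term == "fapar"],
                                base$gpp[base$term == "fapar"])))
  # perturb only the traits: fapar and optimisation terms must not move
  inp3 <- inp
  inp3$traits <- list(vcmax25 = 1.3 * inp$traits$vcmax25,
                      jmax25 = 1.3 * inp$traits$jmax25)
  led3 <- run(inp3)
  expect_equal(led3$gpp[led3$term == "fapar"],
               base$gpp[base$term == "fapar"], tolerance = 1e-12)
  expect_equal(led3$gpp[led3$term == "optimisation"],
               base$gpp[base$term == "optimisation"], tolerance = 1e-12)
})

test_that("gridcell and forest-only GPP weight PFT covers correctly", {
  expect_equal(composite_gpp(1, 23), 23)
  expect_equal(composite_gpp(c(0.5, 0.5), c(20, 10)), 15)
  expect_equal(forest_only_gpp(c(0.5, 0.5), c(20, 10), c(TRUE, FALSE)), 20)
  # three-PFT toy table: two forests and a grass
  fr <- c(0.3, 0.2, 0.4); g <- c(24, 18, 10)
  expect_equal(composite_gpp(fr, g), 0.3 * 24 + 0.2 * 18 + 0.4 * 10)
  expect_equal(forest_only_gpp(fr, g, c(TRUE, TRUE, FALSE)),
               (0.3 * 24 + 0.2 * 18) / 0.5)
  expect_error(composite_gpp(c(-0.1, 0.5), c(1, 1)), "non-negative")
  expect_error(composite_gpp(c(0.7, 0.6), c(1, 1)), "at most 1")
})

test_that("forcing comparison reports bias, RMSE and GPP sensitivity", {
  inp <- synth_inputs()
  a <- inp$forcing
  same <- forcing_bias_report(a, a, fapar = inp$fapar_field)
  expect_true(all(same$stats$bias == 0))
  expect_true(all(same$stats$rmse == 0))
  expect_true(all(same$stats$gpp_delta == 0))
  # a constant temperature offset appears as exactly that bias
  b <- a; b$tc <- a$tc + 1.5
  rep1 <- forcing_bias_report(a, b, fapar = inp$fapar_field)
  expect_equal(rep1$stats$bias[rep1$stats$variable == "tc"], 1.5)
  expect_equal(rep1$stats$rmse[rep1$stats$variable == "tc"], 1.5)
  # swapping ppfd upward raises GPP
  c2 <- a; c2$ppfd <- a$ppfd * 1.1
  rep2 <- forcing_bias_report(a, c2, fapar = inp$fapar_field)
  expect_gt(rep2$stats$gpp_delta[rep2$stats$variable == "ppfd"], 0)
  # misaligned series are rejected
  expect_error(forcing_bias_report(a, a[-1, ]), "misaligned")
})
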