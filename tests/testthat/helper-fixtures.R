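# Shared fixtures: standard forcing conditions and random forcing grids.

standard_forcing <- function(n = 1) {
  list(tc = rep(25, n), vpd = rep(1000, n), co2 = rep(400, n),
       patm = rep(101325, n))
}

# plausible tropical-forest forcing records, seeded
random_forcing <- function(n, seed = 1) {
  set.seed(seed)
  list(tc = runif(n, 18, 32), vpd = runif(n, 0, 2500),
       co2 = runif(n, 350, 450), patm = runif(n, 95000, 102000))
}

toy_fapar_obs <- function(values, states, year = 2015, site = "S1",
                          source = "satellite") {
  data.frame(site = site,
             date = sprintf("%04d-%02d", year, seq_along(values)),
             value = values, source = source, cloud_state = states,
             stringsAsFactors = FALSE)
}
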