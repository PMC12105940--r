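# Simulator: climate field geometry, dispersal bookkeeping, determinism,
# and the qualitative drivers of synchrony (shared forcing, dispersal).

test_that("climate field honours the correlation-range limits", {
  land <- make_landscape(30, extent_km = 100, seed = 5)
  years <- 2000:2011
  # fully correlated limit: enormous range -> all cells share one value
  sc_big <- climate_scenario(years, corr_range_km = 1e9, field_sd = 1,
                             mean_level = 3)
  clim <- simulate_climate(land, sc_big, seed = 5)
  spread <- tapply(clim$value, paste(clim$year, clim$season, clim$variable),
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)

  # independent limit: vanishing range -> near-zero cross-cell correlation
  land2 <- make_landscape(200, extent_km = 400, seed = 6)
  sc_small <- climate_scenario(2000:2029, corr_range_km = 1e-9)
  clim2 <- simulate_climate(land2, sc_small, seed = 6)
  sub <- clim2[clim2$season == "winter" & clim2$variable == "temperature", ]
  M <- tapply(sub$value, list(sub$year, sub$grid_cell), mean)
  C <- cor(M)
  expect_lt(abs(mean(C[upper.tri(C)])), 0.1)
})

test_that("empirical cell-pair correlation matches exp(-d/phi)", {
  # two fixed cells; every year x season x variable draw is an iid field
  # replicate, giving 250 x 8 = 2000 replicates
  land <- structure(list(
    sites = data.frame(site = c("A", "B"),
                       easting_m = c(2500, 32500), northing_m = c(2500, 2500)),
    habitat = data.frame(site = c("A", "B"), biotope = "B01", proportion = 1),
    grid_cell_size_m = 5000, n_biotopes = 1), class = "landscape")
  phi <- 40
  sc <- climate_scenario(seq_len(250) + 1800, corr_range_km = phi)
  clim <- simulate_climate(land, sc, seed = 11)
  va <- clim$value[clim$grid_cell == "g0_0"]
  vb <- clim$value[clim$grid_cell == "g6_0"]
  d <- 30  # centroid distance in km
  expect_equal(cor(va, vb), exp(-d / phi), tolerance = 0.05 / exp(-d / phi))
})

test_that("dispersal weights are a stochastic matrix and conserve abundance", {
  land <- make_landscape(25, extent_km = 60, seed = 3)
  d_km <- as.matrix(dist(land$sites[, c("easting_m", "northing_m")])) / 1000
  W <- synchroscope:::dispersal_weights(d_km, alpha_km = 15)
  expect_equal(unname(rowSums(W)), rep(1, 25), tolerance = 1e-9)
  m <- 0.3
  N <- runif(25, 10, 100)
  N2 <- (1 - m) * N + drop(crossprod(W, m * N))
  expect_equal(sum(N2), sum(N), tolerance = 1e-6 * sum(N))
})

test_that("population counts are independent without forcing or dispersal", {
  land <- make_landscape(15, extent_km = 500, seed = 8)
  sc <- climate_scenario(1990:2019, corr_range_km = 30)
  clim <- simulate_climate(land, sc, seed = 8)
  sp <- species_scenario("a", env_sensitivity = 0, emigration_rate = 0)
  ab <- simulate_populations(land, list(sp), clim, seed = 8, scenario = sc)
  expect_true(all(ab$count >= 0))
  expect_lt(abs(mean_pairwise_growth_sync(ab)), 0.1)
})

test_that("shared climate forcing dominates when the field is uniform", {
  land <- make_landscape(15, extent_km = 60, seed = 2)
  sc <- climate_scenario(1990:2019, corr_range_km = 1e6, mean_level = 10)
  clim <- simulate_climate(land, sc, seed = 2)
  sp <- species_scenario("a", env_sensitivity = 1, emigration_rate = 0)
  ab <- simulate_populations(land, list(sp), clim, seed = 2, scenario = sc)
  expect_gt(mean_pairwise_growth_sync(ab), 0.5)
})

test_that("dispersal increases synchrony (paired runs, shared noise)", {
  wins <- 0
  for (rep in 1:10) {
    land <- make_landscape(12, extent_km = 60, seed = rep)
    sc <- climate_scenario(1996:2015, corr_range_km = 30, mean_level = 10)
    clim <- simulate_climate(land, sc, seed = rep)
    sp0 <- species_scenario("a", emigration_rate = 0, mobility_km = 15)
    sp1 <- species_scenario("a", emigration_rate = 0.3, mobility_km = 15)
    s0 <- mean_pairwise_growth_sync(
      simulate_populations(land, list(sp0), clim, seed = rep, scenario = sc))
    s1 <- mean_pairwise_growth_sync(
      simulate_populations(land, list(sp1), clim, seed = rep, scenario = sc))
    if (s1 > s0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("stronger climate sensitivity increases synchrony", {
  wins <- 0
  for (rep in 1:10) {
    land <- make_landscape(12, extent_km = 60, seed = 20 + rep)
    sc <- climate_scenario(1996:2015, corr_range_km = 30, mean_level = 10)
    clim <- simulate_climate(land, sc, seed = 20 + rep)
    lo <- species_scenario("a", env_sensitivity = 0.5)
    hi <- species_scenario("a", env_sensitivity = 1.5)
    s_lo <- mean_pairwise_growth_sync(
      simulate_populations(land, list(lo), clim, seed = 20 + rep, scenario = sc))
    s_hi <- mean_pairwise_growth_sync(
      simulate_populations(land, list(hi), clim, seed = 20 + rep, scenario = sc))
    if (s_hi > s_lo) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("fixture generation is deterministic and respects gap settings", {
  cfg <- study_config(n_species = 3, n_sites = 12, n_years = 14,
                      gap_prob = 0)
  fx1 <- make_study_fixture(cfg, seed = 9)
  fx2 <- make_study_fixture(cfg, seed = 9)
  expect_identical(fx1$abundance, fx2$abundance)
  expect_identical(fx1$climate, fx2$climate)
  expect_identical(fx1$attributes, fx2$attributes)
  expect_equal(nrow(fx1$abundance), 3 * 12 * 14)

  cfg_gap <- study_config(n_species = 3, n_sites = 12, n_years = 14,
                          gap_prob = 0.1)
  fx3 <- make_study_fixture(cfg_gap, seed = 9)
  expect_lt(nrow(fx3$abundance), 3 * 12 * 14)

  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table(fx1$abundance, f1); write_table(fx2$abundance, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate simulator inputs error", {
  land <- make_landscape(10, seed = 1)
  expect_error(climate_scenario(2000:2011, corr_range_km = -5), "positive")
  expect_error(climate_scenario(2000:2005), "12")
  sp_bad <- species_scenario("a", mobility_km = 0, emigration_rate = 0.2)
  sc <- climate_scenario(2000:2011)
  clim <- simulate_climate(land, sc, seed = 1)
  expect_error(simulate_populations(land, list(sp_bad), clim, seed = 1),
               "alpha")
  expect_error(species_scenario("a", emigration_rate = 1), "emigration")
  expect_error(species_scenario("a", density_dependence = 1.2))
})
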