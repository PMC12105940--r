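# Growth-rate transform, windowing, exclusion rules, and equivalence with
# the brute-force oracle.

test_that("log growth rates use the +1 offset and respect gaps", {
  ab <- data.frame(species = "sp1", site = "A", year = 2000:2002,
                   count = c(0, 9, 99))
  g <- log_growth_rates(ab)
  expect_equal(g$growth, c(log(10), log(100) - log(10)))
  expect_equal(g$growth, rep(log(10), 2))  # both equal ln 10
  expect_equal(g$year, c(2001L, 2002L))

  const <- data.frame(species = "s", site = "A", year = 2000:2004, count = 5)
  expect_true(all(log_growth_rates(const)$growth == 0))

  gap <- data.frame(species = "s", site = "A", year = c(2000, 2002),
                    count = c(3, 7))
  expect_equal(nrow(log_growth_rates(gap)), 0)

  neg <- data.frame(species = "s", site = "A", year = 2000:2001,
                    count = c(3, -1))
  expect_error(log_growth_rates(neg), "negative")
})

test_that("growth rates never bridge two different series", {
  ab <- rbind(
    data.frame(species = "s", site = "A", year = 2000:2001, count = c(1, 2)),
    data.frame(species = "s", site = "B", year = 2002:2003, count = c(3, 4))
  )
  g <- log_growth_rates(ab)
  expect_equal(nrow(g), 2)  # one per site, none across the A->B boundary
  expect_equal(g$site, c("A", "A", "B", "B")[c(2, 4)])
})

test_that("pearson_r matches hand-computed values and drops degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1, 1), "2 observations")
})

test_that("grid-cell assignment uses half-open floor semantics", {
  expect_equal(site_grid_cell(4999, 0), "g0_0")
  expect_equal(site_grid_cell(5000, 0), "g1_0")
  expect_equal(site_grid_cell(12345, 67890), "g2_13")
  expect_equal(site_grid_cell(-1, -1), "g-1_-1")
  expect_error(site_grid_cell(NaN, 0), "finite")
})

test_that("eligible pairs apply the distance cutoff inclusively and subsample reproducibly", {
  sites <- data.frame(site = c("A", "B", "C"),
                      easting_m = c(0, 50000, 120000), northing_m = 0)
  p <- eligible_pairs(sites, max_distance_km = 100)
  expect_equal(nrow(p), 2)
  expect_equal(paste(p$site_a, p$site_b), c("A B", "B C"))

  # 100 km exactly is retained
  s2 <- data.frame(site = c("A", "B"), easting_m = c(0, 100000), northing_m = 0)
  expect_equal(nrow(eligible_pairs(s2, max_distance_km = 100)), 1)

  big <- toy_sites(25, extent_km = 30)
  p1 <- eligible_pairs(big, max_pairs = 50, seed = 3)
  p2 <- eligible_pairs(big, max_pairs = 50, seed = 3)
  expect_equal(nrow(p1), 50)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "n_before_subsample"), choose(25, 2))
  expect_error(eligible_pairs(big, max_pairs = 0), "max_pairs")
})

test_that("pair subsampling is stable: subsample means track the full set", {
  cfg <- study_config(n_species = 2, n_sites = 22, n_years = 14,
                      extent_km = 30, gap_prob = 0)
  fx <- make_study_fixture(cfg, seed = 4)
  full <- moving_window_synchrony(fx$abundance, fx$sites,
                                  pairs = eligible_pairs(fx$sites))
  m_full <- mean(full$records$r)
  for (s in 1:5) {
    sub <- eligible_pairs(fx$sites, max_pairs = 150, seed = s)
    m_sub <- mean(moving_window_synchrony(fx$abundance, fx$sites,
                                          pairs = sub)$records$r)
    expect_lt(abs(m_sub - m_full), 0.02)
  }
})

test_that("window synchrony applies the three record-level rules", {
  yrs <- 2000:2009
  base <- setNames(c(5, 8, 3, 9, 4, 7, 2, 8, 5, 6), yrs)
  # identical growth -> r = 1 with 9 shared growth rates
  out <- window_synchrony(base, base * 2 + 1, start_year = 2000)
  expect_false(out$dropped)
  expect_equal(out$n_shared, 9)
  ident <- window_synchrony(base, base, start_year = 2000)
  expect_equal(ident$r, 1.0)

  # 6 shared growth-rate years -> dropped
  sparse <- base[c(1, 2, 3, 4, 5, 6, 7)]  # 6 growth rates
  out2 <- window_synchrony(base, sparse, start_year = 2000)
  expect_true(out2$dropped)
  expect_equal(out2$reason, "too_few_shared_years")

  # zero followed by positive inside the window -> dropped
  zp <- base; zp["2004"] <- 0  # 2005 positive
  out3 <- window_synchrony(base, zp, start_year = 2000)
  expect_true(out3$dropped)
  expect_equal(out3$reason, "zero_then_positive")
  # trailing zero (never followed by a positive) is fine
  zt <- base; zt["2009"] <- 0
  expect_false(window_synchrony(base, zt, start_year = 2000)$dropped)

  # constant series -> zero variance
  out4 <- window_synchrony(base, setNames(rep(4, 10), yrs), 2000)
  expect_equal(out4$reason, "zero_variance")
})

test_that("moving windows enumerate correctly and match the oracle exactly", {
  # 20-year complete fixture: 11 windows per pair
  ab <- toy_abundance(n_sites = 3, n_years = 20, n_species = 1,
                      n_gaps = 0, n_zeros = 0, seed = 1)
  sites <- toy_sites(3, extent_km = 10)
  res <- moving_window_synchrony(ab, sites)
  expect_equal(sort(unique(res$records$start_year)), 1991:2001)
  expect_equal(nrow(res$records) + sum(res$dropped$reason != "max_distance"),
               3 * 11)
  expect_equal(res$records$mid_year, res$records$start_year + 4.5)

  # gaps + zeros, several seeds: exact agreement with nested-loop oracle
  for (seed in 1:3) {
    ab2 <- toy_abundance(n_sites = 6, n_years = 22, n_species = 2,
                         n_gaps = 14, n_zeros = 8, seed = seed)
    sites2 <- toy_sites(6, extent_km = 60, seed = seed)
    got <- moving_window_synchrony(ab2, sites2)$records
    got <- got[order(got$species, got$site_a, got$site_b, got$start_year), ]
    want <- oracle_synchrony(ab2, sites2)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$species, want$species)
    expect_equal(got$site_a, want$site_a)
    expect_equal(got$start_year, want$start_year)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$n_shared, want$n_shared)
  }
})

test_that("identical dynamics at every site give r = 1 everywhere", {
  yrs <- 1991:2010
  counts <- rpois(20, 30)
  ab <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    data.frame(species = "sp1", site = s, year = yrs, count = counts)
  }))
  sites <- data.frame(site = c("A", "B", "C"),
                      easting_m = c(0, 1000, 2000), northing_m = 0)
  res <- moving_window_synchrony(ab, sites)
  expect_true(all(abs(res$records$r - 1) < 1e-12))
})

test_that("count scaling preserves the sign of r in almost all windows", {
  ab <- toy_abundance(n_sites = 5, n_years = 20, n_species = 1,
                      n_gaps = 5, n_zeros = 0, seed = 10)
  sites <- toy_sites(5, extent_km = 30)
  r1 <- moving_window_synchrony(ab, sites)$records
  ab10 <- ab; ab10$count <- ab10$count * 10L
  r2 <- moving_window_synchrony(ab10, sites)$records
  k1 <- paste(r1$site_a, r1$site_b, r1$start_year)
  k2 <- paste(r2$site_a, r2$site_b, r2$start_year)
  common <- intersect(k1, k2)
  same_sign <- sign(r1$r[match(common, k1)]) == sign(r2$r[match(common, k2)])
  expect_gte(mean(same_sign), 0.95)
})

test_that("all synchrony outputs respect their invariants", {
  fx <- make_study_fixture(study_config(n_species = 3, n_sites = 15,
                                        n_years = 14), seed = 2)
  pairs <- eligible_pairs(fx$sites, max_distance_km = 80)
  res <- moving_window_synchrony(fx$abundance, fx$sites, pairs = pairs)
  expect_true(all(res$records$r >= -1 & res$records$r <= 1))
  expect_true(all(res$records$n_shared >= 7))
  expect_true(all(res$records$site_a < res$records$site_b))
  d <- pairs$distance_km[match(pair_id(res$records$site_a, res$records$site_b),
                               pair_id(pairs$site_a, pairs$site_b))]
  expect_true(all(d <= 80))
})

test_that("climate synchrony handles shared cells, limits and windows", {
  fx <- make_study_fixture(study_config(n_species = 2, n_sites = 12,
                                        n_years = 14, extent_km = 12),
                           seed = 3)
  pairs <- eligible_pairs(fx$sites)
  cs <- climate_synchrony(fx$climate, fx$sites, pairs)
  expect_true(all(cs$records$r >= -1 & cs$records$r <= 1))
  expect_equal(length(unique(cs$records$variable)), 8)
  # same-cell pairs get exactly r = 1
  cellmap <- setNames(site_grid_cell(fx$sites$easting_m, fx$sites$northing_m),
                      fx$sites$site)
  same <- cellmap[cs$records$site_a] == cellmap[cs$records$site_b]
  if (any(same)) expect_true(all(cs$records$r[same] == 1))

  # huge correlation range -> median r near 1
  land <- make_landscape(12, extent_km = 60, seed = 4)
  sc <- climate_scenario(2000:2013, corr_range_km = 1e5)
  clim <- simulate_climate(land, sc, seed = 4)
  p2 <- eligible_pairs(land$sites)
  cs2 <- climate_synchrony(clim, land$sites, p2)
  expect_gt(median(cs2$records$r), 0.95)

  # vanishing range -> mean r near 0
  land3 <- make_landscape(25, extent_km = 300, seed = 5)
  sc3 <- climate_scenario(2000:2013, corr_range_km = 1e-9)
  clim3 <- simulate_climate(land3, sc3, seed = 5)
  p3 <- eligible_pairs(land3$sites, max_distance_km = 500)
  cs3 <- climate_synchrony(clim3, land3$sites, p3)
  expect_lt(abs(mean(cs3$records$r)), 0.1)

  # unknown site -> error naming it
  bad <- data.frame(site_a = "ZZZ", site_b = fx$sites$site[1])
  expect_error(climate_synchrony(fx$climate, fx$sites, bad), "ZZZ")
})

test_that("climate synchrony decays with distance under an exponential field", {
  neg <- 0
  for (rep in 1:10) {
    land <- make_landscape(20, extent_km = 120, seed = 30 + rep)
    sc <- climate_scenario(2000:2013, corr_range_km = 40)
    clim <- simulate_climate(land, sc, seed = 30 + rep)
    pairs <- eligible_pairs(land$sites, max_distance_km = 150)
    cs <- climate_synchrony(clim, land$sites, pairs)
    agg <- aggregate(r ~ site_a + site_b, data = cs$records, FUN = mean)
    agg$dist <- pairs$distance_km[match(pair_id(agg$site_a, agg$site_b),
                                        pair_id(pairs$site_a, pairs$site_b))]
    if (cor(agg$dist, agg$r, method = "spearman") < 0) neg <- neg + 1
  }
  expect_gte(neg, 9)
})
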