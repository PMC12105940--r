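# Synthetic metapopulation / climate generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: site networks on a planar national-grid-style coordinate system,
# seasonal gridded climate with exponentially decaying spatial correlation
# (optionally with a temporal trend in the correlation range), Gompertz
# log-abundance dynamics forced by the site-matched climate anomaly,
# distance-kernel dispersal mixing, and Poisson observation with
# missing-at-random survey gaps.

#' Generate a random site network with habitat composition
#'
#' Sites are placed uniformly at random on a square landscape; each site gets
#' a habitat composition vector (proportions over `n_biotopes` biotopes,
#' summing to 1) drawn from a Dirichlet distribution. Small Dirichlet
#' concentration values give specialised (spiky) compositions, large values
#' homogeneous ones.
#'
#' @param n_sites number of monitoring sites.
#' @param extent_km side length of the square landscape, km.
#' @param n_biotopes number of habitat biotopes (at most 10).
#' @param dirichlet_conc Dirichlet concentration for habitat proportions.
#' @param grid_cell_size_m climate grid cell size in metres (default 5 km).
#' @param seed integer seed.
#' @return an object of class `landscape`: a list with elements `sites`
#'   (data.frame: site, easting_m, northing_m), `habitat` (data.frame: site,
#'   biotope, proportion), `grid_cell_size_m` and `n_biotopes`.
#' @export
make_landscape <- function(n_sites, extent_km = 100, n_biotopes = 5,
                           dirichlet_conc = 0.8, grid_cell_size_m = 5000,
                           seed = 1) {
  stopifnot(n_sites >= 2, extent_km > 0, n_biotopes >= 1, n_biotopes <= 10,
            grid_cell_size_m > 0)
  set.seed(substream_seed(seed, "landscape"))
  site <- sprintf("S%03d", seq_len(n_sites))
  sites <- data.frame(
    site = site,
    easting_m = runif(n_sites, 0, extent_km * 1000),
    northing_m = runif(n_sites, 0, extent_km * 1000),
    stringsAsFactors = FALSE
  )
  g <- matrix(rgamma(n_sites * n_biotopes, shape = dirichlet_conc, rate = 1),
              nrow = n_sites)
  # guard against an all-zero row at tiny concentrations
  g[rowSums(g) == 0, 1] <- 1
  p <- g / rowSums(g)
  habitat <- data.frame(
    site = rep(site, each = n_biotopes),
    biotope = rep(sprintf("B%02d", seq_len(n_biotopes)), times = n_sites),
    proportion = as.vector(t(p)),
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, habitat = habitat,
                 grid_cell_size_m = grid_cell_size_m,
                 n_biotopes = n_biotopes),
            class = "landscape")
}

#' Describe a seasonal climate scenario
#'
#' The climate field is a zero-mean Gaussian random field over occupied grid
#' cells with exponential covariance `field_sd^2 * exp(-d / phi(year))`,
#' shifted by `mean_level`. The correlation range `phi` may be constant, a
#' linear trend from `corr_range_km` to `corr_range_end_km` across the year
#' span (the "dynamic" scenario: the spatial autocorrelation of climate
#' changes over time), or an arbitrary function of year.
#'
#' @param years integer vector of consecutive study years (length >= 12).
#' @param corr_range_km correlation range at the first year, km; or a
#'   function(year) -> km.
#' @param corr_range_end_km optional correlation range at the last year, km;
#'   implies a linear trend in between.
#' @param field_sd marginal standard deviation of the field.
#' @param mean_level additive mean of every value.
#' @param seasons,variables labels; 4 seasons x 2 variables gives the eight
#'   seasonal climate variables used downstream.
#' @return an object of class `climate_scenario`.
#' @export
climate_scenario <- function(years, corr_range_km = 50,
                             corr_range_end_km = NULL,
                             field_sd = 1, mean_level = 0,
                             seasons = c("winter", "spring", "summer", "autumn"),
                             variables = c("temperature", "precipitation")) {
  years <- as.integer(years)
  stopifnot(length(years) >= 12, all(diff(years) == 1L), field_sd > 0)
  if (is.function(corr_range_km)) {
    phi <- corr_range_km
  } else if (!is.null(corr_range_end_km)) {
    y0 <- years[1]; y1 <- years[length(years)]
    a <- corr_range_km; bslope <- (corr_range_end_km - a) / (y1 - y0)
    phi <- function(year) a + bslope * (year - y0)
  } else {
    a <- corr_range_km
    phi <- function(year) rep(a, length(year))
  }
  ph <- vapply(years, function(y) phi(y)[1], numeric(1))
  if (any(!is.finite(ph)) || any(ph <= 0)) {
    stop("correlation range phi(year) must be positive and finite for all years")
  }
  structure(list(years = years, phi = phi, field_sd = field_sd,
                 mean_level = mean_level, seasons = seasons,
                 variables = variables),
            class = "climate_scenario")
}

# Occupied 5-km (by default) grid cells and their centroids for a landscape.
occupied_cells <- function(landscape) {
  s <- landscape$sites
  cs <- landscape$grid_cell_size_m
  cell <- site_grid_cell(s$easting_m, s$northing_m, cs)
  ux <- !duplicated(cell)
  idx <- cbind(floor(s$easting_m[ux] / cs), floor(s$northing_m[ux] / cs))
  data.frame(grid_cell = cell[ux],
             centre_e_m = (idx[, 1] + 0.5) * cs,
             centre_n_m = (idx[, 2] + 0.5) * cs,
             stringsAsFactors = FALSE)
}

#' Simulate the seasonal gridded climate field
#'
#' For each year, season and variable, draws one value per occupied grid cell
#' from a Gaussian random field with covariance
#' `field_sd^2 * exp(-d_km / phi(year))` over cell centroids, plus
#' `mean_level`. Sampling is by Cholesky factorisation of the exact
#' covariance (exact at the modest cell counts of a monitoring network).
#' Draws are deterministic for a fixed seed ("climate" substream).
#'
#' @param landscape a [make_landscape()] object.
#' @param scenario a [climate_scenario()].
#' @param seed master integer seed.
#' @return long data.frame: grid_cell, year, season, variable, value.
#' @export
simulate_climate <- function(landscape, scenario, seed = 1) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(scenario, "climate_scenario"))
  cells <- occupied_cells(landscape)
  n <- nrow(cells)
  if (n == 0L) stop("landscape has no occupied grid cells")
  d_km <- as.matrix(stats::dist(cells[, c("centre_e_m", "centre_n_m")])) / 1000
  set.seed(substream_seed(seed, "climate"))
  years <- scenario$years
  ny <- length(years)
  combos <- expand.grid(season = scenario$seasons,
                        variable = scenario$variables,
                        stringsAsFactors = FALSE)
  out <- vector("list", ny)
  for (k in seq_len(ny)) {
    ph <- scenario$phi(years[k])[1]
    if (!is.finite(ph) || ph <= 0) stop("phi(year) must be positive")
    vals <- matrix(NA_real_, nrow = n, ncol = nrow(combos))
    if (n == 1L || max(d_km) / ph < 1e-6) {
      # perfect-correlation limit: the field degenerates to one shared value
      for (j in seq_len(nrow(combos))) {
        vals[, j] <- scenario$mean_level + scenario$field_sd * rnorm(1)
      }
    } else {
      C <- scenario$field_sd^2 * exp(-d_km / ph)
      L <- chol(C + diag(1e-10 * scenario$field_sd^2, n))
      for (j in seq_len(nrow(combos))) {
        vals[, j] <- scenario$mean_level + drop(crossprod(L, rnorm(n)))
      }
    }
    out[[k]] <- data.frame(
      grid_cell = rep(cells$grid_cell, times = nrow(combos)),
      year = years[k],
      season = rep(combos$season, each = n),
      variable = rep(combos$variable, each = n),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Describe one species' dynamics
#'
#' Parameters of the Gompertz / dispersal / observation model used by
#' [simulate_populations()]. `mobility_km` is the dispersal kernel scale
#' (alpha, km): emigrants from site j settle at site i with weight
#' proportional to `exp(-d_ij / alpha)`. `emigration_rate` is the fraction
#' of individuals leaving a site per year; it may increase with local
#' density (`density_dependent_emigration`) or with time
#' (`emigration_trend`, per year, used for time-varying dispersal
#' scenarios). `env_sensitivity` scales the effect of the shared climate
#' anomaly on log growth, and `density_dependence` is the Gompertz
#' autoregression coefficient (|b| < 1 for stationarity).
#'
#' @param species_id character id.
#' @param specialism `"generalist"` or `"specialist"`.
#' @param mobility_km dispersal kernel scale alpha, km (>= 0).
#' @param emigration_rate baseline emigration fraction m in `[0, 1)`.
#' @param density_dependent_emigration logical.
#' @param dde_slope increase of m per unit latent abundance (only used when
#'   `density_dependent_emigration`).
#' @param emigration_trend additive change of m per year (capped below 1).
#' @param env_sensitivity climate forcing coefficient c.
#' @param density_dependence Gompertz coefficient b, in (-1, 1).
#' @param trend multiplicative abundance trend per year (1 = flat).
#' @param site_noise_sd sd of independent site-level process noise (log
#'   scale).
#' @param obs_noise_sd sd of log-normal observation noise multiplying the
#'   Poisson mean (0 = pure Poisson counts).
#' @param equilibrium_abundance typical site carrying level (individuals).
#' @param habitat_affinity optional weight vector over biotopes; sites whose
#'   composition matches the affinity get higher equilibrium abundance.
#' @return an object of class `species_scenario`.
#' @export
species_scenario <- function(species_id,
                             specialism = c("generalist", "specialist"),
                             mobility_km = 10,
                             emigration_rate = 0,
                             density_dependent_emigration = FALSE,
                             dde_slope = 0,
                             emigration_trend = 0,
                             env_sensitivity = 1,
                             density_dependence = 0.4,
                             trend = 1,
                             site_noise_sd = 0.25,
                             obs_noise_sd = 0,
                             equilibrium_abundance = 50,
                             habitat_affinity = NULL) {
  specialism <- match.arg(specialism)
  stopifnot(emigration_rate >= 0, emigration_rate < 1,
            abs(density_dependence) < 1, mobility_km >= 0,
            site_noise_sd >= 0, obs_noise_sd >= 0, trend > 0,
            equilibrium_abundance > 0)
  structure(list(species_id = as.character(species_id),
                 specialism = specialism, mobility_km = mobility_km,
                 emigration_rate = emigration_rate,
                 density_dependent_emigration = density_dependent_emigration,
                 dde_slope = dde_slope,
                 emigration_trend = emigration_trend,
                 env_sensitivity = env_sensitivity,
                 density_dependence = density_dependence,
                 trend = trend, site_noise_sd = site_noise_sd,
                 obs_noise_sd = obs_noise_sd,
                 equilibrium_abundance = equilibrium_abundance,
                 habitat_affinity = habitat_affinity),
            class = "species_scenario")
}

# Row-normalised dispersal kernel, w_ii = 0; rows of
# diag(1 - m) + m * W sum to 1, so mixing conserves total abundance.
dispersal_weights <- function(d_km, alpha_km) {
  if (alpha_km <= 0) stop("dispersal kernel scale alpha must be positive when emigration occurs")
  K <- exp(-d_km / alpha_km)
  diag(K) <- 0
  rs <- rowSums(K)
  # isolated site (numerically zero kernel row): emigrants return home
  K[rs == 0, ] <- 0
  diag(K)[rs == 0] <- 1
  K / pmax(rowSums(K), .Machine$double.xmin)
}

# Site-matched yearly climate anomaly: mean over seasons and variables of
# (value - mean_level) / field_sd for the site's grid cell. Years x sites.
site_climate_anomaly <- function(climate, landscape, scenario = NULL) {
  s <- landscape$sites
  cellmap <- site_grid_cell(s$easting_m, s$northing_m, landscape$grid_cell_size_m)
  mlev <- if (is.null(scenario)) mean(climate$value) else scenario$mean_level
  fsd <- if (is.null(scenario)) sd(climate$value) else scenario$field_sd
  agg <- aggregate(value ~ grid_cell + year, data = climate, FUN = mean)
  years <- sort(unique(agg$year))
  A <- matrix(NA_real_, nrow = length(years), ncol = nrow(s),
              dimnames = list(years, s$site))
  idx <- match(paste(cellmap[col(A)], years[row(A)]),
               paste(agg$grid_cell, agg$year))
  A[] <- (agg$value[idx] - mlev) / fsd
  A
}

#' Simulate dispersal-coupled population dynamics
#'
#' Log abundance at each site follows a Gompertz update
#' `x[t+1] = a_i + b * x[t] + c * eps[t] + log(trend) + noise`, where
#' `eps[t]` is the site-matched mean seasonal climate anomaly and the noise
#' is independent site-level process noise. After each growth step the
#' natural-scale abundances are mixed by distance-kernel dispersal,
#' `N'_i = (1 - m_i) N_i + sum_j m_j w_ji N_j`, and observed counts are
#' Poisson draws around `N'_i` (optionally with log-normal observation
#' noise). Process-noise and observation draws come from per-species
#' substreams of the master seed, so runs that differ only in dispersal
#' parameters share their noise.
#'
#' @param landscape a [make_landscape()] object.
#' @param species_scenarios list of [species_scenario()] objects.
#' @param climate long climate table from [simulate_climate()].
#' @param seed master integer seed.
#' @param scenario optional [climate_scenario()] used to standardise the
#'   climate anomaly exactly (otherwise the empirical mean/sd are used).
#' @return long data.frame: species, site, year, count (all site-years;
#'   apply [apply_survey_gaps()] for missingness).
#' @export
simulate_populations <- function(landscape, species_scenarios, climate,
                                 seed = 1, scenario = NULL) {
  stopifnot(inherits(landscape, "landscape"), length(species_scenarios) >= 1)
  if (inherits(species_scenarios, "species_scenario")) {
    species_scenarios <- list(species_scenarios)
  }
  s <- landscape$sites
  n_sites <- nrow(s)
  years <- sort(unique(climate$year))
  ny <- length(years)
  A <- site_climate_anomaly(climate, landscape, scenario)
  d_km <- as.matrix(stats::dist(s[, c("easting_m", "northing_m")])) / 1000
  hab <- habitat_matrix(landscape)

  out <- vector("list", length(species_scenarios))
  for (k in seq_along(species_scenarios)) {
    sc <- species_scenarios[[k]]
    b <- sc$density_dependence
    cc <- sc$env_sensitivity
    log_trend <- log(sc$trend)
    # site-level equilibrium log abundance, optionally habitat weighted
    x_eq <- rep(log(sc$equilibrium_abundance), n_sites)
    if (!is.null(sc$habitat_affinity)) {
      aff <- sc$habitat_affinity
      if (length(aff) != ncol(hab)) stop("habitat_affinity length must equal n_biotopes")
      q <- as.vector(hab %*% aff)
      q <- q / mean(q)
      x_eq <- x_eq + log(pmax(q, 0.05))
    }
    a <- (1 - b) * x_eq
    need_disp <- sc$emigration_rate > 0 || sc$emigration_trend > 0 ||
      sc$density_dependent_emigration
    W <- if (need_disp) dispersal_weights(d_km, sc$mobility_km) else NULL

    set.seed(substream_seed(seed, paste0("dynamics:", sc$species_id)))
    E <- matrix(rnorm(ny * n_sites, 0, sc$site_noise_sd), nrow = ny)
    x <- x_eq + E[1, ]
    N <- matrix(NA_real_, nrow = ny, ncol = n_sites)
    N[1, ] <- exp(x)
    for (t in 2:ny) {
      eps <- A[t - 1, ]
      eps[is.na(eps)] <- 0
      x <- a + b * x + cc * eps + log_trend + E[t, ]
      Nt <- exp(x)
      if (need_disp) {
        m <- sc$emigration_rate + sc$emigration_trend * (t - 1)
        m <- rep(m, n_sites)
        if (sc$density_dependent_emigration) m <- m + sc$dde_slope * Nt
        m <- pmin(pmax(m, 0), 0.95)
        Nt <- (1 - m) * Nt + drop(crossprod(W, m * Nt))
        x <- log(pmax(Nt, 1e-12))
      }
      N[t, ] <- Nt
    }
    set.seed(substream_seed(seed, paste0("observation:", sc$species_id)))
    lam <- N
    if (sc$obs_noise_sd > 0) {
      lam <- lam * exp(matrix(rnorm(ny * n_sites, -sc$obs_noise_sd^2 / 2,
                                    sc$obs_noise_sd), nrow = ny))
    }
    counts <- matrix(rpois(ny * n_sites, pmin(lam, 1e9)), nrow = ny)
    out[[k]] <- data.frame(
      species = sc$species_id,
      site = rep(s$site, each = ny),
      year = rep(years, times = n_sites),
      count = as.vector(counts),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

habitat_matrix <- function(landscape) {
  h <- landscape$habitat
  sites <- landscape$sites$site
  biotopes <- sort(unique(h$biotope))
  M <- matrix(0, nrow = length(sites), ncol = length(biotopes),
              dimnames = list(sites, biotopes))
  M[cbind(match(h$site, sites), match(h$biotope, biotopes))] <- h$proportion
  M
}

#' Remove site-years at random to emulate survey gaps
#'
#' Each species x site x year row is dropped independently with probability
#' `gap_prob` ("gaps" substream of the master seed), emulating
#' missing-at-random survey coverage.
#'
#' @param abundance long abundance table.
#' @param gap_prob per-row probability of being unsurveyed.
#' @param seed master integer seed.
#' @return the abundance table with rows removed.
#' @export
apply_survey_gaps <- function(abundance, gap_prob, seed = 1) {
  stopifnot(gap_prob >= 0, gap_prob < 1)
  if (gap_prob == 0) return(abundance)
  set.seed(substream_seed(seed, "gaps"))
  keep <- runif(nrow(abundance)) >= gap_prob
  res <- abundance[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Default configuration for a synthetic study
#'
#' Desk-scale defaults: 12 species at 60 sites over 30 years on a 100-km
#' landscape, climate correlation range 50 km (optionally trending), and a
#' species pool spanning generalists/specialists, a mobility gradient, and
#' mixed abundance trends.
#'
#' @param n_species,n_sites,n_years,start_year study dimensions.
#' @param extent_km landscape side, km.
#' @param n_biotopes habitat biotopes (<= 10).
#' @param corr_range_km,corr_range_end_km climate correlation range (start,
#'   and optional end for a linear temporal trend).
#' @param field_sd,mean_level climate field marginal sd and mean.
#' @param env_sensitivity,density_dependence,site_noise_sd,obs_noise_sd
#'   shared dynamics parameters (see [species_scenario()]).
#' @param emigration_rate baseline emigration fraction applied to all
#'   species (0 disables dispersal).
#' @param mobility_range_km range of dispersal kernel scales assigned along
#'   the species mobility gradient.
#' @param trend_up,trend_down multiplicative yearly abundance trends for the
#'   increasing and decreasing halves of the species pool.
#' @param gap_prob missing-at-random survey gap probability.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_species = 12, n_sites = 60, n_years = 30,
                         start_year = 1986, extent_km = 100, n_biotopes = 5,
                         corr_range_km = 50, corr_range_end_km = NULL,
                         field_sd = 1, mean_level = 10,
                         env_sensitivity = 1, density_dependence = 0.4,
                         site_noise_sd = 0.25, obs_noise_sd = 0,
                         emigration_rate = 0.1,
                         mobility_range_km = c(5, 40),
                         trend_up = 1.01, trend_down = 0.99,
                         gap_prob = 0.05) {
  stopifnot(n_years >= 12, n_species >= 2, n_sites >= 4)
  structure(as.list(environment()), class = "study_config")
}

# Species pool implied by a study_config: alternating specialism, a mobility
# rank gradient mapped linearly onto kernel scales, alternating trends.
config_species_scenarios <- function(config) {
  n <- config$n_species
  ranks <- seq_len(n)
  alphas <- seq(config$mobility_range_km[1], config$mobility_range_km[2],
                length.out = n)
  lapply(seq_len(n), function(i) {
    species_scenario(
      species_id = sprintf("sp%02d", i),
      specialism = if (i %% 2 == 0) "generalist" else "specialist",
      mobility_km = alphas[i],
      emigration_rate = config$emigration_rate,
      env_sensitivity = config$env_sensitivity,
      density_dependence = config$density_dependence,
      trend = if (i <= n / 2) config$trend_up else config$trend_down,
      site_noise_sd = config$site_noise_sd,
      obs_noise_sd = config$obs_noise_sd
    )
  })
}

#' Generate a complete synthetic study
#'
#' Produces the full set of coherent input tables for the analysis —
#' abundance (with survey gaps), site coordinates, seasonal gridded climate,
#' habitat composition and a species-attribute table — plus `truth_*`
#' columns recording each species' generating parameters for recovery
#' tests.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @return list with elements `abundance`, `sites`, `climate`, `habitat`,
#'   `attributes`, `landscape`, `scenario`, `species_scenarios`, `config`,
#'   `seed`.
#' @export
make_study_fixture <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  years <- seq(config$start_year, length.out = config$n_years)
  landscape <- make_landscape(config$n_sites, config$extent_km,
                              config$n_biotopes, seed = seed)
  scenario <- climate_scenario(years, corr_range_km = config$corr_range_km,
                               corr_range_end_km = config$corr_range_end_km,
                               field_sd = config$field_sd,
                               mean_level = config$mean_level)
  climate <- simulate_climate(landscape, scenario, seed = seed)
  sps <- config_species_scenarios(config)
  abundance_full <- simulate_populations(landscape, sps, climate,
                                         seed = seed, scenario = scenario)
  abundance <- apply_survey_gaps(abundance_full, config$gap_prob, seed = seed)

  # attribute table from the observed data plus generating truth
  wlen <- min(10, floor(config$n_years / 2))
  w1 <- years[seq_len(wlen)]
  w2 <- years[(config$n_years - wlen + 1):config$n_years]
  recent <- years[(config$n_years - min(7, config$n_years - 1)):config$n_years]
  attributes <- do.call(rbind, lapply(sps, function(sc) {
    idx <- annual_index(abundance, sc$species_id)
    chg <- abundance_change(idx, w1, w2)
    data.frame(
      species = sc$species_id,
      specialism = sc$specialism,
      mobility = sc$mobility_km,
      mean_abundance = mean_abundance(abundance, sc$species_id, recent),
      change_class_all = chg$class_all,
      change_class_sig = chg$class_sig,
      truth_mobility_km = sc$mobility_km,
      truth_emigration_rate = sc$emigration_rate,
      truth_env_sensitivity = sc$env_sensitivity,
      truth_trend = sc$trend,
      stringsAsFactors = FALSE
    )
  }))
  rownames(attributes) <- NULL
  list(abundance = abundance, sites = landscape$sites, climate = climate,
       habitat = landscape$habitat, attributes = attributes,
       landscape = landscape, scenario = scenario,
       species_scenarios = sps, config = config, seed = seed)
}
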