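# Small programmatic fixtures shared across test files.

# Long abundance table from a sites x years count matrix (NA = unsurveyed).
abundance_from_matrix <- function(M, species = "sp1") {
  years <- as.integer(rownames(M))
  df <- data.frame(
    species = species,
    site = rep(colnames(M), each = length(years)),
    year = rep(years, times = ncol(M)),
    count = as.vector(M),
    stringsAsFactors = FALSE
  )
  df[!is.na(df$count), ]
}

# A small abundance fixture with planted gaps and zeros: n_sites x n_years,
# Poisson counts around site-specific means, a configurable number of
# random gaps and of zero counts.
toy_abundance <- function(n_sites = 5, n_years = 20, n_species = 2,
                          n_gaps = 8, n_zeros = 4, seed = 42,
                          start_year = 1991) {
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_species)) {
    M <- matrix(rpois(n_sites * n_years, lambda = 20),
                nrow = n_years,
                dimnames = list(seq(start_year, length.out = n_years),
                                sprintf("T%02d", seq_len(n_sites))))
    M[sample(length(M), n_zeros)] <- 0
    M[sample(length(M), n_gaps)] <- NA
    out[[k]] <- abundance_from_matrix(M, species = sprintf("sp%d", k))
  }
  do.call(rbind, out)
}

toy_sites <- function(n_sites = 5, extent_km = 50, seed = 7) {
  set.seed(seed)
  data.frame(
    site = sprintf("T%02d", seq_len(n_sites)),
    easting_m = runif(n_sites, 0, extent_km * 1000),
    northing_m = runif(n_sites, 0, extent_km * 1000),
    stringsAsFactors = FALSE
  )
}

# Synthetic modelling table under the null: synchrony = species effect +
# pair effect + noise, one species-level attribute drawn independently.
null_model_table <- function(n_species = 10, n_pairs = 50, n_windows = 5,
                             sp_sd = 0.1, pair_sd = 0.1, noise_sd = 0.2,
                             seed = 1) {
  set.seed(seed)
  d <- expand.grid(species = sprintf("sp%02d", seq_len(n_species)),
                   pair_id = sprintf("p%03d", seq_len(n_pairs)),
                   start_year = seq_len(n_windows),
                   stringsAsFactors = FALSE)
  d$mid_year <- d$start_year + 4.5
  u_sp <- rnorm(n_species, 0, sp_sd)
  v_pair <- rnorm(n_pairs, 0, pair_sd)
  d$r <- u_sp[match(d$species, unique(d$species))] +
    v_pair[match(d$pair_id, unique(d$pair_id))] +
    rnorm(nrow(d), 0, noise_sd)
  d$attr <- rnorm(n_species)[match(d$species, unique(d$species))]
  d
}

# Mean pairwise correlation of growth-rate series across all site pairs.
mean_pairwise_growth_sync <- function(abundance) {
  g <- log_growth_rates(abundance)
  M <- tapply(g$growth, list(g$year, g$site), mean)
  C <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  mean(C[upper.tri(C)], na.rm = TRUE)
}
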