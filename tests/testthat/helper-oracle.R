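# Independent brute-force reference implementation of moving-window
# synchrony, written as plain nested loops with stats::cor. Shares no code
# with the package internals; used to verify record sets and r values.

oracle_growth_rates <- function(counts, years) {
  # counts, years: parallel vectors of surveyed years only
  o <- order(years)
  years <- years[o]; counts <- counts[o]
  g <- list()
  for (i in seq_along(years)) {
    j <- which(years == years[i] - 1)
    if (length(j) == 1) {
      g[[as.character(years[i])]] <- log(counts[i] + 1) - log(counts[j] + 1)
    }
  }
  g
}

oracle_zero_positive <- function(counts, years, y0, y1) {
  o <- order(years)
  years <- years[o]; counts <- counts[o]
  keep <- years >= y0 & years <= y1
  v <- counts[keep]
  if (length(v) < 2) return(FALSE)
  for (i in seq_len(length(v) - 1)) {
    if (v[i] == 0 && v[i + 1] > 0) return(TRUE)
  }
  FALSE
}

# Returns a data.frame of surviving records (species, site_a, site_b,
# start_year, r, n_shared), enumerated with nested loops.
oracle_synchrony <- function(abundance, sites, max_distance_km = 100,
                             window_years = 10, min_shared = 7) {
  abundance <- abundance[!is.na(abundance$count), ]
  years_all <- sort(unique(abundance$year))
  starts <- seq(min(years_all), max(years_all) - window_years + 1)
  site_ids <- sort(sites$site)
  out <- list()
  for (sp in sort(unique(abundance$species))) {
    for (i in seq_along(site_ids)) {
      for (j in seq_along(site_ids)) {
        if (i >= j) next
        sa <- site_ids[i]; sb <- site_ids[j]
        ra <- sites[sites$site == sa, ]
        rb <- sites[sites$site == sb, ]
        d_km <- sqrt((ra$easting_m - rb$easting_m)^2 +
                       (ra$northing_m - rb$northing_m)^2) / 1000
        if (d_km > max_distance_km) next
        da <- abundance[abundance$species == sp & abundance$site == sa, ]
        db <- abundance[abundance$species == sp & abundance$site == sb, ]
        ga <- oracle_growth_rates(da$count, da$year)
        gb <- oracle_growth_rates(db$count, db$year)
        for (y0 in starts) {
          y1 <- y0 + window_years - 1
          shared <- intersect(names(ga), names(gb))
          shared <- shared[as.integer(shared) >= y0 + 1 &
                             as.integer(shared) <= y1]
          if (length(shared) < min_shared) next
          if (oracle_zero_positive(da$count, da$year, y0, y1)) next
          if (oracle_zero_positive(db$count, db$year, y0, y1)) next
          xa <- unlist(ga[shared]); xb <- unlist(gb[shared])
          if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
          out[[length(out) + 1]] <- data.frame(
            species = sp, site_a = sa, site_b = sb, start_year = y0,
            r = stats::cor(xa, xb), n_shared = length(shared),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(species = character(), site_a = character(),
                      site_b = character(), start_year = integer(),
                      r = numeric(), n_shared = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$species, res$site_a, res$site_b, res$start_year), ]
}
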