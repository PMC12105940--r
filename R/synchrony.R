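# Growth rates and moving-window pairwise synchrony.

#' Convert abundance counts to yearly log growth rates
#'
#' `r_t = log(N_t + 1) - log(N_[t-1] + 1)` (natural log), defined only when
#' both year `t` and year `t - 1` were surveyed; the +1 offset keeps zero
#' counts in the data. Working on growth rates rather than raw abundance
#' removes long-term trends so that synchrony reflects interannual
#' fluctuation.
#'
#' @param abundance long table with columns species, site, year, count;
#'   unsurveyed years are absent rows (or `NA` counts).
#' @return long data.frame: species, site, year, growth — one row per
#'   defined growth rate.
#' @export
#' @examples
#' ab <- data.frame(species = "sp1", site = "A",
#'                  year = 2000:2002, count = c(0, 9, 99))
#' log_growth_rates(ab)  # both rates equal log(10)
log_growth_rates <- function(abundance) {
  stop_if_missing_cols(abundance, c("species", "site", "year", "count"),
                       "abundance")
  ab <- abundance[!is.na(abundance$count), , drop = FALSE]
  if (any(ab$count < 0)) stop("negative abundance count")
  ab <- ab[order(ab$species, ab$site, ab$year), , drop = FALSE]
  key <- paste(ab$species, ab$site, sep = "\r")
  same_series <- c(FALSE, key[-1] == key[-nrow(ab)])
  consecutive <- c(FALSE, diff(ab$year) == 1L) & same_series
  lc <- log(ab$count + 1)
  growth <- c(NA_real_, lc[-1] - lc[-length(lc)])
  keep <- consecutive
  data.frame(species = ab$species[keep], site = ab$site[keep],
             year = ab$year[keep], growth = growth[keep],
             stringsAsFactors = FALSE)
}

#' Assign planar coordinates to climate grid cells
#'
#' Half-open floor convention: a coordinate of exactly one cell size falls
#' in the next cell. Negative coordinates are allowed (floor semantics).
#'
#' @param easting_m,northing_m planar coordinates in metres.
#' @param cell_size_m grid cell size (default 5 km).
#' @return character cell ids of the form `"gx_y"`.
#' @export
#' @examples
#' site_grid_cell(4999, 0)   # "g0_0"
#' site_grid_cell(5000, 0)   # "g1_0"
site_grid_cell <- function(easting_m, northing_m, cell_size_m = 5000) {
  if (any(!is.finite(easting_m)) || any(!is.finite(northing_m))) {
    stop("coordinates must be finite")
  }
  stopifnot(cell_size_m > 0)
  sprintf("g%d_%d", floor(easting_m / cell_size_m),
          floor(northing_m / cell_size_m))
}

#' Enumerate (and optionally subsample) eligible site pairs
#'
#' All unordered site pairs with Euclidean distance at most
#' `max_distance_km` (inclusive). Sites can first be restricted to those
#' whose abundance series spans at least `min_series_years` surveyed years
#' (the large-network mode used when pair counts explode). If more than
#' `max_pairs` pairs remain, a uniform random subsample without replacement
#' is drawn ("pairs" substream of the seed).
#'
#' @param sites data.frame: site, easting_m, northing_m.
#' @param max_distance_km pair exclusion distance (default 100).
#' @param max_pairs maximum number of pairs retained (default 10000).
#' @param abundance optional abundance table, needed when
#'   `min_series_years` is set.
#' @param min_series_years optional minimum number of surveyed years per
#'   site (counted over all species).
#' @param seed master integer seed for the subsample.
#' @return data.frame: site_a, site_b (canonical order), distance_km,
#'   mean_northing_km. Carries attribute `n_before_subsample`.
#' @export
eligible_pairs <- function(sites, max_distance_km = 100, max_pairs = 10000,
                           abundance = NULL, min_series_years = NULL,
                           seed = 1) {
  stop_if_missing_cols(sites, c("site", "easting_m", "northing_m"), "sites")
  if (max_pairs < 1) stop("max_pairs must be at least 1")
  s <- sites
  if (!is.null(min_series_years)) {
    if (is.null(abundance)) stop("abundance table required for min_series_years")
    ab <- abundance[!is.na(abundance$count), ]
    yrs <- tapply(ab$year, ab$site, function(y) length(unique(y)))
    keep <- names(yrs)[yrs >= min_series_years]
    s <- s[s$site %in% keep, , drop = FALSE]
  }
  if (nrow(s) < 2L) {
    return(data.frame(site_a = character(), site_b = character(),
                      distance_km = numeric(), mean_northing_km = numeric()))
  }
  s <- s[order(s$site), , drop = FALSE]
  n <- nrow(s)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  de <- s$easting_m[ij[, 1]] - s$easting_m[ij[, 2]]
  dn <- s$northing_m[ij[, 1]] - s$northing_m[ij[, 2]]
  dist_km <- sqrt(de^2 + dn^2) / 1000
  ok <- dist_km <= max_distance_km
  out <- data.frame(
    site_a = s$site[ij[ok, 1]], site_b = s$site[ij[ok, 2]],
    distance_km = dist_km[ok],
    mean_northing_km = (s$northing_m[ij[ok, 1]] + s$northing_m[ij[ok, 2]]) / 2000,
    stringsAsFactors = FALSE
  )
  n_before <- nrow(out)
  if (n_before > max_pairs) {
    set.seed(substream_seed(seed, "pairs"))
    out <- out[sort(sample.int(n_before, max_pairs)), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_before_subsample") <- n_before
  out
}

# Reason codes used in the dropped-record table.
DROP_REASONS <- c(distance = "max_distance",
                  shared = "too_few_shared_years",
                  zero_pos = "zero_then_positive",
                  variance = "zero_variance")

#' Synchrony of one site pair in one window
#'
#' Pearson correlation of the two sites' growth rates over the years of a
#' 10-year window `[start_year, start_year + 9]`, applying the exclusion
#' rules: fewer than `min_shared` shared growth-rate years, or a zero
#' abundance count followed (at the next surveyed year, both inside the
#' window) by a positive count at either site — a colonisation signature
#' that inflates correlations — or zero variance at either site. Growth
#' rates belong to a window only if both years of the underlying change lie
#' inside it, so a complete window yields at most 9 growth rates.
#'
#' @param counts_a,counts_b named numeric vectors of counts (names = years)
#'   for the two sites.
#' @param start_year first year of the window.
#' @param window_years window length in calendar years (default 10).
#' @param min_shared minimum shared growth-rate years (default 7).
#' @return list with `r`, `n_shared`, `dropped` (logical), `reason`
#'   (`NA` or a reason code).
#' @export
window_synchrony <- function(counts_a, counts_b, start_year,
                             window_years = 10, min_shared = 7) {
  end_year <- start_year + window_years - 1
  ga <- series_growth(counts_a)
  gb <- series_growth(counts_b)
  yrs <- intersect(names(ga), names(gb))
  yrs <- yrs[as.integer(yrs) >= start_year + 1 & as.integer(yrs) <= end_year]
  res <- list(r = NA_real_, n_shared = length(yrs), dropped = TRUE,
              reason = NA_character_)
  if (length(yrs) < min_shared) {
    res$reason <- DROP_REASONS[["shared"]]
    return(res)
  }
  if (zero_then_positive(counts_a, start_year, end_year) ||
      zero_then_positive(counts_b, start_year, end_year)) {
    res$reason <- DROP_REASONS[["zero_pos"]]
    return(res)
  }
  r <- pearson_r(unname(ga[yrs]), unname(gb[yrs]))
  if (is.na(r)) {
    res$reason <- DROP_REASONS[["variance"]]
    return(res)
  }
  list(r = r, n_shared = length(yrs), dropped = FALSE, reason = NA_character_)
}

# growth rates of a named count vector: named by year t of log(N_t+1)-log(N_{t-1}+1)
series_growth <- function(counts) {
  counts <- counts[!is.na(counts)]
  yrs <- as.integer(names(counts))
  o <- order(yrs)
  yrs <- yrs[o]; counts <- counts[o]
  if (length(counts) < 2L) return(setNames(numeric(0), character(0)))
  consec <- diff(yrs) == 1L
  lc <- log(counts + 1)
  g <- (lc[-1] - lc[-length(lc)])[consec]
  setNames(g, yrs[-1][consec])
}

# TRUE if a surveyed zero count is followed, at the next surveyed year, by a
# positive count, with both years inside [start_year, end_year].
zero_then_positive <- function(counts, start_year, end_year) {
  counts <- counts[!is.na(counts)]
  yrs <- as.integer(names(counts))
  o <- order(yrs)
  yrs <- yrs[o]; counts <- counts[o]
  inside <- yrs >= start_year & yrs <= end_year
  if (sum(inside) < 2L) return(FALSE)
  v <- counts[inside]
  any(v[-length(v)] == 0 & v[-1] > 0)
}

#' Moving-window population synchrony for every species and eligible pair
#'
#' For each species, each eligible site pair and each 10-year window
#' (stepping one year at a time across the data's year span), computes the
#' Pearson correlation of yearly log growth rates, applying the exclusion
#' rules of [window_synchrony()]. Pairs farther apart than
#' `max_distance_km` are excluded up front and recorded in the dropped
#' table with reason `max_distance`.
#'
#' @param abundance long abundance table (species, site, year, count).
#' @param sites site coordinate table.
#' @param pairs optional precomputed pair table from [eligible_pairs()];
#'   computed internally when `NULL`.
#' @param window_years window length (default 10).
#' @param min_shared minimum shared growth-rate years per window (default 7).
#' @param max_distance_km,max_pairs,seed passed to [eligible_pairs()] when
#'   `pairs` is `NULL`.
#' @return list with `records` (data.frame: variable, species, site_a,
#'   site_b, start_year, mid_year, r, n_shared) and `dropped` (data.frame:
#'   species, site_a, site_b, start_year, reason).
#' @export
moving_window_synchrony <- function(abundance, sites, pairs = NULL,
                                    window_years = 10, min_shared = 7,
                                    max_distance_km = 100, max_pairs = 10000,
                                    seed = 1) {
  stop_if_missing_cols(abundance, c("species", "site", "year", "count"),
                       "abundance")
  dropped_far <- NULL
  if (is.null(pairs)) {
    all_pairs <- eligible_pairs(sites, max_distance_km = Inf,
                                max_pairs = .Machine$integer.max)
    far <- all_pairs$distance_km > max_distance_km
    if (any(far)) {
      dropped_far <- data.frame(species = NA_character_,
                                site_a = all_pairs$site_a[far],
                                site_b = all_pairs$site_b[far],
                                start_year = NA_integer_,
                                reason = DROP_REASONS[["distance"]],
                                stringsAsFactors = FALSE)
    }
    pairs <- eligible_pairs(sites, max_distance_km = max_distance_km,
                            max_pairs = max_pairs, seed = seed)
  }
  years <- sort(unique(abundance$year[!is.na(abundance$count)]))
  if (length(years) == 0L || diff(range(years)) + 1 < window_years) {
    warning("year span shorter than one window; no synchrony computed")
    empty <- data.frame(variable = character(), species = character(),
                        site_a = character(), site_b = character(),
                        start_year = integer(), mid_year = numeric(),
                        r = numeric(), n_shared = integer())
    return(list(records = empty,
                dropped = dropped_far %||% empty_dropped()))
  }
  starts <- seq(min(years), max(years) - window_years + 1)
  species <- sort(unique(abundance$species))
  recs <- list(); drops <- list(); ri <- 0L; di <- 0L

  for (sp in species) {
    ab <- abundance[abundance$species == sp & !is.na(abundance$count), ]
    series <- split(setNames(ab$count, ab$year), ab$site)
    growth <- lapply(series, series_growth)
    for (p in seq_len(nrow(pairs))) {
      sa <- pairs$site_a[p]; sb <- pairs$site_b[p]
      ca <- series[[sa]]; cb <- series[[sb]]
      ga <- growth[[sa]]; gb <- growth[[sb]]
      for (y0 in starts) {
        out <- window_synchrony_fast(ca, cb, ga, gb, y0, window_years,
                                     min_shared)
        if (out$dropped) {
          di <- di + 1L
          drops[[di]] <- c(sp, sa, sb, y0, out$reason)
        } else {
          ri <- ri + 1L
          recs[[ri]] <- list(sp, sa, sb, y0, out$r, out$n_shared)
        }
      }
    }
  }
  records <- if (ri > 0L) {
    data.frame(
      variable = "population",
      species = vapply(recs, `[[`, "", 1L),
      site_a = vapply(recs, `[[`, "", 2L),
      site_b = vapply(recs, `[[`, "", 3L),
      start_year = as.integer(vapply(recs, function(x) x[[4L]], numeric(1))),
      mid_year = vapply(recs, function(x) x[[4L]], numeric(1)) +
        (window_years - 1) / 2,
      r = vapply(recs, function(x) x[[5L]], numeric(1)),
      n_shared = as.integer(vapply(recs, function(x) x[[6L]], numeric(1))),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(variable = character(), species = character(),
               site_a = character(), site_b = character(),
               start_year = integer(), mid_year = numeric(),
               r = numeric(), n_shared = integer())
  }
  dropped <- if (di > 0L) {
    m <- do.call(rbind, drops)
    data.frame(species = m[, 1], site_a = m[, 2], site_b = m[, 3],
               start_year = as.integer(m[, 4]), reason = m[, 5],
               stringsAsFactors = FALSE)
  } else {
    empty_dropped()
  }
  if (!is.null(dropped_far)) dropped <- rbind(dropped_far, dropped)
  rownames(dropped) <- NULL
  list(records = records, dropped = dropped)
}

empty_dropped <- function() {
  data.frame(species = character(), site_a = character(),
             site_b = character(), start_year = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

# Same rules as window_synchrony() but with growth rates precomputed once
# per site; counts are still needed for the zero-then-positive rule.
window_synchrony_fast <- function(counts_a, counts_b, growth_a, growth_b,
                                  start_year, window_years, min_shared) {
  end_year <- start_year + window_years - 1
  if (is.null(growth_a) || is.null(growth_b) ||
      length(growth_a) == 0L || length(growth_b) == 0L) {
    return(list(dropped = TRUE, reason = DROP_REASONS[["shared"]]))
  }
  yrs <- intersect(names(growth_a), names(growth_b))
  yi <- as.integer(yrs)
  yrs <- yrs[yi >= start_year + 1 & yi <= end_year]
  if (length(yrs) < min_shared) {
    return(list(dropped = TRUE, reason = DROP_REASONS[["shared"]]))
  }
  if (zero_then_positive(counts_a, start_year, end_year) ||
      zero_then_positive(counts_b, start_year, end_year)) {
    return(list(dropped = TRUE, reason = DROP_REASONS[["zero_pos"]]))
  }
  r <- pearson_r(unname(growth_a[yrs]), unname(growth_b[yrs]))
  if (is.na(r)) {
    return(list(dropped = TRUE, reason = DROP_REASONS[["variance"]]))
  }
  list(dropped = FALSE, r = r, n_shared = length(yrs))
}

#' Moving-window climate synchrony for each seasonal variable
#'
#' Pearson correlation of the raw seasonal climate values (no growth-rate
#' transform) between the grid cells of each site pair, per window and per
#' variable (each season x each climate variable: eight variables with the
#' default four seasons and two variables). Pairs falling in the same grid
#' cell have identical series and are retained with r = 1 when the series
#' varies, otherwise dropped (zero variance).
#'
#' @param climate long climate table (grid_cell, year, season, variable,
#'   value).
#' @param sites site coordinate table.
#' @param pairs pair table from [eligible_pairs()].
#' @param window_years window length (default 10).
#' @param cell_size_m grid cell size used to match sites to cells.
#' @return list with `records` (variable like "temperature_winter", site_a,
#'   site_b, start_year, mid_year, r, n_shared) and `n_dropped` (count of
#'   zero-variance pair-windows).
#' @export
climate_synchrony <- function(climate, sites, pairs, window_years = 10,
                              cell_size_m = 5000) {
  stop_if_missing_cols(climate, c("grid_cell", "year", "season", "variable",
                                  "value"), "climate")
  stop_if_missing_cols(pairs, c("site_a", "site_b"), "pairs")
  cellmap <- setNames(site_grid_cell(sites$easting_m, sites$northing_m,
                                     cell_size_m), sites$site)
  need <- unique(c(pairs$site_a, pairs$site_b))
  missing_sites <- setdiff(need, names(cellmap))
  if (length(missing_sites) > 0L) {
    stop("no grid-cell mapping for site(s): ",
         paste(missing_sites, collapse = ", "))
  }
  missing_cells <- setdiff(unique(cellmap[need]), unique(climate$grid_cell))
  if (length(missing_cells) > 0L) {
    bad <- need[cellmap[need] %in% missing_cells]
    stop("no climate data for the grid cell(s) of site(s): ",
         paste(bad, collapse = ", "))
  }
  years <- sort(unique(climate$year))
  starts <- seq(min(years), max(years) - window_years + 1)
  vars <- sort(unique(paste(climate$variable, climate$season, sep = "_")))
  cells <- sort(unique(climate$grid_cell))
  # values[[var]]: years x cells matrix
  key_var <- paste(climate$variable, climate$season, sep = "_")
  vals <- lapply(vars, function(v) {
    sub <- climate[key_var == v, ]
    M <- matrix(NA_real_, nrow = length(years), ncol = length(cells),
                dimnames = list(years, cells))
    M[cbind(match(sub$year, years), match(sub$grid_cell, cells))] <- sub$value
    M
  })
  names(vals) <- vars
  ia <- match(cellmap[pairs$site_a], cells)
  ib <- match(cellmap[pairs$site_b], cells)
  recs <- vector("list", length(vars) * length(starts))
  k <- 0L; n_dropped <- 0L
  for (v in vars) {
    M <- vals[[v]]
    for (y0 in starts) {
      rows <- which(years >= y0 & years <= y0 + window_years - 1)
      S <- M[rows, , drop = FALSE]
      mu <- colMeans(S)
      Sc <- sweep(S, 2, mu)
      ss <- colSums(Sc^2)
      n_used <- colSums(!is.na(S))
      r_ab <- colSums(Sc[, ia, drop = FALSE] * Sc[, ib, drop = FALSE]) /
        sqrt(ss[ia] * ss[ib])
      same <- ia == ib
      r_ab[same] <- ifelse(ss[ia[same]] > 0, 1, NA_real_)
      bad <- !is.finite(r_ab)
      n_dropped <- n_dropped + sum(bad)
      k <- k + 1L
      recs[[k]] <- data.frame(
        variable = v,
        site_a = pairs$site_a[!bad], site_b = pairs$site_b[!bad],
        start_year = y0, mid_year = y0 + (window_years - 1) / 2,
        r = pmax(-1, pmin(1, r_ab[!bad])),
        n_shared = as.integer(pmin(n_used[ia[!bad]], n_used[ib[!bad]])),
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, n_dropped = n_dropped)
}
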