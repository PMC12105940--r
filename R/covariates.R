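# Pair-level control covariates: distance, mean northing, habitat
# similarity. These are the standard confounders of synchrony (distance
# decay, range-margin position, shared habitat/microclimate) and enter the
# models as fixed effects.

#' Euclidean distance between two sites, km
#'
#' @param a_coords_m,b_coords_m numeric length-2 vectors `(easting_m,
#'   northing_m)`.
#' @return distance in km.
#' @export
#' @examples
#' pair_distance_km(c(0, 0), c(3000, 4000))  # 5
pair_distance_km <- function(a_coords_m, b_coords_m) {
  if (anyNA(a_coords_m) || anyNA(b_coords_m) ||
      any(!is.finite(c(a_coords_m, b_coords_m)))) {
    stop("coordinates must be finite")
  }
  sqrt(sum((a_coords_m - b_coords_m)^2)) / 1000
}

#' Mean northing of a site pair, km
#'
#' Proxy for the pair's latitudinal range position on a planar national
#' grid.
#'
#' @inheritParams pair_distance_km
#' @return mean of the two northings, km.
#' @export
mean_northing_km <- function(a_coords_m, b_coords_m) {
  if (anyNA(a_coords_m) || anyNA(b_coords_m)) stop("coordinates must be finite")
  (a_coords_m[2] + b_coords_m[2]) / 2 / 1000
}

#' Renkonen percentage similarity of two habitat compositions
#'
#' `sum_i min(p_i, q_i)` over habitat proportion vectors on the same
#' biotope ordering; 1 for identical compositions, 0 for disjoint ones.
#' Computed on proportions (the historical "percentage" name
#' notwithstanding). Inputs that do not sum to 1 are renormalised with a
#' warning.
#'
#' @param p,q non-negative proportion vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' renkonen_similarity(c(0.5, 0.5, 0), c(0.3, 0.7, 0))  # 0.8
renkonen_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched biotope sets")
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    warning("habitat proportions do not sum to 1; renormalising")
    p <- p / sum(p); q <- q / sum(q)
  }
  min(1, sum(pmin(p, q)))
}

#' Binary habitat match for categorical habitat types
#'
#' Used when sites carry a single habitat category (e.g., four woodland
#' types) rather than a composition: 1 if the two types are equal, 0
#' otherwise, `NA` (caller drops the pair) if either type is missing.
#'
#' @param type_a,type_b habitat categories.
#' @return 0, 1, or `NA`.
#' @export
binary_habitat_match <- function(type_a, type_b) {
  if (is.na(type_a) || is.na(type_b)) {
    warning("missing habitat type; pair dropped")
    return(NA_integer_)
  }
  as.integer(as.character(type_a) == as.character(type_b))
}

#' Control covariates for a table of site pairs
#'
#' @param pairs pair table (site_a, site_b), e.g. from [eligible_pairs()].
#' @param sites site coordinate table.
#' @param habitat either a long proportion table (site, biotope,
#'   proportion) for `mode = "proportions"`, or a table (site,
#'   habitat_type) for `mode = "binary"`.
#' @param mode habitat similarity mode.
#' @return data.frame: site_a, site_b, distance_km, mean_northing_km,
#'   habitat_similarity. Pairs with a missing binary habitat type are
#'   dropped with a warning.
#' @export
pair_covariates <- function(pairs, sites, habitat,
                            mode = c("proportions", "binary")) {
  mode <- match.arg(mode)
  stop_if_missing_cols(pairs, c("site_a", "site_b"), "pairs")
  stop_if_missing_cols(sites, c("site", "easting_m", "northing_m"), "sites")
  idx_a <- match(pairs$site_a, sites$site)
  idx_b <- match(pairs$site_b, sites$site)
  if (anyNA(idx_a) || anyNA(idx_b)) stop("pair references unknown site")
  de <- sites$easting_m[idx_a] - sites$easting_m[idx_b]
  dn <- sites$northing_m[idx_a] - sites$northing_m[idx_b]
  out <- data.frame(
    site_a = pairs$site_a, site_b = pairs$site_b,
    distance_km = sqrt(de^2 + dn^2) / 1000,
    mean_northing_km = (sites$northing_m[idx_a] + sites$northing_m[idx_b]) / 2000,
    stringsAsFactors = FALSE
  )
  if (mode == "proportions") {
    stop_if_missing_cols(habitat, c("site", "biotope", "proportion"),
                         "habitat")
    biotopes <- sort(unique(habitat$biotope))
    usites <- unique(habitat$site)
    H <- matrix(0, nrow = length(usites), ncol = length(biotopes),
                dimnames = list(usites, biotopes))
    H[cbind(match(habitat$site, usites),
            match(habitat$biotope, biotopes))] <- habitat$proportion
    out$habitat_similarity <- vapply(seq_len(nrow(out)), function(i) {
      renkonen_similarity(H[out$site_a[i], ], H[out$site_b[i], ])
    }, numeric(1))
  } else {
    stop_if_missing_cols(habitat, c("site", "habitat_type"), "habitat")
    tmap <- setNames(as.character(habitat$habitat_type), habitat$site)
    ta <- tmap[out$site_a]; tb <- tmap[out$site_b]
    sim <- suppressWarnings(
      vapply(seq_along(ta), function(i) {
        if (is.na(ta[i]) || is.na(tb[i])) NA_integer_
        else as.integer(ta[i] == tb[i])
      }, integer(1)))
    if (anyNA(sim)) {
      warning(sum(is.na(sim)), " pair(s) dropped: missing habitat type")
      out <- out[!is.na(sim), , drop = FALSE]
      sim <- sim[!is.na(sim)]
    }
    out$habitat_similarity <- sim
  }
  rownames(out) <- NULL
  out
}
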