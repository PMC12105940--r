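# Species attributes: inclusion filter, abundance-change classification,
# mean abundance, and assembly of the attribute table.

#' Filter species by survey coverage
#'
#' Keeps species for which at least `min_prop_years` of the study years have
#' `min_sites` or more sites with a non-missing count — the inclusion rule
#' that guarantees enough pairwise comparisons in every window.
#'
#' @param abundance long abundance table.
#' @param min_prop_years minimum fraction of years meeting the site
#'   threshold (default 0.75).
#' @param min_sites minimum surveyed sites per qualifying year (default 50).
#' @param study_years optional explicit year range; defaults to the range of
#'   years present in the table.
#' @return character vector of retained species ids.
#' @export
species_inclusion_filter <- function(abundance, min_prop_years = 0.75,
                                     min_sites = 50, study_years = NULL) {
  stop_if_missing_cols(abundance, c("species", "site", "year", "count"),
                       "abundance")
  ab <- abundance[!is.na(abundance$count), , drop = FALSE]
  if (nrow(ab) == 0L) return(character(0))
  if (is.null(study_years)) study_years <- seq(min(ab$year), max(ab$year))
  n_years <- length(study_years)
  keep <- vapply(split(ab, ab$species), function(d) {
    sites_per_year <- tapply(d$site, d$year, function(s) length(unique(s)))
    sum(sites_per_year >= min_sites) / n_years >= min_prop_years
  }, logical(1))
  sort(names(keep)[keep])
}

#' Classify a species' abundance change between two windows
#'
#' Mean difference of an annual index between two non-overlapping windows
#' (`mean(window2) - mean(window1)`), classified as increase/decrease
#' regardless of significance (`class_all`; an exact tie is classed as
#' decrease with a warning), and additionally screened by a two-sample
#' two-sided t test at `alpha` (`class_sig`: increase/decrease when
#' significant with the matching sign, otherwise `"excluded"`).
#'
#' @param index_series named numeric vector: per-year index values, names
#'   are years.
#' @param window1,window2 integer year vectors; must not overlap.
#' @param alpha significance level for the screen (default 0.05).
#' @param var_equal use a pooled-variance (Student) t test instead of the
#'   default Welch test.
#' @return list: `mean_diff`, `class_all`, `class_sig`, `p_value`.
#' @export
abundance_change <- function(index_series, window1, window2, alpha = 0.05,
                             var_equal = FALSE) {
  if (length(intersect(window1, window2)) > 0L) {
    stop("windows must not overlap")
  }
  yrs <- as.integer(names(index_series))
  v1 <- index_series[yrs %in% window1]
  v2 <- index_series[yrs %in% window2]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 2L || length(v2) < 2L) {
    stop("need at least 2 index values in each window")
  }
  mean_diff <- mean(v2) - mean(v1)
  if (mean_diff == 0) warning("exact tie in mean abundance; classing as decrease")
  class_all <- if (mean_diff > 0) "increase" else "decrease"
  p <- if (var(v1) == 0 && var(v2) == 0) {
    # degenerate: identical constants are indistinguishable, different
    # constants are trivially separated
    if (mean_diff == 0) 1 else 0
  } else {
    t.test(v2, v1, var.equal = var_equal)$p.value
  }
  class_sig <- if (p < alpha) class_all else "excluded"
  list(mean_diff = mean_diff, class_all = class_all, class_sig = class_sig,
       p_value = p)
}

#' Mean abundance of a species over a year range
#'
#' Arithmetic mean of counts over all sites and years in `years`, skipping
#' missing values.
#'
#' @param abundance long abundance table.
#' @param species species id.
#' @param years integer year vector.
#' @return the mean count.
#' @export
mean_abundance <- function(abundance, species, years) {
  v <- abundance$count[abundance$species == species &
                         abundance$year %in% years]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no abundance data for ", species,
                            " in the requested years")
  mean(v)
}

#' Annual index of a species (site-mean counts)
#'
#' A simple stand-in for a modelled national collated index: the mean count
#' across surveyed sites per year.
#'
#' @param abundance long abundance table.
#' @param species species id.
#' @return named numeric vector of yearly index values (names = years).
#' @export
annual_index <- function(abundance, species) {
  d <- abundance[abundance$species == species & !is.na(abundance$count), ]
  if (nrow(d) == 0L) stop("no abundance data for ", species)
  idx <- tapply(d$count, d$year, mean)
  setNames(as.numeric(idx), names(idx))
}

#' Assemble the species attribute table
#'
#' Joins supplied specialism/mobility values with abundance-derived
#' attributes: mean abundance over `abundance_years` and the two-window
#' abundance-change classes of [abundance_change()].
#'
#' @param abundance long abundance table.
#' @param species_info data.frame with columns species, specialism,
#'   mobility.
#' @param change_window1,change_window2 year vectors for the change
#'   classification.
#' @param abundance_years years over which mean abundance is taken.
#' @param alpha significance level of the t-test screen.
#' @return data.frame: species, specialism, mobility, mean_abundance,
#'   change_class_all, change_class_sig.
#' @export
species_attribute_table <- function(abundance, species_info,
                                    change_window1, change_window2,
                                    abundance_years, alpha = 0.05) {
  stop_if_missing_cols(species_info, c("species", "specialism", "mobility"),
                       "species_info")
  rows <- lapply(seq_len(nrow(species_info)), function(i) {
    sp <- species_info$species[i]
    chg <- abundance_change(annual_index(abundance, sp),
                            change_window1, change_window2, alpha = alpha)
    data.frame(species = sp,
               specialism = species_info$specialism[i],
               mobility = species_info$mobility[i],
               mean_abundance = mean_abundance(abundance, sp, abundance_years),
               change_class_all = chg$class_all,
               change_class_sig = chg$class_sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
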