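# Assembly of the modelling table: one row per population synchrony record,
# joined to pair covariates, the eight climate synchrony values for the same
# pair-window, and species attributes.

#' Standardise a numeric column to zero mean and unit variance
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#' Idempotent up to floating point; errors on zero variance so silent
#' degenerate predictors cannot enter a model.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return standardised vector.
#' @export
#' @examples
#' standardise(c(1, 2, 3))  # -1 0 1
standardise <- function(x) {
  nm <- deparse(substitute(x))
  if (!is.numeric(x)) stop("cannot standardise non-numeric column ", nm)
  if (anyNA(x)) stop("missing values in column ", nm)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance in column ", nm)
  (x - mean(x)) / s
}

#' Join synchrony records, covariates, climate synchrony and attributes
#'
#' Produces the modelling table: population synchrony `r` as response, one
#' row per species x site pair x window, with pair-level covariates, the
#' wide climate-synchrony columns for the matching pair-window, the window
#' mid-year, and species attributes. Rows with a missing control or climate
#' value are dropped and counted; missing attributes are retained (they are
#' dropped per attribute model).
#'
#' @param population_records records from [moving_window_synchrony()].
#' @param covariates pair covariate table from [pair_covariates()].
#' @param climate_records records from [climate_synchrony()].
#' @param attributes optional species attribute table.
#' @return data.frame with attribute `n_dropped_incomplete`.
#' @export
build_model_table <- function(population_records, covariates,
                              climate_records = NULL, attributes = NULL) {
  stop_if_missing_cols(population_records,
                       c("species", "site_a", "site_b", "start_year",
                         "mid_year", "r"), "population_records")
  tab <- population_records[population_records$variable %in%
                              c("population", NA), , drop = FALSE]
  tab$pair_id <- pair_id(tab$site_a, tab$site_b)
  cv <- covariates
  cv$pair_id <- pair_id(cv$site_a, cv$site_b)
  cvcols <- setdiff(names(cv), c("site_a", "site_b", "pair_id"))
  tab[cvcols] <- cv[match(tab$pair_id, cv$pair_id), cvcols]

  climate_vars <- character(0)
  if (!is.null(climate_records)) {
    cr <- climate_records
    key_cr <- paste(pair_id(cr$site_a, cr$site_b), cr$start_year)
    key_tab <- paste(tab$pair_id, tab$start_year)
    climate_vars <- sort(unique(cr$variable))
    for (v in climate_vars) {
      sel <- cr$variable == v
      tab[[v]] <- cr$r[sel][match(key_tab, key_cr[sel])]
    }
  }
  core <- c("r", "mid_year", cvcols, climate_vars)
  ok <- complete.cases(tab[core])
  n_dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]

  if (!is.null(attributes)) {
    acols <- setdiff(names(attributes), "species")
    acols <- setdiff(acols, grep("^truth_", acols, value = TRUE))
    tab[acols] <- attributes[match(tab$species, attributes$species), acols]
  }
  rownames(tab) <- NULL
  attr(tab, "n_dropped_incomplete") <- n_dropped
  attr(tab, "climate_vars") <- climate_vars
  tab
}
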