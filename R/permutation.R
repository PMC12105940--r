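# Permutation inference for fixed effects in the synchrony mixed models.
#
# Pairwise synchrony records are not independent (each site enters many
# pairs, each pair many windows), so parametric reference distributions for
# fixed-effect tests are not trusted. Instead the observed marginal Wald F
# for a predictor is compared with its distribution under random permutation
# of that predictor, with the add-one empirical p-value
# p = (1 + #{F_b >= F_obs}) / (B + 1).
#
# The permutation unit matters: species-level attributes are permuted as
# labels across species (rows within a species move as a block, since they
# are exchangeable only jointly under the null that the attribute is
# unrelated to synchrony); row-level predictors such as climate synchrony
# are permuted across rows.

# Find the term whose variable set matches `predictor` (interaction order
# insensitive: "a:b" matches term label "b:a").
match_term <- function(term_labels, predictor) {
  want <- sort(strsplit(predictor, ":", fixed = TRUE)[[1]])
  sets <- lapply(strsplit(term_labels, ":", fixed = TRUE), sort)
  k <- which(vapply(sets, function(s) identical(s, want), logical(1)))
  if (length(k) != 1L) {
    stop("predictor '", predictor, "' does not name exactly one model term")
  }
  k
}

#' Permutation F test for one fixed-effect predictor
#'
#' Refits the model `B` times with the predictor permuted, extracting the
#' same marginal Wald F statistic as in the observed fit, and returns the
#' add-one empirical p-value. For an interaction term (e.g.
#' `"specialism:mid_year"`), the species-level attribute is permuted across
#' species and the interaction columns recomputed. Permuted refits reuse
#' the parsed model structure and warm-start at the observed
#' variance-component optimum. Failed refits are dropped and counted (with
#' a warning if more than 1% fail).
#'
#' @param fit a [fit_lmm()] object.
#' @param predictor name of a fixed-effect term of the fit.
#' @param B number of permutations (>= 19; default 1000).
#' @param seed master integer seed ("perm:<predictor>" substream).
#' @param unit `"auto"` (species block if the permuted variable is constant
#'   within species, rows otherwise), `"species"`, or `"rows"`.
#' @return object of class `permutation_result`: list with `predictor`,
#'   `F_observed`, `F_permuted`, `p_empirical`, `unit`, `n_failed`.
#' @export
permutation_test <- function(fit, predictor, B = 1000, seed = 1,
                             unit = c("auto", "species", "rows")) {
  stopifnot(inherits(fit, "sync_lmm"))
  unit <- match.arg(unit)
  if (B < 19) stop("B must be at least 19 to resolve p < 0.05")
  dat <- fit$data
  k_pred <- match_term(fit$term_labels, predictor)
  cols_pred <- which(fit$assign == k_pred)
  F_obs <- fit$coefficients$F[k_pred]

  # which variable gets permuted: for interactions, the species-level part
  parts <- strsplit(fit$term_labels[k_pred], ":", fixed = TRUE)[[1]]
  perm_var <- if (length(parts) == 1L) parts else {
    sl <- vapply(parts, function(v) is_species_level(dat, v), logical(1))
    if (any(sl)) parts[which(sl)[1]] else parts[1]
  }
  if (unit == "auto") {
    unit <- if (is_species_level(dat, perm_var)) "species" else "rows"
  }
  if (unit == "species" && !"species" %in% names(dat)) {
    stop("species column required for species-level permutation")
  }

  mt <- terms(reformulate(fit$fixed))
  set.seed(substream_seed(seed, paste0("perm:", predictor)))
  n <- nrow(dat)
  if (unit == "species") {
    sp <- factor(dat$species)
    sp_idx <- as.integer(sp)
    vals <- dat[[perm_var]][match(levels(sp), as.character(dat$species))]
    n_sp <- nlevels(sp)
  }
  engine <- make_perm_engine(fit)
  F_perm <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    dp <- dat
    if (unit == "species") {
      dp[[perm_var]] <- vals[sample.int(n_sp)][sp_idx]
    } else {
      dp[[perm_var]] <- dat[[perm_var]][sample.int(n)]
    }
    F_perm[b] <- tryCatch({
      Xb <- model.matrix(mt, dp)
      rf <- engine(Xb)
      wald_F(rf$beta, rf$V, cols_pred)
    }, error = function(e) NA_real_)
  }
  engine(NULL)  # release: restore the engine's matrix to the observed X
  ok <- !is.na(F_perm)
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * B) {
    warning(n_failed, " of ", B, " permutation refits failed; p computed ",
            "over completed replicates")
  }
  p <- (1 + sum(F_perm[ok] >= F_obs)) / (sum(ok) + 1)
  structure(list(predictor = fit$term_labels[k_pred], F_observed = F_obs,
                 F_permuted = F_perm[ok], p_empirical = p, unit = unit,
                 B = B, n_failed = n_failed),
            class = "permutation_result")
}

is_species_level <- function(dat, var) {
  if (!"species" %in% names(dat)) return(FALSE)
  v <- as.character(dat[[var]])
  all(tapply(v, dat$species, function(x) length(unique(x)) == 1L))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation F test for '%s' (%s-level permutation)\n",
              x$predictor, x$unit))
  cat(sprintf("  F observed = %.4f, B = %d (%d failed), p = %.4g\n",
              x$F_observed, x$B, x$n_failed, x$p_empirical))
  invisible(x)
}

#' Select climate synchrony covariates by permutation significance
#'
#' Fits the all-species model — controls plus all candidate climate
#' synchrony variables jointly, with crossed random intercepts — and keeps
#' every candidate whose row-level permutation p-value is below `alpha`.
#' Candidate pairs correlated above `collinearity_threshold` in absolute
#' value trigger a warning.
#'
#' @param table modelling table from [build_model_table()].
#' @param candidates climate variable column names (default: the table's
#'   recorded climate variables).
#' @param controls control fixed effects.
#' @param alpha selection threshold on the permutation p (default 0.05).
#' @param B permutations per candidate (default 1000).
#' @param seed master integer seed.
#' @param random random-intercept factors.
#' @param collinearity_threshold absolute pairwise correlation above which
#'   a warning is issued (default 0.7).
#' @return list: `kept` (selected names), `results` (data.frame term, F,
#'   p_perm), `fit` (the joint [fit_lmm()] object).
#' @export
select_climate_covariates <- function(table, candidates = NULL,
                                      controls = c("distance_km",
                                                   "habitat_similarity",
                                                   "mean_northing_km",
                                                   "mid_year"),
                                      alpha = 0.05, B = 1000, seed = 1,
                                      random = c("species", "pair_id"),
                                      collinearity_threshold = 0.7) {
  candidates <- candidates %||% attr(table, "climate_vars")
  if (is.null(candidates) || length(candidates) == 0L) {
    stop("no candidate climate variables supplied or recorded on the table")
  }
  stop_if_missing_cols(table, candidates, "table")
  cm <- cor(as.matrix(table[candidates]))
  hi <- which(abs(cm) > collinearity_threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(hi) > 0L) {
    warning("collinear candidate pair(s): ",
            paste(sprintf("%s~%s (r=%.2f)", candidates[hi[, 1]],
                          candidates[hi[, 2]], cm[hi]), collapse = ", "))
  }
  fit <- fit_lmm(table, fixed = c(controls, candidates), random = random)
  res <- lapply(candidates, function(v) {
    permutation_test(fit, v, B = B, seed = seed, unit = "rows")
  })
  p <- vapply(res, function(x) x$p_empirical, numeric(1))
  results <- data.frame(
    term = candidates,
    F = vapply(res, function(x) x$F_observed, numeric(1)),
    p_perm = p, stringsAsFactors = FALSE
  )
  list(kept = candidates[p < alpha], results = results, fit = fit)
}

#' Attribute effects on average synchrony and on its temporal trend
#'
#' For each species attribute, fits two models on the rows where the
#' attribute is available: (A) the attribute as an additional fixed effect
#' next to the controls and selected climate covariates — its permutation p
#' tests an association with average synchrony; and (B) the same model plus
#' an attribute x mid-year interaction — its permutation p tests a
#' difference in the temporal trend of synchrony between attribute levels.
#' Species-level attributes are permuted across species. For the
#' significance-screened change class (`change_class_sig`), species classed
#' `"excluded"` are dropped first. Attributes with a single level after
#' dropping are skipped with a warning.
#'
#' @param table modelling table with attribute columns.
#' @param attributes attribute column names (default: the standard four).
#' @param climate_vars selected climate covariates (possibly empty).
#' @param controls control fixed effects.
#' @param B permutations per test.
#' @param seed master integer seed.
#' @param random random-intercept factors; if `"family"` is included and
#'   the fit is singular, it is dropped and flagged.
#' @param effects which of the two models to fit per attribute (default
#'   both).
#' @return data.frame: attribute, effect (`average_synchrony` or `trend`),
#'   term, estimate, se, F, p_perm, n_rows, n_species, singular,
#'   family_dropped.
#' @export
attribute_models <- function(table,
                             attributes = c("specialism", "mobility",
                                            "mean_abundance",
                                            "change_class_all"),
                             climate_vars = character(0),
                             controls = c("distance_km",
                                          "habitat_similarity",
                                          "mean_northing_km", "mid_year"),
                             B = 1000, seed = 1,
                             random = c("species", "pair_id"),
                             effects = c("average_synchrony", "trend")) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  for (a in attributes) {
    if (!a %in% names(table)) {
      warning("attribute '", a, "' not in table; skipped")
      next
    }
    sub <- table[!is.na(table[[a]]), , drop = FALSE]
    if (identical(a, "change_class_sig")) {
      sub <- sub[sub[[a]] != "excluded", , drop = FALSE]
    }
    lev <- unique(sub[[a]])
    if (nrow(sub) == 0L || length(lev) < 2L) {
      warning("attribute '", a, "' constant after join; skipped")
      next
    }
    base <- c(controls, climate_vars)
    inter <- paste0(a, ":mid_year")
    for (effect in effects) {
      fx <- if (effect == "average_synchrony") c(base, a) else
        c(base, a, inter)
      pred <- if (effect == "average_synchrony") a else inter
      row <- tryCatch({
        fit <- fit_lmm(sub, fixed = fx, random = random)
        pt <- permutation_test(fit, pred, B = B, seed = seed)
        k <- match_term(fit$term_labels, pred)
        data.frame(attribute = a, effect = effect,
                   term = fit$term_labels[k],
                   estimate = fit$coefficients$estimate[k],
                   se = fit$coefficients$se[k],
                   F = pt$F_observed, p_perm = pt$p_empirical,
                   n_rows = nrow(sub),
                   n_species = length(unique(sub$species)),
                   singular = fit$singular,
                   family_dropped = fit$family_dropped,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("attribute '", a, "' (", effect, ") failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) {
    return(data.frame(attribute = character(), effect = character(),
                      term = character(), estimate = numeric(),
                      se = numeric(), F = numeric(), p_perm = numeric(),
                      n_rows = integer(), n_species = integer(),
                      singular = logical(), family_dropped = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
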