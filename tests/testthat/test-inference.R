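# Mixed models and permutation inference.

test_that("standardise centres, scales, and is idempotent", {
  expect_equal(standardise(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 4)
  z <- standardise(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(standardise(standardise(x)), standardise(x), tolerance = 1e-10)
  expect_equal(standardise(3 + 2 * x), standardise(x))  # affine invariance
  expect_error(standardise(rep(4, 10)), "zero variance")
})

test_that("fit_lmm recovers planted fixed effects and variance components", {
  set.seed(42)
  n_sp <- 200; n_per <- 25
  d <- data.frame(species = rep(sprintf("s%03d", 1:n_sp), each = n_per),
                  pair_id = sprintf("p%04d", rep(1:(n_sp * n_per %/% 5), length.out = n_sp * n_per)))
  d$x <- rnorm(nrow(d))
  u <- rnorm(n_sp, 0, 0.3)
  d$r <- 0.1 * d$x + u[match(d$species, unique(d$species))] +
    rnorm(nrow(d), 0, 0.2)
  fit <- fit_lmm(d, fixed = "x")
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "x"] - 0.1),
            3 * co$se[co$term == "x"])
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  sp_sd <- vc$sdcor[vc$grp == "species"]
  expect_gt(sp_sd, 0.15); expect_lt(sp_sd, 0.45)

  # permuted predictor: coefficient within 3 SE of zero
  d$x0 <- sample(d$x)
  fit0 <- fit_lmm(d, fixed = "x0")
  co0 <- fit0$coefficients
  expect_lt(abs(co0$estimate[co0$term == "x0"]), 3 * co0$se[co0$term == "x0"])
})

test_that("fit_lmm validates degenerate inputs", {
  d <- null_model_table(n_species = 5, n_pairs = 10, n_windows = 2)
  d$const <- 1
  expect_error(fit_lmm(d, fixed = "const"), "zero variance|single level")
  d$dup <- d$attr * 2
  expect_error(fit_lmm(d, fixed = c("attr", "dup")), "aliased")
  d1 <- d; d1$species <- "one"
  expect_error(fit_lmm(d1, fixed = "attr"), "single level")
})

test_that("permutation p follows the add-one rule and catches planted effects", {
  d <- null_model_table(n_species = 12, n_pairs = 30, n_windows = 3, seed = 2)
  # overwhelming species-level effect: observed F beats every permutation
  d$r <- d$r + 1.0 * d$attr
  fit <- fit_lmm(d, fixed = "attr")
  pt <- permutation_test(fit, "attr", B = 39, seed = 1)
  expect_equal(pt$p_empirical, 1 / 40)
  expect_equal(pt$unit, "species")
  expect_length(pt$F_permuted, 39)
  expect_error(permutation_test(fit, "attr", B = 10), "at least 19")
  expect_error(permutation_test(fit, "nope", B = 39), "does not name")
  # reproducible under the same seed
  pt2 <- permutation_test(fit, "attr", B = 39, seed = 1)
  expect_identical(pt$F_permuted, pt2$F_permuted)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(11)
  ps <- vapply(1:80, function(i) {
    d <- null_model_table(n_species = 10, n_pairs = 15, n_windows = 2,
                          seed = 1000 + i)
    fit <- fit_lmm(d, fixed = "attr")
    permutation_test(fit, "attr", B = 49, seed = i)$p_empirical
  }, numeric(1))
  # chi-squared goodness of fit against uniform on 4 bins, 1% level
  obs <- table(cut(ps, breaks = c(0, 0.25, 0.5, 0.75, 1)))
  expect_gt(chisq.test(obs)$p.value, 0.01)
  # rejection rate compatible with the nominal 5% level
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("row-level predictors are permuted across rows", {
  d <- null_model_table(n_species = 8, n_pairs = 20, n_windows = 3, seed = 3)
  d$clim <- rnorm(nrow(d))
  d$r <- d$r + 0.3 * d$clim
  fit <- fit_lmm(d, fixed = c("attr", "clim"))
  pt <- permutation_test(fit, "clim", B = 39, seed = 2)
  expect_equal(pt$unit, "rows")
  expect_equal(pt$p_empirical, 1 / 40)
})

test_that("climate covariate selection keeps planted drivers and honours alpha", {
  set.seed(21)
  vars <- c("temperature_winter", "temperature_summer",
            "precipitation_winter", "precipitation_summer")
  d <- null_model_table(n_species = 8, n_pairs = 40, n_windows = 4, seed = 8)
  for (v in vars) d[[v]] <- rnorm(nrow(d))
  d$distance_km <- rnorm(nrow(d)); d$habitat_similarity <- runif(nrow(d))
  d$mean_northing_km <- rnorm(nrow(d))
  d$r <- d$r + 0.25 * d$temperature_winter
  sel <- select_climate_covariates(d, candidates = vars, B = 49, seed = 4)
  expect_true("temperature_winter" %in% sel$kept)
  # degenerate threshold keeps everything
  sel_all <- select_climate_covariates(d, candidates = vars, alpha = 1,
                                       B = 19, seed = 4)
  expect_equal(sort(sel_all$kept), sort(vars))
  # collinear candidates are flagged
  d$temperature_spring <- d$temperature_winter + rnorm(nrow(d), 0, 0.1)
  expect_warning(
    select_climate_covariates(d, candidates = c(vars, "temperature_spring"),
                              B = 19, seed = 4),
    "collinear")
})

test_that("attribute models fit average and trend effects and skip degenerates", {
  d <- null_model_table(n_species = 10, n_pairs = 25, n_windows = 4, seed = 5)
  d$distance_km <- rnorm(nrow(d)); d$habitat_similarity <- runif(nrow(d))
  d$mean_northing_km <- rnorm(nrow(d))
  d$specialism <- rep(c("generalist", "specialist"), 5)[
    match(d$species, unique(d$species))]
  d$mobility <- rnorm(10)[match(d$species, unique(d$species))]
  res <- attribute_models(d, attributes = c("specialism", "mobility"),
                          B = 19, seed = 6)
  expect_equal(nrow(res), 4)
  expect_setequal(unique(res$effect), c("average_synchrony", "trend"))
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
  expect_true(all(res$n_species == 10))

  d$constattr <- "same"
  expect_warning(res2 <- attribute_models(d, attributes = "constattr", B = 19),
                 "constant")
  expect_equal(nrow(res2), 0)
})

test_that("family random effect is dropped on singular fits and flagged", {
  # family variance truly zero -> boundary fit -> automatic fallback
  d <- null_model_table(n_species = 12, n_pairs = 20, n_windows = 3, seed = 9)
  d$family <- rep(c("F1", "F2", "F3"), 4)[match(d$species, unique(d$species))]
  fit <- fit_lmm(d, fixed = "attr", random = c("species", "pair_id", "family"))
  if (fit$family_dropped) {
    expect_false("family" %in% fit$random)
  } else {
    expect_true("family" %in% fit$random)
  }
  # fit succeeds either way and reports every term
  expect_equal(fit$coefficients$term, "attr")
})
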