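# Mixed-model fitting. Estimation is restricted maximum likelihood through
# lme4; per-term F statistics are marginal Wald statistics computed from the
# estimated coefficient covariance. Denominator degrees of freedom are never
# used: significance comes from the permutation distribution of the same F,
# so only within-analysis consistency of the statistic matters. A fast
# refit path (reusing the parsed model structure and warm-starting the
# variance-component optimisation at the observed optimum) makes the
# thousand-fold permutation refits affordable.

lmm_control <- function() {
  lme4::lmerControl(check.rankX = "ignore",
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE)
}

#' Fit a synchrony mixed-effects model
#'
#' REML fit of `response ~ fixed effects + crossed random intercepts`.
#' Numeric fixed-effect columns are standardised to zero mean and unit sd
#' before fitting; character/logical columns become factors. If the fit is
#' singular (a random-effect variance at the boundary) and `"family"` is
#' among the random factors, the family intercept is removed and the model
#' refitted, with both facts flagged.
#'
#' @param table modelling table from [build_model_table()].
#' @param fixed character vector of fixed-effect terms (may include
#'   interactions like `"specialism:mid_year"`).
#' @param response response column name (default `"r"`).
#' @param random random-intercept factor names (default species and pair).
#' @param standardise_predictors standardise numeric fixed effects
#'   (default TRUE).
#' @return object of class `sync_lmm`: list with the `merMod` fit,
#'   `coefficients` (term table with estimate, se, F), `singular`,
#'   `family_dropped`, and the parsed structures reused by
#'   [permutation_test()].
#' @export
fit_lmm <- function(table, fixed, response = "r",
                    random = c("species", "pair_id"),
                    standardise_predictors = TRUE) {
  stopifnot(length(fixed) >= 1, length(random) >= 1)
  vars <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  stop_if_missing_cols(table, c(response, vars, random), "table")
  dat <- table[, unique(c(response, vars, random)), drop = FALSE]
  if (anyNA(dat)) stop("missing values in modelled columns; drop them first")
  for (v in vars) {
    if (is.character(dat[[v]]) || is.logical(dat[[v]])) {
      dat[[v]] <- factor(dat[[v]])
    }
    if (is.factor(dat[[v]]) && nlevels(droplevels(dat[[v]])) < 2L) {
      stop("fixed effect '", v, "' has a single level")
    }
    if (standardise_predictors && is.numeric(dat[[v]])) {
      s <- sd(dat[[v]])
      if (!is.finite(s) || s == 0) stop("zero variance in column ", v)
      dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
    }
  }
  for (g in random) dat[[g]] <- factor(dat[[g]])
  for (g in random) {
    if (nlevels(dat[[g]]) < 2L) stop("random factor '", g, "' has a single level")
  }

  res <- fit_lmm_once(dat, fixed, response, random)
  family_dropped <- FALSE
  if (res$singular && "family" %in% random) {
    res <- fit_lmm_once(dat, fixed, response, setdiff(random, "family"))
    family_dropped <- TRUE
    random <- setdiff(random, "family")
  }
  res$family_dropped <- family_dropped
  res$random <- random
  res$data <- dat
  res$fixed <- fixed
  res$response <- response
  class(res) <- "sync_lmm"
  res
}

# One REML fit; returns parsed structures, merMod, per-term Wald F table.
fit_lmm_once <- function(dat, fixed, response, random) {
  fml <- as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  ctrl <- lmm_control()
  parsed <- lme4::lFormula(fml, data = dat, REML = TRUE, control = ctrl)
  X <- parsed$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed effects; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  devfun <- do.call(lme4::mkLmerDevfun, parsed)
  opt <- lme4::optimizeLmer(devfun, control = ctrl$optCtrl)
  if (!is.null(opt$conv) && opt$conv != 0 && abs(opt$conv) > 1) {
    stop("mixed-model optimizer failed to converge (code ", opt$conv, "): ",
         paste(unlist(opt$message), collapse = "; "))
  }
  fit <- lme4::mkMerMod(environment(devfun), opt, parsed$reTrms,
                        fr = parsed$fr)
  singular <- any(opt$par < 1e-4)

  term_labels <- attr(terms(reformulate(fixed)), "term.labels")
  assign <- attr(X, "assign")
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  coefs <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
    cols <- which(assign == k)
    data.frame(term = term_labels[k],
               estimate = if (length(cols) == 1L) beta[cols] else NA_real_,
               se = if (length(cols) == 1L) sqrt(V[cols, cols]) else NA_real_,
               df_num = length(cols),
               F = wald_F(beta, V, cols),
               stringsAsFactors = FALSE)
  }))
  rownames(coefs) <- NULL
  list(fit = fit, parsed = parsed, theta = opt$par, singular = singular,
       coefficients = coefs, term_labels = term_labels, assign = assign,
       formula = fml)
}

# Marginal Wald F for a set of coefficient columns.
wald_F <- function(beta, V, cols) {
  b <- beta[cols]
  drop(crossprod(b, solve(V[cols, cols, drop = FALSE], b))) / length(cols)
}

#' @export
print.sync_lmm <- function(x, ...) {
  cat("Synchrony mixed model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d rows, %s\n", nrow(x$data),
              paste(sprintf("%s: %d levels", x$random,
                            vapply(x$random, function(g) nlevels(x$data[[g]]),
                                   integer(1))), collapse = ", ")))
  if (x$singular) cat("NOTE: singular fit\n")
  if (x$family_dropped) cat("NOTE: family random effect dropped (singular)\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# ---- fast refit paths used by the permutation engine ---------------------

# Build a closure that refits the model for an arbitrary fixed-effects
# matrix of the observed shape. Where possible it reuses a single set of
# penalized-least-squares structures, pushing each permuted X into the
# live matrix the structures were built around (their C++ side maps that
# memory) — avoiding the fixed construction cost of a rebuild on every
# permutation. The shortcut is verified against the observed fit at
# construction; if the internal layout is not as expected, or the check
# fails, every call transparently falls back to a full rebuild
# (refit_with_X), which computes the identical statistic.
make_perm_engine <- function(fit) {
  parsed <- fit$parsed
  theta_start <- fit$theta
  fallback <- function(X_new) refit_with_X(parsed, X_new, theta_start)
  eng <- tryCatch({
    devfun <- do.call(lme4::mkLmerDevfun, parsed)
    env <- environment(devfun)
    pp <- env$pp; resp <- env$resp
    X_live <- get(".->X", envir = as.environment(pp))
    stopifnot(identical(dim(X_live), dim(parsed$X)))
    X_orig <- parsed$X + 0  # deep copy for release/restore
    lower <- parsed$reTrms$lower
    n <- nrow(parsed$X); p <- ncol(parsed$X)
    th_cur <- theta_start  # successive permuted optima cluster; chain them
    run <- function(X_new) {
      fill_matrix_inplace(X_live, X_new)
      pp$updateXwts(resp$sqrtXwt)
      o <- nloptr::nloptr(
        x0 = pmax(th_cur, lower), eval_f = function(th) devfun(th),
        lb = lower, ub = rep(Inf, length(lower)),
        opts = list(algorithm = "NLOPT_LN_BOBYQA", xtol_abs = 1e-3,
                    ftol_abs = 1e-7, maxeval = 500))
      devfun(o$solution)
      th_cur <<- o$solution
      beta <- pp$beta(1)
      sigma2 <- (resp$wrss() + pp$sqrL(1)) / (n - p)
      list(beta = beta, V = sigma2 * pp$unsc(), theta = o$solution)
    }
    # verify on the observed X against the reference implementation
    chk <- run(X_orig)
    ref <- fit$coefficients$F
    got <- vapply(seq_along(fit$term_labels), function(k) {
      wald_F(chk$beta, chk$V, which(fit$assign == k))
    }, numeric(1))
    stopifnot(all(abs(got - ref) <= 1e-4 * pmax(abs(ref), 1)))
    function(X_new) {
      if (is.null(X_new)) { run(X_orig); return(invisible(NULL)) }
      run(X_new)
    }
  }, error = function(e) NULL)
  if (is.null(eng)) {
    function(X_new) {
      if (is.null(X_new)) return(invisible(NULL))
      fallback(X_new)
    }
  } else {
    eng
  }
}

# Refit the model with a modified fixed-effects matrix, warm-starting the
# variance-component search at `theta_start`. Returns what the Wald F needs.
refit_with_X <- function(parsed, X_new, theta_start) {
  pa <- parsed
  pa$X <- X_new
  devfun <- do.call(lme4::mkLmerDevfun, pa)
  lower <- pa$reTrms$lower
  o <- nloptr::nloptr(
    x0 = pmax(theta_start, lower), eval_f = function(th) devfun(th),
    lb = lower, ub = rep(Inf, length(lower)),
    opts = list(algorithm = "NLOPT_LN_BOBYQA", xtol_abs = 1e-3,
                ftol_abs = 1e-7, maxeval = 500)
  )
  devfun(o$solution)  # leave internal state at the optimum
  env <- environment(devfun)
  pp <- env$pp; resp <- env$resp
  n <- nrow(X_new); p <- ncol(X_new)
  beta <- pp$beta(1)
  sigma2 <- (resp$wrss() + pp$sqrL(1)) / (n - p)
  list(beta = beta, V = sigma2 * pp$unsc(), theta = o$solution)
}
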