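# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' Simulation stages (climate field, population dynamics, observation,
#' survey gaps, pair subsampling, permutations) each draw from their own
#' substream so that, e.g., two runs differing only in dispersal share the
#' same climate and process-noise draws. The substream seed is a
#' deterministic integer hash of the master seed and the stream label,
#' always in `[0, 2^31 - 1)`.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1, "climate")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  chars <- utf8ToInt(stream)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483423
  as.integer((abs(seed) * 2654435 + h * 97 + 17) %% 2147483423)
}

stop_if_missing_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Canonical unordered pair: site_a < site_b lexicographically.
canonicalise_pairs <- function(site_a, site_b) {
  a <- as.character(site_a); b <- as.character(site_b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(site_a = a, site_b = b, stringsAsFactors = FALSE)
}

#' Canonical identifier for an unordered site pair
#'
#' @param site_a,site_b site ids (already in canonical order).
#' @return character vector of pair ids.
#' @export
pair_id <- function(site_a, site_b) paste(site_a, site_b, sep = "--")

#' Pearson correlation with explicit degenerate handling
#'
#' Sample Pearson correlation of two equal-length vectors. Unlike
#' [stats::cor()], a zero-variance input yields `NA_real_` silently (the
#' caller decides whether to drop the record); length below 2 is an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA_real_` if either input has zero
#'   variance.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; subset first")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  r <- sum(xc * yc) / sqrt(sxx * syy)
  max(-1, min(1, r))
}
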