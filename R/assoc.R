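# Vectorized linear-association engine shared by every pyramid stage and by
# the genome-wide comparison scans.
#
# All stage models are simple linear regressions of a response on a single
# predictor plus an optional shared covariate block W:
#
#   y_i = b0 + b1 x_i + W_i g + e_i,   e_i ~ N(0, s^2)
#
# and every reported statistic concerns b1. With W absent the slope, SE, t
# and p follow from centered cross-products; with W present, predictor and
# response are first projected onto the orthogonal complement of [1, W]
# (Frisch-Waugh-Lovell), after which the same cross-product algebra applies
# with df = n - k - 2.
#
# Numerical contract: per-pair statistics are built exclusively from per-row
# quantities (row means, row sums of squares) and per-pair dot products
# accumulated in sample order via colSums(). Subsetting the feature axes
# therefore reproduces the full-matrix computation bit for bit — the property
# the permutation-null cache relies on.

#' Fit a single linear association
#'
#' Ordinary least squares of `y` on `[1, x, W]`, reporting the slope on `x`,
#' its standard error, the t statistic and a two-sided p-value from the
#' Student t distribution with `n - k - 2` residual degrees of freedom.
#' Rows with a missing value in `y`, `x` or any covariate are dropped
#' (complete-case analysis).
#'
#' A predictor that is constant after complete-case reduction yields a
#' flagged degenerate result (`slope = 0`, `se = NA`, `pvalue = 1`,
#' `degenerate = TRUE`) rather than an error, so genome-wide scans built on
#' this primitive always run to completion.
#'
#' @param y Numeric response vector.
#' @param x Numeric predictor vector, same length as `y`.
#' @param covariates Optional numeric matrix (samples in rows) of shared
#'   covariates, e.g. ancestry principal components or hidden expression
#'   factors. Default none.
#' @param x_id,y_id Identifiers recorded in the output row.
#'
#' @return A one-row tibble with columns `x_id`, `y_id`, `slope`,
#'   `intercept`, `se`, `tstat`, `pvalue`, `n_used`, `df_resid`,
#'   `degenerate`.
#'
#' @examples
#' fit_linear_assoc(c(1, 3, 5, 7), c(0, 1, 2, 3))
#' @export
fit_linear_assoc <- function(y, x, covariates = NULL, x_id = "x", y_id = "y") {
  if (length(y) != length(x)) {
    abort("`y` and `x` must have the same length.")
  }
  W <- check_covariates(covariates, length(y))
  cc <- stats::complete.cases(y, x, if (is.null(W)) rep(0, length(y)) else W)
  n <- sum(cc)
  k <- if (is.null(W)) 0L else ncol(W)
  if (n < k + 3L) {
    abort(sprintf(
      "Too few complete cases (%d) for a slope, intercept and %d covariate(s).",
      n, k
    ))
  }
  yc <- y[cc]
  xc <- x[cc]
  Wc <- if (is.null(W)) NULL else W[cc, , drop = FALSE]

  if (length(unique(xc)) == 1L) {
    return(assoc_row(x_id, y_id,
      slope = 0, intercept = mean(yc), se = NA_real_,
      tstat = NA_real_, pvalue = 1, n_used = n,
      df_resid = n - k - 2L, degenerate = TRUE
    ))
  }

  X <- cbind(`(Intercept)` = 1, x = xc, Wc)
  qx <- qr(X)
  coefs <- qr.coef(qx, yc)
  res <- yc - drop(X %*% coefs)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- coefs[["x"]] / se
  if (is.nan(tval)) { # exact fit with zero slope: no evidence either way
    tval <- 0
    pval <- 1
  } else {
    pval <- 2 * stats::pt(-abs(tval), df)
  }
  assoc_row(x_id, y_id,
    slope = coefs[["x"]], intercept = coefs[["(Intercept)"]], se = se,
    tstat = tval, pvalue = pval, n_used = n, df_resid = df,
    degenerate = FALSE
  )
}

#' Scan all predictor-response pairs for linear association
#'
#' Applies the [fit_linear_assoc()] model to every pair formed by a row of
#' `predictors` and a row of `responses` (or to an explicit pair list), using
#' a vectorized cross-product path when the inputs are complete and falling
#' back to per-pair complete-case fits when missing values are present. The
#' two paths agree with the single-pair fit to numerical precision.
#'
#' @param predictors Feature-by-sample numeric matrix with rownames
#'   (e.g. SNP dosages or miRNA expression).
#' @param responses Feature-by-sample numeric matrix with rownames, sharing
#'   the sample axis with `predictors`.
#' @param covariates Optional sample-by-k covariate matrix.
#' @param pairs Optional two-column data frame (`x_id`, `y_id`) restricting
#'   the scan to the listed pairs; an empty frame yields an empty result.
#'
#' @return A tibble of association rows in deterministic order: predictor
#'   row-major, then response (or the order of `pairs` when supplied).
#' @export
scan_assoc <- function(predictors, responses, covariates = NULL, pairs = NULL) {
  predictors <- as_feature_matrix(predictors, "predictors")
  responses <- as_feature_matrix(responses, "responses")
  if (ncol(predictors) != ncol(responses)) {
    abort("`predictors` and `responses` must share the sample axis.")
  }
  W <- check_covariates(covariates, ncol(predictors))

  if (!is.null(pairs)) {
    pairs <- tibble::as_tibble(pairs)
    names(pairs)[1:2] <- c("x_id", "y_id")
    if (nrow(pairs) == 0L) {
      return(empty_assoc_tbl())
    }
    bad_x <- setdiff(pairs$x_id, rownames(predictors))
    bad_y <- setdiff(pairs$y_id, rownames(responses))
    if (length(bad_x) || length(bad_y)) {
      abort(sprintf(
        "Unknown identifiers in `pairs`: %s",
        paste(head(c(bad_x, bad_y), 5), collapse = ", ")
      ))
    }
  }

  if (nrow(predictors) == 0L || nrow(responses) == 0L) {
    return(empty_assoc_tbl())
  }

  has_na <- anyNA(predictors) || anyNA(responses) || (!is.null(W) && anyNA(W))
  if (has_na) {
    return(scan_assoc_pairwise(predictors, responses, W, pairs))
  }

  stats_mats <- assoc_matrix(predictors, responses, W)
  tbl <- assoc_mats_to_tbl(stats_mats, rownames(predictors), rownames(responses))
  if (!is.null(pairs)) {
    tbl <- dplyr::inner_join(pairs, tbl, by = c("x_id", "y_id"))
  }
  tbl
}

#' Residualize a response on a single predictor
#'
#' Returns `y - (a + b x)` with `(a, b)` the complete-case OLS fit. Missing
#' positions in either input propagate as missing residuals. Over the
#' complete cases the residuals have mean zero and zero sample covariance
#' with `x`. A constant predictor carries no information, so the response is
#' simply mean-centered.
#'
#' @param y Numeric response vector.
#' @param x Numeric predictor vector.
#' @return Numeric vector of residuals, same length as `y`.
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) {
    abort("`y` and `x` must have the same length.")
  }
  cc <- stats::complete.cases(y, x)
  if (sum(cc) < 3L) {
    abort("Need at least 3 complete cases to residualize.")
  }
  out <- rep(NA_real_, length(y))
  xc <- x[cc]
  yc <- y[cc]
  if (length(unique(xc)) == 1L) {
    out[cc] <- yc - mean(yc)
    return(out)
  }
  xm <- xc - mean(xc)
  b <- sum(xm * yc) / sum(xm^2)
  a <- mean(yc) - b * mean(xc)
  out[cc] <- yc - (a + b * xc)
  out
}

# ---- internals --------------------------------------------------------------

# Core matrix engine: X (p x n) predictors, Y (q x n) responses, complete data.
# Returns p x q matrices of slope, se, tstat, pvalue plus scalars df and n.
# Per-pair cross-products are accumulated per response row with colSums() so
# the result is invariant, bit for bit, to subsetting either feature axis.
assoc_matrix <- function(X, Y, W = NULL) {
  n <- ncol(X)
  if (is.null(W)) {
    k <- 0L
    Xc <- X - rowMeans(X)
    Yc <- Y - rowMeans(Y)
  } else {
    k <- ncol(W)
    Q <- qr(cbind(1, W))
    Xc <- t(qr.resid(Q, t(X)))
    Yc <- t(qr.resid(Q, t(Y)))
  }
  df <- n - k - 2L
  if (df < 1L) {
    abort(sprintf("Too few samples (%d) for %d covariate(s).", n, k))
  }
  p <- nrow(X)
  q <- nrow(Y)
  sxx <- rowSums(Xc^2)
  syy <- rowSums(Yc^2)
  tXc <- t(Xc)
  sxy <- matrix(0, p, q)
  for (j in seq_len(q)) {
    sxy[, j] <- colSums(tXc * Yc[j, ])
  }
  degen <- sxx == 0
  sxx_safe <- ifelse(degen, 1, sxx)
  slope <- sxy / sxx_safe
  rss <- pmax(rep(syy, each = p) - slope * sxy, 0)
  se <- sqrt((rss / df) / sxx_safe)
  tstat <- slope / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  nan_t <- is.nan(tstat) # 0/0: zero slope with exact fit (e.g. constant y)
  tstat[nan_t] <- 0
  pval[nan_t] <- 1
  if (any(degen)) {
    slope[degen, ] <- 0
    se[degen, ] <- NA_real_
    tstat[degen, ] <- NA_real_
    pval[degen, ] <- 1
  }
  list(
    slope = slope, se = se, tstat = tstat, pvalue = pval,
    df = df, n = n, degenerate = degen
  )
}

assoc_mats_to_tbl <- function(m, x_ids, y_ids) {
  p <- length(x_ids)
  q <- length(y_ids)
  # deterministic order: predictor row-major, then response
  idx_x <- rep(seq_len(p), each = q)
  idx_y <- rep(seq_len(q), times = p)
  flat <- cbind(idx_x, idx_y)
  tibble::tibble(
    x_id = x_ids[idx_x],
    y_id = y_ids[idx_y],
    slope = m$slope[flat],
    intercept = NA_real_,
    se = m$se[flat],
    tstat = m$tstat[flat],
    pvalue = m$pvalue[flat],
    n_used = m$n,
    df_resid = m$df,
    degenerate = m$degenerate[idx_x]
  )
}

scan_assoc_pairwise <- function(X, Y, W, pairs) {
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(x_id = rownames(X), y_id = rownames(Y))
  }
  purrr::pmap_dfr(pairs[, c("x_id", "y_id")], function(x_id, y_id) {
    fit_linear_assoc(Y[y_id, ], X[x_id, ],
      covariates = W, x_id = x_id, y_id = y_id
    )
  })
}

assoc_row <- function(x_id, y_id, slope, intercept, se, tstat, pvalue,
                      n_used, df_resid, degenerate) {
  tibble::tibble(
    x_id = x_id, y_id = y_id, slope = slope, intercept = intercept,
    se = se, tstat = tstat, pvalue = pvalue, n_used = n_used,
    df_resid = df_resid, degenerate = degenerate
  )
}

empty_assoc_tbl <- function() {
  assoc_row(
    character(), character(), numeric(), numeric(), numeric(),
    numeric(), numeric(), integer(), integer(), logical()
  )
}

check_covariates <- function(covariates, n) {
  if (is.null(covariates)) {
    return(NULL)
  }
  W <- as.matrix(covariates)
  if (!is.numeric(W)) {
    abort("`covariates` must be numeric.")
  }
  if (nrow(W) != n) {
    abort(sprintf(
      "`covariates` has %d rows but there are %d samples.", nrow(W), n
    ))
  }
  W
}

as_feature_matrix <- function(x, what) {
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix.", what))
  }
  if (is.null(rownames(m)) && nrow(m) > 0) {
    rownames(m) <- paste0("f", seq_len(nrow(m)))
  }
  m
}
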