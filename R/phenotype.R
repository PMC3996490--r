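# Drug-specific phenotype (DSP) construction.
#
# Cytotoxicity IC50 in lymphoblastoid cell lines is strongly confounded by
# how fast a line grows: faster-growing cultures look more drug-sensitive
# regardless of any drug-specific biology. The log2 IC50 is therefore
# decomposed as growth plus a drug-specific component, and the DSP is the
# residual of a linear fit of log2 IC50 on the intrinsic growth rate
# (iGrowth, derived upstream and consumed as input). By OLS construction the
# DSP has zero sample covariance with iGrowth.

#' Compute the drug-specific phenotype (DSP)
#'
#' Fits `log2_ic50 ~ igrowth` by OLS over complete cases and returns the
#' residuals as the DSP. Samples missing either input get a missing DSP.
#' A constant `igrowth` carries no growth signal; the DSP then degrades to
#' the mean-centered log2 IC50, with a warning.
#'
#' @param log2_ic50 Per-sample log2 IC50 (or raw IC50 with
#'   `log2_transform = TRUE`; the scale is never guessed).
#' @param igrowth Per-sample intrinsic growth rate.
#' @param drug_label Which agent the IC50 measures (e.g. `"carboplatin"`);
#'   the DSP is computed per drug independently.
#' @param sample_id Optional sample identifiers; defaults to `s1..sn`.
#' @param log2_transform If `TRUE`, `log2()` is applied to `log2_ic50` first.
#'
#' @return A `phenotype_set`: a tibble with columns `sample_id`,
#'   `log2_ic50`, `igrowth`, `dsp`, `drug_label`.
#'
#' @examples
#' set.seed(1)
#' g <- rnorm(20)
#' compute_dsp(2 * g + rnorm(20), g, drug_label = "carboplatin")
#' @export
compute_dsp <- function(log2_ic50, igrowth, drug_label = "drug",
                        sample_id = NULL, log2_transform = FALSE) {
  if (length(log2_ic50) != length(igrowth)) {
    abort("`log2_ic50` and `igrowth` must have the same length.")
  }
  if (log2_transform) {
    if (any(log2_ic50 <= 0, na.rm = TRUE)) {
      abort("Raw IC50 values must be positive to log2-transform.")
    }
    log2_ic50 <- log2(log2_ic50)
  }
  if (sum(stats::complete.cases(log2_ic50, igrowth)) < 3L) {
    abort("Need at least 3 samples with both log2 IC50 and iGrowth.")
  }
  cc <- stats::complete.cases(igrowth)
  if (length(unique(igrowth[cc])) == 1L) {
    warn("`igrowth` is constant; DSP is the mean-centered log2 IC50.")
  }
  dsp <- residualize(log2_ic50, igrowth)
  if (is.null(sample_id)) {
    sample_id <- paste0("s", seq_along(log2_ic50))
  }
  structure(
    tibble::tibble(
      sample_id = as.character(sample_id),
      log2_ic50 = log2_ic50,
      igrowth = igrowth,
      dsp = dsp,
      drug_label = drug_label
    ),
    class = c("phenotype_set", "tbl_df", "tbl", "data.frame")
  )
}

#' Phenotype diagnostics: the three IC50 / growth / DSP panels
#'
#' Squared Pearson correlation and two-sided p-value for each of
#' `log2_ic50 ~ igrowth` (how much growth drives raw sensitivity),
#' `dsp ~ igrowth` (orthogonality check; r-squared is numerically zero by
#' construction) and `dsp ~ log2_ic50` (how much of the raw phenotype the
#' DSP retains).
#'
#' @param pheno A `phenotype_set` from [compute_dsp()].
#' @return A tibble with columns `comparison`, `r_squared`, `pvalue`,
#'   `n_used`.
#' @export
phenotype_diagnostics <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  panels <- list(
    c("log2_ic50", "igrowth"),
    c("dsp", "igrowth"),
    c("dsp", "log2_ic50")
  )
  purrr::map_dfr(panels, function(p) {
    fit <- fit_linear_assoc(pheno[[p[1]]], pheno[[p[2]]],
      x_id = p[2], y_id = p[1]
    )
    r2 <- if (fit$degenerate) NA_real_ else {
      tval <- fit$tstat
      tval^2 / (tval^2 + fit$df_resid)
    }
    tibble::tibble(
      comparison = paste(p[1], "~", p[2]),
      r_squared = r2,
      pvalue = fit$pvalue,
      n_used = fit$n_used
    )
  })
}

#' @describeIn compute_dsp Scatter panels of IC50 vs growth, DSP vs growth
#'   and DSP vs IC50 for a `phenotype_set`.
#' @param object,... `phenotype_set` and ignored extra arguments.
#' @method autoplot phenotype_set
#' @export
autoplot.phenotype_set <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "log2 IC50 vs iGrowth", x = object$igrowth, y = object$log2_ic50),
    tibble::tibble(panel = "DSP vs iGrowth", x = object$igrowth, y = object$dsp),
    tibble::tibble(panel = "DSP vs log2 IC50", x = object$log2_ic50, y = object$dsp)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = unique(object$drug_label)[1]) +
    ggplot2::theme_minimal()
}
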