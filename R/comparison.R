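# Benchmark scans the pyramid is compared against, and QQ utilities for the
# three-way comparison (traditional GWAS vs eQTL-filtered vs pyramid).

#' Traditional GWAS of the trait
#'
#' The stage-6 SNP-trait model applied to every MAF-passing SNP with no
#' pyramid filtering.
#'
#' @inheritParams run_pyramid
#' @return A tibble of association rows (`snp_id`, `slope`, `se`, `tstat`,
#'   `pvalue`, `n_used`, `df_resid`).
#' @export
traditional_gwas <- function(dataset, trait, cfg = pyramid_config()) {
  stopifnot(inherits(dataset, "omic_dataset"))
  dataset <- filter_snps_by_maf(dataset, cfg$maf_min)
  stats <- scan_assoc(
    dataset$genotypes, trait_vector(dataset, trait),
    covariates = stage_covariates(cfg, 6, dataset)
  )
  dplyr::select(dplyr::rename(stats, snp_id = "x_id"), -"y_id", -"intercept")
}

#' eQTL-filtered GWAS of the trait
#'
#' Restricts the SNP-trait scan to SNPs associated with the expression of a
#' trait-associated gene: stage 1 selects genes, stage 4 selects SNPs
#' against those genes, and the stage-6 model is applied to the surviving
#' SNPs. No miRNA layer is involved. With `alpha_stage4 = 1` every SNP
#' passes the expression filter and the result equals [traditional_gwas()].
#'
#' @inheritParams run_pyramid
#' @return A tibble of association rows for the eligible SNPs, with the
#'   stage-1 gene set attached as attribute `"genes"`.
#' @export
eqtl_filtered_gwas <- function(dataset, trait, cfg = pyramid_config()) {
  stopifnot(inherits(dataset, "omic_dataset"))
  dataset <- filter_snps_by_maf(dataset, cfg$maf_min)
  r1 <- stage1_trait_mrna(dataset, trait, cfg)
  r4 <- stage4_eqtl_scan(dataset, r1$stats$gene_id, cfg)
  snps <- unique(r4$stats$snp_id)
  stats <- scan_assoc(
    dataset$genotypes[snps, , drop = FALSE], trait_vector(dataset, trait),
    covariates = stage_covariates(cfg, 6, dataset)
  )
  out <- dplyr::select(dplyr::rename(stats, snp_id = "x_id"),
                       -"y_id", -"intercept")
  attr(out, "genes") <- r1$stats$gene_id
  out
}

#' Expected vs observed quantiles of a p-value set
#'
#' Observed p-values sorted ascending are paired with the uniform quantiles
#' `(i - 0.5) / m`, both on the -log10 scale.
#'
#' @param pvalues Numeric vector of p-values.
#' @return A tibble with columns `pvalue`, `expected`, `observed`
#'   (`expected` and `observed` are -log10).
#' @export
qq_data <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  m <- length(pvalues)
  p <- sort(pvalues)
  tibble::tibble(
    pvalue = p,
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(p)
  )
}

#' QQ plot of one or more p-value sets
#'
#' @param data A data frame with a `pvalue` column and, optionally, a
#'   `method` column distinguishing p-value sets (e.g. `"gwas"`, `"eqtl"`,
#'   `"pyramid"`); quantiles are computed within method.
#' @return A ggplot object.
#' @export
plot_qq <- function(data) {
  stopifnot(is.data.frame(data), "pvalue" %in% names(data))
  if (!"method" %in% names(data)) {
    data$method <- "observed"
  }
  qq <- dplyr::group_modify(
    dplyr::group_by(data, .data$method),
    ~ qq_data(.x$pvalue)
  )
  ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
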