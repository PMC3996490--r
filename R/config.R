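#' Pyramid stage thresholds and policies
#'
#' Holds the six stage p-value cutoffs, their comparison operators, the
#' stage-3 sign constraint, the MAF filter and the covariate policy. The
#' defaults are the method's standard operating point: p < 0.05 for the
#' trait-mRNA and trait-miRNA screens (stages 1-2) and the miRNA-QTL scan
#' (stage 5), p < 1e-4 for the negative miRNA-mRNA correlation (stage 3),
#' and inclusive p <= 1e-4 for the eQTL scan (stage 4) and the final
#' SNP-trait test (stage 6). The strict/inclusive operators are part of the
#' operating point and are not tunable.
#'
#' @param alpha_stage1 Trait-mRNA threshold (strict `<`), default 0.05.
#' @param alpha_stage2 Trait-miRNA threshold (strict `<`), default 0.05.
#' @param alpha_stage3 miRNA-mRNA threshold (strict `<`), default 1e-4.
#' @param alpha_stage4 SNP-mRNA (eQTL) threshold (inclusive `<=`), default 1e-4.
#' @param alpha_stage5 SNP-miRNA threshold (strict `<`), default 0.05.
#' @param alpha_stage6 SNP-trait threshold (inclusive `<=`), default 1e-4.
#' @param require_negative_stage3 Keep only miRNA-mRNA pairs with a negative
#'   slope (miRNA activity assumed to down-regulate targets). Default `TRUE`.
#' @param maf_min Minimum minor-allele frequency for SNP inclusion, default
#'   0.05.
#' @param use_covariates_stages Which stages receive the covariate block `W`
#'   when the dataset carries one. Default `c(1, 2, 4, 5, 6)` — the stage-3
#'   expression-expression model carries no covariate term.
#' @param stage5_snps `"all"` (default) scans every MAF-passing SNP at stage
#'   5 independently of stage 4; `"stage4"` restricts stage 5 to stage-4
#'   surviving SNPs. Either way stage-6 candidates are the SNPs surviving
#'   both QTL stages.
#'
#' @return A `pyramid_config` object (list).
#' @export
pyramid_config <- function(alpha_stage1 = 0.05,
                           alpha_stage2 = 0.05,
                           alpha_stage3 = 1e-4,
                           alpha_stage4 = 1e-4,
                           alpha_stage5 = 0.05,
                           alpha_stage6 = 1e-4,
                           require_negative_stage3 = TRUE,
                           maf_min = 0.05,
                           use_covariates_stages = c(1, 2, 4, 5, 6),
                           stage5_snps = c("all", "stage4")) {
  alphas <- c(alpha_stage1, alpha_stage2, alpha_stage3,
              alpha_stage4, alpha_stage5, alpha_stage6)
  if (any(!is.finite(alphas)) || any(alphas <= 0) || any(alphas > 1)) {
    abort("All stage thresholds must lie in (0, 1].")
  }
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5) {
    abort("`maf_min` must lie in [0, 0.5).")
  }
  stage5_snps <- match.arg(stage5_snps)
  if (3 %in% use_covariates_stages) {
    abort("Stage 3 (miRNA-mRNA) carries no covariate term.")
  }
  structure(
    list(
      alpha_stage1 = alpha_stage1,
      alpha_stage2 = alpha_stage2,
      alpha_stage3 = alpha_stage3,
      alpha_stage4 = alpha_stage4,
      alpha_stage5 = alpha_stage5,
      alpha_stage6 = alpha_stage6,
      # operators are part of the operating point, not tunable
      operators = c("<", "<", "<", "<=", "<", "<="),
      require_negative_stage3 = isTRUE(require_negative_stage3),
      maf_min = maf_min,
      use_covariates_stages = as.integer(use_covariates_stages),
      stage5_snps = stage5_snps
    ),
    class = "pyramid_config"
  )
}

#' @export
print.pyramid_config <- function(x, ...) {
  cat("<pyramid_config>\n")
  labs <- c("trait~mRNA", "trait~miRNA", "mRNA~miRNA (neg.)",
            "mRNA~SNP (eQTL)", "miRNA~SNP", "trait~SNP")
  for (i in 1:6) {
    cat(sprintf("  stage %d  %-18s p %s %g\n", i, labs[i], x$operators[i],
                x[[paste0("alpha_stage", i)]]))
  }
  cat(sprintf("  MAF >= %g; covariates in stages {%s}; stage-5 SNPs: %s\n",
              x$maf_min, paste(x$use_covariates_stages, collapse = ","),
              x$stage5_snps))
  invisible(x)
}

stage_alpha <- function(cfg, stage) cfg[[paste0("alpha_stage", stage)]]

stage_pass <- function(cfg, stage, pvalues) {
  a <- stage_alpha(cfg, stage)
  if (cfg$operators[stage] == "<") pvalues < a else pvalues <= a
}

stage_covariates <- function(cfg, stage, dataset) {
  if (stage %in% cfg$use_covariates_stages) dataset$covariates else NULL
}
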