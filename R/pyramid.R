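# The six-stage pyramid analysis.
#
# Stages 1-5 are biologically motivated filters that shrink the SNP search
# space before the final SNP-trait association test (stage 6):
#
#   1. trait ~ gene expression        (keep trait-associated genes)
#   2. trait ~ miRNA expression       (keep trait-associated miRNAs)
#   3. gene ~ miRNA, slope < 0        (keep putative regulatory pairs)
#   4. gene ~ SNP  (eQTL scan)        (keep SNPs driving surviving genes)
#   5. miRNA ~ SNP (miRNA-QTL scan)   (keep SNPs driving surviving miRNAs)
#   6. trait ~ SNP                    (test SNPs surviving 4 AND 5)
#
# Final assembly emits every (SNP, miRNA, gene) triplet whose six edges all
# satisfy their stage constraints.

new_stage_report <- function(stage, model, cfg, stats, n_tests) {
  structure(
    list(
      stage = stage,
      model = model,
      threshold = stage_alpha(cfg, stage),
      operator = cfg$operators[stage],
      n_tests = n_tests,
      stats = stats
    ),
    class = "stage_report"
  )
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf(
    "<stage_report %d: %s> %d/%d pass at p %s %g\n",
    x$stage, x$model, nrow(x$stats), x$n_tests, x$operator, x$threshold
  ))
  invisible(x)
}

trait_vector <- function(dataset, trait) {
  if (!trait %in% names(dataset$phenotypes)) {
    abort(sprintf("Trait '%s' not found among phenotypes (%s).",
                  trait, paste(setdiff(names(dataset$phenotypes), "sample_id"),
                               collapse = ", ")))
  }
  y <- dataset$phenotypes[[trait]]
  matrix(y, nrow = 1, dimnames = list(trait, dataset$sample_ids))
}

# Shared screen of one trait against the rows of a feature matrix.
trait_screen <- function(dataset, trait, features, id_col, stage, cfg) {
  Y <- trait_vector(dataset, trait)
  if (nrow(features) == 0L) {
    stats <- empty_assoc_tbl()
  } else {
    stats <- scan_assoc(features, Y,
      covariates = stage_covariates(cfg, stage, dataset)
    )
  }
  retained <- dplyr::filter(stats, stage_pass(cfg, stage, .data$pvalue))
  retained <- dplyr::select(
    dplyr::rename(retained, !!id_col := "x_id"),
    -"y_id", -"intercept"
  )
  retained
}

#' Stage 1: trait-associated genes
#'
#' Regresses the trait on each gene's expression and retains genes with
#' `p < alpha_stage1`.
#'
#' @param dataset An `omic_dataset`.
#' @param trait Name of the phenotype column used as the trait (typically a
#'   DSP column).
#' @param cfg A [pyramid_config()].
#' @return A `stage_report`; `$stats` has one row per retained gene.
#' @export
stage1_trait_mrna <- function(dataset, trait, cfg = pyramid_config()) {
  stats <- trait_screen(dataset, trait, dataset$mrna, "gene_id", 1, cfg)
  new_stage_report(1, "trait ~ mRNA", cfg, stats, nrow(dataset$mrna))
}

#' Stage 2: trait-associated miRNAs
#'
#' As [stage1_trait_mrna()] with the miRNA matrix and `alpha_stage2`.
#'
#' @inheritParams stage1_trait_mrna
#' @return A `stage_report`; `$stats` has one row per retained miRNA.
#' @export
stage2_trait_mirna <- function(dataset, trait, cfg = pyramid_config()) {
  stats <- trait_screen(dataset, trait, dataset$mirna, "mirna_id", 2, cfg)
  new_stage_report(2, "trait ~ miRNA", cfg, stats, nrow(dataset$mirna))
}

#' Stage 3: negatively correlated miRNA-mRNA pairs
#'
#' For every (miRNA, gene) pair in the Cartesian product of the stage-1 and
#' stage-2 survivors, regresses gene expression on miRNA expression (no
#' covariate term) and retains pairs with `p < alpha_stage3` and a negative
#' slope — the sign expected if the miRNA down-regulates the gene.
#'
#' @inheritParams stage1_trait_mrna
#' @param genes Character vector of stage-1 surviving gene identifiers.
#' @param mirnas Character vector of stage-2 surviving miRNA identifiers.
#' @return A `stage_report`; `$stats` has one row per retained pair
#'   (`mirna_id`, `gene_id`).
#' @export
stage3_negative_pairs <- function(dataset, genes, mirnas, cfg = pyramid_config()) {
  n_tests <- length(genes) * length(mirnas)
  if (n_tests == 0L) {
    stats <- empty_assoc_tbl()
  } else {
    stats <- scan_assoc(
      dataset$mirna[mirnas, , drop = FALSE],
      dataset$mrna[genes, , drop = FALSE]
    )
  }
  keep <- stage_pass(cfg, 3, stats$pvalue)
  if (cfg$require_negative_stage3) {
    keep <- keep & stats$slope < 0
  }
  stats <- dplyr::select(
    dplyr::rename(stats[keep, ], mirna_id = "x_id", gene_id = "y_id"),
    -"intercept"
  )
  new_stage_report(3, "mRNA ~ miRNA (negative)", cfg, stats, n_tests)
}

qtl_scan <- function(dataset, responses, id_col, stage, cfg, snps = NULL) {
  G <- dataset$genotypes
  if (!is.null(snps)) G <- G[snps, , drop = FALSE]
  n_tests <- nrow(G) * nrow(responses)
  if (n_tests == 0L) {
    stats <- empty_assoc_tbl()
  } else {
    stats <- scan_assoc(G, responses,
      covariates = stage_covariates(cfg, stage, dataset)
    )
  }
  stats <- dplyr::filter(stats, stage_pass(cfg, stage, .data$pvalue))
  stats <- dplyr::select(
    dplyr::rename(stats, snp_id = "x_id", !!id_col := "y_id"),
    -"intercept"
  )
  new_stage_report(
    stage,
    if (stage == 4) "mRNA ~ SNP (eQTL)" else "miRNA ~ SNP (miRNA-QTL)",
    cfg, stats, n_tests
  )
}

#' Stage 4: eQTL scan over stage-3 genes
#'
#' Regresses each stage-3 surviving gene on every MAF-passing SNP (additive
#' coding) and retains pairs with `p <= alpha_stage4`.
#'
#' @inheritParams stage1_trait_mrna
#' @param genes Gene identifiers appearing in a retained stage-3 pair.
#' @return A `stage_report`; `$stats` has one row per retained
#'   (`snp_id`, `gene_id`) hit.
#' @export
stage4_eqtl_scan <- function(dataset, genes, cfg = pyramid_config()) {
  qtl_scan(dataset, dataset$mrna[genes, , drop = FALSE], "gene_id", 4, cfg)
}

#' Stage 5: miRNA-QTL scan over stage-3 miRNAs
#'
#' As [stage4_eqtl_scan()] with miRNA responses and strict `p < alpha_stage5`.
#' By default every MAF-passing SNP is scanned; set
#' `pyramid_config(stage5_snps = "stage4")` to restrict to stage-4 survivors.
#'
#' @inheritParams stage1_trait_mrna
#' @param mirnas miRNA identifiers appearing in a retained stage-3 pair.
#' @param stage4_snp_ids Stage-4 surviving SNPs (used only under the
#'   `"stage4"` policy).
#' @return A `stage_report`; `$stats` has one row per retained
#'   (`snp_id`, `mirna_id`) hit.
#' @export
stage5_miqtl_scan <- function(dataset, mirnas, cfg = pyramid_config(),
                              stage4_snp_ids = NULL) {
  snps <- if (cfg$stage5_snps == "stage4") {
    stage4_snp_ids %||% character()
  } else {
    NULL
  }
  qtl_scan(dataset, dataset$mirna[mirnas, , drop = FALSE], "mirna_id", 5, cfg,
           snps = snps)
}

#' Stage 6: SNP-trait association over the QTL survivors
#'
#' Tests the trait against each candidate SNP (those surviving stages 4 and
#' 5) and retains SNPs with `p <= alpha_stage6`.
#'
#' @inheritParams stage1_trait_mrna
#' @param candidate_snps SNP identifiers surviving both QTL scans.
#' @return A `stage_report`; `$stats` has one row per retained SNP.
#' @export
stage6_snp_trait <- function(dataset, trait, candidate_snps,
                             cfg = pyramid_config()) {
  G <- dataset$genotypes[candidate_snps, , drop = FALSE]
  stats <- trait_screen(dataset, trait, G, "snp_id", 6, cfg)
  new_stage_report(6, "trait ~ SNP", cfg, stats, length(candidate_snps))
}

#' Assemble (SNP, miRNA, gene) triplets from the six stage reports
#'
#' Emits every triplet (S, M, T) such that T passed stage 1, M passed stage
#' 2, (M, T) passed stage 3, (S, T) passed stage 4, (S, M) passed stage 5
#' and S passed stage 6, carrying all six edge p-values and slopes. Output
#' is sorted lexicographically by (snp_id, mirna_id, gene_id).
#'
#' @param stage_reports List of the six `stage_report`s, in stage order.
#' @return A tibble with one row per triplet: identifiers, the six
#'   `p_*` columns and the six `slope_*` columns.
#' @export
assemble_triplets <- function(stage_reports) {
  stopifnot(length(stage_reports) == 6L)
  s <- purrr::map(stage_reports, "stats")
  if (any(purrr::map_int(s, nrow) == 0L)) {
    return(empty_triplet_tbl())
  }
  edge <- function(tbl, keep, suffix) {
    out <- dplyr::select(tbl, dplyr::all_of(keep), "pvalue", "slope")
    dplyr::rename(out,
      !!paste0("p_", suffix) := "pvalue",
      !!paste0("slope_", suffix) := "slope"
    )
  }
  trip <- edge(s[[3]], c("mirna_id", "gene_id"), "mirna_gene")
  trip <- dplyr::inner_join(trip, edge(s[[1]], "gene_id", "gene_trait"),
                            by = "gene_id")
  trip <- dplyr::inner_join(trip, edge(s[[2]], "mirna_id", "mirna_trait"),
                            by = "mirna_id")
  # a gene can have many eQTL SNPs and vice versa: many-to-many by design
  trip <- dplyr::inner_join(trip, edge(s[[4]], c("snp_id", "gene_id"), "snp_gene"),
                            by = "gene_id", relationship = "many-to-many")
  trip <- dplyr::inner_join(trip, edge(s[[5]], c("snp_id", "mirna_id"), "snp_mirna"),
                            by = c("snp_id", "mirna_id"))
  trip <- dplyr::inner_join(trip, edge(s[[6]], "snp_id", "snp_trait"),
                            by = "snp_id")
  trip <- dplyr::select(
    trip,
    "snp_id", "mirna_id", "gene_id",
    "p_snp_trait", "p_snp_mirna", "p_snp_gene",
    "p_mirna_trait", "p_mirna_gene", "p_gene_trait",
    "slope_snp_trait", "slope_snp_mirna", "slope_snp_gene",
    "slope_mirna_trait", "slope_mirna_gene", "slope_gene_trait"
  )
  dplyr::arrange(trip, .data$snp_id, .data$mirna_id, .data$gene_id)
}

empty_triplet_tbl <- function() {
  tibble::tibble(
    snp_id = character(), mirna_id = character(), gene_id = character(),
    p_snp_trait = numeric(), p_snp_mirna = numeric(), p_snp_gene = numeric(),
    p_mirna_trait = numeric(), p_mirna_gene = numeric(),
    p_gene_trait = numeric(),
    slope_snp_trait = numeric(), slope_snp_mirna = numeric(),
    slope_snp_gene = numeric(), slope_mirna_trait = numeric(),
    slope_mirna_gene = numeric(), slope_gene_trait = numeric()
  )
}

#' Run the full six-stage pyramid analysis
#'
#' Applies the MAF filter, executes stages 1 through 6 sequentially — each
#' stage consuming only the survivors of the stages before it — and
#' assembles the final triplets. An empty stage short-circuits the stages
#' downstream of it into empty reports (never an error), so a null dataset
#' yields an empty, well-formed result. Deterministic given dataset and
#' config.
#'
#' @param dataset An `omic_dataset`.
#' @param trait Name of the phenotype column used as the trait.
#' @param cfg A [pyramid_config()].
#' @return A `pyramid_result`: list with `stages` (six `stage_report`s),
#'   `triplets` (tibble, one row per final triplet), `summary` (per-stage
#'   unique-feature counts), `trait`, `cfg`.
#' @export
run_pyramid <- function(dataset, trait, cfg = pyramid_config()) {
  stopifnot(inherits(dataset, "omic_dataset"))
  dataset <- filter_snps_by_maf(dataset, cfg$maf_min)

  r1 <- stage1_trait_mrna(dataset, trait, cfg)
  r2 <- stage2_trait_mirna(dataset, trait, cfg)
  r3 <- stage3_negative_pairs(dataset, r1$stats$gene_id, r2$stats$mirna_id, cfg)
  r4 <- stage4_eqtl_scan(dataset, unique(r3$stats$gene_id), cfg)
  r5 <- stage5_miqtl_scan(dataset, unique(r3$stats$mirna_id), cfg,
                          stage4_snp_ids = unique(r4$stats$snp_id))
  candidates <- intersect(unique(r4$stats$snp_id), unique(r5$stats$snp_id))
  r6 <- stage6_snp_trait(dataset, trait, candidates, cfg)

  reports <- list(r1, r2, r3, r4, r5, r6)
  triplets <- assemble_triplets(reports)

  structure(
    list(
      stages = reports,
      triplets = triplets,
      summary = pyramid_summary(reports, triplets),
      trait = trait,
      cfg = cfg
    ),
    class = "pyramid_result"
  )
}

pyramid_summary <- function(reports, triplets) {
  s <- purrr::map(reports, "stats")
  cnt <- function(tbl, col) length(unique(tbl[[col]]))
  tibble::tibble(
    stage = c("stage1", "stage2", "stage3", "stage4", "stage5", "stage6",
              "final_assembly"),
    n_tests = c(purrr::map_dbl(reports, "n_tests"), nrow(triplets)),
    n_pass = c(purrr::map_dbl(s, nrow), nrow(triplets)),
    n_snps = c(NA, NA, NA, cnt(s[[4]], "snp_id"), cnt(s[[5]], "snp_id"),
               cnt(s[[6]], "snp_id"), cnt(triplets, "snp_id")),
    n_genes = c(cnt(s[[1]], "gene_id"), NA, cnt(s[[3]], "gene_id"),
                cnt(s[[4]], "gene_id"), NA, NA, cnt(triplets, "gene_id")),
    n_mirnas = c(NA, cnt(s[[2]], "mirna_id"), cnt(s[[3]], "mirna_id"), NA,
                 cnt(s[[5]], "mirna_id"), NA, cnt(triplets, "mirna_id"))
  )
}

#' @export
print.pyramid_result <- function(x, ...) {
  cat(sprintf("<pyramid_result> trait '%s'\n", x$trait))
  print(x$summary, n = 7)
  cat(sprintf("%d final triplet(s)\n", nrow(x$triplets)))
  invisible(x)
}

#' Tidy a pyramid result into its triplet table
#'
#' @param x A `pyramid_result`.
#' @param ... Unused.
#' @return The triplet tibble (one row per assembled SNP-miRNA-gene finding).
#' @method tidy pyramid_result
#' @export
tidy.pyramid_result <- function(x, ...) {
  x$triplets
}

#' One-row summary of a pyramid result
#'
#' @param x A `pyramid_result`.
#' @param ... Unused.
#' @return A one-row tibble with per-stage pass counts and the unique
#'   SNP/gene/miRNA counts of the final assembly.
#' @method glance pyramid_result
#' @export
glance.pyramid_result <- function(x, ...) {
  s <- purrr::map(x$stages, "stats")
  tibble::tibble(
    stage1_genes = nrow(s[[1]]),
    stage2_mirnas = nrow(s[[2]]),
    stage3_pairs = nrow(s[[3]]),
    stage4_hits = nrow(s[[4]]),
    stage5_hits = nrow(s[[5]]),
    stage6_snps = nrow(s[[6]]),
    n_triplets = nrow(x$triplets),
    n_snps_final = length(unique(x$triplets$snp_id)),
    n_genes_final = length(unique(x$triplets$gene_id)),
    n_mirnas_final = length(unique(x$triplets$mirna_id))
  )
}
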