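# Permutation-based empirical FDR.
#
# The stage thresholds of the pyramid are user-chosen and the filtering
# stages (1-5) reuse the very samples tested at stage 6, so nominal stage-6
# p-values cannot be taken at face value and a uniform-null FDR (e.g.
# Benjamini-Hochberg) is not appropriate. Instead, the trait vector is
# permuted across samples — leaving the genotype/mRNA/miRNA correlation
# structure intact — and the ENTIRE pyramid is re-run on each permuted
# dataset. The stage-6 p-values of the final assembled SNPs from each
# replicate form the empirical null, and
#
#   FDR(t) = mean_perm #\{null final p <= t\} / max(#\{observed final p <= t\}, 1)
#
# capped at 1, is the empirical false discovery rate at threshold t.
#
# Trait-free edges (the stage-3 pair statistics and the stage-4/5 QTL scans)
# cannot change when only the trait is permuted, so they are computed once
# and re-used; only stages 1, 2 and 6 — and which cached edges are eligible —
# are recomputed per replicate. The cache is exact, not an approximation:
# the association engine produces bit-identical statistics whether a pair is
# computed alone or inside the full matrix.

#' Permute a trait vector reproducibly
#'
#' Uniform random permutation of the trait entries across samples,
#' determined entirely by `(seed, perm_index)` (counter-style seeding), so
#' replicate `i` is reproducible in isolation and independent of execution
#' order. The caller's RNG state is left untouched.
#'
#' @param trait Numeric trait vector (length >= 2 non-missing).
#' @param seed Integer base seed.
#' @param perm_index Replicate counter (1, 2, ...).
#' @return The permuted vector (a multiset-identical rearrangement).
#' @export
permute_trait <- function(trait, seed, perm_index) {
  if (sum(!is.na(trait)) < 2L) {
    abort("`trait` needs at least 2 non-missing values to permute.")
  }
  trait[perm_order(length(trait), seed, perm_index)]
}

perm_seed <- function(seed, perm_index) {
  # counter-based derivation, always a valid 32-bit seed
  as.integer((as.numeric(seed %% 44488L) * 48271 + perm_index) %% 2147483647)
}

perm_order <- function(n, seed, perm_index) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(perm_seed(seed, perm_index))
  sample.int(n)
}

#' Build the permutation null of a discovery method
#'
#' For each of `n_perm` replicates, permutes the trait and re-runs the full
#' discovery pipeline of the chosen method, recording the SNP-trait
#' p-values of that replicate's findings:
#' * `"pyramid"` — all six stages plus triplet assembly; the null set is the
#'   stage-6 p-values of the final assembled SNPs (often empty).
#' * `"eqtl"` — the eQTL-filtered scan of [eqtl_filtered_gwas()]; the null
#'   set is the p-values of all SNPs passing the expression filter.
#' * `"gwas"` — the unfiltered scan; the null set is all SNP p-values.
#'
#' Trait-free edge statistics are cached and re-used across replicates
#' (`cache = TRUE`); `cache = FALSE` re-runs everything naively and yields
#' bit-identical null sets (each set is reported sorted ascending).
#'
#' @param dataset An `omic_dataset`.
#' @param trait Phenotype column to permute and test.
#' @param cfg A [pyramid_config()] (must match the observed analysis).
#' @param n_perm Number of permutations (>= 1); 1000 is the conventional
#'   choice at genome scale.
#' @param seed Integer base seed for [permute_trait()].
#' @param method One of `"pyramid"`, `"eqtl"`, `"gwas"`.
#' @param cache Re-use trait-free edge statistics across replicates.
#' @return A `permutation_null`: list with `method`, `n_perm`, `seed`,
#'   `null_pvalues` (list of sorted numeric vectors, one per replicate),
#'   `per_perm_counts`, `trait`.
#' @export
build_null <- function(dataset, trait, cfg = pyramid_config(),
                       n_perm = 1000, seed = 1,
                       method = c("pyramid", "eqtl", "gwas"),
                       cache = TRUE) {
  method <- match.arg(method)
  if (!is.numeric(n_perm) || n_perm < 1) {
    abort("`n_perm` must be at least 1.")
  }
  n_perm <- as.integer(n_perm)
  stopifnot(inherits(dataset, "omic_dataset"))
  dataset <- filter_snps_by_maf(dataset, cfg$maf_min)
  y <- drop(trait_vector(dataset, trait))

  runner <- if (cache) {
    cached_null_runner(dataset, cfg, method)
  } else {
    naive_null_runner(dataset, trait, cfg, method)
  }

  null_sets <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    null_sets[[i]] <- sort(runner(permute_trait(y, seed, i)))
  }
  structure(
    list(
      method = method,
      n_perm = n_perm,
      seed = seed,
      null_pvalues = null_sets,
      per_perm_counts = lengths(null_sets),
      trait = trait
    ),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> method '%s', %d permutations (seed %s)\n",
    x$method, x$n_perm, format(x$seed)
  ))
  cat(sprintf(
    "  findings per replicate: mean %.2f, max %d\n",
    mean(x$per_perm_counts), max(x$per_perm_counts, 0)
  ))
  invisible(x)
}

# One replicate of the pyramid/eqtl/gwas pipeline against a (permuted) trait,
# re-using cached trait-free edges. Returns the replicate's null p-values.
cached_null_runner <- function(dataset, cfg, method) {
  G <- dataset$genotypes
  E <- dataset$mrna
  M <- dataset$mirna
  W <- function(stage) stage_covariates(cfg, stage, dataset)
  trait_p <- function(X, y, stage) {
    if (nrow(X) == 0L) return(numeric())
    drop(assoc_matrix(X, matrix(y, nrow = 1), W(stage))$pvalue)
  }

  if (method == "gwas") {
    return(function(y) trait_p(G, y, 6))
  }

  A_sg <- if (nrow(G) && nrow(E)) assoc_matrix(G, E, W(4)) # SNP x gene
  stage1_genes <- function(y) which(stage_pass(cfg, 1, trait_p(E, y, 1)))

  if (method == "eqtl") {
    return(function(y) {
      g1 <- stage1_genes(y)
      if (!length(g1) || is.null(A_sg)) return(numeric())
      pass4 <- stage_pass(cfg, 4, A_sg$pvalue[, g1, drop = FALSE])
      snps <- which(rowSums(pass4) > 0)
      trait_p(G[snps, , drop = FALSE], y, 6)
    })
  }

  A_mg <- if (nrow(M) && nrow(E)) assoc_matrix(M, E) # miRNA x gene, no W
  A_sm <- if (nrow(G) && nrow(M)) assoc_matrix(G, M, W(5)) # SNP x miRNA

  function(y) {
    g1 <- stage1_genes(y)
    m2 <- which(stage_pass(cfg, 2, trait_p(M, y, 2)))
    if (!length(g1) || !length(m2) || is.null(A_mg) || is.null(A_sg) ||
        is.null(A_sm)) {
      return(numeric())
    }
    pass3 <- stage_pass(cfg, 3, A_mg$pvalue[m2, g1, drop = FALSE])
    if (cfg$require_negative_stage3) {
      pass3 <- pass3 & A_mg$slope[m2, g1, drop = FALSE] < 0
    }
    pair_idx <- which(pass3, arr.ind = TRUE)
    if (!nrow(pair_idx)) return(numeric())
    pairs_m <- m2[pair_idx[, 1]]
    pairs_g <- g1[pair_idx[, 2]]
    g3 <- unique(pairs_g[order(pairs_g)])
    m3 <- unique(pairs_m[order(pairs_m)])

    pass4 <- stage_pass(cfg, 4, A_sg$pvalue[, g3, drop = FALSE])
    snps4 <- which(rowSums(pass4) > 0)
    rows5 <- if (cfg$stage5_snps == "stage4") snps4 else seq_len(nrow(G))
    pass5 <- stage_pass(cfg, 5, A_sm$pvalue[rows5, m3, drop = FALSE])
    snps5 <- rows5[rowSums(pass5) > 0]
    cand <- intersect(snps4, snps5)
    if (!length(cand)) return(numeric())

    p6 <- trait_p(G[cand, , drop = FALSE], y, 6)
    snps6 <- cand[stage_pass(cfg, 6, p6)]
    if (!length(snps6)) return(numeric())

    # final assembly: a stage-6 SNP survives if some retained (miRNA, gene)
    # pair has both its QTL edges for this SNP
    keep4 <- stage_pass(cfg, 4, A_sg$pvalue[snps6, pairs_g, drop = FALSE])
    keep5 <- stage_pass(cfg, 5, A_sm$pvalue[snps6, pairs_m, drop = FALSE])
    final <- rowSums(keep4 & keep5) > 0
    p6[stage_pass(cfg, 6, p6)][final]
  }
}

naive_null_runner <- function(dataset, trait, cfg, method) {
  function(y) {
    ds <- dataset
    ds$phenotypes[[trait]] <- y
    if (method == "pyramid") {
      res <- run_pyramid(ds, trait, cfg)
      fin <- dplyr::distinct(res$triplets, .data$snp_id, .data$p_snp_trait)
      fin$p_snp_trait
    } else if (method == "eqtl") {
      eqtl_filtered_gwas(ds, trait, cfg)$pvalue
    } else {
      traditional_gwas(ds, trait, cfg)$pvalue
    }
  }
}

#' Empirical FDR of observed findings against a permutation null
#'
#' At each threshold `t`, reports the number of observed findings with
#' `p <= t`, the mean per-replicate number of null findings with `p <= t`,
#' and their ratio capped at 1. With no observed findings at `t` the FDR is
#' undefined (`NA`) — there are no discoveries to rate. Thresholds default
#' to the observed p-values themselves, giving each finding its own
#' empirical FDR.
#'
#' @param observed Observed findings: a numeric vector of p-values, a
#'   `pyramid_result` (uses the distinct final SNPs' stage-6 p-values), or a
#'   scan tibble with a `pvalue` column.
#' @param null A `permutation_null` built with the same config.
#' @param thresholds Numeric vector of cutoffs `t`; default the observed
#'   p-values.
#' @param monotone If `TRUE`, adds `fdr_smoothed`, the cumulative-minimum
#'   smoothing that enforces monotone non-decreasing estimates in `t`.
#' @return A tibble with columns `threshold`, `observed_hits`,
#'   `expected_null_hits`, `fdr` (and optionally `fdr_smoothed`).
#' @export
empirical_fdr <- function(observed, null, thresholds = NULL, monotone = FALSE) {
  stopifnot(inherits(null, "permutation_null"))
  pobs <- observed_pvalues(observed)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(pobs))
  }
  if (!length(thresholds)) {
    return(tibble::tibble(
      threshold = numeric(), observed_hits = integer(),
      expected_null_hits = numeric(), fdr = numeric()
    ))
  }
  all_null <- unlist(null$null_pvalues, use.names = FALSE)
  out <- tibble::tibble(
    threshold = thresholds,
    observed_hits = vapply(thresholds, function(t) sum(pobs <= t), integer(1)),
    expected_null_hits = vapply(
      thresholds, function(t) sum(all_null <= t), numeric(1)
    ) / null$n_perm
  )
  out$fdr <- ifelse(
    out$observed_hits == 0, NA_real_,
    pmin(1, out$expected_null_hits / pmax(out$observed_hits, 1))
  )
  if (monotone) {
    f <- out$fdr[order(out$threshold)]
    s <- rev(cummin(rev(ifelse(is.na(f), Inf, f))))
    s[!is.finite(s)] <- NA_real_
    out$fdr_smoothed <- s[match(out$threshold, sort(out$threshold))]
  }
  out
}

observed_pvalues <- function(observed) {
  if (inherits(observed, "pyramid_result")) {
    fin <- dplyr::distinct(observed$triplets, .data$snp_id, .data$p_snp_trait)
    fin$p_snp_trait
  } else if (is.data.frame(observed)) {
    observed$pvalue
  } else if (is.numeric(observed)) {
    observed
  } else {
    abort("`observed` must be p-values, a scan tibble or a pyramid_result.")
  }
}
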