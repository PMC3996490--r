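# Synthetic cohorts emulating the structure of the real inputs: ~90
# lymphoblastoid lines with biallelic SNP dosages at realistic minor-allele
# frequencies, continuous (log-scale-like) expression, a growth component
# shared between IC50 and iGrowth, and optional planted
# SNP -> miRNA -| gene -> trait causal chains. Every stage and the
# permutation-FDR machinery is testable on these cohorts without any
# external download.
#
# Planted effects are standardized: each expression layer is built to unit
# marginal variance, so a chain effect of, say, 0.75 is (approximately) the
# population correlation between the two ends of that edge.

#' Describe the planted causal structure of a synthetic cohort
#'
#' The generative model, per planted chain (SNP s, miRNA m, gene g):
#' \preformatted{
#'   s      ~ Binomial(2, maf)                        (Hardy-Weinberg)
#'   m      = b_sm * std(s) + sqrt(1 - b_sm^2) * e    (SNP drives miRNA)
#'   g      = b_mg * m + sqrt(1 - b_mg^2) * e         (miRNA represses gene, b_mg < 0)
#'   drug   = sum_chains(b_gt * g + b_mt * m) + N(0, trait_noise_sd)
#'   igrowth ~ N(0, 1)
#'   log2_ic50 = growth_effect * igrowth + drug
#' }
#' Non-planted SNPs are independent Binomial(2, MAF) draws and non-planted
#' expression features are independent standard normal noise.
#'
#' @param n_samples Cohort size; default 90, the size of the discovery
#'   panel the generator emulates.
#' @param n_snps,n_genes,n_mirnas Feature counts; defaults 1000 / 200 / 50
#'   (desk-scale stand-ins for genome-wide panels).
#' @param n_chains Number of planted causal chains (0 = global null). Chain
#'   `j` occupies `snp_j`, `mir_j`, `gene_j`.
#' @param b_snp_mirna Standardized SNP-to-miRNA effect, default 0.75.
#' @param b_mirna_gene Standardized miRNA-to-gene effect, must be negative;
#'   default -0.75.
#' @param b_gene_trait,b_mirna_trait Trait effects of the planted gene and
#'   miRNA; defaults -0.5 and +0.5 (the gene effect opposes the miRNA
#'   effect, as expected when the miRNA represses a sensitivity gene).
#' @param growth_effect Slope of iGrowth on log2 IC50, default -0.8 (faster
#'   growth, lower IC50).
#' @param trait_noise_sd Drug-signal noise sd, default 0.5.
#' @param maf_range MAF range for background SNPs (uniform), default
#'   (0.05, 0.5).
#' @param planted_maf_range MAF range for planted SNPs, default (0.1, 0.4)
#'   (common variants, so the planted dosage is well populated at n = 90).
#' @param seed Integer seed recorded with the truth.
#' @return A `truth_record`: list of the above plus `planted_chains`, a
#'   tibble with one row per chain.
#' @export
truth_record <- function(n_samples = 90, n_snps = 1000, n_genes = 200,
                         n_mirnas = 50, n_chains = 1,
                         b_snp_mirna = 0.75, b_mirna_gene = -0.75,
                         b_gene_trait = -0.5, b_mirna_trait = 0.5,
                         growth_effect = -0.8, trait_noise_sd = 0.5,
                         maf_range = c(0.05, 0.5),
                         planted_maf_range = c(0.1, 0.4),
                         seed = 1) {
  if (n_samples < 10) {
    abort("`n_samples` must be at least 10.")
  }
  if (n_chains > min(n_snps, n_genes, n_mirnas)) {
    abort("More chains than available features.")
  }
  if (n_chains > 0 && any(b_mirna_gene >= 0)) {
    abort("Planted miRNA-to-gene effects must be negative.")
  }
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      any(planted_maf_range <= 0) || any(planted_maf_range > 0.5)) {
    abort("MAF ranges must lie in (0, 0.5].")
  }
  chains <- tibble::tibble(
    snp_id = sprintf("snp_%04d", seq_len(n_chains)),
    mirna_id = sprintf("mir_%03d", seq_len(n_chains)),
    gene_id = sprintf("gene_%04d", seq_len(n_chains)),
    b_snp_mirna = rep_len(b_snp_mirna, n_chains),
    b_mirna_gene = rep_len(b_mirna_gene, n_chains),
    b_gene_trait = rep_len(b_gene_trait, n_chains),
    b_mirna_trait = rep_len(b_mirna_trait, n_chains)
  )
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_snps = as.integer(n_snps),
      n_genes = as.integer(n_genes),
      n_mirnas = as.integer(n_mirnas),
      planted_chains = chains,
      growth_effect = growth_effect,
      trait_noise_sd = trait_noise_sd,
      maf_range = maf_range,
      planted_maf_range = planted_maf_range,
      seed = as.integer(seed)
    ),
    class = "truth_record"
  )
}

#' Simulate Hardy-Weinberg SNP dosages
#'
#' Each SNP's dosages are independent Binomial(2, maf) draws.
#'
#' @param n_snps,n_samples Dimensions.
#' @param maf Scalar or per-SNP vector of minor-allele frequencies.
#' @param seed Integer seed.
#' @return SNP-by-sample dosage matrix with values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n_snps, n_samples, maf, seed = 1) {
  set.seed(seed)
  maf <- rep_len(maf, n_snps)
  g <- matrix(
    as.double(stats::rbinom(n_snps * n_samples, size = 2,
                            prob = rep(maf, n_samples))),
    nrow = n_snps, ncol = n_samples
  )
  dimnames(g) <- list(
    sprintf("snp_%04d", seq_len(n_snps)),
    sprintf("s%03d", seq_len(n_samples))
  )
  g
}

#' Simulate a full multi-omic cohort from a truth record
#'
#' @param truth A [truth_record()].
#' @param seed Integer seed; defaults to the seed recorded in `truth`.
#' @return A list with elements `dataset` (an `omic_dataset` whose
#'   phenotypes include `igrowth`, `log2_ic50` and the DSP trait column
#'   `dsp`), `phenotypes` (the `phenotype_set`), and `truth`.
#' @export
simulate_dataset <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(seed)
  n <- truth$n_samples
  chains <- truth$planted_chains
  n_chains <- nrow(chains)

  mafs <- stats::runif(truth$n_snps, truth$maf_range[1], truth$maf_range[2])
  if (n_chains > 0) {
    mafs[seq_len(n_chains)] <- stats::runif(
      n_chains, truth$planted_maf_range[1], truth$planted_maf_range[2]
    )
  }
  # genotypes drawn inside the same stream, not via simulate_genotypes(),
  # so the whole cohort is one deterministic function of `seed`
  G <- matrix(
    as.double(stats::rbinom(truth$n_snps * n, size = 2, prob = rep(mafs, n))),
    nrow = truth$n_snps
  )
  dimnames(G) <- list(
    sprintf("snp_%04d", seq_len(truth$n_snps)),
    sprintf("s%03d", seq_len(n))
  )

  M <- matrix(stats::rnorm(truth$n_mirnas * n), nrow = truth$n_mirnas,
              dimnames = list(sprintf("mir_%03d", seq_len(truth$n_mirnas)),
                              colnames(G)))
  E <- matrix(stats::rnorm(truth$n_genes * n), nrow = truth$n_genes,
              dimnames = list(sprintf("gene_%04d", seq_len(truth$n_genes)),
                              colnames(G)))

  drug_signal <- stats::rnorm(n, sd = truth$trait_noise_sd)
  for (j in seq_len(n_chains)) {
    maf_j <- mafs[j]
    sd_s <- sqrt(2 * maf_j * (1 - maf_j)) # theoretical HW dosage sd
    s_std <- (G[chains$snp_id[j], ] - 2 * maf_j) / sd_s
    b_sm <- chains$b_snp_mirna[j]
    M[chains$mirna_id[j], ] <- b_sm * s_std +
      sqrt(1 - b_sm^2) * M[chains$mirna_id[j], ]
    b_mg <- chains$b_mirna_gene[j]
    E[chains$gene_id[j], ] <- b_mg * M[chains$mirna_id[j], ] +
      sqrt(1 - b_mg^2) * E[chains$gene_id[j], ]
    drug_signal <- drug_signal +
      chains$b_gene_trait[j] * E[chains$gene_id[j], ] +
      chains$b_mirna_trait[j] * M[chains$mirna_id[j], ]
  }

  igrowth <- stats::rnorm(n)
  log2_ic50 <- truth$growth_effect * igrowth + drug_signal
  pheno <- compute_dsp(log2_ic50, igrowth,
    drug_label = "synthetic", sample_id = colnames(G)
  )

  dataset <- assemble_dataset(
    genotypes = G, mrna = E, mirna = M,
    phenotypes = pheno[, c("sample_id", "log2_ic50", "igrowth", "dsp")]
  )
  list(dataset = dataset, phenotypes = pheno, truth = truth)
}

#' Write a simulated cohort as an on-disk fixture
#'
#' Emits the exact TSV dialects [read_matrix()] and [read_phenotypes()]
#' read, plus the truth record as JSON, so the fixture round-trips
#' losslessly and loads through the command-line interface end to end.
#'
#' @param sim A list from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Files: `genotypes.tsv`, `mrna.tsv`,
#'   `mirna.tsv`, `phenotypes.tsv`, `truth.json`.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  ds <- sim$dataset
  write_matrix(ds$genotypes, file.path(dir, "genotypes.tsv"))
  write_matrix(ds$mrna, file.path(dir, "mrna.tsv"))
  write_matrix(ds$mirna, file.path(dir, "mirna.tsv"))
  write_phenotypes(ds$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- sim$truth
  truth$planted_chains <- as.data.frame(truth$planted_chains)
  jsonlite::write_json(
    unclass(truth), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return An `omic_dataset`.
#' @export
read_fixture <- function(dir) {
  assemble_dataset(
    genotypes = read_matrix(file.path(dir, "genotypes.tsv")),
    mrna = read_matrix(file.path(dir, "mrna.tsv")),
    mirna = read_matrix(file.path(dir, "mirna.tsv")),
    phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv"))
  )
}
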