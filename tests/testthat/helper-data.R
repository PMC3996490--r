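# Small in-code fixtures shared across test files.

# Tiny labelled matrix with explicit values.
tiny_matrix <- function(nr = 3, nc = 2, seed = NULL, prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(round(rnorm(nr * nc), 3), nr, nc)
  dimnames(m) <- list(paste0(prefix, seq_len(nr)), paste0("s", seq_len(nc)))
  m
}

# Planted or null cohort at reduced feature counts for fast tests.
small_sim <- function(seed = 1, n_chains = 1, n_snps = 30, n_genes = 10,
                      n_mirnas = 5, n_samples = 90, ...) {
  simulate_dataset(truth_record(
    n_samples = n_samples, n_snps = n_snps, n_genes = n_genes,
    n_mirnas = n_mirnas, n_chains = n_chains, seed = seed, ...
  ))
}

# Fabricate the bare stage-report list assemble_triplets() consumes.
fake_reports <- function(s1_genes, s2_mirnas, s3_pairs, s4_pairs, s5_pairs,
                         s6_snps) {
  p <- 1e-6 # any value passing every default threshold
  list(
    list(stats = tibble::tibble(gene_id = s1_genes, pvalue = p, slope = 1)),
    list(stats = tibble::tibble(mirna_id = s2_mirnas, pvalue = p, slope = 1)),
    list(stats = tibble::tibble(
      mirna_id = s3_pairs$mirna_id, gene_id = s3_pairs$gene_id,
      pvalue = p, slope = -1
    )),
    list(stats = tibble::tibble(
      snp_id = s4_pairs$snp_id, gene_id = s4_pairs$gene_id,
      pvalue = p, slope = 1
    )),
    list(stats = tibble::tibble(
      snp_id = s5_pairs$snp_id, mirna_id = s5_pairs$mirna_id,
      pvalue = p, slope = 1
    )),
    list(stats = tibble::tibble(snp_id = s6_snps, pvalue = p, slope = 1))
  )
}

# Exhaustive reference join for triplet assembly.
brute_force_triplets <- function(s1_genes, s2_mirnas, s3_pairs, s4_pairs,
                                 s5_pairs, s6_snps, snps, mirnas, genes) {
  out <- list()
  for (s in snps) {
    for (m in mirnas) {
      for (g in genes) {
        ok <- g %in% s1_genes &&
          m %in% s2_mirnas &&
          any(s3_pairs$mirna_id == m & s3_pairs$gene_id == g) &&
          any(s4_pairs$snp_id == s & s4_pairs$gene_id == g) &&
          any(s5_pairs$snp_id == s & s5_pairs$mirna_id == m) &&
          s %in% s6_snps
        if (ok) out[[length(out) + 1]] <- c(s, m, g)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      snp_id = character(), mirna_id = character(), gene_id = character()
    ))
  }
  tbl <- tibble::as_tibble(do.call(rbind, out), .name_repair = "minimal")
  names(tbl) <- c("snp_id", "mirna_id", "gene_id")
  dplyr::arrange(tbl, snp_id, mirna_id, gene_id)
}
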