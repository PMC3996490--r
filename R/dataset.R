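# The aligned multi-omic container: genotype dosages, mRNA and miRNA
# expression, per-sample phenotypes and optional covariates, all indexed by
# one ordered sample axis.

#' Assemble an aligned multi-omic dataset
#'
#' Inner-joins the inputs on their sample labels, in genotype sample order,
#' and enforces the container invariants: a shared ordered sample axis,
#' unique feature identifiers within each matrix, and genotype dosages in
#' \{0, 1, 2\} (or any finite value when `dosage = TRUE`, for imputed data).
#' Samples missing from any input are dropped and reported via a message.
#'
#' @param genotypes SNP-by-sample dosage matrix, additive minor-allele coding.
#' @param mrna Gene-by-sample expression matrix (assumed already normalized,
#'   log scale).
#' @param mirna miRNA-by-sample expression matrix.
#' @param phenotypes Data frame with a `sample_id` column and named numeric
#'   phenotype columns (e.g. `log2_ic50`, `igrowth`, `dsp`).
#' @param covariates Optional sample-by-k numeric matrix with sample rownames
#'   (ancestry PCs, hidden expression factors), consumed as given — never
#'   computed here.
#' @param dosage If `TRUE`, accept fractional dosages in `[0, 2]` (imputed
#'   genotypes); otherwise entries must be 0, 1, 2 or missing.
#'
#' @return An `omic_dataset` object: a list with elements `sample_ids`,
#'   `genotypes`, `mrna`, `mirna`, `phenotypes`, `covariates`, `dosage`,
#'   `dropped` (per-input dropped sample labels).
#' @export
assemble_dataset <- function(genotypes, mrna, mirna, phenotypes,
                             covariates = NULL, dosage = FALSE) {
  genotypes <- as_feature_matrix(genotypes, "genotypes")
  mrna <- as_feature_matrix(mrna, "mrna")
  mirna <- as_feature_matrix(mirna, "mirna")
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!"sample_id" %in% names(phenotypes)) {
    abort("`phenotypes` must contain a `sample_id` column.")
  }
  phenotypes$sample_id <- as.character(phenotypes$sample_id)

  for (nm in c("genotypes", "mrna", "mirna")) {
    m <- get(nm)
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    if (length(dup)) {
      abort(sprintf("Duplicated feature identifier(s) in `%s`: %s",
                    nm, paste(dup, collapse = ", ")))
    }
    if (is.null(colnames(m))) {
      abort(sprintf("`%s` must carry sample labels as colnames.", nm))
    }
  }
  dupp <- unique(phenotypes$sample_id[duplicated(phenotypes$sample_id)])
  if (length(dupp)) {
    abort(sprintf("Duplicated sample_id(s) in `phenotypes`: %s",
                  paste(dupp, collapse = ", ")))
  }

  axes <- list(
    genotypes = colnames(genotypes),
    mrna = colnames(mrna),
    mirna = colnames(mirna),
    phenotypes = phenotypes$sample_id
  )
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) {
      abort("`covariates` must carry sample labels as rownames.")
    }
    axes$covariates <- rownames(covariates)
  }
  shared <- Reduce(intersect, axes)
  if (length(shared) == 0L) {
    abort("The inputs share no sample labels.")
  }
  # deterministic order: genotype sample order restricted to the intersection
  shared <- axes$genotypes[axes$genotypes %in% shared]
  dropped <- purrr::map(axes, ~ setdiff(.x, shared))
  drop_labels <- unique(unlist(dropped))
  if (length(drop_labels) > 0) {
    inform(sprintf(
      "Dropped %d sample label(s) absent from at least one input: %s",
      length(drop_labels),
      paste(head(drop_labels, 10), collapse = ", ")
    ))
  }

  genotypes <- genotypes[, shared, drop = FALSE]
  if (!dosage) {
    bad <- genotypes[!is.na(genotypes) & !genotypes %in% c(0, 1, 2)]
    if (length(bad)) {
      abort(sprintf(
        "Genotype dosage outside {0, 1, 2}: %s (set `dosage = TRUE` for fractional dosages).",
        paste(head(unique(bad), 5), collapse = ", ")
      ))
    }
  } else if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE)) {
    abort("Fractional dosages must lie in [0, 2].")
  }

  structure(
    list(
      sample_ids = shared,
      genotypes = genotypes,
      mrna = mrna[, shared, drop = FALSE],
      mirna = mirna[, shared, drop = FALSE],
      phenotypes = phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE],
      covariates = if (is.null(covariates)) NULL else covariates[shared, , drop = FALSE],
      dosage = dosage,
      dropped = dropped
    ),
    class = "omic_dataset"
  )
}

#' @export
print.omic_dataset <- function(x, ...) {
  cat("<omic_dataset>\n")
  cat(sprintf("  samples:    %d\n", length(x$sample_ids)))
  cat(sprintf("  SNPs:       %d\n", nrow(x$genotypes)))
  cat(sprintf("  genes:      %d\n", nrow(x$mrna)))
  cat(sprintf("  miRNAs:     %d\n", nrow(x$mirna)))
  cat(sprintf("  phenotypes: %s\n",
              paste(setdiff(names(x$phenotypes), "sample_id"), collapse = ", ")))
  cat(sprintf("  covariates: %s\n",
              if (is.null(x$covariates)) "none" else ncol(x$covariates)))
  invisible(x)
}

#' Minor-allele frequency of each SNP
#'
#' `MAF = min(f, 1 - f)` with `f = sum(dosages) / (2 * n_called)` over
#' non-missing calls.
#'
#' @param dataset An `omic_dataset`.
#' @return A tibble with columns `snp_id`, `maf`, `n_called`.
#' @export
snp_maf <- function(dataset) {
  g <- dataset$genotypes
  n_called <- rowSums(!is.na(g))
  f <- rowSums(g, na.rm = TRUE) / (2 * n_called)
  tibble::tibble(
    snp_id = rownames(g),
    maf = unname(pmin(f, 1 - f)),
    n_called = unname(n_called)
  )
}

#' Drop rare and monomorphic SNPs
#'
#' Removes SNPs that are monomorphic (MAF = 0, slope undefined in the
#' additive model) and SNPs with minor-allele frequency below `maf_min`,
#' computed on non-missing calls. Idempotent.
#'
#' @param dataset An `omic_dataset`.
#' @param maf_min Minimum minor-allele frequency in `[0, 0.5)`; default 0.05.
#'   At `maf_min = 0` only monomorphic SNPs are removed.
#' @return The filtered `omic_dataset` (possibly with zero SNPs).
#' @export
filter_snps_by_maf <- function(dataset, maf_min = 0.05) {
  stopifnot(inherits(dataset, "omic_dataset"))
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5) {
    abort("`maf_min` must lie in [0, 0.5).")
  }
  maf <- snp_maf(dataset)$maf
  keep <- !is.na(maf) & maf > 0 & maf >= maf_min
  dataset$genotypes <- dataset$genotypes[keep, , drop = FALSE]
  dataset
}
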