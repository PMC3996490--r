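# Readers and writers for the tab-delimited matrix and phenotype dialects the
# pipeline consumes and emits. Matrices travel feature-by-sample with an `id`
# label column; missing values are the literal "NA".

#' Read a labelled numeric matrix from a delimited text file
#'
#' Expects one header row (sample or feature labels) and one label column.
#' Orientation is normalized to feature-by-sample.
#'
#' @param path Path to a tab-delimited text file.
#' @param orientation Either `"features_in_rows"` (default; rows are genes /
#'   miRNAs / SNPs) or `"samples_in_rows"` (the transpose).
#' @return A numeric matrix, features in rows, with feature rownames and
#'   sample colnames.
#' @export
read_matrix <- function(path, orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < 2L) {
    abort(sprintf("'%s' must have a label column plus at least one data column.", path))
  }
  labels <- raw[[1]]
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) {
    abort(sprintf("Duplicated row label(s) in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  cn <- names(raw)[-1]
  dupc <- unique(cn[duplicated(cn)])
  if (length(dupc)) {
    abort(sprintf("Duplicated column label(s) in '%s': %s", path, paste(dupc, collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-numeric cell in '%s' at row '%s', column '%s': \"%s\"",
      path, labels[bad[1, 1]], cn[bad[1, 2]], cells[bad[1, , drop = FALSE]]
    ))
  }
  dimnames(num) <- list(labels, cn)
  if (orientation == "samples_in_rows") num <- t(num)
  num
}

#' Write a labelled numeric matrix as tab-delimited text
#'
#' Values are written with shortest round-trip precision, so
#' `read_matrix(write_matrix(x))` reproduces `x` exactly.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_label Header for the label column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_label = "id") {
  x <- as_feature_matrix(x, "x")
  tbl <- tibble::as_tibble(x, rownames = id_label)
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a per-sample phenotype table
#'
#' @param path Tab-delimited file with a `sample_id` column and named numeric
#'   phenotype columns (e.g. `log2_ic50`, `igrowth`, `dsp`).
#' @return A tibble with `sample_id` as character and remaining columns numeric
#'   (a `drug_label` column, if present, stays character).
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tbl)) {
    abort(sprintf("'%s' must contain a `sample_id` column.", path))
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl
}

#' Write a per-sample phenotype table
#'
#' @param pheno Data frame with a `sample_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(tibble::as_tibble(pheno), path, na = "NA", progress = FALSE)
  invisible(path)
}
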