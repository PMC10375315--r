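# Cohort ingestion: binary mutation/amplification/deletion matrices, an
# expression matrix, the derived per-term enrichment matrix, and the
# (cell, drug, AUC) sensitivity triplets.

read_gene_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  rn <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

write_gene_matrix <- function(m, path) {
  dt <- data.table::data.table(cell_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

check_binary <- function(m, what) {
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("non-binary value ", m[i, j], " in ", what,
         " matrix at cell ", rownames(m)[i], ", gene ", colnames(m)[j])
  }
  invisible(TRUE)
}

# Restrict a matrix to the layout dictionary for one channel, erroring on
# dictionary genes the file does not provide (the model needs every wired
# input) and dropping extra genes with a message.
align_to_dict <- function(m, dict, what) {
  missing <- setdiff(dict, colnames(m))
  if (length(missing)) {
    stop(what, " matrix is missing ", length(missing),
         " gene(s) required by the layout, e.g. ", missing[1])
  }
  extra <- setdiff(colnames(m), dict)
  if (length(extra)) {
    message("load_cohort: dropped ", length(extra), " ", what,
            " gene(s) not wired into the layout")
  }
  m[, dict, drop = FALSE]
}

#' Load a multiomics cohort aligned to a model layout
#'
#' Reads the three binary matrices and the expression matrix (TSV/CSV, first
#' column cell id, header row of gene symbols), validates the binary channels,
#' intersects the cell sets across files (exclusions reported), aligns gene
#' columns to the layout dictionaries, and computes the per-term enrichment
#' matrix from expression ranks.
#'
#' @param mutation,amplification,deletion,expression File paths.
#' @param layout An `ontology_layout`.
#' @return A `cohort_data`: list with `cells`, binary matrices `M`, `A`, `D`,
#'   expression `E`, and `NES` (cells x retained terms).
#' @export
load_cohort <- function(mutation, amplification, deletion, expression, layout) {
  M <- read_gene_matrix(mutation)
  A <- read_gene_matrix(amplification)
  D <- read_gene_matrix(deletion)
  E <- read_gene_matrix(expression)
  check_binary(M, "mutation"); check_binary(A, "amplification")
  check_binary(D, "deletion")
  if (anyNA(E)) stop("missing values in expression matrix")

  cells <- Reduce(intersect, list(rownames(M), rownames(A),
                                  rownames(D), rownames(E)))
  if (!length(cells)) stop("empty intersection of cells across omics files")
  n_dropped <- length(unique(c(rownames(M), rownames(A),
                               rownames(D), rownames(E)))) - length(cells)
  if (n_dropped > 0L) {
    message("load_cohort: excluded ", n_dropped,
            " cell(s) absent from at least one omics file")
  }

  M <- align_to_dict(M[cells, , drop = FALSE], layout$dict$mutation, "mutation")
  A <- align_to_dict(A[cells, , drop = FALSE], layout$dict$amplification,
                     "amplification")
  D <- align_to_dict(D[cells, , drop = FALSE], layout$dict$deletion, "deletion")
  E <- E[cells, , drop = FALSE]

  NES <- nes_matrix(E, layout$genes$expression)
  NES <- NES[, layout$terms, drop = FALSE]

  structure(list(cells = cells, M = M, A = A, D = D, E = E, NES = NES),
            class = "cohort_data")
}

#' Construct a cohort from in-memory matrices
#'
#' Same validation and alignment as [load_cohort()] but starting from
#' matrices, as produced by the synthetic generator.
#' @param M,A,D,E Matrices cells x genes (binary for `M`, `A`, `D`).
#' @param layout An `ontology_layout`.
#' @return A `cohort_data`.
#' @export
cohort_from_matrices <- function(M, A, D, E, layout) {
  check_binary(M, "mutation"); check_binary(A, "amplification")
  check_binary(D, "deletion")
  storage.mode(M) <- "double"; storage.mode(A) <- "double"
  storage.mode(D) <- "double"; storage.mode(E) <- "double"
  cells <- rownames(M)
  stopifnot(identical(cells, rownames(A)), identical(cells, rownames(D)),
            identical(cells, rownames(E)))
  M <- align_to_dict(M, layout$dict$mutation, "mutation")
  A <- align_to_dict(A, layout$dict$amplification, "amplification")
  D <- align_to_dict(D, layout$dict$deletion, "deletion")
  NES <- nes_matrix(E, layout$genes$expression)[, layout$terms, drop = FALSE]
  structure(list(cells = cells, M = M, A = A, D = D, E = E, NES = NES),
            class = "cohort_data")
}

#' Write a cohort's matrices to TSV files
#' @param cohort A `cohort_data`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mutation = file.path(dir, "mutation.tsv"),
             amplification = file.path(dir, "amplification.tsv"),
             deletion = file.path(dir, "deletion.tsv"),
             expression = file.path(dir, "expression.tsv"))
  write_gene_matrix(cohort$M, paths["mutation"])
  write_gene_matrix(cohort$A, paths["amplification"])
  write_gene_matrix(cohort$D, paths["deletion"])
  write_gene_matrix(cohort$E, paths["expression"])
  invisible(paths)
}

#' Read sensitivity triplets (cell_id, drug_id, auc)
#'
#' AUC is the area under the dose-response curve: near 0 means high
#' sensitivity, near 1 no effect; values above 1 (growth promotion) are
#' permitted.
#' @param path TSV with columns `cell_id`, `drug_id`, `auc`.
#' @return data.frame with those three columns.
#' @export
read_triplets <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("cell_id", "drug_id", "auc")
  if (!all(need %in% names(dt))) {
    stop("triplet file must have columns cell_id, drug_id, auc")
  }
  dt <- dt[, need]
  dt$cell_id <- as.character(dt$cell_id)
  dt$drug_id <- as.character(dt$drug_id)
  dt$auc <- as.numeric(dt$auc)
  if (any(!is.finite(dt$auc))) stop("non-finite AUC values in ", path)
  dt
}

#' @rdname read_triplets
#' @param triplets data.frame as returned by [read_triplets()].
#' @export
write_triplets <- function(triplets, path) {
  data.table::fwrite(triplets, path, sep = "\t")
  invisible(path)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", length(x$cells), "cells;",
      ncol(x$M), "mutation,", ncol(x$A), "amplification,",
      ncol(x$D), "deletion genes;", ncol(x$E), "expression genes;",
      ncol(x$NES), "term enrichment scores\n")
  invisible(x)
}
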