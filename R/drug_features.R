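# Drug representation: binary substructure fingerprint bits concatenated
# with continuous molecular descriptors.

#' Load and assemble the drug feature matrix
#'
#' Reads the fingerprint and descriptor tables (TSV/CSV, first column drug
#' id), intersects their drug sets (exclusions reported), validates that
#' fingerprint entries are binary, and returns the combined drugs x
#' (fingerprints || descriptors) matrix with a fixed, serialized column
#' order.
#'
#' @param fingerprints Path to the fingerprint table (binary bits).
#' @param descriptors Path to the descriptor table (continuous).
#' @return A `drug_feature_matrix`: numeric matrix with attributes
#'   `fingerprint_cols` and `descriptor_cols` (column name vectors) and
#'   `scaled` (logical).
#' @export
load_drug_features <- function(fingerprints, descriptors) {
  F_ <- read_gene_matrix(fingerprints)
  V <- read_gene_matrix(descriptors)
  bad <- which(!(F_ %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(F_)) + 1; j <- ((bad[1] - 1) %/% nrow(F_)) + 1
    stop("non-binary fingerprint entry at drug ", rownames(F_)[i],
         ", bit ", colnames(F_)[j])
  }
  all_na <- colSums(!is.na(V)) == 0
  if (any(all_na)) {
    stop("descriptor column(s) entirely missing: ",
         paste(colnames(V)[all_na], collapse = ", "))
  }
  drugs <- intersect(rownames(F_), rownames(V))
  if (!length(drugs)) stop("no drugs shared between fingerprint and descriptor files")
  excluded <- length(union(rownames(F_), rownames(V))) - length(drugs)
  if (excluded > 0L) {
    message("load_drug_features: excluded ", excluded,
            " drug(s) missing from one of the two files")
  }
  drug_feature_matrix(F_[drugs, , drop = FALSE], V[drugs, , drop = FALSE])
}

#' Assemble a drug feature matrix from in-memory blocks
#' @param F_ Binary fingerprint matrix (drugs x bits).
#' @param V Descriptor matrix (drugs x descriptors), same row order.
#' @return A `drug_feature_matrix`.
#' @export
drug_feature_matrix <- function(F_, V) {
  stopifnot(identical(rownames(F_), rownames(V)))
  X <- cbind(F_, V)
  structure(X, class = c("drug_feature_matrix", "matrix", "array"),
            fingerprint_cols = colnames(F_), descriptor_cols = colnames(V),
            scaled = FALSE)
}

#' Z-score the descriptor block using training-split statistics
#'
#' Descriptor columns are centred and scaled with per-column mean/sd learned
#' on the training rows only; missing values are imputed with the training
#' median; zero-variance columns map to 0. The fingerprint block is never
#' touched. Statistics are attached to the result (and reusable at inference
#' time) so no information leaks from held-out drugs.
#'
#' @param dfm A `drug_feature_matrix`.
#' @param stats Optional statistics from a previous call (named list with
#'   `center`, `scale`, `median`); when supplied they are applied as-is.
#' @param train_drugs Drug ids to learn statistics from; defaults to all rows.
#' @return The `drug_feature_matrix` with scaled descriptors and attribute
#'   `scaling_stats`.
#' @export
scale_descriptors <- function(dfm, stats = NULL, train_drugs = NULL) {
  desc_cols <- attr(dfm, "descriptor_cols")
  if (!length(desc_cols)) return(dfm)
  V <- unclass(dfm)[, desc_cols, drop = FALSE]
  if (is.null(stats)) {
    rows <- if (is.null(train_drugs)) rownames(V) else train_drugs
    missing_rows <- setdiff(rows, rownames(V))
    if (length(missing_rows)) stop("unknown training drugs: ",
                                   paste(missing_rows, collapse = ", "))
    Vt <- V[rows, , drop = FALSE]
    med <- apply(Vt, 2, stats::median, na.rm = TRUE)
    Vt_imp <- Vt
    for (j in seq_len(ncol(Vt_imp))) {
      Vt_imp[is.na(Vt_imp[, j]), j] <- med[j]
    }
    stats <- list(center = colMeans(Vt_imp),
                  scale = apply(Vt_imp, 2, stats::sd),
                  median = med)
  } else {
    if (!identical(names(stats$center), desc_cols)) {
      stop("scaling statistics do not match the descriptor column set")
    }
  }
  n_imputed <- sum(is.na(V))
  if (n_imputed > 0L) {
    message("scale_descriptors: imputed ", n_imputed,
            " missing descriptor value(s) with training medians")
    for (j in seq_len(ncol(V))) V[is.na(V[, j]), j] <- stats$median[j]
  }
  sc <- stats$scale
  sc[!is.finite(sc) | sc == 0] <- Inf   # zero-variance columns -> 0
  V <- sweep(sweep(V, 2, stats$center), 2, sc, "/")
  V[, !is.finite(stats$scale) | stats$scale == 0] <- 0

  out <- unclass(dfm)
  out[, desc_cols] <- V
  structure(out, class = class(dfm),
            fingerprint_cols = attr(dfm, "fingerprint_cols"),
            descriptor_cols = desc_cols,
            scaled = TRUE, scaling_stats = stats)
}

#' Write a drug feature matrix back to its two source tables
#' @param dfm A `drug_feature_matrix`.
#' @param fingerprints,descriptors Output paths.
#' @export
write_drug_features <- function(dfm, fingerprints, descriptors) {
  X <- unclass(dfm)
  write_gene_matrix(X[, attr(dfm, "fingerprint_cols"), drop = FALSE],
                    fingerprints)
  write_gene_matrix(X[, attr(dfm, "descriptor_cols"), drop = FALSE],
                    descriptors)
  invisible(c(fingerprints, descriptors))
}
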