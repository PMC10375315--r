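# Imbalance-aware evaluation: macro-averaged MSE over AUC bins, balanced
# resampled correlations, bin confusion matrices and cross-validation splits.

#' Macro-averaged mean squared error
#'
#' Bins the ground truth into the AUC histogram and averages the per-bin MSE
#' over the occupied bins, so every class contributes equally regardless of
#' its frequency. Trivial majority-class predictors are thereby penalized.
#'
#' @param preds,truths Equal-length numeric vectors.
#' @inheritParams assign_bin
#' @return An `eval_report`: list with `mmse`, `per_bin_mse` (length
#'   `n_bins`, `NA` for empty bins) and `counts`.
#' @export
macro_mse <- function(preds, truths, n_bins = 12L, bin_range = c(0, 1.2)) {
  if (!length(preds)) stop("macro_mse: empty input")
  stopifnot(length(preds) == length(truths))
  bins <- assign_bin(truths, n_bins, bin_range)
  per <- rep(NA_real_, n_bins)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  se <- (preds - truths)^2
  for (i in which(counts > 0L)) {
    per[i] <- mean(se[bins == i - 1L])
  }
  structure(list(mmse = mean(per, na.rm = TRUE), per_bin_mse = per,
                 counts = counts),
            class = "eval_report")
}

#' Balanced resampled correlations
#'
#' Repeatedly samples an equal number of records from each occupied AUC bin
#' (without replacement when the bin is large enough, with replacement
#' otherwise) and computes Pearson and Spearman correlations between
#' predictions and truths on each balanced resample.
#'
#' @param preds,truths Equal-length numeric vectors.
#' @param n_per_class Records drawn per occupied bin (default 100).
#' @param runs Number of resampling runs (default 1000).
#' @param seed Integer seed.
#' @inheritParams assign_bin
#' @return List with `pearson`, `spearman` (means over runs), `pearson_sd`,
#'   `spearman_sd`, and the per-run vectors.
#' @export
balanced_correlation <- function(preds, truths, n_per_class = 100L,
                                 runs = 1000L, seed = 1L,
                                 n_bins = 12L, bin_range = c(0, 1.2)) {
  stopifnot(length(preds) == length(truths))
  bins <- assign_bin(truths, n_bins, bin_range)
  occupied <- sort(unique(bins))
  if (length(occupied) < 2L) {
    stop("balanced_correlation: need at least 2 occupied bins")
  }
  by_bin <- split(seq_along(truths), bins)
  with_seed(seed, {
    pear <- numeric(runs); spear <- numeric(runs)
    for (r in seq_len(runs)) {
      take <- unlist(lapply(by_bin, function(ii) {
        if (length(ii) >= n_per_class) sample(ii, n_per_class)
        else sample(ii, n_per_class, replace = TRUE)
      }), use.names = FALSE)
      pear[r] <- stats::cor(preds[take], truths[take], method = "pearson")
      spear[r] <- stats::cor(preds[take], truths[take], method = "spearman")
    }
    list(pearson = mean(pear), spearman = mean(spear),
         pearson_sd = stats::sd(pear), spearman_sd = stats::sd(spear),
         runs_pearson = pear, runs_spearman = spear)
  })
}

#' Cross-validation fold assignment
#'
#' `"random"` partitions the triplets; `"leave_cell_lines_out"` and
#' `"leave_drugs_out"` partition the cell (or drug) id set so that no group
#' id occurs in two folds. Folds are exhaustive and pairwise disjoint.
#'
#' @param triplets data.frame with `cell_id`, `drug_id`.
#' @param scheme Splitting scheme.
#' @param k_folds Number of folds (`>= 2`).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (`1..k_folds`), one per triplet.
#' @export
split_folds <- function(triplets,
                        scheme = c("random", "leave_cell_lines_out",
                                   "leave_drugs_out"),
                        k_folds = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(k_folds >= 2L)
  n <- nrow(triplets)
  if (scheme == "random") {
    return(with_seed(seed, sample(rep_len(seq_len(k_folds), n))))
  }
  ids <- if (scheme == "leave_cell_lines_out") triplets$cell_id else triplets$drug_id
  groups <- unique(ids)
  if (length(groups) < k_folds) {
    stop("fewer ", if (scheme == "leave_cell_lines_out") "cell lines" else "drugs",
         " (", length(groups), ") than folds (", k_folds, ")")
  }
  gf <- with_seed(seed, sample(rep_len(seq_len(k_folds), length(groups))))
  names(gf) <- groups
  unname(gf[ids])
}

#' Truth-bin by predicted-bin confusion matrix
#'
#' @param preds,truths Equal-length numeric vectors.
#' @inheritParams assign_bin
#' @return `n_bins` x `n_bins` integer matrix; entry (i, j) counts records
#'   with truth in bin i-1 predicted into bin j-1. Row sums equal the truth
#'   histogram.
#' @export
bin_confusion <- function(preds, truths, n_bins = 12L, bin_range = c(0, 1.2)) {
  stopifnot(length(preds) == length(truths))
  tb <- factor(assign_bin(truths, n_bins, bin_range), levels = 0:(n_bins - 1L))
  pb <- factor(assign_bin(preds, n_bins, bin_range), levels = 0:(n_bins - 1L))
  unclass(table(truth = tb, predicted = pb))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: MMSE =", signif(x$mmse, 5), "over",
      sum(x$counts > 0), "occupied bins\n")
  invisible(x)
}
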