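# Single-sample gene-set enrichment via the Mann-Whitney-Wilcoxon gene set
# test. The score is the probability that an in-set gene outranks an
# out-of-set gene within one sample's expression profile.

#' Normalized enrichment score from within-sample ranks
#'
#' Given the ranks of the `m` set genes among all `m + n` genes of a sample
#' (ranks `1..(m+n)`, average ranks on ties), computes
#' `NES = 1 - U/(m*n)` with the standard Mann-Whitney statistic
#' `U = m*n + m*(m+1)/2 - T`, `T` the sum of set-gene ranks. Under no ties
#' this equals the exact probability that a uniformly chosen set gene has
#' higher expression than a uniformly chosen outside gene.
#'
#' @param set_ranks Numeric vector of length `m`: ranks of the set genes.
#' @param m Number of genes in the set (`>= 1`).
#' @param n Number of genes outside the set (`>= 1`).
#' @return A number in `[0, 1]`.
#' @examples
#' compute_nes(c(4, 5), m = 2, n = 3) # set genes hold the top ranks -> 1
#' @export
compute_nes <- function(set_ranks, m, n) {
  if (m < 1 || n < 1) {
    stop("NES undefined: need m >= 1 set genes and n >= 1 outside genes")
  }
  if (length(set_ranks) != m) stop("length(set_ranks) must equal m")
  T_stat <- sum(set_ranks)
  U <- m * n + m * (m + 1) / 2 - T_stat
  1 - U / (m * n)
}

#' Per-term enrichment matrix for a cohort
#'
#' Ranks each cell's expression profile once (average ranks on ties) and
#' evaluates [compute_nes()] for every term's expression gene set. Terms with
#' no expression-annotated genes, or annotated with every gene (`n = 0`), get
#' the uninformative midpoint 0.5 (reported via a message).
#'
#' @param E Numeric matrix, cells x genes, with gene column names.
#' @param term_genes Named list term -> character vector of genes (the
#'   layout's expression channel).
#' @return Numeric matrix cells x terms with entries in `[0, 1]`.
#' @export
nes_matrix <- function(E, term_genes) {
  stopifnot(is.matrix(E), !is.null(colnames(E)))
  G <- ncol(E)
  n_terms <- length(term_genes)
  ind <- matrix(0, G, n_terms, dimnames = list(colnames(E), names(term_genes)))
  for (t in names(term_genes)) {
    g <- intersect(term_genes[[t]], colnames(E))
    ind[g, t] <- 1
  }
  m <- colSums(ind)
  n <- G - m

  R <- t(apply(E, 1, rank))          # average ranks on ties
  T_stat <- R %*% ind                # cells x terms rank sums
  mn <- m * n
  U <- sweep(-T_stat, 2, mn + m * (m + 1) / 2, "+")
  NES <- 1 - sweep(U, 2, pmax(mn, 1), "/")

  degenerate <- m == 0 | n == 0
  if (any(degenerate)) {
    NES[, degenerate] <- 0.5
    message("nes_matrix: ", sum(degenerate),
            " term(s) with empty or all-gene expression sets; NES set to 0.5")
  }
  rownames(NES) <- rownames(E)
  NES
}
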