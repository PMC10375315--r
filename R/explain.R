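# Ablation-based interpretation. For each (cell, drug, term) the relative
# improvement score compares the prediction deviation when silencing a term
# module against silencing its children:
#   s_f  = |p_f  - p|   (term silenced)
#   s_cf = |p_cf - p|   (all its children silenced; for a leaf, its inputs)
#   RIS  = (s_cf - s_f) / (s_cf + s_f)   in [-1, 1]
# Silencing a term (or child) zeroes its embedding wherever consumed,
# equivalent to zeroing the downstream weights that read it; its enrichment
# score is a measurement, not a module output, so it keeps flowing. A leaf's
# input ablation removes its data sources: gene columns are zeroed (absence
# is their null) and its enrichment score is set to the uninformative
# midpoint 0.5 (the imputation value for undefined enrichment).

#' Relative improvement scores for (cell, drug) pairs
#'
#' Runs the trained model in inference mode: one baseline forward pass, then
#' two ablation passes per term (term silenced; children silenced). When both
#' deviations are zero the score is defined as 0 (uninformative).
#'
#' @param model A trained `movida_model` (sensitivity variant).
#' @param cohort A `cohort_data`.
#' @param drugs A `drug_feature_matrix`.
#' @param pairs data.frame `cell_id`, `drug_id`; scores are computed for every
#'   pair and every term.
#' @param terms Terms to score (default: all retained terms).
#' @return data.frame `cell_id`, `drug_id`, `term`, `p`, `p_f`, `p_cf`,
#'   `s_f`, `s_cf`, `ris`.
#' @export
ris_scores <- function(model, cohort, drugs, pairs,
                       terms = model$layout$terms) {
  if (model$synergy) stop("ris_scores supports the sensitivity variant")
  check_ids(pairs$cell_id, cohort$cells, "cell")
  check_ids(pairs$drug_id, rownames(drugs), "drug")
  bad <- setdiff(terms, model$layout$terms)
  if (length(bad)) stop("term(s) not in layout: ", paste(bad, collapse = ", "))

  CF <- cell_features(cohort)[match(pairs$cell_id, cohort$cells), , drop = FALSE]
  DX <- unclass(drugs)[match(pairs$drug_id, rownames(drugs)), , drop = FALSE]
  n <- nrow(pairs)

  p0 <- model_forward(model, CF, DX, training = FALSE)$out
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    s <- terms[i]
    p_f <- model_forward(model, CF, DX, training = FALSE,
                         ablate = list(silence = s))$out
    kids <- model$layout$children[[s]]
    abl_cf <- if (length(kids)) {
      list(silence = kids)
    } else {
      list(silence_inputs = s, silence_nes = s)
    }
    p_cf <- model_forward(model, CF, DX, training = FALSE, ablate = abl_cf)$out
    s_f <- abs(p_f - p0)
    s_cf <- abs(p_cf - p0)
    denom <- s_cf + s_f
    ris <- ifelse(denom > 0, (s_cf - s_f) / denom, 0)
    out[[i]] <- data.frame(cell_id = pairs$cell_id, drug_id = pairs$drug_id,
                           term = s, p = p0, p_f = p_f, p_cf = p_cf,
                           s_f = s_f, s_cf = s_cf, ris = ris,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate RIS records by drug, cell or group
#'
#' @param records data.frame from [ris_scores()].
#' @param by `"drug"`, `"cell"` or `"tissue_group"`.
#' @param group_map For `by = "tissue_group"`: named character vector mapping
#'   cell ids to group labels.
#' @return data.frame `group`, `term`, `mean_ris`, `sd_ris`, `n`, sorted by
#'   group then descending mean (ties broken by term id).
#' @export
aggregate_ris <- function(records, by = c("drug", "cell", "tissue_group"),
                          group_map = NULL) {
  by <- match.arg(by)
  if (!nrow(records)) stop("aggregate_ris: empty records")
  g <- switch(by,
              drug = records$drug_id,
              cell = records$cell_id,
              tissue_group = {
                if (is.null(group_map)) stop("group_map required for tissue_group")
                miss <- setdiff(unique(records$cell_id), names(group_map))
                if (length(miss)) stop("unknown group key(s): ",
                                       paste(miss, collapse = ", "))
                unname(group_map[records$cell_id])
              })
  dt <- data.table::as.data.table(records)
  dt$group <- g
  agg <- dt[, list(mean_ris = mean(ris),
                   sd_ris = if (.N > 1L) stats::sd(ris) else NA_real_,
                   n = .N),
            by = c("group", "term")]
  data.table::setorder(agg, group, -mean_ris, term)
  as.data.frame(agg)
}

#' Drug-combination candidates from top-scoring terms
#'
#' Takes the `top_k` terms by RIS for one (cell, drug) pair (leaf terms by
#' default), unions their annotated genes, and returns every drug in the
#' target table hitting at least one of those genes, excluding the query
#' drug itself.
#'
#' @param ris_table data.frame from [ris_scores()] restricted to one pair.
#' @param layout The model's `ontology_layout` (gene sets per term; the
#'   mutation/amplification/deletion union is used).
#' @param target_table data.frame `drug_id`, `gene`: known drug targets.
#' @param top_k Number of top terms (default 5).
#' @param leaves_only Restrict the ranking to leaf terms (default `TRUE`).
#' @return Character vector of candidate drug ids; attributes `top_terms` and
#'   `genes` record the selection.
#' @export
candidate_combinations <- function(ris_table, layout, target_table,
                                   top_k = 5L, leaves_only = TRUE) {
  if (!nrow(target_table)) stop("empty target table")
  if (length(unique(ris_table$cell_id)) != 1L ||
      length(unique(ris_table$drug_id)) != 1L) {
    stop("ris_table must contain a single (cell, drug) pair")
  }
  tab <- ris_table
  if (leaves_only) {
    leaves <- names(layout$children)[lengths(layout$children) == 0L]
    tab <- tab[tab$term %in% leaves, , drop = FALSE]
  }
  # descending score, ties broken by term id for determinism
  tab <- tab[order(-tab$ris, tab$term), , drop = FALSE]
  top_terms <- head(tab$term, top_k)
  genes <- unique(unlist(lapply(top_terms, function(t) {
    c(layout$genes$mutation[[t]], layout$genes$amplification[[t]],
      layout$genes$deletion[[t]])
  }), use.names = FALSE))
  hit <- unique(as.character(target_table$drug_id[target_table$gene %in% genes]))
  cand <- sort(setdiff(hit, unique(ris_table$drug_id)))
  structure(cand, top_terms = top_terms, genes = genes)
}

#' Enrichment of candidates among validated synergistic partners
#'
#' Among combinations tested for the (cell, drug) pair, `S` are synergistic
#' and `NS` are not; candidates found in the validated set split into `TP`
#' (synergistic) and `FP` (not). Precision `TP/(TP+FP)` is compared with the
#' baseline `S/(S+NS)` via a one-sided binomial tail
#' `P(X >= TP | n = TP+FP, p = S/(S+NS))`.
#'
#' @param candidates Character vector of candidate partner drug ids.
#' @param validated data.frame `drug_id`, `label` (1 synergistic, 0 not): all
#'   partners tested with the query (cell, drug) pair.
#' @return A `synergy_enrichment`: list with `TP`, `FP`, `S`, `NS`,
#'   `precision`, `baseline`, `enrichment`, `p_value`. When no candidate was
#'   tested (`TP + FP = 0`) precision and p-value are `NA` with
#'   `undefined = TRUE`.
#' @export
synergy_enrichment <- function(candidates, validated) {
  if (!nrow(validated)) stop("validated set is empty for this pair")
  S <- sum(validated$label == 1)
  NS <- sum(validated$label == 0)
  tested <- validated[validated$drug_id %in% candidates, , drop = FALSE]
  TP <- sum(tested$label == 1)
  FP <- sum(tested$label == 0)
  baseline <- S / (S + NS)
  if (TP + FP == 0L) {
    return(structure(list(TP = TP, FP = FP, S = S, NS = NS,
                          precision = NA_real_, baseline = baseline,
                          enrichment = NA_real_, p_value = NA_real_,
                          undefined = TRUE),
                     class = "synergy_enrichment"))
  }
  precision <- TP / (TP + FP)
  p_value <- stats::pbinom(TP - 1L, TP + FP, baseline, lower.tail = FALSE)
  structure(list(TP = TP, FP = FP, S = S, NS = NS,
                 precision = precision, baseline = baseline,
                 enrichment = precision / baseline, p_value = p_value,
                 undefined = FALSE),
            class = "synergy_enrichment")
}

#' @export
print.synergy_enrichment <- function(x, ...) {
  cat("synergy_enrichment: TP =", x$TP, "FP =", x$FP,
      "| baseline", signif(x$baseline, 4), "\n")
  if (!x$undefined) {
    cat("  precision", signif(x$precision, 4),
        " enrichment", signif(x$enrichment, 4),
        " one-sided binomial p =", signif(x$p_value, 4), "\n")
  } else {
    cat("  no candidate present in the validated set; test undefined\n")
  }
  invisible(x)
}

#' Read a drug -> target-gene table
#' @param path TSV with columns `drug_id`, `gene`.
#' @return data.frame with those columns.
#' @export
read_target_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("drug_id", "gene") %in% names(dt))) {
    stop("target table must have columns drug_id, gene")
  }
  dt$drug_id <- as.character(dt$drug_id)
  dt$gene <- as.character(dt$gene)
  dt
}

#' Read a validated synergy table
#'
#' Either a binary `label` column or a continuous `loewe` dose-additivity
#' score; scores above `threshold` (default 30) mark synergy.
#' @param path TSV with `cell_id`, `drug_a`, `drug_b` and `label` or `loewe`.
#' @param threshold Synergy threshold on the additivity score.
#' @return data.frame `cell_id`, `drug_a`, `drug_b`, `label`.
#' @export
read_synergy_table <- function(path, threshold = 30) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("cell_id", "drug_a", "drug_b")
  if (!all(need %in% names(dt))) {
    stop("synergy table must have columns cell_id, drug_a, drug_b and label or loewe")
  }
  if (!"label" %in% names(dt)) {
    if (!"loewe" %in% names(dt)) stop("need a label or loewe column")
    dt$label <- as.integer(dt$loewe > threshold)
  }
  dt$cell_id <- as.character(dt$cell_id)
  dt$drug_a <- as.character(dt$drug_a)
  dt$drug_b <- as.character(dt$drug_b)
  dt[, c(need, "label")]
}
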