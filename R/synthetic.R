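# Synthetic study generator: a toy ontology, annotation files, a multiomics
# cohort with planted causal pathways, drug features with mechanism-linked
# fingerprint bits, skewed AUC labels and synergy labels. Every other module
# is testable end-to-end on its output, with no downloads.

#' Generate a toy ontology and its annotation file
#'
#' Builds a complete `branching`-ary tree of the given depth (optionally with
#' extra cross edges, keeping the graph acyclic), annotates every leaf with
#' `genes_per_term` genes sampled from a universe of `n_genes`, and renders
#' the OBO and GMT text. Deterministic given `seed`.
#'
#' @param depth Tree depth (root level included), `>= 2`.
#' @param branching Children per internal term, `>= 1` (1 gives a chain).
#' @param n_genes Size of the gene universe.
#' @param genes_per_term Genes annotated to each leaf.
#' @param cross_edges Number of extra is_a edges from deeper to shallower
#'   terms (DAG fixtures; default 0).
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `ontology.obo` and
#'   `annotations.gmt` are written there.
#' @return List with `obo_text`, `gmt_text`, `terms`, `leaves`, `genes`
#'   (universe), `annotation` (term -> gene list) and, when `dir` is given,
#'   `obo_path`, `gmt_path`.
#' @export
generate_ontology <- function(depth = 4L, branching = 3L, n_genes = 300L,
                              genes_per_term = 8L, cross_edges = 0L,
                              seed = 1L, dir = NULL) {
  stopifnot(depth >= 2L, branching >= 1L)
  if (genes_per_term > n_genes) {
    stop("genes_per_term cannot exceed n_genes")
  }
  n_terms <- sum(branching^(0:(depth - 1L)))
  term_id <- sprintf("GO:SIM%04d", seq_len(n_terms))
  level <- rep(0:(depth - 1L), branching^(0:(depth - 1L)))
  parent <- c(NA_integer_,
              (((2:n_terms) - 2L) %/% branching) + 1L)
  leaves <- which(level == depth - 1L)
  genes <- sprintf("g%04d", seq_len(n_genes))

  drawn <- with_seed(derive_seed(seed, 11L), {
    extra <- NULL
    if (cross_edges > 0L) {
      # extra edges from strictly deeper to strictly shallower terms keep
      # the graph acyclic; skip duplicates of tree edges
      pool_child <- which(level >= 2L)
      ce <- 0L
      picks <- list()
      while (ce < cross_edges) {
        ch <- sample(pool_child, 1L)
        pa <- sample(which(level < level[ch]), 1L)
        if (pa != parent[ch]) {
          picks[[length(picks) + 1L]] <- c(ch, pa)
          ce <- ce + 1L
        }
      }
      extra <- unique(do.call(rbind, picks))
    }
    ann <- lapply(stats::setNames(leaves, term_id[leaves]), function(i) {
      sort(sample(genes, genes_per_term))
    })
    list(extra = extra, ann = ann)
  })
  extra <- drawn$extra
  ann <- drawn$ann

  stanza <- function(i) {
    isa <- character(0)
    if (!is.na(parent[i])) {
      isa <- sprintf("is_a: %s ! parent", term_id[parent[i]])
    }
    if (!is.null(extra)) {
      for (r in which(extra[, 1] == i)) {
        isa <- c(isa, sprintf("is_a: %s ! cross", term_id[extra[r, 2]]))
      }
    }
    c("[Term]", sprintf("id: %s", term_id[i]),
      sprintf("name: simulated term %d (level %d)", i, level[i]),
      "namespace: biological_process", isa, "")
  }
  obo_text <- c("format-version: 1.2", "ontology: go-sim", "",
                unlist(lapply(seq_len(n_terms), stanza)))
  gmt_text <- vapply(names(ann), function(t) {
    paste(c(t, "simulated", ann[[t]]), collapse = "\t")
  }, character(1))

  out <- list(obo_text = obo_text, gmt_text = gmt_text, terms = term_id,
              leaves = term_id[leaves], genes = genes, annotation = ann)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$obo_path <- file.path(dir, "ontology.obo")
    out$gmt_path <- file.path(dir, "annotations.gmt")
    writeLines(obo_text, out$obo_path)
    writeLines(gmt_text, out$gmt_path)
  }
  out
}

#' Ground-truth parameters of a synthetic study
#'
#' Fixes which leaf terms are causal, how cells activate them, how drugs hit
#' them, the effect size and the noise level, and the right-skewed baseline
#' AUC distribution (a scaled Beta concentrated near 1, emulating the strong
#' imbalance of real drug screens).
#'
#' @param layout An `ontology_layout` built from [generate_ontology()] output.
#' @param n_causal Number of causal leaf terms.
#' @param p_active Probability a cell activates each causal term.
#' @param beta Effect size: AUC drop per causal term hit by the drug and
#'   active in the cell.
#' @param sigma Additive Gaussian noise sd on the AUC.
#' @param base_shape Beta shape parameters of the baseline AUC.
#' @param base_scale Baseline scale (AUC support is `[0, base_scale]`).
#' @param mech_probs Probabilities that a drug hits 0, 1 or 2 causal terms.
#' @param n_fp,n_desc Fingerprint bits and descriptor columns.
#' @param label_noise Synergy label flip probability.
#' @param seed Integer seed (selects the causal terms).
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(layout, n_causal = 4L, p_active = 0.3,
                            beta = 0.32, sigma = 0.05,
                            base_shape = c(8.5, 3), base_scale = 1.2,
                            mech_probs = c(0.30, 0.62, 0.08),
                            n_fp = 64L, n_desc = 8L, label_noise = 0.02,
                            seed = 1L) {
  stopifnot(beta >= 0, sigma >= 0, n_causal >= 1L,
            abs(sum(mech_probs) - 1) < 1e-8)
  leaves <- names(layout$children)[lengths(layout$children) == 0L]
  if (n_causal > length(leaves)) stop("more causal terms than leaves")
  causal <- with_seed(derive_seed(seed, 21L), sort(sample(leaves, n_causal)))
  stopifnot(n_fp >= n_causal)
  structure(list(causal_terms = causal, p_active = p_active, beta = beta,
                 sigma = sigma, base_shape = base_shape,
                 base_scale = base_scale, mech_probs = mech_probs,
                 n_fp = as.integer(n_fp), n_desc = as.integer(n_desc),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a synthetic cohort, drug set and sensitivity triplets
#'
#' Cells activate each causal term independently; activation elevates the
#' term's gene ranks in expression (shift model, so the enrichment score is
#' informative) and raises its mutation and amplification rates. Drugs carry
#' mechanism-linked fingerprint bits (bit j mirrors whether the drug hits
#' causal term j). The AUC of a (cell, drug) pair is
#' `clamp(base - beta * hits + noise, 0, base_scale)` with `base` drawn from
#' the right-skewed baseline distribution and `hits` the number of causal
#' terms both hit by the drug and active in the cell.
#'
#' @param layout An `ontology_layout`.
#' @param n_cells,n_drugs Cohort and library sizes.
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @param universe Gene universe of the emitted omics matrices; genes not
#'   wired into the layout carry background noise only (the loaders drop
#'   them). Defaults to the union of the layout dictionaries.
#' @return List: `cohort` (`cohort_data`), `drugs` (`drug_feature_matrix`),
#'   `triplets` (full cell x drug grid), `target_table` (drug -> genes of its
#'   mechanism terms), `activity` (cells x causal terms), `mechanism` (drugs
#'   x causal terms), `truth`, and `raw` (the full-universe matrices as a
#'   real dataset would provide them).
#' @export
generate_cohort <- function(layout, n_cells = 200L, n_drugs = 40L,
                            truth = synthetic_truth(layout), seed = 1L,
                            universe = NULL) {
  causal <- truth$causal_terms
  nc <- length(causal)
  cells <- sprintf("CL%03d", seq_len(n_cells))
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))

  if (is.null(universe)) universe <- sort(unique(unlist(layout$dict)))
  union_genes <- function(t) unique(c(layout$genes$mutation[[t]],
                                      layout$genes$amplification[[t]],
                                      layout$genes$deletion[[t]]))

  with_seed(derive_seed(seed, 31L), {
    activity <- matrix(rbinom(n_cells * nc, 1L, truth$p_active), n_cells, nc,
                       dimnames = list(cells, causal))

    rand_bin <- function(p, genes) {
      matrix(rbinom(n_cells * length(genes), 1L, p), n_cells, length(genes),
             dimnames = list(cells, genes))
    }
    M <- rand_bin(0.03, universe)
    A <- rand_bin(0.03, universe)
    D <- rand_bin(0.03, universe)
    E <- matrix(rnorm(n_cells * length(universe)), n_cells, length(universe),
                dimnames = list(cells, universe))
    for (j in seq_len(nc)) {
      g_mut <- intersect(layout$genes$mutation[[causal[j]]], colnames(M))
      g_amp <- intersect(layout$genes$amplification[[causal[j]]], colnames(A))
      g_exp <- intersect(layout$genes$expression[[causal[j]]], colnames(E))
      act <- activity[, j] == 1L
      if (any(act)) {
        M[act, g_mut] <- matrix(rbinom(sum(act) * length(g_mut), 1L, 0.6),
                                sum(act), length(g_mut))
        A[act, g_amp] <- matrix(rbinom(sum(act) * length(g_amp), 1L, 0.4),
                                sum(act), length(g_amp))
        E[act, g_exp] <- E[act, g_exp] + 2
      }
    }

    n_hits <- sample(0:2, n_drugs, replace = TRUE, prob = truth$mech_probs)
    mechanism <- matrix(0L, n_drugs, nc, dimnames = list(drug_ids, causal))
    for (d in seq_len(n_drugs)) {
      if (n_hits[d] > 0L) {
        mechanism[d, sample(nc, n_hits[d])] <- 1L
      }
    }
    Ffp <- matrix(rbinom(n_drugs * truth$n_fp, 1L, 0.15), n_drugs, truth$n_fp,
                  dimnames = list(drug_ids,
                                  sprintf("fp%03d", seq_len(truth$n_fp))))
    Ffp[, seq_len(nc)] <- mechanism   # mechanism-linked bits
    V <- matrix(rnorm(n_drugs * truth$n_desc), n_drugs, truth$n_desc,
                dimnames = list(drug_ids,
                                sprintf("desc%02d", seq_len(truth$n_desc))))

    grid <- expand.grid(cell_id = cells, drug_id = drug_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    hits <- rowSums(activity[grid$cell_id, , drop = FALSE] *
                      mechanism[grid$drug_id, , drop = FALSE])
    base <- truth$base_scale * rbeta(nrow(grid), truth$base_shape[1],
                                     truth$base_shape[2])
    auc <- base - truth$beta * hits + rnorm(nrow(grid), 0, truth$sigma)
    grid$auc <- pmin(pmax(auc, 0), truth$base_scale)

    target_rows <- lapply(seq_len(n_drugs), function(d) {
      ts <- causal[mechanism[d, ] == 1L]
      gs <- unique(unlist(lapply(ts, union_genes), use.names = FALSE))
      if (!length(gs)) return(NULL)
      data.frame(drug_id = drug_ids[d], gene = gs, stringsAsFactors = FALSE)
    })
    target_table <- do.call(rbind, target_rows)

    cohort <- cohort_from_matrices(M, A, D, E, layout)
    drugs <- drug_feature_matrix(Ffp, V)
    list(cohort = cohort, drugs = drugs, triplets = grid,
         target_table = target_table, activity = activity,
         mechanism = mechanism, truth = truth,
         raw = list(M = M, A = A, D = D, E = E))
  })
}

#' Generate synergy labels for drug pairs
#'
#' Samples (cell, drug_a, drug_b) combinations among drugs that carry at
#' least one mechanism, on cells with at least one active causal term (as in
#' combination screens run on models with a targetable lesion), and labels a
#' pair synergistic when each drug hits at
#' least one causal term that is active in the cell and not hit by the other
#' drug (complementary coverage); drugs with identical mechanisms are never
#' synergistic. Labels are flipped with probability `truth$label_noise`.
#'
#' @param sim Output of [generate_cohort()].
#' @param n_pairs Number of sampled combinations.
#' @param seed Integer seed.
#' @return data.frame `cell_id`, `drug_a`, `drug_b`, `label`.
#' @export
generate_synergy_labels <- function(sim, n_pairs = 2000L, seed = 1L) {
  mech <- sim$mechanism
  act <- sim$activity
  eligible <- rownames(mech)[rowSums(mech) > 0L]
  if (length(eligible) < 2L) stop("need at least two drugs with mechanisms")
  cells_ok <- rownames(act)[rowSums(act) > 0L]
  if (!length(cells_ok)) stop("no cell activates any causal term")
  with_seed(derive_seed(seed, 41L), {
    cell <- sample(cells_ok, n_pairs, replace = TRUE)
    da <- sample(eligible, n_pairs, replace = TRUE)
    db <- vapply(da, function(d) sample(setdiff(eligible, d), 1L), character(1))
    ha <- mech[da, , drop = FALSE] * act[cell, , drop = FALSE]
    hb <- mech[db, , drop = FALSE] * act[cell, , drop = FALSE]
    complementary <- rowSums(ha * (1 - mech[db, , drop = FALSE])) > 0 &
      rowSums(hb * (1 - mech[da, , drop = FALSE])) > 0
    label <- as.integer(complementary)
    flip <- rbinom(n_pairs, 1L, sim$truth$label_noise) == 1L
    label[flip] <- 1L - label[flip]
    data.frame(cell_id = cell, drug_a = unname(da), drug_b = unname(db),
               label = label, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete study preset and write its files
#'
#' Presets: `tiny` (depth-3 chain-like ontology, 60 cells x 12 drugs; quick
#' fixtures), `default` (depth-4 branching-3 ontology, 200 cells x 40 drugs;
#' the reference study conditions) and `synergy` (`default` plus synergy
#' labels).
#'
#' @param preset One of `"tiny"`, `"default"`, `"synergy"`.
#' @param dir Output directory; when `NULL` nothing is written.
#' @param seed Integer seed.
#' @return List with the generated objects (`ontology`, `layout`, `sim`,
#'   optionally `synergy`) and, when `dir` is given, the file `paths`.
#' @export
simulate_preset <- function(preset = c("default", "tiny", "synergy"),
                            dir = NULL, seed = 1L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(depth = 3L, branching = 2L, n_genes = 60L,
                genes_per_term = 5L, n_cells = 60L, n_drugs = 12L,
                n_causal = 2L, n_fp = 16L, n_desc = 4L),
    default = ,
    synergy = list(depth = 4L, branching = 3L, n_genes = 300L,
                   genes_per_term = 8L, n_cells = 200L, n_drugs = 40L,
                   n_causal = 4L, n_fp = 64L, n_desc = 8L))

  ont <- generate_ontology(cfg$depth, cfg$branching, cfg$n_genes,
                           cfg$genes_per_term, seed = seed, dir = dir)
  obo_path <- ont$obo_path %||% {
    p <- tempfile(fileext = ".obo"); writeLines(ont$obo_text, p); p
  }
  gmt_path <- ont$gmt_path %||% {
    p <- tempfile(fileext = ".gmt"); writeLines(ont$gmt_text, p); p
  }
  graph <- parse_obo(obo_path)
  ann <- load_annotations(gmt_path,
                          channels = c("mutation", "amplification",
                                       "deletion", "expression"),
                          graph = graph, universe = ont$genes)
  layout <- build_layout(graph, ann)
  truth <- synthetic_truth(layout, n_causal = cfg$n_causal,
                           n_fp = cfg$n_fp, n_desc = cfg$n_desc, seed = seed)
  sim <- generate_cohort(layout, cfg$n_cells, cfg$n_drugs, truth, seed = seed,
                         universe = ont$genes)
  out <- list(ontology = ont, graph = graph, layout = layout, sim = sim,
              preset = preset, seed = seed)
  if (preset == "synergy") {
    out$synergy <- generate_synergy_labels(sim, n_pairs = 2000L, seed = seed)
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    omics_paths <- c(mutation = file.path(dir, "mutation.tsv"),
                     amplification = file.path(dir, "amplification.tsv"),
                     deletion = file.path(dir, "deletion.tsv"),
                     expression = file.path(dir, "expression.tsv"))
    write_gene_matrix(sim$raw$M, omics_paths[["mutation"]])
    write_gene_matrix(sim$raw$A, omics_paths[["amplification"]])
    write_gene_matrix(sim$raw$D, omics_paths[["deletion"]])
    write_gene_matrix(sim$raw$E, omics_paths[["expression"]])
    paths <- c(ontology = file.path(dir, "ontology.obo"),
               annotations = file.path(dir, "annotations.gmt"),
               omics_paths,
               fingerprints = file.path(dir, "fingerprints.tsv"),
               descriptors = file.path(dir, "descriptors.tsv"),
               triplets = file.path(dir, "triplets.tsv"),
               targets = file.path(dir, "targets.tsv"))
    write_drug_features(sim$drugs, paths[["fingerprints"]],
                        paths[["descriptors"]])
    write_triplets(sim$triplets, paths[["triplets"]])
    data.table::fwrite(sim$target_table, paths[["targets"]], sep = "\t")
    if (preset == "synergy") {
      paths <- c(paths, synergy = file.path(dir, "synergy.tsv"))
      data.table::fwrite(out$synergy, paths[["synergy"]], sep = "\t")
    }
    out$paths <- paths
  }
  out
}
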