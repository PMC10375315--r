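# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

write_obo <- function(lines) {
  p <- tempfile(fileext = ".obo")
  writeLines(lines, p)
  p
}

obo_chain <- function() {
  write_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:ROOT", "name: root", "",
    "[Term]", "id: T:MID", "name: mid", "is_a: T:ROOT", "",
    "[Term]", "id: T:LEAF", "name: leaf", "is_a: T:MID", ""
  ))
}

# annotation object built directly (all four channels share the map)
ann_from_list <- function(sets) {
  structure(
    list(mutation = sets, amplification = sets, deletion = sets,
         expression = sets),
    class = "term_annotation")
}

# small generated ontology + layout (depth 3, branching 2: 7 terms)
tiny_layout <- function() {
  memo("tiny_layout", {
    ont <- generate_ontology(depth = 3L, branching = 2L, n_genes = 60L,
                             genes_per_term = 5L, seed = 101L)
    g <- parse_obo(write_obo(ont$obo_text))
    gmt <- tempfile(fileext = ".gmt")
    writeLines(ont$gmt_text, gmt)
    ann <- load_annotations(gmt, channels = c("mutation", "amplification",
                                              "deletion", "expression"),
                            graph = g, universe = ont$genes)
    build_layout(g, ann)
  })
}

# tiny simulated study around tiny_layout
tiny_sim <- function() {
  memo("tiny_sim", {
    lay <- tiny_layout()
    truth <- synthetic_truth(lay, n_causal = 2L, n_fp = 16L, n_desc = 4L,
                             seed = 101L)
    suppressMessages(generate_cohort(lay, n_cells = 40L, n_drugs = 10L,
                                     truth, seed = 101L))
  })
}

# small untrained model over the tiny study
tiny_model <- function(k = 3L, seed = 7L) {
  sim <- tiny_sim()
  cfg <- movida_config(k = k, drug_layers = c(8L, 4L), head_hidden = 4L,
                       batch_size = 16L, epochs = 0L, seed = seed)
  build_model(tiny_layout(), cfg, ncol(sim$drugs), seed = seed)
}

# default-preset study (the reference conditions); built once
default_study <- function(seed = 1L) {
  memo(paste0("default_study_", seed), {
    suppressMessages(simulate_preset("default", seed = seed))
  })
}

# default-preset trained model, reused across acceptance checks
default_fit <- function(seed = 1L) {
  memo(paste0("default_fit_", seed), {
    ps <- default_study(seed)
    cfg <- movida_config(epochs = 40L, batch_size = 128L,
                         learning_rate = 5e-3, seed = seed)
    m <- build_model(ps$layout, cfg, ncol(ps$sim$drugs))
    fit <- train_model(m, ps$sim$cohort, ps$sim$drugs, ps$sim$triplets)
    fit$study <- ps
    fit
  })
}

# Weight-zeroing oracle: silencing a term equals zeroing, in every parent,
# the weight rows that read the term's embedding (for the root, the head
# rows that read the root embedding). The enrichment pass-up rows stay: the
# score is measured data, not a module output.
zero_consumers <- function(model, s) {
  k <- model$config$k
  lay <- model$layout
  for (q in lay$terms) {
    ti <- model$term_in[[q]]
    i <- match(s, ti$children)
    if (!is.na(i)) {
      off <- ti$n_gene_cols + 1L + (i - 1L) * (k + 1L)
      model$params$terms[[q]]$lin$W[off + seq_len(k), ] <- 0
    }
  }
  if (identical(s, lay$root)) {
    model$params$head$hidden[[1]]$lin$W[seq_len(k), ] <- 0
  }
  model
}

# Parameter-surgery oracle for a leaf's input ablation: gene rows are
# zeroed; each weight row reading the leaf's enrichment score (own module
# and parent pass-ups) is folded into the bias at the neutral value 0.5 and
# then zeroed, so the consumer behaves as if the score were uninformative.
zero_leaf_inputs <- function(model, s) {
  k <- model$config$k
  ng <- model$term_in[[s]]$n_gene_cols
  if (ng > 0) model$params$terms[[s]]$lin$W[seq_len(ng), ] <- 0
  model$params$terms[[s]]$lin$b <-
    model$params$terms[[s]]$lin$b + 0.5 * model$params$terms[[s]]$lin$W[ng + 1L, ]
  model$params$terms[[s]]$lin$W[ng + 1L, ] <- 0
  for (q in model$layout$terms) {
    ti <- model$term_in[[q]]
    i <- match(s, ti$children)
    if (!is.na(i)) {
      off <- ti$n_gene_cols + 1L + (i - 1L) * (k + 1L)
      model$params$terms[[q]]$lin$b <-
        model$params$terms[[q]]$lin$b +
        0.5 * model$params$terms[[q]]$lin$W[off + k + 1L, ]
      model$params$terms[[q]]$lin$W[off + k + 1L, ] <- 0
    }
  }
  model
}

five_term_model <- function(seed = 17L) {
  ont <- generate_ontology(depth = 3L, branching = 2L, n_genes = 30L,
                           genes_per_term = 4L, seed = seed)
  g <- parse_obo(write_obo(ont$obo_text))
  gmt <- tempfile(fileext = ".gmt")
  # annotate one leaf under each internal term: 5 retained terms
  writeLines(ont$gmt_text[c(1, 3)], gmt)
  ann <- load_annotations(gmt, channels = c("mutation", "amplification",
                                            "deletion", "expression"),
                          graph = g, universe = ont$genes)
  lay <- build_layout(g, ann)
  truth <- synthetic_truth(lay, n_causal = 2L, n_fp = 8L, n_desc = 3L,
                           seed = seed)
  sim <- suppressMessages(generate_cohort(lay, n_cells = 20L, n_drugs = 6L,
                                          truth, seed = seed))
  cfg <- movida_config(k = 3L, drug_layers = c(6L, 4L), head_hidden = 3L,
                       batch_size = 16L, epochs = 3L, learning_rate = 3e-3,
                       seed = seed)
  m <- build_model(lay, cfg, ncol(sim$drugs))
  fit <- train_model(m, sim$cohort, sim$drugs, sim$triplets)
  list(model = fit$model, sim = sim, layout = lay)
}


# synergy study + trained twin model, cached
synergy_fit <- function(seed = 1L) {
  memo(paste0("synergy_fit_", seed), {
    ps <- suppressMessages(simulate_preset("synergy", seed = seed))
    cfg <- movida_synergy_config(epochs = 40L, batch_size = 128L,
                                 learning_rate = 5e-3, seed = seed)
    ms <- build_synergy_model(ps$layout, cfg, ncol(ps$sim$drugs))
    fit <- train_synergy(ms, ps$sim$cohort, ps$sim$drugs, ps$synergy)
    fit$study <- ps
    fit
  })
}
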