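# The visible neural network: one small trainable module per retained
# ontology term, wired exactly as the layout dictates, plus a dense drug
# branch and a prediction head. Module s computes
#   E_s = f(W_M M_s + W_A A_s + W_D D_s + W_NES NES_s
#           + sum_c (W_c E_c + W_NESc NES_c) + b_s)
# with f = hyperbolic tangent followed by batch normalization; a child's
# embedding and its enrichment score are passed up to every retained parent.

#' Model configuration
#'
#' @param k Hidden units per ontology-term module (default 6; the synergy
#'   variant uses 16).
#' @param drug_layers Widths of the drug embedding branch (default
#'   `c(100, 50, 6)`; the last width is the drug embedding size).
#' @param head_hidden Width of the prediction head's hidden layer (default 6;
#'   the head ends in a single output node).
#' @param learning_rate Adam learning rate (default `1e-5`).
#' @param epochs Training epochs (default 300; synergy default 50).
#' @param batch_size Minibatch size (default 512).
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Integer seed controlling initialization, splitting and
#'   resampling.
#' @param loss One of `"double_weighted_mse"`, `"mse"`, `"focal"`.
#' @param epsilon Smoothing penalty of the bin weights (default 80 for
#'   sensitivity training; 5 for synergy).
#' @param n_bins,bin_range AUC histogram used for weighting and evaluation.
#' @param sampler Use the multinomial weighted resampler each epoch.
#' @param bn_momentum Running-statistics momentum of batch normalization.
#' @param include_root_nes Also feed the root term's enrichment score to the
#'   head (default off; the root embedding alone represents the cell).
#' @param alpha,gamma Focal-loss hyperparameters (synergy training).
#' @return A `movida_config` list.
#' @export
movida_config <- function(k = 6L, drug_layers = c(100L, 50L, 6L),
                          head_hidden = 6L, learning_rate = 1e-5,
                          epochs = 300L, batch_size = 512L,
                          split = c(0.8, 0.1, 0.1), seed = 1L,
                          loss = c("double_weighted_mse", "mse", "focal"),
                          epsilon = 80, n_bins = 12L, bin_range = c(0, 1.2),
                          sampler = TRUE, bn_momentum = 0.1,
                          include_root_nes = FALSE,
                          alpha = 0.4, gamma = 2) {
  loss <- match.arg(loss)
  stopifnot(k >= 1, all(drug_layers >= 1), head_hidden >= 1,
            learning_rate > 0, epochs >= 0, batch_size >= 2,
            length(split) == 3, abs(sum(split) - 1) < 1e-8,
            epsilon >= 0, n_bins >= 2)
  structure(list(k = as.integer(k), drug_layers = as.integer(drug_layers),
                 head_hidden = as.integer(head_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed), loss = loss, epsilon = epsilon,
                 n_bins = as.integer(n_bins), bin_range = bin_range,
                 sampler = sampler, bn_momentum = bn_momentum,
                 include_root_nes = include_root_nes,
                 alpha = alpha, gamma = gamma),
            class = "movida_config")
}

#' Synergy-variant configuration defaults
#'
#' Same fields as [movida_config()] with the synergy defaults: 16 hidden
#' nodes per term module, 50 epochs, smoothing penalty 5 (the bin weights are
#' used only for the sampler) and focal loss.
#' @param ... Overrides passed to [movida_config()].
#' @export
movida_synergy_config <- function(...) {
  args <- list(...)
  defaults <- list(k = 16L, epochs = 50L, epsilon = 5, loss = "focal")
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(movida_config, args)
}

#' Concatenated cell input features
#'
#' The per-cell input row consumed by the visible network: mutation,
#' amplification and deletion bits (layout dictionary order) followed by the
#' per-term enrichment scores (layout term order).
#' @param cohort A `cohort_data` aligned to the model's layout.
#' @return Numeric matrix cells x (nM + nA + nD + n_terms).
#' @export
cell_features <- function(cohort) {
  cbind(cohort$M, cohort$A, cohort$D, cohort$NES)
}

#' Build a visible network model
#'
#' Instantiates one `k`-unit module per retained layout term, wired to the
#' term's gene index lists and retained children, plus the drug branch and
#' prediction head. No weight exists between a module and a gene or child not
#' present in its layout lists. Initialization is deterministic given `seed`.
#'
#' @param layout An `ontology_layout`.
#' @param config A `movida_config`.
#' @param n_drug_features Width of the drug feature vector.
#' @param seed Initialization seed (defaults to `config$seed`).
#' @param synergy Internal: build the twin-drug-branch variant.
#' @return A `movida_model`.
#' @export
build_model <- function(layout, config = movida_config(), n_drug_features,
                        seed = config$seed, synergy = FALSE) {
  stopifnot(inherits(layout, "ontology_layout"))
  k <- config$k
  nM <- length(layout$dict$mutation)
  nA <- length(layout$dict$amplification)
  nD <- length(layout$dict$deletion)
  nT <- length(layout$terms)
  off <- c(m = 0L, a = nM, d = nM + nA, nes = nM + nA + nD)
  nes_col <- stats::setNames(off[["nes"]] + seq_len(nT), layout$terms)

  term_in <- lapply(stats::setNames(layout$terms, layout$terms), function(s) {
    cols <- c(off[["m"]] + (layout$gene_index$mutation[[s]] %||% integer(0)),
              off[["a"]] + (layout$gene_index$amplification[[s]] %||% integer(0)),
              off[["d"]] + (layout$gene_index$deletion[[s]] %||% integer(0)))
    ch <- layout$children[[s]]
    list(cols = c(cols, nes_col[[s]]), n_gene_cols = length(cols),
         children = ch,
         d_in = length(cols) + 1L + length(ch) * (k + 1L))
  })

  d_emb <- tail(config$drug_layers, 1L)
  head_in <- k + d_emb * (if (synergy) 2L else 1L) +
    (if (config$include_root_nes) 1L else 0L)

  model <- with_seed(seed, {
    terms <- lapply(term_in, function(ti) nn_block_init(ti$d_in, k))
    dims <- c(n_drug_features, config$drug_layers)
    drug <- lapply(seq_along(config$drug_layers), function(i)
      nn_block_init(dims[i], dims[i + 1]))
    head <- list(hidden = list(nn_block_init(head_in, config$head_hidden)),
                 out = nn_linear_init(config$head_hidden, 1L))
    list(terms = terms, drug = drug, head = head)
  })

  structure(list(
    layout = layout, config = config, n_drug_features = as.integer(n_drug_features),
    term_in = term_in, nes_col = nes_col, cf_width = off[["nes"]] + nT,
    synergy = synergy, params = model, trained = FALSE
  ), class = "movida_model")
}

#' @rdname build_model
#' @export
build_synergy_model <- function(layout, config = movida_synergy_config(),
                                n_drug_features, seed = config$seed) {
  build_model(layout, config, n_drug_features, seed, synergy = TRUE)
}

#' Trainable parameter count
#'
#' `n_parameters()` enumerates the stored arrays; `expected_parameter_count()`
#' is the closed form implied by the layout and configuration (weights +
#' biases + batch-norm scale/shift per unit). The two must agree.
#' @param model A `movida_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  count <- function(x) {
    if (is.list(x)) {
      keep <- if (is.null(names(x))) seq_along(x)
              else setdiff(names(x), c("rm", "rv"))
      return(sum(vapply(x[keep], count, numeric(1))))
    }
    length(x)
  }
  as.integer(count(model$params))
}

#' @rdname n_parameters
#' @param layout,config,n_drug_features,synergy As in [build_model()].
#' @export
expected_parameter_count <- function(layout, config, n_drug_features,
                                     synergy = FALSE) {
  k <- config$k
  block <- function(d_in, d_out) d_in * d_out + d_out + 2 * d_out
  total <- 0
  for (s in layout$terms) {
    n_genes <- length(layout$gene_index$mutation[[s]] %||% integer(0)) +
      length(layout$gene_index$amplification[[s]] %||% integer(0)) +
      length(layout$gene_index$deletion[[s]] %||% integer(0))
    d_in <- n_genes + 1 + length(layout$children[[s]]) * (k + 1)
    total <- total + block(d_in, k)
  }
  dims <- c(n_drug_features, config$drug_layers)
  for (i in seq_along(config$drug_layers)) total <- total + block(dims[i], dims[i + 1])
  d_emb <- tail(config$drug_layers, 1L)
  head_in <- k + d_emb * (if (synergy) 2L else 1L) +
    (if (config$include_root_nes) 1L else 0L)
  total <- total + block(head_in, config$head_hidden)
  total <- total + config$head_hidden * 1 + 1
  as.integer(total)
}

# Core forward pass over a batch of rows.
#   CF: cell feature rows (one per record); DX (and DX2 for synergy): drug
#   feature rows. `ablate` holds character vectors
#     silence:        zero a term's embedding wherever it is consumed (its
#                     enrichment score is measured data and keeps flowing)
#     silence_inputs: zero a term's gene input columns
#     silence_nes:    neutralize a term's enrichment score everywhere (own
#                     module input and parent pass-ups) by setting it to the
#                     uninformative midpoint 0.5 - the same value imputed
#                     for terms with undefined enrichment
model_forward <- function(model, CF, DX, DX2 = NULL, training = FALSE,
                          ablate = NULL, want_cache = FALSE) {
  k <- model$config$k
  mom <- model$config$bn_momentum
  sil <- ablate$silence %||% character(0)
  sil_in <- ablate$silence_inputs %||% character(0)
  sil_nes <- ablate$silence_nes %||% character(0)
  if (length(sil_nes)) {
    CF[, unlist(model$nes_col[sil_nes])] <- 0.5
  }
  n <- nrow(CF)

  E <- vector("list", length(model$layout$terms))
  names(E) <- model$layout$terms
  tcache <- if (want_cache) E else NULL

  for (s in model$layout$terms) {
    ti <- model$term_in[[s]]
    X <- CF[, ti$cols, drop = FALSE]
    if (ti$n_gene_cols > 0L && s %in% sil_in) {
      X[, seq_len(ti$n_gene_cols)] <- 0
    }
    if (length(ti$children)) {
      parts <- vector("list", 2L * length(ti$children) + 1L)
      parts[[1L]] <- X
      for (i in seq_along(ti$children)) {
        ch <- ti$children[i]
        Ec <- E[[ch]]
        if (ch %in% sil) Ec <- matrix(0, n, k)
        parts[[2L * i]] <- Ec
        parts[[2L * i + 1L]] <- CF[, model$nes_col[[ch]], drop = FALSE]
      }
      X <- do.call(cbind, parts)
    }
    bf <- block_forward(model$params$terms[[s]], X, training, mom)
    if (training) model$params$terms[[s]]$bn <- bf$bn
    Y <- bf$Y
    if (s %in% sil) Y <- matrix(0, n, k)
    E[[s]] <- Y
    if (want_cache) tcache[[s]] <- bf$cache
  }

  drug_pass <- function(D_) {
    caches <- vector("list", length(model$params$drug))
    H <- D_
    for (i in seq_along(model$params$drug)) {
      bf <- block_forward(model$params$drug[[i]], H, training, mom)
      if (training) model$params$drug[[i]]$bn <<- bf$bn
      H <- bf$Y
      caches[[i]] <- bf$cache
    }
    list(H = H, caches = caches)
  }
  dp1 <- drug_pass(DX)
  dp2 <- if (model$synergy) drug_pass(DX2) else NULL

  Eroot <- E[[model$layout$root]]
  if (model$layout$root %in% sil) Eroot <- matrix(0, n, k)
  Hin <- cbind(Eroot, dp1$H)
  if (model$synergy) Hin <- cbind(Hin, dp2$H)
  if (model$config$include_root_nes) {
    Hin <- cbind(Hin, CF[, model$nes_col[[model$layout$root]], drop = FALSE])
  }

  hcaches <- vector("list", length(model$params$head$hidden))
  H <- Hin
  for (i in seq_along(model$params$head$hidden)) {
    bf <- block_forward(model$params$head$hidden[[i]], H, training, mom)
    if (training) model$params$head$hidden[[i]]$bn <- bf$bn
    H <- bf$Y
    hcaches[[i]] <- bf$cache
  }
  out <- unname(drop(sweep(H %*% model$params$head$out$W, 2,
                           model$params$head$out$b, "+")))

  cache <- NULL
  if (want_cache) {
    cache <- list(terms = tcache, drug = dp1$caches, drug2 = dp2$caches,
                  head = hcaches, Hh = H)
  }
  list(out = out, model = model, cache = cache)
}

# Backpropagation matching model_forward (training mode, no ablation).
model_backward <- function(model, cache, dout) {
  k <- model$config$k
  n <- length(dout)
  dout <- matrix(dout, n, 1L)

  gW_out <- crossprod(cache$Hh, dout)
  gb_out <- colSums(dout)
  dH <- tcrossprod(dout, model$params$head$out$W)

  ghead_hidden <- vector("list", length(model$params$head$hidden))
  for (i in rev(seq_along(model$params$head$hidden))) {
    bb <- block_backward(model$params$head$hidden[[i]], cache$head[[i]], dH)
    ghead_hidden[[i]] <- bb$grads
    dH <- bb$dX
  }

  d_emb <- tail(model$config$drug_layers, 1L)
  dEroot <- dH[, seq_len(k), drop = FALSE]
  dDrug1 <- dH[, k + seq_len(d_emb), drop = FALSE]
  dDrug2 <- if (model$synergy) dH[, k + d_emb + seq_len(d_emb), drop = FALSE]

  drug_back <- function(dY, caches) {
    grads <- vector("list", length(model$params$drug))
    for (i in rev(seq_along(model$params$drug))) {
      bb <- block_backward(model$params$drug[[i]], caches[[i]], dY)
      grads[[i]] <- bb$grads
      dY <- bb$dX
    }
    grads
  }
  gdrug <- drug_back(dDrug1, cache$drug)
  if (model$synergy) gdrug <- grad_add(gdrug, drug_back(dDrug2, cache$drug2))

  dE <- vector("list", length(model$layout$terms))
  names(dE) <- model$layout$terms
  dE[[model$layout$root]] <- dEroot
  gterms <- vector("list", length(model$layout$terms))
  names(gterms) <- model$layout$terms

  for (s in rev(model$layout$terms)) {
    bb <- block_backward(model$params$terms[[s]], cache$terms[[s]], dE[[s]])
    gterms[[s]] <- bb$grads
    ti <- model$term_in[[s]]
    if (length(ti$children)) {
      base <- ti$n_gene_cols + 1L
      for (i in seq_along(ti$children)) {
        ch <- ti$children[i]
        colset <- base + (i - 1L) * (k + 1L) + seq_len(k)
        dch <- bb$dX[, colset, drop = FALSE]
        dE[[ch]] <- if (is.null(dE[[ch]])) dch else dE[[ch]] + dch
      }
    }
  }

  list(terms = gterms, drug = gdrug,
       head = list(hidden = ghead_hidden, out = list(W = gW_out, b = gb_out)))
}

#' @export
print.movida_model <- function(x, ...) {
  cat("movida_model:", length(x$layout$terms), "term modules (k =",
      x$config$k, "),", n_parameters(x), "trainable parameters",
      if (x$synergy) "(synergy twin-branch variant)" else "",
      if (x$trained) "[trained]" else "[untrained]", "\n")
  invisible(x)
}
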