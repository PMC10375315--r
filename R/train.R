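# Training loops for the sensitivity regressor and the synergy classifier,
# batch prediction, and checkpoint serialization.

split_triplets <- function(n, fractions, seed) {
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[setdiff(seq_len(n), seq_len(n_train + n_val))]))
}

make_batches <- function(idx, batch_size) {
  n <- length(idx)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  # batch normalization needs >= 2 rows; fold a trailing singleton in
  if (length(batches) > 1L && length(batches[[length(batches)]]) == 1L) {
    nb <- length(batches)
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

# Two-class analogue of compute_bin_weights for the synergy sampler.
class_weights <- function(labels, epsilon) {
  counts <- c(sum(labels == 0), sum(labels == 1))
  freq <- counts / sum(counts)
  if (epsilon == 0 && any(counts == 0)) stop("epsilon = 0 with an empty class")
  inv <- 1 / (freq + epsilon)
  w <- inv / sum(inv)
  w[labels + 1L]
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' positive's score exceeds a negative's (ties counted half).
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc: need both classes present")
  r <- rank(scores)
  compute_nes(r[labels == 1], n1, n0)
}

#' Train the visible network
#'
#' Splits the triplets into train/validation/test sets, fits bin weights on
#' the training AUCs, then runs Adam for `config$epochs` epochs, re-drawing
#' the training records each epoch with the multinomial weighted sampler.
#' The per-epoch history records training loss, validation loss and
#' validation macro-averaged MSE; the returned model is the best-validation
#' snapshot. Fully reproducible given `config$seed`.
#'
#' @param model An untrained (or resumed) `movida_model`.
#' @param cohort A `cohort_data`.
#' @param drugs A `drug_feature_matrix`.
#' @param triplets data.frame `cell_id`, `drug_id`, `auc`.
#' @param config Training configuration; defaults to the model's.
#' @param split Optional list with integer indices `train`, `val` (and
#'   optionally `test`) into `triplets`; by default drawn at random with the
#'   configured fractions.
#' @param verbose Print a line per epoch.
#' @return A list: `model` (best-validation snapshot), `history` (data.frame
#'   epoch/train_loss/val_loss/val_mmse), `split`, `bin_weights`.
#' @export
train_model <- function(model, cohort, drugs, triplets,
                        config = model$config, split = NULL, verbose = FALSE) {
  check_ids(triplets$cell_id, cohort$cells, "cell")
  check_ids(triplets$drug_id, rownames(drugs), "drug")

  if (is.null(split)) {
    split <- split_triplets(nrow(triplets), config$split,
                            derive_seed(config$seed, 1L))
  }
  if (!length(split$train)) stop("empty training split")
  if (!length(split$val)) stop("empty validation split")

  CF <- cell_features(cohort)
  DXall <- unclass(drugs)
  cell_row <- match(triplets$cell_id, cohort$cells)
  drug_row <- match(triplets$drug_id, rownames(drugs))
  auc <- triplets$auc

  bw <- compute_bin_weights(auc[split$train], config$epsilon,
                            config$n_bins, config$bin_range)
  rw <- record_weights(auc[split$train], bw)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_mmse = numeric(0))
  best <- list(model = model, val_loss = Inf)
  state <- adam_init()
  n_train <- length(split$train)

  for (epoch in seq_len(config$epochs)) {
    draw <- if (config$sampler) {
      sample_indices(rw, n_train, derive_seed(config$seed, 100L + epoch))
    } else {
      with_seed(derive_seed(config$seed, 100L + epoch), sample.int(n_train))
    }
    epoch_idx <- split$train[draw]
    batches <- make_batches(epoch_idx, config$batch_size)

    tot_loss <- 0; tot_n <- 0L
    for (b in batches) {
      CFb <- CF[cell_row[b], , drop = FALSE]
      DXb <- DXall[drug_row[b], , drop = FALSE]
      fwd <- model_forward(model, CFb, DXb, training = TRUE, want_cache = TRUE)
      model <- fwd$model
      p <- fwd$out
      t_ <- auc[b]
      if (config$loss == "double_weighted_mse") {
        # predictions may stray outside the bin range early in training;
        # they are clamped to the edge bins without per-batch warnings
        w <- pmax(suppressWarnings(record_weights(p, bw)),
                  record_weights(t_, bw))
        loss <- mean(w * (p - t_)^2)
        dout <- 2 * w * (p - t_) / length(p)
      } else {
        loss <- mean((p - t_)^2)
        dout <- 2 * (p - t_) / length(p)
      }
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      grads <- model_backward(model, fwd$cache, dout)
      upd <- adam_update(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tot_loss <- tot_loss + loss * length(p)
      tot_n <- tot_n + length(p)
    }

    pv <- predict_rows(model, CF, DXall, cell_row[split$val],
                       drug_row[split$val])
    tv <- auc[split$val]
    val_loss <- if (config$loss == "double_weighted_mse") {
      suppressWarnings(double_weighted_mse(pv, tv, bw))
    } else {
      mean((pv - tv)^2)
    }
    val_mmse <- macro_mse(pv, tv, config$n_bins, config$bin_range)$mmse
    history[epoch, ] <- list(epoch, tot_loss / tot_n, val_loss, val_mmse)
    if (val_loss < best$val_loss) best <- list(model = model, val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  val MMSE %.5f",
                      epoch, tot_loss / tot_n, val_loss, val_mmse))
    }
  }

  out_model <- if (config$epochs > 0L) best$model else model
  out_model$trained <- config$epochs > 0L
  list(model = out_model, history = history, split = split, bin_weights = bw)
}

check_ids <- function(ids, known, what) {
  bad <- setdiff(unique(ids), known)
  if (length(bad)) {
    stop("unknown ", what, " id(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) paste0(" (and ", length(bad) - 5, " more)"))
  }
  invisible(TRUE)
}

# Chunked inference-mode forward over explicit row indices.
predict_rows <- function(model, CF, DX, cell_rows, drug_rows,
                         drug_rows2 = NULL, chunk = 2048L) {
  n <- length(cell_rows)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    out[ii] <- model_forward(
      model, CF[cell_rows[ii], , drop = FALSE],
      DX[drug_rows[ii], , drop = FALSE],
      DX2 = if (!is.null(drug_rows2)) DX[drug_rows2[ii], , drop = FALSE],
      training = FALSE)$out
  }
  out
}

#' Predict sensitivity for (cell, drug) pairs
#'
#' Inference mode: batch normalization uses running statistics, so
#' predictions are deterministic and independent of batch composition.
#' @param model A `movida_model` (sensitivity variant).
#' @param cohort A `cohort_data`.
#' @param drugs A `drug_feature_matrix`.
#' @param pairs data.frame with `cell_id`, `drug_id`.
#' @return data.frame `cell_id`, `drug_id`, `predicted_auc`.
#' @export
predict_batch <- function(model, cohort, drugs, pairs) {
  if (model$synergy) stop("use predict_synergy() for the synergy variant")
  if (!nrow(pairs)) {
    return(data.frame(cell_id = character(0), drug_id = character(0),
                      predicted_auc = numeric(0)))
  }
  check_ids(pairs$cell_id, cohort$cells, "cell")
  check_ids(pairs$drug_id, rownames(drugs), "drug")
  CF <- cell_features(cohort)
  DX <- unclass(drugs)
  p <- predict_rows(model, CF, DX, match(pairs$cell_id, cohort$cells),
                    match(pairs$drug_id, rownames(drugs)))
  data.frame(cell_id = pairs$cell_id, drug_id = pairs$drug_id,
             predicted_auc = p, stringsAsFactors = FALSE)
}

#' Train the twin-branch synergy classifier
#'
#' The drug branch is shared between the two drugs of a pair (Siamese
#' weights). The training set is doubled with both drug orders; sampling
#' weights follow the two-class smoothed inverse frequencies; the focal loss
#' handles the class imbalance. Validation AUROC is tracked per epoch.
#'
#' @param model A synergy `movida_model` from [build_synergy_model()].
#' @param cohort,drugs As in [train_model()].
#' @param pairs data.frame `cell_id`, `drug_a`, `drug_b`, `label` (0/1).
#' @param config Training configuration; defaults to the model's.
#' @param split Optional list of indices into `pairs` (before doubling).
#' @param verbose Print a line per epoch.
#' @return List `model`, `history` (epoch/train_loss/val_loss/val_auroc),
#'   `split`.
#' @export
train_synergy <- function(model, cohort, drugs, pairs,
                          config = model$config, split = NULL, verbose = FALSE) {
  stopifnot(model$synergy)
  check_ids(pairs$cell_id, cohort$cells, "cell")
  check_ids(c(pairs$drug_a, pairs$drug_b), rownames(drugs), "drug")
  if (is.null(split)) {
    split <- split_triplets(nrow(pairs), config$split,
                            derive_seed(config$seed, 1L))
  }

  # double with both drug orders (order matters to the concatenated head)
  doubled <- rbind(
    data.frame(cell_id = pairs$cell_id, d1 = pairs$drug_a, d2 = pairs$drug_b,
               label = pairs$label, orig = seq_len(nrow(pairs))),
    data.frame(cell_id = pairs$cell_id, d1 = pairs$drug_b, d2 = pairs$drug_a,
               label = pairs$label, orig = seq_len(nrow(pairs)))
  )
  tr_idx <- which(doubled$orig %in% split$train)
  val_idx <- which(doubled$orig %in% split$val & seq_len(nrow(doubled)) <= nrow(pairs))

  CF <- cell_features(cohort)
  DX <- unclass(drugs)
  cell_row <- match(doubled$cell_id, cohort$cells)
  d1_row <- match(doubled$d1, rownames(drugs))
  d2_row <- match(doubled$d2, rownames(drugs))
  label <- doubled$label

  rw <- class_weights(label[tr_idx], config$epsilon)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auroc = numeric(0))
  best <- list(model = model, val_loss = Inf)
  state <- adam_init()
  n_train <- length(tr_idx)

  for (epoch in seq_len(config$epochs)) {
    draw <- if (config$sampler) {
      sample_indices(rw, n_train, derive_seed(config$seed, 200L + epoch))
    } else {
      with_seed(derive_seed(config$seed, 200L + epoch), sample.int(n_train))
    }
    batches <- make_batches(tr_idx[draw], config$batch_size)
    tot_loss <- 0; tot_n <- 0L
    for (b in batches) {
      fwd <- model_forward(model, CF[cell_row[b], , drop = FALSE],
                           DX[d1_row[b], , drop = FALSE],
                           DX2 = DX[d2_row[b], , drop = FALSE],
                           training = TRUE, want_cache = TRUE)
      model <- fwd$model
      prob <- plogis(fwd$out)
      y <- label[b]
      loss <- focal_loss(prob, y, config$alpha, config$gamma)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      dout <- focal_loss_grad_logit(prob, y, config$alpha, config$gamma)
      grads <- model_backward(model, fwd$cache, dout)
      upd <- adam_update(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tot_loss <- tot_loss + loss * length(b)
      tot_n <- tot_n + length(b)
    }

    pv <- plogis(predict_rows(model, CF, DX, cell_row[val_idx],
                              d1_row[val_idx], d2_row[val_idx]))
    yv <- label[val_idx]
    val_loss <- focal_loss(pv, yv, config$alpha, config$gamma)
    val_auc <- if (length(unique(yv)) == 2L) auroc(pv, yv) else NA_real_
    history[epoch, ] <- list(epoch, tot_loss / tot_n, val_loss, val_auc)
    if (val_loss < best$val_loss) best <- list(model = model, val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  val AUROC %s",
                      epoch, tot_loss / tot_n, val_loss,
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
    }
  }
  out_model <- if (config$epochs > 0L) best$model else model
  out_model$trained <- config$epochs > 0L
  list(model = out_model, history = history, split = split)
}

#' Predict synergy probabilities for drug pairs
#'
#' The reported score is the mean of both drug orders, so it is exactly
#' symmetric in the pair.
#' @param model A trained synergy `movida_model`.
#' @param cohort,drugs As in [predict_batch()].
#' @param pairs data.frame `cell_id`, `drug_a`, `drug_b`.
#' @return data.frame with `synergy_prob` appended.
#' @export
predict_synergy <- function(model, cohort, drugs, pairs) {
  stopifnot(model$synergy)
  if (!nrow(pairs)) return(cbind(pairs, synergy_prob = numeric(0)))
  check_ids(pairs$cell_id, cohort$cells, "cell")
  check_ids(c(pairs$drug_a, pairs$drug_b), rownames(drugs), "drug")
  CF <- cell_features(cohort)
  DX <- unclass(drugs)
  cr <- match(pairs$cell_id, cohort$cells)
  r1 <- match(pairs$drug_a, rownames(drugs))
  r2 <- match(pairs$drug_b, rownames(drugs))
  p12 <- plogis(predict_rows(model, CF, DX, cr, r1, r2))
  p21 <- plogis(predict_rows(model, CF, DX, cr, r2, r1))
  out <- pairs
  out$synergy_prob <- (p12 + p21) / 2
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON archive holding the layout, the
#' configuration, the feature dimensions and every parameter array at full
#' precision, so a reloaded model reproduces predictions bit-for-bit.
#' @param model A `movida_model`.
#' @param path Checkpoint path (`.json`).
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

serialize_model <- function(model) {
  ser_arr <- function(x) {
    if (is.list(x)) return(lapply(x, ser_arr))
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  }
  list(layout = layout_to_raw(model$layout), config = unclass(model$config),
       n_drug_features = model$n_drug_features, synergy = model$synergy,
       trained = model$trained, params = ser_arr(model$params))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- read_json_plain(path)
  layout <- layout_from_raw(x$layout)
  config <- do.call(movida_config, x$config[setdiff(names(x$config), NULL)])
  model <- build_model(layout, config, x$n_drug_features,
                       synergy = isTRUE(x$synergy))
  deser <- function(tmpl, ser) {
    if (is.list(tmpl) && !all(c("dim", "data") %in% names(ser))) {
      for (nm in names(tmpl)) tmpl[[nm]] <- deser(tmpl[[nm]], ser[[nm]])
      return(tmpl)
    }
    d <- unlist(ser$dim)
    v <- as.numeric(unlist(ser$data))
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  model$params <- deser(model$params, x$params)
  model$trained <- isTRUE(x$trained)
  model
}

# Rebuild a layout from jsonlite's simplified representation.
layout_from_raw <- function(x) {
  relist_chr <- function(l) lapply(l, function(v) as.character(unlist(v)))
  x$children <- relist_chr(x$children)
  x$parents <- relist_chr(x$parents)
  x$depth <- stats::setNames(as.integer(unlist(x$depth)), names(x$depth))
  x$genes <- lapply(x$genes, relist_chr)
  x$dict <- lapply(x$dict, function(v) as.character(unlist(v)))
  x$gene_index <- lapply(x$gene_index, function(l)
    lapply(l, function(v) as.integer(unlist(v))))
  x$min_genes <- as.integer(x$min_genes)
  structure(x, class = "ontology_layout")
}
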