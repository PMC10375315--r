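# Model construction, wiring, forward/backward mechanics and training
# contracts.

test_that("parameter enumeration equals the closed-form count", {
  m <- tiny_model()
  expect_identical(n_parameters(m),
                   expected_parameter_count(tiny_layout(), m$config,
                                            m$n_drug_features))
  ms <- build_synergy_model(tiny_layout(),
                            movida_synergy_config(drug_layers = c(8L, 4L),
                                                  batch_size = 16L),
                            m$n_drug_features)
  expect_identical(n_parameters(ms),
                   expected_parameter_count(tiny_layout(), ms$config,
                                            ms$n_drug_features,
                                            synergy = TRUE))
})

test_that("zero-initialized weights give a constant output for any input", {
  m <- tiny_model()
  # zero every weight/bias/scale but keep running variances at 1
  zero <- function(x, nm = "") {
    if (is.list(x)) {
      return(mapply(zero, x, names(x) %||% rep("", length(x)),
                    SIMPLIFY = FALSE))
    }
    if (nm == "rv") rep(1, length(x)) else x * 0
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  m$params <- zero(m$params)
  sim <- tiny_sim()
  CF <- cell_features(sim$cohort)
  DX <- unclass(sim$drugs)
  o1 <- movida:::model_forward(m, CF[1:3, ], DX[1:3, ])$out
  o2 <- movida:::model_forward(m, CF[11:13, ], DX[4:6, ])$out
  expect_identical(o1, o2)
  expect_equal(stats::sd(o1), 0)
})

test_that("model initialization is deterministic in the seed", {
  m1 <- tiny_model(seed = 13L)
  m2 <- tiny_model(seed = 13L)
  m3 <- tiny_model(seed = 14L)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("outputs are invariant to genes not wired into the model", {
  sim <- tiny_sim(); lay <- tiny_layout(); m <- tiny_model()
  CF <- cell_features(sim$cohort)[1:8, , drop = FALSE]
  DX <- unclass(sim$drugs)[rep(1:4, 2), , drop = FALSE]
  base <- movida:::model_forward(m, CF, DX)$out

  # unannotated genes exist because the universe exceeds the annotated set
  wired <- unique(unlist(lay$dict))
  loose <- setdiff(sprintf("g%04d", 1:60), wired)
  expect_gt(length(loose), 0)

  # flipping mutation/amplification/deletion bits of wired genes changes
  # nothing when the columns aren't part of the cell feature row; the cell
  # feature row only carries dictionary genes, so the probe flips dictionary
  # columns of a channel where the gene is annotated to NO retained term.
  per_term_m <- unique(unlist(lay$genes$mutation))
  only_elsewhere <- setdiff(lay$dict$mutation, per_term_m)
  # every dictionary gene is annotated somewhere by construction
  expect_length(only_elsewhere, 0)

  # a probe on a wired gene must change the output...
  g_wired <- lay$genes$mutation[[names(which(lengths(lay$genes$mutation) > 0))[1]]][1]
  CF2 <- CF
  CF2[, match(g_wired, lay$dict$mutation)] <-
    1 - CF2[, match(g_wired, lay$dict$mutation)]
  expect_false(isTRUE(all.equal(
    movida:::model_forward(m, CF2, DX)$out, base)))
})

test_that("enrichment perturbation of a leaf propagates to the output", {
  sim <- tiny_sim(); lay <- tiny_layout(); m <- tiny_model()
  CF <- cell_features(sim$cohort)[1:4, , drop = FALSE]
  DX <- unclass(sim$drugs)[1:4, , drop = FALSE]
  base <- movida:::model_forward(m, CF, DX)$out
  leaf <- names(which(lengths(lay$children) == 0))[1]
  CF2 <- CF
  CF2[, m$nes_col[[leaf]]] <- CF2[, m$nes_col[[leaf]]] + 0.2
  expect_false(isTRUE(all.equal(
    movida:::model_forward(m, CF2, DX)$out, base)))
})

test_that("a batch of one reproduces its row from a larger batch", {
  sim <- tiny_sim(); m <- tiny_model()
  CF <- cell_features(sim$cohort)[1:6, , drop = FALSE]
  DX <- unclass(sim$drugs)[1:6, , drop = FALSE]
  many <- movida:::model_forward(m, CF, DX)$out
  one <- movida:::model_forward(m, CF[3, , drop = FALSE],
                                DX[3, , drop = FALSE])$out
  expect_equal(one, many[3], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  sim <- tiny_sim(); lay <- tiny_layout(); m <- tiny_model()
  CF <- cell_features(sim$cohort)[1:6, , drop = FALSE]
  DX <- unclass(sim$drugs)[1:6, , drop = FALSE]
  t_ <- sim$triplets$auc[1:6]
  loss_of <- function(model) {
    f <- movida:::model_forward(model, CF, DX, training = TRUE,
                                want_cache = TRUE)
    list(loss = mean((f$out - t_)^2), fwd = f)
  }
  f0 <- loss_of(m)
  grads <- movida:::model_backward(m, f0$fwd$cache,
                                   2 * (f0$fwd$out - t_) / 6)
  probe <- function(get, set) {
    arr <- get(m$params)
    g <- get(grads)
    idx <- withr::with_seed(71, sample(length(arr), min(4, length(arr))))
    for (i in idx) {
      h <- 1e-6
      mp <- m; ap <- arr; ap[i] <- ap[i] + h; mp$params <- set(mp$params, ap)
      mm <- m; am <- arr; am[i] <- am[i] - h; mm$params <- set(mm$params, am)
      num <- (loss_of(mp)$loss - loss_of(mm)$loss) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  leaf <- lay$terms[1]; root <- lay$root
  probe(function(p) p$terms[[leaf]]$lin$W,
        function(p, a) { p$terms[[leaf]]$lin$W <- a; p })
  probe(function(p) p$terms[[root]]$bn$gamma,
        function(p, a) { p$terms[[root]]$bn$gamma <- a; p })
  probe(function(p) p$drug[[1]]$lin$W,
        function(p, a) { p$drug[[1]]$lin$W <- a; p })
  probe(function(p) p$head$hidden[[1]]$lin$b,
        function(p, a) { p$head$hidden[[1]]$lin$b <- a; p })
  probe(function(p) p$head$out$W,
        function(p, a) { p$head$out$W <- a; p })
})

test_that("zero-epoch training returns the initial model and no history", {
  sim <- tiny_sim(); m <- tiny_model()
  fit <- train_model(m, sim$cohort, sim$drugs, sim$triplets,
                     config = m$config)
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0L)
  expect_false(fit$model$trained)
})

test_that("training is reproducible and learns on the tiny study", {
  sim <- tiny_sim()
  cfg <- movida_config(k = 3L, drug_layers = c(8L, 4L), head_hidden = 4L,
                       batch_size = 32L, epochs = 8L, learning_rate = 5e-3,
                       seed = 5L)
  m <- build_model(tiny_layout(), cfg, ncol(sim$drugs))
  f1 <- train_model(m, sim$cohort, sim$drugs, sim$triplets)
  f2 <- train_model(m, sim$cohort, sim$drugs, sim$triplets)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # the fitted model beats the untrained one on validation loss
  va <- f1$split$val
  pr0 <- predict_batch(m, sim$cohort, sim$drugs, sim$triplets[va, ])
  pr1 <- predict_batch(f1$model, sim$cohort, sim$drugs, sim$triplets[va, ])
  t_ <- sim$triplets$auc[va]
  expect_lt(mean((pr1$predicted_auc - t_)^2), mean((pr0$predicted_auc - t_)^2))
})

test_that("unknown ids and empty splits are rejected", {
  sim <- tiny_sim(); m <- tiny_model()
  bad <- sim$triplets
  bad$cell_id[1] <- "NOPE"
  expect_error(train_model(m, sim$cohort, sim$drugs, bad), "unknown cell")
  expect_error(train_model(m, sim$cohort, sim$drugs, sim$triplets,
                           split = list(train = integer(0), val = 1:3)),
               "empty training split")
  expect_error(predict_batch(m, sim$cohort, sim$drugs,
                             data.frame(cell_id = "NOPE", drug_id = "D001")),
               "unknown cell")
})

test_that("prediction is deterministic and shape-faithful", {
  sim <- tiny_sim(); m <- tiny_model()
  pairs <- sim$triplets[c(1, 1, 5), c("cell_id", "drug_id")]
  pr <- predict_batch(m, sim$cohort, sim$drugs, pairs)
  expect_identical(pr$predicted_auc[1], pr$predicted_auc[2])
  empty <- predict_batch(m, sim$cohort, sim$drugs,
                         data.frame(cell_id = character(0),
                                    drug_id = character(0)))
  expect_identical(nrow(empty), 0L)
  grid <- expand.grid(cell_id = sim$cohort$cells[1:5],
                      drug_id = rownames(sim$drugs)[1:3],
                      stringsAsFactors = FALSE)
  expect_identical(nrow(predict_batch(m, sim$cohort, sim$drugs, grid)), 15L)
})

test_that("twin drug branches share weights and symmetrize at inference", {
  sim <- tiny_sim()
  cfg <- movida_synergy_config(k = 4L, drug_layers = c(8L, 4L),
                               head_hidden = 4L, batch_size = 16L,
                               epochs = 2L, learning_rate = 3e-3, seed = 3L)
  ms <- build_synergy_model(tiny_layout(), cfg, ncol(sim$drugs))
  pairs <- data.frame(cell_id = sim$cohort$cells[1:20],
                      drug_a = rownames(sim$drugs)[rep(1:4, 5)],
                      drug_b = rownames(sim$drugs)[rep(5:8, 5)],
                      label = rep(c(0L, 1L), 10))
  fit <- train_synergy(ms, sim$cohort, sim$drugs, pairs,
                       split = list(train = 1:16, val = 17:20))
  # one shared parameter set drives both branches
  expect_length(fit$model$params$drug, length(cfg$drug_layers))
  sc <- predict_synergy(fit$model, sim$cohort, sim$drugs,
                        pairs[1:5, c("cell_id", "drug_a", "drug_b")])
  flipped <- pairs[1:5, c("cell_id", "drug_b", "drug_a")]
  names(flipped) <- c("cell_id", "drug_a", "drug_b")
  sc2 <- predict_synergy(fit$model, sim$cohort, sim$drugs, flipped)
  expect_identical(sc$synergy_prob, sc2$synergy_prob)
})

test_that("label permutation destroys learnability", {
  sim <- tiny_sim()
  cfg <- movida_config(k = 3L, drug_layers = c(8L, 4L), head_hidden = 4L,
                       batch_size = 32L, epochs = 6L, learning_rate = 5e-3,
                       seed = 6L)
  m <- build_model(tiny_layout(), cfg, ncol(sim$drugs))
  cors <- vapply(1:3, function(s) {
    trip <- sim$triplets
    trip$auc <- withr::with_seed(900 + s, sample(trip$auc))
    cfg_s <- cfg; cfg_s$seed <- s
    fit <- train_model(m, sim$cohort, sim$drugs, trip, config = cfg_s)
    te <- fit$split$test
    pr <- predict_batch(fit$model, sim$cohort, sim$drugs, trip[te, ])
    suppressWarnings(balanced_correlation(pr$predicted_auc, trip$auc[te],
                                          n_per_class = 20, runs = 50,
                                          seed = s)$spearman)
  }, numeric(1))
  # mean correlation across seeds is statistically indistinguishable from 0
  expect_lt(abs(mean(cors)), 2 * stats::sd(cors) / sqrt(3) + 0.15)
})
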