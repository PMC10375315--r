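# Ablation interpretability and drug-combination enrichment.

test_that("masked ablation equals the weight-zeroing oracle everywhere", {
  fx <- five_term_model()
  m <- fx$model; sim <- fx$sim
  expect_length(m$layout$terms, 5L)
  pairs <- sim$triplets[1:4, c("cell_id", "drug_id")]
  CF <- cell_features(sim$cohort)[match(pairs$cell_id, sim$cohort$cells), ]
  DX <- unclass(sim$drugs)[match(pairs$drug_id, rownames(sim$drugs)), ]

  for (s in m$layout$terms) {
    masked <- movida:::model_forward(m, CF, DX,
                                     ablate = list(silence = s))$out
    oracle <- movida:::model_forward(zero_consumers(m, s), CF, DX)$out
    expect_equal(masked, oracle, tolerance = 1e-10)

    kids <- m$layout$children[[s]]
    if (length(kids)) {
      masked_c <- movida:::model_forward(m, CF, DX,
                                         ablate = list(silence = kids))$out
      mo <- m
      for (ch in kids) mo <- zero_consumers(mo, ch)
      expect_equal(masked_c, movida:::model_forward(mo, CF, DX)$out,
                   tolerance = 1e-10)
    } else {
      masked_c <- movida:::model_forward(
        m, CF, DX, ablate = list(silence_inputs = s, silence_nes = s))$out
      expect_equal(masked_c,
                   movida:::model_forward(zero_leaf_inputs(m, s), CF, DX)$out,
                   tolerance = 1e-10)
    }
  }
})

test_that("scores live in [-1, 1] with the degenerate case mapped to zero", {
  for (i in 1:20) {
    sim <- tiny_sim()
    cfg <- movida_config(k = 2L, drug_layers = c(6L, 3L), head_hidden = 3L,
                         batch_size = 16L, epochs = 0L, seed = 1000L + i)
    m <- build_model(tiny_layout(), cfg, ncol(sim$drugs), seed = 1000L + i)
    ris <- ris_scores(m, sim$cohort, sim$drugs,
                      sim$triplets[i, c("cell_id", "drug_id")])
    expect_true(all(ris$ris >= -1 & ris$ris <= 1))
    expect_true(all(is.finite(ris$ris)))
  }
})

test_that("limit cases of the score follow the definition", {
  rec <- function(s_f, s_cf) {
    if (s_cf + s_f > 0) (s_cf - s_f) / (s_cf + s_f) else 0
  }
  expect_identical(rec(0, 0.3), 1)
  expect_identical(rec(0.2, 0.2), 0)
  expect_identical(rec(0.4, 0), -1)
  expect_identical(rec(0, 0), 0)
})

test_that("a term with zeroed outgoing weights has s_f exactly 0", {
  fx <- five_term_model()
  m <- fx$model; sim <- fx$sim
  leaf <- names(which(lengths(m$layout$children) == 0))[1]
  m0 <- zero_consumers(m, leaf)
  ris <- ris_scores(m0, sim$cohort, sim$drugs,
                    sim$triplets[1:3, c("cell_id", "drug_id")])
  expect_true(all(ris$s_f[ris$term == leaf] == 0))
})

test_that("aggregation is deterministic and order-invariant", {
  rec <- data.frame(cell_id = c("c1", "c2", "c1", "c2"),
                    drug_id = "d1",
                    term = c("T1", "T1", "T2", "T2"),
                    ris = c(0.2, 0.4, -0.1, 0.3))
  agg <- aggregate_ris(rec, by = "drug")
  expect_equal(agg$mean_ris[agg$term == "T1"], 0.3)
  perm <- aggregate_ris(rec[c(3, 1, 4, 2), ], by = "drug")
  expect_identical(agg, perm)
  one <- aggregate_ris(rec[1, ], by = "cell")
  expect_equal(one$mean_ris, 0.2)
  expect_error(aggregate_ris(rec, by = "tissue_group",
                             group_map = c(c1 = "lung")),
               "unknown group key")
  agg2 <- aggregate_ris(rec, by = "tissue_group",
                        group_map = c(c1 = "lung", c2 = "lung"))
  expect_equal(agg2$n, c(2L, 2L))
})

test_that("candidate generation unions top-term genes and excludes the query", {
  lay <- tiny_layout()
  leaves <- names(which(lengths(lay$children) == 0))
  g1 <- lay$genes$mutation[[leaves[1]]][1]
  g2 <- lay$genes$mutation[[leaves[2]]][1]
  ris_tab <- data.frame(cell_id = "c1", drug_id = "QUERY",
                        term = lay$terms,
                        ris = ifelse(lay$terms == leaves[1], 0.9,
                                     ifelse(lay$terms == leaves[2], 0.5, 0)))
  targets <- data.frame(drug_id = c("dA", "dB", "QUERY"),
                        gene = c(g1, "not-a-gene", g1))
  cand <- candidate_combinations(ris_tab, lay, targets, top_k = 1)
  expect_identical(as.character(cand), "dA")
  expect_identical(attr(cand, "top_terms"), leaves[1])
  # with more terms, dB still matches nothing
  cand5 <- candidate_combinations(ris_tab, lay, targets, top_k = 5)
  expect_false("dB" %in% cand5)
  expect_false("QUERY" %in% cand5)
  expect_error(candidate_combinations(ris_tab, lay, targets[0, ]),
               "empty target table")
  # internal terms are excluded by default but includable
  ris_int <- ris_tab
  ris_int$ris[ris_int$term == lay$root] <- 2
  expect_false(lay$root %in%
                 attr(candidate_combinations(ris_int, lay, targets), "top_terms"))
  expect_true(lay$root %in%
                attr(candidate_combinations(ris_int, lay, targets,
                                            leaves_only = FALSE), "top_terms"))
})

test_that("candidates on a constructed toy equal the hand enumeration", {
  sim <- tiny_sim(); lay <- tiny_layout()
  causal <- sim$truth$causal_terms
  ris_tab <- data.frame(cell_id = "CL001", drug_id = "D001",
                        term = lay$terms,
                        ris = ifelse(lay$terms %in% causal, 0.8, -0.5))
  cand <- candidate_combinations(ris_tab, lay, sim$target_table)
  genes <- unique(unlist(lapply(causal, function(t)
    c(lay$genes$mutation[[t]], lay$genes$amplification[[t]],
      lay$genes$deletion[[t]]))))
  by_hand <- sort(setdiff(
    unique(sim$target_table$drug_id[sim$target_table$gene %in% genes]),
    "D001"))
  expect_identical(as.character(cand), by_hand)
})

test_that("binomial enrichment matches closed forms and an exact oracle", {
  val <- data.frame(drug_id = sprintf("d%d", 1:8),
                    label = c(1, 1, 1, 1, 0, 0, 0, 0))
  enr <- synergy_enrichment(sprintf("d%d", 1:4), val)
  expect_identical(enr$precision, 1)
  expect_equal(enr$p_value, 0.5^4, tolerance = 1e-12)
  expect_equal(enr$enrichment, 2, tolerance = 1e-12)

  # candidates at the baseline rate give enrichment 1
  enr2 <- synergy_enrichment(c("d1", "d5"), val)
  expect_equal(enr2$enrichment, 1, tolerance = 1e-12)

  # no tested candidate -> undefined flag
  enr3 <- synergy_enrichment("nope", val)
  expect_true(enr3$undefined)

  # independent exact tail: sum over choose()
  exact_tail <- function(tp, n, p) {
    if (tp <= 0) return(1)
    sum(vapply(tp:n, function(x)
      choose(n, x) * p^x * (1 - p)^(n - x), numeric(1)))
  }
  withr::with_seed(81, {
    for (i in 1:100) {
      S <- sample(1:30, 1); NS <- sample(1:50, 1)
      vv <- data.frame(drug_id = sprintf("d%d", seq_len(S + NS)),
                       label = sample(c(rep(1, S), rep(0, NS))))
      cand <- sample(vv$drug_id, sample(seq_len(S + NS), 1))
      e <- synergy_enrichment(cand, vv)
      expect_equal(e$p_value,
                   exact_tail(e$TP, e$TP + e$FP, e$baseline),
                   tolerance = 1e-12)
    }
  })
})
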