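# Ontology parsing, annotation handling, and layout construction.

test_that("a minimal is_a chain parses with the expected structure", {
  g <- parse_obo(obo_chain())
  expect_s3_class(g, "ontology_graph")
  expect_setequal(g$terms, c("T:ROOT", "T:MID", "T:LEAF"))
  expect_equal(nrow(g$edges), 2L)
  expect_identical(g$root, "T:ROOT")
})

test_that("cycles are reported with an offending edge", {
  p <- write_obo(c("[Term]", "id: A", "is_a: B", "",
                   "[Term]", "id: B", "is_a: A", ""))
  expect_error(parse_obo(p), "cycle")
})

test_that("missing files and rootless ontologies error", {
  expect_error(parse_obo(tempfile()), "cannot read")
  p2 <- write_obo(c("[Term]", "id: R1", "", "[Term]", "id: R2", ""))
  expect_error(parse_obo(p2), "multiple roots")
})

test_that("obsolete terms are skipped and namespaces filtered", {
  p <- write_obo(c(
    "[Term]", "id: R", "",
    "[Term]", "id: OBS", "is_a: R", "is_obsolete: true", "",
    "[Term]", "id: L", "is_a: R", ""))
  g <- parse_obo(p)
  expect_false("OBS" %in% g$terms)
  expect_setequal(g$terms, c("R", "L"))
})

test_that("a generated complete tree has the geometric-series term count", {
  ont <- generate_ontology(depth = 4L, branching = 3L, seed = 5L)
  g <- parse_obo(write_obo(ont$obo_text))
  expect_equal(length(g$terms), 1 + 3 + 9 + 27)
  expect_equal(nrow(g$edges), 39L)
})

test_that("annotations deduplicate, respect the universe and stay per-channel", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines("T1\tdesc\tg1\tg2\tg2", gmt)
  expect_message(
    ann <- load_annotations(gmt, channels = "mutation",
                            universe = c("g1", "g2", "g3")),
    regexp = NA)
  expect_setequal(ann$mutation$T1, c("g1", "g2"))

  writeLines("T1\tdesc\tg1\tg9", gmt)
  expect_message(
    ann2 <- load_annotations(gmt, channels = "mutation",
                             universe = c("g1", "g2")),
    "dropped 1")
  expect_identical(attr(ann2, "dropped_genes"), 1L)

  # two files for different channels stay independent after merging
  gmt_b <- tempfile(fileext = ".gmt")
  writeLines("T1\tdesc\tg2", gmt_b)
  both <- merge_annotations(
    load_annotations(gmt, channels = "mutation", universe = "g1"),
    load_annotations(gmt_b, channels = "expression", universe = "g2"))
  expect_setequal(both$mutation$T1, "g1")
  expect_setequal(both$expression$T1, "g2")
  expect_error(merge_annotations(both, both), "duplicate channels")
})

test_that("terms absent from the graph warn-and-drop or error", {
  g <- parse_obo(obo_chain())
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("T:LEAF\td\tg1", "T:GHOST\td\tg2"), gmt)
  expect_warning(
    ann <- load_annotations(gmt, channels = "mutation", graph = g),
    "not in ontology")
  expect_null(ann$mutation$`T:GHOST`)
  expect_error(
    suppressWarnings(load_annotations(gmt, channels = "mutation", graph = g,
                                      unknown_term = "error")),
    "not in ontology")
})

test_that("retention keeps annotated leaves and ancestors of retained terms", {
  g <- parse_obo(obo_chain())
  # genes only on the leaf: everything retained
  lay <- build_layout(g, ann_from_list(list(`T:LEAF` = c("g1"))))
  expect_setequal(lay$terms, c("T:ROOT", "T:MID", "T:LEAF"))
  # genes only on the mid term: leaf pruned, mid becomes a leaf
  lay2 <- build_layout(g, ann_from_list(list(`T:MID` = c("g1"))))
  expect_setequal(lay2$terms, c("T:ROOT", "T:MID"))
  expect_length(lay2$children$`T:MID`, 0L)
  # nothing annotated: the root itself fails -> empty model
  expect_error(build_layout(g, ann_from_list(list())), "empty model")
})

test_that("an unpruned complete tree keeps every term in child-first order", {
  lay <- tiny_layout()
  expect_length(lay$terms, 7L)
  pos <- stats::setNames(seq_along(lay$terms), lay$terms)
  for (t in lay$terms) {
    for (ch in lay$children[[t]]) {
      expect_lt(pos[[ch]], pos[[t]])
    }
  }
  expect_equal(unname(lay$depth[lay$root]), max(lay$depth))
})

test_that("min_genes thresholding and propagation behave as documented", {
  g <- parse_obo(obo_chain())
  ann <- ann_from_list(list(`T:LEAF` = c("g1", "g2")))
  expect_setequal(build_layout(g, ann, min_genes = 2L)$terms,
                  c("T:ROOT", "T:MID", "T:LEAF"))
  # with propagation the mid and root inherit the leaf's genes
  lay <- build_layout(g, ann, propagate = TRUE)
  expect_setequal(lay$genes$mutation$`T:ROOT`, c("g1", "g2"))
  lay_direct <- build_layout(g, ann)
  expect_length(lay_direct$genes$mutation$`T:ROOT`, 0L)
})

test_that("layout construction is idempotent on its own graph", {
  lay <- tiny_layout()
  lay2 <- build_layout(layout_as_graph(lay), layout_as_annotation(lay),
                       min_genes = lay$min_genes)
  expect_setequal(lay2$terms, lay$terms)
  expect_equal(lay2$children[order(names(lay2$children))],
               lay$children[order(names(lay$children))])
})

test_that("every retained term reaches the root through retained terms", {
  lay <- tiny_layout()
  reach <- movida:::reachable_to(lay$terms, layout_as_graph(lay)$edges,
                                 lay$root)
  expect_setequal(reach, lay$terms)
})

test_that("topological order holds for random generated DAGs", {
  for (i in 1:100) {
    ont <- generate_ontology(depth = 3L + i %% 2L, branching = 2L,
                             n_genes = 40L, genes_per_term = 3L,
                             cross_edges = i %% 4L, seed = i)
    g <- parse_obo(write_obo(ont$obo_text))
    ord <- movida:::topo_sort_ids(g$terms, g$edges)
    expect_length(ord, length(g$terms))
    pos <- stats::setNames(seq_along(ord), ord)
    expect_true(all(pos[g$edges$child] < pos[g$edges$parent]))
  }
})

test_that("layouts survive a JSON round trip", {
  lay <- tiny_layout()
  p <- tempfile(fileext = ".json")
  layout_to_json(lay, p)
  lay2 <- layout_from_json(p)
  expect_equal(lay2$terms, lay$terms)
  expect_equal(lay2$gene_index, lay$gene_index)
  expect_equal(lay2$dict, lay$dict)
  expect_equal(lay2$depth, lay$depth)
})
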