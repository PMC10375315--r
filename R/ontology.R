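# Ontology parsing, gene annotation and the layered wiring diagram ("layout")
# from which the visible network is built.

#' Parse an OBO ontology into a directed acyclic term graph
#'
#' Reads an OBO 1.2/1.4 file keeping only `is_a` relationships. Obsolete terms
#' are skipped. The returned graph is restricted to terms that can reach the
#' root (the unique term with no outgoing `is_a` edge, or the `root` argument
#' if given).
#'
#' @param path Path to an OBO file.
#' @param root Optional term identifier to use as root; terms unable to reach
#'   it are dropped. When `NULL` the graph must contain exactly one term with
#'   no parent.
#' @param namespace Optional OBO namespace (e.g. `"biological_process"`); terms
#'   declaring a different namespace are ignored.
#' @return An `ontology_graph`: list with `terms` (character), `edges`
#'   (data.frame `child`, `parent`) and `root`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:2", "name: root", "",
#'              "[Term]", "id: T:1", "name: leaf", "is_a: T:2 ! root"), obo)
#' g <- parse_obo(obo)
#' g$root
#' @export
parse_obo <- function(path, root = NULL, namespace = NULL) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  ids <- character(0)
  edges_child <- character(0)
  edges_parent <- character(0)
  cur_id <- NA_character_
  cur_obsolete <- FALSE
  cur_ns_ok <- TRUE
  cur_parents <- character(0)
  in_term <- FALSE

  flush_term <- function() {
    if (in_term && !is.na(cur_id) && !cur_obsolete && cur_ns_ok) {
      ids <<- c(ids, cur_id)
      if (length(cur_parents)) {
        edges_child <<- c(edges_child, rep(cur_id, length(cur_parents)))
        edges_parent <<- c(edges_parent, cur_parents)
      }
    }
  }

  for (ln in lines) {
    ln <- sub("!.*$", "", ln)        # strip trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush_term()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_; cur_obsolete <- FALSE
      cur_ns_ok <- TRUE; cur_parents <- character(0)
      next
    }
    if (!in_term) next
    if (startsWith(ln, "id:")) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    } else if (startsWith(ln, "is_obsolete:")) {
      cur_obsolete <- grepl("true", ln, fixed = TRUE)
    } else if (startsWith(ln, "namespace:") && !is.null(namespace)) {
      cur_ns_ok <- identical(trimws(sub("^namespace:", "", ln)), namespace)
    }
  }
  flush_term()

  if (!length(ids)) stop("no terms found in OBO file: ", path)
  ids <- unique(ids)
  keep <- edges_child %in% ids & edges_parent %in% ids
  edges <- data.frame(child = edges_child[keep], parent = edges_parent[keep],
                      stringsAsFactors = FALSE)
  edges <- unique(edges)

  assert_acyclic(ids, edges)

  if (is.null(root)) {
    has_parent <- ids %in% edges$child
    roots <- ids[!has_parent]
    if (length(roots) == 0L) stop("ontology has no root term")
    if (length(roots) > 1L) {
      stop("ontology has multiple roots (", paste(roots, collapse = ", "),
           "); pass `root` to select one")
    }
    root <- roots
  } else if (!root %in% ids) {
    stop("requested root ", root, " not present in ontology")
  }

  reach <- reachable_to(ids, edges, root)
  ids <- ids[ids %in% reach]
  edges <- edges[edges$child %in% ids & edges$parent %in% ids, , drop = FALSE]
  structure(list(terms = ids, edges = edges, root = root),
            class = "ontology_graph")
}

# Kahn's algorithm; on failure names one edge participating in a cycle.
assert_acyclic <- function(ids, edges) {
  ord <- topo_sort_ids(ids, edges)
  if (length(ord) < length(ids)) {
    left <- setdiff(ids, ord)
    bad <- edges[edges$child %in% left & edges$parent %in% left, , drop = FALSE]
    stop("cycle detected in ontology involving edge ",
         bad$child[1], " is_a ", bad$parent[1])
  }
  invisible(TRUE)
}

# Children-before-parents topological order (returns what it can order;
# callers compare length against the node count to detect cycles).
topo_sort_ids <- function(ids, edges) {
  out_deg <- structure(integer(length(ids)), names = ids) # edges to parents
  for (ch in edges$child) out_deg[ch] <- out_deg[ch] + 1L
  children_of <- split(edges$child, edges$parent)
  # process leaves (no incoming from children ... i.e. nodes all of whose
  # children are already emitted); iterate Kahn on the child->parent DAG
  parents_of <- split(edges$parent, edges$child)
  n_unemitted_children <- structure(integer(length(ids)), names = ids)
  for (p in edges$parent) n_unemitted_children[p] <- n_unemitted_children[p] + 1L
  queue <- ids[n_unemitted_children[ids] == 0L]
  ord <- character(0)
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    ord <- c(ord, x)
    for (p in parents_of[[x]] %||% character(0)) {
      n_unemitted_children[p] <- n_unemitted_children[p] - 1L
      if (n_unemitted_children[p] == 0L) queue <- c(queue, p)
    }
  }
  ord
}

# Terms with a directed path (child -> parent chain) to `root`.
reachable_to <- function(ids, edges, root) {
  children_of <- split(edges$child, edges$parent)
  seen <- character(0)
  frontier <- root
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  seen
}

#' Load term-to-gene annotations for one or more omics channels
#'
#' Accepts GMT (term, description, genes...) or two-column TSV (term, gene)
#' files. Genes outside `universe` are dropped (count reported via a message);
#' duplicate (term, gene) pairs are collapsed. Terms absent from `graph` are
#' warned about and dropped by default.
#'
#' @param path Annotation file (GMT if the extension is `.gmt`, else TSV).
#' @param channels Character vector of channels this file annotates, subset of
#'   `c("mutation", "amplification", "deletion", "expression")`.
#' @param graph Optional `ontology_graph`; used to screen unknown terms.
#' @param universe Optional character vector: the declared gene universe for
#'   these channels; genes outside it are dropped.
#' @param unknown_term `"warn"` (drop with a warning, default) or `"error"`.
#' @return A `term_annotation`: named list channel -> (named list term -> gene
#'   character vector), with attribute `dropped_genes` (count).
#' @export
load_annotations <- function(path, channels,
                             graph = NULL, universe = NULL,
                             unknown_term = c("warn", "error")) {
  unknown_term <- match.arg(unknown_term)
  stopifnot(all(channels %in% c("mutation", "amplification",
                                "deletion", "expression")))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("two-column TSV expected in ", path)
    sets <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  sets <- lapply(sets, unique)

  if (!is.null(graph)) {
    unknown <- setdiff(names(sets), graph$terms)
    if (length(unknown)) {
      if (unknown_term == "error") {
        stop("annotation terms not in ontology: ", paste(unknown, collapse = ", "))
      }
      warning(length(unknown), " annotated term(s) not in ontology; dropped")
      sets <- sets[setdiff(names(sets), unknown)]
    }
  }
  dropped <- 0L
  if (!is.null(universe)) {
    before <- sum(lengths(sets))
    sets <- lapply(sets, function(g) g[g %in% universe])
    dropped <- before - sum(lengths(sets))
    if (dropped > 0L) {
      message("load_annotations: dropped ", dropped,
              " gene annotation(s) outside the declared universe")
    }
  }
  ann <- stats::setNames(rep(list(sets), length(channels)), channels)
  structure(ann, class = "term_annotation", dropped_genes = dropped)
}

#' Merge term annotations loaded from separate files
#'
#' @param ... `term_annotation` objects with disjoint channel sets.
#' @return A single `term_annotation` covering the union of channels.
#' @export
merge_annotations <- function(...) {
  parts <- list(...)
  chans <- unlist(lapply(parts, names))
  if (anyDuplicated(chans)) stop("duplicate channels across annotations")
  out <- do.call(c, lapply(parts, unclass))
  structure(out, class = "term_annotation")
}

#' Build the layered model layout from an ontology and its annotations
#'
#' Applies the retention rule (a term is kept iff the union of its mutation/
#' amplification/deletion genes has at least `min_genes` members, or it has at
#' least one retained child), prunes failing terms, and emits a topologically
#' ordered wiring diagram: per retained term its retained children, its
#' per-channel gene index arrays (indices into per-channel gene dictionaries)
#' and its depth (longest path to a leaf; the root has the maximum depth).
#'
#' Under this rule a pruned term can never have a retained child, so pruning
#' removes maximal unannotated subtrees and no re-attachment is needed.
#'
#' @param graph An `ontology_graph`.
#' @param ann A `term_annotation` (channels `mutation`, `amplification`,
#'   `deletion` drive retention; `expression` drives the enrichment wiring).
#' @param min_genes Minimum annotated-gene count for leaf retention.
#' @param propagate If `TRUE`, each term's gene sets are unioned over itself
#'   and all of its descendants (ontology true-path rule) before retention and
#'   wiring; default `FALSE` uses direct annotations only.
#' @return An `ontology_layout`.
#' @export
build_layout <- function(graph, ann, min_genes = 1L, propagate = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  channels <- c("mutation", "amplification", "deletion", "expression")
  for (ch in channels) if (is.null(ann[[ch]])) ann[[ch]] <- list()

  ord <- topo_sort_ids(graph$terms, graph$edges)  # children first
  if (length(ord) < length(graph$terms)) assert_acyclic(graph$terms, graph$edges)
  children_of <- split(graph$edges$child, graph$edges$parent)

  gene_sets <- lapply(channels, function(ch) {
    lapply(stats::setNames(ord, ord), function(t) unique(ann[[ch]][[t]] %||% character(0)))
  })
  names(gene_sets) <- channels

  if (propagate) {
    # children precede parents in `ord`, so one sweep suffices
    for (t in ord) {
      kids <- children_of[[t]] %||% character(0)
      if (!length(kids)) next
      for (ch in channels) {
        gene_sets[[ch]][[t]] <- unique(c(gene_sets[[ch]][[t]],
                                         unlist(gene_sets[[ch]][kids], use.names = FALSE)))
      }
    }
  }

  retained <- structure(logical(length(ord)), names = ord)
  for (t in ord) {
    omic <- unique(c(gene_sets$mutation[[t]], gene_sets$amplification[[t]],
                     gene_sets$deletion[[t]]))
    kids <- children_of[[t]] %||% character(0)
    retained[t] <- length(omic) >= min_genes || any(retained[kids])
  }
  if (!retained[graph$root]) stop("empty model: root term was pruned")
  keep <- ord[retained[ord]]
  if (!length(keep)) stop("empty layout")

  kept_children <- lapply(stats::setNames(keep, keep), function(t) {
    kids <- children_of[[t]] %||% character(0)
    sort(kids[kids %in% keep])
  })
  parents_of_edge <- split(graph$edges$parent, graph$edges$child)
  kept_parents <- lapply(stats::setNames(keep, keep), function(t) {
    ps <- parents_of_edge[[t]] %||% character(0)
    sort(ps[ps %in% keep])
  })

  depth <- structure(integer(length(keep)), names = keep)
  for (t in keep) {
    kids <- kept_children[[t]]
    depth[t] <- if (length(kids)) 1L + max(depth[kids]) else 0L
  }

  genes <- lapply(channels, function(ch) gene_sets[[ch]][keep])
  names(genes) <- channels
  dict <- lapply(channels, function(ch) {
    sort(unique(unlist(genes[[ch]], use.names = FALSE)))
  })
  names(dict) <- channels
  gene_index <- lapply(channels, function(ch) {
    lapply(genes[[ch]], function(g) match(sort(g), dict[[ch]]))
  })
  names(gene_index) <- channels

  structure(list(
    terms = keep, root = graph$root,
    children = kept_children, parents = kept_parents,
    depth = depth, genes = genes, dict = dict, gene_index = gene_index,
    min_genes = as.integer(min_genes), propagate = propagate
  ), class = "ontology_layout")
}

#' Recover the term graph of a layout
#' @param layout An `ontology_layout`.
#' @return An `ontology_graph` over the retained terms.
#' @export
layout_as_graph <- function(layout) {
  ch <- unlist(lapply(names(layout$children), function(p) layout$children[[p]]),
               use.names = FALSE)
  pa <- rep(names(layout$children), lengths(layout$children))
  structure(list(terms = layout$terms,
                 edges = data.frame(child = ch, parent = pa,
                                    stringsAsFactors = FALSE),
                 root = layout$root),
            class = "ontology_graph")
}

#' Recover the annotation object of a layout
#' @param layout An `ontology_layout`.
#' @return A `term_annotation` with the layout's (possibly propagated) sets.
#' @export
layout_as_annotation <- function(layout) {
  structure(layout$genes, class = "term_annotation")
}

#' Serialize a layout to JSON (and back)
#'
#' The JSON carries the term order, children, depths, gene dictionaries and
#' per-term gene memberships, enough to rebuild the model wiring bit-for-bit.
#' @param layout An `ontology_layout`.
#' @param path Output (input) file path.
#' @return `layout_to_json` returns `path` invisibly; `layout_from_json`
#'   returns the `ontology_layout`.
#' @export
layout_to_json <- function(layout, path) {
  jsonlite::write_json(layout_to_raw(layout), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON-safe representation: named atomic vectors become objects, not arrays
layout_to_raw <- function(layout) {
  x <- unclass(layout)
  x$depth <- as.list(x$depth)
  x
}

#' @rdname layout_to_json
#' @export
layout_from_json <- function(path) {
  layout_from_raw(read_json_plain(path))
}

#' @export
print.ontology_layout <- function(x, ...) {
  cat("ontology_layout:", length(x$terms), "retained terms, root", x$root,
      "(depth", x$depth[x$root], ")\n")
  cat("  gene dictionary sizes:",
      paste(names(x$dict), lengths(x$dict), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges),
      "is_a edges, root", x$root, "\n")
  invisible(x)
}
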