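#' Construct an ontology DAG
#'
#' Builds the directed acyclic graph for one Gene Ontology namespace from a
#' child-to-parent edge table. Only `is_a` and `part_of` relations are
#' admitted; these are the two edge types the similarity measure is defined
#' over. The constructor validates acyclicity, requires a single root (a term
#' with no parent), and precomputes the inclusive ancestor and descendant
#' closure of every term, so that downstream queries (lowest common
#' ancestors, annotation propagation, path-constrained gene sets) are cheap
#' lookups.
#'
#' A term is counted among its own ancestors and descendants throughout the
#' package; this convention makes `lowest_common_ancestors(dag, t, t)`
#' return `t` and keeps self-similarity well defined.
#'
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (each relation `"is_a"` or `"part_of"`); one row per directed
#'   child-to-parent edge.
#' @param namespace ontology namespace the DAG belongs to, one of
#'   `"molecular_function"`, `"biological_process"`,
#'   `"cellular_component"` (abbreviations `"MF"`, `"BP"`, `"CC"`
#'   accepted).
#' @param terms optional character vector of term identifiers; defaults to
#'   all terms mentioned in `edges`. Supply it to retain isolated terms.
#'
#' @return An object of class `ontology_dag`: a list with the term vector,
#'   the edge tibble, the namespace, the root term, and named lists
#'   `parents`, `children`, `ancestors`, `descendants` (the latter two
#'   inclusive of the term itself).
#' @export
ontology_dag <- function(edges, namespace = "molecular_function", terms = NULL) {
  namespace <- normalize_namespace(namespace)
  edges <- as_tibble(edges)
  if (!all(c("child", "parent", "relation") %in% names(edges))) {
    abort("`edges` must have columns child, parent, relation")
  }
  edges <- edges[, c("child", "parent", "relation")]
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) {
    abort(paste0("unsupported edge relation(s): ", paste(bad_rel, collapse = ", ")))
  }
  terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (!length(terms)) abort("ontology has no terms")

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = terms
  )
  if (any(edges$child == edges$parent) || !igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    in_cycle <- names(comp$membership)[comp$membership %in%
      which(tabulate(comp$membership) > 1)]
    if (!length(in_cycle)) in_cycle <- edges$child[edges$child == edges$parent]
    abort(paste0("ontology graph contains a cycle involving term ", in_cycle[[1]]))
  }

  idx <- setNames(seq_along(terms), terms)
  parents_i <- split(idx[edges$parent], factor(edges$child, levels = terms))
  children_i <- split(idx[edges$child], factor(edges$parent, levels = terms))

  roots <- terms[lengths(parents_i) == 0L]
  if (length(roots) != 1L) {
    abort(paste0(
      "expected exactly one root term in namespace slice, found ",
      length(roots), ": ", paste(head(roots, 5), collapse = ", ")
    ))
  }

  # child precedes parent in topological order; closures by dynamic programming
  topo <- idx[names(igraph::topo_sort(g, mode = "out"))]
  anc <- desc <- vector("list", length(terms))
  for (i in rev(topo)) {          # parents first
    anc[[i]] <- sort(unique(c(i, unlist(anc[parents_i[[i]]]))))
  }
  for (i in topo) {               # children first
    desc[[i]] <- sort(unique(c(i, unlist(desc[children_i[[i]]]))))
  }

  structure(
    list(
      terms = terms,
      edges = edges,
      namespace = namespace,
      root = roots,
      parents = lapply(parents_i, function(i) terms[i]),
      children = lapply(children_i, function(i) terms[i]),
      ancestors = setNames(lapply(anc, function(i) terms[i]), terms),
      descendants = setNames(lapply(desc, function(i) terms[i]), terms)
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(
    "<ontology_dag> ", x$namespace, "\n",
    "  terms: ", length(x$terms),
    "  edges: ", nrow(x$edges),
    "  root: ", x$root, "\n",
    sep = ""
  )
  invisible(x)
}

normalize_namespace <- function(namespace) {
  full <- c(
    MF = "molecular_function", BP = "biological_process",
    CC = "cellular_component"
  )
  if (namespace %in% names(full)) namespace <- full[[namespace]]
  if (!namespace %in% full) {
    abort(paste0("unknown namespace: ", namespace))
  }
  namespace
}

#' Read an ontology from an OBO file
#'
#' Streams an OBO 1.2/1.4 file and returns the DAG for a single namespace.
#' Only `is_a` and `part_of` edges are kept; every other relationship
#' (`regulates`, `occurs_in`, ...) is dropped, as are obsolete terms and
#' terms outside the requested namespace.
#'
#' @param path path to an OBO file.
#' @inheritParams ontology_dag
#' @return an [ontology_dag].
#' @export
read_obo <- function(path, namespace = "molecular_function") {
  namespace <- normalize_namespace(namespace)
  if (!file.exists(path)) abort(paste0("cannot read OBO file: ", path))
  lines <- readLines(path, warn = FALSE)

  term_ids <- character()
  term_ns <- character()
  obsolete <- logical()
  edge_child <- edge_parent <- edge_rel <- character()

  in_term <- FALSE
  cur_id <- NA_character_

  for (line in lines) {
    line <- sub("\\s*!.*$", "", trimws(line))
    if (line == "") next
    if (grepl("^\\[", line)) {
      in_term <- identical(line, "[Term]")
      if (in_term) {
        term_ids <- c(term_ids, NA_character_)
        term_ns <- c(term_ns, NA_character_)
        obsolete <- c(obsolete, FALSE)
      }
      cur_id <- NA_character_
      next
    }
    if (!in_term) next
    n <- length(term_ids)
    if (grepl("^id:", line)) {
      cur_id <- trimws(sub("^id:", "", line))
      term_ids[n] <- cur_id
    } else if (grepl("^namespace:", line)) {
      term_ns[n] <- trimws(sub("^namespace:", "", line))
    } else if (grepl("^is_obsolete:\\s*true", line)) {
      obsolete[n] <- TRUE
    } else if (grepl("^is_a:", line)) {
      edge_child <- c(edge_child, cur_id)
      edge_parent <- c(edge_parent, trimws(sub("^is_a:", "", line)))
      edge_rel <- c(edge_rel, "is_a")
    } else if (grepl("^relationship:", line)) {
      rest <- strsplit(trimws(sub("^relationship:", "", line)), "\\s+")[[1]]
      if (length(rest) >= 2 && rest[[1]] == "part_of") {
        edge_child <- c(edge_child, cur_id)
        edge_parent <- c(edge_parent, rest[[2]])
        edge_rel <- c(edge_rel, "part_of")
      }
    }
  }

  keep <- !is.na(term_ids) & !obsolete & !is.na(term_ns) & term_ns == namespace
  kept_terms <- term_ids[keep]
  if (!length(kept_terms)) {
    abort(paste0("no usable terms for namespace ", namespace, " in ", path))
  }
  e <- tibble(child = edge_child, parent = edge_parent, relation = edge_rel)
  e <- e[e$child %in% kept_terms & e$parent %in% kept_terms, ]
  ontology_dag(e, namespace = namespace, terms = kept_terms)
}

#' Ancestors and descendants of a term
#'
#' Inclusive closures: every term is its own ancestor and descendant.
#'
#' @param dag an [ontology_dag].
#' @param term a term identifier present in `dag`.
#' @return character vector of term identifiers.
#' @export
term_ancestors <- function(dag, term) {
  check_term(dag, term)
  dag$ancestors[[term]]
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(dag, term) {
  check_term(dag, term)
  dag$descendants[[term]]
}

check_term <- function(dag, term) {
  missing <- setdiff(term, dag$terms)
  if (length(missing)) {
    abort(paste0("unknown term(s): ", paste(missing, collapse = ", ")))
  }
  invisible(term)
}

#' Lowest common ancestors of two terms
#'
#' Returns every common ancestor of `t1` and `t2` that has no descendant
#' which is also a common ancestor. In a DAG there may be several; the term
#' similarity takes the maximum score over all of them. Because a term is
#' its own ancestor, `lowest_common_ancestors(dag, t, t)` is `t`. The result
#' is never empty: the root is a common ancestor of every pair.
#'
#' @inheritParams term_ancestors
#' @param t1,t2 term identifiers.
#' @return character vector of term identifiers.
#' @export
lowest_common_ancestors <- function(dag, t1, t2) {
  check_term(dag, c(t1, t2))
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  is_lowest <- vapply(common, function(p) {
    # p is lowest iff no *other* common ancestor descends from p
    length(setdiff(intersect(dag$descendants[[p]], common), p)) == 0L
  }, logical(1))
  common[is_lowest]
}

#' Path-constrained annotation gene set
#'
#' The path-constrained annotation `U(t1, t2, p)` replaces the full
#' descendant set of a common ancestor `p` by only the terms that are
#' relevant to the compared pair: genes annotated (after propagation) to
#' `t1` or `t2`, plus the direct annotations of every term lying on some
#' directed path from `t1` to `p` or from `t2` to `p` (including `p`
#' itself). Its cardinality enters the path-constrained similarity
#' component [path_constrained_f()].
#'
#' The set always satisfies
#' `union(G1, G2) <= U(t1, t2, p) <= propagated genes of p`.
#'
#' @inheritParams term_ancestors
#' @param ann an [annotation_map].
#' @param t1,t2 term identifiers.
#' @param p a common ancestor of `t1` and `t2`.
#' @return character vector of gene identifiers.
#' @export
path_constrained_genes <- function(dag, ann, t1, t2, p) {
  check_term(dag, c(t1, t2, p))
  if (!(p %in% dag$ancestors[[t1]]) || !(p %in% dag$ancestors[[t2]])) {
    abort(paste0(p, " is not a common ancestor of ", t1, " and ", t2))
  }
  on_path <- union(
    intersect(dag$ancestors[[t1]], dag$descendants[[p]]),
    intersect(dag$ancestors[[t2]], dag$descendants[[p]])
  )
  sort(unique(c(
    ann$propagated[[t1]],
    ann$propagated[[t2]],
    unlist(ann$direct_by_term[on_path], use.names = FALSE)
  )))
}
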