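#' Build an annotation map
#'
#' Holds both views of a gene-to-term annotation: the direct assignments and
#' the true-path propagated view (a gene annotated to a term is implicitly
#' annotated to all of that term's ancestors, so each term's propagated gene
#' set is the union of direct annotations over the term and its
#' descendants). Propagation crosses `is_a` and `part_of` edges alike — the
#' only two edge types retained in the DAG.
#'
#' The propagated sets are monotone along every child-to-parent edge, and
#' the root's propagated set is the full annotated gene universe `G` whose
#' size `|G|` enters the term-similarity formula.
#'
#' @param dag an [ontology_dag].
#' @param direct named list mapping gene identifier to a character vector of
#'   directly annotated terms (all terms must exist in `dag`).
#' @return An object of class `annotation_map`: a list with `direct`
#'   (gene -> terms), `direct_by_term` (term -> genes directly annotated),
#'   `propagated` (term -> genes, true-path view), and `gene_universe`.
#' @export
annotation_map <- function(dag, direct) {
  if (!inherits(dag, "ontology_dag")) abort("`dag` must be an ontology_dag")
  if (!length(direct)) abort("no annotations supplied")
  direct <- lapply(direct, function(x) sort(unique(as.character(x))))
  all_terms <- unique(unlist(direct, use.names = FALSE))
  check_term(dag, all_terms)

  pairs <- tibble(
    gene = rep(names(direct), lengths(direct)),
    term = unlist(direct, use.names = FALSE)
  )
  direct_by_term <- lapply(
    split(pairs$gene, factor(pairs$term, levels = dag$terms)),
    function(g) sort(unique(g))
  )
  propagated <- setNames(lapply(dag$terms, function(t) {
    as.character(sort(unique(
      unlist(direct_by_term[dag$descendants[[t]]], use.names = FALSE)
    )))
  }), dag$terms)

  structure(
    list(
      direct = direct,
      direct_by_term = direct_by_term,
      propagated = propagated,
      gene_universe = sort(unique(pairs$gene))
    ),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(
    "<annotation_map>  genes: ", length(x$gene_universe),
    "  direct annotations: ", sum(lengths(x$direct)),
    "  annotated terms: ", sum(lengths(x$direct_by_term) > 0), "\n",
    sep = ""
  )
  invisible(x)
}

#' Propagate direct annotations up the ontology
#'
#' Returns the true-path view on its own: for each term, the genes directly
#' annotated to the term or to any of its descendants.
#'
#' @inheritParams annotation_map
#' @return named list term -> character vector of genes.
#' @export
propagate_annotations <- function(dag, direct) {
  annotation_map(dag, direct)$propagated
}

#' Read gene annotations from a GAF file
#'
#' Reads a GAF 2.1/2.2 association file (tab-separated, `!` comment lines)
#' against a parsed ontology. Rows are skipped — with a reported count —
#' when the qualifier contains `NOT`, when the term is absent from the DAG
#' (wrong namespace, obsolete, unknown), or when the row is malformed. All
#' evidence codes are accepted unless an allow-list is supplied.
#'
#' @param path path to a GAF file.
#' @param dag an [ontology_dag]; annotations to terms outside it are
#'   dropped.
#' @param evidence optional character vector of evidence codes to keep
#'   (default: keep all).
#' @return an [annotation_map].
#' @export
read_gaf <- function(path, dag, evidence = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read GAF file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]

  n_skipped <- c(malformed = 0L, not_qualified = 0L, unknown_term = 0L, evidence = 0L)
  genes <- terms <- character(length(lines))
  keep <- logical(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5 || !nzchar(f[[2]]) || !nzchar(f[[5]])) {
      n_skipped[["malformed"]] <- n_skipped[["malformed"]] + 1L
      next
    }
    if (length(f) >= 4 && grepl("(^|\\|)NOT(\\||$)", f[[4]])) {
      n_skipped[["not_qualified"]] <- n_skipped[["not_qualified"]] + 1L
      next
    }
    if (!is.null(evidence) && (length(f) < 7 || !f[[7]] %in% evidence)) {
      n_skipped[["evidence"]] <- n_skipped[["evidence"]] + 1L
      next
    }
    if (!f[[5]] %in% dag$terms) {
      n_skipped[["unknown_term"]] <- n_skipped[["unknown_term"]] + 1L
      next
    }
    genes[k] <- f[[2]]
    terms[k] <- f[[5]]
    keep[k] <- TRUE
  }
  if (!any(keep)) abort(paste0("no usable annotation rows in ", path))
  if (sum(n_skipped) > 0) {
    inform(paste0(
      "read_gaf: skipped ", sum(n_skipped), " row(s) (",
      paste(names(n_skipped)[n_skipped > 0], n_skipped[n_skipped > 0],
        sep = "=", collapse = ", "
      ), ")"
    ))
  }
  direct <- split(terms[keep], genes[keep])
  out <- annotation_map(dag, direct)
  attr(out, "skipped") <- n_skipped
  out
}
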