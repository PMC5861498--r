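#' Gene-set distance between two annotation sets
#'
#' The raw distance between the gene sets of two terms contrasts every gene
#' of one set against the whole of the other through products of pairwise
#' gene distances:
#' \deqn{D = \frac{\sum_{i \in G_1}\prod_{j \in G_2} d_{ij} +
#'                \sum_{i \in G_2}\prod_{j \in G_1} d_{ij}}
#'               {2|G_1 \cup G_2| -
#'                \sum_{i \in G_1}\prod_{j \in G_2} d_{ij} -
#'                \sum_{i \in G_2}\prod_{j \in G_1} d_{ij}}}
#' Any shared gene zeroes its product (self-distances are zero), so
#' `D(G, G) = 0`, and with all `d` in `[0, 1]` the denominator is strictly
#' positive. Products are evaluated in log space, so sets with thousands of
#' genes cannot underflow to spurious zeros.
#'
#' @param g1,g2 nonempty character vectors of gene identifiers.
#' @param dist numeric gene-by-gene distance matrix with dimnames covering
#'   `g1` and `g2`, entries in `[0, 1]`, zero diagonal (see
#'   [gene_distance_matrix()]).
#' @return nonnegative raw distance (at most 1).
#' @export
gene_set_distance <- function(g1, g2, dist) {
  g1 <- unique(as.character(g1))
  g2 <- unique(as.character(g2))
  if (!length(g1) || !length(g2)) abort("gene sets must be nonempty")
  # log-space products; log(0) = -Inf short-circuits shared genes to 0
  a <- sum(exp(rowSums(log(dist[g1, g2, drop = FALSE]))))
  b <- sum(exp(rowSums(log(dist[g2, g1, drop = FALSE]))))
  den <- 2 * length(union(g1, g2)) - a - b
  if (den <= 0) abort("gene-set distance denominator not positive; distances must lie in [0, 1]")
  (a + b) / den
}

#' Min-max normalization of raw gene-set distances
#'
#' Raw distances of all term pairs computed in a run are rescaled to
#' `[0, 1]`. If every raw value is identical the span is degenerate and all
#' values map to 0 — the network is treated as uninformative and the
#' similarity collapses toward its annotation-only form.
#'
#' @param raw numeric vector or matrix of raw distances.
#' @return object of the same shape with values in `[0, 1]`; attribute
#'   `bounds` holds the `(min, max)` used.
#' @export
normalize_distances <- function(raw) {
  rng <- range(raw, na.rm = TRUE)
  out <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  attr(out, "bounds") <- rng
  out
}

#' Path-constrained similarity component
#'
#' Interpolates, by the squared normalized gene-set distance `D`, between
#' the size of the path-constrained annotation `U` (network says the terms
#' are far apart) and the geometric mean of the two terms' annotation-set
#' sizes (network says they are indistinguishable):
#' `f = D^2 |U| + (1 - D^2) sqrt(|G1| |G2|)`.
#'
#' @param d normalized gene-set distance in `[0, 1]`.
#' @param n_u size of the path-constrained annotation set.
#' @param n_g1,n_g2 propagated annotation-set sizes of the two terms.
#' @return numeric score.
#' @export
path_constrained_f <- function(d, n_u, n_g1, n_g2) {
  d^2 * n_u + (1 - d^2) * sqrt(n_g1 * n_g2)
}

#' Common-parent specificity component
#'
#' `h = D^2 |G| + (1 - D^2) max(|G1|, |G2|)`: under a distant pair the
#' common parent is judged against the whole annotated genome, under an
#' indistinguishable pair against the larger of the two annotation sets.
#'
#' @inheritParams path_constrained_f
#' @param n_g size of the full annotated gene universe `G`.
#' @return numeric score.
#' @export
parent_specificity_h <- function(d, n_g, n_g1, n_g2) {
  d^2 * n_g + (1 - d^2) * pmax(n_g1, n_g2)
}

#' Term-pair similarity score for one common ancestor
#'
#' Combines the components for a fixed common ancestor `p`:
#' \deqn{S_p = \frac{2\log|G| - 2\log f}{2\log|G| - (\log|G_1| + \log|G_2|)}
#'   \left(1 - \frac{h}{|G|}\frac{|G_p|}{|G|}\right)}
#' The left factor measures how far the pair sits below `p` (it is
#' invariant to the logarithm base; natural logs are used), the right how
#' specific `p` itself is. If both terms annotate the entire genome the
#' denominator vanishes and the similarity is defined as 0 — such terms
#' carry no information.
#'
#' @inheritParams parent_specificity_h
#' @param n_gp propagated annotation-set size of the common ancestor.
#' @return similarity in `[0, 1]`.
#' @export
term_similarity_score <- function(d, n_g, n_g1, n_g2, n_gp, n_u) {
  den <- 2 * log(n_g) - (log(n_g1) + log(n_g2))
  if (den <= 0) return(0)
  f <- path_constrained_f(d, n_u, n_g1, n_g2)
  h <- parent_specificity_h(d, n_g, n_g1, n_g2)
  left <- (2 * log(n_g) - 2 * log(f)) / den
  right <- 1 - (h / n_g) * (n_gp / n_g)
  # mathematically in [0, 1]; clamp away floating-point sign noise
  min(max(left * right, 0), 1)
}

#' Term-similarity context
#'
#' Assembles everything the term- and gene-level similarities need: the
#' DAG, the propagated annotations, the gene distance matrix derived from
#' the random walk, and the raw and normalized gene-set distances for all
#' pairs of usable terms. Usable terms (`T_G`) are those with a nonempty
#' propagated gene set; terms annotating no gene are retained in the DAG
#' but excluded here, which avoids taking logarithms of zero set sizes.
#' Normalization is min-max over all pairs computed in the run (diagonal
#' included, whose raw distance is structurally 0); the bounds are stored
#' so results are reproducible from the context.
#'
#' @param dag an [ontology_dag].
#' @param ann an [annotation_map].
#' @param rel a `relevance_matrix` from [relevance_matrix()].
#' @param terms optional subset of terms to restrict `T_G` to.
#' @return An object of class `termsim_context`: list with `dag`, `ann`,
#'   `terms` (T_G), `dist` (gene distance matrix), `raw_d` and `norm_d`
#'   (term-pair matrices), `n_universe` (`|G|`), `n_prop` (per-term
#'   propagated sizes), and the normalization `bounds`.
#' @export
termsim_context <- function(dag, ann, rel, terms = NULL) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_map"),
            inherits(rel, "relevance_matrix"))
  tg <- dag$terms[lengths(ann$propagated[dag$terms]) > 0]
  if (!is.null(terms)) {
    check_term(dag, terms)
    tg <- intersect(tg, terms)
  }
  if (length(tg) < 2) abort("need at least two terms with annotated genes")

  dist <- gene_distance_matrix(rel, ann$gene_universe)
  nt <- length(tg)
  raw <- matrix(0, nt, nt, dimnames = list(tg, tg))
  for (i in seq_len(nt - 1)) {
    gi <- ann$propagated[[tg[i]]]
    for (j in seq.int(i + 1, nt)) {
      raw[i, j] <- raw[j, i] <-
        gene_set_distance(gi, ann$propagated[[tg[j]]], dist)
    }
  }
  norm <- normalize_distances(raw)
  bounds <- attr(norm, "bounds")
  attr(norm, "bounds") <- NULL

  structure(
    list(
      dag = dag, ann = ann, terms = tg, dist = dist,
      raw_d = raw, norm_d = norm, bounds = bounds,
      n_universe = length(ann$propagated[[dag$root]]),
      n_prop = setNames(lengths(ann$propagated[dag$terms]), dag$terms)
    ),
    class = "termsim_context"
  )
}

#' @export
print.termsim_context <- function(x, ...) {
  cat(
    "<termsim_context>  terms (T_G): ", length(x$terms),
    "  genes (|G|): ", x$n_universe,
    "  raw-D bounds: [", format(x$bounds[1], digits = 4), ", ",
    format(x$bounds[2], digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Similarity between two ontology terms
#'
#' Evaluates [term_similarity_score()] at every lowest common ancestor of
#' the pair and returns the highest score (a DAG pair can have several
#' lowest common ancestors). Symmetric in its term arguments.
#'
#' @param ctx a [termsim_context].
#' @param t1,t2 term identifiers with nonempty propagated gene sets.
#' @return similarity in `[0, 1]`.
#' @export
term_similarity <- function(ctx, t1, t2) {
  stopifnot(inherits(ctx, "termsim_context"))
  if (!t1 %in% ctx$terms || !t2 %in% ctx$terms) {
    abort(paste0(
      "similarity undefined: term(s) without annotated genes: ",
      paste(setdiff(c(t1, t2), ctx$terms), collapse = ", ")
    ))
  }
  d <- ctx$norm_d[t1, t2]
  n_g1 <- ctx$n_prop[[t1]]
  n_g2 <- ctx$n_prop[[t2]]
  scores <- vapply(
    lowest_common_ancestors(ctx$dag, t1, t2),
    function(p) {
      n_u <- length(path_constrained_genes(ctx$dag, ctx$ann, t1, t2, p))
      term_similarity_score(d, ctx$n_universe, n_g1, n_g2, ctx$n_prop[[p]], n_u)
    },
    numeric(1)
  )
  max(scores)
}

#' All pairwise term similarities
#'
#' @param ctx a [termsim_context].
#' @return symmetric numeric matrix over the context's usable terms.
#' @export
term_similarity_matrix <- function(ctx) {
  stopifnot(inherits(ctx, "termsim_context"))
  tg <- ctx$terms
  S <- matrix(0, length(tg), length(tg), dimnames = list(tg, tg))
  for (i in seq_along(tg)) {
    for (j in seq.int(i, length(tg))) {
      S[i, j] <- S[j, i] <- term_similarity(ctx, tg[i], tg[j])
    }
  }
  S
}

#' Pairwise term similarities as a tibble
#'
#' @param ctx a [termsim_context].
#' @param pairs optional data frame whose first two columns are term
#'   identifiers; defaults to all unordered pairs of the context's terms.
#' @return tibble with columns `term1`, `term2`, `similarity`.
#' @export
term_similarities <- function(ctx, pairs = NULL) {
  stopifnot(inherits(ctx, "termsim_context"))
  if (is.null(pairs)) {
    cmb <- utils::combn(ctx$terms, 2)
    pairs <- tibble(term1 = cmb[1, ], term2 = cmb[2, ])
  } else {
    pairs <- setNames(as_tibble(pairs)[, 1:2], c("term1", "term2"))
  }
  pairs$similarity <- purrr::map2_dbl(
    pairs$term1, pairs$term2,
    function(a, b) term_similarity(ctx, a, b)
  )
  pairs
}
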