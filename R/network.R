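#' Construct a co-functional network
#'
#' A weighted undirected gene network (YeastNet/AraNet style). Duplicate
#' edges keep the maximum weight, self-loops are dropped, and genes left
#' with no edge are removed — a zero-degree gene would produce a
#' non-stochastic column in the walk's transition matrix; such genes fall
#' back to the absent-gene distance of 1 downstream.
#'
#' @param edges data frame with columns `gene1`, `gene2`, `weight`
#'   (nonnegative numeric; extra columns ignored).
#' @return An object of class `cofunc_network`: list with `genes` (ordered
#'   identifiers) and `weights` (sparse symmetric matrix, zero diagonal).
#' @export
cofunctional_network <- function(edges) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 3) abort("network edge table needs >= 3 columns")
  edges <- setNames(edges[, 1:3], c("gene1", "gene2", "weight"))
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  if (!is.numeric(edges$weight) || anyNA(edges$weight)) {
    abort("edge weights must be numeric")
  }
  if (any(edges$weight < 0)) abort("negative edge weight in network")

  n_self <- sum(edges$gene1 == edges$gene2)
  if (n_self > 0) {
    inform(paste0("cofunctional_network: dropped ", n_self, " self-loop(s)"))
    edges <- edges[edges$gene1 != edges$gene2, ]
  }
  edges <- edges[edges$weight > 0, ]
  if (!nrow(edges)) abort("network has no usable edges")

  genes <- sort(unique(c(edges$gene1, edges$gene2)))
  i <- match(edges$gene1, genes)
  j <- match(edges$gene2, genes)
  # undirected: canonical order, duplicates keep the max weight
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  w <- tapply(edges$weight, key, max)
  lo <- as.integer(sub(" .*", "", names(w)))
  hi <- as.integer(sub(".* ", "", names(w)))
  W <- sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = c(w, w),
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes)
  )
  structure(list(genes = genes, weights = W), class = "cofunc_network")
}

#' @export
print.cofunc_network <- function(x, ...) {
  cat(
    "<cofunc_network>  genes: ", length(x$genes),
    "  edges: ", Matrix::nnzero(x$weights) / 2, "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a co-functional network from an edge-list file
#'
#' Reads a 3-column tab-separated edge list (`gene1 TAB gene2 TAB weight`;
#' `#` comment lines and extra columns ignored), the format YeastNet and
#' AraNet distribute.
#'
#' @param path path to the TSV file.
#' @return a [cofunctional_network].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read network file: ", path))
  edges <- readr::read_tsv(
    path,
    comment = "#", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!nrow(edges) || ncol(edges) < 3) abort(paste0("empty or malformed network file: ", path))
  w <- suppressWarnings(as.numeric(edges[[3]]))
  if (anyNA(w)) abort(paste0("non-numeric edge weight in ", path))
  cofunctional_network(tibble(gene1 = edges[[1]], gene2 = edges[[2]], weight = w))
}

#' Column-stochastic transition matrix
#'
#' Normalizes the weight matrix column-wise, `M'[i, j] = M[i, j] / sum_k
#' M[k, j]`, so each column is the outgoing transition distribution of the
#' random walk from gene `j`. Column-stochastic normalization guarantees
#' the resolvent `(I - c M')` is invertible for any continuation
#' probability `c < 1` and that relevance rows sum to one.
#'
#' @param network a [cofunctional_network].
#' @return sparse column-stochastic matrix with the network's gene
#'   dimnames.
#' @export
transition_matrix <- function(network) {
  stopifnot(inherits(network, "cofunc_network"))
  cs <- Matrix::colSums(network$weights)
  if (any(cs == 0)) {
    abort(paste0(
      "zero-degree gene(s) in network: ",
      paste(head(network$genes[cs == 0], 5), collapse = ", ")
    ))
  }
  M <- network$weights %*% Diagonal(x = 1 / cs)
  dimnames(M) <- list(network$genes, network$genes)
  M
}

new_relevance_matrix <- function(R, genes, continuation) {
  dimnames(R) <- list(genes, genes)
  structure(
    list(genes = genes, R = R, continuation = continuation),
    class = "relevance_matrix"
  )
}

#' @export
print.relevance_matrix <- function(x, ...) {
  cat(
    "<relevance_matrix>  genes: ", length(x$genes),
    "  continuation c: ", format(x$continuation), "\n",
    sep = ""
  )
  invisible(x)
}

check_continuation <- function(c) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0 || c >= 1) {
    abort("continuation probability `c` must lie strictly in (0, 1)")
  }
  c
}

#' Random walk with restart: closed form
#'
#' The walker at gene `i` moves to a neighbour with probability `c`
#' (continuation) and restarts at `i` with probability `1 - c`. Its
#' stationary distribution is `r_i = (1 - c) (I - c M')^{-1} e_i`; row `i`
#' of the relevance matrix `R` stores that distribution, so `R[i, j]` is
#' the probability that the walk started from gene `i` rests at gene `j`.
#' Every row sums to one.
#'
#' @param M transition matrix from [transition_matrix()].
#' @param c continuation probability in (0, 1); the restart probability is
#'   `1 - c`.
#' @return a `relevance_matrix` object (genes, dense matrix `R`,
#'   `continuation`).
#' @export
rwr_closed_form <- function(M, c = 0.7) {
  check_continuation(c)
  n <- nrow(M)
  A <- Diagonal(n) - c * M
  inv <- solve(A, Diagonal(n))
  R <- (1 - c) * Matrix::t(as.matrix(inv))
  new_relevance_matrix(as.matrix(R), colnames(M), c)
}

#' Random walk with restart: power iteration
#'
#' Iterates `r <- c M' r + (1 - c) e_i` simultaneously from every start
#' gene until the largest per-start L1 change drops below `tol`. Within
#' convergence it agrees with [rwr_closed_form()] entrywise (L1 distance at
#' most `tol / (1 - c)`); it is the solver of choice when the network is
#' too large to invert densely.
#'
#' @inheritParams rwr_closed_form
#' @param tol convergence threshold on the L1 change per start vector.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last residual.
#' @return a `relevance_matrix`.
#' @export
rwr_iterative <- function(M, c = 0.7, tol = 1e-10, max_iter = 10000L) {
  check_continuation(c)
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive")
  n <- nrow(M)
  E <- diag(n)
  X <- E                      # columns are the per-start distributions
  for (it in seq_len(max_iter)) {
    X_new <- as.matrix(c * (M %*% X)) + (1 - c) * E
    delta <- max(colSums(abs(X_new - X)))
    X <- X_new
    if (delta < tol) {
      return(new_relevance_matrix(t(X), colnames(M), c))
    }
  }
  abort(paste0(
    "random walk failed to converge in ", max_iter,
    " iterations (last L1 residual ", format(delta), ")"
  ))
}

#' Relevance matrix for a network
#'
#' Convenience wrapper choosing the solver: dense closed form up to
#' `closed_form_max` genes, power iteration above.
#'
#' @param network a [cofunctional_network].
#' @param restart restart probability in (0, 1); the walk continues with
#'   probability `c = 1 - restart`.
#' @param method `"auto"`, `"closed_form"` or `"iterative"`.
#' @param tol,max_iter iterative-solver controls.
#' @param closed_form_max largest network solved by dense inversion under
#'   `method = "auto"`.
#' @return a `relevance_matrix`.
#' @export
relevance_matrix <- function(network, restart = 0.3,
                             method = c("auto", "closed_form", "iterative"),
                             tol = 1e-10, max_iter = 10000L,
                             closed_form_max = 2000L) {
  method <- match.arg(method)
  c <- 1 - restart
  check_continuation(c)
  M <- transition_matrix(network)
  if (method == "auto") {
    method <- if (nrow(M) <= closed_form_max) "closed_form" else "iterative"
  }
  switch(method,
    closed_form = rwr_closed_form(M, c),
    iterative = rwr_iterative(M, c, tol = tol, max_iter = max_iter)
  )
}

#' Cache a relevance matrix as TSV
#'
#' Writes / reads the dense stationary-probability matrix with a header
#' row of gene identifiers, so expensive walks can be reused across runs.
#'
#' @param rel a `relevance_matrix`.
#' @param path file path.
#' @return `write_relevance` returns `path` invisibly; `read_relevance`
#'   returns a `relevance_matrix` (the continuation probability is stored
#'   in a `# continuation:` header comment).
#' @export
write_relevance <- function(rel, path) {
  stopifnot(inherits(rel, "relevance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# continuation: ", format(rel$continuation, digits = 17)), con)
  writeLines(paste(c("gene", rel$genes), collapse = "\t"), con)
  for (i in seq_along(rel$genes)) {
    writeLines(paste(
      c(rel$genes[i], format(rel$R[i, ], digits = 17)),
      collapse = "\t"
    ), con)
  }
  invisible(path)
}

#' @rdname write_relevance
#' @export
read_relevance <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read relevance cache: ", path))
  first <- readLines(path, n = 1)
  continuation <- as.numeric(sub("^# continuation:\\s*", "", first))
  x <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(
      gene = readr::col_character(), .default = readr::col_double()
    ), progress = FALSE
  )
  genes <- x$gene
  R <- as.matrix(x[, -1])
  new_relevance_matrix(R, genes, continuation)
}

#' Gene-to-gene distance from the relevance matrix
#'
#' The distance between two genes is one minus their relevance,
#' `d_ij = 1 - R_ij`, after symmetrizing `R` as `(R + R^T) / 2` (the walk
#' on a weighted graph is asymmetric in general while the gene-set distance
#' treats `d` as symmetric). Conventions: `d(g, g) = 0` always, and any
#' gene absent from the network is at distance 1 from every other gene.
#'
#' @param rel a `relevance_matrix`.
#' @param g1,g2 gene identifiers (need not be in the network).
#' @return numeric distance in `[0, 1]`.
#' @export
gene_distance <- function(rel, g1, g2) {
  stopifnot(inherits(rel, "relevance_matrix"))
  if (identical(g1, g2)) return(0)
  if (!(g1 %in% rel$genes) || !(g2 %in% rel$genes)) return(1)
  1 - (rel$R[g1, g2] + rel$R[g2, g1]) / 2
}

#' Dense symmetric distance matrix over a gene universe
#'
#' Applies the [gene_distance()] conventions to every pair of a gene
#' universe (typically the annotated genes, which may include genes missing
#' from the network).
#'
#' @inheritParams gene_distance
#' @param genes character vector of gene identifiers.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
gene_distance_matrix <- function(rel, genes) {
  stopifnot(inherits(rel, "relevance_matrix"))
  genes <- unique(genes)
  D <- matrix(1, length(genes), length(genes), dimnames = list(genes, genes))
  in_net <- intersect(genes, rel$genes)
  if (length(in_net)) {
    S <- (rel$R[in_net, in_net, drop = FALSE] +
      t(rel$R[in_net, in_net, drop = FALSE])) / 2
    D[in_net, in_net] <- 1 - S
  }
  diag(D) <- 0
  D
}
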