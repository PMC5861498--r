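# Shared in-code fixtures and independent oracles.

# root <- A <- B chain, is_a edges
chain_dag <- function() {
  ontology_dag(
    tibble::tibble(
      child = c("GO:0000002", "GO:0000003"),
      parent = c("GO:0000001", "GO:0000002"),
      relation = "is_a"
    )
  )
}

# two incomparable parents p1, p2 over both t1 and t2, under one root:
#   root <- p1, p2;  p1 <- t1, t2;  p2 <- t1, t2
diamond_dag <- function() {
  ontology_dag(
    tibble::tibble(
      child = c("p1", "p2", "t1", "t1", "t2", "t2"),
      parent = c("root", "root", "p1", "p2", "p1", "p2"),
      relation = "is_a"
    )
  )
}

# random layered DAG as an edge tibble; every non-root node picks 1-2
# parents among earlier nodes, so acyclicity and a single root hold by
# construction while the shape is irregular
random_dag_edges <- function(n_terms, seed) {
  withr::with_seed(seed, {
    terms <- sprintf("T%02d", seq_len(n_terms))
    child <- parent <- character()
    for (i in seq.int(2, n_terms)) {
      n_par <- sample(1:min(2, i - 1), 1)
      for (p in sample(terms[seq_len(i - 1)], n_par)) {
        child <- c(child, terms[i])
        parent <- c(parent, p)
      }
    }
    tibble::tibble(
      child = child, parent = parent,
      relation = sample(c("is_a", "part_of"), length(child), replace = TRUE)
    )
  })
}

# oracle: ancestor closure by naive repeated expansion over the edge table
brute_ancestors <- function(edges, t) {
  anc <- t
  repeat {
    more <- unique(c(anc, edges$parent[edges$child %in% anc]))
    if (length(more) == length(anc)) {
      return(sort(anc))
    }
    anc <- more
  }
}

brute_descendants <- function(edges, t) {
  desc <- t
  repeat {
    more <- unique(c(desc, edges$child[edges$parent %in% desc]))
    if (length(more) == length(desc)) {
      return(sort(desc))
    }
    desc <- more
  }
}

# oracle: LCAs = maximal elements of the ancestor-set intersection
brute_lcas <- function(edges, t1, t2) {
  common <- intersect(brute_ancestors(edges, t1), brute_ancestors(edges, t2))
  keep <- vapply(common, function(p) {
    !any(setdiff(common, p) %in% brute_descendants(edges, p))
  }, logical(1))
  sort(common[keep])
}

# oracle: gene-set distance by literal double loops over the formula
brute_gene_set_distance <- function(g1, g2, dmat) {
  a <- 0
  for (i in g1) {
    prod_ij <- 1
    for (j in g2) prod_ij <- prod_ij * dmat[i, j]
    a <- a + prod_ij
  }
  b <- 0
  for (i in g2) {
    prod_ij <- 1
    for (j in g1) prod_ij <- prod_ij * dmat[i, j]
    b <- b + prod_ij
  }
  (a + b) / (2 * length(union(g1, g2)) - a - b)
}

# oracle: literal selection + best-match enumeration
brute_genesim <- function(ti, tj, s, bg, thr = 1.6, select = TRUE) {
  pick <- function(t, cand) {
    if (!select) {
      return(cand)
    }
    k <- match(t, bg$term)
    if (bg$sigma[k] <= 0) {
      return(cand[which.max(s[t, cand])])
    }
    z <- (s[t, cand] - bg$mu[k]) / bg$sigma[k]
    high <- cand[z > thr]
    low <- cand[z < -thr]
    if (!length(high) && !length(low)) {
      return(cand[which.max(abs(z))])
    }
    if (length(high) >= length(low)) high else low
  }
  tot <- 0
  for (t in ti) tot <- tot + max(s[t, pick(t, tj)])
  for (t in tj) tot <- tot + max(s[t, pick(t, ti)])
  tot / (length(ti) + length(tj))
}

# random symmetric distance matrix in [0,1] with zero diagonal
random_distance_matrix <- function(genes, seed) {
  withr::with_seed(seed, {
    n <- length(genes)
    d <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    diag(d) <- 0
    d
  })
}

# random connected-ish network over n genes (every gene gets >= 1 edge)
random_network <- function(n, seed, p = 0.3) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n))
    cmb <- utils::combn(genes, 2)
    keep <- runif(ncol(cmb)) < p
    # spanning path guarantees no isolated gene
    edges <- tibble::tibble(
      gene1 = c(cmb[1, keep], genes[-n]),
      gene2 = c(cmb[2, keep], genes[-1]),
      weight = runif(sum(keep) + n - 1, 0.2, 1)
    )
    cofunctional_network(edges)
  })
}

two_node_network <- function() {
  cofunctional_network(
    tibble::tibble(gene1 = "a", gene2 = "b", weight = 1)
  )
}

# small aligned fixture spec used across tests (kept cheap)
small_spec <- function(seed = 1, ...) {
  fixture_spec(
    seed = seed, n_terms = 15, branching = 4, n_genes = 30,
    n_modules = 3, ...
  )
}

# tiny ready-made model on a small fixture, memoised per test file run
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- suppressMessages(make_fixture(small_spec()))
      cache <<- list(
        fx = fx,
        model = suppressMessages(netsim2_model(fx$dag, fx$ann, fx$network))
      )
    }
    cache
  }
})
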