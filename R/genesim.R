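#' Per-term background statistics of term similarity
#'
#' For each term `t`, the similarities `S(t, t')` to every other usable
#' term (or to a seeded uniform sample of them) form the background
#' distribution against which a candidate pair is judged: its mean `mu_t`
#' and population standard deviation `sigma_t` define the standard score
#' of [z_score()]. A zero standard deviation is retained and flagged; the
#' selection rule falls back to the best raw similarity in that degenerate
#' case.
#'
#' @param s term-similarity matrix from [term_similarity_matrix()].
#' @param sample_size optional cap on the background size per term; when
#'   smaller than the full background a uniform sample without replacement
#'   is drawn.
#' @param seed optional integer seed controlling the background sampling.
#' @return tibble with columns `term`, `mu`, `sigma`, `n` (background size
#'   used).
#' @export
term_backgrounds <- function(s, sample_size = NULL, seed = NULL) {
  terms <- rownames(s)
  if (length(terms) < 3) abort("background requires at least 2 other terms per term")
  compute <- function() {
    purrr::map_dfr(terms, function(t) {
      others <- setdiff(terms, t)
      if (!is.null(sample_size) && sample_size < length(others)) {
        others <- sample(others, sample_size)
      }
      x <- s[t, others]
      tibble(
        term = t,
        mu = mean(x),
        sigma = sqrt(mean((x - mean(x))^2)),
        n = length(x)
      )
    })
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

#' Standard score of a term-pair similarity
#'
#' `z = (S - mu_t) / sigma_t` against the background of term `t`. A pair is
#' called significant when `|z|` exceeds the threshold 1.6 (two-sided
#' p < 0.05 under a normal background).
#'
#' @param s similarity value `S(t, t')`.
#' @param mu,sigma background mean and standard deviation of term `t`.
#' @return numeric standard score.
#' @export
z_score <- function(s, mu, sigma) {
  if (any(sigma <= 0)) abort("degenerate background: sigma must be positive")
  (s - mu) / sigma
}

#' Select the significant term set for one term
#'
#' Given a term `t` and the candidate annotation set of the other gene,
#' standard scores split the candidates into a high set (`z > threshold`)
#' and a low set (`z < -threshold`); the larger of the two is returned
#' (the high set on a tie). If neither set is populated the single
#' candidate with the largest `|z|` is returned, so every term finds at
#' least one partner; with a degenerate (zero-variance) background the
#' candidate with the highest raw similarity is used instead.
#'
#' @param t term identifier.
#' @param candidates nonempty character vector of candidate terms.
#' @param s term-similarity matrix.
#' @param bg background tibble from [term_backgrounds()].
#' @param z_threshold significance cutoff on `|z|` (default 1.6).
#' @return character vector, a subset of `candidates`.
#' @export
select_significant_set <- function(t, candidates, s, bg, z_threshold = 1.6) {
  if (!length(candidates)) abort("candidate set must be nonempty")
  k <- match(t, bg$term)
  if (is.na(k)) abort(paste0("no background for term ", t))
  sv <- s[t, candidates]
  if (bg$sigma[k] <= 0) {
    return(candidates[which.max(sv)])
  }
  z <- (sv - bg$mu[k]) / bg$sigma[k]
  high <- candidates[z > z_threshold]
  low <- candidates[z < -z_threshold]
  if (!length(high) && !length(low)) {
    return(candidates[which.max(abs(z))])
  }
  if (length(high) >= length(low)) high else low
}

# numeric-only best-match of the selected set; mirrors select_significant_set
best_selected_match <- function(sv, mu_t, sigma_t, z_threshold, select) {
  if (!select || sigma_t <= 0) {
    return(max(sv))
  }
  z <- (sv - mu_t) / sigma_t
  nh <- sum(z > z_threshold)
  nl <- sum(z < -z_threshold)
  if (nh == 0 && nl == 0) {
    return(sv[which.max(abs(z))])
  }
  if (nh >= nl) max(sv[z > z_threshold]) else max(sv[z < -z_threshold])
}

genesim_value <- function(ti, tj, s, mu, sigma, z_threshold, select) {
  acc <- 0
  for (t in ti) {
    acc <- acc + best_selected_match(s[t, tj], mu[[t]], sigma[[t]], z_threshold, select)
  }
  for (t in tj) {
    acc <- acc + best_selected_match(s[t, ti], mu[[t]], sigma[[t]], z_threshold, select)
  }
  acc / (length(ti) + length(tj))
}

#' Similarity between two genes
#'
#' Aggregates term similarities over the two genes' direct annotation sets
#' `T_i`, `T_j`. For each term `t` of one gene, a significant subset `T'`
#' of the other gene's terms is selected by [select_significant_set()] and
#' the best match `max S(t, T')` taken; the gene similarity is the
#' two-direction average
#' \deqn{GeneSim = \frac{\sum_{t \in T_i} Sim(t, T'_j) +
#'   \sum_{t \in T_j} Sim(t, T'_i)}{|T_i| + |T_j|}}
#' With `select = FALSE` the selection step is skipped (`T'` is the full
#' annotation set) and the formula reduces to the classic best-match
#' average, the aggregation the measure's direct-link-only predecessor
#' uses.
#'
#' @param g1,g2 gene identifiers with at least one direct annotation among
#'   the usable terms.
#' @param ann an [annotation_map] (direct annotations are used; propagated
#'   closures would drown specific terms in their ancestors).
#' @param s term-similarity matrix.
#' @param bg background tibble from [term_backgrounds()].
#' @param z_threshold significance cutoff on `|z|`.
#' @param select logical; use significant-set selection (default) or the
#'   full candidate set.
#' @return An object of class `gene_pair_result`: list with `gene1`,
#'   `gene2`, `genesim`, and per-direction tibbles `matches` (term,
#'   selected set size, best-match similarity).
#' @export
gene_similarity <- function(g1, g2, ann, s, bg, z_threshold = 1.6, select = TRUE) {
  terms_of <- function(g) {
    t <- intersect(ann$direct[[g]] %||% character(), rownames(s))
    if (!length(t)) abort(paste0("gene ", g, " has no usable annotation"))
    t
  }
  ti <- terms_of(g1)
  tj <- terms_of(g2)
  one_direction <- function(from, to) {
    purrr::map_dfr(from, function(t) {
      sel <- if (select) select_significant_set(t, to, s, bg, z_threshold) else to
      tibble(term = t, n_selected = length(sel), best_match = max(s[t, sel]))
    })
  }
  mi <- one_direction(ti, tj)
  mj <- one_direction(tj, ti)
  structure(
    list(
      gene1 = g1, gene2 = g2,
      genesim = (sum(mi$best_match) + sum(mj$best_match)) / (length(ti) + length(tj)),
      matches = list(forward = mi, reverse = mj)
    ),
    class = "gene_pair_result"
  )
}

#' @export
print.gene_pair_result <- function(x, ...) {
  cat(
    "<gene_pair_result>  ", x$gene1, " ~ ", x$gene2,
    "  GeneSim = ", format(x$genesim, digits = 5), "\n",
    sep = ""
  )
  invisible(x)
}

#' Gene similarities for a table of pairs
#'
#' @param pairs data frame whose first two columns are gene identifiers.
#' @inheritParams gene_similarity
#' @return tibble with columns `gene1`, `gene2`, `genesim`, `n_terms_1`,
#'   `n_terms_2`.
#' @export
gene_similarities <- function(pairs, ann, s, bg, z_threshold = 1.6, select = TRUE) {
  pairs <- setNames(as_tibble(pairs)[, 1:2], c("gene1", "gene2"))
  mu <- setNames(bg$mu, bg$term)
  sigma <- setNames(bg$sigma, bg$term)
  terms_of <- function(g) intersect(ann$direct[[g]] %||% character(), rownames(s))
  tsets <- lapply(setNames(nm = unique(c(pairs$gene1, pairs$gene2))), terms_of)
  empty <- names(tsets)[lengths(tsets) == 0]
  if (length(empty)) {
    abort(paste0("gene(s) without usable annotation: ", paste(head(empty, 5), collapse = ", ")))
  }
  pairs$genesim <- purrr::map2_dbl(pairs$gene1, pairs$gene2, function(a, b) {
    genesim_value(tsets[[a]], tsets[[b]], s, mu, sigma, z_threshold, select)
  })
  pairs$n_terms_1 <- lengths(tsets[pairs$gene1])
  pairs$n_terms_2 <- lengths(tsets[pairs$gene2])
  pairs
}

#' Dense gene-similarity matrix
#'
#' All pairwise gene similarities over a gene set; genes without usable
#' annotations yield `NA` rows/columns (callers such as the LFC benchmark
#' skip and count them).
#'
#' @param genes character vector of gene identifiers.
#' @inheritParams gene_similarity
#' @return symmetric numeric matrix (diagonal is the self-similarity).
#' @export
gene_similarity_matrix <- function(genes, ann, s, bg, z_threshold = 1.6, select = TRUE) {
  genes <- unique(genes)
  tsets <- lapply(
    setNames(nm = genes),
    function(g) intersect(ann$direct[[g]] %||% character(), rownames(s))
  )
  mu <- setNames(bg$mu, bg$term)
  sigma <- setNames(bg$sigma, bg$term)
  G <- matrix(NA_real_, length(genes), length(genes), dimnames = list(genes, genes))
  ok <- genes[lengths(tsets) > 0]
  for (i in seq_along(ok)) {
    for (j in seq.int(i, length(ok))) {
      G[ok[i], ok[j]] <- G[ok[j], ok[i]] <- genesim_value(
        tsets[[ok[i]]], tsets[[ok[j]]], s, mu, sigma, z_threshold, select
      )
    }
  }
  G
}
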