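# hand-built similarity matrix over named terms, for selection tests
toy_s <- function(values) {
  n <- length(values)
  terms <- sprintf("t%02d", seq_len(n))
  s <- matrix(0, n, n, dimnames = list(terms, terms))
  s[1, ] <- values
  s[, 1] <- values
  s
}

test_that("background statistics use the population standard deviation", {
  s <- matrix(c(
    0, 0.2, 0.4,
    0.2, 0, 0.9,
    0.4, 0.9, 0
  ), 3, byrow = TRUE, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  bg <- term_backgrounds(s)
  # two-point background {0.2, 0.4}: mu 0.3, population sigma 0.1
  expect_equal(bg$mu[bg$term == "a"], 0.3)
  expect_equal(bg$sigma[bg$term == "a"], 0.1)
  expect_equal(bg$n, rep(2L, 3))
})

test_that("backgrounds match an independent mean/sd oracle on a 50-term matrix", {
  n <- 50
  terms <- sprintf("t%02d", 1:n)
  s <- withr::with_seed(2, {
    m <- matrix(runif(n * n), n, n, dimnames = list(terms, terms))
    (m + t(m)) / 2
  })
  bg <- term_backgrounds(s)
  for (t in sample(terms, 8)) {
    x <- s[t, setdiff(terms, t)]
    mu <- sum(x) / length(x)
    expect_equal(bg$mu[bg$term == t], mu, tolerance = 1e-12)
    expect_equal(
      bg$sigma[bg$term == t],
      sqrt(sum((x - mu)^2) / length(x)),
      tolerance = 1e-12
    )
  }
  # sampled background is seeded and reproducible
  b1 <- term_backgrounds(s, sample_size = 10, seed = 7)
  b2 <- term_backgrounds(s, sample_size = 10, seed = 7)
  expect_equal(b1, b2)
  expect_equal(b1$n, rep(10L, n))
})

test_that("z-scores behave as standard scores and reject sigma zero", {
  expect_equal(z_score(0.3, 0.3, 0.1), 0)
  expect_equal(z_score(0.4, 0.3, 0.1), 1)
  expect_equal(z_score(0.5, 0.3, 0.1), 2)
  expect_gt(abs(z_score(0.5, 0.3, 0.1)), 1.6) # significant pair
  expect_error(z_score(0.5, 0.3, 0), "degenerate")
})

test_that("significant-set selection follows the size rule with fallbacks", {
  # background mu=0, sigma=1 so S values ARE the z-scores
  bg1 <- tibble::tibble(term = "t01", mu = 0, sigma = 1, n = 10)

  s <- toy_s(c(0, 2.0, 1.8, 1.9))
  expect_setequal(
    select_significant_set("t01", c("t02", "t03", "t04"), s, bg1),
    c("t02", "t03", "t04")
  )

  s2 <- toy_s(c(0, 2.0, -1.8, -1.9))
  expect_setequal(
    select_significant_set("t01", c("t02", "t03", "t04"), s2, bg1),
    c("t03", "t04")
  )

  # all |z| < 1.6: singleton with the largest |z|
  s3 <- toy_s(c(0, 0.5, -1.2, 0.9))
  expect_equal(
    select_significant_set("t01", c("t02", "t03", "t04"), s3, bg1),
    "t03"
  )

  # tie with both sets nonempty prefers the high set
  s4 <- toy_s(c(0, 2.0, -2.0))
  expect_equal(
    select_significant_set("t01", c("t02", "t03"), s4, bg1),
    "t02"
  )

  # degenerate background: best raw similarity
  bg0 <- tibble::tibble(term = "t01", mu = 0.5, sigma = 0, n = 10)
  expect_equal(
    select_significant_set("t01", c("t02", "t03", "t04"), s3, bg0),
    "t04"
  )
})

test_that("selection matches brute-force enumeration on random candidate sets", {
  n <- 30
  terms <- sprintf("t%02d", 1:n)
  s <- withr::with_seed(10, {
    m <- matrix(runif(n * n), n, n, dimnames = list(terms, terms))
    (m + t(m)) / 2
  })
  bg <- term_backgrounds(s)
  for (seed in 1:50) {
    pick <- withr::with_seed(seed + 300, {
      list(t = sample(terms, 1), cand = sample(terms, sample(2:10, 1)))
    })
    got <- select_significant_set(pick$t, pick$cand, s, bg)
    k <- match(pick$t, bg$term)
    z <- (s[pick$t, pick$cand] - bg$mu[k]) / bg$sigma[k]
    high <- pick$cand[z > 1.6]
    low <- pick$cand[z < -1.6]
    want <- if (!length(high) && !length(low)) {
      pick$cand[which.max(abs(z))]
    } else if (length(high) >= length(low)) high else low
    expect_equal(got, want)
  }
})

test_that("gene similarity: singleton pairs reduce to the term similarity", {
  dag <- chain_dag()
  ann <- annotation_map(dag, list(ga = "GO:0000002", gb = "GO:0000003"))
  n <- 3
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003")
  s <- matrix(c(
    1, .2, .1,
    .2, 1, .6,
    .1, .6, 1
  ), n, byrow = TRUE, dimnames = list(terms, terms))
  bg <- term_backgrounds(s)
  res <- gene_similarity("ga", "gb", ann, s, bg)
  expect_equal(res$genesim, s["GO:0000002", "GO:0000003"])
  # self-comparison with equal term sets is the single-direction mean
  res_self <- gene_similarity("ga", "ga", ann, s, bg)
  expect_equal(res_self$genesim, 1)
  expect_error(gene_similarity("ga", "nope", ann, s, bg), "nope")
})

test_that("gene similarity equals the exhaustive oracle and is symmetric", {
  n <- 20
  terms <- sprintf("t%02d", 1:n)
  s <- withr::with_seed(21, {
    m <- matrix(runif(n * n), n, n, dimnames = list(terms, terms))
    (m + t(m)) / 2
  })
  bg <- term_backgrounds(s)
  genes <- sprintf("g%03d", 1:40)
  direct <- withr::with_seed(22, {
    lapply(setNames(nm = genes), function(g) sample(terms, sample(1:4, 1)))
  })
  dag <- ontology_dag(
    tibble::tibble(child = terms[-1], parent = terms[1], relation = "is_a")
  )
  ann <- annotation_map(dag, direct)
  pairs <- withr::with_seed(23, replicate(100, sample(genes, 2)))
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]
    g2 <- pairs[2, k]
    v12 <- gene_similarity(g1, g2, ann, s, bg)$genesim
    v21 <- gene_similarity(g2, g1, ann, s, bg)$genesim
    expect_equal(v12, v21, tolerance = 1e-12)
    expect_equal(v12, brute_genesim(direct[[g1]], direct[[g2]], s, bg),
      tolerance = 1e-12
    )
    # best-match dominance: an average of maxima cannot exceed the global max
    all_terms <- union(direct[[g1]], direct[[g2]])
    expect_lte(v12, max(s[direct[[g1]], direct[[g2]]]) + 1e-12)
    expect_lte(v12, max(s[all_terms, all_terms]) + 1e-12)
    # invariance to term ordering within the annotation sets
    expect_equal(
      brute_genesim(rev(direct[[g1]]), rev(direct[[g2]]), s, bg),
      v12,
      tolerance = 1e-12
    )
  }
})

test_that("selection disabled reduces to the best-match average", {
  n <- 10
  terms <- sprintf("t%02d", 1:n)
  s <- withr::with_seed(31, {
    m <- matrix(runif(n * n), n, n, dimnames = list(terms, terms))
    (m + t(m)) / 2
  })
  bg <- term_backgrounds(s)
  dag <- ontology_dag(
    tibble::tibble(child = terms[-1], parent = terms[1], relation = "is_a")
  )
  ti <- c("t02", "t03", "t04")
  tj <- c("t05", "t06")
  ann <- annotation_map(dag, list(ga = ti, gb = tj))
  got <- gene_similarity("ga", "gb", ann, s, bg, select = FALSE)$genesim
  bma <- (sum(apply(s[ti, tj, drop = FALSE], 1, max)) +
    sum(apply(s[tj, ti, drop = FALSE], 1, max))) / (length(ti) + length(tj))
  expect_equal(got, bma, tolerance = 1e-12)
})

test_that("tibble and matrix front ends agree with the scalar computation", {
  sm <- small_model()
  m <- sm$model
  genes <- withr::with_seed(12, sample(m$ann$gene_universe, 8))
  tab <- gene_similarities(
    tibble::tibble(gene1 = genes[1:4], gene2 = genes[5:8]),
    m$ann, m$s, m$bg
  )
  mat <- gene_similarity_matrix(genes, m$ann, m$s, m$bg)
  expect_equal(mat, t(mat))
  for (k in 1:4) {
    scalar <- gene_similarity(genes[k], genes[k + 4], m$ann, m$s, m$bg)$genesim
    expect_equal(tab$genesim[k], scalar, tolerance = 1e-12)
    expect_equal(mat[genes[k], genes[k + 4]], scalar, tolerance = 1e-12)
  }
})
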