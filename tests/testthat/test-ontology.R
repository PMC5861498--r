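obo_fixture <- function(extra = character()) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: A",
    "namespace: molecular_function",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: B",
    "namespace: molecular_function",
    "is_a: GO:0000002 ! A",
    extra,
    ""
  ), path)
  path
}

test_that("read_obo parses a minimal chain and keeps only is_a/part_of edges", {
  dag <- read_obo(obo_fixture(), "MF")
  expect_s3_class(dag, "ontology_dag")
  expect_length(dag$terms, 3)
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag$root, "GO:0000001")

  # a regulates relationship must not survive parsing
  dag2 <- read_obo(obo_fixture("relationship: regulates GO:0000001"), "MF")
  expect_equal(nrow(dag2$edges), 2)

  # part_of is kept and labeled
  dag3 <- read_obo(obo_fixture("relationship: part_of GO:0000001"), "MF")
  expect_equal(sort(unique(dag3$edges$relation)), c("is_a", "part_of"))

  # obsolete terms are dropped
  path <- obo_fixture(c(
    "", "[Term]", "id: GO:0000009", "namespace: molecular_function",
    "is_a: GO:0000001", "is_obsolete: true"
  ))
  expect_length(read_obo(path, "MF")$terms, 3)
})

test_that("cyclic ontologies are rejected with a named cycle member", {
  edges <- tibble::tibble(
    child = c("A", "B", "A"), parent = c("B", "A", "R"), relation = "is_a"
  )
  expect_error(ontology_dag(edges), "cycle")
  expect_error(
    ontology_dag(tibble::tibble(child = "A", parent = "A", relation = "is_a")),
    "cycle"
  )
})

test_that("multi-rooted namespace slices and unknown relations are rejected", {
  two_roots <- tibble::tibble(
    child = c("a", "b"), parent = c("r1", "r2"), relation = "is_a"
  )
  expect_error(ontology_dag(two_roots), "one root")
  expect_error(
    ontology_dag(tibble::tibble(child = "a", parent = "r", relation = "regulates")),
    "unsupported"
  )
})

test_that("read_gaf builds the direct map, skipping NOT and unknown terms", {
  dag <- chain_dag()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "g1", "g1", "", "GO:0000002", "REF", "IEA", "", "F", sep = "\t"),
    paste("DB", "g2", "g2", "", "GO:0000003", "REF", "IEA", "", "F", sep = "\t"),
    paste("DB", "g3", "g3", "NOT", "GO:0000002", "REF", "IEA", "", "F", sep = "\t"),
    paste("DB", "g4", "g4", "", "GO:9999999", "REF", "IEA", "", "F", sep = "\t")
  ), gaf)
  ann <- suppressMessages(read_gaf(gaf, dag))
  expect_setequal(names(ann$direct), c("g1", "g2"))
  skipped <- attr(ann, "skipped")
  expect_equal(unname(skipped[["not_qualified"]]), 1L)
  expect_equal(unname(skipped[["unknown_term"]]), 1L)

  # all rows unusable -> error
  gaf2 <- withr::local_tempfile(fileext = ".gaf")
  writeLines(paste("DB", "g1", "g1", "NOT", "GO:0000002", sep = "\t"), gaf2)
  expect_error(suppressMessages(read_gaf(gaf2, dag)), "no usable")
})

test_that("evidence allow-list filters annotation rows", {
  dag <- chain_dag()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    paste("DB", "g1", "g1", "", "GO:0000002", "REF", "EXP", "", "F", sep = "\t"),
    paste("DB", "g2", "g2", "", "GO:0000003", "REF", "IEA", "", "F", sep = "\t")
  ), gaf)
  ann <- suppressMessages(read_gaf(gaf, dag, evidence = "EXP"))
  expect_equal(names(ann$direct), "g1")
})

test_that("propagation follows the true-path rule on chains and diamonds", {
  dag <- chain_dag()
  prop <- propagate_annotations(dag, list(g = "GO:0000003"))
  expect_equal(prop[["GO:0000002"]], "g")
  expect_equal(prop[["GO:0000001"]], "g")

  # a root-only annotation stays at the root
  prop2 <- propagate_annotations(dag, list(g = "GO:0000001"))
  expect_equal(prop2[["GO:0000001"]], "g")
  expect_length(prop2[["GO:0000003"]], 0)

  # diamond: apex collects both branches (oracle: brute-force closure)
  dd <- diamond_dag()
  direct <- list(ga = "t1", gb = "t2")
  prop3 <- propagate_annotations(dd, direct)
  for (t in dd$terms) {
    expected <- sort(unique(unlist(
      lapply(names(direct), function(g) {
        if (any(direct[[g]] %in% brute_descendants(dd$edges, t))) g
      })
    )))
    expect_equal(prop3[[t]], expected %||% character())
  }
})

test_that("propagated gene sets are monotone along every edge", {
  for (seed in 1:5) {
    edges <- random_dag_edges(30, seed)
    dag <- ontology_dag(edges)
    genes <- sprintf("g%02d", 1:20)
    direct <- withr::with_seed(seed, {
      lapply(setNames(nm = genes), function(g) sample(dag$terms, sample(1:3, 1)))
    })
    ann <- annotation_map(dag, direct)
    for (k in seq_len(nrow(dag$edges))) {
      expect_true(all(
        ann$propagated[[dag$edges$child[k]]] %in%
          ann$propagated[[dag$edges$parent[k]]]
      ))
    }
    expect_setequal(ann$propagated[[dag$root]], genes)
  }
})

test_that("ancestor closures match the brute-force expansion oracle", {
  edges <- random_dag_edges(40, 11)
  dag <- ontology_dag(edges)
  for (t in sample(dag$terms, 10)) {
    expect_equal(term_ancestors(dag, t), brute_ancestors(edges, t))
    expect_equal(term_descendants(dag, t), brute_descendants(edges, t))
  }
  expect_error(term_ancestors(dag, "nope"), "unknown term")
})

test_that("lowest common ancestors: identity, chain, diamond, random oracle", {
  dag <- chain_dag()
  expect_equal(lowest_common_ancestors(dag, "GO:0000002", "GO:0000002"), "GO:0000002")
  expect_equal(lowest_common_ancestors(dag, "GO:0000002", "GO:0000003"), "GO:0000002")

  dd <- diamond_dag()
  expect_setequal(lowest_common_ancestors(dd, "t1", "t2"), c("p1", "p2"))

  for (seed in 1:10) {
    edges <- random_dag_edges(25, seed + 100)
    dag <- ontology_dag(edges)
    pick <- withr::with_seed(seed, sample(dag$terms, 2))
    got <- sort(lowest_common_ancestors(dag, pick[1], pick[2]))
    expect_equal(got, brute_lcas(edges, pick[1], pick[2]))
    expect_gt(length(got), 0)
  }
})

test_that("path-constrained gene sets follow the path rule and sandwich bound", {
  dd <- diamond_dag()
  direct <- list(ga = "t1", gb = "t2", gp = "p1", gr = "root", gs = "p2")
  ann <- annotation_map(dd, direct)

  # t1, t2 direct children of p1: U = G1 u G2 u direct(p1)
  u <- path_constrained_genes(dd, ann, "t1", "t2", "p1")
  expect_setequal(u, c("ga", "gb", "gp"))

  # genes hanging off p2 (a sibling branch w.r.t. p1) are excluded
  expect_false("gs" %in% u)

  # root as ancestor picks up root's own direct genes and both paths
  u_root <- path_constrained_genes(dd, ann, "t1", "t2", "root")
  expect_setequal(u_root, c("ga", "gb", "gp", "gr", "gs"))

  # non-ancestor precondition
  expect_error(path_constrained_genes(dd, ann, "t1", "t2", "t1"), "not a common ancestor")

  # sandwich invariant on random DAGs: G1 u G2 <= U <= G_p
  for (seed in 1:5) {
    edges <- random_dag_edges(25, seed + 40)
    dag <- ontology_dag(edges)
    genes <- sprintf("g%02d", 1:15)
    direct <- withr::with_seed(seed, {
      lapply(setNames(nm = genes), function(g) sample(dag$terms, 2))
    })
    ann <- annotation_map(dag, direct)
    pick <- withr::with_seed(seed + 1, sample(dag$terms, 2))
    for (p in lowest_common_ancestors(dag, pick[1], pick[2])) {
      u <- path_constrained_genes(dag, ann, pick[1], pick[2], p)
      g12 <- union(ann$propagated[[pick[1]]], ann$propagated[[pick[2]]])
      expect_true(all(g12 %in% u))
      expect_true(all(u %in% ann$propagated[[p]]))
    }
  }
})
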