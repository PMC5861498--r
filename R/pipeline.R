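#' Fit the network-aware semantic-similarity model
#'
#' One-call pipeline: computes the random-walk relevance matrix of the
#' co-functional network, the gene distance matrix, the raw and normalized
#' gene-set distances of every usable term pair, the full term-similarity
#' matrix, and the per-term background statistics that drive
#' significant-pair selection. The returned model is the single object all
#' downstream similarity queries and the EC benchmark take.
#'
#' Inputs may be given as file paths (OBO / GAF / edge-list TSV) or as
#' already-parsed objects.
#'
#' @param ontology an [ontology_dag] or path to an OBO file.
#' @param annotations an [annotation_map] or path to a GAF file.
#' @param network a [cofunctional_network] or path to an edge-list TSV.
#' @param namespace ontology namespace used when reading an OBO path.
#' @param restart restart probability of the walk (default 0.3; the walk
#'   continues with probability `c = 0.7`).
#' @param z_threshold significance cutoff on `|z|` for term-pair selection
#'   (default 1.6, i.e. two-sided p < 0.05 under a normal background).
#' @param bg_sample background sample size per term (default 2000; the
#'   full background is used whenever it is smaller).
#' @param seed integer seed for background sampling.
#' @param ... passed to [relevance_matrix()].
#' @return An object of class `netsim2_model`: list with `dag`, `ann`,
#'   `network`, `rel`, `ctx` ([termsim_context]), `s` (term-similarity
#'   matrix), `bg` (term backgrounds), and the parameters.
#' @export
netsim2_model <- function(ontology, annotations, network,
                          namespace = "molecular_function",
                          restart = 0.3, z_threshold = 1.6,
                          bg_sample = 2000L, seed = 1L, ...) {
  dag <- if (inherits(ontology, "ontology_dag")) {
    ontology
  } else {
    read_obo(ontology, namespace)
  }
  ann <- if (inherits(annotations, "annotation_map")) {
    annotations
  } else {
    read_gaf(annotations, dag)
  }
  net <- if (inherits(network, "cofunc_network")) network else read_network(network)

  rel <- relevance_matrix(net, restart = restart, ...)
  ctx <- termsim_context(dag, ann, rel)
  s <- term_similarity_matrix(ctx)
  bg <- term_backgrounds(s, sample_size = bg_sample, seed = seed)

  structure(
    list(
      dag = dag, ann = ann, network = net, rel = rel, ctx = ctx,
      s = s, bg = bg,
      params = list(
        restart = restart, z_threshold = z_threshold,
        bg_sample = bg_sample, seed = seed
      )
    ),
    class = "netsim2_model"
  )
}

#' @export
print.netsim2_model <- function(x, ...) {
  cat("<netsim2_model>\n")
  cat("  terms (T_G): ", length(x$ctx$terms),
    "   annotated genes (|G|): ", x$ctx$n_universe,
    "   network genes: ", length(x$network$genes), "\n",
    sep = ""
  )
  cat("  restart: ", x$params$restart,
    "   z threshold: ", x$params$z_threshold, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname netsim2_model
#' @param x,object a `netsim2_model`.
#' @method tidy netsim2_model
#' @export
tidy.netsim2_model <- function(x, ...) {
  x$bg
}

#' @rdname netsim2_model
#' @method glance netsim2_model
#' @export
glance.netsim2_model <- function(x, ...) {
  tibble(
    n_terms = length(x$ctx$terms),
    n_genes = x$ctx$n_universe,
    n_network_genes = length(x$network$genes),
    restart = x$params$restart,
    z_threshold = x$params$z_threshold,
    raw_d_min = x$ctx$bounds[1],
    raw_d_max = x$ctx$bounds[2]
  )
}

#' @rdname netsim2_model
#' @method autoplot netsim2_model
#' @export
autoplot.netsim2_model <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$s, responseName = "similarity"))
  names(df)[1:2] <- c("term1", "term2")
  ggplot2::ggplot(df, ggplot2::aes(term1, term2, fill = similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      title = "Term-pair semantic similarity",
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Gene similarities from a fitted model
#'
#' Tidy front end to [gene_similarities()]: takes the fitted model and a
#' two-column table of gene pairs, returns the table with the similarity
#' and annotation counts appended.
#'
#' @param model a [netsim2_model].
#' @param pairs data frame whose first two columns are gene identifiers;
#'   defaults to all unordered pairs of annotated genes.
#' @param select use significant-pair selection (default) or plain
#'   best-match averaging.
#' @return tibble `gene1`, `gene2`, `genesim`, `n_terms_1`, `n_terms_2`.
#' @export
netsim2_gene_similarity <- function(model, pairs = NULL, select = TRUE) {
  stopifnot(inherits(model, "netsim2_model"))
  if (is.null(pairs)) {
    cmb <- utils::combn(model$ann$gene_universe, 2)
    pairs <- tibble(gene1 = cmb[1, ], gene2 = cmb[2, ])
  }
  gene_similarities(pairs, model$ann, model$s, model$bg,
    z_threshold = model$params$z_threshold, select = select
  )
}

#' EC-group LFC benchmark from a fitted model
#'
#' Computes the gene-similarity matrix over the benchmark's genes and runs
#' the logged-fold-change evaluation.
#'
#' @param model a [netsim2_model].
#' @param groups an [ec_groups] object or path to a two-column TSV.
#' @param c_smooth Laplacian smoothing constant of the log-ratio.
#' @param cap reported upper bound on LFC scores.
#' @param select use significant-pair selection (default).
#' @return an [lfc_report] tibble.
#' @export
netsim2_lfc <- function(model, groups, c_smooth = 0.001, cap = 5, select = TRUE) {
  stopifnot(inherits(model, "netsim2_model"))
  if (!inherits(groups, "ec_groups")) groups <- read_ec_groups(groups)
  genes <- unique(unlist(unclass(groups), use.names = FALSE))
  sim <- gene_similarity_matrix(genes, model$ann, model$s, model$bg,
    z_threshold = model$params$z_threshold, select = select
  )
  lfc_report(groups, sim, c_smooth = c_smooth, cap = cap)
}
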