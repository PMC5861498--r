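#' Enzyme Commission gene groups
#'
#' Groups genes by full four-field EC number, the benchmark's operating
#' assumption being that genes sharing a complete EC number perform the
#' same function. Partial EC numbers (any `-` field) are dropped, as are
#' groups with fewer than two genes — the within-group comparison needs a
#' nonempty "group without `g`" set.
#'
#' @param x either a named list (EC number -> character vector of genes) or
#'   a data frame whose first two columns are gene and EC number.
#' @return An object of class `ec_groups`: named list EC -> sorted gene
#'   set.
#' @export
ec_groups <- function(x) {
  if (is.data.frame(x)) {
    x <- setNames(as_tibble(x)[, 1:2], c("gene", "ec"))
    x <- split(as.character(x$gene), as.character(x$ec))
  }
  if (!length(x) || is.null(names(x))) abort("EC groups must be named by EC number")
  full <- grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", names(x))
  if (any(!full)) {
    inform(paste0("ec_groups: dropped ", sum(!full), " partial/malformed EC number(s)"))
    x <- x[full]
  }
  x <- lapply(x, function(g) sort(unique(as.character(g))))
  small <- lengths(x) < 2
  if (any(small)) {
    inform(paste0("ec_groups: dropped ", sum(small), " singleton group(s)"))
    x <- x[!small]
  }
  if (!length(x)) abort("no usable EC groups (need full four-field ECs with >= 2 genes)")
  structure(x[order(names(x))], class = "ec_groups")
}

#' @export
print.ec_groups <- function(x, ...) {
  cat(
    "<ec_groups>  groups: ", length(x),
    "  genes: ", length(unique(unlist(x))),
    "  sizes: ", paste(range(lengths(x)), collapse = "-"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read EC groups from a two-column table
#'
#' Tab-separated `gene TAB ec`, `#` comment lines allowed.
#'
#' @param path path to the TSV file.
#' @return an [ec_groups] object.
#' @export
read_ec_groups <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read EC table: ", path))
  x <- readr::read_tsv(
    path,
    comment = "#", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!nrow(x) || ncol(x) < 2) abort(paste0("empty or malformed EC table: ", path))
  ec_groups(tibble(gene = x[[1]], ec = x[[2]]))
}

sim_lookup <- function(sim) {
  if (is.function(sim)) {
    function(g, others) vapply(others, function(o) sim(g, o), numeric(1))
  } else {
    function(g, others) sim[g, others]
  }
}

#' Within- versus between-group contrast for one gene
#'
#' For a gene `g` of group `e_i` and a disjoint group `e_j`, the
#' log-ratio of mean smoothed distances
#' \deqn{diff_g = \ln\frac{|G(e_i)\setminus g|\sum_{g' \in G(e_j)}
#'   (1 - sim(g,g') + c)}{|G(e_j)|\sum_{g^* \in G(e_i)\setminus g}
#'   (1 - sim(g,g^*) + c)}}
#' is positive when `g` sits closer (more similar) to its own group than
#' to `e_j` on average. The Laplacian smoothing constant `c` keeps the
#' logarithm finite at similarity 1. Pairs with undefined similarity
#' (`NA`) are skipped and the means taken over the remaining pairs; if a
#' whole side is undefined the result is `NA`.
#'
#' @param g gene identifier, member of `groups[[e_i]]`.
#' @param e_i,e_j EC numbers; their gene sets must be disjoint.
#' @param groups an [ec_groups] object.
#' @param sim symmetric gene-similarity matrix (or a function of two
#'   genes).
#' @param c_smooth Laplacian smoothing constant (default 0.001).
#' @return numeric log-ratio.
#' @export
diff_score <- function(g, e_i, e_j, groups, sim, c_smooth = 0.001) {
  gi <- groups[[e_i]]
  gj <- groups[[e_j]]
  if (is.null(gi) || is.null(gj)) abort("unknown EC number")
  if (!g %in% gi) abort(paste0(g, " is not in group ", e_i))
  if (length(intersect(gi, gj))) {
    abort(paste0("groups ", e_i, " and ", e_j, " share genes; LFC requires disjoint groups"))
  }
  if (length(gi) < 2) abort(paste0("group ", e_i, " needs >= 2 genes"))
  look <- sim_lookup(sim)
  inter <- look(g, gj)
  intra <- look(g, setdiff(gi, g))
  inter <- inter[!is.na(inter)]
  intra <- intra[!is.na(intra)]
  if (!length(inter) || !length(intra)) return(NA_real_)
  log(mean(1 - inter + c_smooth) / mean(1 - intra + c_smooth))
}

#' LFC score of one EC group
#'
#' The logged fold change of group `e_i` averages [diff_score()] over the
#' group's genes, then over every partner group whose gene set is disjoint
#' from `e_i`, and finally truncates at `cap` (default 5, the reporting
#' bound used with this benchmark). Genes whose diff is undefined are
#' skipped within each partner average.
#'
#' @param e_i EC number.
#' @inheritParams diff_score
#' @param cap upper bound applied to the reported score.
#' @return numeric LFC (possibly `NA` if no gene is scorable).
#' @export
lfc_score <- function(e_i, groups, sim, c_smooth = 0.001, cap = 5) {
  gi <- groups[[e_i]]
  if (is.null(gi)) abort(paste0("unknown EC number ", e_i))
  partners <- names(groups)[vapply(groups, function(gj) {
    length(intersect(gi, gj)) == 0
  }, logical(1))]
  partners <- setdiff(partners, e_i)
  if (!length(partners)) abort(paste0("no disjoint partner EC for ", e_i))
  per_partner <- vapply(partners, function(e_j) {
    d <- vapply(gi, function(g) diff_score(g, e_i, e_j, groups, sim, c_smooth), numeric(1))
    d <- d[!is.na(d)]
    if (!length(d)) NA_real_ else mean(d)
  }, numeric(1))
  per_partner <- per_partner[!is.na(per_partner)]
  if (!length(per_partner)) return(NA_real_)
  min(mean(per_partner), cap)
}

#' LFC benchmark report over all EC groups
#'
#' @inheritParams lfc_score
#' @return tibble of class `lfc_report` with columns `ec`, `n_genes`,
#'   `n_partners`, `lfc`; groups with no scorable gene are dropped with a
#'   message. [generics::glance()] returns the 25/50/75th percentile
#'   summary; [ggplot2::autoplot()] draws the score distribution.
#' @export
lfc_report <- function(groups, sim, c_smooth = 0.001, cap = 5) {
  stopifnot(inherits(groups, "ec_groups"))
  out <- purrr::map_dfr(names(groups), function(e_i) {
    gi <- groups[[e_i]]
    n_partners <- sum(vapply(
      groups[setdiff(names(groups), e_i)],
      function(gj) length(intersect(gi, gj)) == 0, logical(1)
    ))
    lfc <- if (n_partners > 0) {
      lfc_score(e_i, groups, sim, c_smooth = c_smooth, cap = cap)
    } else {
      NA_real_
    }
    tibble(ec = e_i, n_genes = length(gi), n_partners = n_partners, lfc = lfc)
  })
  dropped <- sum(is.na(out$lfc))
  if (dropped > 0) {
    inform(paste0("lfc_report: dropped ", dropped, " EC group(s) with no scorable gene"))
    out <- out[!is.na(out$lfc), ]
  }
  class(out) <- c("lfc_report", class(out))
  attr(out, "cap") <- cap
  attr(out, "c_smooth") <- c_smooth
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname lfc_report
#' @param x an `lfc_report`.
#' @param ... unused.
#' @method glance lfc_report
#' @export
glance.lfc_report <- function(x, ...) {
  q <- quantile(x$lfc, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(
    n_ec = nrow(x), lfc_q25 = q[1], lfc_median = q[2], lfc_q75 = q[3],
    cap = attr(x, "cap")
  )
}

#' @rdname lfc_report
#' @param object an `lfc_report`.
#' @method autoplot lfc_report
#' @export
autoplot.lfc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = "", y = lfc)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = NULL, y = "LFC score",
      title = "EC-group logged fold change",
      subtitle = paste0(nrow(object), " EC groups, cap = ", attr(object, "cap"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
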