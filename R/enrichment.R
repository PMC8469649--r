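#' Construct an ontology DAG from edge and annotation tables
#'
#' Terms form a directed acyclic graph with child-to-parent edges (multiple
#' parents allowed); genes are directly annotated to terms. Annotation
#' closure under the true-path rule is computed by
#' [propagate_annotations()].
#'
#' @param edges Tibble with columns `child`, `parent` (term ids).
#' @param annotations Tibble with columns `gene_id`, `term_id`.
#' @return A list of class `ontology_dag` with `terms`, `edges`,
#'   `annotations`, `direct` (named list term -> genes) and `propagated`
#'   (`NULL` until propagation).
#' @export
ontology_dag <- function(edges, annotations) {
  if (!all(c("child", "parent") %in% names(edges))) {
    abort("`edges` must have child and parent columns.")
  }
  if (!all(c("gene_id", "term_id") %in% names(annotations))) {
    abort("`annotations` must have gene_id and term_id columns.")
  }
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term_id)))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms)
  )
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, fas[1])
    abort(sprintf(
      "Ontology edges contain a cycle (e.g. through edge %s -> %s).",
      ends[1], ends[2]
    ))
  }
  direct <- annotations %>%
    dplyr::distinct(.data$term_id, .data$gene_id) %>%
    dplyr::summarise(genes = list(sort(.data$gene_id)), .by = "term_id")
  direct_list <- stats::setNames(direct$genes, direct$term_id)
  missing_terms <- setdiff(terms, names(direct_list))
  direct_list[missing_terms] <- list(character())
  structure(
    list(
      terms = terms,
      edges = tibble::as_tibble(edges[, c("child", "parent")]),
      annotations = tibble::as_tibble(annotations[, c("gene_id", "term_id")]),
      graph = g,
      direct = direct_list[terms],
      propagated = NULL
    ),
    class = "ontology_dag"
  )
}

# Children before parents along child->parent edges.
reverse_topological_order <- function(dag) {
  names(igraph::topo_sort(dag$graph, mode = "out"))
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor:
#' `propagated(term) = direct(term) U propagated(children)`. Idempotent.
#'
#' @param dag An [ontology_dag()].
#' @return The dag with its `propagated` field filled.
#' @export
propagate_annotations <- function(dag) {
  if (!inherits(dag, "ontology_dag")) abort("`dag` must be an ontology_dag.")
  order <- reverse_topological_order(dag)
  prop <- dag$direct
  children_of <- split(dag$edges$child, dag$edges$parent)
  for (term in order) {
    kids <- children_of[[term]]
    if (length(kids) > 0) {
      prop[[term]] <- sort(unique(c(prop[[term]], unlist(prop[kids]))))
    }
  }
  dag$propagated <- prop
  dag
}

#' Upper-tail hypergeometric probability by direct summation
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the annotation, the probability of
#' observing `k` or more annotated genes. Exact terms are summed on the
#' log-binomial scale.
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe.
#' @param n Selected genes.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    abort("Inconsistent hypergeometric counts: need 0 <= k <= min(K, n) and K, n <= N.")
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Parent-child conditioned over-representation analysis
#'
#' Tests each term's propagated gene set for over-representation of the
#' selected genes with the upper-tail hypergeometric test, conditioning on
#' the DAG: terms are processed children before parents, and when a term
#' is tested, the gene content of its already-significant immediate
#' children (conditioned p <= `child_alpha`) is excluded — from the term's
#' gene set, from the selection, and from the universe — for that term's
#' test only. A parent is then significant only if it carries enrichment
#' evidence beyond what its specific children already explain. Leaf terms
#' and terms without significant children are tested unconditionally.
#'
#' @param dag An [ontology_dag()] (propagated automatically if needed).
#' @param selected_genes Character set of genes of interest (must be a
#'   subset of the universe).
#' @param universe Character set of background genes; default: all genes in
#'   at least one propagated annotation.
#' @param child_alpha Child-significance threshold for conditioning,
#'   non-strict (default 0.01).
#' @param term_order Optional explicit evaluation order (must place every
#'   child before its parents); mainly for order-independence checks.
#' @return Tibble of class `enrichment_results`, one row per term:
#'   `term_id`, `universe_size`, `term_genes`, `selected_size`, `overlap`,
#'   `p_value` (conditioned), `p_uncond`, `conditioned`,
#'   `excluded_count`, `excluded` (list column).
#' @export
conditional_enrichment <- function(dag, selected_genes, universe = NULL,
                                   child_alpha = 0.01, term_order = NULL) {
  if (!inherits(dag, "ontology_dag")) abort("`dag` must be an ontology_dag.")
  if (is.null(dag$propagated)) dag <- propagate_annotations(dag)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(dag$propagated)))
  }
  selected_genes <- unique(selected_genes)
  if (!all(selected_genes %in% universe)) {
    abort("`selected_genes` must be a subset of the universe.")
  }
  order <- term_order %||% reverse_topological_order(dag)
  if (!setequal(order, dag$terms)) {
    abort("`term_order` must cover exactly the dag's terms.")
  }
  pos <- match(dag$edges$child, order)
  if (any(match(dag$edges$parent, order) < pos)) {
    abort("`term_order` must place children before their parents.")
  }
  children_of <- split(dag$edges$child, dag$edges$parent)
  prop <- lapply(dag$propagated, intersect, x = universe)
  # intersect(x = universe, y = term genes): keep universe membership only
  p_cond <- stats::setNames(rep(NA_real_, length(order)), order)

  rows <- vector("list", length(order))
  names(rows) <- order
  for (term in order) {
    term_genes <- prop[[term]]
    kids <- children_of[[term]]
    sig_kids <- kids[!is.na(p_cond[kids]) & p_cond[kids] <= child_alpha]
    excluded <- sort(unique(unlist(prop[sig_kids])))
    if (is.null(excluded)) excluded <- character()
    uni <- setdiff(universe, excluded)
    sel <- setdiff(selected_genes, excluded)
    tg <- setdiff(term_genes, excluded)
    k <- length(intersect(sel, tg))
    p <- hypergeom_upper_tail(k, length(tg), length(sel), length(uni))
    k0 <- length(intersect(selected_genes, term_genes))
    p0 <- hypergeom_upper_tail(
      k0, length(term_genes), length(selected_genes), length(universe)
    )
    p_cond[term] <- p
    rows[[term]] <- tibble::tibble(
      term_id = term,
      universe_size = length(uni),
      term_genes = length(tg),
      selected_size = length(sel),
      overlap = k,
      p_value = p,
      p_uncond = p0,
      conditioned = length(excluded) > 0,
      excluded_count = length(excluded),
      excluded = list(excluded)
    )
  }
  out <- dplyr::bind_rows(rows) %>% dplyr::arrange(.data$p_value, .data$term_id)
  class(out) <- c("enrichment_results", class(out))
  out
}
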