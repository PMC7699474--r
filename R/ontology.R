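#' Propagate gene-to-term assignments up an ontology DAG
#'
#' Closes the direct gene-to-term mapping over the child-to-parent edge
#' relation: a gene belongs to a term if it is directly assigned to the term
#' or to any of its descendants. Cycles are rejected with an error naming a
#' member of the cycle.
#'
#' @param edges Data.frame with columns `child`, `parent` (term ids).
#' @param gene2term Data.frame with columns `gene_id`, `term` (direct
#'   assignments).
#' @return List with `term_genes` (named list term -> character vector of
#'   genes after propagation) and `gene2term` (the closed mapping as a
#'   data.frame).
#' @export
propagate_ontology <- function(edges, gene2term) {
  assert_that(all(c("child", "parent") %in% names(edges)),
              "edges must have columns child, parent")
  assert_that(all(c("gene_id", "term") %in% names(gene2term)),
              "gene2term must have columns gene_id, term")
  terms <- unique(c(edges$child, edges$parent, gene2term$term))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (length(bad) == 0) {  # self-loop
      lp <- igraph::which_loop(g)
      bad <- igraph::as_ids(igraph::ends(g, igraph::E(g)[lp])[, 1])
    }
    abort_validation("ontology edges contain a cycle involving term '%s'",
                     bad[1])
  }
  # process parents before children (reverse topological order of the
  # child -> parent digraph), accumulating ancestor sets
  topo <- igraph::as_ids(igraph::topo_sort(g, mode = "out"))
  anc <- setNames(vector("list", length(terms)), terms)
  for (t in rev(topo)) {
    parents <- igraph::as_ids(igraph::neighbors(g, t, mode = "out"))
    anc[[t]] <- unique(c(parents, unlist(anc[parents], use.names = FALSE)))
  }
  direct <- split(gene2term$gene_id, gene2term$term)
  term_genes <- setNames(vector("list", length(terms)), terms)
  for (t in terms) term_genes[[t]] <- unique(direct[[t]])
  # push each directly-annotated term's genes to all its ancestors
  for (t in names(direct)) {
    for (a in anc[[t]]) {
      term_genes[[a]] <- unique(c(term_genes[[a]], direct[[t]]))
    }
  }
  term_genes <- term_genes[!vapply(term_genes, is.null, TRUE)]
  closed <- data.frame(
    gene_id = unlist(term_genes, use.names = FALSE),
    term = rep(names(term_genes), lengths(term_genes)),
    stringsAsFactors = FALSE)
  list(term_genes = term_genes, gene2term = closed)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to the
#' input order; m is the number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  assert_that(all(is.finite(p_values) & p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Hypergeometric term enrichment with propagated membership
#'
#' For each term with at least one background gene and at least one list
#' gene (k >= 1), the upper tail of the hypergeometric distribution of
#' drawing `n` genes from the `N`-gene background with `K` marked. Terms
#' whose propagated gene sets are identical within the background are
#' united into one row before testing (redundancy removal); terms with
#' k = 0 are excluded from both the table and the multiple-testing count.
#'
#' @param genes Character vector, the gene list (subset of `background`).
#' @param background Character vector, the universe.
#' @param ontology Output of [propagate_ontology()], or a named list
#'   term -> gene vector.
#' @param labels Optional data.frame (`term`, `label`).
#' @return Data.frame (`term`, `label`, `k`, `n`, `K`, `N`, `p`, `q`)
#'   sorted by q then p.
#' @export
hypergeometric_enrichment <- function(genes, background, ontology,
                                      labels = NULL) {
  assert_that(length(genes) > 0, "empty gene list")
  assert_that(all(genes %in% background),
              "gene list must be a subset of the background")
  term_genes <- if (is.list(ontology) && !is.null(ontology$term_genes))
    ontology$term_genes else ontology
  term_genes <- lapply(term_genes, function(gs)
    sort(unique(intersect(gs, background))))
  term_genes <- term_genes[lengths(term_genes) > 0]
  assert_that(length(term_genes) > 0, "no term has background genes")
  # unite terms with identical background gene sets
  key <- vapply(term_genes, paste, "", collapse = "\r")
  united <- split(names(term_genes), match(key, unique(key)))
  N <- length(background)
  n <- length(unique(genes))
  rows <- lapply(united, function(ids) {
    gs <- term_genes[[ids[1]]]
    k <- sum(genes %in% gs)
    if (k == 0) return(NULL)
    K <- length(gs)
    data.frame(term = paste(sort(ids), collapse = "|"),
               k = k, n = n, K = K, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  assert_that(length(rows) > 0, "no term overlaps the gene list")
  tab <- do.call(rbind, rows)
  tab$q <- adjust_fdr(tab$p)
  if (!is.null(labels)) {
    first <- vapply(strsplit(tab$term, "|", fixed = TRUE), `[[`, "", 1)
    tab$label <- labels$label[match(first, labels$term)]
  } else {
    tab$label <- NA_character_
  }
  tab <- tab[order(tab$q, tab$p, tab$term), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("term", "label", "k", "n", "K", "N", "p", "q")]
}
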