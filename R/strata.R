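#' Phylostratum distribution of a gene list
#'
#' Counts and proportions of a gene list over the 16 phylostrata
#' (1 = cellular organisms ... 16 = Homo sapiens). Genes absent from the
#' annotation are dropped with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Annotation table with `gene_id`, `phylostratum`.
#' @return Data.frame with `stratum`, `n`, `prop` (proportions sum to 1).
#' @export
stratum_distribution <- function(genes, annotation) {
  assert_that(length(genes) > 0, "empty gene list")
  annotation <- validate_annotation(annotation)
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) {
    warning(sprintf("dropping %d unannotated gene(s)", sum(is.na(idx))))
    idx <- idx[!is.na(idx)]
  }
  assert_that(length(idx) > 0, "no gene in the list is annotated")
  counts <- tabulate(annotation$phylostratum[idx], nbins = 16)
  data.frame(stratum = 1:16, n = counts, prop = counts / sum(counts))
}

#' Per-stratum enrichment of up/down lists against the background
#'
#' For each stratum and each list, an exact binomial test of the list count
#' in the stratum (k out of the list size n) against the background stratum
#' fraction p0, one-sided in the direction of the observed deviation;
#' Benjamini-Hochberg correction is applied across the 16 strata within
#' each list. With `compare = "updown"` a two-sided two-proportion test of
#' the up vs down proportions per stratum is reported instead of the
#' background comparison.
#'
#' @param up,down Character vectors of gene ids (subsets of the annotation
#'   universe).
#' @param annotation Annotation table defining the background universe.
#' @param compare `"background"` (default) or `"updown"`.
#' @return Data.frame with per-stratum counts, proportions, one-sided
#'   p-values, BH q-values and direction flags.
#' @export
stratum_shift_test <- function(up, down, annotation,
                               compare = c("background", "updown")) {
  compare <- match.arg(compare)
  annotation <- validate_annotation(annotation)
  assert_that(all(up %in% annotation$gene_id) &&
                all(down %in% annotation$gene_id),
              "lists must be subsets of the annotation universe")
  n_bg <- tabulate(annotation$phylostratum, nbins = 16)
  N <- nrow(annotation)
  res <- data.frame(stratum = 1:16,
                    n_up = tabulate(
                      annotation$phylostratum[match(up, annotation$gene_id)],
                      nbins = 16),
                    n_down = tabulate(
                      annotation$phylostratum[match(down, annotation$gene_id)],
                      nbins = 16),
                    n_background = n_bg)
  res$prop_up <- res$n_up / max(length(up), 1)
  res$prop_down <- res$n_down / max(length(down), 1)
  res$prop_bg <- n_bg / N

  one_sided <- function(k, n, p0) {
    dir <- if (n > 0 && k / n >= p0) "greater" else "less"
    list(p = binom_tail(k, n, p0, dir)$p, dir = dir)
  }
  if (compare == "background") {
    tu <- lapply(1:16, function(s)
      one_sided(res$n_up[s], length(up), res$prop_bg[s]))
    td <- lapply(1:16, function(s)
      one_sided(res$n_down[s], length(down), res$prop_bg[s]))
    res$dir_up <- vapply(tu, `[[`, "", "dir")
    res$dir_down <- vapply(td, `[[`, "", "dir")
    res$p_up <- vapply(tu, `[[`, 0, "p")
    res$p_down <- vapply(td, `[[`, 0, "p")
    res$q_up <- adjust_fdr(res$p_up)
    res$q_down <- adjust_fdr(res$p_down)
  } else {
    res$p_updown <- vapply(1:16, function(s) {
      if (res$n_up[s] + res$n_down[s] == 0) return(1)
      suppressWarnings(stats::prop.test(
        c(res$n_up[s], res$n_down[s]),
        c(length(up), length(down)))$p.value)
    }, 0)
    res$q_updown <- adjust_fdr(res$p_updown)
  }
  res
}
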