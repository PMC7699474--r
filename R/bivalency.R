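#' Exact binomial overlap test from counts
#'
#' One-sided tail of Binomial(n, K/N) at k, computed in log space so that
#' p-values far below the double underflow limit remain meaningful through
#' their log10.
#'
#' @param k Hits in the list (e.g. bivalent genes in the up list).
#' @param n List size.
#' @param K Hits in the background universe.
#' @param N Background size.
#' @param direction `"greater"` (enrichment, default) or `"less"`.
#' @return Object of class `bivalency_result`: `k`, `n`, `K`, `N`,
#'   `fraction` (k/n), `p0` (K/N), `p_value`, `log10_p`, `direction`.
#' @export
bivalent_counts_test <- function(k, n, K, N,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  assert_that(n >= 1, "empty list")
  assert_that(K >= 0 && K <= N, "need 0 <= K <= N")
  assert_that(k >= 0 && k <= n, "need 0 <= k <= n")
  assert_that(n <= N, "list larger than background")
  tail <- binom_tail(k, n, K / N, direction)
  structure(list(k = k, n = n, K = K, N = N,
                 fraction = k / n, p0 = K / N,
                 p_value = tail$p, log10_p = tail$log10_p,
                 direction = direction),
            class = "bivalency_result")
}

#' @export
print.bivalency_result <- function(x, ...) {
  cat(sprintf(
    "bivalent overlap: %d/%d (%.1f%%) vs background %d/%d (%.1f%%)\n",
    x$k, x$n, 100 * x$fraction, x$K, x$N, 100 * x$p0))
  cat(sprintf("one-sided (%s) binomial p = %.3g (log10 p = %.2f)\n",
              x$direction, x$p_value, x$log10_p))
  invisible(x)
}

#' Bivalent-gene enrichment of a gene list
#'
#' Tests whether the bivalent fraction of a gene list exceeds (or falls
#' below) the bivalent fraction of the background universe, via the exact
#' binomial tail of [bivalent_counts_test()].
#'
#' @param genes Character vector of gene ids (must be a subset of
#'   `background`).
#' @param annotation Annotation with `gene_id` and `bivalent`.
#' @param background Character vector defining the universe (default: all
#'   annotated genes).
#' @param direction `"greater"` or `"less"`.
#' @return A `bivalency_result`.
#' @export
bivalent_enrichment_test <- function(genes, annotation,
                                     background = annotation$gene_id,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  annotation <- validate_annotation(annotation)
  assert_that(length(genes) > 0, "empty gene list")
  assert_that(all(genes %in% background),
              "gene list must be a subset of the background")
  biv <- annotation$bivalent[match(background, annotation$gene_id)]
  assert_that(!anyNA(biv), "background contains unannotated genes")
  in_list <- background %in% genes
  bivalent_counts_test(k = sum(biv[in_list]), n = sum(in_list),
                       K = sum(biv), N = length(background),
                       direction = direction)
}

#' Per-stratum bivalent fractions for background, up and down lists
#'
#' @param up,down Character vectors of gene ids.
#' @param annotation Annotation with `gene_id`, `phylostratum`, `bivalent`.
#' @return Data.frame per stratum with gene counts and bivalent fractions
#'   for all genes, the up list and the down list; a stratum holding no
#'   genes of a list has `NA` (absent), not 0.
#' @export
bivalent_by_stratum <- function(up, down, annotation) {
  annotation <- validate_annotation(annotation)
  frac <- function(genes) {
    idx <- match(genes, annotation$gene_id)
    idx <- idx[!is.na(idx)]
    n <- tabulate(annotation$phylostratum[idx], nbins = 16)
    b <- tabulate(annotation$phylostratum[idx][annotation$bivalent[idx]],
                  nbins = 16)
    ifelse(n > 0, b / n, NA_real_)
  }
  n_all <- tabulate(annotation$phylostratum, nbins = 16)
  data.frame(stratum = 1:16,
             n_all = n_all,
             frac_bivalent_all = frac(annotation$gene_id),
             frac_bivalent_up = frac(up),
             frac_bivalent_down = frac(down))
}

#' Cancer-driver panel of the ploidy lists
#'
#' Tabulates the oncogenes and tumour suppressors present in the up/down
#' lists (direction, linear fold, stratum, bivalency) and compares bivalent
#' fractions between driver groups: up-regulated oncogenes vs down-regulated
#' oncogenes, and up-regulated oncogenes vs tumour suppressors (both lists
#' pooled). The default comparison is a one-sided exact binomial using the
#' comparison group's bivalent fraction as p0; `method = "fisher"` uses the
#' one-sided two-sample Fisher exact test instead.
#'
#' @param up,down Character vectors of gene ids.
#' @param annotation Annotation carrying `driver_class`.
#' @param contrasts Optional output of [compute_ploidy_contrasts()]; if
#'   given, the panel reports the linear fold `2^((lfc_heart+lfc_liver)/2)`.
#' @param method `"binomial"` (default) or `"fisher"`.
#' @return List with `panel` (data.frame) and `comparisons` (data.frame of
#'   pairwise tests, empty when no drivers overlap the lists).
#' @export
driver_panel <- function(up, down, annotation, contrasts = NULL,
                         method = c("binomial", "fisher")) {
  method <- match.arg(method)
  annotation <- validate_annotation(annotation)
  listed <- data.frame(gene_id = c(up, down),
                       direction = rep(c("up", "down"),
                                       c(length(up), length(down))),
                       stringsAsFactors = FALSE)
  idx <- match(listed$gene_id, annotation$gene_id)
  listed$driver_class <- annotation$driver_class[idx]
  listed$phylostratum <- annotation$phylostratum[idx]
  listed$bivalent <- annotation$bivalent[idx]
  panel <- listed[!is.na(listed$driver_class) &
                    listed$driver_class != "none", , drop = FALSE]
  if (!is.null(contrasts)) {
    ci <- match(panel$gene_id, contrasts$gene_id)
    panel$fold <- 2^((contrasts$lfc_heart[ci] + contrasts$lfc_liver[ci]) / 2)
  }
  rownames(panel) <- NULL
  if (nrow(panel) == 0) {
    message("no cancer-driver genes overlap the ploidy lists; ",
            "comparative tests skipped")
    return(list(panel = panel, comparisons = data.frame()))
  }
  grp <- function(dir, cls) {
    panel[panel$direction %in% dir & panel$driver_class %in% cls, ]
  }
  compare <- function(name, a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    k <- sum(a$bivalent); n <- nrow(a)
    kb <- sum(b$bivalent); nb <- nrow(b)
    p <- if (method == "binomial") {
      binom_tail(k, n, kb / nb, "greater")$p
    } else {
      stats::fisher.test(matrix(c(k, n - k, kb, nb - kb), 2),
                         alternative = "greater")$p.value
    }
    data.frame(comparison = name, k = k, n = n,
               k_ref = kb, n_ref = nb, p_value = p,
               stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, Filter(Negate(is.null), list(
    compare("up_oncogenes_vs_down_oncogenes",
            grp("up", "oncogene"), grp("down", "oncogene")),
    compare("up_oncogenes_vs_tumour_suppressors",
            grp("up", "oncogene"),
            grp(c("up", "down"), "tumour_suppressor"))
  )))
  list(panel = panel,
       comparisons = if (is.null(comparisons)) data.frame() else comparisons)
}
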