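#' Build a pipeline run configuration
#'
#' Either a `simulate` block (parameters for
#' [simulate_ploidy_dataset()]) or input paths must be supplied.
#'
#' @param simulate `NULL`, or a list of arguments for
#'   [simulate_ploidy_dataset()] (e.g. `list(n_genes = 2000)`).
#' @param expr_a,meta_a,expr_b,meta_b,orthology,annotation Input paths
#'   (ignored when simulating).
#' @param edges Optional interaction edge-list path.
#' @param ontology_edges,gene2term,term_labels Optional ontology paths.
#' @param folds Linear fold thresholds (> 1) for the criss-cross selection.
#' @param pca_sd Score threshold (SD units) for the PCA gene selection.
#' @param hub_degree Degree threshold for network hubs.
#' @param normalize Quantile-normalize within tissue pairs?
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return A list of class `ploidy_config`.
#' @export
ploidy_config <- function(simulate = NULL,
                          expr_a = NULL, meta_a = NULL,
                          expr_b = NULL, meta_b = NULL,
                          orthology = NULL, annotation = NULL,
                          edges = NULL, ontology_edges = NULL,
                          gene2term = NULL, term_labels = NULL,
                          folds = c(2.0, 1.3), pca_sd = 2,
                          hub_degree = 10, normalize = TRUE,
                          seed = 1L, outdir = tempfile("ploidy_run_")) {
  assert_that(all(folds > 1), "fold thresholds must be > 1")
  assert_that(pca_sd > 0, "pca_sd must be > 0")
  if (is.null(simulate)) {
    paths <- c(expr_a = expr_a, meta_a = meta_a, expr_b = expr_b,
               meta_b = meta_b, orthology = orthology,
               annotation = annotation)
    assert_that(length(paths) == 6,
                "without a simulate block, all six input paths are required")
    missing <- paths[!file.exists(paths)]
    assert_that(length(missing) == 0, "missing input file(s): %s",
                paste(missing, collapse = ", "))
  }
  structure(list(simulate = simulate, expr_a = expr_a, meta_a = meta_a,
                 expr_b = expr_b, meta_b = meta_b, orthology = orthology,
                 annotation = annotation, edges = edges,
                 ontology_edges = ontology_edges, gene2term = gene2term,
                 term_labels = term_labels, folds = folds, pca_sd = pca_sd,
                 hub_degree = hub_degree, normalize = normalize,
                 seed = as.integer(seed), outdir = outdir),
            class = "ploidy_config")
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

run_stage <- function(name, log_con, code) {
  tryCatch(force(code), error = function(e) {
    msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
    if (!is.null(log_con)) writeLines(paste(format(Sys.time()), msg), log_con)
    stop(errorCondition(msg, class = c(class(e)[1], "ploidyStrata_stage_error",
                                       "error")))
  })
}

#' Run the full ploidy-phylostratigraphy pipeline
#'
#' Sequences ingestion/simulation, ortholog matching and normalization, the
#' reciprocal criss-cross contrasts at each configured fold threshold, PCA
#' confirmation, stratum-shift tests, bivalency and driver analyses, module
#' (ontology) enrichment and network summaries. All stage outputs are
#' written to `config$outdir` as tab-separated tables plus a deterministic
#' machine-readable `summary.json` (binomial p-values carry their log10
#' alongside, surviving underflow); `run.log` records versions, parameters
#' and timestamps.
#'
#' @param config A `ploidy_config`.
#' @return Invisibly, the summary list.
#' @export
run_ploidy_pipeline <- function(config) {
  stopifnot(inherits(config, "ploidy_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(log_con))
  logmsg <- function(...) writeLines(paste(format(Sys.time()),
                                           sprintf(...)), log_con)
  logmsg("ploidyStrata %s on R %s.%s",
         as.character(utils::packageVersion("ploidyStrata")),
         R.version$major, R.version$minor)
  logmsg("seed=%d folds=%s pca_sd=%g hub_degree=%g normalize=%s",
         config$seed, paste(config$folds, collapse = ","), config$pca_sd,
         config$hub_degree, config$normalize)
  summary <- list(parameters = list(
    seed = config$seed, folds = config$folds, pca_sd = config$pca_sd,
    hub_degree = config$hub_degree, normalize = config$normalize,
    simulated = !is.null(config$simulate)))

  ## -- data ---------------------------------------------------------------
  dat <- run_stage("data", log_con, {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      do.call(simulate_ploidy_dataset, args)
    } else {
      list(expr_a = read_expression(config$expr_a, config$meta_a),
           expr_b = read_expression(config$expr_b, config$meta_b),
           ortholog_map = read_orthology(config$orthology),
           annotation = read_annotation(config$annotation),
           truth = NULL,
           graph = if (!is.null(config$edges))
             read_edge_list(config$edges) else NULL,
           ontology = if (!is.null(config$ontology_edges)) {
             list(edges = read.delim(config$ontology_edges,
                                     comment.char = "#"),
                  gene2term = read.delim(config$gene2term,
                                         comment.char = "#"),
                  terms = if (!is.null(config$term_labels))
                    read.delim(config$term_labels, comment.char = "#")
                  else NULL)
           } else NULL)
    }
  })

  ## -- ingest / normalize -------------------------------------------------
  prepared <- run_stage("ingest", log_con, {
    paired <- match_orthologs(dat$expr_a, dat$expr_b, dat$ortholog_map,
                              dat$annotation)
    logmsg("matched %d ortholog pairs over %d samples",
           nrow(paired$values), ncol(paired$values))
    prepare_paired(paired, normalize = config$normalize)
  })
  annotation <- dat$annotation[dat$annotation$gene_id %in%
                                 rownames(prepared$log2), , drop = FALSE]
  summary$data <- list(n_genes = nrow(prepared$log2),
                       n_samples = ncol(prepared$log2))

  ## -- criss-cross contrasts ----------------------------------------------
  contrasts <- run_stage("crisscross", log_con,
                         compute_ploidy_contrasts(prepared))
  cc_block <- list()
  lists_by_fold <- list()
  for (fold in config$folds) {
    sel <- select_concordant_genes(contrasts, fold, quiet = TRUE)
    tag <- sprintf("fold_%g", fold)
    lists_by_fold[[tag]] <- sel
    cc_block[[tag]] <- list(threshold_fold = fold,
                            n_up = length(sel$up), n_down = length(sel$down))
    write_gene_list(sel$up, file.path(config$outdir,
                                      sprintf("up_%s.txt", tag)))
    write_gene_list(sel$down, file.path(config$outdir,
                                        sprintf("down_%s.txt", tag)))
    logmsg("%s: %d up, %d down", tag, length(sel$up), length(sel$down))
  }
  write_tsv(classify_concordance(contrasts, config$folds[1]),
            file.path(config$outdir, "contrasts.tsv"),
            comment = sprintf("reciprocal ploidy contrasts; call at %g-fold",
                              config$folds[1]))
  summary$crisscross <- cc_block
  main <- lists_by_fold[[sprintf("fold_%g", config$folds[1])]]

  ## -- PCA ----------------------------------------------------------------
  pca_block <- run_stage("pca", log_con, {
    pca <- run_pca(prepared$log2)
    pca <- assign_components(pca, prepared$meta)
    sel <- tryCatch(select_component_genes(pca, config$pca_sd),
                    error = function(e) list(up = character(0),
                                             down = character(0)))
    comp_tab <- data.frame(
      component = seq_along(pca$variance_explained),
      variance_explained = pca$variance_explained,
      factor = vapply(seq_along(pca$variance_explained), function(i) {
        hit <- names(pca$assignment)[which(pca$assignment == i)]
        if (length(hit)) hit[1] else "unassigned"
      }, ""))
    write_tsv(comp_tab, file.path(config$outdir, "pca_components.tsv"))
    write_tsv(data.frame(gene_id = rownames(pca$scores),
                         round(pca$scores[, seq_len(min(6, ncol(pca$scores))),
                                          drop = FALSE], 6)),
              file.path(config$outdir, "pca_scores.tsv"),
              comment = "standardized gene scores (first components)")
    write_gene_list(sel$up, file.path(config$outdir, "up_pca.txt"))
    write_gene_list(sel$down, file.path(config$outdir, "down_pca.txt"))
    overlap <- if (length(sel$up) && length(main$up)) {
      k <- length(intersect(sel$up, main$up))
      list(k = k,
           p_hyper = phyper(k - 1, length(main$up),
                            nrow(prepared$log2) - length(main$up),
                            length(sel$up), lower.tail = FALSE))
    } else NULL
    list(variance_explained = pca$variance_explained,
         assignment = as.list(pca$assignment),
         assignment_r = as.list(pca$assignment_r),
         n_up = length(sel$up), n_down = length(sel$down),
         up_overlap_with_crisscross = overlap,
         lists = sel)
  })
  summary$pca <- pca_block[setdiff(names(pca_block), "lists")]

  ## -- stratum shift -------------------------------------------------------
  strata_tab <- run_stage("strata", log_con,
                          stratum_shift_test(main$up, main$down, annotation))
  write_tsv(strata_tab, file.path(config$outdir, "strata.tsv"),
            comment = "per-stratum enrichment vs background (BH-corrected)")
  old_up <- sum(strata_tab$n_up[1:3]) / max(sum(strata_tab$n_up), 1)
  old_bg <- sum(strata_tab$n_background[1:3]) / sum(strata_tab$n_background)
  summary$strata <- list(
    n_enriched_up = sum(strata_tab$q_up < 0.05 &
                          strata_tab$dir_up == "greater"),
    n_enriched_down = sum(strata_tab$q_down < 0.05 &
                            strata_tab$dir_down == "greater"),
    old_strata_share_up = old_up, old_strata_share_bg = old_bg)

  ## -- bivalency / drivers -------------------------------------------------
  biv_block <- run_stage("bivalency", log_con, {
    up_t <- bivalent_enrichment_test(main$up, annotation)
    down_t <- bivalent_enrichment_test(main$down, annotation)
    write_tsv(bivalent_by_stratum(main$up, main$down, annotation),
              file.path(config$outdir, "bivalency_by_stratum.tsv"))
    drv <- driver_panel(main$up, main$down, annotation, contrasts)
    if (nrow(drv$panel)) {
      write_tsv(drv$panel, file.path(config$outdir, "driver_panel.tsv"))
    }
    list(up = list(k = up_t$k, n = up_t$n, K = up_t$K, N = up_t$N,
                   fraction = up_t$fraction, p = up_t$p_value,
                   log10_p = up_t$log10_p),
         down = list(k = down_t$k, n = down_t$n, K = down_t$K, N = down_t$N,
                     fraction = down_t$fraction, p = down_t$p_value,
                     log10_p = down_t$log10_p),
         n_driver_rows = nrow(drv$panel),
         driver_comparisons = drv$comparisons)
  })
  summary$bivalency <- biv_block

  ## -- module enrichment ----------------------------------------------------
  summary$modules <- run_stage("modules", log_con, {
    if (is.null(dat$ontology)) {
      list(skipped = "no ontology supplied")
    } else {
      closed <- propagate_ontology(dat$ontology$edges, dat$ontology$gene2term)
      bg <- annotation$gene_id
      enr_up <- hypergeometric_enrichment(intersect(main$up, bg), bg, closed,
                                          labels = dat$ontology$terms)
      write_tsv(enr_up, file.path(config$outdir, "enrichment_up.tsv"))
      enr_down <- hypergeometric_enrichment(intersect(main$down, bg), bg,
                                            closed,
                                            labels = dat$ontology$terms)
      write_tsv(enr_down, file.path(config$outdir, "enrichment_down.tsv"))
      list(n_terms_tested_up = nrow(enr_up),
           n_terms_tested_down = nrow(enr_down),
           min_q_up = min(enr_up$q), min_q_down = min(enr_down$q))
    }
  })

  ## -- network ---------------------------------------------------------------
  summary$network <- run_stage("network", log_con, {
    if (is.null(dat$graph)) {
      list(skipped = "no interaction network supplied")
    } else {
      safe_lcs <- function(g) {
        if (igraph::vcount(g) == 0) {
          list(size = 0L, n_edges = 0L, mean_degree = NA_real_,
               hub_count = 0L)
        } else largest_component_summary(g, config$hub_degree)
      }
      lcs <- safe_lcs(dat$graph)
      up_sub <- igraph::induced_subgraph(
        dat$graph, intersect(main$up, igraph::V(dat$graph)$name))
      down_sub <- igraph::induced_subgraph(
        dat$graph, intersect(main$down, igraph::V(dat$graph)$name))
      up_lcs <- safe_lcs(up_sub)
      down_lcs <- safe_lcs(down_sub)
      ret_up <- component_retention(main$up, dat$graph)
      ret_down <- component_retention(main$down, dat$graph)
      deg <- igraph::degree(dat$graph)
      write_tsv(data.frame(gene_id = names(deg), degree = as.integer(deg)),
                file.path(config$outdir, "degree.tsv"))
      write_gene_list(lcs$component %||% character(0),
                      file.path(config$outdir, "component_members.txt"))
      list(whole = lcs[c("size", "n_edges", "mean_degree", "hub_count")],
           up = list(component_size = up_lcs$size,
                     mean_degree = up_lcs$mean_degree,
                     hub_count = up_lcs$hub_count,
                     retention_percent = ret_up$percent,
                     retention_fraction = ret_up$fraction),
           down = list(component_size = down_lcs$size,
                       mean_degree = down_lcs$mean_degree,
                       hub_count = down_lcs$hub_count,
                       retention_percent = ret_down$percent,
                       retention_fraction = ret_down$fraction))
    }
  })

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  logmsg("pipeline complete")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
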