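#' Construct a validated expression matrix
#'
#' Container for a gene x sample expression table (linear scale) plus its
#' sample metadata. Validation enforces the criss-cross design invariants:
#' unique gene ids, no missing or negative values, every (species, tissue)
#' cell populated, and ploidy a deterministic function of (species, tissue)
#' that inverts between the two species (one species polyploid in heart and
#' diploid in liver, the other reversed).
#'
#' @param values Numeric gene x sample matrix, linear scale, rownames = gene
#'   ids, colnames = sample ids.
#' @param meta Data.frame with columns `sample_id`, `species`, `tissue`,
#'   `ploidy`, `batch`, `replicate`.
#' @return An object of class `ploidy_expr` with elements `values`, `meta`.
#' @export
expression_matrix <- function(values, meta) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)), "values must have gene-id rownames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate gene ids")
  assert_that(!anyNA(values), "missing values are not allowed")
  assert_that(all(values >= 0), "negative expression values")
  need <- c("sample_id", "species", "tissue", "ploidy", "batch", "replicate")
  assert_that(all(need %in% names(meta)),
              "metadata must have columns %s", paste(need, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  assert_that(length(missing_meta) == 0,
              "samples missing from metadata: %s",
              paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$sample_id, colnames(values))
  assert_that(length(extra_meta) == 0,
              "metadata samples absent from table: %s",
              paste(extra_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  assert_that(all(meta$tissue %in% c("heart", "liver")),
              "tissue must be 'heart' or 'liver'")
  assert_that(all(meta$ploidy %in% c("polyploid", "diploid")),
              "ploidy must be 'polyploid' or 'diploid'")
  cellp <- unique(meta[, c("species", "tissue", "ploidy")])
  assert_that(!anyDuplicated(cellp[, c("species", "tissue")]),
              "ploidy must be constant within each (species, tissue) cell")
  for (sp in unique(meta$species)) {
    cells <- cellp[cellp$species == sp, ]
    if (nrow(cells) == 2) {
      assert_that(length(unique(cells$ploidy)) == 2,
                  "species %s must have one polyploid and one diploid tissue",
                  sp)
    }
  }
  structure(list(values = values, meta = meta), class = "ploidy_expr")
}

#' @export
print.ploidy_expr <- function(x, ...) {
  cat(sprintf("ploidy_expr: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$meta$species, x$meta$tissue))
  invisible(x)
}

#' Read an expression table and its sample metadata
#'
#' Expects a tab-separated table whose first column holds gene ids and a
#' metadata sidecar with columns `sample_id`, `species`, `tissue`, `ploidy`,
#' `batch`, `replicate`. Genes containing any missing value are dropped with
#' a warning reporting the count.
#'
#' @param table_path,meta_path Paths to the tab-separated files.
#' @return A `ploidy_expr`.
#' @export
read_expression <- function(table_path, meta_path) {
  assert_that(file.exists(table_path), "no such file: %s", table_path)
  assert_that(file.exists(meta_path), "no such file: %s", meta_path)
  tab <- read.delim(table_path, check.names = FALSE, comment.char = "#")
  assert_that(ncol(tab) >= 2, "expression table needs gene ids plus samples")
  ids <- as.character(tab[[1]])
  assert_that(!anyDuplicated(ids), "duplicate gene ids in %s", table_path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  incomplete <- rowSums(is.na(values)) > 0
  if (any(incomplete)) {
    warning(sprintf("dropping %d gene(s) with missing values",
                    sum(incomplete)))
    values <- values[!incomplete, , drop = FALSE]
  }
  meta <- read.delim(meta_path, check.names = FALSE, comment.char = "#")
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata sidecar
#' @param expr A `ploidy_expr`.
#' @param table_path,meta_path Output paths (tab-separated).
#' @export
write_expression <- function(expr, table_path, meta_path) {
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(table_path, meta_path))
}

#' Read and validate a gene annotation table
#'
#' Tab-separated columns: `gene_id`, `phylostratum` (1-16), `bivalent`
#' (0/1 or logical), `driver_class` (`oncogene`, `tumour_suppressor`,
#' `none`).
#'
#' @param path Path to the table.
#' @return Validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  ann <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  need <- c("gene_id", "phylostratum", "bivalent", "driver_class")
  assert_that(all(need %in% names(ann)),
              "annotation must have columns %s", paste(need, collapse = ", "))
  assert_that(!anyDuplicated(ann$gene_id), "duplicate gene ids in annotation")
  assert_that(all(ann$phylostratum %in% 1:16),
              "phylostratum must lie in 1..16")
  ann$bivalent <- as.logical(ann$bivalent)
  assert_that(!anyNA(ann$bivalent), "bivalent must be 0/1 or logical")
  assert_that(all(ann$driver_class %in%
                    c("oncogene", "tumour_suppressor", "none")),
              "driver_class must be oncogene / tumour_suppressor / none")
  ann
}

#' Read a one-to-one orthology map
#'
#' Two tab-separated columns (species A id, species B id). The map must be
#' bijective: no id may appear in more than one pair.
#'
#' @param path Path to the table.
#' @return Data.frame with columns `gene_a`, `gene_b`.
#' @export
read_orthology <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  map <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_that(ncol(map) >= 2, "orthology map needs two columns")
  map <- data.frame(gene_a = as.character(map[[1]]),
                    gene_b = as.character(map[[2]]),
                    stringsAsFactors = FALSE)
  validate_orthology(map)
}

validate_orthology <- function(map) {
  assert_that(nrow(map) > 0, "empty orthology map")
  assert_that(!anyDuplicated(map$gene_a) && !anyDuplicated(map$gene_b),
              "orthology map is not one-to-one")
  map
}

#' Match one-to-one orthologs across the two species
#'
#' Restricts to ortholog pairs present in both expression matrices and
#' carrying a phylostratum in the annotation (the unannotated are dropped,
#' mirroring the restriction of the analysis universe to stratum-annotated
#' ortholog pairs). Rows of the result are keyed by the species-A member of
#' each pair; columns are the union of samples of both species.
#'
#' @param expr_a,expr_b `ploidy_expr` objects for species A and B.
#' @param map One-to-one orthology map (`gene_a`, `gene_b`).
#' @param annotation Annotation keyed by species-A gene ids.
#' @return A `ploidy_expr` whose rows are ortholog pairs (named by the
#'   species-A id) with the pair table attached as element `pairs`.
#' @export
match_orthologs <- function(expr_a, expr_b, map, annotation) {
  stopifnot(inherits(expr_a, "ploidy_expr"), inherits(expr_b, "ploidy_expr"))
  map <- validate_orthology(map)
  annotation <- validate_annotation(annotation)
  keep <- map$gene_a %in% rownames(expr_a$values) &
    map$gene_b %in% rownames(expr_b$values) &
    map$gene_a %in% annotation$gene_id
  map <- map[keep, , drop = FALSE]
  assert_that(nrow(map) > 0,
              "no ortholog pair is present in both matrices and annotated")
  values <- cbind(expr_a$values[map$gene_a, , drop = FALSE],
                  expr_b$values[map$gene_b, , drop = FALSE])
  rownames(values) <- map$gene_a
  meta <- rbind(expr_a$meta, expr_b$meta)
  out <- expression_matrix(values, meta)
  out$pairs <- map
  out
}

#' Quantile normalization within sample groups
#'
#' Within each group, every column is mapped onto the row-wise mean of the
#' groups' order statistics, preserving within-column ranks; tied values
#' receive the mean of the normalized values at their tied ranks. After
#' normalization the sorted values of all columns of a group are identical
#' (up to tie-averaging), and the transform is idempotent.
#'
#' @param values Numeric gene x sample matrix.
#' @param groups Vector/factor of length `ncol(values)` assigning each
#'   sample to a normalization group (e.g. its tissue pair); every group
#'   needs >= 2 samples.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(values, groups) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(length(groups) == ncol(values),
              "groups must have one entry per column")
  out <- values
  for (g in unique(groups)) {
    cols <- which(groups == g)
    assert_that(length(cols) >= 2,
                "normalization group '%s' has fewer than 2 samples", g)
    m <- values[, cols, drop = FALSE]
    target <- rowMeans(apply(m, 2, sort))
    out[, cols] <- apply(m, 2, function(x) {
      v <- target[rank(x, ties.method = "first")]
      ave(v, match(x, x), FUN = mean)  # average within exact-tie groups
    })
  }
  out
}

#' Log-transform and quantile-normalize a paired matrix
#'
#' Applies `log2(x + pseudocount)` and then, optionally, quantile
#' normalization within each tissue pair (all heart samples of both species
#' together; likewise liver), matching the pairwise-comparison normalization
#' of the criss-cross design.
#'
#' @param paired Paired `ploidy_expr` from [match_orthologs()] (or any
#'   `ploidy_expr`).
#' @param normalize Apply within-tissue quantile normalization?
#' @param pseudocount Added before log2 to handle zeros.
#' @return List with `log2` (gene x sample matrix, log2 scale) and `meta`.
#' @export
prepare_paired <- function(paired, normalize = TRUE, pseudocount = 1) {
  stopifnot(inherits(paired, "ploidy_expr"))
  lg <- log2(paired$values + pseudocount)
  if (normalize) lg <- quantile_normalize(lg, paired$meta$tissue)
  list(log2 = lg, meta = paired$meta)
}

#' Read an interaction edge list
#'
#' Two or three tab-separated columns (`gene_a`, `gene_b`[, `score`]), the
#' format interaction databases export. Self-loops and duplicate edges are
#' removed; an optional confidence cutoff filters on the score column.
#'
#' @param path Path to the edge list.
#' @param score_min Optional minimum score; rows below it are dropped.
#' @return An undirected simple [igraph::igraph].
#' @export
read_edge_list <- function(path, score_min = NULL) {
  assert_that(file.exists(path), "no such file: %s", path)
  ed <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_that(ncol(ed) >= 2, "edge list needs at least two columns")
  if (!is.null(score_min)) {
    assert_that(ncol(ed) >= 3, "score filtering requires a third column")
    ed <- ed[ed[[3]] >= score_min, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge list
#' @param graph An igraph object.
#' @param path Output path.
#' @export
write_edge_list <- function(graph, path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[1:2] <- c("gene_a", "gene_b")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
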