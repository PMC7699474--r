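write_fixture_expr <- function(dir, genes = c("g1", "g2", "g3"),
                               na_gene = NULL) {
  meta <- make_meta(1)[make_meta(1)$species == "A", ]
  vals <- matrix(seq_len(length(genes) * 2), nrow = length(genes),
                 dimnames = list(genes, meta$sample_id))
  tab <- data.frame(gene_id = genes, vals, check.names = FALSE)
  if (!is.null(na_gene)) tab[tab$gene_id == na_gene, 2] <- NA
  tp <- file.path(dir, "expr.tsv"); mp <- file.path(dir, "meta.tsv")
  write.table(tab, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tp, meta = mp, meta_df = meta)
}

test_that("read_expression validates and round-trips", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_expr(dir)
  ex <- read_expression(fx$table, fx$meta)
  expect_s3_class(ex, "ploidy_expr")
  expect_identical(nrow(ex$values), 3L)

  # metadata missing one sample -> error naming it
  meta_bad <- fx$meta_df[-1, ]
  mp2 <- file.path(dir, "meta2.tsv")
  write.table(meta_bad, mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(fx$table, mp2), fx$meta_df$sample_id[1])

  # one NA row -> 2 genes retained with a warning
  fx_na <- write_fixture_expr(dir, na_gene = "g2")
  expect_warning(ex2 <- read_expression(fx_na$table, fx_na$meta),
                 "1 gene")
  expect_identical(nrow(ex2$values), 2L)
})

test_that("expression validation rejects malformed input", {
  meta <- make_meta(1)
  vals <- matrix(1, nrow = 2, ncol = nrow(meta),
                 dimnames = list(c("g1", "g1"), meta$sample_id))
  expect_error(expression_matrix(vals, meta), "duplicate")
  vals2 <- matrix(-1, nrow = 1, ncol = nrow(meta),
                  dimnames = list("g1", meta$sample_id))
  expect_error(expression_matrix(vals2, meta), "negative")
  # ploidy inconsistent with the criss-cross table
  meta_bad <- meta
  meta_bad$ploidy <- "polyploid"
  vals3 <- matrix(1, nrow = 1, ncol = nrow(meta),
                  dimnames = list("g1", meta$sample_id))
  expect_error(expression_matrix(vals3, meta_bad), "polyploid and.*diploid")
})

make_species_expr <- function(genes, species, value = 1) {
  meta <- make_meta(1)
  meta <- meta[meta$species == species, ]
  vals <- matrix(value, nrow = length(genes), ncol = nrow(meta),
                 dimnames = list(genes, meta$sample_id))
  expression_matrix(vals, meta)
}

test_that("ortholog matching filters to annotated shared pairs", {
  ea <- make_species_expr(c("a1", "a2", "a3"), "A")
  eb <- make_species_expr("b1", "B")
  map <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  ann <- make_annotation(c("a1", "a2", "a3"))
  paired <- match_orthologs(ea, eb, map, ann)
  expect_identical(rownames(paired$values), "a1")
  expect_identical(ncol(paired$values), 4L)  # union of both species' samples

  expect_error(match_orthologs(ea, eb, map[0, ], ann), "empty")
  expect_error(match_orthologs(ea, eb,
                               data.frame(gene_a = "a3", gene_b = "zz"),
                               ann),
               "no ortholog pair")
})

test_that("pairs lacking stratum annotation are dropped", {
  genes_a <- sprintf("a%03d", 1:100)
  genes_b <- sprintf("b%03d", 1:100)
  ea <- make_species_expr(genes_a, "A")
  eb <- make_species_expr(genes_b, "B")
  map <- data.frame(gene_a = genes_a, gene_b = genes_b)
  ann <- make_annotation(genes_a[1:90])  # 10 pairs lack stratum data
  paired <- match_orthologs(ea, eb, map, ann)
  expect_identical(nrow(paired$values), 90L)
})

test_that("ortholog matching is symmetric in the species arguments", {
  set.seed(42)
  genes_a <- sprintf("a%02d", 1:20)
  genes_b <- sprintf("b%02d", 1:20)
  ea <- make_species_expr(genes_a[1:15], "A")
  eb <- make_species_expr(genes_b[5:20], "B")
  map <- data.frame(gene_a = genes_a, gene_b = genes_b)
  ann_a <- make_annotation(genes_a)
  ann_b <- make_annotation(genes_b)
  fwd <- match_orthologs(ea, eb, map, ann_a)
  rev <- match_orthologs(eb, ea,
                         data.frame(gene_a = map$gene_b,
                                    gene_b = map$gene_a),
                         ann_b)
  expect_setequal(paste(fwd$pairs$gene_a, fwd$pairs$gene_b),
                  paste(rev$pairs$gene_b, rev$pairs$gene_a))
})

test_that("quantile normalization maps columns onto mean order statistics", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(m, groups = c(1, 1))
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  ident <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantile_normalize(ident, c(1, 1)), ident)

  expect_error(quantile_normalize(m, groups = c(1, 2)), "fewer than 2")
})

test_that("quantile normalization post-conditions hold on random input", {
  set.seed(2)
  m <- matrix(rnorm(300), nrow = 50, ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  groups <- rep(c("heart", "liver"), each = 3)
  qn <- quantile_normalize(m, groups)
  for (g in unique(groups)) {
    sorted <- apply(qn[, groups == g], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
    # ranks preserved within each column
    for (j in which(groups == g)) {
      expect_identical(rank(qn[, j]), rank(m[, j]))
    }
  }
  # idempotence
  expect_lt(max(abs(quantile_normalize(qn, groups) - qn)), 1e-12)
})

test_that("quantile normalization matches the limma oracle", {
  set.seed(3)
  m <- matrix(rexp(200), nrow = 40, ncol = 5)
  expect_equal(unname(quantile_normalize(m, rep(1, 5))),
               unname(limma::normalizeQuantiles(m)),
               tolerance = 1e-12)
})

test_that("ties receive the mean of their tied-rank targets", {
  m <- cbind(a = c(1, 1, 3), b = c(10, 20, 30))
  qn <- quantile_normalize(m, c(1, 1))
  target <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  expect_equal(unname(qn[, 1]),
               c(mean(target[1:2]), mean(target[1:2]), target[3]))
})
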