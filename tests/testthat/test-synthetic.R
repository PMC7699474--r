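test_that("annotation generation respects degenerate distributions", {
  one_hot <- replace(rep(0, 16), 5, 1)
  ann <- generate_annotation(16, stratum_probs = one_hot, seed = 1)
  expect_true(all(ann$phylostratum == 5L))

  ann0 <- generate_annotation(50, bivalent_rate = 0, seed = 2)
  expect_identical(sum(ann0$bivalent), 0L)

  expect_error(generate_annotation(10, stratum_probs = rep(0.1, 16)),
               "sum to 1")
  expect_error(generate_annotation(0), "n_genes")
})

test_that("bivalent counts follow binomial sampling at scale", {
  n <- 14093L
  rate <- 3024 / 14093
  ann <- generate_annotation(n, bivalent_rate = rate, seed = 1)
  sd3 <- 3 * sqrt(n * rate * (1 - rate))
  expect_lt(abs(sum(ann$bivalent) - 3024), sd3)
})

test_that("generators are deterministic in the seed", {
  s1 <- simulate_ploidy_dataset(n_genes = 300, n_up = 20, n_down = 25,
                                seed = 9)
  s2 <- simulate_ploidy_dataset(n_genes = 300, n_up = 20, n_down = 25,
                                seed = 9)
  s3 <- simulate_ploidy_dataset(n_genes = 300, n_up = 20, n_down = 25,
                                seed = 10)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$expr_a$values, s2$expr_a$values)
  expect_identical(igraph::as_edgelist(s1$graph),
                   igraph::as_edgelist(s2$graph))
  expect_false(identical(s1$expr_a$values, s3$expr_a$values))
})

test_that("noiseless generation is additive and exact", {
  ann <- make_annotation(paste0("g", 1:10))
  # all effects zero, no planted genes -> constant genes
  flat <- plant_truth(ann, n_up = 0, n_down = 0, noise_sd = 0, batch_sd = 0,
                      tissue_effect = 0, species_effect = 0, seed = 3)
  ex <- generate_expression(flat$truth, flat$annotation, n_reps = 2)
  all_vals <- cbind(ex$expr_a$values, ex$expr_b$values)
  expect_true(all(apply(all_vals, 1, function(x) diff(range(x)) == 0)))

  # single planted gene with delta = +1: both reciprocal contrasts exactly +1
  truth <- plant_truth(ann, n_up = 1, n_down = 0,
                       effect_range = c(1, 1), noise_sd = 0, batch_sd = 0,
                       tissue_effect = 0.8, species_effect = 0, seed = 4)
  ex <- generate_expression(truth$truth, truth$annotation, n_reps = 2)
  prep <- paired_from_sim(c(ex, list(annotation = truth$annotation)),
                          normalize = FALSE, pseudocount = 0)
  ct <- compute_ploidy_contrasts(prep)
  planted <- truth$truth$planted_up
  expect_equal(ct$lfc_heart[ct$gene_id == planted], 1, tolerance = 1e-12)
  expect_equal(ct$lfc_liver[ct$gene_id == planted], 1, tolerance = 1e-12)
  others <- ct$gene_id != planted
  expect_equal(ct$lfc_heart[others], rep(0, sum(others)), tolerance = 1e-12)
})

test_that("planted bivalency rate is realized among up genes", {
  ann <- generate_annotation(14093, seed = 5)
  planted <- plant_truth(ann, seed = 5)
  up_idx <- match(planted$truth$planted_up, planted$annotation$gene_id)
  frac <- mean(planted$annotation$bivalent[up_idx])
  sd3 <- 3 * sqrt(0.457 * (1 - 0.457) / 584)
  expect_lt(abs(frac - 0.457), sd3)
})

test_that("interaction graphs are simple with calibrated mean degree", {
  genes <- sprintf("g%03d", 1:500)
  g <- generate_interactions(genes, mean_degree = 6, seed = 3)
  expect_equal(igraph::vcount(g), 500)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
  # Erdos-Renyi oracle: mean degree 2m/n, m ~ Bin(C(n,2), p)
  n <- 500; p <- 6 / (n - 1)
  se <- 2 * sqrt(choose(n, 2) * p * (1 - p)) / n
  realized <- 2 * igraph::ecount(g) / n
  expect_lt(abs(realized - 6), 3 * se)

  g0 <- generate_interactions(genes, mean_degree = 0, seed = 1)
  expect_equal(igraph::ecount(g0), 0)
  expect_error(generate_interactions(genes, mean_degree = 499),
               "mean_degree")
})

test_that("connectivity boost raises planted-up degree", {
  genes <- sprintf("g%03d", 1:400)
  ann <- make_annotation(genes)
  planted <- plant_truth(ann, n_up = 80, n_down = 80, seed = 6)
  g <- generate_interactions(genes, mean_degree = 6,
                             up_connectivity_boost = 3,
                             truth = planted$truth, seed = 6)
  deg <- igraph::degree(g)
  expect_gt(mean(deg[planted$truth$planted_up]),
            mean(deg[setdiff(genes, planted$truth$planted_up)]))
})

test_that("pair-index decoding is a bijection", {
  n <- 7
  got <- ploidyStrata:::decode_pair_index(seq_len(choose(n, 2)), n)
  expected <- t(combn(n, 2))
  expect_equal(unname(got), expected)
})
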