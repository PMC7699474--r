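test_that("the published overlap counts give the expected tail bounds", {
  up <- bivalent_counts_test(267, 584, 3024, 14093)
  expect_lt(up$p_value, 1e-16)
  expect_lt(up$log10_p, -16)
  expect_equal(100 * up$fraction, 45.7, tolerance = 0.05)

  down <- bivalent_counts_test(222, 711, 3024, 14093)
  expect_lt(down$p_value, 1e-8)
  # the true fraction is 31.2%, not the sometimes-printed 31.6%
  expect_equal(100 * down$fraction, 31.2, tolerance = 0.05)
})

test_that("log-space tails agree with the log-sum-exp oracle", {
  grid <- expand.grid(n = c(10, 50, 200, 584, 711, 1000),
                      frac = c(0.05, 0.3, 0.5, 0.457, 0.9),
                      p0 = c(0.01, 0.2146, 0.5, 0.8))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    k <- max(1, round(grid$frac[i] * n))
    got <- bivalent_counts_test(k, n, round(grid$p0[i] * 1e4), 1e4)$log10_p
    want <- oracle_binom_log10(k, n, grid$p0[i])
    expect_equal(got, want, tolerance = 1e-6 * max(1, abs(want)))
  }
})

test_that("edge cases of the binomial tail are exact", {
  expect_equal(bivalent_counts_test(5, 5, 10, 10)$p_value, 1)  # p0 = 1
  expect_equal(bivalent_counts_test(0, 5, 3, 10)$p_value, 1)   # k = 0
  expect_equal(bivalent_counts_test(1, 5, 0, 10)$p_value, 0)   # p0 = 0, k > 0
  expect_error(bivalent_counts_test(6, 5, 3, 10), "k")
  expect_error(bivalent_counts_test(1, 5, 11, 10), "K")
})

test_that("list-based enrichment counts bivalent genes correctly", {
  ann <- make_annotation(paste0("g", 1:100),
                         bivalent = rep(c(TRUE, FALSE), c(20, 80)))
  res <- bivalent_enrichment_test(paste0("g", 1:10), ann)
  expect_identical(res$k, 10L)
  expect_identical(res$K, 20L)
  expect_equal(res$p_value, oracle_binom_enum(10, 10, 0.2), tolerance = 1e-12)
  expect_error(bivalent_enrichment_test(character(0), ann), "empty")
  expect_error(bivalent_enrichment_test("zz", ann), "subset")
})

test_that("per-stratum bivalent profiles follow the annotation", {
  ann <- make_annotation(paste0("g", 1:60),
                         stratum = rep(c(5L, 7L), each = 30),
                         bivalent = rep(c(TRUE, FALSE), each = 30))
  tab <- bivalent_by_stratum(up = paste0("g", 1:5), down = paste0("g", 31:35),
                             annotation = ann)
  expect_equal(tab$frac_bivalent_all[tab$stratum == 5], 1)
  expect_equal(tab$frac_bivalent_all[tab$stratum == 7], 0)
  expect_equal(tab$frac_bivalent_up[tab$stratum == 5], 1)
  expect_true(is.na(tab$frac_bivalent_up[tab$stratum == 7]))  # absent, not 0
  expect_true(all(is.na(tab$frac_bivalent_all[!tab$stratum %in% c(5, 7)])))
})

test_that("a paper-scale background yields the ~21% genome fraction", {
  n <- 14093
  ann <- make_annotation(sprintf("g%05d", 1:n),
                         stratum = rep_len(1:16, n),
                         bivalent = rep(c(TRUE, FALSE), c(3024, n - 3024)))
  tab <- bivalent_by_stratum(up = "g00001", down = "g00002", annotation = ann)
  overall <- sum(ann$bivalent) / n
  expect_equal(100 * overall, 21.46, tolerance = 0.005)
  # per-stratum fractions agree with a direct count oracle
  for (s in c(1, 8, 16)) {
    in_s <- ann$phylostratum == s
    expect_equal(tab$frac_bivalent_all[s],
                 sum(ann$bivalent & in_s) / sum(in_s))
  }
})

test_that("driver panel rows and comparisons are assembled correctly", {
  genes <- paste0("g", 1:40)
  ann <- make_annotation(
    genes,
    stratum = rep_len(1:4, 40),
    bivalent = c(rep(TRUE, 8), rep(FALSE, 2),   # up oncogenes: 8/10 bivalent
                 rep(TRUE, 2), rep(FALSE, 8),   # down oncogenes: 2/10
                 rep(FALSE, 20)),
    driver = rep(c("oncogene", "oncogene", "tumour_suppressor", "none"),
                 each = 10))
  pan <- driver_panel(up = genes[1:10], down = genes[11:30],
                      annotation = ann)
  expect_identical(nrow(pan$panel), 30L)
  expect_true(all(pan$panel$driver_class != "none"))
  row <- pan$comparisons[pan$comparisons$comparison ==
                           "up_oncogenes_vs_down_oncogenes", ]
  expect_equal(row$p_value, oracle_binom_enum(8, 10, 0.2), tolerance = 1e-12)

  # no drivers in the lists -> empty table, tests skipped with a notice
  expect_message(
    empty <- driver_panel(genes[31:35], genes[36:40], ann),
    "skipped")
  expect_identical(nrow(empty$panel), 0L)
  expect_identical(nrow(empty$comparisons), 0L)
})

test_that("fisher variant agrees directionally with the binomial default", {
  genes <- paste0("g", 1:30)
  ann <- make_annotation(genes,
                         bivalent = rep(c(TRUE, FALSE, FALSE), each = 10),
                         driver = rep(c("oncogene", "oncogene",
                                        "tumour_suppressor"), each = 10))
  pb <- driver_panel(genes[1:10], genes[11:30], ann, method = "binomial")
  pf <- driver_panel(genes[1:10], genes[11:30], ann, method = "fisher")
  expect_true(all(pb$comparisons$p_value < 0.05))
  expect_true(all(pf$comparisons$p_value < 0.05))
})
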