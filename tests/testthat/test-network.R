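graph_from_edges <- function(..., isolated = NULL) {
  g <- igraph::graph_from_edgelist(matrix(c(...), ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (!is.null(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                    name = isolated)
  g
}

test_that("largest component and mean degree follow 2E/V", {
  tri <- graph_from_edges("a", "b", "b", "c", "c", "a", isolated = "z")
  lcs <- largest_component_summary(tri)
  expect_identical(lcs$size, 3L)
  expect_equal(lcs$mean_degree, 2.0)
  expect_setequal(lcs$component, c("a", "b", "c"))

  single <- graph_from_edges("x", "y")
  lcs2 <- largest_component_summary(single)
  expect_identical(lcs2$size, 2L)
  expect_equal(lcs2$mean_degree, 1.0)

  expect_error(largest_component_summary(igraph::make_empty_graph(0)),
               "empty")
})

test_that("mean degree matches an independent edge count on random graphs", {
  g <- generate_interactions(sprintf("g%03d", 1:200), mean_degree = 4,
                             seed = 17)
  lcs <- largest_component_summary(g)
  ed <- igraph::as_data_frame(g, what = "edges")
  inside <- ed$from %in% lcs$component & ed$to %in% lcs$component
  expect_equal(lcs$mean_degree, 2 * sum(inside) / lcs$size)
  expect_identical(lcs$n_edges, as.integer(sum(inside)))
})

test_that("hub calling uses the within-component degree threshold", {
  # star: hub with 12 leaves
  edges <- as.vector(rbind("hub", paste0("leaf", 1:12)))
  g <- graph_from_edges(edges)
  lcs <- largest_component_summary(g, hub_degree = 10)
  expect_identical(lcs$hubs, "hub")
  expect_identical(largest_component_summary(g, hub_degree = 13)$hub_count,
                   0L)
})

test_that("component retention reproduces the published 165/267 = 62%", {
  members <- sprintf("m%03d", 1:165)
  outside <- sprintf("o%03d", 1:102)
  path_edges <- as.vector(rbind(members[-165], members[-1]))
  g <- graph_from_edges(path_edges, isolated = outside)
  ret <- component_retention(c(members, outside), g)
  expect_identical(ret$component_size, 165L)
  expect_identical(ret$percent, 62)
  expect_equal(ret$fraction, 165 / 267, tolerance = 1e-12)
})

test_that("retention edge cases follow the size-2 floor", {
  g <- graph_from_edges("a", "b", "b", "c")
  expect_identical(component_retention(c("a", "b", "c"), g)$percent, 100)

  edgeless <- igraph::make_empty_graph(0, directed = FALSE)
  edgeless <- igraph::add_vertices(edgeless, 3, name = c("a", "b", "c"))
  expect_identical(component_retention(c("a", "b"), edgeless)$percent, 0)

  expect_message(ret0 <- component_retention(c("q1", "q2"), g), "retention")
  expect_identical(ret0$percent, 0)
  expect_error(component_retention(character(0), g), "empty")
})

test_that("neighbor subsetting intersects the list with hub adjacency", {
  g <- graph_from_edges("h", "a", "h", "b", "h", "c", isolated = "d")
  expect_setequal(neighbor_subset(c("a", "b", "d"), g, "h"), c("a", "b"))
  expect_identical(neighbor_subset("d", g, "h"), character(0))
  expect_error(neighbor_subset("a", g, "nope"), "not present")

  # brute-force adjacency oracle on a seeded random graph
  rg <- generate_interactions(sprintf("g%02d", 1:40), mean_degree = 5,
                              seed = 19)
  ed <- igraph::as_data_frame(rg, what = "edges")
  hub <- names(which.max(igraph::degree(rg)))
  lst <- sprintf("g%02d", seq(1, 39, by = 2))
  brute <- lst[lst %in% c(ed$to[ed$from == hub], ed$from[ed$to == hub])]
  expect_setequal(neighbor_subset(lst, rg, hub), brute)
})

test_that("boosted up-lists are better connected than down-lists", {
  wins <- 0
  for (seed in 1:10) {
    genes <- sprintf("g%03d", 1:400)
    ann <- make_annotation(genes)
    planted <- plant_truth(ann, n_up = 60, n_down = 60, seed = seed)
    g <- generate_interactions(genes, mean_degree = 6,
                               up_connectivity_boost = 2.5,
                               truth = planted$truth, seed = seed + 100)
    up_g <- igraph::induced_subgraph(g, planted$truth$planted_up)
    down_g <- igraph::induced_subgraph(g, planted$truth$planted_down)
    md <- function(x) 2 * igraph::ecount(x) / igraph::vcount(x)
    if (md(up_g) > md(down_g)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
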