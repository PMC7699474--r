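#' Default phylostratum frequencies
#'
#' Background probabilities for the 16 phylostrata (1 = cellular organisms,
#' 16 = Homo sapiens) used by [generate_annotation()]. The mass is
#' concentrated in the ancient strata (roughly 60% in strata 1-3), with a
#' secondary contribution from the early-metazoan and vertebrate strata and
#' small recent strata, the qualitative shape of published gene-age tables
#' for mammalian genomes.
#'
#' @return Numeric vector of length 16 summing to 1.
#' @export
default_stratum_probs <- function() {
  p <- c(0.30, 0.19, 0.10, 0.08, 0.07, 0.06, 0.035, 0.055,
         0.03, 0.02, 0.015, 0.015, 0.01, 0.01, 0.005, 0.005)
  p / sum(p)
}

#' Default stratum-dependent sign probabilities
#'
#' Probability, per phylostratum, that a planted ploidy-responsive gene is
#' up-regulated: high (0.8) for the unicellular strata 1-3, neutral (0.5)
#' for the transitional early-metazoan strata 4-5, and low (0.2) for the
#' multicellular strata 6-16. This plants the old-up / young-down age shift
#' that the downstream stratum tests are expected to recover.
#'
#' @return Numeric vector of length 16 with values in \[0, 1\].
#' @export
default_sign_probs <- function() {
  c(rep(0.8, 3), rep(0.5, 2), rep(0.2, 11))
}

#' Generate a synthetic gene annotation table
#'
#' Draws, per gene, a phylostratum (1-16), a bivalent-chromatin flag and a
#' mutually exclusive cancer-driver class (oncogene / tumour suppressor /
#' none).
#'
#' @param n_genes Number of genes (>= 1).
#' @param stratum_probs Probabilities for strata 1-16; must sum to 1.
#' @param bivalent_rate Fraction of bivalent genes in \[0, 1\]. The default
#'   mirrors a background of 3024 bivalent genes in a 14,093-gene universe.
#' @param driver_rates Length-2 vector `c(oncogene, tumour_suppressor)` of
#'   driver-class rates; their sum must be <= 1.
#' @param seed Integer seed.
#' @param prefix Gene-id prefix.
#' @return A data.frame with columns `gene_id`, `phylostratum`, `bivalent`
#'   (logical), `driver_class`.
#' @export
generate_annotation <- function(n_genes,
                                stratum_probs = default_stratum_probs(),
                                bivalent_rate = 3024 / 14093,
                                driver_rates = c(oncogene = 0.02,
                                                 tumour_suppressor = 0.02),
                                seed = 1L,
                                prefix = "g") {
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  assert_that(length(stratum_probs) == 16, "stratum_probs must have length 16")
  assert_that(abs(sum(stratum_probs) - 1) <= 1e-9,
              "stratum_probs must sum to 1 (got %.12f)", sum(stratum_probs))
  assert_that(all(stratum_probs >= 0), "stratum_probs must be nonnegative")
  assert_that(bivalent_rate >= 0 && bivalent_rate <= 1,
              "bivalent_rate must lie in [0, 1]")
  assert_that(length(driver_rates) == 2 && all(driver_rates >= 0) &&
                sum(driver_rates) <= 1,
              "driver_rates must be two nonnegative fractions summing to <= 1")
  local_seed(seed, {
    gene_id <- sprintf("%s%05d", prefix, seq_len(n_genes))
    stratum <- sample.int(16L, n_genes, replace = TRUE, prob = stratum_probs)
    bivalent <- runif(n_genes) < bivalent_rate
    u <- runif(n_genes)
    driver <- ifelse(u < driver_rates[[1]], "oncogene",
                     ifelse(u < sum(driver_rates), "tumour_suppressor", "none"))
    data.frame(gene_id = gene_id,
               phylostratum = as.integer(stratum),
               bivalent = bivalent,
               driver_class = driver,
               stringsAsFactors = FALSE)
  })
}

#' Plant a ground-truth ploidy signature into an annotation
#'
#' Selects `n_up` up- and `n_down` down-regulated genes, with up genes drawn
#' preferentially from strata where `stratum_sign_probs` is high and down
#' genes from strata where it is low (so planted counts are exact while the
#' stratum-direction structure holds in expectation). Effect sizes are drawn
#' uniformly from `effect_range` (log2 units). Bivalent flags of the planted
#' up set are re-drawn at `bivalent_rate_up`, planting the bivalency
#' enrichment the overlap tests are expected to detect.
#'
#' @param annotation Output of [generate_annotation()].
#' @param n_up,n_down Planted list sizes. Defaults mirror a 584-up /
#'   711-down signature at a two-fold threshold.
#' @param effect_range Range (log2) of planted absolute effect sizes.
#' @param stratum_sign_probs Per-stratum probability that a planted gene is
#'   up-regulated; see [default_sign_probs()].
#' @param bivalent_rate_up Bivalent rate among planted up genes (default
#'   0.457, i.e. 267/584).
#' @param noise_sd Residual Gaussian noise SD (log2) per measurement.
#' @param batch_sd SD of the per-gene, per-(species, tissue)-block batch
#'   offset (log2).
#' @param tissue_effect,species_effect SDs of the per-gene tissue and
#'   species effects (log2). Set `species_effect = 0` (and `batch_sd = 0`,
#'   `noise_sd = 0`) for exact noiseless recovery of the planted lists by
#'   the criss-cross selection.
#' @param seed Integer seed.
#' @return A list with elements `truth` (class `ploidy_truth`) and
#'   `annotation` (bivalent flags updated for the planted up set).
#' @export
plant_truth <- function(annotation,
                        n_up = 584L, n_down = 711L,
                        effect_range = c(1.0, 2.5),
                        stratum_sign_probs = default_sign_probs(),
                        bivalent_rate_up = 0.457,
                        noise_sd = 0.3,
                        batch_sd = 0.3,
                        tissue_effect = 1.0,
                        species_effect = 0.7,
                        seed = 1L) {
  n <- nrow(annotation)
  assert_that(n_up + n_down <= n, "n_up + n_down exceeds the number of genes")
  assert_that(length(stratum_sign_probs) == 16 &&
                all(stratum_sign_probs >= 0 & stratum_sign_probs <= 1),
              "stratum_sign_probs must be 16 probabilities in [0, 1]")
  assert_that(bivalent_rate_up >= 0 && bivalent_rate_up <= 1,
              "bivalent_rate_up must lie in [0, 1]")
  local_seed(seed, {
    p_up <- stratum_sign_probs[annotation$phylostratum]
    up_idx <- sample.int(n, n_up, prob = p_up + 1e-12)
    rest <- setdiff(seq_len(n), up_idx)
    down_idx <- rest[sample.int(length(rest), n_down,
                                prob = (1 - p_up[rest]) + 1e-12)]
    planted_up <- annotation$gene_id[up_idx]
    planted_down <- annotation$gene_id[down_idx]
    delta <- c(runif(n_up, effect_range[1], effect_range[2]),
               -runif(n_down, effect_range[1], effect_range[2]))
    names(delta) <- c(planted_up, planted_down)
    annotation$bivalent[up_idx] <- runif(n_up) < bivalent_rate_up
    truth <- structure(list(
      seed = as.integer(seed),
      planted_up = planted_up,
      planted_down = planted_down,
      effect_size = delta,
      stratum_sign_probs = stratum_sign_probs,
      bivalent_rate_background = mean(annotation$bivalent[-c(up_idx, down_idx)]),
      bivalent_rate_up = bivalent_rate_up,
      noise_sd = noise_sd,
      batch_sd = batch_sd,
      tissue_effect = tissue_effect,
      species_effect = species_effect
    ), class = "ploidy_truth")
    list(truth = truth, annotation = annotation)
  })
}

# The criss-cross ploidy table: species A has a polyploid heart and diploid
# liver (primate-like); species B is reversed (rodent-like).
ploidy_for <- function(species, tissue) {
  ifelse((species == "A") == (tissue == "heart"), "polyploid", "diploid")
}

#' Generate a criss-cross expression dataset with planted ploidy effects
#'
#' Emits one expression matrix per species over the 2 x 2 (species x tissue)
#' design with `n_reps` replicates per cell. On the log2 scale each value is
#' gene baseline + per-gene tissue effect (heart) + per-gene species effect
#' (species A) + per-gene block batch offset + planted ploidy effect (if the
#' sample is polyploid under the criss-cross table) + Gaussian noise; the
#' returned matrices are on the linear scale (`2^log2`).
#'
#' @param truth A `ploidy_truth` from [plant_truth()].
#' @param annotation The (updated) annotation from [plant_truth()].
#' @param n_reps Replicates per (species, tissue) cell (>= 1).
#' @param baseline_mean,baseline_sd Distribution of the per-gene log2
#'   baseline.
#' @return A list with `expr_a`, `expr_b` (class `ploidy_expr`),
#'   `ortholog_map` (data.frame `gene_a`, `gene_b`) and `truth`.
#' @export
generate_expression <- function(truth, annotation, n_reps = 3L,
                                baseline_mean = 6, baseline_sd = 1.5) {
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  stopifnot(inherits(truth, "ploidy_truth"))
  genes <- annotation$gene_id
  n <- length(genes)
  delta <- numeric(n)
  names(delta) <- genes
  delta[names(truth$effect_size)] <- truth$effect_size

  design <- expand.grid(replicate = seq_len(n_reps),
                        tissue = c("heart", "liver"),
                        species = c("A", "B"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$ploidy <- ploidy_for(design$species, design$tissue)
  design$batch <- paste0("batch_", design$species, "_", design$tissue)
  design$sample_id <- paste0(design$species, "_", design$tissue,
                             "_r", design$replicate)
  ns <- nrow(design)

  local_seed(derive_seed(truth$seed, 104729), {
    mu <- rnorm(n, baseline_mean, baseline_sd)
    t_g <- rnorm(n, 0, truth$tissue_effect)
    c_g <- rnorm(n, 0, truth$species_effect)
    blocks <- unique(design$batch)
    b_g <- matrix(rnorm(n * length(blocks), 0, truth$batch_sd),
                  nrow = n, dimnames = list(genes, blocks))
    log2val <- matrix(rnorm(n * ns, 0, truth$noise_sd), nrow = n,
                      dimnames = list(genes, design$sample_id))
    for (s in seq_len(ns)) {
      # tissue and species enter as symmetric deviations (+/- half the
      # per-gene effect), so their contrast between conditions equals the
      # drawn effect while the gene baseline keeps its meaning of a
      # condition-average; the ploidy effect is added to polyploid samples
      log2val[, s] <- log2val[, s] + mu +
        t_g * (if (design$tissue[s] == "heart") 0.5 else -0.5) +
        c_g * (if (design$species[s] == "A") 0.5 else -0.5) +
        b_g[, design$batch[s]] +
        delta * (design$ploidy[s] == "polyploid")
    }
    values <- 2^log2val

    map <- data.frame(gene_a = genes, gene_b = paste0(genes, "_B"),
                      stringsAsFactors = FALSE)
    sel_a <- design$species == "A"
    values_b <- values[, !sel_a, drop = FALSE]
    rownames(values_b) <- map$gene_b
    expr_a <- expression_matrix(values[, sel_a, drop = FALSE],
                                design[sel_a, , drop = FALSE])
    expr_b <- expression_matrix(values_b, design[!sel_a, , drop = FALSE])
    list(expr_a = expr_a, expr_b = expr_b, ortholog_map = map, truth = truth)
  })
}

# Decode unordered within-set pair indices k (1-based, i < j, ordered by i
# then j) for a set of size n. Vectorized; double precision is exact here
# because C(n, 2) stays far below 2^53.
decode_pair_index <- function(k, n) {
  # S(i) = number of pairs whose first index is <= i
  S <- function(i) i * n - i * (i + 1) / 2
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  # guard against floating-point boundary error
  i <- pmax(1, pmin(n - 1, i))
  lo <- S(i - 1)
  fix <- which(lo >= k)
  while (length(fix)) {
    i[fix] <- i[fix] - 1
    lo <- S(i - 1)
    fix <- which(lo >= k)
  }
  fix <- which(S(i) < k)
  while (length(fix)) {
    i[fix] <- i[fix] + 1
    lo <- S(i - 1)
    fix <- which(S(i) < k)
  }
  cbind(i = i, j = i + (k - S(i - 1)))
}

# Sample Bernoulli(p) edges among all unordered pairs within `ids`, or
# between `ids` and `ids2`, without materializing the pair space.
sample_pairs <- function(ids, p, ids2 = NULL) {
  if (is.null(ids2)) {
    n <- length(ids)
    npairs <- n * (n - 1) / 2
    if (npairs < 1 || p <= 0) return(NULL)
    m <- rbinom(1, npairs, p)
    if (m == 0) return(NULL)
    k <- sort(sample(npairs, m))
    ij <- decode_pair_index(k, n)
    cbind(ids[ij[, "i"]], ids[ij[, "j"]])
  } else {
    npairs <- length(ids) * length(ids2)
    if (npairs < 1 || p <= 0) return(NULL)
    m <- rbinom(1, npairs, p)
    if (m == 0) return(NULL)
    k <- sort(sample(npairs, m)) - 1
    cbind(ids[k %/% length(ids2) + 1], ids2[k %% length(ids2) + 1])
  }
}

#' Generate a synthetic interaction network
#'
#' Erdos-Renyi-style undirected simple graph over `genes` with edge
#' probability `mean_degree / (n - 1)`; pairs touching a planted up-regulated
#' gene have their edge probability multiplied by `up_connectivity_boost`,
#' planting the higher connectivity of the up-list that the network summaries
#' are expected to recover.
#'
#' @param genes Character vector of node ids.
#' @param mean_degree Target mean degree for background pairs; must be
#'   < `length(genes) - 1`.
#' @param up_connectivity_boost Multiplier (>= 1) on the edge probability of
#'   pairs with at least one endpoint in `truth$planted_up`.
#' @param truth Optional `ploidy_truth`; if `NULL` no boost is applied.
#' @param seed Integer seed.
#' @return An [igraph::igraph] object with all `genes` as vertices.
#' @export
generate_interactions <- function(genes, mean_degree = 6,
                                  up_connectivity_boost = 1,
                                  truth = NULL, seed = 1L) {
  n <- length(genes)
  assert_that(n >= 2, "need at least two genes")
  assert_that(mean_degree >= 0 && mean_degree < n - 1,
              "mean_degree must lie in [0, n - 1)")
  assert_that(up_connectivity_boost >= 1, "up_connectivity_boost must be >= 1")
  p <- mean_degree / (n - 1)
  assert_that(p * up_connectivity_boost <= 1,
              "boosted edge probability exceeds 1; lower mean_degree or boost")
  up <- if (is.null(truth)) character(0) else intersect(genes, truth$planted_up)
  other <- setdiff(genes, up)
  local_seed(seed, {
    edges <- rbind(
      sample_pairs(up, p * up_connectivity_boost),
      sample_pairs(up, p * up_connectivity_boost, other),
      sample_pairs(other, p)
    )
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, n, name = genes)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    g
  })
}

#' Generate a small random ontology (DAG) for pipeline plumbing
#'
#' Builds a random acyclic child-to-parent term hierarchy and random direct
#' gene-to-term assignments. This is test-bed plumbing so the enrichment
#' stage of the pipeline has an input in `simulate` mode; it plants no
#' enrichment signal.
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Number of terms.
#' @param seed Integer seed.
#' @return A list with `edges` (data.frame `child`, `parent`), `gene2term`
#'   (data.frame `gene_id`, `term`) and `terms` (data.frame `term`, `label`).
#' @export
simulate_ontology <- function(genes, n_terms = 30L, seed = 1L) {
  assert_that(n_terms >= 2, "need at least two terms")
  local_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    child <- parent <- character(0)
    for (i in 2:n_terms) {
      k <- sample(1:2, 1)
      par <- sample(i - 1, min(k, i - 1))
      child <- c(child, rep(terms[i], length(par)))
      parent <- c(parent, terms[par])
    }
    n_direct <- rbinom(length(genes), 3, 0.4)
    gene2term <- data.frame(
      gene_id = rep(genes, n_direct),
      term = terms[unlist(lapply(n_direct, function(k)
        if (k > 0) sample(n_terms, k) else integer(0)))],
      stringsAsFactors = FALSE
    )
    list(edges = data.frame(child = child, parent = parent,
                            stringsAsFactors = FALSE),
         gene2term = gene2term,
         terms = data.frame(term = terms, label = paste("module", terms),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a complete criss-cross dataset
#'
#' Convenience wrapper chaining [generate_annotation()], [plant_truth()],
#' [generate_expression()], [generate_interactions()] and
#' [simulate_ontology()]. Defaults state a world mirroring the magnitudes of
#' the motivating study: 14,093 ortholog-matched genes, 584 planted up / 711
#' planted down with log2 effects in \[1.0, 2.5\], a 3024/14093 background
#' bivalency rate rising to 0.457 among planted up genes, and old-up /
#' young-down stratum sign structure.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per design cell.
#' @param mean_degree,up_connectivity_boost Interaction-network parameters.
#' @param seed Integer seed controlling every stage.
#' @param ... Passed on to [plant_truth()].
#' @return A list with `expr_a`, `expr_b`, `ortholog_map`, `annotation`,
#'   `truth`, `graph`, `ontology`.
#' @export
simulate_ploidy_dataset <- function(n_genes = 14093L, n_reps = 3L,
                                    mean_degree = 6,
                                    up_connectivity_boost = 2,
                                    seed = 1L, ...) {
  ann <- generate_annotation(n_genes, seed = derive_seed(seed, 11))
  planted <- plant_truth(ann, seed = seed, ...)
  ex <- generate_expression(planted$truth, planted$annotation, n_reps = n_reps)
  graph <- generate_interactions(planted$annotation$gene_id,
                                 mean_degree = mean_degree,
                                 up_connectivity_boost = up_connectivity_boost,
                                 truth = planted$truth,
                                 seed = derive_seed(seed, 23))
  onto <- simulate_ontology(planted$annotation$gene_id,
                            seed = derive_seed(seed, 37))
  list(expr_a = ex$expr_a, expr_b = ex$expr_b,
       ortholog_map = ex$ortholog_map,
       annotation = planted$annotation, truth = planted$truth,
       graph = graph, ontology = onto)
}
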