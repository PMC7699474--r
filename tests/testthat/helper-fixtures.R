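# Shared fixture builders and independent oracles. Oracles deliberately use
# different primitives than the implementation (choose()-based enumeration,
# log-sum-exp over log pmf terms, boolean matrix closure) so each check has
# two routes.

# --- builders -------------------------------------------------------------

# Balanced criss-cross metadata: species A heart polyploid / liver diploid,
# species B reversed; n_reps samples per cell.
make_meta <- function(n_reps = 1) {
  design <- expand.grid(replicate = seq_len(n_reps),
                        tissue = c("heart", "liver"),
                        species = c("A", "B"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$ploidy <- ifelse((design$species == "A") ==
                            (design$tissue == "heart"),
                          "polyploid", "diploid")
  design$batch <- paste0("batch_", design$species, "_", design$tissue)
  design$sample_id <- paste0(design$species, "_", design$tissue,
                             "_r", design$replicate)
  design
}

# A prepared (log2-scale) object from a matrix of per-cell gene means.
# `means` columns must be named A_heart, B_heart, B_liver, A_liver.
prepared_from_means <- function(means, n_reps = 1, noise_sd = 0, seed = 1) {
  meta <- make_meta(n_reps)
  cell <- paste0(meta$species, "_", meta$tissue)
  lg <- means[, cell, drop = FALSE]
  colnames(lg) <- meta$sample_id
  if (noise_sd > 0) {
    set.seed(seed)
    lg <- lg + matrix(rnorm(length(lg), 0, noise_sd), nrow = nrow(lg))
  }
  if (is.null(rownames(lg))) rownames(lg) <- paste0("g", seq_len(nrow(lg)))
  list(log2 = lg, meta = meta)
}

# Simple annotation table.
make_annotation <- function(gene_id,
                            stratum = 1L,
                            bivalent = FALSE,
                            driver = "none") {
  data.frame(gene_id = gene_id,
             phylostratum = as.integer(rep_len(stratum, length(gene_id))),
             bivalent = rep_len(bivalent, length(gene_id)),
             driver_class = rep_len(driver, length(gene_id)),
             stringsAsFactors = FALSE)
}

# Generate-plant-express in one call without graph/ontology plumbing.
make_sim <- function(n_genes = 14093L, seed = 1L, n_reps = 3L, ...) {
  ann <- generate_annotation(n_genes, seed = seed + 1000L)
  planted <- plant_truth(ann, seed = seed, ...)
  ex <- generate_expression(planted$truth, planted$annotation,
                            n_reps = n_reps)
  c(ex, list(annotation = planted$annotation))
}

paired_from_sim <- function(sim, normalize = TRUE, pseudocount = 1) {
  paired <- match_orthologs(sim$expr_a, sim$expr_b, sim$ortholog_map,
                            sim$annotation)
  prepare_paired(paired, normalize = normalize, pseudocount = pseudocount)
}

# --- oracles --------------------------------------------------------------

# log10 of the one-sided binomial upper tail via log-sum-exp over log pmf
# terms (arbitrary-precision-like summation in log space).
oracle_binom_log10 <- function(k, n, p0) {
  if (k == 0) return(0)
  terms <- dbinom(k:n, n, p0, log = TRUE)
  m <- max(terms)
  (m + log(sum(exp(terms - m)))) / log(10)
}

# Exact enumeration of the binomial upper tail by choose() arithmetic
# (safe for n <= 20 at double precision).
oracle_binom_enum <- function(k, n, p0) {
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# Hypergeometric upper tail P(X >= k) by choose() enumeration.
oracle_hyper_enum <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force transitive closure of a child->parent edge table by boolean
# matrix iteration; returns a named list term -> ancestor set.
oracle_ancestors <- function(edges, terms) {
  A <- matrix(FALSE, length(terms), length(terms),
              dimnames = list(terms, terms))
  A[cbind(edges$child, edges$parent)] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  lapply(setNames(terms, terms), function(t) terms[R[t, ]])
}
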