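#' Principal component analysis with samples as variables
#'
#' Decomposes a log2 expression matrix treating samples as the variables and
#' genes as the statistical units (each sample column is mean-centered, no
#' scaling: covariance PCA). Gene scores are standardized per component to
#' unit variance so a score threshold of 2 means two standard deviations.
#'
#' @param values Gene x sample numeric matrix (log2 scale).
#' @return An object of class `ploidy_pca` with `loadings` (component x
#'   sample), `scores` (gene x component, unit variance), `sdev`,
#'   `variance_explained`, and (after [assign_components()]) `assignment`.
#' @export
run_pca <- function(values) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(ncol(values) >= 4,
              "need at least 4 samples (one per design cell)")
  pr <- prcomp(values, center = TRUE, scale. = FALSE)
  assert_that(any(pr$sdev > 1e-12), "matrix has zero variance")
  keep <- pr$sdev > 1e-12 * max(pr$sdev)
  sdev <- pr$sdev[keep]
  scores <- sweep(pr$x[, keep, drop = FALSE], 2, sdev, "/")
  structure(list(
    loadings = t(pr$rotation[, keep, drop = FALSE]),
    scores = scores,
    sdev = sdev,
    variance_explained = pr$sdev[keep]^2 / sum(pr$sdev^2)
  ), class = "ploidy_pca")
}

#' Assign principal components to design factors
#'
#' Greedily maps tissue, species and ploidy (in that order, descending
#' expected variance) to the component whose sample loadings have maximal
#' absolute point-biserial correlation with the factor indicator (computed
#' as the cosine between the loading direction and the centered indicator,
#' which keeps a dominant common-variation component from masquerading as a
#' factor), without component reuse; assignments with |r| below `r_min` are
#' left unassigned.
#' The highest-variance component left over is labelled `batch`. The ploidy
#' component is sign-oriented so polyploid samples load positively (scores
#' flip with it, keeping scores x loadings invariant).
#'
#' @param pca A `ploidy_pca` from [run_pca()].
#' @param meta Sample metadata with `tissue`, `species`, `ploidy` (rows in
#'   the column order of the PCA input matrix).
#' @param r_min Minimum absolute correlation for an assignment (default
#'   0.5).
#' @return The `ploidy_pca` with `assignment` (named integer vector over
#'   batch/tissue/species/ploidy; NA = unassigned) and `assignment_r`.
#' @export
assign_components <- function(pca, meta, r_min = 0.5) {
  stopifnot(inherits(pca, "ploidy_pca"))
  ncomp <- nrow(pca$loadings)
  assert_that(ncomp >= 4, "fewer components (%d) than design factors", ncomp)
  assert_that(nrow(meta) == ncol(pca$loadings),
              "metadata rows must match samples")
  ind <- list(
    tissue = as.numeric(meta$tissue == "heart"),
    species = as.numeric(meta$species == sort(unique(meta$species))[1]),
    ploidy = as.numeric(meta$ploidy == "polyploid")
  )
  assignment <- c(batch = NA_integer_, tissue = NA_integer_,
                  species = NA_integer_, ploidy = NA_integer_)
  assignment_r <- c(batch = NA_real_, tissue = NA_real_,
                    species = NA_real_, ploidy = NA_real_)
  available <- rep(TRUE, ncomp)
  # Correlation is measured between the loading direction itself and the
  # centered factor indicator (cosine similarity). Centering the loading as
  # well would let a dominant common-variation component - near-constant
  # loadings plus a slight factor tilt - masquerade as a perfect factor
  # match; the uncentered loading keeps such components near zero.
  dir_cor <- function(ld, indicator) {
    ic <- indicator - mean(indicator)
    sum(ld * ic) / sqrt(sum(ld^2) * sum(ic^2))
  }
  for (fac in c("tissue", "species", "ploidy")) {
    if (sd(ind[[fac]]) == 0) next  # factor constant: nothing to correlate
    r <- apply(pca$loadings, 1, dir_cor, indicator = ind[[fac]])
    r[!available] <- NA
    best <- which.max(abs(r))
    if (length(best) && is.finite(r[best]) && abs(r[best]) >= r_min) {
      assignment[fac] <- best
      assignment_r[fac] <- r[best]
      available[best] <- FALSE
    }
  }
  if (any(available)) {
    batch <- which(available)[which.max(pca$variance_explained[available])]
    assignment["batch"] <- batch
    assignment_r["batch"] <- NA_real_
  }
  pc <- assignment[["ploidy"]]
  if (!is.na(pc)) {
    mean_poly <- mean(pca$loadings[pc, ind$ploidy == 1])
    mean_dip <- mean(pca$loadings[pc, ind$ploidy == 0])
    if (mean_poly < mean_dip) {
      pca$loadings[pc, ] <- -pca$loadings[pc, ]
      pca$scores[, pc] <- -pca$scores[, pc]
      assignment_r["ploidy"] <- -assignment_r[["ploidy"]]
    }
  }
  pca$assignment <- assignment
  pca$assignment_r <- assignment_r
  pca
}

#' Select genes with extreme scores on the ploidy component
#'
#' @param pca A `ploidy_pca` with a ploidy component assigned (after sign
#'   orientation positive scores mean higher expression in polyploid
#'   samples).
#' @param threshold Standardized-score cutoff in SD units (default 2);
#'   boundary values are included.
#' @return List with character vectors `up` (score >= threshold) and `down`
#'   (score <= -threshold).
#' @export
select_component_genes <- function(pca, threshold = 2) {
  stopifnot(inherits(pca, "ploidy_pca"))
  assert_that(threshold > 0, "threshold must be > 0")
  assert_that(!is.null(pca$assignment), "run assign_components() first")
  pc <- pca$assignment[["ploidy"]]
  assert_that(!is.na(pc), "no component could be assigned to ploidy")
  sc <- pca$scores[, pc]
  list(up = rownames(pca$scores)[sc >= threshold],
       down = rownames(pca$scores)[sc <= -threshold])
}

#' @export
print.ploidy_pca <- function(x, ...) {
  cat(sprintf("ploidy_pca: %d components over %d samples\n",
              nrow(x$loadings), ncol(x$loadings)))
  ve <- round(100 * x$variance_explained[seq_len(min(6, nrow(x$loadings)))], 1)
  cat("variance explained (%):", paste(ve, collapse = ", "), "\n")
  if (!is.null(x$assignment)) {
    a <- x$assignment
    lab <- ifelse(is.na(a), "unassigned", paste0("PC", a))
    cat("assignment:", paste(names(a), lab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
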