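#' Reciprocal polyploid-vs-diploid contrasts
#'
#' Computes, per gene, the two reciprocal log2 fold-changes of the
#' criss-cross design: within each tissue pair, the mean log2 expression of
#' the polyploid samples minus that of the diploid samples. Because the
#' species that is polyploid inverts between heart and liver, a gene driven
#' by species (or tissue) rather than ploidy cannot be concordant in both
#' contrasts.
#'
#' @param prepared Output of [prepare_paired()]: a list with `log2`
#'   (gene x sample matrix) and `meta`.
#' @return Data.frame with columns `gene_id`, `lfc_heart`, `lfc_liver`
#'   (orientation: polyploid minus diploid in both).
#' @export
compute_ploidy_contrasts <- function(prepared) {
  lg <- prepared$log2
  meta <- prepared$meta
  out <- data.frame(gene_id = rownames(lg), stringsAsFactors = FALSE)
  for (tis in c("heart", "liver")) {
    poly <- meta$tissue == tis & meta$ploidy == "polyploid"
    dip <- meta$tissue == tis & meta$ploidy == "diploid"
    assert_that(any(poly) && any(dip),
                "missing polyploid or diploid samples in %s", tis)
    out[[paste0("lfc_", tis)]] <-
      rowMeans(lg[, poly, drop = FALSE]) - rowMeans(lg[, dip, drop = FALSE])
  }
  out
}

#' Classify genes by criss-cross concordance
#'
#' A gene is `up` when both reciprocal fold-changes are at or above
#' `log2(threshold_fold)`, `down` when both are at or below the negative
#' cutoff, `discordant` when both magnitudes pass the cutoff with opposite
#' signs, otherwise `below_threshold`. Boundary values are included
#' (inclusive comparisons) for determinism.
#'
#' @param contrasts Output of [compute_ploidy_contrasts()].
#' @param threshold_fold Linear fold threshold (> 1), e.g. 2.0 or 1.3.
#' @return The input with an added factor column `call` and attribute
#'   `threshold_fold`.
#' @export
classify_concordance <- function(contrasts, threshold_fold = 2.0) {
  assert_that(threshold_fold > 1, "threshold_fold must be > 1")
  cut <- log2(threshold_fold)
  h <- contrasts$lfc_heart
  l <- contrasts$lfc_liver
  call <- rep("below_threshold", nrow(contrasts))
  call[h >= cut & l >= cut] <- "up"
  call[h <= -cut & l <= -cut] <- "down"
  call[abs(h) >= cut & abs(l) >= cut & sign(h) != sign(l)] <- "discordant"
  contrasts$call <- factor(call, levels = c("up", "down", "discordant",
                                            "below_threshold"))
  attr(contrasts, "threshold_fold") <- threshold_fold
  contrasts
}

#' Select genes concordantly changed in both tissue contrasts
#'
#' @inheritParams classify_concordance
#' @param quiet Suppress the count message?
#' @return List with character vectors `up` and `down` (disjoint by
#'   construction).
#' @export
select_concordant_genes <- function(contrasts, threshold_fold = 2.0,
                                    quiet = FALSE) {
  cc <- classify_concordance(contrasts, threshold_fold)
  up <- cc$gene_id[cc$call == "up"]
  down <- cc$gene_id[cc$call == "down"]
  if (!quiet) {
    message(sprintf("fold %.2g: %d up, %d down concordant genes",
                    threshold_fold, length(up), length(down)))
  }
  list(up = up, down = down)
}

# Invert trigamma by monotone bisection (trigamma is strictly decreasing
# on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < x) return(lo)
  if (trigamma(hi) > x) return(hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Moderated per-gene tests of the two reciprocal contrasts
#'
#' A deliberately simplified empirical-Bayes moderation (not a replica of
#' precision-weighted linear modelling): per gene and tissue contrast, an
#' equal-variance two-sample comparison whose residual variance is shrunk
#' towards a pooled prior. The prior (s0^2, d0) is fitted by moment matching
#' on the log residual variances (digamma/trigamma moments of the scaled
#' chi-square), the posterior variance is the degrees-of-freedom-weighted
#' blend (d0*s0^2 + d*s2)/(d0 + d), and the two-sided p-value uses a t
#' distribution with d + d0 degrees of freedom. Genes with zero residual
#' variance are floored by the prior rather than yielding infinite
#' statistics.
#'
#' @inheritParams compute_ploidy_contrasts
#' @return Data.frame with `gene_id`, and per contrast the moderated `t`,
#'   two-sided `p`, plus attributes `d0` and `s2_prior` per tissue.
#' @export
moderated_test <- function(prepared) {
  lg <- prepared$log2
  meta <- prepared$meta
  out <- data.frame(gene_id = rownames(lg), stringsAsFactors = FALSE)
  for (tis in c("heart", "liver")) {
    poly <- which(meta$tissue == tis & meta$ploidy == "polyploid")
    dip <- which(meta$tissue == tis & meta$ploidy == "diploid")
    n1 <- length(poly); n2 <- length(dip)
    if (n1 < 2 || n2 < 2) {
      abort_validation(paste0(
        "fewer than 2 replicates per condition in ", tis,
        ": moderated testing needs replication; use fold-change-only mode"))
    }
    m1 <- rowMeans(lg[, poly, drop = FALSE])
    m2 <- rowMeans(lg[, dip, drop = FALSE])
    ss <- rowSums((lg[, poly, drop = FALSE] - m1)^2) +
      rowSums((lg[, dip, drop = FALSE] - m2)^2)
    d <- n1 + n2 - 2
    s2 <- ss / d
    z <- log(s2[s2 > 0 & is.finite(s2)])
    evar <- var(z) - trigamma(d / 2)
    if (!is.finite(evar) || evar <= 0) {
      d0 <- Inf
      s2_0 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s2_0 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                    digamma(d0 / 2) - log(d0 / 2))
    }
    s2_post <- if (is.finite(d0)) (d0 * s2_0 + d * s2) / (d0 + d) else
      rep(s2_0, length(s2))
    tt <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
    df <- if (is.finite(d0)) d + d0 else 1e6
    pp <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
    out[[paste0("t_", tis)]] <- tt
    out[[paste0("p_", tis)]] <- pp
    attr(out, paste0("d0_", tis)) <- d0
    attr(out, paste0("s2_prior_", tis)) <- s2_0
  }
  out
}
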