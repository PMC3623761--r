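#' Build the all-pairs differential-peak-count matrix
#'
#' Evaluates [differential_peak_count()] for every ordered pair of ChIP
#' samples: element `(i, j)` is the number of peaks enriched in sample `i`
#' when called against sample `j` that pass the differential filters. The
#' diagonal is zero and the matrix is generally asymmetric.
#'
#' @param reads named list of `genomic_intervals` read tables (ChIP
#'   samples only).
#' @param promoter_totals named vector of promoter-anchored read totals.
#' @param config a [peak_caller_config()].
#' @param p,ratio,min_density differential thresholds, see
#'   [differential_peak_count()].
#' @return integer matrix (samples x samples) with zero diagonal.
#' @export
build_differential_matrix <- function(reads, promoter_totals,
                                      config = peak_caller_config(),
                                      p = 1e-20, ratio = 4, min_density = 0.005) {
  n <- length(reads)
  stopifnot(n >= 3L, !is.null(names(reads)),
            all(names(reads) %in% names(promoter_totals)))
  m <- matrix(0L, n, n, dimnames = list(names(reads), names(reads)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- differential_peak_count(
        reads[[i]], reads[[j]],
        promoter_totals[[names(reads)[i]]], promoter_totals[[names(reads)[j]]],
        p = p, ratio = ratio, min_density = min_density, config = config)
    }
  }
  m
}

#' Principal components of the differential-count matrix
#'
#' Rows are treated as per-sample feature vectors; columns are
#' mean-centred (no variance scaling, since all entries share the count
#' scale) and components come from the eigendecomposition of the column
#' covariance. Components are ordered by descending eigenvalue and each
#' component's sign is fixed by making its loading on the first column
#' non-negative, so identical inputs give bit-identical scores.
#'
#' @param m a complete numeric matrix (samples x features); typically the
#'   output of [build_differential_matrix()].
#' @param symmetrize replace `m` with `m + t(m)` before the PCA.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `variance_fraction`, `loadings`, `eigenvalues`.
#' @export
pca_scores <- function(m, symmetrize = FALSE) {
  if (any(is.na(m))) stop("matrix has missing entries; PCA refuses missing values")
  if (symmetrize) m <- m + t(m)
  if (all(m == 0)) stop("no structure: differential matrix is all zeros")
  centred <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centred), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  flip <- ifelse(vecs[1L, ] < 0, -1, 1)
  vecs <- sweep(vecs, 2L, flip, "*")
  scores <- centred %*% vecs
  k <- ncol(scores)
  colnames(scores) <- colnames(vecs) <- sprintf("PC%d", seq_len(k))
  out <- list(scores = scores, variance_fraction = vals / sum(vals),
              loadings = vecs, eigenvalues = vals)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("pca_result: %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * vf[1L], 100 * ifelse(length(vf) > 1, vf[2L], 0)))
  invisible(x)
}

#' Rank-sum separation of age groups along principal components
#'
#' Quantifies whether the first component separates prenatal samples from
#' the rest and the second separates prenatal-plus-infant samples from the
#' rest. Each test is a Wilcoxon rank-sum on the component scores, taken
#' one-sided in the direction of the observed group difference (the PCA
#' sign convention carries no meaning).
#'
#' @param pca a `pca_result` whose score rows are named by sample.
#' @param groups factor/character vector of age groups per sample
#'   (`prenatal` / `infant` / `older`), aligned with the score rows.
#' @return named vector: `p_pc1_prenatal`, `p_pc2_prenatal_infant`.
#' @export
group_separation_score <- function(pca, groups) {
  sc <- pca$scores
  stopifnot(length(groups) == nrow(sc))
  one_sided <- function(x, in_group) {
    if (sum(in_group) == 0L || sum(!in_group) == 0L) return(NA_real_)
    # exact distribution when scores are tie-free, normal approximation
    # otherwise (tied scores carry no separation signal anyway)
    exact <- !any(duplicated(x))
    lo <- suppressWarnings(stats::wilcox.test(x[in_group], x[!in_group],
                                              alternative = "less", exact = exact)$p.value)
    hi <- suppressWarnings(stats::wilcox.test(x[in_group], x[!in_group],
                                              alternative = "greater", exact = exact)$p.value)
    min(lo, hi)
  }
  c(p_pc1_prenatal = one_sided(sc[, 1L], groups == "prenatal"),
    p_pc2_prenatal_infant = if (ncol(sc) > 1L) {
      one_sided(sc[, 2L], groups %in% c("prenatal", "infant"))
    } else NA_real_)
}
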