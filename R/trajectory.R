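#' Assign samples to developmental age groups
#'
#' `prenatal` if age <= 0 (at or before term: gestational ages map to
#' non-positive years, and a 40-gw specimen is still prenatal), `infant`
#' if 0 < age < 1 yr, `older` if age >= 1 yr. Infants are retained for
#' profiles but never enter the up/down detection test.
#'
#' @param age_years numeric ages (prenatal ages non-positive, see
#'   [gw_to_years()]).
#' @return character vector of group labels.
#' @export
assign_age_groups <- function(age_years) {
  ifelse(age_years <= 0, "prenatal", ifelse(age_years < 1, "infant", "older"))
}

#' Trajectory call configuration
#'
#' @param density_floor minimum mean density in the higher group (default
#'   0.01 on the reads/bp/million-promoter-reads scale).
#' @param min_fold minimum fold change between group means (default 2).
#' @param max_p maximum t-test p-value (default 0.05).
#' @param min_length minimum region length in bp (default 1000; applied to
#'   both up and down calls).
#' @param var_equal use pooled-variance Student's t instead of the default
#'   Welch unequal-variance t.
#' @return list of class `trajectory_call_config`.
#' @export
trajectory_call_config <- function(density_floor = 0.01, min_fold = 2,
                                   max_p = 0.05, min_length = 1000L,
                                   var_equal = FALSE) {
  stopifnot(density_floor > 0, min_fold > 0, max_p > 0, max_p < 1, min_length > 0)
  cfg <- list(density_floor = density_floor, min_fold = min_fold,
              max_p = max_p, min_length = as.integer(min_length),
              var_equal = var_equal)
  class(cfg) <- "trajectory_call_config"
  cfg
}

# vectorised two-sample t over matrix rows; returns p-values
.row_ttest_p <- function(x1, x2, var_equal = FALSE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- NA_real_
  p
}

#' Classify regions into up/down developmental trajectories
#'
#' The core decision rule: a region is called `down` iff its prenatal mean
#' density is at least `density_floor`, the prenatal/older fold is at
#' least `min_fold`, the two-sided t-test p comparing prenatal with older
#' samples is at most `max_p`, and the region is at least `min_length` bp.
#' `up` uses the reciprocal criteria (floor on the older mean, older/
#' prenatal fold). Infant samples never enter the test. Regions with zero
#' variance in both groups get an undefined p and class `none`.
#'
#' @param matrix a `density_matrix`.
#' @param groups age-group labels per sample column (see
#'   [assign_age_groups()]).
#' @param cfg a [trajectory_call_config()].
#' @return data.frame of class `trajectory_calls`: `region_id`, `length`,
#'   `klass` (`up`/`down`/`none`), `prenatal_mean`, `older_mean`, `fold`
#'   (older-relative: > 1 means up), `p_value`.
#' @export
classify_up_down <- function(matrix, groups, cfg = trajectory_call_config()) {
  dm <- matrix
  stopifnot(inherits(dm, "density_matrix"), length(groups) == ncol(dm$values))
  pre <- which(groups == "prenatal")
  old <- which(groups == "older")
  if (length(pre) < 2L || length(old) < 2L) {
    stop("need >= 2 prenatal and >= 2 older samples")
  }
  v <- dm$values
  len <- dm$regions$end - dm$regions$start
  m_pre <- rowMeans(v[, pre, drop = FALSE])
  m_old <- rowMeans(v[, old, drop = FALSE])
  p <- .row_ttest_p(v[, pre, drop = FALSE], v[, old, drop = FALSE],
                    var_equal = cfg$var_equal)
  ok <- !is.na(p) & p <= cfg$max_p & len >= cfg$min_length
  down <- ok & m_pre >= cfg$density_floor & m_pre >= cfg$min_fold * m_old
  up <- ok & m_old >= cfg$density_floor & m_old >= cfg$min_fold * m_pre
  klass <- ifelse(down, "down", ifelse(up, "up", "none"))
  calls <- data.frame(region_id = dm$regions$id, length = len, klass = klass,
                      prenatal_mean = m_pre, older_mean = m_old,
                      fold = ifelse(m_pre == 0, Inf, m_old / m_pre),
                      p_value = p, stringsAsFactors = FALSE)
  class(calls) <- c("trajectory_calls", "data.frame")
  calls
}

#' @export
print.trajectory_calls <- function(x, ...) {
  tb <- table(factor(x$klass, levels = c("down", "up", "none")))
  cat(sprintf("trajectory_calls: %d regions; %d down, %d up, %d unchanged\n",
              nrow(x), tb[["down"]], tb[["up"]], tb[["none"]]))
  invisible(x)
}

#' Average density profile of a region subset
#'
#' Arithmetic mean across the selected regions for each sample, in the
#' matrix's sample order (sort the cohort by age upstream to read the
#' profile as an age course).
#'
#' @param matrix a `density_matrix`.
#' @param region_subset region ids (or logical/integer index into the
#'   region rows).
#' @return named numeric vector, one mean per sample.
#' @export
mean_profile <- function(matrix, region_subset) {
  dm <- matrix
  idx <- if (is.character(region_subset)) {
    match(region_subset, dm$regions$id)
  } else which(rep_len(TRUE, nrow(dm$values)))[region_subset]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("empty region subset")
  colMeans(dm$values[idx, , drop = FALSE])
}

#' Filter regions and max-normalize their profiles for clustering
#'
#' Keeps regions at least `min_length` bp whose mean density reaches the
#' floor in the prenatal or in the older group, excludes chrY, then
#' divides each region's profile by its maximum across samples so every
#' retained profile lies in `[0, 1]` with maximum exactly 1. All-zero
#' profiles are dropped with a message.
#'
#' @param matrix a `density_matrix`.
#' @param groups age-group labels per sample column.
#' @param cfg a [trajectory_call_config()] (supplies the floor and length
#'   threshold).
#' @return numeric matrix of normalized profiles (rows named by region).
#' @export
filter_and_normalize_for_clustering <- function(matrix, groups,
                                                cfg = trajectory_call_config()) {
  dm <- matrix
  v <- dm$values
  len <- dm$regions$end - dm$regions$start
  pre <- groups == "prenatal"
  old <- groups == "older"
  keep <- len >= cfg$min_length & dm$regions$chrom != "chrY" &
    (rowMeans(v[, pre, drop = FALSE]) >= cfg$density_floor |
       rowMeans(v[, old, drop = FALSE]) >= cfg$density_floor)
  v <- v[keep, , drop = FALSE]
  mx <- apply(v, 1L, max)
  if (any(mx == 0)) {
    message(sprintf("dropping %d all-zero profile(s)", sum(mx == 0)))
    v <- v[mx > 0, , drop = FALSE]
    mx <- mx[mx > 0]
  }
  v / mx
}

#' k-means clustering of max-normalized age profiles
#'
#' Euclidean k-means (base R `kmeans`, Hartigan-Wong) with `n_init`
#' random restarts under a fixed seed; the best restart by total
#' within-cluster sum of squares is returned, so identical inputs and
#' seeds give identical assignments.
#'
#' @param profiles normalized profile matrix from
#'   [filter_and_normalize_for_clustering()].
#' @param k number of clusters (default 5).
#' @param seed RNG seed for the restarts.
#' @param n_init number of random restarts.
#' @return list of class `cluster_result`: `k`, `assignment` (named by
#'   region), `centroids` (k x samples), `withinss`.
#' @export
kmeans_profiles <- function(profiles, k = 5L, seed = 1L, n_init = 10L) {
  if (k > nrow(profiles)) stop("k exceeds the number of profiles")
  set.seed(seed)
  km <- stats::kmeans(profiles, centers = k, nstart = n_init, iter.max = 100L)
  out <- list(k = k,
              assignment = stats::setNames(km$cluster, rownames(profiles)),
              centroids = km$centers, withinss = km$tot.withinss)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, sizes %s, total within-SS %.3f\n",
              x$k, paste(table(x$assignment), collapse = "/"), x$withinss))
  invisible(x)
}

#' Label a cluster centroid's age trend
#'
#' Spearman rank correlation of the centroid against sample age: `up` if
#' rho is at least `threshold`, `down` if at most `-threshold`, else
#' `flat`. A constant centroid is `flat`.
#'
#' @param centroid per-sample centroid values.
#' @param ages sample ages aligned with the centroid.
#' @param threshold absolute rank-correlation threshold (default 0.5).
#' @return one of `"up"`, `"down"`, `"flat"`.
#' @export
label_cluster_trend <- function(centroid, ages, threshold = 0.5) {
  stopifnot(length(centroid) == length(ages))
  if (stats::sd(centroid) == 0) return("flat")
  rho <- stats::cor(centroid, ages, method = "spearman")
  if (rho >= threshold) "up" else if (rho <= -threshold) "down" else "flat"
}

#' Mean expression profile of a gene set
#'
#' Arithmetic mean of the log2 expression signals across the gene set for
#' each sample; genes absent from the table are dropped and reported.
#'
#' @param expr expression matrix (genes x samples, log2 scale).
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-sample means, with attribute
#'   `n_missing`.
#' @export
geneset_mean_expression <- function(expr, gene_set) {
  hit <- intersect(gene_set, rownames(expr))
  if (length(hit) == 0L) {
    stop(sprintf("no overlap: gene set of %d gene(s) vs expression table of %d gene(s)",
                 length(gene_set), nrow(expr)))
  }
  miss <- length(gene_set) - length(hit)
  if (miss > 0) message(sprintf("%d gene(s) of the set absent from the expression table", miss))
  structure(colMeans(expr[hit, , drop = FALSE]), n_missing = miss)
}
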