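#' Count reads overlapping each region
#'
#' A read contributes to a region iff its interval overlaps at least one
#' base of the region. The region set must be disjoint so that no read can
#' be assigned twice; overlapping sets are rejected with a pointer to
#' [merge_intervals()].
#'
#' @param reads a `genomic_intervals` table of read intervals.
#' @param regions a disjoint `genomic_intervals` table.
#' @return integer vector of counts, one per region (in region order).
#' @export
count_reads <- function(reads, regions) {
  if (.has_overlap(regions)) {
    stop("regions overlap; counts would double-assign reads - merge them first with merge_intervals()")
  }
  counts <- integer(nrow(regions))
  if (nrow(reads) == 0L || nrow(regions) == 0L) return(counts)
  for (cn in intersect(unique(regions$chrom), unique(reads$chrom))) {
    qi <- which(regions$chrom == cn)
    si <- which(reads$chrom == cn)
    counts[qi] <- IRanges::countOverlaps(.iranges(regions$start[qi], regions$end[qi]),
                                         .iranges(reads$start[si], reads$end[si]))
  }
  counts
}

.has_overlap <- function(regions) {
  if (nrow(regions) < 2L) return(FALSE)
  for (cn in unique(regions$chrom)) {
    i <- which(regions$chrom == cn)
    if (length(i) < 2L) next
    o <- order(regions$start[i])
    if (any(regions$start[i][o][-1L] < regions$end[i][o][-length(i)])) return(TRUE)
  }
  FALSE
}

#' Promoter-anchored normalized read density
#'
#' `density = count / (region_length * promoter_total / 1e6)`: reads per bp
#' per million promoter-anchored reads. On this scale the default call
#' thresholds (density floor 0.01, differential floor 0.005) are
#' meaningful.
#'
#' @param count read count(s) in the region.
#' @param region_length region length(s) in bp (> 0).
#' @param promoter_total the sample's total reads overlapping any promoter
#'   region (> 0; a sample with zero promoter reads is unusable).
#' @return density value(s).
#' @examples
#' promoter_normalized_density(100, 1000, 1e7)  # 0.01
#' @export
promoter_normalized_density <- function(count, region_length, promoter_total) {
  if (any(promoter_total <= 0)) stop("promoter_total must be > 0 (sample unusable)")
  if (any(region_length <= 0)) stop("region_length must be > 0")
  count / (region_length * promoter_total / 1e6)
}

#' Build the regions-by-samples density matrix
#'
#' Counts each sample's reads in the (disjoint) quantification regions and
#' normalizes by region length and by the sample's promoter-anchored read
#' total (reads overlapping any merged promoter region). Samples with zero
#' promoter reads are excluded with a warning.
#'
#' @param reads named list of `genomic_intervals`, one per sample.
#' @param regions disjoint `genomic_intervals` to quantify.
#' @param promoters a `promoter_set` from [build_promoters()] supplying the
#'   per-sample normalization denominator.
#' @return list of class `density_matrix`: `values` (regions x samples),
#'   `regions`, `samples`, `promoter_total` (named vector), `counts`.
#' @export
build_density_matrix <- function(reads, regions, promoters) {
  stopifnot(is.list(reads), length(reads) >= 1L, !is.null(names(reads)))
  prom_total <- vapply(reads, function(r) sum(count_reads(r, promoters$regions)), 0)
  usable <- prom_total > 0
  if (any(!usable)) {
    warning(sprintf("excluding %d sample(s) with zero promoter reads: %s",
                    sum(!usable), paste(names(reads)[!usable], collapse = ", ")))
  }
  reads <- reads[usable]
  prom_total <- prom_total[usable]
  counts <- vapply(reads, function(r) count_reads(r, regions), integer(nrow(regions)))
  if (!is.matrix(counts)) {
    counts <- matrix(counts, nrow = nrow(regions), dimnames = list(NULL, names(reads)))
  }
  len <- regions$end - regions$start
  values <- sweep(counts / len, 2L, prom_total / 1e6, "/")
  rownames(values) <- rownames(counts) <- regions$id
  dm <- list(values = values, regions = regions, samples = names(reads),
             promoter_total = prom_total, counts = counts)
  class(dm) <- "density_matrix"
  dm
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf("density_matrix: %d regions x %d samples (reads/bp/million promoter reads)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  promoter totals: %s-%s reads\n",
              format(min(x$promoter_total)), format(max(x$promoter_total))))
  invisible(x)
}

#' Pairwise Pearson correlation between samples
#'
#' Standard Pearson correlation over the region dimension for every pair of
#' sample columns. Zero-variance samples get `NA` rows/columns and are
#' reported in the `undefined` attribute.
#'
#' @param matrix a `density_matrix` or a plain numeric matrix
#'   (regions x samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_pearson <- function(matrix) {
  m <- if (inherits(matrix, "density_matrix")) matrix$values else matrix
  if (nrow(m) < 2L) stop("need >= 2 regions to correlate samples")
  sds <- apply(m, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  bad <- which(sds == 0)
  if (length(bad)) {
    cc[bad, ] <- NA_real_
    cc[, bad] <- NA_real_
  }
  diag(cc) <- ifelse(seq_len(ncol(m)) %in% bad, NA_real_, 1)
  attr(cc, "undefined") <- colnames(m)[bad]
  cc
}
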