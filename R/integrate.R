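#' Assign peaks to genes by TSS proximity
#'
#' A peak is linked to a gene iff the distance between the peak and one of
#' the gene's TSSs is at most `window` bp (distance 0 when the TSS falls
#' inside the peak; otherwise the gap to the nearer peak edge; the
#' boundary is inclusive). A peak may map to several genes and vice versa;
#' peaks with no link are reported as distal via the `distal` attribute.
#'
#' @param peaks a `genomic_intervals` table (peak or region coordinates
#'   with ids).
#' @param annotation gene annotation (`gene_id`, `chrom`, `tss`).
#' @param window maximum distance in bp (default 2000).
#' @return data.frame `region_id`, `gene_id`, `tss`, `distance`, with
#'   attribute `distal` (unassigned peak ids).
#' @export
peaks_to_genes <- function(peaks, annotation, window = 2000L) {
  stopifnot(window > 0)
  links <- list()
  for (cn in intersect(unique(peaks$chrom), unique(annotation$chrom))) {
    pi <- which(peaks$chrom == cn)
    ai <- which(annotation$chrom == cn)
    ext <- .iranges(pmax(0L, peaks$start[pi] - window), peaks$end[pi] + window)
    ov <- IRanges::findOverlaps(IRanges::IRanges(annotation$tss[ai] + 1L,
                                                 annotation$tss[ai] + 1L), ext)
    qa <- ai[S4Vectors::queryHits(ov)]
    sp <- pi[S4Vectors::subjectHits(ov)]
    tss <- annotation$tss[qa]
    d <- ifelse(tss < peaks$start[sp], peaks$start[sp] - tss,
                ifelse(tss >= peaks$end[sp], tss - peaks$end[sp] + 1L, 0L))
    links[[cn]] <- data.frame(region_id = peaks$id[sp],
                              gene_id = annotation$gene_id[qa],
                              tss = tss, distance = as.integer(d),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(links)) do.call(rbind, links) else {
    data.frame(region_id = character(), gene_id = character(),
               tss = integer(), distance = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "distal") <- setdiff(peaks$id, out$region_id)
  out
}

#' Classify genes by coordinated regulation of alternative promoters
#'
#' For genes with at least two distinct called promoter peaks (class `up`
#' or `down`) whose TSSs lie within `span` bp of each other: `up+down`
#' when a discordant pair exists, otherwise `up+up` or `down+down`.
#' Genes without a qualifying pair are omitted.
#'
#' @param links peak-gene links from [peaks_to_genes()].
#' @param calls a `trajectory_calls` table supplying each region's class.
#' @param span maximum TSS separation in bp (default 100 kb).
#' @return data.frame `gene_id`, `class`, `n_promoters`.
#' @export
alternative_promoter_classes <- function(links, calls, span = 100000L) {
  kl <- stats::setNames(calls$klass, calls$region_id)
  lk <- links[kl[links$region_id] %in% c("up", "down"), , drop = FALSE]
  lk$klass <- kl[lk$region_id]
  out <- list()
  for (g in unique(lk$gene_id)) {
    gi <- lk[lk$gene_id == g, , drop = FALSE]
    gi <- gi[!duplicated(gi$region_id), , drop = FALSE]
    if (nrow(gi) < 2L) next
    pair_class <- character()
    for (i in seq_len(nrow(gi) - 1L)) {
      for (j in (i + 1L):nrow(gi)) {
        if (abs(gi$tss[i] - gi$tss[j]) <= span) {
          pair_class <- c(pair_class,
                          paste(sort(c(gi$klass[i], gi$klass[j])), collapse = "+"))
        }
      }
    }
    if (length(pair_class) == 0L) next
    cls <- if ("down+up" %in% pair_class) "up+down"
           else if ("up+up" %in% pair_class) "up+up" else "down+down"
    out[[g]] <- data.frame(gene_id = g, class = cls, n_promoters = nrow(gi),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(gene_id = character(), class = character(),
               n_promoters = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Per-CpG age test of methylation change
#'
#' Two-sided Welch t-test per CpG comparing prenatal with older-than-one-
#' year samples, Benjamini-Hochberg FDR across all tested CpGs, and a
#' direction call (`decrease` / `increase` / `none`) by the sign of the
#' older-minus-prenatal mean at the chosen FDR cutoff. Constant CpGs are
#' excluded from the FDR family and reported.
#'
#' @param meth methylation table from [simulate_methylation()] (or same
#'   layout: `cpg_id`, `gene_id`, then beta columns).
#' @param groups age-group labels aligned with the beta columns.
#' @param fdr_cutoff FDR threshold for a direction call (0.05 default; the
#'   stricter 1e-10 is the robustness alternative).
#' @return data.frame `cpg_id`, `gene_id`, `delta` (older - prenatal),
#'   `p`, `fdr`, `direction`.
#' @export
cpg_age_test <- function(meth, groups, fdr_cutoff = 0.05) {
  beta_cols <- setdiff(names(meth), c("cpg_id", "gene_id", "chrom", "pos"))
  stopifnot(length(groups) == length(beta_cols))
  b <- as.matrix(meth[, beta_cols, drop = FALSE])
  pre <- which(groups == "prenatal")
  old <- which(groups == "older")
  if (length(pre) < 2L || length(old) < 2L) stop("need >= 2 samples per tested group")
  p <- .row_ttest_p(b[, pre, drop = FALSE], b[, old, drop = FALSE])
  delta <- rowMeans(b[, old, drop = FALSE]) - rowMeans(b[, pre, drop = FALSE])
  if (anyNA(p)) message(sprintf("%d constant CpG(s) excluded from the FDR family", sum(is.na(p))))
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  direction <- ifelse(!is.na(fdr) & fdr <= fdr_cutoff,
                      ifelse(delta < 0, "decrease", "increase"), "none")
  data.frame(cpg_id = meth$cpg_id, gene_id = meth$gene_id,
             delta = delta, p = p, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: `n` draws without
#' replacement from a universe of `N` objects of which `K` are successes.
#' Computed through the log-space distribution function, so extreme tails
#' do not underflow.
#'
#' @param k observed successes among the draws.
#' @param n number of draws.
#' @param K successes in the universe.
#' @param N universe size.
#' @return upper-tail probability.
#' @examples
#' hypergeometric_upper_tail(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  if (any(k < 0 | k > n | n > N | K > N | K < 0)) {
    stop("inconsistent margins: need 0 <= k <= n <= N and 0 <= K <= N")
  }
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Cross-tabulate histone trajectory direction against methylation decrease
#'
#' Rows are CpGs near genes with up- vs down-trajectory histone peaks;
#' columns are CpGs with vs without a significant methylation decrease.
#' The association p-value is the hypergeometric upper tail on the up-row:
#' the probability of at least as many decreased CpGs among the up-gene
#' CpGs if decreased CpGs were distributed at random.
#'
#' @param gene_classes named character vector mapping gene id to `"up"` or
#'   `"down"`.
#' @param cpg_results output of [cpg_age_test()].
#' @return list of class `contingency_result`: `counts` (2x2), `p`.
#' @export
direction_contingency <- function(gene_classes, cpg_results) {
  cls <- gene_classes[cpg_results$gene_id]
  keep <- !is.na(cls) & cls %in% c("up", "down")
  cls <- cls[keep]
  dec <- cpg_results$direction[keep] == "decrease"
  counts <- matrix(c(sum(cls == "up" & dec), sum(cls == "up" & !dec),
                     sum(cls == "down" & dec), sum(cls == "down" & !dec)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c("h3k4me3_up", "h3k4me3_down"),
                                   c("meth_decreased", "not_decreased")))
  n_up <- sum(counts[1L, ])
  p <- if (n_up == 0L || sum(counts[2L, ]) == 0L) NA_real_ else {
    hypergeometric_upper_tail(counts[1L, 1L], n_up, sum(counts[, 1L]), sum(counts))
  }
  structure(list(counts = counts, p = p), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$counts)
  cat(sprintf("hypergeometric upper-tail p = %.3g\n", x$p))
  invisible(x)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, the upper-tail probability of the observed overlap
#' between the gene set and the term's genes within the universe, with
#' Benjamini-Hochberg FDR across terms and an enrichment score of
#' `-log10(FDR)`. Terms disjoint from the universe are skipped.
#'
#' @param gene_set character vector of genes (must be within `universe`).
#' @param term_annotation data.frame with columns `term`, `gene`.
#' @param universe character vector of all assayable genes.
#' @return data.frame `term`, `overlap`, `term_size`, `p`, `fdr`, `score`,
#'   ordered by p.
#' @export
overrepresentation <- function(gene_set, term_annotation, universe) {
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of the universe")
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  terms <- split(term_annotation$gene, term_annotation$term)
  rows <- list()
  for (tm in names(terms)) {
    tg <- intersect(unique(terms[[tm]]), universe)
    if (length(tg) == 0L) {
      message(sprintf("term '%s' disjoint from universe: skipped", tm))
      next
    }
    k <- length(intersect(gene_set, tg))
    rows[[tm]] <- data.frame(term = tm, overlap = k, term_size = length(tg),
                             p = hypergeometric_upper_tail(k, length(gene_set),
                                                           length(tg), length(universe)),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$score <- -log10(res$fdr)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Correlate enrichment-score landscapes between two gene sets
#'
#' Shared terms are included if the FDR is below `inclusion_fdr` in either
#' result list; the Pearson correlation of their `-log10(FDR)` scores is
#' returned together with the term count.
#'
#' @param results_a,results_b outputs of [overrepresentation()].
#' @param inclusion_fdr inclusion threshold (default 0.85).
#' @return list `r` (Pearson correlation, NA if fewer than 3 terms),
#'   `n_terms`.
#' @export
enrichment_score_correlation <- function(results_a, results_b,
                                         inclusion_fdr = 0.85) {
  shared <- intersect(results_a$term, results_b$term)
  a <- results_a[match(shared, results_a$term), ]
  b <- results_b[match(shared, results_b$term), ]
  keep <- a$fdr < inclusion_fdr | b$fdr < inclusion_fdr
  if (sum(keep) < 3L) {
    warning("fewer than 3 terms pass the inclusion threshold: correlation undefined")
    return(list(r = NA_real_, n_terms = sum(keep)))
  }
  list(r = stats::cor(a$score[keep], b$score[keep]), n_terms = sum(keep))
}
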