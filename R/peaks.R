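#' Peak caller configuration
#'
#' A simplified sliding-window local-Poisson enrichment caller: fixed
#' windows of width `2 * bw` advanced by `bw`, with the background
#' expectation taken as the maximum of depth-scaled control rates measured
#' at 1 kb, 5 kb, 10 kb and genome-wide scales around each window.
#'
#' @param bw bandwidth in bp (window width is `2 * bw`, step is `bw`).
#' @param tsize mapped read length in bp.
#' @param p_threshold Poisson upper-tail p-value threshold for a window.
#' @param local_windows widths (bp) of the local background windows; the
#'   genome-wide rate is always included.
#' @return list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(bw = 230L, tsize = 36L, p_threshold = 1e-5,
                               local_windows = c(1000L, 5000L, 10000L)) {
  stopifnot(bw > 0, tsize > 0, p_threshold > 0, p_threshold < 1,
            all(local_windows > 0))
  cfg <- list(bw = as.integer(bw), tsize = as.integer(tsize),
              p_threshold = p_threshold,
              local_windows = as.integer(local_windows))
  class(cfg) <- "peak_caller_config"
  cfg
}

#' Poisson upper-tail probability in log10 space
#'
#' `log10 P(X >= k)` for `X ~ Poisson(lambda)`, computed in log space so
#' extreme counts do not underflow. `P(X >= 0) = 1` by convention.
#'
#' @param k observed count(s), `>= 0`.
#' @param lambda expectation(s), `> 0`.
#' @return log10 p-value(s), `<= 0`.
#' @examples
#' 10^poisson_upper_tail(5, 1)  # ~3.66e-3
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  out <- stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
  out[k == 0] <- 0
  pmin(out, 0)
}

# max-of-scales local lambda for query intervals [start,end) on one
# chromosome, from control read starts/ends there
.local_lambda <- function(start, end, ctrl_start, ctrl_end, scales,
                          genome_rate, depth_ratio) {
  width <- end - start
  lam <- genome_rate * width * depth_ratio
  if (length(ctrl_start)) {
    ctrl <- .iranges(ctrl_start, ctrl_end)
    centre <- (start + end) / 2
    for (w in scales) {
      cnt <- IRanges::countOverlaps(
        .iranges(pmax(0, floor(centre - w / 2)), ceiling(centre + w / 2)), ctrl)
      lam <- pmax(lam, cnt * (width / w) * depth_ratio)
    }
  }
  pmax(lam, 1e-9)
}

#' Call enriched peaks against a control sample
#'
#' Slides windows of width `2 * bw` with step `bw` over every chromosome
#' covered by the treatment; a window is significant iff the Poisson
#' upper-tail p-value of its treatment count against the local background
#' expectation is at or below `p_threshold`. The local expectation is the
#' maximum of the depth-scaled control rate measured over 1 kb, 5 kb,
#' 10 kb windows centred on the window and genome-wide. Overlapping or
#' abutting significant windows are merged into peaks; each peak is then
#' re-scored over its full extent (aggregated count against the
#' peak-scale local lambda), and the minimum member-window p is kept
#' alongside.
#'
#' @param treatment,control `genomic_intervals` read tables; the control
#'   may be the input sample or another ChIP sample.
#' @param config a [peak_caller_config()].
#' @param sample_id optional label stored on the peaks.
#' @return data.frame of class `peak_set`: `chrom`, `start`, `end`,
#'   `count`, `lambda`, `log10p` (peak-scale), `log10p_window` (min member
#'   window), `enrichment`, `sample_id`.
#' @export
call_peaks <- function(treatment, control, config = peak_caller_config(),
                       sample_id = NA_character_) {
  cfg <- config
  if (nrow(treatment) == 0L) {
    warning("empty treatment read set: no peaks")
    return(.empty_peaks(sample_id))
  }
  if (nrow(control) == 0L) stop("control read set is empty")
  depth_ratio <- nrow(treatment) / nrow(control)
  n_windows <- 0L
  n_significant <- 0L
  # genome extent estimated from both read sets
  all_chrom <- unique(c(treatment$chrom, control$chrom))
  extent <- vapply(all_chrom, function(cn) {
    max(treatment$end[treatment$chrom == cn], control$end[control$chrom == cn], 0L)
  }, 0)
  genome_rate <- nrow(control) / sum(extent)
  out <- list()
  for (cn in unique(treatment$chrom)) {
    ti <- which(treatment$chrom == cn)
    ci <- which(control$chrom == cn)
    if (length(ci) == 0L) {
      message(sprintf("chromosome %s absent from control: genome-wide lambda used", cn))
    }
    chrom_end <- extent[[cn]]
    win_start <- seq(0L, max(0L, chrom_end - cfg$bw), by = cfg$bw)
    win_end <- pmin(win_start + 2L * cfg$bw, chrom_end)
    treads <- .iranges(treatment$start[ti], treatment$end[ti])
    cnt <- IRanges::countOverlaps(.iranges(win_start, win_end), treads)
    lam <- .local_lambda(win_start, win_end, control$start[ci], control$end[ci],
                         cfg$local_windows, genome_rate, depth_ratio)
    lp <- poisson_upper_tail(cnt, lam)
    sig <- which(lp <= log10(cfg$p_threshold))
    n_windows <- n_windows + length(win_start)
    n_significant <- n_significant + length(sig)
    if (length(sig) == 0L) next
    merged <- merge_intervals(genomic_intervals(cn, win_start[sig], win_end[sig]))
    # min member-window p per merged peak
    hit <- IRanges::findOverlaps(.iranges(win_start[sig], win_end[sig]),
                                 .iranges(merged$start, merged$end))
    minw <- tapply(lp[sig][S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit), min)
    pk_cnt <- IRanges::countOverlaps(.iranges(merged$start, merged$end), treads)
    pk_lam <- .local_lambda(merged$start, merged$end, control$start[ci],
                            control$end[ci], cfg$local_windows, genome_rate,
                            depth_ratio)
    out[[cn]] <- data.frame(chrom = cn, start = merged$start, end = merged$end,
                            count = pk_cnt, lambda = pk_lam,
                            log10p = poisson_upper_tail(pk_cnt, pk_lam),
                            log10p_window = as.numeric(minw[as.character(seq_len(nrow(merged)))]),
                            enrichment = pk_cnt / pk_lam,
                            sample_id = sample_id,
                            stringsAsFactors = FALSE)
  }
  pk <- if (length(out) == 0L) .empty_peaks(sample_id) else {
    p <- do.call(rbind, out)
    rownames(p) <- NULL
    class(p) <- c("peak_set", "data.frame")
    p
  }
  attr(pk, "n_windows") <- n_windows
  attr(pk, "n_significant") <- n_significant
  pk
}

.empty_peaks <- function(sample_id = NA_character_) {
  pk <- data.frame(chrom = character(), start = integer(), end = integer(),
                   count = integer(), lambda = numeric(), log10p = numeric(),
                   log10p_window = numeric(), enrichment = numeric(),
                   sample_id = character(), stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", lengths %d-%d bp, min log10 p = %.1f",
                min(x$end - x$start), max(x$end - x$start), min(x$log10p)))
  }
  cat("\n")
  invisible(x)
}

#' Count differential peaks between two samples
#'
#' Calls peaks in `sample_a` using `sample_b` as the control, then keeps
#' peaks that additionally satisfy the differential filters: peak-scale
#' p-value below `p`, promoter-normalized density ratio a/b above `ratio`
#' (a zero density in b counts as an infinite ratio), and density in a
#' above `min_density`.
#'
#' @param reads_a,reads_b `genomic_intervals` read tables.
#' @param promoter_total_a,promoter_total_b promoter-anchored read totals
#'   for the two samples (the density denominators).
#' @param p,ratio,min_density differential thresholds (defaults 1e-20, 4,
#'   0.005). The p threshold applies to this caller's own peak-scale
#'   Poisson p and is deliberately configuration-exposed.
#' @param config a [peak_caller_config()].
#' @return integer count of differential peaks, with the filtered peak
#'   table attached as attribute `peaks`.
#' @export
differential_peak_count <- function(reads_a, reads_b,
                                    promoter_total_a, promoter_total_b,
                                    p = 1e-20, ratio = 4, min_density = 0.005,
                                    config = peak_caller_config()) {
  pk <- call_peaks(reads_a, reads_b, config)
  if (nrow(pk) == 0L) return(structure(0L, peaks = pk))
  len <- pk$end - pk$start
  cnt_b <- count_reads(reads_b, genomic_intervals(pk$chrom, pk$start, pk$end))
  dens_a <- promoter_normalized_density(pk$count, len, promoter_total_a)
  dens_b <- promoter_normalized_density(cnt_b, len, promoter_total_b)
  rat <- ifelse(dens_b == 0, Inf, dens_a / dens_b)
  keep <- pk$log10p <= log10(p) & rat > ratio & dens_a > min_density
  structure(sum(keep), peaks = pk[keep, , drop = FALSE])
}

#' Pool per-sample peaks into a consensus set
#'
#' Merges all samples' peak intervals (overlapping or abutting peaks
#' become one region) and records which samples contributed to each merged
#' region.
#'
#' @param per_sample_peaks named list of `peak_set` tables.
#' @return list of class `consensus_peaks`: `regions` (disjoint
#'   `genomic_intervals`, ids `K1..Kn`) and `provenance` (list of
#'   contributing sample names per region).
#' @export
pool_merge_peaks <- function(per_sample_peaks) {
  stopifnot(length(per_sample_peaks) >= 1L)
  if (is.null(names(per_sample_peaks))) {
    names(per_sample_peaks) <- sprintf("sample%d", seq_along(per_sample_peaks))
  }
  all <- do.call(rbind, lapply(names(per_sample_peaks), function(s) {
    pk <- per_sample_peaks[[s]]
    if (nrow(pk) == 0L) return(NULL)
    data.frame(chrom = pk$chrom, start = pk$start, end = pk$end, sample = s,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(structure(list(regions = genomic_intervals(character(), integer(), integer()),
                          provenance = list()), class = "consensus_peaks"))
  }
  merged <- merge_intervals(genomic_intervals(all$chrom, all$start, all$end))
  merged$id <- sprintf("K%d", seq_len(nrow(merged)))
  prov <- vector("list", nrow(merged))
  for (cn in unique(merged$chrom)) {
    mi <- which(merged$chrom == cn)
    ai <- which(all$chrom == cn)
    ov <- IRanges::findOverlaps(.iranges(all$start[ai], all$end[ai]),
                                .iranges(merged$start[mi], merged$end[mi]))
    hits <- split(all$sample[ai][S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov))
    for (j in names(hits)) prov[[mi[as.integer(j)]]] <- sort(unique(hits[[j]]))
  }
  structure(list(regions = merged, provenance = prov), class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat(sprintf("consensus_peaks: %d merged regions from %d contributing sample lists\n",
              nrow(x$regions), length(unique(unlist(x$provenance)))))
  invisible(x)
}

#' Peak-length distribution over exceedance categories
#'
#' Counts peaks whose length exceeds each breakpoint (default categories:
#' >500 bp, >1 kb, >2 kb, >3 kb, >4 kb, >5 kb) and the corresponding
#' proportions of the total peak count.
#'
#' @param peaks a `peak_set` or any table with `start`/`end`.
#' @param breakpoints strictly increasing lengths in bp.
#' @return data.frame `breakpoint`, `count`, `proportion` (NA when there
#'   are no peaks).
#' @export
peak_length_distribution <- function(peaks,
                                     breakpoints = c(500L, 1000L, 2000L, 3000L, 4000L, 5000L)) {
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing")
  }
  len <- peaks$end - peaks$start
  cnt <- vapply(breakpoints, function(b) sum(len > b), 0L)
  data.frame(breakpoint = breakpoints, count = cnt,
             proportion = if (length(len)) cnt / length(len) else NA_real_)
}

#' Write peaks as a BED6+ file
#'
#' Name = sample id, score = `-10 * log10 p` (capped at 10000), extra
#' columns `count`, `lambda`, `enrichment`.
#'
#' @param path output path.
#' @param peaks a `peak_set`.
#' @export
write_peaks <- function(path, peaks) {
  ord <- order(peaks$chrom, peaks$start)
  pk <- peaks[ord, , drop = FALSE]
  score <- pmin(10000, round(-10 * pk$log10p))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%.4g\t%.4g",
                   pk$chrom, pk$start, pk$end,
                   ifelse(is.na(pk$sample_id), ".", pk$sample_id),
                   score, pk$count, pk$lambda, pk$enrichment)
  writeLines(lines, path)
  invisible(path)
}
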