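#' Construct a validated genomic-interval table
#'
#' Intervals are 0-based half-open (`[start, end)`), matching the BED
#' convention used throughout the package. Any 1-based input must be
#' converted at the reader boundary before calling this.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unspecified).
#'   Strand is carried but ignored by all counting.
#' @param id optional character ids.
#' @return A `data.frame` with class `genomic_intervals` and columns
#'   `chrom`, `start`, `end`, `strand`, `id`.
#' @examples
#' genomic_intervals("chr1", 100, 136)
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, id = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) {
    gi <- data.frame(chrom = character(), start = integer(), end = integer(),
                     strand = character(), id = character(),
                     stringsAsFactors = FALSE)
    class(gi) <- c("genomic_intervals", "data.frame")
    return(gi)
  }
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- if (is.null(strand)) rep_len("*", n) else rep_len(as.character(strand), n)
  id <- if (is.null(id)) rep_len(NA_character_, n) else rep_len(as.character(id), n)
  bad <- which(!nzchar(chrom) | is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval at record %d: %s:%s-%s (need chrom non-empty and 0 <= start < end)",
                 bad[1L], chrom[bad[1L]], format(start[bad[1L]]), format(end[bad[1L]])))
  }
  if (!all(strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  gi <- data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
                   strand = strand, id = id, stringsAsFactors = FALSE)
  class(gi) <- c("genomic_intervals", "data.frame")
  gi
}

as_genomic_intervals <- function(x) {
  genomic_intervals(x$chrom, x$start, x$end,
                    strand = if ("strand" %in% names(x)) x$strand else NULL,
                    id = if ("id" %in% names(x)) x$id else NULL)
}

# IRanges view of one chromosome's intervals; half-open [start,end) maps to
# the 1-based closed [start+1, end].
.iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# split row indices by chromosome, in lexicographic chromosome order
.by_chrom <- function(chrom) split(seq_along(chrom), chrom)

#' Merge overlapping genomic intervals
#'
#' Sorts intervals and merges any that share at least one base. With
#' `merge_abutting = TRUE` (default) intervals that touch at a shared
#' boundary (`[a,b)` and `[b,c)`) are also merged; the union of covered
#' bases is identical either way.
#'
#' @param intervals a `genomic_intervals` table (or coercible data.frame).
#' @param merge_abutting merge intervals that abut without overlapping.
#' @return A sorted, pairwise-disjoint `genomic_intervals` table.
#' @examples
#' x <- genomic_intervals("chr1", c(10, 15, 40), c(20, 30, 50))
#' merge_intervals(x)
#' @export
merge_intervals <- function(intervals, merge_abutting = TRUE) {
  gi <- as_genomic_intervals(intervals)
  if (nrow(gi) == 0L) return(gi)
  gap <- if (merge_abutting) 1L else 0L
  pieces <- lapply(.by_chrom(gi$chrom), function(idx) {
    r <- IRanges::reduce(.iranges(gi$start[idx], gi$end[idx]), min.gapwidth = gap)
    data.frame(chrom = gi$chrom[idx[1L]],
               start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Build merged promoter regions around transcription start sites
#'
#' Each TSS is expanded to `[tss - flank, tss + flank)` (clipped at 0) and
#' overlapping expansions are merged into non-overlapping promoter regions.
#' The gene mapping is carried through the merge: one merged region may host
#' the TSSs of several genes.
#'
#' @param annotation a gene annotation `data.frame` with columns `gene_id`,
#'   `chrom`, `tss` (0-based position), `strand` (see [read_annotation()]).
#' @param flank half-width in bp (default 2000, i.e. TSS +/- 2 kb).
#' @param exclude_chrY drop chrY TSSs before expansion (default `TRUE`).
#' @param merge_abutting passed to [merge_intervals()].
#' @return A list of class `promoter_set`: `regions` (disjoint
#'   `genomic_intervals` with `id` = `P1..Pn`) and `gene_map` (data.frame
#'   `region_id`, `gene_id`, `tss`).
#' @export
build_promoters <- function(annotation, flank = 2000L, exclude_chrY = TRUE,
                            merge_abutting = TRUE) {
  stopifnot(flank > 0)
  ann <- annotation
  if (exclude_chrY) ann <- ann[ann$chrom != "chrY", , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("empty annotation: promoter set is empty")
    ps <- list(regions = genomic_intervals(character(), integer(), integer()),
               gene_map = data.frame(region_id = character(), gene_id = character(),
                                     tss = integer(), stringsAsFactors = FALSE))
    class(ps) <- "promoter_set"
    return(ps)
  }
  start <- pmax(0L, as.integer(ann$tss) - as.integer(flank))
  end <- as.integer(ann$tss) + as.integer(flank)
  merged <- merge_intervals(genomic_intervals(ann$chrom, start, end),
                            merge_abutting = merge_abutting)
  merged$id <- sprintf("P%d", seq_len(nrow(merged)))
  # map each TSS into the merged region containing it
  hit <- integer(nrow(ann))
  for (cn in unique(ann$chrom)) {
    ai <- which(ann$chrom == cn)
    mi <- which(merged$chrom == cn)
    ov <- IRanges::findOverlaps(IRanges::IRanges(ann$tss[ai] + 1L, ann$tss[ai] + 1L),
                                .iranges(merged$start[mi], merged$end[mi]))
    hit[ai[S4Vectors::queryHits(ov)]] <- mi[S4Vectors::subjectHits(ov)]
  }
  gene_map <- data.frame(region_id = merged$id[hit], gene_id = ann$gene_id,
                         tss = as.integer(ann$tss), stringsAsFactors = FALSE)
  ps <- list(regions = merged, gene_map = gene_map)
  class(ps) <- "promoter_set"
  ps
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d non-overlapping regions covering %d TSSs (%d genes)\n",
              nrow(x$regions), nrow(x$gene_map), length(unique(x$gene_map$gene_id))))
  invisible(x)
}

#' Read a BED3/BED6 file of intervals
#'
#' Coordinates are taken as 0-based half-open per the BED standard and kept
#' that way. `track`, `browser` and `#` comment lines are skipped; any other
#' line with fewer than three fields is an error naming the line number.
#'
#' @param path file path.
#' @return a `genomic_intervals` table (name column -> `id`, column 6 ->
#'   `strand` when present).
#' @export
read_alignment_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields", lineno[which(nf < 3L)[1L]], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", lineno[bad[1L]], path))
  id <- if (max(nf) >= 4L) vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "") else NULL
  strand <- if (max(nf) >= 6L) {
    s <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
    s[!s %in% c("+", "-")] <- "*"
    s
  } else NULL
  genomic_intervals(chrom, start, end, strand = strand, id = id)
}

#' Write intervals as BED
#'
#' Emits deterministic ordering (chromosome lexicographic, then start).
#' Writes BED6 when any strand or id is set, else BED3.
#'
#' @param path output file path.
#' @param intervals a `genomic_intervals` table.
#' @export
write_intervals <- function(path, intervals) {
  gi <- as_genomic_intervals(intervals)
  ord <- order(gi$chrom, gi$start, gi$end)
  gi <- gi[ord, , drop = FALSE]
  if (all(is.na(gi$id)) && all(gi$strand == "*")) {
    lines <- sprintf("%s\t%d\t%d", gi$chrom, gi$start, gi$end)
  } else {
    nm <- ifelse(is.na(gi$id), ".", gi$id)
    st <- ifelse(gi$strand == "*", ".", gi$strand)
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", gi$chrom, gi$start, gi$end, nm, st)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `tss`, `strand` (header
#' optional if in this order). `tss` is a 0-based position. A gene may
#' appear on several rows, one per TSS.
#'
#' @param path file path.
#' @param exclude_chrY drop chrY rows at load (default `TRUE`, mirroring the
#'   promoter analysis).
#' @return data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_annotation <- function(path, exclude_chrY = TRUE) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  ann <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(ann)[1:4] <- c("gene_id", "chrom", "tss", "strand")
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(ann)))
  if (!"strand" %in% names(ann)) ann$strand <- "*"
  if (any(ann$tss < 0)) stop("annotation TSS positions must be >= 0")
  if (exclude_chrY) ann <- ann[ann$chrom != "chrY", , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation table
#' @param path output path.
#' @param annotation data.frame as returned by [read_annotation()].
#' @export
write_annotation <- function(path, annotation) {
  ord <- order(annotation$chrom, annotation$tss)
  utils::write.table(annotation[ord, c("gene_id", "chrom", "tss", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
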