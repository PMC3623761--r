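#' Convert a gestational-week age to years relative to term birth
#'
#' Prenatal ages are mapped onto the same continuous axis as postnatal ages
#' by `(gw - 40) * 7 / 365.25` (term = 40 gestational weeks), so prenatal
#' samples carry small negative ages.
#'
#' @param gw gestational week(s).
#' @return age in years (negative before term).
#' @export
gw_to_years <- function(gw) (gw - 40) * 7 / 365.25

#' Reference cohort metadata: 31 neuronal ChIP samples plus one input
#'
#' The default study design: 31 NeuN+ H3K4me3 ChIP-seq samples spanning 34
#' gestational weeks to 81 years (three prenatal, three infant, 25 older
#' than one year) and a single input (no-antibody) control.
#'
#' @return data.frame with `sample_id`, `age_label`, `age_years`,
#'   `fraction` (`chip`/`input`), `cell_class`, `sex`.
#' @export
reference_cohort <- function() {
  chip <- data.frame(
    sample_id = sprintf("C%d", 1:31),
    age_label = c("34 gw", "39 gw", "40 gw", "0.5 yr", "0.6 yr", "0.8 yr",
                  "1.3 yr", "2.8 yr", "4 yr", "4.7 yr", "8.8 yr", "14 yr",
                  "17 yr", "18 yr", "19 yr", "20 yr", "23 yr", "24 yr",
                  "24 yr", "26 yr", "28 yr", "38 yr", "41 yr", "55 yr",
                  "63 yr", "64 yr", "68 yr", "69 yr", "74 yr", "74 yr",
                  "81 yr"),
    age_years = c(gw_to_years(c(34, 39, 40)),
                  0.5, 0.6, 0.8, 1.3, 2.8, 4, 4.7, 8.8, 14, 17, 18, 19, 20,
                  23, 24, 24, 26, 28, 38, 41, 55, 63, 64, 68, 69, 74, 74, 81),
    fraction = "chip",
    cell_class = "NeuN+",
    sex = c("F", "F", "F", "M", "M", "F", "M", "F", "F", "M", "M", "M", "M",
            "M", "M", "M", "M", "M", "M", "M", "F", "M", "F", "M", "M", "M",
            "F", "F", "M", "F", "M"),
    stringsAsFactors = FALSE)
  input <- data.frame(sample_id = "C28input", age_label = "69 yr",
                      age_years = 69, fraction = "input",
                      cell_class = "NeuN+", sex = "F", stringsAsFactors = FALSE)
  rbind(chip, input)
}

#' Reduced 12-sample cohort: three samples per age band
#'
#' Three samples in each of four age ranges (gestational, 0-1 yr, 3-14 yr,
#' 15-25 yr) plus the input control; used for the smaller cohort-structure
#' analysis where every ordered sample pair is peak-called.
#'
#' @return data.frame in the same layout as [reference_cohort()].
#' @export
reduced_cohort <- function() {
  full <- reference_cohort()
  keep <- c("C1", "C2", "C3",      # gestational
            "C4", "C5", "C6",      # 0-1 yr
            "C9", "C11", "C12",    # 3-14 yr
            "C13", "C15", "C17",   # 15-25 yr
            "C28input")
  out <- full[match(keep, full$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic-cohort configuration
#'
#' Defaults define the package's reference study conditions: the 31+1
#' sample design of [reference_cohort()], 2000 candidate regions of
#' 1.2-1.8 kb spaced 10 kb apart on two toy chromosomes, 10% planted
#' down-trajectories and 5% up-trajectories with a 5-fold dynamic range on
#' the reads/bp/million-promoter-reads density scale, saturation time
#' constants of 0.5-2 years, and sequencing depth set by a nominal promoter
#' read total of 2e5 plus 0.005 background reads per bp.
#'
#' @param meta sample metadata (default [reference_cohort()]).
#' @param n_regions number of candidate regions.
#' @param n_chrom number of toy chromosomes.
#' @param spacing bp between region starts on a chromosome.
#' @param region_len_range min/max region length in bp.
#' @param fraction_proximal fraction of regions whose gene TSS lies inside
#'   the region (the remainder get a TSS 5 kb upstream, beyond the 2 kb
#'   assignment window).
#' @param fraction_bi_promoter fraction of regions participating in
#'   two-promoter genes (consecutive region pairs <= 100 kb apart share a
#'   gene).
#' @param p_up,p_down planted class fractions (`p_up + p_down <= 1`).
#' @param flat_density_range density range for age-flat regions.
#' @param high_density_range density range for the high end of directional
#'   regions.
#' @param fold dynamic range of directional regions (`d_high / d_low`).
#' @param tau_range time-constant range in years.
#' @param prom_depth nominal promoter-anchored read total used to convert
#'   density to expected read counts.
#' @param background_per_bp background read rate per bp per sample.
#' @param read_length mapped read length in bp.
#' @param bw fragment bandwidth in bp; enriched reads are placed within the
#'   region extended by `bw/2` on each side.
#' @param seed master seed; every simulation draws from substreams of it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(meta = reference_cohort(),
                          n_regions = 2000L,
                          n_chrom = 2L,
                          spacing = 10000L,
                          region_len_range = c(1200L, 1800L),
                          fraction_proximal = 0.66,
                          fraction_bi_promoter = 0.05,
                          p_up = 0.05,
                          p_down = 0.10,
                          flat_density_range = c(0.1, 0.3),
                          high_density_range = c(0.4, 0.6),
                          fold = 5,
                          tau_range = c(0.5, 2),
                          prom_depth = 2e5,
                          background_per_bp = 0.005,
                          read_length = 36L,
                          bw = 230L,
                          seed = 1L) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "age_years", "fraction") %in% names(meta)),
            !anyDuplicated(meta$sample_id),
            all(meta$age_years >= -0.15 & meta$age_years <= 110),
            n_regions >= 1, n_chrom >= 1, spacing > max(region_len_range),
            p_up >= 0, p_down >= 0, p_up + p_down <= 1,
            fold > 1, all(tau_range > 0), prom_depth > 0,
            background_per_bp >= 0, read_length > 0, bw > 0)
  cfg <- list(meta = meta, n_regions = as.integer(n_regions),
              n_chrom = as.integer(n_chrom), spacing = as.integer(spacing),
              region_len_range = as.integer(region_len_range),
              fraction_proximal = fraction_proximal,
              fraction_bi_promoter = fraction_bi_promoter,
              p_up = p_up, p_down = p_down,
              flat_density_range = flat_density_range,
              high_density_range = high_density_range,
              fold = fold, tau_range = tau_range,
              prom_depth = prom_depth, background_per_bp = background_per_bp,
              read_length = as.integer(read_length), bw = as.integer(bw),
              seed = as.integer(seed))
  per_chrom <- ceiling(cfg$n_regions / cfg$n_chrom)
  cfg$chrom_names <- sprintf("chrS%d", seq_len(cfg$n_chrom))
  cfg$chrom_length <- per_chrom * cfg$spacing + 12000L
  class(cfg) <- "cohort_config"
  cfg
}

#' Reduced configuration used for all-pairs differential analysis
#'
#' The 12-sample cohort of [reduced_cohort()] over 500 regions on two
#' 2.5 Mb chromosomes; all other parameters as [cohort_config()].
#'
#' @param seed master seed.
#' @param ... overrides passed to [cohort_config()].
#' @export
reduced_config <- function(seed = 1L, ...) {
  cohort_config(meta = reduced_cohort(), n_regions = 500L, seed = seed, ...)
}

# deterministic substream seeds derived from the master seed
.substream_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Lay out candidate regions and their gene annotation
#'
#' Regions are placed on a fixed grid (`spacing` bp apart, `n_chrom`
#' chromosomes) with seeded lengths. A fraction `fraction_proximal` of
#' regions carry their gene's TSS inside the region; the remainder get a
#' TSS 5 kb upstream of the region start (beyond the 2 kb window, so those
#' regions are TSS-distal). A fraction of consecutive same-chromosome
#' region pairs (10 kb apart, hence within 100 kb) share one gene with two
#' promoters, for alternative-promoter analysis.
#'
#' @param config a [cohort_config()].
#' @return list with `regions` (`genomic_intervals`, ids `R1..Rn`),
#'   `annotation` (gene TSV layout: `gene_id`, `chrom`, `tss`, `strand`),
#'   and `region_genes` (data.frame `region_id`, `gene_id`, `proximal`).
#' @export
simulate_annotation <- function(config) {
  cfg <- config
  n <- cfg$n_regions
  per_chrom <- ceiling(n / cfg$n_chrom)
  idx <- seq_len(n) - 1L
  chrom <- cfg$chrom_names[idx %/% per_chrom + 1L]
  slot <- idx %% per_chrom
  start <- slot * cfg$spacing + 6000L
  if (max(start) + cfg$region_len_range[2L] > cfg$chrom_length) {
    stop("infeasible packing: increase chromosome length or spacing")
  }
  seeds <- .substream_seeds(cfg$seed, 3L)
  set.seed(seeds[1L])
  len <- as.integer(round(stats::runif(n, cfg$region_len_range[1L], cfg$region_len_range[2L])))
  regions <- genomic_intervals(chrom, start, start + len, id = sprintf("R%d", seq_len(n)))

  set.seed(seeds[2L])
  proximal <- stats::runif(n) < cfg$fraction_proximal
  tss <- ifelse(proximal, start + 200L, start - 5000L)
  gene_id <- sprintf("G%d", seq_len(n))
  # two-promoter genes: merge gene ids of disjoint consecutive same-chrom pairs
  n_pairs <- floor(cfg$fraction_bi_promoter * n / 2)
  if (n_pairs > 0) {
    cand <- which(chrom[-1L] == chrom[-n] & seq_len(n - 1L) %% 2L == 1L)
    set.seed(seeds[3L])
    first <- sort(sample(cand, min(n_pairs, length(cand))))
    gene_id[first + 1L] <- gene_id[first]
  }
  annotation <- data.frame(gene_id = gene_id, chrom = chrom,
                           tss = as.integer(tss), strand = "+",
                           stringsAsFactors = FALSE)
  list(regions = regions, annotation = annotation,
       region_genes = data.frame(region_id = regions$id, gene_id = gene_id,
                                 proximal = proximal, stringsAsFactors = FALSE))
}

#' Evaluate a saturating-exponential trajectory
#'
#' The planted kinetic model: density relaxes monotonically from its value
#' at the earliest cohort age `a0` towards an asymptote,
#' `d(age) = d_inf + (d_start - d_inf) * exp(-(age - a0) / tau)`.
#'
#' @param model list/row with `d_start`, `d_inf`, `tau` (years, > 0).
#' @param age_years age(s), must be `>= a0`.
#' @param a0 earliest cohort age (default the reference cohort minimum).
#' @return density value(s), bounded by `d_start` and `d_inf`.
#' @examples
#' m <- list(d_start = 0.01, d_inf = 0.05, tau = 1)
#' trajectory_density(m, 1 + gw_to_years(34), a0 = gw_to_years(34))
#' @export
trajectory_density <- function(model, age_years, a0 = gw_to_years(34)) {
  if (any(model$tau <= 0)) stop("tau must be > 0")
  if (any(age_years < a0 - 1e-12)) stop("age_years must be >= a0")
  model$d_inf + (model$d_start - model$d_inf) * exp(-(age_years - a0) / model$tau)
}

#' Plant per-region trajectory models
#'
#' Assigns exactly `round(p_up * n)` up and `round(p_down * n)` down
#' regions (the rest flat) and draws their kinetic parameters from the
#' configured ranges: flat regions hold a constant density; directional
#' regions span a `fold`-fold range with the high end at the configured
#' high-density range.
#'
#' @param config a [cohort_config()].
#' @param regions region table from [simulate_annotation()].
#' @return data.frame `region_id`, `klass`, `d_start`, `d_inf`, `tau`.
#' @export
simulate_trajectories <- function(config, regions) {
  cfg <- config
  n <- nrow(regions)
  n_up <- round(cfg$p_up * n)
  n_down <- round(cfg$p_down * n)
  seeds <- .substream_seeds(cfg$seed + 1L, 2L)
  set.seed(seeds[1L])
  klass <- rep("flat", n)
  pick <- sample.int(n, n_up + n_down)
  klass[pick[seq_len(n_up)]] <- "up"
  if (n_down > 0) klass[pick[n_up + seq_len(n_down)]] <- "down"
  set.seed(seeds[2L])
  high <- stats::runif(n, cfg$high_density_range[1L], cfg$high_density_range[2L])
  flat <- stats::runif(n, cfg$flat_density_range[1L], cfg$flat_density_range[2L])
  tau <- stats::runif(n, cfg$tau_range[1L], cfg$tau_range[2L])
  d_start <- ifelse(klass == "down", high, ifelse(klass == "up", high / cfg$fold, flat))
  d_inf <- ifelse(klass == "down", high / cfg$fold, ifelse(klass == "up", high, flat))
  data.frame(region_id = regions$id, klass = klass,
             d_start = d_start, d_inf = d_inf, tau = tau,
             stringsAsFactors = FALSE)
}

#' Simulate one sample's mapped reads
#'
#' Reads are uniform background (Poisson count at the configured per-bp
#' rate over the toy genome) plus, for ChIP samples, per-region enriched
#' reads with expected count `density * length * prom_depth / 1e6`, where
#' density follows the region's planted trajectory at the sample's age.
#' Enriched read starts are uniform within the region extended by `bw/2`
#' on each side. Input samples receive background only.
#'
#' @param sample one row of the cohort metadata.
#' @param models trajectory table from [simulate_trajectories()].
#' @param regions region table matching `models`.
#' @param config a [cohort_config()].
#' @param seed substream seed for this sample.
#' @param a0 earliest cohort age.
#' @return a `genomic_intervals` table of read intervals.
#' @export
simulate_sample_reads <- function(sample, models, regions, config, seed,
                                  a0 = min(config$meta$age_years)) {
  cfg <- config
  set.seed(seed)
  rl <- cfg$read_length
  # background, proportional to chromosome length
  n_bg <- stats::rpois(cfg$n_chrom, cfg$background_per_bp * cfg$chrom_length)
  bg_chrom <- rep(cfg$chrom_names, n_bg)
  bg_start <- floor(stats::runif(sum(n_bg), 0, cfg$chrom_length - rl))
  if (sample$fraction == "input") {
    return(genomic_intervals(bg_chrom, bg_start, bg_start + rl))
  }
  d <- trajectory_density(models, sample$age_years, a0 = a0)
  lam <- d * (regions$end - regions$start) * cfg$prom_depth / 1e6
  n_enr <- stats::rpois(length(lam), lam)
  ri <- rep(seq_along(lam), n_enr)
  half <- cfg$bw %/% 2L
  lo <- pmax(0L, regions$start[ri] - half)
  hi <- regions$end[ri] + half - rl
  enr_start <- floor(stats::runif(length(ri), lo, hi))
  genomic_intervals(c(bg_chrom, regions$chrom[ri]),
                    c(bg_start, enr_start),
                    c(bg_start, enr_start) + rl)
}

#' Simulate a complete age-structured cohort
#'
#' Generates the region layout, gene annotation, planted trajectories and
#' per-sample read sets under a single master seed (independent substreams
#' per sample keep the result invariant to evaluation order).
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`: `config`, `meta`, `regions`,
#'   `annotation`, `region_genes`, `models`, `reads` (named list of
#'   `genomic_intervals`), `a0`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  layout <- simulate_annotation(cfg)
  models <- simulate_trajectories(cfg, layout$regions)
  a0 <- min(cfg$meta$age_years)
  seeds <- .substream_seeds(cfg$seed + 2L, nrow(cfg$meta))
  reads <- lapply(seq_len(nrow(cfg$meta)), function(i) {
    simulate_sample_reads(cfg$meta[i, ], models, layout$regions, cfg,
                          seed = seeds[i], a0 = a0)
  })
  names(reads) <- cfg$meta$sample_id
  out <- list(config = cfg, meta = cfg$meta, regions = layout$regions,
              annotation = layout$annotation, region_genes = layout$region_genes,
              models = models, reads = reads, a0 = a0)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  nr <- vapply(x$reads, nrow, 0L)
  cat(sprintf("synthetic_cohort: %d samples (%d ChIP + %d input), %d regions, seed %d\n",
              nrow(x$meta), sum(x$meta$fraction == "chip"),
              sum(x$meta$fraction == "input"), nrow(x$regions), x$config$seed))
  cat(sprintf("  planted classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$models$klass)), table(x$models$klass)), collapse = ", ")))
  cat(sprintf("  reads/sample: %d-%d (median %d)\n", min(nr), max(nr), as.integer(stats::median(nr))))
  invisible(x)
}

# truncate to [0, 1], preserving dimensions
.trunc01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Simulate a CpG methylation table with planted anti-correlation
#'
#' For a fraction `anti_rho` of up-class genes, CpG beta values decrease
#' with age along the region's own time constant (mirrored increase for
#' down-class genes); the remaining CpGs are age-flat. Gaussian noise is
#' truncated to `[0, 1]`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param anti_rho fraction of directional genes with anti-correlated
#'   methylation, in `[0, 1]`.
#' @param n_cpg_per_gene CpGs simulated per gene.
#' @param noise_sd Gaussian noise standard deviation on the beta scale.
#' @param beta_range low/high beta levels for the planted dynamic range.
#' @param seed substream seed (default derived from the cohort master seed).
#' @return data.frame: `cpg_id`, `gene_id`, `chrom`, `pos`, then one beta
#'   column per ChIP sample.
#' @export
simulate_methylation <- function(cohort, anti_rho = 0.8, n_cpg_per_gene = 2L,
                                 noise_sd = 0.05, beta_range = c(0.3, 0.7),
                                 seed = cohort$config$seed + 3L) {
  if (anti_rho < 0 || anti_rho > 1) stop("anti_rho must be in [0, 1]")
  set.seed(seed)
  chip <- cohort$meta[cohort$meta$fraction == "chip", , drop = FALSE]
  rg <- cohort$region_genes
  mod <- cohort$models
  anti <- rep(FALSE, nrow(mod))
  dir_idx <- which(mod$klass != "flat")
  if (length(dir_idx)) {
    anti[dir_idx] <- stats::runif(length(dir_idx)) < anti_rho
  }
  rows <- rep(seq_len(nrow(mod)), each = n_cpg_per_gene)
  ages <- chip$age_years
  base <- matrix(0.5, nrow = length(rows), ncol = nrow(chip))
  for (j in seq_along(ages)) {
    frac <- exp(-(ages[j] - cohort$a0) / mod$tau[rows])
    up_anti <- mod$klass[rows] == "up" & anti[rows]
    down_anti <- mod$klass[rows] == "down" & anti[rows]
    # anti-correlated: beta moves opposite to the histone trajectory
    base[up_anti, j] <- beta_range[1L] + (beta_range[2L] - beta_range[1L]) * frac[up_anti]
    base[down_anti, j] <- beta_range[2L] - (beta_range[2L] - beta_range[1L]) * frac[down_anti]
  }
  beta <- .trunc01(base + matrix(stats::rnorm(length(base), 0, noise_sd), nrow = nrow(base)))
  colnames(beta) <- chip$sample_id
  region_row <- match(mod$region_id[rows], cohort$regions$id)
  out <- data.frame(cpg_id = sprintf("cg%05d", seq_along(rows)),
                    gene_id = rg$gene_id[match(mod$region_id[rows], rg$region_id)],
                    chrom = cohort$regions$chrom[region_row],
                    pos = cohort$regions$start[region_row] +
                      100L * (seq_along(rows) - 1L) %% n_cpg_per_gene + 250L,
                    stringsAsFactors = FALSE)
  attr(out, "anti") <- stats::setNames(anti, mod$region_id)
  cbind(out, as.data.frame(beta))
}

#' Simulate a gene expression table tracking the histone trajectories
#'
#' Expression (log2-signal scale) is an affine image of the gene's region
#' density trajectory plus Gaussian noise; `corr_strength = 0` removes any
#' dependence on the planted classes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param corr_strength slope multiplier linking density to expression.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param seed substream seed.
#' @return matrix (genes x ChIP samples) of log2 signals.
#' @export
simulate_expression <- function(cohort, corr_strength = 1, noise_sd = 0.2,
                                seed = cohort$config$seed + 4L) {
  set.seed(seed)
  chip <- cohort$meta[cohort$meta$fraction == "chip", , drop = FALSE]
  mod <- cohort$models
  d <- vapply(chip$age_years, function(a) trajectory_density(mod, a, a0 = cohort$a0),
              numeric(nrow(mod)))
  expr <- 6 + 5 * corr_strength * d +
    matrix(stats::rnorm(length(d), 0, noise_sd), nrow = nrow(d))
  rownames(expr) <- cohort$region_genes$gene_id[match(mod$region_id, cohort$region_genes$region_id)]
  colnames(expr) <- chip$sample_id
  expr
}

#' Write a cohort to disk as plain-text files
#'
#' One BED per sample plus `samples.tsv`, `annotation.tsv`, `regions.bed`
#' and `truth.tsv` (the planted trajectory table).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(cohort$reads)) {
    write_intervals(file.path(dir, paste0(s, ".bed")), cohort$reads[[s]])
  }
  utils::write.table(cohort$meta, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation(file.path(dir, "annotation.tsv"), cohort$annotation)
  write_intervals(file.path(dir, "regions.bed"), cohort$regions)
  utils::write.table(cohort$models, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
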