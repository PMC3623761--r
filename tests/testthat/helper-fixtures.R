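# Small fixture builders shared across the suite. Everything is generated
# in code under fixed seeds; no data files.

# random intervals on a single toy chromosome
random_intervals <- function(n, chrom_len = 1e5, max_len = 500, seed = 1,
                             chrom = "chrT") {
  set.seed(seed)
  start <- floor(runif(n, 0, chrom_len - max_len))
  len <- ceiling(runif(n, 1, max_len))
  genomic_intervals(chrom, start, start + len)
}

# per-base boolean coverage mask of intervals on one chromosome
coverage_mask <- function(gi, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_len(nrow(gi))) {
    mask[(gi$start[i] + 1):gi$end[i]] <- TRUE
  }
  mask
}

# uniform background reads on one chromosome
background_reads <- function(n, chrom_len, read_len = 36, seed = 1,
                             chrom = "chrT") {
  set.seed(seed)
  start <- floor(runif(n, 0, chrom_len - read_len))
  genomic_intervals(chrom, start, start + read_len)
}

# a density_matrix built directly from a value matrix (unit-length regions
# scale so values are interpretable as densities when lengths are given)
make_density_matrix <- function(values, lengths = rep(1500L, nrow(values)),
                                chrom = "chrT") {
  n <- nrow(values)
  start <- seq(0L, by = 10000L, length.out = n)
  regions <- genomic_intervals(chrom, start, start + lengths,
                               id = sprintf("R%d", seq_len(n)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  rownames(values) <- regions$id
  dm <- list(values = values, regions = regions, samples = colnames(values),
             promoter_total = stats::setNames(rep(1e5, ncol(values)), colnames(values)),
             counts = NULL)
  class(dm) <- "density_matrix"
  dm
}

# small cohort configuration for fast end-to-end tests
tiny_config <- function(seed = 1L, n_regions = 60L, meta = reduced_cohort()) {
  cohort_config(meta = meta, n_regions = n_regions, seed = seed)
}

# recovery metrics of trajectory calls against planted classes
recovery_metrics <- function(cohort, calls) {
  truth <- cohort$models$klass
  called <- calls$klass
  sens <- sum(truth != "flat" & called == truth) / sum(truth != "flat")
  n_called <- sum(called != "none")
  fdp <- if (n_called == 0) 0 else sum(called != "none" & called != truth) / n_called
  list(sensitivity = sens, fdp = fdp)
}

# simulate -> quantify -> classify for one seed under the default design
run_recovery <- function(seed, config = cohort_config(seed = seed)) {
  co <- simulate_cohort(config)
  prom <- build_promoters(co$annotation)
  chip <- co$meta$sample_id[co$meta$fraction == "chip"]
  dm <- build_density_matrix(co$reads[chip], co$regions, prom)
  groups <- assign_age_groups(co$meta$age_years[match(chip, co$meta$sample_id)])
  list(cohort = co, dm = dm, groups = groups,
       calls = classify_up_down(dm, groups))
}
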