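#' Pipeline configuration
#'
#' Bundles every stage's thresholds with the synthetic-cohort design and
#' an output directory. All numeric constants default to the package's
#' reference analysis: promoter flank 2 kb; caller bw 230 / tsize 36 /
#' p 1e-5; differential filters p 1e-20, ratio 4, density 0.005;
#' trajectory floor 0.01, fold 2, p 0.05, length 1 kb; k = 5 clusters;
#' methylation FDR cutoff 0.05 (1e-10 as robustness alternative);
#' enrichment inclusion FDR 0.85; alternative-promoter span 100 kb.
#'
#' @param out_dir output directory for stage files.
#' @param cohort a [cohort_config()] (also carries the master seed).
#' @param caller a [peak_caller_config()].
#' @param trajectory a [trajectory_call_config()].
#' @param promoter_flank promoter half-width in bp.
#' @param diff_p,diff_ratio,diff_density differential-peak filters.
#' @param k number of k-means clusters.
#' @param meth_fdr FDR cutoff for methylation direction calls.
#' @param anti_rho planted methylation anti-correlation fraction.
#' @param enrich_inclusion_fdr inclusion cutoff for enrichment-score
#'   correlation.
#' @param alt_promoter_span alternative-promoter TSS span in bp.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("epitraject_"),
                            cohort = cohort_config(),
                            caller = peak_caller_config(),
                            trajectory = trajectory_call_config(),
                            promoter_flank = 2000L,
                            diff_p = 1e-20, diff_ratio = 4, diff_density = 0.005,
                            k = 5L,
                            meth_fdr = 0.05,
                            anti_rho = 0.8,
                            enrich_inclusion_fdr = 0.85,
                            alt_promoter_span = 100000L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(caller, "peak_caller_config"),
            inherits(trajectory, "trajectory_call_config"),
            promoter_flank > 0,
            diff_p > 0, diff_p < 1, diff_ratio > 0, diff_density > 0,
            k >= 2, meth_fdr > 0, meth_fdr < 1,
            anti_rho >= 0, anti_rho <= 1,
            enrich_inclusion_fdr > 0, enrich_inclusion_fdr <= 1,
            alt_promoter_span > 0)
  cfg <- list(out_dir = out_dir, cohort = cohort, caller = caller,
              trajectory = trajectory, promoter_flank = as.integer(promoter_flank),
              diff_p = diff_p, diff_ratio = diff_ratio, diff_density = diff_density,
              k = as.integer(k), meth_fdr = meth_fdr, anti_rho = anti_rho,
              enrich_inclusion_fdr = enrich_inclusion_fdr,
              alt_promoter_span = as.integer(alt_promoter_span))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `cohort`, `caller` and `trajectory` maps mirror their constructors.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("out_dir", "cohort", "caller", "trajectory", "promoter_flank",
                 "diff_p", "diff_ratio", "diff_density", "k", "meth_fdr",
                 "anti_rho", "enrich_inclusion_fdr", "alt_promoter_span")
  bad <- setdiff(names(y), known_top)
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  build <- function(fun, args, who) {
    if (is.null(args)) args <- list()
    ok <- setdiff(names(formals(fun)), "meta")
    extra <- setdiff(names(args), ok)
    if (length(extra)) stop(sprintf("unknown %s key(s): %s", who, paste(extra, collapse = ", ")))
    do.call(fun, args)
  }
  y$cohort <- build(cohort_config, y$cohort, "cohort")
  y$caller <- build(peak_caller_config, y$caller, "caller")
  y$trajectory <- build(trajectory_call_config, y$trajectory, "trajectory")
  do.call(pipeline_config, y)
}

.write_tsv <- function(x, path, ...) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  invisible(path)
}

#' Write and read a density matrix as TSV
#'
#' Region columns first (`region_id`, `chrom`, `start`, `end`), then one
#' density column per sample; a leading `#` comment line records the
#' per-sample promoter-read denominators.
#'
#' @param dm a `density_matrix`.
#' @param path file path.
#' @export
write_density_matrix <- function(dm, path) {
  hdr <- sprintf("# promoter_total\t%s",
                 paste(sprintf("%s=%d", names(dm$promoter_total),
                               as.integer(dm$promoter_total)), collapse = "\t"))
  tab <- cbind(data.frame(region_id = dm$regions$id, chrom = dm$regions$chrom,
                          start = dm$regions$start, end = dm$regions$end,
                          stringsAsFactors = FALSE),
               as.data.frame(dm$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_matrix
#' @export
read_density_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  denom_fields <- strsplit(sub("^# promoter_total\t", "", hdr), "\t")[[1L]]
  kv <- strsplit(denom_fields, "=", fixed = TRUE)
  denom <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                           vapply(kv, `[[`, "", 1L))
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  samples <- setdiff(names(tab), c("region_id", "chrom", "start", "end"))
  values <- as.matrix(tab[, samples, drop = FALSE])
  rownames(values) <- tab$region_id
  dm <- list(values = values,
             regions = genomic_intervals(tab$chrom, tab$start, tab$end, id = tab$region_id),
             samples = samples, promoter_total = denom[samples],
             counts = NULL)
  class(dm) <- "density_matrix"
  dm
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, each stage reading only what earlier
#' stages wrote under `config$out_dir`:
#' `simulate` (cohort BEDs, annotation, methylation, expression, planted
#' truth), `quantify` (density and correlation matrices), `callpeaks`
#' (per-sample peaks vs input, pooled consensus, length distribution),
#' `structure` (all-pairs differential matrix, PCA scores, group
#' separation), `trajectories` (up/down calls, mean profiles, k-means
#' clusters with trend labels), `integrate` (gene assignment, alternative
#' promoters, CpG age tests, direction contingency) and `report`
#' (JSON summary embedding the resolved configuration).
#'
#' The all-pairs structure stage is quadratic in sample count; size the
#' cohort accordingly (see [reduced_config()]).
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (in canonical order).
#' @return the report list, invisibly; stage files under `config$out_dir`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "quantify", "callpeaks",
                                    "structure", "trajectories", "integrate",
                                    "report")) {
  cfg <- config
  dir <- cfg$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  all_stages <- c("simulate", "quantify", "callpeaks", "structure",
                  "trajectories", "integrate", "report")
  stages <- all_stages[all_stages %in% stages]
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  for (st in stages) {
    switch(st,
      simulate = run_stage(st, function() {
        cohort <- simulate_cohort(cfg$cohort)
        write_cohort(cohort, dir)
        meth <- simulate_methylation(cohort, anti_rho = cfg$anti_rho)
        .write_tsv(meth, file.path(dir, "methylation.tsv"))
        expr <- simulate_expression(cohort)
        .write_tsv(cbind(data.frame(gene_id = rownames(expr)), as.data.frame(expr)),
                   file.path(dir, "expression.tsv"))
      }),
      quantify = run_stage(st, function() {
        meta <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
        ann <- read_annotation(file.path(dir, "annotation.tsv"))
        regions <- read_alignment_bed(file.path(dir, "regions.bed"))
        reads <- lapply(meta$sample_id, function(s) {
          read_alignment_bed(file.path(dir, paste0(s, ".bed")))
        })
        names(reads) <- meta$sample_id
        promoters <- build_promoters(ann, flank = cfg$promoter_flank)
        chip <- meta$sample_id[meta$fraction == "chip"]
        dm <- build_density_matrix(reads[chip], regions, promoters)
        write_density_matrix(dm, file.path(dir, "density_matrix.tsv"))
        cc <- pairwise_pearson(dm)
        .write_tsv(cbind(data.frame(sample = rownames(cc)), as.data.frame(cc)),
                   file.path(dir, "correlation.tsv"))
      }),
      callpeaks = run_stage(st, function() {
        meta <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
        input_id <- meta$sample_id[meta$fraction == "input"][1L]
        if (is.na(input_id)) stop("no input sample in metadata")
        input <- read_alignment_bed(file.path(dir, paste0(input_id, ".bed")))
        chip <- meta$sample_id[meta$fraction == "chip"]
        peaks <- lapply(chip, function(s) {
          call_peaks(read_alignment_bed(file.path(dir, paste0(s, ".bed"))),
                     input, cfg$caller, sample_id = s)
        })
        names(peaks) <- chip
        all_pk <- do.call(rbind, peaks)
        write_peaks(file.path(dir, "peaks.bed"), all_pk)
        cons <- pool_merge_peaks(peaks)
        write_intervals(file.path(dir, "consensus_peaks.bed"), cons$regions)
        .write_tsv(peak_length_distribution(all_pk),
                   file.path(dir, "peak_lengths.tsv"))
      }),
      structure = run_stage(st, function() {
        meta <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
        dm <- read_density_matrix(file.path(dir, "density_matrix.tsv"))
        chip <- dm$samples
        reads <- lapply(chip, function(s) {
          read_alignment_bed(file.path(dir, paste0(s, ".bed")))
        })
        names(reads) <- chip
        m <- build_differential_matrix(reads, dm$promoter_total, cfg$caller,
                                       p = cfg$diff_p, ratio = cfg$diff_ratio,
                                       min_density = cfg$diff_density)
        .write_tsv(cbind(data.frame(sample = rownames(m)), as.data.frame(m)),
                   file.path(dir, "diffmatrix.tsv"))
        pca <- pca_scores(m)
        groups <- assign_age_groups(meta$age_years[match(chip, meta$sample_id)])
        sep <- group_separation_score(pca, groups)
        sc <- data.frame(sample = rownames(pca$scores), group = groups,
                         pca$scores[, seq_len(min(4L, ncol(pca$scores))), drop = FALSE])
        .write_tsv(sc, file.path(dir, "pca_scores.tsv"))
        jsonlite::write_json(list(variance_fraction = pca$variance_fraction,
                                  separation = as.list(sep)),
                             file.path(dir, "structure.json"), auto_unbox = TRUE,
                             digits = NA)
      }),
      trajectories = run_stage(st, function() {
        meta <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
        dm <- read_density_matrix(file.path(dir, "density_matrix.tsv"))
        groups <- assign_age_groups(meta$age_years[match(dm$samples, meta$sample_id)])
        calls <- classify_up_down(dm, groups, cfg$trajectory)
        .write_tsv(calls, file.path(dir, "trajectory_calls.tsv"))
        prof <- rbind(
          if (any(calls$klass == "up")) mean_profile(dm, calls$region_id[calls$klass == "up"]),
          if (any(calls$klass == "down")) mean_profile(dm, calls$region_id[calls$klass == "down"]))
        if (!is.null(prof)) {
          rownames(prof) <- c("up", "down")[seq_len(nrow(prof))]
          .write_tsv(cbind(data.frame(set = rownames(prof)), as.data.frame(prof)),
                     file.path(dir, "profiles.tsv"))
        }
        nm <- filter_and_normalize_for_clustering(dm, groups, cfg$trajectory)
        cl <- kmeans_profiles(nm, k = cfg$k, seed = cfg$cohort$seed)
        ages <- meta$age_years[match(colnames(nm), meta$sample_id)]
        trends <- apply(cl$centroids, 1L, label_cluster_trend, ages = ages)
        .write_tsv(data.frame(region_id = names(cl$assignment),
                              cluster = cl$assignment,
                              trend = trends[cl$assignment]),
                   file.path(dir, "clusters.tsv"))
      }),
      integrate = run_stage(st, function() {
        meta <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
        ann <- read_annotation(file.path(dir, "annotation.tsv"))
        calls <- utils::read.delim(file.path(dir, "trajectory_calls.tsv"),
                                   stringsAsFactors = FALSE)
        regions <- read_alignment_bed(file.path(dir, "regions.bed"))
        links <- peaks_to_genes(regions, ann, window = 2000L)
        .write_tsv(links, file.path(dir, "gene_assignment.tsv"))
        .write_tsv(alternative_promoter_classes(links, calls,
                                                span = cfg$alt_promoter_span),
                   file.path(dir, "alt_promoters.tsv"))
        meth <- utils::read.delim(file.path(dir, "methylation.tsv"),
                                  stringsAsFactors = FALSE)
        beta_cols <- setdiff(names(meth), c("cpg_id", "gene_id", "chrom", "pos"))
        groups <- assign_age_groups(meta$age_years[match(beta_cols, meta$sample_id)])
        cres <- cpg_age_test(meth, groups, fdr_cutoff = cfg$meth_fdr)
        .write_tsv(cres, file.path(dir, "methylation_results.tsv"))
        kl <- stats::setNames(calls$klass, calls$region_id)
        gl <- links[kl[links$region_id] %in% c("up", "down"), ]
        gene_classes <- stats::setNames(kl[gl$region_id], gl$gene_id)
        gene_classes <- gene_classes[!duplicated(names(gene_classes))]
        ct <- direction_contingency(gene_classes, cres)
        jsonlite::write_json(list(counts = ct$counts, p = ct$p),
                             file.path(dir, "contingency.json"),
                             auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      }),
      report = run_stage(st, function() {
        rep <- list(config = .echo_config(cfg))
        calls_path <- file.path(dir, "trajectory_calls.tsv")
        if (file.exists(calls_path)) {
          calls <- utils::read.delim(calls_path, stringsAsFactors = FALSE)
          rep$trajectory <- as.list(table(calls$klass))
        }
        cl_path <- file.path(dir, "clusters.tsv")
        if (file.exists(cl_path)) {
          cl <- utils::read.delim(cl_path, stringsAsFactors = FALSE)
          rep$cluster_trends <- as.list(table(cl$trend))
        }
        st_path <- file.path(dir, "structure.json")
        if (file.exists(st_path)) rep$structure <- jsonlite::read_json(st_path)
        ct_path <- file.path(dir, "contingency.json")
        if (file.exists(ct_path)) rep$contingency <- jsonlite::read_json(ct_path)
        jsonlite::write_json(rep, file.path(dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
      }))
  }
  rp <- file.path(dir, "report.json")
  invisible(if (file.exists(rp)) jsonlite::read_json(rp) else NULL)
}

# fully resolved scalar view of the configuration, for the report
.echo_config <- function(cfg) {
  list(seed = cfg$cohort$seed,
       n_samples = nrow(cfg$cohort$meta),
       n_regions = cfg$cohort$n_regions,
       promoter_flank = cfg$promoter_flank,
       caller = cfg$caller[c("bw", "tsize", "p_threshold")],
       diff = list(p = cfg$diff_p, ratio = cfg$diff_ratio,
                   density = cfg$diff_density),
       trajectory = cfg$trajectory[c("density_floor", "min_fold", "max_p",
                                     "min_length")],
       k = cfg$k, meth_fdr = cfg$meth_fdr, anti_rho = cfg$anti_rho,
       enrich_inclusion_fdr = cfg$enrich_inclusion_fdr,
       alt_promoter_span = cfg$alt_promoter_span)
}
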