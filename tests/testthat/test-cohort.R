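test_that("gestational ages map onto a continuous year axis", {
  expect_equal(gw_to_years(40), 0)
  expect_equal(gw_to_years(34), -6 * 7 / 365.25)
  meta <- reference_cohort()
  expect_equal(nrow(meta), 32L)
  expect_equal(sum(meta$fraction == "chip"), 31L)
  expect_equal(sum(assign_age_groups(meta$age_years[meta$fraction == "chip"]) == "prenatal"), 3L)
  expect_equal(sum(assign_age_groups(meta$age_years[meta$fraction == "chip"]) == "infant"), 3L)
  expect_true(all(meta$age_years >= -0.15 & meta$age_years <= 110))
})

test_that("trajectory_density follows the saturating-exponential kinetics", {
  a0 <- -0.1
  m <- list(d_start = 0.01, d_inf = 0.05, tau = 1)
  # boundary and asymptote
  expect_equal(trajectory_density(m, a0, a0 = a0), 0.01)
  expect_equal(trajectory_density(m, a0 + 40 * m$tau, a0 = a0), 0.05, tolerance = 1e-9)
  # one time constant: 1/e of the gap remains
  expect_equal(trajectory_density(m, a0 + 1, a0 = a0),
               0.05 + (0.01 - 0.05) / exp(1))
  # strict monotonicity for directional models away from the numeric
  # saturation plateau, non-strict over the whole lifespan
  ages <- seq(a0, a0 + 15, length.out = 200)
  d_up <- trajectory_density(m, ages, a0 = a0)
  expect_true(all(diff(d_up) > 0))
  life <- trajectory_density(m, seq(a0, 80, length.out = 200), a0 = a0)
  expect_true(all(diff(life) >= 0))
  expect_true(all(life >= 0.01 & life <= 0.05))
  down <- list(d_start = 0.5, d_inf = 0.1, tau = 2)
  expect_true(all(diff(trajectory_density(down, ages, a0 = a0)) < 0))
  # guards
  expect_error(trajectory_density(list(d_start = 1, d_inf = 2, tau = 0), 1, a0 = 0), "tau")
  expect_error(trajectory_density(m, a0 - 1, a0 = a0), "a0")
})

test_that("simulate_annotation is seeded-deterministic and packs proximal TSSs", {
  cfg <- tiny_config(seed = 11, n_regions = 40L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  # all-proximal layout: every region within 2 kb of some TSS
  cfg2 <- cohort_config(meta = reduced_cohort(), n_regions = 40L,
                        fraction_proximal = 1, seed = 2)
  a3 <- simulate_annotation(cfg2)
  links <- peaks_to_genes(a3$regions, a3$annotation, window = 2000L)
  expect_setequal(links$region_id, a3$regions$id)
})

test_that("proximal fraction lands inside its binomial 99% interval", {
  cfg <- cohort_config(n_regions = 2000L, fraction_proximal = 0.66, seed = 5)
  layout <- simulate_annotation(cfg)
  n_prox <- sum(layout$region_genes$proximal)
  half <- 2.576 * sqrt(2000 * 0.66 * 0.34)
  expect_gt(n_prox, 1320 - half)
  expect_lt(n_prox, 1320 + half)
})

test_that("planted class counts equal the rounded configured fractions", {
  for (seed in c(1, 9)) {
    cfg <- cohort_config(meta = reduced_cohort(), n_regions = 333L,
                         p_up = 0.05, p_down = 0.10, seed = seed)
    mod <- simulate_trajectories(cfg, simulate_annotation(cfg)$regions)
    expect_equal(sum(mod$klass == "up"), round(0.05 * 333))
    expect_equal(sum(mod$klass == "down"), round(0.10 * 333))
    expect_true(all(mod$d_inf[mod$klass == "up"] > mod$d_start[mod$klass == "up"]))
    expect_true(all(mod$d_inf[mod$klass == "down"] < mod$d_start[mod$klass == "down"]))
    expect_true(all(mod$d_inf[mod$klass == "flat"] == mod$d_start[mod$klass == "flat"]))
  }
})

test_that("read simulation is seeded and input samples carry background only", {
  cfg <- tiny_config(seed = 3, n_regions = 30L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$reads, co2$reads)
  # input reads show no enrichment: region counts compatible with background
  input <- co1$reads[["C28input"]]
  cnt <- count_reads(input, co1$regions)
  lam_bg <- cfg$background_per_bp * (co1$regions$end - co1$regions$start + cfg$read_length)
  expect_lt(max(cnt), max(stats::qpois(0.9999, lam_bg)) + 5)
  # byte-identical BED on rewrite
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_intervals(p1, co1$reads[["C1"]])
  write_intervals(p2, co2$reads[["C1"]])
  expect_identical(readLines(p1), readLines(p2))
})

test_that("per-region read counts match the planted Poisson expectation", {
  # single flat region with expected 500 enriched reads, no background
  meta <- data.frame(sample_id = "S1", age_label = "4 yr", age_years = 4,
                     fraction = "chip", cell_class = "NeuN+", sex = "M")
  cfg <- cohort_config(meta = meta, n_regions = 1L, background_per_bp = 0,
                       seed = 1)
  regions <- genomic_intervals("chrS1", 6000L, 7500L, id = "R1")
  d <- 500 * 1e6 / (1500 * cfg$prom_depth)
  models <- data.frame(region_id = "R1", klass = "flat", d_start = d,
                       d_inf = d, tau = 1)
  n <- vapply(1:200, function(s) {
    nrow(simulate_sample_reads(meta[1, ], models, regions, cfg, seed = s))
  }, 0L)
  se <- sqrt(500 / 200)
  expect_lt(abs(mean(n) - 500), 3 * se)
})

test_that("methylation simulation plants the requested anti-correlation", {
  cfg <- tiny_config(seed = 2, n_regions = 100L)
  co <- simulate_cohort(cfg)
  chip <- co$meta[co$meta$fraction == "chip", ]
  ord <- order(chip$age_years)

  # anti_rho = 1, noise -> 0: every up-gene CpG strictly decreasing with age
  m1 <- simulate_methylation(co, anti_rho = 1, noise_sd = 0, seed = 7)
  up_rows <- which(co$models$klass[match(m1$gene_id, co$region_genes$gene_id)] == "up")
  beta <- as.matrix(m1[, chip$sample_id])[, ord, drop = FALSE]
  expect_true(all(apply(beta[up_rows, , drop = FALSE], 1, function(x) all(diff(x) < 0))))
  down_rows <- which(co$models$klass[match(m1$gene_id, co$region_genes$gene_id)] == "down")
  expect_true(all(apply(beta[down_rows, , drop = FALSE], 1, function(x) all(diff(x) > 0))))

  # anti_rho = 0: age test finds (almost) nothing beyond its nominal level
  m0 <- simulate_methylation(co, anti_rho = 0, seed = 8)
  res <- cpg_age_test(m0, assign_age_groups(chip$age_years))
  expect_lt(mean(res$p < 0.05, na.rm = TRUE), 0.15)
  expect_error(simulate_methylation(co, anti_rho = 1.2), "anti_rho")
})

test_that("expression tracks the planted trajectories", {
  cfg <- tiny_config(seed = 4, n_regions = 100L)
  co <- simulate_cohort(cfg)
  chip <- co$meta[co$meta$fraction == "chip", ]
  groups <- assign_age_groups(chip$age_years)

  # noise-free expression is an affine image of the density profile
  e0 <- simulate_expression(co, noise_sd = 0, seed = 5)
  g_up <- which(co$models$klass == "up")[1]
  d <- vapply(chip$age_years, function(a)
    trajectory_density(co$models[g_up, ], a, a0 = co$a0), 0)
  expect_equal(unname(stats::cor(e0[g_up, ], d)), 1)

  # corr_strength = 0 removes any class signal
  eflat <- simulate_expression(co, corr_strength = 0, seed = 5)
  up_genes <- co$region_genes$gene_id[co$models$klass == "up"]
  prof0 <- geneset_mean_expression(eflat, up_genes)
  expect_gt(t.test(prof0[groups == "prenatal"], prof0[groups == "older"])$p.value, 0.05)

  # default: up-gene set mean increases across the group means
  e1 <- simulate_expression(co, seed = 6)
  prof <- geneset_mean_expression(e1, up_genes)
  gm <- tapply(prof, groups, mean)
  expect_true(gm[["prenatal"]] < gm[["infant"]] && gm[["infant"]] < gm[["older"]])
})
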