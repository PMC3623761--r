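make_groups <- function() c(rep("prenatal", 3), rep("infant", 3), rep("older", 25))

test_that("classify_up_down reproduces a hand-computed Welch decision", {
  set.seed(9)
  n_s <- 31
  vals <- matrix(0.5, nrow = 3, ncol = n_s)
  groups <- make_groups()
  older <- groups == "older"
  # region 1: clear down call
  vals[1, groups == "prenatal"] <- c(0.039, 0.040, 0.041)
  vals[1, groups == "infant"] <- 0.02
  vals[1, older] <- rnorm(25, 0.010, 0.001)
  # region 2: both means below the floor
  vals[2, ] <- 0.005
  # region 3: tiny p but fold below 2
  vals[3, groups == "prenatal"] <- c(0.0300, 0.0301, 0.0302)
  vals[3, older] <- rnorm(25, 0.020, 0.0001)
  dm <- make_density_matrix(vals, lengths = rep(1200L, 3))
  calls <- classify_up_down(dm, groups)
  expect_equal(calls$klass, c("down", "none", "none"))
  # p equals the t.test oracle
  oracle <- t.test(vals[1, groups == "prenatal"], vals[1, older])
  expect_equal(calls$p_value[1], oracle$p.value, tolerance = 1e-12)
  # pooled-variance flavour matches its own oracle
  cfgp <- trajectory_call_config(var_equal = TRUE)
  callsp <- classify_up_down(dm, groups, cfgp)
  oracle2 <- t.test(vals[1, groups == "prenatal"], vals[1, older], var.equal = TRUE)
  expect_equal(callsp$p_value[1], oracle2$p.value, tolerance = 1e-12)
})

test_that("length gate, floor reciprocity and degenerate variance are honoured", {
  groups <- make_groups()
  vals <- matrix(0.011, nrow = 3, ncol = 31)
  vals[1, groups == "prenatal"] <- 0.05  # would be down, but region too short
  vals[2, groups == "older"] <- 0.05     # up: floor applies to the older group
  vals[2, groups == "prenatal"] <- 0.005
  vals[3, ] <- 0.02                       # constant: p undefined
  set.seed(1)
  vals[1:2, ] <- vals[1:2, ] * exp(rnorm(62, 0, 0.02))
  dm <- make_density_matrix(vals, lengths = c(800L, 1500L, 1500L))
  calls <- classify_up_down(dm, groups)
  expect_equal(calls$klass, c("none", "up", "none"))
  expect_true(is.na(calls$p_value[3]))
  expect_error(classify_up_down(dm, rep("older", 31)), "prenatal")
})

test_that("swapping the age groups swaps up and down calls exactly", {
  res <- run_recovery(2, tiny_config(seed = 2, n_regions = 150L))
  swapped <- res$groups
  swapped[res$groups == "prenatal"] <- "older"
  swapped[res$groups == "older"] <- "prenatal"
  calls_swap <- classify_up_down(res$dm, swapped)
  expect_equal(calls_swap$klass == "up", res$calls$klass == "down")
  expect_equal(calls_swap$klass == "down", res$calls$klass == "up")
})

test_that("mean_profile averages the selected regions", {
  set.seed(3)
  vals <- matrix(runif(50), nrow = 5)
  dm <- make_density_matrix(vals)
  # single region: its own row; duplicated selection changes nothing
  expect_equal(unname(mean_profile(dm, "R2")), unname(vals[2, ]))
  expect_equal(mean_profile(dm, c("R2", "R2")), mean_profile(dm, "R2"))
  # random subset vs column-mean oracle
  expect_equal(unname(mean_profile(dm, c("R1", "R4", "R5"))),
               unname(colMeans(vals[c(1, 4, 5), ])))
  expect_error(mean_profile(dm, character()), "empty")
})

test_that("clustering filter applies length, floor and chrY rules then max-normalizes", {
  groups <- make_groups()
  vals <- matrix(0.02, nrow = 4, ncol = 31)
  vals[2, ] <- 0.004                 # below floor in both groups
  vals[4, 1] <- 0.04
  dm <- make_density_matrix(vals, lengths = c(1500L, 1500L, 800L, 1500L))
  dm$regions$chrom[4] <- "chrY"
  dm2 <- make_density_matrix(vals[c(1, 4), , drop = FALSE])
  nm <- filter_and_normalize_for_clustering(dm, groups)
  expect_equal(rownames(nm), "R1")   # short, sub-floor and chrY regions dropped
  expect_equal(unname(nm[1, ]), rep(1, 31))
  # profile (0.02, 0.04) -> (0.5, 1.0)
  two <- make_density_matrix(matrix(c(0.02, 0.04), nrow = 1, ncol = 2))
  nm2 <- filter_and_normalize_for_clustering(two, c("prenatal", "prenatal"),
                                             trajectory_call_config(min_length = 100L))
  expect_equal(unname(nm2[1, ]), c(0.5, 1))
  # retained set equals re-applying the predicates directly
  res <- run_recovery(4, tiny_config(seed = 4, n_regions = 150L))
  nm3 <- filter_and_normalize_for_clustering(res$dm, res$groups)
  len <- res$dm$regions$end - res$dm$regions$start
  keep <- len >= 1000 &
    (rowMeans(res$dm$values[, res$groups == "prenatal"]) >= 0.01 |
       rowMeans(res$dm$values[, res$groups == "older"]) >= 0.01)
  expect_equal(rownames(nm3), res$dm$regions$id[keep])
  expect_true(all(apply(nm3, 1, max) == 1))
})

test_that("k-means recovers noiseless archetypes and is seed-stable", {
  ages <- sort(reference_cohort()$age_years[1:31])
  up <- (ages - min(ages)) / diff(range(ages))
  arch <- rbind(up, 1 - up, rep(1, 31))
  prof <- arch[rep(1:3, each = 20), ]
  rownames(prof) <- sprintf("R%d", 1:60)
  cl <- kmeans_profiles(prof, k = 3, seed = 1)
  # planted partition recovered exactly (up to label permutation)
  expect_equal(length(unique(cl$assignment[1:20])), 1L)
  expect_equal(length(unique(cl$assignment[21:40])), 1L)
  expect_equal(length(unique(cl$assignment[41:60])), 1L)
  expect_equal(length(unique(cl$assignment[c(1, 21, 41)])), 3L)
  expect_equal(cl$withinss, 0, tolerance = 1e-12)
  # same seed, same assignments
  expect_identical(cl$assignment, kmeans_profiles(prof, k = 3, seed = 1)$assignment)
  expect_error(kmeans_profiles(prof, k = 100), "exceeds")
})

test_that("cluster trends are labeled by rank correlation with age", {
  ages <- c(-0.1, 0.5, 2, 10, 40, 80)
  expect_equal(label_cluster_trend(c(0.1, 0.2, 0.4, 0.6, 0.8, 1), ages), "up")
  expect_equal(label_cluster_trend(c(1, 0.8, 0.5, 0.3, 0.2, 0.1), ages), "down")
  expect_equal(label_cluster_trend(rep(0.5, 6), ages), "flat")
  # noisy monotone decreasing: decision matches the rank-correlation oracle
  set.seed(11)
  cen <- rev(sort(runif(6))) + rnorm(6, 0, 0.05)
  rho <- cor(cen, ages, method = "spearman")
  want <- if (rho >= 0.5) "up" else if (rho <= -0.5) "down" else "flat"
  expect_equal(label_cluster_trend(cen, ages), want)
})

test_that("geneset_mean_expression averages present genes and errors on none", {
  expr <- matrix(1:12, nrow = 3, dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  expect_equal(as.numeric(geneset_mean_expression(expr, "g2")), as.numeric(expr["g2", ]))
  expect_message(out <- geneset_mean_expression(expr, c("g1", "g3", "zz")), "absent")
  expect_equal(as.numeric(out), unname(colMeans(expr[c("g1", "g3"), ])))
  expect_equal(attr(out, "n_missing"), 1L)
  expect_error(geneset_mean_expression(expr, c("a", "b")), "no overlap")
})
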