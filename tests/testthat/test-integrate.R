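test_that("peaks_to_genes links by inclusive 2 kb distance", {
  peaks <- genomic_intervals("chr1", 10000, 12000, id = "P1")
  ann <- function(tss) data.frame(gene_id = "G", chrom = "chr1", tss = tss, strand = "+")
  # TSS inside the peak: distance 0
  expect_equal(peaks_to_genes(peaks, ann(11000))$distance, 0L)
  # 1.5 kb away: linked; 2.5 kb away: not
  expect_equal(nrow(peaks_to_genes(peaks, ann(8500))), 1L)
  expect_equal(peaks_to_genes(peaks, ann(8500))$distance, 1500L)
  expect_equal(nrow(peaks_to_genes(peaks, ann(14500))), 0L)
  # exact boundary is inclusive on both sides
  expect_equal(nrow(peaks_to_genes(peaks, ann(8000))), 1L)
  expect_equal(peaks_to_genes(peaks, ann(13999))$distance, 2000L)
  expect_equal(nrow(peaks_to_genes(peaks, ann(14000))), 0L)
  expect_equal(attr(peaks_to_genes(peaks, ann(14000)), "distal"), "P1")
})

test_that("peaks_to_genes equals an all-pairs distance oracle", {
  set.seed(13)
  peaks <- merge_intervals(random_intervals(40, chrom_len = 3e5, max_len = 2500, seed = 13))
  peaks$id <- sprintf("P%d", seq_len(nrow(peaks)))
  ann <- data.frame(gene_id = sprintf("G%d", 1:80), chrom = "chrT",
                    tss = sample.int(3e5, 80), strand = "+")
  links <- peaks_to_genes(peaks, ann)
  oracle <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    d <- ifelse(ann$tss < peaks$start[i], peaks$start[i] - ann$tss,
                ifelse(ann$tss >= peaks$end[i], ann$tss - peaks$end[i] + 1L, 0L))
    hit <- which(d <= 2000)
    if (!length(hit)) return(NULL)
    data.frame(region_id = peaks$id[i], gene_id = ann$gene_id[hit],
               distance = d[hit])
  }))
  oracle <- oracle[order(oracle$region_id, oracle$gene_id), ]
  expect_equal(links$region_id, oracle$region_id)
  expect_equal(links$gene_id, oracle$gene_id)
  expect_equal(links$distance, oracle$distance)
  # representation is rebuildable: links emitted and re-derived agree
  expect_equal(nrow(links), nrow(oracle))
})

test_that("alternative promoter classes follow pair distance and concordance", {
  mk_links <- function(tss2) {
    data.frame(region_id = c("P1", "P2"), gene_id = "G",
               tss = c(10000L, tss2), distance = 0L)
  }
  calls <- data.frame(region_id = c("P1", "P2"), klass = c("up", "down"))
  # 50 kb apart, opposing classes
  cls <- alternative_promoter_classes(mk_links(60000L), calls)
  expect_equal(cls$class, "up+down")
  # 150 kb apart: excluded
  expect_equal(nrow(alternative_promoter_classes(mk_links(160000L), calls)), 0L)
  # concordant pair
  calls2 <- data.frame(region_id = c("P1", "P2"), klass = c("down", "down"))
  expect_equal(alternative_promoter_classes(mk_links(60000L), calls2)$class, "down+down")
  # planted bi-promoter genes in the generator are recoverable
  cfg <- cohort_config(meta = reduced_cohort(), n_regions = 200L,
                       fraction_proximal = 1, fraction_bi_promoter = 0.2, seed = 6)
  layout <- simulate_annotation(cfg)
  bi <- names(which(table(layout$region_genes$gene_id) == 2))
  expect_equal(length(bi), 20L)
  calls3 <- data.frame(region_id = layout$region_genes$region_id, klass = "up")
  links3 <- peaks_to_genes(layout$regions, layout$annotation)
  cls3 <- alternative_promoter_classes(links3, calls3)
  expect_setequal(cls3$gene_id, bi)
  expect_true(all(cls3$class == "up+up"))
})

test_that("cpg_age_test computes BH-adjusted directional calls", {
  # BH step-up oracle on a tiny p-vector, via planted group means
  groups <- c("prenatal", "prenatal", "prenatal", rep("older", 4))
  meth <- data.frame(cpg_id = c("c1", "c2", "c3"), gene_id = c("g1", "g2", "g3"),
                     chrom = "chrT", pos = 1:3)
  set.seed(5)
  b <- rbind(c(0.8, 0.82, 0.81, 0.3, 0.31, 0.29, 0.30),   # strong decrease
             c(0.5, 0.52, 0.48, 0.5, 0.49, 0.51, 0.50),   # flat
             c(0.3, 0.31, 0.29, 0.8, 0.79, 0.81, 0.80))   # strong increase
  colnames(b) <- sprintf("s%d", 1:7)
  res <- cpg_age_test(cbind(meth, as.data.frame(b)), groups)
  expect_equal(res$direction, c("decrease", "none", "increase"))
  expect_equal(res$fdr, p.adjust(res$p, method = "BH"))
  # constant CpG excluded from the FDR family
  b2 <- rbind(b, c(rep(0.4, 7)))
  meth2 <- data.frame(cpg_id = sprintf("c%d", 1:4), gene_id = sprintf("g%d", 1:4),
                      chrom = "chrT", pos = 1:4)
  expect_message(res2 <- cpg_age_test(cbind(meth2, as.data.frame(b2)), groups),
                 "constant")
  expect_true(is.na(res2$p[4]))
  expect_equal(res2$fdr[1:3], p.adjust(res2$p[1:3], method = "BH"))
})

test_that("BH adjustment matches the hand step-up rule and dominates Bonferroni", {
  # worked example: (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"), rep(0.03, 3))
  hand_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    bh <- p.adjust(p, method = "BH")
    expect_equal(bh, hand_bh(p))
    # BH never selects fewer hypotheses than Bonferroni
    q <- 0.1
    expect_gte(sum(bh <= q), sum(p.adjust(p, method = "bonferroni") <= q))
    # monotone after step-up
    expect_true(all(diff(bh[order(p)]) >= -1e-15))
  }
})

test_that("hypergeometric_upper_tail equals exhaustive enumeration for N <= 12", {
  enum_tail <- function(k, n, K, N) {
    # enumerate all draw compositions via the pmf definition
    js <- k:min(n, K)
    if (length(js) == 0 || k > min(n, K)) return(0)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  expect_equal(hypergeometric_upper_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  for (N in 1:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:n) {
          expect_equal(hypergeometric_upper_tail(k, n, K, N),
                       if (k == 0) 1 else enum_tail(k, n, K, N),
                       tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeometric_upper_tail(5, 3, 2, 10), "margins")
})

test_that("the reconstructed anti-correlation contingency delegates to the tail", {
  # counts reconstructed from the printed percentages: 62/394 up-row CpGs
  # decreased vs 46/744 in the down row
  p_direct <- hypergeometric_upper_tail(62, 394, 108, 1138)
  gene_classes <- c(setNames(rep("up", 394), sprintf("u%d", 1:394)),
                    setNames(rep("down", 744), sprintf("d%d", 1:744)))
  res <- data.frame(cpg_id = sprintf("c%d", 1:1138),
                    gene_id = names(gene_classes),
                    direction = c(rep("decrease", 62), rep("none", 332),
                                  rep("decrease", 46), rep("none", 698)))
  ct <- direction_contingency(gene_classes, res)
  expect_equal(unname(ct$counts[1, ]), c(62, 332))
  expect_equal(unname(ct$counts[2, ]), c(46, 698))
  expect_equal(ct$p, p_direct, tolerance = 1e-12)
  # all CpGs decreased in both rows: no enrichment
  res2 <- res
  res2$direction <- "decrease"
  expect_equal(direction_contingency(gene_classes, res2)$p, 1, tolerance = 1e-12)
})

test_that("overrepresentation matches the enumeration oracle on a toy universe", {
  universe <- sprintf("g%d", 1:20)
  terms <- data.frame(term = c(rep("T1", 5), rep("T2", 8), rep("T3", 4)),
                      gene = c(sprintf("g%d", 1:5), sprintf("g%d", 4:11),
                               sprintf("g%d", 17:20)))
  gene_set <- sprintf("g%d", 1:5)
  res <- overrepresentation(gene_set, terms, universe)
  enum_tail <- function(k, n, K, N) {
    js <- k:min(n, K)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  for (tm in res$term) {
    r <- res[res$term == tm, ]
    expect_equal(r$p, enum_tail(r$overlap, 5, r$term_size, 20), tolerance = 1e-10)
  }
  # a term identical to the gene set is the most significant
  expect_equal(res$term[1], "T1")
  # zero overlap: p = 1
  expect_equal(res$p[res$term == "T3"], 1)
  expect_equal(res$fdr, p.adjust(res$p, "BH")[order(res$p)])
  expect_equal(res$score, -log10(res$fdr))
  expect_error(overrepresentation("zz", terms, universe), "subset")
})

test_that("enrichment-score correlation honours the inclusion rule", {
  a <- data.frame(term = sprintf("T%d", 1:6), fdr = c(0.001, 0.01, 0.1, 0.5, 0.84, 0.99))
  a$score <- -log10(a$fdr)
  # identical lists correlate perfectly over the 5 included terms
  out <- enrichment_score_correlation(a, a)
  expect_equal(out$r, 1)
  expect_equal(out$n_terms, 5L)
  # reversed landscape: strong negative correlation
  b <- a
  b$fdr <- rev(a$fdr)
  b$score <- -log10(b$fdr)
  out2 <- enrichment_score_correlation(a, b)
  expect_lt(out2$r, -0.8)
  expect_equal(out2$n_terms, 6L)  # union of inclusion in either list
  # direct-formula oracle
  keep <- a$fdr < 0.85 | b$fdr < 0.85
  expect_equal(out2$r, cor(a$score[keep], b$score[keep]), tolerance = 1e-12)
  # too few terms: undefined with a warning
  expect_warning(out3 <- enrichment_score_correlation(a[1:2, ], a[1:2, ]), "fewer than 3")
  expect_true(is.na(out3$r))
})
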