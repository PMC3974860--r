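test_that("spearman_rho matches the reference implementation, ties included", {
  expect_equal(spearman_rho(1:16, 1:16)$rho, 1.0)
  expect_equal(spearman_rho(1:16, 16:1)$rho, -1.0)
  set.seed(12)
  for (i in 1:300) {
    x <- stats::rnorm(16)
    y <- stats::rnorm(16)
    if (i %% 3 == 0) {                        # inject ties
      x <- round(x, 1); y <- round(y, 1)
    }
    expect_equal(spearman_rho(x, y)$rho,
                 stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("small-sample p-values are exact permutation probabilities", {
  set.seed(3)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  mine <- spearman_rho(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("pairs with silent or broadly expressed parents are excluded", {
  tissues <- sprintf("T%02d", 1:16)
  pg <- matrix(stats::rexp(32), 2, 16,
               dimnames = list(c("p1", "p2"), tissues))
  parent <- rbind(g1 = rep(0, 16), g2 = rep(1, 16))   # g2: uniform, JS ~ 0.09
  colnames(parent) <- tissues
  pairs <- data.frame(pg_id = c("p1", "p2"), parent_id = c("g1", "g2"))
  res <- pg_parent_spearman(pg, parent, pairs, parent_js_min = 0.1)
  expect_true(all(res$excluded))
  expect_equal(res$reason, c("parent_all_zero", "parent_js_low"))
  res2 <- pg_parent_spearman(pg, parent, pairs[2, ], parent_js_min = NULL)
  expect_false(res2$excluded)
})

test_that("identical and reversed profiles give rho of 1 and -1", {
  tissues <- sprintf("T%02d", 1:16)
  v <- seq(1, 16) + 0.5
  pg <- matrix(v, 1, 16, dimnames = list("p1", tissues))
  parent_same <- matrix(v * 3, 1, 16, dimnames = list("g1", tissues))
  parent_rev <- matrix(rev(v), 1, 16, dimnames = list("g1", tissues))
  pairs <- data.frame(pg_id = "p1", parent_id = "g1")
  expect_equal(pg_parent_spearman(pg, parent_same, pairs,
                                  parent_js_min = NULL)$rho, 1.0)
  expect_equal(pg_parent_spearman(pg, parent_rev, pairs,
                                  parent_js_min = NULL)$rho, -1.0)
})

test_that("distance grouping uses a 20-kb inclusive cutoff", {
  mk <- function(start, end) matrix(c(start, end), ncol = 2)
  ann <- pg_annotation(data.frame(
    feature_id = c("geneA", "near", "far", "edge"),
    chrom = "chrT",
    start = c(0L, 16000L, 46000L, 121000L),
    end = c(1000L, 17000L, 47000L, 122000L),
    strand = "+",
    class = c("gene", rep("processed_pg", 3)),
    parent_id = c(NA, rep("geneA", 3)),
    blocks = I(list(mk(0L, 1000L), mk(16000L, 17000L),
                    mk(46000L, 47000L), mk(121000L, 122000L))),
    stringsAsFactors = FALSE))
  dg <- distance_groups(ann, cutoff = 20000)
  expect_equal(dg$group[dg$pg_id == "near"], "t1")    # gap 15 kb
  expect_equal(dg$group[dg$pg_id == "far"], "t2")     # gap 45 kb
  expect_equal(dg$distance[dg$pg_id == "edge"], 120000)
  dg2 <- distance_groups(ann, cutoff = 120000)
  expect_equal(dg2$group[dg2$pg_id == "edge"], "t1")  # gap exactly at cutoff
})

test_that("tissue split arithmetic and tie-breaks are fixed", {
  pg <- stats::setNames(1:16, sprintf("T%02d", 1:16))
  parent_const <- stats::setNames(rep(4, 16), names(pg))
  s <- tissue_split_mean_variance(pg, parent_const)
  expect_equal(s$delta_mu, 0)
  expect_equal(s$delta_s, 0)
  s2 <- tissue_split_mean_variance(pg, stats::setNames(1:16, names(pg)))
  expect_equal(s2$mu_h, 12.5)
  expect_equal(s2$mu_l, 4.5)
  expect_equal(s2$delta_mu, 8)
  # tied pseudogene values break on tissue name order
  tied <- stats::setNames(rep(1, 16), sprintf("T%02d", 1:16))
  s3 <- tissue_split_mean_variance(tied, stats::setNames(1:16, names(tied)))
  expect_equal(sort(s3$high_tissues), sprintf("T%02d", 1:8))
  expect_error(tissue_split_mean_variance(1:15, 1:15), "even")
})

test_that("strand inference truth table holds, including the 10x boundary", {
  expect_equal(infer_strand(1.0, 0.05), "sense")         # 20x
  expect_equal(infer_strand(1.0, 0.1), "sense")          # exactly 10x
  expect_equal(infer_strand(0.5, 0.1), "both")           # 5x
  expect_equal(infer_strand(0, 0.3), "antisense")
  expect_equal(infer_strand(0.3, 0), "sense")
  expect_equal(infer_strand(0, 0), "no_call")
  expect_equal(infer_strand(0.04, 0.3, min_expr = 0.05), "antisense")
  expect_equal(infer_strand(0.04, 0.04, min_expr = 0.05), "no_call")
  expect_equal(infer_strand(c(1, 0.5), c(0.05, 0.1)), c("sense", "both"))
})

test_that("miRNA binning reproduces brute-force grouping", {
  expect_equal(mirna_binned_correlation(c(0.9, 0.5, 0.1),
                                        c(-0.8, 0, 0.8))$r, -1.0)
  one_bin <- mirna_binned_correlation(c(0.2, 0.4, 0), c(0.31, 0.35, -0.6))
  b <- one_bin$bins
  row <- which(abs(b$lo - 0.3) < 1e-9)
  expect_equal(b$mean[row], 0.3)
  expect_equal(b$sd[row], stats::sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(b$sd[row], 0.1414, tolerance = 1e-3)
  set.seed(9)
  rp <- stats::runif(200, -1, 1); rm_ <- stats::runif(200, -1, 1)
  res <- mirna_binned_correlation(rp, rm_)
  for (k in seq_len(nrow(res$bins))) {
    lo <- res$bins$lo[k]; hi <- res$bins$hi[k]
    inb <- if (hi >= 1) rm_ >= lo & rm_ <= hi else rm_ >= lo & rm_ < hi
    expect_equal(res$bins$n[k], sum(inb))
    if (sum(inb) > 0) expect_equal(res$bins$mean[k], mean(rp[inb]))
  }
  expect_true(all(res$bins$n >= 0))
  expect_equal(sum(res$bins$n), 200)        # every triple in exactly one bin
  expect_error(mirna_binned_correlation(numeric(0), numeric(0)), "no correlation")
})

test_that("knockdown comparison filters at the fold threshold", {
  fc <- c(a = 1.2, b = 1.4, c = 2.0, d = 1.5, e = 3.0, f = 1.35)
  cl <- c(a = "parent_targeted", b = "parent_targeted", c = "parent_other",
          d = "coding_targeted_no_pg", e = "coding_targeted_no_pg",
          f = "parent_other")
  res <- kd_upregulation_comparison(fc, cl, threshold = 1.3)
  expect_equal(sum(res$summary$n), 5)       # 1.2 excluded
  expect_true(all(!is.na(res$tests$p)))
  # two identical distributions give p = 1
  fc2 <- c(x1 = 1.4, x2 = 2.0, y1 = 1.4, y2 = 2.0)
  cl2 <- c(x1 = "A", x2 = "A", y1 = "B", y2 = "B")
  res2 <- suppressWarnings(kd_upregulation_comparison(fc2, cl2))
  expect_equal(res2$tests$p, 1.0)
  # an empty class after filtering reports NA
  fc3 <- c(x1 = 1.4, y1 = 1.1)
  cl3 <- c(x1 = "A", y1 = "B")
  res3 <- kd_upregulation_comparison(fc3, cl3)
  expect_true(is.na(res3$tests$p))
})

test_that("a stochastically larger class shows the larger median", {
  set.seed(14)
  fc <- c(stats::setNames(1.3 + stats::rexp(80, 2), sprintf("a%02d", 1:80)),
          stats::setNames(1.3 + stats::rexp(80, 1), sprintf("b%02d", 1:80)))
  cl <- c(stats::setNames(rep("parent_targeted", 80), sprintf("a%02d", 1:80)),
          stats::setNames(rep("coding_targeted_no_pg", 80),
                          sprintf("b%02d", 1:80)))
  res <- kd_upregulation_comparison(fc, cl)
  s <- res$summary
  expect_gt(s$median_fold[s$class == "coding_targeted_no_pg"],
            s$median_fold[s$class == "parent_targeted"])
  expect_lt(res$tests$p, 0.05)
})
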