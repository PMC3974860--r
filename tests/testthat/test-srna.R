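test_that("density is reads per kb with 5'-end counting", {
  ann <- spaced_annotation(1, len = 2000L)
  cl <- c(chrT = 100000L)
  reads <- data.frame(chrom = "chrT",
                      start = ann$start[1] + seq(0, 1800, length.out = 10),
                      end = ann$start[1] + seq(0, 1800, length.out = 10) + 22,
                      strand = "+")
  d <- srna_density(reads, ann, chrom_lens = cl)
  expect_equal(d$exonic_density, 5.0)
  expect_equal(d$flank_reads, 0)
  none <- srna_density(reads[0, ], ann, chrom_lens = cl)
  expect_equal(none$exonic_density, 0)
})

test_that("minus-strand reads count at their 5' end and flanks truncate", {
  ann <- pg_annotation(data.frame(
    feature_id = "p", chrom = "chrT", start = 500L, end = 1500L,
    strand = "+", class = "processed_pg", parent_id = "g",
    blocks = I(list(matrix(c(500L, 1500L), ncol = 2))),
    stringsAsFactors = FALSE))
  # minus-strand read [480, 510): 5' end at 509 -> inside the feature
  reads <- data.frame(chrom = "chrT", start = c(480L, 480L),
                      end = c(510L, 510L), strand = c("-", "+"))
  d <- srna_density(reads, ann, chrom_lens = c(chrT = 2000L))
  expect_equal(d$exonic_reads, 1)
  expect_equal(d$flank_reads, 1)
  # left flank truncated at the chromosome start: 500 + 500 bp realized
  expect_equal(d$flank_kb, 1.0)
})

test_that("densities match brute-force interval counting on a random fixture", {
  set.seed(8)
  ann <- spaced_annotation(5, len = 1200L)
  cl <- c(chrT = 100000L)
  pos <- sample(0:99000, 3000, replace = TRUE)
  reads <- data.frame(chrom = "chrT", start = pos, end = pos + 21,
                      strand = sample(c("+", "-"), 3000, replace = TRUE))
  d <- srna_density(reads, ann, chrom_lens = cl)
  fp <- ifelse(reads$strand == "-", reads$end - 1, reads$start)
  for (i in 1:5) {
    expect_equal(d$exonic_reads[i],
                 sum(fp >= ann$start[i] & fp < ann$end[i]))
    expect_equal(d$flank_reads[i],
                 sum(fp >= ann$start[i] - 1000 & fp < ann$start[i]) +
                   sum(fp >= ann$end[i] & fp < ann$end[i] + 1000))
  }
})

test_that("poisson enrichment matches direct pmf summation", {
  expect_equal(poisson_enrichment(0, 1, 5), 1.0)
  # independent log-space summation of the upper tail
  direct_upper <- function(count, lambda) {
    sum(exp(stats::dpois(count:(count + 3000), lambda, log = TRUE)))
  }
  expect_equal(poisson_enrichment(10, 1, 1), 1.1142e-7, tolerance = 1e-3)
  for (count in c(1, 3, 10, 40, 100)) {
    for (lambda in c(0.5, 1, 10)) {
      expect_lt(abs(poisson_enrichment(count, 1, lambda) -
                      direct_upper(count, lambda)), 1e-10)
    }
  }
  p <- poisson_enrichment(0:30, 1, 2)
  expect_true(all(diff(p) < 0))            # monotone decreasing in count
  expect_error(poisson_enrichment(-1, 1, 1), "non-negative")
})

test_that("group classification reproduces the threshold truth table", {
  grid <- expand.grid(exonic = c(0, 2, 5, 5.01, 7),
                      flank = c(0, 2, 5, 5.01, 7))
  records <- data.frame(feature_id = sprintf("f%02d", seq_len(nrow(grid))),
                        exonic_reads = grid$exonic, exonic_kb = 1,
                        exonic_density = grid$exonic,
                        flank_reads = grid$flank * 2, flank_kb = 2,
                        flank_density = grid$flank)
  calls <- classify_srna_groups(records, exonic_min = 5, flank_hi = 5)
  expected <- ifelse(grid$exonic < 5, "not_candidate",
                     ifelse(grid$flank == 0, "group_I",
                            ifelse(grid$flank > 5, "group_II",
                                   "candidate_unassigned")))
  expect_equal(calls$call, expected)
})

test_that("planted sRNA group labels are recovered on the simulated fixture", {
  ann <- spaced_annotation(6, len = 1000L, gap = 6000L)
  cl <- c(chrT = 100000L)
  labels <- stats::setNames(c("I", "I", "II", "II", "none", "none"),
                            ann$feature_id)
  sim <- simulate_srna_reads(ann, labels, exonic_density = 20,
                             flank_density = 12, chrom_lens = cl, seed = 3)
  d <- srna_density(sim$reads, ann, chrom_lens = cl)
  calls <- classify_srna_groups(d)
  got <- stats::setNames(calls$call, calls$feature_id)
  expect_equal(unname(got[labels == "I"]), rep("group_I", 2))
  expect_equal(unname(got[labels == "II"]), rep("group_II", 2))
  expect_equal(unname(got[labels == "none"]), rep("not_candidate", 2))
})

test_that("simulated read lengths recover the planted medians", {
  ann <- spaced_annotation(2, len = 10000L, gap = 8000L)
  cl <- c(chrT = 100000L)
  labels <- stats::setNames(c("I", "II"), ann$feature_id)
  sim <- simulate_srna_reads(ann, labels, exonic_density = 25,
                             flank_density = 10, len_medians = c(22L, 25L),
                             chrom_lens = cl, seed = 5)
  lens <- sim$reads$end - sim$reads$start
  by_grp <- split(lens, sim$reads$origin)
  expect_gte(min(lengths(by_grp)), 200)
  expect_lte(abs(stats::median(by_grp[[ann$feature_id[1]]]) - 22), 1)
  expect_lte(abs(stats::median(by_grp[[ann$feature_id[2]]]) - 25), 1)
})

test_that("all-none labels produce an empty read set", {
  ann <- spaced_annotation(2)
  labels <- stats::setNames(rep("none", 2), ann$feature_id)
  sim <- simulate_srna_reads(ann, labels, chrom_lens = c(chrT = 100000L))
  expect_equal(nrow(sim$reads), 0)
})

test_that("size comparison reports lower medians and detects planted shifts", {
  same <- srna_size_comparison(c(20, 22, 24), c(20, 22, 24))
  expect_equal(same$ks_stat, 0)
  expect_equal(same$delta_median, 0)
  expect_false(same$p_reliable)
  s <- srna_size_comparison(c(21, 22, 23, 22, 22), c(25, 24, 26, 25, 25))
  expect_equal(s$median_I, 22)
  expect_equal(s$median_II, 25)
  expect_equal(s$delta_median, 3)
  # even n: lower of the two middles
  expect_equal(srna_size_comparison(c(22, 23, 24, 25), c(25, 25))$median_I, 23)
  set.seed(4)
  li <- 22 + sample(-2:2, 500, replace = TRUE, prob = c(.1, .2, .4, .2, .1))
  lii <- 25 + sample(-2:2, 500, replace = TRUE, prob = c(.1, .2, .4, .2, .1))
  expect_lt(srna_size_comparison(li, lii)$p, 0.01)
})

test_that("reduction fractions follow strict comparison with ties not reduced", {
  r <- condition_reduction_fraction(c(a = 5, b = 2), c(a = 1, b = 2))
  expect_equal(r$fraction, 0.5)
  expect_equal(condition_reduction_fraction(c(a = 5, b = 2),
                                            c(a = 0, b = 0))$fraction, 1.0)
  set.seed(2)
  ctrl <- stats::setNames(stats::rpois(50, 4), sprintf("p%02d", 1:50))
  kd <- stats::setNames(stats::rpois(50, 2), names(ctrl))
  r2 <- condition_reduction_fraction(ctrl, kd, min_reads = 1)
  u <- names(ctrl)[ctrl >= 1]
  expect_equal(r2$fraction, mean(kd[u] < ctrl[u]))
  expect_error(condition_reduction_fraction(c(a = 0), c(a = 0)), "min_reads")
})
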