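test_that("window counts normalize to tags per 500 bp", {
  tags <- data.frame(chrom = "chrT", pos = seq(1000, 5999, length.out = 50))
  w <- data.frame(chrom = "chrT", start = 1000, end = 6000, name = "body")
  res <- window_tag_count(tags, w)
  expect_equal(res$count, 50)
  expect_equal(res$density, 5.0)
  empty <- window_tag_count(tags, data.frame(chrom = "chrT", start = 50000,
                                             end = 50500, name = "far"))
  expect_equal(empty$count, 0)
  expect_error(window_tag_count(tags, data.frame(chrom = "chrT", start = 5,
                                                 end = 5, name = "zero")),
               "zero-length")
})

test_that("window counts match a brute-force scan on random data", {
  set.seed(7)
  tags <- data.frame(chrom = "chrT", pos = sample(0:49999, 2000, replace = TRUE))
  starts <- sample(0:48000, 20)
  w <- data.frame(chrom = "chrT", start = starts, end = starts + 700,
                  name = sprintf("w%02d", 1:20))
  res <- window_tag_count(tags, w)
  for (i in 1:20) {
    expect_equal(res$count[i],
                 sum(tags$pos >= w$start[i] & tags$pos < w$end[i]))
  }
})

test_that("anchored profiles bin by signed, strand-mirrored offset", {
  tags <- data.frame(chrom = "chrT", pos = c(1050, 1150))
  plus <- data.frame(chrom = "chrT", pos = 1000, strand = "+")
  prof <- anchored_profile(tags, plus, flank = 200, bin = 100)
  expect_equal(prof$mean_tags[prof$bin_start == 0], 1)
  expect_equal(prof$mean_tags[prof$bin_start == 100], 1)
  expect_equal(sum(prof$mean_tags), 2)
  # mirrored anchor sees the same profile from the other side
  minus <- data.frame(chrom = "chrT", pos = 1000, strand = "-")
  prof_m <- anchored_profile(data.frame(chrom = "chrT", pos = c(950, 850)),
                             minus, flank = 200, bin = 100)
  expect_equal(prof_m$mean_tags, prof$mean_tags)
})

test_that("profile mass equals the number of in-range tags", {
  set.seed(10)
  anchors <- data.frame(chrom = "chrT", pos = c(10000, 30000, 50000),
                        strand = c("+", "-", "+"))
  tags <- data.frame(chrom = "chrT", pos = sample(0:60000, 4000, replace = TRUE))
  prof <- anchored_profile(tags, anchors, flank = 2000, bin = 500)
  in_range <- sum(vapply(seq_len(nrow(anchors)), function(i) {
    off <- tags$pos - anchors$pos[i]
    if (anchors$strand[i] == "-") off <- -off
    sum(off >= -2000 & off < 2000)
  }, numeric(1)))
  expect_equal(sum(prof$mean_tags) * nrow(anchors), in_range)
  # against brute-force binning
  for (b in seq_len(nrow(prof))) {
    cnt <- 0
    for (i in seq_len(nrow(anchors))) {
      off <- tags$pos - anchors$pos[i]
      if (anchors$strand[i] == "-") off <- -off
      cnt <- cnt + sum(off >= prof$bin_start[b] & off < prof$bin_end[b])
    }
    expect_equal(prof$mean_tags[b], cnt / nrow(anchors))
  }
})

test_that("promoter factor counts deduplicate factors and respect half-open bounds", {
  ann <- pg_annotation(data.frame(
    feature_id = c("plus", "minus"),
    chrom = "chrT", start = c(10000L, 30000L), end = c(11000L, 31000L),
    strand = c("+", "-"), class = "gene", parent_id = NA_character_,
    blocks = I(list(matrix(c(10000L, 11000L), ncol = 2),
                    matrix(c(30000L, 31000L), ncol = 2))),
    stringsAsFactors = FALSE))
  peaks <- data.frame(
    chrom = "chrT",
    start = c(9000L, 9200L, 9400L, 9500L, 7900L, 31200L),
    end = c(9100L, 9300L, 9500L, 9600L, 8000L, 31300L),
    factor = c("A", "A", "A", "B", "C", "D"))
  res <- promoter_distinct_factor_count(peaks, ann)
  # plus promoter [8000, 10000): A three times -> 1, plus B -> 2;
  # C ends exactly at 8000 and does not count
  expect_equal(res$n_factors[res$feature_id == "plus"], 2)
  # minus promoter [30999+1, 33000): D inside
  expect_equal(res$n_factors[res$feature_id == "minus"], 1)
})

test_that("overlap binomial p equals direct tail summation", {
  feats <- data.frame(chrom = "chrT", start = (0:19) * 1000,
                      end = (0:19) * 1000 + 500)
  hits <- data.frame(chrom = "chrT", start = (0:9) * 1000 + 100,
                     end = (0:9) * 1000 + 200)
  res <- interval_overlap_binomial(feats, hits, background_prob = 0.1)
  expect_equal(res$k, 10)
  direct <- sum(stats::dbinom(10:20, 20, 0.1))
  expect_equal(res$p, direct, tolerance = 1e-12)
  none <- interval_overlap_binomial(feats,
                                    data.frame(chrom = "chrT",
                                               start = 900000, end = 900100),
                                    background_prob = 0.1)
  expect_equal(none$p, 1.0)
  full_p <- interval_overlap_binomial(feats, hits, background_prob = 1)
  expect_equal(full_p$p, 1.0)
})

test_that("flank extension rescues nearby features in the overlap test", {
  feats <- data.frame(chrom = "chrT", start = 1000, end = 2000)
  targets <- data.frame(chrom = "chrT", start = 2500, end = 2600)
  expect_equal(interval_overlap_binomial(feats, targets,
                                         background_prob = 0.5)$k, 0)
  expect_equal(interval_overlap_binomial(feats, targets, flank = 1000,
                                         background_prob = 0.5)$k, 1)
})

test_that("simulated ChIP tags follow the planted background and folds", {
  ann <- spaced_annotation(4, len = 1000L, gap = 8000L)
  cl <- c(chrT = 60000L)
  rate <- 0.02
  tags <- simulate_chip_tags(ann, c(pg001 = 1, pg002 = 1, pg003 = 0,
                                    pg004 = 1),
                             background_rate = rate, anchor = "center",
                             flank = 1000L, chrom_lens = cl, seed = 6)
  n <- nrow(tags)
  lambda <- rate * cl
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  # fold 0 silences the window
  ctr <- (ann$start[3] + ann$end[3]) %/% 2
  expect_equal(sum(tags$pos >= ctr - 1000 & tags$pos < ctr + 1000), 0)
  tags2 <- simulate_chip_tags(ann, c(pg001 = 1, pg002 = 1, pg003 = 0,
                                     pg004 = 1),
                              background_rate = rate, anchor = "center",
                              flank = 1000L, chrom_lens = cl, seed = 6)
  expect_identical(tags, tags2)
})
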