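test_that("identical haplotypes have zero diversity", {
  hs <- haplotype_set(rep(strrep("ACGT", 25), 4))
  expect_equal(nucleotide_diversity(hs)$pi, 0)
})

test_that("two haplotypes differing at one of 100 sites give pi = 0.005", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 50), "C", strrep("A", 49))
  hs <- haplotype_set(c(a, b))
  # 2 ordered pairs x (1/2)(1/2) x 1/100
  expect_equal(nucleotide_diversity(hs)$pi, 0.005, tolerance = 1e-15)
})

test_that("diversity equals the exhaustive ordered-pair oracle", {
  set.seed(19)
  for (trial in 1:10) {
    n <- sample(2:8, 1)
    L <- sample(60:200, 1)
    base <- strsplit(random_dna(L), "")[[1]]
    seqs <- vapply(seq_len(n), function(i) {
      v <- base
      for (p in sample(L, sample(0:6, 1))) {
        v[p] <- sample(c("A", "C", "G", "T"), 1)
      }
      paste(v, collapse = "")
    }, character(1))
    freqs <- stats::runif(n); freqs <- freqs / sum(freqs)
    hs <- haplotype_set(seqs, freqs)
    expect_equal(nucleotide_diversity(hs)$pi, oracle_pi(seqs, freqs),
                 tolerance = 1e-12)
  }
})

test_that("diversity is invariant to order and duplication of the list", {
  set.seed(23)
  seqs <- vapply(1:4, function(i) random_dna(80), character(1))
  pi0 <- nucleotide_diversity(haplotype_set(seqs))$pi
  expect_equal(nucleotide_diversity(haplotype_set(rev(seqs)))$pi, pi0)
  dup <- nucleotide_diversity(haplotype_set(c(seqs, seqs)))$pi
  expect_equal(dup, pi0, tolerance = 1e-12)
})

test_that("adding a segregating site strictly increases two-haplotype diversity", {
  a <- strrep("G", 200)
  mut_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]; v[pos] <- "T"; paste(v, collapse = "")
  }
  pis <- vapply(1:5, function(k) {
    nucleotide_diversity(haplotype_set(c(a, Reduce(mut_at, 1:k, a))))$pi
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("missing calls are excluded pairwise", {
  a <- paste0("ACGT", strrep("A", 6))
  b <- paste0("NCGT", strrep("A", 6))     # N at the only differing site
  c_ <- paste0("TCGT", strrep("A", 6))
  hs <- haplotype_set(c(a, b, c_))
  pi <- nucleotide_diversity(hs)$pi
  # pair (a,b): 0 diffs over 9 called sites; (a,c): 1/10; (b,c): 0/9
  expect_equal(pi, 2 * (1 / 9) * (1 / 10))
})

test_that("the unbiased flag applies the n/(n-1) correction", {
  a <- strrep("A", 100)
  b <- paste0("C", strrep("A", 99))
  hs <- haplotype_set(c(a, b))
  expect_equal(nucleotide_diversity(hs, unbiased = TRUE)$pi,
               nucleotide_diversity(hs)$pi * 2)
})

test_that("simulated haplotypes round-trip their recorded diversity", {
  sim <- simulate_population_haplotypes(500L, 12L, target_pi = 0.004, seed = 2)
  expect_equal(nucleotide_diversity(sim$hapset)$pi, sim$true_pi,
               tolerance = 1e-12)
  zero <- simulate_population_haplotypes(300L, 6L, target_pi = 0, seed = 3)
  expect_equal(length(unique(zero$hapset$seqs)), 1)
  expect_equal(zero$true_pi, 0)
  expect_error(simulate_population_haplotypes(100L, 1L, 0.01), "2 individuals")
})

test_that("mean realized diversity approaches the target over seeds", {
  pis <- vapply(1:30, function(s) {
    simulate_population_haplotypes(400L, 10L, target_pi = 0.005,
                                   seed = s)$true_pi
  }, numeric(1))
  expect_lt(abs(mean(pis) - 0.005), 0.001)
})

test_that("mean conservation averages the block union excluding missing bases", {
  scores <- rep(0.5, 1000)
  blocks <- matrix(c(100L, 300L, 500L, 700L), ncol = 2, byrow = TRUE)
  expect_equal(mean_conservation(scores, blocks)$mean, 0.5)
  half <- c(rep(NA, 500), rep(0.8, 500))
  expect_equal(mean_conservation(half, blocks)$mean, 0.8)
  all_na <- rep(NA_real_, 1000)
  res <- mean_conservation(all_na, blocks)
  expect_false(res$defined)
  # redundant blocks count each base once
  set.seed(30)
  rnd <- stats::runif(1000)
  dup_blocks <- rbind(blocks, blocks[1, , drop = FALSE])
  manual <- mean(rnd[c(101:300, 501:700)])
  expect_equal(mean_conservation(rnd, dup_blocks)$mean, manual,
               tolerance = 1e-12)
})

test_that("variant tables expand to two haplotypes per individual", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\tref\talt\tind1\tind2",
               "10\tA\tC\t0/1\t0/0",
               "20\tG\tT\t1/1\t0/0"), path)
  hs <- read_variant_haplotypes(path, locus_len = 100)
  expect_equal(hs$n, 4)
  # ind1: hap1 carries alt at 20 only, hap2 at both; ind2: reference twice
  d <- nucleotide_diversity(hs)$pi
  # ordered-pair oracle over the 4 haplotypes
  expect_equal(d, oracle_pi(hs$seqs), tolerance = 1e-12)
  expect_gt(d, 0)
})

test_that("bedGraph tracks expand to per-base scores with NA gaps", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chrT\t0\t10\t0.2", "chrT\t20\t30\t0.9"), path)
  tr <- read_bedgraph_track(path, "chrT", 40)
  expect_equal(tr[1], 0.2)
  expect_true(is.na(tr[15]))
  expect_equal(tr[25], 0.9)
  expect_equal(mean_conservation(tr, matrix(c(0L, 30L), ncol = 2))$n_bases, 20)
})
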