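#' Haplotype set over a locus
#'
#' Aligned individual sequences of equal length with per-sequence
#' frequencies (defaulting to 1/n). `N` marks a missing call.
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param freqs per-sequence frequencies summing to 1; default uniform.
#' @param locus_id identifier.
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(seqs, freqs = NULL, locus_id = "locus") {
  n <- length(seqs)
  if (n < 2) pg_stop("need at least 2 haplotypes")
  L <- unique(nchar(seqs))
  if (length(L) != 1) pg_stop("haplotypes must have equal length")
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  if (abs(sum(freqs) - 1) > 1e-9) pg_stop("frequencies must sum to 1")
  structure(list(seqs = seqs, freqs = freqs, n = n, L = L,
                 locus_id = locus_id), class = "haplotype_set")
}

#' Nucleotide diversity of a haplotype set
#'
#' pi = sum_i sum_j x_i x_j pi_ij over ordered pairs (self pairs contribute
#' 0), where x_i is the frequency of the i-th sequence and pi_ij is the
#' per-site difference count between sequences i and j. Sites where either
#' sequence has a missing call (`N`) are excluded from both the difference
#' count and the site total for that pair; a pair with no jointly called
#' site is skipped with a warning. No sample-size correction is applied by
#' default (`unbiased = TRUE` multiplies by n/(n-1)).
#'
#' @param hapset a [haplotype_set()].
#' @param unbiased apply the n/(n-1) correction.
#' @return list with `pi`, `n`, `L`, `locus_id`.
#' @export
nucleotide_diversity <- function(hapset, unbiased = FALSE) {
  stopifnot(inherits(hapset, "haplotype_set"))
  n <- hapset$n
  M <- do.call(rbind, strsplit(hapset$seqs, ""))
  miss <- M == "N"
  pi <- 0
  skipped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      L_ij <- sum(ok)
      if (L_ij == 0) { skipped <- TRUE; next }
      d_ij <- sum(M[i, ok] != M[j, ok]) / L_ij
      pi <- pi + 2 * hapset$freqs[i] * hapset$freqs[j] * d_ij
    }
  }
  if (skipped) pg_warn("pair(s) with no jointly called site were skipped")
  if (unbiased) pi <- pi * n / (n - 1)
  list(pi = pi, n = n, L = hapset$L, locus_id = hapset$locus_id)
}

#' Read haplotypes from a biallelic variant table
#'
#' The table holds one row per site: `pos` (0-based), `ref`, `alt`, then one
#' column per individual with genotypes `0/0`, `0/1`, `1/1` (or `./.` for
#' missing). Each individual contributes two haplotypes; heterozygous calls
#' put the reference allele on the first haplotype and the alternate on the
#' second (phase is irrelevant for pi, which only depends on per-site allele
#' counts across haplotypes).
#'
#' @param path TSV file with header.
#' @param locus_len locus length (bp).
#' @param ref_seq reference sequence; random bases are generated when
#'   omitted (only differences matter for diversity).
#' @return a [haplotype_set()].
#' @export
read_variant_haplotypes <- function(path, locus_len, ref_seq = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ind <- setdiff(names(tab), c("pos", "ref", "alt"))
  if (length(ind) == 0) pg_stop("no individual genotype columns")
  if (is.null(ref_seq)) ref_seq <- strrep("A", locus_len)
  base <- strsplit(ref_seq, "")[[1]]
  haps <- list()
  for (who in ind) {
    h1 <- base; h2 <- base
    for (r in seq_len(nrow(tab))) {
      g <- tab[[who]][r]
      p <- tab$pos[r] + 1L
      if (g == "1/1") { h1[p] <- tab$alt[r]; h2[p] <- tab$alt[r] }
      else if (g %in% c("0/1", "1/0")) { h2[p] <- tab$alt[r] }
      else if (g == "./.") { h1[p] <- "N"; h2[p] <- "N" }
    }
    haps[[paste0(who, "_1")]] <- paste(h1, collapse = "")
    haps[[paste0(who, "_2")]] <- paste(h2, collapse = "")
  }
  haplotype_set(unlist(haps))
}

#' Mean conservation score over exon blocks
#'
#' Averages per-base conservation scores over the union of the supplied
#' blocks; redundant or overlapping blocks count each base once. Missing
#' bases (`NA` scores) are excluded from both numerator and denominator;
#' when no scored base remains the mean is `NA` with `defined = FALSE`.
#'
#' @param scores numeric vector of per-base scores in `[0, 1]` (`NA` for
#'   missing), indexed so that `scores[i]` is the score of 0-based position
#'   `i - 1`.
#' @param blocks two-column matrix of 0-based half-open intervals.
#' @return list with `mean`, `n_bases`, `defined`.
#' @export
mean_conservation <- function(scores, blocks) {
  if (any(blocks[, 2] > length(scores)) || any(blocks[, 1] < 0)) {
    pg_stop("blocks extend beyond the conservation track")
  }
  idx <- unique(unlist(lapply(seq_len(nrow(blocks)), function(k) {
    (blocks[k, 1] + 1L):blocks[k, 2]
  })))
  v <- scores[idx]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(list(mean = NA_real_, n_bases = 0L, defined = FALSE))
  }
  list(mean = mean(v), n_bases = length(v), defined = TRUE)
}

#' Read a bedGraph track into a per-base score vector
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open).
#' @param chrom chromosome to extract.
#' @param chrom_len chromosome length.
#' @return numeric vector of length `chrom_len` with `NA` where uncovered.
#' @export
read_bedgraph_track <- function(path, chrom, chrom_len) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("chrom", "start", "end", "score")
  tab <- tab[tab$chrom == chrom, ]
  out <- rep(NA_real_, chrom_len)
  for (r in seq_len(nrow(tab))) {
    out[(tab$start[r] + 1L):tab$end[r]] <- tab$score[r]
  }
  out
}

#' Simulate population haplotypes with a target nucleotide diversity
#'
#' Plants segregating sites on a random reference: the number of sites is
#' chosen so that the expected diversity matches `target_pi` when each
#' haplotype draws its allele independently with probability 1/2 (a site
#' with k derived alleles among n contributes 2k(n-k)/n^2 / L, whose
#' expectation is (n-1)/(2n) per site). The realized diversity of each
#' draw is recorded exactly by exhaustive pairwise computation.
#'
#' @param locus_len locus length (bp).
#' @param n_individuals number of haplotypes (>= 2).
#' @param target_pi desired expected per-site diversity.
#' @param seed integer seed.
#' @return list with `hapset` (a [haplotype_set()]) and `true_pi`.
#' @export
simulate_population_haplotypes <- function(locus_len, n_individuals,
                                           target_pi, seed = 1L) {
  if (n_individuals < 2) pg_stop("need at least 2 individuals")
  if (target_pi < 0) pg_stop("target_pi must be >= 0")
  set.seed(derive_seed(seed, "haplotypes"))
  ref <- strsplit(random_dna(locus_len), "")[[1]]
  n <- n_individuals
  per_site <- (n - 1) / (2 * n)
  S <- round(target_pi * locus_len / per_site)
  S <- min(S, locus_len)
  haps <- matrix(rep(ref, n), nrow = n, byrow = TRUE)
  if (S > 0) {
    sites <- sample.int(locus_len, S)
    for (p in sites) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1)
      carriers <- stats::runif(n) < 0.5
      haps[carriers, p] <- alt
    }
  }
  seqs <- apply(haps, 1, paste, collapse = "")
  hs <- haplotype_set(seqs, locus_id = "sim")
  # exhaustive pairwise truth (ordered pairs, uniform frequencies)
  true_pi <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      true_pi <- true_pi + 2 * (1 / n) * (1 / n) *
        sum(haps[i, ] != haps[j, ]) / locus_len
    }
  }
  list(hapset = hs, true_pi = true_pi)
}
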