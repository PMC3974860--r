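# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Tiny genome (< 10 kb) with 2 genes and 4 pseudogenes; 2,000 reads.
tiny_filter_fixture <- function() {
  memo("tiny_filter", function() {
    spec <- toy_genome_spec(n_genes = 2, exons_per_gene = 4, exon_len = 100,
                            intron_len = 150, n_processed = 2,
                            n_duplicated = 1, n_unitary = 1,
                            identity_targets = c(0.88, 0.93),
                            chrom_len = 10000, intergenic_gap = 500,
                            seed = 41)
    toy <- build_toy_genome(spec)
    expr <- c(gene01 = 600L, gene02 = 600L, pgp01 = 250L, pgp02 = 250L,
              pgd01 = 200L, pgu01 = 100L)
    sim <- simulate_rnaseq_reads(toy, expr, read_len = 50,
                                 junction_fraction = 0.2, error_rate = 0.002,
                                 seed = 42)
    list(toy = toy, sim = sim)
  })
}

# Junction-rescue fixture: 8 parent/processed-pseudogene pairs spanning
# identities 0.80..0.95, half of the parent fragments junction-spanning.
junction_fixture <- function() {
  memo("junction", function() {
    spec <- toy_genome_spec(n_genes = 8, n_processed = 8, n_duplicated = 0,
                            n_unitary = 0,
                            identity_targets = seq(0.80, 0.95, length.out = 8),
                            exons_per_gene = 4, exon_len = 200,
                            intron_len = 300, chrom_len = 160000, seed = 11)
    toy <- build_toy_genome(spec)
    ann <- toy$annotation
    genes <- ann$feature_id[ann$class == "gene"]
    pgs <- ann$feature_id[ann$class == "processed_pg"]
    expr <- stats::setNames(c(rep(800L, 8), rep(150L, 8)), c(genes, pgs))
    sim <- simulate_rnaseq_reads(toy, expr, read_len = 50,
                                 junction_fraction = 0.5, error_rate = 0,
                                 seed = 11)
    cand <- collect_candidate_reads(sim$genome_aln, ann)
    filt <- filter_pseudogene_reads(cand, sim$cdna_aln)
    kept_aln <- rewrite_alignments(sim$genome_aln, filt$decisions)
    list(toy = toy, sim = sim, cand = cand, filt = filt, kept_aln = kept_aln,
         genes = genes, pgs = pgs)
  })
}

# Pure-R brute-force oracle: minimum Hamming distance of `read` over every
# ungapped offset of `ref`, both strands. Independent of the package's
# Biostrings-based search.
oracle_min_hamming <- function(read, ref) {
  scan1 <- function(rv, refv) {
    L <- length(rv); M <- length(refv)
    if (L > M) return(Inf)
    mism <- integer(M - L + 1L)
    for (j in seq_len(L)) {
      mism <- mism + (rv[j] != refv[j:(j + M - L)])
    }
    min(mism)
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  refv <- utf8ToInt(ref)
  min(scan1(utf8ToInt(read), refv), scan1(utf8ToInt(rc(read)), refv))
}

# Independent JS-divergence evaluation (direct formula, base-2 logs).
oracle_js_score <- function(profile) {
  p <- profile / sum(profile)
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  best <- -Inf
  for (t in seq_along(p)) {
    e <- numeric(length(p)); e[t] <- 1
    m <- (p + e) / 2
    jsd <- sum(xlx(p) + xlx(e)) / 2 - sum(xlx(m))
    # rearranged: JSD = H(M) - (H(p)+H(e))/2 with H(x) = -sum x log2 x
    best <- max(best, 1 - sqrt(jsd))
  }
  best
}

# Exhaustive ordered-pair nucleotide diversity oracle (no missing data).
oracle_pi <- function(seqs, freqs = NULL) {
  n <- length(seqs)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  L <- nchar(seqs[[1]])
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sum(utf8ToInt(seqs[i]) != utf8ToInt(seqs[j])) / L
      tot <- tot + freqs[i] * freqs[j] * d
    }
  }
  tot
}

# Random single-chromosome annotation of spaced single-block features.
spaced_annotation <- function(n, len = 1000L, gap = 6000L, chrom = "chrT") {
  starts <- gap + (seq_len(n) - 1L) * (len + gap)
  pg_annotation(data.frame(
    feature_id = sprintf("pg%03d", seq_len(n)),
    chrom = chrom, start = starts, end = starts + len,
    strand = rep(c("+", "-"), length.out = n),
    class = "processed_pg",
    parent_id = "geneX",
    blocks = I(lapply(starts, function(s) matrix(c(s, s + len), ncol = 2))),
    stringsAsFactors = FALSE))
}
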