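#' Small-RNA read densities over features and their flanks
#'
#' A read counts toward a region when its 5' end (strand-aware: BED start
#' for `+` reads, end - 1 for `-` reads) lies inside it. Exonic counts are
#' taken over the feature's exon-block union; flank counts over the +/-
#' `flank` bp immediately outside the feature span, excluding any bases
#' inside the feature and truncated at chromosome ends (the density
#' denominator is the realized flank length, not the nominal one).
#'
#' @param reads BED-like data.frame (`chrom`, `start`, `end`, `strand`).
#' @param annotation a [pg_annotation()].
#' @param flank flank width in bp on each side.
#' @param chrom_lens named integer vector of chromosome lengths.
#' @return data.frame with `feature_id`, `exonic_reads`, `exonic_kb`,
#'   `exonic_density`, `flank_reads`, `flank_kb`, `flank_density`.
#' @export
srna_density <- function(reads, annotation, flank = 1000L, chrom_lens) {
  five_prime <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  tag_gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = five_prime + 1L, width = 1L))
  blocks <- block_granges(annotation)
  ex_counts <- GenomicRanges::countOverlaps(blocks, tag_gr, ignore.strand = TRUE)
  exonic_reads <- tapply(ex_counts, blocks$feature_id, sum)[annotation$feature_id]
  exonic_kb <- exon_union_length(annotation) / 1000

  fl_reads <- numeric(nrow(annotation))
  fl_kb <- numeric(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    cl <- chrom_lens[[annotation$chrom[i]]]
    if (is.null(cl) || is.na(cl)) pg_stop("missing chromosome length for %s", annotation$chrom[i])
    ls <- max(0L, annotation$start[i] - flank); le <- annotation$start[i]
    rs <- annotation$end[i]; re <- min(cl, annotation$end[i] + flank)
    p <- five_prime[reads$chrom == annotation$chrom[i]]
    fl_reads[i] <- sum(p >= ls & p < le) + sum(p >= rs & p < re)
    fl_kb[i] <- ((le - ls) + (re - rs)) / 1000
  }
  data.frame(feature_id = annotation$feature_id,
             exonic_reads = as.numeric(exonic_reads),
             exonic_kb = as.numeric(exonic_kb),
             exonic_density = as.numeric(exonic_reads) / as.numeric(exonic_kb),
             flank_reads = fl_reads,
             flank_kb = fl_kb,
             flank_density = ifelse(fl_kb > 0, fl_reads / fl_kb, NA_real_),
             stringsAsFactors = FALSE)
}

#' Upper-tail Poisson enrichment p-value
#'
#' p = P(X >= count) for X ~ Poisson(background_rate * region_kb), the
#' probability of seeing at least the observed number of reads under the
#' background rate. A count of 0 gives p = 1.
#'
#' @param count observed read count (>= 0).
#' @param region_kb region length in kb.
#' @param background_rate background reads per kb.
#' @return p-value.
#' @export
poisson_enrichment <- function(count, region_kb, background_rate) {
  if (any(count < 0)) pg_stop("count must be non-negative")
  if (any(background_rate < 0)) pg_stop("background rate must be non-negative")
  lambda <- background_rate * region_kb
  stats::ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Classify small-RNA-producing pseudogenes into groups I and II
#'
#' Features with exonic density below `exonic_min` (5 reads/kb) are not
#' sRNA candidates. Candidates with exactly zero flank reads are group I
#' (sRNA production restricted to the pseudogene body, the signature of
#' parent-interactive dsRNA processing); candidates with flank density above
#' `flank_hi` (5 reads/kb) are group II (parent-independent production
#' spreading into flanking chromatin); candidates in between stay
#' unassigned. Candidates get an upper-tail Poisson p-value for their exonic
#' count against `background_rate`.
#'
#' @param records output of [srna_density()].
#' @param exonic_min candidate threshold on exonic density (reads/kb).
#' @param flank_hi group II threshold on flank density (reads/kb).
#' @param background_rate background reads/kb for the Poisson test
#'   (typically the genome-wide density of the same library).
#' @return data.frame with `feature_id`, `call`, `poisson_p`.
#' @export
classify_srna_groups <- function(records, exonic_min = 5, flank_hi = 5,
                                 background_rate = NULL) {
  call <- rep("candidate_unassigned", nrow(records))
  call[records$exonic_density < exonic_min] <- "not_candidate"
  is_cand <- records$exonic_density >= exonic_min
  call[is_cand & records$flank_reads == 0] <- "group_I"
  call[is_cand & records$flank_density > flank_hi] <- "group_II"
  p <- rep(NA_real_, nrow(records))
  if (!is.null(background_rate)) {
    p[is_cand] <- poisson_enrichment(records$exonic_reads[is_cand],
                                     records$exonic_kb[is_cand],
                                     background_rate)
  }
  data.frame(feature_id = records$feature_id, call = call, poisson_p = p,
             stringsAsFactors = FALSE)
}

#' Compare small-RNA size distributions between groups I and II
#'
#' Medians use the lower of the two middle values for even n. The
#' distributional comparison is a two-sample Kolmogorov-Smirnov test with
#' asymptotic p; with fewer than 5 reads on either side the p-value is
#' flagged unreliable.
#'
#' @param lengths_I,lengths_II read length vectors (bp) for the two groups.
#' @return list with `median_I`, `median_II`, `delta_median`, `ks_stat`,
#'   `p`, `p_reliable`.
#' @export
srna_size_comparison <- function(lengths_I, lengths_II) {
  if (length(lengths_I) == 0 || length(lengths_II) == 0) {
    pg_stop("both groups must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(lengths_I, lengths_II, exact = FALSE))
  list(median_I = median_lower(lengths_I),
       median_II = median_lower(lengths_II),
       delta_median = median_lower(lengths_II) - median_lower(lengths_I),
       ks_stat = unname(ks$statistic),
       p = ks$p.value,
       p_reliable = length(lengths_I) >= 5 && length(lengths_II) >= 5)
}

#' Fraction of pseudogenes with reduced small-RNA counts after a treatment
#'
#' The universe is the set of pseudogenes with at least `min_reads` in the
#' control library; a pseudogene counts as reduced when its treated count is
#' strictly below its control count (ties are not reductions).
#'
#' @param counts_control,counts_kd named numeric vectors over the same
#'   pseudogene universe.
#' @param min_reads minimum control reads for inclusion.
#' @return list with `fraction`, `n`, and a per-pseudogene `table`.
#' @export
condition_reduction_fraction <- function(counts_control, counts_kd,
                                         min_reads = 1) {
  if (!setequal(names(counts_control), names(counts_kd))) {
    pg_stop("control and treated counts must cover the same pseudogenes")
  }
  u <- names(counts_control)[counts_control >= min_reads]
  if (length(u) == 0) pg_stop("no pseudogene reaches min_reads in the control")
  reduced <- counts_kd[u] < counts_control[u]
  list(fraction = mean(reduced), n = length(u),
       table = data.frame(pg_id = u,
                          control = as.numeric(counts_control[u]),
                          treated = as.numeric(counts_kd[u]),
                          reduced = as.logical(reduced),
                          stringsAsFactors = FALSE))
}

#' Simulate small-RNA reads with planted group I/II structure
#'
#' Group I pseudogenes get reads only inside their exon blocks; group II
#' additionally get reads throughout their +/- 1 kb flanks. Read counts are
#' `ceiling(density x kb)` so planted densities are guaranteed to reach the
#' requested level; read lengths are drawn from a symmetric +/- 2 bp
#' distribution centred on the group's median.
#'
#' @param annotation a [pg_annotation()].
#' @param group_labels named character vector over pseudogene ids with
#'   values in `{"I", "II", "none"}`.
#' @param exonic_density planted exonic density (reads/kb) for both groups.
#' @param flank_density planted flank density (reads/kb) for group II.
#' @param len_medians lengths (bp) for groups I and II, `c(22, 25)` by
#'   default (group II small RNAs run 2-6 bp longer).
#' @param flank flank width (bp).
#' @param chrom_lens named chromosome lengths.
#' @param seed integer seed.
#' @return list with `reads` (BED6-style data.frame) and `truth` (the
#'   planted labels).
#' @export
simulate_srna_reads <- function(annotation, group_labels,
                                exonic_density = 20, flank_density = 10,
                                len_medians = c(22L, 25L), flank = 1000L,
                                chrom_lens, seed = 1L) {
  if (exonic_density < 0 || flank_density < 0) pg_stop("densities must be >= 0")
  set.seed(derive_seed(seed, "srna_reads"))
  labelled <- names(group_labels)[group_labels != "none"]
  # flanked spans must not overlap each other or other features
  spans <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = pmax(0L, annotation$start - flank) + 1L,
      end = pmin(unname(chrom_lens[annotation$chrom]), annotation$end + flank)))
  if (any(GenomicRanges::countOverlaps(spans, spans) > 1)) {
    pg_stop("feature flanks overlap; space features by at least 2 x flank")
  }
  rl_draw <- function(n, med) {
    med + sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
                 prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  }
  rows <- list()
  for (id in labelled) {
    f <- annotation[annotation$feature_id == id, ]
    lab <- group_labels[[id]]
    med <- if (lab == "I") len_medians[1] else len_medians[2]
    b <- f$blocks[[1]]
    ex_kb <- sum(b[, 2] - b[, 1]) / 1000
    n_ex <- ceiling(exonic_density * ex_kb)
    # exonic positions: uniform over the block union
    offs <- sample.int(sum(b[, 2] - b[, 1]), n_ex, replace = TRUE) - 1L
    cum <- cumsum(c(0L, b[, 2] - b[, 1]))
    blk <- findInterval(offs, cum)
    starts <- b[blk, 1] + (offs - cum[blk])
    lens <- rl_draw(n_ex, med)
    df <- data.frame(chrom = f$chrom, start = starts, end = starts + lens,
                     name = sprintf("%s_s%04d", id, seq_len(n_ex)),
                     score = 0, strand = "+",
                     origin = id, stringsAsFactors = FALSE)
    if (lab == "II") {
      cl <- chrom_lens[[f$chrom]]
      lf <- c(max(0L, f$start - flank), f$start)
      rf <- c(f$end, min(cl, f$end + flank))
      fl_kb <- ((lf[2] - lf[1]) + (rf[2] - rf[1])) / 1000
      n_fl <- ceiling(flank_density * fl_kb)
      pool <- c(lf[1]:(lf[2] - 1L), rf[1]:(rf[2] - 1L))
      fs <- sample(pool, n_fl, replace = TRUE)
      fl_lens <- rl_draw(n_fl, med)
      df <- rbind(df, data.frame(
        chrom = f$chrom, start = fs, end = fs + fl_lens,
        name = sprintf("%s_fl%04d", id, seq_len(n_fl)),
        score = 0, strand = "+", origin = id, stringsAsFactors = FALSE))
    }
    rows[[id]] <- df
  }
  reads <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character(),
               origin = character(), stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  list(reads = reads, truth = data.frame(feature_id = names(group_labels),
                                         group = unname(group_labels),
                                         stringsAsFactors = FALSE))
}
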