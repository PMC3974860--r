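#' ChIP tag counts and normalized densities over intervals
#'
#' Counts the tags (single-base anchors, 0-based positions) falling in each
#' interval `[start, end)` and normalizes to tags per `normalize_per` bp
#' (500 bp by default): `count * normalize_per / length`.
#'
#' @param tags data.frame with `chrom` and `pos` (0-based tag anchor).
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param normalize_per normalization window (bp).
#' @return data.frame with `name`, `count`, `length`, `density`.
#' @export
window_tag_count <- function(tags, intervals, normalize_per = 500) {
  if (any(intervals$end <= intervals$start)) pg_stop("zero-length interval")
  nm <- intervals$name %||% as.character(seq_len(nrow(intervals)))
  count <- vapply(seq_len(nrow(intervals)), function(i) {
    p <- tags$pos[tags$chrom == intervals$chrom[i]]
    sum(p >= intervals$start[i] & p < intervals$end[i])
  }, numeric(1))
  len <- intervals$end - intervals$start
  data.frame(name = nm, count = count, length = len,
             density = count * normalize_per / len,
             stringsAsFactors = FALSE)
}

#' Average tag profile around anchor points
#'
#' Assigns tags to fixed-width bins by their signed offset from each anchor
#' (minus-strand anchors are mirrored so that positive offsets always point
#' downstream), then averages: per-bin total across anchors divided by the
#' number of anchors. Bins tile `[-flank, +flank)`.
#'
#' @param tags data.frame with `chrom`, `pos`.
#' @param anchors data.frame with `chrom`, `pos` (anchor position, 0-based)
#'   and `strand`.
#' @param flank half-width of the profiled region (bp).
#' @param bin bin width (bp); 100 and 500 are the conventional choices.
#' @return data.frame with `bin_start` (signed offset), `bin_end`,
#'   `mean_tags` (average tags per bin per anchor).
#' @export
anchored_profile <- function(tags, anchors, flank = 2500, bin = 500) {
  if (nrow(anchors) == 0) pg_stop("no anchors supplied")
  edges <- seq(-flank, flank, by = bin)
  nb <- length(edges) - 1L
  total <- numeric(nb)
  for (i in seq_len(nrow(anchors))) {
    p <- tags$pos[tags$chrom == anchors$chrom[i]]
    off <- p - anchors$pos[i]
    if (anchors$strand[i] == "-") off <- -off
    off <- off[off >= -flank & off < flank]
    if (length(off) > 0) {
      idx <- findInterval(off, edges)
      tab <- tabulate(idx, nbins = nb)
      total <- total + tab
    }
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             mean_tags = total / nrow(anchors))
}

#' Distinct transcription factors bound in each promoter
#'
#' The promoter is the 2 kb immediately upstream of the TSS (strand-aware:
#' `[TSS - 2000, TSS)` for plus-strand features, `[TSS, TSS + 2000)`
#' mirrored for minus-strand). A factor counts once per feature regardless
#' of how many of its peaks overlap the promoter by >= 1 bp; intervals are
#' half-open, so a peak ending exactly at the promoter start does not
#' overlap.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `factor`.
#' @param annotation a [pg_annotation()] (TSS taken from the strand-aware
#'   feature start).
#' @param upstream promoter width upstream of the TSS (bp).
#' @return data.frame with `feature_id`, `n_factors`.
#' @export
promoter_distinct_factor_count <- function(peaks, annotation,
                                           upstream = 2000L) {
  tss <- ifelse(annotation$strand == "-", annotation$end - 1L, annotation$start)
  prom_start <- ifelse(annotation$strand == "-", tss + 1L, tss - upstream)
  prom_end <- prom_start + upstream
  n <- vapply(seq_len(nrow(annotation)), function(i) {
    on_chrom <- peaks$chrom == annotation$chrom[i]
    ov <- on_chrom & peaks$start < prom_end[i] & peaks$end > prom_start[i]
    length(unique(peaks$factor[ov]))
  }, numeric(1))
  data.frame(feature_id = annotation$feature_id, n_factors = n,
             stringsAsFactors = FALSE)
}

#' Binomial test for feature overlap with target intervals
#'
#' Scores each feature (extended by `flank` on both sides) as a success when
#' it overlaps at least one target interval by >= 1 bp, and tests the number
#' of successes against Binomial(n, background_prob) with an upper-tail
#' p = P(X >= k). When no background probability is supplied, it defaults to
#' the fraction of the genome covered by the targets after extending each by
#' the mean feature length (the chance that a random feature-sized placement
#' touches a target).
#'
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param targets data.frame with `chrom`, `start`, `end`.
#' @param flank feature extension (bp).
#' @param background_prob per-feature success probability under the null;
#'   `NULL` to use the coverage default.
#' @param genome_len named chromosome lengths (needed for the default
#'   background).
#' @return list with `k` (overlap count), `n`, `background_prob`, `p`.
#' @export
interval_overlap_binomial <- function(features, targets, flank = 0,
                                      background_prob = NULL,
                                      genome_len = NULL) {
  n <- nrow(features)
  if (n == 0) pg_stop("no query features")
  f_gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start - flank + 1L,
                              end = features$end + flank))
  t_gr <- GenomicRanges::GRanges(
    seqnames = targets$chrom,
    ranges = IRanges::IRanges(start = targets$start + 1L, end = targets$end))
  k <- sum(GenomicRanges::countOverlaps(f_gr, t_gr, ignore.strand = TRUE) > 0)
  if (is.null(background_prob)) {
    if (is.null(genome_len)) pg_stop("genome_len needed for the default background")
    mean_len <- mean(features$end - features$start) + 2 * flank
    ext <- GenomicRanges::reduce(GenomicRanges::resize(
      t_gr, IRanges::width(t_gr) + mean_len, fix = "center"))
    background_prob <- min(1, sum(IRanges::width(ext)) / sum(genome_len))
  }
  if (background_prob < 0 || background_prob > 1) {
    pg_stop("background_prob must be in [0, 1]")
  }
  p <- stats::pbinom(k - 1, n, background_prob, lower.tail = FALSE)
  list(k = k, n = n, background_prob = background_prob, p = p)
}

#' Simulate ChIP tags with planted fold enrichment
#'
#' Partitions the chromosome into enrichment windows (one per feature,
#' anchored on the TSS or feature center, +/- `flank`) and background, then
#' draws Poisson tag counts per segment: `fold x background_rate x length`
#' inside a feature's window and `background_rate x length` elsewhere, with
#' uniform positions within each segment. With fold = 1 everywhere, the
#' genome-wide expectation is `background_rate x chrom_len`; fold = 0
#' silences a window entirely.
#'
#' @param annotation a [pg_annotation()].
#' @param enrichment named numeric vector of folds, indexed by feature id
#'   (missing features default to fold 1).
#' @param background_rate background tags per bp.
#' @param anchor `"tss"` or `"center"`.
#' @param flank window half-width (bp).
#' @param chrom_lens named chromosome lengths.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos` (0-based tag anchors), `origin`
#'   (`feature id` or `"background"`).
#' @export
simulate_chip_tags <- function(annotation, enrichment, background_rate,
                               anchor = c("tss", "center"), flank = 2500L,
                               chrom_lens, seed = 1L) {
  anchor <- match.arg(anchor)
  if (any(enrichment < 0)) pg_stop("folds must be >= 0")
  set.seed(derive_seed(seed, "chip_tags"))
  anchors <- feature_anchor(annotation, anchor)
  rows <- list()
  for (chrom in unique(annotation$chrom)) {
    cl <- chrom_lens[[chrom]]
    on <- annotation$chrom == chrom
    ws <- pmax(0L, anchors[on] - flank)
    we <- pmin(cl, anchors[on] + flank)
    ord <- order(ws)
    ws <- ws[ord]; we <- we[ord]
    ids <- annotation$feature_id[on][ord]
    if (any(utils::head(we, -1) > utils::tail(ws, -1))) {
      pg_stop("enrichment windows overlap; space features further apart")
    }
    folds <- ifelse(ids %in% names(enrichment), enrichment[ids], 1)
    seg_start <- c(0L, we); seg_end <- c(ws, cl)   # background segments
    draw <- function(s, e, rate, origin) {
      if (e <= s || rate <= 0) return(NULL)
      cnt <- stats::rpois(1L, rate * (e - s))
      if (cnt == 0) return(NULL)
      data.frame(chrom = chrom, pos = sort(sample(s:(e - 1L), cnt, replace = TRUE)),
                 origin = origin, stringsAsFactors = FALSE)
    }
    for (k in seq_along(seg_start)) {
      rows[[length(rows) + 1L]] <- draw(seg_start[k], seg_end[k],
                                        background_rate, "background")
    }
    for (k in seq_along(ws)) {
      rows[[length(rows) + 1L]] <- draw(ws[k], we[k],
                                        folds[k] * background_rate, ids[k])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      origin = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), ]
}

# Strand-aware TSS or center anchor positions (0-based).
feature_anchor <- function(annotation, anchor = c("tss", "center")) {
  anchor <- match.arg(anchor)
  if (anchor == "tss") {
    ifelse(annotation$strand == "-", annotation$end - 1L, annotation$start)
  } else {
    (annotation$start + annotation$end) %/% 2L
  }
}
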