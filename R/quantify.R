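#' Union-exon FPKM from filtered alignments
#'
#' Counts, per feature, the fragments whose genomic alignment overlaps the
#' feature's exon union by at least 1 bp. Each fragment is counted once: a
#' fragment overlapping several features is assigned to the one with the
#' greatest overlap (ties to the lexicographically smallest feature id).
#' FPKM = count / (exon kb x mapped fragments in millions), with the mapped
#' total taken over all fragments in the (already filtered) alignment
#' stream. This is a deterministic union-exon counting model, not an isoform
#' deconvolution.
#'
#' @param aln filtered genomic alignment records; a `fragment_id` column
#'   groups paired reads into fragments (absent: each read is a fragment).
#' @param annotation a [pg_annotation()].
#' @param tissue label for the resulting column.
#' @return data.frame with `feature_id`, `count`, `fpkm`; the total mapped
#'   fragment count is attached as attribute `total_mapped` and the tissue
#'   label as `tissue`.
#' @export
compute_fpkm <- function(aln, annotation, tissue = "sample") {
  exon_kb <- exon_union_length(annotation) / 1000
  if (any(exon_kb <= 0)) pg_stop("features with empty exon union")
  frag <- if ("fragment_id" %in% names(aln)) aln$fragment_id else aln$read_id
  total <- length(unique(frag))
  counts <- stats::setNames(numeric(nrow(annotation)), annotation$feature_id)
  if (total == 0) {
    pg_warn("no mapped fragments; FPKM column is all zero")
    out <- data.frame(feature_id = annotation$feature_id, count = 0,
                      fpkm = 0, stringsAsFactors = FALSE)
    attr(out, "total_mapped") <- 0L
    attr(out, "tissue") <- tissue
    return(out)
  }

  blocks <- block_granges(annotation)
  bt <- alignment_block_table(aln)
  read_gr <- GenomicRanges::GRanges(
    seqnames = aln$target_id[bt$record],
    ranges = IRanges::IRanges(start = bt$start + 1L, end = bt$end))
  frag_of <- frag[bt$record]

  ov <- GenomicRanges::findOverlaps(read_gr, blocks, ignore.strand = TRUE)
  if (length(ov) > 0) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(read_gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(blocks)[S4Vectors::subjectHits(ov)]))
    hits <- data.frame(fragment = frag_of[S4Vectors::queryHits(ov)],
                       feature_id = blocks$feature_id[S4Vectors::subjectHits(ov)],
                       w = w, stringsAsFactors = FALSE)
    agg <- stats::aggregate(w ~ fragment + feature_id, data = hits, FUN = sum)
    agg <- agg[order(agg$fragment, -agg$w, agg$feature_id), ]
    agg <- agg[!duplicated(agg$fragment), ]
    tab <- table(agg$feature_id)
    counts[names(tab)] <- as.numeric(tab)
  }
  out <- data.frame(feature_id = annotation$feature_id,
                    count = as.numeric(counts),
                    fpkm = as.numeric(counts) / (exon_kb * total / 1e6),
                    stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- total
  attr(out, "tissue") <- tissue
  out
}

#' Assemble FPKM columns into a features x tissues matrix
#' @param columns list of [compute_fpkm()] results (one per tissue).
#' @return numeric matrix, features x tissues.
#' @export
fpkm_matrix <- function(columns) {
  stopifnot(length(columns) > 0)
  ids <- columns[[1]]$feature_id
  mat <- vapply(columns, function(col) {
    stopifnot(identical(col$feature_id, ids))
    col$fpkm
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  rownames(mat) <- ids
  colnames(mat) <- vapply(columns, attr, character(1), "tissue")
  mat
}

#' Call transcribed features from an FPKM matrix
#'
#' A feature is called transcribed when its maximum FPKM across tissues is
#' strictly greater than the threshold (default 1 FPKM; a value of exactly
#' 1.0 is not transcribed).
#'
#' @param mat numeric FPKM matrix (features x tissues).
#' @param threshold FPKM threshold.
#' @return data.frame with `feature_id`, `max_fpkm`, `transcribed`,
#'   `max_tissue`.
#' @export
call_transcribed <- function(mat, threshold = 1.0) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  mx <- apply(mat, 1, max)
  at <- colnames(mat)[apply(mat, 1, which.max)]
  data.frame(feature_id = rownames(mat),
             max_fpkm = unname(mx),
             transcribed = unname(mx > threshold),
             max_tissue = if (is.null(at)) NA_character_ else at,
             stringsAsFactors = FALSE)
}
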