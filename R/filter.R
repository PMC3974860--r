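#' Collect reads whose genomic alignment overlaps a pseudogene
#'
#' A read is a candidate "pseudogene read" when its aligned genomic blocks
#' overlap the exon blocks of a pseudogene by at least 1 bp. Reads
#' overlapping several pseudogenes are attributed to the one with the
#' largest overlap (ties broken by lexicographically smallest feature id).
#'
#' @param genome_aln genomic alignment records (see [write_sam()] for the
#'   expected columns); one record per read.
#' @param annotation a [pg_annotation()].
#' @return data.frame with `read_id`, `pg_id`, `mm_pg`.
#' @export
collect_candidate_reads <- function(genome_aln, annotation) {
  if (anyDuplicated(genome_aln$read_id)) {
    pg_stop("multi-mapped input: genomic alignments must be pre-resolved to one location per read")
  }
  bad <- setdiff(unique(genome_aln$target_id), unique(annotation$chrom))
  if (length(bad) > 0) {
    pg_stop("alignment on unknown chromosome: %s", paste(bad, collapse = ", "))
  }
  empty <- data.frame(read_id = character(), pg_id = character(),
                      mm_pg = integer(), stringsAsFactors = FALSE)
  if (nrow(genome_aln) == 0) return(empty)

  pg <- annotation[is_pseudogene_class(annotation$class), ]
  if (nrow(pg) == 0) return(empty)
  pg_blocks <- block_granges(pg)

  # one GRanges entry per aligned block of each read
  bt <- alignment_block_table(genome_aln)
  read_gr <- GenomicRanges::GRanges(
    seqnames = genome_aln$target_id[bt$record],
    ranges = IRanges::IRanges(start = bt$start + 1L, end = bt$end))
  read_of <- bt$record

  ov <- GenomicRanges::findOverlaps(read_gr, pg_blocks, ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(read_gr)[S4Vectors::queryHits(ov)],
    IRanges::ranges(pg_blocks)[S4Vectors::subjectHits(ov)]))
  hits <- data.frame(
    read = read_of[S4Vectors::queryHits(ov)],
    pg_id = pg_blocks$feature_id[S4Vectors::subjectHits(ov)],
    w = w, stringsAsFactors = FALSE)
  # total overlap per (read, pg), then best pg per read
  agg <- stats::aggregate(w ~ read + pg_id, data = hits, FUN = sum)
  agg <- agg[order(agg$read, -agg$w, agg$pg_id), ]
  agg <- agg[!duplicated(agg$read), ]
  data.frame(read_id = genome_aln$read_id[agg$read],
             pg_id = agg$pg_id,
             mm_pg = genome_aln$mm[agg$read],
             stringsAsFactors = FALSE)
}

#' Adjudicate candidate pseudogene reads against coding cDNAs
#'
#' A candidate read is kept as a genuine pseudogene read only when its
#' mismatch count at the pseudogene locus is strictly smaller than its best
#' (minimum) mismatch count against any coding cDNA. A read with no reported
#' cDNA hit has no competitor (infinite mismatches) and is kept. Equal
#' mismatch counts are treated as ambiguous and the read is removed; the
#' strict inequality makes the call conservative at the boundary.
#'
#' @param candidates output of [collect_candidate_reads()].
#' @param cdna_aln cDNA alignment records (may contain several cDNAs per
#'   read); may be empty.
#' @return list with `kept` and `removed` (character vectors of read ids)
#'   and `decisions`, a data.frame with `read_id`, `pg_id`, `mm_pg`,
#'   `mm_cdna_best`, `kept`.
#' @export
filter_pseudogene_reads <- function(candidates, cdna_aln) {
  if (anyNA(candidates$mm_pg)) pg_stop("candidate read without mm_pg")
  best <- rep(Inf, nrow(candidates))
  if (!is.null(cdna_aln) && nrow(cdna_aln) > 0) {
    mins <- tapply(cdna_aln$mm, cdna_aln$read_id, min)
    idx <- match(candidates$read_id, names(mins))
    best[!is.na(idx)] <- mins[idx[!is.na(idx)]]
  }
  kept <- candidates$mm_pg < best
  decisions <- data.frame(read_id = candidates$read_id,
                          pg_id = candidates$pg_id,
                          mm_pg = candidates$mm_pg,
                          mm_cdna_best = best,
                          kept = kept,
                          stringsAsFactors = FALSE)
  list(kept = candidates$read_id[kept],
       removed = candidates$read_id[!kept],
       decisions = decisions)
}

#' Rewrite a genomic alignment stream after filtering
#'
#' Deletes the records of candidate pseudogene reads that did not survive
#' [filter_pseudogene_reads()]; every other record is passed through
#' unchanged and in its original order.
#'
#' @param genome_aln genomic alignment records.
#' @param decisions the `decisions` table from [filter_pseudogene_reads()].
#' @return the filtered alignment records.
#' @export
rewrite_alignments <- function(genome_aln, decisions) {
  removed <- decisions$read_id[!decisions$kept]
  genome_aln[!(genome_aln$read_id %in% removed), , drop = FALSE]
}
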