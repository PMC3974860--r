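#' Alignment record tables
#'
#' Alignments are carried as plain data.frames with one row per aligned read:
#' `read_id`, `target_id` (chromosome or cDNA id), `pos` (0-based leftmost),
#' `strand`, `mm` (mismatch count), `cigar` (match/skip runs only, e.g.
#' `"50M"` or `"20M300N30M"`), and optionally `fragment_id` and `seq`.
#' SAM is the on-disk representation; these helpers convert between the two.
#'
#' @param records alignment data.frame.
#' @param seq_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @param path output file.
#' @export
write_sam <- function(records, seq_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths), as.integer(seq_lengths)))
  if (nrow(records) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- ifelse(records$strand == "-", 16L, 0L)
  seqf <- if ("seq" %in% names(records)) records$seq else "*"
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  records$read_id, flag, records$target_id,
                  records$pos + 1L, records$cigar, seqf, records$mm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @return `read_sam()` returns an alignment record data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(data.frame(read_id = character(), target_id = character(),
                      pos = integer(), strand = character(),
                      mm = integer(), cigar = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, function(p) {
    hit <- grep("^NM:i:", p, value = TRUE)
    if (length(hit) == 0) NA_integer_ else as.integer(sub("^NM:i:", "", hit[1]))
  }, integer(1))
  data.frame(
    read_id = vapply(parts, `[[`, character(1), 1),
    target_id = vapply(parts, `[[`, character(1), 3),
    pos = as.integer(vapply(parts, `[[`, character(1), 4)) - 1L,
    strand = ifelse(bitwAnd(as.integer(vapply(parts, `[[`, character(1), 2)), 16L) > 0, "-", "+"),
    mm = nm,
    cigar = vapply(parts, `[[`, character(1), 6),
    seq = vapply(parts, `[[`, character(1), 10),
    stringsAsFactors = FALSE
  )
}

# Aligned blocks of every record as a flat table (block start/end, record
# index). Plain "<n>M" cigars are expanded vectorized; only spliced records
# go through the per-record parser.
alignment_block_table <- function(aln) {
  simple <- grepl("^[0-9]+M$", aln$cigar)
  out_start <- integer(0); out_end <- integer(0); out_rec <- integer(0)
  if (any(simple)) {
    w <- as.integer(sub("M$", "", aln$cigar[simple]))
    out_start <- aln$pos[simple]
    out_end <- aln$pos[simple] + w
    out_rec <- which(simple)
  }
  for (i in which(!simple)) {
    b <- cigar_blocks(aln$pos[i], aln$cigar[i])
    out_start <- c(out_start, b[, 1])
    out_end <- c(out_end, b[, 2])
    out_rec <- c(out_rec, rep(i, nrow(b)))
  }
  ord <- order(out_rec)
  list(start = out_start[ord], end = out_end[ord], record = out_rec[ord])
}

# Parse match (M) / skip (N) CIGAR runs into 0-based half-open genome blocks.
cigar_blocks <- function(pos, cigar) {
  ops <- gregexpr("[0-9]+[MN]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MN]", cigar))[[1]]
  lens <- as.integer(sub("[MN]$", "", toks))
  type <- sub("^[0-9]+", "", toks)
  out <- matrix(integer(0), ncol = 2)
  at <- pos
  for (i in seq_along(lens)) {
    if (type[i] == "M") out <- rbind(out, c(at, at + lens[i]))
    at <- at + lens[i]
  }
  out
}

# Aligned genomic span [start, end) of a record, including N-skips.
record_span <- function(records) {
  span <- vapply(seq_len(nrow(records)), function(i) {
    toks <- regmatches(records$cigar[i], gregexpr("[0-9]+[MN]", records$cigar[i]))[[1]]
    sum(as.integer(sub("[MN]$", "", toks)))
  }, numeric(1))
  cbind(start = records$pos, end = records$pos + span)
}

#' Write single-base tags or small-RNA reads as BED6
#' @param bed data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed6 <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  tab
}

#' Write / read an expression matrix as TSV (features x tissues)
#' @param mat numeric matrix with feature row names and tissue column names.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
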