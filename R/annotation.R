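#' Gene / pseudogene annotation container
#'
#' A light data.frame-based container for gene and pseudogene features with
#' exon block structure and parent links. All coordinates are 0-based
#' half-open (BED convention); conversion to 1-based happens only at
#' format boundaries (SAM written by the package, `GRanges` built
#' internally).
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), `class` (one of `gene`,
#'   `processed_pg`, `duplicated_pg`, `unitary_pg`, `lincRNA`), `parent_id`
#'   (`NA` unless class is `processed_pg` or `duplicated_pg`), and a list
#'   column `blocks` of two-column integer matrices (block start, block end;
#'   0-based half-open genome coordinates).
#' @return object of class `pg_annotation` (a validated data.frame).
#' @export
pg_annotation <- function(features) {
  req <- c("feature_id", "chrom", "start", "end", "strand", "class",
           "parent_id", "blocks")
  miss <- setdiff(req, names(features))
  if (length(miss) > 0) {
    pg_stop("annotation is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) {
    pg_stop("duplicate feature ids in annotation")
  }
  ok_class <- c("gene", "processed_pg", "duplicated_pg", "unitary_pg", "lincRNA")
  bad <- setdiff(unique(features$class), ok_class)
  if (length(bad) > 0) pg_stop("unknown feature class: %s", paste(bad, collapse = ", "))
  needs_parent <- features$class %in% c("processed_pg", "duplicated_pg")
  if (any(needs_parent & is.na(features$parent_id))) {
    pg_stop("processed/duplicated pseudogenes must carry parent_id")
  }
  if (any(!needs_parent & !is.na(features$parent_id))) {
    pg_stop("parent_id must be NA unless class is processed_pg or duplicated_pg")
  }
  for (i in seq_len(nrow(features))) {
    b <- features$blocks[[i]]
    if (!is.matrix(b) || ncol(b) != 2) pg_stop("blocks must be 2-column matrices")
    if (is.unsorted(b[, 1], strictly = TRUE) && nrow(b) > 1) {
      pg_stop("blocks of %s are not sorted", features$feature_id[i])
    }
    if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2])) {
      pg_stop("blocks of %s overlap", features$feature_id[i])
    }
    if (any(b[, 2] <= b[, 1])) pg_stop("empty block in %s", features$feature_id[i])
    if (b[1, 1] < features$start[i] || b[nrow(b), 2] > features$end[i]) {
      pg_stop("blocks of %s exceed [start, end)", features$feature_id[i])
    }
  }
  rownames(features) <- features$feature_id
  class(features) <- c("pg_annotation", "data.frame")
  features
}

#' Is a feature class a pseudogene class?
#' @param class character vector of feature classes.
#' @export
is_pseudogene_class <- function(class) {
  class %in% c("processed_pg", "duplicated_pg", "unitary_pg")
}

#' Exon-union length per feature (bp)
#'
#' Blocks are non-overlapping by construction, so the union length is the sum
#' of block widths.
#' @param annotation a [pg_annotation()].
#' @return named integer vector of exon-union lengths.
#' @export
exon_union_length <- function(annotation) {
  out <- vapply(annotation$blocks, function(b) sum(b[, 2] - b[, 1]), numeric(1))
  names(out) <- annotation$feature_id
  out
}

# GRanges of feature spans (1-based internally for IRanges).
feature_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    strand = annotation$strand,
    feature_id = annotation$feature_id,
    class = annotation$class
  )
}

# GRanges of all exon blocks, one range per block, with feature_id metadata.
block_granges <- function(annotation) {
  n_blk <- vapply(annotation$blocks, nrow, integer(1))
  starts <- unlist(lapply(annotation$blocks, function(b) b[, 1]))
  ends <- unlist(lapply(annotation$blocks, function(b) b[, 2]))
  GenomicRanges::GRanges(
    seqnames = rep(annotation$chrom, n_blk),
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    strand = rep(annotation$strand, n_blk),
    feature_id = rep(annotation$feature_id, n_blk),
    class = rep(annotation$class, n_blk)
  )
}

#' Extract the (sense) transcript sequence of a feature
#'
#' Concatenates the exon blocks left to right and reverse-complements when the
#' feature is on the minus strand, so the result reads 5' to 3' in the sense
#' of transcription.
#'
#' @param genome a named `DNAStringSet` (one entry per chromosome).
#' @param annotation a [pg_annotation()].
#' @param feature_id id of the feature.
#' @return character scalar, the transcript sequence.
#' @export
transcript_seq <- function(genome, annotation, feature_id) {
  f <- annotation[annotation$feature_id == feature_id, ]
  if (nrow(f) != 1) pg_stop("unknown feature: %s", feature_id)
  chrom <- as.character(Biostrings::DNAStringSet(genome)[[f$chrom]])
  b <- f$blocks[[1]]
  s <- paste(substring(chrom, b[, 1] + 1L, b[, 2]), collapse = "")
  if (f$strand == "-") s <- revcomp(s)
  s
}

# Reverse complement of a character DNA sequence.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Map transcript coordinates to genome coordinates
#'
#' Given 0-based transcript offsets (5'->3' in the sense of transcription),
#' returns the 0-based genome positions of those bases.
#'
#' @param annotation a [pg_annotation()].
#' @param feature_id feature id.
#' @param t_pos integer vector of 0-based transcript offsets.
#' @return integer vector of 0-based genome positions.
#' @export
transcript_to_genome <- function(annotation, feature_id, t_pos) {
  f <- annotation[annotation$feature_id == feature_id, ]
  if (nrow(f) != 1) pg_stop("unknown feature: %s", feature_id)
  b <- f$blocks[[1]]
  widths <- b[, 2] - b[, 1]
  L <- sum(widths)
  if (any(t_pos < 0 | t_pos >= L)) pg_stop("transcript offset out of range for %s", feature_id)
  if (f$strand == "-") t_pos <- L - 1L - t_pos
  cum <- cumsum(c(0L, widths))
  blk <- findInterval(t_pos, cum, rightmost.closed = FALSE, left.open = FALSE)
  b[blk, 1] + (t_pos - cum[blk])
}

#' Write annotation as BED12 (+ class and parent columns)
#'
#' Standard BED12 with two extra columns (13: class, 14: parent_id, `.` for
#' none). Coordinates are written as stored (0-based half-open).
#' @param annotation a [pg_annotation()].
#' @param path output file.
#' @export
write_annotation_bed <- function(annotation, path) {
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    f <- annotation[i, ]
    b <- f$blocks[[1]]
    c(f$chrom, f$start, f$end, f$feature_id, 0, f$strand, f$start, f$end,
      "0,0,0", nrow(b),
      paste0(paste(b[, 2] - b[, 1], collapse = ","), ","),
      paste0(paste(b[, 1] - f$start, collapse = ","), ","),
      f$class, ifelse(is.na(f$parent_id), ".", f$parent_id))
  })
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
}

#' Read an annotation written by [write_annotation_bed()]
#' @param path BED12(+2) file.
#' @return a [pg_annotation()].
#' @export
read_annotation_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 14) pg_stop("expected BED12 plus class and parent columns")
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    sizes <- as.integer(strsplit(tab[i, 11], ",")[[1]])
    offs <- as.integer(strsplit(tab[i, 12], ",")[[1]])
    st <- as.integer(tab[i, 2]) + offs
    cbind(st, st + sizes, deparse.level = 0)
  })
  pg_annotation(data.frame(
    feature_id = tab[[4]],
    chrom = tab[[1]],
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    strand = tab[[6]],
    class = tab[[13]],
    parent_id = ifelse(tab[[14]] == ".", NA_character_, tab[[14]]),
    blocks = I(blocks),
    stringsAsFactors = FALSE
  ))
}
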