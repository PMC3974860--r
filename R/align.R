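#' Minimum-mismatch placement of a read on a reference
#'
#' Scans every ungapped offset of `read` along `ref` on both strands and
#' returns the placement with the fewest mismatches. This is the exhaustive
#' Hamming search used to build synthetic cDNA alignments for toy fixtures;
#' it emulates an ungapped short-read aligner reporting the best hit. The
#' per-offset mismatch counting is delegated to
#' [Biostrings::neditStartingAt()].
#'
#' @param read character, the read sequence (5'->3').
#' @param ref a `DNAString` (or character) reference sequence.
#' @return list with `mm` (minimum mismatch count), `pos` (0-based offset of
#'   the best placement) and `strand`; `mm` is `Inf` when the read is longer
#'   than the reference.
#' @export
min_mismatch_placement <- function(read, ref) {
  if (!methods::is(ref, "DNAString")) ref <- Biostrings::DNAString(ref)
  L <- nchar(read)
  M <- length(ref)
  if (L > M) return(list(mm = Inf, pos = NA_integer_, strand = NA_character_))
  at <- seq_len(M - L + 1L)
  fwd <- Biostrings::neditStartingAt(Biostrings::DNAString(read), ref,
                                     starting.at = at, with.indels = FALSE)
  rev <- Biostrings::neditStartingAt(
    Biostrings::reverseComplement(Biostrings::DNAString(read)), ref,
    starting.at = at, with.indels = FALSE)
  if (min(fwd) <= min(rev)) {
    i <- which.min(fwd)
    list(mm = fwd[i], pos = at[i] - 1L, strand = "+")
  } else {
    i <- which.min(rev)
    list(mm = rev[i], pos = at[i] - 1L, strand = "-")
  }
}

#' Best hits of reads against a set of cDNA sequences
#'
#' For every read and every cDNA, finds the minimum-mismatch ungapped
#' placement (both strands, all offsets) and keeps it when the mismatch count
#' is at most `max_mismatch`. The default ceiling of 3 mismatches emulates
#' short-read aligner reporting for reads up to ~75 bp; reads whose best hit
#' on a cDNA exceeds the ceiling get no record for that cDNA.
#'
#' @param reads named character vector of read sequences (names are read ids).
#' @param cdnas named character vector or `DNAStringSet` of cDNA sequences.
#' @param max_mismatch mismatch ceiling for reporting a hit.
#' @return alignment record data.frame (`read_id`, `target_id`, `pos`,
#'   `strand`, `mm`, `cigar`).
#' @export
align_to_cdnas <- function(reads, cdnas, max_mismatch = 3L) {
  if (is.null(names(reads))) pg_stop("reads must be named by read id")
  cd <- Biostrings::DNAStringSet(cdnas)
  if (is.null(names(cd))) pg_stop("cdnas must be named")
  empty <- data.frame(read_id = character(), target_id = character(),
                      pos = integer(), strand = character(), mm = integer(),
                      cigar = character(), stringsAsFactors = FALSE)
  if (length(reads) == 0 || length(cd) == 0) return(empty)
  out <- list()
  for (L in unique(nchar(reads))) {
    grp <- reads[nchar(reads) == L]
    out[[as.character(L)]] <- align_group(grp, cd, L, max_mismatch)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(empty)
  rownames(res) <- NULL
  res[order(match(res$read_id, names(reads)), res$target_id), ]
}

# Seed-and-extend search for all hits with <= max_mismatch mismatches of
# equal-length reads on a cDNA set. Splitting each read into
# max_mismatch + 1 non-overlapping seeds guarantees (pigeonhole) that any
# qualifying ungapped placement matches at least one seed exactly; exact
# seed matches are found with matchPDict and verified with
# neditStartingAt. Falls back to the exhaustive scan for reads too short
# to carry informative seeds.
align_group <- function(reads, cd, L, max_mismatch) {
  ns <- max_mismatch + 1L
  sl <- L %/% ns
  if (sl < 8L) return(align_group_exhaustive(reads, cd, max_mismatch))
  seed_at <- (seq_len(ns) - 1L) * sl + 1L
  rs <- Biostrings::DNAStringSet(unlist(reads, use.names = FALSE))
  pdicts <- lapply(seed_at, function(s) {
    Biostrings::PDict(XVector::subseq(rs, start = s, width = sl))
  })
  rows <- list()
  for (j in seq_along(cd)) {
    M <- length(cd[[j]])
    if (L > M) next
    for (dir in c("+", "-")) {
      subject <- if (dir == "+") cd[[j]] else Biostrings::reverseComplement(cd[[j]])
      cand_read <- integer(0); cand_off <- integer(0)
      for (k in seq_along(seed_at)) {
        m <- Biostrings::matchPDict(pdicts[[k]], subject)
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0)
        for (i in hit) {
          off <- st[[i]] - seed_at[k] + 1L
          off <- off[off >= 1L & off <= M - L + 1L]
          cand_read <- c(cand_read, rep(i, length(off)))
          cand_off <- c(cand_off, off)
        }
      }
      if (length(cand_read) == 0) next
      key <- !duplicated(cand_read * (M + 1) + cand_off)
      cand_read <- cand_read[key]; cand_off <- cand_off[key]
      for (i in unique(cand_read)) {
        offs <- cand_off[cand_read == i]
        mm <- Biostrings::neditStartingAt(rs[[i]], subject, starting.at = offs,
                                          with.indels = FALSE)
        best <- which.min(mm)
        if (mm[best] <= max_mismatch) {
          pos1 <- if (dir == "+") offs[best] else M - (offs[best] + L - 1L) + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = names(reads)[i], target_id = names(cd)[j],
            pos = pos1 - 1L, strand = dir, mm = as.integer(mm[best]),
            cigar = paste0(L, "M"), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  res <- do.call(rbind, rows)
  # keep the best strand per (read, cDNA)
  res <- res[order(res$read_id, res$target_id, res$mm), ]
  res[!duplicated(res[, c("read_id", "target_id")]), ]
}

align_group_exhaustive <- function(reads, cd, max_mismatch) {
  rows <- list()
  for (j in seq_along(cd)) {
    for (i in seq_along(reads)) {
      hit <- min_mismatch_placement(reads[[i]], cd[[j]])
      if (is.finite(hit$mm) && hit$mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = names(reads)[i], target_id = names(cd)[j],
          pos = hit$pos, strand = hit$strand, mm = as.integer(hit$mm),
          cigar = paste0(nchar(reads[[i]]), "M"), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
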