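#' Simulate RNA-Seq reads with known origins over a toy genome
#'
#' Draws reads from the spliced transcripts of the requested features and
#' emulates a short-read aligner's behaviour at pseudogene loci:
#'
#' * a parent-gene read spanning an exon-exon junction cannot be placed
#'   contiguously at the parent locus, so its best genomic hit is the
#'   processed pseudogene copy (with one mismatch per diverged site in the
#'   read span);
#' * a parent-gene read carrying no informative site ties between the parent
#'   and the pseudogene copy and is placed at one of the tied loci by a
#'   seeded coin flip, mirroring random placement of multi-mapping reads;
#' * every read also gets its best hits against all coding cDNAs (exhaustive
#'   ungapped scan, mismatch ceiling `cdna_max_mismatch`), which is the
#'   competitor set the downstream filter adjudicates against.
#'
#' The returned truth table records, per read, the true origin, whether it is
#' a junction read, and the number of informative sites (positions where
#' pseudogene and parent differ) inside the read span, so rescue and leakage
#' can be scored exactly.
#'
#' @param toy result of [build_toy_genome()].
#' @param expression named integer vector mapping feature id to fragment
#'   count.
#' @param read_len read length (bp); must not exceed any expressed
#'   transcript.
#' @param junction_fraction fraction of each gene's fragments forced to span
#'   an exon-exon junction (remaining reads are contained in single exons).
#' @param error_rate per-base sequencing error probability (substitutions).
#' @param seed integer seed.
#' @param paired simulate paired-end fragments (two reads per fragment, the
#'   mate reverse-complemented from the fragment end).
#' @param fragment_len fragment length when `paired = TRUE`.
#' @param cdna_max_mismatch reporting ceiling for cDNA competitor hits.
#' @return list with `reads` (truth table), `genome_aln` (one best genomic
#'   record per read), `cdna_aln` (best hit per read per cDNA), and `cdnas`
#'   (named character vector of coding transcript sequences).
#' @export
simulate_rnaseq_reads <- function(toy, expression, read_len = 50L,
                                  junction_fraction = 0.1, error_rate = 0,
                                  seed = 1L, paired = FALSE,
                                  fragment_len = 2L * read_len,
                                  cdna_max_mismatch = 3L) {
  ann <- toy$annotation
  unknown <- setdiff(names(expression), ann$feature_id)
  if (length(unknown) > 0) {
    pg_stop("expression references unknown features: %s",
            paste(unknown, collapse = ", "))
  }
  set.seed(derive_seed(seed, "rnaseq_reads"))

  tx <- stats::setNames(
    lapply(ann$feature_id, function(id) transcript_seq(toy$genome, ann, id)),
    ann$feature_id)
  tx_len <- vapply(tx, nchar, integer(1))
  expressed <- names(expression)[expression > 0]
  if (any(read_len > tx_len[expressed])) {
    pg_stop("read_len exceeds the transcript length of an expressed feature")
  }

  # transcript-coordinate exon boundaries (cumulative block widths, in the
  # sense orientation; the toy layout is symmetric so sense offsets equal
  # genomic offsets)
  tx_bounds <- lapply(ann$feature_id, function(id) {
    b <- ann[id, "blocks"][[1]]
    cumsum(b[, 2] - b[, 1])
  })
  names(tx_bounds) <- ann$feature_id

  # transcript-coordinate diverged positions per pseudogene
  tx_mut <- lapply(ann$feature_id, function(id) {
    cls <- ann[id, "class"]
    mp <- toy$truth$mutated_positions[[id]]
    if (is.null(mp) || cls == "gene") return(integer(0))
    if (cls == "duplicated_pg") {
      b <- ann[id, "blocks"][[1]]
      offs <- cbind(b[, 1] - ann[id, "start"], b[, 2] - ann[id, "start"])
      keep <- integer(0)
      for (k in seq_len(nrow(offs))) {
        inb <- mp[mp >= offs[k, 1] & mp < offs[k, 2]]
        keep <- c(keep, (k - 1L) * (offs[1, 2] - offs[1, 1]) + (inb - offs[k, 1]))
      }
      sort(keep)
    } else {
      mp
    }
  })
  names(tx_mut) <- ann$feature_id

  children <- split(ann$feature_id[!is.na(ann$parent_id)],
                    ann$parent_id[!is.na(ann$parent_id)])

  # valid single-exon start positions for a read of length rl
  exon_starts <- function(id, rl) {
    bounds <- c(0L, tx_bounds[[id]])
    starts <- integer(0)
    for (k in seq_len(length(bounds) - 1L)) {
      if (bounds[k + 1L] - bounds[k] >= rl) {
        starts <- c(starts, bounds[k]:(bounds[k + 1L] - rl))
      }
    }
    starts
  }
  junction_starts <- function(id, rl) {
    J <- tx_bounds[[id]]
    J <- J[J < tx_len[[id]]]           # internal junctions only
    out <- list()
    for (j in J) {
      lo <- max(0L, j - rl + 1L)
      hi <- min(tx_len[[id]] - rl, j - 1L)
      if (hi >= lo) out[[length(out) + 1L]] <- lo:hi
    }
    unlist(out)
  }

  reads <- list()
  n_total <- 0L
  for (id in expressed) {
    n_frag <- as.integer(expression[[id]])
    cls <- ann[id, "class"]
    n_j <- if (cls == "gene") round(junction_fraction * n_frag) else 0L
    js <- junction_starts(id, read_len)
    if (n_j > 0 && length(js) == 0) n_j <- 0L
    es <- exon_starts(id, read_len)
    if (length(es) == 0 && n_frag > n_j) {
      pg_stop("no single-exon position fits read_len on %s", id)
    }
    starts <- c(if (n_j > 0) sample(js, n_j, replace = TRUE),
                if (n_frag - n_j > 0) sample(es, n_frag - n_j, replace = TRUE))
    is_j <- rep(c(TRUE, FALSE), c(n_j, n_frag - n_j))
    reads[[id]] <- data.frame(
      fragment_id = sprintf("%s_f%04d", id, seq_len(n_frag)),
      origin = id, t_start = starts, is_junction = is_j,
      stringsAsFactors = FALSE)
    n_total <- n_total + n_frag
  }
  frags <- do.call(rbind, reads)
  rownames(frags) <- NULL

  # expand fragments to reads (mate 2 reverse-complemented from fragment end)
  if (paired) {
    if (fragment_len < read_len) pg_stop("fragment_len must be >= read_len")
    ok <- frags$t_start + fragment_len <= tx_len[frags$origin]
    frags$t_start[!ok] <- pmax(0L, tx_len[frags$origin[!ok]] - fragment_len)
    rd <- rbind(
      transform(frags, read_id = paste0(fragment_id, "/1"), mate = 1L,
                r_start = t_start, sense = TRUE),
      transform(frags, read_id = paste0(fragment_id, "/2"), mate = 2L,
                r_start = t_start + fragment_len - read_len, sense = FALSE))
  } else {
    rd <- transform(frags, read_id = paste0(fragment_id, "/1"), mate = 1L,
                    r_start = t_start, sense = TRUE)
  }
  rd <- rd[order(rd$fragment_id, rd$mate), ]
  rownames(rd) <- NULL

  # junction flag applies to the read that actually spans a junction
  spans_junction <- function(id, s) {
    J <- tx_bounds[[id]]
    J <- J[J < tx_len[[id]]]
    any(J > s & J < s + read_len)
  }
  rd$is_junction <- vapply(seq_len(nrow(rd)),
                           function(i) spans_junction(rd$origin[i], rd$r_start[i]),
                           logical(1))

  seg <- function(id, s) substr(tx[[id]], s + 1L, s + read_len)
  bases <- c("A", "C", "G", "T")

  n <- nrow(rd)
  rd$seq_sense <- character(n)   # read in the sense orientation of origin tx
  rd$n_err <- integer(n)
  rd$placed_id <- character(n)
  rd$placed_mm <- integer(n)
  rd$n_informative <- NA_integer_
  gen_pos <- integer(n); gen_cigar <- character(n); gen_strand <- character(n)
  gen_seq <- character(n)

  chrom_seq <- as.character(toy$genome[["chrT"]])

  genome_record <- function(feat, t0) {
    g <- sort(transcript_to_genome(ann, feat, t0:(t0 + read_len - 1L)))
    brk <- which(diff(g) != 1L)
    bl_start <- g[c(1L, brk + 1L)]
    bl_end <- g[c(brk, length(g))] + 1L
    cig <- ""
    for (k in seq_along(bl_start)) {
      if (k > 1) cig <- paste0(cig, bl_start[k] - bl_end[k - 1L], "N")
      cig <- paste0(cig, bl_end[k] - bl_start[k], "M")
    }
    list(pos = bl_start[1L], cigar = cig,
         strand = ann[feat, "strand"],
         gseq = paste(substring(chrom_seq, bl_start + 1L, bl_end), collapse = ""))
  }

  for (i in seq_len(n)) {
    id <- rd$origin[i]
    cls <- ann[id, "class"]
    s <- rd$r_start[i]
    true_seg <- seg(id, s)
    # sequencing errors (substitutions)
    n_err <- stats::rbinom(1L, read_len, error_rate)
    v <- strsplit(true_seg, "")[[1]]
    if (n_err > 0) {
      at <- sample.int(read_len, n_err)
      for (p in at) v[p] <- sample(setdiff(bases, v[p]), 1L)
    }
    read_seq <- paste(v, collapse = "")
    rd$seq_sense[i] <- read_seq
    rd$n_err[i] <- n_err

    span_mut <- function(pg) sum(tx_mut[[pg]] >= s & tx_mut[[pg]] < s + read_len)

    # candidate contiguous genomic placements: feature id -> mismatches
    cand <- character(0); cand_mm <- integer(0)
    if (cls == "gene") {
      kids <- children[[id]]
      if (rd$is_junction[i]) {
        proc <- kids[ann[kids, "class"] == "processed_pg"]
        for (p in proc) {
          cand <- c(cand, p); cand_mm <- c(cand_mm, hamming(read_seq, seg(p, s)))
        }
        if (length(cand) == 0 || min(cand_mm) > cdna_max_mismatch) {
          cand <- id; cand_mm <- n_err   # spliced placement at the gene
        }
      } else {
        cand <- id; cand_mm <- n_err
        for (p in kids) {
          cand <- c(cand, p); cand_mm <- c(cand_mm, hamming(read_seq, seg(p, s)))
        }
      }
    } else {
      cand <- id; cand_mm <- n_err
      par <- ann[id, "parent_id"]
      if (!is.na(par)) {
        cand <- c(cand, par); cand_mm <- c(cand_mm, hamming(read_seq, seg(par, s)))
      }
    }
    best <- which(cand_mm == min(cand_mm))
    pick <- if (length(best) > 1) sample(best, 1L) else best
    placed <- cand[pick]
    rd$placed_id[i] <- placed
    rd$placed_mm[i] <- cand_mm[pick]

    # informative sites relative to the relevant pseudogene copy
    rel_pg <- if (is_pseudogene_class(cls)) id
              else if (is_pseudogene_class(ann[placed, "class"])) placed
              else if (length(children[[id]]) > 0) children[[id]][1L]
              else NA_character_
    if (!is.na(rel_pg) && ann[rel_pg, "class"] != "unitary_pg") {
      rd$n_informative[i] <- span_mut(rel_pg)
    }

    rec <- genome_record(placed, s)
    gen_pos[i] <- rec$pos
    gen_cigar[i] <- rec$cigar
    # orientation on the genome: feature strand xor antisense mate
    gen_strand[i] <- if (xor(rec$strand == "-", !rd$sense[i])) "-" else "+"
    gen_seq[i] <- rec$gseq
  }

  genome_aln <- data.frame(
    read_id = rd$read_id, target_id = "chrT", pos = gen_pos,
    strand = gen_strand, mm = rd$placed_mm, cigar = gen_cigar,
    seq = gen_seq, fragment_id = rd$fragment_id,
    stringsAsFactors = FALSE)

  cdnas <- unlist(tx[ann$feature_id[ann$class == "gene"]])
  cdna_aln <- align_to_cdnas(stats::setNames(rd$seq_sense, rd$read_id),
                             cdnas, max_mismatch = cdna_max_mismatch)

  list(reads = rd[, c("read_id", "fragment_id", "origin", "r_start", "mate",
                      "is_junction", "n_err", "n_informative", "placed_id",
                      "placed_mm", "seq_sense")],
       genome_aln = genome_aln,
       cdna_aln = cdna_aln,
       cdnas = cdnas)
}
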