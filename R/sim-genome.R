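#' Specification for a toy genome
#'
#' Defines the layout of a small synthetic chromosome carrying intron-bearing
#' genes and pseudogene copies at controlled sequence identity to their
#' parents. Defaults give two 4-exon genes plus one processed pseudogene per
#' gene at 90% identity, which mirrors the regime where read disambiguation
#' is hard but solvable: most annotated human pseudogenes share less than 90%
#' identity with their parents, leaving several informative sites per 50-75 bp
#' read.
#'
#' @param n_genes number of multi-exon coding genes.
#' @param exons_per_gene exons per gene.
#' @param exon_len exon length (bp).
#' @param intron_len intron length (bp).
#' @param n_processed number of processed (intronless) pseudogenes; parents
#'   are assigned round-robin over the genes.
#' @param n_duplicated number of duplicated pseudogenes (introns retained).
#' @param n_unitary number of unitary pseudogenes (no surviving parent).
#' @param identity_targets fractions in (0.5, 1]; recycled over the processed
#'   and duplicated pseudogenes in order.
#' @param chrom_len chromosome length (bp); must accommodate all features.
#' @param intergenic_gap gap between consecutive features (bp). The default
#'   of 3000 keeps the +/-1 kb flanks used by small-RNA and ChIP analyses
#'   disjoint between neighbouring features.
#' @param seed integer seed.
#' @return object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(n_genes = 2L, exons_per_gene = 4L, exon_len = 200L,
                            intron_len = 300L, n_processed = 2L,
                            n_duplicated = 1L, n_unitary = 1L,
                            identity_targets = 0.9, chrom_len = 60000L,
                            intergenic_gap = 3000L, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               exon_len = as.integer(exon_len),
               intron_len = as.integer(intron_len),
               n_processed = as.integer(n_processed),
               n_duplicated = as.integer(n_duplicated),
               n_unitary = as.integer(n_unitary),
               identity_targets = as.numeric(identity_targets),
               chrom_len = as.integer(chrom_len),
               intergenic_gap = as.integer(intergenic_gap),
               seed = as.integer(seed))
  counts <- c("n_genes", "exons_per_gene", "exon_len", "intron_len",
              "n_processed", "n_duplicated", "n_unitary", "chrom_len",
              "intergenic_gap")
  for (nm in counts) if (spec[[nm]] < 0) pg_stop("%s must be >= 0", nm)
  if ((spec$n_processed + spec$n_duplicated) > 0 && spec$n_genes == 0) {
    pg_stop("pseudogenes with parents require n_genes >= 1")
  }
  if (any(spec$identity_targets <= 0.5 | spec$identity_targets > 1)) {
    pg_stop("identity_targets must lie in (0.5, 1]")
  }
  class(spec) <- "toy_genome_spec"
  spec
}

#' Build a toy genome with genes and pseudogene copies
#'
#' Lays out genes and pseudogenes along one chromosome separated by
#' `intergenic_gap`, fills the chromosome with random sequence, then
#' overwrites each feature locus. A processed pseudogene is a single-block
#' copy of its parent's spliced transcript; a duplicated pseudogene copies
#' the parent locus including introns and mirrors the exon block structure.
#' Pseudogene copies are diverged from the parent by random substitutions
#' (no indels, so mismatch counting downstream is exact without
#' realignment): for identity target q, round((1-q) * L) positions are
#' substituted to a different base. Strands are drawn at random; all
#' sequence bookkeeping is done in the sense orientation of each feature.
#'
#' @param spec a [toy_genome_spec()].
#' @return list with `genome` (named `DNAStringSet`), `annotation`
#'   (a [pg_annotation()]), and `truth`: per-pseudogene realized identity to
#'   parent, substituted positions (0-based, in sense/transcript
#'   coordinates), and strands.
#' @export
build_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  set.seed(derive_seed(spec$seed, "toy_genome"))
  gene_len <- spec$exons_per_gene * spec$exon_len +
    max(spec$exons_per_gene - 1L, 0L) * spec$intron_len
  tx_len <- spec$exons_per_gene * spec$exon_len

  n_pg <- spec$n_processed + spec$n_duplicated
  ids <- c(sprintf("gene%02d", seq_len(spec$n_genes)),
           sprintf("pgp%02d", seq_len(spec$n_processed)),
           sprintf("pgd%02d", seq_len(spec$n_duplicated)),
           sprintf("pgu%02d", seq_len(spec$n_unitary)))
  classes <- c(rep("gene", spec$n_genes),
               rep("processed_pg", spec$n_processed),
               rep("duplicated_pg", spec$n_duplicated),
               rep("unitary_pg", spec$n_unitary))
  lens <- c(rep(gene_len, spec$n_genes),
            rep(tx_len, spec$n_processed),
            rep(gene_len, spec$n_duplicated),
            rep(tx_len, spec$n_unitary))

  gap <- spec$intergenic_gap
  starts <- gap + cumsum(c(0L, utils::head(lens, -1) + gap))
  need <- if (length(lens)) starts[length(lens)] + lens[length(lens)] + gap else 2L * gap
  if (need > spec$chrom_len) {
    pg_stop("features do not fit: chrom_len must be at least %d bp", need)
  }

  strands <- sample(c("+", "-"), length(ids), replace = TRUE)
  parents <- rep(NA_character_, length(ids))
  pg_idx <- which(classes %in% c("processed_pg", "duplicated_pg"))
  if (length(pg_idx) > 0) {
    parents[pg_idx] <- sprintf("gene%02d", ((seq_along(pg_idx) - 1L) %% spec$n_genes) + 1L)
  }
  identities <- rep(NA_real_, length(ids))
  if (length(pg_idx) > 0) {
    identities[pg_idx] <- rep_len(spec$identity_targets, length(pg_idx))
  }

  # exon block offsets relative to a gene locus start, sense-agnostic
  gene_block_offsets <- cbind(
    (seq_len(spec$exons_per_gene) - 1L) * (spec$exon_len + spec$intron_len),
    (seq_len(spec$exons_per_gene) - 1L) * (spec$exon_len + spec$intron_len) + spec$exon_len)

  blocks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    offs <- switch(classes[i],
                   gene = gene_block_offsets,
                   duplicated_pg = gene_block_offsets,
                   matrix(c(0L, lens[i]), ncol = 2))
    blocks[[i]] <- cbind(starts[i] + offs[, 1], starts[i] + offs[, 2],
                         deparse.level = 0)
  }

  annotation <- pg_annotation(data.frame(
    feature_id = ids, chrom = "chrT",
    start = starts, end = starts + lens,
    strand = strands, class = classes, parent_id = parents,
    blocks = I(blocks), stringsAsFactors = FALSE))

  chrom <- strsplit(random_dna(spec$chrom_len), "")[[1]]
  genome <- Biostrings::DNAStringSet(structure(paste(chrom, collapse = ""),
                                               names = "chrT"))

  # write a feature's sense sequence into the chromosome character vector
  put_seq <- function(chrom, start, len, strand, sense_seq) {
    s <- if (strand == "-") revcomp(sense_seq) else sense_seq
    chrom[(start + 1):(start + len)] <- strsplit(s, "")[[1]]
    chrom
  }

  # genes keep whatever random sequence they landed on; record transcripts
  gene_locus_seq <- list()   # sense-oriented full locus sequence per gene
  for (i in which(classes == "gene")) {
    seg <- paste(chrom[(starts[i] + 1):(starts[i] + lens[i])], collapse = "")
    gene_locus_seq[[ids[i]]] <- if (strands[i] == "-") revcomp(seg) else seg
  }
  splice <- function(locus_seq) {
    # sense-locus coordinates of exons: for either strand the exon offsets in
    # sense coordinates are the mirror of the genomic offsets when strand is
    # "-", but the gene layout is symmetric (equal exons and introns), so the
    # sense offsets coincide with the genomic offsets.
    paste(substring(locus_seq, gene_block_offsets[, 1] + 1, gene_block_offsets[, 2]),
          collapse = "")
  }

  mutate_seq <- function(s, q) {
    L <- nchar(s)
    n_mut <- round((1 - q) * L)
    pos <- sort(sample.int(L, n_mut))
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    list(seq = paste(v, collapse = ""), pos = pos - 1L)
  }

  truth <- data.frame(feature_id = ids, class = classes, strand = strands,
                      parent_id = parents, target_identity = identities,
                      realized_identity = NA_real_, stringsAsFactors = FALSE)
  mut_pos <- stats::setNames(vector("list", length(ids)), ids)

  for (i in seq_along(ids)) {
    cls <- classes[i]
    if (cls == "gene") next
    if (cls == "unitary_pg") {
      mut_pos[[ids[i]]] <- integer(0)
      next  # keeps its random sequence; no parent to diverge from
    }
    parent <- parents[i]
    template <- if (cls == "processed_pg") {
      splice(gene_locus_seq[[parent]])
    } else {
      gene_locus_seq[[parent]]
    }
    m <- mutate_seq(template, identities[i])
    chrom <- put_seq(chrom, starts[i], lens[i], strands[i], m$seq)
    mut_pos[[ids[i]]] <- m$pos
    truth$realized_identity[i] <- 1 - length(m$pos) / nchar(template)
  }

  genome <- Biostrings::DNAStringSet(structure(paste(chrom, collapse = ""),
                                               names = "chrT"))
  list(genome = genome,
       annotation = annotation,
       truth = list(features = truth, mutated_positions = mut_pos,
                    spec = spec))
}
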