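#' Spearman rank correlation (average ranks for ties)
#'
#' Computed from the definition: Pearson correlation of the average-rank
#' transformed vectors, which handles ties exactly. The p-value is two-sided:
#' an exact permutation p over all n! rank permutations when n <= 8, and the
#' t-distribution approximation (t = rho * sqrt((n-2)/(1-rho^2)), n - 2 df)
#' otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) pg_stop("need two vectors of equal length >= 3")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  if (!is.finite(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n <= 8) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(pr) {
      stats::cov(rx, ry[pr]) / (stats::sd(rx) * stats::sd(ry))
    })
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- sub + (sub >= k)
  }
  out
}

#' Pseudogene-parent expression correlation over tissues
#'
#' Spearman correlation of the tissue FPKM profiles for each
#' pseudogene-parent pair. Pairs whose parent has 0 FPKM in every tissue are
#' excluded. By default the cohort is additionally restricted to pairs whose
#' parent has a Jensen-Shannon specificity score above `parent_js_min`
#' (0.1), which removes pseudogenes of broadly expressed (housekeeping-like)
#' parents; set `parent_js_min = NULL` to disable.
#'
#' @param pg_mat,parent_mat FPKM matrices sharing tissue columns.
#' @param pairs data.frame with `pg_id` and `parent_id`.
#' @param parent_js_min minimum parent JS score, or `NULL` to keep all.
#' @return data.frame with `pg_id`, `parent_id`, `rho`, `p`, `excluded`,
#'   `reason`.
#' @export
pg_parent_spearman <- function(pg_mat, parent_mat, pairs,
                               parent_js_min = 0.1) {
  shared <- intersect(colnames(pg_mat), colnames(parent_mat))
  if (length(shared) < 3) pg_stop("fewer than 3 shared tissue columns")
  pg_mat <- pg_mat[, shared, drop = FALSE]
  parent_mat <- parent_mat[, shared, drop = FALSE]
  out <- data.frame(pg_id = pairs$pg_id, parent_id = pairs$parent_id,
                    rho = NA_real_, p = NA_real_, excluded = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    pv <- parent_mat[pairs$parent_id[i], ]
    if (all(pv == 0)) {
      out$excluded[i] <- TRUE; out$reason[i] <- "parent_all_zero"
      next
    }
    if (!is.null(parent_js_min) &&
        js_specificity(pv)$score <= parent_js_min) {
      out$excluded[i] <- TRUE; out$reason[i] <- "parent_js_low"
      next
    }
    r <- spearman_rho(pg_mat[pairs$pg_id[i], ], pv)
    out$rho[i] <- r$rho; out$p[i] <- r$p
  }
  out
}

#' Label pseudogenes by distance to the nearest coding gene
#'
#' Distance is the minimum gap in bp to any coding gene span (0 when
#' overlapping or adjacent). Pseudogenes within `cutoff` (inclusive; a gap of
#' exactly 20 kb is t1) are labelled `t1`, the rest `t2`.
#'
#' @param annotation a [pg_annotation()] holding both pseudogenes and genes.
#' @param cutoff distance cutoff in bp.
#' @return data.frame with `pg_id`, `distance`, `group`.
#' @export
distance_groups <- function(annotation, cutoff = 20000) {
  pg <- annotation[is_pseudogene_class(annotation$class), ]
  genes <- annotation[annotation$class == "gene", ]
  if (nrow(genes) == 0) pg_stop("no coding genes in annotation")
  pg_gr <- feature_granges(pg)
  gene_gr <- feature_granges(genes)
  d <- GenomicRanges::distanceToNearest(pg_gr, gene_gr, ignore.strand = TRUE)
  dist <- rep(NA_real_, nrow(pg))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  data.frame(pg_id = pg$feature_id, distance = dist,
             group = ifelse(dist <= cutoff, "t1", "t2"),
             stringsAsFactors = FALSE)
}

#' Parent expression in high- vs low-pseudogene tissue halves
#'
#' Sorts the tissues by the pseudogene's FPKM (descending; ties broken by
#' tissue name order) and splits them into equal halves. Reports the
#' parent's mean and unbiased (n-1) variance in each half, and their
#' differences (high minus low).
#'
#' @param pg_profile,parent_profile named FPKM vectors over the same
#'   tissues; the tissue count must be even (16 in the standard design).
#' @return list with `mu_h`, `mu_l`, `s_h`, `s_l`, `delta_mu`, `delta_s`,
#'   `high_tissues`.
#' @export
tissue_split_mean_variance <- function(pg_profile, parent_profile) {
  n <- length(pg_profile)
  if (n %% 2 != 0) pg_stop("tissue count must be even to split in halves")
  if (length(parent_profile) != n) pg_stop("profiles differ in length")
  nm <- names(pg_profile) %||% as.character(seq_len(n))
  ord <- order(-pg_profile, nm)
  hi <- ord[seq_len(n / 2)]
  lo <- ord[(n / 2 + 1):n]
  list(mu_h = mean(parent_profile[hi]), mu_l = mean(parent_profile[lo]),
       s_h = stats::var(parent_profile[hi]), s_l = stats::var(parent_profile[lo]),
       delta_mu = mean(parent_profile[hi]) - mean(parent_profile[lo]),
       delta_s = stats::var(parent_profile[hi]) - stats::var(parent_profile[lo]),
       high_tissues = nm[hi])
}

#' Infer the transcribed strand from sense/antisense expression
#'
#' A pseudogene is called sense (antisense) transcribed when the expression
#' value on the annotated (opposite) strand is at least `ratio` times (10x)
#' the other strand's value; a lesser strand at or below `min_expr` counts
#' as zero, so any expression on the other strand wins. Values without a
#' 10-fold distinction are called `both`; two values at or below `min_expr`
#' give `no_call`.
#'
#' @param sense_value,antisense_value non-negative expression values
#'   (vectorized).
#' @param ratio dominance ratio.
#' @param min_expr expression floor below which a value is treated as zero
#'   (default 0; 0.05 reduces strand-call error on real data).
#' @return character vector in `{"sense", "antisense", "both", "no_call"}`.
#' @export
infer_strand <- function(sense_value, antisense_value, ratio = 10,
                         min_expr = 0) {
  if (any(sense_value < 0) || any(antisense_value < 0)) {
    pg_stop("expression values must be non-negative")
  }
  s <- ifelse(sense_value <= min_expr, 0, sense_value)
  a <- ifelse(antisense_value <= min_expr, 0, antisense_value)
  out <- rep("both", length(s))
  out[s == 0 & a == 0] <- "no_call"
  out[s > 0 & a == 0] <- "sense"
  out[a > 0 & s == 0] <- "antisense"
  two <- s > 0 & a > 0
  out[two & s / a >= ratio] <- "sense"
  out[two & a / s >= ratio] <- "antisense"
  out
}

#' Bin pseudogene-parent correlations by miRNA-gene correlation
#'
#' Bins the (rho_pg:g, rho_miRNA:g) triples on rho_miRNA:g over [-1, 1]
#' (half-open bins of width `bin_width`, the last bin closed), reporting
#' per-bin mean and unbiased sd of rho_pg:g, plus the overall Pearson
#' correlation over the raw triples.
#'
#' @param rho_pg_g,rho_mirna_g numeric vectors of equal length.
#' @param bin_width bin width on rho_miRNA:g.
#' @return list with `bins` (data.frame `lo`, `hi`, `n`, `mean`, `sd`),
#'   `r`, `p`.
#' @export
mirna_binned_correlation <- function(rho_pg_g, rho_mirna_g, bin_width = 0.1) {
  if (length(rho_pg_g) == 0) pg_stop("no correlation triples supplied")
  stopifnot(length(rho_pg_g) == length(rho_mirna_g))
  edges <- seq(-1, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  idx <- findInterval(rho_mirna_g, edges, rightmost.closed = TRUE)
  bins <- data.frame(lo = edges[-length(edges)], hi = edges[-1])
  bins$n <- vapply(seq_len(nrow(bins)), function(b) sum(idx == b), numeric(1))
  bins$mean <- vapply(seq_len(nrow(bins)), function(b) {
    if (bins$n[b] > 0) mean(rho_pg_g[idx == b]) else NA_real_
  }, numeric(1))
  bins$sd <- vapply(seq_len(nrow(bins)), function(b) {
    if (bins$n[b] > 1) stats::sd(rho_pg_g[idx == b]) else NA_real_
  }, numeric(1))
  ct <- stats::cor.test(rho_mirna_g, rho_pg_g, method = "pearson")
  list(bins = bins, r = unname(ct$estimate), p = ct$p.value)
}

#' Compare fold-change distributions after miRNA knockdown
#'
#' Restricts to genes up-regulated more than `threshold`-fold and compares
#' the fold-change distributions of the gene classes (e.g. parents targeted
#' by the knocked-down miRNAs, other parents, targeted coding genes without
#' a pseudogene) with pairwise two-sided Wilcoxon rank-sum tests.
#'
#' @param fold_changes named numeric vector of knockdown/control fold
#'   changes (> 0).
#' @param classes named character vector assigning each gene to a class.
#' @param threshold fold-change threshold (exclusive).
#' @return list with `summary` (per-class n and median) and `tests`
#'   (pairwise data.frame `class_a`, `class_b`, `p`; `NA` when a class is
#'   empty after filtering).
#' @export
kd_upregulation_comparison <- function(fold_changes, classes,
                                       threshold = 1.3) {
  if (any(fold_changes <= 0)) pg_stop("fold changes must be positive")
  stopifnot(!is.null(names(fold_changes)),
            all(names(fold_changes) %in% names(classes)))
  keep <- fold_changes > threshold
  fc <- fold_changes[keep]
  cl <- classes[names(fc)]
  lev <- unique(classes[names(fold_changes)])
  summary <- data.frame(
    class = lev,
    n = vapply(lev, function(l) sum(cl == l), numeric(1)),
    median_fold = vapply(lev, function(l) {
      if (any(cl == l)) stats::median(fc[cl == l]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  combs <- utils::combn(lev, 2)
  tests <- data.frame(class_a = combs[1, ], class_b = combs[2, ],
                      p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    xa <- fc[cl == combs[1, k]]; xb <- fc[cl == combs[2, k]]
    if (length(xa) > 0 && length(xb) > 0) {
      tests$p[k] <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                                       exact = NULL)$p.value
    }
  }
  list(summary = summary, tests = tests)
}
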