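#' Identity-window diagnostic: read counts vs local sequence identity
#'
#' Tiles the pseudogene-parent alignment with fixed windows (default 200
#' alignment columns), and in each window computes (i) percent identity over
#' the aligned (non-gap in both sequences) columns and (ii) the number of
#' reads whose 5' start falls inside the window, in pseudogene coordinates.
#' Residual parent-derived signal shows up as a positive Pearson correlation
#' between window identity and read count; successful filtering abolishes
#' it. Windows with zero aligned columns are skipped. With fewer than three
#' usable windows, or zero variance in either coordinate, the correlation is
#' reported as undefined (`NA` with `r_defined = FALSE`), never silently as
#' zero.
#'
#' @param alignments either a list with elements `pg` and `parent` (aligned
#'   sequences of equal length, `-` for gaps), or a list of such pairs (one
#'   per pseudogene) to pool windows across loci.
#' @param read_starts 0-based read start positions in pseudogene-local
#'   (ungapped) coordinates; a list parallel to `alignments` when pooling.
#' @param window window width in alignment columns.
#' @return list of class `identity_window_report` with `windows` (data.frame
#'   `locus`, `win_start`, `identity`, `reads`, `aligned_cols`), `r`, `p`,
#'   `n_windows`, `r_defined`.
#' @export
identity_read_correlation <- function(alignments, read_starts, window = 200L) {
  single <- !is.null(alignments$pg) && is.character(alignments$pg)
  if (single) {
    alignments <- list(alignments)
    read_starts <- list(read_starts)
  }
  stopifnot(length(alignments) == length(read_starts))
  win_tabs <- lapply(seq_along(alignments), function(i) {
    w <- identity_windows(alignments[[i]]$pg, alignments[[i]]$parent,
                          read_starts[[i]], window)
    if (nrow(w) > 0) w$locus <- i
    w
  })
  windows <- do.call(rbind, win_tabs)
  usable <- windows[windows$aligned_cols > 0, , drop = FALSE]
  r <- NA_real_; p <- NA_real_; defined <- FALSE
  if (nrow(usable) >= 3 &&
      stats::sd(usable$identity) > 0 && stats::sd(usable$reads) > 0) {
    r <- stats::cor(usable$identity, usable$reads)
    # t-transform of r with n - 2 degrees of freedom, two-sided
    n <- nrow(usable)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    defined <- TRUE
  }
  structure(list(windows = windows, r = r, p = p,
                 n_windows = nrow(usable), r_defined = defined),
            class = "identity_window_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Window table for one pseudogene-parent alignment.
identity_windows <- function(pg_aln, parent_aln, read_starts, window = 200L) {
  if (nchar(pg_aln) != nchar(parent_aln)) {
    pg_stop("aligned sequences must have equal length")
  }
  a <- strsplit(pg_aln, "")[[1]]
  b <- strsplit(parent_aln, "")[[1]]
  ncols <- length(a)
  # map each pseudogene (ungapped) position to its alignment column
  pg_col <- which(a != "-")
  # read starts in pg coordinates -> alignment columns
  if (length(read_starts) > 0 &&
      (min(read_starts) < 0 || max(read_starts) >= length(pg_col))) {
    pg_stop("read start outside the pseudogene coordinate range")
  }
  read_cols <- pg_col[read_starts + 1L]
  win_start <- seq(1L, ncols, by = window)
  out <- lapply(win_start, function(ws) {
    we <- min(ws + window - 1L, ncols)
    idx <- ws:we
    aligned <- a[idx] != "-" & b[idx] != "-"
    n_aligned <- sum(aligned)
    ident <- if (n_aligned > 0) {
      100 * sum(a[idx][aligned] == b[idx][aligned]) / n_aligned
    } else NA_real_
    data.frame(win_start = ws - 1L,
               identity = ident,
               reads = sum(read_cols >= ws & read_cols <= we),
               aligned_cols = n_aligned)
  })
  do.call(rbind, out)
}
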