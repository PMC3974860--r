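#' Simulate pseudogene/parent expression matrices with planted structure
#'
#' Two planting modes:
#'
#' * **Correlation mode** (default): each pair's tissue profiles are drawn
#'   from a Gaussian copula whose latent Pearson correlation is
#'   `2 sin(pi rho / 6)`, the value that makes the population Spearman
#'   correlation equal the planted `rho`; marginals are log-normal (FPKM
#'   scale), a monotone transform that preserves ranks. `noise_sd` adds
#'   independent latent jitter, attenuating the realized correlation by
#'   1/(1 + noise_sd^2); the default of 0 recovers the planted value
#'   without bias.
#' * **Specificity mode** (`planted_js` given): pseudogene profiles are
#'   deterministic mixtures `w x one-hot + (1 - w) x uniform`, with `w`
#'   solved so the Jensen-Shannon specificity score equals the planted
#'   value (a one-hot profile for score 1); parents are drawn independently.
#'   Planted correlations are ignored in this mode.
#'
#' @param n_pairs number of pseudogene-parent pairs.
#' @param n_tissues number of tissues (16 in the standard design).
#' @param planted_rho Spearman correlations, recycled over pairs.
#' @param planted_js JS specificity targets, or `NULL` for correlation mode.
#' @param noise_sd latent noise standard deviation.
#' @param seed integer seed.
#' @return list with `pg` and `parent` (FPKM matrices, features x tissues)
#'   and `truth` (planted values per pair).
#' @export
simulate_expression_profiles <- function(n_pairs, n_tissues = 16L,
                                         planted_rho = 0.4,
                                         planted_js = NULL, noise_sd = 0,
                                         seed = 1L) {
  if (any(abs(planted_rho) > 1)) pg_stop("|planted_rho| must be <= 1")
  set.seed(derive_seed(seed, "expression_profiles"))
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  pg_ids <- sprintf("pg%04d", seq_len(n_pairs))
  parent_ids <- sprintf("gene%04d", seq_len(n_pairs))
  pg <- matrix(0, n_pairs, n_tissues, dimnames = list(pg_ids, tissues))
  parent <- matrix(0, n_pairs, n_tissues, dimnames = list(parent_ids, tissues))

  to_fpkm <- function(z, meanlog, sdlog = 1.2) exp(meanlog + sdlog * z)

  if (is.null(planted_js)) {
    rho <- rep_len(planted_rho, n_pairs)
    r_lat <- 2 * sin(pi * rho / 6)
    for (i in seq_len(n_pairs)) {
      z1 <- stats::rnorm(n_tissues)
      z2 <- r_lat[i] * z1 + sqrt(1 - r_lat[i]^2) * stats::rnorm(n_tissues)
      if (noise_sd > 0) {
        z1 <- z1 + noise_sd * stats::rnorm(n_tissues)
        z2 <- z2 + noise_sd * stats::rnorm(n_tissues)
      }
      pg[i, ] <- to_fpkm(z1, meanlog = log(2))
      parent[i, ] <- to_fpkm(z2, meanlog = log(20))
    }
    truth <- data.frame(pg_id = pg_ids, parent_id = parent_ids,
                        planted_rho = rho, planted_js = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    js <- rep_len(planted_js, n_pairs)
    uniform_score <- 1 - sqrt(js_divergence(rep(1 / n_tissues, n_tissues),
                                            c(1, rep(0, n_tissues - 1L))))
    if (any(js < uniform_score - 1e-9 | js > 1)) {
      pg_stop("planted_js must lie in [%.4f, 1] for %d tissues",
              uniform_score, n_tissues)
    }
    for (i in seq_len(n_pairs)) {
      hot <- sample.int(n_tissues, 1L)
      w <- solve_onehot_weight(js[i], n_tissues)
      prof <- rep((1 - w) / n_tissues, n_tissues)
      prof[hot] <- prof[hot] + w
      pg[i, ] <- prof * stats::rlnorm(1, log(20), 0.5)
      parent[i, ] <- to_fpkm(stats::rnorm(n_tissues), meanlog = log(20))
    }
    truth <- data.frame(pg_id = pg_ids, parent_id = parent_ids,
                        planted_rho = NA_real_, planted_js = js,
                        stringsAsFactors = FALSE)
  }
  list(pg = pg, parent = parent, truth = truth)
}

# Mixture weight w so that w*onehot + (1-w)*uniform has JS score `target`.
solve_onehot_weight <- function(target, n_tissues) {
  score_of <- function(w) {
    p <- rep((1 - w) / n_tissues, n_tissues)
    p[1] <- p[1] + w
    e <- c(1, rep(0, n_tissues - 1L))
    1 - sqrt(js_divergence(p, e))
  }
  if (target >= 1) return(1)
  stats::uniroot(function(w) score_of(w) - target, c(0, 1),
                 tol = 1e-10)$root
}
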