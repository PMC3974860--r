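#' Pipeline configuration
#'
#' Collects every analysis threshold in one validated object. Defaults are
#' the standard operating points of the analysis: transcribed call at
#' maximal FPKM > 1 (highly transcribed > 10), correlation cohort restricted
#' to parents with JS score > 0.1, nearest-gene distance cutoff 20 kb,
#' small-RNA candidate threshold 5 reads/kb with group II flank threshold
#' 5 reads/kb, 10x strand dominance ratio, and 1.3-fold knockdown response
#' threshold.
#'
#' @param ... overrides for the fields below; unknown keys are rejected.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fpkm_transcribed = 1.0,
    fpkm_high = 10.0,
    parent_js_min = 0.1,
    distance_cutoff = 20000,
    srna_exonic_min = 5,
    srna_flank_hi = 5,
    strand_ratio = 10,
    kd_fold = 1.3,
    read_len = 50L,
    junction_fraction = 0.15,
    error_rate = 0,
    n_pairs = 100L,
    n_tissues = 16L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    pg_stop("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  thresholds <- c("fpkm_transcribed", "fpkm_high", "parent_js_min",
                  "distance_cutoff", "srna_exonic_min", "srna_flank_hi",
                  "strand_ratio", "kd_fold")
  for (nm in thresholds) if (cfg[[nm]] <= 0) pg_stop("%s must be positive", nm)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a toy genome plus all downstream data types and pushes them
#' through every analysis stage in dependency order: read filtering,
#' quantification and transcribed calls, the identity-window diagnostic,
#' tissue-specificity and correlation statistics, strand inference,
#' small-RNA classification, ChIP densities and profiles, and
#' diversity/conservation summaries. All report tables are written as TSV
#' under `outdir` together with a JSON manifest carrying the seed,
#' configuration hash and package version, which is sufficient to reproduce
#' the run byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- stage: simulate genome and RNA-Seq; filter; quantify -------------
  spec <- toy_genome_spec(n_genes = 2, n_processed = 2, n_duplicated = 1,
                          n_unitary = 1, identity_targets = c(0.9, 0.85),
                          seed = seed)
  toy <- build_toy_genome(spec)
  ann <- toy$annotation
  genes <- ann$feature_id[ann$class == "gene"]
  pgs <- ann$feature_id[is_pseudogene_class(ann$class)]
  expr <- stats::setNames(c(rep(600L, length(genes)), rep(150L, length(pgs))),
                          c(genes, pgs))
  sim <- simulate_rnaseq_reads(toy, expr, read_len = config$read_len,
                               junction_fraction = config$junction_fraction,
                               error_rate = config$error_rate, seed = seed)
  cand <- collect_candidate_reads(sim$genome_aln, ann)
  filt <- filter_pseudogene_reads(cand, sim$cdna_aln)
  kept_aln <- rewrite_alignments(sim$genome_aln, filt$decisions)
  fpkm_col <- compute_fpkm(kept_aln, ann, tissue = "sim")
  tsv(filt$decisions, "filter_decisions.tsv")
  tsv(fpkm_col, "fpkm.tsv")

  # identity-window diagnostic, pre vs post filter
  qc <- identity_qc_from_sim(toy, sim, kept_aln)
  tsv(qc$windows, "identity_windows.tsv")

  # --- stage: 16-tissue expression statistics ---------------------------
  prof <- simulate_expression_profiles(config$n_pairs,
                                       n_tissues = config$n_tissues,
                                       planted_rho = c(0.8, 0.4, 0, -0.4),
                                       seed = seed)
  calls <- call_transcribed(prof$pg, threshold = config$fpkm_transcribed)
  tsv(calls, "transcribed_calls.tsv")
  js <- js_specificity(prof$pg)
  tsv(js, "js_scores.tsv")
  pairs <- prof$truth[, c("pg_id", "parent_id")]
  cors <- pg_parent_spearman(prof$pg, prof$parent, pairs,
                             parent_js_min = config$parent_js_min)
  tsv(cors, "correlations.tsv")
  dg <- distance_groups(ann, cutoff = config$distance_cutoff)
  tsv(dg, "distance_groups.tsv")
  splits <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    s <- tissue_split_mean_variance(prof$pg[i, ], prof$parent[i, ])
    data.frame(pg_id = pairs$pg_id[i], mu_h = s$mu_h, mu_l = s$mu_l,
               s_h = s$s_h, s_l = s$s_l, delta_mu = s$delta_mu,
               delta_s = s$delta_s, stringsAsFactors = FALSE)
  }))
  tsv(splits, "tissue_split.tsv")

  # planted strand-specific expression and strand calls
  set.seed(derive_seed(seed, "strand_truth"))
  planted_strand <- sample(c("sense", "antisense", "both"),
                           length(pgs), replace = TRUE,
                           prob = c(0.6, 0.25, 0.15))
  hi <- stats::rlnorm(length(pgs), log(5), 0.3)
  lo <- hi / ifelse(planted_strand == "both", 2, 40)
  sense_v <- ifelse(planted_strand == "antisense", lo, hi)
  anti_v <- ifelse(planted_strand == "antisense", hi, lo)
  strand_calls <- data.frame(
    pg_id = pgs, planted = planted_strand,
    call = infer_strand(sense_v, anti_v, ratio = config$strand_ratio),
    stringsAsFactors = FALSE)
  tsv(strand_calls, "strand_calls.tsv")

  # --- stage: small RNA -------------------------------------------------
  chrom_lens <- stats::setNames(spec$chrom_len, "chrT")
  labels <- stats::setNames(rep("none", nrow(ann)), ann$feature_id)
  labels[pgs[1]] <- "I"
  labels[pgs[2]] <- "II"
  srna <- simulate_srna_reads(ann, labels, exonic_density = 20,
                              flank_density = 12, chrom_lens = chrom_lens,
                              seed = seed)
  dens <- srna_density(srna$reads, ann, chrom_lens = chrom_lens)
  srna_calls <- classify_srna_groups(dens, exonic_min = config$srna_exonic_min,
                                     flank_hi = config$srna_flank_hi,
                                     background_rate = 0.5)
  tsv(dens, "srna_density.tsv")
  tsv(srna_calls, "srna_calls.tsv")

  # --- stage: chromatin -------------------------------------------------
  transcribed_pg <- pgs[seq_len(ceiling(length(pgs) / 2))]
  folds <- stats::setNames(rep(1, nrow(ann)), ann$feature_id)
  folds[transcribed_pg] <- 5
  tags <- simulate_chip_tags(ann, folds, background_rate = 0.02, flank = 1500L,
                             chrom_lens = chrom_lens, seed = seed)
  tss <- feature_anchor(ann, "tss")
  wins <- data.frame(chrom = ann$chrom,
                     start = pmax(0L, tss - 1500L),
                     end = pmin(chrom_lens[ann$chrom], tss + 1500L),
                     name = ann$feature_id)
  chip_counts <- window_tag_count(tags, wins)
  profile <- anchored_profile(tags, data.frame(chrom = ann$chrom, pos = tss,
                                               strand = ann$strand),
                              flank = 1500, bin = 500)
  tsv(chip_counts, "chip_counts.tsv")
  tsv(profile, "chip_profile.tsv")
  tfc <- promoter_distinct_factor_count(
    data.frame(chrom = character(), start = integer(), end = integer(),
               factor = character()), ann)
  tsv(tfc, "tf_counts.tsv")

  # --- stage: evolution -------------------------------------------------
  hap <- simulate_population_haplotypes(1000L, 20L, target_pi = 0.002,
                                        seed = seed)
  div <- nucleotide_diversity(hap$hapset)
  set.seed(derive_seed(seed, "conservation_track"))
  track <- stats::rbeta(spec$chrom_len, 1, 4)
  cons <- vapply(pgs, function(id) {
    mean_conservation(track, ann[id, "blocks"][[1]])$mean
  }, numeric(1))
  tsv(data.frame(locus = div$locus_id, pi = div$pi, true_pi = hap$true_pi),
      "diversity.tsv")
  tsv(data.frame(pg_id = pgs, mean_phastcons = unname(cons)),
      "conservation.tsv")

  manifest <- list(
    package = "pseudoshadow",
    version = as.character(utils::packageVersion("pseudoshadow")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(list(unclass(config), seed))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(toy = toy, sim = sim, filter = filt, fpkm = fpkm_col,
                 identity_qc = qc, profiles = prof, correlations = cors,
                 splits = splits, strand_calls = strand_calls,
                 srna_density = dens, srna_calls = srna_calls,
                 chip_counts = chip_counts, chip_profile = profile,
                 diversity = div, manifest = manifest))
}

# Identity-window report for a simulated run: pools windows across the
# processed pseudogenes, pre- and post-filter.
identity_qc_from_sim <- function(toy, sim, kept_aln) {
  ann <- toy$annotation
  proc <- ann$feature_id[ann$class == "processed_pg"]
  aln_pairs <- lapply(proc, function(id) {
    list(pg = transcript_seq(toy$genome, ann, id),
         parent = transcript_seq(toy$genome, ann, ann[id, "parent_id"]))
  })
  starts_of <- function(aln_df) {
    lapply(proc, function(id) {
      f <- ann[id, ]
      on <- aln_df$target_id == f$chrom &
        aln_df$pos >= f$start & aln_df$pos < f$end
      g <- aln_df$pos[on]
      if (f$strand == "-") {
        # pg-local 5' coordinate of the read on a minus-strand feature
        (f$end - (g + vapply(which(on), function(i) {
          sum(as.integer(sub("[MN]$", "", regmatches(
            aln_df$cigar[i], gregexpr("[0-9]+[MN]", aln_df$cigar[i]))[[1]])))
        }, numeric(1))))
      } else {
        g - f$start
      }
    })
  }
  pre <- identity_read_correlation(aln_pairs, starts_of(sim$genome_aln))
  post <- identity_read_correlation(aln_pairs, starts_of(kept_aln))
  wpre <- pre$windows; wpre$stage <- "pre_filter"
  wpost <- post$windows; wpost$stage <- "post_filter"
  list(pre = pre, post = post, windows = rbind(wpre, wpost))
}
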