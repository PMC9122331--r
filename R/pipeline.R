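# Pipeline orchestration: run configuration, stage execution
# (simulate -> fit -> qc -> compare -> features -> correlations -> report),
# deterministic outputs, and a small command-line front end.

#' Run configuration for the end-to-end pipeline
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or
#'   the shape of external inputs).
#' @param precursor_pool a [precursor_pool_params()].
#' @param fit_options see [fit_lifetime()].
#' @param qc_rules see [qc_filter()].
#' @param min_consistent see [consistency_filter()].
#' @param k_extremes see [top_extremes()].
#' @param outdir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       precursor_pool = precursor_pool_params(),
                       fit_options = list(),
                       qc_rules = list(),
                       min_consistent = 3L,
                       k_extremes = 25L,
                       outdir = "turnover_run") {
  structure(list(cohort = cohort, precursor_pool = precursor_pool,
                 fit_options = fit_options, qc_rules = qc_rules,
                 min_consistent = as.integer(min_consistent),
                 k_extremes = as.integer(k_extremes),
                 outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$effect_spec <- unclass(x$cohort$effect_spec)
  x$precursor_pool <- unclass(x$precursor_pool)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cohort$effect_spec <- do.call(effect_spec, as.list(x$cohort$effect_spec))
  x$cohort <- do.call(cohort_config, x$cohort)
  x$precursor_pool <- do.call(precursor_pool_params,
                              as.list(x$precursor_pool))
  do.call(run_config, x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full synthetic-cohort turnover pipeline
#'
#' Executes simulate -> fit -> qc -> compare -> features -> correlations ->
#' report, writing every intermediate TSV, a machine-readable
#' `summary.json` (rescale factors, extremes, compression and raw-ratio
#' reports, statistical tests), and a timestamped `run.log`. Everything
#' except the log is a pure function of the configuration, so reruns with
#' the same config are bit-identical.
#'
#' @param config a [run_config()] or path to its JSON serialization.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con))
  .log_line(log_con, "pipeline start; seed=", config$cohort$seed)

  # --- simulate ------------------------------------------------------------
  simdir <- file.path(outdir, "simulated")
  paths <- simulate_cohort(config$cohort, simdir, config$precursor_pool)
  truth <- utils::read.delim(paths$truth, stringsAsFactors = FALSE)
  smp <- utils::read.delim(paths$sample_map, stringsAsFactors = FALSE)
  .log_line(log_con, "simulated ", config$cohort$n_proteins,
            " proteins x 2 cohorts x 4 datasets")

  # --- fit (round trip through the written TSVs) ---------------------------
  tc_all <- list(); lfq_all <- list()
  for (cohort in COHORTS) {
    for (dataset in DATASETS) {
      f <- paths[[paste0("obs.", cohort, ".", dataset)]]
      pg <- read_protein_groups(f, smp, cohort = cohort, dataset = dataset)
      tc_all[[paste(cohort, dataset)]] <- pg$time_courses
      if (!is.null(pg$lfq)) lfq_all[[paste(cohort, dataset)]] <- pg$lfq
    }
  }
  tc <- do.call(rbind, c(tc_all, list(make.row.names = FALSE)))
  records <- fit_lifetimes(tc, config$precursor_pool, config$fit_options)
  retained <- qc_filter(records, tc, config$qc_rules)
  .write_tsv(records, file.path(outdir, "lifetimes_raw.tsv"))
  .write_tsv(retained, file.path(outdir, "lifetimes.tsv"))
  .log_line(log_con, "fitted ", nrow(records), " courses; retained ",
            nrow(retained))

  lfq <- do.call(rbind, c(lfq_all, list(make.row.names = FALSE)))
  abundance <- summarize_lfq_levels(lfq)
  .write_tsv(abundance, file.path(outdir, "abundance.tsv"))

  # --- compare -------------------------------------------------------------
  aged <- retained[retained$cohort == "aged",
                   c("protein_id", "dataset", "halflife")]
  young <- retained[retained$cohort == "young",
                    c("protein_id", "dataset", "halflife")]
  rsc <- median_rescale(aged, young)
  l2fc <- compute_log2fc(rsc$rescaled, young)
  cons <- consistency_filter(l2fc, config$min_consistent)
  ext <- top_extremes(cons, config$k_extremes)
  cons$percentile_group <- tryCatch(percentile_groups(cons$mean_log2fc),
                                    ta_error = function(e) NA_character_)
  .write_tsv(rsc$factors, file.path(outdir, "rescale_factors.tsv"))
  .write_tsv(l2fc, file.path(outdir, "log2fc.tsv"))
  .write_tsv(cons, file.path(outdir, "consistent.tsv"))
  .write_tsv(ext$rll, file.path(outdir, "extremes_rll.tsv"))
  .write_tsv(ext$rsl, file.path(outdir, "extremes_rsl.tsv"))

  # mean lifetime (rescaled aged + young averaged per dataset, then across)
  mean_lt <- .mean_lifetime(rsc$rescaled, young)
  m <- match(cons$protein_id, names(mean_lt))
  comp <- lifetime_compression(cons$mean_log2fc, as.numeric(mean_lt[m]))
  tert <- stats::setNames(comp$tertiles, cons$protein_id)

  fracs <- .mean_fractions(tc)
  rr <- raw_ratio_check(fracs, tert)
  if (nrow(rr$table) > 0)
    .write_tsv(rr$table, file.path(outdir, "raw_ratio_check.tsv"))

  # abundance quadrants on mean log2fc vs abundance change
  ab_a <- abundance[abundance$cohort == "aged", ]
  ab_y <- abundance[abundance$cohort == "young", ]
  dl <- cons$mean_log2fc
  da <- vapply(cons$protein_id, function(p) {
    ya <- ab_a$lfq[ab_a$protein_id == p]
    yy <- ab_y$lfq[ab_y$protein_id == p & ab_y$dataset %in%
                     ab_a$dataset[ab_a$protein_id == p]]
    if (length(ya) == 0 || length(yy) == 0) return(NA_real_)
    log2(mean(ya) / mean(yy))
  }, numeric(1))
  cons$quadrant <- quadrant_classify(dl, da)

  ann <- utils::read.delim(paths$annotations, stringsAsFactors = FALSE)
  expr <- as.matrix(ann[, CELL_TYPES])
  rownames(expr) <- ann$protein_id
  ct <- celltype_specificity(expr)
  cons$cell_type <- unname(ct[cons$protein_id])
  .write_tsv(cons, file.path(outdir, "comparison_records.tsv"))

  # --- features + correlations --------------------------------------------
  feats <- build_feature_table(paths$fasta, ann)
  .write_tsv(feats, file.path(outdir, "features.tsv"))
  corr <- feature_correlations(feats, l2fc)
  .write_tsv(corr, file.path(outdir, "feature_correlations.tsv"))

  # --- statistics ----------------------------------------------------------
  shared <- intersect(aged$protein_id[aged$dataset == "cortex_hom"],
                      young$protein_id[young$dataset == "cortex_hom"])
  av <- aged$halflife[aged$dataset == "cortex_hom"][
    match(shared, aged$protein_id[aged$dataset == "cortex_hom"])]
  yv <- young$halflife[young$dataset == "cortex_hom"][
    match(shared, young$protein_id[young$dataset == "cortex_hom"])]
  wil <- paired_lifetime_test(av, yv)
  logn <- lognormality_check(yv)

  summary <- list(
    n_proteins = config$cohort$n_proteins,
    seed = config$cohort$seed,
    rescale_factors = stats::setNames(as.list(rsc$factors$percent),
                                      rsc$factors$dataset),
    n_consistent = nrow(cons),
    rll_extremes = ext$rll$protein_id,
    rsl_extremes = ext$rsl$protein_id,
    compression = list(r = comp$r, p = comp$p, n = comp$n),
    raw_ratio_bidirectional = rr$bidirectional,
    wilcoxon_cortex_hom = wil,
    lognormality_young_cortex = logn[c("n", "statistic", "pass")])
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, null = "null")
  .log_line(log_con, "pipeline done")
  invisible(summary)
}

# average of rescaled-aged and young lifetime per dataset, then across
# datasets; returns a named vector keyed by protein_id
.mean_lifetime <- function(rescaled_aged, young) {
  key <- function(df) paste(df$protein_id, df$dataset)
  sh <- intersect(key(rescaled_aged), key(young))
  a <- rescaled_aged[match(sh, key(rescaled_aged)), ]
  y <- young[match(sh, key(young)), ]
  per_ds <- (a$halflife + y$halflife) / 2
  tapply(per_ds, a$protein_id, mean)
}

# replicate-mean labeled fraction per (protein, cohort, time), averaged
# over datasets, from the long time-course table
.mean_fractions <- function(tc) {
  tc <- tc[tc$time > 0 & !is.na(tc$hl_ratio), ]
  f <- ratio_to_fraction(tc$hl_ratio)
  key <- paste(tc$protein_id, tc$cohort, tc$time, sep = "\r")
  m <- tapply(f, key, mean)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  data.frame(protein_id = vapply(parts, `[`, "", 1L),
             cohort = vapply(parts, `[`, "", 2L),
             time = as.numeric(vapply(parts, `[`, "", 3L)),
             fraction = as.numeric(m), stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Implements `turnover-aging <simulate|all> --config <file>
#' [--outdir <dir>]`. `simulate` writes a synthetic cohort from a
#' [cohort_config()] JSON; `all` runs the whole pipeline
#' ([run_pipeline()]) from a [run_config()] JSON — individual stages are
#' exposed as ordinary R functions rather than CLI verbs. Exit codes:
#' 0 ok, 2 validation error, 3 data error, 4 numerical error.
#'
#' @param args character vector of command-line arguments.
#' @return exit status integer, invisibly.
#' @export
turnover_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: turnover-aging <simulate|all> --config <file> [--outdir <dir>]")
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  status <- tryCatch({
    if (length(args) < 1) stop(usage, call. = FALSE)
    verb <- args[1]
    cfg_path <- get_opt("--config")
    if (is.null(cfg_path)) stop(usage, call. = FALSE)
    if (verb == "simulate") {
      cfg <- read_cohort_config(cfg_path)
      outdir <- get_opt("--outdir") %||% "simulated"
      simulate_cohort(cfg, outdir)
      0L
    } else if (verb == "all") {
      cfg <- read_run_config(cfg_path)
      od <- get_opt("--outdir")
      if (!is.null(od)) cfg$outdir <- od
      run_pipeline(cfg)
      0L
    } else stop(usage, call. = FALSE)
  },
  ta_config_error = function(e) { message(conditionMessage(e)); 2L },
  ta_format_error = function(e) { message(conditionMessage(e)); 2L },
  ta_data_error = function(e) { message(conditionMessage(e)); 3L },
  ta_comparison_error = function(e) { message(conditionMessage(e)); 3L },
  ta_fit_error = function(e) { message(conditionMessage(e)); 4L },
  ta_internal_error = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) { message(conditionMessage(e)); 2L })
  invisible(status)
}
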