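# Parsing of proteinGroups-dialect tables, peptide-ratio summarization,
# reuse-corrected half-life fitting with profile-likelihood 95% CIs, QC
# filtering, and LFQ abundance summarization.

#' Read a proteinGroups-dialect TSV into label time courses
#'
#' Rows flagged as reverse hits (id prefix `REV__` or a `+` in the
#' `Reverse` column), potential contaminants (`CON__` prefix or flag
#' column), or only-identified-by-site are dropped. Each remaining protein
#' yields one time course per (cohort, dataset) with a single t = 0 anchor
#' observation at H/L = 0; t = 0 cells present in the file are validated
#' and collapsed into that anchor. Malformed numeric cells become missing.
#'
#' @param path TSV file path.
#' @param sample_map data.frame with columns `sample`, `time`, `replicate`
#'   (and optionally `cohort`, `dataset` overriding the defaults below);
#'   `sample` must match the suffix of each `Ratio H/L <sample>` column.
#' @param cohort,dataset labels attached to all rows of this file.
#' @return list with `time_courses` (long data.frame: `protein_id`,
#'   `cohort`, `dataset`, `time`, `replicate`, `hl_ratio`), `lfq` (long
#'   data.frame of summed H+L intensities per sample, or NULL when no LFQ
#'   columns are present), and `n_dropped` (flagged rows removed).
#' @export
read_protein_groups <- function(path, sample_map, cohort = "young",
                                dataset = "cortex_hom") {
  if (!file.exists(path))
    ta_format_error(sprintf("read_protein_groups: no such file: %s", path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
  if (nrow(tab) == 0 || ncol(tab) == 0)
    ta_format_error("read_protein_groups: empty file")
  if (!"Protein IDs" %in% names(tab))
    ta_format_error("read_protein_groups: missing mandatory column 'Protein IDs'")
  ratio_cols <- paste("Ratio H/L", sample_map$sample)
  missing_cols <- setdiff(ratio_cols, names(tab))
  if (length(missing_cols) > 0)
    ta_format_error(sprintf("read_protein_groups: missing mandatory column '%s'",
                            missing_cols[1]))

  flag <- function(col) {
    if (col %in% names(tab)) !is.na(tab[[col]]) & tab[[col]] == "+" else
      rep(FALSE, nrow(tab))
  }
  drop <- grepl("^REV__", tab$`Protein IDs`) |
    grepl("^CON__", tab$`Protein IDs`) |
    flag("Reverse") | flag("Potential contaminant") |
    flag("Only identified by site")
  n_dropped <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]

  rows <- list()
  for (j in seq_len(nrow(sample_map))) {
    if (sample_map$time[j] == 0) next  # collapsed into the single anchor
    v <- suppressWarnings(as.numeric(tab[[ratio_cols[j]]]))
    rows[[j]] <- data.frame(
      protein_id = tab$`Protein IDs`, cohort = cohort, dataset = dataset,
      time = sample_map$time[j], replicate = sample_map$replicate[j],
      hl_ratio = v, stringsAsFactors = FALSE)
  }
  tc <- do.call(rbind, rows)
  anchor <- data.frame(protein_id = tab$`Protein IDs`, cohort = cohort,
                       dataset = dataset, time = 0, replicate = 0L,
                       hl_ratio = 0, stringsAsFactors = FALSE)
  tc <- rbind(anchor, tc)
  tc <- tc[order(tc$protein_id, tc$time, tc$replicate), ]
  rownames(tc) <- NULL

  lfq <- NULL
  lfqh_cols <- paste("LFQ intensity H", sample_map$sample)
  lfql_cols <- paste("LFQ intensity L", sample_map$sample)
  if (all(lfqh_cols %in% names(tab)) && all(lfql_cols %in% names(tab))) {
    lrows <- list()
    for (j in seq_len(nrow(sample_map))) {
      h <- suppressWarnings(as.numeric(tab[[lfqh_cols[j]]]))
      l <- suppressWarnings(as.numeric(tab[[lfql_cols[j]]]))
      lrows[[j]] <- data.frame(
        protein_id = tab$`Protein IDs`, cohort = cohort, dataset = dataset,
        sample = sample_map$sample[j], time = sample_map$time[j],
        replicate = sample_map$replicate[j],
        lfq_h = h, lfq_l = l, stringsAsFactors = FALSE)
    }
    lfq <- do.call(rbind, lrows)
    rownames(lfq) <- NULL
  }
  list(time_courses = tc, lfq = lfq, n_dropped = n_dropped)
}

#' Summarize peptide-level H/L ratios to protein level
#'
#' Per (protein, sample), the median of peptide ratios is reported only when
#' the peptide count reaches `min_peptides` (default 4, i.e. strictly more
#' than 3 peptides); otherwise the cell is missing.
#'
#' @param peptide_table data.frame with columns `protein_id`, `sample`,
#'   `hl_ratio`.
#' @param min_peptides minimum peptide count for a protein-level median.
#' @return data.frame `protein_id`, `sample`, `hl_ratio`, `n_peptides`
#'   (cells below the threshold have `hl_ratio = NA`).
#' @export
summarize_peptide_ratios <- function(peptide_table, min_peptides = 4L) {
  stopifnot(nrow(peptide_table) > 0)
  if (any(peptide_table$hl_ratio < 0, na.rm = TRUE))
    ta_data_error("summarize_peptide_ratios: negative H/L ratios")
  key <- interaction(peptide_table$protein_id, peptide_table$sample,
                     drop = TRUE, sep = "\r")
  med <- tapply(peptide_table$hl_ratio, key, stats::median, na.rm = TRUE)
  n <- tapply(!is.na(peptide_table$hl_ratio), key, sum)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    sample = vapply(parts, `[`, "", 2L),
    hl_ratio = ifelse(n >= min_peptides, as.numeric(med), NA_real_),
    n_peptides = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$protein_id, out$sample), ]
}

.default_fit_options <- function() {
  list(halflife_bounds = c(0.1, 1000), n_grid = 60L, conf_level = 0.95,
       compute_ci = TRUE)
}

# fast unvalidated heavy-fraction kernel; t and k may both be vectors
# (result: length(t) x length(k) matrix)
.heavy_fraction_mat <- function(t, k, params, tol = 1e-6) {
  a <- params$a; b <- params$b; c <- 1 / params$r
  ekt <- exp(-outer(t, k))                      # nt x nk
  term <- function(d) {
    deg <- abs(k - d) < tol
    out <- ekt
    if (any(!deg)) {
      kk <- k[!deg]
      out[, !deg] <- sweep(exp(-d * t) - ekt[, !deg, drop = FALSE],
                           2, kk / (kk - d), "*")
    }
    if (any(deg)) {
      kk <- k[deg]
      out[, deg] <- ekt[, deg, drop = FALSE] *
        outer(t, kk, function(tt, ki) ki * tt * (1 + (ki - d) * tt / 2))
    }
    out
  }
  h <- 1 - ekt - a * term(b) - (1 - a) * term(c)
  pmin(pmax(h, 0), 1 - 1e-15)
}

# residual sum of squares on the fraction scale for half-life th (vectorized
# over log10_th)
.fit_rss <- function(log10_th, times, fracs, params) {
  if (length(log10_th) == 1L) {
    k <- log(2) / 10^log10_th
    a <- params$a; b <- params$b; c <- 1 / params$r
    ekt <- exp(-k * times)
    tb <- if (abs(k - b) < 1e-6)
      k * ekt * times * (1 + (k - b) * times / 2)
    else k / (k - b) * (exp(-b * times) - ekt)
    tc <- if (abs(k - c) < 1e-6)
      k * ekt * times * (1 + (k - c) * times / 2)
    else k / (k - c) * (exp(-c * times) - ekt)
    h <- 1 - ekt - a * tb - (1 - a) * tc
    return(sum((fracs - pmin(pmax(h, 0), 1 - 1e-15))^2))
  }
  h <- .heavy_fraction_mat(times, log(2) / 10^log10_th, params)
  colSums((fracs - h)^2)
}

#' Fit a reuse-corrected half-life to one label time course
#'
#' Observed H/L ratios are converted to labeled fractions
#' `f = ratio/(1+ratio)` and the degradation rate constant `k` minimizing
#' `sum((f_obs - h(t; k))^2)` is found by a coarse log-spaced grid over
#' half-life in `halflife_bounds` followed by golden-section refinement
#' ([stats::optimize()]). All replicate observations enter the objective
#' individually. The 95% confidence interval is the profile of the RSS: the
#' half-lives where `RSS(k) = RSS_min * (1 + qf(0.95, 1, n - 1)/(n - 1))`,
#' found by root bracketing on either side of the optimum. Solutions pinned
#' at a bound are flagged `censored_slow` / `censored_fast`.
#'
#' @param times observation times in days (including the t = 0 anchor).
#' @param ratios observed H/L ratios (0 at the anchor); NAs are dropped.
#' @param params a [precursor_pool_params()].
#' @param options list overriding defaults `halflife_bounds = c(0.1, 1000)`,
#'   `n_grid = 60`, `conf_level = 0.95`, `compute_ci = TRUE`.
#' @return one-row data.frame: `halflife`, `k`, `ci_lower`, `ci_upper`,
#'   `rss`, `n_obs`, `n_timepoints` (positive times with data), `qc_flags`
#'   (comma-separated).
#' @export
fit_lifetime <- function(times, ratios, params = precursor_pool_params(),
                         options = list()) {
  opt <- utils::modifyList(.default_fit_options(), options)
  keep <- !is.na(ratios)
  times <- times[keep]; ratios <- ratios[keep]
  if (any(!is.finite(ratios)))
    ta_data_error("fit_lifetime: non-finite H/L ratios")
  if (any(ratios < 0))
    ta_data_error("fit_lifetime: negative H/L ratios")
  pos_times <- unique(times[times > 0])
  if (length(times[times > 0]) == 0)
    ta_fit_error("fit_lifetime: no observations at positive times")
  fracs <- ratio_to_fraction(ratios)
  n <- length(times)

  lb <- log10(opt$halflife_bounds[1]); ub <- log10(opt$halflife_bounds[2])
  grid <- seq(lb, ub, length.out = opt$n_grid)
  rss_grid <- .fit_rss(grid, times, fracs, params)
  i <- which.min(rss_grid)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  o <- stats::optimize(.fit_rss, c(lo, hi), times = times, fracs = fracs,
                       params = params, tol = 1e-9)
  log10_th <- o$minimum; rss_min <- o$objective
  # the boundary can beat the interior refinement
  if (rss_grid[1] < rss_min) { log10_th <- grid[1]; rss_min <- rss_grid[1] }
  if (rss_grid[length(grid)] < rss_min) {
    log10_th <- grid[length(grid)]; rss_min <- rss_grid[length(grid)]
  }

  flags <- character(0)
  bound_tol <- 1e-6
  if (log10_th <= lb + bound_tol) flags <- c(flags, "censored_fast")
  if (log10_th >= ub - bound_tol) flags <- c(flags, "censored_slow")
  if (length(pos_times) < 2) flags <- c(flags, "single_timepoint")

  halflife <- 10^log10_th
  ci <- c(NA_real_, NA_real_)
  if (isTRUE(opt$compute_ci)) {
    # error df counts only noise-carrying observations: the t = 0 anchor has
    # zero residual by construction and carries no information on sigma
    n_inf <- sum(times > 0)
    thr <- rss_min *
      (1 + stats::qf(opt$conf_level, 1, n_inf - 1) / (n_inf - 1))
    if (thr - rss_min < 1e-15) {
      ci <- c(halflife, halflife)  # essentially perfect fit: degenerate CI
    } else {
      g <- function(x) .fit_rss(x, times, fracs, params) - thr
      ci_lo <- if (g(lb) <= 0) opt$halflife_bounds[1] else
        10^stats::uniroot(g, c(lb, log10_th), tol = 1e-8)$root
      ci_hi <- if (g(ub) <= 0) opt$halflife_bounds[2] else
        10^stats::uniroot(g, c(log10_th, ub), tol = 1e-8)$root
      ci <- c(ci_lo, ci_hi)
    }
  }
  data.frame(halflife = halflife, k = log(2) / halflife,
             ci_lower = ci[1], ci_upper = ci[2], rss = rss_min,
             n_obs = n, n_timepoints = length(pos_times),
             qc_flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Fit half-lives for every (protein, cohort, dataset) time course
#'
#' @param time_courses long data.frame as produced by
#'   [read_protein_groups()].
#' @param params a [precursor_pool_params()].
#' @param options see [fit_lifetime()].
#' @return data.frame of lifetime records (one row per fit); courses with
#'   fewer than two informative positive times are emitted with NA halflife
#'   and the `single_timepoint` flag rather than fitted.
#' @export
fit_lifetimes <- function(time_courses, params = precursor_pool_params(),
                          options = list()) {
  key <- interaction(time_courses$protein_id, time_courses$cohort,
                     time_courses$dataset, drop = TRUE, sep = "\r")
  out <- lapply(split(seq_len(nrow(time_courses)), key), function(idx) {
    tc <- time_courses[idx, ]
    pos <- tc$time > 0 & !is.na(tc$hl_ratio)
    id <- data.frame(protein_id = tc$protein_id[1], cohort = tc$cohort[1],
                     dataset = tc$dataset[1], stringsAsFactors = FALSE)
    if (length(unique(tc$time[pos])) < 2) {
      return(cbind(id, data.frame(
        halflife = NA_real_, k = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_, rss = NA_real_, n_obs = sum(!is.na(tc$hl_ratio)),
        n_timepoints = length(unique(tc$time[pos])),
        qc_flags = "single_timepoint", stringsAsFactors = FALSE)))
    }
    cbind(id, fit_lifetime(tc$time, tc$hl_ratio, params, options))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$protein_id, res$cohort, res$dataset), ]
}

.has_flag <- function(flags, f) {
  vapply(strsplit(flags, ",", fixed = TRUE), function(x) f %in% x, logical(1))
}

#' Quality-control filter on fitted lifetime records
#'
#' Removes fits whose course has data at only one positive time, and fits
#' whose mean labeled fraction decreases between consecutive positive pulse
#' times (labeling decreasing during the pulse is physically inconsistent).
#' Annotates `wide_ci` when the CI width `(c2 - c1)` exceeds
#' `wide_ci_factor` times the half-life, and `ci_upper_high` when
#' `c2 > upper_ci_factor * halflife` (the stricter flag used for
#' category-level analyses).
#'
#' @param records output of [fit_lifetimes()].
#' @param time_courses the matching time courses (for the decreasing rule).
#' @param rules list overriding `wide_ci_factor = 1.0`,
#'   `upper_ci_factor = 2.0`.
#' @return the retained records with added logical columns `wide_ci`,
#'   `ci_upper_high`.
#' @export
qc_filter <- function(records, time_courses,
                      rules = list()) {
  rules <- utils::modifyList(list(wide_ci_factor = 1.0,
                                  upper_ci_factor = 2.0), rules)
  keep <- !.has_flag(records$qc_flags, "single_timepoint")

  # decreasing-labeling rule on replicate-mean fractions per positive time
  tc <- time_courses[time_courses$time > 0 & !is.na(time_courses$hl_ratio), ]
  if (nrow(tc) > 0) {
    tc$frac <- ratio_to_fraction(tc$hl_ratio)
    key <- paste(tc$protein_id, tc$cohort, tc$dataset, sep = "\r")
    dec_key <- names(Filter(Negate(is.null), lapply(split(tc, key), function(d) {
      m <- tapply(d$frac, d$time, mean)
      m <- m[order(as.numeric(names(m)))]
      if (length(m) >= 2 && any(diff(m) < 0)) TRUE else NULL
    })))
    rec_key <- paste(records$protein_id, records$cohort, records$dataset,
                     sep = "\r")
    keep <- keep & !(rec_key %in% dec_key)
  }
  out <- records[keep, , drop = FALSE]
  width <- out$ci_upper - out$ci_lower
  out$wide_ci <- !is.na(width) & width > rules$wide_ci_factor * out$halflife
  out$ci_upper_high <- !is.na(out$ci_upper) &
    out$ci_upper > rules$upper_ci_factor * out$halflife
  rownames(out) <- NULL
  out
}

#' Summarize LFQ intensities into normalized per-protein abundances
#'
#' Per protein and sample, H and L intensities are summed to one value; each
#' sample column is divided by its median and multiplied by the grand median
#' (so per-sample medians agree after normalization); values are then
#' averaged across replicates and pulse lengths within (cohort, dataset).
#'
#' @param lfq long data.frame from [read_protein_groups()] (columns
#'   `protein_id`, `cohort`, `dataset`, `sample`, `lfq_h`, `lfq_l`).
#' @return data.frame `protein_id`, `cohort`, `dataset`, `lfq`.
#' @export
summarize_lfq_levels <- function(lfq) {
  stopifnot(!is.null(lfq), nrow(lfq) > 0)
  lfq$total <- lfq$lfq_h + lfq$lfq_l
  grp <- paste(lfq$cohort, lfq$dataset, lfq$sample, sep = "\r")
  med <- tapply(lfq$total, grp, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med == 0))
    ta_data_error("summarize_lfq_levels: a sample column has zero/NA median")
  grand <- stats::median(lfq$total, na.rm = TRUE)
  lfq$norm <- lfq$total / as.numeric(med[grp]) * grand
  key <- paste(lfq$protein_id, lfq$cohort, lfq$dataset, sep = "\r")
  m <- tapply(lfq$norm, key, mean, na.rm = TRUE)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, "", 1L),
                    cohort = vapply(parts, `[`, "", 2L),
                    dataset = vapply(parts, `[`, "", 3L),
                    lfq = as.numeric(m), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$protein_id, out$cohort, out$dataset), ]
}
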