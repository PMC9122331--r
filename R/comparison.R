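# Aged-versus-young comparative machinery: median rescaling, log2 fold
# changes, direction-consistency filtering, extremes, percentile groups,
# z-scores, lifetime compression, raw-ratio bidirectionality, abundance
# quadrants, and cell-type specificity.

#' Median-rescale aged lifetimes onto the young cohort
#'
#' For each dataset, the rescale factor is the median over shared proteins
#' of `aged/young - 1` (0.217 means aged lifetimes are 21.7% longer);
#' rescaled aged lifetimes are `aged / (1 + factor)`, so the median of
#' `rescaled/young` over shared proteins is exactly 1.
#'
#' @param aged,young data.frames with columns `protein_id`, `dataset`,
#'   `halflife`.
#' @param min_overlap minimum shared proteins per dataset.
#' @return list with `factors` (data.frame `dataset`, `factor`,
#'   `percent`, `n_shared`) and `rescaled` (the aged table with `halflife`
#'   replaced by its rescaled value).
#' @export
median_rescale <- function(aged, young, min_overlap = 10L) {
  out_f <- list(); out_r <- list()
  for (ds in unique(aged$dataset)) {
    a <- aged[aged$dataset == ds & !is.na(aged$halflife), ]
    y <- young[young$dataset == ds & !is.na(young$halflife), ]
    shared <- intersect(a$protein_id, y$protein_id)
    if (length(shared) < min_overlap)
      ta_comparison_error(sprintf(
        "median_rescale: only %d shared proteins in dataset '%s' (need >= %d)",
        length(shared), ds, min_overlap))
    av <- a$halflife[match(shared, a$protein_id)]
    yv <- y$halflife[match(shared, y$protein_id)]
    fac <- stats::median(av / yv) - 1
    r <- a
    r$halflife <- r$halflife / (1 + fac)
    out_f[[ds]] <- data.frame(dataset = ds, factor = fac,
                              percent = 100 * fac,
                              n_shared = length(shared),
                              stringsAsFactors = FALSE)
    out_r[[ds]] <- r
  }
  list(factors = do.call(rbind, c(out_f, list(make.row.names = FALSE))),
       rescaled = do.call(rbind, c(out_r, list(make.row.names = FALSE))))
}

#' Per-dataset log2 fold change of rescaled aged over young lifetimes
#'
#' @param rescaled_aged,young data.frames (`protein_id`, `dataset`,
#'   `halflife`); `rescaled_aged` should come from [median_rescale()].
#' @return wide data.frame: `protein_id` plus one `log2fc` column per
#'   dataset; missing where either cohort lacks a retained lifetime.
#' @export
compute_log2fc <- function(rescaled_aged, young) {
  if (any(rescaled_aged$halflife <= 0, na.rm = TRUE) ||
      any(young$halflife <= 0, na.rm = TRUE))
    ta_data_error("compute_log2fc: non-positive lifetime")
  datasets <- sort(unique(c(rescaled_aged$dataset, young$dataset)))
  ids <- sort(unique(c(rescaled_aged$protein_id, young$protein_id)))
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (ds in datasets) {
    a <- rescaled_aged[rescaled_aged$dataset == ds, ]
    y <- young[young$dataset == ds, ]
    av <- a$halflife[match(ids, a$protein_id)]
    yv <- y$halflife[match(ids, y$protein_id)]
    out[[ds]] <- log2(av / yv)
  }
  out
}

#' Direction-consistency filter across datasets
#'
#' Retains proteins whose per-dataset log2FC has the same sign in at least
#' `min_consistent` datasets (default 3 of 4). Zeros count toward neither
#' direction. The summary `mean_log2fc` and its SEM are computed over all
#' measured datasets, not only the consistent ones.
#'
#' @param log2fc wide table from [compute_log2fc()].
#' @param min_consistent minimum same-sign datasets to qualify.
#' @return data.frame of retained records: `protein_id`, `n_measured`,
#'   `n_increase`, `n_decrease`, `direction` (+1/-1), `mean_log2fc`,
#'   `sem_log2fc`.
#' @export
consistency_filter <- function(log2fc, min_consistent = 3L) {
  ds_cols <- setdiff(names(log2fc), "protein_id")
  if (length(ds_cols) > 4L)
    ta_comparison_error("consistency_filter: more than 4 datasets")
  m <- as.matrix(log2fc[, ds_cols, drop = FALSE])
  n_meas <- rowSums(!is.na(m))
  n_inc <- rowSums(m > 0, na.rm = TRUE)
  n_dec <- rowSums(m < 0, na.rm = TRUE)
  keep <- n_inc >= min_consistent | n_dec >= min_consistent
  mean_fc <- rowMeans(m, na.rm = TRUE)
  sem <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  out <- data.frame(protein_id = log2fc$protein_id,
                    n_measured = n_meas, n_increase = n_inc,
                    n_decrease = n_dec,
                    direction = ifelse(n_inc >= min_consistent, 1L,
                                       ifelse(n_dec >= min_consistent, -1L,
                                              0L)),
                    mean_log2fc = mean_fc, sem_log2fc = sem,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top relatively longer-lived / shorter-lived extremes
#'
#' Sorts consistent records by `mean_log2fc`; the top `k` form the rLL list
#' and the bottom `k` the rSL list. Ties are broken by lexicographic
#' `protein_id` order for determinism.
#'
#' @param records output of [consistency_filter()].
#' @param k extremes per side (default 25).
#' @return list with `rll` and `rsl` data.frames.
#' @export
top_extremes <- function(records, k = 25L) {
  if (k > nrow(records)) {
    warning("top_extremes: fewer records than k; returning all")
    k <- nrow(records)
  }
  if (k == 0L) return(list(rll = records[0, ], rsl = records[0, ]))
  dec <- records[order(-records$mean_log2fc, records$protein_id), ]
  inc <- records[order(records$mean_log2fc, records$protein_id), ]
  list(rll = utils::head(dec, k), rsl = utils::head(inc, k))
}

#' Percentile group labels for mean log2FC values
#'
#' Using the linear-interpolation percentile convention
#' ([stats::quantile()] type 7): rSL is strictly below the 25th percentile,
#' middle lies within \[37.5th, 67.5th\], rLL is strictly above the 75th;
#' values in the gaps are unassigned. If all values are equal every value
#' sits on every boundary and all are unassigned.
#'
#' @param values numeric vector (NAs allowed, returned as unassigned).
#' @return character vector of labels `rSL`, `middle`, `rLL`, `unassigned`.
#' @export
percentile_groups <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 8) ta_comparison_error("percentile_groups: need >= 8 values")
  out <- rep("unassigned", length(values))
  v <- values[ok]
  if (max(v) > min(v)) {
    q <- stats::quantile(v, c(0.25, 0.375, 0.675, 0.75), type = 7,
                         names = FALSE)
    lab <- rep("unassigned", length(v))
    lab[v < q[1]] <- "rSL"
    lab[v >= q[2] & v <= q[3]] <- "middle"
    lab[v > q[4]] <- "rLL"
    out[ok] <- lab
  }
  out
}

#' Row-wise z-scores of a lifetime matrix
#'
#' Per row (protein): `(x - mean) / sd` with the sample SD (n - 1), over
#' the finite entries; missing cells stay missing. Rows with zero SD
#' become rows of zeros with a warning.
#'
#' @param x numeric matrix (proteins x datasets), >= 2 finite values/row.
#' @return matrix of z-scores with the same dimnames.
#' @export
zscore_matrix <- function(x) {
  x <- as.matrix(x)
  n_fin <- rowSums(is.finite(x))
  if (any(n_fin < 2))
    ta_data_error("zscore_matrix: every row needs >= 2 finite values")
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1, stats::sd, na.rm = TRUE)
  if (any(sd == 0)) {
    warning("zscore_matrix: zero row SD; returning zeros for those rows")
    z <- sweep(x, 1, mu, "-")
    z[sd == 0, ] <- 0 * z[sd == 0, ]  # keeps NAs missing
    nz <- sd != 0
    z[nz, ] <- sweep(z[nz, , drop = FALSE], 1, sd[nz], "/")
    return(z)
  }
  sweep(sweep(x, 1, mu, "-"), 1, sd, "/")
}

#' Lifetime-compression analysis
#'
#' Pearson correlation between the mean log2FC and the average protein
#' lifetime (arithmetic mean of the rescaled aged and young lifetime per
#' dataset, averaged across datasets), plus a summary over equal-count
#' lifetime tertiles (short/middle/long-lived). A negative r with short
#' tertile mean log2FC > 0 and long tertile mean log2FC < 0 is the
#' compression signature. When the log2FC values have zero variance (the
#' pure-scaling null) r is reported as exactly 0 with p = 1.
#'
#' @param mean_log2fc numeric vector, one value per protein.
#' @param mean_lifetime matching average lifetimes (days).
#' @return list: `r`, `p`, `n`, `tertiles` (character vector), and
#'   `tertile_summary` (data.frame `tertile`, `n`, `mean_log2fc`).
#' @export
lifetime_compression <- function(mean_log2fc, mean_lifetime) {
  ok <- !is.na(mean_log2fc) & !is.na(mean_lifetime)
  fc <- mean_log2fc[ok]; lt <- mean_lifetime[ok]
  if (length(fc) < 30)
    ta_comparison_error("lifetime_compression: need >= 30 proteins")
  if (stats::sd(lt) == 0)
    ta_comparison_error("lifetime_compression: degenerate lifetime variance")
  if (stats::sd(fc) < 1e-9) {
    # pure-scaling null: log2FC variation at floating-point rounding level
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(fc, lt, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  q <- stats::quantile(lt, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  tert <- ifelse(lt < q[1], "short", ifelse(lt <= q[2], "middle", "long"))
  summ <- data.frame(
    tertile = c("short", "middle", "long"),
    n = vapply(c("short", "middle", "long"),
               function(g) sum(tert == g), integer(1)),
    mean_log2fc = vapply(c("short", "middle", "long"),
                         function(g) mean(fc[tert == g]), numeric(1)),
    stringsAsFactors = FALSE)
  tertiles <- rep(NA_character_, length(mean_log2fc))
  tertiles[ok] <- tert
  list(r = r, p = p, n = length(fc), tertiles = tertiles,
       tertile_summary = summ)
}

#' Raw-ratio bidirectionality check
#'
#' Works on uncorrected labeled fractions: per lifetime tertile and pulse
#' time, the median difference (aged - young) and a two-sided sign test.
#' The report flags `bidirectional = TRUE` when, at every evaluated pulse
#' time, the short-lived tertile median difference is negative and the
#' long-lived tertile median difference is positive, each significant at
#' `alpha`. True compression moves the raw ratios in opposite directions;
#' the regression-to-the-mean artifact of rescaled log2FCs does not.
#'
#' @param fractions data.frame with columns `protein_id`, `cohort`, `time`,
#'   `fraction` (replicate-mean labeled fraction at a pulse time).
#' @param tertiles named character vector (`protein_id` -> tertile label
#'   from [lifetime_compression()]).
#' @param alpha sign-test significance level.
#' @param min_per_tertile tertiles with fewer matched proteins are skipped
#'   with a warning.
#' @return list: `table` (data.frame `time`, `tertile`, `n`,
#'   `median_diff`, `p_sign`) and `bidirectional` (logical flag).
#' @export
raw_ratio_check <- function(fractions, tertiles, alpha = 0.05,
                            min_per_tertile = 10L) {
  times <- sort(unique(fractions$time[fractions$time > 0]))
  rows <- list(); verdicts <- logical(0)
  for (tt in times) {
    a <- fractions[fractions$cohort == "aged" & fractions$time == tt, ]
    y <- fractions[fractions$cohort == "young" & fractions$time == tt, ]
    shared <- intersect(a$protein_id, y$protein_id)
    d <- a$fraction[match(shared, a$protein_id)] -
      y$fraction[match(shared, y$protein_id)]
    tert <- tertiles[shared]
    res <- list()
    for (g in c("short", "long")) {
      dg <- d[!is.na(tert) & tert == g]
      if (length(dg) < min_per_tertile) {
        warning(sprintf("raw_ratio_check: tertile '%s' at t=%g skipped (n=%d)",
                        g, tt, length(dg)))
        res[[g]] <- NULL
        next
      }
      nz <- dg[dg != 0]
      p <- if (length(nz) == 0) 1 else
        stats::binom.test(sum(nz > 0), length(nz))$p.value
      res[[g]] <- data.frame(time = tt, tertile = g, n = length(dg),
                             median_diff = stats::median(dg), p_sign = p,
                             stringsAsFactors = FALSE)
    }
    rows <- c(rows, res)
    if (!is.null(res$short) && !is.null(res$long)) {
      verdicts <- c(verdicts,
                    res$short$median_diff < 0 && res$short$p_sign < alpha &&
                      res$long$median_diff > 0 && res$long$p_sign < alpha)
    }
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  list(table = tab,
       bidirectional = length(verdicts) > 0 && all(verdicts))
}

#' Quadrant classification of lifetime versus abundance change
#'
#' Maps the signs of the lifetime change and abundance change to quadrants:
#' `(+,+) -> up_up`, `(+,-) -> up_down`, `(-,-) -> down_down`,
#' `(-,+) -> down_up`. A zero in either delta (or a missing value) gives
#' `unclassified`.
#'
#' @param delta_lifetime,delta_abundance numeric vectors (any common scale;
#'   only the sign is used).
#' @return character vector of quadrant labels.
#' @export
quadrant_classify <- function(delta_lifetime, delta_abundance) {
  sl <- sign(delta_lifetime); sa <- sign(delta_abundance)
  out <- rep("unclassified", length(sl))
  out[!is.na(sl) & !is.na(sa) & sl > 0 & sa > 0] <- "up_up"
  out[!is.na(sl) & !is.na(sa) & sl > 0 & sa < 0] <- "up_down"
  out[!is.na(sl) & !is.na(sa) & sl < 0 & sa < 0] <- "down_down"
  out[!is.na(sl) & !is.na(sa) & sl < 0 & sa > 0] <- "down_up"
  out
}

#' Assign proteins to a specific cell type from an expression matrix
#'
#' A protein is assigned a cell type iff that type's (log2) expression
#' exceeds each of the other three by strictly more than `threshold`
#' log2 units; otherwise `none`.
#'
#' @param expr numeric matrix or data.frame, proteins x 4 cell types,
#'   log2 scale, rownames = protein ids.
#' @param threshold log2 margin (default 1).
#' @return named character vector protein -> cell type or `"none"`.
#' @export
celltype_specificity <- function(expr, threshold = 1.0) {
  expr <- as.matrix(expr)
  if (ncol(expr) != 4L)
    ta_format_error("celltype_specificity: need exactly 4 cell-type columns")
  out <- apply(expr, 1, function(x) {
    if (any(is.na(x))) return("none")
    i <- which.max(x)
    if (all(x[i] - x[-i] > threshold)) colnames(expr)[i] else "none"
  })
  out
}
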