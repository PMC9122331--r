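# Statistical battery: feature/log2FC correlations, paired signed-rank
# test, Welch ANOVA with Games-Howell or permutation-Dunnett post hoc, and
# an Anderson-Darling log-normality check.

#' Pearson correlations between protein features and per-dataset log2FC
#'
#' Per feature and dataset, Pearson r and its two-sided p-value over the
#' pairwise-complete proteins, plus the cross-dataset mean r and SEM.
#' Zero-variance features are reported as missing with a warning.
#'
#' @param features data.frame from [build_feature_table()] (keyed by
#'   `protein_id`; all other numeric columns are treated as features).
#' @param log2fc wide table from [compute_log2fc()].
#' @param min_n minimum joined proteins per (feature, dataset).
#' @return data.frame `feature`, `dataset`, `n`, `r`, `p`, `sem`; per-feature
#'   summary rows with `dataset = "mean"` carry the cross-dataset mean r in
#'   `r` and its SEM in `sem`.
#' @export
feature_correlations <- function(features, log2fc, min_n = 3L) {
  ds_cols <- setdiff(names(log2fc), "protein_id")
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))], "protein_id")
  idx <- match(log2fc$protein_id, features$protein_id)
  row1 <- function(f, ds, n, r, p, sem = NA_real_)
    data.frame(feature = f, dataset = ds, n = n, r = r, p = p, sem = sem,
               stringsAsFactors = FALSE)
  rows <- list()
  for (f in feat_cols) {
    x_all <- features[[f]][idx]
    rs <- c()
    for (ds in ds_cols) {
      y <- log2fc[[ds]]
      ok <- !is.na(x_all) & !is.na(y)
      n <- sum(ok)
      if (n < min_n) {
        rows[[paste(f, ds)]] <- row1(f, ds, n, NA_real_, NA_real_)
        next
      }
      if (stats::sd(x_all[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning(sprintf("feature_correlations: zero variance for '%s' in %s",
                        f, ds))
        rows[[paste(f, ds)]] <- row1(f, ds, n, NA_real_, NA_real_)
        next
      }
      ct <- stats::cor.test(x_all[ok], y[ok], method = "pearson")
      rows[[paste(f, ds)]] <- row1(f, ds, n, unname(ct$estimate), ct$p.value)
      rs <- c(rs, unname(ct$estimate))
    }
    rows[[paste(f, "mean")]] <- row1(
      f, "mean", length(rs),
      if (length(rs)) mean(rs) else NA_real_, NA_real_,
      if (length(rs) >= 2) stats::sd(rs) / sqrt(length(rs)) else NA_real_)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Paired Wilcoxon signed-rank test on matched lifetimes
#'
#' Two-sided matched-pairs signed-rank test with zero differences dropped
#' and the normal approximation with tie correction. If every difference is
#' zero, p = 1 by convention (with a warning).
#'
#' @param aged,young numeric vectors of matched lifetimes (same proteins,
#'   same order). NAs in either member drop the pair.
#' @param min_n minimum usable pairs.
#' @return list `n` (pairs tested), `statistic` (V), `p`.
#' @export
paired_lifetime_test <- function(aged, young, min_n = 6L) {
  ok <- !is.na(aged) & !is.na(young)
  if (sum(ok) < min_n)
    ta_data_error("paired_lifetime_test: need >= min_n shared proteins")
  d <- aged[ok] - young[ok]
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("paired_lifetime_test: all differences zero; p = 1 by convention")
    return(list(n = 0L, statistic = NA_real_, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  list(n = length(d), statistic = unname(wt$statistic), p = wt$p.value)
}

# Games-Howell pairwise comparison of group i against reference
.games_howell_p <- function(mi, mr, vi, vr, ni, nr, k) {
  se2 <- vi / ni + vr / nr
  t <- abs(mi - mr) / sqrt(se2)
  df <- se2^2 / ((vi / ni)^2 / (ni - 1) + (vr / nr)^2 / (nr - 1))
  # studentized-range based p across k groups
  stats::ptukey(t * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
}

#' Welch ANOVA across categories with reference-based post hoc tests
#'
#' Omnibus: Welch's heteroscedasticity-robust one-way ANOVA
#' ([stats::oneway.test()]). Post hoc, each category is compared against
#' the `reference` category following the sample-size rule: a
#' permutation-based Dunnett-style max-|t| correction when the category has
#' fewer than `dunnett_max_n` members, and Games-Howell otherwise.
#' Categories with fewer than 3 members are excluded with a warning.
#'
#' @param values numeric vector.
#' @param groups category labels, same length.
#' @param reference the reference category name (default: the largest
#'   category).
#' @param dunnett_max_n size threshold switching Dunnett-style to
#'   Games-Howell (default 50).
#' @param n_perm permutations for the Dunnett-style correction.
#' @param seed seed for the permutation stream.
#' @return list: `omnibus` (list `F`, `df1`, `df2`, `p`), `posthoc`
#'   (data.frame `group`, `n`, `effect` (mean difference vs reference),
#'   `p_adj`, `method`), `reference`.
#' @export
group_anova <- function(values, groups, reference = NULL,
                        dunnett_max_n = 50L, n_perm = 2000L, seed = 1L) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    warning(sprintf("group_anova: excluding groups with < 3 members: %s",
                    paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  if (length(tab) < 2)
    ta_data_error("group_anova: need >= 2 groups with >= 3 members")
  if (is.null(reference)) reference <- names(tab)[which.max(tab)]
  if (!reference %in% names(tab))
    ta_config_error("group_anova: reference group not present")

  ow <- stats::oneway.test(values ~ factor(groups), var.equal = FALSE)
  omnibus <- list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
                  df2 = unname(ow$parameter[2]), p = ow$p.value)

  others <- setdiff(names(tab), reference)
  k <- length(tab)
  vr <- values[groups == reference]
  post <- lapply(others, function(g) {
    vg <- values[groups == g]
    eff <- mean(vg) - mean(vr)
    if (length(vg) < dunnett_max_n) {
      # permutation Dunnett-style: max-|t| over all comparisons vs reference
      obs_t <- abs(eff) / sqrt(stats::var(vg) / length(vg) +
                                 stats::var(vr) / length(vr))
      maxt <- with_seed(child_seed(seed, "dunnett", g), {
        vapply(seq_len(n_perm), function(i) {
          perm <- sample(values)
          pr <- perm[groups == reference]
          max(vapply(others, function(h) {
            ph <- perm[groups == h]
            abs(mean(ph) - mean(pr)) /
              sqrt(stats::var(ph) / length(ph) + stats::var(pr) / length(pr))
          }, numeric(1)))
        }, numeric(1))
      })
      p <- (1 + sum(maxt >= obs_t)) / (1 + n_perm)
      method <- "dunnett_permutation"
    } else {
      p <- .games_howell_p(mean(vg), mean(vr), stats::var(vg),
                           stats::var(vr), length(vg), length(vr), k)
      method <- "games_howell"
    }
    data.frame(group = g, n = length(vg), effect = eff, p_adj = p,
               method = method, stringsAsFactors = FALSE)
  })
  list(omnibus = omnibus,
       posthoc = do.call(rbind, c(post, list(make.row.names = FALSE))),
       reference = reference)
}

#' Anderson-Darling log-normality check for lifetimes
#'
#' Computes the Anderson-Darling normality statistic on log10(lifetimes)
#' with estimated mean and SD (the composite-hypothesis case), applies the
#' small-sample modification `A* = A^2 (1 + 0.75/n + 2.25/n^2)`, and
#' compares against the 5% critical value 0.752.
#'
#' @param lifetimes positive lifetimes, n >= 20.
#' @return list `n`, `statistic` (modified A*), `critical_5pct`, `pass`
#'   (TRUE when the log-normal hypothesis is not rejected at 5%).
#' @export
lognormality_check <- function(lifetimes) {
  lifetimes <- lifetimes[!is.na(lifetimes)]
  if (any(lifetimes <= 0))
    ta_domain_error("lognormality_check: lifetimes must be positive")
  n <- length(lifetimes)
  if (n < 20)
    ta_data_error("lognormality_check: need n >= 20")
  x <- sort(log10(lifetimes))
  z <- stats::pnorm((x - mean(x)) / stats::sd(x))
  z <- pmin(pmax(z, 1e-15), 1 - 1e-15)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  a_star <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  list(n = n, statistic = a_star, critical_5pct = 0.752,
       pass = a_star < 0.752)
}
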