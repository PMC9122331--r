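# Aged-vs-young comparison machinery.

lt_table <- function(ids, halflife, dataset = "cortex_hom")
  data.frame(protein_id = ids, dataset = dataset, halflife = halflife)

test_that("median_rescale recovers exact scaling and is idempotent", {
  ids <- sprintf("P%02d", 1:20)
  young <- lt_table(ids, seq(2, 40, by = 2))
  aged <- lt_table(ids, seq(2, 40, by = 2) * 1.25)
  rsc <- median_rescale(aged, young)
  expect_equal(rsc$factors$percent, 25.0)
  l2 <- compute_log2fc(rsc$rescaled, young)
  expect_equal(l2$cortex_hom, rep(0, 20))
  # identity input: factor 0
  expect_equal(median_rescale(young, young)$factors$factor, 0)
  # idempotence: rescaling already-rescaled data gives factor 0
  expect_equal(median_rescale(rsc$rescaled, young)$factors$factor, 0,
               tolerance = 1e-12)
  # invariant: median of rescaled/young is exactly 1
  expect_equal(stats::median(rsc$rescaled$halflife / young$halflife), 1)
  expect_error(median_rescale(lt_table("P1", 5), lt_table("P1", 5)),
               class = "ta_comparison_error")
})

test_that("compute_log2fc basics and per-dataset median-zero property", {
  ids <- sprintf("P%02d", 1:15)
  young <- lt_table(ids, 10)
  expect_equal(compute_log2fc(lt_table(ids, 10), young)$cortex_hom,
               rep(0, 15))
  expect_equal(compute_log2fc(lt_table(ids, 20), young)$cortex_hom,
               rep(1, 15))
  expect_error(compute_log2fc(lt_table(ids, -1), young),
               class = "ta_data_error")
  set.seed(8)
  aged <- lt_table(ids, 10 * exp(stats::rnorm(15, 0.2, 0.3)))
  rsc <- median_rescale(aged, young)
  l2 <- compute_log2fc(rsc$rescaled, young)
  expect_equal(stats::median(l2$cortex_hom), 0)
})

test_that("consistency_filter matches exhaustive enumeration on all 81 patterns", {
  signs <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1, d4 = -1:1)
  vals <- as.matrix(signs) * 0.5
  tab <- data.frame(protein_id = sprintf("S%02d", seq_len(nrow(vals))),
                    cortex_hom = vals[, 1], cerebellum_hom = vals[, 2],
                    cortex_syn = vals[, 3], cerebellum_syn = vals[, 4])
  out <- consistency_filter(tab, 3L)
  # brute-force oracle: count same-sign entries directly
  brute_keep <- apply(vals, 1, function(v)
    sum(v > 0) >= 3 || sum(v < 0) >= 3)
  expect_setequal(out$protein_id, tab$protein_id[brute_keep])
  brute_dir <- apply(vals, 1, function(v)
    if (sum(v > 0) >= 3) 1L else if (sum(v < 0) >= 3) -1L else 0L)
  expect_equal(out$direction,
               unname(brute_dir[match(out$protein_id, tab$protein_id)]))
  # spec examples: (+,+,+,-) kept with direction +; (+,+,-,-) excluded
  ex <- data.frame(protein_id = c("a", "b"),
                   cortex_hom = c(1, 1), cerebellum_hom = c(1, 1),
                   cortex_syn = c(1, -1), cerebellum_syn = c(-1, -1))
  got <- consistency_filter(ex)
  expect_equal(got$protein_id, "a")
  expect_equal(got$direction, 1L)
})

test_that("consistency_filter mean/SEM cover all measured datasets", {
  tab <- data.frame(protein_id = "p", cortex_hom = 0.4,
                    cerebellum_hom = 0.2, cortex_syn = 0.6,
                    cerebellum_syn = -0.1)
  out <- consistency_filter(tab)
  expect_equal(out$mean_log2fc, mean(c(0.4, 0.2, 0.6, -0.1)))
  expect_equal(out$sem_log2fc, stats::sd(c(0.4, 0.2, 0.6, -0.1)) / 2)
  # NAs are excluded from counts and averaging
  tab$cerebellum_syn <- NA
  out2 <- consistency_filter(tab)
  expect_equal(out2$n_measured, 3)
  expect_equal(out2$mean_log2fc, mean(c(0.4, 0.2, 0.6)))
})

test_that("top_extremes ordering, ties, and edge cases", {
  rec <- data.frame(protein_id = c("b", "a", "c", "d"),
                    mean_log2fc = c(0.5, 0.5, -0.2, 0.1))
  ext <- top_extremes(rec, 2L)
  expect_equal(ext$rll$protein_id, c("a", "b"))  # tie broken by id
  expect_equal(ext$rsl$protein_id, c("c", "d"))
  expect_equal(nrow(top_extremes(rec, 0L)$rll), 0L)
  expect_warning(big <- top_extremes(rec, 10L), "fewer")
  expect_equal(nrow(big$rll), 4L)
})

test_that("percentile_groups follows the linear-interpolation convention", {
  g <- percentile_groups(1:100)
  expect_equal(sum(g == "rSL"), 25L)     # strictly below q25 = 25.75
  expect_equal(sum(g == "middle"), 29L)  # within [38.125, 67.825]
  expect_equal(sum(g == "rLL"), 25L)     # strictly above q75 = 75.25
  expect_true(all(g[1:25] == "rSL"))
  expect_true(all(g[76:100] == "rLL"))
  # all-equal degenerate input: everything unassigned
  expect_true(all(percentile_groups(rep(1, 10)) == "unassigned"))
  # 8 values under type-7 interpolation: q25 = 2.75, q75 = 6.25
  g8 <- percentile_groups(1:8)
  expect_equal(which(g8 == "rSL"), 1:2)
  expect_equal(which(g8 == "rLL"), 7:8)
  expect_error(percentile_groups(1:5), class = "ta_comparison_error")
})

test_that("zscore_matrix row-standardizes and preserves missingness", {
  expect_equal(as.numeric(zscore_matrix(rbind(c(1, 2, 3)))), c(-1, 0, 1))
  set.seed(3)
  m <- matrix(stats::rnorm(20), 4)
  z <- zscore_matrix(m)
  expect_equal(rowMeans(z), rep(0, 4))
  expect_equal(apply(z, 1, stats::sd), rep(1, 4))
  m2 <- rbind(c(4, 6, NA, 8))
  z2 <- zscore_matrix(m2)
  expect_true(is.na(z2[1, 3]))
  expect_equal(mean(z2[1, ], na.rm = TRUE), 0)
  expect_warning(zc <- zscore_matrix(rbind(c(5, 5, 5))), "zero row SD")
  expect_equal(as.numeric(zc), c(0, 0, 0))
  expect_error(zscore_matrix(rbind(c(1, NA, NA))), class = "ta_data_error")
})

test_that("lifetime_compression detects injected compression and nulls", {
  cfg <- cohort_config(n_proteins = 300, seed = 5, ratio_noise_cv = 0,
                       missing_rate = 0,
                       effect_spec = effect_spec(0, 0,
                                                 compression_slope = 0.3))
  truth <- generate_truth(cfg)
  young <- truth_lifetimes(truth, "young")
  aged <- truth_lifetimes(truth, "aged")
  rsc <- median_rescale(aged, young)
  l2 <- compute_log2fc(rsc$rescaled, young)
  cons <- consistency_filter(l2)
  mlt <- tapply((rsc$rescaled$halflife +
                   young$halflife[match(paste(rsc$rescaled$protein_id,
                                              rsc$rescaled$dataset),
                                        paste(young$protein_id,
                                              young$dataset))]) / 2,
                rsc$rescaled$protein_id, mean)
  comp <- lifetime_compression(cons$mean_log2fc,
                               as.numeric(mlt[cons$protein_id]))
  expect_lt(comp$r, 0)
  expect_gt(comp$tertile_summary$mean_log2fc[
    comp$tertile_summary$tertile == "short"], 0)
  expect_lt(comp$tertile_summary$mean_log2fc[
    comp$tertile_summary$tertile == "long"], 0)
  # pure-scaling null: r exactly 0
  cfg0 <- cohort_config(n_proteins = 300, seed = 5, ratio_noise_cv = 0,
                        missing_rate = 0, effect_spec = effect_spec(0, 0))
  tr0 <- generate_truth(cfg0)
  y0 <- truth_lifetimes(tr0, "young")
  rsc0 <- median_rescale(truth_lifetimes(tr0, "aged"), y0)
  l20 <- compute_log2fc(rsc0$rescaled, y0)
  c0 <- consistency_filter(l20, min_consistent = 0L)
  m0 <- tapply(y0$halflife, y0$protein_id, mean)
  comp0 <- lifetime_compression(c0$mean_log2fc,
                                as.numeric(m0[c0$protein_id]))
  expect_identical(comp0$r, 0)
  expect_error(lifetime_compression(stats::rnorm(40), rep(3, 40)),
               class = "ta_comparison_error")
  expect_error(lifetime_compression(stats::rnorm(10), stats::runif(10)),
               class = "ta_comparison_error")
})

test_that("raw_ratio_check flags constructed bidirectionality, not identity", {
  ids <- sprintf("P%03d", 1:90)
  tert <- stats::setNames(rep(c("short", "middle", "long"), each = 30), ids)
  mk_fr <- function(young, aged) {
    rbind(data.frame(protein_id = ids, cohort = "young", time = 14,
                     fraction = young),
          data.frame(protein_id = ids, cohort = "aged", time = 14,
                     fraction = aged))
  }
  y <- c(rep(0.8, 30), rep(0.5, 30), rep(0.2, 30))
  # aged shifted down for short-lived, up for long-lived
  a <- y + c(rep(-0.05, 30), rep(0, 30), rep(0.05, 30))
  rr <- raw_ratio_check(mk_fr(y, a), tert)
  expect_true(rr$bidirectional)
  expect_lt(rr$table$median_diff[rr$table$tertile == "short"], 0)
  # identical fractions: all diffs zero, no flag
  rr0 <- raw_ratio_check(mk_fr(y, y), tert)
  expect_false(rr0$bidirectional)
  expect_equal(rr0$table$median_diff, c(0, 0))
  # undersized tertiles skipped with one warning each (short and long)
  expect_warning(
    expect_warning(raw_ratio_check(mk_fr(y, a)[c(1:5, 91:95), ], tert),
                   "skipped"),
    "skipped")
})

test_that("quadrant_classify maps signs with zeros unclassified", {
  expect_equal(quadrant_classify(0.3, 0.2), "up_up")
  expect_equal(quadrant_classify(-0.1, 0.5), "down_up")
  expect_equal(quadrant_classify(0.4, -0.2), "up_down")
  expect_equal(quadrant_classify(-0.4, -0.2), "down_down")
  expect_equal(quadrant_classify(0, 0.5), "unclassified")
  expect_equal(quadrant_classify(c(0.1, NA), c(-1, 1)),
               c("up_down", "unclassified"))
})

test_that("celltype_specificity requires a strict > 1 log2 margin", {
  expr <- rbind(A = c(neuron = 12, microglia = 10, astrocyte = 8,
                      oligodendrocyte = 5),
                B = c(10, 10, 10, 10),
                C = c(11, 10, 9, 9))  # margin exactly 1 -> none
  got <- celltype_specificity(expr)
  expect_equal(unname(got["A"]), "neuron")
  expect_equal(unname(got["B"]), "none")
  expect_equal(unname(got["C"]), "none")
  expect_error(celltype_specificity(expr[, 1:3]),
               class = "ta_format_error")
})
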