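# proteinGroups parsing, peptide summarization, half-life fitting, QC,
# and LFQ summarization.

toy_pg <- function() {
  data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = c("P1", "P2", "REV__X", "CON__Y", "P5"),
    `Gene names` = paste0("G", 1:5),
    `Ratio H/L d14_r1` = c(0.5, 0.8, 1, 1, "abc"),
    `Ratio H/L d21_r1` = c(0.9, 1.4, 1, 1, 2.0),
    Reverse = c("", "", "+", "", ""),
    `Potential contaminant` = c("", "", "", "+", ""),
    `Only identified by site` = c("", "", "", "", ""))
}

toy_map <- data.frame(sample = c("d14_r1", "d21_r1"), time = c(14, 21),
                      replicate = c(1L, 1L))

test_that("read_protein_groups drops flagged rows and handles bad cells", {
  f <- write_pg(toy_pg())
  pg <- read_protein_groups(f, toy_map)
  expect_setequal(unique(pg$time_courses$protein_id), c("P1", "P2", "P5"))
  expect_equal(pg$n_dropped, 2L)
  # malformed numeric cell became missing
  p5 <- pg$time_courses[pg$time_courses$protein_id == "P5", ]
  expect_true(is.na(p5$hl_ratio[p5$time == 14]))
  expect_equal(p5$hl_ratio[p5$time == 21], 2.0)
})

test_that("read_protein_groups excludes only-identified-by-site rows", {
  df <- toy_pg()
  df$`Only identified by site`[1] <- "+"
  pg <- read_protein_groups(write_pg(df), toy_map)
  expect_false("P1" %in% pg$time_courses$protein_id)
})

test_that("read_protein_groups format errors name the problem", {
  df <- toy_pg()
  names(df)[names(df) == "Ratio H/L d21_r1"] <- "bogus"
  expect_error(read_protein_groups(write_pg(df), toy_map),
               "Ratio H/L d21_r1", class = "ta_format_error")
  empty <- tempfile(); writeLines("Protein IDs", empty)
  expect_error(read_protein_groups(empty, toy_map),
               class = "ta_format_error")
  expect_error(read_protein_groups(tempfile(), toy_map),
               class = "ta_format_error")
})

test_that("summarize_peptide_ratios applies the >3-peptide median rule", {
  pep <- data.frame(
    protein_id = c(rep("A", 4), rep("B", 3), rep("C", 10)),
    sample = "s1",
    hl_ratio = c(1, 2, 4, 8, 1, 2, 4, rep(0.5, 10)))
  out <- summarize_peptide_ratios(pep)
  expect_equal(out$hl_ratio[out$protein_id == "A"], 3.0)
  expect_true(is.na(out$hl_ratio[out$protein_id == "B"]))  # n = 3 < 4
  expect_equal(out$n_peptides[out$protein_id == "B"], 3L)
  expect_equal(out$hl_ratio[out$protein_id == "C"], 0.5)
  # relaxed threshold keeps the 3-peptide protein
  out3 <- summarize_peptide_ratios(pep, min_peptides = 3L)
  expect_equal(out3$hl_ratio[out3$protein_id == "B"], 2.0)
  pep$hl_ratio[1] <- -1
  expect_error(summarize_peptide_ratios(pep), class = "ta_data_error")
})

test_that("fit_lifetime recovers noiseless half-lives with tight CIs", {
  for (th in c(2, 10, 48)) {
    cs <- make_course(th)
    ft <- fit_lifetime(cs$times, cs$ratios, PP)
    expect_equal(ft$halflife, th, tolerance = 1e-3 / th)
    expect_lt(ft$ci_upper - ft$ci_lower, 1e-2)
    expect_equal(ft$k * ft$halflife, log(2))
    expect_identical(ft$qc_flags, "")
  }
})

test_that("fit_lifetime censoring and error paths", {
  # no labeling at all: pinned slow
  ft <- fit_lifetime(c(0, 14, 14, 21, 21), c(0, 0, 0, 0, 0), PP)
  expect_equal(ft$halflife, 1000)
  expect_match(ft$qc_flags, "censored_slow")
  # labeling at precursor ceiling: pinned fast
  fmax <- precursor_fraction(c(14, 21), PP)
  ft2 <- fit_lifetime(c(0, 14, 21), c(0, fraction_to_ratio(fmax)), PP)
  expect_match(ft2$qc_flags, "censored_fast")
  expect_error(fit_lifetime(c(0, 14), c(0, NA), PP), class = "ta_fit_error")
  expect_error(fit_lifetime(c(0, 14), c(0, Inf), PP),
               class = "ta_data_error")
  expect_error(fit_lifetime(c(0, 14), c(0, -2), PP),
               class = "ta_data_error")
})

test_that("fit objective is order-invariant and deterministic", {
  cs <- make_course(12, cv = 0.15, seed = 9)
  ft1 <- fit_lifetime(cs$times, cs$ratios, PP)
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  ft2 <- fit_lifetime(cs$times[perm], cs$ratios[perm], PP)
  expect_equal(ft1$halflife, ft2$halflife)
  expect_equal(ft1$ci_lower, ft2$ci_lower)
  expect_identical(fit_lifetime(cs$times, cs$ratios, PP), ft1)
})

test_that("noiseless RSS profile has a single interior minimum", {
  cs <- make_course(15)
  fr <- ratio_to_fraction(cs$ratios)
  grid <- seq(log10(0.1), log10(1000), length.out = 200)
  rss <- turnoverAging:::.fit_rss(grid, cs$times, fr, PP)
  i <- which.min(rss)
  expect_gt(i, 1); expect_lt(i, 200)
  expect_true(all(diff(rss[seq_len(i)]) <= 1e-14))
  expect_true(all(diff(rss[i:200]) >= -1e-14))
})

test_that("increasing all observed ratios strictly decreases fitted half-life", {
  cs <- make_course(20, cv = 0.1, seed = 4)
  base <- fit_lifetime(cs$times, cs$ratios, PP)$halflife
  up <- fit_lifetime(cs$times, cs$ratios * 1.3, PP)$halflife
  expect_lt(up, base)
})

test_that("qc_filter removes single-timepoint and decreasing courses", {
  tc <- rbind(
    data.frame(protein_id = "A", cohort = "young", dataset = "cortex_hom",
               time = c(0, 14, 14), replicate = 0:2,
               hl_ratio = c(0, 0.5, 0.6)),             # one positive time
    data.frame(protein_id = "B", cohort = "young", dataset = "cortex_hom",
               time = c(0, 14, 21), replicate = 0:2,
               hl_ratio = c(0, fraction_to_ratio(0.4),
                            fraction_to_ratio(0.3))),  # decreasing labeling
    data.frame(protein_id = "C", cohort = "young", dataset = "cortex_hom",
               time = c(0, 14, 21), replicate = 0:2,
               hl_ratio = c(0, 0.5, 0.9)))
  rec <- fit_lifetimes(tc, PP)
  out <- qc_filter(rec, tc)
  expect_setequal(out$protein_id, "C")
  expect_match(rec$qc_flags[rec$protein_id == "A"], "single_timepoint")
})

test_that("qc_filter CI-width flags follow the documented arithmetic", {
  rec <- data.frame(protein_id = c("X", "Y"), cohort = "young",
                    dataset = "cortex_hom", halflife = c(10, 10),
                    k = log(2) / 10, ci_lower = c(4, 8),
                    ci_upper = c(19, 21), rss = 0, n_obs = 7L,
                    n_timepoints = 2L, qc_flags = "")
  tc <- data.frame(protein_id = rep(c("X", "Y"), each = 3),
                   cohort = "young", dataset = "cortex_hom",
                   time = c(0, 14, 21), replicate = 0L,
                   hl_ratio = c(0, 0.5, 0.9))
  out <- qc_filter(rec, tc)
  # X: width 15 > 10 -> wide_ci; c2 = 19 < 2*10 -> no upper flag
  expect_true(out$wide_ci[out$protein_id == "X"])
  expect_false(out$ci_upper_high[out$protein_id == "X"])
  # Y: width 13 > 10 -> wide_ci; c2 = 21 > 20 -> upper flag
  expect_true(out$ci_upper_high[out$protein_id == "Y"])
})

test_that("summarize_lfq_levels sums, median-centers, and averages", {
  lfq <- expand.grid(protein_id = c("P1", "P2", "P3"),
                     sample = c("s1", "s2"), stringsAsFactors = FALSE)
  lfq$cohort <- "young"; lfq$dataset <- "cortex_hom"
  lfq$time <- 14; lfq$replicate <- 1L
  base <- c(P1 = 8, P2 = 10, P3 = 40)
  lfq$lfq_h <- ifelse(lfq$sample == "s1", base[lfq$protein_id] * 0.375,
                      base[lfq$protein_id] * 2 * 0.375)
  lfq$lfq_l <- ifelse(lfq$sample == "s1", base[lfq$protein_id] * 0.625,
                      base[lfq$protein_id] * 2 * 0.625)
  # H=3, L=5 for P1/s1: summed to 8 before normalization
  expect_equal(lfq$lfq_h[lfq$protein_id == "P1" & lfq$sample == "s1"] +
                 lfq$lfq_l[lfq$protein_id == "P1" & lfq$sample == "s1"], 8)
  out <- summarize_lfq_levels(lfq)
  # the two samples differ by exactly x2 -> after centering both agree;
  # grand median of (8,10,40,16,20,80) is 18, sample medians 10 and 20
  expect_equal(out$lfq, unname(base[out$protein_id]) * 1.8)
  bad <- lfq; bad$lfq_h <- 0; bad$lfq_l <- 0
  expect_error(summarize_lfq_levels(bad), class = "ta_data_error")
})

test_that("abundance doubling survives the LFQ round trip", {
  cfg <- small_config(n_proteins = 40L, ratio_noise_cv = 0,
                      missing_rate = 0)
  truth <- generate_truth(cfg)
  # mark one high-abundance protein as doubled in the aged cohort
  target <- truth$protein_id[which.max(truth$true_abundance)][1]
  truth$true_abundance[truth$cohort == "aged" &
                         truth$protein_id == target] <-
    truth$true_abundance[truth$cohort == "aged" &
                           truth$protein_id == target] * 2
  obs <- simulate_observations(truth, PP, cfg)
  smp <- data.frame(sample = sprintf("d%02d_r%d",
                                     rep(c(0, 14, 21), each = 3),
                                     rep(1:3, 3)),
                    time = rep(c(0, 14, 21), each = 3),
                    replicate = rep(1:3, 3))
  get_lfq <- function(co) {
    f <- write_pg(obs[[paste0(co, ".cortex_hom")]])
    read_protein_groups(f, smp, cohort = co, dataset = "cortex_hom")$lfq
  }
  ab <- rbind(summarize_lfq_levels(get_lfq("young")),
              summarize_lfq_levels(get_lfq("aged")))
  a <- ab$lfq[ab$cohort == "aged" & ab$protein_id == target]
  y <- ab$lfq[ab$cohort == "young" & ab$protein_id == target]
  expect_equal(a / y, 2, tolerance = 1e-9)
})
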