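# Shared fixtures: all synthetic, built in code at test time.

PP <- precursor_pool_params()

# a small, fast cohort configuration; overrides via ...
small_config <- function(...) {
  defaults <- list(n_proteins = 80L, seed = 101L, missing_rate = 0.05,
                   effect_spec = effect_spec(n_rll = 5, n_rsl = 5))
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# one noiseless or noisy time course at a given half-life
make_course <- function(halflife, times = c(14, 21), reps = 3, cv = 0,
                        seed = 1) {
  f <- vapply(times, function(t)
    protein_heavy_fraction(t, log(2) / halflife, PP), numeric(1))
  ratios <- rep(f / (1 - f), each = reps)
  if (cv > 0) {
    set.seed(seed)
    ratios <- ratios * exp(stats::rnorm(length(ratios), 0,
                                        sqrt(log(1 + cv^2))))
  }
  list(times = c(0, rep(times, each = reps)), ratios = c(0, ratios))
}

# write a proteinGroups-dialect data.frame to a temp TSV
write_pg <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NaN")
  f
}

# truth -> per-cohort lifetime tables (protein_id, dataset, halflife)
truth_lifetimes <- function(truth, cohort) {
  d <- truth[truth$cohort == cohort, c("protein_id", "dataset",
                                       "true_halflife")]
  names(d)[3] <- "halflife"
  d
}

# generate, write, read back and fit one (cohort, dataset) slice
fit_cohort_dataset <- function(cfg, cohort, dataset = "cortex_hom",
                               options = list(compute_ci = FALSE)) {
  truth <- generate_truth(cfg)
  truth <- truth[truth$dataset == dataset, ]
  obs <- simulate_observations(truth, PP, cfg)
  smp <- data.frame(sample = sprintf("d%02d_r%d",
                                     rep(cfg$pulse_times,
                                         each = cfg$replicates_per_time),
                                     rep(seq_len(cfg$replicates_per_time),
                                         times = length(cfg$pulse_times))),
                    time = rep(cfg$pulse_times,
                               each = cfg$replicates_per_time),
                    replicate = rep(seq_len(cfg$replicates_per_time),
                                    times = length(cfg$pulse_times)))
  f <- write_pg(obs[[paste(cohort, dataset, sep = ".")]])
  tc <- read_protein_groups(f, smp, cohort = cohort,
                            dataset = dataset)$time_courses
  fit_lifetimes(tc, PP, options)
}
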