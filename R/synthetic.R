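# Synthetic pulse-labeling cohort generator.
#
# Emulates the data structure the analysis assumes: two cohorts (young, aged),
# four datasets (cortex/cerebellum homogenate and synaptic fraction), three
# biological replicates per pulse length at t in {0, 14, 21} days, log-normal
# lifetime distributions, multiplicative ratio noise, random missingness, and
# injected aging effects (global lengthening, targeted rLL/rSL subsets,
# lifetime compression). Output tables use the MaxQuant proteinGroups dialect
# so the parsers downstream are exercised end to end.

DATASETS <- c("cortex_hom", "cerebellum_hom", "cortex_syn", "cerebellum_syn")
COHORTS <- c("young", "aged")
CELL_TYPES <- c("neuron", "astrocyte", "microglia", "oligodendrocyte")

#' Targeted aging-effect specification for the synthetic cohort
#'
#' @param n_rll number of proteins given extra lifetime lengthening in the
#'   aged cohort (the injected relatively-longer-lived set).
#' @param n_rsl number given extra shortening (relatively shorter-lived).
#' @param extra_factor multiplier (> 0) applied (rLL) or divided (rSL).
#' @param compression_slope regression-to-the-mean exponent; aged lifetimes
#'   are pivoted around their median as
#'   `t_aged <- median * (t_aged / median)^(1 - slope)`. 0 disables it.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(n_rll = 25, n_rsl = 25, extra_factor = 1.5,
                        compression_slope = 0) {
  for (f in c("n_rll", "n_rsl"))
    if (get(f) < 0 || get(f) != round(get(f)))
      ta_config_error(sprintf("field '%s' must be a non-negative integer", f))
  stopifnot_scalar_number(extra_factor, "extra_factor", positive = TRUE)
  stopifnot_scalar_number(compression_slope, "compression_slope")
  structure(list(n_rll = as.integer(n_rll), n_rsl = as.integer(n_rsl),
                 extra_factor = as.numeric(extra_factor),
                 compression_slope = as.numeric(compression_slope)),
            class = "effect_spec")
}

#' Synthetic cohort configuration
#'
#' The stated world of the generator. Defaults: young homogenate median
#' lifetime 9.4 days (so that a global aging factor of 1.217 yields an aged
#' cortex median near 11.4 days), log10 sigma 0.35, a 20% synaptic-fraction
#' lengthening, three replicates per pulse length at 0/14/21 days, and 10%
#' multiplicative coefficient of variation on the observed H/L ratios.
#'
#' @param n_proteins number of proteins simulated.
#' @param young_median_halflife median young homogenate lifetime, days.
#' @param lognormal_sigma sd of log10(lifetime).
#' @param global_aging_factor multiplier applied to all aged lifetimes.
#' @param synaptic_factor multiplier for synaptic-fraction lifetimes.
#' @param pulse_times pulse lengths in days; must contain 0 and at least one
#'   positive time.
#' @param replicates_per_time biological replicates per pulse length.
#' @param ratio_noise_cv coefficient of variation of the multiplicative
#'   log-normal noise on observed H/L ratios (and LFQ intensities).
#' @param missing_rate probability, in \[0, 1), that a positive-time ratio
#'   cell is missing (missing completely at random).
#' @param effect_spec an [effect_spec()].
#' @param seed master integer seed; all child streams derive from it.
#' @param sequence_length_range min/max residues of generated sequences.
#' @param enrich_residue optional single residue letter enriched in rLL
#'   proteins' sequences (creates a detectable composition/log2FC coupling).
#' @param enrich_strength added probability mass for `enrich_residue`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_proteins = 500,
                          young_median_halflife = 9.4,
                          lognormal_sigma = 0.35,
                          global_aging_factor = 1.217,
                          synaptic_factor = 1.20,
                          pulse_times = c(0, 14, 21),
                          replicates_per_time = 3,
                          ratio_noise_cv = 0.10,
                          missing_rate = 0.05,
                          effect_spec = turnoverAging::effect_spec(),
                          seed = 1L,
                          sequence_length_range = c(150L, 1200L),
                          enrich_residue = NULL,
                          enrich_strength = 0.10) {
  if (n_proteins < 1 || n_proteins != round(n_proteins))
    ta_config_error("field 'n_proteins' must be a positive integer")
  stopifnot_scalar_number(young_median_halflife, "young_median_halflife",
                          positive = TRUE)
  stopifnot_scalar_number(lognormal_sigma, "lognormal_sigma", positive = TRUE)
  stopifnot_scalar_number(global_aging_factor, "global_aging_factor",
                          positive = TRUE)
  stopifnot_scalar_number(synaptic_factor, "synaptic_factor", positive = TRUE)
  if (!is.numeric(pulse_times) || !any(pulse_times == 0) ||
      !any(pulse_times > 0) || any(pulse_times < 0))
    ta_config_error(
      "field 'pulse_times' must contain 0 and at least one positive time")
  if (replicates_per_time < 1 ||
      replicates_per_time != round(replicates_per_time))
    ta_config_error("field 'replicates_per_time' must be a positive integer")
  if (!is.numeric(ratio_noise_cv) || ratio_noise_cv < 0)
    ta_config_error("field 'ratio_noise_cv' must be >= 0")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    ta_config_error("field 'missing_rate' must lie in [0, 1)")
  if (!inherits(effect_spec, "effect_spec"))
    effect_spec <- do.call(turnoverAging::effect_spec, as.list(effect_spec))
  if (effect_spec$n_rll + effect_spec$n_rsl > n_proteins)
    ta_config_error("field 'effect_spec': n_rll + n_rsl exceeds n_proteins")
  if (length(sequence_length_range) != 2L ||
      sequence_length_range[1] < 1 ||
      sequence_length_range[2] < sequence_length_range[1])
    ta_config_error("field 'sequence_length_range' must be c(min, max), min >= 1")
  if (!is.null(enrich_residue) &&
      (!is.character(enrich_residue) || nchar(enrich_residue) != 1L ||
       !enrich_residue %in% AA_ALPHABET))
    ta_config_error("field 'enrich_residue' must be a standard residue letter")
  structure(list(
    n_proteins = as.integer(n_proteins),
    young_median_halflife = as.numeric(young_median_halflife),
    lognormal_sigma = as.numeric(lognormal_sigma),
    global_aging_factor = as.numeric(global_aging_factor),
    synaptic_factor = as.numeric(synaptic_factor),
    pulse_times = sort(unique(as.numeric(pulse_times))),
    replicates_per_time = as.integer(replicates_per_time),
    ratio_noise_cv = as.numeric(ratio_noise_cv),
    missing_rate = as.numeric(missing_rate),
    effect_spec = effect_spec,
    seed = as.integer(seed),
    sequence_length_range = as.integer(sequence_length_range),
    enrich_residue = enrich_residue,
    enrich_strength = as.numeric(enrich_strength)
  ), class = "cohort_config")
}

#' Serialize / deserialize a cohort configuration (JSON)
#'
#' Round-trips exactly: `read_cohort_config(write_cohort_config(cfg, f))`
#' reproduces identical values.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$effect_spec <- unclass(x$effect_spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$effect_spec <- do.call(effect_spec, as.list(x$effect_spec))
  do.call(cohort_config, x)
}

#' Generate ground-truth lifetimes, abundances, and cell types
#'
#' Young homogenate lifetimes are drawn log-normal (base-10 parameters from
#' the config); the aged cohort is the young one times
#' `global_aging_factor`, after which the injected rLL proteins are
#' multiplied and rSL proteins divided by `extra_factor`, and compression is
#' applied as a power-law pivot around the aged median. Both homogenate
#' datasets share a protein's homogenate lifetime; synaptic datasets are the
#' homogenate times `synaptic_factor`. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a data.frame in long form with columns `protein_id`, `gene_name`,
#'   `cohort`, `dataset`, `true_halflife`, `effect_label`, `true_abundance`,
#'   `cell_type`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_proteins
  es <- config$effect_spec
  with_seed(child_seed(config$seed, "truth"), {
    protein_id <- sprintf("SYNP%05d", seq_len(n))
    gene_name <- sprintf("Gene%05d", seq_len(n))
    young_hom <- 10^stats::rnorm(n, log10(config$young_median_halflife),
                                 config$lognormal_sigma)
    effect_label <- rep("none", n)
    idx <- sample.int(n, es$n_rll + es$n_rsl)
    if (es$n_rll > 0) effect_label[idx[seq_len(es$n_rll)]] <- "rll"
    if (es$n_rsl > 0) effect_label[idx[es$n_rll + seq_len(es$n_rsl)]] <- "rsl"

    aged_hom <- young_hom * config$global_aging_factor
    aged_hom[effect_label == "rll"] <- aged_hom[effect_label == "rll"] *
      es$extra_factor
    aged_hom[effect_label == "rsl"] <- aged_hom[effect_label == "rsl"] /
      es$extra_factor
    if (es$compression_slope != 0) {
      med <- stats::median(aged_hom)
      aged_hom <- med * (aged_hom / med)^(1 - es$compression_slope)
    }

    abundance_young <- 10^stats::rnorm(n, 6, 0.5)
    abundance_aged <- abundance_young
    cell_type <- sample(c(CELL_TYPES, "none"), n, replace = TRUE,
                        prob = c(0.30, 0.15, 0.10, 0.10, 0.35))

    hom <- list(young = young_hom, aged = aged_hom)
    rows <- list()
    for (cohort in COHORTS) {
      ab <- if (cohort == "young") abundance_young else abundance_aged
      for (dataset in DATASETS) {
        hl <- hom[[cohort]]
        if (grepl("_syn$", dataset)) hl <- hl * config$synaptic_factor
        rows[[paste(cohort, dataset)]] <- data.frame(
          protein_id = protein_id, gene_name = gene_name,
          cohort = cohort, dataset = dataset,
          true_halflife = hl, effect_label = effect_label,
          true_abundance = ab, cell_type = cell_type,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

.sample_names <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates_per_time),
                      time = config$pulse_times)
  data.frame(sample = sprintf("d%02d_r%d", grid$time, grid$replicate),
             time = grid$time, replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Simulate proteinGroups-dialect observation tables
#'
#' For each protein, replicate and pulse time `t`, the expected labeled
#' fraction is [protein_heavy_fraction()] with `k = ln(2)/true_halflife`;
#' the observed H/L ratio is `f/(1-f)` times multiplicative log-normal noise
#' with CV `ratio_noise_cv`. t = 0 columns are exactly 0 (unlabeled
#' baseline) and are never made missing; positive-time cells are removed
#' completely at random with probability `missing_rate`. LFQ H/L intensity
#' pairs derive from `true_abundance` split by the labeled fraction, with
#' the same multiplicative noise on the total. Three decoy rows (REV__,
#' CON__, only-identified-by-site) are appended to exercise the parsers.
#'
#' @param truth output of [generate_truth()].
#' @param params a [precursor_pool_params()].
#' @param config the [cohort_config()] used for `truth`.
#' @return named list of data.frames, one per `"cohort.dataset"`, in the
#'   proteinGroups TSV dialect (see [read_protein_groups()]).
#' @export
simulate_observations <- function(truth, params = precursor_pool_params(),
                                  config) {
  stopifnot(inherits(config, "cohort_config"), nrow(truth) > 0)
  params <- as_precursor_pool_params(params)
  smp <- .sample_names(config)
  sdlog <- cv_to_sdlog(config$ratio_noise_cv)
  out <- list()
  for (cohort in COHORTS) {
    for (dataset in DATASETS) {
      tr <- truth[truth$cohort == cohort & truth$dataset == dataset, ]
      if (nrow(tr) == 0) next
      with_seed(child_seed(config$seed, "obs", cohort, dataset), {
        n <- nrow(tr)
        tab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                          `Protein IDs` = tr$protein_id,
                          `Gene names` = tr$gene_name)
        ratio_cols <- list(); lfqh_cols <- list(); lfql_cols <- list()
        for (j in seq_len(nrow(smp))) {
          t <- smp$time[j]
          if (t == 0) {
            ratio <- rep(0, n)
            f <- rep(0, n)
          } else {
            k <- log(2) / tr$true_halflife
            f <- vapply(k, function(ki)
              protein_heavy_fraction(t, ki, params), numeric(1))
            if (any(f >= 1))
              ta_internal_error("simulate_observations: fraction >= 1")
            noise <- if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else 1
            ratio <- (f / (1 - f)) * noise
            if (config$missing_rate > 0) {
              miss <- stats::runif(n) < config$missing_rate
              ratio[miss] <- NA_real_
            }
          }
          total <- tr$true_abundance *
            (if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else 1)
          ratio_cols[[smp$sample[j]]] <- ratio
          lfqh_cols[[smp$sample[j]]] <- total * f
          lfql_cols[[smp$sample[j]]] <- total * (1 - f)
        }
        for (s in names(ratio_cols))
          tab[[paste("Ratio H/L", s)]] <- ratio_cols[[s]]
        for (s in names(lfqh_cols))
          tab[[paste("LFQ intensity H", s)]] <- lfqh_cols[[s]]
        for (s in names(lfql_cols))
          tab[[paste("LFQ intensity L", s)]] <- lfql_cols[[s]]
        tab$Reverse <- ""
        tab$`Potential contaminant` <- ""
        tab$`Only identified by site` <- ""
        # decoy rows exercising the parser's filters
        decoys <- tab[rep(1L, 3L), ]
        decoys$`Protein IDs` <- c("REV__SYND0001", "CON__SYND0002",
                                  "SYND0003")
        decoys$`Gene names` <- c("RevDecoy", "ConDecoy", "SiteDecoy")
        decoys$Reverse <- c("+", "", "")
        decoys$`Potential contaminant` <- c("", "+", "")
        decoys$`Only identified by site` <- c("", "", "+")
        tab <- rbind(tab, decoys)
        rownames(tab) <- NULL
        out[[paste(cohort, dataset, sep = ".")]] <- tab
      })
    }
  }
  out
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# baseline residue sampling weights, loosely modeled on vertebrate
# proteome-average composition
.AA_BASE_FREQ <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.8, C = 2.2, Q = 4.8,
                   E = 7.1, G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7,
                   M = 2.2, F = 3.6, P = 6.3, S = 8.3, T = 5.4, W = 1.2,
                   Y = 2.7, V = 6.0)

#' Generate protein sequences and annotation table for the synthetic cohort
#'
#' One random sequence per protein (length uniform in the configured range,
#' residues drawn from a fixed proteome-like composition). When
#' `config$enrich_residue` is set, rLL proteins receive extra probability
#' mass for that residue, creating a detectable composition/log2FC coupling.
#' The annotation table carries fabricated glycosylation-site counts,
#' disorder fractions, aggregation scores, and a four-column cell-type
#' expression matrix (log2 scale) in which a protein's assigned type exceeds
#' every other type by more than 1 log2 unit.
#'
#' @param truth output of [generate_truth()].
#' @param config the [cohort_config()] used for `truth`.
#' @return list with `sequences` (a [Biostrings::AAStringSet]) and
#'   `annotations` (a data.frame keyed by `protein_id`).
#' @export
generate_sequences <- function(truth, config) {
  stopifnot(inherits(config, "cohort_config"), nrow(truth) > 0)
  prot <- unique(truth[truth$cohort == "young" &
                         truth$dataset == "cortex_hom",
                       c("protein_id", "effect_label", "cell_type")])
  n <- nrow(prot)
  with_seed(child_seed(config$seed, "sequences"), {
    lens <- sample(seq(config$sequence_length_range[1],
                       config$sequence_length_range[2]), n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      w <- .AA_BASE_FREQ
      if (!is.null(config$enrich_residue) &&
          prot$effect_label[i] == "rll") {
        w[config$enrich_residue] <- w[config$enrich_residue] +
          config$enrich_strength * sum(w)
      }
      seqs[i] <- paste(sample(AA_ALPHABET, lens[i], replace = TRUE,
                              prob = w), collapse = "")
    }
    names(seqs) <- prot$protein_id

    expr <- matrix(stats::rnorm(n * 4, 8, 1), nrow = n,
                   dimnames = list(prot$protein_id, CELL_TYPES))
    for (i in seq_len(n)) {
      ct <- prot$cell_type[i]
      if (ct == "none") {
        base <- expr[i, 1]
        expr[i, ] <- base + stats::runif(4, -0.45, 0.45)
      } else {
        others <- setdiff(CELL_TYPES, ct)
        expr[i, ct] <- max(expr[i, others]) + 1 + stats::runif(1, 0.1, 1.5)
      }
    }
    ann <- data.frame(
      protein_id = prot$protein_id,
      n_glyco = stats::rpois(n, 2),
      disorder_fraction = stats::rbeta(n, 2, 5),
      aggregation_score = stats::rnorm(n, 0, 1),
      stringsAsFactors = FALSE)
    ann <- cbind(ann, as.data.frame(expr))
    rownames(ann) <- NULL
    list(sequences = Biostrings::AAStringSet(seqs), annotations = ann)
  })
}

#' Write synthetic cohort outputs to disk
#'
#' Writes one proteinGroups-dialect TSV per (cohort, dataset), the truth
#' table, a FASTA (wrapped at 60 columns), the annotation TSV, and a sample
#' map TSV consumable by [read_protein_groups()].
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @param params a [precursor_pool_params()].
#' @return invisibly, a named list of the written file paths.
#' @export
simulate_cohort <- function(config, outdir,
                            params = precursor_pool_params()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth(config)
  obs <- simulate_observations(truth, params, config)
  seqs <- generate_sequences(truth, config)
  paths <- list()
  write_tsv <- function(df, f) {
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NaN")
    f
  }
  paths$truth <- write_tsv(truth, file.path(outdir, "truth.tsv"))
  for (nm in names(obs)) {
    f <- file.path(outdir, paste0("proteinGroups_", nm, ".tsv"))
    paths[[paste0("obs.", nm)]] <- write_tsv(obs[[nm]], f)
  }
  smp <- .sample_names(config)
  paths$sample_map <- write_tsv(smp, file.path(outdir, "sample_map.tsv"))
  fasta <- file.path(outdir, "sequences.fasta")
  Biostrings::writeXStringSet(seqs$sequences, fasta, width = 60L)
  paths$fasta <- fasta
  paths$annotations <- write_tsv(seqs$annotations,
                                 file.path(outdir, "annotations.tsv"))
  paths$config <- write_cohort_config(config, file.path(outdir, "config.json"))
  invisible(paths)
}
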