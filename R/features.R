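# Sequence-derived biochemical features: composition, molecular weight,
# isoelectric point, GRAVY, and average biosynthetic cost (avECPA), plus
# assembly of the per-protein feature table with optional annotations.
#
# All shipped features are composition-based (permutation-invariant); the
# constant tables below are documented, replaceable inputs.

# Kyte & Doolittle (1982) hydropathy scale
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# EMBOSS pKa set for ionizable groups (side chains plus termini)
PKA_TABLE <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# average (isotope-abundance-weighted) residue masses, Da; +water for a chain
AA_MONOMER_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                     C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
                     H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                     M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                     T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

.clean_sequence <- function(sequence, caller) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0)
    ta_domain_error(sprintf("%s: sequence must be a non-empty string", caller))
  res <- strsplit(toupper(sequence), "")[[1]]
  nonstd <- !(res %in% AA_ALPHABET)
  if (any(nonstd)) {
    warning(sprintf("%s: skipping %d non-standard residue(s): %s", caller,
                    sum(nonstd), paste(unique(res[nonstd]), collapse = ",")))
    res <- res[!nonstd]
  }
  if (length(res) == 0)
    ta_domain_error(sprintf("%s: no standard residues in sequence", caller))
  res
}

#' Amino-acid composition of a sequence
#'
#' Counts per residue divided by the number of counted residues.
#' Non-standard letters (X, U, B, Z, ...) are skipped with a warning and
#' excluded from the denominator.
#'
#' @param sequence amino-acid string.
#' @return list with `composition` (named vector of 20 fractions summing
#'   to 1) and `length` (number of counted residues).
#' @export
aa_composition <- function(sequence) {
  res <- .clean_sequence(sequence, "aa_composition")
  counts <- table(factor(res, levels = AA_ALPHABET))
  comp <- stats::setNames(as.numeric(counts) / length(res), AA_ALPHABET)
  list(composition = comp, length = length(res))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence.
#'
#' @param sequence amino-acid string.
#' @return dimensionless scalar.
#' @export
compute_gravy <- function(sequence) {
  res <- .clean_sequence(sequence, "compute_gravy")
  mean(KYTE_DOOLITTLE[res])
}

# net charge at a given pH (Henderson-Hasselbalch over ionizable groups)
protein_net_charge <- function(counts, pH, pka = PKA_TABLE) {
  pos <- c(Nterm = 1, counts["K"], counts["R"], counts["H"])
  names(pos) <- c("Nterm", "K", "R", "H")
  neg <- c(Cterm = 1, counts["D"], counts["E"], counts["C"], counts["Y"])
  names(neg) <- c("Cterm", "D", "E", "C", "Y")
  sum(pos / (1 + 10^(pH - pka[names(pos)]))) -
    sum(neg / (1 + 10^(pka[names(neg)] - pH)))
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' The net charge is computed by Henderson-Hasselbalch over the ionizable
#' groups (D, E, C, Y, H, K, R and the two termini) with the shipped EMBOSS
#' pKa set; because charge is strictly decreasing in pH, the root in
#' (0, 14) is found by bisection to `tol` pH units.
#'
#' @param sequence amino-acid string.
#' @param pka named pKa vector (`Nterm`, `Cterm`, side chains); defaults to
#'   the EMBOSS values.
#' @param tol bisection tolerance in pH units.
#' @return the pI in pH units.
#' @export
compute_pI <- function(sequence, pka = PKA_TABLE, tol = 1e-4) {
  res <- .clean_sequence(sequence, "compute_pI")
  counts <- table(factor(res, levels = AA_ALPHABET))
  counts <- stats::setNames(as.numeric(counts), AA_ALPHABET)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Load the shipped per-residue biosynthetic cost table
#'
#' The installed default (`aa_cost_synthetic.tsv`) carries published ATP
#' synthesis costs in `energy_cost` and a clearly-marked synthetic
#' placeholder `decay_normalized_metric` that reproduces the qualitative
#' expensive/affordable classes (C, D, N expensive). The file is the single
#' source of truth; point `path` at a replacement to change the cost model.
#'
#' @param path TSV with columns `aa`, `energy_cost`,
#'   `decay_normalized_metric`; `#` lines are comments.
#' @return data.frame with one row per standard residue.
#' @export
load_cost_table <- function(path = system.file("extdata",
                                               "aa_cost_synthetic.tsv",
                                               package = "turnoverAging")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!setequal(tab$aa, AA_ALPHABET) || nrow(tab) != 20L)
    ta_format_error("load_cost_table: need exactly the 20 standard residues")
  if (any(tab$energy_cost <= 0) || any(tab$decay_normalized_metric <= 0))
    ta_format_error("load_cost_table: all cost values must be positive")
  tab
}

#' Average biosynthetic energy cost per residue (avECPA)
#'
#' Mean of per-residue `energy_cost` over the sequence.
#'
#' @param sequence amino-acid string.
#' @param costs cost table from [load_cost_table()].
#' @return cost units per residue.
#' @export
compute_avECPA <- function(sequence, costs = load_cost_table()) {
  res <- .clean_sequence(sequence, "compute_avECPA")
  cost <- stats::setNames(costs$energy_cost, costs$aa)
  if (any(!(res %in% names(cost))))
    ta_domain_error("compute_avECPA: residue missing from cost table")
  mean(cost[res])
}

#' Classify amino acids as metabolically expensive or affordable
#'
#' Residues whose decay-normalized cost metric is strictly above `hi`
#' (default 60) are expensive; strictly below `lo` (default 20) affordable;
#' the rest unclassified.
#'
#' @param costs cost table from [load_cost_table()].
#' @param hi,lo classification thresholds, `hi > lo`.
#' @return list with character vectors `expensive`, `affordable`,
#'   `unclassified`.
#' @export
classify_amino_acids <- function(costs = load_cost_table(), hi = 60, lo = 20) {
  if (hi <= lo)
    ta_config_error("classify_amino_acids: need hi > lo")
  m <- stats::setNames(costs$decay_normalized_metric, costs$aa)
  list(expensive = sort(names(m)[m > hi]),
       affordable = sort(names(m)[m < lo]),
       unclassified = sort(names(m)[m >= lo & m <= hi]))
}

#' Build the per-protein feature table from FASTA (+ optional annotations)
#'
#' One row per protein with length, molecular weight (average masses), pI,
#' GRAVY, the 20 composition fractions (columns `frac_<residue>`), avECPA,
#' and the expensive/affordable composition fractions under the shipped
#' cost classes. Optional annotation columns are left-joined on
#' `protein_id`; proteins without annotations keep missing values.
#'
#' @param fasta path to a protein FASTA file.
#' @param annotations optional data.frame (or TSV path) keyed by
#'   `protein_id`.
#' @param costs cost table from [load_cost_table()].
#' @return data.frame, one row per FASTA record.
#' @export
build_feature_table <- function(fasta, annotations = NULL,
                                costs = load_cost_table()) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    ta_format_error("build_feature_table: duplicate FASTA ids")
  cls <- classify_amino_acids(costs)
  cost <- stats::setNames(costs$energy_cost, costs$aa)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    comp <- aa_composition(s)
    fr <- comp$composition
    data.frame(
      protein_id = ids[i],
      length = comp$length,
      molecular_weight = sum(fr * AA_MONOMER_MASS[names(fr)]) * comp$length +
        WATER_MASS,
      pI = compute_pI(s),
      gravy = compute_gravy(s),
      avECPA = sum(fr * cost[names(fr)]),
      frac_expensive = sum(fr[cls$expensive]),
      frac_affordable = sum(fr[cls$affordable]),
      t(stats::setNames(fr, paste0("frac_", names(fr)))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    if (is.character(annotations))
      annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
    if (anyDuplicated(annotations$protein_id))
      ta_format_error("build_feature_table: duplicate annotation ids")
    out <- merge(out, annotations, by = "protein_id", all.x = TRUE,
                 sort = TRUE)
  }
  out[order(out$protein_id), ]
}
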