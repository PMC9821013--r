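#' Specification of the synthetic KRAS G12C-like dataset generator
#'
#' The generator emulates the statistical structure of the curated
#' KRAS G12C activity dataset so every pipeline stage can be exercised
#' offline: an 1188-column conjoint fingerprint block (881 binary bits at a
#' realistic bit density plus 307 small non-negative counts), and pIC50
#' values produced by a sparse additive bit-activity relationship plus
#' Gaussian noise. The defaults are calibrated so the simulated pIC50
#' distribution matches the real dataset's training summary (mean 6.56,
#' SD 1.22), so actives (pIC50 >= 6) form the majority class as in the
#' curated data, and so the signal-to-noise ratio is compatible with the
#' external predictivity reported for the real dataset (Q2 near 0.76 and
#' external MAE below 0.5), allowing for the fraction of planted signal a
#' greedy tree ensemble typically leaves unexplained.
#'
#' With the default planted weights and bit density 0.35 on planted bits,
#' the deterministic signal has mean `intercept + 1.54` and variance
#' `0.2275 * sum(w^2) = 1.38`; adding `noise_sd = 0.4` gives a total SD of
#' about 1.24 and, with `intercept = 5.02`, a mean of 6.56.
#'
#' @param n_compounds Number of compounds to simulate.
#' @param n_binary Number of binary fingerprint bits.
#' @param n_counts Number of count fingerprint columns.
#' @param planted_features Integer indices (into the binary block) of the
#'   bits that carry activity signal.
#' @param planted_weights Additive pIC50 effect of each planted bit.
#' @param planted_density Bernoulli rate of the planted bits.
#' @param bit_density Bernoulli rate of the background bits.
#' @param count_mean Poisson mean of the count columns.
#' @param intercept Baseline pIC50 of a compound with no planted bits set.
#' @param noise_sd SD of the Gaussian pIC50 noise.
#' @param seed Integer seed; everything the generator emits is a pure
#'   function of the spec including this seed.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_compounds = 1255,
                           n_binary = 881,
                           n_counts = 307,
                           planted_features = 1:10,
                           planted_weights = c(1.1, 0.9, -0.9, 0.8, 0.8,
                                               -0.7, 0.7, 0.6, 0.6, 0.5),
                           planted_density = 0.35,
                           bit_density = 0.12,
                           count_mean = 1.5,
                           intercept = 5.02,
                           noise_sd = 0.4,
                           seed = 20221230) {
  stopifnot(n_compounds >= 1, n_binary >= 0, n_counts >= 0,
            length(planted_features) == length(planted_weights),
            noise_sd >= 0, bit_density > 0, bit_density < 1,
            planted_density > 0, planted_density < 1)
  if (length(planted_features) == 0) {
    stop("at least one planted feature is required")
  }
  if (any(planted_features < 1 | planted_features > n_binary)) {
    stop("planted features must index the binary block (1..n_binary)")
  }
  structure(list(n_compounds = n_compounds, n_binary = n_binary,
                 n_counts = n_counts, planted_features = planted_features,
                 planted_weights = planted_weights,
                 planted_density = planted_density,
                 bit_density = bit_density, count_mean = count_mean,
                 intercept = intercept, noise_sd = noise_sd, seed = seed),
            class = "generator_spec")
}

draw_features <- function(spec, n) {
  schema <- conjoint_schema(spec$n_binary, spec$n_counts)
  density <- rep(spec$bit_density, spec$n_binary)
  density[spec$planted_features] <- spec$planted_density
  bits <- matrix(stats::rbinom(n * spec$n_binary, 1,
                               rep(density, each = n)),
                 nrow = n)
  counts <- matrix(stats::rpois(n * spec$n_counts, spec$count_mean), nrow = n)
  values <- cbind(bits, counts)
  colnames(values) <- schema$name
  list(values = values, schema = schema)
}

signal_of <- function(spec, values) {
  planted_cols <- spec$planted_features
  drop(spec$intercept +
         values[, planted_cols, drop = FALSE] %*% spec$planted_weights)
}

#' Generate a synthetic activity dataset with known ground truth
#'
#' Draws fingerprints by the generator law, computes the noiseless planted
#' signal, adds Gaussian noise, and returns both the observables and the
#' ground truth needed for parameter-recovery tests. Deterministic per
#' seed.
#'
#' @param spec A [generator_spec()].
#' @return A list with `features` (a `feature_matrix`), `pic50`,
#'   `records` (compound table with ids, pIC50, activity), and `truth`
#'   (planted indices and weights, noiseless signal, noise draws).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- spec$n_compounds
  fs <- draw_features(spec, n)
  signal <- signal_of(spec, fs$values)
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  pic50 <- signal + noise
  ids <- sprintf("SYN%05d", seq_len(n))
  rownames(fs$values) <- ids
  features <- structure(list(values = fs$values, schema = fs$schema,
                             provider_name = "synthetic_generator",
                             excluded = data.frame(compound_id = character(),
                                                   reason = character())),
                        class = "feature_matrix")
  records <- data.frame(compound_id = ids, pic50 = pic50,
                        activity = label_activity(pic50),
                        stringsAsFactors = FALSE)
  truth <- list(planted_features = spec$planted_features,
                planted_names = fs$schema$name[spec$planted_features],
                planted_weights = spec$planted_weights,
                signal = signal, noise = noise, spec = spec)
  list(features = features, pic50 = pic50, records = records, truth = truth)
}

#' Emit a raw activity table in the curation input dialect
#'
#' Wraps a synthetic dataset as the delimited activity table the curation
#' stage consumes, optionally planting curation work: duplicate records
#' (same structure key, strictly weaker potency, so deduplication removes
#' exactly them) and over-heavy records (molecular weight above 1000 Da).
#' Molecular weights are drawn to match the real dataset's summary
#' (539 +/- 83 Da); synthetic structure keys stand in for canonical SMILES
#' since the generator emits fingerprints, not structures.
#'
#' @param spec A [generator_spec()].
#' @param n_duplicates Number of duplicate records to interleave.
#' @param n_heavy Number of over-1000-Da records to append.
#' @return A list with `table` (raw activity data frame of
#'   `n_compounds + n_duplicates + n_heavy` rows), `dataset` (the clean
#'   [generate_dataset()] output the table was derived from), and
#'   `expected_n_curated`.
#' @export
generate_activity_table <- function(spec, n_duplicates = 45, n_heavy = 20) {
  dataset <- generate_dataset(spec)
  old <- local_seed(spec$seed + 1L)
  on.exit(restore_seed(old), add = TRUE)
  rec <- dataset$records
  n <- nrow(rec)
  tbl <- data.frame(compound_id = rec$compound_id,
                    smiles = paste0("SYNTHETIC[", rec$compound_id, "]"),
                    structure_key = paste0("KEY-", rec$compound_id),
                    ic50 = 10^(-rec$pic50) * 1e9, # nM
                    ic50_units = "nM",
                    molecular_weight = pmin(
                      stats::rnorm(n, 539.41, 83.12), 1000),
                    source = "synthetic",
                    stringsAsFactors = FALSE)
  if (n_duplicates > 0) {
    dup_of <- sample(n, n_duplicates, replace = n_duplicates > n)
    dup <- tbl[dup_of, , drop = FALSE]
    dup$compound_id <- sprintf("DUP%05d", seq_len(n_duplicates))
    dup$ic50 <- dup$ic50 * stats::runif(n_duplicates, 1.5, 20) # weaker
    tbl <- rbind(tbl, dup)
  }
  if (n_heavy > 0) {
    heavy_ids <- sprintf("HVY%05d", seq_len(n_heavy))
    heavy <- data.frame(compound_id = heavy_ids,
                        smiles = paste0("SYNTHETIC[", heavy_ids, "]"),
                        structure_key = paste0("KEY-", heavy_ids),
                        ic50 = 10^(-stats::rnorm(n_heavy, 6.56, 1.22)) * 1e9,
                        ic50_units = "nM",
                        molecular_weight = stats::runif(n_heavy, 1001, 1400),
                        source = "synthetic",
                        stringsAsFactors = FALSE)
    tbl <- rbind(tbl, heavy)
  }
  tbl <- tbl[sample(nrow(tbl)), , drop = FALSE]
  rownames(tbl) <- NULL
  list(table = tbl, dataset = dataset, expected_n_curated = n)
}

#' Generate a candidate screening library with planted actives
#'
#' Emulates a covalent-drug library screened against the trained models: 67
#' candidates by default, drawn from the same feature law as the training
#' compounds, of which a known subset (7 by default) are true hits and the
#' rest are clearly inactive. Composition is controlled by rejection
#' sampling on the noiseless planted signal: hits must clear the activity
#' threshold, the remainder must sit at least `margin` pIC50 units below
#' it — the few-true-hits structure of a repurposing library, whose
#' members are mostly unambiguous non-binders. True activity is derivable
#' from the ground truth (the noiseless signal).
#'
#' @param spec The [generator_spec()] shared with the training generator.
#' @param n_candidates Library size.
#' @param n_active Number of true hits.
#' @param threshold Activity threshold on the noiseless signal.
#' @param margin Inactive candidates have signal below `threshold - margin`.
#' @return A list with `candidates` (name, annotation columns), `features`
#'   (a `feature_matrix`), and `truth` (signal and true class per
#'   candidate).
#' @export
generate_candidate_library <- function(spec, n_candidates = 67,
                                       n_active = 7, threshold = 6,
                                       margin = 1.5) {
  stopifnot(inherits(spec, "generator_spec"), n_active <= n_candidates)
  old <- local_seed(spec$seed + 2L)
  on.exit(restore_seed(old), add = TRUE)
  fs <- draw_features(spec, n_candidates)
  values <- fs$values
  draw_row <- function(accept) {
    repeat {
      row <- draw_features(spec, 1)$values
      if (accept(signal_of(spec, row))) return(row)
    }
  }
  for (i in seq_len(n_candidates)) {
    values[i, ] <- if (i <= n_active) {
      draw_row(function(s) s >= threshold)
    } else {
      draw_row(function(s) s <= threshold - margin)
    }
  }
  values <- values[sample(n_candidates), , drop = FALSE]
  names <- sprintf("CAND%03d", seq_len(n_candidates))
  rownames(values) <- names
  signal <- signal_of(spec, values)
  candidates <- data.frame(compound_id = names, name = names,
                           warhead = "synthetic",
                           primary_target = "synthetic",
                           stringsAsFactors = FALSE)
  features <- structure(list(values = values, schema = fs$schema,
                             provider_name = "synthetic_generator",
                             excluded = data.frame(compound_id = character(),
                                                   reason = character())),
                        class = "feature_matrix")
  truth <- data.frame(compound_id = names, signal = signal,
                      true_class = label_activity(signal, threshold),
                      stringsAsFactors = FALSE)
  list(candidates = candidates, features = features, truth = truth)
}

#' SMILES fixtures of reference molecules
#'
#' A small set of well-known molecules (including covalent EGFR-family
#' inhibitors carrying the Michael-acceptor warhead) used by the curation
#' and drug-likeness tests.
#'
#' @return A data frame with `compound_id`, `name`, and `smiles`.
#' @export
fixture_smiles <- function() {
  path <- system.file("extdata", "fixture_molecules.csv",
                      package = "qsarboost", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
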