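#' Convert an IC50 concentration to pIC50
#'
#' `pIC50 = -log10(IC50)` with the IC50 expressed in molar units.
#'
#' @param ic50 IC50 values in molar concentration; must be positive.
#' @return pIC50 values (`-log10` molar).
#' @export
#' @examples
#' to_pic50(1e-6)     # 6
#' to_pic50(3.02e-8)  # 7.52
to_pic50 <- function(ic50) {
  if (length(ic50) == 0 || anyNA(ic50)) {
    stop("IC50 values are missing; cannot convert to pIC50")
  }
  if (any(ic50 <= 0)) {
    stop("IC50 must be a positive concentration to take -log10")
  }
  -log10(ic50)
}

#' Convert an IC50 value to molar units
#'
#' @param value Concentration values.
#' @param units One of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"` (recycled).
#' @return Values in molar.
#' @export
ic50_to_molar <- function(value, units = "nM") {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  units <- rep_len(as.character(units), length(value))
  bad <- setdiff(unique(units), names(scale))
  if (length(bad) > 0) stop("unknown concentration units: ",
                            paste(bad, collapse = ", "))
  value * unname(scale[units])
}

#' Label compounds active or inactive by pIC50
#'
#' Active means pIC50 greater than or equal to the threshold (6 by default,
#' i.e. IC50 of 1 micromolar or better).
#'
#' @param pic50 Numeric pIC50 values (finite).
#' @param threshold Activity cutoff in pIC50 units.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
#' @examples
#' label_activity(c(6, 5.99, 7.43))  # active, inactive, active
label_activity <- function(pic50, threshold = 6) {
  if (any(!is.finite(pic50))) stop("pIC50 values must be finite")
  ifelse(pic50 >= threshold, "active", "inactive")
}

#' Count Lipinski rule-of-five violations
#'
#' One violation per rule broken: MW > 500 Da, SLogP > 5, more than 5
#' hydrogen-bond donors, more than 10 hydrogen-bond acceptors.
#'
#' @param molecular_weight Molecular weight in Da.
#' @param slogp Calculated LogP.
#' @param h_bond_donors Hydrogen-bond donor count.
#' @param h_bond_acceptors Hydrogen-bond acceptor count.
#' @return Integer count of violations in 0..4.
#' @export
#' @examples
#' lipinski_violations(600, 6, 0, 2)  # 2
lipinski_violations <- function(molecular_weight, slogp, h_bond_donors,
                                h_bond_acceptors) {
  (molecular_weight > 500) + (slogp > 5) + (h_bond_donors > 5) +
    (h_bond_acceptors > 10)
}

#' Drug-likeness profile of molecules
#'
#' Computes the four Lipinski descriptors from SMILES (via Open Babel) and
#' the number of rule-of-five violations. Molecules whose descriptors cannot
#' be computed are returned with `available = FALSE` and a reason.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data frame with the descriptors, `violations`, `available`,
#'   and `reason`.
#' @export
lipinski_profile <- function(smiles) {
  desc <- molecular_descriptors(smiles)
  desc$violations <- ifelse(
    desc$available,
    lipinski_violations(desc$molecular_weight, desc$slogp,
                        desc$h_bond_donors, desc$h_bond_acceptors),
    NA_integer_)
  desc
}

#' Read a delimited activity table
#'
#' Accepts the CSV/TSV export dialect of activity databases: required
#' columns `compound_id` and `smiles`, plus either `pic50` or `ic50` (with
#' an optional `ic50_units` column, nanomolar assumed when absent). Optional
#' columns `split`, `source`, `structure_key`, and `molecular_weight` are
#' carried through.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A data frame of raw activity records.
#' @export
read_activity_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  required <- c("compound_id", "smiles")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("activity table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!("pic50" %in% names(df)) && !("ic50" %in% names(df))) {
    stop("activity table must carry either a pic50 or an ic50 column")
  }
  df
}

# Ensure a pic50 column in -log10 molar; accepts ic50 (+units) instead.
complete_pic50 <- function(records) {
  if (!("pic50" %in% names(records))) records$pic50 <- NA_real_
  if ("ic50" %in% names(records)) {
    units <- if ("ic50_units" %in% names(records)) records$ic50_units else "nM"
    molar <- ic50_to_molar(records$ic50, units)
    need <- is.na(records$pic50) & !is.na(molar)
    if (any(need)) records$pic50[need] <- to_pic50(molar[need])
    records$ic50_molar <- molar
  } else {
    records$ic50_molar <- 10^(-records$pic50)
  }
  if (anyNA(records$pic50)) {
    stop("some records carry neither a usable pIC50 nor a positive IC50")
  }
  records
}

#' Remove redundant compounds, keeping the most potent record
#'
#' Groups records by a canonical structure key and keeps, per group, the
#' record with the lowest IC50 (highest pIC50); ties keep the first record
#' in input order, and the surviving records preserve input order.
#' Records whose key is missing (unparseable structures) are routed to a
#' rejects table, not silently dropped.
#'
#' @param records Data frame with a `pic50` column.
#' @param key Character vector of structure keys aligned with `records`
#'   (e.g. from [canonical_key()]), or the name of a column of `records`.
#' @return A list with `records` (deduplicated), `rejects`, and `n_removed`.
#' @export
deduplicate_compounds <- function(records, key = "structure_key") {
  if (is.character(key) && length(key) == 1 && key %in% names(records)) {
    key <- records[[key]]
  }
  if (length(key) != nrow(records)) {
    stop("structure keys must align with the records")
  }
  bad <- is.na(key) | !nzchar(as.character(key))
  rejects <- records[bad, , drop = FALSE]
  kept <- records[!bad, , drop = FALSE]
  key <- as.character(key)[!bad]
  if (nrow(kept) > 0) {
    # stable arg-max of pic50 per key: order by descending pic50 with
    # input order as tie-break, then keep the first row per key
    ord <- order(-kept$pic50, seq_len(nrow(kept)))
    first <- ord[!duplicated(key[ord])]
    keep_rows <- sort(first)
    n_removed <- nrow(kept) - length(keep_rows)
    kept <- kept[keep_rows, , drop = FALSE]
  } else {
    n_removed <- 0L
  }
  rownames(kept) <- NULL
  list(records = kept, rejects = rejects, n_removed = n_removed)
}

#' Remove compounds above a molecular-weight cutoff
#'
#' Compounds strictly heavier than the cutoff (1000 Da by default) are
#' removed; a compound exactly at the cutoff is retained.
#'
#' @param records Data frame with a `molecular_weight` column.
#' @param cutoff Maximum molecular weight in Da.
#' @return A list with `records` (retained) and `n_removed`.
#' @export
filter_molecular_weight <- function(records, cutoff = 1000) {
  if (!("molecular_weight" %in% names(records))) {
    stop("records need a molecular_weight column; ",
         "compute one with molecular_descriptors()")
  }
  keep <- records$molecular_weight <= cutoff
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(!keep))
}

#' Curate a raw activity table into a modelling-ready dataset
#'
#' Applies the curation rules in order: (1) convert IC50 values to pIC50,
#' (2) deduplicate by canonical structure key keeping the most potent
#' record, (3) remove compounds heavier than `mw_cutoff` Da, (4) label each
#' compound active (pIC50 >= `activity_threshold`) or inactive. Structure
#' keys and molecular weights are taken from `structure_key` /
#' `molecular_weight` columns when present and computed from SMILES with
#' Open Babel otherwise.
#'
#' @param raw Data frame from [read_activity_table()].
#' @param mw_cutoff Molecular-weight cutoff in Da.
#' @param activity_threshold pIC50 activity cutoff.
#' @return A `curated_dataset`: `records`, `rejects`, and a curation `log`
#'   (a data frame of rule / kept / removed counts).
#' @export
curate_dataset <- function(raw, mw_cutoff = 1000, activity_threshold = 6) {
  n_input <- nrow(raw)
  records <- complete_pic50(raw)
  if (!("structure_key" %in% names(records))) {
    records$structure_key <- canonical_key(records$smiles)
  }
  if (!("molecular_weight" %in% names(records))) {
    desc <- molecular_descriptors(records$smiles)
    records$molecular_weight <- desc$molecular_weight
  }
  dedup <- deduplicate_compounds(records)
  mw <- filter_molecular_weight(dedup$records, cutoff = mw_cutoff)
  records <- mw$records
  records$activity <- label_activity(records$pic50, activity_threshold)
  if (!("split" %in% names(records))) records$split <- "unassigned"
  log <- data.frame(
    rule = c("input", "unparseable_structure", "duplicate_structure",
             paste0("molecular_weight_gt_", mw_cutoff), "curated"),
    removed = c(0L, nrow(dedup$rejects), dedup$n_removed, mw$n_removed, 0L),
    remaining = c(n_input, n_input - nrow(dedup$rejects),
                  nrow(dedup$records), nrow(records), nrow(records)))
  structure(list(records = records, rejects = dedup$rejects, log = log),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("Curated dataset: %d compounds (%d active, %d inactive)\n",
              nrow(x$records), sum(x$records$activity == "active"),
              sum(x$records$activity == "inactive")))
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-28s removed %4d, remaining %4d\n", x$log$rule[i],
                x$log$removed[i], x$log$remaining[i]))
  }
  invisible(x)
}

#' Assign training / test split labels
#'
#' Stratified-by-activity random split: within each activity class,
#' `floor(train_fraction * n)` compounds overall go to the training set (the
#' per-class allocation is rounded so that the total training size is exactly
#' `floor(train_fraction * n)`). Records that already carry `"train"` or
#' `"test"` labels (e.g. from a supplementary file) are preserved verbatim
#' unless `force = TRUE`.
#'
#' @param records Data frame with `activity` and optionally `split` columns,
#'   or a `curated_dataset`.
#' @param train_fraction Fraction of compounds assigned to training, in (0, 1).
#' @param seed Integer seed making the assignment reproducible.
#' @param force Reassign even when split labels are already present.
#' @return The records with a filled-in `split` column.
#' @export
#' @examples
#' rec <- data.frame(pic50 = rnorm(10, 6), activity = "active")
#' table(split_train_test(rec, 0.5, seed = 1)$split)  # 5 train / 5 test
split_train_test <- function(records, train_fraction = 0.7, seed = 1,
                             force = FALSE) {
  if (inherits(records, "curated_dataset")) records <- records$records
  n <- nrow(records)
  if (n == 0) stop("cannot split an empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  if (!("split" %in% names(records))) records$split <- "unassigned"
  assigned <- records$split %in% c("train", "test")
  if (all(assigned) && !force) return(records)
  if (any(assigned) && !force) {
    stop("records carry a partial split assignment; use force = TRUE ",
         "to reassign all of them")
  }
  n_train <- floor(train_fraction * n)
  strata <- if ("activity" %in% names(records)) records$activity
            else rep("all", n)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # largest-remainder allocation of n_train across strata
  counts <- table(strata)
  exact <- as.numeric(counts) * n_train / n
  base <- floor(exact)
  shortfall <- n_train - sum(base)
  if (shortfall > 0) {
    extra <- order(-(exact - base))[seq_len(shortfall)]
    base[extra] <- base[extra] + 1
  }
  split <- rep("test", n)
  for (s in seq_along(counts)) {
    idx <- which(strata == names(counts)[s])
    take <- sample(idx, base[s])
    split[take] <- "train"
  }
  records$split <- split
  records
}

#' Write a curated dataset and its curation log
#'
#' @param dataset A `curated_dataset`.
#' @param csv_path Output CSV for the records.
#' @param log_path Optional output JSON for the curation log.
#' @return `csv_path`, invisibly.
#' @export
write_curated <- function(dataset, csv_path, log_path = NULL) {
  stopifnot(inherits(dataset, "curated_dataset"))
  utils::write.csv(dataset$records, csv_path, row.names = FALSE)
  if (!is.null(log_path)) {
    jsonlite::write_json(dataset$log, log_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
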