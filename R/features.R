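#' Column schema of the conjoint fingerprint block
#'
#' The full conjoint block concatenates the 881 PubChem binary
#' fingerprint bits (`PubchemFP0` ... `PubchemFP880`) with the 307
#' substructure fingerprint counts (`SubFPC1` ... `SubFPC307`), following
#' the PaDEL-descriptor output naming convention.
#'
#' @param n_binary Number of binary bit columns.
#' @param n_counts Number of count columns.
#' @return A data frame with `name` and `kind` (`"binary_bit"` / `"count"`).
#' @export
conjoint_schema <- function(n_binary = 881, n_counts = 307) {
  data.frame(
    name = c(if (n_binary > 0) paste0("PubchemFP", seq_len(n_binary) - 1),
             if (n_counts > 0) paste0("SubFPC", seq_len(n_counts))),
    kind = c(rep("binary_bit", n_binary), rep("count", n_counts)),
    stringsAsFactors = FALSE)
}

#' Construct a fingerprint provider
#'
#' A provider is the pluggable contract behind featurization: it declares a
#' fixed column schema and maps molecules (by identifier and SMILES) to one
#' named numeric row per molecule, deterministically. The fingerprint bit
#' definitions themselves live outside this package (descriptor software
#' such as PaDEL); providers typically replay cached descriptor output or
#' generate synthetic features.
#'
#' @param name Provider name (recorded in artifacts).
#' @param schema Data frame with columns `name` and `kind` as in
#'   [conjoint_schema()].
#' @param compute `function(compound_id, smiles)` returning an
#'   `n x nrow(schema)` numeric matrix, or `NA` rows for failures.
#' @return An `fp_provider` object.
#' @export
fp_provider <- function(name, schema, compute) {
  stopifnot(is.character(name), is.data.frame(schema),
            all(c("name", "kind") %in% names(schema)), is.function(compute))
  if (anyDuplicated(schema$name)) stop("schema column names must be unique")
  if (!all(schema$kind %in% c("binary_bit", "count", "numeric"))) {
    stop("schema kinds must be binary_bit, count, or numeric")
  }
  structure(list(name = name, schema = schema, compute = compute),
            class = "fp_provider")
}

#' @export
print.fp_provider <- function(x, ...) {
  cat(sprintf("Fingerprint provider '%s': %d columns (%s)\n", x$name,
              nrow(x$schema),
              paste(names(table(x$schema$kind)), table(x$schema$kind),
                    sep = " x ", collapse = ", ")))
  invisible(x)
}

#' Provider replaying a cached descriptor table
#'
#' Wraps a precomputed fingerprint table (e.g. PaDEL-descriptor output read
#' with `read.csv`) as a provider. Molecules are matched by identifier;
#' molecules absent from the table yield `NA` rows, which [featurize()]
#' reports as failures.
#'
#' @param table Data frame with an identifier column and one column per
#'   fingerprint.
#' @param id_col Name of the identifier column.
#' @param kinds Optional character vector of column kinds aligned with the
#'   non-id columns; by default columns taking only 0/1 values are declared
#'   `binary_bit` and the rest `count`.
#' @param name Provider name.
#' @return An `fp_provider`.
#' @export
table_fp_provider <- function(table, id_col = "compound_id", kinds = NULL,
                              name = "cached_table") {
  stopifnot(id_col %in% names(table))
  ids <- as.character(table[[id_col]])
  values <- as.matrix(table[, setdiff(names(table), id_col), drop = FALSE])
  storage.mode(values) <- "double"
  if (is.null(kinds)) {
    kinds <- apply(values, 2, function(col) {
      if (all(col %in% c(0, 1), na.rm = TRUE)) "binary_bit" else "count"
    })
  }
  schema <- data.frame(name = colnames(values), kind = unname(kinds),
                       stringsAsFactors = FALSE)
  fp_provider(name, schema, function(compound_id, smiles) {
    values[match(as.character(compound_id), ids), , drop = FALSE]
  })
}

#' Build the feature matrix for a set of compounds
#'
#' Applies a fingerprint provider to the records, preserving row order.
#' Rows the provider fails on (any non-finite value) are excluded from the
#' matrix and reported in the `excluded` table instead of failing the run.
#'
#' @param records Data frame with `compound_id` and `smiles` columns.
#' @param provider An [fp_provider()].
#' @return A `feature_matrix`: list with `values` (numeric matrix, rows
#'   named by compound id), `schema`, `provider_name`, and `excluded`
#'   (data frame of compound id / reason).
#' @export
featurize <- function(records, provider) {
  stopifnot(inherits(provider, "fp_provider"))
  ids <- as.character(records$compound_id)
  values <- provider$compute(records$compound_id, records$smiles)
  if (!is.matrix(values) || nrow(values) != nrow(records) ||
      ncol(values) != nrow(provider$schema)) {
    stop("provider '", provider$name, "' violated its contract: expected a ",
         nrow(records), " x ", nrow(provider$schema), " matrix")
  }
  colnames(values) <- provider$schema$name
  ok <- apply(values, 1, function(r) all(is.finite(r)))
  excluded <- data.frame(compound_id = ids[!ok],
                         reason = rep_len("provider failed to featurize",
                                          sum(!ok)),
                         stringsAsFactors = FALSE)
  values <- values[ok, , drop = FALSE]
  rownames(values) <- ids[ok]
  bad_bit <- provider$schema$kind == "binary_bit" &
    apply(values, 2, function(col) !all(col %in% c(0, 1)))
  if (any(bad_bit)) {
    stop("binary_bit columns contain non 0/1 values: ",
         paste(utils::head(provider$schema$name[bad_bit], 5), collapse = ", "))
  }
  structure(list(values = values, schema = provider$schema,
                 provider_name = provider$name, excluded = excluded),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d compounds x %d features (provider '%s')\n",
              nrow(x$values), ncol(x$values), x$provider_name))
  if (nrow(x$excluded) > 0) {
    cat(sprintf("  %d compounds excluded by the provider\n", nrow(x$excluded)))
  }
  invisible(x)
}

feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as_feature_values(x)
}

#' Max-min normalization to the unit interval
#'
#' Maps every non-constant column through `(x - min) / (max - min)`;
#' constant columns (including all-zero fingerprint bits) are mapped to
#' zeros, which keeps them uninformative without dividing by zero. The
#' transform is idempotent.
#'
#' @param x Numeric matrix or `feature_matrix`.
#' @return A numeric matrix with the same dimensions and names.
#' @export
#' @examples
#' maxmin_normalize(cbind(a = c(0, 2, 4)))  # 0, 0.5, 1
maxmin_normalize <- function(x) {
  m <- feature_values(x)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  range <- hi - lo
  constant <- range == 0
  range[constant] <- 1
  out <- sweep(sweep(m, 2, lo, "-"), 2, range, "/")
  out[, constant] <- 0
  out
}

#' PCA projection of the normalized chemical space
#'
#' Centers the max-min-normalized fingerprint block and computes principal
#' components, retaining the smallest number `m` of leading components whose
#' cumulative explained-variance fraction reaches the threshold.
#'
#' @param x Normalized numeric matrix (rows = compounds).
#' @param variance_threshold Cumulative explained-variance target in (0, 1].
#' @return A `pca_result`: `scores` (n x m), `explained_variance_fraction`
#'   (all components), `m`, and the `rotation` used.
#' @export
pca_project <- function(x, variance_threshold = 0.95) {
  m <- feature_values(x)
  if (nrow(m) < 2) stop("PCA needs at least two compounds")
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    stop("all feature columns are constant; PCA is undefined")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  n_keep <- which(cumsum(frac) >= variance_threshold)[1]
  if (is.na(n_keep)) n_keep <- length(frac)
  structure(list(scores = fit$x[, seq_len(n_keep), drop = FALSE],
                 explained_variance_fraction = frac,
                 m = n_keep,
                 rotation = fit$rotation[, seq_len(n_keep), drop = FALSE],
                 center = fit$center,
                 variance_threshold = variance_threshold),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "PCA projection: %d components reach %.0f%% variance (PC1 = %.1f%%)\n",
    x$m, 100 * x$variance_threshold,
    100 * x$explained_variance_fraction[1]))
  invisible(x)
}

#' Write PCA scores as CSV for chemical-space plots
#'
#' One row per compound, one column per retained principal component
#' (`PC1..PCm`), with an optional grouping column (e.g. train/test or an
#' activity label) for colouring score plots.
#'
#' @param pca A `pca_result` from [pca_project()].
#' @param path Output CSV path.
#' @param group Optional vector aligned with the rows.
#' @return `path`, invisibly.
#' @export
write_pca_scores <- function(pca, path, group = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  df <- as.data.frame(pca$scores)
  names(df) <- paste0("PC", seq_len(ncol(df)))
  if (!is.null(group)) df$group <- group
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as a delimited table
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path; columns follow the provider schema with a
#'   leading `compound_id` column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(compound_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
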