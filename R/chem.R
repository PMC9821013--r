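# Thin wrappers around Open Babel (via ChemmineOB) for the chemistry steps:
# SMILES validation, canonical structure keys, and the handful of molecular
# descriptors the curation rules need. All higher-level functions accept
# precomputed columns instead, so the package works on descriptor tables when
# no chemistry toolkit is attached.

require_chem <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("this operation needs the ChemmineOB package (Open Babel); ",
         "supply precomputed structure keys / descriptors instead",
         call. = FALSE)
  }
}

#' Parse and canonicalize SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data frame with `smiles`, `valid`, and the canonical SMILES
#'   (`cansmi`, `NA` where parsing failed).
#' @export
parse_smiles <- function(smiles) {
  require_chem()
  cansmi <- vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) NA_character_)
    if (is.na(out) || !nzchar(trimws(out))) NA_character_
    else sub("\t.*$", "", strsplit(out, "\n")[[1]][1])
  }, character(1), USE.NAMES = FALSE)
  data.frame(smiles = smiles, valid = !is.na(cansmi), cansmi = cansmi,
             stringsAsFactors = FALSE)
}

#' Canonical structure key for deduplication
#'
#' Returns the standard InChIKey of each molecule (method `"inchikey"`), or
#' the Open Babel canonical SMILES (method `"cansmiles"`). Unparseable
#' SMILES give `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param method `"inchikey"` (default) or `"cansmiles"`.
#' @return Character vector of structure keys.
#' @export
canonical_key <- function(smiles, method = c("inchikey", "cansmiles")) {
  method <- match.arg(method)
  require_chem()
  to <- if (method == "inchikey") "INCHIKEY" else "CAN"
  vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", to, paste0(s, "\n")),
      error = function(e) NA_character_)
    if (is.na(out) || !nzchar(trimws(out))) NA_character_
    else sub("\t.*$", "", strsplit(out, "\n")[[1]][1])
  }, character(1), USE.NAMES = FALSE)
}

#' Molecular descriptors used by the curation and drug-likeness rules
#'
#' Computes molecular weight, SLogP, and hydrogen-bond donor/acceptor counts
#' with Open Babel. Rows whose SMILES fail to parse are flagged unavailable
#' with a reason rather than dropped.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data frame with `smiles`, `available`, `reason`,
#'   `molecular_weight` (Da), `slogp`, `h_bond_donors`, `h_bond_acceptors`.
#' @export
molecular_descriptors <- function(smiles) {
  require_chem()
  rows <- lapply(smiles, function(s) {
    props <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::prop_OB(mol)
    }, error = function(e) NULL)
    if (is.null(props) || nrow(props) != 1) {
      data.frame(available = FALSE, reason = "SMILES failed to parse",
                 molecular_weight = NA_real_, slogp = NA_real_,
                 h_bond_donors = NA_real_, h_bond_acceptors = NA_real_)
    } else {
      data.frame(available = TRUE, reason = NA_character_,
                 molecular_weight = props$MW, slogp = props$logP,
                 h_bond_donors = props$HBD, h_bond_acceptors = props$HBA1)
    }
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE), out)
}
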