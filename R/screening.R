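#' Screen a candidate library with the trained classifier and regressor
#'
#' Scores every candidate with both model heads: the classifier decides
#' `"active"` / `"inactive"` (probability threshold 0.5) and the regressor
#' supplies a predicted pIC50, reported side by side even when the two
#' disagree (a class-active candidate may carry a predicted pIC50 below 6;
#' no reconciliation is attempted). Candidates are ranked by predicted
#' pIC50 descending, ties keeping input order. Candidates the provider
#' fails to featurize are listed with a status instead of a rank.
#'
#' A nearest-training-neighbour feature distance is attached as advisory
#' metadata (`nn_distance`, Euclidean distance to the closest training row,
#' when a training matrix is supplied): candidates far from all training
#' compounds are outside the model's experience. This diagnostic is an
#' extension of the reported workflow, not part of it; the
#' standardized-residual applicability domain needs experimental
#' activities, which screening candidates lack.
#'
#' @param candidates Data frame with `compound_id` (or `name`), `smiles`
#'   if the provider needs it, and any annotation columns to pass through.
#' @param classifier Logistic-loss `qsar_booster`.
#' @param regressor Squared-loss `qsar_booster`.
#' @param provider [fp_provider()] used to featurize the candidates, or an
#'   already-built `feature_matrix` whose rows are named by candidate id.
#' @param x_train Optional training feature matrix for the
#'   nearest-neighbour diagnostic.
#' @return A `screening_report`: `results` data frame (name, predicted
#'   class, predicted pIC50, rank, probability, annotations), `excluded`,
#'   and metadata.
#' @export
screen_library <- function(candidates, classifier, regressor, provider,
                           x_train = NULL) {
  stopifnot(inherits(classifier, "qsar_booster"),
            inherits(regressor, "qsar_booster"))
  if (classifier$params$loss != "logistic") {
    stop("the classifier must be a logistic-loss model")
  }
  if (regressor$params$loss != "squared") {
    stop("the regressor must be a squared-loss model")
  }
  if (!("compound_id" %in% names(candidates))) {
    if (!("name" %in% names(candidates))) {
      stop("candidates need a compound_id or name column")
    }
    candidates$compound_id <- candidates$name
  }
  fm <- if (inherits(provider, "feature_matrix")) provider
        else featurize(candidates, provider)
  scored_ids <- rownames(fm$values)
  keep <- candidates$compound_id %in% scored_ids
  excluded <- data.frame(compound_id = candidates$compound_id[!keep],
                         status = rep_len("featurization failed", sum(!keep)),
                         stringsAsFactors = FALSE)
  if (nrow(fm$excluded) > 0) {
    excluded$status <- fm$excluded$reason[
      match(excluded$compound_id, fm$excluded$compound_id)]
  }
  scored <- candidates[keep, , drop = FALSE]
  x <- fm$values[match(scored$compound_id, scored_ids), , drop = FALSE]
  prob <- predict(classifier, x, type = "response")
  cls <- ifelse(prob >= 0.5, "active", "inactive")
  pic50 <- predict(regressor, x, type = "response")
  ord <- order(-pic50, seq_along(pic50)) # ties keep input order
  results <- scored
  results$predicted_class <- cls
  results$predicted_pic50 <- pic50
  results$active_probability <- prob
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  if (!is.null(x_train)) {
    xt <- feature_values(x_train)
    results$nn_distance <- vapply(ord, function(i) {
      d2 <- rowSums(sweep(xt, 2, x[i, ], "-")^2)
      sqrt(min(d2))
    }, numeric(1))
  }
  rownames(results) <- NULL
  structure(list(results = results, excluded = excluded,
                 n_active = sum(cls == "active"),
                 provider_name = fm$provider_name),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report: %d candidates scored, %d predicted active\n",
              nrow(x$results), x$n_active))
  if (nrow(x$excluded) > 0) {
    cat(sprintf("  %d candidates excluded\n", nrow(x$excluded)))
  }
  top <- utils::head(x$results, 10)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-12s %-8s pIC50 = %.2f\n", top$rank[i],
                top$compound_id[i], top$predicted_class[i],
                top$predicted_pic50[i]))
  }
  invisible(x)
}

#' Render a screening report as CSV or Markdown
#'
#' Emits the ranked candidate table (name, predicted class, predicted pIC50
#' to two decimals, annotations) in the layout of the repurposing summary
#' table. The CSV round-trips through `read.csv`.
#'
#' @param report A `screening_report`.
#' @param path Output path; `NULL` returns the rendered text invisibly
#'   without writing.
#' @param format `"csv"` or `"markdown"`.
#' @return The rendered lines, invisibly.
#' @export
format_screening_table <- function(report, path = NULL,
                                   format = c("csv", "markdown")) {
  stopifnot(inherits(report, "screening_report"))
  format <- match.arg(format)
  res <- report$results
  annot <- setdiff(names(res),
                   c("compound_id", "name", "smiles", "predicted_class",
                     "predicted_pic50", "active_probability", "rank",
                     "nn_distance"))
  name_col <- if ("name" %in% names(res)) res$name else res$compound_id
  out <- data.frame(Name = name_col,
                    `Predicted Class` = res$predicted_class,
                    `Predicted pIC50` = sprintf("%.2f", res$predicted_pic50),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (a in annot) out[[a]] <- res[[a]]
  if (format == "csv") {
    lines <- utils::capture.output(
      utils::write.csv(out, stdout(), row.names = FALSE))
  } else {
    header <- paste0("| ", paste(names(out), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
    body <- apply(out, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    lines <- c(header, rule, body)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
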