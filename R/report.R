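#' Classify genes as essential and convert probabilities to scores
#'
#' A gene is reported as essential when its predicted essentiality
#' probability is at least the threshold (inclusive; default 0.70). Its
#' essentiality score is the probability times 100, rounded to one
#' decimal, so reported scores run from 70.0 to 100.0. Rows are sorted by
#' descending score, ties broken by gene id.
#'
#' @param probs named numeric vector of probabilities in `[0, 1]`.
#' @param threshold inclusive probability cutoff (default 0.70).
#' @return data.frame `gene_id`, `essentiality_score`; zero rows when no
#'   gene reaches the threshold.
#' @export
classify_and_score <- function(probs, threshold = 0.70) {
  stopifnot(is.numeric(probs), !is.null(names(probs)),
            all(probs >= 0 & probs <= 1))
  keep <- probs >= threshold
  score <- round(probs[keep] * 100, 1)
  out <- data.frame(gene_id = names(probs)[keep],
                    essentiality_score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$essentiality_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-organism prediction table as CSV
#'
#' Emits the database-style table with header
#' `gene_id,preferred_name,function,essentiality_score`. Genes absent
#' from the annotation table get their own id as preferred name and `NA`
#' as function. Output is byte-stable for fixed inputs.
#'
#' @param table data.frame from [classify_and_score()].
#' @param annotations an `annotation_table` from [read_annotations()], or
#'   `NULL`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(table, annotations, path) {
  ann <- annotate_genes(annotations, table$gene_id)
  out <- data.frame(gene_id = table$gene_id,
                    preferred_name = ann$preferred_name,
                    `function` = ifelse(is.na(ann$gene_function), "NA",
                                        ann$gene_function),
                    essentiality_score = sprintf("%.1f", table$essentiality_score),
                    stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("gene_id,preferred_name,function,essentiality_score", con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(out, sep = ",")), con)
  }
  invisible(path)
}

#' Read back a prediction CSV
#'
#' @param path a CSV written by [write_predictions_csv()].
#' @return data.frame with the four table columns (`essentiality_score`
#'   numeric).
#' @export
read_predictions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = character(0),
                        colClasses = c("character", "character", "character",
                                       "numeric"))
  df
}
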