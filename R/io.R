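# Writers for classification calls, curation reports and risk results.
# All outputs are deterministic and byte-stable: fixed column order, sorted
# keys, LF line endings and 6-significant-digit float formatting (p-values at
# full precision where they must round-trip).

.fmt_num <- function(x, digits = 6) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, digits), trim = TRUE,
                                 digits = digits)
  }, character(1))
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# supporting evidence encoded as "study_id:population:grade" joined by ";"
.encode_supporting <- function(supporting) {
  vapply(supporting, function(s) {
    if (nrow(s) == 0) return("")
    paste(paste(s$study_id, s$population, s$grade, sep = ":"), collapse = ";")
  }, character(1))
}

.decode_supporting <- function(x) {
  lapply(x, function(enc) {
    if (is.na(enc) || enc == "") {
      return(tibble::tibble(study_id = character(0),
                            population = character(0),
                            grade = character(0)))
    }
    parts <- strsplit(strsplit(enc, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(study_id = vapply(parts, `[`, "", 1),
                   population = vapply(parts, `[`, "", 2),
                   grade = vapply(parts, `[`, "", 3))
  })
}

#' Write reproducibility calls as tab-separated text
#'
#' Supporting evidence is flattened to `study_id:population:grade` triples
#' joined by `;`. Output is byte-stable for identical input;
#' [read_calls()] reproduces the call table exactly.
#'
#' @param calls Call tibble from [classify_inter()] / [classify_intra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  flat <- tibble::tibble(
    variant_id = calls$variant_id,
    klass = calls$klass,
    n_supporting = calls$n_supporting,
    supporting = .encode_supporting(calls$supporting),
    locus_id = calls$locus_id,
    note = calls$note
  )
  .write_tsv(flat, path)
}

#' Read reproducibility calls written by [write_calls()]
#'
#' @param path Path to the calls TSV.
#' @return Call tibble with the `supporting` list column reconstructed.
#' @export
read_calls <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  tibble::tibble(
    variant_id = raw$variant_id,
    klass = raw$klass,
    n_supporting = as.integer(raw$n_supporting),
    supporting = .decode_supporting(raw$supporting),
    locus_id = ifelse(raw$locus_id == "", NA_character_, raw$locus_id),
    note = ifelse(raw$note == "", NA_character_, raw$note)
  )
}

#' Summarize a curation run
#'
#' Runs the full curation pipeline (grade, select representatives, classify
#' inter- and intra-population reproducibility) and returns the flow counts:
#' records in, representatives, significant representatives, inter- and
#' intra-reproduced variants, and loci spanned by confirmed variants.
#'
#' @param records Association records.
#' @param loci Optional `variant_id`/`locus_id` map; when `NULL`, the
#'   `locus_id` column of `records` is used if present, and the locus count is
#'   `NA` otherwise.
#' @return List of class `"curation_report"`: `n_records`,
#'   `n_representatives`, `n_significant`, `n_inter_variants`,
#'   `n_intra_variants`, `n_loci`, plus the `inter` and `intra` call tibbles.
#' @export
curation_report <- function(records, loci = NULL) {
  graded <- grade_associations(records)
  reps <- select_representatives(graded)
  inter <- classify_inter(reps)
  intra <- classify_intra(reps, graded)
  n_loci <- if (!is.null(loci) || "locus_id" %in% names(records)) {
    both <- dplyr::bind_rows(inter, intra)
    count_confirmed_loci(both, loci)
  } else {
    NA_integer_
  }
  out <- list(
    n_records = nrow(graded),
    n_representatives = nrow(reps),
    n_significant = sum(is_significant(reps$grade)),
    n_inter_variants = sum(inter$klass == "inter_population"),
    n_intra_variants = sum(intra$klass == "intra_population"),
    n_loci = n_loci,
    inter = inter,
    intra = intra
  )
  class(out) <- "curation_report"
  out
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  records                 : %d\n", x$n_records))
  cat(sprintf("  representatives         : %d\n", x$n_representatives))
  cat(sprintf("  significant             : %d\n", x$n_significant))
  cat(sprintf("  inter-reproduced variants: %d\n", x$n_inter_variants))
  cat(sprintf("  intra-reproduced variants: %d\n", x$n_intra_variants))
  cat(sprintf("  loci (confirmed)        : %s\n", x$n_loci))
  invisible(x)
}

#' Combine inter- and intra-population calls into one table
#'
#' Confirmed calls from both classifiers are kept (a variant reproduced both
#' ways appears twice, once per class); a variant confirmed by neither keeps a
#' single `unconfirmed` row (the inter row, which carries any
#' direction-conflict note).
#'
#' @param inter Calls from [classify_inter()].
#' @param intra Calls from [classify_intra()].
#' @return Combined call tibble sorted by `variant_id`, then `klass`.
#' @export
combine_calls <- function(inter, intra) {
  confirmed <- dplyr::bind_rows(
    inter[inter$klass == "inter_population", , drop = FALSE],
    intra[intra$klass == "intra_population", , drop = FALSE]
  )
  leftover <- setdiff(union(inter$variant_id, intra$variant_id),
                      confirmed$variant_id)
  out <- dplyr::bind_rows(
    confirmed,
    inter[inter$variant_id %in% leftover, , drop = FALSE]
  )
  out[order(out$variant_id, out$klass), , drop = FALSE]
}

#' Write a curation report as JSON
#'
#' Counts only (not the call tables), with sorted keys and stable formatting.
#'
#' @param report A `"curation_report"` (or plain named list of counts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  counts <- report[c("n_records", "n_representatives", "n_significant",
                     "n_inter_variants", "n_intra_variants", "n_loci")]
  .write_json(counts, path)
}

#' Write a risk result as JSON
#'
#' @param result A `"risk_result"` from [predict_risk()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk <- function(result, path) {
  payload <- list(
    grs = signif(result$grs, 6),
    per_marker_rgr = as.list(signif(result$per_marker_rgr, 6)),
    overall_rgr = signif(result$overall_rgr, 6),
    lifetime_risk = signif(result$lifetime_risk, 6),
    n_markers_used = result$n_markers_used,
    prevalence = signif(result$prevalence, 6)
  )
  .write_json(payload, path)
}

.write_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}
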