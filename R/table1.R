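# Packaged fixture: the 40 published associations of the 19 risk variants
# confirmed between populations, transcribed with variant, risk allele (where
# printed), p-value, odds ratio (where printed), case/control counts,
# population, genotyping coverage and the gene-group locus label. Rows from
# meta-analyses of follow-up data are encoded design=followup so they are
# graded at the follow-up thresholds under which they were reported as
# confirmed; the genome-wide exception applies to meta-analyses of GWAS,
# which the genome-wide-coverage rows represent.

#' Load the packaged table of inter-population confirmed associations
#'
#' Returns the 40 published representative associations (19 variants in 12
#' gene-group loci) shipped with the package, validated and carrying a
#' `locus_id` column. These records exercise every evidence path of the
#' classifier: missing odds ratios, missing risk alleles, opposite-allele
#' reporting and both grading regimes.
#'
#' @return Tibble of 40 validated association records.
#' @export
#' @examples
#' tab1 <- load_table1_fixture()
#' nrow(tab1)
#' length(unique(tab1$variant_id))
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.tsv", package = "ravarkit",
                      mustWork = TRUE)
  read_association_table(path)
}

#' Variant-to-locus map of the packaged fixture
#'
#' @param records Association records with a `locus_id` column; defaults to
#'   the packaged fixture.
#' @return Tibble with one row per variant: `variant_id`, `locus_id`.
#' @export
table1_loci <- function(records = load_table1_fixture()) {
  stopifnot("locus_id" %in% names(records))
  out <- unique(tibble::tibble(variant_id = records$variant_id,
                               locus_id = records$locus_id))
  if (anyDuplicated(out$variant_id)) {
    stop("variant assigned to more than one locus", call. = FALSE)
  }
  out[order(out$variant_id), , drop = FALSE]
}
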