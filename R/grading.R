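# Dual significance regimes. Genome-wide assays (and meta-analyses of GWAS or
# combined GWAS+replication analyses) are judged at genome-wide thresholds;
# follow-up studies assaying a few selected markers are judged at nominal
# thresholds.

#' Significance thresholds of the two grading regimes
#'
#' @return Named list: `genome_wide` and `followup`, each with `strong`
#'   (strict upper bound for a strong association) and `moderate` (inclusive
#'   upper bound for a moderate association).
#' @export
significance_thresholds <- function() {
  list(
    genome_wide = list(strong = 5.0e-8, moderate = 1.0e-5),
    followup    = list(strong = 0.01,   moderate = 0.05)
  )
}

#' Select the grading regime for association records
#'
#' A record is graded at genome-wide thresholds when its design is `gwas`,
#' `meta_of_gwas` or `combined_gwas_replication`, or when its genotyping
#' coverage is `genome_wide`; all other records (follow-up studies on selected
#' markers) are graded at nominal follow-up thresholds.
#'
#' @param design Character vector of study designs.
#' @param coverage Character vector of genotyping coverage values.
#' @return Character vector: `"genome_wide"` or `"followup"`.
#' @export
select_regime <- function(design, coverage) {
  stopifnot(length(design) == length(coverage))
  gw <- design %in% c("gwas", "meta_of_gwas", "combined_gwas_replication") |
    coverage == "genome_wide"
  ifelse(gw, "genome_wide", "followup")
}

#' Grade association p-values under a significance regime
#'
#' Genome-wide regime: P < 5.0e-8 is `strong`; 5.0e-8 <= P <= 1.0e-5 is
#' `moderate`; P > 1.0e-5 is `not_significant`. Follow-up regime: P < 0.01 is
#' `strong`; 0.01 <= P <= 0.05 is `moderate`; P > 0.05 is `not_significant`.
#' Strong is strictly below its threshold and moderate closes the interval at
#' the weak endpoint, matching the strict "not significant above" cut.
#'
#' @param p_value Numeric vector of p-values in (0, 1].
#' @param regime Character vector (recycled if scalar): `"genome_wide"` or
#'   `"followup"`.
#' @return Character vector: `"strong"`, `"moderate"` or `"not_significant"`.
#' @export
#' @examples
#' grade_significance(2.1e-17, "genome_wide")
#' grade_significance(0.04, "followup")
grade_significance <- function(p_value, regime) {
  if (length(regime) == 1) regime <- rep(regime, length(p_value))
  stopifnot(length(p_value) == length(regime),
            all(regime %in% c("genome_wide", "followup")))
  th <- significance_thresholds()
  strong_at <- ifelse(regime == "genome_wide",
                      th$genome_wide$strong, th$followup$strong)
  moderate_at <- ifelse(regime == "genome_wide",
                        th$genome_wide$moderate, th$followup$moderate)
  ifelse(p_value < strong_at, "strong",
         ifelse(p_value <= moderate_at, "moderate", "not_significant"))
}

#' Grade a table of association records
#'
#' Appends `regime` and `grade` columns; grading is a pure function of
#' `(p_value, regime)` and every record receives exactly one grade.
#'
#' @param records Association records (see [validate_association_records()]).
#' @return The validated records with `regime` and `grade` columns appended.
#' @export
grade_associations <- function(records) {
  records <- validate_association_records(records)
  records$regime <- select_regime(records$design, records$coverage)
  records$grade <- grade_significance(records$p_value, records$regime)
  records
}

#' Is a grade statistically significant?
#'
#' Both strong and moderate associations count as statistically significant
#' for reproducibility support.
#'
#' @param grade Character vector of grades.
#' @return Logical vector.
#' @export
is_significant <- function(grade) grade %in% c("strong", "moderate")
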