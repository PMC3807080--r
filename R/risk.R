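# Genetic risk prediction from a panel of confirmed risk markers.
#
# For marker i with allelic odds ratio r_i and risk-allele control frequency
# p_i, an individual carrying X_i copies of the risk allele has
# genotype-specific risk s_i = r_i^X_i. Under Hardy-Weinberg equilibrium the
# population-average risk is a_i = p_i^2 r_i^2 + 2 p_i (1 - p_i) r_i +
# (1 - p_i)^2, so the per-marker relative genetic risk (RGR) is s_i / a_i and
# averages exactly 1 over HWE genotypes. The overall RGR is the product over
# markers; the weighted genetic risk score (GRS) is sum X_i * log(r_i); the
# lifetime risk is overall RGR times the population prevalence, capped at 1.

.panel_required_cols <- c("variant_id", "risk_allele", "odds_ratio",
                          "risk_allele_freq", "p_value", "locus_id",
                          "population")

#' Validate a risk-marker panel
#'
#' Required columns: `variant_id`, `risk_allele`, `odds_ratio` (r_i > 0),
#' `risk_allele_freq` (p_i in \[0, 1\]), `p_value` (used for LD pruning),
#' `locus_id`, `population`. An optional `other_allele` column is carried
#' through (used when flipping orientation).
#'
#' @param panel Data frame of risk markers.
#' @return Validated tibble with canonical population labels.
#' @export
validate_marker_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  missing_cols <- setdiff(.panel_required_cols, names(panel))
  if (length(missing_cols) > 0) {
    stop("marker panel is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(panel$variant_id)) {
    stop("duplicate variant_id in marker panel: ",
         paste(unique(panel$variant_id[duplicated(panel$variant_id)]),
               collapse = ", "), call. = FALSE)
  }
  stopifnot(
    all(!is.na(panel$odds_ratio) & panel$odds_ratio > 0),
    all(!is.na(panel$risk_allele_freq) & panel$risk_allele_freq >= 0 &
          panel$risk_allele_freq <= 1),
    all(!is.na(panel$p_value) & panel$p_value > 0 & panel$p_value <= 1),
    all(!is.na(panel$locus_id) & nzchar(panel$locus_id))
  )
  panel$population <- resolve_population(panel$population)
  panel
}

#' Read a risk-marker panel from tab-separated text
#'
#' @param path Path to a TSV with the panel columns (see
#'   [validate_marker_panel()]); `""` and `"."` denote missing optional values.
#' @param ensure_risk_orientation If `TRUE`, rows whose declared allele is
#'   protective (odds ratio < 1) are flipped to risk orientation via
#'   [flip_marker_orientation()].
#' @return Validated tibble of risk markers.
#' @export
read_marker_panel <- function(path, ensure_risk_orientation = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  blank_to_na <- function(x) ifelse(x == "" | x == ".", NA_character_, x)
  panel <- tibble::tibble(
    variant_id = raw$variant_id,
    risk_allele = blank_to_na(raw$risk_allele),
    odds_ratio = as.numeric(raw$odds_ratio),
    risk_allele_freq = as.numeric(raw$risk_allele_freq),
    p_value = as.numeric(raw$p_value),
    locus_id = raw$locus_id,
    population = raw$population
  )
  if ("other_allele" %in% names(raw)) {
    panel$other_allele <- blank_to_na(raw$other_allele)
  }
  panel <- validate_marker_panel(panel)
  if (ensure_risk_orientation) panel <- flip_marker_orientation(panel) else panel
}

#' Write a risk-marker panel as tab-separated text
#'
#' Inverse of [read_marker_panel()]; byte-stable output with missing alleles
#' written as empty strings, 6-significant-digit odds ratios and frequencies,
#' and full-precision p-values.
#'
#' @param panel Validated marker panel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  panel <- validate_marker_panel(panel)
  out <- panel
  out$odds_ratio <- .fmt_num(out$odds_ratio)
  out$risk_allele_freq <- .fmt_num(out$risk_allele_freq)
  out$p_value <- .fmt_num(out$p_value, digits = 15)
  .write_tsv(out, path)
}

#' Flip protective-orientation panel rows to risk orientation
#'
#' A row declaring the protective allele (odds ratio < 1) describes the same
#' marker as the row for the other allele with `r -> 1/r` and `p -> 1 - p`
#' (and genotype copy number `X -> 2 - X`); per-marker RGR is invariant under
#' this relabeling. Flipped rows take their risk allele from the
#' `other_allele` column when present and `NA` otherwise (the identity of the
#' other allele cannot be inferred from the flipped row alone).
#'
#' @param panel Validated marker panel.
#' @return Panel with every row in risk orientation (odds ratio >= 1).
#' @export
flip_marker_orientation <- function(panel) {
  panel <- validate_marker_panel(panel)
  flip <- panel$odds_ratio < 1
  if (!any(flip)) return(panel)
  new_allele <- if ("other_allele" %in% names(panel)) {
    panel$other_allele[flip]
  } else {
    rep(NA_character_, sum(flip))
  }
  if ("other_allele" %in% names(panel)) {
    panel$other_allele[flip] <- panel$risk_allele[flip]
  }
  panel$risk_allele[flip] <- new_allele
  panel$odds_ratio[flip] <- 1 / panel$odds_ratio[flip]
  panel$risk_allele_freq[flip] <- 1 - panel$risk_allele_freq[flip]
  panel
}

#' Prune linked markers to one lead marker per locus
#'
#' Confirmed variants in the same linkage-disequilibrium block would double
#' count one risk signal; within each `locus_id` only the marker with the
#' smallest association p-value is kept (ties broken by lexicographically
#' smallest `variant_id`). Output is ordered by `locus_id`.
#'
#' @param panel Validated marker panel.
#' @return Panel with exactly one row per distinct `locus_id`.
#' @export
#' @examples
#' panel <- tibble::tibble(
#'   variant_id = c("rsA", "rsB", "rsC"), risk_allele = "A",
#'   odds_ratio = 1.2, risk_allele_freq = 0.3,
#'   p_value = c(1e-10, 1e-6, 1e-8), locus_id = c("L1", "L1", "L2"),
#'   population = "European")
#' prune_ld(panel)$variant_id
prune_ld <- function(panel) {
  panel <- validate_marker_panel(panel)
  ord <- order(panel$locus_id, panel$p_value, panel$variant_id)
  sorted <- panel[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted genetic risk score
#'
#' GRS = sum over available markers of `X_i * log(r_i)` (natural log), where
#' `X_i` is the individual's risk-allele copy number. Markers with missing
#' genotype are skipped.
#'
#' @param panel Validated marker panel (pruned to independent loci).
#' @param copies Named numeric vector of risk-allele copy numbers in
#'   `{0, 1, 2}` (or `NA` for missing), named by `variant_id`.
#' @return Scalar GRS.
#' @export
grs <- function(panel, copies) {
  panel <- validate_marker_panel(panel)
  x <- .match_copies(panel, copies)
  avail <- !is.na(x)
  sum(x[avail] * log(panel$odds_ratio[avail]))
}

#' Per-marker relative genetic risk
#'
#' `marker_rgr(r, p, x)` returns `r^x / (p^2 r^2 + 2 p (1-p) r + (1-p)^2)`:
#' the genotype-specific risk relative to the Hardy-Weinberg population
#' average. It equals 1 for a null marker (r = 1), exceeds 1 for above-average
#' genotypes, and averages exactly 1 over HWE genotype frequencies.
#'
#' @param r Allelic odds ratio(s), > 0.
#' @param p Risk-allele frequency(ies) in the control population, in \[0, 1\].
#' @param x Risk-allele copy number(s) in `{0, 1, 2}`.
#' @return Numeric vector of per-marker RGR values.
#' @export
#' @examples
#' marker_rgr(2, 0.5, 2)  # 4 / 2.25
marker_rgr <- function(r, p, x) {
  n <- max(length(r), length(p), length(x))
  r <- rep_len(r, n); p <- rep_len(p, n); x <- rep_len(x, n)
  stopifnot(all(r > 0), all(p >= 0 & p <= 1), all(x %in% c(0, 1, 2)))
  bad <- (p == 0 & x > 0) | (p == 1 & x < 2)
  if (any(bad)) {
    stop("genotype impossible at stated risk-allele frequency ",
         "(p = 0 with x > 0, or p = 1 with x < 2)", call. = FALSE)
  }
  s <- r^x
  a <- p^2 * r^2 + 2 * p * (1 - p) * r + (1 - p)^2
  s / a
}

#' Overall relative genetic risk
#'
#' Product of per-marker RGRs over markers with an available genotype; an
#' empty marker set yields 1 (the average individual).
#'
#' @inheritParams grs
#' @return Scalar overall RGR.
#' @export
overall_rgr <- function(panel, copies) {
  panel <- validate_marker_panel(panel)
  x <- .match_copies(panel, copies)
  avail <- !is.na(x)
  if (!any(avail)) return(1)
  prod(marker_rgr(panel$odds_ratio[avail], panel$risk_allele_freq[avail],
                  x[avail]))
}

#' Lifetime disease risk from relative genetic risk
#'
#' `min(rgr * prevalence, 1)`: the population lifetime prevalence scaled by
#' the individual's overall relative genetic risk, capped at certainty.
#'
#' @param rgr Overall relative genetic risk (positive).
#' @param prevalence Population lifetime prevalence, in (0, 1).
#' @return Lifetime risk in \[0, 1\].
#' @export
#' @examples
#' lifetime_risk(2.6, 0.01)  # 0.026
lifetime_risk <- function(rgr, prevalence) {
  stopifnot(all(rgr > 0))
  if (any(is.na(prevalence)) || any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  pmin(rgr * prevalence, 1)
}

#' Default population prevalence values
#'
#' Shipped configuration (extdata/prevalence.tsv), user-overridable in
#' [predict_risk()]. The European value of 1% is the baseline used by the
#' lifetime-risk example.
#'
#' @return Named numeric vector of prevalence by population.
#' @export
default_prevalence <- function() {
  path <- system.file("extdata", "prevalence.tsv", package = "ravarkit",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(tab$prevalence, tab$population)
}

#' Risk-allele copy number from a two-letter genotype
#'
#' Counts how many of the two genotype characters equal the marker's risk
#' allele. Genotype letters must be A/C/G/T (or exactly the risk allele for
#' named alleles); anything else is an error naming the marker, because a
#' silent zero would understate risk.
#'
#' @param genotype Character vector of two-letter genotypes (e.g. `"AG"`),
#'   `NA` for missing.
#' @param risk_allele Risk allele per marker.
#' @param variant_id Marker names used in error messages.
#' @return Numeric vector of copy numbers in `{0, 1, 2}` (`NA` where missing).
#' @export
genotype_copy_number <- function(genotype, risk_allele,
                                 variant_id = seq_along(genotype)) {
  n <- length(genotype)
  stopifnot(length(risk_allele) == n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genotype[i]
    if (is.na(g)) next
    if (is.na(risk_allele[i])) {
      stop("marker ", variant_id[i], ": risk allele unknown, cannot count ",
           "genotype copies", call. = FALSE)
    }
    alleles <- toupper(strsplit(g, "")[[1]])
    if (length(alleles) != 2) {
      stop("marker ", variant_id[i], ": genotype '", g,
           "' is not a two-letter string", call. = FALSE)
    }
    known <- alleles %in% c("A", "C", "G", "T") |
      alleles == toupper(risk_allele[i])
    if (!all(known)) {
      stop("marker ", variant_id[i], ": unknown allele '",
           alleles[!known][1], "' in genotype '", g, "'", call. = FALSE)
    }
    out[i] <- sum(alleles == toupper(risk_allele[i]))
  }
  out
}

# align a named copies vector (or genotype tibble) with the panel rows
.match_copies <- function(panel, copies) {
  if (is.data.frame(copies)) {
    stopifnot(all(c("variant_id", "genotype") %in% names(copies)))
    idx <- match(panel$variant_id, copies$variant_id)
    genotype <- copies$genotype[idx]
    return(genotype_copy_number(genotype, panel$risk_allele, panel$variant_id))
  }
  x <- unname(copies[panel$variant_id])
  stopifnot(all(is.na(x) | x %in% c(0, 1, 2)))
  x
}

#' Read an individual's genotypes from tab-separated text
#'
#' @param path TSV with columns `variant_id` and `genotype` (two-letter
#'   strings such as `"AG"`; `""` or `"."` for missing).
#' @return Tibble with `variant_id` and `genotype`.
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("variant_id", "genotype") %in% names(raw)))
  tibble::tibble(
    variant_id = raw$variant_id,
    genotype = ifelse(raw$genotype == "" | raw$genotype == ".",
                      NA_character_, raw$genotype)
  )
}

#' Predict an individual's genetic disease risk
#'
#' End-to-end risk computation: prune the panel to one lead marker per locus,
#' convert genotypes to risk-allele copy numbers, and compute the weighted
#' GRS, per-marker RGR, overall RGR (product) and lifetime risk
#' (RGR x prevalence). Markers without a genotype are skipped and
#' `n_markers_used` reports how many contributed.
#'
#' @param panel Risk-marker panel (validated; pruned internally).
#' @param genotypes Tibble with `variant_id`/`genotype` columns (see
#'   [read_genotypes()]) or a named copy-number vector.
#' @param prevalence Population prevalence in (0, 1); defaults to the shipped
#'   value for `population`.
#' @param population Population whose default prevalence to use when
#'   `prevalence` is not given.
#' @return List of class `"risk_result"` with elements `grs`,
#'   `per_marker_rgr` (named), `overall_rgr`, `lifetime_risk`,
#'   `n_markers_used`, `prevalence`.
#' @export
predict_risk <- function(panel, genotypes, prevalence = NULL,
                         population = "European") {
  panel <- prune_ld(panel)
  if (is.null(prevalence)) {
    defaults <- default_prevalence()
    population <- resolve_population(population)
    if (!population %in% names(defaults)) {
      stop("no default prevalence for population ", population,
           "; supply `prevalence`", call. = FALSE)
    }
    prevalence <- unname(defaults[population])
  }
  x <- .match_copies(panel, genotypes)
  avail <- !is.na(x)
  per <- marker_rgr(panel$odds_ratio[avail], panel$risk_allele_freq[avail],
                    x[avail])
  names(per) <- panel$variant_id[avail]
  rgr <- if (length(per) == 0) 1 else prod(per)
  result <- list(
    grs = sum(x[avail] * log(panel$odds_ratio[avail])),
    per_marker_rgr = per,
    overall_rgr = rgr,
    lifetime_risk = lifetime_risk(rgr, prevalence),
    n_markers_used = sum(avail),
    prevalence = prevalence
  )
  class(result) <- "risk_result"
  result
}

#' @export
print.risk_result <- function(x, ...) {
  cat("Genetic risk prediction\n")
  cat(sprintf("  markers used : %d\n", x$n_markers_used))
  cat(sprintf("  GRS          : %.6g\n", x$grs))
  cat(sprintf("  overall RGR  : %.6g\n", x$overall_rgr))
  cat(sprintf("  lifetime risk: %.3g%% (prevalence %.3g%%)\n",
              100 * x$lifetime_risk, 100 * x$prevalence))
  invisible(x)
}
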