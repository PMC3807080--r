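# Reproducibility assessment. For each variant and geographical population the
# association from the study with the most cases is the representative; a
# variant is inter-population reproduced when significant, direction-consistent
# representatives exist in at least two populations, and intra-population
# reproduced when a significant representative is replicated by an independent
# significant study of the same population. Opposite-direction "replications"
# are excluded.

#' Reverse-strand complement of a single-base allele
#'
#' Returns `NA` for anything but a single A/C/G/T character (named alleles,
#' indels, multi-base strings never complement-match).
#'
#' @param allele Character vector.
#' @return Character vector of complements or `NA`.
#' @export
complement_allele <- function(allele) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(comp[toupper(allele)])
  out[is.na(allele)] <- NA_character_
  out
}

#' Select the representative association per variant and population
#'
#' Among all records for one `(variant_id, population)`, the representative is
#' the record from the study with the largest number of cases. Ties are broken
#' deterministically: smallest p-value, then largest control count, then
#' lexicographically smallest `study_id`. The result is invariant under input
#' permutation and idempotent.
#'
#' @param records Association records; graded columns are preserved if present.
#' @return Tibble with exactly one row per `(variant_id, population)` in the
#'   input, ordered by variant then population.
#' @export
select_representatives <- function(records) {
  records <- if (all(c("regime", "grade") %in% names(records))) {
    tibble::as_tibble(records)
  } else {
    validate_association_records(records)
  }
  ord <- order(records$variant_id, records$population,
               -records$n_cases, records$p_value,
               -records$n_controls, records$study_id)
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(paste(sorted$variant_id, sorted$population, sep = "\r"))
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction verdict between two reports of the same variant
#'
#' Determines whether two reported associations point the same way.
#' `indeterminate` arises when either odds ratio is missing or exactly 1.
#' With both risk alleles reported: the same allele (or its reverse-strand
#' complement) must sit on the same side of OR = 1 to be `consistent`;
#' different, non-complementary alleles of a biallelic pair must sit on
#' opposite sides. When an allele is missing on either side, raw odds ratios
#' are compared directly (same side of 1 is `consistent`). Note that for A/T
#' and C/G palindromic markers the complement of one allele *is* the other
#' allele, so those pairs are compared as same-allele reports.
#'
#' @param allele_a,allele_b Risk alleles as reported (`NA` when unreported).
#' @param or_a,or_b Allelic odds ratios (`NA` when unreported).
#' @return `"consistent"`, `"conflicting"` or `"indeterminate"`.
#' @export
#' @examples
#' direction_verdict("G", 0.91, "A", 1.09)  # opposite alleles, opposite sides
direction_verdict <- function(allele_a, or_a, allele_b, or_b) {
  if (is.na(or_a) || is.na(or_b)) return("indeterminate")
  if (or_a == 1 || or_b == 1) return("indeterminate")
  same_side <- (or_a > 1) == (or_b > 1)
  if (!is.na(allele_a) && !is.na(allele_b)) {
    same_allele <- toupper(allele_a) == toupper(allele_b) ||
      identical(toupper(allele_a), complement_allele(allele_b))
    if (same_allele) {
      if (same_side) "consistent" else "conflicting"
    } else {
      if (same_side) "conflicting" else "consistent"
    }
  } else {
    if (same_side) "consistent" else "conflicting"
  }
}

# pairwise verdicts among rows of a representatives tibble; returns TRUE if
# any pair conflicts
.any_conflict <- function(rows) {
  n <- nrow(rows)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- direction_verdict(rows$risk_allele[i], rows$odds_ratio[i],
                             rows$risk_allele[j], rows$odds_ratio[j])
      if (v == "conflicting") return(TRUE)
    }
  }
  FALSE
}

.supporting_tbl <- function(rows) {
  tibble::tibble(study_id = rows$study_id, population = rows$population,
                 grade = rows$grade)
}

.locus_of <- function(rows) {
  if (!"locus_id" %in% names(rows)) return(NA_character_)
  loc <- unique(rows$locus_id[!is.na(rows$locus_id)])
  if (length(loc) == 0) NA_character_ else loc[1]
}

.call_tbl <- function(variant_id, klass, supporting, locus_id, note) {
  tibble::tibble(
    variant_id = variant_id, klass = klass,
    n_supporting = vapply(supporting, nrow, integer(1)),
    supporting = supporting, locus_id = locus_id, note = note
  )
}

#' Classify variants by inter-population reproducibility
#'
#' A variant is `inter_population` reproduced when its statistically
#' significant representative associations (strong or moderate) span at least
#' two distinct populations and no pair of them conflicts in direction. Any
#' conflicting pair excludes the variant (klass `unconfirmed`, noted as a
#' direction conflict). All significant representatives of a confirmed variant
#' are attached as supporting evidence. The classification is symmetric in
#' population order and invariant under input permutation.
#'
#' @param representatives Output of [select_representatives()]; graded via
#'   [grade_associations()] first if `grade` is absent.
#' @return Tibble with one row per variant: `variant_id`, `klass`
#'   (`inter_population` / `unconfirmed`), `n_supporting`, `supporting`
#'   (list column of tibbles with `study_id`, `population`, `grade`),
#'   `locus_id`, `note`.
#' @export
classify_inter <- function(representatives) {
  if (!"grade" %in% names(representatives)) {
    representatives <- grade_associations(representatives)
  }
  reps <- tibble::as_tibble(representatives)
  pieces <- lapply(split(reps, reps$variant_id), function(rows) {
    sig <- rows[is_significant(rows$grade), , drop = FALSE]
    if (nrow(sig) >= 2 && .any_conflict(sig)) {
      .call_tbl(rows$variant_id[1], "unconfirmed",
                list(.supporting_tbl(sig[0, ])), .locus_of(rows),
                "direction_conflict")
    } else if (length(unique(sig$population)) >= 2) {
      sig <- sig[order(sig$population, sig$study_id), , drop = FALSE]
      .call_tbl(rows$variant_id[1], "inter_population",
                list(.supporting_tbl(sig)), .locus_of(rows), NA_character_)
    } else {
      .call_tbl(rows$variant_id[1], "unconfirmed",
                list(.supporting_tbl(sig[0, ])), .locus_of(rows),
                NA_character_)
    }
  })
  out <- dplyr::bind_rows(pieces)
  out[order(out$variant_id), , drop = FALSE]
}

#' Classify variants by intra-population reproducibility
#'
#' A variant is `intra_population` reproduced when, in some population, its
#' significant representative association is replicated by at least one other
#' record from an independent study (distinct `study_id`) of the same
#' population that is itself significant under its own regime and does not
#' conflict in direction with the representative. Supporting evidence lists
#' the representative and every qualifying independent record.
#'
#' @param representatives Output of [select_representatives()] (graded if
#'   `grade` is absent).
#' @param records The full association table the representatives were drawn
#'   from (graded internally).
#' @return Tibble with one row per variant, same shape as [classify_inter()],
#'   with `klass` in `{intra_population, unconfirmed}`.
#' @export
classify_intra <- function(representatives, records) {
  if (!"grade" %in% names(representatives)) {
    representatives <- grade_associations(representatives)
  }
  reps <- tibble::as_tibble(representatives)
  recs <- grade_associations(records)
  pieces <- lapply(split(reps, reps$variant_id), function(rows) {
    supporting <- rows[0, , drop = FALSE]
    sig_reps <- rows[is_significant(rows$grade), , drop = FALSE]
    for (i in seq_len(nrow(sig_reps))) {
      rep_i <- sig_reps[i, , drop = FALSE]
      others <- recs[recs$variant_id == rep_i$variant_id &
                       recs$population == rep_i$population &
                       recs$study_id != rep_i$study_id, , drop = FALSE]
      if (nrow(others) == 0) next
      ok <- is_significant(others$grade) &
        vapply(seq_len(nrow(others)), function(j) {
          direction_verdict(rep_i$risk_allele, rep_i$odds_ratio,
                            others$risk_allele[j], others$odds_ratio[j]) !=
            "conflicting"
        }, logical(1))
      if (any(ok)) {
        supporting <- dplyr::bind_rows(supporting, rep_i,
                                       others[ok, names(rows)[names(rows) %in% names(others)], drop = FALSE])
      }
    }
    if (nrow(supporting) > 0) {
      supporting <- supporting[order(supporting$population, supporting$study_id), ,
                               drop = FALSE]
      .call_tbl(rows$variant_id[1], "intra_population",
                list(.supporting_tbl(supporting)), .locus_of(rows),
                NA_character_)
    } else {
      .call_tbl(rows$variant_id[1], "unconfirmed",
                list(.supporting_tbl(supporting)), .locus_of(rows),
                NA_character_)
    }
  })
  out <- dplyr::bind_rows(pieces)
  out[order(out$variant_id), , drop = FALSE]
}

#' Count distinct loci among confirmed variants
#'
#' @param calls Classification calls ([classify_inter()] / [classify_intra()]).
#' @param loci Optional tibble mapping `variant_id` to `locus_id`; when
#'   omitted, the `locus_id` column carried on `calls` is used. A confirmed
#'   variant with no locus assignment is an error.
#' @return Integer count of distinct locus identifiers spanned by confirmed
#'   (non-`unconfirmed`) variants.
#' @export
count_confirmed_loci <- function(calls, loci = NULL) {
  confirmed <- calls[calls$klass != "unconfirmed", , drop = FALSE]
  if (nrow(confirmed) == 0) return(0L)
  if (!is.null(loci)) {
    idx <- match(confirmed$variant_id, loci$variant_id)
    locus <- loci$locus_id[idx]
  } else {
    locus <- confirmed$locus_id
  }
  if (anyNA(locus)) {
    stop("confirmed variant(s) without locus assignment: ",
         paste(confirmed$variant_id[is.na(locus)], collapse = ", "),
         call. = FALSE)
  }
  length(unique(locus))
}
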