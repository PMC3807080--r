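# Independent brute-force oracles. Everything here is re-derived with naive
# loops and explicit enumeration, deliberately sharing no code with the
# package implementation.

oracle_regime <- function(design, coverage) {
  if (design %in% c("gwas", "meta_of_gwas", "combined_gwas_replication")) {
    return("genome_wide")
  }
  if (coverage == "genome_wide") return("genome_wide")
  "followup"
}

oracle_grade <- function(p, design, coverage) {
  if (oracle_regime(design, coverage) == "genome_wide") {
    if (p < 5e-8) return("strong")
    if (p <= 1e-5) return("moderate")
    return("not_significant")
  }
  if (p < 0.01) return("strong")
  if (p <= 0.05) return("moderate")
  "not_significant"
}

oracle_sig <- function(grade) grade %in% c("strong", "moderate")

# representative row index per (variant, population) by explicit pairwise
# comparison: more cases wins, then smaller p, then more controls, then
# smaller study_id
oracle_representatives <- function(records) {
  keep <- integer(0)
  for (v in unique(records$variant_id)) {
    for (pop in unique(records$population[records$variant_id == v])) {
      idx <- which(records$variant_id == v & records$population == pop)
      best <- idx[1]
      for (i in idx[-1]) {
        better <- FALSE
        if (records$n_cases[i] > records$n_cases[best]) better <- TRUE
        else if (records$n_cases[i] == records$n_cases[best]) {
          if (records$p_value[i] < records$p_value[best]) better <- TRUE
          else if (records$p_value[i] == records$p_value[best]) {
            if (records$n_controls[i] > records$n_controls[best]) better <- TRUE
            else if (records$n_controls[i] == records$n_controls[best] &&
                     records$study_id[i] < records$study_id[best]) better <- TRUE
          }
        }
        if (better) best <- i
      }
      keep <- c(keep, best)
    }
  }
  records[sort(keep), , drop = FALSE]
}

oracle_complement <- function(a) {
  switch(a, A = "T", T = "A", C = "G", G = "C", NA_character_)
}

oracle_direction <- function(a1, or1, a2, or2) {
  if (is.na(or1) || is.na(or2) || or1 == 1 || or2 == 1) return("indeterminate")
  side1 <- or1 > 1
  side2 <- or2 > 1
  if (!is.na(a1) && !is.na(a2)) {
    same <- (a1 == a2) || (!is.na(oracle_complement(a2)) &&
                             a1 == oracle_complement(a2))
    if (same) {
      if (side1 == side2) "consistent" else "conflicting"
    } else {
      if (side1 != side2) "consistent" else "conflicting"
    }
  } else {
    if (side1 == side2) "consistent" else "conflicting"
  }
}

# variant -> klass, enumerating every representative pair
oracle_inter <- function(records) {
  reps <- oracle_representatives(records)
  out <- character(0)
  for (v in unique(records$variant_id)) {
    rows <- reps[reps$variant_id == v, , drop = FALSE]
    grades <- vapply(seq_len(nrow(rows)), function(i) {
      oracle_grade(rows$p_value[i], rows$design[i], rows$coverage[i])
    }, character(1))
    sig <- rows[oracle_sig(grades), , drop = FALSE]
    conflict <- FALSE
    n <- nrow(sig)
    if (n >= 2) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (oracle_direction(sig$risk_allele[i], sig$odds_ratio[i],
                             sig$risk_allele[j], sig$odds_ratio[j]) ==
            "conflicting") conflict <- TRUE
      }
    }
    out[v] <- if (!conflict && length(unique(sig$population)) >= 2) {
      "inter_population"
    } else {
      "unconfirmed"
    }
  }
  out
}

oracle_intra <- function(records) {
  reps <- oracle_representatives(records)
  out <- character(0)
  for (v in unique(records$variant_id)) {
    hit <- FALSE
    rrows <- reps[reps$variant_id == v, , drop = FALSE]
    for (i in seq_len(nrow(rrows))) {
      gi <- oracle_grade(rrows$p_value[i], rrows$design[i], rrows$coverage[i])
      if (!oracle_sig(gi)) next
      others <- records[records$variant_id == v &
                          records$population == rrows$population[i] &
                          records$study_id != rrows$study_id[i], ,
                        drop = FALSE]
      for (j in seq_len(nrow(others))) {
        gj <- oracle_grade(others$p_value[j], others$design[j],
                           others$coverage[j])
        dj <- oracle_direction(rrows$risk_allele[i], rrows$odds_ratio[i],
                               others$risk_allele[j], others$odds_ratio[j])
        if (oracle_sig(gj) && dj != "conflicting") hit <- TRUE
      }
    }
    out[v] <- if (hit) "intra_population" else "unconfirmed"
  }
  out
}

# explicit three-genotype HWE enumeration of the average risk
oracle_hwe_mean_rgr <- function(r, p) {
  a <- p^2 * r^2 + 2 * p * (1 - p) * r + (1 - p)^2
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  s <- c(1, r, r^2)
  sum(w * (s / a))
}

# small hand-rolled association row builder for tests
assoc_row <- function(study_id, variant_id, population, p_value,
                      odds_ratio = NA_real_, risk_allele = NA_character_,
                      n_cases = 1000, n_controls = 1000,
                      coverage = "genome_wide", design = "gwas",
                      locus_id = NULL) {
  row <- tibble::tibble(
    study_id = study_id, variant_id = variant_id, risk_allele = risk_allele,
    p_value = p_value, odds_ratio = odds_ratio, n_cases = n_cases,
    n_controls = n_controls, population = population, coverage = coverage,
    design = design
  )
  if (!is.null(locus_id)) row$locus_id <- locus_id
  row
}
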