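# Synthetic association tables with planted reproducibility classes, and
# HWE genotype simulation for risk-math calibration. P-values are planted an
# order of magnitude beyond the grading thresholds (1e-9 on the genome-wide
# side, 1e-3 / 0.5 on the follow-up side) so recovery tests never sit on a
# boundary; boundary behaviour is tested in the grading module. Odds ratios
# for risk variants are drawn log-uniform in [1.05, 2.5], the magnitude range
# of the published confirmed associations (0.61-2.88 across both
# orientations).

.synth_classes <- c("inter_reproduced", "intra_reproduced", "lone_significant",
                    "never_significant", "direction_conflict",
                    "small_study_only")

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic association table
#'
#' Counts of variants to plant per reproducibility class:
#' `inter_reproduced` (significant, direction-consistent representatives in
#' >= 2 populations), `intra_reproduced` (a significant representative plus
#' an independent significant study in the same population),
#' `lone_significant` (one significant study only), `never_significant`,
#' `direction_conflict` (significant in two populations with the same allele
#' on opposite sides of OR 1), and `small_study_only` (a significant small
#' study displaced by a larger non-significant representative).
#'
#' @param inter_reproduced,intra_reproduced,lone_significant,never_significant,direction_conflict,small_study_only
#'   Non-negative variant counts per class.
#' @param populations Canonical population labels to draw from (>= 2 required
#'   when inter or conflict classes are requested).
#' @param seed Integer seed; fully determines the generated table.
#' @return List of class `"synth_spec"`.
#' @export
synth_spec <- function(inter_reproduced = 0, intra_reproduced = 0,
                       lone_significant = 0, never_significant = 0,
                       direction_conflict = 0, small_study_only = 0,
                       populations = c("European", "EastAsian"),
                       seed = 1L) {
  counts <- c(inter_reproduced = inter_reproduced,
              intra_reproduced = intra_reproduced,
              lone_significant = lone_significant,
              never_significant = never_significant,
              direction_conflict = direction_conflict,
              small_study_only = small_study_only)
  stopifnot(all(counts >= 0), all(counts == round(counts)),
            length(populations) >= 1, length(seed) == 1, is.finite(seed))
  populations <- resolve_population(populations)
  if (anyDuplicated(populations)) {
    stop("duplicate populations in synth_spec", call. = FALSE)
  }
  needs_two <- counts[["inter_reproduced"]] > 0 ||
    counts[["direction_conflict"]] > 0
  if (needs_two && length(populations) < 2) {
    stop("inter_reproduced and direction_conflict classes require at least ",
         "two populations", call. = FALSE)
  }
  structure(list(counts = counts, populations = populations,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.rand_or <- function(n) exp(stats::runif(n, log(1.05), log(2.5)))
.rand_allele <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate a synthetic association table with planted classes
#'
#' Each planted variant receives study records whose p-values, odds ratios,
#' alleles, populations and case counts force its class under the curation
#' rules; the returned truth table is the ground-truth oracle for recovery
#' tests. Deterministic given the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return List with `records` (association tibble, including `locus_id`),
#'   `truth` (tibble `variant_id`, `class`) and `loci` (tibble `variant_id`,
#'   `locus_id`; one synthetic locus per variant).
#' @export
simulate_association_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    idx <- 0L
    emit <- function(class, maker) {
      n <- spec$counts[[class]]
      for (k in seq_len(n)) {
        idx <<- idx + 1L
        vid <- sprintf("rs%06d", idx)
        locus <- sprintf("locus_%04d", idx)
        rec <- maker(vid, locus)
        rows[[length(rows) + 1L]] <<- rec
        truth[[length(truth) + 1L]] <<-
          tibble::tibble(variant_id = vid, class = class)
      }
    }
    pops <- function(n) sample(spec$populations, n)
    base_row <- function(vid, locus, study, pop, p, or, allele, n_cases,
                         coverage = "genome_wide",
                         design = "gwas") {
      tibble::tibble(study_id = study, variant_id = vid, risk_allele = allele,
                     p_value = p, odds_ratio = or,
                     n_cases = n_cases,
                     n_controls = n_cases + sample(100:2000, 1),
                     population = pop, coverage = coverage, design = design,
                     locus_id = locus)
    }

    emit("inter_reproduced", function(vid, locus) {
      # resample() semantics: sample() on a length-1 vector would misfire
      k_choices <- 2:min(3, length(spec$populations))
      k <- k_choices[sample.int(length(k_choices), 1)]
      pop <- pops(k)
      allele <- .rand_allele(1)
      or <- .rand_or(k)                      # all > 1: direction-consistent
      dplyr::bind_rows(lapply(seq_len(k), function(i) {
        base_row(vid, locus, sprintf("S_%s_%d", vid, i), pop[i],
                 p = 10^stats::runif(1, -20, -9), or = or[i], allele = allele,
                 n_cases = sample(2000:20000, 1))
      }))
    })

    emit("intra_reproduced", function(vid, locus) {
      pop <- pops(1)
      allele <- .rand_allele(1)
      or <- .rand_or(1)
      dplyr::bind_rows(
        base_row(vid, locus, sprintf("S_%s_1", vid), pop,
                 p = 10^stats::runif(1, -20, -9), or = or, allele = allele,
                 n_cases = sample(5000:20000, 1)),
        base_row(vid, locus, sprintf("S_%s_2", vid), pop,
                 p = 10^stats::runif(1, -4, -3), or = or * 0.98,
                 allele = allele, n_cases = sample(500:2000, 1),
                 coverage = "selected", design = "followup")
      )
    })

    emit("lone_significant", function(vid, locus) {
      base_row(vid, locus, sprintf("S_%s_1", vid), pops(1),
               p = 10^stats::runif(1, -20, -9), or = .rand_or(1),
               allele = .rand_allele(1), n_cases = sample(2000:20000, 1))
    })

    emit("never_significant", function(vid, locus) {
      k <- sample(1:2, 1)
      pop <- pops(k)
      dplyr::bind_rows(lapply(seq_len(k), function(i) {
        base_row(vid, locus, sprintf("S_%s_%d", vid, i), pop[i],
                 p = stats::runif(1, 0.2, 0.9), or = .rand_or(1),
                 allele = .rand_allele(1), n_cases = sample(500:5000, 1))
      }))
    })

    emit("direction_conflict", function(vid, locus) {
      pop <- pops(2)
      allele <- .rand_allele(1)
      or <- .rand_or(1)
      dplyr::bind_rows(
        base_row(vid, locus, sprintf("S_%s_1", vid), pop[1],
                 p = 10^stats::runif(1, -20, -9), or = or, allele = allele,
                 n_cases = sample(2000:20000, 1)),
        base_row(vid, locus, sprintf("S_%s_2", vid), pop[2],
                 p = 10^stats::runif(1, -20, -9), or = 1 / or,
                 allele = allele, n_cases = sample(2000:20000, 1))
      )
    })

    emit("small_study_only", function(vid, locus) {
      pop <- pops(1)
      allele <- .rand_allele(1)
      dplyr::bind_rows(
        base_row(vid, locus, sprintf("S_%s_small", vid), pop,
                 p = 10^stats::runif(1, -4, -3), or = .rand_or(1),
                 allele = allele, n_cases = sample(100:400, 1),
                 coverage = "selected", design = "followup"),
        base_row(vid, locus, sprintf("S_%s_large", vid), pop,
                 p = stats::runif(1, 0.2, 0.9), or = 1.01, allele = allele,
                 n_cases = sample(5000:20000, 1))
      )
    })

    records <- if (length(rows) == 0) {
      tibble::tibble(study_id = character(0), variant_id = character(0),
                     risk_allele = character(0), p_value = numeric(0),
                     odds_ratio = numeric(0), n_cases = numeric(0),
                     n_controls = numeric(0), population = character(0),
                     coverage = character(0), design = character(0),
                     locus_id = character(0))
    } else {
      validate_association_records(dplyr::bind_rows(rows))
    }
    truth <- if (length(truth) == 0) {
      tibble::tibble(variant_id = character(0), class = character(0))
    } else {
      dplyr::bind_rows(truth)
    }
    loci <- unique(tibble::tibble(variant_id = records$variant_id,
                                  locus_id = records$locus_id))
    list(records = records, truth = truth, loci = loci)
  })
}

#' Simulate a synthetic risk-marker panel
#'
#' Markers get log-uniform odds ratios in \[1.05, 2.5\], risk-allele
#' frequencies uniform in \[0.05, 0.95\] and one locus each. Intended for
#' risk-math calibration tests and examples; it carries none of the linkage
#' structure of real panels.
#'
#' @param n_markers Number of markers.
#' @param seed Integer seed.
#' @param population Canonical population label for all markers.
#' @return Validated marker panel tibble.
#' @export
simulate_marker_panel <- function(n_markers, seed = 1L,
                                  population = "European") {
  stopifnot(n_markers >= 1)
  .with_seed(seed, {
    validate_marker_panel(tibble::tibble(
      variant_id = sprintf("rsM%05d", seq_len(n_markers)),
      risk_allele = .rand_allele(n_markers),
      odds_ratio = .rand_or(n_markers),
      risk_allele_freq = stats::runif(n_markers, 0.05, 0.95),
      p_value = 10^stats::runif(n_markers, -30, -9),
      locus_id = sprintf("locus_M%05d", seq_len(n_markers)),
      population = population
    ))
  })
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws each marker's risk-allele copy number as Binomial(2, p). With
#' `n_individuals > 1` a matrix of draws is returned (rows = individuals),
#' which is the basis of the mean-RGR calibration check: the expected overall
#' RGR of an HWE individual is exactly 1.
#'
#' @param panel Validated marker panel with `0 < p < 1` for every marker.
#' @param seed Integer seed; fully determines the draws.
#' @param n_individuals Number of individuals to draw.
#' @return Named numeric vector of copy numbers (one individual) or a matrix
#'   with one column per marker.
#' @export
simulate_genotype <- function(panel, seed = 1L, n_individuals = 1L) {
  panel <- validate_marker_panel(panel)
  p <- panel$risk_allele_freq
  stopifnot(all(p > 0 & p < 1))
  .with_seed(seed, {
    draws <- matrix(stats::rbinom(n_individuals * nrow(panel), size = 2,
                                  prob = rep(p, each = n_individuals)),
                    nrow = n_individuals, ncol = nrow(panel),
                    dimnames = list(NULL, panel$variant_id))
    if (n_individuals == 1L) draws[1, ] else draws
  })
}
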