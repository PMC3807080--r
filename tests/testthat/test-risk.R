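panel_row <- function(variant_id, locus_id, odds_ratio = 1.2,
                      risk_allele_freq = 0.3, p_value = 1e-9,
                      risk_allele = "A", population = "European") {
  tibble::tibble(variant_id = variant_id, risk_allele = risk_allele,
                 odds_ratio = odds_ratio, risk_allele_freq = risk_allele_freq,
                 p_value = p_value, locus_id = locus_id,
                 population = population)
}

test_that("linked markers prune to the smallest p-value per locus", {
  panel <- rbind(panel_row("rsA", "L1", p_value = 1e-10),
                 panel_row("rsB", "L1", p_value = 1e-6),
                 panel_row("rsC", "L2", p_value = 1e-8))
  pruned <- prune_ld(panel)
  expect_identical(pruned$variant_id, c("rsA", "rsC"))
  expect_identical(prune_ld(panel_row("rs_solo", "L9"))$variant_id, "rs_solo")
  # ties break lexicographically
  tie <- rbind(panel_row("rsZ", "L1", p_value = 1e-8),
               panel_row("rsY", "L1", p_value = 1e-8))
  expect_identical(prune_ld(tie)$variant_id, "rsY")
  # output size equals the number of distinct loci
  sim <- simulate_marker_panel(8, seed = 3)
  sim$locus_id <- rep(c("La", "Lb", "Lc", "Ld"), each = 2)
  expect_identical(nrow(prune_ld(sim)), 4L)
})

test_that("the six published lead markers survive pruning of the confirmed table", {
  tab1 <- load_table1_fixture()
  # build a panel from the fixture's best row per variant (needs an OR)
  best <- do.call(rbind, lapply(split(tab1, tab1$variant_id), function(rows) {
    rows <- rows[!is.na(rows$odds_ratio), , drop = FALSE]
    rows[which.min(rows$p_value), , drop = FALSE]
  }))
  panel <- tibble::tibble(
    variant_id = best$variant_id, risk_allele = best$risk_allele,
    odds_ratio = best$odds_ratio, risk_allele_freq = 0.3,
    p_value = best$p_value, locus_id = best$locus_id,
    population = best$population
  )
  pruned <- prune_ld(panel)
  expect_identical(nrow(pruned), 12L)
  # the HLA-DRB1 block collapses to its strongest signal
  expect_identical(pruned$variant_id[pruned$locus_id == "HLA-DRB1"],
                   "rs2157337")
})

test_that("the weighted score adds copy-weighted log odds ratios", {
  panel <- rbind(panel_row("rs1", "L1", odds_ratio = 1.5),
                 panel_row("rs2", "L2", odds_ratio = 2.0))
  expect_equal(grs(panel, c(rs1 = 0, rs2 = 0)), 0)
  expect_equal(grs(panel, c(rs1 = 1, rs2 = 2)), log(1.5) + 2 * log(2),
               tolerance = 1e-12)
  # null marker contributes nothing; missing genotypes are skipped
  null_panel <- panel_row("rs3", "L3", odds_ratio = 1)
  expect_equal(grs(null_panel, c(rs3 = 2)), 0)
  expect_equal(grs(panel, c(rs1 = 1, rs2 = NA)), log(1.5), tolerance = 1e-12)
  # additivity over disjoint marker sets
  expect_equal(grs(panel, c(rs1 = 1, rs2 = 2)),
               grs(panel[1, ], c(rs1 = 1)) + grs(panel[2, ], c(rs2 = 2)),
               tolerance = 1e-12)
})

test_that("per-marker relative risk normalizes genotype risk by the HWE average", {
  # hand-expanded: s = 4, a = 0.25*4 + 0.5*2 + 0.25 = 2.25
  expect_equal(marker_rgr(2, 0.5, 2), 4 / 2.25, tolerance = 1e-12)
  expect_equal(marker_rgr(1, 0.3, 1), 1)
  expect_equal(marker_rgr(1.7, 1, 2), 1)  # fixed allele: everyone is average
  # impossible genotypes at degenerate frequencies
  expect_error(marker_rgr(1.5, 0, 1), "impossible")
  expect_error(marker_rgr(1.5, 1, 0), "impossible")
  expect_silent(marker_rgr(1.5, 0, 0))

  # defining property: HWE-weighted mean is exactly 1
  for (r in c(0.4, 0.9, 1, 1.3, 2.9)) {
    for (p in c(0.01, 0.2, 0.5, 0.8, 0.99)) {
      expect_equal(oracle_hwe_mean_rgr(r, p), 1, tolerance = 1e-12)
      w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      expect_equal(sum(w * marker_rgr(r, p, c(0, 1, 2))), 1,
                   tolerance = 1e-12)
    }
  }

  # monotone in copy number: increasing for risk, decreasing for protective
  expect_true(all(diff(marker_rgr(1.4, 0.3, c(0, 1, 2))) > 0))
  expect_true(all(diff(marker_rgr(0.7, 0.3, c(0, 1, 2))) < 0))
})

test_that("relabeling risk and non-risk alleles leaves per-marker risk unchanged", {
  grid <- expand.grid(r = c(0.5, 0.8, 1.2, 2.5), p = c(0.1, 0.4, 0.7),
                      x = 0:2)
  expect_equal(marker_rgr(grid$r, grid$p, grid$x),
               marker_rgr(1 / grid$r, 1 - grid$p, 2 - grid$x),
               tolerance = 1e-12)
})

test_that("overall risk multiplies marker risks and defaults to the average individual", {
  panel <- rbind(panel_row("rs1", "L1", odds_ratio = 2, risk_allele_freq = 0.5),
                 panel_row("rs2", "L2", odds_ratio = 1, risk_allele_freq = 0.4))
  expect_equal(overall_rgr(panel, c(rs1 = 2, rs2 = 1)), 4 / 2.25,
               tolerance = 1e-12)
  expect_equal(overall_rgr(panel[0, ], setNames(numeric(0), character(0))), 1)
  expect_equal(overall_rgr(panel, c(rs1 = NA, rs2 = NA)), 1)
  # multiplicative over disjoint sets
  expect_equal(overall_rgr(panel, c(rs1 = 2, rs2 = 2)),
               overall_rgr(panel[1, ], c(rs1 = 2)) *
                 overall_rgr(panel[2, ], c(rs2 = 2)),
               tolerance = 1e-12)
})

test_that("lifetime risk scales prevalence and caps at certainty", {
  expect_equal(lifetime_risk(2.6, 0.01), 0.026, tolerance = 1e-15)
  expect_equal(lifetime_risk(1, 0.01), 0.01)
  expect_equal(lifetime_risk(200, 0.01), 1)
  expect_error(lifetime_risk(1.2, 0), "prevalence")
  expect_error(lifetime_risk(1.2, 1), "prevalence")
})

test_that("genotype strings convert to risk-allele copy numbers", {
  expect_identical(genotype_copy_number(c("AG", "GG", "AA", NA),
                                        rep("A", 4),
                                        paste0("rs", 1:4)),
                   c(1, 0, 2, NA))
  expect_error(genotype_copy_number("AX", "A", "rs9"), "rs9")
  expect_error(genotype_copy_number("AAG", "A", "rs9"), "two-letter")
})

test_that("orientation flips preserve the marker and restore risk orientation", {
  panel <- rbind(panel_row("rs1", "L1", odds_ratio = 0.8,
                           risk_allele_freq = 0.7, risk_allele = "C"),
                 panel_row("rs2", "L2", odds_ratio = 1.3))
  panel$other_allele <- c("T", "G")
  flipped <- flip_marker_orientation(panel)
  expect_equal(flipped$odds_ratio, c(1.25, 1.3), tolerance = 1e-12)
  expect_equal(flipped$risk_allele_freq[1], 0.3, tolerance = 1e-12)
  expect_identical(flipped$risk_allele, c("T", "A"))
  # same per-marker RGR for the same person either way (X -> 2 - X)
  expect_equal(marker_rgr(panel$odds_ratio[1], panel$risk_allele_freq[1], 2),
               marker_rgr(flipped$odds_ratio[1], flipped$risk_allele_freq[1], 0),
               tolerance = 1e-12)
})

test_that("end-to-end prediction prunes, scores and reports markers used", {
  panel <- rbind(
    panel_row("rs1", "L1", odds_ratio = 2, risk_allele_freq = 0.5,
              risk_allele = "A", p_value = 1e-12),
    panel_row("rs1b", "L1", odds_ratio = 1.5, risk_allele_freq = 0.2,
              risk_allele = "G", p_value = 1e-6),  # pruned away
    panel_row("rs2", "L2", odds_ratio = 1.5, risk_allele_freq = 0.3,
              risk_allele = "G", p_value = 1e-8)
  )
  geno <- tibble::tibble(variant_id = c("rs1", "rs2"),
                         genotype = c("AA", NA))
  res <- predict_risk(panel, geno, prevalence = 0.01)
  expect_s3_class(res, "risk_result")
  expect_identical(res$n_markers_used, 1L)
  expect_equal(res$overall_rgr, 4 / 2.25, tolerance = 1e-12)
  expect_equal(res$overall_rgr, prod(res$per_marker_rgr), tolerance = 1e-12)
  expect_equal(res$lifetime_risk, res$overall_rgr * 0.01, tolerance = 1e-12)
  expect_equal(res$grs, 2 * log(2), tolerance = 1e-12)

  # default prevalence comes from the shipped configuration
  res2 <- predict_risk(panel, geno, population = "European")
  expect_equal(res2$prevalence, default_prevalence()[["European"]])
  expect_error(predict_risk(panel, geno, population = "SouthAsian"),
               "prevalence")
})
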