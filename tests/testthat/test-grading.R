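test_that("regime follows design first, then genotyping coverage", {
  expect_identical(select_regime("gwas", "genome_wide"), "genome_wide")
  expect_identical(select_regime("meta_of_gwas", "selected"), "genome_wide")
  expect_identical(select_regime("combined_gwas_replication", "selected"),
                   "genome_wide")
  expect_identical(select_regime("followup", "selected"), "followup")
  # fine-mapping style follow-up on a genome-wide platform is genome-wide
  expect_identical(select_regime("followup", "genome_wide"), "genome_wide")
})

test_that("p-values grade to strong/moderate/not_significant at the regime thresholds", {
  # published examples
  expect_identical(grade_significance(2.1e-17, "genome_wide"), "strong")
  expect_identical(grade_significance(9.4e-7, "genome_wide"), "moderate")
  expect_identical(grade_significance(0.04, "followup"), "moderate")
  expect_identical(grade_significance(1.0, "genome_wide"), "not_significant")
  expect_identical(grade_significance(1.0, "followup"), "not_significant")

  # boundary handling: strong strictly below, moderate closes both endpoints
  expect_identical(grade_significance(5e-8, "genome_wide"), "moderate")
  expect_identical(grade_significance(1e-5, "genome_wide"), "moderate")
  expect_identical(
    grade_significance(1e-5 + 1e-20, "genome_wide"), "not_significant")
  expect_identical(grade_significance(0.01, "followup"), "moderate")
  expect_identical(grade_significance(0.05, "followup"), "moderate")
  expect_identical(grade_significance(0.051, "followup"), "not_significant")
})

test_that("grading is monotone in p within each regime and matches the oracle", {
  rank <- c(strong = 3, moderate = 2, not_significant = 1)
  set.seed(41)
  p <- sort(c(10^runif(200, -12, 0), 5e-8, 1e-5, 0.01, 0.05))
  for (regime in c("genome_wide", "followup")) {
    g <- grade_significance(p, regime)
    expect_true(all(diff(rank[g]) <= 0))
  }
  # oracle equivalence across designs and coverages
  designs <- sample(c("gwas", "followup", "meta_of_gwas",
                      "combined_gwas_replication"), 200, replace = TRUE)
  coverages <- sample(c("genome_wide", "selected"), 200, replace = TRUE)
  got <- grade_significance(p[1:200], select_regime(designs, coverages))
  want <- vapply(1:200, function(i) {
    oracle_grade(p[i], designs[i], coverages[i])
  }, character(1))
  expect_identical(got, want)
})

test_that("every packaged confirmed association grades as significant", {
  graded <- grade_associations(load_table1_fixture())
  expect_identical(nrow(graded), 40L)
  expect_true(all(is_significant(graded$grade)))
})
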