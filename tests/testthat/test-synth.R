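test_that("the generator is deterministic given its seed and validates its spec", {
  spec <- synth_spec(inter_reproduced = 3, intra_reproduced = 4,
                     never_significant = 5, seed = 7)
  a <- simulate_association_table(spec)
  b <- simulate_association_table(spec)
  expect_identical(a, b)
  c <- simulate_association_table(synth_spec(inter_reproduced = 3,
                                             intra_reproduced = 4,
                                             never_significant = 5,
                                             seed = 8))
  expect_false(identical(a$records, c$records))

  expect_error(synth_spec(inter_reproduced = 1, populations = "European"),
               "two populations")
  expect_error(synth_spec(inter_reproduced = -1))
  empty <- simulate_association_table(synth_spec(seed = 1))
  expect_identical(nrow(empty$records), 0L)
  expect_identical(nrow(empty$truth), 0L)
})

test_that("the pipeline recovers every planted reproducibility class", {
  spec <- synth_spec(inter_reproduced = 3, intra_reproduced = 4,
                     lone_significant = 2, never_significant = 5,
                     direction_conflict = 2, small_study_only = 3,
                     populations = c("European", "EastAsian", "SouthAsian"),
                     seed = 7)
  sim <- simulate_association_table(spec)
  graded <- grade_associations(sim$records)
  reps <- select_representatives(graded)
  inter <- classify_inter(reps)
  intra <- classify_intra(reps, graded)

  got_inter <- inter$variant_id[inter$klass == "inter_population"]
  got_intra <- intra$variant_id[intra$klass == "intra_population"]
  expect_setequal(got_inter,
                  sim$truth$variant_id[sim$truth$class == "inter_reproduced"])
  expect_setequal(got_intra,
                  sim$truth$variant_id[sim$truth$class == "intra_reproduced"])
  # planted conflicts carry the exclusion note
  conflicts <- sim$truth$variant_id[sim$truth$class == "direction_conflict"]
  expect_identical(
    sort(inter$variant_id[!is.na(inter$note) &
                            inter$note == "direction_conflict"]),
    sort(conflicts))
})

test_that("small-study-only variants lose their significance to the larger representative", {
  sim <- simulate_association_table(synth_spec(small_study_only = 4, seed = 13))
  graded <- grade_associations(sim$records)
  reps <- select_representatives(graded)
  # each planted variant had a significant small study...
  small <- graded[grepl("_small$", graded$study_id), , drop = FALSE]
  expect_true(all(is_significant(small$grade)))
  # ...but its representative is the larger, non-significant study
  expect_true(all(reps$grade == "not_significant"))
  expect_true(all(grepl("_large$", reps$study_id)))
  inter <- classify_inter(reps)
  intra <- classify_intra(reps, graded)
  expect_true(all(inter$klass == "unconfirmed"))
  expect_true(all(intra$klass == "unconfirmed"))
})

test_that("simulated genotypes follow Hardy-Weinberg genotype frequencies", {
  panel <- simulate_marker_panel(3, seed = 5)
  panel$risk_allele_freq <- c(0.9, 0.5, 0.1)
  draws <- simulate_genotype(panel, seed = 21, n_individuals = 20000)
  expect_identical(dim(draws), c(20000L, 3L))
  # X = 2 frequency ~ p^2 within 3 binomial standard errors
  for (j in 1:3) {
    p2 <- panel$risk_allele_freq[j]^2
    se <- sqrt(p2 * (1 - p2) / 20000)
    expect_lt(abs(mean(draws[, j] == 2) - p2), 3 * se + 1e-12)
  }
  # determinism
  expect_identical(simulate_genotype(panel, seed = 21),
                   simulate_genotype(panel, seed = 21))
})

test_that("generated tables load back through the tabular interface", {
  sim <- simulate_association_table(synth_spec(inter_reproduced = 2,
                                               small_study_only = 1,
                                               seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(sim$records, path)
  back <- read_association_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               tolerance = 1e-12)
})
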