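tte <- dd_thresholds("TTE-2016")
cmr <- dd_thresholds("CMR-paper")

test_that("the grade-3 worked example grades 3 under both cutoff sets", {
  g_tte <- dd_grade(figure6_tte_panel(), tte, assume_myocardial_disease = TRUE)
  expect_equal(as.character(g_tte$grade), "grade3")
  g_cmr <- dd_grade(figure6_cmr_panel(), cmr, assume_myocardial_disease = TRUE)
  expect_equal(as.character(g_cmr$grade), "grade3")
  expect_true(g_tte$dd_present && g_cmr$dd_present)
})

test_that("low E/A with low E is grade 1", {
  g <- dd_grade(list(E = 45, A = 64.3), tte, assume_myocardial_disease = TRUE)
  expect_equal(as.character(g$grade), "grade1")
})

test_that("the screening branch counts positive criteria over those available", {
  base <- list(E = 70, A = 60, e_septal = 9, e_lateral = 12,
               lavi = 28, tr_velocity = 200)
  expect_equal(as.character(dd_grade(base, tte)$grade), "normal")
  # two of four positive -> indeterminate
  half <- modifyList(base, list(e_septal = 5, lavi = 40))
  expect_equal(as.character(dd_grade(half, tte)$grade), "indeterminate")
  # three of four positive -> proceeds to grading (dysfunction present)
  most <- modifyList(base, list(e_septal = 5, lavi = 40, tr_velocity = 300))
  g <- dd_grade(most, tte)
  expect_true(g$dd_present)
  expect_true(as.character(g$grade) %in% c("grade1", "grade2", "grade3",
                                           "indeterminate"))
})

test_that("missing TR or LAVi narrows the criterion count with a qc flag", {
  p <- list(E = 70, A = 60, e_septal = 9, e_lateral = 12, lavi = 28)
  g <- dd_grade(p, tte)
  expect_equal(as.character(g$grade), "normal")
  expect_match(g$qc_flags, "TR", all = FALSE)
  expect_error(dd_grade(list(E = NA, A = NA), tte), "missing")
})

test_that("every grade carries a non-empty audit trail with operand values", {
  g <- dd_grade(figure6_tte_panel(), tte, assume_myocardial_disease = TRUE)
  expect_gt(nrow(g$criteria_fired), 0)
  expect_true(all(c("criterion", "value", "comparison", "fired") %in%
                    names(g$criteria_fired)))
})

test_that("worsening one parameter past its cutoff never lowers the grade", {
  ranks <- c(normal = 0, grade1 = 2, grade2 = 3, grade3 = 4)
  # indeterminate sits between normal and definite dysfunction
  ranks <- c(ranks, indeterminate = 1)
  worsen <- list(
    lavi = c(20, 30, 36, 50),
    tr_velocity = c(200, 260, 290, 320),
    e_septal = c(9, 7.5, 6, 3),
    e_lateral = c(12, 10.5, 8, 5))
  base <- list(E = 70, A = 55, e_septal = 9, e_lateral = 12,
               lavi = 28, tr_velocity = 200)
  for (par in names(worsen)) {
    prev <- -Inf
    for (v in worsen[[par]]) {               # each sequence ordered benign -> worse
      p <- modifyList(base, stats::setNames(list(v), par))
      r <- ranks[[as.character(dd_grade(p, tte)$grade)]]
      expect_gte(r, prev)
      prev <- r
    }
  }
})

test_that("cross_tabulate reproduces identity, reported and empty tables", {
  g <- c("normal", "grade1", "grade2", "grade3", "indeterminate")
  tab <- cross_tabulate(g, g)
  expect_equal(sum(diag(tab)), 5L)
  expect_equal(attr(tab, "n_total"), 5L)

  pairs <- contingency_pairs(reported_grade_table())
  expect_equal(nrow(pairs), 28L)
  rebuilt <- cross_tabulate(pairs$tte, pairs$cmr)
  expect_equal(unclass(rebuilt)[, ], unclass(reported_grade_table())[, ])

  empty <- cross_tabulate(character(0), character(0))
  expect_equal(sum(empty), 0L)
  expect_equal(attr(empty, "n_total"), 0L)
  expect_error(cross_tabulate(c("normal"), character(0)), "length")
})

test_that("presence collapses indeterminate into dysfunction", {
  expect_true(presence(factor("indeterminate")))
  expect_false(presence(factor("normal")))
  expect_true(presence(factor("grade2")))
  g <- dd_grade(figure6_tte_panel(), tte, assume_myocardial_disease = TRUE)
  expect_true(presence(g))
})

test_that("counting indeterminate as dysfunction never lowers sensitivity", {
  cohort <- simulate_paired_cohort(cohort_spec(n_subjects = 120, seed = 31))
  g_tte <- grade_panels(cohort_panels(cohort, "tte"), tte)
  g_cmr <- grade_panels(cohort_panels(cohort, "cmr"), cmr)
  ref <- presence(g_tte$grade)
  if (any(ref) && any(!ref)) {
    sens_with <- mean(presence(g_cmr$grade)[ref])
    sens_without <- mean((g_cmr$grade[ref] %in%
                            c("grade1", "grade2", "grade3")))
    expect_gte(sens_with, sens_without)
  } else skip("degenerate simulated cohort")
})

test_that("threshold sets validate and round-trip through JSON", {
  expect_error(dd_thresholds_custom("bad",
                                    E_over_A_low = list(value = 3, op = "<")),
               "below the high")
  path <- tempfile(fileext = ".json")
  write_thresholds_json(cmr, path)
  back <- read_thresholds_json(path)
  expect_equal(back$E_over_A_high$value, 1.5)
  expect_equal(back$E_over_A_high$op, ">=")
  expect_equal(back$label, "CMR-paper")
  g <- dd_grade(figure6_cmr_panel(), back, assume_myocardial_disease = TRUE)
  expect_equal(as.character(g$grade), "grade3")
})
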