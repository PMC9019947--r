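test_that("count-percentage formatting matches clinical table style", {
  expect_equal(format_count_pct(4300, 4658), "4300 (92.31%)")
  expect_equal(format_count_pct(323, 8588), "323 (3.76%)")
  expect_equal(format_count_pct(91768, 238259, big_mark = ","),
               "91,768 (38.52%)")
  expect_equal(format_count_pct(0, 100), "0 (0%)")
  expect_equal(format_count_pct(1110, 1737), "1110 (63.9%)")
  expect_error(format_count_pct(1, 0), "positive")
})

test_that("p-value display collapses below the reporting floor", {
  expect_equal(format_pvalue(2e-5), "< .0001")
  expect_equal(format_pvalue(0.92931), "0.9293")
  expect_equal(format_pvalue(c(0.0255, 1e-6)), c("0.0255", "< .0001"))
})

test_that("2x2 chi-square matches the expected-counts formula", {
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # swapping rows or columns leaves the statistic unchanged
  t1 <- chi_square_2x2(12, 5, 7, 20)
  expect_equal(chi_square_2x2(7, 20, 12, 5)$statistic, t1$statistic)
  expect_equal(chi_square_2x2(5, 12, 20, 7)$statistic, t1$statistic)
  expect_error(chi_square_2x2(0, 0, 5, 5), "degenerate")
  set.seed(97)
  for (rep in 1:1000) {
    cells <- rpois(4, 30) + 1
    got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$statistic,
                 brute_chisq(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("strongly contrasting prevalences give vanishing p-values", {
  # patients with vs without a respiratory diagnosis, reference cluster of
  # 8588 (2003 positive) against a CC cluster of 4658 (4300 positive)
  res <- chi_square_2x2(2003, 8588 - 2003, 4300, 4658 - 4300)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$statistic, brute_chisq(2003, 6585, 4300, 358),
               tolerance = 1e-10)
})

test_that("cluster roles follow dominance and the purity floor", {
  sizes <- c(1000, 500, 200, 100)
  labels <- rep(1:4, sizes)
  cc <- unlist(lapply(1:4, function(k) {
    n_cc <- round(sizes[k] * c(0.838, 1 - 0.731, 0.70, 0.55)[k])
    c(rep("CC", n_cc), rep("non-CC", sizes[k] - n_cc))
  }))
  roles <- label_cluster_roles(labels, cc, purity_floor = 0.7)
  expect_equal(roles$name[1], "CC-1")    # largest CC cluster
  expect_equal(roles$role[2], "non-CC")
  expect_equal(roles$name[3], "CC-2")    # second by size
  expect_equal(roles$role[4], "unlabeled")
  expect_true(is.na(roles$name[4]))
})

test_that("prevalence report counts patients once per category", {
  events <- data.frame(
    patient_id = c("a", "a", "a", "b", "c", "d", "d", "e"),
    event_date = as.Date("2012-01-01"),
    code = c("J44.9", "J44.1", "E11.2", "J45", "R05", "J44", "QQ9", "E10"),
    domain = "diagnosis")
  map <- as_category_map(data.frame(
    code = c("J44", "J45", "R05", "E11", "E10"),
    domain = "diagnosis",
    category = c("Respiratory", "Respiratory", "Cough",
                 "Endocrine", "Endocrine")))
  assignments <- data.frame(patient_id = c("a", "b", "c", "d", "e"),
                            cluster = c(1, 1, 2, 2, 2))
  classes <- c("CC", "CC", "non-CC", "non-CC", "non-CC")
  roles <- label_cluster_roles(c(1, 1, 2, 2, 2), classes, purity_floor = 0.6)
  rep_tab <- prevalence_table(events, map, assignments, roles)
  resp_cc <- rep_tab[rep_tab$category == "Respiratory" &
                       rep_tab$role == "CC", ]
  # patient a has two J44 events but counts once; b has J45
  expect_equal(resp_cc$count, 2)
  expect_equal(resp_cc$formatted, "2 (100%)")
  resp_ref <- rep_tab[rep_tab$category == "Respiratory" &
                        rep_tab$role == "non-CC", ]
  expect_equal(resp_ref$count, 1)   # d only
  expect_equal(resp_ref$formatted, "1 (33.33%)")
  # chi-square computed for CC rows against the non-CC reference
  expect_false(is.na(resp_cc$p_value))
  expect_true(is.na(resp_ref$p_value))
  # unmapped code tallied, not counted
  expect_equal(sum(attr(rep_tab, "skipped_codes")), 1)
  cough_zero <- rep_tab[rep_tab$category == "Cough" & rep_tab$role == "CC", ]
  expect_equal(cough_zero$formatted, "0 (0%)")
  lines <- render_prevalence(rep_tab)
  expect_true(any(grepl("Respiratory", lines)))
})

test_that("prevalence percentages recompute exactly from their counts", {
  cohort <- small_cohort(n = 120)
  fm <- build_feature_matrix(cohort$events)
  classes <- cohort$labels$class[match(fm$row_ids, cohort$labels$patient_id)]
  km <- kmeans_pca(fm, 4, 20, seed = 2)
  roles <- label_cluster_roles(km$labels, classes, purity_floor = 0.5)
  rep_tab <- prevalence_table(cohort$events, cohort$map,
                              data.frame(patient_id = fm$row_ids,
                                         cluster = km$labels), roles)
  expect_true(all(abs(rep_tab$percentage -
                        100 * rep_tab$count / rep_tab$size) < 0.005))
  expect_true(all(rep_tab$count >= 0 & rep_tab$count <= rep_tab$size))
  # deterministic given inputs
  rep_tab2 <- prevalence_table(cohort$events, cohort$map,
                               data.frame(patient_id = fm$row_ids,
                                          cluster = km$labels), roles)
  expect_identical(rep_tab, rep_tab2)
})

test_that("cohort summary formats means, percentages, and unknowns", {
  demo <- data.frame(
    class = rep(c("non-CC", "CC"), c(6, 4)),
    age = c(40, 50, 60, 30, 20, 70, 55, 65, 45, 35),
    gender = c("Male", "Male", "Female", "Female", "Female", NA,
               "Male", "Female", "Female", "Female"))
  out <- cohort_summary(demo, group_col = "class")
  age_row <- out[out$variable == "age", ]
  expect_equal(age_row[["CC"]], sprintf("%.2f (%.2f)", 50, sd(c(55, 65, 45, 35))))
  male_row <- out[out$level == "Male", ]
  # denominators exclude the unknown gender
  expect_equal(male_row[["non-CC"]], format_count_pct(2, 5, big_mark = ","))
  unk_row <- out[out$level == "Unknown", ]
  expect_equal(unk_row[["non-CC"]], "1")
  expect_equal(unk_row[["CC"]], "")
  # single observation: SD reported blank
  single <- cohort_summary(data.frame(class = "CC", age = 50),
                           group_col = "class")
  expect_equal(single[["CC"]], "50.00 ()")
})
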