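test_that("IPSS-R component points, totals and tiers follow the table", {
  b <- score_ipssr(9.5, 120, 1.0, 1, "Good")
  expect_equal(unname(b$points[c("cytogenetics", "bm_blast_pct", "hemoglobin",
                                 "platelets", "anc")]),
               c(1, 0, 1, 0, 0))
  expect_equal(b$total, 2.0)
  expect_equal(b$tier, "Low")

  b <- score_ipssr(7, 40, 0.5, 12, "VeryPoor")
  expect_equal(b$total, 10)
  expect_equal(b$tier, "VeryHigh")

  # blast bin edges: 5% sits in the closed 5-10 bin, 2% in the lowest
  expect_equal(unname(score_ipssr(10, 100, 1, 5, "Good")$points["bm_blast_pct"]), 2)
  expect_equal(unname(score_ipssr(10, 100, 1, 2, "Good")$points["bm_blast_pct"]), 0)
  expect_equal(unname(score_ipssr(10, 100, 1, 2.5, "Good")$points["bm_blast_pct"]), 1)

  # VeryLow collapses into Low in the four-group view
  b <- score_ipssr(11, 150, 1.5, 1, "VeryGood")
  expect_equal(b$tier, "VeryLow")
  expect_equal(b$tier4, "Low")

  expect_error(score_ipssr(NA, 100, 1, 1, "Good"), "hemoglobin")
  expect_error(score_ipssr(10, 100, 1, 1, "Unknown"), "Unknown")
})

test_that("the 3.5-point dichotomy separates lower from higher risk", {
  expect_equal(dichotomize_ipssr(3.5), "lower")
  expect_equal(dichotomize_ipssr(4.0), "higher")
  expect_equal(dichotomize_ipssr(0), "lower")
  b <- score_ipssr(9.5, 120, 1.0, 1, "Good")
  expect_equal(dichotomize_ipssr(b), "lower")
})

test_that("selected-gene mutation counting is distinct-gene after pooling", {
  expect_equal(count_selected_mutations(c("TP53", "NRAS")), 2)
  expect_equal(count_selected_mutations("SF3B1"), 0)
  expect_equal(count_selected_mutations(c("TP53", "TP53")), 1)
  expect_equal(count_selected_mutations(character()), 0)
  expect_error(count_selected_mutations("TP53", selected = character()),
               "empty")
})

test_that("M-IPSS-R factor sums and tier boundaries match the proposed system", {
  expect_equal(score_mipssr(0, "SLD", 1, "Good", 25)$total, 0)
  expect_equal(score_mipssr(1, "EB", 12, "VeryPoor", 65)$total, 9)
  expect_equal(score_mipssr(2, "MLD", 2, "Intermediate", 55)$total, 5)
  # MLD with blasts in 2-<5% scores the dysplasia bin, not a blast bin
  expect_equal(unname(score_mipssr(0, "MLD", 4, "Good", 40)$points["morphology"]), 1)
  # blasts >= 5% pull any patient onto the blast bins
  expect_equal(unname(score_mipssr(0, "MLD", 7, "Good", 40)$points["morphology"]), 2)
  expect_equal(unname(score_mipssr(0, "EB", 10, "Good", 40)$points["morphology"]), 2)
  expect_equal(unname(score_mipssr(0, "EB", 10.5, "Good", 40)$points["morphology"]), 3)
  # >4 mutations cap at 5 points
  expect_equal(unname(score_mipssr(6, "SLD", 1, "Good", 25)$points["gene_mutations"]), 5)

  expect_equal(classify_mipssr(3.0), "Low")
  expect_equal(classify_mipssr(0.5), "Low")
  expect_equal(classify_mipssr(3.5), "Intermediate")
  expect_equal(classify_mipssr(5.5), "Intermediate")
  expect_equal(classify_mipssr(6.0), "High")
  expect_error(classify_mipssr(-1), "non-negative")
})

test_that("scores are bounded multiples of 0.5 and monotone in risk factors", {
  morphs <- list(c("SLD", 1), c("MLD", 1), c("EB", 7), c("EB", 12))
  cytos <- c("Good", "Intermediate", "Poor", "VeryPoor")
  ages <- c(25, 40, 55, 70)
  totals <- c()
  for (m in morphs) for (cy in cytos) for (a in ages) for (k in c(0, 2, 5)) {
    t_ <- score_mipssr(k, m[1], as.numeric(m[2]), cy, a)$total
    expect_gte(t_, 0); expect_lte(t_, 13)
    expect_equal((t_ * 2) %% 1, 0)
    totals <- c(totals, t_)
  }
  expect_equal(max(totals), 13)

  # adding a selected-gene mutation never decreases the total
  for (k in 0:6) {
    expect_gte(score_mipssr(k + 1, "MLD", 2, "Intermediate", 55)$total,
               score_mipssr(k, "MLD", 2, "Intermediate", 55)$total)
  }
  # worsening any single factor bin never decreases the total
  for (i in seq_len(length(morphs) - 1)) {
    expect_gte(score_mipssr(1, morphs[[i + 1]][1], as.numeric(morphs[[i + 1]][2]),
                            "Good", 40)$total,
               score_mipssr(1, morphs[[i]][1], as.numeric(morphs[[i]][2]),
                            "Good", 40)$total)
  }
  for (i in seq_len(length(cytos) - 1)) {
    expect_gte(score_mipssr(1, "SLD", 1, cytos[i + 1], 40)$total,
               score_mipssr(1, "SLD", 1, cytos[i], 40)$total)
  }
  for (i in seq_len(length(ages) - 1)) {
    expect_gte(score_mipssr(1, "SLD", 1, "Good", ages[i + 1])$total,
               score_mipssr(1, "SLD", 1, "Good", ages[i])$total)
  }
})

test_that("score tables are data and malformed tables are rejected at load", {
  tab <- jsonlite::read_json(system.file("extdata", "config",
                                         "mipssr_default.json",
                                         package = "mdsrisk"))
  f <- withr::local_tempfile(fileext = ".json")
  # overlapping age bins must be refused
  tab$factors$age$bins[[2]]$lo <- 20
  jsonlite::write_json(tab, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_score_table(f), "overlap|gap")

  # swapping a table changes outputs with no code change
  tab <- jsonlite::read_json(system.file("extdata", "config",
                                         "mipssr_default.json",
                                         package = "mdsrisk"))
  tab$factors$age$bins[[4]]$points <- 3
  tab$version <- "modified"
  jsonlite::write_json(tab, f, auto_unbox = TRUE, digits = NA)
  alt <- load_score_table(f)
  expect_equal(score_mipssr(0, "SLD", 1, "Good", 70, table = alt)$total, 3)
  expect_equal(score_mipssr(0, "SLD", 1, "Good", 70)$total, 2)
})

test_that("reclassification directions conserve N and match a brute-force recount", {
  g <- generate_cohort(simulation_config(seed = 17))
  scores <- score_cohort(g$cohort)
  rep_ <- compare_stratification(scores)
  expect_equal(sum(rep_$counts), rep_$n_compared)
  expect_equal(rep_$n_compared, nrow(g$cohort$patients))

  # independent per-patient recount on the ordinal alignment
  ord_ip <- c(Low = 1, Intermediate = 2, High = 3, VeryHigh = 3)
  ord_mp <- c(Low = 1, Intermediate = 2, High = 3)
  dirs <- mapply(function(ip, mp) {
    d <- ord_mp[[mp]] - ord_ip[[ip]]
    if (d < 0) "decreased" else if (d > 0) "increased" else "unchanged"
  }, scores$ipssr_group4, scores$mipssr_tier)
  expect_equal(unname(rep_$counts["decreased"]), sum(dirs == "decreased"))
  expect_equal(unname(rep_$counts["increased"]), sum(dirs == "increased"))
  expect_equal(rep_$per_patient$direction, unname(dirs))

  # a cohort where both systems agree everywhere moves nobody
  same <- data.frame(patient_id = c("A", "B"),
                     ipssr_group4 = c("Low", "High"),
                     mipssr_tier = c("Low", "High"),
                     stringsAsFactors = FALSE)
  rep0 <- compare_stratification(same)
  expect_equal(unname(rep0$counts), c(0L, 2L, 0L))
})
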