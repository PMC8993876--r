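test_that("patient table round-trips through write and read", {
  ch <- make_test_cohort(5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_patient_table(ch, f)
  back <- read_patient_table(f)
  for (col in c("patient_id", "sex", "morphology", "karyotype")) {
    expect_identical(back$patients[[col]], ch$patients[[col]])
  }
  for (col in c("age", "hemoglobin", "platelets", "anc", "bm_blast_pct",
                "os_months")) {
    expect_equal(back$patients[[col]], ch$patients[[col]])
  }
  expect_identical(back$patients$event, ch$patients$event)
  # csv dialect too
  fc <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(ch, fc, dialect = "csv")
  expect_equal(read_patient_table(fc, dialect = "csv")$patients$hemoglobin,
               ch$patients$hemoglobin)
})

test_that("schema and value errors name the offending column or row", {
  df <- make_test_patients(3)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[setdiff(names(df), "os_months")], f, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_patient_table(f), "os_months")

  bad <- df
  bad$age[2] <- "twelve"
  utils::write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_patient_table(f), "age.*2")

  dup <- df
  dup$patient_id[2] <- dup$patient_id[1]
  expect_error(mds_cohort(dup), "duplicate")

  rng <- df
  rng$bm_blast_pct[1] <- 150
  expect_error(mds_cohort(rng), "bm_blast_pct")
})

test_that("extreme cohort ages are accepted and EB below 5% blasts warns", {
  df <- make_test_patients(2)
  df$age <- c(16, 90)
  expect_silent(ch <- mds_cohort(df))
  expect_equal(ch$patients$age, c(16, 90))

  eb <- make_test_patients(1)
  eb$morphology <- "EB"
  eb$bm_blast_pct <- 3
  expect_warning(mds_cohort(eb), "EB.*blasts < 5")
})

test_that("mutation table reading normalizes symbols and derives classes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgene\traw_ref\traw_alt",
               "P01\ttp53\tA\tG",
               "P01\tSF3B1\tAT\tA",
               "P02\tASXL1\tA\tAGG"), f)
  calls <- read_mutation_table(f)
  expect_equal(calls$gene, c("TP53", "SF3B1", "ASXL1"))
  expect_equal(calls$variant_class,
               c("substitution", "deletion", "insertion"))

  # empty file with a valid header
  writeLines("patient_id\tgene\tvariant_class", f)
  expect_equal(nrow(read_mutation_table(f)), 0)

  # a row with no class and no alleles is an indexed error
  writeLines(c("patient_id\tgene\tvariant_class\traw_ref\traw_alt",
               "P01\tTP53\tsubstitution\tNA\tNA",
               "P02\tTET2\tNA\tNA\tNA"), f)
  expect_error(read_mutation_table(f), "row 2")
})

test_that("variant classification is total over allele pairs and never calls duplication without context", {
  expect_equal(classify_variant_class("A", "G"), "substitution")
  expect_equal(classify_variant_class("AT", "A"), "deletion")
  expect_equal(classify_variant_class("A", "AGG"), "insertion")
  expect_error(classify_variant_class("AN", "A"), "non-nucleotide")
  # with upstream context a repeated inserted segment is a duplication
  expect_equal(classify_variant_class("A", "AG", context = "TTA"), "insertion")
  expect_equal(classify_variant_class("T", "TT", context = "GCA"), "duplication")
  expect_equal(classify_variant_class("A", "AA"), "insertion")
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
    cls <- classify_variant_class(ref, alt)
    expect_true(cls %in% c("substitution", "deletion", "insertion"))
    nr <- nchar(ref); na_ <- nchar(alt)
    expect_equal(cls, if (nr == na_) "substitution"
                 else if (na_ < nr) "deletion" else "insertion")
  }
})

test_that("attaching mutations respects strictness and identity", {
  ch <- make_test_cohort(3)
  ch2 <- attach_mutations(ch, make_calls(c("P01", "P01"), c("TP53", "TET2")))
  expect_equal(nrow(ch2$mutations), 2)
  expect_equal(sort(patient_genes(ch2, "P01")), c("TET2", "TP53"))

  expect_error(attach_mutations(ch, make_calls("P99", "TP53"), strict = TRUE),
               "P99")
  expect_warning(lenient <- attach_mutations(ch, make_calls("P99", "TP53")),
                 "P99")
  expect_equal(nrow(lenient$mutations), 0)
  # zero calls leave the cohort unchanged
  expect_identical(attach_mutations(ch, make_calls(character(), character())),
                   ch)
})

test_that("cohort summary reproduces per-subtype means and recount oracle", {
  # 46 EB patients with 93 calls: mean calls per patient 2.02
  df <- make_test_patients(46)
  df$morphology <- "EB"
  df$bm_blast_pct <- 10
  ch <- mds_cohort(df)
  calls <- make_calls(rep(df$patient_id, length.out = 93),
                      rep(c("TP53", "TET2", "ASXL1"), length.out = 93))
  ch <- attach_mutations(ch, calls)
  s <- summarize_cohort(ch)
  expect_equal(s$per_subtype$mean_calls[s$per_subtype$subtype == "EB"], 2.02)

  # no calls: median 0, all means 0
  s0 <- summarize_cohort(make_test_cohort(5))
  expect_equal(s0$median_mutations, 0)
  expect_equal(s0$per_subtype$mean_calls, rep(0, 3))
  expect_equal(s0$n_with_mutation, 0)
  expect_error(summarize_cohort(mds_cohort(make_test_patients(0))), "empty")

  # random fixture: summary equals an independent brute-force recount
  set.seed(5)
  df <- make_test_patients(20)
  ch <- mds_cohort(df)
  calls <- make_calls(sample(df$patient_id, 37, replace = TRUE),
                      sample(c("TP53", "SF3B1", "TET2", "RUNX1"), 37,
                             replace = TRUE))
  ch <- attach_mutations(ch, calls)
  s <- summarize_cohort(ch)
  counts <- vapply(df$patient_id, function(id)
    sum(calls$patient_id == id), 0L)
  expect_equal(s$median_mutations, median(counts))
  expect_equal(s$range_mutations, range(counts))
  expect_equal(s$n_with_mutation, sum(counts > 0))
  # conservation: per-subtype call totals sum to the total call count
  expect_equal(sum(s$per_subtype$n_calls), nrow(ch$mutations))
  expect_equal(sum(s$variant_class_tally), nrow(ch$mutations))
})

test_that("gene pooling maps families to their shared labels", {
  pooling <- load_gene_pooling()
  expect_equal(pool_genes(c("JAK2", "JAK3", "TP53"), pooling),
               c("JAK2/3", "JAK2/3", "TP53"))
  ch <- make_test_cohort(2, make_calls(c("P01", "P01"), c("JAK2", "JAK3")))
  expect_equal(patient_genes(ch, "P01", pooling), "JAK2/3")
})
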