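test_that("cohort tables round-trip through the canonical CSV dialect", {
  co <- simulate_cohort(cohort_params(n_patients = 25, seed = 14))
  f <- tempfile(fileext = ".csv")
  write_cohort_table(co, f)
  tab <- read_cohort_table(f)
  expect_s3_class(tab, "cohort_table")
  expect_equal(tab$n_read, 25)
  expect_equal(tab$n_rejected, 0)
  expect_equal(nrow(tab$records), 25)
  expect_equal(tab$records$patient_id, co$patient_id)
  expect_equal(tab$records$ki67_sum, co$ki67_sum, tolerance = 1e-10)
  expect_equal(tab$records$event, co$event)
  # write(read(x)) preserves all mapped fields: re-reading is a fixed point
  f2 <- tempfile(fileext = ".csv")
  write_cohort_table(tab$records, f2)
  tab2 <- read_cohort_table(f2)
  expect_equal(tab2$records, tab$records, tolerance = 1e-12)
  expect_equal(names(tab2$records), names(tab$records))
})

test_that("schema violations and malformed rows are caught", {
  co <- simulate_cohort(cohort_params(n_patients = 12, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_cohort_table(co[, setdiff(names(co), "ck_sum")], f)
  expect_error(read_cohort_table(f), "schema error.*ck_sum")
  # 3-row fixture with one malformed row: 2 accepted, 1 rejected
  fix <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,ki67_sum,ck_sum",
               "P1,100,1000",
               "P2,not-a-number,1000",
               "P3,50,500"), fix)
  tab <- suppressMessages(read_cohort_table(fix))
  expect_equal(tab$n_read, 3)
  expect_equal(tab$n_rejected, 1)
  expect_equal(tab$records$patient_id, c("P1", "P3"))
  expect_true(any(grepl("row 2", tab$log)))
  # inconsistent stored ratio is rejected; consistent one is recomputed
  fr <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,ki67_sum,ck_sum,ki67_ck_ratio",
               "P1,100,1000,0.1",
               "P2,100,1000,0.2"), fr)
  tab2 <- suppressMessages(read_cohort_table(fr))
  expect_equal(nrow(tab2$records), 1)
  expect_equal(tab2$records$ki67_ck_ratio, 0.1)
  # column mapping onto foreign headers
  fm <- tempfile(fileext = ".csv")
  writeLines(c("id,Ki67 value,CK value", "P1,10,100", "P2,20,100"), fm)
  tab3 <- read_cohort_table(fm, column_map = c(patient_id = "id",
                                               ki67_sum = "Ki67 value",
                                               ck_sum = "CK value"))
  expect_equal(tab3$records$ki67_ck_ratio, c(0.1, 0.2))
  expect_error(read_cohort_table(fm, column_map = c(ki67_sum = "absent")),
               "schema error")
})

test_that("the pipeline runs end to end deterministically", {
  cfg <- list(seed = 5,
              scene = list(enabled = TRUE, height = 64, width = 64, n_nests = 2,
                           nest_axes = c(8, 14), n_fields = 2),
              cohort = list(source = "simulate", n_patients = 120,
                            baseline_hazard = 0.006))
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  rep1 <- suppressWarnings(suppressMessages(run_pipeline(cfg, output_dir = out1)))
  rep2 <- suppressWarnings(suppressMessages(run_pipeline(cfg, output_dir = out2)))
  # all artifacts emitted
  expect_true(all(file.exists(file.path(out1, c(
    "cohort_with_grades.csv", "cutpoint_scan_ki67_sum.csv",
    "cutpoint_scan_ki67_ck_ratio.csv", "cox_ki67_sum.csv",
    "cox_ki67_ck_ratio.csv", "roc.csv", "manifest.json")))))
  # identical config + seed -> byte-identical result tables
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }
  # report structure is complete and grades recomputed from the cut-offs
  expect_s3_class(rep1$cutpoints$ki67_ck_ratio, "cutpoint_result")
  expect_identical(rep1$cohort$ki67_ck_ratio_grade,
                   assign_grade(rep1$cohort$ki67_ck_ratio,
                                rep1$cutpoints$ki67_ck_ratio$cutoff))
  expect_s3_class(rep1$cox$ki67_ck_ratio, "cox_fit_table")
  expect_true("ki67_ck_ratio_grade_ii" %in% rep1$cox$ki67_ck_ratio$term)
  expect_s3_class(rep1$roc$ki67_ck_ratio_grade, "roc_result")
  expect_false(is.null(rep1$imaging))
  expect_lt(rep1$imaging$ratio_recovery_error, 0.10)
  # a pipeline fed a cohort file reproduces the simulate branch
  f <- tempfile(fileext = ".csv")
  write_cohort_table(rep1$cohort[, 1:13], f)
  rep3 <- suppressWarnings(suppressMessages(run_pipeline(
    list(seed = 5, scene = list(enabled = FALSE),
         cohort = list(source = "file", path = f)))))
  expect_equal(rep3$cutpoints$ki67_ck_ratio$cutoff,
               rep1$cutpoints$ki67_ck_ratio$cutoff)
  expect_null(rep3$imaging)
})

test_that("the bundled YAML demo config drives the pipeline", {
  cfg <- system.file("extdata", "demo_config.yaml", package = "ki67ck")
  expect_true(nzchar(cfg))
  rep <- suppressWarnings(suppressMessages(run_pipeline(cfg, seed = 2)))
  expect_equal(nrow(rep$cohort), 240)
  expect_false(is.null(rep$imaging))
  expect_equal(rep$manifest$seed, 2L)
})

test_that("pipeline recovers the designed hazard ratio for the ratio grade", {
  rep <- suppressWarnings(suppressMessages(run_pipeline(
    list(seed = 11, scene = list(enabled = FALSE),
         cohort = list(source = "simulate", n_patients = 500,
                       log_hr = log(2), baseline_hazard = 0.006,
                       censor_rate = 0.001)))))
  cx <- rep$cox$ki67_ck_ratio
  hr <- cx$hr[cx$term == "ki67_ck_ratio_grade_ii"]
  expect_gte(hr, 1.5)
  expect_lte(hr, 2.7)
})
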