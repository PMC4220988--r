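# Cohort container, event-CSV round trips, record filtering rules and
# genotype QC.

test_that("a hand-written event CSV loads into the expected cohort", {
  path <- tempfile(fileext = ".csv")
  hdr <- paste("ID,EVID,DATE,TIME,AMT,II,SS,DV_CONC,DV_GGT,AGE,SEX,WT,",
               "DDOSE,SOD2,CYP2C9,CYP2C19,GSTM1,GSTT1,IDIS,CBZ,CLB,PB,",
               "PHT,TPM,ZNS,GBP,START", sep = "")
  cov1 <- "20,male,55,800,ValVal,*1/*1,homEM,null,present,0,0,0,0,0,0,0,0,2001-01-01"
  cov2 <- "10,female,30,400,ValAla,*1/*1,hetEM,present,null,1,1,0,0,0,0,0,0,2002-03-01"
  cov3 <- "35,female,60,1200,ValVal,*1/*3,PM,null,null,0,0,1,0,1,0,0,0,2000-07-15"
  rows <- c(
    paste0("A,0,,2,400,24,1,55.1,,", cov1),
    paste0("A,0,,9,400,24,1,70.3,,", cov1),
    paste0("A,2,2002-06-01,,,,,,80,", cov1),
    paste0("B,0,,4,200,24,1,48.0,,", cov2),
    paste0("B,0,,16,200,24,1,31.2,,", cov2),
    paste0("C,0,,6,600,24,1,90.5,,", cov3),
    paste0("C,0,,23,600,24,1,60.0,,", cov3))
  writeLines(c(hdr, rows), path)
  co <- load_cohort(path, default_uln())
  expect_s3_class(co, "vpa_cohort")
  expect_equal(nrow(co$subjects), 3)
  expect_equal(nrow(co$pk_records), 6)
  expect_equal(nrow(co$ggt_records), 1)
  # subject A is a 20-year-old male: ULN 70, value 80 -> elevated
  expect_equal(co$ggt_records$elevated, 1L)
  expect_equal(co$ggt_records$months_since_vpa_start,
               as.numeric(as.Date("2002-06-01") - as.Date("2001-01-01")) /
                 30.4375)
  # a concentration row for an unknown subject is an integrity error
  writeLines(c(hdr, rows, paste0("ZZ,0,,2,400,24,1,50,,",
                                 ",,,,,,,,,,,,,,,,,")), path)
  expect_error(load_cohort(path, default_uln()), "integrity")
  # a missing required column is a format error
  writeLines(c(sub("DV_CONC,", "", hdr)), path)
  expect_error(load_cohort(path, default_uln()), "missing column")
})

test_that("write/load round trip reproduces a synthetic cohort exactly", {
  st <- generate_study(generator_config(n_subjects = 25), seed = 11)
  path <- tempfile(fileext = ".csv")
  write_cohort(st$cohort, path)
  back <- load_cohort(path, default_uln())
  orig <- st$cohort
  rownames(orig$pk_records) <- rownames(back$pk_records) <- NULL
  rownames(orig$ggt_records) <- rownames(back$ggt_records) <- NULL
  expect_equal(back$subjects, orig$subjects, tolerance = 1e-12)
  expect_equal(back$pk_records, orig$pk_records, tolerance = 1e-12)
  expect_equal(back$ggt_records, orig$ggt_records, tolerance = 1e-12)
  # double round trip is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("constructor enforces referential and domain invariants", {
  s <- make_subjects(3)
  bad_pk <- data.frame(subject_id = "NOPE", time_after_last_dose = 2,
                       dose_per_administration = 200, dosing_interval = 24,
                       value = 50, steady_state = TRUE)
  expect_error(vpa_cohort(s, bad_pk), "integrity")
  s_bad <- s
  s_bad$sod2[1] <- "ValVal/Ala"
  expect_error(vpa_cohort(s_bad), "sod2")
  s_bad2 <- s
  s_bad2$daily_dose[2] <- 5000
  expect_error(vpa_cohort(s_bad2), "daily_dose")
})

test_that("noncompliance filtering partitions records at the LOQ", {
  rec <- data.frame(subject_id = c("a", "b", "c"),
                    value = c(0.5, 7.7, 68.2))
  out <- flag_noncompliance(rec, loq = 1)
  expect_equal(out$kept$value, c(7.7, 68.2))
  expect_equal(out$excluded$value, 0.5)
  # partition preserving and order preserving
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(rec))
  # idempotent on the kept part
  again <- flag_noncompliance(out$kept, loq = 1)
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$excluded), 0)
  # edge cases
  empty <- flag_noncompliance(rec[0, ], loq = 1)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)
  all_ok <- flag_noncompliance(data.frame(value = c(5, 9)), loq = 1)
  expect_equal(nrow(all_ok$excluded), 0)
  expect_error(flag_noncompliance(rec, loq = -1), "loq")
})

test_that("gamma-GT binarisation is strict, stratified and monotone", {
  uln <- uln_table(sex = c("male", "female"), age_lo = c(0, 0),
                   age_hi = c(100, 100), uln = c(70, 40))
  # value equal to its limit is normal
  expect_equal(binarize_ggt(70, 30, "male", uln), 0L)
  # same value, different sex strata
  expect_equal(binarize_ggt(51.3, 25, "male", uln), 0L)
  expect_equal(binarize_ggt(51.3, 25, "female", uln), 1L)
  # the cohort's observed maximum is elevated under any limit <= 100
  expect_equal(binarize_ggt(515, 40, "male", uln), 1L)
  # monotone in value for fixed (age, sex, table)
  v <- binarize_ggt(seq(10, 120, 5), 30, "male", uln)
  expect_true(all(diff(v) >= 0))
  # no covering band is a coverage error naming sex and age
  narrow <- uln_table("male", 0, 18, 35)
  expect_error(binarize_ggt(50, 30, "male", narrow), "male.*30")
})

test_that("early-therapy gamma-GT records are excluded with the 6-month boundary kept", {
  rec <- data.frame(subject_id = "x", months_since_vpa_start = c(2, 6, 14))
  out <- filter_early_ggt(rec)
  expect_equal(out$months_since_vpa_start, c(6, 14))
  expect_equal(filter_early_ggt(rec, min_months = 0), rec)
  none <- filter_early_ggt(data.frame(months_since_vpa_start = c(1, 5)))
  expect_equal(nrow(none), 0)
  # idempotent
  expect_equal(filter_early_ggt(out), out)
})

test_that("genotype QC computes allele frequency and the HWE Pearson statistic", {
  # genotype distribution of the 237-patient cohort: 93.7% / 6.3% / 0%
  qc <- genotype_qc(c(222, 15, 0))
  expect_equal(round(100 * qc$allele_freq, 1), 3.2)
  # monomorphic marker: frequency 0, chi2 0
  mono <- genotype_qc(c(100, 0, 0))
  expect_equal(mono$allele_freq, 0)
  expect_equal(mono$hwe_chi2, 0)
  # spreadsheet-style Pearson oracle, frozen from sum((obs-exp)^2/exp)
  # with N = 100, q = 0.3: expected (49, 42, 9)
  qc2 <- genotype_qc(c(50, 40, 10))
  expect_equal(qc2$hwe_chi2, 1 / 49 + 4 / 42 + 1 / 9, tolerance = 1e-12)
  expect_equal(qc2$hwe_p, pchisq(qc2$hwe_chi2, 1, lower.tail = FALSE))
  # chi2 is zero exactly at HWE counts and positive otherwise
  expect_equal(genotype_qc(c(49, 42, 9))$hwe_chi2, 0, tolerance = 1e-12)
  expect_gt(genotype_qc(c(60, 20, 20))$hwe_chi2, 0)
  expect_error(genotype_qc(c(0, 0, 0)), "zero")
})

test_that("the QC report summarises cohort genotype frequencies", {
  st <- generate_study(generator_config(n_subjects = 50), seed = 3)
  rep <- qc_report(st$cohort)
  expect_equal(rep$n_subjects, 50)
  expect_true(rep$sod2$allele_freq >= 0 && rep$sod2$allele_freq <= 1)
  path <- tempfile(fileext = ".json")
  qc_report(st$cohort, path)
  expect_true(file.exists(path))
  expect_equal(jsonlite::read_json(path)$n_subjects, 50)
})
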