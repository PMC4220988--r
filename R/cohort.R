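# Cohort container, NONMEM-style event CSV reader/writer, and the
# record-level filtering / QC rules applied before modelling.

.sod2_levels <- c("ValVal", "ValAla", "AlaAla")
.cyp2c9_levels <- c("*1/*1", "*1/*3", "*3/*3")
.cyp2c19_levels <- c("homEM", "hetEM", "PM")
.gst_levels <- c("null", "present")
.comed_cols <- c("cbz", "clb", "pb", "pht", "tpm", "zns", "gbp")

#' Construct a validated VPA cohort
#'
#' A cohort bundles the subject covariate table with the longitudinal
#' concentration records and binary gamma-GT records. Every record's
#' \code{subject_id} must resolve to a subject (integrity error otherwise).
#'
#' @param subjects data.frame with columns \code{subject_id}, \code{age}
#'   (years), \code{sex} ("male"/"female"), \code{body_weight} (kg),
#'   \code{daily_dose} (mg/day), \code{sod2}, \code{cyp2c9}, \code{cyp2c19},
#'   \code{gstm1}, \code{gstt1}, \code{intellectual_disability} (logical),
#'   0/1 co-medication flags \code{cbz}, \code{clb}, \code{pb}, \code{pht},
#'   \code{tpm}, \code{zns}, \code{gbp}, and \code{vpa_start_date} (Date).
#' @param pk_records data.frame with \code{subject_id},
#'   \code{time_after_last_dose} (h), \code{dose_per_administration} (mg),
#'   \code{dosing_interval} (h), \code{value} (mg/L), \code{steady_state}
#'   (logical). May be empty.
#' @param ggt_records data.frame with \code{subject_id},
#'   \code{measurement_date} (Date), \code{value} (IU/L), \code{elevated}
#'   (0/1 or NA before binarisation); \code{months_since_vpa_start} is
#'   derived from the dates here.
#' @param dose_range admissible daily-dose range (mg/day), configurable.
#' @return object of class \code{vpa_cohort}.
#' @export
vpa_cohort <- function(subjects, pk_records = NULL, ggt_records = NULL,
                       dose_range = c(100, 2600)) {
  req <- c("subject_id", "age", "sex", "body_weight", "daily_dose", "sod2",
           "cyp2c9", "cyp2c19", "gstm1", "gstt1", "intellectual_disability",
           .comed_cols, "vpa_start_date")
  miss <- setdiff(req, names(subjects))
  if (length(miss))
    stop("vpa_cohort: subjects is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("vpa_cohort: duplicated subject_id")
  if (any(subjects$age <= 0) || any(subjects$body_weight <= 0))
    stop("vpa_cohort: age and body_weight must be positive")
  if (any(subjects$daily_dose < dose_range[1]) ||
      any(subjects$daily_dose > dose_range[2]))
    stop("vpa_cohort: daily_dose outside [", dose_range[1], ", ",
         dose_range[2], "] mg/day")
  chk <- function(col, levels)
    if (!all(subjects[[col]] %in% levels))
      stop("vpa_cohort: invalid ", col, " value(s); allowed: ",
           paste(levels, collapse = ", "))
  chk("sex", c("male", "female"))
  chk("sod2", .sod2_levels)
  chk("cyp2c9", .cyp2c9_levels)
  chk("cyp2c19", .cyp2c19_levels)
  chk("gstm1", .gst_levels)
  chk("gstt1", .gst_levels)

  if (is.null(pk_records))
    pk_records <- data.frame(subject_id = character(),
                             time_after_last_dose = numeric(),
                             dose_per_administration = numeric(),
                             dosing_interval = numeric(), value = numeric(),
                             steady_state = logical())
  if (is.null(ggt_records))
    ggt_records <- data.frame(subject_id = character(),
                              measurement_date = as.Date(character()),
                              value = numeric(), elevated = integer())

  ids <- subjects$subject_id
  bad_pk <- setdiff(unique(pk_records$subject_id), ids)
  bad_ggt <- setdiff(unique(ggt_records$subject_id), ids)
  if (length(bad_pk) || length(bad_ggt))
    stop("vpa_cohort: integrity error, record(s) reference unknown ",
         "subject_id: ", paste(unique(c(bad_pk, bad_ggt)), collapse = ", "))
  if (nrow(pk_records) && any(pk_records$value < 0))
    stop("vpa_cohort: negative concentration value")
  if (nrow(ggt_records)) {
    start <- subjects$vpa_start_date[match(ggt_records$subject_id, ids)]
    ggt_records$months_since_vpa_start <-
      as.numeric(ggt_records$measurement_date - start) / 30.4375
    if (any(ggt_records$value <= 0))
      stop("vpa_cohort: gamma-GT values must be positive")
  } else {
    ggt_records$months_since_vpa_start <- numeric()
  }
  structure(list(subjects = subjects, pk_records = pk_records,
                 ggt_records = ggt_records),
            class = "vpa_cohort")
}

#' @export
print.vpa_cohort <- function(x, ...) {
  cat("VPA cohort:", nrow(x$subjects), "subjects,",
      nrow(x$pk_records), "concentration records,",
      nrow(x$ggt_records), "gamma-GT records\n")
  invisible(x)
}

#' Read an age/sex-stratified gamma-GT upper-limit-of-normal table
#'
#' CSV columns: \code{SEX} ("male"/"female"), \code{AGE_LO}, \code{AGE_HI}
#' (years, band is [AGE_LO, AGE_HI)), \code{ULN} (IU/L). Bands per sex must
#' not overlap. No authoritative limits are published for the reference
#' cohort; the table is user-supplied configuration (a clearly synthetic
#' default ships in \code{inst/extdata/uln_synthetic.csv}).
#'
#' @param path CSV file path.
#' @return data.frame of class \code{uln_table}.
#' @export
read_uln <- function(path) {
  u <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("SEX", "AGE_LO", "AGE_HI", "ULN")
  if (!all(need %in% names(u)))
    stop("read_uln: file must have columns ", paste(need, collapse = ", "))
  uln_table(u$SEX, u$AGE_LO, u$AGE_HI, u$ULN)
}

#' Construct a ULN table
#' @param sex,age_lo,age_hi,uln vectors defining the bands (band is
#'   [age_lo, age_hi), IU/L).
#' @return data.frame of class \code{uln_table}.
#' @export
uln_table <- function(sex, age_lo, age_hi, uln) {
  u <- data.frame(sex = sex, age_lo = age_lo, age_hi = age_hi, uln = uln)
  if (!all(u$sex %in% c("male", "female")))
    stop("uln_table: sex must be male/female")
  if (any(u$age_hi <= u$age_lo) || any(u$uln <= 0))
    stop("uln_table: bands need age_hi > age_lo and ULN > 0")
  for (s in unique(u$sex)) {
    b <- u[u$sex == s, ]
    b <- b[order(b$age_lo), ]
    if (nrow(b) > 1 && any(b$age_lo[-1] < b$age_hi[-nrow(b)]))
      stop("uln_table: overlapping age bands for sex ", s)
  }
  class(u) <- c("uln_table", "data.frame")
  u
}

#' Binarise a gamma-GT value against the age/sex-stratified ULN
#'
#' Returns 1 iff the value STRICTLY exceeds the upper limit of normal matched
#' on (sex, age); a value exactly at the limit is normal (0). Vectorised.
#'
#' @param value gamma-GT in IU/L.
#' @param age years.
#' @param sex "male"/"female".
#' @param uln a \code{\link{uln_table}}.
#' @return integer 0/1 vector.
#' @export
binarize_ggt <- function(value, age, sex, uln) {
  stopifnot(inherits(uln, "uln_table"))
  n <- max(length(value), length(age), length(sex))
  value <- rep_len(value, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  lim <- numeric(n)
  for (i in seq_len(n)) {
    row <- uln$sex == sex[i] & uln$age_lo <= age[i] & age[i] < uln$age_hi
    if (sum(row) != 1)
      stop("binarize_ggt: no ULN band covers (", sex[i], ", ", age[i],
           " years)")
    lim[i] <- uln$uln[row]
  }
  as.integer(value > lim)
}

#' Exclude concentrations below the limit of quantification
#'
#' Concentrations under the assay LOQ (1 mg/L in the reference analysis) are
#' treated as suspected temporary noncompliance and excluded. The input is
#' partitioned, order preserved.
#'
#' @param records concentration record data.frame (needs a \code{value}
#'   column).
#' @param loq limit of quantification, mg/L (> 0).
#' @return list(kept, excluded) of data.frames.
#' @export
flag_noncompliance <- function(records, loq = 1) {
  if (!is.finite(loq) || loq <= 0) stop("flag_noncompliance: loq must be > 0")
  keep <- records$value >= loq
  list(kept = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}

#' Drop gamma-GT records from the early phase of VPA therapy
#'
#' Records earlier than \code{min_months} after VPA initiation are excluded
#' (transient early elevations confound the endpoint); a record at exactly
#' \code{min_months} is kept.
#'
#' @param records gamma-GT record data.frame with
#'   \code{months_since_vpa_start}.
#' @param min_months months (default 6).
#' @return filtered data.frame.
#' @export
filter_early_ggt <- function(records, min_months = 6) {
  if (min_months < 0) stop("filter_early_ggt: min_months must be >= 0")
  records[records$months_since_vpa_start >= min_months, , drop = FALSE]
}

#' Allele frequency and Hardy-Weinberg equilibrium check
#'
#' For biallelic genotype counts (AA, Aa, aa): the 'a' allele frequency
#' \code{(n_Aa + 2 n_aa) / (2 N)}, the 1-df Pearson chi-square statistic of
#' the observed counts against the HWE-expected counts, and its upper-tail
#' p-value.
#'
#' @param counts integer vector length 3: (n_AA, n_Aa, n_aa).
#' @return list(allele_freq, hwe_chi2, hwe_p).
#' @export
genotype_qc <- function(counts) {
  if (length(counts) != 3 || any(counts < 0))
    stop("genotype_qc: counts must be 3 non-negative values")
  n <- sum(counts)
  if (n == 0) stop("genotype_qc: total count is zero")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  p <- 1 - q
  expd <- n * c(p^2, 2 * p * q, q^2)
  term <- ifelse(expd > 0, (counts - expd)^2 / expd,
                 ifelse(counts > 0, Inf, 0))
  chi2 <- sum(term)
  list(allele_freq = q, hwe_chi2 = chi2,
       hwe_p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genotype QC report for a cohort
#'
#' Allele frequencies and HWE chi-square tests for the biallelic markers
#' (SOD2 Val16Ala, CYP2C9*3) plus genotype-group and null-genotype
#' frequencies, as a list; optionally written as JSON.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @param path optional path to write the report as JSON.
#' @return report list, invisibly if written.
#' @export
qc_report <- function(cohort, path = NULL) {
  s <- cohort$subjects
  sod2 <- genotype_qc(as.integer(table(factor(s$sod2, .sod2_levels))))
  c9 <- genotype_qc(as.integer(table(factor(s$cyp2c9, .cyp2c9_levels))))
  rep <- list(
    n_subjects = nrow(s),
    sod2 = c(sod2, list(genotype_pct = as.list(round(
      100 * prop.table(table(factor(s$sod2, .sod2_levels))), 1)))),
    cyp2c9 = c9,
    cyp2c19_group_pct = as.list(round(
      100 * prop.table(table(factor(s$cyp2c19, .cyp2c19_levels))), 1)),
    gstm1_null_pct = round(100 * mean(s$gstm1 == "null"), 1),
    gstt1_null_pct = round(100 * mean(s$gstt1 == "null"), 1))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

# column layout of the event CSV
.csv_cov_cols <- c("AGE", "SEX", "WT", "DDOSE", "SOD2", "CYP2C9", "CYP2C19",
                   "GSTM1", "GSTT1", "IDIS", "CBZ", "CLB", "PB", "PHT",
                   "TPM", "ZNS", "GBP", "START")
.csv_cols <- c("ID", "EVID", "DATE", "TIME", "AMT", "II", "SS",
               "DV_CONC", "DV_GGT", .csv_cov_cols)

#' Load a cohort from a NONMEM-style event CSV
#'
#' One row per event. \code{EVID} 0 = concentration observation (uses
#' \code{TIME} h after last dose, \code{AMT} mg per administration, \code{II}
#' h dosing interval, \code{SS} 0/1, \code{DV_CONC} mg/L); \code{EVID} 2 =
#' gamma-GT observation (uses \code{DATE} ISO-8601, \code{DV_GGT} IU/L);
#' \code{EVID} 3 = covariate-only row (subjects without records).
#' Subject covariates are carried on the rows (any row per subject may supply
#' them; a subject whose rows never carry covariates is an integrity error).
#' gamma-GT values are binarised against \code{uln} at load.
#'
#' @param path CSV path.
#' @param uln a \code{\link{uln_table}}.
#' @return a \code{\link{vpa_cohort}}.
#' @export
load_cohort <- function(path, uln) {
  if (!file.exists(path)) stop("load_cohort: no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(ID = "character"))
  miss <- setdiff(.csv_cols, names(d))
  if (length(miss))
    stop("load_cohort: format error, missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!d$EVID %in% c(0, 2, 3))  # 3 = covariate-only row
  if (length(bad))
    stop("load_cohort: malformed row(s) (unknown EVID): ",
         paste(utils::head(bad, 10), collapse = ", "))

  hascov <- !is.na(d$AGE)
  ids <- unique(d$ID)
  nocov <- ids[!ids %in% unique(d$ID[hascov])]
  if (length(nocov))
    stop("load_cohort: integrity error, no covariate row for subject(s): ",
         paste(nocov, collapse = ", "))
  first <- d[hascov, ][match(ids, d$ID[hascov]), ]
  subjects <- data.frame(
    subject_id = first$ID, age = first$AGE,
    sex = first$SEX, body_weight = first$WT, daily_dose = first$DDOSE,
    sod2 = first$SOD2, cyp2c9 = first$CYP2C9, cyp2c19 = first$CYP2C19,
    gstm1 = first$GSTM1, gstt1 = first$GSTT1,
    intellectual_disability = first$IDIS == 1,
    cbz = first$CBZ, clb = first$CLB, pb = first$PB, pht = first$PHT,
    tpm = first$TPM, zns = first$ZNS, gbp = first$GBP,
    vpa_start_date = as.Date(first$START))

  pkr <- d[d$EVID == 0, ]
  pk_records <- data.frame(
    subject_id = pkr$ID, time_after_last_dose = pkr$TIME,
    dose_per_administration = pkr$AMT, dosing_interval = pkr$II,
    value = pkr$DV_CONC, steady_state = pkr$SS == 1)

  ggr <- d[d$EVID == 2, ]
  ggt_records <- data.frame(
    subject_id = ggr$ID, measurement_date = as.Date(ggr$DATE),
    value = ggr$DV_GGT, elevated = NA_integer_)
  if (nrow(ggt_records)) {
    i <- match(ggt_records$subject_id, subjects$subject_id)
    ggt_records$elevated <- binarize_ggt(ggt_records$value,
                                         subjects$age[i], subjects$sex[i],
                                         uln)
  }
  vpa_cohort(subjects, pk_records, ggt_records)
}

#' Write a cohort as a NONMEM-style event CSV
#'
#' Inverse of \code{\link{load_cohort}}: writing then re-loading with the
#' same ULN table reproduces the cohort.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  s <- cohort$subjects
  covrow <- function(i) data.frame(
    AGE = s$age[i], SEX = s$sex[i], WT = s$body_weight[i],
    DDOSE = s$daily_dose[i], SOD2 = s$sod2[i], CYP2C9 = s$cyp2c9[i],
    CYP2C19 = s$cyp2c19[i], GSTM1 = s$gstm1[i], GSTT1 = s$gstt1[i],
    IDIS = as.integer(s$intellectual_disability[i]),
    CBZ = s$cbz[i], CLB = s$clb[i], PB = s$pb[i], PHT = s$pht[i],
    TPM = s$tpm[i], ZNS = s$zns[i], GBP = s$gbp[i],
    START = format(s$vpa_start_date[i]))
  rows <- vector("list", 0)
  for (i in seq_len(nrow(s))) {
    id <- s$subject_id[i]
    cv <- covrow(i)
    pk <- cohort$pk_records[cohort$pk_records$subject_id == id, ,
                            drop = FALSE]
    gg <- cohort$ggt_records[cohort$ggt_records$subject_id == id, ,
                             drop = FALSE]
    if (nrow(pk))
      rows[[length(rows) + 1]] <- data.frame(
        ID = id, EVID = 0, DATE = NA, TIME = pk$time_after_last_dose,
        AMT = pk$dose_per_administration, II = pk$dosing_interval,
        SS = as.integer(pk$steady_state), DV_CONC = pk$value,
        DV_GGT = NA, cv, row.names = NULL)
    if (nrow(gg))
      rows[[length(rows) + 1]] <- data.frame(
        ID = id, EVID = 2, DATE = format(gg$measurement_date), TIME = NA,
        AMT = NA, II = NA, SS = NA, DV_CONC = NA, DV_GGT = gg$value,
        cv, row.names = NULL)
    if (!nrow(pk) && !nrow(gg))
      rows[[length(rows) + 1]] <- data.frame(
        ID = id, EVID = 3, DATE = NA, TIME = NA, AMT = NA, II = NA,
        SS = NA, DV_CONC = NA, DV_GGT = NA, cv, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out <- out[, .csv_cols]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
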