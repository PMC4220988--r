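# End-to-end orchestration: generate (or load) -> filter -> fit PK -> derive
# individual AUCs -> fit PD -> bootstrap -> VPC -> risk table, with per-stage
# child seeds and a JSON manifest. Estimation is strictly sequential: the
# individual PK parameters are frozen before the PD stage.

#' Deterministic per-stage child seeds from a master seed
#'
#' Stages can be re-run in isolation with identical draws: each stage gets a
#' fixed offset from the master seed (kept below 2^31).
#'
#' @param master integer master seed.
#' @return named integer vector of stage seeds.
#' @export
stage_seeds <- function(master) {
  offs <- c(generate = 1L, fit_pk = 2L, fit_pd = 3L, bootstrap = 4L,
            vpc = 5L, risk = 6L)
  (as.integer(master) * 131L + offs) %% 2000000011L
}

#' Run the full PK-PD analysis pipeline
#'
#' Executes the enabled stages in order and writes every artifact (cohort
#' CSV, QC report, fit summaries, bootstrap, VPC, risk table) plus a manifest
#' naming the exact seeds into \code{out_dir}. The PD stage consumes the
#' frozen individual AUCs of the PK stage (sequential estimation); re-running
#' later stages never alters earlier artifacts.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; spawns per-stage child seeds via
#'   \code{\link{stage_seeds}}.
#' @param stages character subset of
#'   c("generate", "fit_pk", "fit_pd", "bootstrap", "vpc", "risk").
#' @param config \code{\link{generator_config}} for the generate stage.
#' @param cohort_csv optional path to an existing event CSV (used instead of
#'   generation when "generate" is not among \code{stages}).
#' @param uln ULN table for loading/binarisation.
#' @param thetas,variance,pd generating truth for the generate stage and
#'   parameter presets for the risk stage.
#' @param n_bootstrap,n_vpc,n_risk,n_risk_replicates stage sizes.
#' @param loq concentration limit of quantification, mg/L.
#' @param min_months early gamma-GT exclusion window, months.
#' @return (invisibly) list of stage results; artifacts on disk.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         stages = c("generate", "fit_pk", "fit_pd",
                                    "bootstrap", "vpc", "risk"),
                         config = generator_config(),
                         cohort_csv = NULL, uln = default_uln(),
                         thetas = pk_thetas(), variance = pk_variance(),
                         pd = pd_parameters(),
                         n_bootstrap = 100, n_vpc = 500, n_risk = 1000,
                         n_risk_replicates = 100, loq = 1, min_months = 6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(seed)
  manifest <- list(master_seed = seed, stages = stages,
                   stage_seeds = as.list(seeds))
  res <- list()
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial artifacts kept in ", out_dir, ")", call. = FALSE)

  csv_path <- file.path(out_dir, "cohort.csv")
  if ("generate" %in% stages) {
    tryCatch({
      st <- generate_study(config, thetas, variance, pd,
                           seed = seeds[["generate"]])
      write_cohort(st$cohort, csv_path)
      cohort <- st$cohort
    }, error = function(e) fail("generate", e))
  } else {
    if (is.null(cohort_csv)) stop("run_pipeline: need cohort_csv when not generating")
    csv_path <- cohort_csv
  }
  cohort <- load_cohort(csv_path, uln)

  # record-level QC and filtering
  nc <- flag_noncompliance(cohort$pk_records, loq = loq)
  ggt <- filter_early_ggt(cohort$ggt_records, min_months = min_months)
  cohort <- vpa_cohort(cohort$subjects, nc$kept, ggt)
  qc_report(cohort, file.path(out_dir, "qc_report.json"))
  manifest$n_excluded_loq <- nrow(nc$excluded)
  res$cohort <- cohort

  if (!"fit_pk" %in% stages) {
    .write_manifest(manifest, out_dir)
    return(invisible(res))
  }
  pkfit <- tryCatch(fit_pk_model(cohort), error = function(e) fail("fit_pk", e))
  utils::write.csv(
    data.frame(parameter = names(coef(pkfit)), estimate = coef(pkfit)),
    file.path(out_dir, "pk_estimates.csv"), row.names = FALSE)
  gof <- gof_diagnostics(pkfit)
  utils::write.csv(gof, file.path(out_dir, "pk_gof.csv"), row.names = FALSE)
  grDevices::png(file.path(out_dir, "pk_gof.png"), width = 1200, height = 400)
  plot(gof); grDevices::dev.off()
  manifest$pk_ofv <- pkfit$ofv
  manifest$pk_converged <- pkfit$converged
  res$pk <- pkfit
  auc <- individual_auc(pkfit, cohort)   # frozen before the PD stage
  utils::write.csv(data.frame(subject_id = names(auc), auc_g = auc),
                   file.path(out_dir, "individual_auc.csv"),
                   row.names = FALSE)

  if ("fit_pd" %in% stages) {
    pdfit <- tryCatch(fit_pd_model(cohort, auc),
                      error = function(e) fail("fit_pd", e))
    utils::write.csv(
      data.frame(parameter = names(coef(pdfit)), estimate = coef(pdfit)),
      file.path(out_dir, "pd_estimates.csv"), row.names = FALSE)
    manifest$pd_ofv <- pdfit$ofv
    manifest$pd_converged <- pdfit$converged
    res$pd <- pdfit

    if ("bootstrap" %in% stages) {
      strata <- stats::setNames(
        paste0(cohort$subjects$sod2 == "ValVal", "_",
               cohort$subjects$intellectual_disability),
        cohort$subjects$subject_id)
      bs <- tryCatch(
        bootstrap_fit(pdfit, n = n_bootstrap, strata = strata,
                      seed = seeds[["bootstrap"]]),
        error = function(e) fail("bootstrap", e))
      utils::write.csv(bs$summary, file.path(out_dir, "pd_bootstrap.csv"),
                       row.names = FALSE)
      manifest$bootstrap_successful <- bs$n_successful
      res$bootstrap <- bs
    }
    if ("vpc" %in% stages) {
      strata <- stats::setNames(
        ifelse(cohort$subjects$sod2 == "ValVal", "ValVal", "Ala carrier"),
        cohort$subjects$subject_id)
      vp <- tryCatch(
        vpc_check(pdfit, n_sim = n_vpc, strata = strata,
                  seed = seeds[["vpc"]]),
        error = function(e) fail("vpc", e))
      utils::write.csv(as.data.frame(vp), file.path(out_dir, "vpc.csv"),
                       row.names = FALSE)
      grDevices::png(file.path(out_dir, "vpc.png"), width = 900, height = 450)
      plot(vp); grDevices::dev.off()
      res$vpc <- vp
    }
  }
  if ("risk" %in% stages) {
    rt <- tryCatch(
      simulate_risk(thetas, variance, pd_parameters(omega2_logit = 3.48),
                    n = n_risk, n_replicates = n_risk_replicates,
                    seed = seeds[["risk"]]),
      error = function(e) fail("risk", e))
    write_risk_table(rt, file.path(out_dir, "risk_table.csv"))
    res$risk <- rt
  }
  .write_manifest(manifest, out_dir)
  invisible(res)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
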