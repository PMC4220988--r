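# Synthetic-cohort generator: emulates the covariate structure of the
# reference Japanese epilepsy cohort (demographics, genotype and
# co-medication frequencies) and simulates concentration and binary gamma-GT
# observations from the PK and PD models, so the full pipeline is testable
# without patient data.

#' Configuration of the synthetic-cohort generator
#'
#' Defaults reproduce the printed characteristics of the reference cohort:
#' 60.4\% male, 57.4\% intellectual disability, SOD2 genotype split
#' 77.6/20.7/1.7\% (Val/Val, Val/Ala, Ala/Ala), GSTM1 null 56.8\%, GSTT1 null
#' 47.9\%, CYP2C9*3 allele 3.2\% under HWE, CYP2C19*2/*3 alleles 29.3/11.2\%,
#' daily dose log-normal with mean 934 and SD 540 mg truncated to [100, 2600]
#' and rounded to 100 mg, age log-normal with mean 18.0 and SD 7.8 years
#' truncated to [3, 52], body weight a monotone function of age (about 51 kg
#' at the cohort mean age) with 20\% log-normal noise, and co-medication
#' prevalences per the printed proportions with the enzyme-inducer flags
#' (CBZ, PB, PHT) about twice as prevalent under intellectual disability.
#'
#' @param n_subjects number of subjects.
#' @param p_male,p_disability Bernoulli probabilities.
#' @param sod2_probs length-3 multinomial over (ValVal, ValAla, AlaAla).
#' @param p_gstm1_null,p_gstt1_null null-genotype frequencies.
#' @param cyp2c9_star3_allele,cyp2c19_star2_allele,cyp2c19_star3_allele
#'   allele frequencies (HWE random mating).
#' @param dose_mean,dose_sd,dose_range daily-dose distribution (mg/day).
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param comed_prev named prevalences for cbz, clb, pb, pht, tpm, zns, gbp.
#' @param inducer_or odds multiplier on CBZ/PB/PHT prevalence under
#'   intellectual disability (prevalence ratio ~2 at the defaults).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_subjects = 169,
                             p_male = 0.604, p_disability = 0.574,
                             sod2_probs = c(0.776, 0.207, 0.017),
                             p_gstm1_null = 0.568, p_gstt1_null = 0.479,
                             cyp2c9_star3_allele = 0.032,
                             cyp2c19_star2_allele = 0.293,
                             cyp2c19_star3_allele = 0.112,
                             dose_mean = 934, dose_sd = 540,
                             dose_range = c(100, 2600),
                             age_mean = 18.0, age_sd = 7.8,
                             age_range = c(3, 52),
                             comed_prev = c(cbz = 0.230, clb = 0.155,
                                            pb = 0.088, pht = 0.106,
                                            tpm = 0.053, zns = 0.071,
                                            gbp = 0.010),
                             inducer_or = 2) {
  if (n_subjects <= 0) stop("generator_config: n_subjects must be positive")
  pr <- c(p_male, p_disability, sod2_probs, p_gstm1_null, p_gstt1_null,
          cyp2c9_star3_allele, cyp2c19_star2_allele, cyp2c19_star3_allele,
          comed_prev)
  if (any(pr < 0 | pr > 1))
    stop("generator_config: frequencies must be in [0, 1]")
  if (abs(sum(sod2_probs) - 1) > 1e-8)
    stop("generator_config: sod2_probs must sum to 1")
  if (cyp2c19_star2_allele + cyp2c19_star3_allele > 1)
    stop("generator_config: CYP2C19 allele frequencies exceed 1")
  if (dose_range[1] >= dose_range[2] || age_range[1] >= age_range[2])
    stop("generator_config: invalid truncation range")
  structure(as.list(environment()), class = "generator_config")
}

# moment-matched log-normal draw truncated to [lo, hi] by redraw
.rlnorm_trunc <- function(n, mean, sd, lo, hi) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  if (stats::plnorm(hi, meanlog, sdlog) - stats::plnorm(lo, meanlog, sdlog)
      < 0.1)
    stop("infeasible truncation range for log-normal(", mean, ", ", sd, ")")
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (it in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a covariate-only synthetic cohort
#'
#' Draws \code{n_subjects} i.i.d. subjects per \code{\link{generator_config}}
#' (no concentration or gamma-GT records yet; see
#' \code{\link{simulate_concentrations}} and
#' \code{\link{simulate_ggt_events}}).
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed optional integer seed.
#' @return a \code{\link{vpa_cohort}} with empty record tables.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  idis <- stats::runif(n) < config$p_disability
  sod2 <- sample(.sod2_levels, n, replace = TRUE, prob = config$sod2_probs)
  gstm1 <- ifelse(stats::runif(n) < config$p_gstm1_null, "null", "present")
  gstt1 <- ifelse(stats::runif(n) < config$p_gstt1_null, "null", "present")
  q9 <- config$cyp2c9_star3_allele
  n3 <- stats::rbinom(n, 2, q9)
  cyp2c9 <- .cyp2c9_levels[n3 + 1]
  a1 <- sample(c("*1", "*2", "*3"), n, replace = TRUE,
               prob = c(1 - config$cyp2c19_star2_allele -
                          config$cyp2c19_star3_allele,
                        config$cyp2c19_star2_allele,
                        config$cyp2c19_star3_allele))
  a2 <- sample(c("*1", "*2", "*3"), n, replace = TRUE,
               prob = c(1 - config$cyp2c19_star2_allele -
                          config$cyp2c19_star3_allele,
                        config$cyp2c19_star2_allele,
                        config$cyp2c19_star3_allele))
  nvar <- (a1 != "*1") + (a2 != "*1")
  cyp2c19 <- .cyp2c19_levels[nvar + 1]
  age <- .rlnorm_trunc(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
  wt_mean <- 70 * age / (age + 6.5)
  wt <- pmin(pmax(wt_mean * exp(stats::rnorm(n, 0, 0.2) - 0.02), 10), 121)
  dose <- .rlnorm_trunc(n, config$dose_mean, config$dose_sd,
                        config$dose_range[1], config$dose_range[2])
  dose <- pmax(round(dose / 100) * 100, config$dose_range[1])

  comed <- matrix(0L, n, length(.comed_cols),
                  dimnames = list(NULL, .comed_cols))
  w <- config$p_disability
  for (nm in .comed_cols) {
    m <- unname(config$comed_prev[[nm]])
    if (m == 0) next
    if (nm %in% c("cbz", "pb", "pht") && config$inducer_or != 1) {
      # base rate p0 solving the marginal: w*p1 + (1-w)*p0 = m with
      # p1/(1-p1) = OR * p0/(1-p0); solved numerically
      fn <- function(p0) {
        odds1 <- config$inducer_or * p0 / (1 - p0)
        p1 <- odds1 / (1 + odds1)
        w * p1 + (1 - w) * p0 - m
      }
      p0 <- stats::uniroot(fn, c(1e-6, m))$root
      odds1 <- config$inducer_or * p0 / (1 - p0)
      p1 <- odds1 / (1 + odds1)
      p <- ifelse(idis, p1, p0)
    } else {
      p <- rep(m, n)
    }
    comed[, nm] <- as.integer(stats::runif(n) < p)
  }
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)), age = age, sex = sex,
    body_weight = wt, daily_dose = dose, sod2 = sod2, cyp2c9 = cyp2c9,
    cyp2c19 = cyp2c19, gstm1 = gstm1, gstt1 = gstt1,
    intellectual_disability = idis,
    cbz = comed[, "cbz"], clb = comed[, "clb"], pb = comed[, "pb"],
    pht = comed[, "pht"], tpm = comed[, "tpm"], zns = comed[, "zns"],
    gbp = comed[, "gbp"],
    vpa_start_date = as.Date("2000-01-01") +
      sample.int(3650, n, replace = TRUE))
  vpa_cohort(subjects, dose_range = config$dose_range)
}

#' Simulate sparse steady-state concentration records
#'
#' Per subject: exponential random effects drawn from \code{variance}, 2-5
#' sampling times uniform over the dosing interval (once-daily
#' sustained-release dosing, tau = 24 h, by default, so sampling spans the
#' whole 24-h profile; steady-state AUC is invariant to how the daily dose is
#' split, so the choice of tau does not touch the exposure-response stage),
#' observation = prediction x (1 + eps) with proportional eps ~ N(0, sigma2),
#' negative observations redrawn.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @param thetas generating \code{\link{pk_thetas}}.
#' @param variance generating \code{\link{pk_variance}}.
#' @param tau dosing interval, h (daily dose split evenly across intervals).
#' @param n_samples_range integer range of samples per subject (uniform;
#'   default 2:5, expectation 3.5).
#' @param seed optional integer seed.
#' @return concentration-record data.frame with attributes \code{eta_cl}
#'   (named true random effects) and \code{cl_i} (true individual
#'   clearances).
#' @export
simulate_concentrations <- function(cohort, thetas = pk_thetas(),
                                    variance = pk_variance(), tau = 24,
                                    n_samples_range = 2:5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cohort$subjects
  n <- nrow(s)
  eta_cl <- stats::rnorm(n, 0, sqrt(variance$omega2_cl))
  eta_ka <- stats::rnorm(n, 0, sqrt(variance$omega2_ka))
  eta_vd <- stats::rnorm(n, 0, sqrt(variance$omega2_vd))
  eta_alag <- stats::rnorm(n, 0, sqrt(variance$omega2_alag))
  ind <- pk_individual(thetas, s$daily_dose,
                       female = as.integer(s$sex == "female"),
                       cbz = s$cbz, clb = s$clb, pb = s$pb, pht = s$pht,
                       eta_cl = eta_cl, eta_ka = eta_ka, eta_vd = eta_vd,
                       eta_alag = eta_alag)
  nobs <- sample(n_samples_range, n, replace = TRUE)
  idx <- rep(seq_len(n), nobs)
  tad <- stats::runif(sum(nobs), 0, tau)
  ind_rows <- structure(lapply(unclass(ind), function(x) x[idx]),
                        class = "pk_individual")
  dose_admin <- s$daily_dose[idx] * tau / 24
  f <- pk_concentration(tad, dose_admin, tau, ind_rows, steady_state = TRUE)
  eps <- stats::rnorm(length(f), 0, sqrt(variance$sigma2))
  for (it in 1:100) {
    bad <- (1 + eps) <= 0
    if (!any(bad)) break
    eps[bad] <- stats::rnorm(sum(bad), 0, sqrt(variance$sigma2))
  }
  rec <- data.frame(subject_id = s$subject_id[idx],
                    time_after_last_dose = tad,
                    dose_per_administration = dose_admin,
                    dosing_interval = tau, value = f * (1 + eps),
                    steady_state = TRUE)
  attr(rec, "eta_cl") <- stats::setNames(eta_cl, s$subject_id)
  attr(rec, "cl_i") <- stats::setNames(ind$cl_i, s$subject_id)
  rec
}

#' True individual AUCs under generating PK parameters
#'
#' \code{AUC_i = daily_dose / cl_i} in g.h/L, the fixed exposure input of the
#' PD stage when simulating from known truth.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @param thetas generating \code{\link{pk_thetas}}.
#' @param eta_cl named (by subject_id) random effects on CL/F (default 0).
#' @return named AUC vector, g.h/L.
#' @export
true_auc <- function(cohort, thetas = pk_thetas(), eta_cl = NULL) {
  s <- cohort$subjects
  e <- if (is.null(eta_cl)) numeric(nrow(s)) else
    unname(eta_cl[as.character(s$subject_id)])
  ind <- pk_individual(thetas, s$daily_dose,
                       female = as.integer(s$sex == "female"),
                       cbz = s$cbz, clb = s$clb, pb = s$pb, pht = s$pht,
                       eta_cl = e)
  stats::setNames(auc_ss(ind, s$daily_dose) / 1000, s$subject_id)
}

#' Simulate binary gamma-GT observations
#'
#' One normal random effect per subject on the logit; per visit the event is
#' Bernoulli(inverse-logit). Visit months are uniform on
#' \code{months_range} (at or after the 6-month floor); visits per subject
#' default to 2-4 with expectation 2.8. Each record carries a constructed
#' IU/L value (1.5 x ULN if elevated, 0.5 x ULN otherwise) so that
#' binarisation against the same ULN table reproduces the simulated outcome.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @param pd a \code{\link{pd_parameters}} generating truth.
#' @param auc named per-subject AUC in g.h/L (see \code{\link{true_auc}}).
#' @param months_range visit-time window, months since VPA start.
#' @param visit_counts,visit_probs visits-per-subject distribution.
#' @param uln ULN table used to construct the stored IU/L values.
#' @param seed optional integer seed.
#' @return gamma-GT record data.frame with attribute \code{eta_logit}.
#' @export
simulate_ggt_events <- function(cohort, pd = pd_parameters(), auc,
                                months_range = c(6, 80),
                                visit_counts = 2:4,
                                visit_probs = c(0.35, 0.5, 0.15),
                                uln = default_uln(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cohort$subjects
  n <- nrow(s)
  a <- auc[as.character(s$subject_id)]
  if (anyNA(a)) stop("simulate_ggt_events: missing AUC for some subjects")
  eta <- stats::rnorm(n, 0, sqrt(pd$omega2_logit))
  lg <- logit_linear(pd, unname(a),
                     id_flag = as.integer(s$intellectual_disability),
                     valval_flag = as.integer(s$sod2 == "ValVal"),
                     eta = eta)
  nv <- sample(visit_counts, n, replace = TRUE, prob = visit_probs)
  idx <- rep(seq_len(n), nv)
  months <- stats::runif(sum(nv), months_range[1], months_range[2])
  y <- stats::rbinom(sum(nv), 1, stats::plogis(lg[idx]))
  lim <- vapply(seq_len(sum(nv)), function(k) {
    i <- idx[k]
    r <- uln$sex == s$sex[i] & uln$age_lo <= s$age[i] & s$age[i] < uln$age_hi
    uln$uln[r][1]
  }, numeric(1))
  rec <- data.frame(
    subject_id = s$subject_id[idx],
    measurement_date = s$vpa_start_date[idx] + round(months * 30.4375),
    value = ifelse(y == 1, 1.5 * lim, 0.5 * lim),
    elevated = y)
  attr(rec, "eta_logit") <- stats::setNames(eta, s$subject_id)
  rec
}

#' Synthetic default gamma-GT ULN table
#'
#' A deliberately simple, non-authoritative two-band-per-sex table (IU/L)
#' used by the generator and examples; real analyses must supply their
#' laboratory's age/sex-stratified limits.
#'
#' @return a \code{\link{uln_table}}.
#' @export
default_uln <- function() {
  uln_table(sex = c("male", "male", "female", "female"),
            age_lo = c(0, 15, 0, 15), age_hi = c(15, 120, 15, 120),
            uln = c(35, 70, 30, 40))
}

#' Generate a complete synthetic study (covariates + PK + PD records)
#'
#' Convenience wrapper: covariates via \code{\link{generate_cohort}},
#' concentrations via \code{\link{simulate_concentrations}} at the PK truth,
#' individual AUCs from the simulated clearances, and binary gamma-GT events
#' via \code{\link{simulate_ggt_events}} at the PD truth.
#'
#' @param config a \code{\link{generator_config}}.
#' @param thetas,variance PK generating truth.
#' @param pd PD generating truth.
#' @param seed integer seed (drives every draw).
#' @return list(cohort, auc_g, eta_cl, eta_logit).
#' @export
generate_study <- function(config = generator_config(),
                           thetas = pk_thetas(), variance = pk_variance(),
                           pd = pd_parameters(), seed = 1) {
  set.seed(seed)
  cohort <- generate_cohort(config)
  pk <- simulate_concentrations(cohort, thetas, variance)
  auc <- stats::setNames(
    cohort$subjects$daily_dose / attr(pk, "cl_i") / 1000,
    cohort$subjects$subject_id)
  ggt <- simulate_ggt_events(cohort, pd, auc)
  eta_cl <- attr(pk, "eta_cl")
  eta_logit <- attr(ggt, "eta_logit")
  attr(pk, "eta_cl") <- attr(pk, "cl_i") <- attr(ggt, "eta_logit") <- NULL
  cohort <- vpa_cohort(cohort$subjects, pk, ggt,
                       dose_range = config$dose_range)
  list(cohort = cohort, auc_g = auc, eta_cl = eta_cl,
       eta_logit = eta_logit)
}
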