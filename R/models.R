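# Bridges between the domain models (pk.R, pd.R) and the estimation engine
# (engine.R): data-frame construction from a cohort, me_model factories with
# selectable covariates, and the user-facing fit_pk_model / fit_pd_model.

#' Assemble the PK estimation data frame from a cohort
#'
#' One row per concentration record, joined with the subject covariates the
#' PK covariate model can use. Columns: \code{id}, \code{dv} (mg/L),
#' \code{tad} (h), \code{dose_admin} (mg), \code{tau} (h), \code{ss},
#' \code{daily_dose}, \code{female}, \code{cbz}, \code{clb}, \code{pb},
#' \code{pht}, \code{age}, \code{body_weight}.
#'
#' @param cohort a \code{\link{vpa_cohort}}.
#' @return data.frame ready for \code{\link{mefit}}.
#' @export
pk_data <- function(cohort) {
  stopifnot(inherits(cohort, "vpa_cohort"))
  pk <- cohort$pk_records
  i <- match(pk$subject_id, cohort$subjects$subject_id)
  s <- cohort$subjects[i, ]
  data.frame(id = pk$subject_id, dv = pk$value, tad = pk$time_after_last_dose,
             dose_admin = pk$dose_per_administration,
             tau = pk$dosing_interval, ss = pk$steady_state,
             daily_dose = s$daily_dose,
             female = as.integer(s$sex == "female"),
             cbz = s$cbz, clb = s$clb, pb = s$pb, pht = s$pht,
             age = s$age, body_weight = s$body_weight,
             row.names = NULL)
}

# Covariate effect registry for the PK model: how each named candidate
# modifies CL/F or Vd/F. "power" effects use a normalised continuous column,
# "factor" effects a 0/1 column.
.pk_effects <- list(
  dose_cl = list(target = "cl", form = "power", column = "daily_dose",
                 ref = 1000, init = 0.6),
  dose_vd = list(target = "vd", form = "power", column = "daily_dose",
                 ref = 1000, init = 1.0),
  female  = list(target = "cl", form = "factor", column = "female", init = 1),
  cbz     = list(target = "cl", form = "factor", column = "cbz", init = 1),
  clb     = list(target = "cl", form = "factor", column = "clb", init = 1),
  pb      = list(target = "cl", form = "factor", column = "pb", init = 1),
  pht     = list(target = "cl", form = "factor", column = "pht", init = 1),
  age_cl  = list(target = "cl", form = "power", column = "age",
                 ref = 18, init = 0),
  wt_cl   = list(target = "cl", form = "power", column = "body_weight",
                 ref = 50, init = 0.75)
)

#' Factory for the one-compartment PK mixed-effects model
#'
#' Builds an \code{\link{me_model}} for the oral one-compartment model with
#' lag, a selectable covariate set on CL/F and Vd/F, exponential
#' inter-individual variability on CL/F, and proportional (default) or
#' additive residual error. Available covariate names: \code{dose_cl},
#' \code{dose_vd} (powers of dose/1000 on CL/F and Vd/F), \code{female},
#' \code{cbz}, \code{clb}, \code{pb}, \code{pht} (multiplicative factors on
#' CL/F), \code{age_cl}, \code{wt_cl} (powers of normalised age/weight on
#' CL/F, candidates for selection).
#'
#' @param include character vector of covariate effect names.
#' @param error residual error model.
#' @param alag absorption lag time (h), fixed (not estimated).
#' @param init_override named numeric vector overriding default initial
#'   values.
#' @return list with \code{model} (me_model), \code{init} (named vector),
#'   \code{fixed} (names fixed during estimation), \code{df} (named vector:
#'   degrees of freedom each covariate adds).
#' @export
pk_model_spec <- function(include = c("dose_cl", "dose_vd", "female", "cbz",
                                      "clb", "pb", "pht"),
                          error = "proportional", alag = 3.00,
                          init_override = NULL) {
  unknown <- setdiff(include, names(.pk_effects))
  if (length(unknown))
    stop("pk_model_spec: unknown covariate(s): ",
         paste(unknown, collapse = ", "))
  effs <- .pk_effects[include]
  f <- function(par, eta, data) {
    cl <- rep_len(par[["cl"]], nrow(data))
    vd <- rep_len(par[["vd"]], nrow(data))
    for (nm in names(effs)) {
      e <- effs[[nm]]
      mult <- if (e$form == "power") {
        (data[[e$column]] / e$ref)^par[[nm]]
      } else {
        par[[nm]]^data[[e$column]]
      }
      if (e$target == "cl") cl <- cl * mult else vd <- vd * mult
    }
    cl <- cl * exp(eta)
    ka <- par[["ka"]]
    ke <- cl / vd
    tp <- (data$tad - par[["alag"]]) %% data$tau
    tie <- abs(ka - ke) <= 1e-8 * pmax(ka, ke)
    acc_ke <- 1 - exp(-ke * data$tau)
    acc_ka <- 1 - exp(-ka * data$tau)
    conc <- data$dose_admin / vd * ka / ifelse(tie, 1, ka - ke) *
      (exp(-ke * tp) / acc_ke - exp(-ka * tp) / acc_ka)
    if (any(tie)) {
      k <- (ka + ke[tie]) / 2
      ek <- exp(-k * tp[tie]); ekt <- exp(-k * data$tau[tie])
      acc <- 1 - ekt
      fprime <- (-tp[tie] * ek * acc - ek * data$tau[tie] * ekt) / acc^2
      conc[tie] <- data$dose_admin[tie] / vd[tie] * k * (-fprime)
    }
    pmax(conc, 1e-12)
  }
  init <- c(ka = 0.1, cl = 0.6, vd = 20, alag = alag)
  for (nm in names(effs)) init[nm] <- effs[[nm]]$init
  init["omega2"] <- 0.05
  init["sigma2"] <- 0.05
  if (!is.null(init_override)) init[names(init_override)] <- init_override
  transform <- stats::setNames(rep("identity", length(init)), names(init))
  transform[c("ka", "cl", "vd", "alag", "omega2", "sigma2")] <- "log"
  for (nm in names(effs))
    if (effs[[nm]]$form == "factor") transform[nm] <- "log"
  list(model = me_model("continuous", f, error = error, name = "VPA 1-cpt PK"),
       init = init, fixed = "alag", transform = transform,
       df = stats::setNames(rep(1L, length(include)), include))
}

#' Fit the population PK model to a cohort
#'
#' FOCE-with-interaction fit of the one-compartment VPA model. Returns a
#' \code{pkfit} object (subclass of \code{\link{mefit}}) whose empirical
#' Bayes clearances feed the PK-PD stage via \code{\link{individual_auc}}.
#'
#' @param cohort a \code{\link{vpa_cohort}} with pk_records.
#' @param include covariate effects (see \code{\link{pk_model_spec}}).
#' @param method "foce" or "laplace".
#' @param error residual error model.
#' @param init_override optional named initial values.
#' @param control outer optimiser control.
#' @return object of class \code{c("pkfit", "mefit")}.
#' @export
fit_pk_model <- function(cohort, include = c("dose_cl", "dose_vd", "female",
                                             "cbz", "clb", "pb", "pht"),
                         method = "foce", error = "proportional",
                         init_override = NULL, control = list()) {
  spec <- pk_model_spec(include, error = error, init_override = init_override)
  fit <- mefit(spec$model, pk_data(cohort), spec$init, method = method,
               transform = spec$transform, fixed = spec$fixed,
               control = control)
  fit$include <- include
  class(fit) <- c("pkfit", class(fit))
  fit
}

#' Individual steady-state AUCs from a fitted PK model
#'
#' \code{AUC_i = daily_dose_i / CL_i} with \code{CL_i} built from the
#' estimated fixed effects, each subject's covariates and its empirical Bayes
#' \eqn{\eta}. Subjects without concentration data get \eqn{\eta = 0}
#' (population prediction).
#'
#' @param fit a \code{pkfit}.
#' @param cohort the cohort whose subjects need AUCs (defaults to the fitted
#'   one's subjects).
#' @param scale "g" for g.h/L (default, the exposure-response scale) or "mg"
#'   for mg.h/L.
#' @return named numeric vector of AUCs by subject_id.
#' @export
individual_auc <- function(fit, cohort, scale = c("g", "mg")) {
  stopifnot(inherits(fit, "pkfit"))
  scale <- match.arg(scale)
  s <- cohort$subjects
  par <- coef(fit)
  eta <- fit$ebes[as.character(s$subject_id)]
  eta[is.na(eta)] <- 0
  cl <- rep_len(par[["cl"]], nrow(s))
  for (nm in fit$include) {
    e <- .pk_effects[[nm]]
    if (e$target != "cl") next
    colv <- switch(e$column,
                   daily_dose = s$daily_dose,
                   female = as.integer(s$sex == "female"),
                   age = s$age, body_weight = s$body_weight,
                   s[[e$column]])
    cl <- cl * if (e$form == "power") (colv / e$ref)^par[[nm]]
               else par[[nm]]^colv
  }
  cl <- cl * exp(eta)
  auc <- s$daily_dose / cl
  if (scale == "g") auc <- auc / 1000
  stats::setNames(auc, s$subject_id)
}

#' Assemble the PK-PD estimation data frame
#'
#' One row per binary gamma-GT observation with the subject's fixed
#' individual AUC (g.h/L) and PD covariates. Columns: \code{id}, \code{dv}
#' (0/1), \code{auc_g}, \code{id_flag}, \code{valval}, \code{female},
#' \code{gstm1_null}, \code{gstt1_null}, \code{cbz}, \code{pb}, \code{pht}.
#'
#' @param cohort a \code{\link{vpa_cohort}} with ggt_records.
#' @param auc named per-subject AUC vector in g.h/L (from
#'   \code{\link{individual_auc}} or the generating truth).
#' @return data.frame ready for \code{\link{mefit}}.
#' @export
pd_data <- function(cohort, auc) {
  stopifnot(inherits(cohort, "vpa_cohort"))
  g <- cohort$ggt_records
  i <- match(g$subject_id, cohort$subjects$subject_id)
  s <- cohort$subjects[i, ]
  a <- auc[as.character(g$subject_id)]
  if (anyNA(a)) stop("pd_data: missing AUC for some subjects")
  data.frame(id = g$subject_id, dv = g$elevated, auc_g = unname(a),
             id_flag = as.integer(s$intellectual_disability),
             valval = as.integer(s$sod2 == "ValVal"),
             female = as.integer(s$sex == "female"),
             gstm1_null = as.integer(s$gstm1 == "null"),
             gstt1_null = as.integer(s$gstt1 == "null"),
             cbz = s$cbz, pb = s$pb, pht = s$pht,
             row.names = NULL)
}

#' Factory for the exposure-response mixed-effects logistic model
#'
#' logit(Pr) = BASE + sum(coef_c * column_c) + SLOPE * AUC + eta, with one
#' normal random effect per subject. Covariates enter additively on the logit
#' (each contributes 1 df); any column of \code{\link{pd_data}} can be named.
#'
#' @param include character vector of covariate column names shifting BASE.
#' @param exposure "linear" or "emax".
#' @param init_override optional named initial values.
#' @return list(model, init, fixed, transform, df) as in
#'   \code{\link{pk_model_spec}}.
#' @export
pd_model_spec <- function(include = c("id_flag", "valval"),
                          exposure = c("linear", "emax"),
                          init_override = NULL) {
  exposure <- match.arg(exposure)
  f <- if (exposure == "linear") {
    function(par, eta, data) {
      lg <- par[["base"]] + par[["slope"]] * data$auc_g + eta
      for (nm in include) lg <- lg + par[[paste0("coef_", nm)]] * data[[nm]]
      lg
    }
  } else {
    function(par, eta, data) {
      lg <- par[["base"]] +
        par[["emax"]] * data$auc_g / (par[["ec50"]] + data$auc_g) + eta
      for (nm in include) lg <- lg + par[[paste0("coef_", nm)]] * data[[nm]]
      lg
    }
  }
  init <- c(base = -2)
  if (exposure == "linear") init["slope"] <- 1
  else { init["emax"] <- 4; init["ec50"] <- 1 }
  for (nm in include) init[paste0("coef_", nm)] <- 0.5
  init["omega2"] <- 2
  if (!is.null(init_override)) init[names(init_override)] <- init_override
  transform <- stats::setNames(rep("identity", length(init)), names(init))
  transform["omega2"] <- "log"
  if (exposure == "emax") transform["ec50"] <- "log"
  # upper bound on the logit variance: past ~2x the published estimate the
  # sparse-binary likelihood is flat along an inflation ridge (intercept,
  # covariate shifts and omega2 growing together) and the Laplace
  # approximation error grows with omega2, so estimates there are artefacts
  list(model = me_model("binary", f, name = "gamma-GT logit PD"),
       init = init, fixed = character(),
       transform = transform, upper = c(omega2 = 25),
       df = stats::setNames(rep(1L, length(include)), include))
}

#' Fit the exposure-response model for gamma-GT elevation
#'
#' Laplace fit of the random-intercept logistic model linking individual VPA
#' AUC (g.h/L) to the probability of gamma-GT elevation. The individual AUCs
#' are fixed inputs (sequential PK then PD estimation).
#'
#' @param cohort a \code{\link{vpa_cohort}} with ggt_records.
#' @param auc named per-subject AUC vector in g.h/L.
#' @param include additive covariates on BASE (columns of
#'   \code{\link{pd_data}}).
#' @param exposure "linear" or "emax".
#' @param init_override optional named initial values.
#' @param control outer optimiser control.
#' @return object of class \code{c("pdfit", "mefit")}.
#' @export
fit_pd_model <- function(cohort, auc, include = c("id_flag", "valval"),
                         exposure = "linear", init_override = NULL,
                         control = list()) {
  spec <- pd_model_spec(include, exposure = exposure,
                        init_override = init_override)
  dat <- pd_data(cohort, auc)
  fit <- mefit(spec$model, dat, spec$init, method = "laplace",
               transform = spec$transform, fixed = spec$fixed,
               upper = spec$upper, control = control)
  fit$include <- include
  fit$exposure <- exposure
  class(fit) <- c("pdfit", class(fit))
  fit
}

#' Predictions from a fitted model
#'
#' Population predictions use \eqn{\eta = 0}; individual predictions use the
#' empirical Bayes modes. For PD fits the prediction is the event
#' probability.
#'
#' @param object a \code{pkfit} or \code{pdfit}.
#' @param type "population" or "individual".
#' @param newdata optional data frame in the layout of \code{\link{pk_data}}
#'   / \code{\link{pd_data}} (individual predictions require fitted
#'   subjects).
#' @param ... unused.
#' @return numeric vector, one value per row.
#' @export
predict.mefit <- function(object, type = c("population", "individual"),
                          newdata = NULL, ...) {
  type <- match.arg(type)
  dat <- if (is.null(newdata)) object$data else newdata
  eta <- if (type == "population") numeric(nrow(dat)) else {
    e <- object$ebes[as.character(dat$id)]
    if (anyNA(e)) stop("predict: individual predictions need fitted subjects")
    unname(e)
  }
  fx <- object$model$f(coef(object), eta, dat)
  if (object$model$kind == "binary") stats::plogis(fx) else fx
}

#' Simulate observation vectors from a fitted model at its own design
#'
#' Draws new subject random effects and residual/Bernoulli noise at the
#' estimated parameters, at the rows of the fitted data. This is the
#' primitive under the visual predictive check.
#'
#' @param object a \code{mefit}.
#' @param nsim number of replicate observation vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return matrix (nrow(data) x nsim) of simulated \code{dv}.
#' @export
simulate.mefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  par <- coef(object)
  dat <- object$data
  subjects <- unique(dat$id)
  sid <- match(dat$id, subjects)
  out <- matrix(NA_real_, nrow(dat), nsim)
  for (k in seq_len(nsim)) {
    eta <- stats::rnorm(length(subjects), 0, sqrt(par[["omega2"]]))
    fx <- object$model$f(par, eta[sid], dat)
    if (object$model$kind == "binary") {
      out[, k] <- stats::rbinom(nrow(dat), 1, stats::plogis(fx))
    } else if (object$model$error == "proportional") {
      out[, k] <- fx * (1 + stats::rnorm(nrow(dat), 0, sqrt(par[["sigma2"]])))
    } else {
      out[, k] <- fx + stats::rnorm(nrow(dat), 0, sqrt(par[["sigma2"]]))
    }
  }
  out
}
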