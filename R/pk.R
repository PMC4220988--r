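#' Typical (population) PK parameters for the VPA one-compartment model
#'
#' Container for the fixed effects of the oral one-compartment model with
#' absorption lag: absorption rate constant \code{ka} (1/h), typical apparent
#' clearance \code{cl} (L/h), typical apparent volume \code{vd} (L), lag time
#' \code{alag} (h, fixed at 3.00 in the reference model), power exponents of
#' daily dose (normalised by \code{dose_ref} mg) on CL/F and Vd/F, and
#' multiplicative covariate factors on CL/F for female sex and co-administered
#' carbamazepine (CBZ), clobazam (CLB), phenobarbital (PB) and phenytoin (PHT).
#'
#' @param ka absorption rate constant, 1/h.
#' @param cl typical apparent oral clearance CL/F, L/h.
#' @param vd typical apparent volume of distribution Vd/F, L.
#' @param alag absorption lag time, h.
#' @param dose_exp_cl,dose_exp_vd dimensionless power exponents of
#'   dose/\code{dose_ref} on CL/F and Vd/F.
#' @param factor_female,factor_cbz,factor_clb,factor_pb,factor_pht
#'   dimensionless multiplicative factors on CL/F.
#' @param dose_ref reference daily dose used to normalise the dose covariate,
#'   mg/day.
#' @return An object of class \code{pk_thetas} (a named list).
#' @export
pk_thetas <- function(ka = 0.109, cl = 0.559, vd = 21.4, alag = 3.00,
                      dose_exp_cl = 0.596, dose_exp_vd = 1.52,
                      factor_female = 0.917, factor_cbz = 1.19,
                      factor_clb = 0.906, factor_pb = 1.12,
                      factor_pht = 1.43, dose_ref = 1000) {
  th <- list(ka = ka, cl = cl, vd = vd, alag = alag,
             dose_exp_cl = dose_exp_cl, dose_exp_vd = dose_exp_vd,
             factor_female = factor_female, factor_cbz = factor_cbz,
             factor_clb = factor_clb, factor_pb = factor_pb,
             factor_pht = factor_pht, dose_ref = dose_ref)
  pos <- c("ka", "cl", "vd", "factor_female", "factor_cbz", "factor_clb",
           "factor_pb", "factor_pht", "dose_ref")
  for (nm in pos) {
    if (!is.finite(th[[nm]]) || th[[nm]] <= 0)
      stop("pk_thetas: '", nm, "' must be positive and finite")
  }
  structure(th, class = "pk_thetas")
}

#' Inter-individual and residual variance components of the PK model
#'
#' Exponential inter-individual random effects have variances \code{omega2};
#' only the CL/F effect is non-negligible in the reference model (the others
#' were estimated at ~1e-7 and are fixed to zero here by default). Residual
#' error is proportional with variance \code{sigma2}.
#'
#' @param omega2_cl variance of the exponential random effect on CL/F.
#' @param omega2_ka,omega2_vd,omega2_alag variances for Ka, Vd/F and ALAG
#'   (default 0, i.e. fixed).
#' @param sigma2 proportional residual error variance.
#' @return An object of class \code{pk_variance}.
#' @export
pk_variance <- function(omega2_cl = 0.0587, omega2_ka = 0, omega2_vd = 0,
                        omega2_alag = 0, sigma2 = 0.0617) {
  v <- list(omega2_cl = omega2_cl, omega2_ka = omega2_ka,
            omega2_vd = omega2_vd, omega2_alag = omega2_alag,
            sigma2 = sigma2)
  if (any(!vapply(v, is.finite, logical(1))) || any(unlist(v) < 0))
    stop("pk_variance: all variance components must be finite and >= 0")
  structure(v, class = "pk_variance")
}

#' Individual PK parameters after covariates and random effects
#'
#' Applies the covariate model and exponential random effects to the typical
#' values:
#' \deqn{CL_i = CL \cdot (Dose/Dose_{ref})^{\theta_{dose,CL}} \cdot
#'   f_{female}^{[female]} \cdot f_{CBZ}^{[CBZ]} \cdot f_{CLB}^{[CLB]} \cdot
#'   f_{PB}^{[PB]} \cdot f_{PHT}^{[PHT]} \cdot e^{\eta_{CL}}}
#' and analogously \eqn{Vd_i} with its own dose exponent,
#' \eqn{Ka_i = Ka\,e^{\eta_{Ka}}}, \eqn{ALAG_i = ALAG\,e^{\eta_{ALAG}}}.
#'
#' All covariate arguments are vectorised; the result holds one parameter set
#' per subject (row).
#'
#' @param thetas a \code{\link{pk_thetas}} object.
#' @param daily_dose daily VPA dose, mg/day.
#' @param female,cbz,clb,pb,pht 0/1 covariate indicators.
#' @param eta_cl,eta_ka,eta_vd,eta_alag individual random effects (default 0).
#' @return An object of class \code{pk_individual}: list of vectors
#'   \code{ka_i}, \code{cl_i}, \code{vd_i}, \code{alag_i}, \code{ke_i}.
#' @export
pk_individual <- function(thetas, daily_dose, female = 0, cbz = 0, clb = 0,
                          pb = 0, pht = 0, eta_cl = 0, eta_ka = 0,
                          eta_vd = 0, eta_alag = 0) {
  stopifnot(inherits(thetas, "pk_thetas"))
  dn <- daily_dose / thetas$dose_ref
  cl_i <- thetas$cl * dn^thetas$dose_exp_cl *
    thetas$factor_female^female * thetas$factor_cbz^cbz *
    thetas$factor_clb^clb * thetas$factor_pb^pb *
    thetas$factor_pht^pht * exp(eta_cl)
  vd_i <- thetas$vd * dn^thetas$dose_exp_vd * exp(eta_vd)
  ka_i <- thetas$ka * exp(eta_ka)
  alag_i <- thetas$alag * exp(eta_alag)
  out <- list(ka_i = ka_i, cl_i = cl_i, vd_i = vd_i, alag_i = alag_i,
              ke_i = cl_i / vd_i)
  bad <- vapply(out, function(x) any(!is.finite(x)), logical(1))
  if (any(bad))
    stop("pk_individual: non-finite result for ",
         paste(names(out)[bad], collapse = ", "))
  out$class <- NULL
  structure(out, class = "pk_individual")
}

#' One-compartment oral concentration with absorption lag
#'
#' Closed-form concentration (mg/L) of the one-compartment model with
#' first-order absorption and elimination and an absorption lag. For a single
#' dose, with \eqn{t' = t - ALAG_i} (0 before the lag):
#' \deqn{C(t) = \frac{D}{Vd_i}\frac{Ka_i}{Ka_i - Ke_i}
#'   (e^{-Ke_i t'} - e^{-Ka_i t'})}
#' At steady state under repeated dosing every \eqn{\tau} hours, each
#' exponential term is divided by \eqn{1 - e^{-k\tau}} and the time after the
#' lag wraps modulo \eqn{\tau}. When \eqn{|Ka_i - Ke_i|} is below a relative
#' tolerance of 1e-8 the analytic limiting form
#' \eqn{(D/Vd_i)\,k^2 t' e^{-k t'}} (with its steady-state counterpart) is
#' used.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param t time since the last administration, h.
#' @param dose dose per administration, mg.
#' @param tau dosing interval, h.
#' @param ind a \code{\link{pk_individual}} object (its vectors recycle
#'   against \code{t}).
#' @param steady_state logical; superposition steady state if \code{TRUE}.
#' @return concentration(s) in mg/L.
#' @export
pk_concentration <- function(t, dose, tau, ind, steady_state = TRUE) {
  stopifnot(inherits(ind, "pk_individual"))
  if (any(t < 0)) stop("pk_concentration: t must be >= 0")
  if (any(dose <= 0) || any(tau <= 0))
    stop("pk_concentration: dose and tau must be positive")
  n <- max(length(t), length(dose), length(tau), length(ind$cl_i))
  t <- rep_len(t, n); dose <- rep_len(dose, n); tau <- rep_len(tau, n)
  ka <- rep_len(ind$ka_i, n); ke <- rep_len(ind$ke_i, n)
  vd <- rep_len(ind$vd_i, n); alag <- rep_len(ind$alag_i, n)
  ss <- rep_len(steady_state, n)

  tp <- t - alag
  tp <- ifelse(ss, tp %% tau, tp)

  tie <- abs(ka - ke) <= 1e-8 * pmax(ka, ke)
  conc <- numeric(n)

  if (any(!tie)) {
    i <- !tie
    e_ke <- exp(-ke[i] * tp[i])
    e_ka <- exp(-ka[i] * tp[i])
    acc_ke <- ifelse(ss[i], 1 - exp(-ke[i] * tau[i]), 1)
    acc_ka <- ifelse(ss[i], 1 - exp(-ka[i] * tau[i]), 1)
    conc[i] <- dose[i] / vd[i] * ka[i] / (ka[i] - ke[i]) *
      (e_ke / acc_ke - e_ka / acc_ka)
  }
  if (any(tie)) {
    # ka -> ke limit: C = (D/V) * k * (-f'(k)) with f(k) = e^{-k t'} / acc(k),
    # acc(k) = 1 - e^{-k tau} at steady state, 1 for a single dose; the single
    # dose case reduces to the familiar (D/V) k t' e^{-k t'}.
    i <- tie
    k <- (ka[i] + ke[i]) / 2
    ek <- exp(-k * tp[i])
    ekt <- exp(-k * tau[i])
    acc <- ifelse(ss[i], 1 - ekt, 1)
    dacc <- ifelse(ss[i], tau[i] * ekt, 0)  # d(acc)/dk
    fprime <- (-tp[i] * ek * acc - ek * dacc) / acc^2
    conc[i] <- dose[i] / vd[i] * k * (-fprime)
  }
  conc[!ss & (t < alag)] <- 0
  pmax(conc, 0)
}

#' Steady-state 24-hour AUC of VPA
#'
#' At steady state the area under the concentration-time curve over 24 h
#' equals \code{daily_dose / cl_i} (mg.h/L), independent of how the daily
#' dose is split across dosing intervals.
#'
#' @param ind a \code{\link{pk_individual}} object.
#' @param daily_dose daily dose, mg/day.
#' @return AUC in mg.h/L (divide by 1000 for the g.h/L scale used by the
#'   exposure-response model).
#' @export
auc_ss <- function(ind, daily_dose) {
  stopifnot(inherits(ind, "pk_individual"))
  if (any(ind$cl_i <= 0)) stop("auc_ss: cl_i must be positive")
  daily_dose / ind$cl_i
}
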