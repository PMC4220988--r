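#' Define a nonlinear mixed-effects model for the estimation engine
#'
#' The engine handles models with one scalar random effect per subject
#' (\eqn{\eta_i \sim N(0, \omega^2)}). A model is defined by a deterministic
#' structural function \code{f(par, eta, data)} returning one value per row of
#' \code{data} (a concentration prediction for continuous models, a logit for
#' binary models), where \code{eta} is the subject-level random effect already
#' expanded to row length. \code{par} is a named numeric vector that must
#' contain the reserved names \code{omega2} and, for continuous models,
#' \code{sigma2}.
#'
#' \code{data} must be a data.frame with columns \code{id} (subject key) and
#' \code{dv} (the observation: mg/L for continuous, 0/1 for binary), plus
#' whatever columns \code{f} reads.
#'
#' @param kind "continuous" (Gaussian residual) or "binary" (Bernoulli via
#'   inverse logit).
#' @param f structural function \code{function(par, eta, data)}.
#' @param error residual model for continuous data: "proportional" or
#'   "additive".
#' @param name label used in printing.
#' @return An object of class \code{me_model}.
#' @export
me_model <- function(kind = c("continuous", "binary"), f,
                     error = c("proportional", "additive"),
                     name = "model") {
  kind <- match.arg(kind)
  error <- match.arg(error)
  stopifnot(is.function(f))
  structure(list(kind = kind, f = f, error = error, name = name),
            class = "me_model")
}

# Sort the data by subject block and precompute the group layout used by the
# fast per-subject sums. Done once per fit, not per objective evaluation.
.me_prep <- function(data, subjects) {
  sid <- match(data$id, subjects)
  if (anyNA(sid)) stop("engine: data contains ids not in 'subjects'")
  if (is.unsorted(sid)) {
    o <- order(sid)
    data <- data[o, , drop = FALSE]
    sid <- sid[o]
  }
  ends <- cumsum(tabulate(sid, nbins = length(subjects)))
  list(data = data, sid = sid, ends = ends, nsub = length(subjects),
       subjects = subjects)
}

# per-subject sums over block-sorted rows; empty subjects contribute 0
.group_sum <- function(x, ends) {
  cs <- cumsum(x)[ends]
  cs[ends == 0] <- 0
  c(cs[1], diff(cs))
}

# Per-row log-likelihood given predictions (continuous) or logits (binary).
.me_ll_rows <- function(model, fx, y, par) {
  if (model$kind == "continuous") {
    if (model$error == "proportional") {
      sd <- sqrt(par[["sigma2"]]) * pmax(abs(fx), 1e-12)
    } else {
      sd <- rep_len(sqrt(par[["sigma2"]]), length(fx))
    }
    stats::dnorm(y, mean = fx, sd = sd, log = TRUE)
  } else {
    p <- stats::plogis(fx)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    y * log(p) + (1 - y) * log1p(-p)
  }
}

# Joint per-subject log density log p(y_i | eta_i) + log p(eta_i).
.me_joint <- function(model, prep, par, eta, prior = TRUE) {
  fx <- model$f(par, eta[prep$sid], prep$data)
  ll <- .me_ll_rows(model, fx, prep$data$dv, par)
  ll[!is.finite(ll)] <- -1e10
  js <- .group_sum(ll, prep$ends)
  if (prior) {
    om <- par[["omega2"]]
    js <- js - 0.5 * log(2 * pi * om) - eta^2 / (2 * om)
  }
  js
}

#' Empirical Bayes modes of the subject-level random effects
#'
#' For each subject, maximises the joint log density of the data and
#' \eqn{\eta_i} at fixed population parameters (the "inner" problem of
#' FOCE/Laplace estimation), by a vectorised damped Newton iteration with
#' finite-difference derivatives. Subjects with no observations get the prior
#' mode 0.
#'
#' @param model an \code{\link{me_model}}.
#' @param data model data frame (columns \code{id}, \code{dv}, ...).
#' @param par named parameter vector including \code{omega2} (and
#'   \code{sigma2} for continuous models).
#' @param subjects optional vector of subject ids (defaults to those present
#'   in \code{data}; may include subjects with no rows).
#' @param eta_start optional starting values (length = number of subjects).
#' @param prep internal precomputed layout (overrides \code{data} and
#'   \code{subjects}).
#' @return list with \code{eta} (modes, named by subject), \code{hess}
#'   (negative curvature \eqn{-\partial^2 J/\partial\eta^2} at the mode,
#'   positive at a proper maximum), \code{flag} (logical: inner problem did
#'   not converge cleanly and a guarded value is used), \code{joint} (joint
#'   log density at the mode).
#' @export
inner_modes <- function(model, data, par, subjects = NULL, eta_start = NULL,
                        prep = NULL) {
  if (is.null(prep)) {
    if (is.null(subjects)) subjects <- unique(data$id)
    prep <- .me_prep(data, subjects)
  }
  nsub <- prep$nsub
  om <- par[["omega2"]]
  if (om < 0) stop("inner_modes: omega2 must be >= 0")
  if (om == 0) {
    eta <- numeric(nsub)
    j <- .me_joint(model, prep, par, eta, prior = FALSE)
    return(list(eta = stats::setNames(eta, prep$subjects),
                hess = rep(Inf, nsub), flag = rep(FALSE, nsub), joint = j))
  }
  eta <- if (is.null(eta_start)) numeric(nsub) else rep_len(eta_start, nsub)
  h <- 1e-4
  J0 <- .me_joint(model, prep, par, eta)
  g <- H <- numeric(nsub)
  for (it in seq_len(100)) {
    Jp <- .me_joint(model, prep, par, eta + h)
    Jm <- .me_joint(model, prep, par, eta - h)
    g <- (Jp - Jm) / (2 * h)
    H <- (Jp - 2 * J0 + Jm) / h^2
    conv <- abs(g) < 1e-9 * pmax(1, abs(J0))
    if (all(conv)) break
    Hn <- pmin(H, -1e-8)            # force ascent direction
    step <- ifelse(conv, 0, -g / Hn)
    step <- pmin(pmax(step, -2), 2) # trust region on the eta scale
    if (max(abs(step)) > 1e-6) {
      # vectorised backtracking: halve steps that do not improve the joint
      for (bt in seq_len(8)) {
        Jn <- .me_joint(model, prep, par, eta + step)
        worse <- Jn < J0 - 1e-10 & abs(step) > 1e-10
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      moved <- Jn >= J0 - 1e-10
      eta <- ifelse(moved, eta + step, eta)
      J0 <- ifelse(moved, Jn, J0)
    } else {
      # asymptotic regime: plain Newton update, no line search needed
      eta <- eta + step
      J0 <- .me_joint(model, prep, par, eta)
      if (max(abs(step)) < 1e-10) break
    }
  }
  Jp <- .me_joint(model, prep, par, eta + h)
  Jm <- .me_joint(model, prep, par, eta - h)
  g <- (Jp - Jm) / (2 * h)
  # final curvature with a wider step: the second difference of a joint
  # log-density of magnitude ~1e3 at h = 1e-4 is dominated by cancellation
  # error (~eps |J| / h^2), while truncation at h = 1e-2 is ~1e-4
  h2 <- 1e-2
  Jp2 <- .me_joint(model, prep, par, eta + h2)
  Jm2 <- .me_joint(model, prep, par, eta - h2)
  H <- (Jp2 - 2 * J0 + Jm2) / h2^2
  flag <- !(abs(g) < 1e-4 * pmax(1, abs(J0))) | H >= 0
  list(eta = stats::setNames(eta, prep$subjects), hess = -H, flag = flag,
       joint = J0)
}

#' Marginal -2 log-likelihood (objective function value)
#'
#' Computes the total objective function value (OFV) for the model at fixed
#' parameters, by the Laplace approximation
#' \deqn{-2\sum_i [\,J_i(\hat\eta_i) + \tfrac12\log(2\pi) -
#'   \tfrac12\log(-J''_i(\hat\eta_i))\,]}
#' or, for continuous data, by the FOCE-with-interaction linearisation about
#' the empirical Bayes mode (residual variance evaluated at
#' \eqn{\hat\eta_i}). Constants (2\eqn{\pi} terms) are included, so only OFV
#' differences are comparable with other software.
#'
#' @inheritParams inner_modes
#' @param method "foce" (continuous only) or "laplace".
#' @param inner optional precomputed result of \code{\link{inner_modes}}.
#' @return scalar OFV, with attributes \code{ebes} (the modes) and
#'   \code{n_flagged} (inner-problem failures contributing guarded values).
#' @export
marginal_nll <- function(model, data, par,
                         method = c("laplace", "foce"),
                         subjects = NULL, inner = NULL, prep = NULL) {
  method <- match.arg(method)
  if (method == "foce" && model$kind != "continuous")
    stop("marginal_nll: FOCE applies to continuous data only")
  if (is.null(prep)) {
    if (is.null(subjects)) subjects <- unique(data$id)
    prep <- .me_prep(data, subjects)
  }
  nsub <- prep$nsub
  om <- par[["omega2"]]

  if (om == 0) {
    # no-random-effects limit: fixed-effects -2 log-likelihood at eta = 0
    fx <- model$f(par, numeric(nrow(prep$data)), prep$data)
    ll <- .me_ll_rows(model, fx, prep$data$dv, par)
    val <- -2 * sum(ll)
    attr(val, "ebes") <- stats::setNames(numeric(nsub), prep$subjects)
    attr(val, "n_flagged") <- 0L
    return(val)
  }

  if (is.null(inner)) inner <- inner_modes(model, par = par, prep = prep)
  eta <- unname(inner$eta)

  if (method == "laplace") {
    hs <- pmax(inner$hess, 1e-8)  # ridge guard for non-PD curvature
    ofv_i <- -2 * inner$joint + log(hs) - log(2 * pi)
  } else {
    # FOCE with interaction: linearise f about eta-hat, Gaussian marginal.
    dh <- 1e-4
    d <- prep$data
    sid <- prep$sid
    f0 <- model$f(par, eta[sid], d)
    fp <- model$f(par, (eta + dh)[sid], d)
    fm <- model$f(par, (eta - dh)[sid], d)
    grow <- (fp - fm) / (2 * dh)
    if (model$error == "proportional") {
      D <- par[["sigma2"]] * pmax(f0^2, 1e-24)
    } else {
      D <- rep_len(par[["sigma2"]], length(f0))
    }
    r <- d$dv - f0 + grow * eta[sid]
    a <- .group_sum(grow^2 / D, prep$ends)
    b <- .group_sum(r * grow / D, prep$ends)
    cc <- .group_sum(r^2 / D, prep$ends)
    logdetD <- .group_sum(log(D), prep$ends)
    nobs_i <- c(prep$ends[1], diff(prep$ends))
    ofv_i <- nobs_i * log(2 * pi) + logdetD + log1p(om * a) +
      cc - om * b^2 / (1 + om * a)
  }
  val <- sum(ofv_i)
  attr(val, "ebes") <- inner$eta
  attr(val, "n_flagged") <- sum(inner$flag)
  val
}

# transform helpers: optimisation runs on an unconstrained scale
.me_fwd <- function(x, tr) {
  i <- tr == "log"
  x[i] <- log(x[i])
  x
}
.me_bwd <- function(z, tr) {
  i <- tr == "log"
  z[i] <- exp(z[i])
  z
}

#' Fit a nonlinear mixed-effects model by FOCE or Laplace
#'
#' Minimises the total objective function value (sum over subjects of the
#' marginal -2 log-likelihood, \code{\link{marginal_nll}}) over the population
#' parameters. Positive parameters are log-transformed for the outer
#' quasi-Newton optimiser (\code{\link[stats]{nlminb}} with an explicit
#' central-difference gradient); empirical Bayes modes are warm-started
#' across outer iterations. A fit is declared converged when the optimiser
#' reports success and at most 5\% of subjects had flagged inner problems at
#' the optimum.
#'
#' @param model an \code{\link{me_model}}.
#' @param data model data frame (columns \code{id}, \code{dv}, ...).
#' @param init named numeric vector of starting values, including
#'   \code{omega2} (and \code{sigma2} for continuous models).
#' @param method "foce" (continuous default) or "laplace" (binary default).
#' @param transform named character vector ("log" or "identity") per
#'   parameter; defaults to "log" for \code{omega2}/\code{sigma2} and every
#'   strictly positive initial value, "identity" otherwise. Parameters
#'   transformed "log" are constrained positive.
#' @param fixed character vector of parameter names held at their initial
#'   values.
#' @param lower,upper optional named bounds on the natural scale (applied on
#'   the transformed scale through \code{\link[stats]{nlminb}}'s box
#'   constraints); parameters not named are unbounded.
#' @param control list passed to \code{\link[stats]{nlminb}} control
#'   (defaults: \code{rel.tol = 1e-6}, \code{iter.max = 400},
#'   \code{eval.max = 2000}).
#' @return An object of class \code{mefit} with components
#'   \code{coefficients} (all parameters, natural scale), \code{ofv},
#'   \code{converged}, \code{ebes}, \code{n_flagged}, \code{opt},
#'   \code{model}, \code{data}, \code{method}, \code{fixed},
#'   \code{transform}.
#' @export
mefit <- function(model, data, init, method = NULL, transform = NULL,
                  fixed = character(), lower = NULL, upper = NULL,
                  control = list()) {
  stopifnot(inherits(model, "me_model"))
  if (!all(c("id", "dv") %in% names(data)))
    stop("mefit: data must have columns 'id' and 'dv'")
  if (is.null(method)) method <- if (model$kind == "binary") "laplace" else "foce"
  need <- if (model$kind == "continuous") c("omega2", "sigma2") else "omega2"
  if (!all(need %in% names(init)))
    stop("mefit: init must name ", paste(need, collapse = ", "))
  if (is.null(transform)) {
    transform <- ifelse(names(init) %in% c("omega2", "sigma2") | init > 0,
                        "log", "identity")
    names(transform) <- names(init)
  }
  transform <- transform[names(init)]
  subjects <- unique(data$id)
  prep <- .me_prep(data, subjects)
  free <- setdiff(names(init), fixed)
  if (!length(free)) stop("mefit: no free parameters")

  # omega2 floor: near-zero variances are estimated down to 1e-10, below
  # which the effect is effectively fixed (see pk_variance defaults)
  om_floor <- 1e-10

  env <- new.env(parent = emptyenv())
  env$eta <- numeric(length(subjects))
  env$best <- Inf
  env$best_par <- init

  obj <- function(z) {
    par <- init
    par[free] <- .me_bwd(z, transform[free])
    if (par[["omega2"]] < om_floor) par[["omega2"]] <- om_floor
    inner <- tryCatch(
      inner_modes(model, par = par, eta_start = env$eta, prep = prep),
      error = function(e) NULL)
    if (is.null(inner)) return(1e10)
    env$eta <- unname(inner$eta)
    val <- tryCatch(
      as.numeric(marginal_nll(model, par = par, method = method,
                              inner = inner, prep = prep)),
      error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    if (val < env$best) {
      env$best <- val
      env$best_par <- par
    }
    val
  }

  ctrl <- utils::modifyList(
    list(rel.tol = 1e-6, iter.max = 400, eval.max = 2000), control)
  z0 <- .me_fwd(init[free], transform[free])
  zlo <- rep(-Inf, length(free)); zhi <- rep(Inf, length(free))
  names(zlo) <- names(zhi) <- free
  if (!is.null(lower)) {
    nm <- intersect(names(lower), free)
    zlo[nm] <- .me_fwd(lower[nm], transform[nm])
  }
  if (!is.null(upper)) {
    nm <- intersect(names(upper), free)
    zhi[nm] <- .me_fwd(upper[nm], transform[nm])
  }
  # explicit central-difference gradient: the inner problem is solved
  # iteratively, so the objective carries tiny numerical noise and the
  # optimiser's own sqrt(eps)-step differencing is unreliable
  grad <- function(z) {
    vapply(seq_along(z), function(i) {
      h <- 1e-4 * max(1, abs(z[i]))
      zp <- z; zp[i] <- z[i] + h
      zm <- z; zm[i] <- z[i] - h
      (obj(zp) - obj(zm)) / (2 * h)
    }, numeric(1))
  }
  opt <- stats::nlminb(z0, obj, gradient = grad, control = ctrl,
                       lower = zlo, upper = zhi)
  if (opt$convergence != 0) {
    # one restart from the incumbent: clears most spurious terminations
    opt2 <- stats::nlminb(opt$par, obj, gradient = grad, control = ctrl,
                          lower = zlo, upper = zhi)
    if (opt2$objective <= opt$objective) opt <- opt2
  }

  par <- init
  par[free] <- .me_bwd(opt$par, transform[free])
  if (par[["omega2"]] < om_floor) par[["omega2"]] <- om_floor
  if (env$best < opt$objective) par <- env$best_par  # best-so-far on failure
  inner <- inner_modes(model, par = par, eta_start = env$eta, prep = prep)
  ofv <- marginal_nll(model, par = par, method = method, inner = inner,
                      prep = prep)
  n_flag <- attr(ofv, "n_flagged")
  # optimiser success, or a stationary point in all but name: the objective
  # carries ~1e-7 iteration noise, so nlminb can report "false convergence"
  # with a negligible gradient left
  g_end <- grad(.me_fwd(par[free], transform[free]))
  opt_ok <- opt$convergence == 0 || max(abs(g_end)) < 0.5
  converged <- opt_ok && n_flag <= 0.05 * length(subjects)

  structure(list(coefficients = par, ofv = as.numeric(ofv),
                 converged = converged, ebes = inner$eta,
                 eta_hess = inner$hess, n_flagged = n_flag,
                 grad_end = g_end, opt = opt, model = model,
                 data = data, method = method, lower = lower, upper = upper,
                 init = init, fixed = fixed, transform = transform,
                 n_subjects = length(subjects), n_obs = nrow(data)),
            class = "mefit")
}

#' @export
print.mefit <- function(x, ...) {
  cat("Nonlinear mixed-effects fit (", x$model$name, ", ",
      toupper(x$method), ")\n", sep = "")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  cat("  OFV:", format(x$ofv, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  parameters:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.mefit <- function(object, ...) object$coefficients

#' @export
logLik.mefit <- function(object, ...) {
  structure(-object$ofv / 2,
            df = length(setdiff(names(object$init), object$fixed)),
            class = "logLik")
}

#' Summary of a mixed-effects fit, optionally with standard errors
#'
#' Standard errors (and relative standard errors, \%) come from a central
#' finite-difference Hessian of half the objective function on the natural
#' parameter scale; they are optional because the Hessian costs
#' \code{O(p^2)} objective evaluations.
#'
#' @param object a \code{\link{mefit}}.
#' @param se compute standard errors (default FALSE).
#' @param ... unused.
#' @export
summary.mefit <- function(object, se = FALSE, ...) {
  free <- setdiff(names(object$init), object$fixed)
  est <- object$coefficients[free]
  tab <- data.frame(estimate = est, row.names = free)
  if (se) {
    V <- vcov(object)
    tab$se <- sqrt(pmax(diag(V), 0))
    tab$rse_pct <- 100 * tab$se / abs(tab$estimate)
  }
  out <- list(table = tab, ofv = object$ofv, converged = object$converged,
              method = object$method, n_subjects = object$n_subjects,
              n_obs = object$n_obs, n_flagged = object$n_flagged,
              fixed = object$coefficients[object$fixed])
  class(out) <- "summary.mefit"
  out
}

#' @export
print.summary.mefit <- function(x, ...) {
  cat("Mixed-effects fit (", toupper(x$method), "): OFV ",
      format(x$ofv, digits = 8),
      if (x$converged) " (converged)\n" else " (NOT converged)\n", sep = "")
  cat(x$n_subjects, "subjects,", x$n_obs, "observations,",
      x$n_flagged, "flagged inner problems\n")
  print(round(x$table, 5))
  if (length(x$fixed)) {
    cat("fixed:\n"); print(round(x$fixed, 5))
  }
  invisible(x)
}

#' @export
vcov.mefit <- function(object, ...) {
  free <- setdiff(names(object$init), object$fixed)
  par0 <- object$coefficients
  prep <- .me_prep(object$data, unique(object$data$id))
  fobj <- function(p) {
    par <- par0
    par[free] <- p
    as.numeric(marginal_nll(object$model, par = par,
                            method = object$method, prep = prep)) / 2
  }
  p0 <- par0[free]
  np <- length(p0)
  hstep <- pmax(abs(p0), 1e-2) * 1e-3
  H <- matrix(NA_real_, np, np, dimnames = list(free, free))
  f0 <- fobj(p0)
  for (i in seq_len(np)) {
    for (j in i:np) {
      ei <- ej <- numeric(np)
      ei[i] <- hstep[i]; ej[j] <- hstep[j]
      if (i == j) {
        H[i, i] <- (fobj(p0 + ei) - 2 * f0 + fobj(p0 - ei)) / hstep[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fobj(p0 + ei + ej) - fobj(p0 + ei - ej) -
             fobj(p0 - ei + ej) + fobj(p0 - ei - ej)) /
          (4 * hstep[i] * hstep[j])
      }
    }
  }
  V <- tryCatch(solve(H), error = function(e) {
    warning("vcov.mefit: singular information matrix; ridge-adjusted")
    solve(H + diag(1e-6, np))
  })
  V
}
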