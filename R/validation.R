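# Model evaluation: stratified nonparametric bootstrap, visual predictive
# check for the binary gamma-GT endpoint, and goodness-of-fit diagnostics
# (population/individual predictions, conditional weighted residuals).

#' Stratified nonparametric bootstrap of a fitted model
#'
#' Draws \code{n} resampled datasets using the SUBJECT as the sampling unit,
#' with replacement, preserving stratum sizes exactly; refits the model on
#' each (initialised at the original estimates); and summarises the
#' successful replicates by per-parameter median and 2.5/97.5 percentile
#' bounds. A replicate is successful when the refit converges ("successful
#' minimisation": optimiser success and at most 5\% flagged inner problems).
#' The result is flagged unreliable when fewer than half the replicates
#' succeed.
#'
#' @param fit a \code{\link{mefit}} (or pkfit/pdfit).
#' @param n number of bootstrap replicates.
#' @param strata named vector (by subject id) of stratum labels; default one
#'   stratum.
#' @param seed integer seed.
#' @param control optimiser control for the refits.
#' @return object of class \code{me_bootstrap}: list with \code{summary}
#'   (data.frame: parameter, median, lo2.5, hi97.5), \code{estimates}
#'   (successful replicate matrix), \code{n_requested},
#'   \code{n_successful}, \code{reliable}.
#' @export
bootstrap_fit <- function(fit, n = 1000, strata = NULL, seed = 1,
                          control = list()) {
  stopifnot(inherits(fit, "mefit"))
  set.seed(seed)
  dat <- fit$data
  subjects <- unique(dat$id)
  if (is.null(strata))
    strata <- stats::setNames(rep("all", length(subjects)), subjects)
  strata <- strata[as.character(subjects)]
  free <- setdiff(names(fit$init), fit$fixed)
  rows_by_subject <- split(seq_len(nrow(dat)), match(dat$id, subjects))
  ests <- matrix(NA_real_, n, length(free), dimnames = list(NULL, free))
  ok <- logical(n)
  for (b in seq_len(n)) {
    picked <- unlist(lapply(split(seq_along(subjects), strata), function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    newdat <- dat[unlist(rows_by_subject[picked], use.names = FALSE), ,
                  drop = FALSE]
    reps <- vapply(rows_by_subject[picked], length, integer(1))
    newdat$id <- rep(paste0("B", seq_along(picked)), reps)
    f <- tryCatch(
      mefit(fit$model, newdat, init = coef(fit), method = fit$method,
            transform = fit$transform, fixed = fit$fixed,
            lower = fit$lower, upper = fit$upper, control = control),
      error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      ests[b, ] <- coef(f)[free]
      ok[b] <- TRUE
    }
  }
  est_ok <- ests[ok, , drop = FALSE]
  qs <- apply(est_ok, 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975), na.rm = TRUE)
  summ <- data.frame(parameter = free, median = qs[1, ], lo2.5 = qs[2, ],
                     hi97.5 = qs[3, ], row.names = NULL)
  structure(list(summary = summ, estimates = est_ok, n_requested = n,
                 n_successful = sum(ok), reliable = sum(ok) >= 0.5 * n),
            class = "me_bootstrap")
}

#' @export
print.me_bootstrap <- function(x, ...) {
  cat("Nonparametric bootstrap:", x$n_successful, "of", x$n_requested,
      "replicates with successful minimisation",
      if (!x$reliable) "(UNRELIABLE: < 50% success)" else "", "\n")
  print(transform(x$summary, median = signif(median, 4),
                  lo2.5 = signif(lo2.5, 4), hi97.5 = signif(hi97.5, 4)))
  invisible(x)
}

#' Visual predictive check for the binary gamma-GT endpoint
#'
#' Simulates \code{n_sim} replicate outcome sets at the observed design from
#' the fitted model and compares, per stratum and exposure bin, the observed
#' proportion of elevation with the 5th-95th percentile band (90\% prediction
#' interval) of the simulated proportions. Bins are quantile bins of the
#' binning variable (individual AUC by default) within each stratum; empty
#' bins are dropped with a warning.
#'
#' @param fit a \code{pdfit} (binary \code{\link{mefit}}).
#' @param n_sim number of simulated datasets.
#' @param strata named vector (by subject id) of stratum labels, or NULL for
#'   a single stratum.
#' @param bins number of quantile bins (default 4).
#' @param bin_on column of the fit data to bin on (default \code{auc_g}).
#' @param seed integer seed.
#' @return object of class \code{me_vpc}: data.frame with stratum, bin,
#'   bin_mid, n_obs, observed, lo5, hi95.
#' @export
vpc_check <- function(fit, n_sim = 1000, strata = NULL, bins = 4,
                      bin_on = "auc_g", seed = 1) {
  stopifnot(inherits(fit, "mefit"), fit$model$kind == "binary")
  dat <- fit$data
  if (!bin_on %in% names(dat)) stop("vpc_check: no column '", bin_on, "'")
  st <- if (is.null(strata)) rep("all", nrow(dat)) else
    as.character(strata[as.character(dat$id)])
  sims <- stats::simulate(fit, nsim = n_sim, seed = seed)
  out <- list()
  for (s in unique(st)) {
    rows <- which(st == s)
    x <- dat[[bin_on]][rows]
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    bi <- cut(x, br, include.lowest = TRUE)
    for (lev in levels(bi)) {
      r <- rows[which(bi == lev)]
      if (!length(r)) {
        warning("vpc_check: empty bin ", lev, " in stratum ", s, "; dropped")
        next
      }
      simp <- colMeans(sims[r, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        stratum = s, bin = lev, bin_mid = stats::median(x[bi == lev]),
        n_obs = length(r), observed = mean(dat$dv[r]),
        lo5 = unname(stats::quantile(simp, 0.05)),
        hi95 = unname(stats::quantile(simp, 0.95)))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("me_vpc", "data.frame")
  res
}

#' @export
plot.me_vpc <- function(x, ...) {
  strata <- unique(x$stratum)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(strata)))
  on.exit(graphics::par(old))
  for (s in strata) {
    b <- x[x$stratum == s, ]
    b <- b[order(b$bin_mid), ]
    graphics::plot(b$bin_mid, b$observed, type = "n", ylim = c(0, 1),
                   xlab = "individual AUC (g·h/L)",
                   ylab = "proportion gamma-GT elevated", main = s, ...)
    graphics::polygon(c(b$bin_mid, rev(b$bin_mid)), c(b$lo5, rev(b$hi95)),
                      col = grDevices::adjustcolor("steelblue", 0.4),
                      border = NA)
    graphics::lines(b$bin_mid, b$observed, type = "b", pch = 16)
  }
  invisible(x)
}

#' Goodness-of-fit diagnostics for a fitted continuous (PK) model
#'
#' Population predictions (eta = 0), individual predictions (eta at the
#' empirical Bayes mode) and conditional weighted residuals (CWRES): the
#' FOCE-with-interaction mean-corrected residual decorrelated by the
#' model-implied covariance (residual variance at the mode plus the
#' linearised random-effect contribution). Subjects with a singular implied
#' covariance fall back to plain weighted residuals with a flag.
#'
#' @param fit a \code{pkfit} (continuous \code{\link{mefit}}).
#' @return object of class \code{me_gof}: data.frame with id, dv, pred,
#'   ipred, cwres, fallback.
#' @export
gof_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mefit"), fit$model$kind == "continuous")
  dat <- fit$data
  par <- coef(fit)
  subjects <- unique(dat$id)
  sid <- match(dat$id, subjects)
  eta <- unname(fit$ebes[as.character(subjects)])
  pred <- fit$model$f(par, numeric(nrow(dat)), dat)
  ipred <- fit$model$f(par, eta[sid], dat)
  dh <- 1e-4
  fp <- fit$model$f(par, (eta + dh)[sid], dat)
  fm <- fit$model$f(par, (eta - dh)[sid], dat)
  g <- (fp - fm) / (2 * dh)
  Dv <- if (fit$model$error == "proportional")
    par[["sigma2"]] * pmax(ipred^2, 1e-24) else
    rep_len(par[["sigma2"]], nrow(dat))
  r <- dat$dv - ipred + g * eta[sid]
  om <- par[["omega2"]]
  cwres <- numeric(nrow(dat))
  fallback <- logical(nrow(dat))
  for (j in seq_along(subjects)) {
    rows <- which(sid == j)
    V <- diag(Dv[rows], length(rows)) + om * tcrossprod(g[rows])
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      cwres[rows] <- r[rows] / sqrt(Dv[rows])
      fallback[rows] <- TRUE
    } else {
      cwres[rows] <- backsolve(L, r[rows], transpose = TRUE)
    }
  }
  res <- data.frame(id = dat$id, dv = dat$dv, pred = pred, ipred = ipred,
                    cwres = cwres, fallback = fallback)
  class(res) <- c("me_gof", "data.frame")
  res
}

#' @export
plot.me_gof <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  lim <- range(c(x$dv, x$pred, x$ipred))
  graphics::plot(x$pred, x$dv, xlab = "population prediction (mg/L)",
                 ylab = "observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(x$ipred, x$dv, xlab = "individual prediction (mg/L)",
                 ylab = "observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(x$pred, x$cwres, xlab = "population prediction (mg/L)",
                 ylab = "CWRES", ...)
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}

#' Residuals of a mixed-effects fit
#'
#' Conditional weighted residuals for continuous fits; raw
#' observed-minus-fitted-probability residuals for binary fits.
#'
#' @param object a \code{\link{mefit}}.
#' @param ... unused.
#' @export
residuals.mefit <- function(object, ...) {
  if (object$model$kind == "continuous") gof_diagnostics(object)$cwres
  else object$data$dv - predict(object, type = "individual")
}
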