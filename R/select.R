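# Stepwise covariate model building on objective-function changes:
# forward inclusion then backward elimination against chi-square thresholds
# (3.84 for 1 df, 5.99 for 2 df at P < 0.05).

#' Chi-square significance thresholds for stepwise selection
#'
#' The 95th percentiles of the chi-square distribution used as change-in-OFV
#' thresholds: 3.84 for 1 df, 5.99 for 2 df.
#'
#' @param df degrees of freedom (1 or 2).
#' @param alpha significance level.
#' @return threshold value(s).
#' @export
ofv_threshold <- function(df, alpha = 0.05) {
  stats::qchisq(1 - alpha, df = df)
}

# fit one candidate set through a model factory; returns NULL on failure
.fit_included <- function(factory, data, include, control) {
  spec <- factory(include)
  fit <- tryCatch(
    mefit(spec$model, data, spec$init, method = spec$method,
          transform = spec$transform, fixed = spec$fixed,
          lower = spec$lower, upper = spec$upper, control = control),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit
}

#' Forward inclusion of covariates by largest significant drop in OFV
#'
#' Starting from the base model, repeatedly fits each remaining candidate on
#' top of the current model and adds the one with the largest OFV decrease,
#' provided that decrease meets the chi-square threshold for its df (3.84 for
#' 1 df, 5.99 for 2 df by default); ties break by candidate order.
#' Non-convergent candidate fits are skipped with a warning.
#'
#' @param factory function(include) returning a model spec: a list with
#'   \code{model} (\code{\link{me_model}}), \code{init}, \code{fixed},
#'   \code{transform}, \code{df} (named df per candidate) and optionally
#'   \code{method}. \code{\link{pk_model_spec}} and
#'   \code{\link{pd_model_spec}} have this shape (their \code{method}
#'   defaults to the model kind's default).
#' @param data estimation data frame.
#' @param candidates character vector of candidate covariate names
#'   understood by the factory.
#' @param base character vector always included (the base model).
#' @param thresholds named vector \code{c(df1 = 3.84, df2 = 5.99)}.
#' @param control optimiser control passed to \code{\link{mefit}}.
#' @return list with \code{fit} (the full-model fit), \code{include}
#'   (selected names) and \code{trace} (data.frame of tested steps:
#'   step, candidate, ofv, delta_ofv, threshold, decision).
#' @export
forward_inclusion <- function(factory, data, candidates,
                              base = character(),
                              thresholds = c(df1 = 3.84, df2 = 5.99),
                              control = list()) {
  factory2 <- function(inc) {
    spec <- factory(inc)
    if (is.null(spec$method))
      spec$method <- if (spec$model$kind == "binary") "laplace" else "foce"
    spec
  }
  cur <- .fit_included(factory2, data, base, control)
  if (is.null(cur)) stop("forward_inclusion: base model did not converge")
  include <- base
  remaining <- setdiff(candidates, base)
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    best <- NULL; best_d <- -Inf
    for (cand in remaining) {
      spec <- factory2(c(include, cand))
      dfc <- spec$df[[cand]]
      thr <- unname(thresholds[[paste0("df", dfc)]])
      f <- .fit_included(factory2, data, c(include, cand), control)
      if (is.null(f)) {
        warning("forward_inclusion: candidate '", cand,
                "' skipped (non-convergence)")
        trace[[length(trace) + 1]] <- data.frame(
          step = step, candidate = cand, ofv = NA, delta_ofv = NA,
          threshold = thr, decision = "skipped")
        next
      }
      d <- cur$ofv - f$ofv
      sig <- d >= thr
      trace[[length(trace) + 1]] <- data.frame(
        step = step, candidate = cand, ofv = f$ofv, delta_ofv = d,
        threshold = thr,
        decision = if (sig) "significant" else "not significant")
      if (sig && d > best_d) { best <- list(cand = cand, fit = f); best_d <- d }
    }
    if (is.null(best)) break
    include <- c(include, best$cand)
    remaining <- setdiff(remaining, best$cand)
    cur <- best$fit
    trace[[length(trace)]]$decision <- trace[[length(trace)]]$decision
    trace[[length(trace) + 1]] <- data.frame(
      step = step, candidate = best$cand, ofv = cur$ofv, delta_ofv = best_d,
      threshold = unname(thresholds[[paste0(
        "df", factory2(include)$df[[best$cand]])]]),
      decision = "included")
  }
  list(fit = cur, include = include, trace = do.call(rbind, trace))
}

#' Backward elimination of covariates by smallest increase in OFV
#'
#' Starting from the full model, repeatedly removes the covariate whose
#' removal increases the OFV least, as long as that increase is below the
#' chi-square threshold for its df; stops when every removal is significant.
#' Covariates named in \code{keep} (e.g. the structural dose effects) are
#' never removed.
#'
#' @inheritParams forward_inclusion
#' @param include the full model's covariate set.
#' @param keep covariates exempt from elimination.
#' @return list(fit, include, trace) as in \code{\link{forward_inclusion}}.
#' @export
backward_elimination <- function(factory, data, include,
                                 keep = character(),
                                 thresholds = c(df1 = 3.84, df2 = 5.99),
                                 control = list()) {
  factory2 <- function(inc) {
    spec <- factory(inc)
    if (is.null(spec$method))
      spec$method <- if (spec$model$kind == "binary") "laplace" else "foce"
    spec
  }
  cur <- .fit_included(factory2, data, include, control)
  if (is.null(cur)) stop("backward_elimination: full model did not converge")
  trace <- list()
  step <- 0L
  repeat {
    removable <- setdiff(include, keep)
    if (!length(removable)) break
    step <- step + 1L
    best <- NULL; best_d <- Inf
    for (cand in removable) {
      spec <- factory2(include)
      dfc <- spec$df[[cand]]
      thr <- unname(thresholds[[paste0("df", dfc)]])
      f <- .fit_included(factory2, data, setdiff(include, cand), control)
      if (is.null(f)) {
        warning("backward_elimination: removal of '", cand,
                "' skipped (non-convergence)")
        trace[[length(trace) + 1]] <- data.frame(
          step = step, candidate = cand, ofv = NA, delta_ofv = NA,
          threshold = thr, decision = "skipped")
        next
      }
      d <- f$ofv - cur$ofv   # increase on removal; >= 0 for nested optima
      sig <- d >= thr
      trace[[length(trace) + 1]] <- data.frame(
        step = step, candidate = cand, ofv = f$ofv, delta_ofv = d,
        threshold = thr,
        decision = if (sig) "retained" else "removable")
      if (!sig && d < best_d) { best <- list(cand = cand, fit = f); best_d <- d }
    }
    if (is.null(best)) break
    include <- setdiff(include, best$cand)
    cur <- best$fit
    trace[[length(trace) + 1]] <- data.frame(
      step = step, candidate = best$cand, ofv = cur$ofv, delta_ofv = best_d,
      threshold = NA, decision = "removed")
  }
  list(fit = cur, include = include, trace = do.call(rbind, trace))
}

#' Write a selection trace as CSV
#'
#' @param trace the \code{trace} element of a selection result.
#' @param path output CSV path.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
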