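# Mixed-effects estimation engine: empirical Bayes inner problem, Laplace /
# FOCE objectives against independent oracles, and the outer fit.

test_that("inner modes solve the empirical Bayes problem", {
  mb <- toy_bin_model()
  par <- c(b0 = 0.2, b1 = 1.1, omega2 = 0.8)
  db <- toy_bin_data(12, 4, b0 = 0.2, b1 = 1.1, omega2 = 0.8, seed = 7)
  im <- inner_modes(mb, db, par)
  # mode matches a dense grid search over eta, subject by subject
  for (id in unique(db$id)[1:6]) {
    d <- db[db$id == id, ]
    grid <- seq(-5, 5, by = 1e-4)
    lj <- vapply(grid, function(e) {
      p <- plogis(mb$f(par, rep(e, nrow(d)), d))
      sum(d$dv * log(p) + (1 - d$dv) * log1p(-p)) +
        dnorm(e, 0, sqrt(par[["omega2"]]), log = TRUE)
    }, numeric(1))
    expect_lt(abs(unname(im$eta[id]) - grid[which.max(lj)]), 2e-4)
  }
  expect_true(all(im$hess > 0))
  expect_false(any(im$flag))

  # a subject with no observations sits at the prior mode 0
  im2 <- inner_modes(mb, db, par, subjects = c(unique(db$id), "EMPTY"))
  expect_equal(unname(im2$eta[["EMPTY"]]), 0)
  expect_equal(unname(im2$hess[length(im2$hess)]), 1 / 0.8,
               tolerance = 1e-4)

  # omega2 -> 0 shrinks every mode to 0
  im3 <- inner_modes(mb, db, c(b0 = 0.2, b1 = 1.1, omega2 = 1e-8))
  expect_lt(max(abs(im3$eta)), 1e-3)
})

test_that("Laplace objective matches the closed-form linear-Gaussian marginal", {
  m <- toy_lin_model()
  d <- toy_lin_data(40, 3, mu = 1, omega2 = 0.5, sigma2 = 0.25, seed = 1)
  for (par in list(c(mu = 1, omega2 = 0.5, sigma2 = 0.25),
                   c(mu = 0.4, omega2 = 1.2, sigma2 = 0.1),
                   c(mu = 2, omega2 = 0.05, sigma2 = 0.8))) {
    lap <- as.numeric(marginal_nll(m, d, par, method = "laplace"))
    expect_equal(lap, toy_lin_nll_exact(d, par[["mu"]], par[["omega2"]],
                                        par[["sigma2"]]),
                 tolerance = 1e-6)
    # FOCE linearisation is also exact for a model linear in eta
    foce <- as.numeric(marginal_nll(m, d, par, method = "foce"))
    expect_equal(foce, lap, tolerance = 1e-6)
  }
})

test_that("Laplace objective matches 64-node adaptive quadrature on binary toys", {
  mb <- toy_bin_model()
  for (cfg in list(list(n_sub = 2, n_obs = 1500, om = 0.2),
                   list(n_sub = 2, n_obs = 2000, om = 0.3))) {
    db <- toy_bin_data(cfg$n_sub, cfg$n_obs, b0 = 0.4, b1 = 0.8,
                       omega2 = cfg$om, seed = 5)
    par <- c(b0 = 0.4, b1 = 0.8, omega2 = cfg$om)
    lap <- as.numeric(marginal_nll(mb, db, par, method = "laplace"))
    expect_equal(lap, agq_nll_binary(db, par, mb$f), tolerance = 1e-3)
  }
})

test_that("omega2 = 0 reduces to the fixed-effects -2 log-likelihood", {
  mb <- toy_bin_model()
  db <- toy_bin_data(15, 4, b0 = 0.5, b1 = 0.7, omega2 = 0.5, seed = 3)
  par <- c(b0 = 0.5, b1 = 0.7, omega2 = 0)
  v <- as.numeric(marginal_nll(mb, db, par))
  p <- plogis(mb$f(par, numeric(nrow(db)), db))
  expect_equal(v, -2 * sum(dbinom(db$dv, 1, p, log = TRUE)),
               tolerance = 1e-10)
})

test_that("objective is invariant to subject ordering", {
  mb <- toy_bin_model()
  db <- toy_bin_data(20, 4, b0 = 0.3, b1 = 0.9, omega2 = 0.6, seed = 8)
  par <- c(b0 = 0.3, b1 = 0.9, omega2 = 0.6)
  v1 <- as.numeric(marginal_nll(mb, db, par))
  perm <- sample(nrow(db))
  v2 <- as.numeric(marginal_nll(mb, db[perm, ], par))
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("the outer fit recovers generating values and is a fixed point", {
  m <- toy_lin_model()
  d <- toy_lin_data(150, 4, mu = 1.5, omega2 = 0.6, sigma2 = 0.2, seed = 21)
  fit <- mefit(m, d, c(mu = 0.5, omega2 = 1, sigma2 = 0.5))
  expect_true(fit$converged)
  # closed-form ML for the balanced linear-Gaussian design as oracle
  ybar <- mean(d$dv)
  expect_equal(coef(fit)[["mu"]], ybar, tolerance = 1e-3)
  expect_lt(abs(coef(fit)[["omega2"]] - 0.6), 0.2)
  expect_lt(abs(coef(fit)[["sigma2"]] - 0.2), 0.04)
  # refitting from the optimum moves the OFV by less than 0.01
  fit2 <- mefit(m, d, coef(fit))
  expect_lt(abs(fit2$ofv - fit$ofv), 0.01)
  # logLik bookkeeping
  expect_equal(as.numeric(logLik(fit)), -fit$ofv / 2)
  expect_equal(attr(logLik(fit), "df"), 3)
})

test_that("binary fit recovers generating values within Monte-Carlo spread", {
  mb <- toy_bin_model()
  ests <- t(sapply(1:5, function(s) {
    db <- toy_bin_data(120, 6, b0 = 0.5, b1 = 1.2, omega2 = 0.7,
                       seed = 100 + s)
    coef(mefit(mb, db, c(b0 = 0, b1 = 0.5, omega2 = 1)))[c("b0", "b1")]
  }))
  expect_lt(abs(mean(ests[, "b0"]) - 0.5), 3 * max(sd(ests[, "b0"]), 0.05))
  expect_lt(abs(mean(ests[, "b1"]) - 1.2), 3 * max(sd(ests[, "b1"]), 0.05))
})

test_that("OFV is monotone in model richness (nested models)", {
  st <- generate_study(generator_config(n_subjects = 60), seed = 31)
  d <- pd_data(st$cohort, st$auc_g)
  fit0 <- .pd_fit_for_test(d, c("id_flag"))
  fit1 <- .pd_fit_for_test(d, c("id_flag", "valval"))
  expect_lte(fit1$ofv, fit0$ofv + 1e-6)
})

test_that("a null covariate rarely moves the OFV past the 1-df threshold", {
  # chi-square(1) calibration of delta-OFV for a covariate with zero true
  # effect: under the null the drop exceeds 3.84 in about 5% of replicates
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    st <- generate_study(generator_config(n_subjects = 70), seed = 300 + s)
    d <- pd_data(st$cohort, st$auc_g)
    f0 <- .pd_fit_for_test(d, c("id_flag", "valval"))
    f1 <- .pd_fit_for_test(d, c("id_flag", "valval", "gstm1_null"))
    if ((f0$ofv - f1$ofv) >= 3.84) hits <- hits + 1L
  }
  expect_lte(hits, 0.1 * n_rep)  # >= 90% of replicates below threshold
})

test_that("standard errors from the outer information matrix are sane", {
  m <- toy_lin_model()
  d <- toy_lin_data(100, 4, mu = 1, omega2 = 0.5, sigma2 = 0.25, seed = 77)
  fit <- mefit(m, d, c(mu = 0.8, omega2 = 0.7, sigma2 = 0.3))
  s <- summary(fit, se = TRUE)
  # balanced-design closed form: var(mu-hat) = (sigma2 + n omega2)/(N n)
  par <- coef(fit)
  se_mu_exact <- sqrt((par[["sigma2"]] + 4 * par[["omega2"]]) / (100 * 4))
  expect_equal(s$table["mu", "se"], se_mu_exact, tolerance = 0.05)
})
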