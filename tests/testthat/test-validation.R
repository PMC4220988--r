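# Bootstrap, visual predictive check and goodness-of-fit diagnostics.

# construct a fit object at known parameters without optimisation (for
# diagnostics that only need a parameterised model + EBEs)
fit_at <- function(model, data, par, method = "foce") {
  inner <- inner_modes(model, data, par)
  structure(list(coefficients = par, ofv = NA_real_, converged = TRUE,
                 ebes = inner$eta, eta_hess = inner$hess, n_flagged = 0,
                 model = model, data = data, method = method,
                 init = par, fixed = character(),
                 transform = setNames(rep("identity", length(par)),
                                      names(par)),
                 n_subjects = length(unique(data$id)), n_obs = nrow(data)),
            class = "mefit")
}

test_that("bootstrap with n = 1 is the single replicate with degenerate CI", {
  m <- toy_lin_model()
  d <- toy_lin_data(25, 3, mu = 1, omega2 = 0.4, sigma2 = 0.2, seed = 14)
  fit <- mefit(m, d, c(mu = 0.8, omega2 = 0.5, sigma2 = 0.3))
  bs <- bootstrap_fit(fit, n = 1, seed = 99)
  expect_equal(bs$n_requested, 1)
  expect_equal(bs$n_successful, 1)
  expect_equal(bs$summary$median, bs$summary$lo2.5, tolerance = 1e-12)
  expect_equal(bs$summary$median, bs$summary$hi97.5, tolerance = 1e-12)
})

test_that("singleton strata make every bootstrap replicate the original data", {
  m <- toy_lin_model()
  d <- toy_lin_data(10, 3, mu = 1, omega2 = 0.4, sigma2 = 0.2, seed = 15)
  fit <- mefit(m, d, c(mu = 0.8, omega2 = 0.5, sigma2 = 0.3))
  subjects <- unique(d$id)
  strata <- setNames(subjects, subjects)  # one stratum per subject
  bs <- bootstrap_fit(fit, n = 5, strata = strata, seed = 1)
  # stratum sizes preserved exactly => resample == original every time
  expect_lt(max(apply(bs$estimates, 2, sd)), 1e-6)
  # each replicate refits the original data from the optimum
  expect_equal(unname(bs$summary$median),
               unname(coef(fit)[bs$summary$parameter]), tolerance = 0.05)
})

test_that("bootstrap CIs shrink as clones accumulate", {
  m <- toy_lin_model()
  width <- vapply(c(15, 60), function(nclone) {
    set.seed(33)
    base <- data.frame(id = "c", dv = c(0.6, 1.1, 1.6))
    d <- do.call(rbind, lapply(seq_len(nclone), function(k)
      transform(base, id = paste0("c", k),
                dv = dv + rnorm(3, 0, 0.05))))
    fit <- mefit(m, d, c(mu = 1, omega2 = 0.1, sigma2 = 0.3))
    bs <- bootstrap_fit(fit, n = 40, seed = 7)
    i <- which(bs$summary$parameter == "mu")
    bs$summary$hi97.5[i] - bs$summary$lo2.5[i]
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("VPC band is degenerate when no events can occur", {
  st <- generate_study(generator_config(n_subjects = 40), seed = 17)
  d <- pd_data(st$cohort, st$auc_g)
  d$dv <- 0
  fit <- fit_at(pd_model_spec()$model, d,
                c(base = -50, slope = 0, coef_id_flag = 0, coef_valval = 0,
                  omega2 = 1e-6), method = "laplace")
  v <- vpc_check(fit, n_sim = 100, bins = 3, seed = 2)
  expect_true(all(v$observed == 0))
  expect_true(all(v$lo5 == 0 & v$hi95 == 0))
})

test_that("VPC respects strata, bins and seed reproducibility", {
  st <- generate_study(generator_config(n_subjects = 100), seed = 18)
  d <- pd_data(st$cohort, st$auc_g)
  fit <- fit_at(pd_model_spec()$model, d,
                c(base = -6.63, slope = 1.55, coef_id_flag = 3.62,
                  coef_valval = 1.96, omega2 = 3.48), method = "laplace")
  strata <- setNames(ifelse(st$cohort$subjects$sod2 == "ValVal",
                            "ValVal", "Ala"),
                     st$cohort$subjects$subject_id)
  v1 <- vpc_check(fit, n_sim = 200, strata = strata, bins = 3, seed = 5)
  v2 <- vpc_check(fit, n_sim = 200, strata = strata, bins = 3, seed = 5)
  expect_identical(v1, v2)
  expect_setequal(unique(v1$stratum), c("ValVal", "Ala"))
  expect_true(all(v1$lo5 <= v1$hi95))
  expect_true(all(v1$observed >= 0 & v1$observed <= 1))
  # subject order must not matter
  perm <- sample(nrow(d))
  fitp <- fit_at(pd_model_spec()$model, d[perm, ], coef(fit),
                 method = "laplace")
  v3 <- vpc_check(fitp, n_sim = 200, strata = strata, bins = 3, seed = 5)
  o1 <- v1[order(v1$stratum, v1$bin_mid), c("observed", "n_obs")]
  o3 <- v3[order(v3$stratum, v3$bin_mid), c("observed", "n_obs")]
  expect_equal(o1$observed, o3$observed)
})

test_that("GOF residuals vanish on noise-free data and standardise on noisy data", {
  set.seed(19)
  cohort <- generate_cohort(generator_config(n_subjects = 60))
  rec0 <- simulate_concentrations(cohort, variance = pk_variance(
    omega2_cl = 0, sigma2 = 0), seed = 19)
  co0 <- vpa_cohort(cohort$subjects, rec0)
  spec <- pk_model_spec()
  par <- c(ka = 0.109, cl = 0.559, vd = 21.4, alag = 3, dose_cl = 0.596,
           dose_vd = 1.52, female = 0.917, cbz = 1.19, clb = 0.906,
           pb = 1.12, pht = 1.43, omega2 = 1e-8, sigma2 = 1e-6)
  g0 <- gof_diagnostics(fit_at(spec$model, pk_data(co0), par))
  expect_lt(max(abs(g0$dv - g0$pred) / g0$pred), 1e-6)
  expect_lt(max(abs(g0$cwres)), 0.05)

  # model-true noisy data: CWRES approximately standard
  rec <- simulate_concentrations(cohort, seed = 20)
  co <- vpa_cohort(cohort$subjects, rec)
  par2 <- par; par2["omega2"] <- 0.0587; par2["sigma2"] <- 0.0617
  g <- gof_diagnostics(fit_at(spec$model, pk_data(co), par2))
  expect_lt(abs(mean(g$cwres)), 0.2)
  expect_gt(var(g$cwres), 0.6)
  expect_lt(var(g$cwres), 1.4)
  # individual predictions never fit worse than population predictions
  w <- 1 / pmax(g$ipred, 1e-6)^2
  expect_lte(sum(w * (g$dv - g$ipred)^2), sum(w * (g$dv - g$pred)^2))
})

test_that("residuals methods dispatch for both model kinds", {
  m <- toy_lin_model()
  d <- toy_lin_data(20, 3, mu = 1, omega2 = 0.4, sigma2 = 0.2, seed = 21)
  fit <- mefit(m, d, c(mu = 0.8, omega2 = 0.5, sigma2 = 0.3))
  expect_length(residuals(fit), nrow(d))
  st <- generate_study(generator_config(n_subjects = 30), seed = 22)
  pdf <- fit_at(pd_model_spec()$model, pd_data(st$cohort, st$auc_g),
                c(base = -6.63, slope = 1.55, coef_id_flag = 3.62,
                  coef_valval = 1.96, omega2 = 3.48), method = "laplace")
  r <- residuals(pdf)
  expect_true(all(abs(r) <= 1))
})
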