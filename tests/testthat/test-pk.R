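# One-compartment oral PK model: covariate model, closed-form concentration
# and steady-state AUC, checked against published typical values, hand
# arithmetic and an independent ODE solver.

test_that("individual parameters reproduce typical values and covariate arithmetic", {
  th <- pk_thetas()
  # reference male at the 1000 mg reference dose, all eta = 0
  ref <- pk_individual(th, daily_dose = 1000)
  expect_equal(ref$cl_i, 0.559)
  expect_equal(ref$vd_i, 21.4)
  expect_equal(ref$alag_i, 3.00)
  # female multiplies CL/F by 0.917
  fem <- pk_individual(th, daily_dose = 1000, female = 1)
  expect_equal(fem$cl_i, 0.559 * 0.917)
  # exponential IIV: eta = ln 2 doubles CL exactly
  dbl <- pk_individual(th, daily_dose = 1000, eta_cl = log(2))
  expect_equal(dbl$cl_i, 2 * ref$cl_i)
  # multiplicative factors commute: order of covariates irrelevant by
  # construction, product of all factors
  all_cov <- pk_individual(th, daily_dose = 1000, female = 1, cbz = 1,
                           clb = 1, pb = 1, pht = 1)
  expect_equal(all_cov$cl_i,
               0.559 * 0.917 * 1.19 * 0.906 * 1.12 * 1.43)
  # dose enters as a power of dose/1000
  d2 <- pk_individual(th, daily_dose = 2000)
  expect_equal(d2$cl_i, 0.559 * 2^0.596)
  expect_equal(d2$vd_i, 21.4 * 2^1.52)
})

test_that("parameter monotonicity in eta holds for each component", {
  th <- pk_thetas()
  etas <- seq(-1, 1, 0.5)
  cls <- vapply(etas, function(e)
    pk_individual(th, 800, eta_cl = e)$cl_i, numeric(1))
  expect_true(all(diff(cls) > 0))
  kas <- vapply(etas, function(e)
    pk_individual(th, 800, eta_ka = e)$ka_i, numeric(1))
  expect_true(all(diff(kas) > 0))
})

test_that("single-dose concentration is zero before the lag and matches the ODE system", {
  skip_if_not_installed("deSolve")
  th <- pk_thetas()
  ind <- pk_individual(th, daily_dose = 1000)
  expect_equal(pk_concentration(1, 500, 24, ind, steady_state = FALSE), 0)
  expect_equal(pk_concentration(2.999, 500, 24, ind, steady_state = FALSE), 0)

  # independent oracle: two-compartment (gut + central) ODE system
  ode_conc <- function(t, dose, ind) {
    rhs <- function(t, y, p)
      list(c(-p$ka * y[1], p$ka * y[1] - p$ke * y[2]))
    p <- list(ka = ind$ka_i, ke = ind$ke_i)
    tt <- sort(unique(c(0, t - ind$alag_i)))
    tt <- tt[tt >= 0]
    out <- deSolve::lsoda(c(gut = dose, cen = 0), tt, rhs, p,
                          rtol = 1e-10, atol = 1e-12)
    lookup <- approxfun(out[, "time"], out[, "cen"] / ind$vd_i, rule = 2)
    ifelse(t < ind$alag_i, 0, lookup(t - ind$alag_i))
  }
  t <- c(3.5, 5, 8, 12, 18, 24, 36)
  closed <- pk_concentration(t, 500, 24, ind, steady_state = FALSE)
  ode <- ode_conc(t, 500, ind)
  expect_equal(closed, ode, tolerance = 1e-3)
})

test_that("steady state equals superposition of many single doses", {
  th <- pk_thetas()
  ind <- pk_individual(th, daily_dose = 900)
  tau <- 24
  t <- c(0.5, 4, 7, 13, 20)
  ss <- pk_concentration(t, 450, tau, ind, steady_state = TRUE)
  super <- rowSums(vapply(0:40, function(n)
    pk_concentration(t + n * tau, 450, tau, ind, steady_state = FALSE),
    numeric(length(t))))
  expect_equal(ss, super, tolerance = 5e-3)
})

test_that("ka = ke limiting form agrees with the near-tie closed form", {
  th <- pk_thetas()
  base <- pk_individual(th, daily_dose = 1000)
  mk <- function(ka) {
    x <- base
    x$ka_i <- ka
    x
  }
  k <- base$ke_i
  exact_tie <- pk_concentration(c(5, 10, 20), 500, 24, mk(k),
                                steady_state = TRUE)
  near_tie <- pk_concentration(c(5, 10, 20), 500, 24, mk(k * (1 + 1e-6)),
                               steady_state = TRUE)
  expect_equal(exact_tie, near_tie, tolerance = 1e-4)
  # single-dose tie reduces to (D/V) k t' exp(-k t')
  tie_sd <- pk_concentration(8, 500, 24, mk(k), steady_state = FALSE)
  tp <- 8 - base$alag_i
  expect_equal(tie_sd, 500 / base$vd_i * k * tp * exp(-k * tp),
               tolerance = 1e-6)
})

test_that("concentration is non-negative and continuous at the lag", {
  th <- pk_thetas()
  ind <- pk_individual(th, daily_dose = 600)
  t <- seq(0, 48, by = 0.05)
  c_sd <- pk_concentration(t, 300, 24, ind, steady_state = FALSE)
  expect_true(all(c_sd >= 0))
  just_before <- pk_concentration(ind$alag_i - 1e-9, 300, 24, ind, FALSE)
  just_after <- pk_concentration(ind$alag_i + 1e-9, 300, 24, ind, FALSE)
  expect_equal(just_before, just_after, tolerance = 1e-6)
})

test_that("steady-state AUC is dose/CL and invariant to dose splitting", {
  th <- pk_thetas()
  ind <- pk_individual(th, daily_dose = 1000)
  expect_equal(auc_ss(structure(list(cl_i = 1, vd_i = 1, ka_i = 1,
                                     alag_i = 0, ke_i = 1),
                                class = "pk_individual"), 1), 1)
  expect_equal(auc_ss(ind, 1000), 1000 / ind$cl_i)
  # doubling clearance halves the AUC exactly
  ind2 <- pk_individual(th, daily_dose = 1000, eta_cl = log(2))
  expect_equal(auc_ss(ind2, 1000), auc_ss(ind, 1000) / 2)

  # trapezoidal integral over one day at steady state, for two splittings
  for (tau in c(12, 24)) {
    t <- seq(0, tau, length.out = 4001)
    conc <- pk_concentration(t, 1000 * tau / 24, tau, ind,
                             steady_state = TRUE)
    auc_num <- sum(diff(t) * (head(conc, -1) + tail(conc, -1)) / 2) * 24 / tau
    expect_equal(auc_num, 1000 / ind$cl_i, tolerance = 5e-3)
  }
})
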