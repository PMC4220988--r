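# Independent oracles and toy-model builders shared across tests.
# Everything here is deliberately implemented from first principles
# (quadrature, closed forms, brute force) and never calls the engine paths
# it is used to check.

# --- toy mixed models ------------------------------------------------------

# linear-Gaussian random-intercept model: y_ij = mu + eta_i + e_ij
toy_lin_model <- function() {
  me_model("continuous", function(par, eta, data) par[["mu"]] + eta,
           error = "additive", name = "linear-Gaussian toy")
}

toy_lin_data <- function(n_sub, n_obs, mu, omega2, sigma2, seed) {
  set.seed(seed)
  eta <- rnorm(n_sub, 0, sqrt(omega2))
  idx <- rep(seq_len(n_sub), each = n_obs)
  data.frame(id = sprintf("T%03d", idx),
             dv = mu + eta[idx] + rnorm(n_sub * n_obs, 0, sqrt(sigma2)))
}

# exact -2 log marginal likelihood of the linear-Gaussian toy:
# per subject y ~ N(mu 1, sigma2 I + omega2 J), via determinant and
# Sherman-Morrison identities written out directly
toy_lin_nll_exact <- function(data, mu, omega2, sigma2) {
  tot <- 0
  for (id in unique(data$id)) {
    y <- data$dv[data$id == id]
    n <- length(y)
    r <- y - mu
    detV <- sigma2^(n - 1) * (sigma2 + n * omega2)
    quad <- (sum(r^2) - omega2 * n^2 * mean(r)^2 /
               (sigma2 + n * omega2)) / sigma2
    tot <- tot + n * log(2 * pi) + log(detV) + quad
  }
  tot
}

# random-intercept logistic toy: logit = b0 + b1 x + eta
toy_bin_model <- function() {
  me_model("binary",
           function(par, eta, data) par[["b0"]] + par[["b1"]] * data$x + eta,
           name = "logistic toy")
}

toy_bin_data <- function(n_sub, n_obs, b0, b1, omega2, seed) {
  set.seed(seed)
  eta <- rnorm(n_sub, 0, sqrt(omega2))
  idx <- rep(seq_len(n_sub), each = n_obs)
  x <- runif(n_sub * n_obs, -1, 1)
  data.frame(id = sprintf("T%03d", idx), x = x,
             dv = rbinom(n_sub * n_obs, 1, plogis(b0 + b1 * x + eta[idx])))
}

# --- quadrature oracle -----------------------------------------------------

# Gauss-Hermite nodes/weights by the Golub-Welsch eigenvalue construction
gh_rule <- function(n) {
  i <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- i
  J <- J + t(J)
  E <- eigen(J, symmetric = TRUE)
  list(x = E$values, w = (E$vectors[1, ])^2 * sqrt(pi))
}

# -2 log marginal likelihood of a 1-eta binary toy by 64-node adaptive
# Gauss-Hermite quadrature; the per-subject centring/scaling comes from a
# dense grid scan, independent of the engine's inner problem
agq_nll_binary <- function(data, par, f, n_nodes = 64) {
  rule <- gh_rule(n_nodes)
  om <- par[["omega2"]]
  tot <- 0
  for (id in unique(data$id)) {
    d <- data[data$id == id, , drop = FALSE]
    lj <- function(e) {
      p <- pmin(pmax(plogis(f(par, rep(e, nrow(d)), d)), 1e-12), 1 - 1e-12)
      sum(d$dv * log(p) + (1 - d$dv) * log1p(-p)) +
        dnorm(e, 0, sqrt(om), log = TRUE)
    }
    grid <- seq(-8 * sqrt(om), 8 * sqrt(om), length.out = 801)
    lg <- vapply(grid, lj, numeric(1))
    k <- which.max(lg)
    mu <- grid[k]
    h <- grid[2] - grid[1]
    curv <- -(lg[k + 1] - 2 * lg[k] + lg[k - 1]) / h^2
    sdv <- 1 / sqrt(max(curv, 1e-8))
    z <- mu + sqrt(2) * sdv * rule$x
    lz <- vapply(z, lj, numeric(1))
    m <- max(lz + rule$x^2)
    tot <- tot - 2 * (log(sum(rule$w * exp(lz + rule$x^2 - m))) + m +
                        log(sqrt(2) * sdv))
  }
  tot
}

# fit the PD logit model on a prebuilt pd_data frame with a chosen
# covariate set (bypasses the cohort plumbing for speed in engine tests)
.pd_fit_for_test <- function(d, include, control = list()) {
  spec <- pd_model_spec(include)
  mefit(spec$model, d, spec$init, method = "laplace",
        transform = spec$transform, upper = spec$upper, control = control)
}

# --- small-cohort builder --------------------------------------------------

make_subjects <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(runif(n, 5, 40), 1),
    sex = sample(c("male", "female"), n, TRUE),
    body_weight = round(runif(n, 20, 80), 1),
    daily_dose = sample(seq(200, 1600, 100), n, TRUE),
    sod2 = sample(c("ValVal", "ValAla", "AlaAla"), n, TRUE,
                  prob = c(0.776, 0.207, 0.017)),
    cyp2c9 = sample(c("*1/*1", "*1/*3"), n, TRUE, prob = c(0.94, 0.06)),
    cyp2c19 = sample(c("homEM", "hetEM", "PM"), n, TRUE),
    gstm1 = sample(c("null", "present"), n, TRUE),
    gstt1 = sample(c("null", "present"), n, TRUE),
    intellectual_disability = runif(n) < 0.574,
    cbz = rbinom(n, 1, 0.2), clb = rbinom(n, 1, 0.15),
    pb = rbinom(n, 1, 0.1), pht = rbinom(n, 1, 0.1),
    tpm = rbinom(n, 1, 0.05), zns = rbinom(n, 1, 0.05),
    gbp = rbinom(n, 1, 0.01),
    vpa_start_date = as.Date("2005-06-01") + seq_len(n))
}
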