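test_that("model log likelihood matches closed forms and the dpois oracle", {
  n <- 6
  adj <- lattice_adjacency(2, 3)
  state0 <- list(alpha = c(0, 0, 0), beta = c(0, 0, 0), w = rep(1 / 9, 9),
                 u = numeric(n), v = numeric(n), s = matrix(0, n, 3))
  # y = 0, theta*E = 1 everywhere -> -3n
  data <- list(y = matrix(0, n, 3), E = matrix(1, n, 3),
               q = matrix(0, n, 9))
  expect_equal(log_likelihood(state0, data), -3 * n)
  # single informative cell: y = 2, theta*E = 2
  data1 <- list(y = matrix(c(2, rep(0, 17)), n, 3),
                E = matrix(c(2, rep(1e-12, 17)), n, 3), q = matrix(0, n, 9))
  ll <- log_likelihood(state0, data1)
  expect_equal(ll, 2 * log(2) - 2 - log(2), tolerance = 1e-6)

  # random states against an independent Poisson log-pmf oracle
  set.seed(99)
  for (i in 1:10) {
    state <- list(alpha = rnorm(3, 0, 0.3), beta = rnorm(3, 0, 0.1),
                  w = as.vector(prop.table(rexp(9))),
                  u = rnorm(n, 0, 0.2), v = rnorm(n, 0, 0.2),
                  s = matrix(rnorm(3 * n, 0, 0.2), n, 3))
    q <- matrix(sample(0:9, 9 * n, TRUE), n, 9)
    E <- matrix(runif(3 * n, 0.5, 3), n, 3)
    ndi <- as.vector(q %*% state$w)
    theta <- exp(sapply(1:3, function(k)
      state$alpha[k] + state$beta[k] * ndi + state$u + state$v + state$s[, k]))
    y <- matrix(rpois(3 * n, theta * E), n, 3)
    expect_equal(log_likelihood(state, list(y = y, E = E, q = q)),
                 sum(dpois(y, theta * E, log = TRUE)), tolerance = 1e-8)
  }
})

test_that("ICAR log density follows the pairwise-difference kernel", {
  adj2 <- ndi_adjacency(list(a = "b", b = "a"))
  # z = (1, -1), tau = 1: Q = 4, rank = n - components = 1
  expect_equal(icar_logdensity(c(1, -1), 1, adj2), 0.5 * log(1) - 2)
  # constant field lies in the null space
  adj <- lattice_adjacency(3, 3)
  expect_equal(icar_logdensity(rep(2, 9), 3, adj), (8 / 2) * log(3))
  # doubling tau: density changes by (n_eff/2) log 2 - (tau/2) Q
  z <- rnorm(9); z <- z - mean(z)
  Q <- 0
  for (i in 1:9) for (j in adj$neighbors[[i]]) if (j > i) Q <- Q + (z[i] - z[j])^2
  tau <- 1.7
  expect_equal(icar_logdensity(z, 2 * tau, adj) - icar_logdensity(z, tau, adj),
               (8 / 2) * log(2) - (tau / 2) * Q)
  expect_error(icar_logdensity(c(0, 0), 1,
                               ndi_adjacency(list(a = character(),
                                                  b = character()))),
               "no edges")
})

test_that("Gelman-Rubin matches the textbook formula and flags divergence", {
  set.seed(12)
  x <- cbind(rnorm(200), rnorm(200), rnorm(200))
  expect_equal(gelman_rubin(x), psrf_ref(x))
  # identical chains: B = 0, psrf = sqrt((m-1)/m) <= 1
  same <- cbind(rnorm(100))
  expect_equal(gelman_rubin(cbind(same, same)), sqrt(99 / 100))
  # disjoint supports diverge
  far <- cbind(rnorm(100), rnorm(100, 50))
  expect_gt(gelman_rubin(far), 5)
  expect_warning(g0 <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "zero")
  expect_true(is.nan(g0))
  if (requireNamespace("coda", quietly = TRUE)) {
    # coda applies an extra d.f. correction; agreement should still be close
    cl <- coda::mcmc.list(coda::mcmc(x[, 1, drop = FALSE]),
                          coda::mcmc(x[, 2, drop = FALSE]),
                          coda::mcmc(x[, 3, drop = FALSE]))
    expect_equal(gelman_rubin(x),
                 unname(coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1]),
                 tolerance = 0.05)
  }
})

test_that("stored draws satisfy the simplex and centering constraints", {
  sd <- small_synth_data(seed = 31, rows = 5, cols = 5)
  fit <- fit_shared_car(sd$data, config = model_config(
    n_iter = 800, n_burnin = 400, seed = 5))
  wsums <- apply(fit$w, c(1, 3), sum)
  expect_true(all(abs(wsums - 1) < 1e-9))
  expect_true(all(fit$w > 0 & fit$w < 1))
  expect_true(all(abs(apply(fit$v, c(1, 3), sum)) < 1e-6))
  expect_true(all(abs(apply(fit$s, c(1, 3, 4), sum)) < 1e-6))
  expect_true(all(is.finite(fit$beta)))
})

test_that("with flat index and no spatial terms the intercept recovers the rate", {
  set.seed(44)
  n <- 100
  adj <- lattice_adjacency(10, 10)
  E <- matrix(runif(3 * n, 1, 4), n, 3)
  alpha_true <- c(-0.3, 0.1, 0.4)
  y <- sapply(1:3, function(k) rpois(n, exp(alpha_true[k]) * E[, k]))
  data <- list(y = y, E = E, q = matrix(0, n, 9))
  fit <- fit_shared_car(data, adjacency = adj, config = model_config(
    include_u = FALSE, include_v = FALSE, include_s = FALSE,
    n_iter = 3000, n_burnin = 1000, seed = 6))
  mle <- log(colSums(y) / colSums(E))  # intercept-only Poisson MLE oracle
  post <- apply(fit$alpha, 2, median)
  se <- 1 / sqrt(colSums(y))
  expect_true(all(abs(post - mle) < 4 * se))
})

test_that("without spatial terms posterior medians track the MAP oracle", {
  sd <- small_synth_data(seed = 61, rows = 12, cols = 12,
                         sd_u = 0, sd_v = 0, sd_s = c(0, 0, 0),
                         baseline_rate = 0.01)
  dat <- sd$data
  fit <- fit_shared_car(dat, config = model_config(
    include_u = FALSE, include_v = FALSE, include_s = FALSE,
    n_iter = 6000, n_burnin = 2000, seed = 13))
  # penalized-likelihood oracle: optimize alpha, beta, softmax weights under
  # the same Dirichlet(1)-with-Jacobian penalty, sigma_beta fixed wide
  nll <- function(par) {
    alpha <- par[1:3]; beta <- par[4:6]
    phi <- c(0, par[7:14])
    w <- exp(phi) / sum(exp(phi))
    ndi <- as.vector(dat$q %*% w)
    eta <- sapply(1:3, function(k) alpha[k] + beta[k] * ndi)
    -(sum(dat$y * eta - dat$E * exp(eta)) + sum(log(w)) +
        sum(dnorm(beta, 1, 100, log = TRUE)))
  }
  opt <- optim(c(rep(0, 3), rep(0.1, 3), rep(0, 8)), nll, method = "BFGS",
               control = list(maxit = 500))
  beta_map <- opt$par[4:6]
  beta_post <- apply(fit$beta, 2, median)
  expect_equal(beta_post, beta_map, tolerance = 0.05)
})

test_that("two chains on simulated data converge by the Gelman-Rubin rule", {
  sd <- small_synth_data(seed = 71)
  fit <- fit_shared_car(sd$data, config = model_config(
    n_iter = 3000, n_burnin = 1500, seed = 14))
  expect_true(all(gelman_rubin(fit$beta) < 1.2))
  # true effects inside wide posterior ranges (smoke-level recovery)
  qs <- apply(fit$beta, 2, quantile, c(0.005, 0.995))
  expect_true(all(sd$synth$truth$betas > qs[1, ] &
                    sd$synth$truth$betas < qs[2, ]))
})

test_that("config validation enforces run-length and positivity constraints", {
  expect_error(model_config(n_iter = 100, n_burnin = 100), "less than")
  expect_error(model_config(tau_gamma_shape = 0), "positive")
  expect_error(model_config(n_chains = 0), "n_chains")
})
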