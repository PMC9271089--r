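test_that("intercept-only Poisson fits have their closed forms", {
  f <- fit_poisson_glm(ones(3), c(1L, 2L, 3L))
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)

  E <- c(2, 5, 9, 1)
  y <- c(3L, 4L, 10L, 0L)
  f2 <- fit_poisson_glm(ones(4), y, offset = log(E))
  expect_equal(unname(f2$coefficients), log(sum(y) / sum(E)), tolerance = 1e-8)
  # log likelihood includes the factorial term
  mu <- E * sum(y) / sum(E)
  expect_equal(f2$log_likelihood, sum(dpois(y, mu, log = TRUE)),
               tolerance = 1e-8)
  expect_equal(f2$aic, -2 * f2$log_likelihood + 2)
})

test_that("Poisson coefficients match a brute-force Newton oracle to 1e-6", {
  set.seed(11)
  n <- 50
  X <- cbind(1, rnorm(n), runif(n), rbinom(n, 1, 0.4))
  beta_true <- c(0.5, 0.3, -0.6, 0.2)
  off <- log(runif(n, 1, 4))
  y <- rpois(n, exp(off + X %*% beta_true))
  fit <- fit_poisson_glm(X, y, off)
  # independent oracle: direct maximisation of the log likelihood
  nll <- function(b) -sum(y * (off + X %*% b) - exp(off + X %*% b))
  ora <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(unname(fit$coefficients) - ora$par)), 1e-6)
})

test_that("rank-deficient designs are refused with the offending column", {
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(fit_poisson_glm(X, rep(1L, 10)), "c")
})

test_that("the lag screen recovers a lag-1 rainfall effect", {
  hits <- 0L
  for (r in 1:20) {
    g <- make_lattice_adjacency(6, 6)
    tr <- ground_truth(g, seed = 300 + r, omega = 0.1)
    sim <- simulate_dataset(g, 24, tr, seed = 300 + r)
    sel <- screen_lags(sim$panel, sim$climate, "rainfall_mm", 0:3,
                       scale = 10)
    if (!sel$excluded && sel$chosen_lag == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})

test_that("a covariate with no effect is usually excluded", {
  excl <- 0L
  for (r in 1:20) {
    g <- make_lattice_adjacency(4, 4)
    # omega = 0: the univariate Poisson screen is calibrated only for
    # genuinely Poisson counts (zero inflation would overdisperse them
    # and inflate the type-I rate of the Wald screen)
    tr <- ground_truth(g, seed = 500 + r, omega = 0,
                       beta = c(age = log(2.3), sex = -0.1, trend = 0,
                                altitude = 0, tmax = 0, rainfall = 0, rh = 0))
    tr$u[] <- 0; tr$v[] <- 0; tr$delta[] <- 0
    sim <- simulate_dataset(g, 24, tr, seed = 500 + r)
    sel <- screen_lags(sim$panel, sim$climate, "rainfall_mm", 0:3,
                       scale = 10)
    if (sel$excluded) excl <- excl + 1L
  }
  # four correlated lag tests at alpha = 0.05: exclusion of a null
  # covariate should happen in roughly (0.95)^4 ~ 81% of replicates
  expect_gte(excl, 13)
})

test_that("equal-AIC candidates resolve to the smaller lag", {
  sim <- desk_sim(seed = 61, T = 16, nrow_lat = 3, ncol_lat = 3)
  sel <- screen_lags(sim$panel, sim$climate, "rainfall_mm", c(2L, 2L),
                     scale = 10)
  expect_equal(nrow(sel$table), 2)
  expect_equal(sel$table$aic[1], sel$table$aic[2])
  if (!sel$excluded) expect_equal(sel$chosen_lag, 2L)
})

test_that("variance inflation factors match their OLS definition", {
  z <- c(1, -1, 1, -1) / 2
  w <- c(1, 1, -1, -1) / 2            # orthonormal, centred
  expect_equal(unname(vif(cbind(z, w))), c(1, 1))
  # constructed pair with R^2 exactly 0.75 -> VIF exactly 4
  x2 <- sqrt(3) * z + w
  expect_equal(unname(vif(cbind(x1 = z, x2 = x2))), c(4, 4))
  # duplicated column is flagged infinite
  expect_true(all(is.infinite(vif(cbind(z, z)))))
  expect_error(vif(cbind(z)), "two covariates")
})

test_that("VIF agrees with the car package on a random design", {
  skip_if_not_installed("car")
  set.seed(5)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  X[, 3] <- X[, 1] * 0.8 + rnorm(200, sd = 0.5)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(200)
  ref <- car::vif(lm(y ~ a + b + c, data = as.data.frame(cbind(X, y = y))))
  expect_equal(unname(vif(X)), unname(ref), tolerance = 1e-10)
})

test_that("ZIP maximum likelihood recovers a constant inflation probability", {
  set.seed(17)
  n <- 10000
  y <- ifelse(runif(n) < 0.3, 0L, rpois(n, 5))
  fit <- fit_zip_mle(ones(length(y)), y)
  expect_lt(abs(fit$omega_hat - 0.3), 0.02)
  expect_equal(unname(exp(fit$coefficients)), 5, tolerance = 0.1)
  expect_equal(sum(fit$pointwise_loglik), fit$log_likelihood)
})

test_that("ZIP degenerate inputs reduce or fail as they should", {
  y <- c(1L, 2L, 3L, 4L)
  expect_warning(fz <- fit_zip_mle(ones(length(y)), y), "no zero counts")
  fp <- fit_poisson_glm(ones(length(y)), y)
  expect_equal(fz$omega_hat, 0)
  expect_equal(fz$log_likelihood, fp$log_likelihood, tolerance = 1e-10)
  expect_error(fit_zip_mle(ones(3), c(0L, 0L, 0L)), "unbounded")
})

test_that("ZIP log likelihood dominates Poisson at the MLE (nesting)", {
  set.seed(19)
  for (om in c(0, 0.15, 0.4)) {
    y <- ifelse(runif(500) < om, 0L, rpois(500, 2))
    X <- cbind(1, rnorm(500))
    pois <- fit_poisson_glm(X, y)
    zip <- suppressWarnings(fit_zip_mle(X, y))
    expect_gte(zip$log_likelihood, pois$log_likelihood - 1e-6)
  }
})

test_that("AIC ordering is invariant to affine rescaling of covariates", {
  set.seed(23)
  n <- 300
  x <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.4 * x))
  a1 <- fit_poisson_glm(cbind(1, x), y)$aic
  a2 <- fit_poisson_glm(cbind(1, x * 100 + 7), y)$aic
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("the Vuong test behaves at its boundaries and has power", {
  set.seed(29)
  y <- ifelse(runif(2000) < 0.3, 0L, rpois(2000, 4))
  pois <- fit_poisson_glm(ones(length(y)), y)
  zip <- fit_zip_mle(ones(length(y)), y)
  # identical pointwise log likelihoods -> z = 0, inconclusive
  same <- vuong_test(zip, zip)
  expect_equal(same$z, 0)
  expect_true(same$inconclusive)
  # n = 1 is inconclusive
  z1 <- zip; z1$pointwise_loglik <- z1$pointwise_loglik[1]
  p1 <- pois; p1$pointwise_loglik <- p1$pointwise_loglik[1]
  expect_true(vuong_test(z1, p1)$inconclusive)
  expect_error(vuong_test(z1, pois), "different numbers of rows")

  # power under genuine zero inflation: omega 0.4, mu 3, n 5000
  wins <- 0L
  for (r in 1:20) {
    set.seed(700 + r)
    y <- ifelse(runif(5000) < 0.4, 0L, rpois(5000, 3))
    vg <- vuong_test(fit_zip_mle(ones(length(y)), y), fit_poisson_glm(ones(length(y)), y))
    if (vg$z > 1.96) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})
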