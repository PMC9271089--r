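test_that("ZIP log pmf matches direct arithmetic and nests Poisson", {
  expect_equal(zip_loglik(0, 1e-12, 0.5), 0, tolerance = 1e-9)
  expect_equal(zip_loglik(1, 1, 0), -1)
  expect_equal(zip_loglik(0, 2, 0.2), log(0.2 + 0.8 * exp(-2)))
  # vectorised, and equal to dpois when omega = 0
  y <- c(0L, 1L, 5L, 12L)
  mu <- c(0.5, 1, 4, 9)
  expect_equal(zip_loglik(y, mu, 0), dpois(y, mu, log = TRUE))
  expect_error(zip_loglik(1, 0, 0.1), "positive")
  expect_error(zip_loglik(1, 1, 1), "omega")
})

test_that("ICAR quadratic forms match hand enumeration on small graphs", {
  path3 <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(icar_quadform(c(5, 5, 5), path3), 0)
  expect_equal(icar_quadform(c(0, 1, -1), path3), 5)  # 1 + 4
  k4 <- make_lattice_adjacency(2, 2)                  # queen 2x2 = K4
  expect_equal(icar_quadform(c(1, -1, 1, -1), k4), 16)
  expect_error(icar_quadform(c(1, 2), k4), "per area")
  # log density normalisation uses n - c
  expect_equal(icar_logdens(c(0, 1, -1), path3, tau = 2),
               (3 - 1) / 2 * log(2) - 1 * 5)
})

test_that("the ICAR full conditional is centred at the neighbour average", {
  # path A-B-C-D: quadform as a function of v_B, others fixed, is
  # minimised at the mean of B's neighbours
  g <- adjacency_graph(LETTERS[1:4],
                       rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  v <- c(0.3, 0, -0.8, 1.1)
  qf_of_b <- function(b) icar_quadform(replace(v, 2, b), g)
  opt <- optimize(qf_of_b, c(-5, 5), tol = 1e-10)
  expect_equal(opt$minimum, mean(v[c(1, 3)]), tolerance = 1e-6)
  # and the curvature equals tau * degree (coefficient of the square)
  expect_equal(qf_of_b(2) + qf_of_b(0) - 2 * qf_of_b(1), 2 * 2,
               tolerance = 1e-9)
})

test_that("chains are bitwise reproducible under a fixed seed", {
  sim <- desk_sim(seed = 41, T = 13, nrow_lat = 3, ncol_lat = 3)
  cfg <- fast_config(seed = 5, total = 800, burn = 200)
  f1 <- mcmc_fit(model_spec("IV"), sim$panel, sim$climate, sim$graph, cfg)
  f2 <- mcmc_fit(model_spec("IV"), sim$panel, sim$climate, sim$graph, cfg)
  expect_identical(f1$chains$beta, f2$chains$beta)
  expect_identical(f1$chains$omega, f2$chains$omega)
  expect_identical(f1$chains$delta, f2$chains$delta)
})

test_that("model structure switches follow the four nested specifications", {
  expect_false(model_spec("I")$use_v)
  expect_true(model_spec("I")$use_u)
  expect_true(model_spec("II")$use_v)
  expect_false(model_spec("II")$use_u)
  expect_true(all(unlist(model_spec("III")[c("use_u", "use_v")])))
  expect_false(model_spec("III")$use_delta)
  expect_true(model_spec("IV")$use_delta)
})

test_that("ICAR chains respect the sum-to-zero constraint every draw", {
  sim <- desk_sim(seed = 43, T = 13, nrow_lat = 3, ncol_lat = 3)
  fit <- mcmc_fit(model_spec("IV"), sim$panel, sim$climate, sim$graph,
                  fast_config(seed = 6, total = 700, burn = 200))
  expect_lt(max(abs(rowSums(fit$chains$v))), 1e-8)
  expect_lt(max(abs(rowSums(fit$chains$delta))), 1e-8)
})

test_that("model I recovers the inflation probability on 3000+ rows", {
  sim <- desk_sim(seed = 47, omega = 0.25)
  fit <- mcmc_fit(model_spec("I"), sim$panel, sim$climate, sim$graph,
                  fast_config(seed = 7, total = 4000, burn = 1000))
  expect_gte(length(fit$data$y), 3000)
  expect_lt(abs(fit$omega_summary$mean - 0.25), 0.03)
})

test_that("with no zero inflation the posterior matches the Poisson MLE", {
  g <- make_lattice_adjacency(4, 4)
  tr <- ground_truth(g, seed = 53, omega = 0, tau_u = 400, tau_v = 400,
                     tau_delta = 400)
  tr$u[] <- 0; tr$v[] <- 0; tr$delta[] <- 0
  sim <- simulate_dataset(g, 24, tr, seed = 53, base_rate = 0.05)
  expect_equal(sum(sim$panel$cases == 0), 0)
  fit <- mcmc_fit(model_spec("I"), sim$panel, sim$climate, g,
                  fast_config(seed = 8, total = 6000, burn = 2000),
                  fix_omega = 0)
  mf <- build_model_frame(sim$panel, sim$climate, g)
  mle <- fit_poisson_glm(mf$X, mf$y, mf$offset)
  B <- fit$chains$beta
  for (term in c("age", "sex", "tmax", "rainfall", "rh")) {
    expect_lt(abs(mean(B[, term]) - mle$coefficients[[term]]),
              2 * sd(B[, term]) + 2 * mle$se[[term]])
  }
})

test_that("credible intervals bracket their posterior means", {
  sim <- desk_sim(seed = 59, T = 13, nrow_lat = 3, ncol_lat = 3)
  fit <- mcmc_fit(model_spec("III"), sim$panel, sim$climate, sim$graph,
                  fast_config(seed = 9, total = 900, burn = 300))
  rr <- fit$rr_summary
  expect_true(all(rr$lower <= rr$estimate & rr$estimate <= rr$upper))
  expect_true(fit$omega_summary$lower <= fit$omega_summary$mean)
  expect_true(all(is.finite(unlist(fit$diagnostics$geweke))))
})

test_that("DIC composes Dbar and pD as defined", {
  # a point-mass posterior has pD = 0 and DIC = D(theta-hat)
  d0 <- dic_from_deviances(rep(42.5, 100), 42.5)
  expect_equal(d0$pD, 0)
  expect_equal(d0$DIC, 42.5)
  expect_error(dic_from_deviances(numeric(0), 1), "empty")

  # conjugate normal-means toy: k free means sampled exactly from their
  # posterior give pD ~ k
  set.seed(67)
  k <- 5; sigma <- 1; tau0 <- 100   # prior variance
  y <- rnorm(k, 2, 1)
  post_var <- 1 / (1 / sigma^2 + 1 / tau0)
  post_mean <- post_var * y / sigma^2
  draws <- matrix(rnorm(10000 * k, rep(post_mean, each = 10000),
                        sqrt(post_var)), ncol = k)
  dev <- vapply(seq_len(10000),
                function(i) sum((y - draws[i, ])^2) / sigma^2, numeric(1))
  dhat <- sum((y - colMeans(draws))^2) / sigma^2
  dic <- dic_from_deviances(dev, dhat)
  expect_lt(abs(dic$pD - k * post_var / sigma^2), 0.5)
})

test_that("exceedance and trend classification read the draws correctly", {
  fake <- structure(list(
    area_ids = c("a", "b", "c"),
    chains = list(beta = matrix(0, 100, 1),
                  u = matrix(rnorm(300, c(2, 0, -2), 0.1), 100, 3,
                             byrow = TRUE),
                  v = NULL,
                  delta = matrix(c(abs(rnorm(100)), rnorm(100),
                                   -abs(rnorm(100))), 100, 3))),
    class = "posterior_result")
  out <- exceedance_and_trend(fake, threshold = 0.95)
  expect_equal(out$trend_class, c("above", "uncertain", "below"))
  expect_equal(out$p_exceed, c(1, 0.5, 0), tolerance = 0.2)
  expect_error(exceedance_and_trend(fake, threshold = 0.4), "threshold")
  expect_error(exceedance_and_trend(fake, threshold = 1), "threshold")
})

test_that("strong simulated trend deviations are classified from one fit", {
  g <- make_lattice_adjacency(5, 5)
  tr <- ground_truth(g, seed = 71, omega = 0.15)
  strong_up <- names(which(tr$delta > 0.6))
  strong_dn <- names(which(tr$delta < -0.6))
  skip_if(length(strong_up) == 0 || length(strong_dn) == 0,
          "realised truth has no strong trend areas")
  sim <- simulate_dataset(g, 24, tr, seed = 71)
  fit <- mcmc_fit(model_spec("IV"), sim$panel, sim$climate, g,
                  fast_config(seed = 10, total = 6000, burn = 2000))
  cls <- exceedance_and_trend(fit, threshold = 0.8)
  expect_true(all(cls$trend_class[cls$area_id %in% strong_up] == "above"))
  expect_true(all(cls$trend_class[cls$area_id %in% strong_dn] == "below"))
})

test_that("degenerate inputs fail loudly", {
  sim <- desk_sim(seed = 73, T = 13, nrow_lat = 2, ncol_lat = 2, omega = 1)
  expect_error(
    mcmc_fit(model_spec("I"), sim$panel, sim$climate, sim$graph,
             fast_config()),
    "all counts are zero")
})
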