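test_that("queen lattice degrees match hand enumeration", {
  g22 <- make_lattice_adjacency(2, 2)   # all four cells mutually adjacent
  expect_true(all(g22$degree == 3))
  g33 <- make_lattice_adjacency(3, 3)
  expect_equal(sort(unique(unname(g33$degree))), c(3L, 5L, 8L))
  expect_equal(sum(g33$degree == 3), 4)  # corners
  expect_equal(sum(g33$degree == 5), 4)  # edge midpoints
  expect_equal(sum(g33$degree == 8), 1)  # centre
  g15 <- make_lattice_adjacency(1, 5)    # degenerate row = path graph
  expect_equal(unname(g15$degree), c(1L, 2L, 2L, 2L, 1L))
  expect_error(make_lattice_adjacency(0, 3), "positive")
})

test_that("simulated climate is deterministic, in range, and seasonal", {
  g <- make_lattice_adjacency(3, 3)
  c1 <- simulate_climate(g, 24, seed = 11)
  c2 <- simulate_climate(g, 24, seed = 11)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(all(c1$rh_pct >= 0 & c1$rh_pct <= 100))
  expect_true(all(c1$rainfall_mm >= 0))
  expect_true(all(c1$tmax_c >= 11 & c1$tmax_c <= 34))
  expect_true(all(c1$altitude_m >= 300 & c1$altitude_m <= 4600))
  # static altitude
  expect_equal(nrow(unique(as.data.frame(c1)[, c("area_id", "altitude_m")])), 9)
  expect_error(simulate_climate(g, 12, seed = 1), "13")
  # rainfall peaks mid-year on average
  mm <- tapply(c1$rainfall_mm, c1$month, mean)
  expect_gt(mean(mm[c("6", "7", "8")]), mean(mm[c("12", "1", "2")]))
})

test_that("rainfall Monte-Carlo mean matches its configured annual mean", {
  g <- make_lattice_adjacency(15, 15)
  cl <- simulate_climate(g, 48, seed = 21)   # 225 x 48 = 10,800 values
  x <- cl$rainfall_mm
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 5.2), 3 * se)
})

test_that("ICAR draws live on the sum-to-zero subspace with the right scale", {
  g <- make_lattice_adjacency(3, 3)
  v <- sample_icar(g, tau = 2, seed = 5)
  expect_lt(abs(sum(v)), 1e-10)
  expect_error(sample_icar(g, tau = 0), "positive")

  # K2 closed form: draws are (z, -z); the density restricted to that
  # line is exp(-tau/2 * (2z)^2), i.e. z ~ Normal(0, 1/(4 tau))
  k2 <- adjacency_graph(c("A", "B"), cbind("A", "B"))
  set.seed(31)
  draws <- t(replicate(5000, sample_icar(k2, tau = 3)))
  expect_true(all(abs(draws[, 1] + draws[, 2]) < 1e-10))
  z <- draws[, 1]
  expect_lt(abs(var(z) - 1 / (4 * 3)), 4 * sqrt(2 / 5000) * 1 / (4 * 3))

  # quadrupling tau scales the variance by 1/4
  set.seed(32)
  z4 <- t(replicate(5000, sample_icar(k2, tau = 12)))[, 1]
  expect_lt(abs(var(z4) / var(z) - 0.25), 0.04)
})

test_that("degenerate mixtures behave: omega = 1 silences every count", {
  g <- make_lattice_adjacency(2, 2)
  tr <- ground_truth(g, seed = 2, omega = 1)
  sim <- simulate_dataset(g, 13, tr, seed = 2)
  expect_true(all(sim$panel$cases == 0))
})

test_that("with no effects and omega 0 counts are Poisson(E)", {
  g <- make_lattice_adjacency(15, 15)
  tr <- ground_truth(g, seed = 7, alpha = 0,
                     beta = c(age = 0, sex = 0, trend = 0, altitude = 0,
                              tmax = 0, rainfall = 0, rh = 0),
                     omega = 0)
  tr$u[] <- 0; tr$v[] <- 0; tr$delta[] <- 0
  sim <- simulate_dataset(g, 56, tr, seed = 7)  # 225 x 56 x 4 = 50,400 rows
  r <- sim$panel$cases / sim$panel$expected_cases
  expect_gt(nrow(sim$panel), 50000)
  expect_lt(abs(mean(r) - 1), 3 * sd(r) / sqrt(length(r)))
})

test_that("structural zeros appear at rate omega when Poisson zeros are negligible", {
  g <- make_lattice_adjacency(6, 6)
  tr <- ground_truth(g, seed = 9, omega = 0.2)
  sim <- simulate_dataset(g, 24, tr, seed = 9, base_rate = 0.1)  # large mu
  expect_true(all(sim$panel$expected_cases * 0.5 > 5))
  zf <- zero_fraction(sim$panel)
  se <- sqrt(0.2 * 0.8 / zf$n_total)
  expect_lt(abs(zf$percent / 100 - 0.2), 3 * se)
})

test_that("observed zero fraction is at least the structural rate up to binomial error", {
  for (s in 1:3) {
    sim <- desk_sim(seed = 100 + s, omega = 0.3)
    zf <- zero_fraction(sim$panel)
    se <- sqrt(0.3 * 0.7 / zf$n_total)
    expect_gt(zf$percent / 100, 0.3 - 3 * se)
  }
})

test_that("an exploding linear predictor is rejected with advice", {
  g <- make_lattice_adjacency(2, 2)
  tr <- ground_truth(g, seed = 3, alpha = 60)
  expect_error(simulate_dataset(g, 13, tr, seed = 3), "rescale")
})

test_that("simulated datasets round-trip through the on-disk formats", {
  sim <- desk_sim(seed = 13, T = 13, nrow_lat = 2, ncol_lat = 2)
  d <- withr::local_tempdir()
  write_dataset(sim[c("panel", "climate", "truth")], sim$graph, d)
  expect_true(all(file.exists(file.path(d,
    c("surveillance.csv", "climate.csv", "altitude.csv", "adjacency.txt",
      "truth.yaml")))))
  back <- read_surveillance(file.path(d, "surveillance.csv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$panel),
               tolerance = 1e-12)
  tr <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(tr$omega, sim$truth$omega)
  expect_equal(unlist(tr$beta), sim$truth$beta, tolerance = 1e-12)
})
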