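#' Queen-contiguity lattice adjacency
#'
#' Builds the adjacency graph of an `n_rows` x `n_cols` grid under queen
#' contiguity: two cells are neighbours when they differ by at most one in
#' both the row and column index (8-neighbour rule). Stands in for
#' sub-district polygons when exercising the spatial models on synthetic
#' data.
#'
#' @param n_rows,n_cols positive integers
#' @return an [adjacency_graph()] with area ids `gXX`
#' @export
make_lattice_adjacency <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("lattice dimensions must be positive integers")
  n <- n_rows * n_cols
  ids <- sprintf("g%03d", seq_len(n))
  cell <- function(r, c) (r - 1L) * n_cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= n_rows && c2 >= 1 && c2 <= n_cols) {
        i <- cell(r, c); j <- cell(r2, c2)
        if (i < j) { from <- c(from, i); to <- c(to, j) }
      }
    }
  }
  adjacency_graph(ids, cbind(ids[from], ids[to]))
}

#' Simulate seasonal monsoon-type climate
#'
#' Generates a complete area-by-month climate panel with a 12-month cycle:
#' gamma-distributed rainfall whose seasonal mean peaks mid-year, sinusoidal
#' maximum temperature attenuated by altitude, sinusoidal relative humidity,
#' and a static altitude per area drawn uniformly on 300-4600 m. The
#' marginal moments are tuned to a high-altitude monsoon regime (area-month
#' rainfall mean near 5.2 mm, maximum temperature within 11-34 degrees C,
#' humidity within 0-100%).
#'
#' @param graph an [adjacency_graph()] naming the areas
#' @param T number of months (>= 13 so that lag-3 lookups and a full
#'   seasonal cycle are exercisable)
#' @param seed integer seed; all draws use R's Mersenne-Twister stream
#' @param rain_mean annual mean of the rainfall distribution (mm)
#' @return a [climate_panel()]
#' @export
simulate_climate <- function(graph, T, seed = NULL, rain_mean = 5.2) {
  if (T < 13) stop("T must be at least 13 months")
  if (!is.null(seed)) set.seed(seed)
  areas <- graph$area_ids
  n <- length(areas)
  altitude <- data.frame(area_id = areas,
                         altitude_m = runif(n, 300, 4600))
  grid <- expand.grid(area_id = areas, month_index = seq_len(T),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$area_id, grid$month_index), , drop = FALSE]
  cal_month <- ((grid$month_index - 1L) %% 12L) + 1L
  cyc <- cos(2 * pi * (cal_month - 7) / 12)  # peaks in July (monsoon)
  alt <- altitude$altitude_m[match(grid$area_id, altitude$area_id)]

  # rainfall: gamma with seasonally varying mean, annual average = rain_mean
  m_t <- rain_mean * (1 + 0.85 * cyc)
  shape <- 0.45
  rain <- rgamma(nrow(grid), shape = shape, scale = m_t / shape)

  tmax <- 30 - 0.0035 * alt + 5.5 * cyc + rnorm(nrow(grid), 0, 1.0)
  tmax <- pmin(pmax(tmax, 11), 34)
  rh <- 68 + 16 * cos(2 * pi * (cal_month - 8) / 12) + rnorm(nrow(grid), 0, 6)
  rh <- pmin(pmax(rh, 0), 100)

  years <- 2000L + (grid$month_index - 1L) %/% 12L
  climate_panel(
    data.frame(area_id = grid$area_id, year = years, month = cal_month,
               rainfall_mm = rain, tmax_c = tmax, rh_pct = rh),
    altitude)
}

#' Draw from an intrinsic CAR (ICAR) distribution
#'
#' Samples the improper Gaussian prior with density proportional to
#' `exp(-tau/2 * sum_{i~j} (v_i - v_j)^2)`, restricted to the proper
#' subspace: eigendecompose the graph Laplacian `Q = D - W`, draw
#' independent normals with variance `1/(tau * lambda_k)` on the
#' eigenvectors with positive eigenvalue, and set the null-space
#' coefficients (one per connected component) to zero. The draw therefore
#' sums to zero within each connected component.
#'
#' @param graph an [adjacency_graph()]
#' @param tau positive precision
#' @param seed optional integer seed
#' @return numeric vector of per-area effects, named by area id
#' @export
sample_icar <- function(graph, tau, seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(graph$area_ids)
  Q <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges[k, 1], graph$area_ids)
    j <- match(graph$edges[k, 2], graph$area_ids)
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
  }
  diag(Q) <- graph$degree
  eig <- eigen(Q, symmetric = TRUE)
  pos <- eig$values > 1e-9 * max(eig$values, 1)
  z <- rep(0, n)
  z[pos] <- rnorm(sum(pos), 0, 1 / sqrt(tau * eig$values[pos]))
  v <- as.vector(eig$vectors %*% z)
  # exact recentring per component kills numerical drift in the null space
  for (cc in seq_len(graph$n_components)) {
    idx <- graph$component == cc
    v[idx] <- v[idx] - mean(v[idx])
  }
  setNames(v, graph$area_ids)
}

#' Ground truth for the synthetic generative model
#'
#' Bundles every parameter of the data-generating process: intercept,
#' fixed-effect coefficients (age, sex, scaled trend, altitude per 100 m,
#' maximum temperature per degree C, rainfall per 10 mm lagged 1 month,
#' relative humidity % lagged 3 months), structural-zero probability
#' `omega`, random-effect precisions, and the realised per-area effects
#' `u` (iid), `v` (ICAR) and `delta` (ICAR trend deviations).
#'
#' Defaults mirror the relative risks typical of respiratory-infection
#' surveillance: children at roughly 2.3-fold risk, males slightly below
#' females, small positive rainfall/temperature effects, weak negative
#' altitude and humidity effects, about 20% structural zeros, moderate
#' unstructured and spatial heterogeneity and a pronounced area-specific
#' trend component.
#'
#' @param graph an [adjacency_graph()]
#' @param seed integer seed used to realise `u`, `v`, `delta`
#' @param alpha intercept (log relative risk at reference levels)
#' @param beta named numeric vector of the seven fixed effects
#' @param omega structural-zero probability in `[0, 1)`
#' @param tau_u,tau_v,tau_delta positive precisions
#' @return a `ground_truth` list
#' @export
ground_truth <- function(graph, seed = 1L,
                         alpha = 0,
                         beta = c(age = log(2.34), sex = log(0.876),
                                  trend = log(1.086), altitude = log(0.999),
                                  tmax = log(1.026), rainfall = log(1.051),
                                  rh = log(0.997)),
                         omega = 0.2, tau_u = 10, tau_v = 4, tau_delta = 1) {
  # omega = 1 (every row a structural zero) is allowed for degenerate
  # simulations; the fitting side requires omega < 1
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (any(c(tau_u, tau_v, tau_delta) <= 0)) stop("precisions must be positive")
  need <- c("age", "sex", "trend", "altitude", "tmax", "rainfall", "rh")
  if (!setequal(names(beta), need))
    stop("beta must be named: ", paste(need, collapse = ", "))
  beta <- beta[need]
  set.seed(seed)
  n <- length(graph$area_ids)
  u <- setNames(rnorm(n, 0, 1 / sqrt(tau_u)), graph$area_ids)
  v <- sample_icar(graph, tau_v)
  delta <- sample_icar(graph, tau_delta)
  structure(list(alpha = alpha, beta = beta, omega = omega,
                 tau_u = tau_u, tau_v = tau_v, tau_delta = tau_delta,
                 u = u, v = v, delta = delta, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Scaled month-index trend covariate
#'
#' The linear trend enters the model as the month index centred at the
#' series midpoint and scaled by `1/T`, so it spans roughly (-1/2, 1/2)
#' regardless of series length; this keeps the linear predictor bounded
#' and makes the trend coefficient comparable across study lengths.
#'
#' @param month_index integer vector
#' @param T total number of months
#' @export
scaled_trend <- function(month_index, T) (month_index - (T + 1) / 2) / T

#' Simulate a complete surveillance dataset with known truth
#'
#' Generates climate, per-area random effects and ZIP counts from the
#' hierarchical model the package fits: for each (area, month, age, sex)
#' row the log relative risk is
#' `theta = alpha + beta.x + u_i + v_i + delta_i * t_j`, the Poisson mean
#' is `E * exp(theta)` with `E` = stratum population x baseline rate, and
#' with probability `omega` the row is replaced by a structural zero.
#' The spatio-temporal term is a Bernardinelli-type interaction: an ICAR
#' set of per-area trend deviations `delta_i` multiplying the scaled month
#' index `t_j`.
#'
#' Climate is simulated with a 3-month warm-up so that rainfall lagged one
#' month and humidity lagged three months exist for every panel month; the
#' returned climate panel starts at panel month 1, so lagged lookups for
#' the first `lag` months are reported missing, exactly as with real data.
#'
#' @param graph an [adjacency_graph()]
#' @param T number of panel months (>= 13)
#' @param truth a [ground_truth()] for this graph
#' @param base_population mean stratum population; per-area sizes are
#'   jittered uniformly on (0.5, 1.5) times this
#' @param base_rate baseline cases per person-month at reference levels
#' @param seed integer seed for counts, climate and populations
#' @return list with `panel` ([surveillance_panel()]), `climate`
#'   ([climate_panel()]) and `truth`
#' @export
simulate_dataset <- function(graph, T, truth, base_population = 800,
                             base_rate = 0.01, seed = 1L) {
  if (!inherits(truth, "ground_truth")) stop("truth must be a ground_truth")
  if (length(truth$u) != length(graph$area_ids))
    stop("truth was built for a different number of areas")
  set.seed(seed)
  warm <- 3L
  climate_ext <- simulate_climate(graph, T + warm, seed = NULL)
  areas <- graph$area_ids
  n_areas <- length(areas)

  pop_area <- setNames(base_population * runif(n_areas, 0.5, 1.5), areas)

  grid <- expand.grid(area_id = areas, month_index = seq_len(T),
                      age_group = AGE_LEVELS, sex = SEX_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$area_id, grid$month_index,
                     grid$age_group, grid$sex), , drop = FALSE]

  # lagged climate from the extended series: panel month j = extended month j + warm
  cx <- as.data.frame(climate_ext)
  kx <- paste(cx$area_id, cx$month_index)
  look <- function(var, lag) {
    cx[[var]][match(paste(grid$area_id, grid$month_index + warm - lag), kx)]
  }
  tmax <- look("tmax_c", 0L)
  rain1 <- look("rainfall_mm", 1L)
  rh3 <- look("rh_pct", 3L)
  alt <- cx$altitude_m[match(grid$area_id, cx$area_id)]

  x_age <- as.numeric(grid$age_group == "under15")
  x_sex <- as.numeric(grid$sex == "male")
  tj <- scaled_trend(grid$month_index, T)
  b <- truth$beta
  theta <- truth$alpha + b[["age"]] * x_age + b[["sex"]] * x_sex +
    b[["trend"]] * tj + b[["altitude"]] * alt / 100 + b[["tmax"]] * tmax +
    b[["rainfall"]] * rain1 / 10 + b[["rh"]] * rh3 +
    truth$u[grid$area_id] + truth$v[grid$area_id] +
    truth$delta[grid$area_id] * tj
  if (any(theta > 50))
    stop("linear predictor exceeds 50; rescale the ground-truth parameters")

  pop <- pop_area[grid$area_id]
  E <- pop * base_rate
  mu <- E * exp(theta)
  nr <- nrow(grid)
  structural <- runif(nr) < truth$omega
  cases <- ifelse(structural, 0L, rpois(nr, mu))

  years <- 2000L + (grid$month_index - 1L) %/% 12L
  cal_month <- ((grid$month_index - 1L) %% 12L) + 1L
  panel <- surveillance_panel(data.frame(
    area_id = grid$area_id, year = years, month = cal_month,
    age_group = grid$age_group, sex = grid$sex,
    cases = as.integer(cases), population = as.numeric(pop),
    expected_cases = as.numeric(E)))

  climate <- climate_panel(
    data.frame(area_id = cx$area_id[cx$month_index > warm],
               year = 2000L + (cx$month_index[cx$month_index > warm] - warm - 1L) %/% 12L,
               month = ((cx$month_index[cx$month_index > warm] - warm - 1L) %% 12L) + 1L,
               rainfall_mm = cx$rainfall_mm[cx$month_index > warm],
               tmax_c = cx$tmax_c[cx$month_index > warm],
               rh_pct = cx$rh_pct[cx$month_index > warm]),
    unique(cx[, c("area_id", "altitude_m")]))

  list(panel = panel, climate = climate, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `surveillance.csv`, `climate.csv`, `altitude.csv`,
#' `adjacency.txt` and `truth.yaml` into `dir`.
#'
#' @param sim result of [simulate_dataset()]
#' @param graph the adjacency graph used
#' @param dir output directory (created if needed)
#' @export
write_dataset <- function(sim, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surveillance(sim$panel, file.path(dir, "surveillance.csv"))
  write_climate(sim$climate, dir)
  write_adjacency(graph, file.path(dir, "adjacency.txt"))
  tr <- sim$truth
  yaml::write_yaml(list(alpha = tr$alpha, beta = as.list(tr$beta),
                        omega = tr$omega, tau_u = tr$tau_u, tau_v = tr$tau_v,
                        tau_delta = tr$tau_delta, u = as.list(tr$u),
                        v = as.list(tr$v), delta = as.list(tr$delta),
                        seed = tr$seed),
                   file.path(dir, "truth.yaml"), precision = 15)
  invisible(dir)
}
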