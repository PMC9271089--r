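#' Zero-inflated Poisson log probability
#'
#' The standard ZIP pmf: a structural zero with probability `omega`,
#' otherwise Poisson with mean `mu`, so
#' `P(Y = 0) = omega + (1 - omega) exp(-mu)` and
#' `P(Y = y) = (1 - omega) exp(-mu) mu^y / y!` for positive y.
#'
#' @param y non-negative integer count(s)
#' @param mu positive Poisson mean(s)
#' @param omega structural-zero probability in `[0, 1)`
#' @return vector of log probabilities
#' @export
zip_loglik <- function(y, mu, omega) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (length(omega) != 1 || omega < 0 || omega >= 1)
    stop("omega must be a scalar in [0, 1)")
  if (any(y < 0 | y != round(y))) stop("y must be non-negative integers")
  out <- numeric(length(y))
  z <- y == 0
  mu <- rep_len(mu, length(y))
  out[z] <- log(omega + exp(log1p(-omega) - mu[z]))
  out[!z] <- log1p(-omega) - mu[!z] + y[!z] * log(mu[!z]) - lgamma(y[!z] + 1)
  out
}

#' ICAR pairwise quadratic form
#'
#' `sum over adjacent pairs {i,j} of (v_i - v_j)^2`, the kernel of the
#' intrinsic CAR log density
#' `(n - c)/2 log(tau) - tau/2 * quadform` where `c` is the number of
#' connected components of the graph.
#'
#' @param v per-area numeric vector, ordered as `graph$area_ids`
#' @param graph an [adjacency_graph()]
#' @return scalar quadratic form
#' @export
icar_quadform <- function(v, graph) {
  if (length(v) != length(graph$area_ids))
    stop("v must have one entry per area")
  if (nrow(graph$edges) == 0L) return(0)
  i <- match(graph$edges[, 1], graph$area_ids)
  j <- match(graph$edges[, 2], graph$area_ids)
  sum((v[i] - v[j])^2)
}

#' @rdname icar_quadform
#' @param tau positive precision
#' @export
icar_logdens <- function(v, graph, tau) {
  if (tau <= 0) stop("tau must be positive")
  n <- length(graph$area_ids)
  (n - graph$n_components) / 2 * log(tau) - tau / 2 * icar_quadform(v, graph)
}

#' Specification of the four nested spatial ZIP models
#'
#' All four share the fixed effects (age, sex, scaled trend, altitude per
#' 100 m, maximum temperature per degree C, rainfall per 10 mm lagged one
#' month, relative humidity % lagged three months) and differ in the
#' random-effect structure: model I has unstructured iid area effects
#' only; model II has ICAR spatial effects only; model III is the BYM
#' convolution (both); model IV adds ICAR per-area linear-trend deviations
#' (a Bernardinelli-type spatio-temporal interaction).
#'
#' Priors: flat on the intercept, Normal(0, precision 1e-4) on the
#' coefficients, Gamma(0.001, 0.001) on every random-effect precision,
#' Uniform(0, 1) on the structural-zero probability.
#'
#' @param model_id `"I"`, `"II"`, `"III"` or `"IV"`
#' @return a `model_spec` list with random-effect switches
#' @export
model_spec <- function(model_id = c("IV", "I", "II", "III")) {
  model_id <- match.arg(model_id)
  structure(list(model_id = model_id,
                 use_u = model_id %in% c("I", "III", "IV"),
                 use_v = model_id %in% c("II", "III", "IV"),
                 use_delta = model_id == "IV",
                 beta_precision = 1e-4,
                 gamma_shape = 0.001, gamma_rate = 0.001),
            class = "model_spec")
}

#' Assemble the spatial model frame
#'
#' Builds the response, log-expected-count offset, fixed-effect design
#' (intercept, age, sex, scaled trend, altitude per 100 m, maximum
#' temperature, rainfall per 10 mm lagged, relative humidity % lagged),
#' area index and scaled-trend vector shared by the Bayesian models and
#' the frequentist ZIP/Poisson comparisons. Rows whose lagged covariates
#' have no antecedent observation (the first `max(lag)` months) are
#' dropped, never zero-filled.
#'
#' @param panel a [surveillance_panel()]
#' @param climate a [climate_panel()]
#' @param graph an [adjacency_graph()]
#' @param rain_lag,rh_lag months of lag for rainfall and humidity
#' @return list with `y`, `offset`, `X`, `area_index`, `tvec`,
#'   `month_index`, `n_dropped`, `T`
#' @export
build_model_frame <- function(panel, climate, graph,
                              rain_lag = 1L, rh_lag = 3L) {
  if (!"expected_cases" %in% names(panel)) panel <- expected_cases(panel)
  if (!setequal(attr(panel, "areas"), graph$area_ids))
    stop("panel areas do not match the adjacency graph")
  T <- attr(panel, "n_months")
  df <- as.data.frame(panel)
  key <- paste(df$area_id, df$month_index)
  ckey <- paste(climate$area_id, climate$month_index)
  tmax <- climate$tmax_c[match(key, ckey)]
  alt <- climate$altitude_m[match(key, ckey)]
  r1 <- lagged_covariate(climate, "rainfall_mm", rain_lag)
  rain <- r1$value[match(key, paste(r1$area_id, r1$month_index))]
  h3 <- lagged_covariate(climate, "rh_pct", rh_lag)
  rh <- h3$value[match(key, paste(h3$area_id, h3$month_index))]
  keep <- !is.na(rain) & !is.na(rh) & !is.na(tmax)
  df <- df[keep, , drop = FALSE]
  tj <- scaled_trend(df$month_index, T)
  X <- cbind(intercept = 1,
             age = as.numeric(df$age_group == "under15"),
             sex = as.numeric(df$sex == "male"),
             trend = tj,
             altitude = alt[keep] / 100,
             tmax = tmax[keep],
             rainfall = rain[keep] / 10,
             rh = rh[keep])
  list(y = as.integer(df$cases), offset = log(df$expected_cases),
       X = X, area_index = match(df$area_id, graph$area_ids),
       tvec = tj, n_dropped = sum(!keep), month_index = df$month_index,
       T = T)
}

#' Fit a Bayesian spatial ZIP model by Metropolis-within-Gibbs MCMC
#'
#' Runs the sampler described in [model_spec()]: exact Bernoulli updates
#' of the latent structural-zero indicators, a conjugate Beta update of
#' the inflation probability, adaptive random-walk Metropolis for the
#' fixed effects, single-site Metropolis for the area effects against
#' their iid / ICAR full-conditional priors, conjugate Gamma updates of
#' the precisions, and sum-to-zero recentring of the ICAR vectors with the
#' shift absorbed by the intercept (spatial effects) or the trend
#' coefficient (trend deviations). Chains are retained after burn-in with
#' thinning and are bitwise reproducible for a fixed `config$mcmc$seed`.
#'
#' @param spec a [model_spec()]
#' @param panel a [surveillance_panel()] (expected counts computed if
#'   absent)
#' @param climate a [climate_panel()]
#' @param graph an [adjacency_graph()] over the panel areas
#' @param config a [run_config()]
#' @param fix_omega optional value at which to pin the structural-zero
#'   probability (mainly for Poisson-reduction checks)
#' @return a `posterior_result` with `chains` (matrices of draws),
#'   summaries, `dic`, and `diagnostics`
#' @export
mcmc_fit <- function(spec, panel, climate, graph, config = run_config(),
                     fix_omega = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  mf <- build_model_frame(panel, climate, graph)
  if (all(mf$y == 0)) stop("all counts are zero; the model is degenerate")
  if (any(graph$degree == 0) && (spec$use_v || spec$use_delta))
    warning("graph has islands; their ICAR effects are pinned at 0")
  m <- config$mcmc
  set.seed(m$seed)
  res <- zip_mcmc_cpp(
    y = mf$y, off = mf$offset, X = mf$X,
    area = mf$area_index - 1L, tvec = mf$tvec,
    edge_from = match(graph$edges[, 1], graph$area_ids) - 1L,
    edge_to = match(graph$edges[, 2], graph$area_ids) - 1L,
    nb_list = lapply(graph$neighbours, function(v) as.integer(v - 1L)),
    deg = as.integer(graph$degree),
    n_areas = length(graph$area_ids), n_comp = graph$n_components,
    use_u = spec$use_u, use_v = spec$use_v, use_d = spec$use_delta,
    trend_col = which(colnames(mf$X) == "trend") - 1L,
    iters = as.integer(m$total_iterations), burn = as.integer(m$burn_in),
    thin = as.integer(m$thin),
    beta_prec = spec$beta_precision,
    gam_shape = spec$gamma_shape, gam_rate = spec$gamma_rate,
    omega_init = if (is.null(fix_omega)) 0.1 else fix_omega,
    fix_omega = !is.null(fix_omega))

  colnames(res$beta) <- colnames(mf$X)
  nm <- graph$area_ids
  if (spec$use_u) colnames(res$u) <- nm
  if (spec$use_v) colnames(res$v) <- nm
  if (spec$use_delta) colnames(res$delta) <- nm

  out <- structure(list(
    spec = spec, config = config,
    chains = list(beta = res$beta,
                  u = if (spec$use_u) res$u else NULL,
                  v = if (spec$use_v) res$v else NULL,
                  delta = if (spec$use_delta) res$delta else NULL,
                  omega = res$omega,
                  tau_u = if (spec$use_u) res$tau_u else NULL,
                  tau_v = if (spec$use_v) res$tau_v else NULL,
                  tau_delta = if (spec$use_delta) res$tau_delta else NULL,
                  deviance = res$deviance),
    data = mf, area_ids = nm,
    diagnostics = list(acceptance_beta = res$acc_rate_beta,
                       acceptance_sites = res$acc_rate_site)),
    class = "posterior_result")
  if (!is.na(res$acc_rate_beta) && res$acc_rate_beta < 0.01)
    warning("fixed-effect acceptance rate below 1% after adaptation")

  out$rr_summary <- summarize_rr(out, config$cri_level)
  out$omega_summary <- chain_summary(res$omega, config$cri_level)
  out$precision_summaries <- do.call(rbind, lapply(
    c(u = "tau_u", v = "tau_v", delta = "tau_delta"),
    function(nmv) if (!is.null(out$chains[[nmv]]))
      chain_summary(out$chains[[nmv]], config$cri_level)))
  out$dic <- compute_dic(out)
  out$diagnostics$geweke <- geweke_diagnostics(out)
  out
}

chain_summary <- function(draws, cri_level = 0.95) {
  a <- (1 - cri_level) / 2
  data.frame(mean = mean(draws), sd = sd(draws),
             lower = quantile(draws, a, names = FALSE),
             upper = quantile(draws, 1 - a, names = FALSE))
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("<posterior_result> model %s, %d retained draws\n",
              x$spec$model_id, nrow(x$chains$beta)))
  print(x$rr_summary, digits = 4)
  cat(sprintf("omega: %.3f (%.3f, %.3f)   DIC: %.1f (pD %.1f)\n",
              x$omega_summary$mean, x$omega_summary$lower,
              x$omega_summary$upper, x$dic$DIC, x$dic$pD))
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the deviance
#' `D(theta) = -2 sum_r log ZIP(y_r | mu_r, omega)` and
#' `pD = Dbar - D(theta_hat)` the effective number of parameters, the
#' deviance evaluated at the posterior means of all parameters (random
#' effects included). A negative `pD` is reported with a flag rather than
#' suppressed.
#'
#' @param result a `posterior_result`
#' @return list `Dbar`, `pD`, `DIC`, `pD_negative`
#' @export
compute_dic <- function(result) {
  ch <- result$chains
  if (length(ch$deviance) == 0L) stop("empty chain")
  dbar <- mean(ch$deviance)
  mf <- result$data
  beta_hat <- colMeans(ch$beta)
  eta <- mf$offset + drop(mf$X %*% beta_hat)
  if (!is.null(ch$u)) eta <- eta + colMeans(ch$u)[mf$area_index]
  if (!is.null(ch$v)) eta <- eta + colMeans(ch$v)[mf$area_index]
  if (!is.null(ch$delta))
    eta <- eta + colMeans(ch$delta)[mf$area_index] * mf$tvec
  om_hat <- mean(ch$omega)
  om_hat <- min(max(om_hat, 0), 1 - 1e-12)
  dhat <- -2 * sum(zip_loglik(mf$y, exp(eta), om_hat))
  dic_from_deviances(ch$deviance, dhat)
}

#' @rdname compute_dic
#' @param deviance_draws per-draw deviances
#' @param deviance_at_means deviance evaluated at the posterior means
#' @export
dic_from_deviances <- function(deviance_draws, deviance_at_means) {
  if (length(deviance_draws) == 0L) stop("empty chain")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_means
  list(Dbar = dbar, pD = pd, DIC = dbar + pd, pD_negative = pd < 0)
}

#' Posterior relative risks of the fixed effects
#'
#' Exponentiates the coefficient draws and reports the posterior mean and
#' equal-tailed credible interval of each relative risk, together with the
#' percent change `100 (RR - 1)`. The intercept is reported on the
#' coefficient (log) scale, as is conventional for disease-mapping tables.
#'
#' @param result a `posterior_result`
#' @param cri_level credible-interval mass
#' @return data frame `term, estimate, lower, upper, scale, pct_change`
#' @export
summarize_rr <- function(result, cri_level = 0.95) {
  B <- result$chains$beta
  a <- (1 - cri_level) / 2
  rows <- lapply(colnames(B), function(tm) {
    dr <- B[, tm]
    if (tm == "intercept") {
      data.frame(term = tm, estimate = mean(dr),
                 lower = quantile(dr, a, names = FALSE),
                 upper = quantile(dr, 1 - a, names = FALSE),
                 scale = "coefficient", pct_change = NA_real_)
    } else {
      rr <- exp(dr)
      est <- mean(rr)
      data.frame(term = tm, estimate = est,
                 lower = quantile(rr, a, names = FALSE),
                 upper = quantile(rr, 1 - a, names = FALSE),
                 scale = "relative risk", pct_change = pct_change(est))
    }
  })
  do.call(rbind, rows)
}

#' Percent change implied by a relative risk
#'
#' `100 * (RR - 1)`, rounded to one decimal: RR 0.876 is a 12.4%
#' reduction, RR 1.051 a 5.1% increase.
#'
#' @param rr relative risk(s)
#' @export
pct_change <- function(rr) round(100 * (rr - 1), 1)

#' Residual-risk exceedance and per-area trend classification
#'
#' The residual (unexplained) relative risk of area i is
#' `exp(u_i + v_i)`; its exceedance probability is the posterior fraction
#' of draws with `u_i + v_i > 0`. The trend class compares each area's
#' trend deviation to the national average trend: `above` when
#' `P(delta_i > 0)` exceeds the threshold, `below` when `P(delta_i < 0)`
#' does, otherwise `uncertain`.
#'
#' @param result a `posterior_result`
#' @param threshold posterior probability cut-off in (0.5, 1)
#' @return data frame `area_id, u_mean, v_mean, delta_mean,
#'   p_exceed, trend_prob_above, trend_class`
#' @export
exceedance_and_trend <- function(result, threshold = 0.95) {
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  ch <- result$chains
  n_areas <- length(result$area_ids)
  n_draws <- nrow(ch$beta)
  resid <- matrix(0, n_draws, n_areas)
  if (!is.null(ch$u)) resid <- resid + ch$u
  if (!is.null(ch$v)) resid <- resid + ch$v
  p_exceed <- colMeans(resid > 0)
  out <- data.frame(area_id = result$area_ids,
                    u_mean = if (!is.null(ch$u)) colMeans(ch$u) else NA_real_,
                    v_mean = if (!is.null(ch$v)) colMeans(ch$v) else NA_real_,
                    delta_mean = if (!is.null(ch$delta))
                      colMeans(ch$delta) else NA_real_,
                    p_exceed = p_exceed)
  if (!is.null(ch$delta)) {
    p_above <- colMeans(ch$delta > 0)
    out$trend_prob_above <- p_above
    out$trend_class <- ifelse(p_above > threshold, "above",
                        ifelse(1 - p_above > threshold, "below", "uncertain"))
  } else {
    out$trend_prob_above <- NA_real_
    out$trend_class <- NA_character_
  }
  rownames(out) <- NULL
  out
}

# Geweke convergence z-scores (first 10% vs last 50% of the chain, batch
# -mean variance estimates); |z| > 2 hints at non-convergence.
geweke_z <- function(draws) {
  n <- length(draws)
  if (n < 40) return(NA_real_)
  a <- draws[seq_len(floor(0.1 * n))]
  b <- draws[seq(floor(0.5 * n) + 1, n)]
  bm_var <- function(x) {
    nb <- max(2L, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    mns <- vapply(seq_len(nb), function(k)
      mean(x[((k - 1) * bs + 1):(k * bs)]), numeric(1))
    var(mns) / nb
  }
  va <- bm_var(a); vb <- bm_var(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

geweke_diagnostics <- function(result) {
  ch <- result$chains
  z <- c(apply(ch$beta, 2, geweke_z), omega = geweke_z(ch$omega))
  for (nmv in c("tau_u", "tau_v", "tau_delta"))
    if (!is.null(ch[[nmv]])) z[nmv] <- geweke_z(ch[[nmv]])
  z
}
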