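#' Poisson log-linear regression with offset
#'
#' Fits `y ~ Poisson(exp(offset + X beta))` by iteratively reweighted least
#' squares and returns the quantities the covariate-selection pipeline
#' needs: Wald standard errors and p-values, the exact log likelihood
#' (factorial term included), AIC/BIC and the per-row log likelihood used
#' by the Vuong test.
#'
#' @param design numeric matrix including an intercept column if wanted
#' @param counts non-negative integer response
#' @param offset log expected counts (default all zero)
#' @return a `glm_fit` list
#' @export
fit_poisson_glm <- function(design, counts, offset = NULL) {
  design <- as.matrix(design)
  if (nrow(design) != length(counts))
    stop("design has ", nrow(design), " rows but there are ",
         length(counts), " counts")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (is.null(offset)) offset <- rep(0, length(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(!is.finite(offset))) stop("offsets must be finite")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- glm.fit(design, counts, family = poisson(), offset = offset,
                 control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) stop("Poisson IRLS did not converge in 100 iterations")
  beta <- coef(fit)
  eta <- offset + drop(design %*% beta)
  mu <- exp(eta)
  pointwise <- counts * eta - mu - lgamma(counts + 1)
  ll <- sum(pointwise)
  # Wald covariance from the Fisher information X' W X, W = diag(mu)
  info <- crossprod(design * sqrt(mu))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  k <- length(beta)
  structure(list(coefficients = beta, se = se,
                 p_values = 2 * pnorm(-abs(z)),
                 log_likelihood = ll, aic = -2 * ll + 2 * k,
                 bic = -2 * ll + log(length(counts)) * k,
                 pointwise_loglik = pointwise, fitted = mu,
                 n = length(counts), k = k),
            class = "glm_fit")
}

#' Screen lags of a climate covariate with univariate Poisson models
#'
#' For each candidate lag, fits a univariate Poisson regression of the
#' area-month case totals on the lagged covariate with the log expected
#' count as offset. All lags are fitted on the common set of months where
#' every candidate lag has an antecedent observation (the first
#' `max(lags)` months are dropped, never zero-filled), so the per-lag AIC
#' values are computed on identical data and are directly comparable. The
#' chosen lag minimises AIC among lags whose Wald p-value is below
#' `alpha`; ties break to the smaller (most proximal) lag. When no lag
#' reaches significance the variable is excluded.
#'
#' @param panel a [surveillance_panel()] with expected counts (computed if
#'   absent)
#' @param climate a [climate_panel()]
#' @param variable climate column name
#' @param lags integer vector of candidate lags
#' @param alpha Wald significance threshold
#' @param scale divisor applied to the covariate before fitting (10 for
#'   rainfall per 10 mm, 100 for altitude per 100 m)
#' @return list with `chosen_lag` (NA when excluded), `excluded`, `reason`,
#'   and a per-lag data frame `table` (lag, coefficient, p, aic, n)
#' @export
screen_lags <- function(panel, climate, variable, lags = 0:3, alpha = 0.05,
                        scale = 1) {
  if (!"expected_cases" %in% names(panel)) panel <- expected_cases(panel)
  T <- attr(panel, "n_months")
  if (T <= max(lags)) stop("series shorter than the largest lag")
  cells <- aggregate(cbind(cases, expected_cases) ~ area_id + month_index,
                     data = panel, FUN = sum)
  cells <- cells[cells$month_index > max(lags), , drop = FALSE]
  rows <- lapply(lags, function(L) {
    lv <- lagged_covariate(climate, variable, L)
    x <- lv$value[match(paste(cells$area_id, cells$month_index),
                        paste(lv$area_id, lv$month_index))] / scale
    X <- cbind(intercept = 1, value = x)
    fit <- fit_poisson_glm(X, cells$cases, log(cells$expected_cases))
    data.frame(lag = L, coefficient = fit$coefficients[["value"]],
               p = fit$p_values[["value"]], aic = fit$aic, n = nrow(cells))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$p < alpha
  if (!any(ok)) {
    return(list(chosen_lag = NA_integer_, excluded = TRUE,
                reason = sprintf("no lag reached p < %g", alpha), table = tab))
  }
  cand <- tab[ok, , drop = FALSE]
  best <- cand[order(cand$aic, cand$lag), , drop = FALSE][1, ]
  list(chosen_lag = as.integer(best$lag), excluded = FALSE, reason = "min AIC",
       table = tab)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary least
#' squares regression of covariate j on the remaining covariates plus an
#' intercept. Exactly collinear columns are reported as `Inf`.
#'
#' @param design numeric matrix of covariates (no intercept column)
#' @return named numeric vector of VIFs
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop("VIF needs at least two covariates")
  if (nrow(design) <= ncol(design)) stop("need more rows than covariates")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  vapply(seq_len(ncol(design)), function(j) {
    yj <- design[, j]
    Xj <- cbind(1, design[, -j, drop = FALSE])
    fit <- lm.fit(Xj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)  # constant column
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(design))
}

#' Zero-inflated Poisson maximum likelihood (constant inflation)
#'
#' Maximises the ZIP likelihood with a single structural-zero probability
#' `omega` and log-linear Poisson mean by expectation-maximisation:
#' the E-step computes each zero row's posterior probability of being a
#' structural zero, the M-step runs a weighted Poisson IRLS and updates
#' `omega` as the mean membership. Iterates until the log likelihood moves
#' by less than `tol`.
#'
#' @inheritParams fit_poisson_glm
#' @param tol EM convergence tolerance on the log likelihood
#' @param max_iter maximum EM iterations
#' @return a `zip_fit` list with count-part `coefficients`, `omega_hat`,
#'   `log_likelihood`, `aic`, `bic` and `pointwise_loglik`
#' @export
fit_zip_mle <- function(design, counts, offset = NULL, tol = 1e-8,
                        max_iter = 2000) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (is.null(offset)) offset <- rep(0, length(counts))
  if (all(counts == 0))
    stop("all counts are zero: the ZIP likelihood is unbounded as omega -> 1")
  n <- length(counts)
  zero <- counts == 0
  if (!any(zero)) {
    warning("no zero counts: omega pinned to 0; fit reduces to Poisson")
    pf <- fit_poisson_glm(design, counts, offset)
    return(structure(list(coefficients = pf$coefficients, omega_hat = 0,
                          log_likelihood = pf$log_likelihood,
                          aic = -2 * pf$log_likelihood + 2 * (pf$k + 1),
                          bic = -2 * pf$log_likelihood + log(n) * (pf$k + 1),
                          pointwise_loglik = pf$pointwise_loglik,
                          iterations = 0L, converged = TRUE),
                     class = "zip_fit"))
  }
  omega <- mean(zero) / 2
  fit <- glm.fit(design, counts, family = poisson(), offset = offset)
  beta <- coef(fit)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mu <- exp(offset + drop(design %*% beta))
    # E-step: membership of zero rows in the structural-zero component
    w <- rep(0, n)
    w[zero] <- omega / (omega + (1 - omega) * exp(-mu[zero]))
    # M-step
    omega <- mean(w)
    fit <- glm.fit(design, counts, family = poisson(), offset = offset,
                   weights = 1 - w, start = beta,
                   control = list(epsilon = 1e-12, maxit = 100))
    beta <- coef(fit)
    mu <- exp(offset + drop(design %*% beta))
    ll <- sum(zip_loglik(counts, mu, omega))
    # boundary: data carry no evidence of extra zeros, the likelihood is
    # flat in omega near 0 and EM creeps — stop at the boundary
    if ((is.finite(ll) && abs(ll - ll_old) < tol) || omega < 1e-6) {
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (it == max_iter) stop("ZIP EM did not converge in ", max_iter,
                             " iterations")
  }
  if (omega < 1e-6) {
    # collapse to the boundary exactly: omega = 0 is the Poisson MLE
    omega <- 0
    pf <- fit_poisson_glm(design, counts, offset)
    beta <- pf$coefficients
  }
  mu <- exp(offset + drop(design %*% beta))
  pointwise <- zip_loglik(counts, mu, omega)
  k <- length(beta) + 1  # + omega
  structure(list(coefficients = beta, omega_hat = omega,
                 log_likelihood = sum(pointwise),
                 aic = -2 * sum(pointwise) + 2 * k,
                 bic = -2 * sum(pointwise) + log(n) * k,
                 pointwise_loglik = pointwise, iterations = it,
                 converged = TRUE),
            class = "zip_fit")
}

#' Vuong closeness test: ZIP versus Poisson
#'
#' For per-row log-likelihood differences `m_i = l_i(ZIP) - l_i(Poisson)`,
#' the statistic is `z = sqrt(n) * mean(m) / sd(m)`, referred to a standard
#' normal; positive z favours the zero-inflated model. The uncorrected
#' statistic is reported (no AIC/BIC degrees-of-freedom adjustment).
#'
#' @param zip a `zip_fit`
#' @param pois a `glm_fit` on the same rows
#' @return list with `z`, `p_value`, `favours`, `inconclusive`
#' @export
vuong_test <- function(zip, pois) {
  if (length(zip$pointwise_loglik) != length(pois$pointwise_loglik))
    stop("fits cover different numbers of rows")
  m <- zip$pointwise_loglik - pois$pointwise_loglik
  n <- length(m)
  if (n < 2)
    return(list(z = NA_real_, p_value = NA_real_, favours = "inconclusive",
                inconclusive = TRUE))
  s <- sd(m)
  if (s == 0) {
    if (abs(mean(m)) < 1e-12)
      return(list(z = 0, p_value = 1, favours = "inconclusive",
                  inconclusive = TRUE))
    stop("degenerate pointwise differences: zero variance with nonzero mean")
  }
  z <- sqrt(n) * mean(m) / s
  list(z = z, p_value = 2 * pnorm(-abs(z)),
       favours = if (z > 0) "zip" else "poisson",
       inconclusive = FALSE)
}
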