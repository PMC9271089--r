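#' Seasonal-trend decomposition by loess of a monthly series
#'
#' Decomposes the log-transformed monthly series additively into trend,
#' seasonal and remainder components, `Y_t = T_t + S_t + R_t`, using STL
#' with the periodic seasonal setting (the seasonal component of each
#' calendar month is its cycle-subseries mean, so the 12-value cycle
#' repeats exactly). The remainder is defined by subtraction, so the three
#' components reproduce the log series to machine precision.
#'
#' Zero months make the strict log transform undefined; set
#' `log_offset = 1` to use `log(x + 1)` instead (recorded in the result).
#'
#' @param series positive numeric vector of monthly totals, length >= 2
#'   periods
#' @param period season length in observations (12 for monthly data)
#' @param log_transform take logs before decomposing (the default)
#' @param log_offset added inside the log; 0 = strict log
#' @param t_window odd integer span (in observations) of the trend loess;
#'   `NULL` uses the reference STL default
#'   `nextodd(ceiling(1.5 * period / (1 - 1.5/s.window)))`, which for the
#'   periodic seasonal (infinite seasonal window) is `nextodd(1.5 * period)`
#' @param max_iter inner-loop iterations; stops earlier once the trend
#'   changes by less than `tol`
#' @param tol inner-loop convergence tolerance
#' @return a `seasonal_decomposition` with `series` (transformed), `trend`,
#'   `seasonal`, `remainder`, `period`, `log_offset`
#' @details The inner loop alternates (i) the periodic seasonal estimate:
#'   cycle-subseries means of the detrended series, centred so a full
#'   cycle sums to zero (the low-pass step is exact for a strictly
#'   periodic candidate), and (ii) a degree-1 loess of the deseasonalised
#'   series for the trend. Both steps are linear in the data, so the
#'   decomposition is location-equivariant; the remainder is defined by
#'   subtraction, making additivity exact. Unlike a windowed seasonal
#'   smoother this periodic mode is well defined down to exactly two
#'   observed cycles.
#' @export
stl_decompose <- function(series, period = 12, log_transform = TRUE,
                          log_offset = 0, t_window = NULL,
                          max_iter = 10, tol = 1e-8) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2 * period)
    stop("series must span at least two periods (", 2 * period, " months)")
  if (log_transform) {
    if (any(series + log_offset <= 0))
      stop("non-positive values under log transform; set log_offset = 1 ",
           "or disable log_transform")
    y <- log(series + log_offset)
  } else {
    y <- series
  }
  if (is.null(t_window)) {
    tw <- ceiling(1.5 * period)
    if (tw %% 2 == 0) tw <- tw + 1
  } else {
    tw <- t_window
  }
  tt <- seq_len(n)
  cyc_pos <- ((tt - 1L) %% period) + 1L
  trend <- rep(mean(y), n)
  seasonal <- rep(0, n)
  for (k in seq_len(max_iter)) {
    detr <- y - trend
    sub_means <- vapply(seq_len(period),
                        function(m) mean(detr[cyc_pos == m]), numeric(1))
    sub_means <- sub_means - mean(sub_means)
    seasonal <- sub_means[cyc_pos]
    deseason <- y - seasonal
    lo <- loess(deseason ~ tt, span = min(1, tw / n), degree = 1,
                family = "gaussian",
                control = loess.control(surface = "direct"))
    new_trend <- as.numeric(fitted(lo))
    delta <- max(abs(new_trend - trend))
    trend <- new_trend
    if (delta < tol) break
  }
  structure(list(series = y, trend = trend, seasonal = seasonal,
                 remainder = y - trend - seasonal,
                 period = period, log_offset = log_offset,
                 log_transform = log_transform),
            class = "seasonal_decomposition")
}

#' @export
print.seasonal_decomposition <- function(x, ...) {
  cat(sprintf("<seasonal_decomposition> T = %d, period = %d%s\n",
              length(x$series), x$period,
              if (x$log_transform)
                sprintf(", log(x + %g) transform", x$log_offset) else ""))
  cyc <- seasonal_cycle(x)
  cat("seasonal cycle:", paste(sprintf("%.3f", cyc), collapse = " "), "\n")
  invisible(x)
}

#' The repeating seasonal cycle
#'
#' @param decomposition a [stl_decompose()] result
#' @return the `period`-length seasonal pattern, position 1 = first month
#'   of the series
#' @export
seasonal_cycle <- function(decomposition) {
  s <- decomposition$seasonal
  p <- decomposition$period
  vapply(seq_len(p), function(m) mean(s[seq(m, length(s), by = p)]),
         numeric(1))
}

#' Calendar months of the seasonal maxima
#'
#' Finds the local maxima of the periodic seasonal cycle (circular
#' neighbourhood) and reports the two largest, ordered by month. A cycle
#' with fewer than two local maxima returns what it has with
#' `degenerate = TRUE`.
#'
#' @param decomposition a [stl_decompose()] result (periodic seasonal)
#' @param first_calendar_month calendar month of the first observation
#'   (1 = January), used to convert cycle positions to calendar months
#' @return list with `months` (integer vector) and `degenerate` flag
#' @export
peak_months <- function(decomposition, first_calendar_month = 1L) {
  cyc <- seasonal_cycle(decomposition)
  p <- decomposition$period
  if (diff(range(cyc)) < 1e-8)   # flat cycle: no meaningful seasonality
    return(list(months = integer(0), degenerate = TRUE))
  left <- cyc[c(p, seq_len(p - 1))]
  right <- cyc[c(seq(2, p), 1)]
  is_peak <- cyc > left & cyc >= right
  if (!any(is_peak))
    return(list(months = integer(0), degenerate = TRUE))
  pk <- which(is_peak)
  pk <- pk[order(cyc[pk], decreasing = TRUE)]
  pk <- sort(pk[seq_len(min(2L, length(pk)))])
  months <- ((pk - 1L + first_calendar_month - 1L) %% 12L) + 1L
  list(months = sort(months), degenerate = length(pk) < 2L)
}
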