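#' Cumulative incidence per 1000 population
#'
#' @param cases non-negative case count
#' @param population positive person count
#' @return `1000 * cases / population`, rounded to 2 decimals
#' @export
incidence_per_1000 <- function(cases, population) {
  if (any(population <= 0)) stop("population must be positive")
  round(1000 * cases / population, 2)
}

#' Annual incidence by age group
#'
#' Sums cases over areas, months and sexes within each (year, age group)
#' cell, using that year's stratum population.
#'
#' @param panel a [surveillance_panel()]
#' @return data frame `year, age_group, cases, population, incidence_per_1000`
#' @export
annual_incidence <- function(panel) {
  agg <- aggregate(cases ~ year + age_group, data = panel, FUN = sum)
  # population of a (year, age) cell: sum over areas and sexes of the
  # stratum population (constant within a year in this data model)
  popc <- aggregate(population ~ year + age_group + area_id + sex,
                    data = panel, FUN = function(x) mean(x))
  pop <- aggregate(population ~ year + age_group, data = popc, FUN = sum)
  out <- merge(agg, pop, by = c("year", "age_group"))
  out$incidence_per_1000 <- incidence_per_1000(out$cases, out$population)
  out[order(out$year, out$age_group), ]
}

#' Expected case counts from the overall rate
#'
#' The expected count of a panel row is the stratum population multiplied
#' by the study-wide rate (total cases / total population) divided by the
#' number of months, so that summed expected counts reproduce the total
#' observed count exactly. Population totals use the average population of
#' each (area, age, sex) stratum over the study period.
#'
#' @param panel a [surveillance_panel()]
#' @return the panel with an `expected_cases` column (replaced if present)
#' @export
expected_cases <- function(panel) {
  T <- attr(panel, "n_months")
  popc <- aggregate(population ~ area_id + age_group + sex, data = panel,
                    FUN = mean)
  tot_pop <- sum(popc$population)
  if (tot_pop <= 0) stop("total population is zero")
  rate <- sum(panel$cases) / tot_pop  # cases per person over the whole period
  panel$expected_cases <- panel$population * rate / T
  panel
}

#' Standardized morbidity ratios per area
#'
#' The SMR of area i is the ratio of observed to expected cases
#' accumulated over the full study period, `Y_i = O_i / E_i`; 1 means the
#' area tracks the national average risk. By default expected counts are
#' the total (all-strata) expectation; `by_stratum = TRUE` instead sums
#' stratum-specific expectations (identical here because the expectation is
#' built from a single overall rate, but exposed for rate tables supplied
#' externally).
#'
#' @param panel a [surveillance_panel()]; `expected_cases` computed if absent
#' @param by_stratum logical, see above
#' @return data frame `area_id, observed, expected, smr`
#' @export
smr <- function(panel, by_stratum = FALSE) {
  if (!"expected_cases" %in% names(panel)) panel <- expected_cases(panel)
  if (any(panel$expected_cases <= 0)) stop("expected counts must be positive")
  obs <- aggregate(cases ~ area_id, data = panel, FUN = sum)
  exp_ <- aggregate(expected_cases ~ area_id, data = panel, FUN = sum)
  out <- merge(obs, exp_, by = "area_id")
  names(out) <- c("area_id", "observed", "expected")
  out$smr <- out$observed / out$expected
  out[order(out$area_id), ]
}

#' Monthly mean and standard deviation of case counts
#'
#' Sums counts within each area-month cell (over the requested stratum, or
#' all four strata) and reports the mean and standard deviation over the
#' `n_areas * T` cells, together with the range.
#'
#' @param panel a [surveillance_panel()]
#' @param age_group optional `"under15"`/`"over15"` filter
#' @param sex optional `"male"`/`"female"` filter
#' @return one-row data frame `mean, sd, min, max, n_cells`
#' @export
monthly_mean_cases <- function(panel, age_group = NULL, sex = NULL) {
  if (nrow(panel) == 0L) stop("empty panel")
  df <- as.data.frame(panel)
  if (!is.null(age_group)) df <- df[df$age_group == age_group, , drop = FALSE]
  if (!is.null(sex)) df <- df[df$sex == sex, , drop = FALSE]
  cells <- aggregate(cases ~ area_id + month_index, data = df, FUN = sum)
  data.frame(mean = mean(cells$cases), sd = sd(cells$cases),
             min = min(cells$cases), max = max(cells$cases),
             n_cells = nrow(cells))
}

#' Proportion of zero-count observations
#'
#' @param panel a [surveillance_panel()]
#' @return list with `n_zero`, `n_total` and `percent`
#' @export
zero_fraction <- function(panel) {
  n0 <- sum(panel$cases == 0)
  list(n_zero = n0, n_total = nrow(panel),
       percent = 100 * n0 / nrow(panel))
}
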