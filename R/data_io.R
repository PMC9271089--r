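#' @useDynLib spatzip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @importFrom utils read.csv write.csv head
NULL

AGE_LEVELS <- c("over15", "under15")  # reference first, coded 0
SEX_LEVELS <- c("female", "male")    # reference first, coded 0

#' Surveillance panel constructor
#'
#' Builds a validated long-format surveillance panel: one row per
#' (area, month, age group, sex) with a case count and the population at
#' risk. The grid must be complete: every area contributes every month and
#' all four age-by-sex strata. A 1-based chronological `month_index` is
#' derived from (year, month).
#'
#' @param df data frame with columns `area_id`, `year`, `month`,
#'   `age_group` (`under15`/`over15`), `sex` (`male`/`female`), `cases`,
#'   `population`, and optionally `expected_cases`.
#' @return a `surveillance_panel` data frame with derived `month_index`.
#' @export
surveillance_panel <- function(df) {
  req <- c("area_id", "year", "month", "age_group", "sex", "cases", "population")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("surveillance data is missing columns: ", paste(miss, collapse = ", "))
  df$area_id <- as.character(df$area_id)
  if (!all(df$age_group %in% AGE_LEVELS))
    stop("age_group must be one of: ", paste(AGE_LEVELS, collapse = ", "))
  if (!all(df$sex %in% SEX_LEVELS))
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  bad <- which(!is.finite(df$cases) | df$cases < 0 | df$cases != round(df$cases))
  if (length(bad) > 0L)
    stop("cases must be non-negative integers; offending rows: ",
         paste(head(bad, 10L), collapse = ", "))
  if (any(!is.finite(df$population) | df$population <= 0))
    stop("population must be positive")

  ym <- unique(df[, c("year", "month")])
  ym <- ym[order(ym$year, ym$month), , drop = FALSE]
  ym$month_index <- seq_len(nrow(ym))
  df$month_index <- ym$month_index[match(
    paste(df$year, df$month), paste(ym$year, ym$month))]

  areas <- sort(unique(df$area_id))
  grid <- expand.grid(area_id = areas, month_index = ym$month_index,
                      age_group = AGE_LEVELS, sex = SEX_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$area_id, d$month_index, d$age_group, d$sex, sep = "|")
  kd <- key(df)
  if (anyDuplicated(kd))
    stop("duplicate (area, month, age, sex) rows: ",
         paste(head(kd[duplicated(kd)], 5L), collapse = "; "))
  gaps <- setdiff(key(grid), kd)
  if (length(gaps) > 0L)
    stop("incomplete stratum grid; missing (area|month_index|age|sex): ",
         paste(head(gaps, 10L), collapse = "; "),
         if (length(gaps) > 10L) sprintf(" ... and %d more", length(gaps) - 10L) else "")

  df <- df[order(df$area_id, df$month_index, df$age_group, df$sex), , drop = FALSE]
  rownames(df) <- NULL
  ord <- c("area_id", "month_index", "year", "month", "age_group", "sex",
           "cases", "population",
           intersect("expected_cases", names(df)))
  df <- df[, ord, drop = FALSE]
  structure(df, class = c("surveillance_panel", "data.frame"),
            areas = areas, n_months = nrow(ym))
}

#' @export
print.surveillance_panel <- function(x, ...) {
  cat(sprintf("<surveillance_panel> %d areas x %d months x 4 strata = %d rows\n",
              length(attr(x, "areas")), attr(x, "n_months"), nrow(x)))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a surveillance CSV
#'
#' @param path CSV with columns `area_id, year, month, age_group, sex,
#'   cases, population` (optionally `expected_cases`).
#' @param schema optional named character vector mapping the required
#'   column names to the names used in the file, e.g.
#'   `c(area_id = "gewog")`.
#' @return a [surveillance_panel()].
#' @export
read_surveillance <- function(path, schema = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        stop("schema column not found in file: ", schema[[std]])
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  surveillance_panel(df)
}

#' @rdname read_surveillance
#' @param panel a `surveillance_panel`
#' @export
write_surveillance <- function(panel, path) {
  out <- as.data.frame(panel)
  out$month_index <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Climate panel constructor
#'
#' Area-by-month climate covariates (rainfall in mm, maximum temperature in
#' degrees C, relative humidity in percent) together with a static altitude
#' per area. The grid must be complete.
#'
#' @param df data frame with `area_id, year, month, rainfall_mm, tmax_c, rh_pct`
#' @param altitude data frame with `area_id, altitude_m`
#' @return a `climate_panel` data frame with derived `month_index`.
#' @export
climate_panel <- function(df, altitude) {
  req <- c("area_id", "year", "month", "rainfall_mm", "tmax_c", "rh_pct")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("climate data is missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("area_id", "altitude_m") %in% names(altitude)))
    stop("altitude table needs columns area_id, altitude_m")
  df$area_id <- as.character(df$area_id)
  altitude$area_id <- as.character(altitude$area_id)
  if (any(df$rh_pct < 0 | df$rh_pct > 100))
    stop("relative humidity must lie in [0, 100]")
  if (any(df$rainfall_mm < 0)) stop("rainfall must be non-negative")
  if (any(!is.finite(df$rainfall_mm) | !is.finite(df$tmax_c) | !is.finite(df$rh_pct)))
    stop("missing climate records are not allowed")

  ym <- unique(df[, c("year", "month")])
  ym <- ym[order(ym$year, ym$month), , drop = FALSE]
  ym$month_index <- seq_len(nrow(ym))
  df$month_index <- ym$month_index[match(
    paste(df$year, df$month), paste(ym$year, ym$month))]
  areas <- sort(unique(df$area_id))
  if (!setequal(areas, altitude$area_id))
    stop("altitude table areas do not match climate areas")
  kd <- paste(df$area_id, df$month_index)
  need <- as.vector(outer(areas, ym$month_index, paste))
  if (anyDuplicated(kd) || length(setdiff(need, kd)) > 0L)
    stop("climate grid must be complete with no duplicates; missing: ",
         paste(head(setdiff(need, kd), 10L), collapse = "; "))
  df$altitude_m <- altitude$altitude_m[match(df$area_id, altitude$area_id)]
  df <- df[order(df$area_id, df$month_index), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("climate_panel", "data.frame"),
            areas = areas, n_months = nrow(ym))
}

#' Read climate and altitude CSVs
#'
#' @param climate_path CSV with `area_id, year, month, rainfall_mm, tmax_c, rh_pct`
#' @param altitude_path CSV with `area_id, altitude_m`
#' @return a [climate_panel()]
#' @export
read_climate <- function(climate_path, altitude_path) {
  climate_panel(read.csv(climate_path, stringsAsFactors = FALSE),
                read.csv(altitude_path, stringsAsFactors = FALSE))
}

#' @rdname read_climate
#' @param climate a `climate_panel`
#' @param dir directory receiving `climate.csv` and `altitude.csv`
#' @export
write_climate <- function(climate, dir) {
  df <- as.data.frame(climate)
  alt <- unique(df[, c("area_id", "altitude_m")])
  df <- df[, c("area_id", "year", "month", "rainfall_mm", "tmax_c", "rh_pct")]
  write.csv(df, file.path(dir, "climate.csv"), row.names = FALSE, quote = FALSE)
  write.csv(alt, file.path(dir, "altitude.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Lagged climate covariate lookup
#'
#' Returns the covariate value observed `lag` months before each requested
#' month. Months with `month_index <= lag` have no antecedent observation
#' and are returned as `NA` (never zero-filled); downstream model fits drop
#' those rows.
#'
#' @param climate a `climate_panel`
#' @param variable one of `"rainfall_mm"`, `"tmax_c"`, `"rh_pct"`
#' @param lag non-negative integer number of months
#' @return data frame `area_id, month_index, value`
#' @export
lagged_covariate <- function(climate, variable, lag) {
  stopifnot(variable %in% c("rainfall_mm", "tmax_c", "rh_pct"),
            lag >= 0, lag == round(lag))
  out <- data.frame(area_id = climate$area_id,
                    month_index = climate$month_index)
  src <- match(paste(out$area_id, out$month_index - lag),
               paste(climate$area_id, climate$month_index))
  out$value <- climate[[variable]][src]
  out$value[out$month_index <= lag] <- NA_real_
  out
}

#' Adjacency graph constructor
#'
#' Symmetric 0/1 spatial weights over areas (queen contiguity convention:
#' weight 1 for areas sharing a border, 0 otherwise), stored as an edge
#' list of unordered pairs. Self-loops are forbidden; duplicate and
#' reversed edges collapse.
#'
#' @param area_ids character vector of all areas (isolated areas allowed)
#' @param edges two-column character matrix/data frame of area pairs
#' @return an `adjacency_graph` list with `area_ids`, `edges` (2-col matrix),
#'   `neighbours` (per-area list), `degree`, `n_components`.
#' @export
adjacency_graph <- function(area_ids, edges) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area ids")
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    storage.mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loop in adjacency list: ", edges[edges[, 1] == edges[, 2], 1][1])
    unknown <- setdiff(c(edges), area_ids)
    if (length(unknown) > 0L)
      stop("edge references unknown area(s): ", paste(unknown, collapse = ", "))
    swp <- edges[, 1] > edges[, 2]
    edges[swp, ] <- edges[swp, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else {
    edges <- matrix(character(0), ncol = 2)
  }
  colnames(edges) <- c("from", "to")
  n <- length(area_ids)
  nb <- vector("list", n)
  names(nb) <- area_ids
  for (k in seq_len(nrow(edges))) {
    i <- match(edges[k, 1], area_ids); j <- match(edges[k, 2], area_ids)
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  deg <- vapply(nb, length, integer(1))
  # connected components by repeated BFS (islands count as their own component)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      while (length(queue) > 0L) {
        i <- queue[1]; queue <- queue[-1]
        if (comp[i] == 0L) {
          comp[i] <- cur
          queue <- c(queue, nb[[i]][comp[nb[[i]]] == 0L])
        }
      }
    }
  }
  structure(list(area_ids = area_ids, edges = edges, neighbours = nb,
                 degree = deg, component = comp, n_components = cur),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d areas, %d edges, %d component(s)\n",
              length(x$area_ids), nrow(x$edges), x$n_components))
  invisible(x)
}

#' Read an adjacency edge list
#'
#' One unordered pair per line, whitespace- or comma-separated. Reversed
#' duplicates collapse to one edge. An optional `area_ids` supplies the
#' full area list (required when some areas are islands with no edges).
#'
#' @param path edge-list text file
#' @param area_ids optional character vector of all areas
#' @return an [adjacency_graph()]
#' @export
read_adjacency <- function(path, area_ids = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(lines, function(l) strsplit(l, "[,[:space:]]+")[[1]])
  if (any(vapply(parts, length, integer(1)) != 2L))
    stop("each adjacency line must contain exactly two area ids")
  edges <- do.call(rbind, parts)
  if (is.null(area_ids)) area_ids <- sort(unique(c(edges)))
  adjacency_graph(area_ids, edges)
}

#' @rdname read_adjacency
#' @param graph an `adjacency_graph`
#' @export
write_adjacency <- function(graph, path) {
  writeLines(paste(graph$edges[, 1], graph$edges[, 2]), path)
  invisible(path)
}

#' Run configuration
#'
#' All tunable analysis settings in one object. Defaults are the desk-scale
#' settings; the long-chain settings used for full-scale surveillance runs
#' (burn-in 10,000, ~100,000 iterations) are selected by overriding `mcmc`.
#'
#' @param lags_to_screen integer lags screened for each climate variable
#' @param vif_threshold covariates above this variance inflation factor are
#'   dropped as collinear
#' @param alpha significance level for the covariate screen
#' @param mcmc list with `burn_in`, `total_iterations`, `thin`,
#'   `check_block`, `seed`
#' @param cri_level credible-interval mass
#' @param trend_prob_threshold posterior probability needed to call an
#'   area's trend above/below the national average
#' @return a `run_config` list
#' @export
run_config <- function(lags_to_screen = 0:3, vif_threshold = 4.0, alpha = 0.05,
                       mcmc = list(), cri_level = 0.95,
                       trend_prob_threshold = 0.95) {
  m <- list(burn_in = 1000L, total_iterations = 11000L, thin = 5L,
            check_block = 20000L, seed = 1L)
  m[names(mcmc)] <- mcmc
  if (m$burn_in >= m$total_iterations)
    stop("burn_in must be smaller than total_iterations")
  if (cri_level <= 0 || cri_level >= 1) stop("cri_level must lie in (0, 1)")
  structure(list(lags_to_screen = as.integer(lags_to_screen),
                 vif_threshold = vif_threshold, alpha = alpha, mcmc = m,
                 cri_level = cri_level,
                 trend_prob_threshold = trend_prob_threshold),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file mirroring the `run_config` fields
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
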