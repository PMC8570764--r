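#' Parameter registry for the diabetes / HEF microsimulation
#'
#' The model is driven by a single validated registry of unit costs, care
#' delivery probabilities, population characteristics, complication profiles,
#' and Health Equity Fund (HEF) design parameters, all in 2019 USD. The
#' packaged base case (`base_parameters.yaml` under `extdata`) holds the
#' published point values together with the probability distributions used
#' by the sensitivity analysis.
#'
#' @param path Path to a YAML configuration. Defaults to the packaged
#'   base-case registry.
#' @return A validated parameter registry of class `hef_params`: a nested
#'   list with blocks `costs`, `population`, `disability`, `complications`
#'   (eight named profiles), `care`, and `hef`. Uncertain entries are
#'   [dist_spec()] objects; scalars are plain numerics.
#' @examples
#' p <- load_parameters()
#' p$costs$oad_annual$point
#' @export
load_parameters <- function(path = default_parameter_path()) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  raw$meta <- NULL
  params <- parse_parameters(raw)
  validate_parameters(params)
}

#' @rdname load_parameters
#' @export
default_parameter_path <- function() {
  system.file("extdata", "base_parameters.yaml", package = "hefsim", mustWork = TRUE)
}

complication_names <- c("nephropathy", "retinopathy", "neuropathy", "angina",
                        "pvd", "mi", "stroke", "heart_failure")
provider_levels <- c("hc", "cpa1", "cpa2", "cpa3")

## keys that hold distributions (everything else is a plain scalar)
dist_keys_costs <- c("diagnostics", "laboratory", "oad_annual", "insulin_annual",
                     "transport_outpatient", "transport_inpatient")
dist_keys_care <- c("p_diagnosis", "p_outpatient_nonhef", "p_outpatient_hef",
                    "p_inpatient")

schema <- list(
  costs = c(dist_keys_costs, "outpatient_visit", "inpatient_day", "discount_rate"),
  population = c("all_cause_mortality", "diabetes_incidence", "diabetes_prevalence",
                 "diabetes_mortality", "income", "life_expectancy", "sex_ratio_male",
                 "age_min", "age_max", "poverty_line_daily", "mortality_gompertz_slope"),
  disability = c("uncomplicated", "dw_undiagnosed_counts"),
  complications = complication_names,
  care = c(dist_keys_care, "provider_shares", "p_oad", "p_insulin", "p_combo",
           "p_oad_to_insulin", "p_adherence", "rr_diet", "los_days"),
  hef = c("eligibility_percentile", "enrollment", "subsidy", "utilization")
)
comp_fields <- c("incidence", "rr_therapy", "disability_weight", "case_fatality",
                 "cost", "cost_unit", "cost_setting", "acute")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown parameter key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing) > 0) {
    stop(sprintf("missing parameter key(s) in %s: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

parse_parameters <- function(raw) {
  check_keys(raw, names(schema), "config")
  for (blk in names(schema)) check_keys(raw[[blk]], schema[[blk]], blk)

  p <- raw
  for (k in dist_keys_costs) p$costs[[k]] <- as_dist(p$costs[[k]], k)
  for (lvl in provider_levels) {
    p$costs$outpatient_visit[[lvl]] <- as_dist(p$costs$outpatient_visit[[lvl]],
                                               paste0("outpatient_visit.", lvl))
    p$costs$inpatient_day[[lvl]] <- as_dist(p$costs$inpatient_day[[lvl]],
                                            paste0("inpatient_day.", lvl))
  }
  p$population$income <- as_dist(p$population$income, "income")
  for (k in dist_keys_care) p$care[[k]] <- as_dist(p$care[[k]], k)
  for (lvl in provider_levels) {
    p$care$provider_shares[[lvl]] <- as_dist(p$care$provider_shares[[lvl]],
                                             paste0("provider_shares.", lvl))
  }
  for (cn in complication_names) {
    check_keys(p$complications[[cn]], comp_fields, paste0("complications.", cn))
    p$complications[[cn]]$cost <- as_dist(p$complications[[cn]]$cost,
                                          paste0(cn, ".cost"))
  }
  structure(p, class = "hef_params")
}

pv <- function(x) if (inherits(x, "hef_dist")) x$point else as.numeric(x)

check_prob <- function(value, name) {
  if (!is.numeric(value) || is.na(value) || value < 0 || value > 1) {
    stop(sprintf("parameter '%s' must be a probability in [0, 1], got %s",
                 name, format(value)), call. = FALSE)
  }
}
check_nonneg <- function(value, name) {
  if (!is.numeric(value) || is.na(value) || value < 0) {
    stop(sprintf("parameter '%s' must be non-negative, got %s",
                 name, format(value)), call. = FALSE)
  }
}

#' Validate a parameter registry
#'
#' Checks range constraints: probabilities in `[0, 1]`, costs non-negative,
#' therapy assignment probabilities summing to at most 1, disability weights
#' in `[0, 1]`, and exactly the eight modelled complications. Errors name the
#' offending parameter.
#'
#' @param params A parameter registry (as parsed by [load_parameters()]).
#' @return `params`, invisibly validated (returned unchanged on success).
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "hef_params"))
  for (k in c(dist_keys_costs)) check_nonneg(pv(params$costs[[k]]), k)
  for (lvl in provider_levels) {
    check_nonneg(pv(params$costs$outpatient_visit[[lvl]]), paste0("outpatient_visit.", lvl))
    check_nonneg(pv(params$costs$inpatient_day[[lvl]]), paste0("inpatient_day.", lvl))
  }
  check_nonneg(params$costs$discount_rate, "discount_rate")
  pop <- params$population
  for (k in c("all_cause_mortality", "diabetes_incidence", "diabetes_prevalence",
              "diabetes_mortality")) {
    check_prob(pop[[k]], k)
  }
  check_prob(pop$sex_ratio_male, "sex_ratio_male")
  check_nonneg(pv(pop$income), "income")
  check_nonneg(pop$poverty_line_daily, "poverty_line_daily")
  if (pop$age_min >= pop$age_max) stop("age_min must be below age_max", call. = FALSE)
  check_prob(params$disability$uncomplicated, "disability.uncomplicated")

  for (cn in complication_names) {
    cp <- params$complications[[cn]]
    check_prob(cp$incidence, paste0(cn, ".incidence"))
    check_prob(cp$case_fatality, paste0(cn, ".case_fatality"))
    check_prob(cp$disability_weight, paste0(cn, ".disability_weight"))
    if (cp$rr_therapy <= 0 || cp$rr_therapy > 1) {
      stop(sprintf("parameter '%s.rr_therapy' must be in (0, 1]", cn), call. = FALSE)
    }
    check_nonneg(pv(cp$cost), paste0(cn, ".cost"))
    if (!cp$cost_unit %in% c("per_day", "per_year")) {
      stop(sprintf("'%s.cost_unit' must be per_day or per_year", cn), call. = FALSE)
    }
    if (!cp$cost_setting %in% c("inpatient", "outpatient")) {
      stop(sprintf("'%s.cost_setting' must be inpatient or outpatient", cn), call. = FALSE)
    }
  }

  care <- params$care
  for (k in dist_keys_care) check_prob(pv(care[[k]]), k)
  for (lvl in provider_levels) {
    check_prob(pv(care$provider_shares[[lvl]]), paste0("provider_shares.", lvl))
  }
  for (k in c("p_oad", "p_insulin", "p_combo", "p_oad_to_insulin", "p_adherence")) {
    check_prob(care[[k]], k)
  }
  if (care$p_oad + care$p_insulin + care$p_combo > 1) {
    stop("p_oad + p_insulin + p_combo must not exceed 1", call. = FALSE)
  }
  if (care$rr_diet <= 0 || care$rr_diet > 1) {
    stop("parameter 'rr_diet' must be in (0, 1]", call. = FALSE)
  }
  check_nonneg(care$los_days, "los_days")
  check_prob(params$hef$eligibility_percentile, "hef.eligibility_percentile")
  check_prob(params$hef$enrollment, "hef.enrollment")
  check_prob(params$hef$subsidy, "hef.subsidy")
  check_prob(params$hef$utilization, "hef.utilization")
  params
}

#' Serialize a parameter registry back to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p` field-by-field.
#'
#' @param params A validated `hef_params` registry.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "hef_params"))
  strip <- function(x) {
    if (inherits(x, "hef_dist")) {
      if (x$family == "point") return(x$point)
      return(list(point = x$point, family = x$family, p1 = x$p1, p2 = x$p2))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  yaml::write_yaml(strip(unclass(params)), path, precision = 12)
  invisible(path)
}

#' Tabulate every parameter with its distribution
#'
#' Flattens the registry into one row per parameter, with the point value,
#' distribution family and parameters, and the analytic distribution mean.
#' Per-day drug cost distributions are specified on the annualized scale, so
#' their means are compared to `365 * point`.
#'
#' @param params A validated `hef_params` registry.
#' @return A tibble with columns `parameter`, `group`, `point`, `family`,
#'   `p1`, `p2`, `dist_mean`, `comparable_point` (point value on the scale of
#'   the distribution).
#' @export
parameter_table <- function(params) {
  stopifnot(inherits(params, "hef_params"))
  rows <- list()
  add <- function(name, group, spec, scale = 1) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = name, group = group, point = spec$point,
      family = spec$family, p1 = spec$p1, p2 = spec$p2,
      dist_mean = dist_mean(spec), comparable_point = spec$point * scale
    )
  }
  for (k in dist_keys_costs) add(k, "costs", params$costs[[k]])
  for (lvl in provider_levels) {
    add(paste0("outpatient_visit_", lvl), "costs", params$costs$outpatient_visit[[lvl]])
    add(paste0("inpatient_day_", lvl), "costs", params$costs$inpatient_day[[lvl]])
  }
  for (cn in complication_names) {
    cp <- params$complications[[cn]]
    add(paste0(cn, "_cost"), "complications", cp$cost,
        scale = if (cp$cost_unit == "per_day") 365 else 1)
  }
  add("income", "population", params$population$income)
  for (k in dist_keys_care) add(k, "care", params$care[[k]])
  for (lvl in provider_levels) {
    add(paste0("provider_share_", lvl), "care", params$care$provider_shares[[lvl]])
  }
  dplyr::bind_rows(rows)
}

#' Audit distribution/point-value consistency
#'
#' For every parameter with a non-point distribution, compares the analytic
#' distribution mean against the base-case point value and reports entries
#' whose relative deviation exceeds `tol`. The registry carries a handful of
#' known inconsistencies from its published sources (the two outpatient
#' care-seeking betas appear swapped; the provider-share beta means sit below
#' their point values), which this report surfaces rather than silently
#' repairs. Never raises.
#'
#' @param params A validated `hef_params` registry.
#' @param tol Relative deviation above which a parameter is reported
#'   (default 0.05).
#' @return A tibble of flagged parameters with columns `parameter`, `point`,
#'   `dist_mean`, `rel_dev`; zero rows when all distributions agree.
#' @examples
#' consistency_report(load_parameters())
#' @export
consistency_report <- function(params, tol = 0.05) {
  tab <- parameter_table(params)
  tab <- dplyr::filter(tab, .data$family != "point")
  tab <- dplyr::mutate(
    tab, rel_dev = abs(.data$dist_mean - .data$comparable_point) /
      pmax(abs(.data$comparable_point), .Machine$double.eps)
  )
  dplyr::select(
    dplyr::filter(tab, .data$rel_dev > tol),
    "parameter", point = "comparable_point", "dist_mean", "rel_dev"
  )
}

#' Background mortality hazard by age
#'
#' A synthetic Gompertz-shaped schedule: relative hazard
#' `exp(slope * (age - age_min))`, rescaled so that its mean over the uniform
#' baseline age range equals the published mean all-cause annual mortality,
#' and capped at 0.95. Published five-year abridged schedules can be emulated
#' by adjusting the slope; a slope of zero gives a flat hazard.
#'
#' @param age Numeric vector of ages in years.
#' @param params A validated `hef_params` registry.
#' @return Annual death probabilities, same length as `age`.
#' @export
background_mortality <- function(age, params) {
  pop <- params$population
  slope <- pop$mortality_gompertz_slope
  base_ages <- seq(pop$age_min, pop$age_max)
  k <- pop$all_cause_mortality / mean(exp(slope * (base_ages - pop$age_min)))
  pmin(k * exp(slope * (age - pop$age_min)), 0.95)
}
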