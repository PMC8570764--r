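#' Disability-adjusted life-years from a simulation
#'
#' DALYs are the sum of years of life lost (YLL) to premature
#' diabetes-attributable death and years lived with disability (YLD). YLL
#' per death is the remaining life expectancy at the age of death (life
#' expectancy 67/71 years for men/women in the base case, floored at zero);
#' deaths from background all-cause mortality contribute no YLL, since the
#' outcome of interest is the burden of diabetes and its consequences. YLD
#' is the sum of person-years weighted by the combined disability weight
#' accrued in the ledger (multiplicative comorbidity combination
#' `1 - prod(1 - w_i)`, including the 0.049 weight of uncomplicated
#' diabetes). DALYs are not discounted.
#'
#' @param sim A `hef_sim` result.
#' @param params A validated `hef_params` registry.
#' @return One-row tibble: `yll`, `yld`, `dalys`, and the YLL split by cause
#'   (`yll_diabetes`, `yll_complication`). Unscaled (simulated persons).
#' @export
compute_dalys <- function(sim, params) {
  stopifnot(inherits(sim, "hef_sim"))
  le <- params$population$life_expectancy
  d <- dplyr::left_join(sim$deaths,
                        dplyr::select(tibble::as_tibble(sim$cohort), "id", "sex"),
                        by = c(person_id = "id"))
  d <- dplyr::mutate(
    d,
    le_sex = ifelse(.data$sex == "male", le$male, le$female),
    yll = pmax(.data$le_sex - .data$age_at_death, 0)
  )
  yll_dm <- sum(d$yll[d$cause == "diabetes"])
  yll_cx <- sum(d$yll[d$cause == "complication"])
  yld <- sum(sim$ledger$yld)
  tibble::tibble(yll = yll_dm + yll_cx, yld = yld,
                 dalys = yll_dm + yll_cx + yld,
                 yll_diabetes = yll_dm, yll_complication = yll_cx)
}

#' Present value of a cost
#'
#' `amount / (1 + rate)^year`; cycle 0 is undiscounted.
#'
#' @param amount Cost (vectorized, >= 0).
#' @param year Cycle index (0-based, vectorized).
#' @param rate Annual discount rate (default 0.03; must exceed -1).
#' @return Discounted amount.
#' @examples
#' discounted_cost(100, 2, 0.03)
#' @export
discounted_cost <- function(amount, year, rate = 0.03) {
  stopifnot(all(amount >= 0), all(year >= 0))
  if (rate <= -1) stop("discount rate must exceed -1", call. = FALSE)
  amount / (1 + rate)^year
}

#' Catastrophic health expenditure cases
#'
#' Counts diabetic person-years in which annual out-of-pocket spending
#' (medical plus transport, undiscounted) strictly exceeds `threshold` times
#' the person's annual household income. Assessed per person-year against
#' annual income, not cumulatively.
#'
#' @param sim A `hef_sim` result.
#' @param threshold Income share in (0, 1); the headline threshold is 0.40,
#'   with 0.10 and 0.25 also examined.
#' @return Unscaled case count (simulated person-years).
#' @export
che_cases <- function(sim, threshold = 0.40) {
  stopifnot(inherits(sim, "hef_sim"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  led <- dplyr::left_join(
    sim$ledger,
    dplyr::select(tibble::as_tibble(sim$cohort), "id", "income"),
    by = c(person_id = "id")
  )
  oop <- led$cost_oop_medical + led$cost_oop_transport
  sum(led$disease_state != "no_diabetes" & oop > threshold * led$income)
}

#' Impoverishment cases
#'
#' Counts person-years in which a household above the international poverty
#' line (1.90 USD/day, i.e. 693.5 USD/yr) is pushed below it by its annual
#' out-of-pocket health spending.
#'
#' @param sim A `hef_sim` result.
#' @param params A validated `hef_params` registry.
#' @return Unscaled case count.
#' @export
impoverishment_cases <- function(sim, params) {
  stopifnot(inherits(sim, "hef_sim"))
  line <- params$population$poverty_line_daily * 365
  led <- dplyr::left_join(
    sim$ledger,
    dplyr::select(tibble::as_tibble(sim$cohort), "id", "income"),
    by = c(person_id = "id")
  )
  oop <- led$cost_oop_medical + led$cost_oop_transport
  sum(led$income >= line & led$income - oop < line)
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / effect_averted`, rounded to the nearest dollar.
#' `effect_averted` is the health or financial-protection gain (e.g. DALYs
#' averted or CHE cases averted), so a negative incremental-effect column
#' (fewer DALYs) enters here with a positive sign. Status:
#' * `"dominant"` when the strategy saves money and averts effects
#'   (`delta_cost <= 0`, `effect_averted > 0`): the signed ratio is retained
#'   for table fidelity;
#' * `"dominated"` (value `NA`) when it costs more and averts nothing;
#' * `"undefined"` when no effects are averted and no cost is added.
#'
#' @param delta_cost Incremental cost vs the comparator (USD).
#' @param effect_averted Effects averted vs the comparator (> 0 means the
#'   strategy is better).
#' @return List with `value` (USD per unit averted, rounded; `NA` when
#'   dominated/undefined) and `status` (`"ratio"`, `"dominant"`,
#'   `"dominated"` or `"undefined"`).
#' @examples
#' icer(1041566, 38404)    # $27 per DALY averted
#' icer(-1212155, 38404)   # dominant, signed ratio -32
#' @export
icer <- function(delta_cost, effect_averted) {
  stopifnot(is.finite(delta_cost), is.finite(effect_averted))
  if (effect_averted > 0) {
    value <- round(delta_cost / effect_averted)
    status <- if (delta_cost <= 0) "dominant" else "ratio"
    return(list(value = value, status = status))
  }
  if (delta_cost > 0) return(list(value = NA_real_, status = "dominated"))
  list(value = NA_real_, status = "undefined")
}

#' Aggregate a simulation into the economic outcome set
#'
#' Collapses the person-year ledger into the published outcome measures:
#' discounted societal costs split by payer, undiscounted out-of-pocket
#' spending, undiscounted DALYs with the YLL/YLD split, catastrophic health
#' expenditure cases at each threshold, impoverishment cases, and per-sex
#' DALY and CHE breakdowns. Extensive quantities are inflated by the
#' cohort's scale factor (persons represented per simulated person).
#'
#' @param sim A `hef_sim` result.
#' @param params A validated `hef_params` registry.
#' @param che_thresholds CHE thresholds (default `c(0.10, 0.25, 0.40)`).
#' @param scale_factor Persons represented per simulated person; defaults to
#'   the cohort attribute.
#' @return One-row tibble of class `hef_outcome`. Cost columns are
#'   discounted at the configured rate and scaled; `oop_undiscounted` is the
#'   raw out-of-pocket total (scaled); `mean_annual_cost_per_diabetic` is the
#'   undiscounted direct medical cost per diabetic person-year (a per-person
#'   intensity, unscaled by construction).
#' @examples
#' p <- load_parameters()
#' cohort <- generate_cohort(p, 500, seed = 1)
#' sim <- simulate_cohort(cohort, build_strategy("current_standard"), p, seed = 2)
#' summarize_outcomes(sim, p)
#' @export
summarize_outcomes <- function(sim, params, che_thresholds = c(0.10, 0.25, 0.40),
                               scale_factor = NULL) {
  stopifnot(inherits(sim, "hef_sim"))
  sf <- scale_factor %||% attr(sim$cohort, "scale_factor") %||% 1
  rate <- params$costs$discount_rate
  led <- sim$ledger
  disc <- 1 / (1 + rate)^led$year
  cost_gov <- sum(led$cost_government * disc)
  cost_oop_med <- sum(led$cost_oop_medical * disc)
  cost_oop_tr <- sum(led$cost_oop_transport * disc)
  oop_undisc <- sum(led$cost_oop_medical + led$cost_oop_transport)

  dal <- compute_dalys(sim, params)
  che <- vapply(che_thresholds, function(t) che_cases(sim, t), 0)
  imp <- impoverishment_cases(sim, params)

  cohort_tbl <- tibble::as_tibble(sim$cohort)
  diabetic_states <- c("undiagnosed", "diagnosed_untreated", "on_oad",
                       "on_insulin", "on_combo")
  dm_py_tbl <- dplyr::filter(led, .data$disease_state %in% diabetic_states)
  dm_py <- nrow(dm_py_tbl)
  dm_persons <- dplyr::n_distinct(dm_py_tbl$person_id)
  med_undisc_dm <- sum(dm_py_tbl$cost_government + dm_py_tbl$cost_oop_medical)

  # per-sex splits
  sexes <- dplyr::select(cohort_tbl, "id", "sex")
  led_sex <- dplyr::left_join(led, sexes, by = c(person_id = "id"))
  d_sex <- compute_dalys_by_sex(sim, params)
  che40_sex <- che_by_sex(sim, threshold = 0.40)

  out <- tibble::tibble(
    strategy = sim$strategy$name,
    eligibility = sim$strategy$eligibility_percentile,
    subsidy = sim$strategy$subsidy_rate,
    n_simulated = nrow(cohort_tbl),
    scale_factor = sf,
    diabetic_persons = dm_persons,
    diabetic_person_years = dm_py,
    total_cost = (cost_gov + cost_oop_med + cost_oop_tr) * sf,
    cost_government = cost_gov * sf,
    cost_oop = (cost_oop_med + cost_oop_tr) * sf,
    oop_undiscounted = oop_undisc * sf,
    dalys = dal$dalys * sf,
    yll = dal$yll * sf,
    yld = dal$yld * sf,
    yll_diabetes = dal$yll_diabetes * sf,
    yll_complication = dal$yll_complication * sf,
    impoverishment = imp * sf,
    dalys_male = d_sex$dalys[d_sex$sex == "male"] * sf,
    dalys_female = d_sex$dalys[d_sex$sex == "female"] * sf,
    che_40_male = unname(che40_sex["male"]) * sf,
    che_40_female = unname(che40_sex["female"]) * sf,
    mean_annual_cost_per_diabetic = med_undisc_dm / max(dm_py, 1)
  )
  for (i in seq_along(che_thresholds)) {
    out[[sprintf("che_%02.0f", 100 * che_thresholds[i])]] <- che[i] * sf
  }
  class(out) <- c("hef_outcome", class(out))
  out
}

compute_dalys_by_sex <- function(sim, params) {
  le <- params$population$life_expectancy
  sexes <- dplyr::select(tibble::as_tibble(sim$cohort), "id", "sex")
  d <- dplyr::left_join(sim$deaths, sexes, by = c(person_id = "id"))
  d <- dplyr::filter(d, .data$cause %in% c("diabetes", "complication"))
  d <- dplyr::mutate(d, le_sex = ifelse(.data$sex == "male", le$male, le$female),
                     yll = pmax(.data$le_sex - .data$age_at_death, 0))
  yll_by <- dplyr::summarise(dplyr::group_by(d, .data$sex), yll = sum(.data$yll))
  led <- dplyr::left_join(sim$ledger, sexes, by = c(person_id = "id"))
  yld_by <- dplyr::summarise(dplyr::group_by(led, .data$sex), yld = sum(.data$yld))
  res <- dplyr::full_join(yll_by, yld_by, by = "sex")
  res <- tidyr::complete(res, sex = c("male", "female"),
                         fill = list(yll = 0, yld = 0))
  res$yll[is.na(res$yll)] <- 0
  res$yld[is.na(res$yld)] <- 0
  dplyr::mutate(res, dalys = .data$yll + .data$yld)
}

che_by_sex <- function(sim, threshold = 0.40) {
  info <- dplyr::select(tibble::as_tibble(sim$cohort), "id", "sex", "income")
  led <- dplyr::left_join(sim$ledger, info, by = c(person_id = "id"))
  oop <- led$cost_oop_medical + led$cost_oop_transport
  case <- led$disease_state != "no_diabetes" & oop > threshold * led$income
  c(male = sum(case & led$sex == "male"),
    female = sum(case & led$sex == "female"))
}

#' Inflate outcomes to the represented population
#'
#' Multiplies every extensive quantity (costs, DALYs, CHE and
#' impoverishment counts) by a scale factor; intensities and ratios (the
#' per-diabetic mean cost, ICERs) are unchanged.
#'
#' @param summary A `hef_outcome` row from [summarize_outcomes()].
#' @param scale_factor Multiplier (> 0).
#' @return The rescaled `hef_outcome`.
#' @export
scale_results <- function(summary, scale_factor) {
  stopifnot(inherits(summary, "hef_outcome"), scale_factor > 0)
  extensive <- c("total_cost", "cost_government", "cost_oop", "oop_undiscounted",
                 "dalys", "yll", "yld", "yll_diabetes", "yll_complication",
                 "impoverishment", "dalys_male", "dalys_female",
                 "che_40_male", "che_40_female",
                 grep("^che_\\d+$", names(summary), value = TRUE))
  for (col in extensive) summary[[col]] <- summary[[col]] * scale_factor
  summary$scale_factor <- summary$scale_factor * scale_factor
  summary
}

#' Incremental comparison against the current standard
#'
#' Differences every outcome of an intervention run against its comparator
#' (strategies should be simulated on the same cohort with the same seed,
#' i.e. common random numbers) and attaches ICERs per DALY averted and per
#' CHE case averted.
#'
#' @param intervention,comparator `hef_outcome` rows from
#'   [summarize_outcomes()].
#' @return One-row tibble: strategy labels, `delta_cost`, `delta_dalys`
#'   (negative = averted), `delta_che` (at the 40% threshold),
#'   `delta_oop_undiscounted`, `icer_daly`, `icer_daly_status`, `icer_che`,
#'   `icer_che_status`.
#' @export
incremental_result <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "hef_outcome"),
            inherits(comparator, "hef_outcome"))
  delta_cost <- intervention$total_cost - comparator$total_cost
  delta_dalys <- intervention$dalys - comparator$dalys
  delta_che <- intervention$che_40 - comparator$che_40
  delta_oop <- intervention$oop_undiscounted - comparator$oop_undiscounted
  ic_daly <- icer(delta_cost, -delta_dalys)
  ic_che <- icer(delta_cost, -delta_che)
  tibble::tibble(
    strategy = intervention$strategy,
    comparator = comparator$strategy,
    eligibility = intervention$eligibility,
    subsidy = intervention$subsidy,
    delta_cost = delta_cost,
    delta_dalys = delta_dalys,
    delta_che = delta_che,
    delta_oop_undiscounted = delta_oop,
    icer_daly = ic_daly$value,
    icer_daly_status = ic_daly$status,
    icer_che = ic_che$value,
    icer_che_status = ic_che$status
  )
}
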