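#' Tidy a simulation into its person-year ledger
#'
#' @param x A `hef_sim` result.
#' @param ... Unused.
#' @return The person-year ledger tibble, joined with the individual's sex,
#'   age at baseline, income, and HEF status.
#' @method tidy hef_sim
#' @export
tidy.hef_sim <- function(x, ...) {
  dplyr::left_join(
    x$ledger,
    dplyr::select(tibble::as_tibble(x$cohort), "id", "sex", baseline_age = "age",
                  "income", "hef_eligible", "hef_enrolled"),
    by = c(person_id = "id")
  )
}

#' One-row summary of a simulation
#'
#' @param x A `hef_sim` result.
#' @param ... Unused.
#' @return A one-row tibble: strategy, persons, person-years, deaths by
#'   cause, undiscounted cost totals by payer, and total YLD.
#' @method glance hef_sim
#' @export
glance.hef_sim <- function(x, ...) {
  led <- x$ledger
  tibble::tibble(
    strategy = x$strategy$name,
    persons = nrow(x$cohort),
    horizon = x$horizon,
    person_years = nrow(led),
    deaths = nrow(x$deaths),
    deaths_background = sum(x$deaths$cause == "background"),
    deaths_diabetes = sum(x$deaths$cause == "diabetes"),
    deaths_complication = sum(x$deaths$cause == "complication"),
    cost_government = sum(led$cost_government),
    cost_oop = sum(led$cost_oop_medical + led$cost_oop_transport),
    yld = sum(led$yld)
  )
}

#' Tidy an uncertainty analysis
#'
#' @param x A `hef_psa` tibble.
#' @param ... Unused.
#' @return Long format: one row per strategy x cell x outcome with columns
#'   `strategy`, `population_id`, `param_set_id`, `outcome`, `value`.
#' @method tidy hef_psa
#' @export
tidy.hef_psa <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = c("delta_cost", "delta_dalys", "delta_che"),
                      names_to = "outcome", values_to = "value")
}

#' @rdname summarize_uncertainty
#' @param x A `hef_psa` tibble.
#' @param ... Unused.
#' @method glance hef_psa
#' @export
glance.hef_psa <- function(x, ...) {
  summarize_uncertainty(x)
}
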