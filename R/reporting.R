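#' Run one strategy end-to-end
#'
#' Convenience wrapper: sets the eligibility percentile, generates the
#' HEF-eligible cohort, simulates the strategy, and aggregates outcomes.
#' Used by the comparison tables, the command-line front end, and the
#' reproduction script.
#'
#' @param params A validated `hef_params` registry.
#' @param strategy_name One of [strategy_names()].
#' @param n Cohort size (eligible individuals simulated).
#' @param seed Integer seed. The cohort is derived from `seed` and the
#'   simulation from `seed + 1`, so two strategies run with the same `seed`
#'   share both the cohort and the random event stream.
#' @param eligibility,subsidy Strategy configuration.
#' @param scale_factor Persons represented per simulated person.
#' @param horizon Annual cycles.
#' @param cohort Optionally, a pre-built cohort (overrides `n`/`seed`
#'   cohort generation; required when comparing strategies on one cohort).
#' @param keep_events Forwarded to [simulate_cohort()].
#' @return List with `sim` (`hef_sim`), `outcome` (`hef_outcome` row) and
#'   `cohort`.
#' @export
run_strategy <- function(params, strategy_name, n = 16000, seed = 1,
                         eligibility = 0.20, subsidy = 1.00,
                         scale_factor = 20, horizon = 45, cohort = NULL,
                         keep_events = FALSE) {
  params$hef$eligibility_percentile <- eligibility
  strategy <- build_strategy(strategy_name, eligibility, subsidy)
  if (is.null(cohort)) {
    cohort <- generate_cohort(params, n, seed = seed, eligible_only = TRUE,
                              scale_factor = scale_factor)
  }
  sim <- simulate_cohort(cohort, strategy, params, seed = seed + 1L,
                         horizon = horizon, keep_events = keep_events)
  list(sim = sim, outcome = summarize_outcomes(sim, params), cohort = cohort)
}

#' Strategy comparison tables
#'
#' Simulates the requested strategy grid on a common cohort per eligibility
#' level (common random numbers throughout) and assembles the two published
#' table layouts: a health-impact table (total and incremental discounted
#' costs, DALYs, incremental DALYs, ICER per DALY averted; reported at full
#' subsidy) and a financial-risk-protection table (CHE cases at the 40%
#' threshold and ICER per CHE case averted, at each subsidy rate).
#'
#' @param params A validated `hef_params` registry.
#' @param n Eligible individuals simulated per eligibility level.
#' @param seed Integer seed.
#' @param strategies Strategy names to include (the current standard is
#'   always run as comparator).
#' @param eligibility,subsidy Grid levels.
#' @param scale_factor,horizon Forwarded to [run_strategy()].
#' @return List of class `hef_compare`: `daly_table`, `che_table`,
#'   `outcomes` (all raw `hef_outcome` rows).
#' @export
compare_strategies <- function(params, n = 16000, seed = 1,
                               strategies = strategy_names(),
                               eligibility = c(0.20, 0.30),
                               subsidy = c(1.00, 0.80),
                               scale_factor = 20, horizon = 45) {
  strategies <- union("current_standard", strategies)
  outcomes <- list()
  daly_rows <- list()
  che_rows <- list()
  for (el in eligibility) {
    p_el <- params
    p_el$hef$eligibility_percentile <- el
    cohort <- generate_cohort(p_el, n, seed = seed, eligible_only = TRUE,
                              scale_factor = scale_factor)
    base <- run_strategy(p_el, "current_standard", eligibility = el,
                         subsidy = subsidy[1], cohort = cohort, seed = seed,
                         horizon = horizon)$outcome
    for (sn in strategies) {
      for (sb in subsidy) {
        res <- run_strategy(p_el, sn, eligibility = el, subsidy = sb,
                            cohort = cohort, seed = seed, horizon = horizon)
        outcomes[[length(outcomes) + 1L]] <- res$outcome
        inc <- incremental_result(res$outcome, base)
        is_base <- sn == "current_standard"
        if (sb == subsidy[1]) {
          daly_rows[[length(daly_rows) + 1L]] <- tibble::tibble(
            strategy = sn, eligibility = el,
            total_cost = res$outcome$total_cost,
            incremental_cost = if (is_base) NA_real_ else inc$delta_cost,
            dalys = res$outcome$dalys,
            incremental_dalys = if (is_base) NA_real_ else inc$delta_dalys,
            icer_daly = if (is_base) NA_real_ else inc$icer_daly,
            icer_status = if (is_base) NA_character_ else inc$icer_daly_status
          )
        }
        che_rows[[length(che_rows) + 1L]] <- tibble::tibble(
          strategy = sn, eligibility = el, oop_coverage = sb,
          total_cost = res$outcome$total_cost,
          incremental_cost = if (is_base) NA_real_ else inc$delta_cost,
          che = res$outcome$che_40,
          incremental_che = if (is_base) NA_real_ else inc$delta_che,
          icer_che = if (is_base) NA_real_ else inc$icer_che,
          icer_status = if (is_base) NA_character_ else inc$icer_che_status
        )
      }
    }
  }
  structure(list(daly_table = dplyr::bind_rows(daly_rows),
                 che_table = dplyr::bind_rows(che_rows),
                 outcomes = dplyr::bind_rows(outcomes)),
            class = "hef_compare")
}

#' @export
print.hef_compare <- function(x, ...) {
  cat("<hef_compare>\n$daly_table:\n")
  print(x$daly_table)
  cat("$che_table:\n")
  print(x$che_table)
  invisible(x)
}

#' Write run outputs to disk
#'
#' Emits the outcome row as CSV, a compact JSON ledger summary, and a JSON
#' manifest recording the seed, package version, and a parameter hash, so a
#' run can be re-identified and reproduced.
#'
#' @param result A list from [run_strategy()] (or a `hef_compare`).
#' @param params The registry the run used.
#' @param out_dir Output directory, created if absent.
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(result, params, out_dir, prefix = "run") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  manifest <- list(
    package = "hefsim",
    version = as.character(utils::packageVersion("hefsim")),
    parameter_hash = rlang::hash(unclass(params)),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (inherits(result, "hef_compare")) {
    p1 <- file.path(out_dir, paste0(prefix, "_daly_table.csv"))
    p2 <- file.path(out_dir, paste0(prefix, "_che_table.csv"))
    utils::write.csv(result$daly_table, p1, row.names = FALSE)
    utils::write.csv(result$che_table, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  } else {
    p1 <- file.path(out_dir, paste0(prefix, "_outcome.csv"))
    utils::write.csv(result$outcome, p1, row.names = FALSE)
    led <- result$sim$ledger
    summ <- list(
      strategy = result$sim$strategy$name,
      seed = result$sim$seed,
      horizon = result$sim$horizon,
      persons = nrow(result$sim$cohort),
      person_years = nrow(led),
      deaths = nrow(result$sim$deaths),
      total_cost_government = sum(led$cost_government),
      total_cost_oop = sum(led$cost_oop_medical + led$cost_oop_transport),
      total_yld = sum(led$yld)
    )
    p2 <- file.path(out_dir, paste0(prefix, "_ledger_summary.json"))
    jsonlite::write_json(summ, p2, auto_unbox = TRUE, digits = NA)
    manifest$seed <- result$sim$seed
    paths <- c(paths, p1, p2)
  }
  p3 <- file.path(out_dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, p3, auto_unbox = TRUE)
  invisible(c(paths, p3))
}

#' Export a person-year ledger as CSV
#'
#' One row per person-year with the documented schema (see
#' [simulate_cohort()]).
#'
#' @param sim A `hef_sim` result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(sim, path) {
  stopifnot(inherits(sim, "hef_sim"))
  utils::write.csv(sim$ledger, path, row.names = FALSE)
  invisible(path)
}
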