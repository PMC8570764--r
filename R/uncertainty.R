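#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Generates `n_sets` complete parameter registries by drawing each
#' uncertain entry from its configured distribution: costs from their
#' lognormals, probabilities from their betas. Entries without a
#' distribution stay at their point values, and the gamma income spec is
#' left untouched (it describes the population income distribution, not a
#' scalar). Strategy effect modifiers (the diagnosis and care-seeking
#' relative risks and the adherence override) are drawn from normal
#' distributions centred on their base values with variance `rr_variance`,
#' truncated at zero; the adherence draw is additionally capped at 1.
#'
#' @param params The base `hef_params` registry.
#' @param n_sets Number of parameter sets (published design: 50).
#' @param rr_variance Variance of the normal strategy-effect draws
#'   (published design: 0.1).
#' @param seed Integer seed. With a fixed seed, the first `k` sets are
#'   identical whether you request `k` or more (stream stability).
#' @return A list of length `n_sets`; each element has `params` (a
#'   validated `hef_params` with sampled point values) and
#'   `strategy_effects` (named list `rr_diagnosis`, `rr_care_seeking`,
#'   `rr_complication_care`, `adherence_override`).
#' @export
draw_psa_sets <- function(params, n_sets = 50, rr_variance = 0.1, seed = 1) {
  stopifnot(inherits(params, "hef_params"), n_sets >= 1)
  base_strategy_effects <- c(rr_diagnosis = 1.5, rr_care_seeking = 2.0,
                             rr_complication_care = 2.0, adherence_override = 0.40)
  out <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    withr_seed(seed + i)
    p <- sample_registry(params)
    eff <- pmax(rnorm(4, mean = base_strategy_effects, sd = sqrt(rr_variance)), 0)
    names(eff) <- names(base_strategy_effects)
    eff["adherence_override"] <- min(eff["adherence_override"], 1)
    out[[i]] <- list(params = validate_parameters(p),
                     strategy_effects = as.list(eff))
  }
  out
}

## one stochastic realisation of every lognormal/beta entry (point value
## replaced by the draw; distribution spec retained)
sample_registry <- function(params) {
  draw <- function(spec) {
    if (!inherits(spec, "hef_dist") || spec$family %in% c("point", "gamma")) {
      return(spec)
    }
    spec$point <- sample_parameter(spec, 1)
    spec
  }
  p <- params
  for (k in dist_keys_costs) p$costs[[k]] <- draw(p$costs[[k]])
  for (lvl in provider_levels) {
    p$costs$outpatient_visit[[lvl]] <- draw(p$costs$outpatient_visit[[lvl]])
    p$costs$inpatient_day[[lvl]] <- draw(p$costs$inpatient_day[[lvl]])
    p$care$provider_shares[[lvl]] <- draw(p$care$provider_shares[[lvl]])
  }
  for (k in dist_keys_care) p$care[[k]] <- draw(p$care[[k]])
  for (cn in complication_names) {
    spec <- p$complications[[cn]]$cost
    drawn <- draw(spec)
    # per-day cost distributions are specified on the annualized scale
    if (drawn$family != "point" && p$complications[[cn]]$cost_unit == "per_day") {
      drawn$point <- drawn$point / 365
    }
    p$complications[[cn]]$cost <- drawn
  }
  p
}

## override a strategy's non-neutral modifiers with PSA draws
apply_strategy_effects <- function(strategy, effects) {
  if (strategy$covers_diagnostics) {
    strategy$rr_diagnosis <- effects$rr_diagnosis
    strategy$rr_care_seeking <- effects$rr_care_seeking
  }
  if (strategy$covers_drugs) {
    strategy$adherence_override <- effects$adherence_override
  }
  if (strategy$covers_complications) {
    strategy$rr_complication_care <- effects$rr_complication_care
  }
  strategy
}

#' Two-layer uncertainty analysis: parameter draws x population bootstrap
#'
#' Crosses `n_populations` bootstrap resamples of the cohort (sampled with
#' replacement, published design: 100 populations of 40,000) with `n_sets`
#' parameter draws (published design: 50). In each cell every strategy and
#' the current standard are simulated with the same seed (common random
#' numbers) and incremental outcomes are recorded.
#'
#' @param cohort The source `hef_cohort` to resample from.
#' @param strategies A list of `hef_strategy` objects to compare against the
#'   current standard.
#' @param params Base `hef_params` registry.
#' @param n_sets,rr_variance Passed to [draw_psa_sets()].
#' @param n_populations Number of bootstrap populations.
#' @param sample_size Individuals per bootstrap population.
#' @param seed Integer master seed.
#' @param horizon Annual cycles per run.
#' @return A tibble of class `hef_psa`, one row per
#'   strategy x population x parameter set: `strategy`, `population_id`,
#'   `param_set_id`, `delta_cost`, `delta_dalys`, `delta_che`. Scaled by the
#'   cohort scale factor.
#' @export
run_uncertainty <- function(cohort, strategies, params, n_sets = 50,
                            rr_variance = 0.1, n_populations = 100,
                            sample_size = 40000, seed = 1, horizon = 45) {
  stopifnot(inherits(cohort, "hef_cohort"), sample_size >= 1, n_populations >= 1)
  if (inherits(strategies, "hef_strategy")) strategies <- list(strategies)
  psa_sets <- draw_psa_sets(params, n_sets = n_sets, rr_variance = rr_variance,
                            seed = seed)
  comparator <- build_strategy("current_standard",
                               strategies[[1]]$eligibility_percentile,
                               strategies[[1]]$subsidy_rate)
  rows <- list()
  for (b in seq_len(n_populations)) {
    withr_seed(seed + 7919L * b)
    idx <- sample.int(nrow(cohort), sample_size, replace = TRUE)
    boot <- tibble::as_tibble(cohort)[idx, ]
    boot$id <- seq_len(sample_size)
    boot <- structure(boot, class = class(cohort),
                      scale_factor = attr(cohort, "scale_factor"),
                      seed = attr(cohort, "seed"))
    for (s in seq_len(n_sets)) {
      cell_seed <- seed + 100000L * b + s
      p_s <- psa_sets[[s]]$params
      base_sim <- simulate_cohort(boot, comparator, p_s, seed = cell_seed,
                                  horizon = horizon, keep_events = FALSE)
      base_out <- summarize_outcomes(base_sim, p_s)
      for (st in strategies) {
        st_s <- apply_strategy_effects(st, psa_sets[[s]]$strategy_effects)
        sim <- simulate_cohort(boot, st_s, p_s, seed = cell_seed,
                               horizon = horizon, keep_events = FALSE)
        outc <- summarize_outcomes(sim, p_s)
        inc <- incremental_result(outc, base_out)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strategy = st$name, population_id = b, param_set_id = s,
          delta_cost = inc$delta_cost, delta_dalys = inc$delta_dalys,
          delta_che = inc$delta_che
        )
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  class(res) <- c("hef_psa", class(res))
  res
}

#' Percentile summary of an uncertainty analysis
#'
#' 2.5th/97.5th percentile ranges of the incremental outcomes per strategy,
#' plus the fraction of cells in which no DALYs were averted.
#'
#' @param psa A `hef_psa` tibble from [run_uncertainty()].
#' @return A tibble, one row per strategy, with `lo`/`hi` columns per
#'   outcome and `frac_no_daly_gain`.
#' @export
summarize_uncertainty <- function(psa) {
  stopifnot(inherits(psa, "hef_psa"))
  q <- function(x, p) unname(quantile(x, p, type = 7))
  dplyr::summarise(
    dplyr::group_by(psa, .data$strategy),
    n_cells = dplyr::n(),
    delta_cost_lo = q(.data$delta_cost, 0.025),
    delta_cost_hi = q(.data$delta_cost, 0.975),
    delta_dalys_lo = q(.data$delta_dalys, 0.025),
    delta_dalys_hi = q(.data$delta_dalys, 0.975),
    delta_che_lo = q(.data$delta_che, 0.025),
    delta_che_hi = q(.data$delta_che, 0.975),
    frac_no_daly_gain = mean(-.data$delta_dalys <= 0),
    .groups = "drop"
  )
}
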