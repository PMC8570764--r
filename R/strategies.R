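#' HEF benefit-package strategies
#'
#' Seven strategies are compared: the current standard (no financial
#' coverage for diabetes services) and six benefit packages covering
#' combinations of three care segments. Coverage translates into behavioural
#' effect modifiers applied only to enrolled HEF beneficiaries:
#'
#' * diagnostics coverage: relative risk 1.5 on diagnosis conditional on a
#'   visit, 2.0 on outpatient care seeking;
#' * drug coverage: adherence probability replaced by 0.40 (from the 0.125
#'   baseline);
#' * complication coverage: relative risk 2.0 on care seeking (outpatient
#'   and inpatient) for complications.
#'
#' Combined packages carry the union of their components' modifiers.
#'
#' @param name One of `strategy_names()`.
#' @param eligibility_percentile HEF eligibility cutoff as an income
#'   percentile (0.20 or 0.30 in the published analysis; any value in (0,1)
#'   is accepted).
#' @param subsidy_rate Share of covered direct medical costs paid by the
#'   fund (0.80 or 1.00 in the published analysis).
#' @return A list of class `hef_strategy` with fields `name`,
#'   `covers_diagnostics`, `covers_drugs`, `covers_complications`,
#'   `rr_diagnosis`, `rr_care_seeking`, `adherence_override` (or `NA`),
#'   `rr_complication_care`, `eligibility_percentile`, `subsidy_rate`.
#' @examples
#' build_strategy("drug_therapy_only", 0.20, 1.00)
#' @export
build_strategy <- function(name, eligibility_percentile = 0.20,
                           subsidy_rate = 1.00) {
  if (!name %in% strategy_names()) {
    stop("unknown strategy '", name, "'; valid names: ",
         paste(strategy_names(), collapse = ", "), call. = FALSE)
  }
  if (eligibility_percentile <= 0 || eligibility_percentile >= 1) {
    stop("eligibility_percentile must lie in (0, 1)", call. = FALSE)
  }
  if (subsidy_rate < 0 || subsidy_rate > 1) {
    stop("subsidy_rate must lie in [0, 1]", call. = FALSE)
  }
  dx <- grepl("diagnostics", name)
  rx <- grepl("drug", name)
  cx <- grepl("complications", name)
  if (name == "current_standard") dx <- rx <- cx <- FALSE
  structure(list(
    name = name,
    covers_diagnostics = dx,
    covers_drugs = rx,
    covers_complications = cx,
    rr_diagnosis = if (dx) 1.5 else 1.0,
    rr_care_seeking = if (dx) 2.0 else 1.0,
    adherence_override = if (rx) 0.40 else NA_real_,
    rr_complication_care = if (cx) 2.0 else 1.0,
    eligibility_percentile = eligibility_percentile,
    subsidy_rate = subsidy_rate
  ), class = "hef_strategy")
}

#' @rdname build_strategy
#' @export
strategy_names <- function() {
  c("current_standard", "diagnostics_only", "drug_therapy_only",
    "complications_only", "diagnostics_drug", "drug_complications",
    "diagnostics_drug_complications")
}

#' @export
print.hef_strategy <- function(x, ...) {
  cat(sprintf("<hef_strategy %s | eligibility %g%% | subsidy %g%%>\n",
              x$name, 100 * x$eligibility_percentile, 100 * x$subsidy_rate))
  cat(sprintf("  covers: diagnostics=%s drugs=%s complications=%s\n",
              x$covers_diagnostics, x$covers_drugs, x$covers_complications))
  invisible(x)
}

#' Default strategy comparison grid
#'
#' The published design: all seven strategies crossed with eligibility
#' percentiles 0.20/0.30 and subsidy rates 0.80/1.00.
#'
#' @param eligibility Vector of eligibility percentiles.
#' @param subsidy Vector of subsidy rates.
#' @return A tibble with columns `name`, `eligibility`, `subsidy`.
#' @export
strategy_grid <- function(eligibility = c(0.20, 0.30), subsidy = c(0.80, 1.00)) {
  tidyr::expand_grid(name = strategy_names(), eligibility = eligibility,
                     subsidy = subsidy)
}

#' Apply a relative risk to a probability
#'
#' `min(base * rr, 1)`, vectorized.
#'
#' @param base Baseline probability in `[0, 1]`.
#' @param rr Relative risk (>= 0).
#' @return Probability in `[0, 1]`.
#' @examples
#' effective_probability(0.370, 1.5)
#' @export
effective_probability <- function(base, rr) {
  stopifnot(all(base >= 0 & base <= 1), all(rr >= 0))
  pmin(base * rr, 1.0)
}

#' Split a direct medical cost between the fund and the patient
#'
#' For enrolled beneficiaries and a covered care segment, the fund pays
#' `subsidy_rate * cost` and the patient pays the remainder out-of-pocket;
#' otherwise the full cost is out-of-pocket. Government plus out-of-pocket
#' always equals the cost. Transport costs are never split (they are not
#' direct medical costs) and must not be passed here.
#'
#' @param cost Direct medical cost (vectorized, >= 0).
#' @param segment One of `"diagnostics"`, `"drugs"`, `"complications"`,
#'   `"routine_visit"`.
#' @param enrolled Logical vector: is the person an enrolled HEF beneficiary?
#' @param strategy A `hef_strategy`.
#' @return A list with numeric vectors `government` and `oop`.
#' @examples
#' s <- build_strategy("drug_therapy_only", 0.20, 0.80)
#' payer_split(100, "drugs", TRUE, s)
#' @export
payer_split <- function(cost, segment, enrolled, strategy) {
  stopifnot(all(cost >= 0), inherits(strategy, "hef_strategy"))
  segment <- match.arg(segment,
                       c("diagnostics", "drugs", "complications", "routine_visit"))
  covered <- switch(segment,
    diagnostics = strategy$covers_diagnostics,
    # the screening visit itself is part of the diagnostic service package
    routine_visit = strategy$covers_diagnostics,
    drugs = strategy$covers_drugs,
    complications = strategy$covers_complications
  )
  gov_share <- ifelse(enrolled & covered, strategy$subsidy_rate, 0)
  government <- gov_share * cost
  list(government = government, oop = cost - government)
}
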