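# Shared fixtures: parameter variants and hand-built cohorts used to isolate
# single transitions of the engine.

base_params <- load_parameters()

# all stochastic hazards off: nobody dies, nothing happens unless switched on
quiet_params <- function(p = base_params) {
  p$population$all_cause_mortality <- 0
  p$population$diabetes_incidence <- 0
  p$population$diabetes_mortality <- 0
  p$care$p_outpatient_nonhef <- dist_spec("point", point = 0)
  p$care$p_outpatient_hef <- dist_spec("point", point = 0)
  p$care$p_inpatient <- dist_spec("point", point = 0)
  for (cn in names(p$complications)) {
    p$complications[[cn]]$incidence <- 0
    p$complications[[cn]]$case_fatality <- 0
  }
  p
}

# route every provider draw to the health center
hc_only <- function(p) {
  for (lvl in c("cpa1", "cpa2", "cpa3")) {
    p$care$provider_shares[[lvl]] <- dist_spec("point", point = 0)
  }
  p$care$provider_shares$hc <- dist_spec("point", point = 1)
  p
}

# a cohort built by hand, bypassing generate_cohort, to pin initial states
mk_cohort <- function(n, state = "no_diabetes", income = 1000, age = 40,
                      sex = "female", enrolled = FALSE, scale_factor = 1) {
  tbl <- tibble::tibble(
    id = seq_len(n),
    sex = rep_len(sex, n),
    age = rep_len(age, n),
    income = rep_len(income, n),
    hef_eligible = rep_len(enrolled, n),
    hef_enrolled = rep_len(enrolled, n),
    disease_state = rep_len(state, n)
  )
  structure(tbl, class = c("hef_cohort", class(tibble::tibble())),
            scale_factor = scale_factor, seed = 0L)
}

# a strategy object with every modifier neutral and no coverage, used to
# check that an inert package reproduces the current standard exactly
neutral_strategy <- function(name = "diagnostics_only") {
  s <- build_strategy(name, 0.20, 1.00)
  s$covers_diagnostics <- s$covers_drugs <- s$covers_complications <- FALSE
  s$rr_diagnosis <- s$rr_care_seeking <- s$rr_complication_care <- 1.0
  s$adherence_override <- NA_real_
  s
}

current_std <- build_strategy("current_standard", 0.20, 1.00)
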