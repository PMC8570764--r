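#' Run the annual diabetes care microsimulation
#'
#' Simulates each individual of a cohort through `horizon` annual cycles
#' (45 by default) of a discrete-time Markov model that couples the natural
#' history of diabetes with the care delivery pathway. Within a cycle events
#' fire in a fixed order: (1) background all-cause mortality on the
#' age-scaled schedule, (2) diabetes onset among non-diabetics, (3) care
#' seeking and screening/diagnosis among undiagnosed diabetics, (4) therapy
#' switching/assignment and the annual adherence draw, (5) complication
#' incidence modified by glucose control, (6) care seeking and treatment
#' costs for active complications, (7) complication case fatality and
#' diabetes-related mortality, (8) accrual of disability and the person-year
#' ledger row.
#'
#' Glucose control: the complication-specific therapy relative risks apply
#' in adherent treated person-years; diagnosed untreated (diet-consultation)
#' person-years carry the diet relative risk 0.90; undiagnosed and
#' non-adherent person-years are uncontrolled. Diabetes-related mortality
#' (0.030/yr in the base case) applies to diabetic person-years without
#' adherent drug therapy. Acute complications (myocardial infarction,
#' stroke) apply their case fatality in the event year only and persist
#' afterwards as chronic disability; chronic fatal complications
#' (nephropathy, peripheral vascular disease) apply theirs every year while
#' active.
#'
#' Random draws are made in a fixed order and a fixed count per cycle for
#' the whole cohort, so two strategies simulated with the same seed share
#' common random numbers: a strategy that changes no probability and covers
#' no segment reproduces the current standard ledger exactly.
#'
#' @param cohort A `hef_cohort` tibble from [generate_cohort()].
#' @param strategy A `hef_strategy` from [build_strategy()].
#' @param params A validated `hef_params` registry.
#' @param seed Integer seed; the full ledger is bit-reproducible.
#' @param horizon Number of annual cycles (default 45).
#' @param keep_events If `TRUE` (default), record discrete events (onset,
#'   diagnosis, therapy starts, complications, deaths) in an events table.
#' @return An object of class `hef_sim`: a list with
#'   * `ledger`: tibble of person-years (`person_id`, `year` 0-based,
#'     `disease_state`, `cost_government`, `cost_oop_medical`,
#'     `cost_oop_transport`, `yld`), undiscounted costs, one row per person
#'     per year lived (the death year included, later years excluded);
#'   * `deaths`: tibble (`person_id`, `year`, `age_at_death`, `cause` one of
#'     `background`, `diabetes`, `complication`);
#'   * `events`: tibble (`person_id`, `year`, `event`) when `keep_events`;
#'   * `cohort`, `strategy`, `seed`, `horizon`.
#' @examples
#' p <- load_parameters()
#' cohort <- generate_cohort(p, 500, seed = 1)
#' sim <- simulate_cohort(cohort, build_strategy("current_standard"), p, seed = 2)
#' dplyr::summarise(sim$ledger, oop = sum(cost_oop_medical + cost_oop_transport))
#' @export
simulate_cohort <- function(cohort, strategy, params, seed, horizon = 45,
                            keep_events = TRUE) {
  stopifnot(inherits(cohort, "hef_cohort"), inherits(strategy, "hef_strategy"),
            inherits(params, "hef_params"))
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty", call. = FALSE)

  state_levels <- c("no_diabetes", "undiagnosed", "diagnosed_untreated",
                    "on_oad", "on_insulin", "on_combo")
  state <- match(cohort$disease_state, state_levels) - 1L
  if (anyNA(state)) stop("cohort has unknown disease_state values", call. = FALSE)
  age <- cohort$age
  enrolled <- cohort$hef_enrolled
  alive <- rep(TRUE, n)
  comp <- matrix(FALSE, n, 8L, dimnames = list(NULL, complication_names))

  care <- params$care
  cps <- params$complications
  inc <- vapply(cps, function(z) z$incidence, 0)
  rr_thx <- vapply(cps, function(z) z$rr_therapy, 0)
  dw <- vapply(cps, function(z) z$disability_weight, 0)
  cf <- vapply(cps, function(z) z$case_fatality, 0)
  acute <- vapply(cps, function(z) isTRUE(z$acute), NA)
  setting <- vapply(cps, function(z) z$cost_setting, "")
  unit <- vapply(cps, function(z) z$cost_unit, "")
  cost_pt <- vapply(cps, function(z) pv(z$cost), 0)
  op_idx <- which(setting == "outpatient")
  ip_idx <- which(setting == "inpatient")
  # chronic outpatient therapy: per-day drug costs run all year
  op_annual <- ifelse(unit[op_idx] == "per_day", cost_pt[op_idx] * 365,
                      cost_pt[op_idx])
  ip_daily <- ifelse(unit[ip_idx] == "per_day", cost_pt[ip_idx],
                     cost_pt[ip_idx] / 365)
  los <- care$los_days

  out_cost <- vapply(provider_levels,
                     function(l) pv(params$costs$outpatient_visit[[l]]), 0)
  inp_day <- vapply(provider_levels,
                    function(l) pv(params$costs$inpatient_day[[l]]), 0)
  shares <- vapply(provider_levels,
                   function(l) pv(params$care$provider_shares[[l]]), 0)
  # printed shares are population proportions; condition on a public visit
  cum_shares <- cumsum(shares / sum(shares))
  fpg <- pv(params$costs$diagnostics)
  lab <- pv(params$costs$laboratory)
  tr_out <- pv(params$costs$transport_outpatient)
  tr_in <- pv(params$costs$transport_inpatient)
  oad_cost <- pv(params$costs$oad_annual)
  ins_cost <- pv(params$costs$insulin_annual)

  p_out_base <- ifelse(enrolled, pv(care$p_outpatient_hef),
                       pv(care$p_outpatient_nonhef))
  p_inpat <- pv(care$p_inpatient)
  p_diag <- pv(care$p_diagnosis)
  p_onset <- params$population$diabetes_incidence
  p_dm_mort <- params$population$diabetes_mortality
  dw_base <- params$disability$uncomplicated
  dw_undx <- isTRUE(params$disability$dw_undiagnosed_counts)

  rr_seek <- ifelse(enrolled, strategy$rr_care_seeking, 1)
  rr_dx <- ifelse(enrolled, strategy$rr_diagnosis, 1)
  rr_compcare <- ifelse(enrolled, strategy$rr_complication_care, 1)
  p_adh <- ifelse(enrolled & strategy$covers_drugs, strategy$adherence_override,
                  care$p_adherence)
  # benefit share of covered direct medical costs (point-of-service
  # utilization scales the claimed share)
  benefit <- strategy$subsidy_rate * params$hef$utilization
  cover_dx <- enrolled & strategy$covers_diagnostics
  cover_rx <- enrolled & strategy$covers_drugs
  cover_cx <- enrolled & strategy$covers_complications

  led <- vector("list", horizon)
  death_rows <- list()
  event_rows <- list()
  push_event <- function(mask, yr, label) {
    if (keep_events && any(mask)) {
      event_rows[[length(event_rows) + 1L]] <<-
        list(person_id = which(mask), year = yr, event = label)
    }
  }

  withr_seed(seed)
  for (yr in seq_len(horizon) - 1L) {
    at_risk <- alive
    if (!any(at_risk)) break
    # fixed draw order and count: common random numbers across strategies
    u_bg <- runif(n); u_onset <- runif(n); u_visit <- runif(n)
    u_prov <- runif(n); u_diag <- runif(n); u_thx <- runif(n)
    u_switch <- runif(n); u_adh <- runif(n)
    u_comp <- matrix(runif(n * 8L), n, 8L)
    u_opcare <- runif(n); u_ipcare <- runif(n)
    u_cf <- matrix(runif(n * 8L), n, 8L)
    u_dm <- runif(n)

    gov <- numeric(n); med <- numeric(n); trn <- numeric(n)

    ## 1. background mortality
    die_bg <- at_risk & u_bg < background_mortality(age, params)
    alive_now <- at_risk & !die_bg

    ## 2. diabetes onset
    onset <- alive_now & state == 0L & u_onset < p_onset
    state[onset] <- 1L
    push_event(onset, yr, "onset")

    ## 3. screening visit and diagnosis (undiagnosed only)
    visit <- alive_now & state == 1L &
      u_visit < pmin(p_out_base * rr_seek, 1)
    level <- findInterval(u_prov, cum_shares) + 1L
    level[level > 4L] <- 4L
    if (any(visit)) {
      vcost <- out_cost[level]
      gov_share_visit <- ifelse(cover_dx, benefit, 0)
      scr <- vcost + fpg + lab          # visit + FPG test + laboratory
      gov[visit] <- gov[visit] + gov_share_visit[visit] * scr[visit]
      med[visit] <- med[visit] + (1 - gov_share_visit[visit]) * scr[visit]
      trn[visit] <- trn[visit] + tr_out
    }
    diagnosed <- visit & u_diag < pmin(p_diag * rr_dx, 1)
    state[diagnosed] <- 2L
    push_event(diagnosed, yr, "diagnosis")

    ## 4. therapy: existing OAD users may switch; the newly diagnosed are
    ## assigned a regimen; everyone treated draws adherence for the year
    sw <- alive_now & state == 3L & !diagnosed & u_switch < care$p_oad_to_insulin
    state[sw] <- 4L
    push_event(sw, yr, "switch_to_insulin")
    new_oad <- diagnosed & u_thx < care$p_oad
    new_ins <- diagnosed & u_thx >= care$p_oad &
      u_thx < care$p_oad + care$p_insulin
    new_combo <- diagnosed & u_thx >= care$p_oad + care$p_insulin &
      u_thx < care$p_oad + care$p_insulin + care$p_combo
    state[new_oad] <- 3L; state[new_ins] <- 4L; state[new_combo] <- 5L
    push_event(new_oad, yr, "start_oad")
    push_event(new_ins | new_combo, yr, "start_insulin")

    treated <- alive_now & state >= 3L
    adherent <- treated & u_adh < p_adh
    drug_cost <- numeric(n)
    drug_cost[adherent & state == 3L] <- oad_cost
    drug_cost[adherent & state == 4L] <- ins_cost
    drug_cost[adherent & state == 5L] <- oad_cost + ins_cost
    gov_share_rx <- ifelse(cover_rx, benefit, 0)
    gov <- gov + gov_share_rx * drug_cost
    med <- med + (1 - gov_share_rx) * drug_cost

    ## 5. complication incidence
    diabetic <- alive_now & state >= 1L
    ctrl <- rep(1, n)
    ctrl[alive_now & state == 2L] <- care$rr_diet
    new_comp <- matrix(FALSE, n, 8L)
    for (j in seq_len(8L)) {
      mj <- ctrl
      mj[adherent] <- rr_thx[j]
      hit <- diabetic & !comp[, j] & u_comp[, j] < inc[j] * mj
      new_comp[, j] <- hit
      push_event(hit, yr, paste0("complication:", complication_names[j]))
    }
    comp <- comp | new_comp

    ## 6. complication care and costs
    gov_share_cx <- ifelse(cover_cx, benefit, 0)
    has_op <- rowSums(comp[, op_idx, drop = FALSE]) > 0
    opcare <- alive_now & has_op &
      u_opcare < pmin(p_out_base * rr_compcare, 1)
    if (any(opcare)) {
      # a treated year costs the complication therapies themselves (the
      # published treated-year example carries no separate facility fee)
      ccost <- drop(comp[, op_idx, drop = FALSE] %*% op_annual)
      gov[opcare] <- gov[opcare] + gov_share_cx[opcare] * ccost[opcare]
      med[opcare] <- med[opcare] + (1 - gov_share_cx[opcare]) * ccost[opcare]
      trn[opcare] <- trn[opcare] + tr_out
    }
    has_ip <- rowSums(comp[, ip_idx, drop = FALSE]) > 0
    ipcare <- alive_now & has_ip &
      u_ipcare < pmin(p_inpat * rr_compcare, 1)
    if (any(ipcare)) {
      ip_drug <- drop(comp[, ip_idx, drop = FALSE] %*% ip_daily)
      icost <- (inp_day[level] + ip_drug) * los
      gov[ipcare] <- gov[ipcare] + gov_share_cx[ipcare] * icost[ipcare]
      med[ipcare] <- med[ipcare] + (1 - gov_share_cx[ipcare]) * icost[ipcare]
      trn[ipcare] <- trn[ipcare] + tr_in
    }

    ## 7. mortality from complications and diabetes
    die_comp <- rep(FALSE, n)
    for (j in seq_len(8L)) {
      if (cf[j] <= 0) next
      exposed <- if (acute[j]) new_comp[, j] else comp[, j]
      die_comp <- die_comp | (alive_now & exposed & u_cf[, j] < cf[j])
    }
    die_dm <- alive_now & !die_comp & diabetic & !adherent & u_dm < p_dm_mort

    ## 8. disability accrual and ledger
    survived <- alive_now & !die_comp & !die_dm
    base_w <- ifelse(state >= 2L | (state == 1L & dw_undx), dw_base, 0)
    prod_h <- rep(1, n)
    for (j in seq_len(8L)) {
      prod_h[comp[, j]] <- prod_h[comp[, j]] * (1 - dw[j])
    }
    yld <- ifelse(survived, 1 - (1 - base_w) * prod_h, 0)

    if (any(die_bg)) push_event(die_bg, yr, "death_background")
    if (any(die_dm)) push_event(die_dm, yr, "death_diabetes")
    if (any(die_comp)) push_event(die_comp, yr, "death_complication")
    dead_now <- die_bg | die_comp | die_dm
    if (any(dead_now)) {
      cause <- character(sum(dead_now))
      idx <- which(dead_now)
      cause[die_bg[idx]] <- "background"
      cause[die_comp[idx]] <- "complication"
      cause[die_dm[idx]] <- "diabetes"
      death_rows[[length(death_rows) + 1L]] <- list(
        person_id = idx, year = yr, age_at_death = age[idx], cause = cause
      )
    }

    keep <- which(at_risk)
    led[[yr + 1L]] <- list(
      person_id = keep, year = yr, disease_state = state[keep],
      cost_government = gov[keep], cost_oop_medical = med[keep],
      cost_oop_transport = trn[keep], yld = yld[keep]
    )
    alive <- survived
    age <- age + 1
  }

  led <- led[!vapply(led, is.null, NA)]
  ledger <- tibble::tibble(
    person_id = unlist(lapply(led, `[[`, "person_id"), use.names = FALSE),
    year = rep(vapply(led, function(z) z$year[1] %||% 0L, 0L),
               vapply(led, function(z) length(z$person_id), 0L)),
    disease_state = state_levels[
      unlist(lapply(led, `[[`, "disease_state"), use.names = FALSE) + 1L],
    cost_government = unlist(lapply(led, `[[`, "cost_government"), use.names = FALSE),
    cost_oop_medical = unlist(lapply(led, `[[`, "cost_oop_medical"), use.names = FALSE),
    cost_oop_transport = unlist(lapply(led, `[[`, "cost_oop_transport"), use.names = FALSE),
    yld = unlist(lapply(led, `[[`, "yld"), use.names = FALSE)
  )
  deaths <- if (length(death_rows) > 0) {
    tibble::tibble(
      person_id = unlist(lapply(death_rows, `[[`, "person_id"), use.names = FALSE),
      year = rep(vapply(death_rows, `[[`, 0L, "year"),
                 vapply(death_rows, function(z) length(z$person_id), 0L)),
      age_at_death = unlist(lapply(death_rows, `[[`, "age_at_death"), use.names = FALSE),
      cause = unlist(lapply(death_rows, `[[`, "cause"), use.names = FALSE)
    )
  } else {
    tibble::tibble(person_id = integer(), year = integer(),
                   age_at_death = numeric(), cause = character())
  }
  events <- if (keep_events) {
    if (length(event_rows) > 0) {
      tibble::tibble(
        person_id = unlist(lapply(event_rows, `[[`, "person_id"), use.names = FALSE),
        year = rep(vapply(event_rows, `[[`, 0L, "year"),
                   vapply(event_rows, function(z) length(z$person_id), 0L)),
        event = rep(vapply(event_rows, `[[`, "", "event"),
                    vapply(event_rows, function(z) length(z$person_id), 0L))
      )
    } else {
      tibble::tibble(person_id = integer(), year = integer(), event = character())
    }
  } else {
    NULL
  }

  structure(list(ledger = ledger, deaths = deaths, events = events,
                 cohort = cohort, strategy = strategy, seed = seed,
                 horizon = horizon),
            class = "hef_sim")
}

#' @export
print.hef_sim <- function(x, ...) {
  cat(sprintf("<hef_sim: %s | %d persons x %d cycles | %d person-years, %d deaths>\n",
              x$strategy$name, nrow(x$cohort), x$horizon, nrow(x$ledger),
              nrow(x$deaths)))
  invisible(x)
}
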