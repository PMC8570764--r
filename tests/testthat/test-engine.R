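test_that("with all hazards off everyone survives 45 cycles at zero cost", {
  p <- quiet_params()
  cohort <- mk_cohort(3)
  sim <- simulate_cohort(cohort, current_std, p, seed = 1)
  expect_equal(nrow(sim$ledger), 3 * 45)
  expect_equal(sum(sim$ledger$cost_government), 0)
  expect_equal(sum(sim$ledger$cost_oop_medical), 0)
  expect_equal(sum(sim$ledger$cost_oop_transport), 0)
  expect_equal(sum(sim$ledger$yld), 0)
  expect_equal(nrow(sim$deaths), 0)
  expect_error(simulate_cohort(cohort[0, ], current_std, p, seed = 1), "empty")
})

test_that("ledgers are bit-reproducible and a neutral package equals the current standard", {
  cohort <- generate_cohort(base_params, 2000, seed = 4, eligible_only = TRUE)
  a <- simulate_cohort(cohort, current_std, base_params, seed = 9)
  b <- simulate_cohort(cohort, current_std, base_params, seed = 9)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$events, b$events)

  # all modifiers neutral, nothing covered: same event stream, same money
  z <- simulate_cohort(cohort, neutral_strategy(), base_params, seed = 9)
  expect_identical(z$ledger, a$ledger)
  expect_identical(z$deaths, a$deaths)
})

test_that("person-time is conserved: records = min(death year + 1, horizon)", {
  cohort <- generate_cohort(base_params, 3000, seed = 12, eligible_only = TRUE)
  sim <- simulate_cohort(cohort, current_std, base_params, seed = 13)
  rec <- dplyr::count(sim$ledger, person_id)
  expected <- rep(45L, nrow(cohort))
  expected[sim$deaths$person_id] <- sim$deaths$year + 1L
  expect_equal(rec$n[order(rec$person_id)],
               expected[sort(unique(sim$ledger$person_id))])
  # nobody appears after death, and everyone appears
  expect_setequal(unique(sim$ledger$person_id), seq_len(nrow(cohort)))
  # at most one death per person
  expect_false(any(duplicated(sim$deaths$person_id)))
  # per-year disability is a proper fraction and costs are non-negative
  expect_true(all(sim$ledger$yld >= 0 & sim$ledger$yld <= 1))
  expect_true(all(sim$ledger$cost_oop_medical >= 0))
  expect_true(all(sim$ledger$cost_government >= 0))
})

test_that("single Bernoulli steps match their configured rates within 3 SE", {
  n <- 100000
  # screening care-seeking at 0.117 among undiagnosed non-beneficiaries
  p <- quiet_params()
  p$care$p_outpatient_nonhef <- dist_spec("point", point = 0.117)
  cohort <- mk_cohort(n, state = "undiagnosed")
  sim <- simulate_cohort(cohort, current_std, p, seed = 31, horizon = 1)
  visited <- sum(sim$ledger$cost_oop_transport > 0)
  se <- sqrt(n * 0.117 * (1 - 0.117))
  expect_lt(abs(visited - n * 0.117), 3 * se)

  # first-year MI hazard under adherent OAD therapy: 0.174 * 0.39
  p <- quiet_params()
  p$care$p_adherence <- 1
  p$complications$mi$incidence <- 0.174
  p$complications$mi$case_fatality <- 0
  cohort <- mk_cohort(n, state = "on_oad")
  sim <- simulate_cohort(cohort, current_std, p, seed = 32, horizon = 1)
  mi <- sum(sim$events$event == "complication:mi")
  rate <- 0.174 * 0.39
  expect_lt(abs(mi - n * rate), 3 * sqrt(n * rate * (1 - rate)))
})

test_that("care events carry the published unit costs", {
  # screening visit at a health center: 4.15 + 1.10 + 1.41 medical, 0.92 transport
  p <- hc_only(quiet_params())
  p$care$p_outpatient_nonhef <- dist_spec("point", point = 1)
  p$care$p_diagnosis <- dist_spec("point", point = 1)
  p$care$p_oad <- 0; p$care$p_insulin <- 0; p$care$p_combo <- 0
  cohort <- mk_cohort(1, state = "undiagnosed")
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, 4.15 + 1.10 + 1.41)
  expect_equal(sim$ledger$cost_oop_transport, 0.92)
  expect_equal(sim$ledger$disease_state, "diagnosed_untreated")
  expect_equal(sim$ledger$yld, 0.049)
  expect_true("diagnosis" %in% sim$events$event)

  # adherent combination therapy: OAD + insulin annual costs
  p <- quiet_params()
  p$care$p_adherence <- 1
  cohort <- mk_cohort(1, state = "on_combo")
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, 27.86 + 125.80)
  cohort <- mk_cohort(1, state = "on_oad")
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, 27.86)
  # non-adherent patients do not purchase therapy
  p$care$p_adherence <- 0
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, 0)

  # a treated nephropathy year costs the annual hemodialysis price + visit
  p <- hc_only(quiet_params())
  p$complications$nephropathy$incidence <- 1
  p$care$p_outpatient_nonhef <- dist_spec("point", point = 1)
  p$care$rr_diet <- 1
  cohort <- mk_cohort(1, state = "diagnosed_untreated")
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, 6358)
  expect_equal(sim$ledger$cost_oop_transport, 0.92)
  # diabetes + nephropathy disability combine multiplicatively
  expect_equal(sim$ledger$yld, 1 - (1 - 0.049) * (1 - 0.569))

  # an inpatient episode: (facility per-day + drug per-day) * LOS + transport
  p <- hc_only(quiet_params())
  p$complications$mi$incidence <- 1
  p$care$p_inpatient <- dist_spec("point", point = 1)
  cohort <- mk_cohort(1, state = "undiagnosed")
  sim <- simulate_cohort(cohort, current_std, p, seed = 2, horizon = 1)
  expect_equal(sim$ledger$cost_oop_medical, (4.77 + 7.07) * 5)
  expect_equal(sim$ledger$cost_oop_transport, 11.65)
})

test_that("mortality pathways fire as specified", {
  # an acute MI with certain case fatality kills in the event year
  p <- quiet_params()
  p$complications$mi$incidence <- 1
  p$complications$mi$case_fatality <- 1
  cohort <- mk_cohort(50, state = "undiagnosed")
  sim <- simulate_cohort(cohort, current_std, p, seed = 3)
  expect_equal(nrow(sim$ledger), 50)  # one record each, year 0
  expect_true(all(sim$deaths$cause == "complication"))
  expect_equal(nrow(sim$deaths), 50)

  # but an acute complication is only lethal in its event year
  p$complications$mi$case_fatality <- 0.5
  sim <- simulate_cohort(cohort, current_std, p, seed = 3)
  expect_true(all(sim$deaths$year == 0))

  # chronic nephropathy keeps killing while active
  p <- quiet_params()
  p$complications$nephropathy$incidence <- 1
  p$complications$nephropathy$case_fatality <- 0.311
  sim <- simulate_cohort(mk_cohort(200, state = "undiagnosed"), current_std,
                         p, seed = 4, horizon = 10)
  expect_gt(length(unique(sim$deaths$year)), 3)

  # non-fatal complications (retinopathy) never kill
  p <- quiet_params()
  p$complications$retinopathy$incidence <- 1
  sim <- simulate_cohort(mk_cohort(100, state = "undiagnosed"), current_std,
                         p, seed = 5, horizon = 5)
  expect_equal(nrow(sim$deaths), 0)

  # diabetes-related mortality spares person-years with adherent drug therapy
  p <- quiet_params()
  p$population$diabetes_mortality <- 1
  p$care$p_adherence <- 1
  sim <- simulate_cohort(mk_cohort(20, state = "on_oad"), current_std, p,
                         seed = 6, horizon = 3)
  expect_equal(nrow(sim$deaths), 0)
  p$care$p_adherence <- 0
  sim <- simulate_cohort(mk_cohort(20, state = "on_oad"), current_std, p,
                         seed = 6, horizon = 3)
  expect_equal(nrow(sim$deaths), 20)
  expect_true(all(sim$deaths$cause == "diabetes"))
  expect_true(all(sim$deaths$year == 0))
})

test_that("drug coverage cannot increase complication events under common random numbers", {
  # equal person-time (no mortality) isolates the glucose-control pathway
  p <- base_params
  p$population$all_cause_mortality <- 0
  p$population$diabetes_mortality <- 0
  for (cn in names(p$complications)) p$complications[[cn]]$case_fatality <- 0
  cohort <- generate_cohort(p, 4000, seed = 8, eligible_only = TRUE)
  drug <- build_strategy("drug_therapy_only", 0.20, 1.00)
  s0 <- simulate_cohort(cohort, current_std, p, seed = 44)
  s1 <- simulate_cohort(cohort, drug, p, seed = 44)
  n0 <- sum(grepl("^complication:", s0$events$event))
  n1 <- sum(grepl("^complication:", s1$events$event))
  expect_lte(n1, n0)
  expect_equal(nrow(s0$ledger), nrow(s1$ledger))
})

test_that("payer conservation holds on a full stochastic run", {
  # under full coverage the fund picks up exactly the covered medical costs;
  # re-running the same events uncovered yields the same gross spending
  p <- base_params
  cohort <- generate_cohort(p, 2000, seed = 18, eligible_only = TRUE)
  full <- build_strategy("diagnostics_drug_complications", 0.20, 0.80)
  s0 <- simulate_cohort(cohort, current_std, p, seed = 19)
  s1 <- simulate_cohort(cohort, full, p, seed = 19)
  # no negative payer shares anywhere
  expect_true(all(s1$ledger$cost_government >= 0))
  expect_true(all(s1$ledger$cost_oop_medical >= 0))
  # coverage changes who pays and (for beneficiaries) behaviour; for
  # non-enrolled individuals the person-year ledgers must be identical
  non_enr <- which(!cohort$hef_enrolled)
  l0 <- dplyr::filter(s0$ledger, person_id %in% non_enr)
  l1 <- dplyr::filter(s1$ledger, person_id %in% non_enr)
  expect_identical(l0, l1)
  expect_true(all(l1$cost_government == 0))
})
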