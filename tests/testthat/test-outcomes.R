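# a hand-built simulation result, for boundary arithmetic on the aggregators
mk_sim <- function(ledger, deaths = NULL, cohort = NULL,
                   strategy = current_std) {
  if (is.null(deaths)) {
    deaths <- tibble::tibble(person_id = integer(), year = integer(),
                             age_at_death = numeric(), cause = character())
  }
  if (is.null(cohort)) cohort <- mk_cohort(max(ledger$person_id))
  structure(list(ledger = ledger, deaths = deaths, events = NULL,
                 cohort = cohort, strategy = strategy, seed = 0L, horizon = 45),
            class = "hef_sim")
}

led_row <- function(person_id, year = 0, state = "undiagnosed", gov = 0,
                    med = 0, trn = 0, yld = 0) {
  tibble::tibble(person_id = person_id, year = year, disease_state = state,
                 cost_government = gov, cost_oop_medical = med,
                 cost_oop_transport = trn, yld = yld)
}

test_that("YLL uses remaining life expectancy for diabetes-attributable deaths only", {
  cohort <- mk_cohort(3, sex = c("male", "female", "female"))
  deaths <- tibble::tibble(
    person_id = 1:3, year = c(5L, 10L, 3L),
    age_at_death = c(67, 61, 50),
    cause = c("diabetes", "complication", "background")
  )
  sim <- mk_sim(led_row(1:3), deaths, cohort)
  d <- compute_dalys(sim, base_params)
  # male dying exactly at male life expectancy: zero YLL
  expect_equal(d$yll_diabetes, 0)
  # female at 61: 71 - 61 = 10; background death contributes nothing
  expect_equal(d$yll_complication, 10)
  expect_equal(d$yll, 10)
  expect_equal(d$dalys, d$yll + d$yld)
})

test_that("YLD sums the ledger's per-year disability", {
  led <- led_row(c(1, 1, 2), year = c(0, 1, 0), state = "diagnosed_untreated",
                 yld = c(0.049, 0.049, 1 - (1 - 0.049) * (1 - 0.588)))
  d <- compute_dalys(mk_sim(led, cohort = mk_cohort(2)), base_params)
  expect_equal(d$yld, 2 * 0.049 + 0.6082, tolerance = 1e-4)
  expect_equal(d$yll, 0)
})

test_that("DALYs are additive over disjoint subcohorts", {
  cohort <- generate_cohort(base_params, 1000, seed = 50, eligible_only = TRUE)
  sim <- simulate_cohort(cohort, current_std, base_params, seed = 51)
  whole <- compute_dalys(sim, base_params)
  split_ids <- sim$cohort$id <= 500
  part <- function(ids) {
    s <- sim
    s$ledger <- dplyr::filter(sim$ledger, person_id %in% ids)
    s$deaths <- dplyr::filter(sim$deaths, person_id %in% ids)
    compute_dalys(s, base_params)
  }
  a <- part(which(split_ids)); b <- part(which(!split_ids))
  expect_equal(a$dalys + b$dalys, whole$dalys)
  expect_equal(a$yll + b$yll, whole$yll)
})

test_that("discounting follows 1/(1+r)^t with year zero undiscounted", {
  expect_equal(discounted_cost(100, 0, 0.03), 100)
  expect_equal(discounted_cost(100, 2, 0.03), 94.26, tolerance = 1e-4)
  expect_equal(discounted_cost(100, 5, 0), 100)
  expect_error(discounted_cost(100, 1, -1.5), "exceed")
})

test_that("CHE counting is strict, per person-year, and threshold-monotone", {
  cohort <- mk_cohort(3, state = "undiagnosed", income = 1000)
  led <- led_row(1:3, state = "undiagnosed", med = c(401, 400, 0))
  sim <- mk_sim(led, cohort = cohort)
  expect_equal(che_cases(sim, 0.40), 1)   # 401 > 400: catastrophic
  # 400 is not strictly above the threshold; zero OOP never counts
  expect_equal(che_cases(sim, 0.10), 2)
  expect_error(che_cases(sim, 0), "strictly")

  # non-diabetic person-years are excluded
  led_nd <- led_row(1, state = "no_diabetes", med = 999)
  expect_equal(che_cases(mk_sim(led_nd, cohort = cohort), 0.40), 0)

  # monotone in threshold on a stochastic ledger
  c2 <- generate_cohort(base_params, 2000, seed = 60, eligible_only = TRUE)
  s2 <- simulate_cohort(c2, current_std, base_params, seed = 61)
  expect_gte(che_cases(s2, 0.10), che_cases(s2, 0.25))
  expect_gte(che_cases(s2, 0.25), che_cases(s2, 0.40))
})

test_that("CHE and OOP are non-increasing in the subsidy rate under common random numbers", {
  p <- base_params
  cohort <- generate_cohort(p, 3000, seed = 70, eligible_only = TRUE)
  sims <- lapply(list(current_std,
                      build_strategy("diagnostics_drug_complications", 0.20, 0.80),
                      build_strategy("diagnostics_drug_complications", 0.20, 1.00)),
                 function(s) simulate_cohort(cohort, s, p, seed = 71))
  che <- vapply(sims, che_cases, 0, threshold = 0.40)
  oop <- vapply(sims, function(s)
    sum(s$ledger$cost_oop_medical + s$ledger$cost_oop_transport), 0)
  # full subsidy <= partial subsidy (identical event stream, cheaper OOP)
  expect_lte(che[3], che[2])
  expect_lte(oop[3], oop[2])
})

test_that("impoverishment counts crossings of the poverty line only", {
  line <- 1.90 * 365
  cohort <- mk_cohort(3, state = "undiagnosed", income = c(700, 650, 10000))
  led <- led_row(1:3, med = c(20, 50, 100))
  sim <- mk_sim(led, cohort = cohort)
  expect_equal(impoverishment_cases(sim, base_params), 1)
  expect_lt(650, line)   # already poor: cannot be pushed below
  expect_gt(10000 - 100, line)
})

test_that("ICERs round to the dollar and classify dominance", {
  expect_equal(icer(1041566, 38404)$value, 27)
  expect_equal(icer(142898661, 38341)$value, 3727)
  d <- icer(-1212155, 38404)
  expect_equal(d$value, -32)
  expect_equal(d$status, "dominant")
  expect_equal(icer(1041566, 479260)$value, 2)
  dom <- icer(5000, 0)
  expect_true(is.na(dom$value))
  expect_equal(dom$status, "dominated")
  expect_equal(icer(-10, 0)$status, "undefined")
})

test_that("scaling inflates extensive quantities and leaves ratios unchanged", {
  cohort <- generate_cohort(base_params, 1500, seed = 80, eligible_only = TRUE,
                            scale_factor = 1)
  s0 <- simulate_cohort(cohort, current_std, base_params, seed = 81)
  s1 <- simulate_cohort(cohort, build_strategy("drug_therapy_only", 0.20, 1),
                        base_params, seed = 81)
  o0 <- summarize_outcomes(s0, base_params)
  o1 <- summarize_outcomes(s1, base_params)
  o0s <- scale_results(o0, 20)
  o1s <- scale_results(o1, 20)
  expect_equal(o0s$dalys, 20 * o0$dalys)
  expect_equal(o0s$che_40, 20 * o0$che_40)
  expect_equal(o0s$total_cost, 20 * o0$total_cost)
  expect_equal(o0s$mean_annual_cost_per_diabetic, o0$mean_annual_cost_per_diabetic)
  expect_identical(scale_results(o0, 1)$dalys, o0$dalys)
  # ICER invariance under common scaling
  i_raw <- incremental_result(o1, o0)
  i_scl <- incremental_result(o1s, o0s)
  expect_equal(i_scl$icer_daly, i_raw$icer_daly)
  expect_equal(i_scl$delta_cost, 20 * i_raw$delta_cost)
})

test_that("outcome summaries balance their own accounting identities", {
  cohort <- generate_cohort(base_params, 2000, seed = 90, eligible_only = TRUE)
  sim <- simulate_cohort(cohort, build_strategy("diagnostics_drug", 0.20, 0.80),
                         base_params, seed = 91)
  o <- summarize_outcomes(sim, base_params)
  expect_equal(o$total_cost, o$cost_government + o$cost_oop)
  expect_equal(o$dalys, o$yll + o$yld)
  expect_equal(o$yll, o$yll_diabetes + o$yll_complication)
  expect_equal(o$dalys, o$dalys_male + o$dalys_female)
  expect_equal(o$che_40, o$che_40_male + o$che_40_female)
  expect_gte(o$che_10, o$che_25)
  expect_gte(o$che_25, o$che_40)
})
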