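# a profile with all mortality and incidence switched off, for the
# closed-form reward checks
zeroed_params <- function(discount = 0, horizon = 100) {
  p <- base_params()
  p$life_table$female <- 0
  p$life_table$male <- 0
  p$ec_mortality$ls_per_1000py <- 0
  p$ec_mortality$sporadic_by_age$rate_per_1000py <- 0
  p$crc$incidence_ls$rate <- 0
  p$crc$incidence_general$rate <- 0
  p$crc$mortality_general$early <- 0
  p$crc$mortality_general$late <- 0
  p$discount_rate_annual <- discount
  p$horizon_age <- horizon
  p
}

flat_utility <- function(p) {
  p$utilities$norms$female <- 1
  p$utilities$norms$male <- 1
  p
}

test_that("rate/probability and discounting closed forms", {
  expect_equal(rate_to_prob(0, 1 / 12), 0)
  expect_equal(rate_to_prob(0.004, 1 / 12), 1 - exp(-0.004 / 12))
  expect_equal(signif(rate_to_prob(0.004, 1 / 12), 5), 0.00033328)
  expect_equal(signif(rate_to_prob(0.0921, 1 / 12), 5), 0.0076456)
  expect_error(rate_to_prob(-0.1, 1), "non-negative")

  expect_equal(discount_factor(0.035, 0), 1)
  expect_equal(discount_factor(0.035, 12), 1 / 1.035)
  expect_equal(round(discount_factor(0.035, 12), 6), 0.966184)
  expect_equal(discount_factor(0, 240), 1)
})

test_that("transition matrix limits: zero rates, null surveillance effect,
           LS mortality hazard ratio", {
  p <- zeroed_params()
  pr <- markov_profile(FALSE, surveillance = FALSE, is_proband = FALSE)
  m <- build_transition_matrix(pr, 60, p)
  expect_equal(m, diag(6), ignore_attr = TRUE)

  # HR = 1 removes the incidence difference between arms for carriers
  p2 <- base_params()
  p2$crc$surveillance_incidence_hr <- 1
  prs <- markov_profile(TRUE, "MLH1", TRUE, FALSE)
  prn <- markov_profile(TRUE, "MLH1", FALSE, FALSE)
  ms <- build_transition_matrix(prs, 60, p2)
  mn <- build_transition_matrix(prn, 60, p2)
  # total CRC inflow identical; only the stage split differs
  expect_equal(ms[1, 2] + ms[1, 3], mn[1, 2] + mn[1, 3], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ms[1, 3], mn[1, 3])))

  # LS vs non-LS stage I-III monthly CRC death probability ratio -> 0.66
  p3 <- base_params()
  m_ls <- build_transition_matrix(markov_profile(TRUE, "MLH1", TRUE, FALSE),
                                  60, p3)
  m_sp <- build_transition_matrix(markov_profile(FALSE, NA, TRUE, FALSE),
                                  60, p3)
  expect_equal(m_ls[2, 4] / m_sp[2, 4], 0.66, tolerance = 0.01)

  # row-stochasticity on assorted profiles/ages
  for (a in c(30, 60, 90)) {
    m <- build_transition_matrix(markov_profile(TRUE, "MSH6", FALSE, TRUE),
                                 a, p3)
    expect_equal(rowSums(m), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("reward closed forms: QALY accrual, geometric-series life
           expectancy, colonoscopy schedule", {
  # no mortality, utility 1, no discounting, 12 cycles -> exactly 1 QALY
  p <- flat_utility(zeroed_params(discount = 0, horizon = 61))
  pr <- markov_profile(FALSE, surveillance = FALSE, is_proband = FALSE)
  tr <- run_cohort(pr, 60, p)
  expect_equal(tr$total_qaly, 1, tolerance = 1e-12)
  expect_equal(tr$total_cost, 0)

  # constant monthly death probability: life years match the geometric
  # series sum_{t>=1} (S^{t-1}+S^t)/2 / 12
  rate <- 0.24 # per year
  p2 <- flat_utility(zeroed_params(discount = 0, horizon = 110))
  p2$horizon_age <- 160 # effectively infinite horizon
  p2$life_table <- data.frame(age = 0:160, female = rate, male = rate)
  tr2 <- run_cohort(pr, 60, p2)
  s <- exp(-rate / 12)
  n <- (160 - 60) * 12
  closed <- sum((s^(0:(n - 1)) + s^(1:n)) / 2) / 12
  expect_equal(tr2$total_qaly, closed, tolerance = 1e-6)

  # surveilled arm, 21 years, no deaths, no discounting -> 10 colonoscopies
  p3 <- flat_utility(zeroed_params(discount = 0, horizon = 71))
  pr_s <- markov_profile(FALSE, surveillance = TRUE, is_proband = FALSE)
  tr3 <- run_cohort(pr_s, 50, p3)
  expect_equal(tr3$total_cost, 10 * 583, tolerance = 1e-9)
})

test_that("trace invariants: mass conservation, monotone survival,
           discounting bounds", {
  p <- base_params()
  profiles <- list(
    markov_profile(TRUE, "MLH1", TRUE, TRUE),
    markov_profile(TRUE, "MSH6", FALSE, FALSE, sex = "male"),
    markov_profile(FALSE, NA, TRUE, TRUE),
    markov_profile(FALSE, NA, FALSE, FALSE))
  for (pr in profiles) {
    tr <- run_cohort(pr, 55, p)
    expect_true(all(abs(rowSums(tr$trace) - 1) < 1e-9))
    expect_true(all(tr$trace >= -1e-12))
    alive <- rowSums(tr$trace[, 1:3])
    expect_true(all(diff(alive) < 1e-12))
    # discounted QALYs cannot exceed discounted life years
    expect_lte(tr$total_qaly, tr$life_years + 1e-9)
    expect_equal(tr$total_cost, sum(tr$cost))
    expect_equal(tr$total_qaly, sum(tr$qaly))
  }
})

test_that("run_cohort agrees with explicit transition-matrix iteration", {
  p <- base_params()
  pr <- markov_profile(TRUE, "MSH2", TRUE, TRUE)
  tr <- run_cohort(pr, 60, p)
  v <- c(1, 0, 0, 0, 0, 0)
  for (t in 1:24) {
    m <- build_transition_matrix(pr, 60 + (t - 1) / 12, p,
                                 t_years = (t - 1) / 12)
    v <- as.numeric(v %*% m)
  }
  expect_equal(unname(tr$trace[25, ]), v, tolerance = 1e-12)
})

test_that("surveillance lowers lifetime CRC incidence for carriers when
           the hazard ratio is below 1", {
  p <- base_params()
  for (g in c("MLH1", "MSH6")) {
    tr_s <- run_cohort(markov_profile(TRUE, g, TRUE, FALSE), 45, p)
    tr_n <- run_cohort(markov_profile(TRUE, g, FALSE, FALSE), 45, p)
    expect_lt(tr_s$cum_crc_incidence, tr_n$cum_crc_incidence)
  }
})

test_that("remaining discounted QALYs weakly decrease in start age", {
  p <- base_params()
  pr <- markov_profile(FALSE, NA, FALSE, FALSE)
  q <- vapply(c(40, 50, 60, 70, 80, 90),
              function(a) run_cohort(pr, a, p)$total_qaly, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("lifetime_outcomes mixes linearly and validates weights", {
  p <- base_params()
  mix1 <- data.frame(weight = 1, start_age = 60, carrier = TRUE,
                     gene = "MLH1", surveillance = TRUE,
                     is_proband = FALSE, sex = "female")
  tr <- run_cohort(markov_profile(TRUE, "MLH1", TRUE, FALSE), 60, p)
  o1 <- lifetime_outcomes(mix1, p)
  expect_equal(o1$cost, tr$total_cost)
  expect_equal(o1$qaly, tr$total_qaly)

  mix2 <- rbind(mix1, mix1)
  mix2$weight <- c(0.5, 0.5)
  mix2$gene[2] <- "PMS2"
  tr2 <- run_cohort(markov_profile(TRUE, "PMS2", TRUE, FALSE), 60, p)
  o2 <- lifetime_outcomes(mix2, p)
  expect_equal(o2$qaly, (tr$total_qaly + tr2$total_qaly) / 2)

  mix3 <- mix1
  mix3$weight <- 0.6
  expect_error(lifetime_outcomes(mix3, p), "sum to 1")
  # zero-weight entries contribute nothing
  mix4 <- rbind(mix1, mix1)
  mix4$weight <- c(1, 0)
  mix4$gene[2] <- "MSH6"
  expect_equal(lifetime_outcomes(mix4, p)$qaly, tr$total_qaly)
})
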