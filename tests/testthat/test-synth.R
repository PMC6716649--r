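test_that("accuracy-study generator: reproducible, concentrated at tau=0", {
  spec <- synth_spec(seed = 3, n_studies = 8)
  a <- gen_accuracy_studies(spec)
  b <- gen_accuracy_studies(spec)
  expect_identical(a, b)
  expect_true(all(a$tp + a$fn == spec$n_diseased))
  expect_true(all(a$tn + a$fp == spec$n_nondiseased))

  big <- synth_spec(seed = 4, n_studies = 20, tau_sens = 0, tau_spec = 0,
                    n_diseased = 5000L, n_nondiseased = 5000L)
  tab <- gen_accuracy_studies(big)
  expect_equal(mean(tab$tp / (tab$tp + tab$fn)), 0.944, tolerance = 0.01)
  expect_equal(mean(tab$tn / (tab$tn + tab$fp)), 0.748, tolerance = 0.01)
})

test_that("life table: deterministic, monotone adult mortality, plausible
           life expectancy band at 60", {
  spec <- synth_spec()
  lt <- gen_life_table(spec)
  expect_identical(lt, gen_life_table(spec))
  adult <- lt[lt$age >= 35, ]
  expect_true(all(diff(adult$female) > 0))
  expect_true(all(adult$male >= adult$female))
  # remaining life expectancy at 60 (annual steps) in the 20-30y band
  surv <- cumprod(exp(-lt$female[lt$age >= 60]))
  e60 <- sum(surv)
  expect_gt(e60, 20)
  expect_lt(e60, 30)
  # constant-hazard table: truncated-geometric closed form is exact, and
  # doubling the rate halves e60 up to the age-100 truncation
  flat <- gen_life_table(synth_spec(makeham_a = 0.04, gompertz_b = 1e-12))
  expect_true(all(abs(flat$female[flat$age >= 35] - 0.04) < 1e-6))
  geom <- function(m, k) {
    s <- exp(-m)
    s * (1 - s^k) / (1 - s)
  }
  k <- sum(flat$age >= 60)
  s1 <- sum(cumprod(exp(-rep(0.04, k))))
  s2 <- sum(cumprod(exp(-rep(0.08, k))))
  expect_equal(s1, geom(0.04, k), tolerance = 1e-9)
  expect_equal(s2, geom(0.08, k), tolerance = 1e-9)
  expect_gt(s2 / s1, 0.5)
  expect_lt(s2 / s1, 0.65)
  # for the default (age-increasing) table the ratio sits above 0.5
  surv2 <- cumprod(exp(-2 * lt$female[lt$age >= 60]))
  expect_gt(sum(surv2) / e60, 0.5)
  expect_lt(sum(surv2) / e60, 0.9)
})

test_that("EC age distribution: normalised, unimodal, mode in the 60s", {
  spec <- synth_spec()
  d <- gen_ec_age_distribution(spec)
  expect_equal(sum(d$weight), 1, tolerance = 1e-12)
  mode_age <- d$age[which.max(d$weight)]
  expect_gte(mode_age, 60)
  expect_lte(mode_age, 70)
  # unimodal: increasing then decreasing
  k <- which.max(d$weight)
  expect_true(all(diff(d$weight[1:k]) > 0))
  expect_true(all(diff(d$weight[k:length(d$weight)]) < 0))
  expect_true(all(diff(cumsum(d$weight)) > 0))
})

test_that("gene-mixture fixture matches the published knot table and the
           incidence curves close the Bayes loop", {
  mix <- gen_gene_mix(40:85)
  knots <- data.frame(
    age = seq(50, 80, 5),
    MLH1 = c(17.0, 13.6, 11.0, 8.8, 6.9, 5.2, 3.9),
    MSH2 = c(28.6, 28.4, 28.5, 29.2, 30.5, 32.1, 33.9))
  for (i in seq_len(nrow(knots))) {
    row <- mix[mix$age == knots$age[i], ]
    expect_equal(row$MLH1, knots$MLH1[i] / 100, tolerance = 0.005)
    expect_equal(row$MSH2, knots$MSH2[i] / 100, tolerance = 0.005)
  }
  expect_true(all(abs(rowSums(mix[, -1]) - 1) < 1e-9))
  expect_true(all(diff(mix$MLH1) < 0))

  overall <- c(MLH1 = 0.169, MSH2 = 0.246, MSH6 = 0.477, PMS2 = 0.108)
  curves <- gen_ec_incidence_curves(overall, ages = 40:85)
  back <- gene_mix_at_age(overall, curves)
  expect_equal(back$MLH1, mix$MLH1, tolerance = 1e-9)
  expect_equal(back$PMS2, mix$PMS2, tolerance = 1e-9)
})

test_that("natural-history schedules have the stated shapes", {
  inc <- gen_crc_incidence_general()
  expect_true(all(diff(inc$rate) > 0))
  expect_equal(inc$rate[inc$age == 60], 1.6e-3)
  # cumulative risk to 85 stays within the documented band
  lt <- gen_life_table(synth_spec())
  surv <- cumprod(exp(-lt$female[lt$age >= 25] -
                        inc$rate[inc$age >= 25]))
  keep <- inc$age[inc$age >= 25] <= 85
  risk85 <- sum((surv * inc$rate[inc$age >= 25])[keep])
  expect_gt(risk85, 0.06)
  expect_lt(risk85, 0.12)

  ls <- gen_crc_incidence_ls()
  at70 <- sapply(split(ls, ls$gene), function(d) d$rate[d$age == 70])
  expect_gt(at70[["MLH1"]], at70[["MSH2"]])
  expect_gt(at70[["MSH2"]], at70[["MSH6"]])
  expect_gt(at70[["MSH6"]], at70[["PMS2"]])

  em <- gen_ec_mortality_sporadic()
  expect_equal(em$rate_per_1000py[em$age == 40], 26.4)
  expect_equal(em$rate_per_1000py[em$age == 85], 92.1)

  pr <- gen_prevalence_by_age()
  expect_equal(pr$prevalence[pr$age == 60], 0.039, tolerance = 1e-9)
  expect_true(all(diff(pr$prevalence) < 0))
})
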