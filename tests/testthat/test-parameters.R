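test_that("packaged base case loads with the published base values", {
  p <- base_params()
  expect_s3_class(p, "lynch_params")
  expect_equal(p$prevalence_ls, 0.039)
  expect_equal(unname(p$overall_gene_mix),
               c(0.169, 0.246, 0.477, 0.108))
  expect_equal(p$ihc$sensitivity, 0.944)
  expect_equal(p$msi$specificity, 0.771)
  expect_equal(p$costs$diagnostic_test_gbp, 755)
  expect_equal(p$discount_rate_annual, 0.035)
  expect_equal(p$wtp_threshold_gbp, 20000)
  expect_equal(p$colonoscopy_interval_years, 2.1)
})

test_that("scenarios override exactly their parameters", {
  p0 <- base_params()
  p <- load_parameters(scenario = "low_prevalence")
  expect_equal(p$prevalence_ls, 0.030)
  expect_equal(prevalence_at(p, 60), 0.030, tolerance = 1e-9)
  # everything else unchanged
  expect_equal(p$ihc, p0$ihc)
  expect_equal(p$costs$ihc_gbp, p0$costs$ihc_gbp)

  p2 <- load_parameters(scenario = "counselling_decline_9pct")
  expect_equal(p2$uptake$p_attend_counselling, 0.91)
  expect_error(load_parameters(scenario = "nope"), "unknown scenario")
})

test_that("missing and unknown keys are rejected by name", {
  raw <- yaml::read_yaml(lynch_extdata("base_case.yaml"))
  tmp <- withr::local_tempdir()
  file.copy(list.files(dirname(lynch_extdata("base_case.yaml")),
                       pattern = "\\.csv$", full.names = TRUE), tmp)
  bad <- raw
  bad$costs$colonoscopy_gbp <- NULL
  yaml::write_yaml(bad, file.path(tmp, "bad.yaml"))
  expect_error(load_parameters(file.path(tmp, "bad.yaml")),
               "costs.colonoscopy_gbp")
  bad2 <- raw
  bad2$not_a_real_key <- 1
  yaml::write_yaml(bad2, file.path(tmp, "bad2.yaml"))
  expect_error(load_parameters(file.path(tmp, "bad2.yaml")),
               "not_a_real_key")
  expect_error(load_parameters(file.path(tmp, "missing.yaml")),
               "not found")
})

test_that("validation catches invariant violations", {
  p <- base_params()
  p$prevalence_ls <- 1.2
  expect_error(validate_parameters(p), "probability")
  p <- base_params()
  p$overall_gene_mix <- c(MLH1 = 0.5, MSH2 = 0.5, MSH6 = 0.5, PMS2 = 0.5)
  expect_error(validate_parameters(p), "sum to 1")
  p <- base_params()
  p$costs$ihc_gbp <- -1
  expect_error(validate_parameters(p), "costs")
  p <- base_params()
  p$discount_rate_annual <- 0.5
  expect_error(validate_parameters(p), "discount")
})

test_that("write/load round trip reproduces the parameter set", {
  p <- base_params()
  tmp <- withr::local_tempdir()
  path <- write_parameters(p, tmp)
  p2 <- load_parameters(path)
  # numeric payloads identical (ignore attribute ordering)
  expect_equal(p2, p, tolerance = 1e-12)
})

test_that("gene mixture and prevalence lookups cover ages 40-85", {
  p <- base_params()
  for (a in c(40, 60, 85)) {
    mix <- gene_mix_at(p, a)
    expect_equal(sum(mix), 1, tolerance = 1e-9)
  }
  expect_error(gene_mix_at(p, 30), "not tabulated")
  expect_true(all(diff(p$prevalence_by_age$prevalence) < 0))
})

test_that("PSA draws respect domains, reproduce under a seed, and fixed
           specs are degenerate", {
  p <- base_params()
  specs <- default_psa_specs(p)
  d1 <- sample_psa_draw(p, specs, seed = 1)
  d2 <- sample_psa_draw(p, specs, seed = 1)
  expect_identical(d1, d2)
  d3 <- sample_psa_draw(p, specs, seed = 2)
  expect_false(identical(d1$ihc$sensitivity, d3$ihc$sensitivity))
  # every draw passes the same validators as the base case
  for (s in 1:5) {
    expect_silent(validate_parameters(sample_psa_draw(p, specs, seed = s)))
  }
  # all-fixed specs reproduce the base case exactly
  fixed <- list(field_param("prevalence_ls",
                            dist_spec("fixed", value = p$prevalence_ls),
                            "prevalence_ls"))
  names(fixed) <- "prevalence_ls"
  expect_equal(sample_psa_draw(p, fixed, seed = 7), p)
})

test_that("moment-matched beta sampler hits its analytic mean", {
  spec <- beta_from_mean_se(0.944)
  expect_equal(spec_mean(spec), 0.944, tolerance = 1e-12)
  draws <- with_local_seed(42, spec_sample(spec, 1e5))
  # probability domain is the closed unit interval (shape2 < 1 puts mass
  # arbitrarily close to 1)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws), 0.944, tolerance = 0.005)
})

test_that("confidence limits match closed forms", {
  expect_equal(confidence_limits(dist_spec("beta", shape1 = 1, shape2 = 1)),
               c(0.025, 0.975))
  expect_equal(
    confidence_limits(dist_spec("lognormal", meanlog = 0, sdlog = 1)),
    exp(c(-1, 1) * qnorm(0.975)), tolerance = 1e-6)
  lim <- confidence_limits(dist_spec("gamma", shape = 100, scale = 1))
  expect_true(lim[1] < 100 && lim[2] > 100)
  expect_true(lim[1] > 80 && lim[2] < 121)
  expect_error(confidence_limits(dist_spec("fixed", value = 1)),
               "no uncertainty")
  expect_error(
    confidence_limits(dist_spec("dirichlet", alpha = c(1, 1))),
    "not univariate")
})
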