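# Shared fixtures: the packaged base case is loaded once per test run, and
# small modified copies are derived from it in the tests.

base_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_parameters()
    cached
  }
})

# parameter set with tumour-test failure branches switched off (used by the
# hand-derived tree examples, which exclude the failure branch)
params_no_failure <- function() {
  p <- base_params()
  p$ihc$failure_rate <- 0
  p$msi$failure_rate <- 0
  p
}

# Monte-Carlo pathway simulator: an independent stochastic oracle for the
# analytic tree enumeration. Simulates n probands step by step with
# explicit per-stage draws and returns the empirical diagnostic-category
# distribution and mean testing cost.
simulate_pathway <- function(strategy, status, params, n = 2e5, seed = 1) {
  s <- strategy_def(strategy)
  p <- params
  is_ls <- status %in% c("MLH1", "MSH2", "MSH6", "PMS2")
  withr::with_seed(seed, {
    cat_out <- character(n)
    cost <- numeric(n)
    rb <- function(prob) stats::runif(n) < prob
    # stage 1: tumour test
    if (s$name == "NO_TESTING") {
      return(list(p_diag = c(LS_CONFIRMED = 0, PLS = 0, DISCHARGED = 1),
                  cost = 0))
    }
    referred <- rep(FALSE, n)
    via_positive_tumour <- rep(FALSE, n)
    if (s$tumour_test != "none") {
      test <- p[[s$tumour_test]]
      cost <- cost + p$costs[[paste0(s$tumour_test, "_gbp")]]
      failed <- rb(test$failure_rate)
      p_pos <- if (is_ls) test$sensitivity else 1 - test$specificity
      positive <- !failed & rb(p_pos)
      if (s$methylation) {
        meth_tested <- rep(FALSE, n)
        cont <- rep(TRUE, n)
        if (s$tumour_test == "ihc") {
          q <- if (status == "MLH1") p$staining$mlh1_carrier
          else if (is_ls) p$staining$other_carrier
          else p$staining$sporadic
          dmlh1 <- positive & rb(q)
          meth_tested <- dmlh1
          pc <- if (status == "MLH1") p$meth_dmlh1$sensitivity
          else if (is_ls) p$meth_dmlh1$specificity
          else 1 - p$meth_dmlh1$specificity
          cont[dmlh1] <- rb(pc)[dmlh1]
        } else {
          meth_tested <- positive
          pc <- if (status == "MLH1") p$meth_msi$sensitivity
          else if (is_ls) 1 - p$meth_msi$p_meth_other_carrier
          else 1 - p$meth_msi$p_meth_sporadic
          cont[positive] <- rb(pc)[positive]
        }
        cost <- cost + meth_tested * p$costs$methylation_gbp
        via_positive_tumour <- positive & cont
      } else {
        via_positive_tumour <- positive
      }
      referred <- via_positive_tumour |
        (failed & p$failure_policy == "refer")
    } else {
      referred <- rep(TRUE, n) # direct referral
    }
    # stage 2: counselling and germline testing
    cost <- cost + referred * p$costs$counselling_offer_gbp
    attend <- referred & rb(p$uptake$p_attend_counselling)
    cost <- cost + attend * p$costs$pretest_counselling_proband_gbp
    tested <- attend & rb(1 - p$uptake$p_decline_test)
    cost <- cost + tested * (p$costs$diagnostic_test_gbp +
                               p$costs$posttest_counselling_gbp)
    confirmed <- tested & is_ls & rb(p$germline$diagnostic_sensitivity)
    # sporadic PLS requires a suggestive (positive) tumour test
    pls <- tested & !confirmed & (is_ls | via_positive_tumour)
    cat_out[confirmed] <- "LS_CONFIRMED"
    cat_out[pls & !confirmed] <- "PLS"
    cat_out[cat_out == ""] <- "DISCHARGED"
    tab <- table(factor(cat_out,
                        levels = c("LS_CONFIRMED", "PLS", "DISCHARGED")))
    list(p_diag = as.numeric(tab) / n, cost = mean(cost))
  })
}
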