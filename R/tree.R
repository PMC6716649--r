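#' @title Diagnostic decision tree
#' @description
#' Exhaustive enumeration of the proband testing pathway for each strategy:
#' tumour-based triage (IHC or MSI, with optional MLH1-methylation triage),
#' direct referral, or no testing; then genetic counselling, diagnostic
#' germline testing, and classification as confirmed Lynch syndrome (LS),
#' putative LS (PLS) or discharged. The relative cascade converts the
#' proband's diagnostic outcome into per-relative costs and long-term arm
#' assignments.
#' @name tree
NULL

diag_categories <- function() c("LS_CONFIRMED", "PLS", "DISCHARGED")

true_statuses <- function() c(ls_genes(), "SPORADIC")

#' Resolve a strategy name to its tree-topology flags
#'
#' @param name one of `NO_TESTING`, `IHC`, `IHC_METH`, `MSI`, `MSI_METH`,
#'   `DIRECT`
#' @return list with `name`, `tumour_test` ("ihc"/"msi"/"none"),
#'   `methylation` (logical), `direct_referral` (logical)
#' @export
strategy_def <- function(name) {
  name <- match.arg(name, strategy_names())
  switch(name,
    NO_TESTING = list(name = name, tumour_test = "none",
                      methylation = FALSE, direct_referral = FALSE),
    IHC = list(name = name, tumour_test = "ihc",
               methylation = FALSE, direct_referral = FALSE),
    IHC_METH = list(name = name, tumour_test = "ihc",
                    methylation = TRUE, direct_referral = FALSE),
    MSI = list(name = name, tumour_test = "msi",
               methylation = FALSE, direct_referral = FALSE),
    MSI_METH = list(name = name, tumour_test = "msi",
                    methylation = TRUE, direct_referral = FALSE),
    DIRECT = list(name = name, tumour_test = "none",
                  methylation = FALSE, direct_referral = TRUE))
}

# Probability that the methylation triage lets the patient continue to
# counselling, by route and true status.
meth_continue_prob <- function(route, status, params) {
  is_mlh1 <- status == "MLH1"
  is_ls <- status %in% ls_genes()
  if (route == "ihc") {
    if (is_mlh1) {
      params$meth_dmlh1$sensitivity
    } else if (is_ls) {
      # non-MLH1 carriers' dMLH1-staining tumours are truly unmethylated;
      # the test correctly reads them as such with its specificity
      params$meth_dmlh1$specificity
    } else {
      1 - params$meth_dmlh1$specificity
    }
  } else { # msi route: all test-positives get methylation testing
    if (is_mlh1) {
      params$meth_msi$sensitivity
    } else if (is_ls) {
      1 - params$meth_msi$p_meth_other_carrier
    } else {
      1 - params$meth_msi$p_meth_sporadic
    }
  }
}

#' Enumerate the proband testing pathway
#'
#' Walks every branch of the decision tree for one strategy and true
#' status, returning the exact distribution over diagnostic categories,
#' the expected testing-phase cost, and expected test/counselling counts.
#' Probabilities: tumour test positive with its sensitivity (LS statuses)
#' or 1 - specificity (sporadic); failed tests follow
#' `params$failure_policy` ("refer" sends them onward without methylation
#' triage, "discharge" ends the pathway); the dMLH1 staining split and
#' methylation triage apply per true status; counselling attendance,
#' test acceptance and diagnostic sensitivity/specificity close the tree.
#' Tested carriers with a negative germline result and all tested sporadics
#' end as PLS; everyone else not confirmed is discharged.
#'
#' @param strategy a strategy name or [strategy_def()] result
#' @param status one of `MLH1`, `MSH2`, `MSH6`, `PMS2`, `SPORADIC`
#' @param params a `lynch_params` object
#' @return list of class `lynch_pathway`: `p_diag` (named probability
#'   vector over LS_CONFIRMED / PLS / DISCHARGED), `expected_cost` (GBP per
#'   proband), `counts` (expected tumour tests, methylation tests,
#'   counselling offers, counselling attended, germline tests)
#' @export
proband_pathway <- function(strategy, status, params) {
  if (is.character(strategy)) strategy <- strategy_def(strategy)
  status <- match.arg(status, true_statuses())
  p <- params
  is_ls <- status %in% ls_genes()

  acc <- new.env(parent = emptyenv())
  acc$p_diag <- stats::setNames(numeric(3), diag_categories())
  acc$cost <- 0
  acc$counts <- c(tumour_tests = 0, methylation_tests = 0,
                  counselling_offers = 0, counselling_attended = 0,
                  germline_tests = 0)
  leaf <- function(prob, category, cost, counts) {
    acc$p_diag[category] <- acc$p_diag[category] + prob
    acc$cost <- acc$cost + prob * cost
    acc$counts <- acc$counts + prob * counts
  }

  # Referral stage shared by all routes reaching counselling.
  # `sporadic_pls`: a germline-negative patient is only managed as putative
  # LS when the work-up was suggestive — a positive tumour test, or (for
  # true carriers) a Lynch-type family history. Sporadic patients referred
  # without a positive tumour test (direct referral, failed tests) are
  # discharged after a negative germline test.
  referral <- function(prob, cost, counts, sporadic_pls = TRUE) {
    counts["counselling_offers"] <- counts["counselling_offers"] + 1
    cost <- cost + p$costs$counselling_offer_gbp
    att <- p$uptake$p_attend_counselling
    # non-attenders
    leaf(prob * (1 - att), "DISCHARGED", cost, counts)
    cost_att <- cost + p$costs$pretest_counselling_proband_gbp
    counts_att <- counts
    counts_att["counselling_attended"] <- counts_att["counselling_attended"] + 1
    dec <- p$uptake$p_decline_test
    leaf(prob * att * dec, "DISCHARGED", cost_att, counts_att)
    # tested
    cost_t <- cost_att + p$costs$diagnostic_test_gbp +
      p$costs$posttest_counselling_gbp
    counts_t <- counts_att
    counts_t["germline_tests"] <- counts_t["germline_tests"] + 1
    p_t <- prob * att * (1 - dec)
    if (is_ls) {
      sens <- p$germline$diagnostic_sensitivity
      leaf(p_t * sens, "LS_CONFIRMED", cost_t, counts_t)
      leaf(p_t * (1 - sens), "PLS", cost_t, counts_t)
    } else {
      # diagnostic specificity 1: no false positives
      fp <- 1 - p$germline$diagnostic_specificity
      leaf(p_t * fp, "LS_CONFIRMED", cost_t, counts_t)
      leaf(p_t * (1 - fp), if (sporadic_pls) "PLS" else "DISCHARGED",
           cost_t, counts_t)
    }
  }

  counts0 <- acc$counts * 0
  if (strategy$name == "NO_TESTING") {
    leaf(1, "DISCHARGED", 0, counts0)
  } else if (strategy$direct_referral) {
    referral(1, 0, counts0, sporadic_pls = FALSE)
  } else {
    test <- p[[strategy$tumour_test]]
    cost0 <- p$costs[[paste0(strategy$tumour_test, "_gbp")]]
    counts1 <- counts0
    counts1["tumour_tests"] <- 1
    f <- test$failure_rate
    # failure branch
    if (f > 0) {
      if (p$failure_policy == "refer") {
        referral(f, cost0, counts1, sporadic_pls = FALSE)
      } else {
        leaf(f, "DISCHARGED", cost0, counts1)
      }
    }
    p_pos <- if (is_ls) test$sensitivity else 1 - test$specificity
    # negative branch
    leaf((1 - f) * (1 - p_pos), "DISCHARGED", cost0, counts1)
    p_branch <- (1 - f) * p_pos
    if (!strategy$methylation) {
      referral(p_branch, cost0, counts1)
    } else if (strategy$tumour_test == "ihc") {
      q <- if (status == "MLH1") {
        p$staining$mlh1_carrier
      } else if (is_ls) {
        p$staining$other_carrier
      } else {
        p$staining$sporadic
      }
      # non-dMLH1 staining pattern: no methylation test, straight onward
      referral(p_branch * (1 - q), cost0, counts1)
      cost_m <- cost0 + p$costs$methylation_gbp
      counts_m <- counts1
      counts_m["methylation_tests"] <- 1
      cont <- meth_continue_prob("ihc", status, p)
      referral(p_branch * q * cont, cost_m, counts_m)
      leaf(p_branch * q * (1 - cont), "DISCHARGED", cost_m, counts_m)
    } else { # msi + methylation: every positive gets the methylation test
      cost_m <- cost0 + p$costs$methylation_gbp
      counts_m <- counts1
      counts_m["methylation_tests"] <- 1
      cont <- meth_continue_prob("msi", status, p)
      referral(p_branch * cont, cost_m, counts_m)
      leaf(p_branch * (1 - cont), "DISCHARGED", cost_m, counts_m)
    }
  }

  stopifnot(abs(sum(acc$p_diag) - 1) < 1e-12)
  structure(list(strategy = strategy$name, status = status,
                 p_diag = acc$p_diag, expected_cost = acc$cost,
                 counts = acc$counts),
            class = "lynch_pathway")
}

#' @export
print.lynch_pathway <- function(x, ...) {
  cat("<pathway>", x$strategy, "/", x$status, "\n")
  print(round(x$p_diag, 6))
  cat(sprintf("  expected testing cost: GBP %.2f\n", x$expected_cost))
  invisible(x)
}

#' Expected per-relative cascade outcomes
#'
#' Converts a proband's diagnostic-category distribution into the expected
#' testing cost and long-term arm probabilities for one modelled relative.
#' If the proband is confirmed LS, relatives are offered predictive testing
#' (referral, pre-test counselling, perfect-accuracy test, post-test
#' counselling); identified carriers (first-degree transmission probability
#' 0.5) enter surveillance. If the proband is PLS, relatives are invited to
#' counselling and enter surveillance unresolved, without a germline test.
#' Discharged probands generate no contact; their carrier relatives remain
#' at Lynch-syndrome risk without surveillance.
#'
#' @param proband_outcome a `lynch_pathway` from [proband_pathway()]
#' @param status the proband's true status (determines the relatives'
#'   carrier probability: 0.5 for LS probands, 0 for sporadic)
#' @param params a `lynch_params` object
#' @return list of class `lynch_cascade`: `expected_cost` (GBP per
#'   relative), `arms` (data.frame with columns carrier, surveillance,
#'   prob summing to 1), `expected_predictive_tests`
#' @export
relative_cascade <- function(proband_outcome, status, params) {
  stopifnot(inherits(proband_outcome, "lynch_pathway"))
  p <- params
  pd <- proband_outcome$p_diag
  carrier_p <- if (status %in% ls_genes()) 0.5 else 0
  u <- p$uptake$relative_uptake %||% 1
  u2 <- p$uptake$p_surveillance_unresolved %||% 1

  # confirmed-LS proband: full predictive cascade
  cost_conf <- p$costs$relative_referral_gbp +
    u * (p$costs$pretest_counselling_relative_gbp +
           p$costs$predictive_test_gbp +
           p$costs$posttest_counselling_gbp)
  # PLS proband: counselling and surveillance, no germline test
  cost_pls <- p$costs$relative_referral_gbp +
    p$costs$pretest_counselling_relative_gbp

  expected_cost <- pd[["LS_CONFIRMED"]] * cost_conf +
    pd[["PLS"]] * cost_pls

  arms <- rbind(
    # proband confirmed: tested relatives resolved by perfect accuracy
    data.frame(carrier = TRUE, surveillance = TRUE,
               prob = pd[["LS_CONFIRMED"]] * carrier_p * u),
    data.frame(carrier = TRUE, surveillance = FALSE,
               prob = pd[["LS_CONFIRMED"]] * carrier_p * (1 - u)),
    data.frame(carrier = FALSE, surveillance = FALSE,
               prob = pd[["LS_CONFIRMED"]] * (1 - carrier_p)),
    # proband PLS: surveillance offered with carrier status unresolved;
    # long-term adherence without a confirmed molecular diagnosis is
    # partial (p_surveillance_unresolved)
    data.frame(carrier = TRUE, surveillance = TRUE,
               prob = pd[["PLS"]] * carrier_p * u2),
    data.frame(carrier = TRUE, surveillance = FALSE,
               prob = pd[["PLS"]] * carrier_p * (1 - u2)),
    data.frame(carrier = FALSE, surveillance = TRUE,
               prob = pd[["PLS"]] * (1 - carrier_p) * u2),
    data.frame(carrier = FALSE, surveillance = FALSE,
               prob = pd[["PLS"]] * (1 - carrier_p) * (1 - u2)),
    # proband discharged: no contact
    data.frame(carrier = TRUE, surveillance = FALSE,
               prob = pd[["DISCHARGED"]] * carrier_p),
    data.frame(carrier = FALSE, surveillance = FALSE,
               prob = pd[["DISCHARGED"]] * (1 - carrier_p))
  )
  arms <- stats::aggregate(prob ~ carrier + surveillance, arms, sum)
  stopifnot(abs(sum(arms$prob) - 1) < 1e-12)
  structure(list(expected_cost = as.numeric(expected_cost),
                 arms = arms,
                 expected_predictive_tests = pd[["LS_CONFIRMED"]] * u),
            class = "lynch_cascade")
}
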