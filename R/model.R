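#' @title Full strategy evaluation
#' @description
#' Glue between the decision tree and the Markov engine: for each testing
#' strategy, mixes proband pathways over true status (prevalence and gene
#' mixture at the proband age), attaches the relative cascade, and
#' aggregates population-level discounted costs and QALYs for 1000 probands
#' and 6000 relatives (configurable). Cohort traces are memoised across
#' strategies within one evaluation because they depend only on the
#' profile, not the strategy.
#' @name model
NULL

# distribution over true statuses at the proband age
status_distribution <- function(params, age = params$proband_age) {
  prev <- prevalence_at(params, age)
  mix <- gene_mix_at(params, age)
  data.frame(status = c(ls_genes(), "SPORADIC"),
             prob = c(prev * mix, 1 - prev))
}

# expected per-relative (cost, qaly) for a cascade, mixing over sex 0.5 and
# the relative age weights (or the single representative age)
relative_outcomes <- function(cascade, status, params, relative_ages,
                              cache) {
  gene <- if (status %in% ls_genes()) status else NA_character_
  ages <- relative_ages$age
  agew <- relative_ages$weight
  cost <- cascade$expected_cost
  qaly <- 0
  for (i in seq_len(nrow(cascade$arms))) {
    w <- cascade$arms$prob[i]
    if (w == 0) next
    carrier <- cascade$arms$carrier[i]
    surv <- cascade$arms$surveillance[i]
    for (sex in c("female", "male")) {
      pr <- markov_profile(carrier, if (carrier) gene else NA_character_,
                           surv, is_proband = FALSE, sex = sex)
      for (j in seq_along(ages)) {
        key <- profile_key(pr, ages[j])
        trace <- cache[[key]]
        if (is.null(trace)) {
          trace <- run_cohort(pr, ages[j], params)
          cache[[key]] <- trace
        }
        ww <- w * 0.5 * agew[j]
        cost <- cost + ww * trace$total_cost
        qaly <- qaly + ww * trace$total_qaly
      }
    }
  }
  list(cost = cost, qaly = qaly)
}

#' Evaluate testing strategies end to end
#'
#' Runs the decision tree and Markov model for each strategy and returns
#' population totals (discounted GBP and QALYs) for
#' `params$n_probands` probands plus their modelled relatives.
#'
#' @param params a `lynch_params` object
#' @param strategies character vector of strategy names (default all six)
#' @param relative_ages `"weighted"` (mix over the packaged relatives' age
#'   distribution; base case) or `"fixed"` (all relatives at
#'   `params$relative_age`; used in PSA/OWSA)
#' @param proband_age proband cohort age (default `params$proband_age`)
#' @return data.frame of class `lynch_results` with columns `strategy`,
#'   `cost`, `qaly`
#' @export
evaluate_strategies <- function(params, strategies = strategy_names(),
                                relative_ages = c("weighted", "fixed"),
                                proband_age = params$proband_age) {
  relative_ages <- match.arg(relative_ages)
  p <- params
  rel_ages <- if (relative_ages == "weighted") {
    p$relative_age_weights
  } else {
    data.frame(age = p$relative_age, weight = 1)
  }
  sd <- status_distribution(p, proband_age)
  cache <- new.env(parent = emptyenv())
  n_p <- p$n_probands
  n_r <- p$relatives_per_proband

  out <- lapply(strategies, function(sname) {
    cost <- 0
    qaly <- 0
    for (i in seq_len(nrow(sd))) {
      status <- sd$status[i]
      w <- sd$prob[i]
      if (w == 0) next
      path <- proband_pathway(sname, status, p)
      # proband long-term outcomes: surveilled iff diagnosed (P)LS
      carrier <- status %in% ls_genes()
      gene <- if (carrier) status else NA_character_
      pc <- path$expected_cost
      pq <- 0
      # diagnosed probands enter surveillance; those managed as putative
      # LS adhere with probability p_surveillance_unresolved
      u2 <- p$uptake$p_surveillance_unresolved %||% 1
      p_surv <- c(LS_CONFIRMED = 1, PLS = u2, DISCHARGED = 0)
      for (dcat in diag_categories()) {
        for (surv in c(TRUE, FALSE)) {
          dp <- path$p_diag[[dcat]] *
            (if (surv) p_surv[[dcat]] else 1 - p_surv[[dcat]])
          if (dp == 0) next
          pr <- markov_profile(carrier, gene, surv, is_proband = TRUE,
                               sex = "female")
          key <- profile_key(pr, proband_age)
          trace <- cache[[key]]
          if (is.null(trace)) {
            trace <- run_cohort(pr, proband_age, p)
            cache[[key]] <- trace
          }
          pc <- pc + dp * trace$total_cost
          pq <- pq + dp * trace$total_qaly
        }
      }
      casc <- relative_cascade(path, status, p)
      rel <- relative_outcomes(casc, status, p, rel_ages, cache)
      cost <- cost + w * (pc + n_r * rel$cost)
      qaly <- qaly + w * (pq + n_r * rel$qaly)
    }
    data.frame(strategy = sname, cost = n_p * cost, qaly = n_p * qaly)
  })
  res <- do.call(rbind, out)
  class(res) <- c("lynch_results", class(res))
  res
}

#' Incremental net monetary benefit per proband of one strategy vs another
#'
#' @param params a `lynch_params` object
#' @param strategy,comparator strategy names
#' @param lambda willingness to pay (GBP/QALY; default the packaged
#'   threshold)
#' @param relative_ages passed to [evaluate_strategies()]
#' @param proband_age proband cohort age
#' @return INMB in GBP per proband
#' @export
inmb_per_proband <- function(params, strategy = "IHC_METH",
                             comparator = "NO_TESTING",
                             lambda = params$wtp_threshold_gbp,
                             relative_ages = "fixed",
                             proband_age = params$proband_age) {
  res <- evaluate_strategies(params, c(comparator, strategy),
                             relative_ages = relative_ages,
                             proband_age = proband_age)
  dq <- res$qaly[2] - res$qaly[1]
  dc <- res$cost[2] - res$cost[1]
  (lambda * dq - dc) / params$n_probands
}
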