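#' @title Sensitivity and heterogeneity analyses
#' @description
#' Probabilistic sensitivity analysis (joint sampling of all uncertain
#' inputs), one-way sensitivity analysis with tornado ordering and the
#' published filtering rule, proband-age heterogeneity, and the
#' age-threshold testing-policy analysis.
#' @name sensitivity
NULL

#' Run the probabilistic sensitivity analysis
#'
#' Each iteration draws a full parameter set via [sample_psa_draw()] and
#' re-evaluates every strategy end to end. Relatives enter at the single
#' representative age (`params$relative_age`, 54 in the base
#' configuration), as in the published analysis. Per-iteration seeds are
#' derived deterministically from `seed`, so results are reproducible and
#' insensitive to iteration order. Draws failing validation are resampled
#' with a hard cap of 10x the requested iterations.
#'
#' @param params base-case `lynch_params`
#' @param specs PSA registry (default [default_psa_specs()])
#' @param n_iter number of iterations (>= 1)
#' @param seed integer master seed
#' @param strategies strategy names to evaluate
#' @return list of class `lynch_psa`: `cost` and `qaly` (n_iter x strategy
#'   matrices), `seed`, `n_iter`, `n_resampled`
#' @export
run_psa <- function(params, specs = default_psa_specs(params),
                    n_iter = 1000L, seed = 1L,
                    strategies = strategy_names()) {
  stopifnot(n_iter >= 1)
  cost <- matrix(NA_real_, n_iter, length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  n_resampled <- 0L
  max_draws <- 10L * n_iter
  draws <- 0L
  sub_seed <- function(i) (as.integer(seed) * 1009L + i) %% .Machine$integer.max
  for (i in seq_len(n_iter)) {
    repeat {
      draws <- draws + 1L
      if (draws > max_draws) stop("PSA resampling cap exceeded")
      draw <- tryCatch(
        sample_psa_draw(params, specs, seed = sub_seed(draws)),
        error = function(e) NULL)
      if (!is.null(draw)) break
      n_resampled <- n_resampled + 1L
    }
    res <- evaluate_strategies(draw, strategies, relative_ages = "fixed")
    cost[i, ] <- res$cost
    qaly[i, ] <- res$qaly
  }
  structure(list(cost = cost, qaly = qaly, seed = as.integer(seed),
                 n_iter = as.integer(n_iter), n_resampled = n_resampled),
            class = "lynch_psa")
}

#' One-way sensitivity analysis (tornado)
#'
#' For every non-fixed, univariate parameter in `specs`, sets the parameter
#' to its 2.5th then 97.5th percentile (others at base case), recomputes
#' the incremental net monetary benefit (INMB) per proband of
#' `strategy` versus `comparator`, and reports entries sorted by
#' descending INMB range. Entries with range below 1% of the maximum range
#' are filtered out, following the published tornado convention. Dirichlet
#' (joint-vector) specs are excluded as they have no univariate limits.
#'
#' @param params base-case `lynch_params`
#' @param specs PSA registry
#' @param strategy,comparator the strategy pair (defaults IHC_METH vs
#'   NO_TESTING)
#' @param lambda willingness to pay (GBP/QALY)
#' @return data.frame of class `lynch_owsa`: parameter, low/high parameter
#'   values, INMB at each, inmb_range
#' @export
owsa <- function(params, specs = default_psa_specs(params),
                 strategy = "IHC_METH", comparator = "NO_TESTING",
                 lambda = params$wtp_threshold_gbp) {
  stopifnot(length(specs) > 0)
  rows <- list()
  for (entry in specs) {
    if (entry$spec$family %in% c("fixed", "dirichlet")) next
    lim <- confidence_limits(entry$spec)
    vals <- vapply(lim, function(v) {
      p2 <- entry$set(params, v)
      validate_parameters(p2)
      inmb_per_proband(p2, strategy, comparator, lambda,
                       relative_ages = "fixed")
    }, numeric(1))
    rows[[entry$name]] <- data.frame(
      parameter = entry$name, low = lim[1], high = lim[2],
      inmb_low = vals[1], inmb_high = vals[2],
      inmb_range = abs(vals[2] - vals[1]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$inmb_range), ]
  out <- out[out$inmb_range >= 0.01 * max(out$inmb_range), ]
  class(out) <- c("lynch_owsa", "data.frame")
  out
}

#' Proband-age heterogeneity analysis
#'
#' Re-evaluates all strategies for proband cohorts aged `ages`, with
#' age-appropriate prevalence, gene mixture and endometrial-cancer
#' mortality, holding the relatives' age distribution fixed. Reports the
#' per-proband INMB of each testing strategy versus no testing.
#'
#' @param params a `lynch_params` object
#' @param ages proband ages (default 40:85; must be covered by the gene
#'   mixture table)
#' @param lambda willingness to pay
#' @return data.frame with columns `age`, `strategy`, `cost`, `qaly`,
#'   `inmb_per_proband`
#' @export
age_heterogeneity <- function(params, ages = 40:85,
                              lambda = params$wtp_threshold_gbp) {
  stopifnot(all(ages %in% params$gene_mix_by_age$age))
  out <- lapply(ages, function(a) {
    res <- evaluate_strategies(params, relative_ages = "weighted",
                               proband_age = a)
    base <- res[res$strategy == "NO_TESTING", ]
    res$inmb_per_proband <- (lambda * (res$qaly - base$qaly) -
                               (res$cost - base$cost)) / params$n_probands
    cbind(age = a, res)
  })
  out <- do.call(rbind, out)
  class(out) <- "data.frame"
  out
}

#' Age-threshold testing-policy analysis
#'
#' Cost-effectiveness of testing only probands up to an age threshold:
#' population INMB(T) = sum over ages a <= T of w(a) * INMB(a), where w is
#' the endometrial-cancer age-at-diagnosis distribution and INMB(a) the
#' per-proband INMB of `strategy` versus no testing at proband age a
#' (probands above the threshold are untested, contributing zero).
#'
#' @param params a `lynch_params` object
#' @param ec_age_distribution data.frame with columns `age`, `weight`
#'   summing to 1 (default the packaged fixture)
#' @param thresholds candidate age thresholds (default every modelled age)
#' @param strategy testing strategy (default IHC_METH)
#' @param lambda willingness to pay
#' @param heterogeneity optional precomputed [age_heterogeneity()] result
#' @return list of class `lynch_threshold`: `table` (threshold,
#'   population_inmb_per_proband), `argmax` (threshold with maximal INMB),
#'   `per_age` (the underlying INMB-by-age input)
#' @export
age_threshold_policy <- function(params,
                                 ec_age_distribution =
                                   params$ec_age_distribution,
                                 thresholds = sort(ec_age_distribution$age),
                                 strategy = "IHC_METH",
                                 lambda = params$wtp_threshold_gbp,
                                 heterogeneity = NULL) {
  w <- ec_age_distribution
  if (abs(sum(w$weight) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(heterogeneity)) {
    heterogeneity <- age_heterogeneity(params, ages = sort(w$age),
                                       lambda = lambda)
  }
  h <- heterogeneity[heterogeneity$strategy == strategy, ]
  inmb_a <- h$inmb_per_proband[match(w$age, h$age)]
  tab <- data.frame(
    threshold = thresholds,
    population_inmb_per_proband = vapply(thresholds, function(th) {
      sum(w$weight[w$age <= th] * inmb_a[w$age <= th])
    }, numeric(1)))
  structure(list(
    table = tab,
    argmax = tab$threshold[which.max(tab$population_inmb_per_proband)],
    per_age = data.frame(age = w$age, weight = w$weight, inmb = inmb_a)
  ), class = "lynch_threshold")
}
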