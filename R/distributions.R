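#' @title Uncertainty distributions for sensitivity analysis
#' @description
#' Each uncertain model input carries a `dist_spec` describing its sampling
#' distribution in the probabilistic sensitivity analysis (PSA) and the 95%
#' limits used in one-way sensitivity analysis. Families: `beta` for
#' probabilities and utility multipliers, `gamma` for costs, `lognormal`
#' for hazard ratios, `dirichlet` for probability vectors (sampled jointly
#' so they still sum to 1), and `fixed` for no declared uncertainty. The
#' default hyperparameters are moment-matched to the base value with an
#' assumed standard error (10% of the mean for probabilities, 20% for
#' costs) because the original study's distribution tables are not
#' reproducible; every spec is configurable so real hyperparameters can be
#' dropped in.
#' @name distributions
NULL

#' Construct a distribution specification
#'
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"dirichlet"`,
#'   `"fixed"`
#' @param ... family hyperparameters: `shape1`/`shape2` (beta),
#'   `shape`/`scale` (gamma), `meanlog`/`sdlog` (lognormal), `alpha`
#'   (dirichlet concentration vector), `value` (fixed)
#' @param group optional correlation-group tag (draws within a group share
#'   one uniform via a Gaussian copula is *not* implemented; the tag is
#'   carried for bookkeeping)
#' @return object of class `dist_spec`
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "dirichlet",
                                 "fixed"),
                      ..., group = NULL) {
  family <- match.arg(family)
  hyper <- list(...)
  need <- switch(family,
    beta = c("shape1", "shape2"),
    gamma = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    dirichlet = "alpha",
    fixed = "value")
  missing <- setdiff(need, names(hyper))
  if (length(missing)) {
    stop("dist_spec(", family, "): missing hyperparameter(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- switch(family,
    beta = hyper$shape1 <= 0 || hyper$shape2 <= 0,
    gamma = hyper$shape <= 0 || hyper$scale <= 0,
    lognormal = hyper$sdlog < 0,
    dirichlet = any(hyper$alpha <= 0),
    fixed = FALSE)
  if (isTRUE(bad)) stop("dist_spec(", family, "): invalid hyperparameters")
  structure(list(family = family, hyper = hyper, group = group),
            class = "dist_spec")
}

#' Moment-matched specs
#'
#' Helpers building a `dist_spec` from a mean and standard error.
#'
#' @param mean target mean
#' @param se target standard error (defaults: 10% of the mean for beta,
#'   20% for gamma, 20% of log-scale for lognormal)
#' @return a `dist_spec`
#' @export
beta_from_mean_se <- function(mean, se = 0.1 * mean) {
  stopifnot(mean > 0, mean < 1)
  se <- min(se, 0.95 * sqrt(mean * (1 - mean)))
  nu <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @rdname beta_from_mean_se
#' @export
gamma_from_mean_se <- function(mean, se = 0.2 * mean) {
  stopifnot(mean > 0)
  dist_spec("gamma", shape = (mean / se)^2, scale = se^2 / mean)
}

#' @rdname beta_from_mean_se
#' @param sdlog log-scale SD for the lognormal
#' @export
lognormal_from_mean <- function(mean, sdlog = 0.2) {
  stopifnot(mean > 0)
  dist_spec("lognormal", meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet sampler via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha # degenerate underflow guard
  g / sum(g)
}

#' Sample from a distribution specification
#'
#' @param spec a `dist_spec`
#' @param n number of draws (dirichlet returns an n x k matrix)
#' @return numeric vector (or matrix for dirichlet)
#' @export
spec_sample <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyper
  switch(spec$family,
    beta = stats::rbeta(n, h$shape1, h$shape2),
    gamma = stats::rgamma(n, shape = h$shape, scale = h$scale),
    lognormal = stats::rlnorm(n, h$meanlog, h$sdlog),
    dirichlet = t(replicate(n, rdirichlet1(h$alpha))),
    fixed = rep(h$value, n))
}

#' Mean of a distribution specification
#'
#' @param spec a `dist_spec`
#' @return analytic mean (vector for dirichlet)
#' @export
spec_mean <- function(spec) {
  h <- spec$hyper
  switch(spec$family,
    beta = h$shape1 / (h$shape1 + h$shape2),
    gamma = h$shape * h$scale,
    lognormal = exp(h$meanlog + h$sdlog^2 / 2),
    dirichlet = h$alpha / sum(h$alpha),
    fixed = h$value)
}

#' 95% confidence limits of a distribution specification
#'
#' Returns the 2.5th and 97.5th percentiles, used as the low/high values in
#' one-way sensitivity analysis. Errors for `fixed` (no uncertainty
#' declared) and `dirichlet` (not univariate) families.
#'
#' @param spec a `dist_spec`
#' @return numeric length-2 vector `c(low, high)`
#' @export
confidence_limits <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyper
  q <- c(0.025, 0.975)
  switch(spec$family,
    beta = stats::qbeta(q, h$shape1, h$shape2),
    gamma = stats::qgamma(q, shape = h$shape, scale = h$scale),
    lognormal = stats::qlnorm(q, h$meanlog, h$sdlog),
    dirichlet = stop("confidence_limits: dirichlet is not univariate"),
    fixed = stop("confidence_limits: no uncertainty declared"))
}

# One PSA-able parameter: a spec plus getter/setter into lynch_params.
psa_param <- function(name, spec, get, set) {
  list(name = name, spec = spec, get = get, set = set)
}

field_param <- function(name, spec, path) {
  # path: character vector into the nested params list
  psa_param(name, spec,
    get = function(p) p[[path]],
    set = function(p, v) {
      p[[path]] <- v
      p
    })
}

#' Default PSA distribution specifications
#'
#' Builds the full registry of uncertain parameters with moment-matched
#' default distributions: beta for probabilities (SE 10% of mean), gamma for
#' unit costs (SE 20%), lognormal for the two hazard ratios, dirichlet for
#' the gene mixture and stage-at-diagnosis vectors. These defaults are
#' placeholders for the original (unavailable) distribution tables and are
#' flagged as such in the documentation; override or extend the returned
#' list to use other hyperparameters.
#'
#' @param params a `lynch_params` object supplying the base-case means
#' @return named list of PSA parameter entries (each with `spec`, `get`,
#'   `set`)
#' @export
default_psa_specs <- function(params) {
  p <- params
  out <- list()
  add <- function(entry) out[[entry$name]] <<- entry

  prob <- function(name, value, path) {
    field_param(name, beta_from_mean_se(value), path)
  }
  add(field_param("prevalence_ls", beta_from_mean_se(p$prevalence_ls),
    path = "prevalence_ls"))
  # prevalence draw also rescales the age curve so heterogeneity analyses
  # stay consistent with the drawn level
  out$prevalence_ls$set <- function(pp, v) {
    sc <- v / pp$prevalence_ls
    pp$prevalence_ls <- v
    pp$prevalence_by_age$prevalence <-
      pmin(1, pp$prevalence_by_age$prevalence * sc)
    pp
  }

  two <- function(name, value, outer, inner) {
    e <- psa_param(name, beta_from_mean_se(value),
      get = function(pp) pp[[outer]][[inner]],
      set = function(pp, v) {
        pp[[outer]][[inner]] <- v
        pp
      })
    add(e)
  }
  two("ihc_sensitivity", p$ihc$sensitivity, "ihc", "sensitivity")
  two("ihc_specificity", p$ihc$specificity, "ihc", "specificity")
  two("ihc_failure_rate", p$ihc$failure_rate, "ihc", "failure_rate")
  two("msi_sensitivity", p$msi$sensitivity, "msi", "sensitivity")
  two("msi_specificity", p$msi$specificity, "msi", "specificity")
  two("msi_failure_rate", p$msi$failure_rate, "msi", "failure_rate")
  two("p_dmlh1_mlh1_carrier", p$staining$mlh1_carrier,
      "staining", "mlh1_carrier")
  two("p_dmlh1_other_carrier", p$staining$other_carrier,
      "staining", "other_carrier")
  two("p_dmlh1_sporadic", p$staining$sporadic, "staining", "sporadic")
  two("meth_dmlh1_sensitivity", p$meth_dmlh1$sensitivity,
      "meth_dmlh1", "sensitivity")
  two("meth_dmlh1_specificity", p$meth_dmlh1$specificity,
      "meth_dmlh1", "specificity")
  two("meth_msi_sensitivity", p$meth_msi$sensitivity,
      "meth_msi", "sensitivity")
  two("meth_msi_p_meth_other_carrier", p$meth_msi$p_meth_other_carrier,
      "meth_msi", "p_meth_other_carrier")
  two("meth_msi_p_meth_sporadic", p$meth_msi$p_meth_sporadic,
      "meth_msi", "p_meth_sporadic")
  two("germline_diagnostic_sensitivity", p$germline$diagnostic_sensitivity,
      "germline", "diagnostic_sensitivity")
  two("p_attend_counselling", p$uptake$p_attend_counselling,
      "uptake", "p_attend_counselling")
  two("p_decline_test", p$uptake$p_decline_test, "uptake", "p_decline_test")

  add(psa_param("ec_mortality_ls_per_1000py",
    gamma_from_mean_se(p$ec_mortality$ls_per_1000py),
    get = function(pp) pp$ec_mortality$ls_per_1000py,
    set = function(pp, v) {
      pp$ec_mortality$ls_per_1000py <- v
      pp
    }))
  add(psa_param("surveillance_incidence_hr",
    lognormal_from_mean(p$crc$surveillance_incidence_hr, sdlog = 0.25),
    get = function(pp) pp$crc$surveillance_incidence_hr,
    set = function(pp, v) {
      pp$crc$surveillance_incidence_hr <- v
      pp
    }))
  add(psa_param("crc_mortality_hr_ls_stage123",
    lognormal_from_mean(p$crc$mortality_hr_ls_early, sdlog = 0.15),
    get = function(pp) pp$crc$mortality_hr_ls_early,
    set = function(pp, v) {
      pp$crc$mortality_hr_ls_early <- v
      pp
    }))
  add(psa_param("stage4_utility_multiplier",
    beta_from_mean_se(p$utilities$stage4_multiplier),
    get = function(pp) pp$utilities$stage4_multiplier,
    set = function(pp, v) {
      pp$utilities$stage4_multiplier <- v
      pp
    }))
  # LS CRC incidence level: a single multiplicative uncertainty on the whole
  # gene/age surface (curve-level uncertainty; shape held fixed)
  add(psa_param("crc_incidence_ls_scale",
    lognormal_from_mean(1, sdlog = 0.15),
    get = function(pp) pp$crc$incidence_ls_scale %||% 1,
    set = function(pp, v) {
      base <- pp$crc$incidence_ls_scale %||% 1
      pp$crc$incidence_ls$rate <- pp$crc$incidence_ls$rate * v / base
      pp$crc$incidence_ls_scale <- v
      pp
    }))

  for (k in required_cost_keys()) {
    local({
      key <- k
      add(psa_param(paste0("cost_", sub("_gbp$", "", key)),
        gamma_from_mean_se(p$costs[[key]]),
        get = function(pp) pp$costs[[key]],
        set = function(pp, v) {
          pp$costs[[key]] <- v
          pp
        }))
    })
  }

  add(psa_param("overall_gene_mix",
    dist_spec("dirichlet", alpha = 100 * p$overall_gene_mix),
    get = function(pp) pp$overall_gene_mix,
    set = function(pp, v) {
      v <- stats::setNames(as.numeric(v), ls_genes())
      # shift the whole age-resolved mixture consistently with the drawn
      # overall mixture (reweight and renormalise each row)
      ratio <- v / pp$overall_gene_mix
      mix <- as.matrix(pp$gene_mix_by_age[, ls_genes()])
      mix <- sweep(mix, 2, ratio, `*`)
      mix <- mix / rowSums(mix)
      pp$gene_mix_by_age[, ls_genes()] <- mix
      pp$overall_gene_mix <- v
      pp
    }))
  for (arm in c("surveillance", "none")) {
    local({
      a <- arm
      add(psa_param(paste0("stage_distribution_", a),
        dist_spec("dirichlet", alpha = 50 * p$crc$stage_distribution[[a]]),
        get = function(pp) pp$crc$stage_distribution[[a]],
        set = function(pp, v) {
          pp$crc$stage_distribution[[a]] <- as.numeric(v)
          pp
        }))
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Samples every entry in `specs` jointly (probability vectors via
#' dirichlet, so they still sum to 1), writes the draws into a copy of
#' `params`, and re-validates. Identical seeds give identical draws. Values
#' outside a parameter's domain are resampled (up to 100 attempts) rather
#' than silently accepted; with the packaged families this never triggers.
#'
#' @param params base-case `lynch_params`
#' @param specs registry from [default_psa_specs()] (or a modified copy)
#' @param seed integer seed
#' @return a new validated `lynch_params`
#' @export
sample_psa_draw <- function(params, specs = default_psa_specs(params),
                            seed) {
  with_local_seed(seed, {
    p <- params
    for (entry in specs) {
      for (attempt in 1:100) {
        v <- spec_sample(entry$spec, 1L)
        if (entry$spec$family == "dirichlet") v <- as.numeric(v)
        ok <- tryCatch({
          p2 <- entry$set(p, v)
          TRUE
        }, error = function(e) FALSE)
        if (ok) {
          p <- p2
          break
        }
        if (attempt == 100) {
          stop("could not draw a valid value for ", entry$name)
        }
      }
    }
    validate_parameters(p)
    p
  })
}
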