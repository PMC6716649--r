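#' @title Synthetic data generators
#' @description
#' Generators for every tabulated model input that the published analysis
#' sourced from registries, national statistics or supplementary appendices.
#' They stand in for data that cannot be shipped: all-cause life tables,
#' sporadic colorectal cancer (CRC) incidence and survival schedules,
#' gene- and age-specific CRC incidence in Lynch syndrome (LS) carriers,
#' CRC management costs, utility population norms, the endometrial cancer
#' (EC) age-at-diagnosis distribution and the relatives' age distribution.
#' All generators are pure functions of their arguments (plus an explicit
#' seed where random), so fixtures regenerate bit-identically.
#' @name synth
NULL

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Run code with a local RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library code never perturbs user-level randomness.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification for synthetic data generation
#'
#' Collects the generating parameters shared by the synthetic fixtures:
#' bivariate accuracy-study parameters, Gompertz-Makeham life-table shape,
#' and the EC age-distribution shape.
#'
#' @param seed integer seed for the random generators
#' @param n_studies number of diagnostic accuracy studies
#' @param mu_sens,mu_spec logit-scale means of study-level sensitivity and
#'   specificity
#' @param tau_sens,tau_spec between-study SDs on the logit scale (>= 0)
#' @param rho correlation of logit sensitivity and specificity, in [-1, 1]
#' @param n_diseased,n_nondiseased subjects per study arm
#' @param makeham_a,gompertz_b,gompertz_theta female all-cause hazard
#'   m(a) = makeham_a + gompertz_b * exp(gompertz_theta * a); male rates use
#'   `male_b` in place of `gompertz_b`
#' @param male_b Gompertz slope coefficient for males
#' @param ec_age_shape,ec_age_scale,ec_age_shift gamma shape/scale/shift for
#'   the EC age-at-diagnosis distribution (mode = shift + (shape-1)*scale)
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(seed = 1L,
                       n_studies = 30L,
                       mu_sens = logit(0.944), mu_spec = logit(0.748),
                       tau_sens = 0.3, tau_spec = 0.3, rho = -0.2,
                       n_diseased = 150L, n_nondiseased = 150L,
                       makeham_a = 1.5e-4, gompertz_b = 1.2e-5,
                       gompertz_theta = 0.101, male_b = 2.0e-5,
                       ec_age_shape = 9, ec_age_scale = 3.4,
                       ec_age_shift = 35) {
  stopifnot(tau_sens >= 0, tau_spec >= 0, rho >= -1, rho <= 1,
            n_studies >= 1, n_diseased >= 1, n_nondiseased >= 1)
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate study-level diagnostic accuracy tables
#'
#' Study-level (logit sensitivity, logit specificity) pairs are drawn from a
#' bivariate normal with means `(mu_sens, mu_spec)`, SDs `(tau_sens,
#' tau_spec)` and correlation `rho`; cell counts are then binomial within
#' each study arm. This is exactly the data-generating process assumed by
#' [fit_bivariate()], closing the parameter-recovery loop.
#'
#' @param spec a [synth_spec()]
#' @return data.frame with columns study_id, tp, fn, tn, fp
#' @export
gen_accuracy_studies <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_studies
    z1 <- stats::rnorm(n)
    z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * stats::rnorm(n)
    l_sens <- spec$mu_sens + spec$tau_sens * z1
    l_spec <- spec$mu_spec + spec$tau_spec * z2
    tp <- stats::rbinom(n, spec$n_diseased, expit(l_sens))
    tn <- stats::rbinom(n, spec$n_nondiseased, expit(l_spec))
    data.frame(
      study_id = sprintf("S%02d", seq_len(n)),
      tp = tp, fn = spec$n_diseased - tp,
      tn = tn, fp = spec$n_nondiseased - tn
    )
  })
}

#' Generate an all-cause mortality life table
#'
#' Gompertz-Makeham annual hazards by single year of age 0-100 and sex.
#' Deterministic in the spec (no sampling). With the default shape the
#' implied remaining life expectancy at age 60 sits in the mid-20s (years),
#' a plausible band for a high-income country; this is documented, not
#' asserted against any national table.
#'
#' @param spec a [synth_spec()]
#' @return data.frame with columns age, female, male (annual rates)
#' @export
gen_life_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  age <- 0:100
  gomp <- function(b) spec$makeham_a + b * exp(spec$gompertz_theta * age)
  # flat juvenile floor below age 30 so infant/child rates stay tiny
  f <- pmax(gomp(spec$gompertz_b), 2e-4)
  m <- pmax(gomp(spec$male_b), 2.5e-4)
  data.frame(age = age, female = f, male = m)
}

#' Generate the endometrial-cancer age-at-diagnosis distribution
#'
#' Discretised shifted-gamma weights over ages 40-85, unimodal with mode in
#' the mid-60s (typical registry shape), normalised to sum to 1.
#'
#' @param spec a [synth_spec()]
#' @param ages integer ages covered (default 40:85)
#' @return data.frame with columns age, weight
#' @export
gen_ec_age_distribution <- function(spec, ages = 40:85) {
  stopifnot(inherits(spec, "synth_spec"))
  w <- stats::dgamma(ages - spec$ec_age_shift,
                     shape = spec$ec_age_shape, scale = spec$ec_age_scale)
  data.frame(age = ages, weight = w / sum(w))
}

#' Generate the relatives' age distribution
#'
#' Truncated-normal weights on a 5-year grid (ages 25-80), centred near the
#' low 50s so that the single representative age of 54 used in the PSA/OWSA
#' approximates the weighted average.
#'
#' @param mean,sd normal location and spread
#' @param ages age grid
#' @return data.frame with columns age, weight
#' @export
gen_relative_age_distribution <- function(mean = 52, sd = 13,
                                          ages = seq(25, 80, by = 5)) {
  w <- stats::dnorm(ages, mean, sd)
  data.frame(age = ages, weight = w / sum(w))
}

#' Sporadic (general population) CRC incidence schedule
#'
#' Exponentially age-increasing annual incidence, anchored at 1.6 per 1000
#' at age 60 and doubling roughly every 11 years. Cumulative risk to age 85
#' under the packaged life table is just over 9% — deliberately at/above
#' the top of high-income registry estimates; the level was set in the
#' one-off fixture calibration (see the methods vignette).
#'
#' @param ages ages covered
#' @return data.frame with columns age, rate (annual, per person)
#' @export
gen_crc_incidence_general <- function(ages = 25:100) {
  data.frame(age = ages, rate = 1.6e-3 * exp(0.065 * (ages - 60)))
}

#' General-population CRC mortality by stage group
#'
#' Annual mortality rates after diagnosis for early (stage I-III) and late
#' (stage IV) disease, mildly age-increasing.
#'
#' @param ages ages covered
#' @return data.frame with columns age, early, late (annual rates)
#' @export
gen_crc_mortality_general <- function(ages = 25:100) {
  data.frame(
    age = ages,
    early = 0.045 * exp(0.010 * (ages - 60)),
    late = 0.60 * exp(0.008 * (ages - 60))
  )
}

#' Gene- and age-specific CRC incidence in LS carriers under surveillance
#'
#' Logistic-ramp annual incidence curves by mismatch-repair gene, highest
#' for MLH1 and progressively lower for MSH2, MSH6 and PMS2, emulating the
#' prospective-registry risk ordering. Values are rates *under surveillance*;
#' the model divides by the surveillance hazard ratio for the unsurveilled.
#'
#' @param ages ages covered
#' @return data.frame with columns gene, age, rate
#' @export
gen_crc_incidence_ls <- function(ages = 25:100) {
  shape <- list(
    MLH1 = c(peak = 0.019, mid = 55),
    MSH2 = c(peak = 0.016, mid = 58),
    MSH6 = c(peak = 0.009, mid = 65),
    PMS2 = c(peak = 0.003, mid = 68)
  )
  do.call(rbind, lapply(names(shape), function(g) {
    p <- shape[[g]]
    data.frame(gene = g, age = ages,
               rate = p[["peak"]] * stats::plogis((ages - p[["mid"]]) / 8))
  }))
}

#' One-off CRC management cost by age and stage at diagnosis
#'
#' Discounted-lifetime management cost charged once at incidence, by stage
#' I-IV (stage IV dearest: systemic therapy), declining slowly with age at
#' diagnosis (shorter horizons).
#'
#' @param ages ages covered
#' @return data.frame with columns age, stage1..stage4 (GBP)
#' @export
gen_crc_costs <- function(ages = 25:100) {
  base <- c(14000, 22000, 32000, 38000)
  f <- 1 - 0.004 * pmax(0, ages - 60)
  out <- data.frame(age = ages)
  for (s in 1:4) out[[paste0("stage", s)]] <- round(base[s] * f, 2)
  out
}

#' Population-norm utility values by age and sex
#'
#' Quadratic-in-age EQ-5D-like norms, female and male.
#'
#' @param ages ages covered
#' @return data.frame with columns age, female, male
#' @export
gen_utility_norms <- function(ages = 25:100) {
  u <- function(a) pmin(1, 1 - 0.0018 * a - 8e-6 * a^2)
  data.frame(age = ages, female = u(ages), male = pmin(1, u(ages) + 0.01))
}

#' Sporadic endometrial-cancer mortality schedule
#'
#' Linear interpolation between the published endpoints 26.4 per 1000
#' person-years at age 40 and 92.1 per 1000 person-years at age 85
#' (clamped outside that range).
#'
#' @param ages ages covered
#' @return data.frame with columns age, rate_per_1000py
#' @export
gen_ec_mortality_sporadic <- function(ages = 40:100) {
  a <- pmin(pmax(ages, 40), 85)
  data.frame(age = ages,
             rate_per_1000py = 26.4 + (92.1 - 26.4) * (a - 40) / 45)
}

#' LS prevalence among EC probands by age
#'
#' Logit-linear decline with age, anchored at 3.9% at age 60 (the base-case
#' proband age). The slope is a synthetic calibration choice: prevalence is
#' substantially higher in younger probands.
#'
#' @param ages ages covered
#' @param anchor prevalence at age 60
#' @param slope logit decline per year of age
#' @return data.frame with columns age, prevalence
#' @export
gen_prevalence_by_age <- function(ages = 40:85, anchor = 0.039,
                                  slope = 0.07) {
  data.frame(age = ages,
             prevalence = expit(logit(anchor) - slope * (ages - 60)))
}

# Published age-knot table of the MMR gene mixture in EC patients
# (proportions at 5-year intervals, MLH1 / MSH2 / MSH6 / PMS2).
gene_mix_knots <- function() {
  k <- data.frame(
    age  = seq(50, 80, by = 5),
    MLH1 = c(17.0, 13.6, 11.0, 8.8, 6.9, 5.2, 3.9) / 100,
    MSH2 = c(28.6, 28.4, 28.5, 29.2, 30.5, 32.1, 33.9) / 100,
    MSH6 = c(47.1, 49.8, 51.4, 52.3, 52.6, 52.4, 51.9) / 100,
    PMS2 = c(7.3, 8.2, 9.0, 9.7, 10.0, 10.2, 10.3) / 100
  )
  k
}

#' MMR gene mixture among LS-positive EC probands, by single year of age
#'
#' Interpolates the published 5-year knot table of the MLH1/MSH2/MSH6/PMS2
#' mixture on the logit scale, extrapolates logit-linearly below age 50 and
#' above age 80 using the boundary slopes, and renormalises each age's
#' 4-vector to sum to 1. MLH1's share is decreasing in age throughout.
#'
#' @param ages ages covered (default 40:85)
#' @return data.frame with columns age, MLH1, MSH2, MSH6, PMS2
#' @export
gen_gene_mix <- function(ages = 40:85) {
  k <- gene_mix_knots()
  genes <- c("MLH1", "MSH2", "MSH6", "PMS2")
  out <- sapply(genes, function(g) {
    lk <- logit(k[[g]])
    lo_slope <- (lk[2] - lk[1]) / 5
    hi_slope <- (lk[7] - lk[6]) / 5
    v <- numeric(length(ages))
    inside <- ages >= 50 & ages <= 80
    v[inside] <- stats::approx(k$age, lk, xout = ages[inside])$y
    v[ages < 50] <- lk[1] + lo_slope * (ages[ages < 50] - 50)
    v[ages > 80] <- lk[7] + hi_slope * (ages[ages > 80] - 80)
    expit(v)
  })
  out <- out / rowSums(out)
  data.frame(age = ages, out)
}

#' Relative EC incidence curves by MMR gene
#'
#' The curves used to localise the overall gene mixture in age: by Bayes'
#' rule the age-specific mixture is proportional to overall mixture times
#' the gene's relative EC incidence at that age, so the packaged curves are
#' defined as (age-specific share) / (overall share). Feeding them back
#' through [gene_mix_at_age()] reproduces the packaged mixture table
#' exactly, and the published knot rows to printed precision.
#'
#' @param overall_mix named 4-vector of overall gene proportions
#' @param ages ages covered
#' @return data.frame with columns gene, age, rate (relative incidence)
#' @export
gen_ec_incidence_curves <- function(overall_mix = c(MLH1 = 0.169,
                                                    MSH2 = 0.246,
                                                    MSH6 = 0.477,
                                                    PMS2 = 0.108),
                                    ages = 40:85) {
  mix <- gen_gene_mix(ages)
  do.call(rbind, lapply(names(overall_mix), function(g) {
    data.frame(gene = g, age = ages, rate = mix[[g]] / overall_mix[[g]])
  }))
}
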