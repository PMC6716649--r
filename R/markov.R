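#' @title Lifetime Markov cohort model
#' @description
#' Monthly-cycle cohort model of colorectal cancer (CRC) outcomes from
#' model entry to age 100, conditional on a *profile*: Lynch-syndrome
#' carrier status and gene, surveillance arm, proband/relative role (which
#' controls endometrial-cancer mortality) and sex. States: alive without
#' CRC, CRC stage I-III, CRC stage IV, dead of CRC, dead of EC, dead of
#' other causes. Transitions occur mid-cycle (life-table half-cycle
#' accrual); costs and QALYs are discounted at mid-cycle time. CRC carries
#' a one-off management cost at incidence; surveillance carries a per-cycle
#' colonoscopy cost equivalent.
#' @name markov
NULL

markov_states <- function() {
  c("ALIVE_NO_CRC", "CRC_STAGE_I_III", "CRC_STAGE_IV",
    "DEAD_CRC", "DEAD_EC", "DEAD_OTHER")
}

#' Convert an annual event rate to a transition probability
#'
#' `1 - exp(-rate * dt)` for a constant hazard over `dt` years.
#'
#' @param rate events per person-year (>= 0)
#' @param dt interval length in years (> 0)
#' @return transition probability
#' @examples
#' rate_to_prob(0.004, 1 / 12)
#' @export
rate_to_prob <- function(rate, dt) {
  if (any(rate < 0)) stop("rate must be non-negative")
  stopifnot(dt > 0)
  1 - exp(-rate * dt)
}

#' Discount factor at a time measured in months
#'
#' `(1 + annual_rate)^(-t/12)`.
#'
#' @param annual_rate annual discount rate (proportion)
#' @param t_months time in months (>= 0)
#' @return discount factor
#' @examples
#' discount_factor(0.035, 12)
#' @export
discount_factor <- function(annual_rate, t_months) {
  stopifnot(all(t_months >= 0))
  (1 + annual_rate)^(-t_months / 12)
}

#' Define a Markov profile
#'
#' @param carrier logical: Lynch-syndrome carrier?
#' @param gene mismatch-repair gene (required if `carrier`)
#' @param surveillance logical: under biennial colonoscopic surveillance?
#' @param is_proband logical: probands carry endometrial-cancer mortality
#' @param sex `"female"` or `"male"`
#' @return list of class `lynch_profile`
#' @export
markov_profile <- function(carrier, gene = NA_character_, surveillance,
                           is_proband, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (carrier && !(gene %in% ls_genes())) {
    stop("carrier profiles need a gene in ", paste(ls_genes(), collapse = "/"))
  }
  structure(list(carrier = carrier, gene = gene,
                 surveillance = surveillance, is_proband = is_proband,
                 sex = sex),
            class = "lynch_profile")
}

profile_key <- function(profile, start_age) {
  paste(profile$carrier, profile$gene, profile$surveillance,
        profile$is_proband, profile$sex, start_age, sep = "|")
}

# Cause-specific annual rates for a profile at a vector of (fractional)
# ages; `t_years` is time since model entry (EC mortality applies to the
# first `ec_mortality_duration_years` only: survivors treated as cured).
cohort_rates <- function(profile, ages, t_years, params) {
  p <- params
  r_oth <- lookup_rate(p$life_table, ages, col = profile$sex)
  if (profile$is_proband) {
    r_ec_raw <- if (profile$carrier) {
      rep(p$ec_mortality$ls_per_1000py / 1000, length(ages))
    } else {
      lookup_rate(p$ec_mortality$sporadic_by_age, ages,
                  col = "rate_per_1000py") / 1000
    }
    r_ec <- ifelse(t_years < ec_mortality_duration_years(), r_ec_raw, 0)
  } else {
    r_ec <- rep(0, length(ages))
  }
  hr <- p$crc$surveillance_incidence_hr
  # surveillance is active while the person is under the stop age
  active <- profile$surveillance & ages < p$surveillance_stop_age
  if (profile$carrier) {
    curve <- p$crc$incidence_ls[p$crc$incidence_ls$gene == profile$gene, ]
    r_surv <- lookup_rate(curve, ages)
    r_crc <- ifelse(active, r_surv, r_surv / hr)
  } else {
    # non-carriers keep their true underlying incidence even when
    # surveilled; surveillance benefits them through the stage shift only
    r_crc <- lookup_rate(p$crc$incidence_general, ages)
  }
  d_early <- lookup_rate(p$crc$mortality_general, ages, col = "early")
  if (profile$carrier) d_early <- d_early * p$crc$mortality_hr_ls_early
  d_late <- lookup_rate(p$crc$mortality_general, ages, col = "late")
  list(r_oth = r_oth, r_ec = r_ec, r_crc = r_crc,
       d_early = d_early, d_late = d_late, active = active)
}

# fixed duration over which EC excess mortality applies (design choice;
# estimates derive from 5-year survival)
ec_mortality_duration_years <- function() 5

# competing-risk apportionment: total probability from summed monthly
# rates, shared across causes proportionally to rates
split_competing <- function(rates_list, dt) {
  total <- Reduce(`+`, rates_list)
  p_total <- rate_to_prob(total, dt)
  share <- ifelse(total > 0, p_total / total, 0)
  lapply(rates_list, function(r) r * share)
}

#' One-cycle transition matrix for a profile at an age
#'
#' Row-stochastic 6x6 matrix over the model states, built from the same
#' cause-specific rates the cohort engine uses (competing risks combined by
#' rate addition and proportional apportionment).
#'
#' @param profile a [markov_profile()]
#' @param age age in years at cycle start
#' @param params a `lynch_params` object
#' @param t_years time since model entry in years (default 0; controls the
#'   endometrial-cancer mortality window for probands)
#' @return 6x6 matrix with dimnames [markov_states()]
#' @export
build_transition_matrix <- function(profile, age, params, t_years = 0) {
  dt <- params$cycle_length_months / 12
  r <- cohort_rates(profile, age, t_years, params)
  sd4 <- params$crc$stage_distribution[[
    if (r$active) "surveillance" else "none"]]
  s_late <- sd4[4]

  st <- markov_states()
  m <- matrix(0, 6, 6, dimnames = list(st, st))
  # from ALIVE
  a <- split_competing(list(crc = r$r_crc, ec = r$r_ec, oth = r$r_oth), dt)
  m[1, 2] <- a$crc * (1 - s_late)
  m[1, 3] <- a$crc * s_late
  m[1, 5] <- a$ec
  m[1, 6] <- a$oth
  m[1, 1] <- 1 - sum(m[1, -1])
  # from CRC I-III
  b <- split_competing(list(crc = r$d_early, ec = r$r_ec, oth = r$r_oth), dt)
  m[2, 4] <- b$crc
  m[2, 5] <- b$ec
  m[2, 6] <- b$oth
  m[2, 2] <- 1 - sum(m[2, -2])
  # from CRC IV
  d <- split_competing(list(crc = r$d_late, ec = r$r_ec, oth = r$r_oth), dt)
  m[3, 4] <- d$crc
  m[3, 5] <- d$ec
  m[3, 6] <- d$oth
  m[3, 3] <- 1 - sum(m[3, -3])
  for (i in 4:6) m[i, i] <- 1
  if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < -1e-12)) {
    stop("transition matrix is not row-stochastic")
  }
  m
}

#' Run the monthly cohort model for one profile
#'
#' Iterates from `start_age` to the horizon age in monthly cycles, accruing
#' half-cycle-corrected, mid-cycle-discounted costs and QALYs. Utilities are
#' the age/sex population norm, multiplied by the stage IV decrement in
#' metastatic CRC and zero when dead. Costs: a one-off CRC management cost
#' on the incident flow into CRC states (expected over the stage split),
#' and for surveilled profiles a per-cycle colonoscopy cost equivalent
#' (unit cost divided by the interval) applied to CRC-free alive occupancy.
#'
#' @param profile a [markov_profile()]
#' @param start_age entry age in years (below the horizon age)
#' @param params a `lynch_params` object
#' @return object of class `lynch_trace`: occupancy matrix `trace`
#'   (cycles+1 x 6), per-cycle discounted `cost` and `qaly` increments, and
#'   totals `total_cost`, `total_qaly`, `life_years` (discounted),
#'   `cum_crc_incidence`
#' @export
run_cohort <- function(profile, start_age, params) {
  p <- params
  stopifnot(start_age < p$horizon_age)
  dt <- p$cycle_length_months / 12
  n <- ceiling((p$horizon_age - start_age) / dt)
  ages <- start_age + (0:(n - 1)) * dt
  t_years <- (0:(n - 1)) * dt

  r <- cohort_rates(profile, ages, t_years, p)
  sd_s <- p$crc$stage_distribution$surveillance
  sd_n <- p$crc$stage_distribution$none
  s_late <- ifelse(r$active, sd_s[4], sd_n[4])

  a <- split_competing(list(crc = r$r_crc, ec = r$r_ec, oth = r$r_oth), dt)
  b <- split_competing(list(crc = r$d_early, ec = r$r_ec, oth = r$r_oth), dt)
  d <- split_competing(list(crc = r$d_late, ec = r$r_ec, oth = r$r_oth), dt)

  tr <- matrix(0, n + 1, 6, dimnames = list(NULL, markov_states()))
  tr[1, 1] <- 1
  inflow_e <- numeric(n)
  inflow_l <- numeric(n)
  for (t in seq_len(n)) {
    al <- tr[t, 1]; ce <- tr[t, 2]; cl <- tr[t, 3]
    ie <- al * a$crc[t] * (1 - s_late[t])
    il <- al * a$crc[t] * s_late[t]
    inflow_e[t] <- ie
    inflow_l[t] <- il
    tr[t + 1, 1] <- al - ie - il - al * (a$ec[t] + a$oth[t])
    tr[t + 1, 2] <- ce + ie - ce * (b$crc[t] + b$ec[t] + b$oth[t])
    tr[t + 1, 3] <- cl + il - cl * (d$crc[t] + d$ec[t] + d$oth[t])
    tr[t + 1, 4] <- tr[t, 4] + ce * b$crc[t] + cl * d$crc[t]
    tr[t + 1, 5] <- tr[t, 5] + (al * a$ec[t] + ce * b$ec[t] + cl * d$ec[t])
    tr[t + 1, 6] <- tr[t, 6] + (al * a$oth[t] + ce * b$oth[t] + cl * d$oth[t])
  }

  disc <- discount_factor(p$discount_rate_annual,
                          ((seq_len(n)) - 0.5) * p$cycle_length_months)
  u_base <- lookup_rate(p$utilities$norms, ages + dt / 2, col = profile$sex)
  # half-cycle (life-table) occupancy
  occ_alive <- (tr[1:n, 1] + tr[2:(n + 1), 1]) / 2
  occ_e <- (tr[1:n, 2] + tr[2:(n + 1), 2]) / 2
  occ_l <- (tr[1:n, 3] + tr[2:(n + 1), 3]) / 2

  qaly_t <- (occ_alive * u_base + occ_e * u_base +
               occ_l * u_base * p$utilities$stage4_multiplier) * dt * disc
  ly_t <- (occ_alive + occ_e + occ_l) * dt * disc

  # one-off CRC cost at incidence: expected stage-specific cost by arm
  cm <- p$costs$crc_management
  early_cost_for <- function(sd4) {
    w <- sd4[1:3] / sum(sd4[1:3])
    w[1] * lookup_rate(cm, ages, "stage1") +
      w[2] * lookup_rate(cm, ages, "stage2") +
      w[3] * lookup_rate(cm, ages, "stage3")
  }
  cost_early <- ifelse(r$active, early_cost_for(sd_s), early_cost_for(sd_n))
  cost_late <- lookup_rate(cm, ages, "stage4")
  crc_cost_t <- (inflow_e * cost_early + inflow_l * cost_late) * disc

  # colonoscopy while surveillance is active, as a per-cycle equivalent
  colo_t <- p$costs$colonoscopy_gbp / (p$colonoscopy_interval_years / dt) *
    occ_alive * disc * as.numeric(r$active)

  cost_t <- crc_cost_t + colo_t
  structure(list(
    profile = profile, start_age = start_age,
    trace = tr, ages = c(ages, start_age + n * dt),
    cost = cost_t, qaly = qaly_t,
    total_cost = sum(cost_t), total_qaly = sum(qaly_t),
    life_years = sum(ly_t),
    cum_crc_incidence = sum(inflow_e) + sum(inflow_l)
  ), class = "lynch_trace")
}

#' @export
print.lynch_trace <- function(x, ...) {
  cat("<cohort trace> start age", x$start_age, "-", nrow(x$trace) - 1,
      "monthly cycles\n")
  cat(sprintf("  discounted cost GBP %.2f, QALYs %.4f, CRC incidence %.4f\n",
              x$total_cost, x$total_qaly, x$cum_crc_incidence))
  invisible(x)
}

#' Export a cohort trace as a long data.frame
#'
#' @param trace a `lynch_trace`
#' @return data.frame with cycle, age, one column per state, and the
#'   discounted per-cycle cost and QALY increments (NA on the final row)
#' @export
trace_as_df <- function(trace) {
  n <- nrow(trace$trace)
  data.frame(cycle = 0:(n - 1), age = trace$ages, trace$trace,
             disc_cost = c(trace$cost, NA), disc_qaly = c(trace$qaly, NA))
}

#' Probability-weighted lifetime outcomes over a profile mixture
#'
#' @param mix data.frame with columns `weight`, `start_age`, and the
#'   profile fields `carrier`, `gene`, `surveillance`, `is_proband`, `sex`;
#'   weights must sum to 1
#' @param params a `lynch_params` object
#' @param cache optional environment memoising traces across calls
#' @return list with `cost` and `qaly` (expected per person, GBP and QALYs)
#' @export
lifetime_outcomes <- function(mix, params, cache = new.env()) {
  if (abs(sum(mix$weight) - 1) > 1e-9) stop("mixture weights must sum to 1")
  cost <- 0
  qaly <- 0
  for (i in seq_len(nrow(mix))) {
    w <- mix$weight[i]
    if (w == 0) next
    pr <- markov_profile(mix$carrier[i], mix$gene[i], mix$surveillance[i],
                         mix$is_proband[i], mix$sex[i])
    key <- profile_key(pr, mix$start_age[i])
    trace <- cache[[key]]
    if (is.null(trace)) {
      trace <- run_cohort(pr, mix$start_age[i], params)
      cache[[key]] <- trace
    }
    cost <- cost + w * trace$total_cost
    qaly <- qaly + w * trace$total_qaly
  }
  list(cost = cost, qaly = qaly)
}
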