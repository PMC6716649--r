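#' @title Evidence synthesis
#' @description
#' The computations used to turn study-level evidence into model inputs:
#' bivariate random-effects meta-analysis of diagnostic sensitivity and
#' specificity (Reitsma-type model, normal approximation on the logit scale
#' within study), univariate random-effects pooling of proportions, and the
#' Bayes-rule localisation of the overall mismatch-repair gene mixture into
#' age-specific mixtures using relative endometrial-cancer incidence
#' curves.
#' @name evidence
NULL

# logit transforms with 0.5 continuity correction applied to all four cells
# of any study containing a zero cell
logit_cells <- function(a, b) {
  cc <- ifelse(a == 0 | b == 0, 0.5, 0)
  y <- log((a + cc) / (b + cc))
  v <- 1 / (a + cc) + 1 / (b + cc)
  list(y = y, v = v)
}

validate_studies <- function(studies) {
  need <- c("tp", "fn", "tn", "fp")
  if (!is.data.frame(studies) || !all(need %in% names(studies))) {
    stop("studies must be a data.frame with columns tp, fn, tn, fp")
  }
  m <- as.matrix(studies[, need])
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(studies$tp + studies$fn < 1) || any(studies$tn + studies$fp < 1)) {
    stop("each study needs at least 1 diseased and 1 non-diseased subject")
  }
  studies
}

#' Bivariate random-effects meta-analysis of sensitivity and specificity
#'
#' Fits the two-level model in which each study's (logit sensitivity, logit
#' specificity) is drawn from a bivariate normal with mean `mu` and
#' between-study covariance `Sigma`, and the within-study likelihood is
#' approximated by a normal on the logit scale with variance from the cell
#' counts (0.5 continuity correction on zero-cell studies). Maximum
#' likelihood via `optim` (L-BFGS-B on log-SD / atanh-correlation scale).
#'
#' @param studies data.frame with columns `tp`, `fn`, `tn`, `fp` (and
#'   optionally `study_id`); at least 3 studies
#' @return object of class `lynch_bivariate`: `pooled_sens`, `pooled_spec`,
#'   `mu` (logit scale), `Sigma` (2x2 between-study covariance), `tau`
#'   (between-study SDs), `rho`, `logLik`, `converged`, `n_studies`
#' @export
fit_bivariate <- function(studies) {
  studies <- validate_studies(studies)
  n <- nrow(studies)
  if (n < 3) stop("fit_bivariate requires at least 3 studies")

  se <- logit_cells(studies$tp, studies$fn)
  sp <- logit_cells(studies$tn, studies$fp)
  y <- cbind(se$y, sp$y)
  v <- cbind(se$v, sp$v)

  nll <- function(theta) {
    mu <- theta[1:2]
    t1 <- exp(theta[3])
    t2 <- exp(theta[4])
    rho <- tanh(theta[5])
    ll <- 0
    for (i in seq_len(n)) {
      s11 <- t1^2 + v[i, 1]
      s22 <- t2^2 + v[i, 2]
      s12 <- rho * t1 * t2
      det <- s11 * s22 - s12^2
      d <- y[i, ] - mu
      q <- (d[1]^2 * s22 - 2 * d[1] * d[2] * s12 + d[2]^2 * s11) / det
      ll <- ll - 0.5 * (log(2 * pi) * 2 + log(det) + q)
    }
    -ll
  }

  init <- c(colMeans(y),
            log(pmax(apply(y, 2, stats::sd), 0.05)),
            0)
  fit <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(-20, -20, log(1e-6), log(1e-6), -5),
                      upper = c(20, 20, log(10), log(10), 5),
                      control = list(maxit = 500))
  mu <- fit$par[1:2]
  tau <- exp(fit$par[3:4])
  rho <- tanh(fit$par[5])
  Sigma <- matrix(c(tau[1]^2, rho * prod(tau),
                    rho * prod(tau), tau[2]^2), 2, 2)
  structure(list(
    pooled_sens = expit(mu[1]),
    pooled_spec = expit(mu[2]),
    mu = mu, Sigma = Sigma, tau = tau, rho = rho,
    logLik = -fit$value,
    converged = fit$convergence == 0,
    n_studies = n
  ), class = "lynch_bivariate")
}

#' @export
print.lynch_bivariate <- function(x, ...) {
  cat("Bivariate diagnostic accuracy meta-analysis (", x$n_studies,
      " studies)\n", sep = "")
  cat(sprintf("  pooled sensitivity: %.3f  pooled specificity: %.3f\n",
              x$pooled_sens, x$pooled_spec))
  cat(sprintf("  between-study SD (logit): %.3f / %.3f, rho = %.2f\n",
              x$tau[1], x$tau[2], x$rho))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' Random-effects pooling of proportions on the logit scale
#'
#' Normal-normal model on logit proportions with within-study variance from
#' the counts (0.5 continuity correction for zero/full cells), fitted by
#' maximum likelihood. A single study reduces to its simple proportion.
#'
#' @param events integer vector of event counts
#' @param totals integer vector of denominators
#' @return list with `estimate`, `ci` (95%), `tau` (between-study logit SD),
#'   `mu` (pooled logit)
#' @export
pool_proportion <- function(events, totals) {
  if (length(events) == 0) stop("no studies supplied")
  if (length(events) != length(totals)) stop("lengths differ")
  if (any(events < 0) || any(events > totals)) stop("events must be in [0, total]")
  if (length(events) == 1) {
    p <- events / totals
    se <- sqrt(max(p * (1 - p), 0.25 / totals) / totals)
    return(list(estimate = p,
                ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
                tau = 0, mu = if (p %in% c(0, 1)) NA_real_ else logit(p)))
  }
  lc <- logit_cells(events, totals - events)
  y <- lc$y
  v <- lc$v
  nll <- function(theta) {
    mu <- theta[1]
    t2 <- exp(theta[2])^2
    0.5 * sum(log(2 * pi * (t2 + v)) + (y - mu)^2 / (t2 + v))
  }
  fit <- stats::optim(c(mean(y), log(max(stats::sd(y), 0.05))), nll,
                      method = "L-BFGS-B",
                      lower = c(-20, log(1e-6)), upper = c(20, log(10)))
  mu <- fit$par[1]
  tau <- exp(fit$par[2])
  se_mu <- sqrt(1 / sum(1 / (tau^2 + v)))
  list(estimate = expit(mu),
       ci = expit(mu + c(-1.96, 1.96) * se_mu),
       tau = tau, mu = mu)
}

#' Age-specific gene mixture from overall mixture and incidence curves
#'
#' By Bayes' rule, the probability that an LS-positive EC proband of age
#' `a` carries gene `g` is proportional to the overall carrier mixture times
#' the gene's relative EC incidence at that age; each age's 4-vector is
#' renormalised to sum to 1.
#'
#' @param overall_mix named probability 4-vector over MLH1, MSH2, MSH6, PMS2
#' @param curves data.frame with columns `gene`, `age`, `rate` (relative EC
#'   incidence; positive on all modelled ages)
#' @return data.frame with columns age, MLH1, MSH2, MSH6, PMS2
#' @export
gene_mix_at_age <- function(overall_mix, curves) {
  stopifnot(abs(sum(overall_mix) - 1) < 1e-9)
  genes <- names(overall_mix)
  ages <- sort(unique(curves$age))
  w <- vapply(genes, function(g) {
    cg <- curves[curves$gene == g, ]
    if (!all(ages %in% cg$age)) stop("curve for ", g, " missing ages")
    overall_mix[[g]] * cg$rate[match(ages, cg$age)]
  }, numeric(length(ages)))
  w <- matrix(w, nrow = length(ages), dimnames = list(NULL, genes))
  tot <- rowSums(w)
  if (any(tot <= 0)) {
    stop("zero total incidence at age ", ages[which(tot <= 0)[1]])
  }
  data.frame(age = ages, w / tot)
}
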