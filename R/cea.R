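#' @title Cost-effectiveness engine
#' @description
#' Incremental cost-effectiveness ratios (ICERs), strict and extended
#' dominance, the fully incremental frontier, net monetary benefit (NMB)
#' and cost-effectiveness acceptability curves (CEACs).
#' @name cea
NULL

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (GBP)
#' @param delta_qaly incremental QALYs
#' @return list with `value` (GBP/QALY or NA) and `flag` (`"ICER"`,
#'   `"DOMINANT"` — cheaper and more effective, `"DOMINATED"` — dearer and
#'   no more effective, or `"UNDEFINED"` when both deltas are zero)
#' @examples
#' icer(545000, 34.5)
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(value = NA_real_, flag = "UNDEFINED"))
  }
  if (delta_qaly > 0 && delta_cost < 0) {
    return(list(value = NA_real_, flag = "DOMINANT"))
  }
  if (delta_qaly < 0 && delta_cost >= 0 ||
        delta_qaly == 0 && delta_cost > 0) {
    return(list(value = NA_real_, flag = "DOMINATED"))
  }
  list(value = delta_cost / delta_qaly, flag = "ICER")
}

#' Round to 3 significant figures (reporting convention)
#'
#' @param x numeric
#' @return x rounded to 3 significant figures
#' @export
signif3 <- function(x) signif(x, 3)

#' Net monetary benefit versus a comparator
#'
#' `lambda * (Q - Q0) - (C - C0)`.
#'
#' @param cost,qaly strategy totals
#' @param cost0,qaly0 comparator totals
#' @param lambda willingness to pay (GBP/QALY, >= 0)
#' @return NMB in GBP
#' @export
nmb <- function(cost, qaly, cost0 = 0, qaly0 = 0, lambda) {
  stopifnot(lambda >= 0)
  lambda * (qaly - qaly0) - (cost - cost0)
}

#' Fully incremental cost-effectiveness analysis
#'
#' Sorts strategies by cost, removes strictly dominated strategies (another
#' strategy no dearer and no less effective, with one inequality strict;
#' exact ties keep the first-listed strategy), then iteratively removes
#' extendedly dominated strategies until consecutive ICERs along the
#' frontier are strictly increasing. ICERs versus the least costly strategy
#' (the comparator) and fully incremental ICERs along the frontier are
#' reported raw and rounded to 3 significant figures.
#'
#' @param results data.frame with columns `strategy`, `cost`, `qaly`
#'   (>= 2 rows, unique names)
#' @return data.frame of class `lynch_cea`: per strategy, incremental cost
#'   and QALYs vs the comparator, `icer_vs_comparator`, `frontier_label`
#'   (`COMPARATOR`, `ON_FRONTIER`, `DOMINATED`, `EXTENDEDLY_DOMINATED`),
#'   and `fully_incremental_icer` for frontier members
#' @export
frontier <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("strategy", "cost", "qaly") %in% names(results)))
  if (nrow(results) < 2) stop("need at least 2 strategies")
  if (anyDuplicated(results$strategy)) stop("strategy names must be unique")
  if (!all(is.finite(results$cost)) || !all(is.finite(results$qaly))) {
    stop("totals must be finite")
  }
  r <- results
  r$.ord <- seq_len(nrow(r))
  r <- r[order(r$cost, -r$qaly, r$.ord), ]

  label <- stats::setNames(rep("ON_FRONTIER", nrow(r)), r$strategy)
  # strict dominance (ties resolved in favour of the earlier-listed)
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(nrow(r))) {
      if (i == j) next
      ci <- r$cost[i]; qi <- r$qaly[i]
      cj <- r$cost[j]; qj <- r$qaly[j]
      dominates <- (cj < ci && qj >= qi) || (cj <= ci && qj > qi) ||
        (cj == ci && qj == qi && r$.ord[j] < r$.ord[i])
      if (dominates) {
        label[r$strategy[i]] <- "DOMINATED"
        break
      }
    }
  }
  # extended dominance: on the cost-sorted survivors, drop any interior
  # strategy whose ICER to its predecessor exceeds its successor's onward
  # ICER, until ICERs increase monotonically
  repeat {
    surv <- r[label[r$strategy] == "ON_FRONTIER", ]
    if (nrow(surv) < 3) break
    ic <- diff(surv$cost) / diff(surv$qaly)
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    label[surv$strategy[bad[1] + 1]] <- "EXTENDEDLY_DOMINATED"
  }
  comp <- r$strategy[1]
  label[comp] <- "COMPARATOR"

  out <- results
  out$inc_cost_vs_comparator <- out$cost - r$cost[1]
  out$inc_qaly_vs_comparator <- out$qaly - r$qaly[1]
  out$icer_vs_comparator <- NA_real_
  out$icer_flag <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (out$strategy[i] == comp) next
    ic <- icer(out$inc_cost_vs_comparator[i], out$inc_qaly_vs_comparator[i])
    out$icer_vs_comparator[i] <- ic$value
    out$icer_flag[i] <- ic$flag
  }
  out$frontier_label <- label[out$strategy]
  out$fully_incremental_icer <- NA_real_
  surv <- r[label[r$strategy] %in% c("COMPARATOR", "ON_FRONTIER"), ]
  if (nrow(surv) >= 2) {
    fic <- diff(surv$cost) / diff(surv$qaly)
    out$fully_incremental_icer[match(surv$strategy[-1], out$strategy)] <- fic
  }
  out$icer_vs_comparator_3sf <- signif3(out$icer_vs_comparator)
  out$fully_incremental_icer_3sf <- signif3(out$fully_incremental_icer)
  class(out) <- c("lynch_cea", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains maximal net monetary benefit; exact NMB ties
#' split their iteration's probability equally.
#'
#' @param psa_costs,psa_qalys iterations x strategies matrices with strategy
#'   column names
#' @param lambda_grid non-negative willingness-to-pay values
#' @return data.frame with columns `lambda`, `strategy`, `probability`;
#'   probabilities sum to 1 within each lambda
#' @export
ceac <- function(psa_costs, psa_qalys, lambda_grid) {
  stopifnot(is.matrix(psa_costs), is.matrix(psa_qalys),
            all(dim(psa_costs) == dim(psa_qalys)),
            nrow(psa_costs) >= 1, all(lambda_grid >= 0))
  strategies <- colnames(psa_costs)
  out <- lapply(lambda_grid, function(l) {
    nmb_it <- l * psa_qalys - psa_costs
    best <- nmb_it == apply(nmb_it, 1, max)
    share <- best / rowSums(best)
    data.frame(lambda = l, strategy = strategies,
               probability = colMeans(share), row.names = NULL)
  })
  do.call(rbind, out)
}
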