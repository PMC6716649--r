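# the published incremental results (1000 probands + 6000 relatives),
# packaged as a fixture for the printed-arithmetic checks
published <- function(analysis = "base_case") {
  tab <- utils::read.csv(lynch_extdata("published_increments.csv"))
  tab[tab$analysis == analysis, ]
}

published_results <- function(analysis = "base_case") {
  tab <- published(analysis)
  rbind(data.frame(strategy = "NO_TESTING", cost = 0, qaly = 0),
        data.frame(strategy = tab$strategy, cost = tab$inc_cost_vs_none_gbp,
                   qaly = tab$inc_qalys_vs_none))
}

test_that("icer reproduces printed ratios and flags dominance", {
  r1 <- icer(545000, 34.5)
  expect_equal(r1$flag, "ICER")
  expect_equal(signif3(r1$value), 15800)
  r2 <- icer(538000, 37.9)
  expect_equal(signif3(r2$value), 14200)
  expect_equal(icer(-1, 1)$flag, "DOMINANT")
  expect_equal(icer(1, -1)$flag, "DOMINATED")
  expect_equal(icer(1, 0)$flag, "DOMINATED")
  expect_equal(icer(0, 0)$flag, "UNDEFINED")
})

test_that("frontier reproduces the published base-case classification", {
  cea <- frontier(published_results())
  lab <- setNames(cea$frontier_label, cea$strategy)
  expect_equal(lab[["MSI_METH"]], "DOMINATED")
  expect_equal(lab[["DIRECT"]], "DOMINATED")
  expect_equal(lab[["MSI"]], "EXTENDEDLY_DOMINATED")
  expect_equal(lab[["NO_TESTING"]], "COMPARATOR")
  expect_equal(lab[["IHC_METH"]], "ON_FRONTIER")
  expect_equal(lab[["IHC"]], "ON_FRONTIER")
  # fully incremental ICERs along the surviving frontier
  expect_equal(cea$fully_incremental_icer[cea$strategy == "IHC_METH"],
               538000 / 37.9, tolerance = 1e-9)
  expect_equal(cea$fully_incremental_icer[cea$strategy == "IHC"],
               288000 / 2.3, tolerance = 1e-9)
})

test_that("frontier handles ties and degenerate cases", {
  r <- data.frame(strategy = c("A", "B"), cost = c(10, 20),
                  qaly = c(1, 1))
  cea <- frontier(r)
  expect_equal(cea$frontier_label, c("COMPARATOR", "DOMINATED"))
  # exact tie: earlier-listed strategy kept
  r2 <- data.frame(strategy = c("A", "B"), cost = c(10, 10), qaly = c(1, 1))
  cea2 <- frontier(r2)
  expect_equal(cea2$frontier_label, c("COMPARATOR", "DOMINATED"))
  expect_error(frontier(r[1, ]), "at least 2")
  expect_error(frontier(rbind(r, r)), "unique")
})

test_that("frontier is invariant to input order and affine cost scaling", {
  res <- published_results()
  base <- frontier(res)
  perm <- res[c(4, 1, 6, 2, 5, 3), ]
  permuted <- frontier(perm)
  expect_equal(
    setNames(permuted$frontier_label, permuted$strategy)[res$strategy],
    setNames(base$frontier_label, base$strategy)[res$strategy])
  scaled <- res
  scaled$cost <- scaled$cost * 3.7
  expect_equal(frontier(scaled)$frontier_label, base$frontier_label)
})

test_that("frontier agrees with the brute-force NMB-maximiser oracle", {
  check_one <- function(res) {
    cea <- frontier(res)
    on_f <- cea$frontier_label %in% c("ON_FRONTIER", "COMPARATOR")
    # candidate breakpoints: every pairwise ICER in the data; testing at
    # midpoints between consecutive breakpoints guarantees each linear
    # NMB-maximising segment is visited
    dq <- outer(res$qaly, res$qaly, `-`)
    dc <- outer(res$cost, res$cost, `-`)
    br <- sort(unique(c(0, pmax(0, dc[dq != 0] / dq[dq != 0]))))
    br <- br[is.finite(br)]
    lambdas <- c((br[-1] + br[-length(br)]) / 2, max(br) + 1, 0)
    best_somewhere <- rep(FALSE, nrow(res))
    for (l in lambdas) {
      nmb_l <- l * res$qaly - res$cost
      best <- nmb_l >= max(nmb_l) - 1e-9 * max(1, abs(max(nmb_l)))
      # ties resolved toward the frontier candidate
      if (any(best & on_f)) best[!on_f] <- FALSE
      best_somewhere <- best_somewhere | best
    }
    expect_equal(on_f, best_somewhere,
                 info = paste(utils::capture.output(print(res)),
                              collapse = "\n"))
  }
  check_one(published_results())
  withr::with_seed(42, {
    for (i in 1:200) {
      k <- sample(2:8, 1)
      res <- data.frame(strategy = paste0("S", 1:k),
                        cost = round(stats::runif(k, 0, 1e6)),
                        qaly = round(stats::runif(k, 0, 100), 1))
      check_one(res)
    }
  })
})

test_that("nmb arithmetic", {
  expect_equal(nmb(538000, 37.9, 0, 0, lambda = 20000),
               20000 * 37.9 - 538000)
  expect_equal(nmb(538000, 37.9, 0, 0, lambda = 538000 / 37.9), 0,
               tolerance = 1e-9)
  expect_equal(nmb(538000, 37.9, 0, 0, lambda = 0), -538000)
  expect_error(nmb(1, 1, 0, 0, lambda = -5))
})

test_that("ceac basics: indicator vector, step function, rows sum to 1", {
  co <- matrix(c(100, 200), 1, dimnames = list(NULL, c("A", "B")))
  qa <- matrix(c(1, 2), 1, dimnames = list(NULL, c("A", "B")))
  out <- ceac(co, qa, c(50, 200))
  # at lambda=50 A wins (NMB -50 vs -100); at 200 B wins (0 vs 100... )
  expect_equal(out$probability[out$lambda == 50 & out$strategy == "A"], 1)
  expect_equal(out$probability[out$lambda == 200 & out$strategy == "B"], 1)
  # identical iterations: step function of lambda
  co2 <- co[rep(1, 10), , drop = FALSE]
  qa2 <- qa[rep(1, 10), , drop = FALSE]
  out2 <- ceac(co2, qa2, seq(0, 300, by = 50))
  expect_true(all(out2$probability %in% c(0, 0.5, 1)))
  for (l in unique(out2$lambda)) {
    expect_equal(sum(out2$probability[out2$lambda == l]), 1)
  }
})

test_that("ceac matches the closed-form normal probability", {
  n <- 1e5
  mq <- 0.5; sq <- 1; mc <- 5000; sc <- 3000
  withr::with_seed(9, {
    dq <- rnorm(n, mq, sq)
    dc <- rnorm(n, mc, sc)
  })
  co <- cbind(A = rep(0, n), B = dc)
  qa <- cbind(A = rep(0, n), B = dq)
  for (l in c(5000, 10000, 20000)) {
    out <- ceac(co, qa, l)
    analytic <- stats::pnorm(0, l * mq - mc, sqrt(l^2 * sq^2 + sc^2),
                             lower.tail = FALSE)
    expect_equal(out$probability[out$strategy == "B"], analytic,
                 tolerance = 0.01)
  }
})
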