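# Per-CpG testing: coverage-corrected difference, beta-binomial LRT,
# BH adjustment, DMC calling and pre-seroconversion subsetting.

test_that("coverage-corrected difference pools counts before dividing", {
  expect_equal(coverageCorrectedDifference(8, 10, 3, 10), 0.5)
  expect_equal(coverageCorrectedDifference(c(5, 5), c(10, 10),
                                           c(5, 5), c(10, 10)), 0)
  # hand-evaluated pooled proportions: (15/30) - (3/20) = 0.35
  expect_equal(coverageCorrectedDifference(c(5, 10), c(10, 20),
                                           c(2, 1), c(10, 10)), 0.35)
  # zero-coverage group is undefined
  expect_true(is.na(coverageCorrectedDifference(0, 0, 3, 10)))
})

test_that("delta is antisymmetric under swapping group labels", {
  me <- makePairedME(n_sites = 30, delta = 0.2, seed = 11)
  d1 <- methpairs:::.deltaVector(me)
  flipped <- me
  flipped$group <- ifelse(me$group == "case", "control", "case")
  d2 <- methpairs:::.deltaVector(flipped)
  expect_equal(d1, -d2)
})

test_that("identical counts in both groups give p = 1", {
  meth <- matrix(5L, 3, 8)
  total <- matrix(10L, 3, 8)
  me <- makeToyME(meth, total, n_pairs = 4,
                  group = rep(c("case", "control"), 4),
                  pair = rep(sprintf("P%02d", 1:4), each = 2))
  res <- testDMCs(me)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$delta == 0))
})

test_that("an extreme fully separated site matches the brute-force fit", {
  # case cells all 30/30, control cells all 0/30, 7 pairs: the free
  # dispersion lets the null absorb the bimodality, so the LRT is finite;
  # the statistic must match an independent likelihood evaluation
  meth <- matrix(rep(c(30L, 0L), 7), 1, 14)
  total <- matrix(30L, 1, 14)
  me <- makeToyME(meth, total, n_pairs = 7,
                  group = rep(c("case", "control"), 7),
                  pair = rep(sprintf("P%02d", 1:7), each = 2))
  res <- testDMCs(me)
  expect_equal(res$delta, 1)
  expect_lt(res$p_value, 0.01)
  # independent oracle: pure-R beta-binomial likelihood + Nelder-Mead
  bbnll <- function(par, X, m, n) {
    eta <- pmin(pmax(drop(X %*% par[-length(par)]), -13.8), 13.8)
    mu <- plogis(eta)
    s <- exp(pmin(pmax(par[length(par)], -7), 12))
    a <- mu * s; b <- (1 - mu) * s
    -sum(lbeta(m + a, n - m + b) - lbeta(a, b))
  }
  grp <- rep(c(1, 0), 7); pairf <- rep(1:7, each = 2)
  Xf <- cbind(1, sapply(2:7, function(k) as.numeric(pairf == k)), grp)
  X0 <- Xf[, -ncol(Xf)]
  fitO <- function(X) {
    st <- c(rep(0, ncol(X)), 3)
    o <- optim(st, bbnll, X = X, m = meth[1, ], n = total[1, ],
               method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-13))
    optim(o$par, bbnll, X = X, m = meth[1, ], n = total[1, ],
          method = "Nelder-Mead",
          control = list(maxit = 20000, reltol = 1e-13))$value
  }
  lrt_oracle <- 2 * (fitO(X0) - fitO(Xf))
  expect_equal(res$stat, lrt_oracle, tolerance = 1e-3)
})

test_that("p-values are invariant to permuting sample order", {
  me <- makePairedME(n_sites = 25, delta = 0.15, seed = 12)
  res <- testDMCs(me)
  perm <- sample(ncol(me))
  res2 <- testDMCs(me[, perm])
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-6)
  expect_equal(res$delta, res2$delta)
})

test_that("BH adjustment matches the closed-form micro-examples", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(numeric(0)), numeric(0))
  # NA p-values are excluded from the universe
  q <- bhAdjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bhAdjust(c(0.01, 0.02)))
})

test_that("BH equals the brute-force step-up oracle elementwise", {
  set.seed(99)
  for (i in 1:5) {
    p <- runif(100)^(1 + i / 2)
    expect_equal(bhAdjust(p), bhStepUpOracle(p), tolerance = 1e-15)
  }
})

test_that("DMC calling applies q and delta thresholds after testing", {
  me <- makePairedME(n_sites = 40, n_pairs = 7, n_tp = 3, delta = 0.4,
                     p0 = runif(40, 0.2, 0.5), seed = 13)
  called <- callDMCs(me, fdr = 0.1, min_delta = 0.1)
  expect_gt(length(called), 0)
  expect_true(all(called$q_value < 0.1))
  expect_true(all(abs(called$delta) > 0.1))
  # sorted by p
  expect_true(!is.unsorted(called$p_value))
  # delta threshold dominance: an impossible delta yields no calls
  expect_length(callDMCs(me, min_delta = 1.1), 0)
  # determinism
  called2 <- callDMCs(me, fdr = 0.1, min_delta = 0.1)
  expect_identical(as.data.frame(called), as.data.frame(called2))
})

test_that("q-values are computed over all tested sites, then filtered", {
  me <- makePairedME(n_sites = 30, delta = 0.3, seed = 14)
  called <- callDMCs(me)
  all_sites <- attr(called, "all_sites")
  expect_equal(sort(all_sites$q_value),
               sort(bhAdjust(all_sites$p_value)))
  expect_equal(length(all_sites), nrow(me))
})

test_that("pre-seroconversion subsetting keeps strictly earlier samples", {
  # one pair, samples at 12/18/24 months, case seroconverts at 18
  meth <- matrix(5L, 2, 6)
  total <- matrix(10L, 2, 6)
  age <- c(12, 18, 24, 12, 18, 24)
  grp <- rep(c("case", "control"), each = 3)
  me <- makeToyME(meth, total, n_pairs = 1, group = grp,
                  pair = rep("P1", 6), age = age,
                  sc_age = ifelse(grp == "case", 18, NA))
  sub <- subsetPreSeroconversion(me)
  expect_equal(ncol(sub), 2L)
  expect_equal(sort(sub$group), c("case", "control"))
  expect_true(all(sub$age_months == 12))
})

test_that("control-only time points are dropped from the pre-sc subset", {
  meth <- matrix(5L, 1, 5)
  total <- matrix(10L, 1, 5)
  age <- c(12, 18, 12, 18, 24)  # control has an extra 24-month sample
  grp <- c("case", "case", "control", "control", "control")
  me <- makeToyME(meth, total, n_pairs = 1, group = grp,
                  pair = rep("P1", 5), age = age,
                  sc_age = ifelse(grp == "case", 20, NA))
  sub <- subsetPreSeroconversion(me)
  expect_equal(sort(sub$age_months), c(12, 12, 18, 18))
})

test_that("degenerate pre-sc subsets and missing ages are errors", {
  meth <- matrix(5L, 1, 4); total <- matrix(10L, 1, 4)
  grp <- rep(c("case", "control"), 2)
  me <- makeToyME(meth, total, n_pairs = 2, group = grp,
                  pair = rep(c("P1", "P2"), each = 2), age = rep(24, 4),
                  sc_age = ifelse(grp == "case", 12, NA))
  expect_error(subsetPreSeroconversion(me), "seroconverted")
  me2 <- makeToyME(meth, total, n_pairs = 2, group = grp,
                   pair = rep(c("P1", "P2"), each = 2), age = rep(24, 4),
                   sc_age = NA_real_)
  expect_error(subsetPreSeroconversion(me2), "without a seroconversion age")
})
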