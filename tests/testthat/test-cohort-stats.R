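test_that("fisher_2x2 handles canonical and degenerate tables", {
  expect_equal(fisher_2x2(c(5, 5, 5, 5))$p, 1)
  ## closed form: [[0,10],[10,0]] -> 2 / C(20,10)
  expect_equal(fisher_2x2(c(0, 10, 10, 0))$p, 2 / choose(20, 10), tolerance = 1e-12)
  d <- fisher_2x2(c(0, 0, 3, 4))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_error(fisher_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fisher_2x2 matches full enumeration on all tables with total <= 40", {
  ## oracle: direct (non-log) summation of hypergeometric probabilities
  oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    supp <- max(0, k - n):min(k, m)
    pr <- dhyper(supp, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  worst <- 0
  for (t in seq(2, 40, by = 2)) {
    tabs <- expand.grid(a = 0:t, b = 0:t)
    tabs <- tabs[tabs$a + tabs$b <= t, ]
    for (i in seq_len(nrow(tabs))) {
      a <- tabs$a[i]; b <- tabs$b[i]
      rest <- t - a - b
      c <- rest %/% 2; d <- rest - c
      if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
      p <- fisher_2x2(c(a, b, c, d))$p
      worst <- max(worst, abs(p - oracle(a, b, c, d)))
    }
  }
  expect_lt(worst, 1e-10)
  ## spot-check agreement with the reference implementation in stats
  set.seed(51)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_2x2(tab)$p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_2x2 stays exact for extreme tables via log space", {
  p <- fisher_2x2(matrix(c(165, 22, 232, 884), 2, 2, byrow = TRUE))
  expect_equal(p$p, fisher.test(matrix(c(165, 22, 232, 884), 2, 2, byrow = TRUE))$p.value,
               tolerance = 1e-6)
  expect_lt(p$p, 1e-70)
  big <- fisher_2x2(matrix(c(187, 0, 57, 1059), 2, 2, byrow = TRUE))
  expect_true(is.finite(big$log10_p) && big$log10_p < -150)
})

test_that("welch_from_summary reproduces closed forms", {
  w <- welch_from_summary(0, 1, 100, 1, 1, 100)
  expect_equal(w$t, -1 / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(w$df, 198, tolerance = 1e-9)
  same <- welch_from_summary(5, 2, 50, 5, 2, 50)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_from_summary(0, 1, 1, 1, 1, 50), "n >= 2")
  expect_error(welch_from_summary(0, 0, 10, 1, 1, 50), "sd > 0")
  ## agrees with t.test on raw data summaries
  set.seed(52)
  x <- rnorm(40, 1, 2); y <- rnorm(60, 0, 1)
  ref <- t.test(x, y)
  w2 <- welch_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 60)
  expect_equal(w2$p, ref$p.value, tolerance = 1e-9)
  expect_equal(w2$df, unname(ref$parameter), tolerance = 1e-9)
})

test_that("prevalence comparison reports counts, Fisher and adjusted p", {
  set.seed(53)
  cohort <- rep(c("A", "B"), each = 200)
  x <- c(rbinom(200, 1, 0.4), rbinom(200, 1, 0.1))
  covars <- data.frame(age = rnorm(400, 50, 10))
  out <- prevalence_compare(cbind(mut = x), cohort, covars)
  expect_lt(out$fisher_p, 1e-6)
  expect_lt(out$adjusted_p, 1e-6)
  expect_equal(out$k_1 + out$k_2, sum(x))

  ## independence: balanced table -> Fisher p = 1
  bal <- rep(c(1, 0), 200)
  out2 <- prevalence_compare(cbind(f = bal), cohort)
  expect_equal(out2$fisher_p, 1)

  ## germline carrier rate reported as printed: 35 of 186 is 18.8%
  carrier <- c(rep(1, 35), rep(0, 151))
  expect_equal(round(100 * mean(carrier), 1), 18.8)

  ## complete separation is flagged
  sep <- as.integer(cohort == "B")
  out3 <- suppressWarnings(prevalence_compare(cbind(s = sep), cohort))
  expect_true(out3$separation)
  expect_true(is.na(out3$adjusted_p))
  expect_gt(out3$log_odds, 0)
})

test_that("adjusted and unadjusted comparisons agree in direction", {
  set.seed(54)
  for (rep in 1:5) {
    cohort <- rep(c("A", "B"), each = 150)
    p1 <- runif(1, 0.1, 0.5); p2 <- runif(1, 0.1, 0.5)
    x <- c(rbinom(150, 1, p1), rbinom(150, 1, p2))
    if (sd(x) == 0) next
    out <- prevalence_compare(cbind(f = x), cohort)
    or_dir <- sign(log(out$k_2 / (out$n_2 - out$k_2)) -
                   log(out$k_1 / (out$n_1 - out$k_1)))
    if (is.finite(or_dir) && or_dir != 0 && !out$separation)
      expect_equal(sign(out$log_odds), or_dir)
  }
})

test_that("variable usage separates perfect predictors from noise", {
  set.seed(55)
  n <- 200
  y <- rep(c("A", "B"), each = n / 2)
  X <- cbind(strong = rnorm(n, ifelse(y == "B", 1.5, 0)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  u <- variable_usage(X, y, n_boot = 60, seed = 1)
  expect_equal(unname(u["strong"]), 100)
  expect_lt(max(u[c("noise1", "noise2")]), 30)

  ## scaling invariance (internal standardisation)
  X2 <- X; X2[, "noise1"] <- X2[, "noise1"] * 1000
  u2 <- variable_usage(X2, y, n_boot = 60, seed = 1)
  expect_equal(u, u2)

  ## constant feature gets usage 0 with a warning
  X3 <- cbind(X, const = 1)
  expect_warning(u3 <- variable_usage(X3, y, n_boot = 20, seed = 1), "constant")
  expect_equal(unname(u3["const"]), 0)

  ## duplicated strong predictor: combined usage at least the single usage
  X4 <- cbind(strong = rnorm(n, ifelse(y == "B", 2, 0)), noise = rnorm(n))
  X5 <- cbind(X4, strong2 = X4[, "strong"] + rnorm(n, 0, 1e-4))
  u4 <- variable_usage(X4, y, n_boot = 40, seed = 2)
  expect_message(u5 <- variable_usage(X5, y, n_boot = 40, seed = 2), "collinearity")
  expect_gte(max(u5["strong"] + u5["strong2"], u5["strong"]) + 1e-9, u4["strong"] - 25)
})

test_that("feature-covariate matrix finds the generating covariate", {
  set.seed(56)
  n <- 240
  cov <- data.frame(cohort = rep(c("A", "B"), each = n / 2),
                    age = rnorm(n, 50, 10), purity = runif(n, 0.3, 1))
  feats <- data.frame(
    coh_driven = as.numeric(cov$cohort == "B") * 2 + rnorm(n, 0, 0.4),
    pure_noise = rnorm(n),
    binary_coh = rbinom(n, 1, ifelse(cov$cohort == "B", 0.8, 0.2)))
  rep_ <- feature_covariate_matrix(feats, cov)
  expect_equal(colnames(rep_$p), c("cohortB", "age", "purity"))
  expect_equal(names(which.min(rep_$p["coh_driven", ])), "cohortB")
  expect_equal(names(which.min(rep_$p["binary_coh", ])), "cohortB")
  expect_gt(min(rep_$p["pure_noise", ]), 0.001)
  expect_warning(feature_covariate_matrix(data.frame(c1 = rep(1, n)), cov),
                 "constant")
})
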