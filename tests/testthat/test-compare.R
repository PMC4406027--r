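test_that("discrimination measures: closed cases and ordering invariant", {
  h <- evidem_hierarchy()
  expect_equal(unname(discrimination_measures(equal_weights(h))),
               c(0, 0, 0))
  # direct arithmetic oracle on a 3-vector
  w3 <- setNames(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  m <- discrimination_measures(w3)
  expect_equal(unname(m["d13"]), 0.3)
  expect_equal(unname(m["dml"]), 0.3)
  expect_equal(unname(m["deq"]),
               mean(abs(c(0.5, 0.3, 0.2) - 1 / 3)))
  expect_error(discrimination_measures(c(a = 0.5, b = 0.5)), "at least 3")
  # dml >= d13 >= 0 for random simplex vectors, invariant to relabeling
  set.seed(12)
  for (rep in 1:50) {
    x <- runif(14); x <- x / sum(x)
    names(x) <- paste0("c", 1:14)
    dm <- discrimination_measures(x)
    expect_gte(dm[["d13"]], 0)
    expect_gte(dm[["dml"]], dm[["d13"]])
    perm <- sample(14)
    expect_equal(discrimination_measures(x[perm]), dm)
  }
})

test_that("the reference group weights separate most from least important", {
  w <- evidem_reference_weights()
  r <- rank_order(w)
  expect_identical(names(which(r == 1)), "D2")
  expect_identical(names(which(r == 14)), "C1")
  # most-least distance of the unnormalized published profile: 0.100 - 0.052
  raw <- c(D1 = 0.089, D2 = 0.100, C1 = 0.052, C2 = 0.072, I1 = 0.080,
           I2 = 0.065, I3 = 0.085, T1 = 0.075, T2 = 0.057, E1 = 0.061,
           E2 = 0.066, E3 = 0.057, Q1 = 0.069, Q2 = 0.076)
  expect_equal(unname(discrimination_measures(raw / sum(raw))["dml"]) * sum(raw),
               0.048)
})

test_that("one-sample t-test matches the textbook formula", {
  x <- c(0.4, -0.2, 0.3, 0.1, 0.0, 0.2, -0.1, 0.5, 0.3, 0.1)
  res <- test_nonzero(x)
  expect_equal(res$t, mean(x) / (sd(x) / sqrt(length(x))))
  expect_equal(res$p, 2 * pt(-abs(res$t), length(x) - 1))
  # degenerate cases
  expect_equal(test_nonzero(rep(0, 4)), list(t = 0, p = 1, mean = 0, n = 4,
                                             degenerate = FALSE))
  deg <- test_nonzero(rep(1, 4))
  expect_true(deg$degenerate)
  expect_identical(deg$t, Inf)
  expect_identical(deg$p, 0)
  expect_error(test_nonzero(1), "at least 2")
})

test_that("rank_order breaks ties canonically and flags them", {
  w <- c(a = 0.4, b = 0.3, c = 0.3)
  r <- rank_order(w)
  expect_identical(as.integer(r), c(1L, 2L, 3L))
  expect_true(attr(r, "ties"))
  r2 <- rank_order(c(a = 0.2, b = 0.5, c = 0.3))
  expect_identical(as.integer(r2), c(3L, 1L, 2L))
  expect_false(attr(r2, "ties"))
})

test_that("rank differences: hand-enumerated cases, symmetry, bounds", {
  ra <- setNames(1:4, letters[1:4])
  rb <- setNames(4:1, letters[1:4])
  rd <- rank_difference(ra, rb)
  expect_equal(unname(rd$per_criterion), c(3, 1, 1, 3))
  expect_equal(rd$mean, 2)
  # identical rankings: zero mean and sd
  expect_equal(rank_difference(ra, ra)$mean, 0)
  expect_equal(rank_difference(ra, ra)$sd, 0)
  # swapping two adjacent items among 14: two diffs of 1
  r14 <- setNames(1:14, paste0("c", 1:14))
  r14b <- r14; r14b[c(3, 4)] <- r14[c(4, 3)]
  expect_equal(rank_difference(r14, r14b)$mean, 2 / 14)
  # symmetric in its arguments; bounded by (n^2-1)/n for all perms, n <= 6
  for (n in 2:6) {
    ident <- setNames(seq_len(n), paste0("i", seq_len(n)))
    perms <- combinat_perms(n)
    bound <- (n^2 - 1) / (2 * n) * 2
    for (p in perms) {
      pr <- setNames(p, names(ident))
      d1 <- rank_difference(ident, pr)
      d2 <- rank_difference(pr, ident)
      expect_equal(d1$mean, d2$mean)
      expect_lte(d1$mean, bound)
    }
  }
  expect_error(rank_difference(ra, setNames(1:4, letters[2:5])), "different")
})

test_that("agreement correlations: identity, affine invariance, noise", {
  set.seed(31)
  W <- matrix(runif(10 * 14), 10, 14)
  W <- W / rowSums(W)
  colnames(W) <- paste0("c", 1:14)
  ac <- agreement_correlations(W, W)
  expect_equal(ac$across_r, 1)
  expect_equal(ac$mean_within_r, 1)
  # per-respondent affine transforms leave correlations at 1
  W2 <- 0.5 * W + 0.01
  expect_equal(agreement_correlations(W, W2)$mean_within_r, 1)
  # zero-variance respondents are excluded and logged
  W3 <- W; W3[1, ] <- 1 / 14
  ac3 <- agreement_correlations(W, W3)
  expect_identical(ac3$excluded, "1")
  expect_false(anyNA(ac3$mean_within_r))
})

test_that("noise averages out of means: across_r >= mean_within_r", {
  # Monte-Carlo over 200 simulated paired cohorts: the across-respondent
  # correlation of the means beats the mean within-respondent correlation
  # on average, because independent response noise cancels in group means
  set.seed(55)
  base <- as.numeric(evidem_reference_weights())
  wins <- 0; diffs <- numeric(200)
  for (b in 1:200) {
    W1 <- t(replicate(12, {
      x <- base * exp(rnorm(14, sd = 0.35)); x / sum(x)
    }))
    W2 <- t(replicate(12, {
      x <- base * exp(rnorm(14, sd = 0.35)); x / sum(x)
    }))
    ac <- agreement_correlations(W1, W2)
    diffs[b] <- ac$across_r - ac$mean_within_r
  }
  expect_gt(mean(diffs), 0)
})

test_that("Bland-Altman: exact zero on identical input, offset, hand oracle", {
  x <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.25, e = 0.15)
  ba0 <- bland_altman(x, x)
  expect_identical(ba0$bias, 0)
  expect_identical(unname(ba0$loa), c(0, 0))
  expect_length(ba0$outliers, 0)
  # constant offset: pure fixed bias, zero spread
  ba1 <- bland_altman(x + 0.05, x)
  expect_equal(ba1$bias, 0.05)
  expect_equal(ba1$sd_diff, 0)
  expect_true(ba1$t_test$degenerate)
  # 5-pair toy set against direct arithmetic
  y <- c(a = 0.12, b = 0.17, c = 0.33, d = 0.22, e = 0.16)
  ba2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba2$bias, mean(d))
  expect_equal(unname(ba2$loa),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
  expect_equal(ba2$data$mean, unname((x + y) / 2))
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("order-effect analysis detects shrinkage toward uniform", {
  # anchored second positions must show smaller deq than first positions
  d <- study_design(n_respondents = 16,
                    arms = c(RA_PA = 4, PC = 4, BWS = 4, RS_H = 4),
                    anchoring = 0.6, seed = 99)
  co <- simulate_cohort(d, kappa = 20)
  wt <- derive_weights(co)$table
  oe <- order_effect_analysis(wt)
  expect_true(length(oe) >= 1)
  for (tech in names(oe)) {
    expect_s3_class(oe[[tech]]$bland_altman, "bland_altman")
    expect_gt(oe[[tech]]$n_first + oe[[tech]]$n_second, 0)
  }
  # a single-order table errors on the empty split
  wt1 <- wt[wt$position == "first", ]
  expect_error(order_effect_analysis(wt1, techniques = unique(wt1$technique)),
               "no respondents in")
})
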