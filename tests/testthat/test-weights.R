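test_that("flat ratings sum-normalize to weights", {
  h <- evidem_hierarchy()
  w <- weights_from_ratings(full_flat_rating(h), h)
  expect_equal(unname(as.numeric(w)), rep(1 / 14, 14), tolerance = 1e-12)
  h1 <- one_category_hierarchy()
  r <- rating_response("R1", c(X1 = 5, X2 = 1))
  w2 <- weights_from_ratings(r, h1)
  expect_equal(unname(as.numeric(w2)), c(5 / 6, 1 / 6))
  expect_error(weights_from_ratings(rating_response("R1", c(X1 = 0, X2 = 3)), h1),
               "1..5")
})

test_that("hierarchical uniform blocks propagate to 1/12 and 1/18 leaves", {
  h <- evidem_hierarchy()
  w <- weights_from_ratings(uniform_hier_rating(h), h)
  # category share 1/6 times within share 1/2 (2-leaf) or 1/3 (3-leaf):
  # hierarchical-uniform is NOT flat-uniform
  sizes <- category_sizes(h)
  expected <- unlist(lapply(names(sizes), function(cc)
    rep(1 / 6 / sizes[[cc]], sizes[[cc]])))
  expect_equal(unname(as.numeric(w)), unname(expected), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("point allocations multiply through the hierarchy", {
  h <- tiny_hierarchy()
  p <- point_allocation_response("R1",
    category_points = c(A = 50, B = 50),
    within_points = list(A = c(A1 = 60, A2 = 40),
                         B = c(B1 = 100, B2 = 0, B3 = 0)))
  w <- weights_from_points(p, h)
  expect_equal(as.numeric(w[c("A1", "A2", "B1")]), c(0.30, 0.20, 0.50))
  # all weight inside one category partitions that category
  p2 <- point_allocation_response("R1",
    category_points = c(A = 100, B = 0),
    within_points = list(A = c(A1 = 50, A2 = 50),
                         B = c(B1 = 50, B2 = 25, B3 = 25)))
  w2 <- weights_from_points(p2, h)
  expect_equal(sum(w2[c("A1", "A2")]), 1)
  expect_equal(unname(as.numeric(w2[c("B1", "B2", "B3")])), c(0, 0, 0))
  # uniform blocks give hierarchical-uniform weights
  h14 <- evidem_hierarchy()
  w3 <- weights_from_points(uniform_points(h14), h14)
  expect_equal(sum(w3), 1, tolerance = 1e-9)
  expect_equal(unname(as.numeric(w3[c("D1", "I1")])), c(1 / 12, 1 / 18))
  # a zero block total is an error
  p$within_points$A <- c(A1 = 0, A2 = 0)
  expect_error(weights_from_points(p, h), "not positive")
})

test_that("rank surrogates match their closed forms", {
  expect_equal(rank_shares(c(1, 2), "rank_sum"), c(2 / 3, 1 / 3))
  # rank-order centroid for a block of 3, evaluated by hand
  expect_equal(rank_shares(c(1, 2, 3), "centroid"),
               c(11 / 18, 5 / 18, 2 / 18))
  expect_equal(rank_shares(1, "rank_sum"), 1)
  expect_equal(rank_shares(1, "centroid"), 1)
  expect_error(rank_shares(c(1, 3), "rank_sum"), "permutation")
  # both schemes are decreasing in rank and sum to 1
  for (n in 2:6) for (sch in c("rank_sum", "centroid")) {
    s <- rank_shares(seq_len(n), sch)
    expect_equal(sum(s), 1)
    expect_true(all(diff(s) < 0))
  }
})

test_that("ranking responses propagate rank shares", {
  h <- tiny_hierarchy()
  k <- ranking_response("R1",
    category_ranks = c(A = 1, B = 2),
    within_ranks = list(A = c(A1 = 1, A2 = 2), B = c(B1 = 2, B2 = 1, B3 = 3)))
  w <- weights_from_ranking(k, h)
  expect_equal(as.numeric(w["A1"]), (2 / 3) * (2 / 3))
  expect_equal(as.numeric(w["B2"]), (1 / 3) * (3 / 6))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  k$within_ranks$A <- c(A1 = 1, A2 = 1)
  expect_error(weights_from_ranking(k, h), "permutation")
})

test_that("AHP local weights: closed forms and consistency identity", {
  # 2x2 block with judgment 3: shares a/(a+1) = (3/4, 1/4)
  M2 <- matrix(c(1, 1 / 3, 3, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(ahp_local_weights(M2, "geometric_mean")), c(3 / 4, 1 / 4))
  expect_equal(unname(ahp_local_weights(M2, "eigenvector")), c(3 / 4, 1 / 4),
               tolerance = 1e-9)
  # a consistent matrix is recovered exactly by both methods
  s <- c(a = 0.5, b = 0.3, c = 0.2)
  M3 <- consistent_matrix(s)
  expect_equal(ahp_local_weights(M3, "geometric_mean"), s, tolerance = 1e-9)
  expect_equal(ahp_local_weights(M3, "eigenvector"), s, tolerance = 1e-9)
  expect_equal(consistency_ratio(M3), 0, tolerance = 1e-6)
  expect_error(ahp_local_weights(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
})

test_that("geometric-mean weights track an eigen-decomposition oracle", {
  set.seed(101)
  for (rep in 1:50) {
    M <- random_reciprocal_matrix(3)
    gm <- ahp_local_weights(M, "geometric_mean")
    # oracle: dense eigen solve, principal right eigenvector
    ev <- eigen(M)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sum(v)
    # for 3x3 reciprocal matrices the two solutions coincide
    expect_equal(unname(gm), v, tolerance = 1e-6)
    # and the package's power iteration matches the oracle too
    expect_equal(unname(ahp_local_weights(M, "eigenvector")), v,
                 tolerance = 1e-6)
  }
})

test_that("hierarchical pairwise responses yield consistent weights", {
  h <- tiny_hierarchy()
  w <- weights_from_pairwise(unit_pairwise(h), h)
  expect_equal(unname(as.numeric(w)),
               c(1 / 4, 1 / 4, 1 / 6, 1 / 6, 1 / 6), tolerance = 1e-12)
  cons <- attr(w, "consistency")
  expect_true(all(cons < 1e-8))
  # a missing pair raises (derivation is strict where validation reports)
  pw <- unit_pairwise(h)
  pw$judgments <- pw$judgments[-1, ]
  expect_error(weights_from_pairwise(pw, h), "incomplete")
})

test_that("BWS counting analysis matches a hand tally", {
  h1 <- criteria_hierarchy(hier_df(c("w", "x", "y", "z"), rep("Only", 4)))
  d <- structure(list(sets = list(c("w", "x", "y"), c("x", "y", "z"),
                                  c("w", "y", "z")),
                      set_size = 3L, codes = c("w", "x", "y", "z")),
                 class = "bws_design")
  ch <- data.frame(set_index = 1:3,
                   best = c("w", "x", "w"), worst = c("y", "z", "z"))
  b <- bws_response("R1", ch)
  w <- weights_from_bws(b, d)
  # hand tally: B = (2,1,0,0), W = (0,0,1,2), r = (2,2,3,2)
  # shifted scores: (4/4, 3/4, 2/6, 0/4) = (1, 3/4, 1/3, 0), sum 25/12
  expect_equal(unname(as.numeric(w)),
               c(1, 3 / 4, 1 / 3, 0) * 12 / 25)
  expect_equal(as.numeric(w), unname(bws_count_oracle(ch, d)))
  counts <- attr(w, "counts")
  expect_identical(counts$B, c(2, 1, 0, 0))
  expect_identical(counts$r, c(2L, 2L, 3L, 2L))
})

test_that("shifted BWS scores hit the [0, 1] endpoints", {
  # always-best scores 1 and never-best-always-worst scores 0 before
  # normalization
  h1 <- criteria_hierarchy(hier_df(c("w", "x", "y"), rep("Only", 3)))
  d <- structure(list(sets = list(c("w", "x", "y"), c("w", "x", "y"),
                                  c("w", "x", "y")),
                      set_size = 3L, codes = c("w", "x", "y")),
                 class = "bws_design")
  ch <- data.frame(set_index = 1:3, best = "w", worst = "y")
  w <- weights_from_bws(bws_response("R1", ch), d)
  score <- as.numeric(w) * sum(c(1, 0.5, 0)) # undo normalization
  expect_equal(score, c(1, 0.5, 0))
})

test_that("weight invariants hold across techniques", {
  h <- evidem_hierarchy()
  set.seed(77)
  d <- study_design(n_respondents = 8,
                    arms = c(RA_PA = 2, PC = 2, BWS = 2, RS_H = 2), seed = 77)
  co <- simulate_cohort(d)
  dw <- derive_weights(co)
  sums <- tapply(dw$table$weight,
                 paste(dw$table$respondent_id, dw$table$technique), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(dw$table$weight >= 0))
})

test_that("weights are scale invariant and label equivariant", {
  h <- tiny_hierarchy()
  # scale invariance: multiplying a points block by a constant changes nothing
  p1 <- point_allocation_response("R1",
    category_points = c(A = 30, B = 70),
    within_points = list(A = c(A1 = 80, A2 = 20),
                         B = c(B1 = 10, B2 = 30, B3 = 60)))
  p2 <- p1
  p2$within_points$A <- p1$within_points$A * 7
  expect_equal(as.numeric(weights_from_points(p1, h)),
               as.numeric(weights_from_points(p2, h)))
  # permuting criterion labels permutes weights identically
  hp <- criteria_hierarchy(hier_df(
    c("A2", "A1", "B1", "B2", "B3"),
    c("Alpha", "Alpha", "Beta", "Beta", "Beta")))
  w1 <- weights_from_points(p1, h)
  w2 <- weights_from_points(p1, hp)
  expect_equal(w1[c("A1", "A2", "B1")], w2[c("A1", "A2", "B1")])
})

test_that("propagate_hierarchy conserves mass and rejects bad blocks", {
  h <- tiny_hierarchy()
  set.seed(5)
  for (rep in 1:20) {
    top <- runif(2); top <- setNames(top / sum(top), c("A", "B"))
    within <- lapply(h$structure, function(cc) {
      s <- runif(length(cc)); setNames(s / sum(s), cc)
    })
    w <- propagate_hierarchy(top, within, h)
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  bad <- list(A = c(A1 = 0.7, A2 = 0.7),
              B = c(B1 = 1 / 3, B2 = 1 / 3, B3 = 1 / 3))
  expect_error(propagate_hierarchy(c(A = 0.5, B = 0.5), bad, h), "sum to 1")
})

test_that("elicit_weights dispatches on the response class", {
  h <- evidem_hierarchy()
  expect_equal(as.numeric(elicit_weights(full_flat_rating(h), h)),
               as.numeric(weights_from_ratings(full_flat_rating(h), h)))
  expect_equal(as.numeric(elicit_weights(uniform_ranking(h), h,
                                         scheme = "centroid")),
               as.numeric(weights_from_ranking(uniform_ranking(h), h,
                                               scheme = "centroid")))
})
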