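# Fixtures are built in code: small hierarchies, complete responses for the
# bundled EVIDEM hierarchy, and matrix generators used as AHP oracles.

hier_df <- function(codes, cats, names = codes) {
  data.frame(code = codes, name = names, category = cats,
             stringsAsFactors = FALSE)
}

# two categories of sizes 2 and 3 (exercises unequal block sizes)
tiny_hierarchy <- function() {
  criteria_hierarchy(hier_df(
    c("A1", "A2", "B1", "B2", "B3"),
    c("Alpha", "Alpha", "Beta", "Beta", "Beta")))
}

one_category_hierarchy <- function() {
  criteria_hierarchy(hier_df(c("X1", "X2"), c("Only", "Only")))
}

# a complete flat rating response for the EVIDEM hierarchy
full_flat_rating <- function(h, value = 3) {
  rating_response("R1", setNames(rep(value, 14), flat_criteria(h)))
}

# uniform hierarchical blocks for EVIDEM: all category ratings equal, all
# within-category ratings equal
uniform_hier_rating <- function(h, value = 3) {
  rating_response("R1", setNames(rep(value, 14), flat_criteria(h)),
                  category_ratings = setNames(rep(value, 6), h$categories))
}

uniform_ranking <- function(h) {
  ranking_response("R1",
    category_ranks = setNames(seq_along(h$categories), h$categories),
    within_ranks = lapply(h$structure, function(cc)
      setNames(seq_along(cc), cc)))
}

uniform_points <- function(h) {
  point_allocation_response("R1",
    category_points = setNames(rep(100 / length(h$categories),
                                   length(h$categories)), h$categories),
    within_points = lapply(h$structure, function(cc)
      setNames(rep(100 / length(cc), length(cc)), cc)))
}

# a perfectly consistent reciprocal matrix from a share vector
consistent_matrix <- function(shares) {
  M <- outer(shares, shares, "/")
  dimnames(M) <- list(names(shares), names(shares))
  M
}

# random reciprocal matrix with judgments on the admissible 1/9..9 grid
random_reciprocal_matrix <- function(n) {
  grid <- c(1 / (9:2), 1, 2:9)
  M <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- sample(grid, 1)
    M[i, j] <- v
    M[j, i] <- 1 / v
  }
  dimnames(M) <- list(paste0("i", 1:n), paste0("i", 1:n))
  M
}

# a complete pairwise response for any hierarchy, judgments all 1
unit_pairwise <- function(h) {
  blocks <- c(list(TOP = h$categories), h$structure)
  rows <- do.call(rbind, lapply(names(blocks), function(bl) {
    items <- blocks[[bl]]
    if (length(items) < 2) return(NULL)
    pr <- combn(items, 2)
    data.frame(block = bl, a = pr[1, ], b = pr[2, ], value = 1,
               stringsAsFactors = FALSE)
  }))
  pairwise_response("R1", rows)
}

# all permutations of 1..n (n small), for brute-force bounds
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1)
  }
  out
}

# independent counting oracle for BWS: tally B, W, r directly
bws_count_oracle <- function(choices, design) {
  codes <- design$codes
  B <- W <- r <- setNames(numeric(length(codes)), codes)
  for (s in design$sets) r[s] <- r[s] + 1
  for (i in seq_len(nrow(choices))) {
    B[choices$best[i]] <- B[choices$best[i]] + 1
    W[choices$worst[i]] <- W[choices$worst[i]] + 1
  }
  score <- (B - W + r) / (2 * r)
  score / sum(score)
}
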