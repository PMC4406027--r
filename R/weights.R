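#' Normalized weight vectors
#'
#' A `weight_vector` is a named numeric vector over the hierarchy's leaves,
#' nonnegative and summing to 1, tagged with the technique that produced it
#' and the respondent it belongs to (`"GROUP_MEAN"` for aggregates).
#'
#' @param w named nonnegative numeric vector summing to 1 (tolerance 1e-9).
#' @param technique technique label.
#' @param respondent respondent id.
#' @return object of class `weight_vector`.
#' @export
weight_vector <- function(w, technique = NA_character_,
                          respondent = NA_character_) {
  stopifnot(is.numeric(w), !is.null(names(w)))
  if (any(w < -1e-12)) stop("negative weight")
  if (abs(sum(w) - 1) > 1e-9) stop("weights do not sum to 1")
  structure(pmax(w, 0), technique = technique, respondent = respondent,
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 3, ...) {
  cat(sprintf("Weights (%s, respondent %s):\n",
              attr(x, "technique"), attr(x, "respondent")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Equal-weight baseline
#'
#' The uniform weight vector 1/n over the hierarchy's leaves — 1/14 (0.07
#' at two decimals) for the EVIDEM set. Used as the no-prioritization
#' reference in discrimination analysis.
#'
#' @param h a [criteria_hierarchy].
#' @export
equal_weights <- function(h) {
  codes <- flat_criteria(h)
  weight_vector(stats::setNames(rep(1 / length(codes), length(codes)), codes),
                technique = "EQUAL", respondent = "BASELINE")
}

#' Propagate local block shares down a two-level hierarchy
#'
#' Leaf weight = category share x within-category share. Each block of
#' shares must be nonnegative and sum to 1.
#'
#' @param top_shares named shares over category codes.
#' @param within_shares named list (by category code) of shares over that
#'   category's leaves.
#' @param h a [criteria_hierarchy].
#' @return named numeric leaf weights in canonical order (sums to 1).
#' @export
propagate_hierarchy <- function(top_shares, within_shares, h) {
  check_shares <- function(s, label) {
    if (any(s < -1e-12)) stop(label, ": negative share")
    if (abs(sum(s) - 1) > 1e-8) stop(label, ": shares do not sum to 1")
  }
  stopifnot(setequal(names(top_shares), h$categories))
  check_shares(top_shares, "category block")
  out <- numeric(0)
  for (cc in h$categories) {
    leaves <- h$structure[[cc]]
    ws <- within_shares[[cc]]
    if (is.null(ws)) stop("missing within-category shares for ", cc)
    stopifnot(setequal(names(ws), leaves))
    check_shares(ws, paste("block", cc))
    out <- c(out, top_shares[[cc]] * ws[leaves])
  }
  out[flat_criteria(h)]
}

block_normalize <- function(x, label) {
  s <- sum(x)
  if (s <= 0) stop(label, ": block total is not positive")
  x / s
}

#' Derive weights from a response
#'
#' The generic front door: dispatches on the response class to the
#' technique-specific derivation ([weights_from_ratings()],
#' [weights_from_ranking()], [weights_from_points()],
#' [weights_from_pairwise()], [weights_from_bws()]).
#'
#' @param x a response object.
#' @param h a [criteria_hierarchy].
#' @param ... technique options passed through (`scheme`, `method`,
#'   `transform`, `design`).
#' @return a [weight_vector].
#' @export
elicit_weights <- function(x, h, ...) UseMethod("elicit_weights")

#' @export
elicit_weights.rating_response <- function(x, h, ...) weights_from_ratings(x, h)

#' @export
elicit_weights.ranking_response <- function(x, h, ...) weights_from_ranking(x, h, ...)

#' @export
elicit_weights.point_allocation_response <- function(x, h, ...) weights_from_points(x, h)

#' @export
elicit_weights.pairwise_response <- function(x, h, ...) weights_from_pairwise(x, h, ...)

#' @export
elicit_weights.bws_response <- function(x, h, design, ...) weights_from_bws(x, design, ...)

#' Weights from five-point ratings
#'
#' Flat mode: `w_i = rating_i / sum(ratings)` (the EVIDEM framework's
#' published convention). Hierarchical mode: category ratings and
#' within-category ratings are sum-normalized per block and propagated.
#'
#' @param r a [rating_response()].
#' @param h a [criteria_hierarchy].
#' @return a [weight_vector].
#' @export
weights_from_ratings <- function(r, h) {
  stopifnot(inherits(r, "rating_response"))
  codes <- flat_criteria(h)
  check_scale <- function(v, label) {
    if (!all(v %in% 1:5)) stop(label, ": ratings must be integers in 1..5")
  }
  check_scale(r$ratings, "ratings")
  if (identical(r$mode, "flat")) {
    stopifnot(setequal(names(r$ratings), codes))
    w <- block_normalize(r$ratings[codes], "ratings")
  } else {
    check_scale(r$category_ratings, "category ratings")
    stopifnot(setequal(names(r$category_ratings), h$categories))
    top <- block_normalize(r$category_ratings[h$categories], "category ratings")
    within <- lapply(h$categories, function(cc)
      block_normalize(r$ratings[h$structure[[cc]]], paste("block", cc)))
    names(within) <- h$categories
    w <- propagate_hierarchy(top, within, h)
  }
  weight_vector(w, technique = r$technique, respondent = r$respondent)
}

#' Weights from 100-point allocations
#'
#' Block allocations are normalized by their block total (so the weights
#' are invariant to rescaling a block) and propagated down the hierarchy.
#' A block totalling zero is an error; totals that are not 100 are flagged
#' by [validate_responses()].
#'
#' @param p a [point_allocation_response()].
#' @param h a [criteria_hierarchy].
#' @return a [weight_vector].
#' @export
weights_from_points <- function(p, h) {
  stopifnot(inherits(p, "point_allocation_response"))
  if (any(p$category_points < 0) ||
      any(unlist(p$within_points, use.names = FALSE) < 0))
    stop("negative point allocation")
  stopifnot(setequal(names(p$category_points), h$categories))
  top <- block_normalize(p$category_points[h$categories], "category points")
  within <- lapply(h$categories, function(cc) {
    leaves <- h$structure[[cc]]
    pts <- p$within_points[[cc]]
    if (is.null(pts)) stop("missing within-category points for ", cc)
    stopifnot(setequal(names(pts), leaves))
    block_normalize(pts[leaves], paste("block", cc))
  })
  names(within) <- h$categories
  weight_vector(propagate_hierarchy(top, within, h),
                technique = p$technique, respondent = p$respondent)
}

#' Surrogate shares for a rank within a block
#'
#' `rank_sum`: rank j of n gets `(n - j + 1) / (n(n+1)/2)`.
#' `centroid`: the rank-order-centroid share `(1/n) * sum(1/t, t = j..n)`.
#'
#' @param ranks integer ranks 1..n (1 = most important).
#' @param scheme `"rank_sum"` or `"centroid"`.
#' @return shares summing to 1, same order as `ranks`.
#' @export
rank_shares <- function(ranks, scheme = c("rank_sum", "centroid")) {
  scheme <- match.arg(scheme)
  n <- length(ranks)
  if (!setequal(ranks, seq_len(n)))
    stop("ranks must be a complete permutation of 1..", n)
  if (scheme == "rank_sum") {
    (n - ranks + 1) / (n * (n + 1) / 2)
  } else {
    vapply(ranks, function(j) sum(1 / (j:n)) / n, numeric(1))
  }
}

#' Weights from hierarchical ranking
#'
#' Each rank block (categories; leaves within each category) is converted
#' to local shares by the rank-sum rule (default) or rank-order centroids,
#' then propagated.
#'
#' @param k a [ranking_response()].
#' @param h a [criteria_hierarchy].
#' @param scheme surrogate-weight scheme, `"rank_sum"` (default) or
#'   `"centroid"`.
#' @return a [weight_vector].
#' @export
weights_from_ranking <- function(k, h, scheme = c("rank_sum", "centroid")) {
  stopifnot(inherits(k, "ranking_response"))
  scheme <- match.arg(scheme)
  stopifnot(setequal(names(k$category_ranks), h$categories))
  top <- stats::setNames(
    rank_shares(as.numeric(k$category_ranks[h$categories]), scheme),
    h$categories)
  within <- lapply(h$categories, function(cc) {
    leaves <- h$structure[[cc]]
    rr <- k$within_ranks[[cc]]
    if (is.null(rr)) stop("missing within-category ranks for ", cc)
    stopifnot(setequal(names(rr), leaves))
    stats::setNames(rank_shares(as.numeric(rr[leaves]), scheme), leaves)
  })
  names(within) <- h$categories
  weight_vector(propagate_hierarchy(top, within, h),
                technique = k$technique, respondent = k$respondent)
}

# ---- pairwise (AHP) -------------------------------------------------------

# Build the reciprocal comparison matrix of one block from stored judgments.
pairwise_matrix <- function(judgments, items) {
  n <- length(items)
  M <- diag(1, n)
  dimnames(M) <- list(items, items)
  seen <- matrix(FALSE, n, n, dimnames = list(items, items))
  for (i in seq_len(nrow(judgments))) {
    a <- judgments$a[i]; b <- judgments$b[i]; v <- judgments$value[i]
    if (!(a %in% items) || !(b %in% items))
      stop("judgment references items outside the block")
    if (!is.finite(v) || v <= 0) stop("non-positive judgment value")
    if (v < 1 / 9 - 1e-12 || v > 9 + 1e-12)
      stop("judgment outside the admissible [1/9, 9] scale")
    if (seen[a, b]) stop("duplicated judgment for pair ", a, ":", b)
    M[a, b] <- v
    M[b, a] <- 1 / v
    seen[a, b] <- seen[b, a] <- TRUE
  }
  off <- upper.tri(seen)
  if (!all(seen[off]))
    stop("incomplete pairwise block: ", sum(!seen[off]), " missing pair(s)")
  M
}

# Principal right eigenvector by power iteration.
power_eigenvector <- function(M, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(M)
  w <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    w_new <- as.numeric(M %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) return(w_new)
    w <- w_new
  }
  warning("power iteration did not converge to ", tol)
  w
}

#' Local AHP weights of one reciprocal comparison matrix
#'
#' @param M square positive reciprocal matrix.
#' @param method `"geometric_mean"` (row geometric means, default) or
#'   `"eigenvector"` (principal right eigenvector by power iteration,
#'   tolerance 1e-10). The two coincide exactly on consistent matrices.
#' @return normalized local weights (sum 1).
#' @export
ahp_local_weights <- function(M, method = c("geometric_mean", "eigenvector")) {
  method <- match.arg(method)
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(M > 0))
  if (max(abs(M * t(M) - 1)) > 1e-8)
    stop("matrix is not reciprocal")
  w <- if (method == "geometric_mean") {
    g <- exp(rowMeans(log(M)))
    g / sum(g)
  } else {
    power_eigenvector(M)
  }
  stats::setNames(w, rownames(M))
}

#' Saaty consistency ratio of a reciprocal matrix
#'
#' CI = (lambda_max - n)/(n - 1) scaled by the random consistency index
#' for matrices up to order 10; 0 for orders 1-2, NA beyond 10. Reported
#' for diagnostics only; responses are never rejected on consistency.
#'
#' @param M square positive reciprocal matrix.
#' @return the consistency ratio.
#' @export
consistency_ratio <- function(M) {
  n <- nrow(M)
  if (n <= 2L) return(0)
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (n > length(ri)) return(NA_real_)
  w <- power_eigenvector(M)
  lambda <- mean(as.numeric(M %*% w) / w)
  ((lambda - n) / (n - 1)) / ri[n]
}

#' Weights from hierarchical pairwise comparisons (AHP)
#'
#' Builds a reciprocal matrix per block (the category block plus each
#' within-category block), extracts local weights by row geometric means
#' (default) or the principal eigenvector, and propagates. Per-block
#' consistency ratios are attached as attribute `"consistency"`.
#'
#' @param j a [pairwise_response()].
#' @param h a [criteria_hierarchy].
#' @param method `"geometric_mean"` or `"eigenvector"`.
#' @return a [weight_vector] with a `"consistency"` attribute.
#' @export
weights_from_pairwise <- function(j, h,
                                  method = c("geometric_mean", "eigenvector")) {
  stopifnot(inherits(j, "pairwise_response"))
  method <- match.arg(method)
  blocks <- pairwise_blocks(h)
  shares <- list()
  cons <- stats::setNames(numeric(length(blocks)), names(blocks))
  for (bl in names(blocks)) {
    items <- blocks[[bl]]
    if (length(items) == 1L) {
      shares[[bl]] <- stats::setNames(1, items)
      cons[[bl]] <- 0
      next
    }
    M <- pairwise_matrix(j$judgments[j$judgments$block == bl, , drop = FALSE],
                         items)
    shares[[bl]] <- ahp_local_weights(M, method)
    cons[[bl]] <- consistency_ratio(M)
  }
  w <- propagate_hierarchy(shares$TOP, shares[h$categories], h)
  out <- weight_vector(w, technique = j$technique, respondent = j$respondent)
  attr(out, "consistency") <- cons
  out
}

#' Weights from best-worst scaling choices
#'
#' Counting analysis of BWS case 1: for each criterion tally how often it
#' was chosen best (`B`), worst (`W`) and how often it appeared (`r`).
#' The default `shifted_bw` transform scores each criterion
#' `(B - W + r) / (2r)`, which lies in `[0, 1]`; `sqrt_ratio` scores
#' `sqrt((B + 0.5) / (W + 0.5))`. Scores are normalized to sum to 1.
#'
#' @param b a [bws_response()].
#' @param design the [bws_design] the choices answer.
#' @param transform `"shifted_bw"` (default) or `"sqrt_ratio"`.
#' @return a [weight_vector] with attribute `"counts"` (B, W, r).
#' @export
weights_from_bws <- function(b, design,
                             transform = c("shifted_bw", "sqrt_ratio")) {
  stopifnot(inherits(b, "bws_response"), inherits(design, "bws_design"))
  transform <- match.arg(transform)
  codes <- design$codes
  r <- bws_appearances(design)
  if (any(r == 0))
    stop("criterion never shown in the design: ",
         paste(codes[r == 0], collapse = ","))
  ch <- b$choices
  if (!setequal(ch$set_index, seq_along(design$sets)))
    stop("response does not answer every choice set exactly once")
  for (i in seq_len(nrow(ch))) {
    members <- design$sets[[ch$set_index[i]]]
    if (!(ch$best[i] %in% members) || !(ch$worst[i] %in% members) ||
        ch$best[i] == ch$worst[i])
      stop("invalid best/worst choice in set ", ch$set_index[i])
  }
  B <- table(factor(ch$best, levels = codes))
  W <- table(factor(ch$worst, levels = codes))
  B <- stats::setNames(as.numeric(B), codes)
  W <- stats::setNames(as.numeric(W), codes)
  score <- if (transform == "shifted_bw") {
    (B - W + r) / (2 * r)
  } else {
    sqrt((B + 0.5) / (W + 0.5))
  }
  out <- weight_vector(score / sum(score), technique = b$technique,
                       respondent = b$respondent)
  attr(out, "counts") <- data.frame(criterion = codes, B = B, W = W, r = r,
                                    row.names = NULL)
  out
}
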