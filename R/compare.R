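#' Discriminative-power measures of a weight vector
#'
#' Three within-respondent measures of how strongly a technique separates
#' important from unimportant criteria: sort the weights descending, then
#' `d13` = weight distance between the 1st and 3rd ranked criterion,
#' `dml` = distance between the most and least important criterion, and
#' `deq` = mean absolute distance from the equal weight `1/n`. All three
#' are zero iff the vector is uniform, and `dml >= d13 >= 0` always.
#'
#' @param w a [weight_vector] (or named numeric summing to 1) over at
#'   least 3 criteria.
#' @return named numeric `c(d13, dml, deq)`.
#' @export
discrimination_measures <- function(w) {
  x <- as.numeric(w)
  n <- length(x)
  if (n < 3L) stop("discrimination measures need at least 3 criteria")
  s <- sort(x, decreasing = TRUE)
  c(d13 = s[1] - s[3], dml = s[1] - s[n], deq = mean(abs(x - 1 / n)))
}

#' One-sample t-test of differences against zero
#'
#' Classical two-sided one-sample t-test of mean zero, with the degenerate
#' zero-variance cases handled explicitly: all-zero differences give
#' `t = 0, p = 1`; constant nonzero differences give `t = +/-Inf, p = 0`
#' and are flagged `degenerate`.
#'
#' @param differences numeric vector, length >= 2.
#' @return list with `t`, `p`, `mean`, `n`, `degenerate`.
#' @export
test_nonzero <- function(differences) {
  x <- differences[is.finite(differences)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 differences")
  m <- mean(x)
  s <- stats::sd(x)
  # zero variance up to floating-point noise: t is undefined; report the
  # documented convention instead of failing inside t.test
  if (s <= 1e-10 * max(1, abs(m))) {
    if (abs(m) <= s)
      return(list(t = 0, p = 1, mean = m, n = n, degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = 0, mean = m, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(x), n = n,
       degenerate = FALSE)
}

#' Rank criteria by weight
#'
#' Rank 1 is the largest weight. Ties are broken by the canonical criterion
#' order (the order of the vector) and flagged via the `"ties"` attribute.
#'
#' @param w a [weight_vector] or named numeric.
#' @return named integer ranks with attribute `ties` (logical).
#' @export
rank_order <- function(w) {
  x <- as.numeric(w)
  r <- rank(-x, ties.method = "first")
  structure(stats::setNames(as.integer(r), names(w)),
            ties = anyDuplicated(x) > 0L)
}

#' Per-criterion rank differences between two rankings
#'
#' Mean and standard deviation of the absolute per-criterion rank
#' difference — the package's operationalization of rank reversal between
#' two techniques. Symmetric in its arguments and zero on identical
#' rankings.
#'
#' @param ranks_a,ranks_b named integer rank maps over the same criteria.
#' @return list with `mean`, `sd`, `per_criterion`.
#' @export
rank_difference <- function(ranks_a, ranks_b) {
  if (!setequal(names(ranks_a), names(ranks_b)))
    stop("rankings cover different criteria sets")
  d <- abs(as.numeric(ranks_a) - as.numeric(ranks_b)[match(names(ranks_a), names(ranks_b))])
  names(d) <- names(ranks_a)
  list(mean = mean(d), sd = stats::sd(d), per_criterion = d)
}

#' Across- and within-respondent agreement correlations
#'
#' Two complementary agreement statistics for paired techniques: the
#' correlation between the two techniques' per-criterion group mean
#' weights (across-respondent), and the mean over respondents of each
#' respondent's own per-criterion correlation (within-respondent).
#' Respondents with zero-variance weights under either technique are
#' excluded from the within-respondent mean and listed in `excluded`.
#'
#' @param weights_a,weights_b matrices (respondents x criteria, identical
#'   row/column order) of weights under technique A and B.
#' @param method correlation coefficient, `"pearson"` (default) or
#'   `"spearman"`.
#' @return list with `across_r`, `mean_within_r`, `within_r` (per
#'   respondent), `excluded` (row names or indices skipped), `method`.
#' @export
agreement_correlations <- function(weights_a, weights_b,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  weights_a <- as.matrix(weights_a); weights_b <- as.matrix(weights_b)
  stopifnot(all(dim(weights_a) == dim(weights_b)))
  across_r <- stats::cor(colMeans(weights_a), colMeans(weights_b),
                         method = method)
  ids <- rownames(weights_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(weights_a)))
  within <- rep(NA_real_, nrow(weights_a))
  for (i in seq_len(nrow(weights_a))) {
    if (stats::sd(weights_a[i, ]) == 0 || stats::sd(weights_b[i, ]) == 0) next
    within[i] <- stats::cor(weights_a[i, ], weights_b[i, ], method = method)
  }
  excluded <- ids[is.na(within)]
  list(across_r = across_r, mean_within_r = mean(within, na.rm = TRUE),
       within_r = stats::setNames(within, ids), excluded = excluded,
       method = method)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, plots the
#' pairwise mean against the pairwise difference. The bias is the mean
#' difference; the 95% limits of agreement are `bias +/- 1.96 * sd` of
#' the differences; points outside the limits are outliers. A paired
#' t-test (one-sample t on the differences) tests for systematic bias.
#'
#' @param x,y paired numeric vectors (method A, method B); at least 3
#'   pairs.
#' @param level `"group"` (per-criterion group means) or `"individual"`
#'   (per respondent-criterion pairs) — a label carried into reports.
#' @param labels optional point labels (defaults to `names(x)`).
#' @param conf_mult multiplier for the limits of agreement (1.96 for the
#'   95% interval).
#' @return object of class `bland_altman`: list with `data` (mean, diff,
#'   label), `bias`, `sd_diff`, `loa` (lower, upper), `outliers`, `t_test`,
#'   `level`, `n`.
#' @export
bland_altman <- function(x, y, level = c("group", "individual"),
                         labels = names(x), conf_mult = 1.96) {
  level <- match.arg(level)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("Bland-Altman needs at least 3 pairs")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  m <- (as.numeric(x) + as.numeric(y)) / 2
  d <- as.numeric(x) - as.numeric(y)
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(lower = bias - conf_mult * s, upper = bias + conf_mult * s)
  outliers <- labels[d < loa["lower"] | d > loa["upper"]]
  structure(list(
    data = data.frame(label = labels, mean = m, diff = d,
                      stringsAsFactors = FALSE),
    bias = bias, sd_diff = s, loa = loa, outliers = outliers,
    t_test = test_nonzero(d), level = level, n = length(x)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s level, n = %d pairs)\n", x$level, x$n))
  cat(sprintf("  bias %.4f, limits of agreement [%.4f, %.4f]\n",
              x$bias, x$loa["lower"], x$loa["upper"]))
  cat(sprintf("  paired t-test of bias: t = %.3f, p = %.4f\n",
              x$t_test$t, x$t_test$p))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bland_altman <- function(x, ...) x$data

#' @describeIn bland_altman plot the agreement diagram (base graphics):
#'   mean vs difference with bias and limits of agreement.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman plot", ...) {
  graphics::plot(x$data$mean, x$data$diff,
                 xlab = "Mean of the two methods",
                 ylab = "Difference between methods",
                 main = main, pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Order-effect analysis of technique position
#'
#' Splits each technique's respondents by whether the technique came first
#' or second in their survey, computes the group mean weights per split,
#' and compares the two positions with a group-level Bland-Altman plus
#' the mean-from-equal-weights discrimination (`deq`) of each split. An
#' anchoring effect shows up as second-position weights shrunk toward
#' uniform (lower `deq`) relative to first-position weights.
#'
#' @param weights_table data frame with columns `respondent_id`,
#'   `technique`, `position` (`"first"`/`"second"`), `criterion`, `weight`.
#' @param techniques techniques to analyze (default: all with both
#'   positions present). Requesting a technique with an empty split is an
#'   error.
#' @return named list per technique: list with `bland_altman`,
#'   `deq_first`, `deq_second`, `n_first`, `n_second`.
#' @export
order_effect_analysis <- function(weights_table, techniques = NULL) {
  stopifnot(all(c("respondent_id", "technique", "position", "criterion",
                  "weight") %in% names(weights_table)))
  if (is.null(techniques)) {
    both <- tapply(weights_table$position, weights_table$technique,
                   function(p) all(c("first", "second") %in% p))
    techniques <- names(both)[both]
    if (!length(techniques))
      stop("no technique has respondents in both positions")
  }
  out <- list()
  for (tech in techniques) {
    tw <- weights_table[weights_table$technique == tech, , drop = FALSE]
    splits <- lapply(c(first = "first", second = "second"), function(pos) {
      sw <- tw[tw$position == pos, , drop = FALSE]
      if (!nrow(sw)) stop("technique ", tech, ": no respondents in ",
                          pos, " position")
      gm <- tapply(sw$weight, sw$criterion, mean)
      gm[order(match(names(gm), unique(tw$criterion)))]
    })
    ba <- bland_altman(splits$first, splits$second, level = "group",
                       labels = names(splits$first))
    out[[tech]] <- list(
      bland_altman = ba,
      deq_first = unname(discrimination_measures(splits$first /
                                                   sum(splits$first))["deq"]),
      deq_second = unname(discrimination_measures(splits$second /
                                                    sum(splits$second))["deq"]),
      n_first = length(unique(tw$respondent_id[tw$position == "first"])),
      n_second = length(unique(tw$respondent_id[tw$position == "second"])))
  }
  out
}
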