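#' Performance scores
#'
#' Scores `v_i` describe how well an intervention performs on each
#' criterion, on a declared scale `[0, s_max]` (default 0-3, the scale
#' implied by published EVIDEM value tables).
#'
#' @param scores named numeric vector over the leaf codes.
#' @param s_max scale maximum, positive.
#' @return object of class `score_vector` with attribute `s_max`.
#' @export
score_vector <- function(scores, s_max = 3) {
  stopifnot(is.numeric(scores), !is.null(names(scores)), s_max > 0)
  if (any(scores < 0 | scores > s_max))
    stop("scores must lie in [0, s_max]")
  structure(scores, s_max = s_max, class = "score_vector")
}

#' Read/write score vectors as CSV (columns criterion, score; s_max in a
#' comment-free extra column on every row)
#' @param v a [score_vector()]; `file` a path.
#' @name score_io
#' @export
write_scores <- function(v, file) {
  utils::write.csv(data.frame(criterion = names(v), score = as.numeric(v),
                              s_max = attr(v, "s_max")),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname score_io
#' @export
read_scores <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  score_vector(stats::setNames(df$score, df$criterion), s_max = df$s_max[1])
}

#' Normalize a value estimate to percent of maximum
#'
#' Because weights sum to 1, the maximum attainable weighted sum is the
#' score-scale maximum, so `percent_of_max(V, s_max) = 100 * V / s_max`.
#'
#' @param V the overall value estimate.
#' @param s_max the score-scale maximum.
#' @return value on the 0-100 scale.
#' @export
percent_of_max <- function(V, s_max) {
  if (s_max <= 0) stop("s_max must be positive")
  if (any(V < -1e-12) || any(V > s_max + 1e-12))
    stop("V outside [0, s_max]")
  100 * V / s_max
}

#' Overall value estimate of an intervention
#'
#' The additive MCDA value `V = sum(w_i * v_i)`, plus its normalization to
#' a score out of 100 (percent of the maximum attainable value).
#'
#' @param w a [weight_vector].
#' @param v a [score_vector()] over the same criteria.
#' @return object of class `mcda_value`: list with `V`, `pct_of_max`,
#'   `s_max`, `technique`, `respondent`.
#' @examples
#' h <- evidem_hierarchy()
#' v <- score_vector(stats::setNames(rep(1.5, 14), flat_criteria(h)), s_max = 3)
#' overall_value(equal_weights(h), v)
#' @export
overall_value <- function(w, v) {
  stopifnot(inherits(w, "weight_vector"), inherits(v, "score_vector"))
  if (!setequal(names(w), names(v)))
    stop("weights and scores cover different criteria sets")
  V <- sum(as.numeric(w) * as.numeric(v)[match(names(w), names(v))])
  s_max <- attr(v, "s_max")
  structure(list(V = V, pct_of_max = percent_of_max(V, s_max), s_max = s_max,
                 technique = attr(w, "technique"),
                 respondent = attr(w, "respondent")),
            class = "mcda_value")
}

#' @export
print.mcda_value <- function(x, ...) {
  cat(sprintf("Overall value V = %.3f on [0, %g]  (%.1f%% of maximum)\n",
              x$V, x$s_max, x$pct_of_max))
  invisible(x)
}
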