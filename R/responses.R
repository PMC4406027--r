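#' Raw elicitation responses
#'
#' Constructors for one respondent's raw answers under each technique.
#' Constructors perform only structural checks (types, names); substantive
#' invariants (complete permutations, 100-point budgets, admissible
#' judgment values, ...) are checked by [validate_responses()], which
#' reports violations instead of raising, and enforced by the
#' weight-derivation functions, which do raise.
#'
#' Block labels follow the response-file convention: `"FLAT"` for a
#' single block over all leaves, `"TOP"` for the category-level block,
#' and a category code for each within-category block.
#'
#' @name responses
NULL

new_response <- function(x, subclass, technique, respondent) {
  x$respondent <- as.character(respondent)
  x$technique <- technique
  class(x) <- c(subclass, "mcda_response")
  x
}

#' @rdname responses
#' @param respondent respondent identifier.
#' @param ratings named integer vector of 1-5 ratings over the leaf codes.
#' @param category_ratings optional named 1-5 ratings over category codes;
#'   when supplied the response is hierarchical and leaf ratings are read
#'   within-category.
#' @param technique technique label stored on the response (`"RS_nH"` for
#'   flat, `"RS_H"` for hierarchical rating by default).
#' @export
rating_response <- function(respondent, ratings, category_ratings = NULL,
                            technique = if (is.null(category_ratings)) "RS_nH" else "RS_H") {
  stopifnot(is.numeric(ratings), !is.null(names(ratings)))
  if (!is.null(category_ratings))
    stopifnot(is.numeric(category_ratings), !is.null(names(category_ratings)))
  new_response(list(ratings = ratings, category_ratings = category_ratings,
                    mode = if (is.null(category_ratings)) "flat" else "hierarchical"),
               "rating_response", technique, respondent)
}

#' @rdname responses
#' @param category_ranks named permutation of `1:n_categories` over
#'   category codes (rank 1 = most important).
#' @param within_ranks named list (by category code) of named rank
#'   permutations over that category's leaves.
#' @export
ranking_response <- function(respondent, category_ranks, within_ranks,
                             technique = "RA") {
  stopifnot(is.numeric(category_ranks), !is.null(names(category_ranks)),
            is.list(within_ranks))
  new_response(list(category_ranks = category_ranks, within_ranks = within_ranks),
               "ranking_response", technique, respondent)
}

#' @rdname responses
#' @param category_points named nonnegative allocation summing to 100 over
#'   category codes.
#' @param within_points named list (by category code) of 100-point
#'   allocations over that category's leaves.
#' @export
point_allocation_response <- function(respondent, category_points, within_points,
                                      technique = "PA") {
  stopifnot(is.numeric(category_points), !is.null(names(category_points)),
            is.list(within_points))
  new_response(list(category_points = category_points, within_points = within_points),
               "point_allocation_response", technique, respondent)
}

#' @rdname responses
#' @param judgments data frame with columns `block` (`"TOP"` or a category
#'   code), `a`, `b` (sibling codes within the block) and `value` (the
#'   preference ratio for `a` over `b` on the reciprocal 1/9..9 scale;
#'   1 = equally important). Only one orientation per pair is stored; the
#'   reciprocal is implied.
#' @export
pairwise_response <- function(respondent, judgments, technique = "PC") {
  stopifnot(is.data.frame(judgments),
            all(c("block", "a", "b", "value") %in% names(judgments)))
  judgments$block <- as.character(judgments$block)
  judgments$a <- as.character(judgments$a)
  judgments$b <- as.character(judgments$b)
  new_response(list(judgments = judgments), "pairwise_response",
               technique, respondent)
}

#' @rdname responses
#' @param choices data frame with columns `set_index`, `best`, `worst`:
#'   for each choice set of the design, the codes picked as most and least
#'   important.
#' @export
bws_response <- function(respondent, choices, technique = "BWS") {
  stopifnot(is.data.frame(choices),
            all(c("set_index", "best", "worst") %in% names(choices)))
  choices$best <- as.character(choices$best)
  choices$worst <- as.character(choices$worst)
  new_response(list(choices = choices), "bws_response", technique, respondent)
}

#' @export
print.mcda_response <- function(x, ...) {
  cat(sprintf("<%s> respondent %s, technique %s\n",
              class(x)[1], x$respondent, x$technique))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

violation <- function(resp, check, message) {
  data.frame(respondent_id = resp$respondent, technique = resp$technique,
             check = check, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(respondent_id = character(), technique = character(),
             check = character(), message = character(),
             stringsAsFactors = FALSE)
}

check_block_names <- function(resp, got, want, label) {
  miss <- setdiff(want, got)
  extra <- setdiff(got, want)
  out <- no_violations()
  if (length(miss))
    out <- rbind(out, violation(resp, "missing_item",
      sprintf("%s: missing %s", label, paste(miss, collapse = ","))))
  if (length(extra))
    out <- rbind(out, violation(resp, "unknown_item",
      sprintf("%s: unknown %s", label, paste(extra, collapse = ","))))
  out
}

#' Validate responses against a hierarchy
#'
#' Checks every invariant of a response (complete blocks, rating values in
#' 1-5, rank permutations without ties, 100-point budgets, judgments on the
#' admissible reciprocal scale, best/worst drawn from the presented set) and
#' returns a report of violations; valid input yields a zero-row report.
#' Nothing is raised: explicit failure reporting beats silent imputation.
#'
#' @param x a single response object, or a list of them.
#' @param h a [criteria_hierarchy].
#' @param design a [bws_design], required to validate BWS responses.
#' @return data frame with columns `respondent_id`, `technique`, `check`,
#'   `message`; zero rows when everything is valid.
#' @export
validate_responses <- function(x, h, design = NULL) {
  if (is.list(x) && !inherits(x, "mcda_response")) {
    reports <- lapply(x, validate_responses, h = h, design = design)
    return(do.call(rbind, c(reports, list(no_violations()))))
  }
  UseMethod("validate_responses")
}

#' @export
validate_responses.rating_response <- function(x, h, design = NULL) {
  out <- no_violations()
  leaves <- flat_criteria(h)
  out <- rbind(out, check_block_names(x, names(x$ratings), leaves, "ratings"))
  bad <- x$ratings[!(x$ratings %in% 1:5)]
  if (length(bad))
    out <- rbind(out, violation(x, "invalid_rating",
      sprintf("rating outside 1..5 for %s", paste(names(bad), collapse = ","))))
  if (identical(x$mode, "hierarchical")) {
    out <- rbind(out, check_block_names(x, names(x$category_ratings),
                                        h$categories, "category ratings"))
    badc <- x$category_ratings[!(x$category_ratings %in% 1:5)]
    if (length(badc))
      out <- rbind(out, violation(x, "invalid_rating",
        sprintf("category rating outside 1..5 for %s",
                paste(names(badc), collapse = ","))))
  }
  out
}

check_permutation <- function(resp, ranks, items, label) {
  out <- check_block_names(resp, names(ranks), items, label)
  n <- length(items)
  if (!nrow(out) && !setequal(ranks, seq_len(n)))
    out <- rbind(out, violation(resp, "invalid_permutation",
      sprintf("%s: ranks are not a permutation of 1..%d", label, n)))
  out
}

#' @export
validate_responses.ranking_response <- function(x, h, design = NULL) {
  out <- check_permutation(x, x$category_ranks, h$categories, "category ranks")
  for (cc in intersect(names(x$within_ranks), h$categories))
    out <- rbind(out, check_permutation(x, x$within_ranks[[cc]],
                                        h$structure[[cc]], paste0("block ", cc)))
  miss <- setdiff(h$categories, names(x$within_ranks))
  if (length(miss))
    out <- rbind(out, violation(x, "missing_block",
      paste("missing within-category ranks for", paste(miss, collapse = ","))))
  out
}

check_points <- function(resp, pts, items, label, tol = 1e-9) {
  out <- check_block_names(resp, names(pts), items, label)
  if (any(pts < 0))
    out <- rbind(out, violation(resp, "negative_points",
      sprintf("%s: negative allocation", label)))
  if (abs(sum(pts) - 100) > tol)
    out <- rbind(out, violation(resp, "budget_violation",
      sprintf("%s: points sum to %g, not 100", label, sum(pts))))
  out
}

#' @export
validate_responses.point_allocation_response <- function(x, h, design = NULL) {
  out <- check_points(x, x$category_points, h$categories, "category points")
  for (cc in intersect(names(x$within_points), h$categories))
    out <- rbind(out, check_points(x, x$within_points[[cc]],
                                   h$structure[[cc]], paste0("block ", cc)))
  miss <- setdiff(h$categories, names(x$within_points))
  if (length(miss))
    out <- rbind(out, violation(x, "missing_block",
      paste("missing within-category points for", paste(miss, collapse = ","))))
  out
}

#' @export
validate_responses.pairwise_response <- function(x, h, design = NULL) {
  out <- no_violations()
  j <- x$judgments
  blocks <- pairwise_blocks(h)
  for (bl in names(blocks)) {
    items <- blocks[[bl]]
    if (length(items) < 2L) next
    want <- utils::combn(items, 2L)
    jb <- j[j$block == bl, , drop = FALSE]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    have <- key(jb$a, jb$b)
    need <- key(want[1, ], want[2, ])
    miss <- setdiff(need, have)
    if (length(miss))
      out <- rbind(out, violation(x, "missing_pair",
        sprintf("block %s: missing %d of %d comparisons", bl,
                length(miss), length(need))))
    if (anyDuplicated(have))
      out <- rbind(out, violation(x, "duplicate_pair",
        sprintf("block %s: duplicated comparison", bl)))
    bad <- jb$value[!is.finite(jb$value) | jb$value < 1 / 9 - 1e-12 |
                      jb$value > 9 + 1e-12]
    if (length(bad))
      out <- rbind(out, violation(x, "invalid_judgment",
        sprintf("block %s: judgment outside [1/9, 9]", bl)))
  }
  unknown <- setdiff(j$block, names(blocks))
  if (length(unknown))
    out <- rbind(out, violation(x, "unknown_block",
      paste("unknown block(s):", paste(unique(unknown), collapse = ","))))
  out
}

#' @export
validate_responses.bws_response <- function(x, h, design = NULL) {
  out <- no_violations()
  if (is.null(design)) {
    return(rbind(out, violation(x, "no_design",
                                "BWS validation requires the choice-set design")))
  }
  ch <- x$choices
  n_sets <- length(design$sets)
  miss <- setdiff(seq_len(n_sets), ch$set_index)
  if (length(miss))
    out <- rbind(out, violation(x, "missing_set",
      paste("unanswered choice set(s):", paste(miss, collapse = ","))))
  for (i in seq_len(nrow(ch))) {
    si <- ch$set_index[i]
    if (!(si %in% seq_len(n_sets))) {
      out <- rbind(out, violation(x, "unknown_set",
                                  paste("unknown set index", si)))
      next
    }
    members <- design$sets[[si]]
    if (!(ch$best[i] %in% members) || !(ch$worst[i] %in% members))
      out <- rbind(out, violation(x, "choice_outside_set",
        sprintf("set %d: best/worst not members of the set", si)))
    if (ch$best[i] == ch$worst[i])
      out <- rbind(out, violation(x, "best_equals_worst",
        sprintf("set %d: best equals worst", si)))
  }
  out
}

# Blocks addressed by hierarchical pairwise comparison: the category-level
# block "TOP" plus one block per category (singleton categories need no
# judgments).
pairwise_blocks <- function(h) {
  c(list(TOP = h$categories), h$structure)
}
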