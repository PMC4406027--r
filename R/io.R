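#' Response file input/output
#'
#' Long-format CSV dialect shared by the simulator and the parsers: one
#' row per (respondent, technique, block, item, value). Blocks are
#' `"FLAT"` (one block over all leaves), `"TOP"` (category block) or a
#' category code; for pairwise judgments the item is `"A:B"`. BWS choices
#' travel in their own file (respondent_id, set_index, best, worst).
#'
#' @name response_io
NULL

response_rows <- function(x, h) UseMethod("response_rows")

#' @export
response_rows.rating_response <- function(x, h) {
  if (x$mode == "flat") {
    return(data.frame(respondent_id = x$respondent, technique = x$technique,
                      block = "FLAT", item = names(x$ratings),
                      value = as.numeric(x$ratings), stringsAsFactors = FALSE))
  }
  cat_of <- stats::setNames(h$criteria$category_code, h$criteria$code)
  rows <- data.frame(respondent_id = x$respondent, technique = x$technique,
                     block = unname(cat_of[names(x$ratings)]),
                     item = names(x$ratings), value = as.numeric(x$ratings),
                     stringsAsFactors = FALSE)
  rbind(data.frame(respondent_id = x$respondent,
                   technique = x$technique, block = "TOP",
                   item = names(x$category_ratings),
                   value = as.numeric(x$category_ratings),
                   stringsAsFactors = FALSE), rows)
}

block_rows <- function(x, top, within) {
  rows <- data.frame(respondent_id = x$respondent, technique = x$technique,
                     block = "TOP", item = names(top),
                     value = as.numeric(top), stringsAsFactors = FALSE)
  for (cc in names(within))
    rows <- rbind(rows, data.frame(respondent_id = x$respondent,
                                   technique = x$technique, block = cc,
                                   item = names(within[[cc]]),
                                   value = as.numeric(within[[cc]]),
                                   stringsAsFactors = FALSE))
  rows
}

#' @export
response_rows.ranking_response <- function(x, h)
  block_rows(x, x$category_ranks, x$within_ranks)

#' @export
response_rows.point_allocation_response <- function(x, h)
  block_rows(x, x$category_points, x$within_points)

#' @export
response_rows.pairwise_response <- function(x, h) {
  data.frame(respondent_id = x$respondent, technique = x$technique,
             block = x$judgments$block,
             item = paste(x$judgments$a, x$judgments$b, sep = ":"),
             value = x$judgments$value, stringsAsFactors = FALSE)
}

#' Write cohort response files
#'
#' Emits `responses.csv`, and when BWS responses or a design are present
#' `bws_responses.csv` and `bws_design.csv`, plus `ground_truth.csv`
#' (respondent_id, criterion, latent_weight, kappa, arm, order).
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mcda_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list(); bws <- list()
  for (rl in cohort$responses) {
    for (resp in rl) {
      if (inherits(resp, "bws_response")) {
        b <- resp$choices
        b$respondent_id <- resp$respondent
        bws[[length(bws) + 1L]] <- b[, c("respondent_id", "set_index",
                                         "best", "worst")]
      } else {
        long[[length(long) + 1L]] <- response_rows(resp, cohort$hierarchy)
      }
    }
  }
  utils::write.csv(do.call(rbind, long), file.path(dir, "responses.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(bws))
    utils::write.csv(do.call(rbind, bws), file.path(dir, "bws_responses.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$bws_design))
    write_bws_design(cohort$bws_design, file.path(dir, "bws_design.csv"))
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Parse a long-format response file
#'
#' @param file path to a `responses.csv` in the package dialect.
#' @param h a [criteria_hierarchy].
#' @return list of response objects (one per respondent-technique).
#' @export
read_responses <- function(file, h) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character"))
  out <- list()
  for (key in unique(paste(df$respondent_id, df$technique, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    id <- parts[1]; tech <- parts[2]
    sub <- df[df$respondent_id == id & df$technique == tech, , drop = FALSE]
    named <- function(rows) stats::setNames(rows$value, rows$item)
    obj <- switch(tech,
      RS_nH = rating_response(id, named(sub[sub$block == "FLAT", ]),
                              technique = tech),
      RS_H = rating_response(id, named(sub[sub$block != "TOP", ]),
                             category_ratings = named(sub[sub$block == "TOP", ]),
                             technique = tech),
      RA = ranking_response(id, named(sub[sub$block == "TOP", ]),
                            within_blocks(sub, h), technique = tech),
      PA = point_allocation_response(id, named(sub[sub$block == "TOP", ]),
                                     within_blocks(sub, h), technique = tech),
      PC = {
        ab <- do.call(rbind, strsplit(sub$item, ":", fixed = TRUE))
        pairwise_response(id, data.frame(block = sub$block, a = ab[, 1],
                                         b = ab[, 2], value = sub$value,
                                         stringsAsFactors = FALSE),
                          technique = tech)
      },
      stop("unknown technique in response file: ", tech))
    out[[length(out) + 1L]] <- obj
  }
  out
}

within_blocks <- function(sub, h) {
  out <- lapply(h$categories, function(cc) {
    rows <- sub[sub$block == cc, , drop = FALSE]
    stats::setNames(rows$value, rows$item)
  })
  names(out) <- h$categories
  out
}

#' @rdname response_io
#' @param file path to a `bws_responses.csv`.
#' @return for `read_bws_responses`, a list of [bws_response()] objects.
#' @export
read_bws_responses <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character"))
  lapply(split(df, df$respondent_id), function(sub)
    bws_response(sub$respondent_id[1],
                 sub[, c("set_index", "best", "worst")]))
}

#' Export weight vectors as a long CSV
#'
#' Columns respondent_id, technique, criterion, weight; set `times100` to
#' export weights multiplied by 100 for presentation.
#'
#' @param weights list of [weight_vector] objects (or a weights table data
#'   frame from [derive_weights()]).
#' @param file output path.
#' @param times100 multiply weights by 100.
#' @export
write_weights <- function(weights, file, times100 = FALSE) {
  df <- if (is.data.frame(weights)) weights else do.call(rbind, lapply(
    weights, function(w) data.frame(
      respondent_id = attr(w, "respondent"), technique = attr(w, "technique"),
      criterion = names(w), weight = as.numeric(w),
      stringsAsFactors = FALSE)))
  if (times100) df$weight <- df$weight * 100
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
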