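#' Number of pairwise comparisons among n items
#'
#' Full pairwise comparison of `n` items requires `n(n-1)/2` judgments —
#' 91 for the 14 EVIDEM criteria, which is why the pairwise instrument is
#' administered hierarchically by default.
#'
#' @param n_items number of items, at least 2.
#' @return integer count of unordered pairs.
#' @examples
#' pc_num_comparisons(14) # 91
#' @export
pc_num_comparisons <- function(n_items) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2 ||
      n_items != round(n_items))
    stop("n_items must be a single integer >= 2")
  as.integer(n_items * (n_items - 1) / 2)
}

#' Generate a balanced best-worst scaling (case 1) design
#'
#' Builds `n_sets` choice sets of `set_size` criteria each. Appearance
#' counts are kept as equal as the arithmetic permits (for 14 criteria in
#' 12 sets of 4 there are 48 slots, so counts are 3 or 4, never exactly
#' equal), and within-set co-appearance is spread greedily: each slot is
#' filled from the least-shown criteria, tie-broken by least co-appearance
#' with the criteria already in the set, then at random. Reproducible from
#' `seed`.
#'
#' @param h a [criteria_hierarchy].
#' @param n_sets number of choice sets (default 12).
#' @param set_size criteria per set (default 4); must be smaller than the
#'   number of leaves, and `n_sets * set_size` must cover every leaf.
#' @param seed integer seed for the randomized tie-breaks.
#' @return an object of class `bws_design`: list with `sets` (list of
#'   character vectors), `set_size`, `codes`.
#' @export
make_bws_design <- function(h, n_sets = 12L, set_size = 4L, seed = 1L) {
  codes <- flat_criteria(h)
  k <- length(codes)
  if (set_size >= k)
    stop("set_size must be smaller than the number of criteria")
  if (set_size < 2L) stop("set_size must be at least 2")
  if (n_sets * set_size < k)
    stop("design too small: n_sets * set_size must cover every criterion")

  count <- stats::setNames(numeric(k), codes)
  co <- matrix(0, k, k, dimnames = list(codes, codes))
  sets <- vector("list", n_sets)
  # keep the caller's RNG stream untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  for (s in seq_len(n_sets)) {
    pick <- character(0)
    for (j in seq_len(set_size)) {
      cand <- setdiff(codes, pick)
      cand <- cand[count[cand] == min(count[cand])]
      if (length(pick)) {
        cosum <- colSums(co[pick, cand, drop = FALSE])
        cand <- cand[cosum == min(cosum)]
      }
      chosen <- if (length(cand) == 1L) cand else sample(cand, 1L)
      pick <- c(pick, chosen)
      count[chosen] <- count[chosen] + 1
    }
    co[pick, pick] <- co[pick, pick] + 1
    sets[[s]] <- pick
  }
  structure(list(sets = sets, set_size = as.integer(set_size), codes = codes),
            class = "bws_design")
}

#' Appearance counts of a BWS design
#' @param design a [bws_design].
#' @return named integer vector: how often each criterion is shown.
#' @export
bws_appearances <- function(design) {
  tab <- table(factor(unlist(design$sets), levels = design$codes))
  stats::setNames(as.integer(tab), design$codes)
}

#' @export
print.bws_design <- function(x, ...) {
  cat(sprintf("BWS design: %d sets of %d over %d criteria\n",
              length(x$sets), x$set_size, length(x$codes)))
  app <- bws_appearances(x)
  cat("appearances:", paste(sprintf("%s=%d", names(app), app), collapse = " "), "\n")
  invisible(x)
}

#' Read/write a BWS design as CSV (columns set_index, code)
#' @param design a [bws_design]; `file` a path; `h` a [criteria_hierarchy].
#' @name bws_design_io
#' @export
write_bws_design <- function(design, file) {
  df <- data.frame(
    set_index = rep(seq_along(design$sets), each = design$set_size),
    code = unlist(design$sets), stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname bws_design_io
#' @export
read_bws_design <- function(file, h) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  sets <- split(as.character(df$code), df$set_index)
  sizes <- unique(lengths(sets))
  if (length(sizes) != 1L) stop("inconsistent set sizes in design file")
  structure(list(sets = unname(sets), set_size = as.integer(sizes),
                 codes = flat_criteria(h)), class = "bws_design")
}
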