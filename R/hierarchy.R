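#' Criteria hierarchies
#'
#' A criteria hierarchy is the two-level tree used throughout the package:
#' an ordered set of categories, each holding an ordered set of leaf
#' criteria. Weight elicitation can address the flat list of leaves or the
#' hierarchy (category weights times within-category weights). The default
#' hierarchy bundled with the package is the EVIDEM set of 14 quantitative
#' criteria in 6 categories.
#'
#' @param criteria a data frame with columns `code`, `name`, `category` and
#'   optionally `category_code` (a short unique label per category; derived
#'   from the category names' initials when absent). Rows define the
#'   canonical leaf order; categories are ordered by first appearance.
#' @return an object of class `criteria_hierarchy` with components
#'   `criteria` (the validated data frame), `categories` (character vector
#'   of category codes in order) and `structure` (named list mapping each
#'   category code to its member leaf codes).
#' @examples
#' h <- evidem_hierarchy()
#' flat_criteria(h)
#' @export
criteria_hierarchy <- function(criteria) {
  stopifnot(is.data.frame(criteria))
  need <- c("code", "name", "category")
  missing_cols <- setdiff(need, names(criteria))
  if (length(missing_cols))
    stop("hierarchy definition lacks column(s): ", paste(missing_cols, collapse = ", "))
  criteria$code <- as.character(criteria$code)
  criteria$name <- as.character(criteria$name)
  criteria$category <- as.character(criteria$category)
  if (nrow(criteria) < 1L) stop("hierarchy has no criteria")
  dup <- criteria$code[duplicated(criteria$code)]
  if (length(dup)) stop("duplicate criterion code(s): ", paste(unique(dup), collapse = ", "))
  if (any(is.na(criteria$code) | criteria$code == ""))
    stop("empty criterion code")
  if (any(is.na(criteria$category) | criteria$category == ""))
    stop("criterion with empty category")

  cats <- unique(criteria$category)
  if (is.null(criteria$category_code)) {
    cc <- toupper(substr(cats, 1L, 1L))
    if (anyDuplicated(cc))
      stop("category initials are not unique; supply a category_code column")
    criteria$category_code <- cc[match(criteria$category, cats)]
  } else {
    criteria$category_code <- as.character(criteria$category_code)
    tab <- unique(criteria[, c("category", "category_code")])
    if (anyDuplicated(tab$category) || anyDuplicated(tab$category_code))
      stop("category_code must map one-to-one onto category")
  }
  cat_codes <- criteria$category_code[match(cats, criteria$category)]
  if (any(cat_codes %in% criteria$code))
    stop("category_code collides with a criterion code: ",
         paste(intersect(cat_codes, criteria$code), collapse = ", "))
  structure_list <- lapply(cat_codes, function(cc)
    criteria$code[criteria$category_code == cc])
  names(structure_list) <- cat_codes

  out <- list(criteria = criteria, categories = cat_codes,
              structure = structure_list)
  class(out) <- "criteria_hierarchy"
  out
}

#' Load a criteria hierarchy from a definition file
#'
#' @param file path to a CSV file with columns `code`, `name`, `category`
#'   and optionally `category_code`.
#' @return a [criteria_hierarchy] object.
#' @export
load_hierarchy <- function(file) {
  criteria_hierarchy(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' The bundled EVIDEM hierarchy: 14 criteria in 6 categories
#'
#' @return a [criteria_hierarchy] with leaves
#'   D1, D2, C1, C2, I1, I2, I3, T1, T2, E1, E2, E3, Q1, Q2.
#' @export
evidem_hierarchy <- function() {
  f <- system.file("extdata", "evidem_criteria.csv", package = "elicitMCDA",
                   mustWork = TRUE)
  h <- load_hierarchy(f)
  stopifnot(length(flat_criteria(h)) == 14L, length(h$categories) == 6L)
  h
}

#' Flat leaf order of a hierarchy
#'
#' Returns the canonical leaf order (category order, then within-category
#' order) used for every weight and score vector in the package.
#'
#' @param h a [criteria_hierarchy].
#' @return character vector of criterion codes.
#' @export
flat_criteria <- function(h) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  unlist(h$structure, use.names = FALSE)
}

#' Number of leaves per category
#' @param h a [criteria_hierarchy].
#' @return named integer vector over category codes.
#' @export
category_sizes <- function(h) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  vapply(h$structure, length, integer(1))
}

#' @export
print.criteria_hierarchy <- function(x, ...) {
  cat("Criteria hierarchy:", nrow(x$criteria), "criteria in",
      length(x$categories), "categories\n")
  for (cc in x$categories) {
    cat_name <- x$criteria$category[match(cc, x$criteria$category_code)]
    cat(sprintf("  %s (%s): %s\n", cc, cat_name,
                paste(x$structure[[cc]], collapse = ", ")))
  }
  invisible(x)
}
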