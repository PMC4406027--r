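#' Derive weights for every respondent-technique instance of a cohort
#'
#' @param cohort an [simulate_cohort()] result (or a compatible list of
#'   response lists with `meta`, `bws_design`, `hierarchy`).
#' @param ranking_scheme,ahp_method,bws_transform technique options passed
#'   to the derivation functions.
#' @return list with `table` (long data frame: `respondent_id`,
#'   `technique`, `position`, `criterion`, `weight`) and `vectors`
#'   (list of [weight_vector] objects).
#' @export
derive_weights <- function(cohort, ranking_scheme = "rank_sum",
                           ahp_method = "geometric_mean",
                           bws_transform = "shifted_bw") {
  h <- cohort$hierarchy
  vectors <- list()
  rows <- list()
  for (rl in cohort$responses) {
    for (resp in rl) {
      w <- switch(class(resp)[1],
        rating_response = weights_from_ratings(resp, h),
        ranking_response = weights_from_ranking(resp, h, scheme = ranking_scheme),
        point_allocation_response = weights_from_points(resp, h),
        pairwise_response = weights_from_pairwise(resp, h, method = ahp_method),
        bws_response = weights_from_bws(resp, cohort$bws_design,
                                        transform = bws_transform),
        stop("unknown response class"))
      vectors[[length(vectors) + 1L]] <- w
      pos <- cohort$meta$position[
        cohort$meta$respondent_id == resp$respondent &
          cohort$meta$technique == resp$technique]
      rows[[length(rows) + 1L]] <- data.frame(
        respondent_id = resp$respondent, technique = resp$technique,
        position = if (length(pos)) pos[1] else NA_character_,
        criterion = names(w), weight = as.numeric(w),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), vectors = vectors)
}

group_mean_weights <- function(weights_table, technique, codes) {
  sub <- weights_table[weights_table$technique == technique, , drop = FALSE]
  gm <- tapply(sub$weight, sub$criterion, mean)
  v <- as.numeric(gm[codes])
  weight_vector(stats::setNames(v / sum(v), codes), technique = technique,
                respondent = "GROUP_MEAN")
}

weights_matrix <- function(weights_table, technique, codes, ids = NULL) {
  sub <- weights_table[weights_table$technique == technique, , drop = FALSE]
  if (!is.null(ids)) sub <- sub[sub$respondent_id %in% ids, , drop = FALSE]
  ids_here <- unique(sub$respondent_id)
  m <- matrix(NA_real_, length(ids_here), length(codes),
              dimnames = list(ids_here, codes))
  for (i in seq_len(nrow(sub)))
    m[sub$respondent_id[i], sub$criterion[i]] <- sub$weight[i]
  m
}

#' Run the full simulate - derive - value - compare pipeline
#'
#' Simulates a cohort (or consumes a supplied one), derives every weight
#' vector, aggregates value estimates for a hypothetical intervention, and
#' computes the comparison statistics with the flat five-point rating
#' scale as the reference technique: per-technique group mean weights and
#' rank order, discrimination measures (with one-sample t-tests against
#' zero), group- and individual-level rank differences, across- and
#' within-respondent correlations, group-level Bland-Altman agreement, and
#' the order-effect (first versus second position) analysis.
#'
#' When `out_dir` is given, every table is written as CSV together with a
#' run log recording seed, options and package version; plots are emitted
#' as PNG plus a CSV of plotted coordinates so every number is testable.
#'
#' @param seed master seed (mandatory; drives simulation and scores).
#' @param design a [study_design()]; default is the 60-respondent,
#'   four-arm pilot layout with the given seed.
#' @param h a [criteria_hierarchy].
#' @param concentration,kappa,rating_gain simulator parameters, see
#'   [draw_latents()] and [respond()].
#' @param s_max score-scale maximum for the value model.
#' @param scores optional fixed performance scores (else drawn uniformly
#'   from the scores substream).
#' @param ranking_scheme,ahp_method,bws_transform,correlation analysis
#'   options.
#' @param out_dir optional output directory.
#' @param write_plots also write Bland-Altman PNGs (requires `out_dir`).
#' @return object of class `mcda_run`; see Details.
#' @details The returned bundle contains `weights` (long table),
#'   `group_weights` (per-technique group means), `rank_table`
#'   (Table-1-style rank order), `discrimination` (per-technique means,
#'   sds and t-tests), `rank_differences`, `correlations`,
#'   `bland_altman` (per technique vs the reference), `order_effects`,
#'   `values` (per respondent-technique), `value_summary` (Table-3-style),
#'   `scores`, `cohort`, `config`.
#' @export
run_pipeline <- function(seed, design = NULL, h = evidem_hierarchy(),
                         concentration = NULL, kappa = 4, rating_gain = 3,
                         s_max = 3, scores = NULL,
                         ranking_scheme = "rank_sum",
                         ahp_method = "geometric_mean",
                         bws_transform = "shifted_bw",
                         correlation = "pearson",
                         out_dir = NULL, write_plots = FALSE) {
  if (missing(seed)) stop("a master seed is mandatory for simulation runs")
  if (is.null(design)) design <- study_design(seed = seed)
  cohort <- simulate_cohort(design, h, concentration = concentration,
                            kappa = kappa, rating_gain = rating_gain)
  viol <- validate_responses(
    unlist(cohort$responses, recursive = FALSE, use.names = FALSE),
    h, design = cohort$bws_design)
  if (nrow(viol))
    stop("simulated responses failed validation (", nrow(viol), " violations)")

  dw <- derive_weights(cohort, ranking_scheme = ranking_scheme,
                       ahp_method = ahp_method, bws_transform = bws_transform)
  wt <- dw$table
  codes <- flat_criteria(h)
  techniques <- unique(wt$technique)
  reference <- "RS_nH"

  if (is.null(scores)) {
    score_seed <- substream_seeds(seed, c("latents", "order", "noise",
                                          "design", "scores"))[["scores"]]
    sv <- draw_scores(h, s_max = s_max, seed = score_seed)
  } else {
    sv <- if (inherits(scores, "score_vector")) scores
          else score_vector(stats::setNames(rep_len(scores, length(codes)),
                                            codes), s_max = s_max)
  }

  # per-respondent value estimates and Table-3-style summary
  values <- do.call(rbind, lapply(dw$vectors, function(w) {
    val <- overall_value(w, sv)
    data.frame(respondent_id = attr(w, "respondent"),
               technique = attr(w, "technique"),
               V = val$V, pct_of_max = val$pct_of_max,
               stringsAsFactors = FALSE)
  }))
  value_summary <- do.call(rbind, lapply(techniques, function(tech) {
    v <- values[values$technique == tech, ]
    data.frame(technique = tech, N = nrow(v), V_mean = mean(v$V),
               V_se = stats::sd(v$V) / sqrt(nrow(v)), V_sd = stats::sd(v$V),
               pct_of_max = mean(v$pct_of_max),
               pct_min = min(v$pct_of_max), pct_max = max(v$pct_of_max),
               stringsAsFactors = FALSE)
  }))

  # group mean weights, rank order, discrimination
  group_weights <- lapply(stats::setNames(techniques, techniques),
                          group_mean_weights, weights_table = wt,
                          codes = codes)
  group_ranks <- lapply(group_weights, rank_order)
  rank_table <- do.call(rbind, lapply(techniques, function(tech)
    data.frame(technique = tech, criterion = codes,
               group_weight = as.numeric(group_weights[[tech]]),
               rank = as.integer(group_ranks[[tech]]),
               stringsAsFactors = FALSE)))

  discrimination <- do.call(rbind, lapply(techniques, function(tech) {
    m <- weights_matrix(wt, tech, codes)
    dm <- t(apply(m, 1, discrimination_measures))
    t13 <- test_nonzero(dm[, "d13"]); tml <- test_nonzero(dm[, "dml"])
    data.frame(technique = tech, n = nrow(dm),
               d13_mean = mean(dm[, "d13"]), d13_sd = stats::sd(dm[, "d13"]),
               dml_mean = mean(dm[, "dml"]), dml_sd = stats::sd(dm[, "dml"]),
               deq_mean = mean(dm[, "deq"]), deq_sd = stats::sd(dm[, "deq"]),
               d13_p = t13$p, dml_p = tml$p, stringsAsFactors = FALSE)
  }))

  # comparisons against the flat rating scale
  others <- setdiff(techniques, reference)
  rank_differences <- do.call(rbind, lapply(others, function(tech) {
    grp <- rank_difference(group_ranks[[reference]], group_ranks[[tech]])
    ids <- unique(wt$respondent_id[wt$technique == tech])
    ma <- weights_matrix(wt, reference, codes, ids)
    mb <- weights_matrix(wt, tech, codes, ids)
    indiv <- vapply(ids, function(id)
      rank_difference(rank_order(ma[id, ]), rank_order(mb[id, ]))$mean,
      numeric(1))
    data.frame(technique = tech, group_mean = grp$mean, group_sd = grp$sd,
               individual_mean = mean(indiv), individual_sd = stats::sd(indiv),
               stringsAsFactors = FALSE)
  }))

  correlations <- do.call(rbind, lapply(others, function(tech) {
    ids <- unique(wt$respondent_id[wt$technique == tech])
    ma <- weights_matrix(wt, reference, codes, ids)
    mb <- weights_matrix(wt, tech, codes, ids)
    ac <- agreement_correlations(ma, mb, method = correlation)
    data.frame(technique = tech, across_r = ac$across_r,
               mean_within_r = ac$mean_within_r,
               n = length(ids) - length(ac$excluded),
               stringsAsFactors = FALSE)
  }))

  bland_altman_list <- lapply(stats::setNames(others, others), function(tech) {
    ids <- unique(wt$respondent_id[wt$technique == tech])
    ma <- weights_matrix(wt, reference, codes, ids)
    mb <- weights_matrix(wt, tech, codes, ids)
    bland_altman(colMeans(ma), colMeans(mb), level = "group", labels = codes)
  })

  order_effects <- tryCatch(order_effect_analysis(wt), error = function(e) NULL)

  config <- list(seed = seed, design = design, kappa = kappa,
                 rating_gain = rating_gain, s_max = s_max,
                 ranking_scheme = ranking_scheme, ahp_method = ahp_method,
                 bws_transform = bws_transform, correlation = correlation,
                 reference = reference)
  run <- structure(list(weights = wt, group_weights = group_weights,
                        rank_table = rank_table, discrimination = discrimination,
                        rank_differences = rank_differences,
                        correlations = correlations,
                        bland_altman = bland_altman_list,
                        order_effects = order_effects,
                        values = values, value_summary = value_summary,
                        scores = sv, cohort = cohort, config = config),
                   class = "mcda_run")
  if (!is.null(out_dir)) write_run(run, out_dir, write_plots = write_plots)
  run
}

write_run <- function(run, out_dir, write_plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  write_weights(run$weights, file.path(out_dir, "weights.csv"))
  wcsv(run$rank_table, "rank_table.csv")
  wcsv(run$discrimination, "discrimination.csv")
  wcsv(run$rank_differences, "rank_differences.csv")
  wcsv(run$correlations, "correlations.csv")
  wcsv(run$values, "values.csv")
  wcsv(run$value_summary, "value_summary.csv")
  ba_rows <- do.call(rbind, lapply(names(run$bland_altman), function(tech) {
    ba <- run$bland_altman[[tech]]
    cbind(technique = tech, ba$data, bias = ba$bias,
          loa_lower = ba$loa[["lower"]], loa_upper = ba$loa[["upper"]])
  }))
  if (!is.null(ba_rows)) wcsv(ba_rows, "bland_altman.csv")
  if (!is.null(run$order_effects)) {
    oe <- do.call(rbind, lapply(names(run$order_effects), function(tech) {
      x <- run$order_effects[[tech]]
      data.frame(technique = tech, bias = x$bland_altman$bias,
                 loa_lower = x$bland_altman$loa[["lower"]],
                 loa_upper = x$bland_altman$loa[["upper"]],
                 deq_first = x$deq_first, deq_second = x$deq_second,
                 n_first = x$n_first, n_second = x$n_second,
                 stringsAsFactors = FALSE)
    }))
    wcsv(oe, "order_effects.csv")
  }
  write_scores(run$scores, file.path(out_dir, "scores.csv"))
  if (write_plots) {
    for (tech in names(run$bland_altman)) {
      grDevices::png(file.path(out_dir, paste0("bland_altman_", tech, ".png")),
                     width = 600, height = 500)
      plot(run$bland_altman[[tech]],
           main = paste("Agreement:", run$config$reference, "vs", tech))
      grDevices::dev.off()
    }
  }
  log_lines <- c(
    paste("elicitMCDA version:", as.character(utils::packageVersion("elicitMCDA"))),
    paste("R version:", R.version.string),
    paste("seed:", run$config$seed),
    paste("cohort:", run$config$design$n_respondents, "respondents; arms",
          paste(sprintf("%s=%d", names(run$config$design$arms),
                        run$config$design$arms), collapse = " ")),
    paste("anchoring:", run$config$design$anchoring),
    paste("kappa:", run$config$kappa),
    paste("rating_gain:", run$config$rating_gain),
    paste("s_max:", run$config$s_max),
    paste("ranking_scheme:", run$config$ranking_scheme),
    paste("ahp_method:", run$config$ahp_method),
    paste("bws_transform:", run$config$bws_transform),
    paste("correlation:", run$config$correlation),
    paste("reference technique:", run$config$reference))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Cross-technique comparison summary
#'
#' Tabulates, per technique, the group value estimate, the discrimination
#' measures, and the rank-difference and correlation statistics against
#' the flat rating-scale reference.
#'
#' @param run an [run_pipeline()] result.
#' @return data frame, one row per technique.
#' @export
compare_report <- function(run) {
  stopifnot(inherits(run, "mcda_run"))
  vs <- run$value_summary
  d <- run$discrimination
  out <- merge(vs[, c("technique", "N", "V_mean", "pct_of_max")],
               d[, c("technique", "d13_mean", "dml_mean", "deq_mean")],
               by = "technique")
  out <- merge(out, run$rank_differences[, c("technique", "group_mean",
                                             "individual_mean")],
               by = "technique", all.x = TRUE)
  out <- merge(out, run$correlations[, c("technique", "across_r",
                                         "mean_within_r")],
               by = "technique", all.x = TRUE)
  out[order(match(out$technique, unique(run$weights$technique))), ]
}

#' @export
print.mcda_run <- function(x, ...) {
  cat("MCDA weight-elicitation comparison run (seed", x$config$seed, ")\n\n")
  cat("Value estimates by technique:\n")
  print(x$value_summary, digits = 4, row.names = FALSE)
  cat("\nDiscrimination (group means):\n")
  print(x$discrimination[, c("technique", "d13_mean", "dml_mean", "deq_mean")],
        digits = 3, row.names = FALSE)
  if (nrow(x$correlations)) {
    cat("\nAgreement with", x$config$reference, ":\n")
    print(x$correlations, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
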