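#' Reference group-mean weights for the EVIDEM criteria
#'
#' Group-mean five-point rating-scale weights over the 14 EVIDEM criteria
#' reported from a published student-sample weighting exercise: a mildly
#' peaked importance profile with population size and disease severity at
#' the top and clinical guidelines at the bottom. Used as the default base
#' preference profile of the synthetic-respondent generator and as a
#' worked-example input for the discrimination measures.
#'
#' @return a [weight_vector] (technique `"RS_nH"`, respondent
#'   `"GROUP_MEAN"`).
#' @export
evidem_reference_weights <- function() {
  w <- c(D1 = 0.089, D2 = 0.100, C1 = 0.052, C2 = 0.072,
         I1 = 0.080, I2 = 0.065, I3 = 0.085,
         T1 = 0.075, T2 = 0.057,
         E1 = 0.061, E2 = 0.066, E3 = 0.057,
         Q1 = 0.069, Q2 = 0.076)
  weight_vector(w / sum(w), technique = "RS_nH", respondent = "GROUP_MEAN")
}

# Independent substream seeds derived from one master seed, so each stage
# (latents, order, noise, scores, design) is reproducible on its own.
substream_seeds <- function(seed, names) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  stats::setNames(s, names)
}

#' Study design of a simulated cohort
#'
#' Mirrors the pilot design: every respondent answers the flat five-point
#' rating scale plus the technique of their arm, in randomized order.
#' Default: 60 respondents in four arms of 15 (ranking + point allocation;
#' pairwise comparison; best-worst scaling; hierarchical rating).
#'
#' @param n_respondents cohort size.
#' @param arms named integer vector of arm sizes over
#'   `RA_PA`, `PC`, `BWS`, `RS_H` (must sum to `n_respondents`).
#' @param randomize_order randomize which technique comes first (else the
#'   rating scale always comes first).
#' @param anchoring anchoring strength `alpha >= 0`: the latent importance
#'   vector of a second-position instrument is shrunk toward uniform by
#'   `w <- (1 - alpha) * w + alpha / n`. `alpha = 0` disables order
#'   effects.
#' @param seed master seed; all randomness flows from it through named
#'   substreams.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_respondents = 60L,
                         arms = c(RA_PA = 15L, PC = 15L, BWS = 15L, RS_H = 15L),
                         randomize_order = TRUE, anchoring = 0.3,
                         seed = 1L) {
  stopifnot(is.numeric(arms), !is.null(names(arms)), anchoring >= 0)
  if (sum(arms) != n_respondents)
    stop("arm sizes sum to ", sum(arms), ", not n_respondents = ", n_respondents)
  structure(list(n_respondents = as.integer(n_respondents), arms = arms,
                 randomize_order = isTRUE(randomize_order),
                 anchoring = anchoring, seed = as.integer(seed)),
            class = "study_design")
}

#' Draw latent importance vectors
#'
#' Latent per-respondent preferences are Dirichlet draws on the
#' 14-criterion simplex. The default concentration is 75 times the
#' reference profile ([evidem_reference_weights()]), which reproduces the
#' individual-level weight spread typical of student weighting samples
#' (mean distance from equal weights around 0.02-0.03).
#'
#' @param n number of respondents.
#' @param h a [criteria_hierarchy].
#' @param concentration positive Dirichlet parameter vector over the
#'   leaves (scalar recycled); default `75 * reference profile` for the
#'   EVIDEM hierarchy, symmetric 5 otherwise.
#' @param kappa consistency parameter(s), higher = less response noise;
#'   recycled over respondents. `Inf` = noiseless.
#' @param seed integer seed.
#' @return object of class `latent_preferences`: list with `W`
#'   (n x k matrix, rows on the simplex), `kappa`, `codes`.
#' @export
draw_latents <- function(n, h, concentration = NULL, kappa = 4, seed = 1L) {
  codes <- flat_criteria(h)
  k <- length(codes)
  if (is.null(concentration)) {
    concentration <- if (setequal(codes, names(evidem_reference_weights())))
      75 * as.numeric(evidem_reference_weights())[match(codes, names(evidem_reference_weights()))]
    else rep(5, k)
  }
  concentration <- rep_len(concentration, k)
  if (any(!is.finite(concentration) | concentration <= 0))
    stop("Dirichlet concentration must be strictly positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  g <- matrix(stats::rgamma(n * k, shape = rep(concentration, each = n)), n, k)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  W <- g / rowSums(g)
  dimnames(W) <- list(sprintf("R%03d", seq_len(n)), codes)
  structure(list(W = W, kappa = rep_len(kappa, n), codes = codes),
            class = "latent_preferences")
}

shrink_to_uniform <- function(w, alpha) {
  (1 - alpha) * w + alpha / length(w)
}

# multiplicative perturbation of a share vector; kappa = Inf is noiseless
perturb_shares <- function(w, kappa, family = c("normal", "logistic")) {
  if (!is.finite(kappa)) return(w)
  family <- match.arg(family)
  eps <- switch(family,
                normal = stats::rnorm(length(w)) / kappa,
                logistic = stats::rlogis(length(w)) / kappa)
  z <- w * exp(eps)
  z / sum(z)
}

# absolute anchored five-point rating of a block of shares: the scale
# midpoint 3 is "as important as average", each rating step is a factor
# exp(1/gain) in relative importance
anchored_rating <- function(shares, gain = 3) {
  stats::setNames(pmin(5, pmax(1, round(3 + gain * log(shares * length(shares))))),
                  names(shares))
}

# 100-point allocation by largest-remainder rounding
largest_remainder <- function(shares, total = 100L) {
  x <- shares * total
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    o <- order(x - f, decreasing = TRUE)
    f[o[seq_len(rem)]] <- f[o[seq_len(rem)]] + 1
  }
  f
}

# admissible pairwise judgment grid 1/9..9, snapped on the log scale
pc_grid <- function() c(1 / (9:2), 1, 2:9)

snap_to_grid <- function(ratio) {
  g <- pc_grid()
  g[which.min(abs(log(g) - log(ratio)))]
}

block_shares_of <- function(w, h) {
  cat_sum <- vapply(h$structure, function(cc) sum(w[cc]), numeric(1))
  within <- lapply(h$structure, function(cc) w[cc] / sum(w[cc]))
  list(top = cat_sum / sum(cat_sum), within = within)
}

#' Simulate one response from a latent preference
#'
#' Technique-specific response models, all driven by the respondent's
#' latent importance vector `w` and consistency `kappa` (noise scale
#' `1/kappa`; `kappa = Inf` is noiseless):
#' ratings map block shares to 1-5 through an anchored log rule with
#' logistic noise; ranking ranks a perturbed latent per block; point
#' allocation distributes 100 points per block by largest-remainder
#' rounding of perturbed shares; pairwise judgments are latent ratios with
#' lognormal noise snapped to the admissible 1/9..9 grid (reciprocity by
#' construction); BWS picks the argmax/argmin of a freshly perturbed
#' latent per choice set. A second-position instrument is anchored: the
#' latent is shrunk toward uniform by `alpha` before responding.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param w named latent importance vector (simplex) over the leaves.
#' @param kappa consistency parameter, > 0 (may be `Inf`).
#' @param technique one of `"RS_nH"`, `"RS_H"`, `"RA"`, `"PA"`, `"PC"`,
#'   `"BWS"`.
#' @param h a [criteria_hierarchy].
#' @param respondent respondent id stored on the response.
#' @param bws_design a [bws_design] (required for `"BWS"`).
#' @param position `"first"` or `"second"`.
#' @param anchoring anchoring strength applied at second position.
#' @param rating_gain gain of the anchored rating rule (ratings only).
#' @return the technique's response object.
#' @export
respond <- function(w, kappa, technique, h, respondent = "R001",
                    bws_design = NULL, position = "first", anchoring = 0,
                    rating_gain = 3) {
  stopifnot(abs(sum(w) - 1) < 1e-8, kappa > 0)
  codes <- flat_criteria(h)
  w <- w[codes]
  if (identical(position, "second") && anchoring > 0)
    w <- shrink_to_uniform(w, anchoring)
  switch(technique,
    RS_nH = {
      p <- perturb_shares(w, kappa, "logistic")
      rating_response(respondent, anchored_rating(p, rating_gain),
                      technique = "RS_nH")
    },
    RS_H = {
      p <- perturb_shares(w, kappa, "logistic")
      bs <- block_shares_of(p, h)
      ratings <- unlist(lapply(bs$within, anchored_rating, gain = rating_gain))
      names(ratings) <- unlist(h$structure, use.names = FALSE)
      rating_response(respondent, ratings[codes],
                      category_ratings = anchored_rating(bs$top, rating_gain),
                      technique = "RS_H")
    },
    RA = {
      p <- perturb_shares(w, kappa)
      bs <- block_shares_of(p, h)
      ranking_response(respondent,
        category_ranks = rank(-bs$top, ties.method = "first"),
        within_ranks = lapply(bs$within, function(s)
          rank(-s, ties.method = "first")))
    },
    PA = {
      p <- perturb_shares(w, kappa)
      bs <- block_shares_of(p, h)
      point_allocation_response(respondent,
        category_points = stats::setNames(largest_remainder(bs$top),
                                          names(bs$top)),
        within_points = lapply(bs$within, function(s)
          stats::setNames(largest_remainder(s), names(s))))
    },
    PC = {
      bs <- block_shares_of(w, h)
      blocks <- pairwise_blocks(h)
      shares <- c(list(TOP = bs$top), bs$within)
      rows <- list()
      for (bl in names(blocks)) {
        items <- blocks[[bl]]
        if (length(items) < 2L) next
        pr <- utils::combn(items, 2L)
        s <- shares[[bl]]
        for (q in seq_len(ncol(pr))) {
          a <- pr[1, q]; b <- pr[2, q]
          ratio <- (s[[a]] / s[[b]])
          if (is.finite(kappa)) ratio <- ratio * exp(stats::rnorm(1) / kappa)
          rows[[length(rows) + 1L]] <- data.frame(
            block = bl, a = a, b = b, value = snap_to_grid(ratio),
            stringsAsFactors = FALSE)
        }
      }
      pairwise_response(respondent, do.call(rbind, rows))
    },
    BWS = {
      if (is.null(bws_design)) stop("BWS responses need a design")
      ch <- lapply(seq_along(bws_design$sets), function(si) {
        members <- bws_design$sets[[si]]
        p <- perturb_shares(w, kappa)[members]
        data.frame(set_index = si,
                   best = members[which.max(p)],
                   worst = members[which.min(p)],
                   stringsAsFactors = FALSE)
      })
      bws_response(respondent, do.call(rbind, ch))
    },
    stop("unknown technique: ", technique))
}

arm_techniques <- function(arm) {
  switch(arm,
         RA_PA = c("RA", "PA"),
         PC = "PC", BWS = "BWS", RS_H = "RS_H",
         stop("unknown arm: ", arm))
}

#' Simulate a full cohort
#'
#' Draws latent preferences, assigns respondents to arms, randomizes the
#' order of the flat rating scale versus the arm's technique, and
#' generates every response, reproducibly from the design's master seed
#' through named substreams (latents, order, noise, design).
#'
#' @param design a [study_design()].
#' @param h a [criteria_hierarchy] (default the bundled EVIDEM set).
#' @param concentration,kappa passed to [draw_latents()].
#' @param rating_gain gain of the anchored rating rule.
#' @param bws_design optional [bws_design]; generated from the design
#'   substream when a BWS arm exists and none is given.
#' @return object of class `mcda_cohort`: list with `responses` (per
#'   respondent, a named list technique -> response), `meta` (one row per
#'   respondent-technique instance: `respondent_id`, `arm`, `technique`,
#'   `position`), `ground_truth` (long data frame of latent weights with
#'   `kappa`, `arm`, `order`), `design`, `bws_design`, `hierarchy`.
#' @export
simulate_cohort <- function(design, h = evidem_hierarchy(),
                            concentration = NULL, kappa = 4,
                            rating_gain = 3, bws_design = NULL) {
  stopifnot(inherits(design, "study_design"))
  seeds <- substream_seeds(design$seed, c("latents", "order", "noise", "design"))
  n <- design$n_respondents
  lat <- draw_latents(n, h, concentration = concentration, kappa = kappa,
                      seed = seeds[["latents"]])
  ids <- rownames(lat$W)
  arm <- rep(names(design$arms), design$arms)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })

  if (is.null(bws_design) && any(arm == "BWS"))
    bws_design <- make_bws_design(h, seed = seeds[["design"]])

  set.seed(seeds[["order"]])
  rs_first <- if (design$randomize_order) sample(c(TRUE, FALSE), n, replace = TRUE)
              else rep(TRUE, n)

  set.seed(seeds[["noise"]])
  responses <- vector("list", n)
  names(responses) <- ids
  meta <- list()
  for (i in seq_len(n)) {
    w <- lat$W[i, ]
    kap <- lat$kappa[i]
    techs_arm <- arm_techniques(arm[i])
    rs_pos <- if (rs_first[i]) "first" else "second"
    arm_pos <- if (rs_first[i]) "second" else "first"
    rl <- list()
    rl[["RS_nH"]] <- respond(w, kap, "RS_nH", h, respondent = ids[i],
                             position = rs_pos, anchoring = design$anchoring,
                             rating_gain = rating_gain)
    for (tech in techs_arm)
      rl[[tech]] <- respond(w, kap, tech, h, respondent = ids[i],
                            bws_design = bws_design, position = arm_pos,
                            anchoring = design$anchoring,
                            rating_gain = rating_gain)
    responses[[i]] <- rl
    meta[[i]] <- data.frame(
      respondent_id = ids[i], arm = arm[i],
      technique = c("RS_nH", techs_arm),
      position = c(rs_pos, rep(arm_pos, length(techs_arm))),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  k <- length(lat$codes)
  ground_truth <- data.frame(
    respondent_id = rep(ids, each = k),
    criterion = rep(lat$codes, n),
    latent_weight = as.numeric(t(lat$W)),
    kappa = rep(lat$kappa, each = k),
    arm = rep(arm, each = k),
    order = rep(ifelse(rs_first, "RS_first", "RS_second"), each = k),
    stringsAsFactors = FALSE)

  structure(list(responses = responses, meta = meta,
                 ground_truth = ground_truth, design = design,
                 bws_design = bws_design, hierarchy = h,
                 latents = lat),
            class = "mcda_cohort")
}

#' @export
print.mcda_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d respondents, arms %s, anchoring %.2f, seed %d\n",
              x$design$n_respondents,
              paste(sprintf("%s=%d", names(x$design$arms), x$design$arms),
                    collapse = " "),
              x$design$anchoring, x$design$seed))
  invisible(x)
}

#' Draw performance scores for a hypothetical intervention
#'
#' Uniform draws on `[0, s_max]` per criterion by default, or fixed
#' configured scores. Stands in for intervention performance scores
#' obtained in a separate scoring exercise.
#'
#' @param h a [criteria_hierarchy].
#' @param s_max score-scale maximum.
#' @param seed integer seed (ignored when `scores` is given).
#' @param scores optional fixed score value(s), recycled over criteria.
#' @return a [score_vector()].
#' @export
draw_scores <- function(h, s_max = 3, seed = 1L, scores = NULL) {
  codes <- flat_criteria(h)
  if (!is.null(scores)) {
    return(score_vector(stats::setNames(rep_len(scores, length(codes)), codes),
                        s_max = s_max))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  v <- stats::runif(length(codes), 0, s_max)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  score_vector(stats::setNames(v, codes), s_max = s_max)
}
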