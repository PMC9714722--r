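#' Resampled optimal policies for one data type
#'
#' The policy-agreement analysis asks whether the optimal policy learned
#' from activities of one type (quitting smoking, increasing physical
#' activity, or both) transfers to the other. Per repetition it draws
#' `n_per_type` samples (without replacement by default) from each
#' included activity type -- so `"BOTH"` uses twice as many samples --
#' computes the optimal policy at the requested complexity level, resolves
#' multi-action maxima uniformly at random, and appends the eight state
#' actions. The concatenated labels over all repetitions form the unit of
#' comparison for [cohens_kappa()].
#'
#' Level-4 policies are personalized, so for the agreement analysis they
#' are computed for a single reference trait vector: by default the
#' component-wise median of the supplied trait table.
#'
#' @param samples A samples data frame with an `activity_type` column.
#' @param source `"SMOKING"`, `"PHYSICAL_ACTIVITY"` or `"BOTH"`.
#' @param level Complexity level 2, 3 or 4.
#' @param n_per_type Samples drawn per included activity type (default
#'   1000).
#' @param reps Number of repetitions (default 100).
#' @param gamma Discount factor for levels 3--4.
#' @param traits Scaled trait matrix (row names = person ids); required at
#'   level 4.
#' @param ref_trait Reference trait vector for level 4; default
#'   column-wise median of `traits`.
#' @param replace Draw with replacement instead (default `FALSE`).
#' @return An object of class `policy_list`: list with `labels` (length
#'   `reps * 8`, states 0--7 in order within each repetition), `source`,
#'   `level`, `reps`.
#' @export
resample_policies <- function(samples, source = c("BOTH", "SMOKING",
                                                  "PHYSICAL_ACTIVITY"),
                              level = 2L, n_per_type = 1000L, reps = 100L,
                              gamma = 0.85, traits = NULL, ref_trait = NULL,
                              replace = FALSE) {
  source <- match.arg(source)
  stopifnot(level %in% 2:4, reps >= 1L)
  samples <- as_samples(samples)
  if (is.null(samples$activity_type)) {
    stop("samples need an activity_type column")
  }
  types <- if (source == "BOTH") activity_types() else source
  idx_by_type <- lapply(types, function(tp) which(samples$activity_type == tp))
  short <- vapply(idx_by_type, length, integer(1)) < n_per_type
  if (!replace && any(short)) {
    stop("fewer than n_per_type = ", n_per_type, " samples for type(s): ",
         paste(types[short], collapse = ", "))
  }
  if (level == 4L) {
    if (is.null(traits)) stop("level 4 requires a scaled trait table")
    if (is.null(ref_trait)) ref_trait <- apply(traits, 2, stats::median)
  }

  labels <- character(reps * 8L)
  for (r in seq_len(reps)) {
    draw <- unlist(lapply(idx_by_type, function(ix) {
      sample(ix, n_per_type, replace = replace)
    }))
    sub <- samples[draw, ]
    w <- if (level == 4L) {
      similarity_weights(ref_trait, traits, sub$person_id)
    } else NULL
    pol <- policy_for_level(level, sub, gamma = gamma, weights = w,
                            tie_break = "random")
    labels[(r - 1L) * 8L + 1:8] <- unname(pol$mapping)
  }
  structure(list(labels = labels, source = source, level = as.integer(level),
                 reps = as.integer(reps)),
            class = "policy_list")
}

#' Cohen's kappa between two policy lists
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two equal-length label sequences, with expected agreement \eqn{p_e}
#' computed from the two sequences' marginal label frequencies. When both
#' lists are constant and identical (\eqn{p_e = 1}), kappa is defined as
#' 1.
#'
#' @param a,b `policy_list` objects or character vectors of equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  la <- if (inherits(a, "policy_list")) a$labels else as.character(a)
  lb <- if (inherits(b, "policy_list")) b$labels else as.character(b)
  if (length(la) != length(lb)) stop("policy lists differ in length")
  if (length(la) == 0L) stop("empty policy lists")
  labs <- union(la, lb)
  po <- mean(la == lb)
  pe <- sum((table(factor(la, labs)) / length(la)) *
              (table(factor(lb, labs)) / length(lb)))
  if (pe >= 1) return(if (po >= 1) 1 else -Inf)
  (po - pe) / (1 - pe)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Conventional qualitative bands: below 0 poor, 0--0.20 slight,
#' 0.21--0.40 fair, 0.41--0.60 moderate, 0.61--0.80 substantial,
#' 0.81--1.00 almost perfect.
#'
#' @param kappa Numeric kappa value(s) in \[-1, 1\].
#' @return Character label(s).
#' @export
interpret_kappa <- function(kappa) {
  if (anyNA(kappa) || any(kappa < -1) || any(kappa > 1)) {
    stop("kappa must lie in [-1, 1]")
  }
  vapply(kappa, function(k) {
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Policy-agreement report across activity types
#'
#' Runs the full resampled agreement analysis for the non-baseline
#' complexity levels: the main comparisons (each single activity type
#' against both types together) and the reference comparisons (two
#' independent resamples from the same data type, giving the upper limit
#' of agreement attainable on that data).
#'
#' @inheritParams resample_policies
#' @param levels Complexity levels to analyze (default 2:4).
#' @param seed Optional seed for the whole analysis.
#' @return Data frame with columns `level`, `data_a`, `data_b`, `kappa`,
#'   `interpretation`, and an `analysis` tag (`"main"` or `"reference"`).
#' @export
agreement_report <- function(samples, levels = 2:4, n_per_type = 1000L,
                             reps = 100L, gamma = 0.85, traits = NULL,
                             ref_trait = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- list(
    list("SMOKING", "BOTH", "main"),
    list("PHYSICAL_ACTIVITY", "BOTH", "main"),
    list("BOTH", "BOTH", "reference"),
    list("SMOKING", "SMOKING", "reference"),
    list("PHYSICAL_ACTIVITY", "PHYSICAL_ACTIVITY", "reference")
  )
  res <- list()
  for (lv in levels) {
    for (p in pairs) {
      pa <- resample_policies(samples, p[[1]], lv, n_per_type, reps, gamma,
                              traits, ref_trait)
      pb <- resample_policies(samples, p[[2]], lv, n_per_type, reps, gamma,
                              traits, ref_trait)
      k <- cohens_kappa(pa, pb)
      res[[length(res) + 1L]] <- data.frame(
        level = lv, data_a = p[[1]], data_b = p[[2]], kappa = k,
        interpretation = interpret_kappa(k), analysis = p[[3]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
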