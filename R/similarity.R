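#' Scale personality and TTM-stage traits to the unit interval
#'
#' The similarity between two people is computed on a six-dimensional trait
#' vector: the five Big-Five personality dimensions and the
#' transtheoretical-model (TTM) stage of change for physical activity.
#' Each dimension is min-max scaled to \[0, 1\] using the instrument's
#' scale bounds (not the observed sample range, so scaling is stable as
#' the cohort grows), giving all six features equal footing in the
#' Euclidean distance.
#'
#' @param personality Numeric vector of 5 personality scores, or a matrix/
#'   data frame with 5 columns (one row per person).
#' @param ttm TTM stage (ordinal), one value per person.
#' @param personality_range Instrument bounds of the personality scores
#'   (default 1--7, the TIPI response scale).
#' @param ttm_range Instrument bounds of the TTM stage (default 1--5,
#'   precontemplation through maintenance).
#' @return Numeric matrix with 6 columns, all entries in \[0, 1\], one row
#'   per person.
#' @export
scale_traits <- function(personality, ttm,
                         personality_range = c(1, 7), ttm_range = c(1, 5)) {
  if (is.null(dim(personality))) personality <- matrix(personality, nrow = 1L)
  personality <- as.matrix(personality)
  if (ncol(personality) != 5L) stop("expected 5 personality dimensions")
  if (nrow(personality) != length(ttm)) {
    stop("one TTM stage per person is required")
  }
  if (any(personality < personality_range[1]) ||
      any(personality > personality_range[2])) {
    stop("personality scores outside the instrument range [",
         personality_range[1], ", ", personality_range[2], "]")
  }
  if (any(ttm < ttm_range[1]) || any(ttm > ttm_range[2])) {
    stop("TTM stages outside the instrument range [",
         ttm_range[1], ", ", ttm_range[2], "]")
  }
  pscaled <- (personality - personality_range[1]) /
    diff(personality_range)
  tscaled <- (ttm - ttm_range[1]) / diff(ttm_range)
  out <- cbind(pscaled, tscaled)
  colnames(out) <- c(paste0("personality_", 1:5), "ttm_stage")
  out
}

#' Similarities of one person to a bank of others
#'
#' Euclidean distances between six-dimensional scaled trait vectors,
#' mapped linearly so that the smallest distance in the bank becomes
#' similarity 1 and the largest becomes 0. When all distances are equal
#' (including a single other person) there is no information to
#' discriminate, and every similarity is set to 1.
#'
#' @param target Scaled trait vector of the target person (length 6).
#' @param others Matrix of scaled trait vectors, one row per other person.
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
pairwise_similarity <- function(target, others) {
  if (is.null(dim(others))) others <- matrix(others, nrow = 1L)
  others <- as.matrix(others)
  if (nrow(others) == 0L) stop("need at least one other person")
  target <- as.numeric(target)
  if (length(target) != ncol(others)) stop("trait dimensions do not match")
  d <- sqrt(rowSums(sweep(others, 2L, target)^2))
  spread <- max(d) - min(d)
  if (spread == 0) return(rep(1, length(d)))
  (max(d) - d) / spread
}

#' Per-contributor sample weights from similarities
#'
#' Normalizes similarities over the contributing people and floors the
#' result so that no sample is ever given weight zero:
#' \deqn{w_{ij} = \max\!\left(\frac{s_{ij}}{\sum_k s_{ik}},\ 0.0001\right)}
#'
#' @param similarities Nonnegative similarities, one per contributor, with
#'   a positive sum.
#' @return Weights, one per contributor, each at least 0.0001.
#' @export
sample_weights <- function(similarities) {
  if (anyNA(similarities) || any(similarities < 0)) {
    stop("similarities must be nonnegative")
  }
  total <- sum(similarities)
  if (total <= 0) stop("all similarities are zero; weights are undefined")
  pmax(similarities / total, 0.0001)
}

#' Per-sample weights for a target person
#'
#' Convenience wrapper tying the similarity pipeline to a sample bank:
#' scales nothing (traits must already be scaled), computes the target's
#' similarity to every person contributing samples, converts similarities
#' to per-person weights with [sample_weights()], and expands them to one
#' weight per sample. The target's own samples, when present in the bank,
#' enter at distance 0 and hence maximal similarity.
#'
#' @param target Scaled trait vector (length 6) of the person a policy is
#'   being computed for.
#' @param traits Matrix of scaled trait vectors with row names equal to
#'   person ids, covering every person appearing in `person_id`.
#' @param person_id Per-sample person ids.
#' @return Numeric weight per sample.
#' @export
similarity_weights <- function(target, traits, person_id) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("traits must have person ids as row names")
  contributors <- unique(as.character(person_id))
  missing <- setdiff(contributors, rownames(traits))
  if (length(missing) > 0L) {
    stop("no trait vector for person(s): ", paste(missing, collapse = ", "))
  }
  sims <- pairwise_similarity(target, traits[contributors, , drop = FALSE])
  w_person <- sample_weights(sims)
  names(w_person) <- contributors
  unname(w_person[as.character(person_id)])
}
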