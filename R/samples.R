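#' Construct and validate a table of learning samples
#'
#' A sample is one persuasive attempt: the state the person was in, the
#' persuasion type sent, the reward derived from the effort they later
#' reported, and the state they transitioned to. This is the unit of
#' learning for all four algorithm complexity levels.
#'
#' @param df A data frame with columns `state` (integer 0--7), `action`
#'   (one of [persuasion_types()]), `reward` (numeric in \[-1, 1\]) and
#'   `next_state` (integer 0--7). Optional columns `person_id`, `session`,
#'   `effort` (0--10) and `activity_type` are validated when present and
#'   carried through.
#' @return The validated data frame, with class `rl_samples` prepended.
#' @export
as_samples <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("state", "action", "reward", "next_state")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("samples are missing column(s): ", paste(missing, collapse = ", "))
  }
  df$state <- check_state_index(df$state)
  df$next_state <- check_state_index(df$next_state, "next_state")
  action_index(df$action)  # validates
  if (anyNA(df$reward) || any(df$reward < -1 - 1e-12) || any(df$reward > 1 + 1e-12)) {
    stop("rewards must lie in [-1, 1]")
  }
  if (!is.null(df$effort) &&
      (anyNA(df$effort) || any(df$effort < 0) || any(df$effort > 10))) {
    stop("effort must lie in [0, 10]")
  }
  if (!is.null(df$activity_type) &&
      !all(df$activity_type %in% activity_types())) {
    stop("activity_type must be one of: ", paste(activity_types(), collapse = ", "))
  }
  class(df) <- unique(c("rl_samples", class(df)))
  df
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (length(weights) != n) {
    stop("weights must align 1:1 with samples (", length(weights),
         " weights for ", n, " samples)")
  }
  if (anyNA(weights) || any(weights <= 0)) stop("weights must be positive")
  as.numeric(weights)
}
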