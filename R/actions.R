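#' Persuasion types (the action space)
#'
#' The five persuasion types available to the virtual coach, in canonical
#' order. Three are Cialdini principles (commitment, consensus, authority),
#' one is action planning (if-then plans), and one is sending the activity
#' without any persuasive message. The canonical order is used for
#' deterministic tie-breaking and for serialization.
#'
#' @return Character vector of the five action codes.
#' @export
#' @examples
#' persuasion_types()
persuasion_types <- function() {
  c("COMMITMENT", "CONSENSUS", "AUTHORITY", "ACTION_PLANNING", "NO_PERSUASION")
}

#' Conventional abbreviations for the persuasion types
#'
#' @return Named character vector mapping action codes to the abbreviations
#'   used in rendered policy tables (Com., Con., Au., AP, NP).
#' @export
action_abbrev <- function() {
  c(COMMITMENT = "Com.", CONSENSUS = "Con.", AUTHORITY = "Au.",
    ACTION_PLANNING = "AP", NO_PERSUASION = "NP")
}

#' Activity types
#' @return Character vector of the two preparatory-activity types.
#' @export
activity_types <- function() {
  c("SMOKING", "PHYSICAL_ACTIVITY")
}

n_states <- function() 8L
n_actions <- function() 5L

# Map action codes to canonical 1..5 indices, erroring on unknown codes.
action_index <- function(action) {
  idx <- match(action, persuasion_types())
  if (anyNA(idx)) {
    stop("unknown persuasion type(s): ",
         paste(unique(action[is.na(idx)]), collapse = ", "))
  }
  idx
}

check_state_index <- function(state, what = "state") {
  if (anyNA(state) || !all(state == as.integer(state)) ||
      any(state < 0L) || any(state > 7L)) {
    stop(what, " indices must be integers in [0, 7]")
  }
  as.integer(state)
}
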