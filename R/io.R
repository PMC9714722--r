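COHORT_HEADER <- "# persuadeRL cohort v1"
TRAITS_HEADER <- "# persuadeRL traits v1 personality:1-7 ttm:1-5"

#' Write / read a cohort session table
#'
#' Plain CSV with a versioned header comment line, one row per session
#' record. `read_cohort()` refuses files whose header version it does not
#' recognize, so schema changes fail loudly rather than silently.
#'
#' @param records Session records data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort()` returns the records data frame.
#' @export
write_cohort <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COHORT_HEADER, con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, COHORT_HEADER)) {
    stop("not a persuadeRL cohort v1 file: ", path)
  }
  utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Write / read a per-person trait table
#'
#' CSV with a versioned header declaring the instrument scale bounds
#' (personality 1--7, TTM stage 1--5). One row per person: id, five
#' personality dimensions, TTM stage.
#'
#' @param traits Trait data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_traits()` returns the trait data frame.
#' @export
write_traits <- function(traits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TRAITS_HEADER, con)
  utils::write.csv(traits, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# persuadeRL traits v1")) {
    stop("not a persuadeRL traits v1 file: ", path)
  }
  utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Preprocess a raw submission log
#'
#' Applies the data-cleaning rules used before any analysis:
#' \enumerate{
#'   \item records of a study component are kept only if the person passed
#'     at least one attention check during that component;
#'   \item when a person submitted the same component more than once, only
#'     the first recorded submission is kept;
#'   \item people without a surviving session-2 record were never assigned
#'     to a condition; they are excluded from condition-level analyses and
#'     reported separately.
#' }
#' Malformed records (missing ids, components or submission order) are
#' dropped with a warning rather than aborting the run.
#'
#' @param log Data frame with columns `person_id`, `component` (e.g.
#'   `"session_1"`, `"post"`), `submission` (order of submission within a
#'   person-component, strictly ordered), `checks_passed` (number of
#'   attention checks passed), plus arbitrary payload columns.
#' @return List with `clean` (surviving records), `excluded_persons`
#'   (person ids lacking session 2), `n_dropped_attention` and
#'   `n_dropped_duplicate`.
#' @export
preprocess_log <- function(log) {
  stopifnot(is.data.frame(log))
  needed <- c("person_id", "component", "submission", "checks_passed")
  missing <- setdiff(needed, names(log))
  if (length(missing) > 0L) {
    stop("log is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- is.na(log$person_id) | is.na(log$component) | is.na(log$submission)
  if (any(bad)) {
    warning(sum(bad), " malformed record(s) dropped")
    log <- log[!bad, ]
  }
  # rule 1: at least one attention check passed for the component
  keep1 <- !is.na(log$checks_passed) & log$checks_passed >= 1L
  n_attention <- sum(!keep1)
  log <- log[keep1, ]
  # rule 2: first recorded submission per (person, component)
  ord <- order(log$person_id, log$component, log$submission)
  log <- log[ord, ]
  dup <- duplicated(log[, c("person_id", "component")])
  n_duplicate <- sum(dup)
  log <- log[!dup, ]
  # rule 3: people without session 2 were never assigned to a condition
  with_s2 <- unique(log$person_id[log$component == "session_2"])
  excluded <- setdiff(unique(log$person_id), with_s2)
  clean <- log[log$person_id %in% with_s2, ]
  rownames(clean) <- NULL
  list(clean = clean, excluded_persons = excluded,
       n_dropped_attention = n_attention, n_dropped_duplicate = n_duplicate)
}

#' Run configuration
#'
#' Bundles the frozen quantities an auditable training run depends on:
#' the discount factor, value-iteration tolerance, tie-break mode, trait
#' scale bounds, seed, and -- once training has happened -- the frozen
#' mean effort, binarization thresholds and feature selection.
#'
#' @param gamma Discount factor in \[0, 1) (default 0.85).
#' @param vi_tol Value-iteration tolerance (> 0).
#' @param tie_break `"canonical"` or `"random"`.
#' @param personality_range,ttm_range Trait instrument bounds.
#' @param seed Optional integer seed.
#' @param mean_effort,thresholds,selection Frozen training artifacts
#'   (optional until training).
#' @return A list of class `run_config`.
#' @export
run_config <- function(gamma = 0.85, vi_tol = 1e-9,
                       tie_break = c("canonical", "random"),
                       personality_range = c(1, 7), ttm_range = c(1, 5),
                       seed = NULL, mean_effort = NULL, thresholds = NULL,
                       selection = NULL) {
  tie_break <- match.arg(tie_break)
  stopifnot(gamma >= 0, gamma < 1, vi_tol > 0)
  structure(list(gamma = gamma, vi_tol = vi_tol, tie_break = tie_break,
                 personality_range = personality_range,
                 ttm_range = ttm_range, seed = seed,
                 mean_effort = mean_effort, thresholds = thresholds,
                 selection = selection),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  if (!is.null(out$selection)) out$selection <- unclass(out$selection)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sel <- raw$selection
  cfg <- run_config(gamma = raw$gamma, vi_tol = raw$vi_tol,
                    tie_break = raw$tie_break,
                    personality_range = as.numeric(raw$personality_range),
                    ttm_range = as.numeric(raw$ttm_range), seed = raw$seed,
                    mean_effort = raw$mean_effort,
                    thresholds = if (!is.null(raw$thresholds))
                      as.numeric(raw$thresholds),
                    selection = if (!is.null(sel))
                      structure(list(chosen = as.integer(sel$chosen),
                                     scores = as.numeric(sel$scores),
                                     level = as.integer(sel$level)),
                                class = "feature_selection"))
  cfg
}

#' Render a learned policy as a human-readable table
#'
#' Serializes a policy in the conventional layout: one row per selected
#' state feature giving its bit pattern across the eight states (first
#' selected feature = most significant bit), followed by the chosen
#' action abbreviation per state.
#'
#' @param policy A `persuasion_policy`.
#' @param selection Optional `feature_selection` identifying the three
#'   state features.
#' @param feature_labels Optional character vector of labels for all raw
#'   features (indexed by `selection$chosen`); defaults to `"F<i>"`.
#' @return Character vector of lines; also usable via [writeLines()].
#' @export
render_policy <- function(policy, selection = NULL, feature_labels = NULL) {
  stopifnot(inherits(policy, "persuasion_policy"))
  bits <- decode_state(0:7)
  lines <- sprintf("Complexity level %d policy", policy$level)
  lines <- c(lines, paste(c(format("State feature", width = 44),
                            format(as.character(1:8), width = 5)),
                          collapse = ""))
  if (policy$level >= 2L) {
    chosen <- if (!is.null(selection)) selection$chosen else 1:3
    labels <- if (!is.null(feature_labels)) {
      feature_labels[chosen]
    } else {
      sprintf("F%d", chosen)
    }
    for (b in 1:3) {
      lines <- c(lines, paste(c(format(labels[b], width = 44),
                                format(as.character(bits[, b]), width = 5)),
                              collapse = ""))
    }
  }
  ab <- action_abbrev()
  lines <- c(lines, paste(c(format("Action", width = 44),
                            format(unname(ab[policy$mapping]), width = 5)),
                          collapse = ""))
  lines
}
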