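# State domains and the condition/action transition semantics.
#
# Two domain kinds are supported:
#   * "ordered"     -- states form a severity axis (e.g. low < normal < high).
#                      Conditions "up"/"down" detect one-level movement along
#                      the axis, with the extremes self-sustaining: a state
#                      held at the top level keeps satisfying "up" (and the
#                      bottom level keeps satisfying "down").  Actions
#                      "up"/"down" move one level and are absorbing at the
#                      extremes.
#   * "categorical" -- unordered states (e.g. close/open, absent/present).
#                      A condition labelled with a state holds iff the current
#                      state equals that label; an action labelled with a
#                      state sets the attribute to that state.

#' Define a state domain for an attribute type
#'
#' A state domain gives an attribute type (gene, metabolite, hormone,
#' channel, drug presence, ...) its ordered set of discrete states and the
#' condition/action vocabularies that rules may use against it.
#'
#' @param name Attribute type this domain describes (e.g. `"gene"`).
#' @param states Character vector of at least two unique state labels.  For
#'   ordered domains the order is the severity axis, lowest first.
#' @param kind `"ordered"` (conditions/actions are `up`/`down`) or
#'   `"categorical"` (conditions/actions are the state labels themselves).
#'   Defaults to `"ordered"`.
#' @param default_state State used when neither a disease nor a drug file
#'   overrides the attribute.  Defaults to the middle state of an ordered
#'   domain and the first state of a categorical one.
#' @return An object of class `state_domain` with fields `name`, `states`,
#'   `kind`, `condition_labels`, `action_labels`, `default_state`.
#' @examples
#' gene <- state_domain("gene", c("low", "normal", "high"))
#' evaluate_condition("normal", "high", "up", gene)
#' apply_action("normal", "up", gene)
#' @export
state_domain <- function(name, states,
                         kind = c("ordered", "categorical"),
                         default_state = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.character(states) || length(states) < 2L)
    stop("state domain '", name, "' needs at least 2 states", call. = FALSE)
  if (anyDuplicated(states))
    stop("state domain '", name, "' has duplicate state labels", call. = FALSE)
  if (is.null(default_state)) {
    default_state <- if (kind == "ordered") states[ceiling(length(states) / 2)]
                     else states[1L]
  }
  if (!default_state %in% states)
    stop("default_state '", default_state, "' is not a state of domain '",
         name, "'", call. = FALSE)
  labels <- if (kind == "ordered") c("up", "down") else states
  dom <- structure(
    list(name = name, states = states, kind = kind,
         condition_labels = labels, action_labels = labels,
         default_state = default_state),
    class = "state_domain")
  dom$cond_rel <- stats::setNames(
    lapply(labels, function(l) condition_relation(dom, l)), labels)
  dom$act_map <- stats::setNames(
    lapply(labels, function(l) action_map(dom, l)), labels)
  dom
}

#' @export
print.state_domain <- function(x, ...) {
  cat("<state_domain> ", x$name, " (", x$kind, "): ",
      paste(x$states, collapse = " < "),
      "  [default ", x$default_state, "]\n", sep = "")
  invisible(x)
}

# prev x curr logical matrix: does `label` hold on the transition prev -> curr?
condition_relation <- function(domain, label) {
  n <- length(domain$states)
  m <- matrix(FALSE, n, n, dimnames = list(domain$states, domain$states))
  if (domain$kind == "ordered") {
    if (label == "up") {
      for (p in seq_len(n)) for (cc in seq_len(n))
        m[p, cc] <- (cc == p + 1L) || (p == n && cc == n)
    } else if (label == "down") {
      for (p in seq_len(n)) for (cc in seq_len(n))
        m[p, cc] <- (cc == p - 1L) || (p == 1L && cc == 1L)
    } else {
      stop("unknown condition label '", label, "' for ordered domain '",
           domain$name, "'", call. = FALSE)
    }
  } else {
    i <- match(label, domain$states)
    if (is.na(i))
      stop("unknown condition label '", label, "' for categorical domain '",
           domain$name, "'", call. = FALSE)
    m[, i] <- TRUE
  }
  m
}

# current-state index -> successor-state index under `label`
action_map <- function(domain, label) {
  n <- length(domain$states)
  if (domain$kind == "ordered") {
    if (label == "up") pmin(seq_len(n) + 1L, n)
    else if (label == "down") pmax(seq_len(n) - 1L, 1L)
    else stop("unknown action label '", label, "' for ordered domain '",
              domain$name, "'", call. = FALSE)
  } else {
    i <- match(label, domain$states)
    if (is.na(i))
      stop("unknown action label '", label, "' for categorical domain '",
           domain$name, "'", call. = FALSE)
    rep.int(i, n)
  }
}

state_index <- function(state, domain, what = "state") {
  i <- match(state, domain$states)
  if (is.na(i))
    stop("unknown ", what, " label '", state, "' for domain '",
         domain$name, "'", call. = FALSE)
  i
}

#' Evaluate a rule condition on a one-step state transition
#'
#' Conditions are judged on the pair (state at the previous step, state at
#' the current step).  For an ordered ternary domain the condition `"up"`
#' holds when the state moved one level upward or is being held at the top
#' level; `"down"` is symmetric.  For a categorical domain a condition holds
#' iff the current state equals the condition label, regardless of the
#' previous state.
#'
#' @param prev_state,curr_state State labels at the previous / current step.
#' @param condition A condition label valid for `domain`.
#' @param domain A [state_domain()].
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_condition <- function(prev_state, curr_state, condition, domain) {
  stopifnot(inherits(domain, "state_domain"))
  if (!condition %in% domain$condition_labels)
    stop("unknown condition label '", condition, "' for domain '",
         domain$name, "'", call. = FALSE)
  p <- state_index(prev_state, domain, "previous state")
  cc <- state_index(curr_state, domain, "current state")
  domain$cond_rel[[condition]][p, cc]
}

#' Apply a rule action to a state
#'
#' For an ordered domain the action `"up"` moves the state one level up
#' (top level absorbing) and `"down"` one level down (bottom absorbing).
#' For a categorical domain the action sets the state to the action label.
#'
#' @param curr_state Current state label.
#' @param action An action label valid for `domain`.
#' @param domain A [state_domain()].
#' @return The successor state label, always a member of `domain$states`.
#' @export
apply_action <- function(curr_state, action, domain) {
  stopifnot(inherits(domain, "state_domain"))
  if (!action %in% domain$action_labels)
    stop("unknown action label '", action, "' for domain '",
         domain$name, "'", call. = FALSE)
  cc <- state_index(curr_state, domain, "current state")
  domain$states[domain$act_map[[action]][cc]]
}
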