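# Model containers: attribute references, components, rules, model specs.

#' Reference an attribute of a component
#'
#' An attribute is addressed by the 4-tuple (component type, component name,
#' attribute type, attribute name), mirroring the first four features of
#' each side of a rule.  The attribute type selects the state domain.
#'
#' @param component_type Category of the owning component
#'   (`"Organ"`, `"Cell"`, `"Tissue"`, `"Drug"`, ...).
#' @param component_name Name of the owning component.
#' @param attribute_type Category of the attribute (`"gene"`,
#'   `"metabolite"`, `"hormone"`, `"channel"`, `"presence"`, ...); must map
#'   to a declared state domain.
#' @param attribute_name Name of the attribute.
#' @return An object of class `attribute_ref`.
#' @examples
#' attribute_ref("Cell", "hepatocyte", "gene", "PRKAB1")
#' @export
attribute_ref <- function(component_type, component_name,
                          attribute_type, attribute_name) {
  parts <- c(component_type, component_name, attribute_type, attribute_name)
  if (!is.character(parts) || length(parts) != 4L || anyNA(parts) ||
      any(!nzchar(parts)))
    stop("attribute_ref needs 4 non-empty character fields", call. = FALSE)
  if (any(grepl(",", parts, fixed = TRUE)))
    stop("attribute_ref fields may not contain ','", call. = FALSE)
  structure(
    list(component_type = component_type, component_name = component_name,
         attribute_type = attribute_type, attribute_name = attribute_name),
    class = "attribute_ref")
}

# canonical comma-joined key forms used throughout the package
attr_key <- function(ref) {
  paste(ref$component_type, ref$component_name,
        ref$attribute_type, ref$attribute_name, sep = ",")
}
comp_key <- function(component_type, component_name) {
  paste(component_type, component_name, sep = ",")
}
attr_ref_from_key <- function(key) {
  p <- strsplit(key, ",", fixed = TRUE)[[1]]
  if (length(p) != 4L)
    stop("malformed attribute reference '", key,
         "' (need 4 comma-separated fields)", call. = FALSE)
  attribute_ref(p[1], p[2], p[3], p[4])
}

#' @export
print.attribute_ref <- function(x, ...) {
  cat("<attribute_ref> ", attr_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.attribute_ref <- function(x, ...) attr_key(x)

# component-type classes used for threshold defaulting (case-insensitive)
FAST_TYPES <- c("molecule", "cell", "drug")
SLOW_TYPES <- c("tissue", "organ")

#' Default rule-execution threshold for a component type
#'
#' Molecules, cells and drugs respond fast and get threshold 1.0; tissues
#' and organs integrate many molecular events and get threshold 60.0,
#' encoding the slower timescale of organ-level state change.  Unknown
#' types default to 1.0.
#'
#' @param component_type Component type label (matched case-insensitively).
#' @return A positive scalar threshold.
#' @export
default_threshold <- function(component_type) {
  if (tolower(component_type) %in% SLOW_TYPES) 60.0 else 1.0
}

#' Declare a component
#'
#' A component is a modelled entity at any scale (organ, cell, drug, ...)
#' holding typed attributes and carrying the rule-execution threshold
#' `TH(c)` that gates how many accumulated rule firings are needed before
#' one of its attributes changes state.
#'
#' @param component_type,name Component type and name.
#' @param attributes A list of `c(attribute_type, attribute_name)` pairs
#'   (or a 2-column character matrix).
#' @param threshold Positive rule-execution threshold; if `NULL`, defaulted
#'   from the component type via [default_threshold()].
#' @return An object of class `component`.
#' @export
component <- function(component_type, name, attributes = list(),
                      threshold = NULL) {
  if (is.matrix(attributes))
    attributes <- lapply(seq_len(nrow(attributes)),
                         function(i) attributes[i, ])
  attributes <- lapply(attributes, function(a) {
    a <- as.character(a)
    if (length(a) != 2L || any(!nzchar(a)))
      stop("component attribute must be a (type, name) pair", call. = FALSE)
    a
  })
  keys <- vapply(attributes, paste, "", collapse = ",")
  if (anyDuplicated(keys))
    stop("duplicate attribute in component '",
         comp_key(component_type, name), "'", call. = FALSE)
  if (is.null(threshold)) threshold <- default_threshold(component_type)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("component threshold must be a positive number", call. = FALSE)
  structure(
    list(component_type = component_type, name = name,
         attributes = attributes, threshold = as.numeric(threshold)),
    class = "component")
}

#' Build a rule term
#'
#' @param ref An [attribute_ref()] (or a `"type,name,atype,aname"` key).
#' @param label Condition label (LHS term) or action label (RHS term).
#' @return A list with fields `ref` and `label`.
#' @export
rule_term <- function(ref, label) {
  if (is.character(ref)) ref <- attr_ref_from_key(ref)
  stopifnot(inherits(ref, "attribute_ref"),
            is.character(label), length(label) == 1L)
  list(ref = ref, label = label)
}

#' Declare a condition -> action rule
#'
#' The left-hand side is a conjunction of (attribute, condition) terms that
#' detect state transitions; when all hold, the rule may fire and each
#' right-hand (attribute, action) term adds the rule effect score `RS(r)`
#' to its target component's firing score, perturbing the target state once
#' the component threshold is reached.
#'
#' @param rule_id Unique identifier.
#' @param lhs,rhs Non-empty lists of [rule_term()]s.
#' @param effect_score Positive rule effect score `RS(r)`; default 1.0.
#' @param is_disease_rule Flag marking a disease-causing rule.
#' @param persistent If `TRUE` the rule is re-enqueued every step while its
#'   condition holds (chronic processes, sustained drug action).
#' @param provenance Free-text origin (`"curated"`, `"ode"`, `"petri-net"`,
#'   pathway database, ...).
#' @return An object of class `rule`.
#' @export
rule <- function(rule_id, lhs, rhs, effect_score = 1.0,
                 is_disease_rule = FALSE, persistent = FALSE,
                 provenance = "curated") {
  if (!is.character(rule_id) || length(rule_id) != 1L || !nzchar(rule_id))
    stop("rule_id must be a non-empty string", call. = FALSE)
  if (!is.list(lhs) || length(lhs) == 0L || !is.list(rhs) || length(rhs) == 0L)
    stop("rule '", rule_id, "': lhs and rhs must be non-empty term lists",
         call. = FALSE)
  fix <- function(t) if (!is.null(t$ref)) t else rule_term(t[[1]], t[[2]])
  lhs <- lapply(lhs, fix); rhs <- lapply(rhs, fix)
  if (!is.numeric(effect_score) || length(effect_score) != 1L ||
      effect_score <= 0)
    stop("rule '", rule_id, "': effect_score must be > 0", call. = FALSE)
  structure(
    list(rule_id = rule_id, lhs = lhs, rhs = rhs,
         effect_score = as.numeric(effect_score),
         is_disease_rule = isTRUE(is_disease_rule),
         persistent = isTRUE(persistent),
         provenance = provenance),
    class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Assemble a model specification
#'
#' @param state_domains List of [state_domain()]s; each domain's `name` is
#'   the attribute type it governs.
#' @param components List of [component()]s.
#' @param rules List of [rule()]s (may be empty; rules can be attached
#'   later, e.g. by [read_rule_file()]).
#' @return An object of class `model_spec` with named lookup lists
#'   `domains` (by attribute type), `components` (by `"type,name"` key) and
#'   `rules` (by rule id).
#' @export
model_spec <- function(state_domains = list(), components = list(),
                       rules = list()) {
  dn <- vapply(state_domains, function(d) d$name, "")
  if (anyDuplicated(dn))
    stop("duplicate state domain for attribute type(s): ",
         paste(unique(dn[duplicated(dn)]), collapse = ", "), call. = FALSE)
  ck <- vapply(components, function(co) comp_key(co$component_type, co$name), "")
  if (anyDuplicated(ck))
    stop("duplicate component(s): ",
         paste(unique(ck[duplicated(ck)]), collapse = "; "), call. = FALSE)
  rid <- vapply(rules, function(r) r$rule_id, "")
  if (anyDuplicated(rid))
    stop("duplicate rule id(s): ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "), call. = FALSE)
  structure(
    list(domains = stats::setNames(state_domains, dn),
         components = stats::setNames(components, ck),
         rules = stats::setNames(rules, rid)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", length(x$domains), " state domains, ",
      length(x$components), " components, ",
      length(x$rules), " rules\n", sep = "")
  invisible(x)
}

# all attribute keys declared by the model's components
model_attr_keys <- function(model) {
  unlist(lapply(model$components, function(co) {
    vapply(co$attributes, function(a)
      paste(co$component_type, co$name, a[1], a[2], sep = ","), "")
  }), use.names = FALSE)
}

# resolve an attribute_ref; NULL if undeclared
resolve_attr <- function(model, ref) {
  co <- model$components[[comp_key(ref$component_type, ref$component_name)]]
  if (is.null(co)) return(NULL)
  for (a in co$attributes)
    if (a[1] == ref$attribute_type && a[2] == ref$attribute_name)
      return(list(component = co, domain = model$domains[[a[1]]]))
  NULL
}

#' Validate a model specification
#'
#' Checks every structural invariant of the model: each attribute type has
#' a state domain, thresholds are positive, every rule term resolves to a
#' declared component attribute, and every condition/action label belongs
#' to its attribute's domain vocabulary.  Violations are returned, not
#' raised, so curators can fix a rule file in one pass.
#'
#' @param model A [model_spec()].
#' @return A data frame of class `validation_report` with columns
#'   `location` and `message`; zero rows means the model is valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  loc <- character(); msg <- character()
  note <- function(l, m) { loc[[length(loc) + 1L]] <<- l
                           msg[[length(msg) + 1L]] <<- m }
  for (co in model$components) {
    ck <- comp_key(co$component_type, co$name)
    if (co$threshold <= 0)
      note(ck, "threshold must be > 0")
    for (a in co$attributes)
      if (is.null(model$domains[[a[1]]]))
        note(paste0(ck, ",", a[1], ",", a[2]),
             paste0("attribute type '", a[1], "' has no state domain"))
  }
  check_side <- function(r, side, terms, slot) {
    for (t in terms) {
      ak <- attr_key(t$ref)
      res <- resolve_attr(model, t$ref)
      if (is.null(res)) {
        note(paste0("rule ", r$rule_id, " ", side),
             paste0("dangling attribute reference '", ak, "'"))
      } else if (!is.null(res$domain) &&
                 !t$label %in% res$domain[[slot]]) {
        note(paste0("rule ", r$rule_id, " ", side),
             paste0("label '", t$label, "' is not a valid ",
                    if (slot == "condition_labels") "condition" else "action",
                    " for domain '", res$domain$name, "'"))
      }
    }
  }
  for (r in model$rules) {
    if (r$effect_score <= 0)
      note(paste0("rule ", r$rule_id), "effect_score must be > 0")
    check_side(r, "lhs", r$lhs, "condition_labels")
    check_side(r, "rhs", r$rhs, "action_labels")
  }
  structure(data.frame(location = loc, message = msg,
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("model is valid (no violations)\n")
  else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x)))
      cat("  [", x$location[i], "] ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}
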