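# The asynchronous, threshold-gated simulation core.
#
# One step:  the active-rule set AR(t) is purged of rules whose condition no
# longer holds on the (previous, current) state pair; one rule is then drawn
# uniformly at random from the satisfied remainder and executed.  Execution
# adds the rule effect score RS(r) to the firing score RFS(c) of every
# target component; when RFS(c) reaches the component threshold TH(c) the
# action is applied to the target attribute and RFS(c) resets to 0.  Rules
# newly enabled by this step's state changes join AR(t+1); a persistent
# rule rejoins while its condition still holds.  The run ends when AR is
# empty (quiescent) or max_steps is reached.

# ---- model compilation ------------------------------------------------------

# Flatten a validated model_spec into integer-indexed structures for the
# hot loop.  States are stored as indices into each domain's state vector.
compile_model <- function(model, rfs_per_attribute = FALSE) {
  rep <- validate_model(model)
  if (nrow(rep) > 0L)
    stop("cannot compile an invalid model; run validate_model() for details",
         call. = FALSE)
  comps <- model$components
  comp_keys <- names(comps)
  attr_keys <- character(); attr_comp <- integer(); attr_dom <- character()
  for (ci in seq_along(comps)) {
    co <- comps[[ci]]
    for (a in co$attributes) {
      attr_keys <- c(attr_keys,
                     paste(co$component_type, co$name, a[1], a[2], sep = ","))
      attr_comp <- c(attr_comp, ci)
      attr_dom <- c(attr_dom, a[1])
    }
  }
  attr_index <- stats::setNames(seq_along(attr_keys), attr_keys)
  domains <- model$domains
  defaults <- vapply(attr_dom, function(d)
    match(domains[[d]]$default_state, domains[[d]]$states), 1L)
  n_rules <- length(model$rules)
  lhs_attr <- vector("list", n_rules); lhs_rel <- vector("list", n_rules)
  rhs_attr <- vector("list", n_rules); rhs_map <- vector("list", n_rules)
  rhs_label <- vector("list", n_rules)
  rs <- numeric(n_rules); persistent <- logical(n_rules)
  disease <- logical(n_rules)
  rules_by_attr <- vector("list", length(attr_keys))
  for (ri in seq_len(n_rules)) {
    r <- model$rules[[ri]]
    la <- integer(); lr <- list()
    for (t in r$lhs) {
      ai <- attr_index[[attr_key(t$ref)]]
      la <- c(la, ai)
      lr[[length(lr) + 1L]] <- domains[[attr_dom[ai]]]$cond_rel[[t$label]]
      rules_by_attr[[ai]] <- c(rules_by_attr[[ai]], ri)
    }
    ra <- integer(); rm <- list(); rl <- character()
    for (t in r$rhs) {
      ai <- attr_index[[attr_key(t$ref)]]
      ra <- c(ra, ai)
      rm[[length(rm) + 1L]] <- domains[[attr_dom[ai]]]$act_map[[t$label]]
      rl <- c(rl, t$label)
    }
    lhs_attr[[ri]] <- la; lhs_rel[[ri]] <- lr
    rhs_attr[[ri]] <- ra; rhs_map[[ri]] <- rm; rhs_label[[ri]] <- rl
    rs[ri] <- r$effect_score
    persistent[ri] <- r$persistent
    disease[ri] <- r$is_disease_rule
  }
  rules_by_attr <- lapply(rules_by_attr,
                          function(x) if (is.null(x)) integer() else unique(x))
  structure(list(
    model = model,
    comp_keys = comp_keys,
    thresholds = vapply(comps, function(co) co$threshold, 1.0),
    attr_keys = attr_keys, attr_index = attr_index,
    attr_comp = attr_comp, attr_dom = attr_dom,
    domain_states = lapply(domains, function(d) d$states),
    defaults = defaults,
    rule_ids = names(model$rules),
    lhs_attr = lhs_attr, lhs_rel = lhs_rel,
    rhs_attr = rhs_attr, rhs_map = rhs_map, rhs_label = rhs_label,
    rs = rs, persistent = persistent, disease = disease,
    rules_by_attr = rules_by_attr,
    rfs_per_attribute = isTRUE(rfs_per_attribute),
    n_pools = if (isTRUE(rfs_per_attribute)) length(attr_keys)
              else length(comp_keys)
  ), class = "compiled_model")
}

rule_sat <- function(cm, ri, prev, curr) {
  la <- cm$lhs_attr[[ri]]; lr <- cm$lhs_rel[[ri]]
  for (j in seq_along(la)) {
    a <- la[j]
    if (!lr[[j]][prev[a], curr[a]]) return(FALSE)
  }
  TRUE
}

sat_subset <- function(cm, rules, prev, curr) {
  if (!length(rules)) return(integer())
  rules[vapply(rules, function(ri) rule_sat(cm, ri, prev, curr), TRUE)]
}

# ---- simulation state -------------------------------------------------------

new_sim_state <- function(cm, states, prev, seed, strict_threshold) {
  st <- new.env(parent = emptyenv())
  st$cm <- cm
  st$step <- 0L
  st$states <- states
  st$prev <- prev
  st$initial <- states
  st$rfs <- numeric(cm$n_pools)
  st$strict <- isTRUE(strict_threshold)
  st$seed <- seed
  st$ev_cap <- 1024L
  st$ev_n <- 0L
  st$ev_step <- integer(st$ev_cap); st$ev_rule <- integer(st$ev_cap)
  st$ev_attr <- integer(st$ev_cap); st$ev_old <- integer(st$ev_cap)
  st$ev_new <- integer(st$ev_cap); st$ev_rfs <- numeric(st$ev_cap)
  st$ar <- sat_subset(cm, seq_along(cm$rule_ids), prev, states)
  class(st) <- "simulation_state"
  st
}

record_event <- function(st, step, ri, a, old, new, rfs_after) {
  n <- st$ev_n + 1L
  if (n > st$ev_cap) {
    st$ev_cap <- st$ev_cap * 2L
    length(st$ev_step) <- st$ev_cap; length(st$ev_rule) <- st$ev_cap
    length(st$ev_attr) <- st$ev_cap; length(st$ev_old) <- st$ev_cap
    length(st$ev_new) <- st$ev_cap; length(st$ev_rfs) <- st$ev_cap
  }
  st$ev_step[n] <- step; st$ev_rule[n] <- ri; st$ev_attr[n] <- a
  st$ev_old[n] <- old; st$ev_new[n] <- new; st$ev_rfs[n] <- rfs_after
  st$ev_n <- n
}

# Pure semantics of executing rule ri's right-hand side: accumulate RFS,
# apply actions on threshold crossings.  Shared by the engine and the
# brute-force oracle so the two cannot drift apart.
fire_pure <- function(cm, states, rfs, ri, strict) {
  ra <- cm$rhs_attr[[ri]]; rm <- cm$rhs_map[[ri]]
  changed <- integer()
  ev_a <- integer(); ev_old <- integer(); ev_new <- integer()
  ev_rfs <- numeric()
  for (j in seq_along(ra)) {
    a <- ra[j]
    pool <- if (cm$rfs_per_attribute) a else cm$attr_comp[a]
    th <- cm$thresholds[cm$attr_comp[a]]
    v <- rfs[pool] + cm$rs[ri]
    crossed <- if (strict) v > th else v >= th
    if (crossed) {
      old <- states[a]
      new <- rm[[j]][old]
      states[a] <- new
      rfs[pool] <- 0
      ev_a <- c(ev_a, a); ev_old <- c(ev_old, old); ev_new <- c(ev_new, new)
      ev_rfs <- c(ev_rfs, 0)
      if (new != old) changed <- c(changed, a)
    } else {
      rfs[pool] <- v
      cur <- states[a]
      ev_a <- c(ev_a, a); ev_old <- c(ev_old, cur); ev_new <- c(ev_new, cur)
      ev_rfs <- c(ev_rfs, v)
    }
  }
  list(states = states, rfs = rfs, changed = changed,
       ev_a = ev_a, ev_old = ev_old, ev_new = ev_new, ev_rfs = ev_rfs)
}

# The active-rule set after firing ri: satisfied non-fired rules stay,
# rules newly enabled by the state changes join, a persistent fired rule
# rejoins while its condition still holds.
next_active <- function(cm, sat, ri, changed, curr_before, states_after) {
  add <- integer()
  if (length(changed)) {
    cand <- unique(unlist(cm$rules_by_attr[changed], use.names = FALSE))
    add <- sat_subset(cm, cand, curr_before, states_after)
  }
  arn <- union(setdiff(sat, ri), add)
  if (cm$persistent[ri] && rule_sat(cm, ri, curr_before, states_after))
    arn <- union(arn, ri)
  arn
}

# Engine wrapper: apply fire_pure to the mutable state and record events.
fire_rule <- function(cm, st, ri) {
  res <- fire_pure(cm, st$states, st$rfs, ri, st$strict)
  st$states <- res$states
  st$rfs <- res$rfs
  for (j in seq_along(res$ev_a))
    record_event(st, st$step, ri, res$ev_a[j], res$ev_old[j],
                 res$ev_new[j], res$ev_rfs[j])
  res$changed
}

# One asynchronous step, using the *global* RNG (callers manage seeding).
step_inner <- function(cm, st) {
  ar <- st$ar
  if (!length(ar)) return(invisible(FALSE))
  prev <- st$prev; curr <- st$states
  sat <- sat_subset(cm, ar, prev, curr)
  if (!length(sat)) {
    st$ar <- integer()
    st$prev <- curr
    st$step <- st$step + 1L
    return(invisible(FALSE))
  }
  ri <- if (length(sat) == 1L) sat else sat[sample.int(length(sat), 1L)]
  changed <- fire_rule(cm, st, ri)
  st$ar <- next_active(cm, sat, ri, changed, curr, st$states)
  st$prev <- curr
  st$step <- st$step + 1L
  invisible(TRUE)
}

# ---- public API -------------------------------------------------------------

#' Initialise a simulation
#'
#' All attributes start at their domain defaults, overridden by the disease
#' file's abnormal initial states; every presence-domain attribute of each
#' injected drug is set to `"present"`.  The initial active-rule set AR(0)
#' holds every rule whose condition is satisfied on the transition from the
#' all-default state to the overridden state (persistent disease rules
#' included on the same basis) — drug injection is the event that starts
#' the simulation.
#'
#' @param model A validated [model_spec()] (or a pre-compiled model).
#' @param disease A [disease_spec()] or `NULL`.
#' @param drugs A [drug_spec()] or `NULL`.
#' @param seed Integer seed recorded in the state (the run's RNG is seeded
#'   by [run_simulation()]).
#' @param strict_threshold If `TRUE`, a firing-score pool must strictly
#'   exceed the threshold to trigger a state change (literal "greater
#'   than"); the default `FALSE` uses `>=`, which with the default
#'   `RS = TH = 1` gives single-firing molecular response.
#' @param rfs_per_attribute If `TRUE`, firing scores accumulate per
#'   attribute rather than pooled per component.
#' @return An environment of class `simulation_state`.
#' @export
sim_initialize <- function(model, disease = NULL, drugs = NULL, seed = 1L,
                           strict_threshold = FALSE,
                           rfs_per_attribute = FALSE) {
  cm <- if (inherits(model, "compiled_model")) model
        else compile_model(model, rfs_per_attribute = rfs_per_attribute)
  defaults <- cm$defaults
  states <- defaults
  overridden <- rep(FALSE, length(states))
  if (!is.null(disease)) {
    stopifnot(inherits(disease, "disease_spec"))
    validate_disease(disease, cm$model)
    for (k in names(disease$initial_states)) {
      a <- cm$attr_index[[k]]
      v <- match(disease$initial_states[[k]],
                 cm$domain_states[[cm$attr_dom[a]]])
      if (overridden[a] && states[a] != v)
        stop("conflicting initial-state overrides for '", k, "'",
             call. = FALSE)
      states[a] <- v
      overridden[a] <- TRUE
    }
  }
  if (!is.null(drugs)) {
    stopifnot(inherits(drugs, "drug_spec"))
    validate_drugs(drugs, cm$model)
    for (d in drugs$drugs) {
      for (a in seq_along(cm$attr_keys)) {
        ref <- strsplit(cm$attr_keys[a], ",", fixed = TRUE)[[1]]
        if (tolower(ref[1]) == "drug" && ref[2] == d &&
            "present" %in% cm$domain_states[[cm$attr_dom[a]]]) {
          v <- match("present", cm$domain_states[[cm$attr_dom[a]]])
          if (overridden[a] && states[a] != v)
            stop("conflicting initial-state overrides for '",
                 cm$attr_keys[a], "'", call. = FALSE)
          states[a] <- v
          overridden[a] <- TRUE
        }
      }
    }
  }
  new_sim_state(cm, states, defaults, as.integer(seed), strict_threshold)
}

#' Advance a simulation by one step
#'
#' Draws one satisfied rule uniformly at random from the active-rule set
#' and executes it (stale rules — whose condition no longer holds — are
#' purged first).  Uses and preserves an RNG stream private to the state.
#'
#' @param state A `simulation_state` from [sim_initialize()].
#' @return The state, invisibly; `state$ar` empty signals quiescence.
#' @export
sim_step <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (is.null(old_rng)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_rng, envir = globalenv()))
  if (is.null(state$rng)) set.seed(state$seed)
  else assign(".Random.seed", state$rng, envir = globalenv())
  step_inner(state$cm, state)
  state$rng <- get(".Random.seed", envir = globalenv())
  invisible(state)
}

#' Execute one rule's right-hand side against the current state
#'
#' Exposed mainly for didactic single-rule experiments: accumulates the
#' rule's effect score into each target pool and applies the action on a
#' threshold crossing, exactly as the engine does internally.
#'
#' @param state A `simulation_state`.
#' @param rule_id Id of a rule of the model.
#' @return Character vector of attribute keys whose state changed.
#' @export
update_component_set <- function(state, rule_id) {
  stopifnot(inherits(state, "simulation_state"))
  cm <- state$cm
  ri <- match(rule_id, cm$rule_ids)
  if (is.na(ri)) stop("unknown rule id '", rule_id, "'", call. = FALSE)
  changed <- fire_rule(cm, state, ri)
  invisible(cm$attr_keys[changed])
}

decode_states <- function(cm, states) {
  stats::setNames(
    vapply(seq_along(states), function(a)
      cm$domain_states[[cm$attr_dom[a]]][states[a]], ""),
    cm$attr_keys)
}

build_trace <- function(cm, st, max_steps) {
  n <- st$ev_n
  idx <- seq_len(n)
  attrs <- st$ev_attr[idx]
  parts <- strsplit(cm$attr_keys[attrs], ",", fixed = TRUE)
  lab <- function(a, s) cm$domain_states[[cm$attr_dom[a]]][s]
  events <- data.frame(
    step = st$ev_step[idx],
    rule_id = cm$rule_ids[st$ev_rule[idx]],
    component_type = vapply(parts, `[`, "", 1L),
    component_name = vapply(parts, `[`, "", 2L),
    attribute_type = vapply(parts, `[`, "", 3L),
    attribute_name = vapply(parts, `[`, "", 4L),
    old_state = vapply(idx, function(i) lab(attrs[i], st$ev_old[i]), ""),
    new_state = vapply(idx, function(i) lab(attrs[i], st$ev_new[i]), ""),
    rfs_after = st$ev_rfs[idx],
    stringsAsFactors = FALSE)
  structure(list(
    seed = st$seed,
    events = events,
    initial_states = decode_states(cm, st$initial),
    terminal_states = decode_states(cm, st$states),
    termination = if (length(st$ar) == 0L) "quiescent" else "max_steps",
    n_steps = st$step,
    config = list(strict_threshold = st$strict,
                  rfs_per_attribute = cm$rfs_per_attribute,
                  max_steps = max_steps)
  ), class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace> seed ", x$seed, ": ", x$n_steps, " steps, ",
      nrow(x$events), " events, ", x$termination, "\n", sep = "")
  invisible(x)
}

#' Run one simulation to quiescence
#'
#' Repeats the asynchronous step until no rule's condition holds
#' (quiescence) or `max_steps` is reached.  Identical model, disease,
#' drugs and seed reproduce the trace bit for bit.
#'
#' @inheritParams sim_initialize
#' @param max_steps Step budget; default 10000.
#' @return An object of class `simulation_trace`: the firing/accumulation
#'   events, initial and terminal states, termination reason and seed.
#' @export
run_simulation <- function(model, disease = NULL, drugs = NULL, seed = 1L,
                           max_steps = 10000L,
                           strict_threshold = FALSE,
                           rfs_per_attribute = FALSE) {
  stopifnot(max_steps > 0L)
  st <- sim_initialize(model, disease, drugs, seed = seed,
                       strict_threshold = strict_threshold,
                       rfs_per_attribute = rfs_per_attribute)
  cm <- st$cm
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (is.null(old_rng)) suppressWarnings(rm(".Random.seed",
                                              envir = globalenv()))
    else assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(st$seed)
  while (length(st$ar) && st$step < max_steps)
    step_inner(cm, st)
  build_trace(cm, st, max_steps)
}
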