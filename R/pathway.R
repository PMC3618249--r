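# Monte Carlo ensembles, drug-effect-pathway extraction and combination
# screening.  The stochastic firing order differs between runs, so the
# pathway graph aggregates rule firings over an ensemble: an edge's
# frequency is the fraction of runs in which its rule fired at least once.

#' Run a Monte Carlo ensemble of simulations
#'
#' Repeats the simulation with seeds `base_seed`, `base_seed + 1`, ...,
#' `base_seed + n_runs - 1`.  The default of 100 repetitions is the usual
#' Monte Carlo depth for pathway extraction.
#'
#' @inheritParams run_simulation
#' @param n_runs Number of independent runs (>= 1); default 100.
#' @param base_seed Seed of the first run.
#' @return An object of class `ensemble`: a list of `simulation_trace`s
#'   plus the shared inputs.
#' @export
run_ensemble <- function(model, disease = NULL, drugs = NULL,
                         n_runs = 100L, base_seed = 1L,
                         max_steps = 10000L,
                         strict_threshold = FALSE,
                         rfs_per_attribute = FALSE) {
  stopifnot(n_runs >= 1L)
  cm <- if (inherits(model, "compiled_model")) model
        else compile_model(model, rfs_per_attribute = rfs_per_attribute)
  traces <- lapply(seq_len(n_runs) - 1L, function(i)
    run_simulation(cm, disease, drugs, seed = base_seed + i,
                   max_steps = max_steps,
                   strict_threshold = strict_threshold,
                   rfs_per_attribute = rfs_per_attribute))
  structure(list(traces = traces, base_seed = as.integer(base_seed),
                 n_runs = as.integer(n_runs), model = cm$model,
                 drugs = if (is.null(drugs)) character() else drugs$drugs),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", x$n_runs, " runs (base seed ", x$base_seed, ")",
      if (length(x$drugs)) paste0(", drugs: ",
                                  paste(x$drugs, collapse = "+")),
      "\n", sep = "")
  invisible(x)
}

# fraction of runs in which each rule fired at least once
rule_firing_frequency <- function(ensemble) {
  ids <- names(ensemble$model$rules)
  counts <- stats::setNames(numeric(length(ids)), ids)
  for (tr in ensemble$traces) {
    fired <- unique(tr$events$rule_id)
    counts[fired] <- counts[fired] + 1
  }
  counts / ensemble$n_runs
}

#' Build a drug-effect-pathway graph from an ensemble
#'
#' Every rule contributes one directed edge per (LHS attribute, RHS
#' attribute) pair, labelled with the rule id, the effect direction (the
#' RHS action) and the firing frequency.  Edges below `min_frequency` are
#' pruned, and only nodes reachable from the injected drug roots are kept,
#' so the graph traces how the drug's action propagates from its target to
#' the final nodes.
#'
#' @param ensemble An [run_ensemble()] result.
#' @param min_frequency Prune edges whose rule fired in fewer than this
#'   fraction of runs (default 0.05).
#' @return An object of class `pathway_graph` with data frames `nodes`
#'   (column `key`) and `edges` (columns `source`, `target`, `rule_id`,
#'   `direction`, `frequency`) in deterministic order, plus `roots`.
#' @export
build_pathway_graph <- function(ensemble, min_frequency = 0.05) {
  stopifnot(inherits(ensemble, "ensemble"), ensemble$n_runs >= 1L)
  freq <- rule_firing_frequency(ensemble)
  model <- ensemble$model
  src <- character(); tgt <- character(); rid <- character()
  dir <- character(); frq <- numeric()
  for (r in model$rules) {
    f <- freq[[r$rule_id]]
    if (f <= 0 || f < min_frequency) next
    for (lt in r$lhs) for (rt in r$rhs) {
      src <- c(src, attr_key(lt$ref)); tgt <- c(tgt, attr_key(rt$ref))
      rid <- c(rid, r$rule_id); dir <- c(dir, rt$label); frq <- c(frq, f)
    }
  }
  roots <- character()
  for (d in ensemble$drugs)
    for (co in model$components)
      if (tolower(co$component_type) == "drug" && co$name == d)
        for (a in co$attributes)
          roots <- c(roots, paste(co$component_type, co$name, a[1], a[2],
                                  sep = ","))
  edges <- data.frame(source = src, target = tgt, rule_id = rid,
                      direction = dir, frequency = frq,
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$source, edges$target, roots)))
  if (nrow(edges) > 0L && length(roots) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       vertices = nodes, directed = TRUE)
    reach <- unique(unlist(lapply(roots, function(rt)
      names(igraph::subcomponent(g, rt, mode = "out")))))
    keep <- edges$source %in% reach & edges$target %in% reach
    edges <- edges[keep, , drop = FALSE]
    nodes <- sort(intersect(nodes, c(reach, roots)))
  }
  o <- order(edges$source, edges$target, edges$rule_id)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(key = nodes, stringsAsFactors = FALSE),
                 edges = edges, roots = sort(unique(roots)),
                 min_frequency = min_frequency),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, roots: ", paste(x$roots, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Export a pathway graph as SIF
#'
#' One line per edge: `source<TAB>rule_id:direction:frequency<TAB>target`.
#' Node keys are comma-joined attribute references.
#'
#' @param graph A [build_pathway_graph()] result.
#' @param path Output path.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  writeLines(paste(e$source,
                   paste(e$rule_id, e$direction,
                         formatC(e$frequency, format = "g"), sep = ":"),
                   e$target, sep = "\t"), path)
  invisible(path)
}

#' Export a pathway graph as Graphviz DOT
#'
#' Drug-root nodes are drawn as boxes; edge labels carry
#' `rule_id:direction:frequency`.
#'
#' @inheritParams write_sif
#' @export
write_dot <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  out <- c("digraph pathway {")
  for (nk in graph$nodes$key) {
    shape <- if (nk %in% graph$roots) " [shape=box]" else ""
    out <- c(out, paste0("  ", q(nk), shape, ";"))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e)))
    out <- c(out, paste0("  ", q(e$source[i]), " -> ", q(e$target[i]),
                         " [label=", q(paste(e$rule_id[i], e$direction[i],
                                             formatC(e$frequency[i],
                                                     format = "g"),
                                             sep = ":")), "];"))
  out <- c(out, "}")
  writeLines(out, path)
  invisible(path)
}

#' Judge drug efficacy against a terminal-state criterion
#'
#' The diagnostic criterion is an attribute (for the diabetes model, blood
#' glucose in the circulation) and a target state; the drug (set) is
#' effective when the fraction of runs whose terminal criterion state
#' equals the target reaches the cutoff.
#'
#' @param ensemble An [run_ensemble()] result.
#' @param criterion An [attribute_ref()] (or key string) resolving in the
#'   model.
#' @param target_state Desired terminal state label (e.g. `"normal"`).
#' @param cutoff Fraction of runs required for an `"effective"` verdict
#'   (`>=` comparison); default 0.5.
#' @return An object of class `efficacy_result` with fields `drugs`,
#'   `criterion`, `target_state`, `fraction`, `verdict`, `cutoff`.
#' @export
assess_efficacy <- function(ensemble, criterion, target_state,
                            cutoff = 0.5) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.character(criterion)) criterion <- attr_ref_from_key(criterion)
  if (is.null(resolve_attr(ensemble$model, criterion)))
    stop("criterion attribute '", attr_key(criterion),
         "' does not resolve in the model", call. = FALSE)
  key <- attr_key(criterion)
  hits <- vapply(ensemble$traces,
                 function(tr) identical(tr$terminal_states[[key]],
                                        target_state), TRUE)
  fraction <- mean(hits)
  structure(list(drugs = ensemble$drugs, criterion = key,
                 target_state = target_state, fraction = fraction,
                 verdict = if (fraction >= cutoff) "effective"
                           else "not effective",
                 cutoff = cutoff),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat("<efficacy_result> ",
      if (length(x$drugs)) paste(x$drugs, collapse = "+") else "(no drug)",
      ": ", x$criterion, " == ", x$target_state, " in ",
      format(x$fraction), " of runs -> ", x$verdict,
      " (cutoff ", format(x$cutoff), ")\n", sep = "")
  invisible(x)
}

#' Screen drug combinations for efficacy
#'
#' Evaluates every k-drug combination (all k-subsets of `drug_names`, or
#' with `anchor` given, the anchor plus every (k-1)-subset of the rest)
#' with one Monte Carlo ensemble per combination.
#'
#' @inheritParams run_ensemble
#' @param drug_names Catalogue of drug component names.
#' @param anchor Optional drug that must appear in every combination.
#' @param k Combination size (>= 2); default 2.
#' @param criterion,target_state,cutoff Passed to [assess_efficacy()].
#' @return A data frame (class `screening_result`) with one row per
#'   combination: `combination`, `fraction`, `verdict`, sorted by fraction
#'   descending, ties broken by combination name.
#' @export
screen_combinations <- function(model, disease, drug_names,
                                anchor = NULL, k = 2L,
                                criterion, target_state,
                                n_runs = 100L, base_seed = 1L,
                                cutoff = 0.5, max_steps = 10000L) {
  stopifnot(k >= 2L)
  drug_names <- unique(as.character(drug_names))
  if (!is.null(anchor) && !anchor %in% drug_names)
    stop("anchor '", anchor, "' is not in drug_names", call. = FALSE)
  combos <-
    if (is.null(anchor)) {
      utils::combn(sort(drug_names), k, simplify = FALSE)
    } else {
      rest <- sort(setdiff(drug_names, anchor))
      lapply(utils::combn(rest, k - 1L, simplify = FALSE),
             function(s) c(anchor, s))
    }
  cm <- if (inherits(model, "compiled_model")) model else compile_model(model)
  rows <- lapply(seq_along(combos), function(i) {
    combo <- combos[[i]]
    ens <- run_ensemble(cm, disease, drug_spec(combo),
                        n_runs = n_runs,
                        base_seed = base_seed + (i - 1L) * n_runs,
                        max_steps = max_steps)
    eff <- assess_efficacy(ens, criterion, target_state, cutoff = cutoff)
    data.frame(combination = paste(combo, collapse = "+"),
               fraction = eff$fraction, verdict = eff$verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}
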