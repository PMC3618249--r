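# Readers/writers for the platform's input files and the result trace.
#
# Four inputs drive a simulation:
#   component file -- state domains + components/attributes/thresholds
#   rule file      -- one rule per line in a small DSL mirroring the
#                     5-tuple -> 5-tuple rule form
#   disease file   -- abnormal initial states + disease-rule flags
#   drug file      -- drug components to inject at t = 0
# '#' comments and blank lines are permitted everywhere.  Loading order is
# components -> rules -> disease -> drugs; readers that need a model error
# if it is missing rather than defaulting silently.

strip_comment <- function(line) sub("\\s*#.*$", "", line)

read_clean_lines <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  data.frame(n = seq_along(raw), text = vapply(raw, strip_comment, "",
                                               USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

io_stop <- function(path, n, ...) {
  stop(basename(path), ":", n, ": ", ..., call. = FALSE)
}

#' Read a component file
#'
#' The component file declares the state domains and the components with
#' their attributes and (optional) thresholds.  Format: a block opens with
#' an unindented `domain <attribute-type>` or `component <type> <name>`
#' line; indented `key: value` lines fill the block.  Domain keys:
#' `states` (comma-separated, required), `kind` (`ordered`/`categorical`),
#' `default`.  Component keys: `threshold` and `attributes:` followed by
#' indented `type, name` lines.  Missing thresholds are defaulted by
#' component type class (molecule/cell/drug 1.0, tissue/organ 60.0).
#'
#' @param path Path to the component file.
#' @return A [model_spec()] with domains and components but no rules.
#' @export
read_component_file <- function(path) {
  ln <- read_clean_lines(path)
  domains <- list(); components <- list()
  cur <- NULL          # list(kind = "domain"/"component", fields...)
  in_attrs <- FALSE

  flush <- function() {
    if (is.null(cur)) return()
    if (cur$what == "domain") {
      if (is.null(cur$states))
        io_stop(path, cur$line, "domain '", cur$name, "' has no 'states:'")
      domains[[length(domains) + 1L]] <<-
        state_domain(cur$name, cur$states,
                     kind = if (is.null(cur$kind)) "ordered" else cur$kind,
                     default_state = cur$default)
    } else {
      co <- component(cur$type, cur$name, attributes = cur$attrs,
                      threshold = cur$threshold)
      ck <- comp_key(co$component_type, co$name)
      if (ck %in% names(components))
        io_stop(path, cur$line, "duplicate component '", ck, "'")
      components[[ck]] <<- co
    }
  }

  for (i in seq_len(nrow(ln))) {
    text <- ln$text[i]
    if (!nzchar(trimws(text))) next
    indented <- grepl("^\\s", text)
    t <- trimws(text)
    if (!indented) {
      flush()
      in_attrs <- FALSE
      tok <- strsplit(t, "\\s+")[[1]]
      if (tok[1] == "domain" && length(tok) == 2L) {
        cur <- list(what = "domain", name = tok[2], line = ln$n[i],
                    states = NULL, kind = NULL, default = NULL)
      } else if (tok[1] == "component" && length(tok) >= 3L) {
        cur <- list(what = "component", type = tok[2],
                    name = paste(tok[-(1:2)], collapse = " "),
                    line = ln$n[i], threshold = NULL, attrs = list())
      } else {
        io_stop(path, ln$n[i], "expected 'domain <type>' or ",
                "'component <type> <name>', got '", t, "'")
      }
    } else {
      if (is.null(cur))
        io_stop(path, ln$n[i], "indented line outside any block")
      if (grepl(":", t, fixed = TRUE)) {
        kv <- regmatches(t, regexpr(":", t, fixed = TRUE), invert = TRUE)[[1]]
        key <- trimws(kv[1]); val <- trimws(kv[2])
        in_attrs <- FALSE
        if (cur$what == "domain") {
          if (key == "states")
            cur$states <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
          else if (key == "kind") cur$kind <- val
          else if (key == "default") cur$default <- val
          else io_stop(path, ln$n[i], "unknown domain key '", key, "'")
        } else {
          if (key == "threshold") {
            th <- suppressWarnings(as.numeric(val))
            if (is.na(th))
              io_stop(path, ln$n[i], "threshold '", val, "' is not a number")
            cur$threshold <- th
          } else if (key == "attributes") {
            in_attrs <- TRUE
          } else io_stop(path, ln$n[i], "unknown component key '", key, "'")
        }
      } else if (in_attrs && cur$what == "component") {
        pair <- trimws(strsplit(t, ",", fixed = TRUE)[[1]])
        if (length(pair) != 2L)
          io_stop(path, ln$n[i], "attribute line must be 'type, name'")
        cur$attrs[[length(cur$attrs) + 1L]] <- pair
      } else {
        io_stop(path, ln$n[i], "unparseable line '", t, "'")
      }
    }
  }
  flush()

  model <- model_spec(domains, unname(components))
  for (co in model$components)
    for (a in co$attributes)
      if (is.null(model$domains[[a[1]]]))
        stop(basename(path), ": component '",
             comp_key(co$component_type, co$name),
             "' uses attribute type '", a[1],
             "' with no declared state domain", call. = FALSE)
  model
}

#' Write a component file
#'
#' Inverse of [read_component_file()]; write-then-read is the identity.
#'
#' @param model A [model_spec()] (rules, if any, are not written).
#' @param path Output path.
#' @export
write_component_file <- function(model, path) {
  out <- character()
  for (d in model$domains) {
    out <- c(out, paste("domain", d$name),
             paste0("  states: ", paste(d$states, collapse = ", ")),
             paste0("  kind: ", d$kind),
             paste0("  default: ", d$default_state))
  }
  for (co in model$components) {
    out <- c(out, paste("component", co$component_type, co$name),
             paste0("  threshold: ", format(co$threshold)),
             "  attributes:",
             vapply(co$attributes,
                    function(a) paste0("    ", a[1], ", ", a[2]), ""))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- rule DSL ---------------------------------------------------------------

parse_rule_term <- function(txt, path = "<string>", n = NA) {
  p <- trimws(strsplit(trimws(txt), ",", fixed = TRUE)[[1]])
  if (length(p) != 5L)
    io_stop(path, n, "rule term '", txt,
            "' must have 5 comma-separated fields")
  rule_term(attribute_ref(p[1], p[2], p[3], p[4]), p[5])
}

#' Parse one line of the rule DSL
#'
#' Grammar: `LHS (& LHS)* -> RHS (& RHS)* [annotations]` where each term is
#' `ComponentType,ComponentName,AttributeType,AttributeName,Label` and the
#' trailing annotations are `@rs=FLOAT`, `@disease`, `@persistent` and
#' `@src=TEXT`.  Both `->` and a literal arrow are accepted.
#'
#' @param line One rule line (comments already stripped).
#' @param rule_id Identifier to assign; defaults derived by the caller.
#' @param path,n Origin used in error messages.
#' @return A [rule()].
#' @export
parse_rule_line <- function(line, rule_id = "r", path = "<string>", n = NA) {
  txt <- trimws(line)
  txt <- gsub("→", "->", txt)   # accept a literal arrow character
  ann <- list(rs = 1.0, disease = FALSE, persistent = FALSE, src = "curated")
  repeat {
    m <- regmatches(txt, regexpr("@[A-Za-z]+(=[^@]*)?\\s*$", txt))
    if (length(m) == 0L) break
    a <- trimws(m)
    txt <- trimws(sub("@[A-Za-z]+(=[^@]*)?\\s*$", "", txt))
    if (grepl("^@rs=", a)) {
      v <- suppressWarnings(as.numeric(sub("^@rs=", "", a)))
      if (is.na(v)) io_stop(path, n, "bad @rs annotation '", a, "'")
      ann$rs <- v
    } else if (a == "@disease") ann$disease <- TRUE
    else if (a == "@persistent") ann$persistent <- TRUE
    else if (grepl("^@src=", a)) ann$src <- sub("^@src=", "", a)
    else io_stop(path, n, "unknown annotation '", a, "'")
  }
  sides <- strsplit(txt, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    io_stop(path, n, "rule must contain exactly one '->'")
  lhs <- lapply(strsplit(sides[1], "&", fixed = TRUE)[[1]],
                parse_rule_term, path = path, n = n)
  rhs <- lapply(strsplit(sides[2], "&", fixed = TRUE)[[1]],
                parse_rule_term, path = path, n = n)
  rule(rule_id, lhs, rhs, effect_score = ann$rs,
       is_disease_rule = ann$disease, persistent = ann$persistent,
       provenance = ann$src)
}

#' Serialise a rule to its DSL line
#'
#' @param r A [rule()].
#' @param with_id Prefix the line with `rule_id:`.
#' @return A single character string; [parse_rule_line()] of it round-trips.
#' @export
format_rule <- function(r, with_id = FALSE) {
  term <- function(t) paste(attr_key(t$ref), t$label, sep = ",")
  s <- paste(paste(vapply(r$lhs, term, ""), collapse = " & "),
             "->",
             paste(vapply(r$rhs, term, ""), collapse = " & "))
  if (r$effect_score != 1.0) s <- paste0(s, " @rs=", format(r$effect_score))
  if (r$is_disease_rule) s <- paste0(s, " @disease")
  if (r$persistent) s <- paste0(s, " @persistent")
  if (!identical(r$provenance, "curated"))
    s <- paste0(s, " @src=", r$provenance)
  if (with_id) s <- paste0(r$rule_id, ": ", s)
  s
}

#' Read a rule file and attach its rules to a model
#'
#' Each non-comment line is one rule in the DSL of [parse_rule_line()].  A
#' line may carry an explicit id prefix `id: rule...`; otherwise ids
#' `r0001`, `r0002`, ... are assigned in file order.  All attribute
#' references and condition/action labels are validated against the model.
#'
#' @param path Path to the rule file.
#' @param model A [model_spec()] from [read_component_file()].
#' @return `model` with the rules attached.
#' @export
read_rule_file <- function(path, model) {
  stopifnot(inherits(model, "model_spec"))
  ln <- read_clean_lines(path)
  rules <- list(); k <- 0L
  for (i in seq_len(nrow(ln))) {
    t <- trimws(ln$text[i])
    if (!nzchar(t)) next
    k <- k + 1L
    id <- sprintf("r%04d", k)
    m <- regmatches(t, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", t))[[1]]
    if (length(m) == 3L && grepl("->", m[3], fixed = TRUE)) {
      id <- m[2]; t <- m[3]
    }
    r <- parse_rule_line(t, rule_id = id, path = path, n = ln$n[i])
    if (id %in% names(rules))
      io_stop(path, ln$n[i], "duplicate rule id '", id, "'")
    rules[[id]] <- r
  }
  out <- model_spec(unname(model$domains), unname(model$components),
                    unname(rules))
  rep <- validate_model(out)
  if (nrow(rep) > 0L)
    stop(basename(path), ": invalid rules:\n",
         paste0("  [", rep$location, "] ", rep$message, collapse = "\n"),
         call. = FALSE)
  out
}

#' Write a rule file
#'
#' @param model A [model_spec()] whose rules are written one per line with
#'   explicit id prefixes.
#' @param path Output path.
#' @export
write_rule_file <- function(model, path) {
  writeLines(vapply(model$rules, format_rule, "", with_id = TRUE), path)
  invisible(path)
}

# ---- disease / drug files ---------------------------------------------------

#' Specify a disease context
#'
#' @param name Disease identifier.
#' @param initial_states Named character vector or list mapping attribute
#'   keys (`"type,name,atype,aname"`) to abnormal initial state labels.
#' @param disease_rule_ids Ids of rules flagged `is_disease_rule` in the
#'   companion model.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(name = "disease", initial_states = character(),
                         disease_rule_ids = character()) {
  initial_states <- unlist(initial_states)
  if (length(initial_states) == 0L) initial_states <- character()
  structure(list(name = name,
                 initial_states = initial_states,
                 disease_rule_ids = as.character(disease_rule_ids)),
            class = "disease_spec")
}

#' Specify drugs to inject
#'
#' @param drugs Character vector of drug component names; at t = 0 every
#'   presence-domain attribute of each named drug is set to `"present"`,
#'   which is the event that starts the simulation.
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(drugs = character()) {
  structure(list(drugs = as.character(drugs)), class = "drug_spec")
}

validate_disease <- function(disease, model) {
  for (k in names(disease$initial_states)) {
    res <- resolve_attr(model, attr_ref_from_key(k))
    if (is.null(res))
      stop("disease '", disease$name, "': unknown attribute '", k, "'",
           call. = FALSE)
    if (!disease$initial_states[[k]] %in% res$domain$states)
      stop("disease '", disease$name, "': state '",
           disease$initial_states[[k]], "' invalid for '", k, "'",
           call. = FALSE)
  }
  for (id in disease$disease_rule_ids) {
    r <- model$rules[[id]]
    if (is.null(r))
      stop("disease '", disease$name, "': unknown rule id '", id, "'",
           call. = FALSE)
    if (!r$is_disease_rule)
      stop("disease '", disease$name, "': rule '", id,
           "' is not flagged @disease", call. = FALSE)
  }
  invisible(TRUE)
}

validate_drugs <- function(drugs, model) {
  for (d in drugs$drugs) {
    hit <- Filter(function(co) tolower(co$component_type) == "drug" &&
                    co$name == d, model$components)
    if (length(hit) == 0L)
      stop("drug '", d, "' is not a drug component of the model",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a disease file
#'
#' Lines: `name <id>`, `state <attribute-ref> = <label>` and
#' `disease_rule <rule-id>`.  An empty file yields a disease with no
#' overrides, i.e. every attribute starts at its domain default.
#'
#' @param path Path to the disease file.
#' @param model The loaded [model_spec()] (with rules) used for validation.
#' @return A [disease_spec()].
#' @export
read_disease_file <- function(path, model) {
  stopifnot(inherits(model, "model_spec"))
  ln <- read_clean_lines(path)
  name <- "disease"; states <- character(); rids <- character()
  for (i in seq_len(nrow(ln))) {
    t <- trimws(ln$text[i])
    if (!nzchar(t)) next
    tok <- strsplit(t, "\\s+")[[1]]
    if (tok[1] == "name" && length(tok) >= 2L) {
      name <- tok[2]
    } else if (tok[1] == "state") {
      m <- regmatches(t, regexec("^state\\s+(\\S+)\\s*=\\s*(\\S+)$", t))[[1]]
      if (length(m) != 3L)
        io_stop(path, ln$n[i], "expected 'state <ref> = <label>'")
      if (m[2] %in% names(states) && states[[m[2]]] != m[3])
        io_stop(path, ln$n[i], "conflicting overrides for '", m[2], "'")
      states[[m[2]]] <- m[3]
    } else if (tok[1] == "disease_rule" && length(tok) == 2L) {
      rids <- c(rids, tok[2])
    } else {
      io_stop(path, ln$n[i], "unparseable disease line '", t, "'")
    }
  }
  d <- disease_spec(name, states, rids)
  validate_disease(d, model)
  d
}

#' Write a disease file
#' @param disease A [disease_spec()].
#' @param path Output path.
#' @export
write_disease_file <- function(disease, path) {
  out <- paste("name", disease$name)
  for (k in names(disease$initial_states))
    out <- c(out, paste("state", k, "=", disease$initial_states[[k]]))
  for (id in disease$disease_rule_ids)
    out <- c(out, paste("disease_rule", id))
  writeLines(out, path)
  invisible(path)
}

#' Read a drug file
#'
#' One drug component name per non-comment line.
#'
#' @param path Path to the drug file.
#' @param model The loaded [model_spec()] used for validation.
#' @return A [drug_spec()].
#' @export
read_drug_file <- function(path, model) {
  stopifnot(inherits(model, "model_spec"))
  ln <- read_clean_lines(path)
  drugs <- character()
  for (i in seq_len(nrow(ln))) {
    t <- trimws(ln$text[i])
    if (nzchar(t)) drugs <- c(drugs, t)
  }
  d <- drug_spec(drugs)
  validate_drugs(d, model)
  d
}

#' Write a drug file
#' @param drugs A [drug_spec()].
#' @param path Output path.
#' @export
write_drug_file <- function(drugs, path) {
  writeLines(drugs$drugs, path)
  invisible(path)
}

# ---- trace file -------------------------------------------------------------

TRACE_COLS <- c("step", "rule_id", "component_type", "component_name",
                "attribute_type", "attribute_name",
                "old_state", "new_state", "rfs_after")

#' Write a simulation trace to a tab-separated result file
#'
#' One row per rule-effect event, in firing order: threshold crossings
#' carry the old and new state and `rfs_after = 0`; sub-threshold
#' accumulations carry `old_state == new_state` and the accumulated score.
#' Lines beginning `#` hold the reproducibility header.
#'
#' @param trace A `simulation_trace` from [run_simulation()].
#' @param path Output path.
#' @param header Optional extra comment lines (without the leading `#`).
#' @export
write_trace <- function(trace, path, header = character()) {
  stopifnot(inherits(trace, "simulation_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("seed=", trace$seed,
                  " steps=", trace$n_steps,
                  " termination=", trace$termination),
           header)
  writeLines(paste0("# ", hdr), con)
  utils::write.table(trace$events[TRACE_COLS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace file back into a data frame
#'
#' @param path Path written by [write_trace()].
#' @return A data frame with the 9 trace columns.
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(step = "integer",
                                         rfs_after = "numeric"))
  if (!identical(names(df), TRACE_COLS))
    stop("not a trace file: ", path, call. = FALSE)
  df
}
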