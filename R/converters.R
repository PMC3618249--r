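# Rule extraction from other modelling formalisms.
#
# ODE systems: the qualitative engine only needs the *direction* of each
# variable-to-variable effect, so the converter estimates the sign of
# d(dx_target/dt)/d(source) by central finite differences on a grid over
# the declared variable ranges.  A uniformly positive (negative) sign
# yields an activation (inhibition) rule pair; a sign that flips along the
# source axis but is independent of the other variables is partitioned at
# the estimated sign-change point; anything else is unconvertible.
#
# Petri nets: a transition is the changing action mediating its input and
# output places, so each transition maps structurally to one rule (inputs
# -> conditions, outputs -> actions).  Token dynamics are not simulated;
# the rule engine replaces them.

#' Declare an ODE system for rule extraction
#'
#' @param variables Named list mapping variable names to [attribute_ref()]s
#'   (or `"type,name,atype,aname"` keys) in the companion model.
#' @param equations Named character vector: for each variable, the
#'   right-hand side dx/dt as plain infix arithmetic (`+ - * / ^`,
#'   parentheses) over variables and parameters.
#' @param parameters Named numeric vector of parameter values.
#' @param ranges Named list mapping each variable to `c(lo, hi)` with
#'   `lo < hi`; the biologically plausible range sampled by the analysis.
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(variables, equations, parameters = numeric(),
                       ranges) {
  vn <- names(variables)
  stopifnot(length(vn) > 0L, !is.null(names(equations)),
            all(names(equations) %in% vn), all(vn %in% names(equations)))
  variables <- lapply(variables, function(r)
    if (is.character(r)) attr_ref_from_key(r) else r)
  exprs <- lapply(equations, function(e) {
    ex <- tryCatch(parse(text = e)[[1]],
                   error = function(err)
                     stop("cannot parse expression '", e, "': ",
                          conditionMessage(err), call. = FALSE))
    ex
  })
  allowed <- c(vn, names(parameters))
  for (v in vn) {
    syms <- all.vars(exprs[[v]])
    bad <- setdiff(syms, allowed)
    if (length(bad))
      stop("equation for '", v, "' uses undeclared symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (v in vn) {
    rg <- ranges[[v]]
    if (is.null(rg) || length(rg) != 2L || !(rg[1] < rg[2]))
      stop("variable '", v, "' needs a range c(lo, hi) with lo < hi",
           call. = FALSE)
  }
  structure(list(variables = variables, equations = equations,
                 exprs = exprs, parameters = parameters,
                 ranges = ranges[vn]),
            class = "ode_system")
}

# evaluate d(target)/dt on vectorised variable values
eval_rhs <- function(system, target, vals) {
  eval(system$exprs[[target]],
       envir = c(vals, as.list(system$parameters)))
}

#' Classify the influence of one ODE variable on another
#'
#' Estimates the partial effect of `source` on `d(target)/dt` by central
#' finite differences at every point of a full-factorial grid over the
#' declared variable ranges.
#'
#' @param system An [ode_system()].
#' @param source,target Variable names.
#' @param grid_points_per_dim Grid resolution per variable (>= 3);
#'   default 7.
#' @param fd_step Finite-difference half-step as a fraction of the source
#'   range width; default 1e-4.
#' @param zero_tol Effects with absolute value at or below this are
#'   treated as zero; default 1e-9.
#' @return A list (class `influence_entry`): `source`, `target`,
#'   `classification` (`"positive"`, `"negative"`, `"none"`,
#'   `"non-monotone-partitioned"` or `"unconvertible"`), `segments` (for
#'   partitioned influences, a data frame `lo`/`hi`/`sign` of source
#'   sub-intervals), and `effect_range` summarising the sampled effects.
#' @export
classify_influence <- function(system, source, target,
                               grid_points_per_dim = 7L,
                               fd_step = 1e-4, zero_tol = 1e-9) {
  stopifnot(inherits(system, "ode_system"),
            grid_points_per_dim >= 3L)
  vn <- names(system$variables)
  stopifnot(source %in% vn, target %in% vn)
  entry <- function(classification, segments = NULL, fd = numeric()) {
    structure(list(source = source, target = target,
                   classification = classification, segments = segments,
                   effect_range = if (length(fd)) range(fd) else c(0, 0),
                   grid_points_per_dim = grid_points_per_dim),
              class = "influence_entry")
  }
  if (!source %in% all.vars(system$exprs[[target]]))
    return(entry("none"))

  axes <- lapply(vn, function(v)
    seq(system$ranges[[v]][1], system$ranges[[v]][2],
        length.out = grid_points_per_dim))
  names(axes) <- vn
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  h <- fd_step * diff(system$ranges[[source]])
  fd_at <- function(vals) {
    up <- vals; up[[source]] <- up[[source]] + h
    dn <- vals; dn[[source]] <- dn[[source]] - h
    (eval_rhs(system, target, up) - eval_rhs(system, target, dn)) / (2 * h)
  }
  fd <- fd_at(as.list(grid))
  s <- ifelse(fd > zero_tol, 1L, ifelse(fd < -zero_tol, -1L, 0L))

  if (all(s == 0L)) return(entry("none", fd = fd))
  if (all(s >= 0L)) return(entry("positive", fd = fd))
  if (all(s <= 0L)) return(entry("negative", fd = fd))

  # mixed signs: usable only if the sign depends on the source value alone
  src_vals <- axes[[source]]
  slice_sign <- integer(length(src_vals))
  for (j in seq_along(src_vals)) {
    sl <- s[abs(grid[[source]] - src_vals[j]) < 1e-12]
    nz <- unique(sl[sl != 0L])
    if (length(nz) > 1L) return(entry("unconvertible", fd = fd))
    slice_sign[j] <- if (length(nz)) nz else 0L
  }
  # bisect the 1-D finite-difference estimate (other variables at range
  # midpoints) to locate each sign-change point
  mids <- lapply(vn, function(v) mean(system$ranges[[v]]))
  names(mids) <- vn
  fd_1d <- function(v) { vals <- mids; vals[[source]] <- v; fd_at(vals) }
  nz_idx <- which(slice_sign != 0L)
  seg_lo <- numeric(); seg_hi <- numeric(); seg_sign <- integer()
  start <- system$ranges[[source]][1]
  for (k in seq_along(nz_idx)[-1]) {
    a <- nz_idx[k - 1L]; b <- nz_idx[k]
    if (slice_sign[a] == slice_sign[b]) next
    lo <- src_vals[a]; hi <- src_vals[b]
    flo <- fd_1d(lo)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      fmid <- fd_1d(mid)
      if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid } else hi <- mid
      if (hi - lo < diff(system$ranges[[source]]) * 1e-9) break
    }
    bp <- (lo + hi) / 2
    seg_lo <- c(seg_lo, start); seg_hi <- c(seg_hi, bp)
    seg_sign <- c(seg_sign, slice_sign[a])
    start <- bp
  }
  seg_lo <- c(seg_lo, start)
  seg_hi <- c(seg_hi, system$ranges[[source]][2])
  seg_sign <- c(seg_sign, slice_sign[nz_idx[length(nz_idx)]])
  entry("non-monotone-partitioned",
        segments = data.frame(lo = seg_lo, hi = seg_hi, sign = seg_sign),
        fd = fd)
}

#' @export
print.influence_entry <- function(x, ...) {
  cat("<influence> ", x$source, " -> d(", x$target, ")/dt: ",
      x$classification, "\n", sep = "")
  if (!is.null(x$segments)) {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  [%.4g, %.4g] sign %+d\n", x$segments$lo[i],
                  x$segments$hi[i], x$segments$sign[i]))
  }
  invisible(x)
}

influence_rules <- function(system, ent, note = NULL) {
  src_ref <- system$variables[[ent$source]]
  tgt_ref <- system$variables[[ent$target]]
  sgn <- if (ent$classification == "positive") 1L else -1L
  prov <- paste0("ode:", ent$source, "->", ent$target,
                 if (!is.null(note)) paste0(" [", note, "]"))
  suffix <- if (!is.null(note)) paste0("_", gsub("[^0-9a-z]+", "",
                                                 tolower(note))) else ""
  mk <- function(cl, al, tag)
    rule(paste0("ode_", ent$source, "_", ent$target, "_", tag, suffix),
         list(rule_term(src_ref, cl)), list(rule_term(tgt_ref, al)),
         provenance = prov)
  if (sgn > 0L) list(mk("up", "up", "up"), mk("down", "down", "down"))
  else list(mk("up", "down", "up"), mk("down", "up", "down"))
}

#' Extract qualitative rules from an ODE system
#'
#' Classifies every ordered variable pair with [classify_influence()] and
#' emits rules: a positive influence yields the pair `src up -> tgt up`,
#' `src down -> tgt down`; a negative influence the crossed pair; a
#' partitioned influence yields one pair per sub-interval with the valid
#' interval recorded in the rule provenance; unconvertible pairs emit
#' nothing and are flagged in the report.
#'
#' @inheritParams classify_influence
#' @return A list with `rules` (list of [rule()]s) and `report` (list of
#'   `influence_entry`s, one per ordered pair with a candidate influence).
#' @export
ode_to_rules <- function(system, grid_points_per_dim = 7L,
                         fd_step = 1e-4, zero_tol = 1e-9) {
  vn <- names(system$variables)
  rules <- list(); report <- list()
  for (tgt in vn) for (src in setdiff(vn, tgt)) {
    ent <- classify_influence(system, src, tgt,
                              grid_points_per_dim = grid_points_per_dim,
                              fd_step = fd_step, zero_tol = zero_tol)
    report[[paste(src, tgt, sep = "->")]] <- ent
    if (ent$classification %in% c("positive", "negative")) {
      rules <- c(rules, influence_rules(system, ent))
    } else if (ent$classification == "non-monotone-partitioned") {
      for (i in seq_len(nrow(ent$segments))) {
        seg <- ent$segments[i, ]
        sub <- ent
        sub$classification <- if (seg$sign > 0) "positive" else "negative"
        note <- sprintf("%s in %.6g..%.6g (seg%d)", src, seg$lo, seg$hi, i)
        rules <- c(rules, influence_rules(system, sub, note = note))
      }
    }
  }
  list(rules = rules, report = report)
}

# ---- Petri nets -------------------------------------------------------------

#' Declare a minimal Petri net for rule extraction
#'
#' @param places Named list mapping place ids to [attribute_ref()]s (or
#'   key strings): the components of the body system that take the change.
#' @param transitions List of transitions; each a list with `inputs` and
#'   `outputs` (lists of `c(place_id, label)` pairs — condition labels on
#'   inputs, action labels on outputs) and an optional `annotation`.
#' @return An object of class `petri_net`.
#' @export
petri_net <- function(places, transitions = list()) {
  stopifnot(is.list(places), length(places) > 0L, !is.null(names(places)))
  places <- lapply(places, function(r)
    if (is.character(r)) attr_ref_from_key(r) else r)
  for (i in seq_along(transitions)) {
    tr <- transitions[[i]]
    for (arc in c(tr$inputs, tr$outputs)) {
      pid <- arc[[1]]
      if (!pid %in% names(places))
        stop("transition ", i, " references undeclared place '", pid, "'",
             call. = FALSE)
    }
  }
  structure(list(places = places, transitions = transitions),
            class = "petri_net")
}

#' Convert a Petri net to rules
#'
#' One rule per transition: input places become the conjunctive condition
#' side, output places the action side, and the transition annotation is
#' recorded in the rule provenance.  Isolated places contribute nothing.
#'
#' @param net A [petri_net()].
#' @return List of [rule()]s, one per transition, in declaration order.
#' @export
petrinet_to_rules <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  lapply(seq_along(net$transitions), function(i) {
    tr <- net$transitions[[i]]
    if (length(tr$inputs) == 0L || length(tr$outputs) == 0L)
      stop("transition ", i, " must have at least one input and one output",
           call. = FALSE)
    term <- function(arc)
      rule_term(net$places[[arc[[1]]]], arc[[2]])
    ann <- if (is.null(tr$annotation)) "" else tr$annotation
    rule(if (!is.null(tr$id)) tr$id else sprintf("petri_t%02d", i),
         lapply(tr$inputs, term), lapply(tr$outputs, term),
         provenance = paste0("petri-net",
                             if (nzchar(ann)) paste0(":", ann)))
  })
}

# ---- file formats -----------------------------------------------------------

#' Read an ODE system file
#'
#' Line-oriented format:
#' `variable <name> = <attribute-ref> range <lo> <hi>`,
#' `parameter <name> = <value>`, `equation <name> = <expression>`.
#'
#' @param path Path to the system file.
#' @return An [ode_system()].
#' @export
read_ode_file <- function(path) {
  ln <- read_clean_lines(path)
  vars <- list(); eqs <- character(); params <- numeric(); ranges <- list()
  for (i in seq_len(nrow(ln))) {
    t <- trimws(ln$text[i])
    if (!nzchar(t)) next
    if (grepl("^variable\\s", t)) {
      m <- regmatches(t, regexec(
        "^variable\\s+(\\S+)\\s*=\\s*(\\S+)\\s+range\\s+(\\S+)\\s+(\\S+)$",
        t))[[1]]
      if (length(m) != 5L)
        io_stop(path, ln$n[i],
                "expected 'variable <name> = <ref> range <lo> <hi>'")
      vars[[m[2]]] <- attr_ref_from_key(m[3])
      ranges[[m[2]]] <- as.numeric(c(m[4], m[5]))
    } else if (grepl("^parameter\\s", t)) {
      m <- regmatches(t, regexec("^parameter\\s+(\\S+)\\s*=\\s*(\\S+)$",
                                 t))[[1]]
      if (length(m) != 3L)
        io_stop(path, ln$n[i], "expected 'parameter <name> = <value>'")
      params[[m[2]]] <- as.numeric(m[3])
    } else if (grepl("^equation\\s", t)) {
      m <- regmatches(t, regexec("^equation\\s+(\\S+)\\s*=\\s*(.+)$", t))[[1]]
      if (length(m) != 3L)
        io_stop(path, ln$n[i], "expected 'equation <name> = <expression>'")
      eqs[[m[2]]] <- m[3]
    } else {
      io_stop(path, ln$n[i], "unparseable ODE line '", t, "'")
    }
  }
  ode_system(vars, eqs, params, ranges)
}

#' Read a Petri net file
#'
#' Line-oriented format: `place <id> = <attribute-ref>` and
#' `transition <id> : <place>,<label> (& <place>,<label>)* ->
#' <place>,<label> (& ...)* [@note TEXT]`.
#'
#' @param path Path to the net file.
#' @return A [petri_net()].
#' @export
read_petri_file <- function(path) {
  ln <- read_clean_lines(path)
  places <- list(); transitions <- list()
  for (i in seq_len(nrow(ln))) {
    t <- trimws(ln$text[i])
    if (!nzchar(t)) next
    if (grepl("^place\\s", t)) {
      m <- regmatches(t, regexec("^place\\s+(\\S+)\\s*=\\s*(\\S+)$", t))[[1]]
      if (length(m) != 3L)
        io_stop(path, ln$n[i], "expected 'place <id> = <ref>'")
      places[[m[2]]] <- attr_ref_from_key(m[3])
    } else if (grepl("^transition\\s", t)) {
      note <- ""
      nm <- regmatches(t, regexec("@note\\s+(.*)$", t))[[1]]
      if (length(nm) == 2L) {
        note <- nm[2]
        t <- trimws(sub("@note\\s+.*$", "", t))
      }
      m <- regmatches(t, regexec("^transition\\s+(\\S+)\\s*:\\s*(.+)$",
                                 t))[[1]]
      if (length(m) != 3L)
        io_stop(path, ln$n[i], "expected 'transition <id> : arcs'")
      sides <- strsplit(m[3], "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L)
        io_stop(path, ln$n[i], "transition needs exactly one '->'")
      arcs <- function(side)
        lapply(strsplit(side, "&", fixed = TRUE)[[1]], function(a) {
          p <- trimws(strsplit(trimws(a), ",", fixed = TRUE)[[1]])
          if (length(p) != 2L)
            io_stop(path, ln$n[i], "arc must be '<place>,<label>'")
          p
        })
      transitions[[length(transitions) + 1L]] <-
        list(id = m[2], inputs = arcs(sides[1]), outputs = arcs(sides[2]),
             annotation = note)
    } else {
      io_stop(path, ln$n[i], "unparseable Petri line '", t, "'")
    }
  }
  petri_net(places, transitions)
}
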