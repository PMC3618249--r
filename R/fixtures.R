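# Packaged models: a reconstructed miniature type-2-diabetes (T2D) model
# with a 22-drug catalogue, a parameterised random model generator, and an
# exhaustive brute-force oracle for validating the stochastic engine on
# tiny models.
#
# The T2D model is an explicit small-scale reconstruction wired at drug-
# class resolution (hepatic sensitizer / adipocyte-muscle sensitizer /
# beta-cell secretagogue); it makes no claim to completeness.  Insulin
# resistance in liver, fat and muscle is the chronic disease process:
# persistent disease rules push circulation glucose back up whenever a
# drug pulls it down, so drug-induced and disease-causing rules compete
# through the random firing order.

T2D_GLUCOSE <- "Organ,circulation,metabolite,glucose"
T2D_INSULIN <- "Organ,circulation,hormone,insulin"

t2d_drug_table <- function() {
  secretagogues <- c("saxagliptin", "sitagliptin", "vildagliptin",
                     "miglitol", "voglibose", "acarbose",
                     "exenatide", "liraglutide",
                     "mitiglinide", "nateglinide", "repaglinide",
                     "chlorpropamide", "glipizide", "gliquidone",
                     "tolbutamide", "glimepiride", "glyburide",
                     "pramlintide")
  sensitizers <- c("pioglitazone", "rosiglitazone", "troglitazone")
  data.frame(
    name = c("metformin", sensitizers, secretagogues),
    class = c("hepatic sensitizer", rep("sensitizer", 3L),
              rep("secretagogue", length(secretagogues))),
    target = c("Cell,hepatocyte,gene,PRKAB1",
               rep("Cell,adipocyte,gene,PPARG", 3L),
               rep("Cell,beta-cell,process,insulin_secretion",
                   length(secretagogues))),
    stringsAsFactors = FALSE)
}

#' Build the miniature type-2-diabetes model
#'
#' A deterministic multi-scale model: beta-cell, hepatocyte, adipocyte and
#' muscle cells (threshold 1.0) feeding a circulation organ carrying blood
#' glucose and insulin (threshold 60.0), plus 22 anti-diabetic drug
#' components in three mechanistic classes.  Metformin acts through
#' hepatic PRKAB1 (AMPK subunit): it raises GLUT4 and represses the
#' gluconeogenic enzymes PEPCK and Glucose-6-phosphatase, cutting hepatic
#' glucose output.  Glitazones act through adipocyte PPARG, relieving
#' insulin resistance and raising muscle glucose uptake.  The remaining
#' drugs are wired at class level as beta-cell secretagogues that raise
#' circulating insulin.  The disease context sets circulation glucose and
#' the three tissue insulin-resistance processes high and attaches
#' persistent disease rules that drive glucose back up whenever it falls.
#'
#' @return A list with elements `model` (a validated [model_spec()]),
#'   `disease` (a [disease_spec()]), `drugs` (a data frame catalogue with
#'   columns `name`, `class`, `target`), and `criterion` (the attribute
#'   key of the diagnostic criterion, blood glucose in the circulation).
#' @examples
#' fx <- build_t2d_fixture()
#' nrow(validate_model(fx$model))   # 0
#' @export
build_t2d_fixture <- function() {
  domains <- list(
    state_domain("gene", c("low", "normal", "high")),
    state_domain("metabolite", c("low", "normal", "high")),
    state_domain("hormone", c("low", "normal", "high")),
    state_domain("process", c("low", "normal", "high")),
    state_domain("presence", c("absent", "present"), kind = "categorical"))
  drug_tab <- t2d_drug_table()
  comps <- c(
    list(
      component("Cell", "beta-cell", list(
        c("process", "insulin_secretion"), c("gene", "INS"))),
      component("Cell", "hepatocyte", list(
        c("gene", "PRKAB1"), c("gene", "AGRP"), c("gene", "GLUT4"),
        c("gene", "PEPCK"), c("gene", "Glucose-6-phosphatase"),
        c("process", "insulin_resistance"))),
      component("Cell", "adipocyte", list(
        c("gene", "PPARG"), c("process", "insulin_resistance"))),
      component("Cell", "muscle", list(
        c("process", "insulin_resistance"), c("process", "glucose_uptake"))),
      component("Organ", "circulation", list(
        c("metabolite", "glucose"), c("hormone", "insulin")))),
    lapply(drug_tab$name, function(d)
      component("Drug", d, list(c("presence", "status")))))

  R <- function(id, line, ...) {
    r <- parse_rule_line(line, rule_id = id)
    extra <- list(...)
    for (nm in names(extra)) r[[nm]] <- extra[[nm]]
    r
  }
  gl <- T2D_GLUCOSE
  rules <- list(
    # -- metformin: hepatic AMPK branch
    R("met_prkab1",
      "Drug,metformin,presence,status,present -> Cell,hepatocyte,gene,PRKAB1,up",
      provenance = "metformin activates hepatic AMPK (PRKAB1)"),
    R("prkab1_agrp",
      "Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,AGRP,up",
      provenance = "AMPK induces AGRP"),
    R("prkab1_glut4",
      "Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,GLUT4,up",
      provenance = "AMPK promotes GLUT4 glucose transport"),
    R("prkab1_pepck",
      "Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,PEPCK,down",
      provenance = "AMPK represses gluconeogenic PEPCK"),
    R("prkab1_g6pase",
      paste0("Cell,hepatocyte,gene,PRKAB1,up -> ",
             "Cell,hepatocyte,gene,Glucose-6-phosphatase,down"),
      provenance = "AMPK represses Glucose-6-phosphatase"),
    R("prkab1_ir",
      paste0("Cell,hepatocyte,gene,PRKAB1,up -> ",
             "Cell,hepatocyte,process,insulin_resistance,down"),
      provenance = "hepatic sensitization"),
    R("gng_glucose",
      paste0("Cell,hepatocyte,gene,PEPCK,down & ",
             "Cell,hepatocyte,gene,Glucose-6-phosphatase,down & ",
             gl, ",up -> ", gl, ",down @persistent"),
      provenance = "reduced gluconeogenesis lowers blood glucose"),
    R("glut4_glucose",
      paste0("Cell,hepatocyte,gene,GLUT4,up & ", gl, ",up -> ",
             gl, ",down @persistent"),
      provenance = "GLUT4-mediated glucose disposal"),
    # -- glitazones: adipocyte PPARG branch
    R("pparg_adipo_ir",
      paste0("Cell,adipocyte,gene,PPARG,up -> ",
             "Cell,adipocyte,process,insulin_resistance,down"),
      provenance = "PPARG relieves adipocyte insulin resistance"),
    R("pparg_muscle_ir",
      paste0("Cell,adipocyte,gene,PPARG,up -> ",
             "Cell,muscle,process,insulin_resistance,down"),
      provenance = "adipokine signalling sensitizes muscle"),
    R("pparg_uptake",
      paste0("Cell,adipocyte,gene,PPARG,up -> ",
             "Cell,muscle,process,glucose_uptake,up"),
      provenance = "sensitized muscle takes up more glucose"),
    R("uptake_glucose",
      paste0("Cell,muscle,process,glucose_uptake,up & ", gl, ",up -> ",
             gl, ",down @persistent"),
      provenance = "muscle glucose uptake lowers blood glucose"),
    # -- secretagogue branch
    R("secretion_ins",
      paste0("Cell,beta-cell,process,insulin_secretion,up -> ",
             "Cell,beta-cell,gene,INS,up"),
      provenance = "secretory demand induces insulin gene expression"),
    R("secretion_insulin",
      paste0("Cell,beta-cell,process,insulin_secretion,up & ", gl,
             ",up -> ", T2D_INSULIN, ",up @persistent"),
      provenance = "glucose-stimulated insulin secretion"),
    R("insulin_glucose",
      paste0(T2D_INSULIN, ",up & ", gl, ",up -> ", gl,
             ",down @persistent"),
      provenance = "insulin drives glucose disposal"))
  for (i in seq_len(nrow(drug_tab))) {
    d <- drug_tab$name[i]
    if (d == "metformin") next
    lab <- if (drug_tab$class[i] == "sensitizer") "up" else "up"
    rules[[length(rules) + 1L]] <-
      R(paste0(gsub("[^a-z0-9]", "", d), "_target"),
        paste0("Drug,", d, ",presence,status,present -> ",
               drug_tab$target[i], ",", lab),
        provenance = paste(drug_tab$class[i], "drug target"))
  }
  # -- chronic disease process: persistent insulin resistance pushes
  #    glucose back up whenever therapy pulls it down
  for (cell in c("hepatocyte", "adipocyte", "muscle")) {
    rules[[length(rules) + 1L]] <-
      R(paste0("t2d_", cell, "_ir"),
        paste0("Cell,", cell, ",process,insulin_resistance,up & ", gl,
               ",down -> ", gl, ",up @disease @persistent"),
        provenance = "insulin resistance sustains hyperglycaemia")
  }
  model <- model_spec(domains, comps, rules)
  disease <- disease_spec(
    "T2D",
    initial_states = c(
      stats::setNames("high", gl),
      stats::setNames("high", "Cell,hepatocyte,process,insulin_resistance"),
      stats::setNames("high", "Cell,adipocyte,process,insulin_resistance"),
      stats::setNames("high", "Cell,muscle,process,insulin_resistance")),
    disease_rule_ids = c("t2d_hepatocyte_ir", "t2d_adipocyte_ir",
                         "t2d_muscle_ir"))
  list(model = model, disease = disease, drugs = drug_tab, criterion = gl)
}

#' Parameters for the random model generator
#'
#' @param n_organs,n_cells Component counts at the organ and cell scale.
#' @param n_molecules_per_cell Gene attributes per cell (organs carry the
#'   same number of metabolite attributes).
#' @param n_rules Total rule count (including guaranteed-path rules).
#' @param disease_fraction,persistent_fraction Fractions of the random
#'   rules flagged as disease rules / persistent.
#' @param n_drugs Drug components (each with a presence attribute).
#' @param organ_threshold,cell_threshold Rule-execution thresholds.
#' @param guaranteed_path If `TRUE`, each drug is wired to the phenotype
#'   criterion attribute (first organ, first metabolite) by a rule chain.
#' @param acyclic If `TRUE` (default), rule wiring follows a fixed
#'   topological order over attributes, guaranteeing quiescence — needed
#'   when comparing the engine against the exhaustive oracle.
#' @param seed Generator seed.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_organs = 1L, n_cells = 2L,
                             n_molecules_per_cell = 3L, n_rules = 6L,
                             disease_fraction = 0, persistent_fraction = 0,
                             n_drugs = 1L, organ_threshold = 60,
                             cell_threshold = 1,
                             guaranteed_path = TRUE, acyclic = TRUE,
                             seed = 1L) {
  p <- list(n_organs = as.integer(n_organs), n_cells = as.integer(n_cells),
            n_molecules_per_cell = as.integer(n_molecules_per_cell),
            n_rules = as.integer(n_rules),
            disease_fraction = disease_fraction,
            persistent_fraction = persistent_fraction,
            n_drugs = as.integer(n_drugs),
            organ_threshold = organ_threshold,
            cell_threshold = cell_threshold,
            guaranteed_path = isTRUE(guaranteed_path),
            acyclic = isTRUE(acyclic), seed = as.integer(seed))
  stopifnot(p$n_organs >= 0L, p$n_cells >= 0L,
            p$n_molecules_per_cell >= 0L, p$n_rules >= 0L, p$n_drugs >= 0L,
            p$disease_fraction >= 0, p$disease_fraction <= 1,
            p$persistent_fraction >= 0, p$persistent_fraction <= 1)
  class(p) <- "generator_params"
  p
}

#' Generate a random model
#'
#' Seeded-deterministic: the same parameters always yield the same model.
#' Attributes are laid out drugs -> cell genes -> organ metabolites; with
#' `acyclic = TRUE` every rule points forward in that order, so runs are
#' guaranteed to quiesce.  The phenotype criterion is the first metabolite
#' of the first organ.
#'
#' @param params A [generator_params()].
#' @return A list with `model`, `disease`, `drugs` (character vector of
#'   drug names) and `criterion` (attribute key, or `NA` without organs).
#' @export
generate_random_model <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (is.null(old_rng)) suppressWarnings(rm(".Random.seed",
                                              envir = globalenv()))
    else assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(p$seed)
  domains <- list(
    state_domain("gene", c("low", "normal", "high")),
    state_domain("metabolite", c("low", "normal", "high")),
    state_domain("presence", c("absent", "present"), kind = "categorical"))
  comps <- list(); attrs <- character()   # attrs in topological order
  drug_names <- if (p$n_drugs > 0L) sprintf("D%d", seq_len(p$n_drugs))
                else character()
  for (d in drug_names) {
    comps[[length(comps) + 1L]] <- component("Drug", d,
                                             list(c("presence", "status")))
    attrs <- c(attrs, paste0("Drug,", d, ",presence,status"))
  }
  for (i in seq_len(p$n_cells)) {
    nm <- sprintf("C%d", i)
    ats <- lapply(seq_len(p$n_molecules_per_cell),
                  function(k) c("gene", sprintf("g%d", k)))
    comps[[length(comps) + 1L]] <-
      component("Cell", nm, ats, threshold = p$cell_threshold)
    attrs <- c(attrs, vapply(ats, function(a)
      paste("Cell", nm, a[1], a[2], sep = ","), ""))
  }
  for (i in seq_len(p$n_organs)) {
    nm <- sprintf("O%d", i)
    ats <- lapply(seq_len(max(1L, p$n_molecules_per_cell)),
                  function(k) c("metabolite", sprintf("m%d", k)))
    comps[[length(comps) + 1L]] <-
      component("Organ", nm, ats, threshold = p$organ_threshold)
    attrs <- c(attrs, vapply(ats, function(a)
      paste("Organ", nm, a[1], a[2], sep = ","), ""))
  }
  criterion <- if (p$n_organs > 0L)
    paste0("Organ,O1,metabolite,m1") else NA_character_
  non_drug <- attrs[!grepl("^Drug,", attrs)]
  if (p$n_rules > 0L && length(non_drug) == 0L)
    stop("cannot generate rules for a model with no non-drug attributes",
         call. = FALSE)
  labels_for <- function(key, side) {
    if (grepl("^Drug,", key)) {
      if (side == "lhs") "present" else "absent"   # actions on drugs rare
    } else c("up", "down")
  }
  rules <- list(); rid <- 0L
  add_rule <- function(lhs_key, lhs_lab, rhs_key, rhs_lab,
                       persistent = FALSE, dis = FALSE) {
    rid <<- rid + 1L
    rules[[length(rules) + 1L]] <<-
      rule(sprintf("g%04d", rid),
           list(rule_term(lhs_key, lhs_lab)),
           list(rule_term(rhs_key, rhs_lab)),
           is_disease_rule = dis, persistent = persistent,
           provenance = "generated")
  }
  n_left <- p$n_rules
  if (p$guaranteed_path && !is.na(criterion)) {
    for (d in drug_names) {
      if (n_left <= 0L) break
      dk <- paste0("Drug,", d, ",presence,status")
      mid <- non_drug[non_drug != criterion]
      path <- c(dk, if (length(mid) && n_left > 1L)
                      mid[sample.int(length(mid), 1L)], criterion)
      for (j in seq_len(length(path) - 1L)) {
        if (n_left <= 0L) break
        l_lab <- if (grepl("^Drug,", path[j])) "present" else "up"
        add_rule(path[j], l_lab, path[j + 1L], "up")
        n_left <- n_left - 1L
      }
    }
  }
  while (n_left > 0L) {
    li <- sample.int(length(attrs), 1L)
    lk <- attrs[li]
    # RHS must be a non-drug attribute; under acyclicity, strictly later
    pool <- if (p$acyclic) non_drug[match(non_drug, attrs) > li]
            else non_drug
    if (length(pool) == 0L) { # LHS too late in the order; resample
      if (all(match(non_drug, attrs) <= 1L)) break
      next
    }
    rk <- pool[sample.int(length(pool), 1L)]
    l_labs <- labels_for(lk, "lhs")
    add_rule(lk, l_labs[sample.int(length(l_labs), 1L)],
             rk, c("up", "down")[sample.int(2L, 1L)],
             persistent = stats::runif(1) < p$persistent_fraction,
             dis = stats::runif(1) < p$disease_fraction)
    n_left <- n_left - 1L
  }
  model <- model_spec(domains, comps, rules)
  dis_ids <- names(Filter(function(r) r$is_disease_rule, model$rules))
  disease <- disease_spec("generated", disease_rule_ids = dis_ids)
  list(model = model, disease = disease, drugs = drug_names,
       criterion = criterion)
}

#' Enumerate all reachable terminal states by exhaustive search
#'
#' Depth-first enumeration of every possible firing order under exactly
#' the engine's condition/threshold/firing-score semantics (the two share
#' one implementation).  Intended for tiny models (<= 10 rules); serves as
#' the independent scheduling oracle for the stochastic engine.
#'
#' @inheritParams run_simulation
#' @param max_depth Bound on firing-sequence length; configurations still
#'   active at the bound are recorded and flagged.
#' @param max_configs Budget on distinct explored configurations.
#' @return A list with `terminals` (list of named terminal state vectors,
#'   keyed deterministically), `partial` (`TRUE` if a depth or budget cap
#'   was hit) and `n_configs` explored.
#' @export
brute_force_reachable <- function(model, disease = NULL, drugs = NULL,
                                  max_depth = 50L, max_configs = 100000L,
                                  strict_threshold = FALSE,
                                  rfs_per_attribute = FALSE) {
  st0 <- sim_initialize(model, disease, drugs, seed = 0L,
                        strict_threshold = strict_threshold,
                        rfs_per_attribute = rfs_per_attribute)
  cm <- st0$cm
  strict <- st0$strict
  terminals <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())
  partial <- FALSE
  n_configs <- 0L
  cfg_key <- function(states, prev, rfs, ar)
    paste(c(states, prev, rfs, sort(ar)), collapse = "|")
  stack <- list(list(states = st0$states, prev = st0$prev, rfs = st0$rfs,
                     ar = st0$ar, depth = 0L))
  while (length(stack)) {
    cfg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sat <- sat_subset(cm, cfg$ar, cfg$prev, cfg$states)
    if (!length(sat)) {
      terminals[[paste(cfg$states, collapse = "|")]] <- cfg$states
      next
    }
    if (cfg$depth >= max_depth) {
      partial <- TRUE
      terminals[[paste(cfg$states, collapse = "|")]] <- cfg$states
      next
    }
    for (ri in sat) {
      res <- fire_pure(cm, cfg$states, cfg$rfs, ri, strict)
      arn <- next_active(cm, sat, ri, res$changed, cfg$states, res$states)
      k <- cfg_key(res$states, cfg$states, res$rfs, arn)
      if (!is.null(visited[[k]])) next
      visited[[k]] <- TRUE
      n_configs <- n_configs + 1L
      if (n_configs > max_configs) {
        partial <- TRUE
        break
      }
      stack[[length(stack) + 1L]] <-
        list(states = res$states, prev = cfg$states, rfs = res$rfs,
             ar = arn, depth = cfg$depth + 1L)
    }
    if (n_configs > max_configs) break
  }
  keys <- sort(ls(terminals))
  list(terminals = lapply(keys, function(k)
         decode_states(cm, terminals[[k]])),
       partial = partial, n_configs = n_configs)
}
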