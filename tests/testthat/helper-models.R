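# Small hand-built models used across the test files.

ternary_gene <- function() state_domain("gene", c("low", "normal", "high"))

presence_domain <- function()
  state_domain("presence", c("absent", "present"), kind = "categorical")

# drug D --(present)--> A up ; A up --> B up   (all thresholds 1.0)
tiny_chain_model <- function() {
  model_spec(
    list(ternary_gene(), presence_domain()),
    list(component("Drug", "D", list(c("presence", "status"))),
         component("Cell", "C1", list(c("gene", "A"), c("gene", "B")))),
    list(rule("r1", list(rule_term("Drug,D,presence,status", "present")),
              list(rule_term("Cell,C1,gene,A", "up"))),
         rule("r2", list(rule_term("Cell,C1,gene,A", "up")),
              list(rule_term("Cell,C1,gene,B", "up")))))
}

# Two rules triggered by the same transient signal transition compete for
# attribute X; whichever fires first survives (the other goes stale), so
# exactly two terminal states are reachable.  The signal domain defaults
# to "low" so the disease override low -> normal is a one-shot 'up' event.
competing_model <- function() {
  sig <- state_domain("signal", c("low", "normal", "high"),
                      default_state = "low")
  model <- model_spec(
    list(ternary_gene(), sig),
    list(component("Cell", "C1",
                   list(c("signal", "S"), c("gene", "X")))),
    list(rule("r_up", list(rule_term("Cell,C1,signal,S", "up")),
              list(rule_term("Cell,C1,gene,X", "up"))),
         rule("r_down", list(rule_term("Cell,C1,signal,S", "up")),
              list(rule_term("Cell,C1,gene,X", "down")))))
  disease <- disease_spec("competition",
                          c("Cell,C1,signal,S" = "normal"))
  list(model = model, disease = disease)
}

# One persistent source (an injected drug) drives one molecule-scale rule
# and one organ-scale rule with RS = 1: thresholds 1.0 vs 60.0.
timescale_model <- function() {
  model <- model_spec(
    list(ternary_gene(),
         state_domain("metabolite", c("low", "normal", "high")),
         presence_domain()),
    list(component("Drug", "S", list(c("presence", "status"))),
         component("Cell", "C1", list(c("gene", "x"))),
         component("Organ", "O1", list(c("metabolite", "m")))),
    list(rule("r_mol", list(rule_term("Drug,S,presence,status", "present")),
              list(rule_term("Cell,C1,gene,x", "up")), persistent = TRUE),
         rule("r_org", list(rule_term("Drug,S,presence,status", "present")),
              list(rule_term("Organ,O1,metabolite,m", "up")),
              persistent = TRUE)))
  model
}

tiny_params <- function(seed, n_rules = 4L)
  generator_params(n_organs = 1L, n_cells = 1L, n_molecules_per_cell = 3L,
                   n_rules = n_rules, persistent_fraction = 0,
                   organ_threshold = 1, cell_threshold = 1, seed = seed)

terminal_key <- function(states) paste(states, collapse = "|")

# the shared T2D fixture (built once per test run)
t2d <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_t2d_fixture()
    cache
  }
})
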