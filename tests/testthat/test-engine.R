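# Engine semantics: initialisation, stepping, threshold gating,
# determinism and structural invariants.

# decode the current states of a simulation_state
decode_terminal <- function(st)
  stats::setNames(
    vapply(seq_along(st$states), function(a)
      st$cm$domain_states[[st$cm$attr_dom[a]]][st$states[a]], ""),
    st$cm$attr_keys)

test_that("initialisation: defaults, overrides, drug injection, AR(0)", {
  fx <- t2d()
  # nothing abnormal, nothing injected: nothing to do
  st <- sim_initialize(fx$model)
  expect_length(st$ar, 0L)

  # a disease override enables rules conditioned on the induced transition
  dz <- disease_spec("d", c("Cell,hepatocyte,gene,GLUT4" = "high",
                            "Organ,circulation,metabolite,glucose" = "high"))
  st <- sim_initialize(fx$model, dz)
  expect_true("glut4_glucose" %in% st$cm$rule_ids[st$ar])

  # drug injection sets presence and enables the target rule
  st <- sim_initialize(fx$model, drugs = drug_spec("metformin"))
  expect_identical(
    unname(decode_terminal(st)[["Drug,metformin,presence,status"]]),
    "present")
  expect_identical(st$cm$rule_ids[st$ar], "met_prkab1")
})

test_that("stepping: firing, chain activation, stale purge", {
  m <- tiny_chain_model()
  st <- sim_initialize(m, drugs = drug_spec("D"), seed = 3)
  expect_identical(st$cm$rule_ids[st$ar], "r1")
  sim_step(st)   # r1 fires; A rises; r2 becomes active, r1 leaves
  expect_identical(st$cm$rule_ids[st$ar], "r2")
  expect_identical(unname(decode_terminal(st)[["Cell,C1,gene,A"]]), "high")
  sim_step(st)
  expect_length(st$ar, 0L)
  expect_identical(unname(decode_terminal(st)[["Cell,C1,gene,B"]]), "high")

  # a stale rule empties AR without changing state
  cm <- competing_model()
  st <- sim_initialize(cm$model, cm$disease, seed = 1)
  expect_setequal(st$cm$rule_ids[st$ar], c("r_up", "r_down"))
  sim_step(st)   # one of the two fires; prev rolls, the other goes stale
  x_after <- decode_terminal(st)[["Cell,C1,gene,X"]]
  sim_step(st)
  expect_length(st$ar, 0L)
  expect_identical(decode_terminal(st)[["Cell,C1,gene,X"]], x_after)
})

test_that("threshold gating: 1-hit molecules, 60-hit organs, pooling", {
  m <- timescale_model()
  st <- sim_initialize(m, drugs = drug_spec("S"), seed = 1)
  # molecule: first firing crosses TH = 1
  changed <- update_component_set(st, "r_mol")
  expect_identical(changed, "Cell,C1,gene,x")
  # organ: firings 1..59 accumulate, the 60th applies the action
  for (i in 1:59) {
    changed <- update_component_set(st, "r_org")
    expect_length(changed, 0L)
  }
  expect_identical(update_component_set(st, "r_org"),
                   "Organ,O1,metabolite,m")
  expect_identical(unname(decode_terminal(st)[["Organ,O1,metabolite,m"]]),
                   "high")

  # a rule with two RHS terms on different components increments both
  # pools independently
  m2 <- model_spec(
    list(ternary_gene()),
    list(component("Organ", "O1", list(c("gene", "a")), threshold = 5),
         component("Organ", "O2", list(c("gene", "b")), threshold = 5)),
    list(rule("both", list(rule_term("Organ,O1,gene,a", "up")),
              list(rule_term("Organ,O1,gene,a", "up"),
                   rule_term("Organ,O2,gene,b", "up")))))
  st2 <- sim_initialize(m2, seed = 1)
  update_component_set(st2, "both")
  expect_identical(st2$rfs, c(1, 1))
})

test_that("strict_threshold and rfs_per_attribute switches", {
  m <- tiny_chain_model()
  # strict: RFS must exceed TH, so RS = TH = 1 never fires a state change
  tr <- run_simulation(m, drugs = drug_spec("D"), seed = 1,
                       strict_threshold = TRUE, max_steps = 50)
  expect_identical(unname(tr$terminal_states[["Cell,C1,gene,A"]]), "normal")
  expect_true(all(tr$events$old_state == tr$events$new_state))

  # per-attribute pools: two rules on different attributes of one organ
  # no longer share a pool
  m3 <- model_spec(
    list(ternary_gene(), presence_domain()),
    list(component("Drug", "D", list(c("presence", "status"))),
         component("Organ", "O", list(c("gene", "a"), c("gene", "b")),
                   threshold = 2)),
    list(rule("ra", list(rule_term("Drug,D,presence,status", "present")),
              list(rule_term("Organ,O,gene,a", "up")), persistent = TRUE),
         rule("rb", list(rule_term("Drug,D,presence,status", "present")),
              list(rule_term("Organ,O,gene,b", "up")), persistent = TRUE)))
  pooled <- sim_initialize(m3, drugs = drug_spec("D"))
  expect_length(update_component_set(pooled, "ra"), 0L)
  # shared pool: rb's hit reaches the threshold ra started filling
  expect_identical(update_component_set(pooled, "rb"), "Organ,O,gene,b")
  split <- sim_initialize(m3, drugs = drug_spec("D"),
                          rfs_per_attribute = TRUE)
  expect_length(update_component_set(split, "ra"), 0L)
  expect_length(update_component_set(split, "rb"), 0L)
  expect_identical(update_component_set(split, "ra"), "Organ,O,gene,a")
})

test_that("run_simulation: termination, determinism, replay", {
  # empty rule set: quiescent at step 0
  m0 <- model_spec(list(ternary_gene()),
                   list(component("Cell", "C", list(c("gene", "A")))))
  tr0 <- run_simulation(m0, seed = 1)
  expect_identical(tr0$n_steps, 0L)
  expect_identical(tr0$termination, "quiescent")
  expect_identical(tr0$terminal_states, tr0$initial_states)

  # the 2-rule chain ends with B high under every seed
  m <- tiny_chain_model()
  for (s in 1:10) {
    tr <- run_simulation(m, drugs = drug_spec("D"), seed = s)
    expect_identical(unname(tr$terminal_states[["Cell,C1,gene,B"]]), "high")
    expect_identical(tr$termination, "quiescent")
  }

  # identical inputs + seed give identical traces; seeds differ
  fx <- t2d()
  a <- run_simulation(fx$model, fx$disease, drug_spec("glyburide"),
                      seed = 99)
  b <- run_simulation(fx$model, fx$disease, drug_spec("glyburide"),
                      seed = 99)
  expect_identical(a, b)

  # replaying the recorded state changes reproduces the terminal states
  states <- a$initial_states
  ch <- a$events[a$events$old_state != a$events$new_state, ]
  for (i in seq_len(nrow(ch))) {
    key <- paste(ch$component_type[i], ch$component_name[i],
                 ch$attribute_type[i], ch$attribute_name[i], sep = ",")
    expect_identical(unname(states[[key]]), ch$old_state[i])
    states[[key]] <- ch$new_state[i]
  }
  expect_identical(states, a$terminal_states)
})

test_that("engine invariants hold across random models", {
  for (s in 1:15) {
    gen <- generate_random_model(tiny_params(seed = 100 + s, n_rules = 5L))
    tr <- run_simulation(gen$model, gen$disease, drug_spec(gen$drugs),
                         seed = s)
    # conservation: the attribute universe never changes
    expect_identical(names(tr$terminal_states), names(tr$initial_states))
    # every sub-threshold accumulation stays below the component threshold
    # (all thresholds 1 here, so accumulations must be crossings)
    th <- vapply(gen$model$components, function(co) co$threshold, 1.0)
    expect_true(all(tr$events$rfs_after < max(th)))
    # every state change is a recorded crossing (rfs_after == 0)
    changes <- tr$events$old_state != tr$events$new_state
    expect_true(all(tr$events$rfs_after[changes] == 0))
  }
})

test_that("run_simulation does not disturb the caller's RNG", {
  set.seed(123)
  expected <- stats::runif(3)
  set.seed(123)
  invisible(run_simulation(tiny_chain_model(), drugs = drug_spec("D"),
                           seed = 7))
  expect_identical(stats::runif(3), expected)
})
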