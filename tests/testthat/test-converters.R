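# ODE monotonicity analysis and Petri-net conversion.

# demo glucose/insulin/beta-cell system used across tests; the quadratic
# term in dB/dt makes the G -> B influence non-monotone with an analytic
# sign change at G = r1 / (2 * r2).
demo_system <- function(r1 = 1, r2 = 0.05)
  ode_system(
    variables = list(G = "Organ,O,metabolite,G",
                     I = "Organ,O,hormone,I",
                     B = "Cell,B,gene,B"),
    equations = c(G = "a - b*I*G",
                  I = "c*B*G/(1 + G) - d*I",
                  B = "r1*G - r2*G^2 - e*B"),
    parameters = c(a = 5, b = 0.5, c = 1, d = 0.2,
                   r1 = r1, r2 = r2, e = 0.1),
    ranges = list(G = c(0.1, 20), I = c(0.1, 10), B = c(0.1, 10)))

demo_companion_model <- function()
  model_spec(
    list(state_domain("metabolite", c("low", "normal", "high")),
         state_domain("hormone", c("low", "normal", "high")),
         state_domain("gene", c("low", "normal", "high"))),
    list(component("Organ", "O", list(c("metabolite", "G"),
                                      c("hormone", "I"))),
         component("Cell", "B", list(c("gene", "B")))))

# independent oracle: symbolic partial derivative of the RHS with respect
# to the source, evaluated over the same grid the converter samples
symbolic_signs <- function(system, source, target, n = 7) {
  dexpr <- stats::D(parse(text = system$equations[[target]])[[1]], source)
  axes <- lapply(names(system$variables), function(v)
    seq(system$ranges[[v]][1], system$ranges[[v]][2], length.out = n))
  names(axes) <- names(system$variables)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  vals <- eval(dexpr, envir = c(as.list(grid),
                                as.list(system$parameters)))
  unique(sign(zapsmall(rep(vals, length.out = nrow(grid)))))
}

test_that("classify_influence agrees in sign with symbolic derivatives", {
  sys <- demo_system()
  cases <- list(c("I", "G"), c("G", "I"), c("B", "I"), c("B", "G"),
                c("I", "B"))
  for (cs in cases) {
    ent <- classify_influence(sys, cs[1], cs[2])
    s <- symbolic_signs(sys, cs[1], cs[2])
    expected <- if (identical(s, 0)) "none"
                else if (all(s >= 0)) "positive"
                else if (all(s <= 0)) "negative"
                else "mixed"
    if (expected != "mixed")
      expect_identical(ent$classification, expected,
                       info = paste(cs, collapse = "->"))
  }
  # linear positive influence: y raises dx/dt everywhere
  lin <- ode_system(list(x = "Cell,B,gene,B", y = "Organ,O,hormone,I"),
                    c(x = "-x + y", y = "-y"),
                    ranges = list(x = c(0, 10), y = c(0, 10)))
  expect_identical(classify_influence(lin, "y", "x")$classification,
                   "positive")
  # target not containing source
  expect_identical(classify_influence(lin, "x", "y")$classification,
                   "none")
})

test_that("the quadratic influence partitions at its analytic breakpoint", {
  sys <- demo_system(r1 = 1, r2 = 0.05)     # breakpoint at G = 10
  ent <- classify_influence(sys, "G", "B")
  expect_identical(ent$classification, "non-monotone-partitioned")
  expect_identical(nrow(ent$segments), 2L)
  expect_identical(ent$segments$sign, c(1L, -1L))
  grid_resolution <- diff(sys$ranges$G) / (ent$grid_points_per_dim - 1)
  expect_lt(abs(ent$segments$hi[1] - 10), grid_resolution)
})

test_that("non-separable sign dependence is reported unconvertible", {
  # d(x)/dt = (y - 5) * s: the sign of ds depends on y, not on s
  sys <- ode_system(
    list(x = "Cell,B,gene,B", y = "Organ,O,hormone,I",
         s = "Organ,O,metabolite,G"),
    c(x = "(y - 5) * s", y = "-y", s = "-s"),
    ranges = list(x = c(0, 10), y = c(0, 10), s = c(0, 10)))
  expect_identical(classify_influence(sys, "s", "x")$classification,
                   "unconvertible")
})

test_that("ode_to_rules emits paired rules that validate in a model", {
  sys <- demo_system()
  conv <- ode_to_rules(sys)
  ids <- vapply(conv$rules, function(r) r$rule_id, "")
  # up/down always paired: even rule count per (source, target) pair
  pair_of <- sub("_(up|down)(_|$).*", "", sub("^ode_", "", ids))
  expect_true(all(table(pair_of) %% 2 == 0))
  # a negative influence produces the crossed pair
  upI <- conv$rules[[match("ode_I_G_up", ids)]]
  expect_identical(upI$lhs[[1]]$label, "up")
  expect_identical(upI$rhs[[1]]$label, "down")
  # every emitted rule validates against the companion model
  m <- demo_companion_model()
  full <- model_spec(unname(m$domains), unname(m$components), conv$rules)
  expect_identical(nrow(validate_model(full)), 0L)
  # every rule round-trips through the DSL
  for (r in conv$rules)
    expect_identical(parse_rule_line(format_rule(r), rule_id = r$rule_id),
                     r)
  # 'none' influences emit nothing
  expect_false(any(grepl("^ode_B_G_", ids)))
})

test_that("petrinet_to_rules maps transitions one-to-one", {
  net <- petri_net(
    places = list(p1 = "Cell,B,gene,B", p2 = "Organ,O,hormone,I",
                  p3 = "Organ,O,metabolite,G",
                  lonely = "Organ,O,metabolite,G"),
    transitions = list(
      list(id = "t1", inputs = list(c("p1", "up")),
           outputs = list(c("p2", "up")), annotation = "secretion"),
      list(id = "t2", inputs = list(c("p1", "up"), c("p2", "up")),
           outputs = list(c("p3", "down")))))
  rules <- petrinet_to_rules(net)
  expect_length(rules, 2L)                 # one rule per transition
  expect_length(rules[[2]]$lhs, 2L)        # conjunctive multi-input
  expect_match(rules[[1]]$provenance, "secretion")
  m <- demo_companion_model()
  full <- model_spec(unname(m$domains), unname(m$components), rules)
  expect_identical(nrow(validate_model(full)), 0L)
  # the single-input single-output transition has the worked-rule shape
  expect_identical(format_rule(rules[[1]]),
                   paste("Cell,B,gene,B,up -> Organ,O,hormone,I,up",
                         "@src=petri-net:secretion"))

  expect_error(petrinet_to_rules(petri_net(
    places = list(p1 = "Cell,B,gene,B"),
    transitions = list(list(inputs = list(), outputs = list(c("p1", "up")))))),
    "at least one input")
  expect_error(petri_net(places = list(p1 = "Cell,B,gene,B"),
                         transitions = list(list(inputs = list(c("zz", "up")),
                                                 outputs = list(c("p1", "up"))))),
               "undeclared place")
})

test_that("ODE and Petri files parse", {
  d <- withr::local_tempdir()
  ode_f <- file.path(d, "sys.txt")
  writeLines(c(
    "# demo",
    "variable x = Cell,B,gene,B range 0 10",
    "variable y = Organ,O,hormone,I range 0 10",
    "parameter k = 2",
    "equation x = k*y - x",
    "equation y = -y"), ode_f)
  sys <- read_ode_file(ode_f)
  expect_identical(classify_influence(sys, "y", "x")$classification,
                   "positive")
  expect_error(read_ode_file(local({
    f <- file.path(d, "bad.txt"); writeLines("variable x", f); f
  })), "bad.txt:1")

  pn_f <- file.path(d, "net.txt")
  writeLines(c(
    "place p1 = Cell,B,gene,B",
    "place p2 = Organ,O,hormone,I",
    "transition t1 : p1,up -> p2,up @note secretion"), pn_f)
  net <- read_petri_file(pn_f)
  expect_length(net$transitions, 1L)
  expect_identical(net$transitions[[1]]$annotation, "secretion")
})
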