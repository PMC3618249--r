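# File formats: component / rule / disease / drug files and the trace.

write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("component file parsing, threshold defaulting, empty file", {
  f <- write_tmp(c(
    "# demo",
    "domain gene",
    "  states: low, normal, high",
    "domain presence",
    "  states: absent, present",
    "  kind: categorical",
    "component Cell hepatocyte",
    "  attributes:",
    "    gene, PRKAB1",
    "component Organ circulation",
    "  attributes:",
    "    gene, g1",
    "component Tissue fat",
    "  threshold: 7.5",
    "  attributes:",
    "    gene, g2"))
  m <- read_component_file(f)
  expect_identical(m$components[["Cell,hepatocyte"]]$threshold, 1.0)
  expect_identical(m$components[["Organ,circulation"]]$threshold, 60.0)
  expect_identical(m$components[["Tissue,fat"]]$threshold, 7.5)
  expect_identical(m$components[["Cell,hepatocyte"]]$attributes,
                   list(c("gene", "PRKAB1")))

  empty <- read_component_file(write_tmp("# nothing here"))
  expect_identical(length(empty$components), 0L)
  expect_identical(length(empty$rules), 0L)
})

test_that("component file errors carry line numbers", {
  f <- write_tmp(c("domain gene", "  states: low, normal, high",
                   "component Cell c1", "  attributes:", "    gene, A",
                   "component Cell c1", "  attributes:", "    gene, A"))
  expect_error(read_component_file(f), ":6")
  f2 <- write_tmp(c("domain gene", "  states: low, normal, high",
                    "wat is this"))
  expect_error(read_component_file(f2), ":3")
  f3 <- write_tmp(c("domain gene", "  states: low, normal, high",
                    "component Cell c1", "  attributes:",
                    "    hormone, H"))
  expect_error(read_component_file(f3), "no declared state domain")
})

test_that("rule DSL: worked form, annotations, conjunctions, round trip", {
  r <- parse_rule_line(
    "Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,AGRP,up")
  expect_length(r$lhs, 1L)
  expect_length(r$rhs, 1L)
  expect_identical(format(r$lhs[[1]]$ref), "Cell,hepatocyte,gene,PRKAB1")
  expect_identical(r$rhs[[1]]$label, "up")
  expect_identical(r$effect_score, 1.0)

  r2 <- parse_rule_line(paste(
    "Cell,c,gene,A,up & Cell,c,gene,B,down -> Cell,c,gene,C,up",
    "@rs=2.5 @disease @persistent @src=petri-net"))
  expect_length(r2$lhs, 2L)
  expect_identical(r2$effect_score, 2.5)
  expect_true(r2$is_disease_rule)
  expect_true(r2$persistent)
  expect_identical(r2$provenance, "petri-net")
  # serialise -> parse is the identity (up to rule id)
  r3 <- parse_rule_line(format_rule(r2), rule_id = r2$rule_id)
  expect_identical(r3, r2)

  expect_error(parse_rule_line("Cell,c,gene,A,up"), "->")
  expect_error(parse_rule_line("Cell,c,gene,A -> Cell,c,gene,B,up"),
               "5 comma-separated")
})

test_that("rule file validates against the model and names bad lines", {
  m <- tiny_chain_model()
  f <- write_tmp(c(
    "# chain",
    "s1: Drug,D,presence,status,present -> Cell,C1,gene,A,up",
    "Cell,C1,gene,A,up -> Cell,C1,gene,B,up @rs=2"))
  m2 <- read_rule_file(f, model_spec(unname(m$domains),
                                     unname(m$components)))
  expect_named(m2$rules, c("s1", "r0002"))
  expect_identical(m2$rules$r0002$effect_score, 2.0)

  bad <- write_tmp("Cell,C1,gene,NOPE,up -> Cell,C1,gene,B,up")
  expect_error(read_rule_file(bad, m), "dangling")
})

test_that("disease and drug files round-trip and validate", {
  fx <- t2d()
  d <- withr::local_tempdir()
  dz <- file.path(d, "disease.txt")
  write_disease_file(fx$disease, dz)
  back <- read_disease_file(dz, fx$model)
  expect_identical(unclass(back), unclass(fx$disease))

  dg <- file.path(d, "drugs.txt")
  write_drug_file(drug_spec(c("metformin", "rosiglitazone")), dg)
  expect_identical(read_drug_file(dg, fx$model)$drugs,
                   c("metformin", "rosiglitazone"))

  expect_error(read_disease_file(
    write_tmp("state Cell,nowhere,gene,X = high"), fx$model), "unknown")
  expect_error(read_disease_file(
    write_tmp(c("state Organ,circulation,metabolite,glucose = high",
                "state Organ,circulation,metabolite,glucose = low")),
    fx$model), "conflicting")
  expect_error(read_disease_file(
    write_tmp("disease_rule met_prkab1"), fx$model), "not flagged")
  expect_error(read_drug_file(write_tmp("aspirin"), fx$model),
               "aspirin")

  # empty disease file = everything at domain defaults
  empty <- read_disease_file(write_tmp("# none"), fx$model)
  expect_length(empty$initial_states, 0L)
})

test_that("model write-then-read is the identity", {
  fx <- t2d()
  d <- withr::local_tempdir()
  write_component_file(fx$model, file.path(d, "c.txt"))
  write_rule_file(fx$model, file.path(d, "r.txt"))
  m2 <- read_rule_file(file.path(d, "r.txt"),
                       read_component_file(file.path(d, "c.txt")))
  expect_identical(lapply(m2$components, unclass),
                   lapply(fx$model$components, unclass))
  expect_identical(lapply(m2$rules, unclass),
                   lapply(fx$model$rules, unclass))
  for (dn in names(fx$model$domains))
    expect_identical(m2$domains[[dn]]$states, fx$model$domains[[dn]]$states)
})

test_that("trace files round-trip, including the zero-firing case", {
  m <- tiny_chain_model()
  d <- withr::local_tempdir()
  tr <- run_simulation(m, drugs = drug_spec("D"), seed = 11)
  p <- file.path(d, "trace.tsv")
  write_trace(tr, p)
  back <- read_trace(p)
  expect_identical(back, tr$events)
  expect_gt(nrow(back), 0L)

  quiet <- run_simulation(m, seed = 1)   # nothing to do without the drug
  p2 <- file.path(d, "empty.tsv")
  write_trace(quiet, p2)
  expect_identical(nrow(read_trace(p2)), 0L)
})
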