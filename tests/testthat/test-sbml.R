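minimal_sbml <- function(path) {
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini">',
    '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cell" initialConcentration="2"/>',
    '<species id="B" compartment="cell" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="k" value="0.5"/></listOfParameters>',
    '<listOfReactions><reaction id="v1" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>k</ci><ci>A</ci></apply>',
    '</math></kineticLaw></reaction></listOfReactions>',
    '</model></sbml>'), path)
  path
}

test_that("a minimal one-reaction SBML file imports with its kinetic law", {
  f <- withr::local_tempfile(fileext = ".xml")
  minimal_sbml(f)
  m <- import_sbml(f)
  expect_setequal(m$species, c("A", "B"))
  expect_equal(m$initial[["A"]], 2)
  expect_equal(m$parameters[["k"]], 0.5)
  expect_equal(m$rate_text[["v1"]], "k * A")
  tc <- simulate_timecourse(m, c(0, 1))
  expect_equal(tc$A[2], 2 * exp(-0.5), tolerance = 1e-6)
})

test_that("import(export(model)) preserves simulated trajectories", {
  models <- list(
    fixture_model("decay"),
    fixture_model("mini_krebs"),
    kinetic_model("v1: 2*A <=> B\nv2: B => C", initial = c(A = 3, B = 1),
                  parameters = c(kf_v1 = 1.2, kr_v1 = 0.4, kf_v2 = 0.9)))
  for (m in models) {
    f <- withr::local_tempfile(fileext = ".xml")
    export_sbml(m, f)
    m2 <- import_sbml(f)
    times <- seq(0, 5, by = 0.25)
    t1 <- simulate_timecourse(m, times, rtol = 1e-9, atol = 1e-12)
    t2 <- simulate_timecourse(m2, times, rtol = 1e-9, atol = 1e-12)
    for (sp in m$species)
      expect_lt(max(abs(t1[[sp]] - t2[[sp]])), 1e-8)
  }
})

test_that("conserved models export one assignment rule per dependent species", {
  m <- kinetic_model("v1: A <=> B", initial = c(A = 2),
                     parameters = c(kf_v1 = 3, kr_v1 = 1))
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  xml2::xml_ns_strip(doc)
  rules <- xml2::xml_find_all(doc, "//assignmentRule")
  expect_length(rules, 1)
  expect_equal(xml2::xml_attr(rules[[1]], "variable"), "B")
  dep <- xml2::xml_find_first(doc, "//species[@id='B']")
  expect_equal(xml2::xml_attr(dep, "boundaryCondition"), "true")
})

test_that("export is deterministic", {
  m <- fixture_model("brusselator")
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f1)
  export_sbml(m, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("exported documents satisfy the reference SBML validator", {
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(fixture_model("decay"), f)
  script <- paste(
    "import libsbml, sys",
    sprintf("d = libsbml.readSBML('%s')", f),
    "d.checkConsistency()",
    "n = sum(1 for i in range(d.getNumErrors())",
    "        if d.getError(i).getSeverity() >= libsbml.LIBSBML_SEV_ERROR)",
    "print(n)", sep = "\n")
  out <- tryCatch(system2("python", c("-c", shQuote(script)),
                          stdout = TRUE, stderr = TRUE),
                  error = function(e) NULL)
  # libsbml ships with the pre-installed python stack; a missing python
  # would itself be a failure of the declared environment
  expect_false(is.null(out))
  expect_equal(tail(out, 1), "0")
})

test_that("unsupported SBML constructs are rejected by name", {
  f <- withr::local_tempfile(fileext = ".xml")
  base <- readLines(minimal_sbml(f))
  with_events <- append(base,
    "<listOfEvents><event id='e'/></listOfEvents>",
    after = grep("listOfReactions>", base)[2])
  writeLines(with_events, f)
  expect_error(import_sbml(f), "unsupported SBML feature: events")

  with_rate <- append(base, paste0(
    "<listOfRules><rateRule variable='A'><math xmlns='http://www.w3.org/1998/Math/MathML'>",
    "<cn>1</cn></math></rateRule></listOfRules>"),
    after = grep("</listOfParameters>", base))
  writeLines(with_rate, f)
  expect_error(import_sbml(f), "rate rules")

  writeLines(gsub('level="2"', 'level="3"', base), f)
  expect_error(import_sbml(f), "unsupported SBML level")
})
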