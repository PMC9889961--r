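minimal_sbml <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>\n',
  '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
  '  <model id="mini">\n',
  '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>\n',
  '    <listOfSpecies><species id="A" compartment="c" initialConcentration="1"',
  ' boundaryCondition="false" constant="false"/></listOfSpecies>\n',
  '    <listOfParameters><parameter id="k" value="0.5" constant="true"/></listOfParameters>\n',
  '    <listOfReactions><reaction id="v1" reversible="false">\n',
  '      <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>\n',
  '      <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
  '<apply><times/><ci>k</ci><ci>A</ci></apply></math></kineticLaw>\n',
  '    </reaction></listOfReactions>\n',
  '  </model>\n</sbml>\n')

test_that("minimal SBML maps directly into a kinetic model", {
  res <- read_sbml(minimal_sbml)
  expect_identical(nrow(res$report), 0L)
  m <- res$model
  expect_identical(names(m$species), "A")
  expect_identical(m$species$A$init, 1)
  expect_identical(names(m$reactions), "v1")
  expect_identical(m$parameters$k$value, 0.5)
  expect_identical(write_infix(m$reactions$v1$law), "k*A")
})

test_that("events are dropped with a warning entry, not an error", {
  withev <- sub("</model>",
                "<listOfEvents><event id='e1'/></listOfEvents></model>",
                minimal_sbml)
  res <- read_sbml(withev)
  expect_true(report_ok(res$report))
  expect_true(any(res$report$code == "UNSUPPORTED_DROPPED"))
  expect_identical(names(res$model$species), "A")
})

test_that("initialAmount converts to concentration via compartment size", {
  amt <- sub('size="1"', 'size="2.0"', minimal_sbml)
  amt <- sub('initialConcentration="1"', 'initialAmount="4.0"', amt)
  res <- read_sbml(amt)
  # oracle: concentration = amount / volume = 4.0 / 2.0
  expect_identical(res$model$species$A$init, 2)
})

test_that("local kinetic-law parameters hoist with reaction-prefixed ids", {
  loc <- sub("<kineticLaw>", paste0(
    "<kineticLaw><listOfLocalParameters>",
    '<localParameter id="k" value="0.25"/>',
    "</listOfLocalParameters>"), minimal_sbml)
  res <- read_sbml(loc)
  expect_true("v1__k" %in% names(res$model$parameters))
  expect_identical(res$model$parameters$v1__k$value, 0.25)
  expect_identical(write_infix(res$model$reactions$v1$law), "v1__k*A")
})

test_that("Level 2 documents read compatibly", {
  l2 <- gsub("level3/version2/core", "level2/version4", minimal_sbml)
  l2 <- gsub('level="3" version="2"', 'level="2" version="4"', l2)
  res <- read_sbml(l2)
  expect_identical(nrow(res$report), 0L)
  expect_identical(res$model$parameters$k$value, 0.5)
})

test_that("write-read round trip preserves the model", {
  for (kind in c("chain", "reversible-pair", "michaelis-menten-pathway")) {
    m <- make_toy_model(kind, seed = 11)
    back <- read_sbml(write_sbml(m))$model
    expect_identical(names(back$species), names(m$species))
    expect_identical(names(back$parameters), names(m$parameters))
    for (s in names(m$species)) expect_identical(back$species[[s]]$init,
                                                 m$species[[s]]$init)
    for (p in names(m$parameters)) expect_identical(back$parameters[[p]]$value,
                                                    m$parameters[[p]]$value)
    for (r in names(m$reactions)) {
      expect_true(expr_identical(back$reactions[[r]]$law, m$reactions[[r]]$law))
    }
  }
})

test_that("tanh survives the MathML round trip and ml origins are tagged", {
  m <- make_toy_model("chain", seed = 2)
  m$parameters[["w"]] <- kin_parameter("w", 0.7, origin = "ml-weight")
  m$parameters[["h"]] <- kin_parameter("h", 0, constant = FALSE)
  m$assignment_rules <- list(kin_assignment_rule("h", "tanh(w*A)"))
  xml <- write_sbml(m)
  expect_match(xml, "<tanh/>", fixed = TRUE)
  back <- read_sbml(xml)$model
  expect_identical(back$parameters$w$origin, "ml-weight")
  expect_true(expr_identical(back$assignment_rules[[1]]$expr,
                             parse_infix("tanh(w*A)")))
})

test_that("writer refuses inconsistent models with the report", {
  m <- make_toy_model("chain", seed = 2)
  m$reactions[["v1"]]$law <- parse_infix("nosuch*A")
  expect_error(write_sbml(m), "DANGLING_REF")
})

test_that("every written document passes structural validation cleanly", {
  for (kind in TOY_KINDS) {
    m <- make_toy_model(kind, seed = 4)
    rep <- validate_sbml_structure(write_sbml(m))
    expect_identical(nrow(rep), 0L)
  }
})

test_that("structural validator flags duplicate ids and dangling math symbols", {
  dup <- sub("<listOfSpecies>",
             paste0("<listOfSpecies><species id='A' compartment='c' ",
                    "initialConcentration='2' boundaryCondition='false' ",
                    "constant='false'/>"), minimal_sbml)
  expect_true(any(validate_sbml_structure(dup)$code == "DUPLICATE_ID"))
  bad <- sub("<ci>k</ci>", "<ci>zz</ci>", minimal_sbml)
  expect_true(any(validate_sbml_structure(bad)$code == "DANGLING_REF"))
  expect_true(any(validate_sbml_structure("<notxml") $code == "NOT_XML"))
})
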