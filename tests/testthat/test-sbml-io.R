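test_that("minimal L3 model reads back directly", {
  doc <- parse_model(minimal_l3_xml())
  expect_equal(doc$level_version, "L3V2")
  expect_equal(doc$parameters$id, "k1")
  expect_equal(doc$parameters$value, 0.5)
  expect_equal(doc$species$id, "S")
  expect_equal(doc$species$initial, 10)
})

test_that("write-then-parse round trip is field-for-field identical", {
  docs <- c(list(make_decay_model(), make_reversible_model(),
                 build_th17_model(),
                 make_decay_model(level_version = "L2V4")),
            lapply(1:10, make_random_hill_model))
  for (doc in docs) {
    back <- parse_model(write_model(doc))
    expect_equal(back$model_id, doc$model_id)
    expect_equal(back$level_version, doc$level_version)
    expect_equal(back$compartments, doc$compartments)
    expect_equal(back$species, doc$species)
    expect_equal(back$parameters, doc$parameters)
    expect_equal(length(back$reactions), length(doc$reactions))
    for (i in seq_along(doc$reactions)) {
      expect_equal(back$reactions[[i]]$kinetic_law,
                   doc$reactions[[i]]$kinetic_law)
      expect_equal(back$reactions[[i]]$reactants,
                   doc$reactions[[i]]$reactants)
      expect_equal(back$reactions[[i]]$products,
                   doc$reactions[[i]]$products)
    }
  }
})

test_that("awkward doubles round trip bit-exactly", {
  doc <- make_decay_model(s0 = 2.2999999999999998)
  doc$parameters$value <- 1 / 3
  back <- parse_model(write_model(doc))
  expect_identical(back$species$initial, 2.2999999999999998)
  expect_identical(back$parameters$value, 1 / 3)
  # integer-valued double prints without decoration
  doc2 <- make_decay_model(k = 3.0)
  expect_match(write_model(doc2), 'id="k" value="3"')
})

test_that("annotations survive the round trip", {
  doc <- make_decay_model()
  doc$annotations$snapshot_time <- 144
  doc$annotations$interventions <- list(
    intervention("S", "species_initial", "SET", 100))
  back <- parse_model(write_model(doc))
  expect_equal(back$annotations$snapshot_time, 144)
  expect_equal(back$annotations$interventions[[1]]$target_id, "S")
  expect_equal(back$annotations$interventions[[1]]$magnitude, 100)
})

test_that("validation rejects undeclared symbols and duplicate ids", {
  xml <- sub("k * S", "q9 * S", write_model(make_decay_model()), fixed = TRUE)
  xml <- sub("<ci> k </ci>", "<ci> q9 </ci>", write_model(make_decay_model()),
             fixed = TRUE)
  expect_error(parse_model(xml), "q9")
  expect_error(
    model_document("dup",
      species = data.frame(id = "k", compartment = "cell", initial = 1,
                           boundary = FALSE),
      parameters = data.frame(id = "k", value = 1, constant = TRUE)),
    "duplicate")
  expect_error(parse_model("<sbml><model"), "parse error")
  expect_error(
    model_document("neg",
      species = data.frame(id = "S", compartment = "cell", initial = -1,
                           boundary = FALSE)),
    "non-negative")
})

test_that("set_value copies, commutes and is idempotent", {
  doc <- build_th17_model()
  d1 <- set_value(doc, "a6", 1.5)
  expect_equal(get("get_value", asNamespace("sbmlsens"))(d1, "a6"), 1.5)
  expect_equal(doc$parameters$value[doc$parameters$id == "a6"], 0.1)
  # only the named field differs
  d1r <- d1
  d1r$parameters$value[d1r$parameters$id == "a6"] <- 0.1
  expect_equal(d1r, doc)
  # species target sets the initial concentration
  d2 <- set_value(doc, "CX", 100)
  expect_equal(d2$species$initial[d2$species$id == "CX"], 100)
  # idempotence and commutativity
  expect_equal(set_value(d1, "a6", 1.5), d1)
  expect_equal(set_value(set_value(doc, "a6", 2), "CX", 7),
               set_value(set_value(doc, "CX", 7), "a6", 2))
  expect_error(set_value(doc, "nope", 1), "available ids")
})

test_that("initialAmount is normalised to concentration on read", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2"',
    ' version="4"><model id="amt">',
    '<listOfCompartments><compartment id="c" size="4"/>',
    '</listOfCompartments>',
    '<listOfSpecies><species id="S" compartment="c" initialAmount="10"/>',
    '</listOfSpecies></model></sbml>')
  doc <- parse_model(xml)
  expect_equal(doc$species$initial, 2.5)
})

test_that("events warn and are preserved verbatim; unsupported MathML is loud", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3"',
    ' version="2"><model id="ev">',
    '<listOfSpecies><species id="S" compartment="c"',
    ' initialConcentration="1" boundaryCondition="false"/></listOfSpecies>',
    '<listOfEvents><event id="e1"/></listOfEvents>',
    '</model></sbml>')
  expect_warning(doc <- parse_model(xml), "events")
  expect_match(doc$extras$events, "e1")
  expect_match(write_model(doc), "listOfEvents")

  bad <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3"',
    ' version="2"><model id="pw">',
    '<listOfSpecies><species id="S" compartment="c"',
    ' initialConcentration="1"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1"><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<piecewise><piece><cn>1</cn><true/></piece></piecewise>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>')
  expect_error(parse_model(bad), "piecewise")
})
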