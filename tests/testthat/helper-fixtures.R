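# Fixture builders: every model used in the tests is constructed in code.

# single species S with first-order decay at rate k
make_decay_model <- function(k = 1, s0 = 1, level_version = "L3V2") {
  model_document(
    "decay", level_version = level_version,
    species = data.frame(id = "S", compartment = "cell", initial = s0,
                         boundary = FALSE),
    parameters = data.frame(id = "k", value = k, constant = TRUE),
    reactions = list(list(
      id = "deg",
      reactants = data.frame(species = "S", stoich = 1),
      products = data.frame(species = character(), stoich = numeric()),
      kinetic_law = quote(k * S))))
}

# reversible A <-> B mass action
make_reversible_model <- function(kf = 0.7, kr = 0.3, a0 = 1, b0 = 0) {
  model_document(
    "rev",
    species = data.frame(id = c("A", "B"), compartment = "cell",
                         initial = c(a0, b0), boundary = FALSE),
    parameters = data.frame(id = c("kf", "kr"), value = c(kf, kr),
                            constant = TRUE),
    reactions = list(
      list(id = "fwd",
           reactants = data.frame(species = "A", stoich = 1),
           products = data.frame(species = "B", stoich = 1),
           kinetic_law = quote(kf * A)),
      list(id = "rev",
           reactants = data.frame(species = "B", stoich = 1),
           products = data.frame(species = "A", stoich = 1),
           kinetic_law = quote(kr * B))))
}

# random stable linear 3-species network: source -> S1 -> S2 -> S3, decays
make_random_toy_model <- function(seed) {
  set.seed(seed)
  r <- round(stats::runif(6, 0.1, 1), 3)
  y0 <- round(stats::runif(3, 0.5, 5), 3)
  empty <- data.frame(species = character(), stoich = numeric())
  one <- function(id) data.frame(species = id, stoich = 1)
  model_document(
    paste0("toy", seed),
    species = data.frame(id = c("S1", "S2", "S3"), compartment = "cell",
                         initial = y0, boundary = FALSE),
    parameters = data.frame(id = paste0("r", 1:6), value = r,
                            constant = TRUE),
    reactions = list(
      list(id = "src", reactants = empty, products = one("S1"),
           kinetic_law = quote(r1)),
      list(id = "c12", reactants = one("S1"), products = one("S2"),
           kinetic_law = quote(r2 * S1)),
      list(id = "c23", reactants = one("S2"), products = one("S3"),
           kinetic_law = quote(r3 * S2)),
      list(id = "d1", reactants = one("S1"), products = empty,
           kinetic_law = quote(r4 * S1)),
      list(id = "d2", reactants = one("S2"), products = empty,
           kinetic_law = quote(r5 * S2)),
      list(id = "d3", reactants = one("S3"), products = empty,
           kinetic_law = quote(r6 * S3))))
}

# random model with awkward doubles and a Hill law, for round-trip tests
make_random_hill_model <- function(seed) {
  set.seed(seed)
  model_document(
    paste0("hill", seed),
    compartments = data.frame(id = "cell", size = stats::runif(1, 0.5, 2)),
    species = data.frame(id = c("P", "Q"), compartment = "cell",
                         initial = stats::runif(2, 0, 10),
                         boundary = c(FALSE, stats::runif(1) < 0.3)),
    parameters = data.frame(id = c("vmax", "km", "h"),
                            value = c(stats::runif(1, 0, 5),
                                      stats::runif(1, 0.01, 2),
                                      sample(1:4, 1)),
                            constant = TRUE),
    reactions = list(list(
      id = "hill",
      reactants = data.frame(species = "Q", stoich = 1),
      products = data.frame(species = "P", stoich = 2),
      kinetic_law = quote(vmax * Q^h / (km^h + Q^h)))))
}

minimal_l3_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core"',
    ' level="3" version="2">\n',
    '  <model id="mini">\n',
    '    <listOfCompartments><compartment id="cell" size="1"/>',
    '</listOfCompartments>\n',
    '    <listOfSpecies><species id="S" compartment="cell"',
    ' initialConcentration="10" boundaryCondition="false"/>',
    '</listOfSpecies>\n',
    '    <listOfParameters><parameter id="k1" value="0.5"',
    ' constant="true"/></listOfParameters>\n',
    '  </model>\n</sbml>')
}

settings_xml <- function(technique = "LHS", samples = 200,
                         model_path = "model.xml", extra = "") {
  paste0(
    '<?xml version="1.0"?>\n<sensitivitySettings>\n',
    '  <technique>', technique, '</technique>\n',
    '  <modelPath>', model_path, '</modelPath>\n',
    '  <outputDir>out</outputDir>\n',
    if (!is.na(samples)) paste0('  <lhs samples="', samples, '"/>\n') else "",
    '  <ranges>\n',
    paste0('    <range target="p', 1:8, '" kind="parameter" min="0" ',
           'max="1" baseline="0.5"/>\n', collapse = ""),
    '  </ranges>\n', extra, '</sensitivitySettings>')
}

# ranges helper
unit_ranges <- function(k, baseline = 0.5) {
  lapply(paste0("p", seq_len(k)), parameter_range, min = 0, max = 1,
         baseline = baseline)
}
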