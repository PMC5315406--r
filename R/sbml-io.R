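#' In-memory SBML model document
#'
#' A `model_document` is a faithful in-memory image of the SBML subset this
#' toolkit manipulates: compartments, species, global parameters and
#' reactions with arithmetic kinetic laws. Species initialisation is
#' normalised to concentration on read (`initialAmount` is divided by the
#' compartment size), because interventions and the solver operate on
#' concentration fields.
#'
#' @param model_id model identifier.
#' @param level_version SBML dialect, one of `"L2V4"` or `"L3V2"`.
#' @param compartments data.frame with columns `id`, `size`.
#' @param species data.frame with columns `id`, `compartment`, `initial`
#'   (concentration, non-negative), `boundary` (logical).
#' @param parameters data.frame with columns `id`, `value`, `constant`.
#' @param reactions list; each element a list with `id`,
#'   `reactants`/`products` (data.frames of `species`, `stoich`) and
#'   `kinetic_law`, an R call over declared identifiers using
#'   `+ - * / ^` only.
#' @param annotations named list of toolkit annotations (snapshot time,
#'   applied interventions); carried through write/parse round trips.
#' @return an object of class `model_document`.
#' @export
model_document <- function(model_id,
                           level_version = "L3V2",
                           compartments = data.frame(id = "cell", size = 1),
                           species = data.frame(id = character(),
                                                compartment = character(),
                                                initial = numeric(),
                                                boundary = logical()),
                           parameters = data.frame(id = character(),
                                                   value = numeric(),
                                                   constant = logical()),
                           reactions = list(),
                           annotations = list()) {
  reactions <- lapply(reactions, function(rx) {
    rx$kinetic_law <- strip_parens(rx$kinetic_law)
    rx
  })
  doc <- structure(
    list(model_id = as.character(model_id),
         level_version = match.arg(level_version, c("L3V2", "L2V4")),
         compartments = normalise_df(compartments, c("id", "size")),
         species = normalise_df(species,
                                c("id", "compartment", "initial", "boundary")),
         parameters = normalise_df(parameters, c("id", "value", "constant")),
         reactions = reactions,
         annotations = annotations,
         extras = list()),
    class = "model_document")
  validate_model(doc)
  doc
}

normalise_df <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  abort_if(!all(cols %in% names(df)),
           "missing column(s): ", paste(setdiff(cols, names(df)),
                                        collapse = ", "))
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Validate a model document against its invariants
#'
#' Checks id uniqueness across parameters and species, resolvability of all
#' kinetic-law symbols, and finiteness/non-negativity of species initials.
#' Called by every operation that constructs or rewrites a document.
#'
#' @param doc a `model_document`.
#' @return `doc`, invisibly; errors describe the violated invariant.
#' @export
validate_model <- function(doc) {
  abort_if(!inherits(doc, "model_document"), "not a model_document")
  ids <- c(doc$parameters$id, doc$species$id)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0,
           "duplicate identifier(s): ", paste(dup, collapse = ", "))
  bad <- !is.finite(doc$species$initial) | doc$species$initial < 0
  abort_if(any(bad), "species initial concentration must be finite and ",
           "non-negative: ", paste(doc$species$id[bad], collapse = ", "))
  abort_if(any(!is.finite(doc$compartments$size) | doc$compartments$size <= 0),
           "compartment sizes must be positive and finite")
  known <- c(ids, doc$compartments$id)
  for (rx in doc$reactions) {
    syms <- expr_symbols(rx$kinetic_law)
    missing <- setdiff(syms, known)
    abort_if(length(missing) > 0,
             "kinetic law of reaction '", rx$id,
             "' references undeclared symbol(s): ",
             paste(missing, collapse = ", "))
    for (side in c("reactants", "products")) {
      sr <- rx[[side]]
      if (is.null(sr) || nrow(sr) == 0) next
      unknown <- setdiff(sr$species, doc$species$id)
      abort_if(length(unknown) > 0, "reaction '", rx$id, "' ", side,
               " reference unknown species: ", paste(unknown, collapse = ", "))
      abort_if(any(sr$stoich <= 0), "stoichiometries must be positive")
    }
  }
  invisible(doc)
}

sbml_ns_uri <- function(level_version) {
  switch(level_version,
    L2V4 = "http://www.sbml.org/sbml/level2/version4",
    L3V2 = "http://www.sbml.org/sbml/level3/version2/core",
    stop("unsupported SBML dialect: ", level_version, call. = FALSE))
}

ANNOT_NS <- "https://sbmlsens.invalid/annotations"

#' Parse an SBML document
#'
#' Reads the L2V4/L3V2 core subset: compartments, species, global
#' parameters, and reactions with arithmetic kinetic laws. Species declared
#' with `initialAmount` are converted to concentration using the
#' compartment size. Events are preserved verbatim (with a warning) but
#' never modified; rules, function definitions and constraints are reported
#' as warnings and recorded in the document's `extras$unsupported` rather
#' than silently dropped.
#'
#' @param xml_text SBML as a string, or a path to an SBML file.
#' @return a `model_document`.
#' @export
parse_model <- function(xml_text) {
  x <- tryCatch(xml2::read_xml(xml_text),
                error = function(e) stop("SBML parse error: ",
                                         conditionMessage(e), call. = FALSE))
  root <- x
  abort_if(xml2::xml_name(root) != "sbml",
           "root element is <", xml2::xml_name(root), ">, expected <sbml>")
  level <- xml2::xml_attr(root, "level")
  version <- xml2::xml_attr(root, "version")
  lv <- paste0("L", level, "V", version)
  abort_if(!lv %in% c("L2V4", "L3V2"),
           "unsupported SBML dialect ", lv, " (supported: L2V4, L3V2)")
  xml2::xml_ns_strip(x)

  model <- xml2::xml_find_first(x, "./model")
  abort_if(inherits(model, "xml_missing"), "no <model> element")
  model_id <- xml2::xml_attr(model, "id") %||% "model"
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    size = num_attr(comp_nodes, "size", default = 1),
    stringsAsFactors = FALSE)
  if (nrow(compartments) == 0) {
    compartments <- data.frame(id = character(), size = numeric())
  }

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  init_conc <- num_attr(sp_nodes, "initialConcentration", default = NA_real_)
  init_amt <- num_attr(sp_nodes, "initialAmount", default = NA_real_)
  comp_of <- xml2::xml_attr(sp_nodes, "compartment")
  sizes <- compartments$size[match(comp_of, compartments$id)]
  initial <- ifelse(!is.na(init_conc), init_conc,
                    init_amt / ifelse(is.na(sizes), 1, sizes))
  initial[is.na(initial)] <- 0
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = comp_of,
    initial = initial,
    boundary = tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in%
      "true",
    stringsAsFactors = FALSE)
  if (nrow(species) == 0) {
    species <- data.frame(id = character(), compartment = character(),
                          initial = numeric(), boundary = logical())
  }

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- data.frame(
    id = xml2::xml_attr(par_nodes, "id"),
    value = num_attr(par_nodes, "value", default = NA_real_),
    constant = !(tolower(xml2::xml_attr(par_nodes, "constant")) %in% "false"),
    stringsAsFactors = FALSE)
  if (nrow(parameters) == 0) {
    parameters <- data.frame(id = character(), value = numeric(),
                             constant = logical())
  }

  reactions <- lapply(
    xml2::xml_find_all(model, "./listOfReactions/reaction"),
    parse_reaction)

  annotations <- parse_annotations(model)

  extras <- list()
  events <- xml2::xml_find_first(model, "./listOfEvents")
  if (!inherits(events, "xml_missing")) {
    warning("SBML events are preserved verbatim but never modified",
            call. = FALSE)
    extras$events <- as.character(events)
  }
  for (tag in c("listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model, paste0("./", tag)),
                  "xml_missing")) {
      warning("unsupported SBML construct <", tag,
              "> recorded but not interpreted", call. = FALSE)
      extras$unsupported <- c(extras$unsupported, tag)
    }
  }

  doc <- model_document(model_id = model_id, level_version = lv,
                        compartments = compartments, species = species,
                        parameters = parameters, reactions = reactions,
                        annotations = annotations)
  doc$extras <- extras
  doc
}

num_attr <- function(nodes, attr, default) {
  v <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, attr)))
  v[is.na(v)] <- default
  v
}

parse_reaction <- function(node) {
  side <- function(tag) {
    refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
    if (length(refs) == 0) {
      return(data.frame(species = character(), stoich = numeric(),
                        stringsAsFactors = FALSE))
    }
    data.frame(species = xml2::xml_attr(refs, "species"),
               stoich = num_attr(refs, "stoichiometry", default = 1),
               stringsAsFactors = FALSE)
  }
  math <- xml2::xml_find_first(node, "./kineticLaw/math")
  abort_if(inherits(math, "xml_missing"),
           "reaction '", xml2::xml_attr(node, "id"), "' has no kinetic law")
  law <- mathml_to_expr(math)
  locals <- xml2::xml_find_all(
    node, "./kineticLaw/listOfLocalParameters/localParameter |
           ./kineticLaw/listOfParameters/parameter")
  if (length(locals) > 0) {
    # local parameters are inlined by value; our writer never emits them
    warning("local kinetic-law parameters inlined by value in reaction '",
            xml2::xml_attr(node, "id"), "'", call. = FALSE)
    vals <- as.list(num_attr(locals, "value", default = NA_real_))
    names(vals) <- xml2::xml_attr(locals, "id")
    law <- substitute_symbols(law, vals)
  }
  list(id = xml2::xml_attr(node, "id"),
       reactants = side("listOfReactants"),
       products = side("listOfProducts"),
       kinetic_law = law)
}

substitute_symbols <- function(e, values) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(values)) return(values[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- substitute_symbols(e[[i]], values)
  }
  e
}

parse_annotations <- function(model) {
  ann <- list()
  snap <- xml2::xml_find_first(model, "./annotation/state")
  if (!inherits(snap, "xml_missing")) {
    ann$snapshot_time <- as.numeric(xml2::xml_attr(snap, "snapshotTime"))
    src <- xml2::xml_attr(snap, "source")
    if (!is.na(src)) ann$snapshot_source <- src
  }
  ivs <- xml2::xml_find_all(model, "./annotation/intervention")
  if (length(ivs) > 0) {
    ann$interventions <- lapply(ivs, function(n) {
      intervention(target_id = xml2::xml_attr(n, "target"),
                   target_kind = xml2::xml_attr(n, "kind"),
                   mode = xml2::xml_attr(n, "mode"),
                   magnitude = as.numeric(xml2::xml_attr(n, "magnitude")))
    })
  }
  ann
}

#' Serialise a model document to SBML
#'
#' Emits SBML of the document's `level_version`. Numeric values are written
#' with 17 significant digits so that write-then-parse recovers every
#' double bit-for-bit. Refuses to write a document that violates its
#' invariants.
#'
#' @param doc a `model_document`.
#' @param path optional file path; when given the XML is also written there.
#' @return the SBML document as a single string, invisibly when `path` is
#'   given.
#' @export
write_model <- function(doc, path = NULL) {
  validate_model(doc)
  lv <- doc$level_version
  ns <- sbml_ns_uri(lv)
  level <- substr(lv, 2, 2)
  version <- substr(lv, 4, 4)
  b <- character(0)
  add <- function(...) b <<- c(b, paste0(...))
  l3 <- identical(lv, "L3V2")

  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"", ns, "\" level=\"", level, "\" version=\"", version,
      "\">")
  add("  <model id=\"", doc$model_id, "\">")
  add(annotation_block(doc))
  if (nrow(doc$compartments) > 0) {
    add("    <listOfCompartments>")
    for (i in seq_len(nrow(doc$compartments))) {
      add("      <compartment id=\"", doc$compartments$id[i],
          "\" size=\"", fmt_num(doc$compartments$size[i]), "\"",
          if (l3) " constant=\"true\"" else "", "/>")
    }
    add("    </listOfCompartments>")
  }
  if (nrow(doc$species) > 0) {
    add("    <listOfSpecies>")
    for (i in seq_len(nrow(doc$species))) {
      s <- doc$species[i, ]
      add("      <species id=\"", s$id, "\" compartment=\"", s$compartment,
          "\" initialConcentration=\"", fmt_num(s$initial),
          "\" boundaryCondition=\"", tolower(as.character(s$boundary)), "\"",
          if (l3) {
            paste0(" hasOnlySubstanceUnits=\"false\" constant=\"",
                   tolower(as.character(s$boundary)), "\"")
          } else "",
          "/>")
    }
    add("    </listOfSpecies>")
  }
  if (nrow(doc$parameters) > 0) {
    add("    <listOfParameters>")
    for (i in seq_len(nrow(doc$parameters))) {
      p <- doc$parameters[i, ]
      add("      <parameter id=\"", p$id, "\" value=\"", fmt_num(p$value),
          "\" constant=\"", tolower(as.character(p$constant)), "\"/>")
    }
    add("    </listOfParameters>")
  }
  if (length(doc$reactions) > 0) {
    add("    <listOfReactions>")
    for (rx in doc$reactions) add(reaction_block(rx, l3))
    add("    </listOfReactions>")
  }
  if (!is.null(doc$extras$events)) add("    ", doc$extras$events)
  add("  </model>")
  add("</sbml>")
  out <- paste(b[nzchar(b)], collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

annotation_block <- function(doc) {
  ann <- doc$annotations
  if (length(ann) == 0) return("")
  b <- c("    <annotation>")
  if (!is.null(ann$snapshot_time)) {
    b <- c(b, paste0("      <state xmlns=\"", ANNOT_NS, "\" snapshotTime=\"",
                     fmt_num(ann$snapshot_time), "\"",
                     if (!is.null(ann$snapshot_source)) {
                       paste0(" source=\"", ann$snapshot_source, "\"")
                     } else "",
                     "/>"))
  }
  for (iv in ann$interventions) {
    b <- c(b, paste0("      <intervention xmlns=\"", ANNOT_NS,
                     "\" target=\"", iv$target_id,
                     "\" kind=\"", iv$target_kind,
                     "\" mode=\"", iv$mode,
                     "\" magnitude=\"", fmt_num(iv$magnitude), "\"/>"))
  }
  paste(c(b, "    </annotation>"), collapse = "\n")
}

reaction_block <- function(rx, l3) {
  b <- c(paste0("      <reaction id=\"", rx$id, "\" reversible=\"false\"",
                if (l3) "" else "", ">"))
  side <- function(tag, df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    c(paste0("        <", tag, ">"),
      vapply(seq_len(nrow(df)), function(i) {
        paste0("          <speciesReference species=\"", df$species[i],
               "\" stoichiometry=\"", fmt_num(df$stoich[i]), "\"",
               if (l3) " constant=\"true\"" else "", "/>")
      }, character(1)),
      paste0("        </", tag, ">"))
  }
  b <- c(b, side("listOfReactants", rx$reactants),
         side("listOfProducts", rx$products),
         "        <kineticLaw>",
         paste0("          ", expr_to_mathml_string(rx$kinetic_law)),
         "        </kineticLaw>",
         "      </reaction>")
  paste(b, collapse = "\n")
}

#' Set a parameter value or species initial concentration
#'
#' Returns a modified copy of the document; the original is untouched.
#' Species targets have their initial concentration set.
#'
#' @param doc a `model_document`.
#' @param target_id id of a parameter or species.
#' @param value new value (finite; non-negative for species).
#' @return a new `model_document` differing from `doc` only in the named
#'   field.
#' @export
set_value <- function(doc, target_id, value) {
  abort_if(!is_scalar_num(value), "value must be a finite scalar")
  if (target_id %in% doc$parameters$id) {
    doc$parameters$value[doc$parameters$id == target_id] <- value
  } else if (target_id %in% doc$species$id) {
    doc$species$initial[doc$species$id == target_id] <- value
  } else {
    stop("unknown target '", target_id, "'; available ids: ",
         paste(c(doc$parameters$id, doc$species$id), collapse = ", "),
         call. = FALSE)
  }
  validate_model(doc)
  doc
}

get_value <- function(doc, target_id) {
  if (target_id %in% doc$parameters$id) {
    return(doc$parameters$value[doc$parameters$id == target_id])
  }
  if (target_id %in% doc$species$id) {
    return(doc$species$initial[doc$species$id == target_id])
  }
  stop("unknown target '", target_id, "'", call. = FALSE)
}

#' @export
print.model_document <- function(x, ...) {
  cat("<model_document> ", x$model_id, " (", x$level_version, ")\n", sep = "")
  cat("  compartments:", nrow(x$compartments),
      " species:", nrow(x$species),
      " parameters:", nrow(x$parameters),
      " reactions:", length(x$reactions), "\n")
  if (!is.null(x$annotations$snapshot_time)) {
    cat("  snapshot at t =", x$annotations$snapshot_time, "\n")
  }
  invisible(x)
}
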