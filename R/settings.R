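# XML settings file: one document configures a whole run (technique,
# model/output locations, ranges, design sizes, interventions, solver
# options). The tag vocabulary is defined by this package (see
# inst/schema/settings.xsd); byte compatibility with other tools' settings
# files is a non-goal.

SETTINGS_DEFAULTS <- list(efast_curves = 3L, local_increments = 10L,
                          t_end = 144, step = 0.12,
                          efast_samples_per_curve = 65L)

#' Parse a run-settings XML document
#'
#' Missing optional tags receive documented defaults (`efast curves = 3`,
#' `local increments = 10`, solver `tEnd = 144`, `step = 0.12`), recorded
#' in the returned object's `defaults_applied`.
#'
#' @param xml_text settings XML as a string or file path.
#' @return an object of class `run_settings`: list with `technique`
#'   (`LOCAL`, `LHS`, `EFAST`, `SNAPSHOT`, `INTERVENTION`), `model_path`,
#'   `output_dir`, `ranges` (list of [parameter_range()]), design sizes,
#'   `interventions`, and `solver` options.
#' @export
parse_settings <- function(xml_text) {
  x <- tryCatch(xml2::read_xml(xml_text),
                error = function(e) stop("settings parse error: ",
                                         conditionMessage(e), call. = FALSE))
  abort_if(xml2::xml_name(x) != "sensitivitySettings",
           "root element must be <sensitivitySettings>")
  txt1 <- function(tag) {
    node <- xml2::xml_find_first(x, paste0("./", tag))
    if (inherits(node, "xml_missing")) return(NULL)
    trimws(xml2::xml_text(node))
  }
  technique <- toupper(txt1("technique") %||%
                         stop("technique required", call. = FALSE))
  abort_if(!technique %in% c("LOCAL", "LHS", "EFAST", "SNAPSHOT",
                             "INTERVENTION"),
           "unknown technique '", technique, "'")
  model_path <- txt1("modelPath")
  abort_if(is.null(model_path) || !nzchar(model_path), "modelPath required")
  output_dir <- txt1("outputDir") %||% "."

  defaults_applied <- character(0)
  solver_node <- xml2::xml_find_first(x, "./solver")
  getattr_num <- function(node, attr, default, name) {
    v <- if (inherits(node, "xml_missing")) NA else {
      suppressWarnings(as.numeric(xml2::xml_attr(node, attr)))
    }
    if (is.na(v)) {
      defaults_applied <<- c(defaults_applied, name)
      default
    } else v
  }
  t_end <- getattr_num(solver_node, "tEnd", SETTINGS_DEFAULTS$t_end,
                       "solver.tEnd")
  step <- getattr_num(solver_node, "step", SETTINGS_DEFAULTS$step,
                      "solver.step")
  abort_if(t_end <= 0 || step <= 0, "solver tEnd and step must be > 0")

  rng_nodes <- xml2::xml_find_all(x, "./ranges/range")
  ranges <- lapply(rng_nodes, function(n) {
    minv <- as.numeric(xml2::xml_attr(n, "min"))
    maxv <- as.numeric(xml2::xml_attr(n, "max"))
    basev <- suppressWarnings(as.numeric(xml2::xml_attr(n, "baseline")))
    abort_if(anyNA(c(minv, maxv)), "range for '",
             xml2::xml_attr(n, "target"), "' needs min and max")
    parameter_range(
      target_id = xml2::xml_attr(n, "target"),
      min = minv, max = maxv,
      baseline = if (is.na(basev)) NULL else basev,
      target_kind = xml2::xml_attr(n, "kind") %|na|% "parameter")
  })

  lhs_node <- xml2::xml_find_first(x, "./lhs")
  lhs_samples <- getattr_num(lhs_node, "samples", NA_real_, "lhs.samples")
  efast_node <- xml2::xml_find_first(x, "./efast")
  efast_curves <- getattr_num(efast_node, "curves",
                              SETTINGS_DEFAULTS$efast_curves, "efast.curves")
  efast_spc <- getattr_num(efast_node, "samplesPerCurve",
                           SETTINGS_DEFAULTS$efast_samples_per_curve,
                           "efast.samplesPerCurve")
  local_node <- xml2::xml_find_first(x, "./local")
  local_increments <- getattr_num(local_node, "increments",
                                  SETTINGS_DEFAULTS$local_increments,
                                  "local.increments")

  iv_nodes <- xml2::xml_find_all(x, "./interventions/intervention")
  interventions <- lapply(iv_nodes, function(n) {
    intervention(target_id = xml2::xml_attr(n, "target"),
                 target_kind = xml2::xml_attr(n, "kind") %|na|%
                   "species_initial",
                 mode = toupper(xml2::xml_attr(n, "mode") %|na|% "SET"),
                 magnitude = as.numeric(xml2::xml_attr(n, "magnitude")))
  })

  s <- structure(
    list(technique = technique, model_path = model_path,
         output_dir = output_dir, ranges = ranges,
         lhs_samples = if (is.na(lhs_samples)) NULL else
           as.integer(lhs_samples),
         efast_curves = as.integer(efast_curves),
         efast_samples_per_curve = as.integer(efast_spc),
         local_increments = as.integer(local_increments),
         interventions = interventions,
         solver = list(t_end = t_end, step = step),
         defaults_applied = defaults_applied),
    class = "run_settings")
  validate_settings(s)
  s
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

validate_settings <- function(s) {
  if (s$technique == "LHS") {
    abort_if(is.null(s$lhs_samples) || s$lhs_samples < 2,
             "lhs samples must be >= 2 for technique LHS")
  }
  if (s$technique == "EFAST") {
    abort_if(s$efast_samples_per_curve %% 2 == 0 ||
               s$efast_samples_per_curve < 65,
             "efast samplesPerCurve must be odd and >= 65")
  }
  if (s$technique %in% c("LOCAL", "LHS", "EFAST")) {
    abort_if(length(s$ranges) == 0,
             "technique ", s$technique, " requires at least one <range>")
  }
  if (s$technique == "INTERVENTION") {
    abort_if(length(s$interventions) == 0,
             "technique INTERVENTION requires at least one <intervention>")
  }
  invisible(s)
}

#' Serialise run settings back to XML
#'
#' `parse_settings(serialise_settings(s))` reproduces `s` for any valid
#' settings object.
#'
#' @param s a `run_settings` object.
#' @return XML as a single string.
#' @export
serialise_settings <- function(s) {
  b <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
         "<sensitivitySettings>",
         paste0("  <technique>", s$technique, "</technique>"),
         paste0("  <modelPath>", s$model_path, "</modelPath>"),
         paste0("  <outputDir>", s$output_dir, "</outputDir>"),
         paste0("  <solver tEnd=\"", fmt_num(s$solver$t_end),
                "\" step=\"", fmt_num(s$solver$step), "\"/>"))
  if (!is.null(s$lhs_samples)) {
    b <- c(b, paste0("  <lhs samples=\"", s$lhs_samples, "\"/>"))
  }
  b <- c(b, paste0("  <efast curves=\"", s$efast_curves,
                   "\" samplesPerCurve=\"", s$efast_samples_per_curve,
                   "\"/>"),
         paste0("  <local increments=\"", s$local_increments, "\"/>"))
  if (length(s$ranges) > 0) {
    b <- c(b, "  <ranges>",
           vapply(s$ranges, function(r) {
             paste0("    <range target=\"", r$target_id,
                    "\" kind=\"", r$target_kind,
                    "\" min=\"", fmt_num(r$min),
                    "\" max=\"", fmt_num(r$max), "\"",
                    if (!is.null(r$baseline)) {
                      paste0(" baseline=\"", fmt_num(r$baseline), "\"")
                    } else "",
                    "/>")
           }, character(1)),
           "  </ranges>")
  }
  if (length(s$interventions) > 0) {
    b <- c(b, "  <interventions>",
           vapply(s$interventions, function(iv) {
             paste0("    <intervention target=\"", iv$target_id,
                    "\" kind=\"", iv$target_kind,
                    "\" mode=\"", iv$mode,
                    "\" magnitude=\"", fmt_num(iv$magnitude), "\"/>")
           }, character(1)),
           "  </interventions>")
  }
  paste(c(b, "</sensitivitySettings>"), collapse = "\n")
}

#' Run a settings-driven analysis
#'
#' Dispatches on the settings' technique: `LOCAL`/`LHS`/`EFAST` build the
#' design and write one SBML file per row plus a `manifest.csv` to the
#' output directory; `SNAPSHOT` turns a trajectory CSV into a new SBML
#' file; `INTERVENTION` additionally applies the configured interventions.
#'
#' @param settings a `run_settings` object or path to a settings XML file.
#' @param seed integer seed for stochastic designs.
#' @param trajectory_path trajectory CSV (required for `SNAPSHOT` and
#'   `INTERVENTION`).
#' @return invisibly, a list describing the produced artefacts.
#' @export
run_settings <- function(settings, seed = 1L, trajectory_path = NULL) {
  if (is.character(settings)) settings <- parse_settings(settings)
  abort_if(!inherits(settings, "run_settings"), "invalid settings object")
  base <- parse_model(settings$model_path)
  dir.create(settings$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (settings$technique %in% c("LOCAL", "LHS", "EFAST")) {
    design <- switch(settings$technique,
      LOCAL = local_sweep(settings$ranges, settings$local_increments),
      LHS = lhs_sample(settings$ranges, settings$lhs_samples, seed = seed),
      EFAST = efast_sample(settings$ranges,
                           settings$efast_samples_per_curve,
                           settings$efast_curves, seed = seed))
    gen <- generate_models(base, design, output_dir = settings$output_dir)
    write_sample_set(design, file.path(settings$output_dir, "design.csv"))
    return(invisible(list(technique = settings$technique, design = design,
                          manifest = gen$manifest)))
  }
  abort_if(is.null(trajectory_path),
           settings$technique, " requires a trajectory CSV")
  traj <- read_trajectory(trajectory_path)
  snap <- snapshot_from_trajectory(base, traj, "auto")
  if (settings$technique == "INTERVENTION") {
    final <- trajectory_row(traj, traj$times[length(traj$times)])
    snap <- apply_interventions(snap, settings$interventions, final)
  }
  out_file <- file.path(settings$output_dir,
                        paste0(base$model_id, "_",
                               tolower(settings$technique), ".xml"))
  write_model(snap, out_file)
  invisible(list(technique = settings$technique, file = out_file,
                 model = snap))
}
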