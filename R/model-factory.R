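# Turning designs and solver output into SBML files: perturbed ensembles,
# state snapshots, and intervention models.

#' Describe a biological intervention
#'
#' An intervention alters one parameter or species initial concentration of
#' a snapshotted model, either to a discrete new value (`SET`) or to a
#' multiple of the value that quantity had in the solver's final state
#' (`SCALE`).
#'
#' @param target_id identifier of the altered quantity.
#' @param target_kind `"parameter"` or `"species_initial"`.
#' @param mode `"SET"` or `"SCALE"`.
#' @param magnitude new value (`SET`, finite) or positive multiplicative
#'   factor (`SCALE`).
#' @return an object of class `intervention`.
#' @export
intervention <- function(target_id,
                         target_kind = c("species_initial", "parameter"),
                         mode = c("SET", "SCALE"), magnitude) {
  target_kind <- match.arg(target_kind)
  mode <- match.arg(mode)
  abort_if(!is_scalar_num(magnitude), "magnitude must be a finite scalar")
  abort_if(mode == "SCALE" && magnitude <= 0, "SCALE magnitude must be > 0")
  structure(list(target_id = target_id, target_kind = target_kind,
                 mode = mode, magnitude = magnitude),
            class = "intervention")
}

#' Generate one perturbed model per design row
#'
#' Each output document differs from `base` only in the designed targets.
#' The operation is atomic: if any design column fails to resolve in the
#' base model, no document is produced.
#'
#' @param base a `model_document`.
#' @param design a `sample_set`.
#' @param output_dir optional directory; when given every model is written
#'   as `<model_id>_<technique>_<row>.xml` together with `manifest.csv`.
#' @return list with `models` (list of `model_document`) and `manifest`
#'   (data.frame: `filename`, then one column per designed target).
#' @export
generate_models <- function(base, design, output_dir = NULL) {
  validate_model(base)
  abort_if(!inherits(design, "sample_set"), "design must be a sample_set")
  known <- c(base$parameters$id, base$species$id)
  missing <- setdiff(design$targets, known)
  abort_if(length(missing) > 0,
           "design column(s) not in model: ", paste(missing, collapse = ", "),
           " (no files emitted)")
  nr <- nrow(design$values)
  fnames <- sprintf("%s_%s_%d.xml", base$model_id,
                    tolower(design$technique), seq_len(nr))
  models <- vector("list", nr)
  for (i in seq_len(nr)) {
    doc <- base
    for (j in seq_along(design$targets)) {
      doc <- set_value(doc, design$targets[j], design$values[i, j])
    }
    models[[i]] <- doc
  }
  manifest <- data.frame(filename = fnames,
                         as.data.frame(design$values),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nr == 0) {
    manifest <- data.frame(filename = character(0))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nr)) {
      write_model(models[[i]], file.path(output_dir, fnames[i]))
    }
    utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(models = models, manifest = manifest)
}

#' Snapshot a solved model state into a new SBML document
#'
#' Produces a copy of `base` whose species initial concentrations (and any
#' non-constant parameters present as trajectory columns) are set to the
#' trajectory values at `at_time`. `at_time = "auto"` selects the last time
#' point, so interventions can be added wherever the steady state happens
#' to occur. The selected time is recorded in the document's annotations.
#'
#' @param base a `model_document`.
#' @param traj a `trajectory` covering every non-boundary species of `base`.
#' @param at_time numeric time on the trajectory grid, or `"auto"`.
#' @return a new `model_document`.
#' @export
snapshot_from_trajectory <- function(base, traj, at_time = "auto") {
  validate_model(base)
  abort_if(!inherits(traj, "trajectory"), "traj must be a trajectory")
  need <- base$species$id[!base$species$boundary]
  missing <- setdiff(need, colnames(traj$values))
  abort_if(length(missing) > 0,
           "species missing from trajectory: ", paste(missing, collapse = ", "))
  if (identical(at_time, "auto") || identical(at_time, "AUTO")) {
    at_time <- traj$times[length(traj$times)]
  } else {
    abort_if(!is_scalar_num(at_time), "at_time must be numeric or \"auto\"")
    abort_if(at_time < traj$times[1] || at_time > traj$times[length(traj$times)],
             "at_time ", at_time, " outside trajectory span [",
             traj$times[1], ", ", traj$times[length(traj$times)], "]")
  }
  state <- trajectory_row(traj, at_time)
  doc <- base
  for (sid in intersect(colnames(traj$values), doc$species$id)) {
    doc$species$initial[doc$species$id == sid] <- state[[sid]]
  }
  for (pid in intersect(colnames(traj$values), doc$parameters$id)) {
    doc$parameters$value[doc$parameters$id == pid] <- state[[pid]]
  }
  doc$annotations$snapshot_time <- at_time
  validate_model(doc)
  doc
}

#' Apply interventions to a snapshotted model
#'
#' `SET` targets take the intervention magnitude verbatim; `SCALE` targets
#' take `final_state[target] * magnitude`, where `final_state` is the
#' solver's final state row (as returned by [trajectory_row()] or the last
#' row of the trajectory the snapshot came from). All other fields are
#' untouched and the interventions are recorded in the document
#' annotations.
#'
#' @param snapshot a `model_document` (normally from
#'   [snapshot_from_trajectory()]).
#' @param interventions list of [intervention()] objects.
#' @param final_state named numeric vector; required for `SCALE`.
#' @return a new `model_document`.
#' @export
apply_interventions <- function(snapshot, interventions, final_state = NULL) {
  validate_model(snapshot)
  doc <- snapshot
  applied <- doc$annotations$interventions %||% list()
  for (iv in interventions) {
    abort_if(!inherits(iv, "intervention"), "expected intervention objects")
    value <- if (iv$mode == "SET") {
      iv$magnitude
    } else {
      abort_if(is.null(final_state) || !iv$target_id %in% names(final_state),
               "SCALE intervention target '", iv$target_id,
               "' absent from final state")
      final_state[[iv$target_id]] * iv$magnitude
    }
    doc <- set_value(doc, iv$target_id, value)
    applied <- c(applied, list(iv))
  }
  doc$annotations$interventions <- applied
  doc
}

#' Sweep a single intervention target over a set of values
#'
#' One model per value, `SET` semantics — e.g. ten log-spaced initial
#' cytokine concentrations to probe robustness of a response.
#'
#' @param snapshot a `model_document`.
#' @param target identifier of the swept parameter or species.
#' @param values non-empty numeric vector of values.
#' @return list of `model_document`, one per value.
#' @export
intervention_sweep <- function(snapshot, target, values) {
  abort_if(length(values) == 0, "values must be non-empty")
  kind <- if (target %in% snapshot$parameters$id) "parameter"
          else "species_initial"
  lapply(values, function(v) {
    apply_interventions(snapshot,
                        list(intervention(target, kind, "SET", v)))
  })
}
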