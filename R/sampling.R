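# Parameter-value designs: one-at-a-time local sweeps, latin-hypercube
# samples, and eFAST sinusoidal search curves.

#' Declare a perturbation range for one parameter or species initial
#'
#' @param target_id identifier of the perturbed quantity.
#' @param min,max range bounds, `min < max`.
#' @param baseline optional baseline value inside `[min, max]`; required by
#'   local sweeps.
#' @param target_kind `"parameter"` or `"species_initial"`.
#' @return an object of class `parameter_range`.
#' @export
parameter_range <- function(target_id, min, max, baseline = NULL,
                            target_kind = c("parameter", "species_initial")) {
  target_kind <- match.arg(target_kind)
  abort_if(!is_scalar_num(min) || !is_scalar_num(max) || min >= max,
           "range for '", target_id, "' must have min < max")
  if (!is.null(baseline)) {
    abort_if(!is_scalar_num(baseline) || baseline < min || baseline > max,
             "baseline for '", target_id, "' must lie in [min, max]")
  }
  structure(list(target_id = target_id, target_kind = target_kind,
                 min = min, max = max, baseline = baseline),
            class = "parameter_range")
}

ranges_df <- function(ranges) {
  abort_if(length(ranges) == 0, "at least one parameter range is required")
  data.frame(
    target_id = vapply(ranges, `[[`, character(1), "target_id"),
    target_kind = vapply(ranges, `[[`, character(1), "target_kind"),
    min = vapply(ranges, `[[`, numeric(1), "min"),
    max = vapply(ranges, `[[`, numeric(1), "max"),
    baseline = vapply(ranges, function(r) r$baseline %||% NA_real_,
                      numeric(1)),
    stringsAsFactors = FALSE)
}

new_sample_set <- function(technique, targets, values, seed = NA_integer_,
                           ranges = NULL, efast_meta = NULL,
                           local_meta = NULL) {
  colnames(values) <- targets
  structure(list(technique = technique, targets = targets, values = values,
                 seed = seed, ranges = ranges, efast_meta = efast_meta,
                 local_meta = local_meta),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", x$technique, ": ", nrow(x$values), " rows x ",
      ncol(x$values), " targets (", paste(x$targets, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' One-at-a-time local sensitivity design
#'
#' Each range in turn becomes the factor of interest and is assigned
#' `increments` evenly spaced values across `[min, max]` (endpoints
#' included) while every other target is held at its baseline.
#'
#' @param ranges list of [parameter_range()] objects, each with a baseline.
#' @param increments number of values per factor (>= 1; a single increment
#'   degenerates to the minimum and warns).
#' @return a `sample_set` with `sum(increments)` rows; `local_meta$factor`
#'   records the factor of interest of each row.
#' @export
local_sweep <- function(ranges, increments = 10) {
  abort_if(!is_count(increments), "increments must be a positive integer")
  rdf <- ranges_df(ranges)
  abort_if(anyNA(rdf$baseline),
           "local_sweep requires a baseline for every range (missing: ",
           paste(rdf$target_id[is.na(rdf$baseline)], collapse = ", "), ")")
  if (increments == 1) {
    warning("increments = 1 degenerates to the range minimum", call. = FALSE)
  }
  k <- nrow(rdf)
  rows <- matrix(rep(rdf$baseline, each = k * increments),
                 nrow = k * increments, ncol = k)
  factor_of <- character(k * increments)
  for (j in seq_len(k)) {
    vals <- if (increments == 1) rdf$min[j] else {
      seq(rdf$min[j], rdf$max[j], length.out = increments)
    }
    idx <- (j - 1) * increments + seq_len(increments)
    rows[idx, j] <- vals
    factor_of[idx] <- rdf$target_id[j]
  }
  new_sample_set("LOCAL", rdf$target_id, rows, ranges = rdf,
                 local_meta = list(factor = factor_of,
                                   increments = increments))
}

#' Latin-hypercube sample
#'
#' Stratified random design: for each target, `[min, max]` is divided into
#' `n` equal-width strata; each stratum receives exactly one value, the
#' stratum order is an independent random permutation per column, and the
#' within-stratum position is uniform.
#'
#' @param ranges list of [parameter_range()] objects.
#' @param n number of samples (>= 2).
#' @param seed integer seed; the same seed reproduces the same design.
#' @return a `sample_set` with `n` rows.
#' @export
lhs_sample <- function(ranges, n, seed = 1L) {
  abort_if(!is_count(n) || n < 2, "n must be an integer >= 2")
  rdf <- ranges_df(ranges)
  k <- nrow(rdf)
  u <- with_seed(seed, {
    vapply(seq_len(k), function(j) {
      (sample.int(n) - stats::runif(n)) / n
    }, numeric(n))
  })
  rows <- sweep(sweep(u, 2, rdf$max - rdf$min, "*"), 2, rdf$min, "+")
  new_sample_set("LHS", rdf$target_id, rows, seed = as.integer(seed),
                 ranges = rdf)
}

#' eFAST sinusoidal search-curve design
#'
#' For each factor of interest `i` and each resample curve, a block of
#' `samples_per_curve` rows is generated in which factor `i` follows the
#' high frequency `omega_max = floor((samples_per_curve - 1) / (2 * M))`
#' (interference factor `M = 4`) and every complementary factor follows a
#' low, distinct-as-possible frequency `<= omega_max / (2 * M)`, via the
#' search-curve transform
#' `x_j(s) = min_j + (max_j - min_j) * (1/2 + asin(sin(w_j * s + phi_jc)) / pi)`
#' over `s` equally spaced in `(-pi, pi]`. Phase offsets `phi_jc` are drawn
#' uniformly per factor and curve under `seed`.
#'
#' @param ranges list of [parameter_range()] objects.
#' @param samples_per_curve odd integer >= 65.
#' @param curves number of resample curves (random phase shifts).
#' @param include_dummy add a dummy factor (uniform on \[0, 1\]) used as the
#'   significance floor in the analysis. Default `TRUE`.
#' @param seed integer seed.
#' @param M interference factor (harmonics attributed to a frequency).
#' @return a `sample_set` with `k * curves * samples_per_curve` rows where
#'   `k` counts the dummy if present; `efast_meta$blocks` records, per
#'   block, the factor of interest, curve index, row range, frequencies and
#'   phases.
#' @export
efast_sample <- function(ranges, samples_per_curve = 65, curves = 3,
                         include_dummy = TRUE, seed = 1L, M = 4) {
  abort_if(!is_count(samples_per_curve) || samples_per_curve %% 2 == 0,
           "samples_per_curve must be an odd integer")
  abort_if(samples_per_curve < 65, "samples_per_curve must be >= 65")
  abort_if(!is_count(curves), "curves must be a positive integer")
  rdf <- ranges_df(ranges)
  if (include_dummy) {
    rdf <- rbind(rdf, data.frame(target_id = "dummy",
                                 target_kind = "parameter",
                                 min = 0, max = 1, baseline = NA_real_))
  }
  k <- nrow(rdf)
  ns <- samples_per_curve
  omega_max <- floor((ns - 1) / (2 * M))
  abort_if(ns < 4 * omega_max + 1,
           "design error: samples_per_curve causes aliasing")
  omega_comp_max <- max(1, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(ns) - ns - 1) / ns

  phases <- with_seed(seed, {
    array(stats::runif(k * k * curves, 0, 2 * pi), dim = c(k, k, curves))
  })

  total <- k * curves * ns
  rows <- matrix(NA_real_, nrow = total, ncol = k)
  blocks <- vector("list", k * curves)
  bi <- 0L
  row0 <- 0L
  for (i in seq_len(k)) {
    # standard step pattern: complementary factors cycle 1..omega_comp_max
    omega <- rep(seq_len(omega_comp_max), length.out = k)
    omega[i] <- omega_max
    for (cv in seq_len(curves)) {
      phi <- phases[i, , cv]
      for (j in seq_len(k)) {
        x01 <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
        rows[row0 + seq_len(ns), j] <- rdf$min[j] +
          (rdf$max[j] - rdf$min[j]) * x01
      }
      bi <- bi + 1L
      blocks[[bi]] <- list(factor = rdf$target_id[i], curve = cv,
                           rows = row0 + seq_len(ns),
                           omega = stats::setNames(omega, rdf$target_id),
                           phases = stats::setNames(phi, rdf$target_id))
      row0 <- row0 + ns
    }
  }
  new_sample_set("EFAST", rdf$target_id, rows, seed = as.integer(seed),
                 ranges = rdf,
                 efast_meta = list(M = M, omega_max = omega_max,
                                   samples_per_curve = ns, curves = curves,
                                   include_dummy = include_dummy,
                                   blocks = blocks))
}

#' Write a sample set to CSV (+ JSON design sidecar)
#'
#' @param design a `sample_set`.
#' @param path CSV path; design metadata goes to `<path>.design.json`.
#' @export
write_sample_set <- function(design, path) {
  df <- as.data.frame(design$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(technique = design$technique, targets = design$targets,
               seed = design$seed)
  if (!is.null(design$efast_meta)) {
    em <- design$efast_meta
    meta$efast <- list(M = em$M, omega_max = em$omega_max,
                       samples_per_curve = em$samples_per_curve,
                       curves = em$curves, include_dummy = em$include_dummy)
  }
  if (!is.null(design$local_meta)) meta$local <- design$local_meta
  jsonlite::write_json(meta, paste0(path, ".design.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
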