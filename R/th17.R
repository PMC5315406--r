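# Th17/Th1 phenotype-switching case study.
#
# A CD4+ T cell is modelled by the mutual-inhibition / autoactivation
# dynamics of the lineage transcription factors T-bet (T, Th1) and
# RORgammat (R, Th17), driven by decaying polarising cytokines C1 and C17,
# extended with a hypothetical receptor X whose formation is driven by
# RORgammat. Receptor X binds a hypothetical cytokine CX into a complex XC
# which either promotes T-bet (PROMOTE_TBET, production term +a6) or
# inhibits RORgammat (INHIBIT_RORGT, saturable degradation term -a6).
#
# d T  /dt = beta1 + a1*T^2/((k1^2+T^2)*(1+R/k2))
#                  + a3*C1/((k3+C1)*(1+R/k4)) [+ a6*XC/(k10+XC)] - mu1*T
# d R  /dt = beta2 + a2*R^2/((k5^2+R^2)*(1+T/k6))
#                  + a4*C17/((k7+C17)*(1+T/k8))
#                  [- a6*R*XC/(k10+XC)] - mu2*R
# d C1 /dt = -mu3*C1          d C17/dt = -mu4*C17
# d X  /dt = a5*R/(k9+R) - b1*X*CX - mu7*X
# d XC /dt = b1*X*CX - mu8*XC
# d CX /dt = -b1*X*CX - mu9*CX
#
# The core T/R equations are a reconstruction in the established
# autoactivation + mutual-inhibition lineage; the receptor block mirrors
# receptor-upregulation models of Th1 commitment. Time unit: hours;
# concentrations in arbitrary units.

#' Default parameter set for the Th17/Th1 switching model
#'
#' One normative set, tuned (see `scratch`/vignette) so that: (i) with no
#' cytokines the model sits at its basal fixed point; (ii) a decaying C17
#' pulse polarises to a stable Th17 state; (iii) a subsequent C1 pulse does
#' not destabilise the Th17 state; (iv) under PROMOTE_TBET a CX pulse
#' drives a switch to an ex-Th17 (T-bet high) state, while under
#' INHIBIT_RORGT it causes only a transient RORgammat dip.
#'
#' @return named list of strictly positive rates and Hill constants.
#' @export
th17_default_params <- function() {
  list(
    # basal transcription and autoactivation of T-bet / RORgammat
    beta1 = 0.001, beta2 = 0.001,
    a1 = 1, a2 = 1,        # autoactivation max rates, 1/h
    k1 = 1, k5 = 1,        # autoactivation half-max levels
    k2 = 0.1, k6 = 0.1,    # mutual-inhibition constants
    # cytokine-driven induction
    a3 = 0.5, a4 = 0.5,    # max induction rates by C1 / C17
    k3 = 1, k7 = 1,        # cytokine half-max levels
    k4 = 0.01, k8 = 0.01,  # cross-inhibition of induction
    mu1 = 0.1, mu2 = 0.1,  # T-bet / RORgammat decay, 1/h
    mu3 = 0.05, mu4 = 0.05, # C1 / C17 decay
    # receptor X block
    a5 = 0.01,             # receptor X upregulation rate
    k9 = 1,                # RORgammat level at half-max X formation
    mu7 = 0.1,             # receptor X decay
    b1 = 1,                # X + CX binding rate
    mu8 = 0.01,            # X-CX complex decay
    mu9 = 0.01,            # CX decay
    a6 = 0.1,              # T-bet promotion / RORgammat inhibition rate
    k10 = 0.1              # XC level at half-max a6 effect
  )
}

th17_param_names <- function() names(th17_default_params())

RECEPTOR_BLOCK <- c("a5", "a6", "k9", "k10", "mu7", "mu8", "mu9", "b1")

#' Perturbation ranges for the receptor-X parameter block
#'
#' Ten-fold above and below each default (or supplied) value, the stated
#' procedure for exploring the unknown receptor kinetics.
#'
#' @param params parameter list, defaults to [th17_default_params()].
#' @param fold range half-width as a multiplicative factor.
#' @return list of [parameter_range()] objects for the receptor block.
#' @export
th17_receptor_ranges <- function(params = th17_default_params(), fold = 10) {
  lapply(RECEPTOR_BLOCK, function(nm) {
    v <- params[[nm]]
    parameter_range(nm, min = v / fold, max = v * fold, baseline = v)
  })
}

# basal fixed point of the cytokine-free system, by damped iteration
th17_baseline_state <- function(p) {
  T <- p$beta1 / p$mu1
  R <- p$beta2 / p$mu2
  for (i in 1:500) {
    Tn <- (p$beta1 + p$a1 * T^2 / ((p$k1^2 + T^2) * (1 + R / p$k2))) / p$mu1
    Rn <- (p$beta2 + p$a2 * R^2 / ((p$k5^2 + R^2) * (1 + T / p$k6))) / p$mu2
    if (abs(Tn - T) < 1e-15 && abs(Rn - R) < 1e-15) {
      T <- Tn; R <- Rn
      break
    }
    T <- Tn; R <- Rn
  }
  X <- p$a5 * R / (p$k9 + R) / p$mu7
  c(T = T, R = R, C1 = 0, C17 = 0, X = X, XC = 0, CX = 0)
}

#' Build the Th17/Th1 switching model as an SBML document
#'
#' Species start at the basal (cytokine-free) fixed point so that an
#' unstimulated solve is flat; stimulation is applied downstream as a
#' snapshot + intervention, never inside the model itself.
#'
#' @param params named list of strictly positive parameters; see
#'   [th17_default_params()].
#' @param variant `"PROMOTE_TBET"` (complex XC adds a T-bet production term
#'   `+a6*XC/(k10+XC)`) or `"INHIBIT_RORGT"` (XC adds a RORgammat
#'   degradation term `-a6*R*XC/(k10+XC)`).
#' @return a `model_document` (SBML L3V2).
#' @export
build_th17_model <- function(params = th17_default_params(),
                             variant = c("PROMOTE_TBET", "INHIBIT_RORGT")) {
  variant <- match.arg(variant)
  need <- th17_param_names()
  missing <- setdiff(need, names(params))
  abort_if(length(missing) > 0,
           "missing parameter(s): ", paste(missing, collapse = ", "))
  vals <- unlist(params[need])
  abort_if(any(!is.finite(vals) | vals <= 0),
           "all parameters must be strictly positive: ",
           paste(need[!is.finite(vals) | vals <= 0], collapse = ", "))
  p <- as.list(vals)
  y0 <- th17_baseline_state(p)

  sp <- data.frame(
    id = names(y0), compartment = "cell", initial = as.numeric(y0),
    boundary = FALSE, stringsAsFactors = FALSE)
  pars <- data.frame(id = need, value = as.numeric(vals), constant = TRUE,
                     stringsAsFactors = FALSE)
  no_sp <- data.frame(species = character(), stoich = numeric())
  prod1 <- function(id) data.frame(species = id, stoich = 1)
  rx <- function(id, reactants, products, law) {
    list(id = id, reactants = reactants, products = products,
         kinetic_law = law)
  }
  reactions <- list(
    rx("T_basal", no_sp, prod1("T"), quote(beta1)),
    rx("T_auto", no_sp, prod1("T"),
       quote(a1 * T^2 / ((k1^2 + T^2) * (1 + R / k2)))),
    rx("T_induction", no_sp, prod1("T"),
       quote(a3 * C1 / ((k3 + C1) * (1 + R / k4)))),
    rx("T_decay", prod1("T"), no_sp, quote(mu1 * T)),
    rx("R_basal", no_sp, prod1("R"), quote(beta2)),
    rx("R_auto", no_sp, prod1("R"),
       quote(a2 * R^2 / ((k5^2 + R^2) * (1 + T / k6)))),
    rx("R_induction", no_sp, prod1("R"),
       quote(a4 * C17 / ((k7 + C17) * (1 + T / k8)))),
    rx("R_decay", prod1("R"), no_sp, quote(mu2 * R)),
    rx("C1_decay", prod1("C1"), no_sp, quote(mu3 * C1)),
    rx("C17_decay", prod1("C17"), no_sp, quote(mu4 * C17)),
    rx("X_upregulation", no_sp, prod1("X"), quote(a5 * R / (k9 + R))),
    rx("X_decay", prod1("X"), no_sp, quote(mu7 * X)),
    rx("X_CX_binding",
       data.frame(species = c("X", "CX"), stoich = c(1, 1)),
       prod1("XC"), quote(b1 * X * CX)),
    rx("XC_decay", prod1("XC"), no_sp, quote(mu8 * XC)),
    rx("CX_decay", prod1("CX"), no_sp, quote(mu9 * CX))
  )
  reactions <- c(reactions, list(
    if (variant == "PROMOTE_TBET") {
      rx("Tbet_promotion", no_sp, prod1("T"),
         quote(a6 * XC / (k10 + XC)))
    } else {
      rx("RORgt_inhibition", prod1("R"), no_sp,
         quote(a6 * R * XC / (k10 + XC)))
    }))

  doc <- model_document(
    model_id = paste0("th17_", tolower(sub("_.*", "", variant))),
    level_version = "L3V2",
    compartments = data.frame(id = "cell", size = 1),
    species = sp, parameters = pars, reactions = reactions)
  doc$annotations$variant <- variant
  doc
}

#' Classify the polarisation phenotype of a trajectory
#'
#' A cell is polarised when a transcription factor is stably expressed
#' above baseline: `above = level > fold_threshold * baseline` at the
#' evaluation time (the detected steady state, falling back to the final
#' time with a warning). Labels: neither above — `UNPOLARISED`; RORgammat
#' only — `TH17`; both — `DOUBLE_POSITIVE`; T-bet only — `TH1`, or
#' `EX_TH17` when the cell's history (earlier in this trajectory, or the
#' `history` argument spanning earlier pipeline stages) contains a Th17
#' state.
#'
#' @param traj a `trajectory` with columns `T` and `R`.
#' @param baselines numeric `c(T0, R0)`, strictly positive.
#' @param fold_threshold fold change over baseline counted as expression
#'   (default 2).
#' @param history character vector of labels from earlier pipeline stages.
#' @param eval_time `"steady"` (default), `"end"`, or a numeric time.
#' @return a `phenotype_call`: list with `label`, `T_level`, `R_level`,
#'   `baselines`, `time`.
#' @export
classify_phenotype <- function(traj, baselines, fold_threshold = 2,
                               history = character(), eval_time = "steady") {
  abort_if(length(baselines) != 2 || any(!is.finite(baselines)) ||
             any(baselines <= 0), "baselines must be two positive numbers")
  abort_if(!all(c("T", "R") %in% colnames(traj$values)),
           "trajectory must contain species T and R")
  t_eval <- if (identical(eval_time, "steady")) {
    span <- diff(range(traj$times))
    ts <- detect_steady_state(traj, window = 0.1 * span, rel_tol = 1e-3)
    if (is.na(ts)) {
      warning("no steady state detected; classifying at the final time",
              call. = FALSE)
      traj$times[length(traj$times)]
    } else {
      # classify at the settled value, i.e. the end of the steady stretch
      traj$times[length(traj$times)]
    }
  } else if (identical(eval_time, "end")) {
    traj$times[length(traj$times)]
  } else {
    eval_time
  }
  idx <- which.min(abs(traj$times - t_eval))
  T_level <- traj$values[idx, "T"]
  R_level <- traj$values[idx, "R"]
  above_T <- T_level > fold_threshold * baselines[1]
  above_R <- R_level > fold_threshold * baselines[2]
  prior_th17 <- "TH17" %in% history ||
    any(traj$values[seq_len(idx), "R"] > fold_threshold * baselines[2] &
          traj$values[seq_len(idx), "T"] <= fold_threshold * baselines[1])
  label <- if (!above_T && !above_R) {
    "UNPOLARISED"
  } else if (above_T && above_R) {
    "DOUBLE_POSITIVE"
  } else if (!above_T && above_R) {
    "TH17"
  } else if (prior_th17) {
    "EX_TH17"
  } else {
    "TH1"
  }
  structure(list(label = label, T_level = unname(T_level),
                 R_level = unname(R_level),
                 baselines = stats::setNames(baselines, c("T0", "R0")),
                 fold_threshold = fold_threshold, time = traj$times[idx]),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("<phenotype_call> ", x$label, " (T = ", signif(x$T_level, 4),
      ", R = ", signif(x$R_level, 4), " at t = ", x$time, ")\n", sep = "")
  invisible(x)
}

# One full intervention pipeline for a single parameter set:
# baseline solve -> snapshot -> +C17 -> solve -> snapshot -> +CX -> solve.
th17_pipeline <- function(params, variant, c17_dose = 100, cx_dose = 100,
                          t_end = 144, step = 0.12, fold_threshold = 2) {
  doc <- build_th17_model(params, variant)
  baselines <- c(get_value(doc, "T"), get_value(doc, "R"))
  traj0 <- solve_model(doc, t_end, step)
  snap0 <- snapshot_from_trajectory(doc, traj0, "auto")
  stim17 <- apply_interventions(
    snap0, list(intervention("C17", "species_initial", "SET", c17_dose)))
  traj17 <- solve_model(stim17, t_end, step)
  call17 <- classify_phenotype(traj17, baselines, fold_threshold,
                               eval_time = "end")
  snap17 <- snapshot_from_trajectory(stim17, traj17, "auto")
  stimx <- apply_interventions(
    snap17, list(intervention("CX", "species_initial", "SET", cx_dose)))
  trajx <- solve_model(stimx, t_end, step)
  callx <- classify_phenotype(trajx, baselines, fold_threshold,
                              history = call17$label, eval_time = "end")
  list(doc = doc, baselines = baselines,
       traj0 = traj0, traj17 = traj17, trajx = trajx,
       snap0 = snap0, snap17 = snap17,
       call17 = call17, callx = callx)
}

# earliest grid time (measured from CX addition) after which the ex-Th17
# condition (T above, R not above) holds through the end of the trajectory
time_to_switch <- function(traj, baselines, fold_threshold = 2) {
  above_T <- traj$values[, "T"] > fold_threshold * baselines[1]
  above_R <- traj$values[, "R"] > fold_threshold * baselines[2]
  ex <- above_T & !above_R
  if (!ex[length(ex)]) return(NA_real_)
  runs <- rev(cumprod(rev(ex)))
  traj$times[which(runs == 1)[1]]
}

#' Run the phenotype-switching ensemble experiment
#'
#' Latin-hypercube samples the receptor-block parameters (ten-fold above
#' and below their defaults), and for each set runs the full intervention
#' pipeline: build the variant model, solve 144 h (step 0.12), snapshot,
#' stimulate with C17, solve to a stable Th17 state, snapshot again,
#' stimulate with CX, solve, and classify. A model "switched" when the
#' final call is `EX_TH17`.
#'
#' @param n_sets number of parameter sets (0 gives an empty report).
#' @param ranges list of [parameter_range()]s; default
#'   [th17_receptor_ranges()].
#' @param variant `"PROMOTE_TBET"` or `"INHIBIT_RORGT"`.
#' @param seed integer seed for the latin-hypercube design.
#' @param params core parameter set; default [th17_default_params()].
#' @param c17_dose,cx_dose stimulus concentrations (SET interventions).
#' @param t_end,step solve horizon and output step per stage.
#' @return a `switch_report`: data.frame with one row per set (`set`,
#'   `th17_established`, `switched`, `time_to_switch`, `error`), with
#'   attributes `n_switched`, `n_not_switched`, `variant`, `design`.
#' @export
run_switching_experiment <- function(n_sets,
                                     ranges = th17_receptor_ranges(),
                                     variant = c("PROMOTE_TBET",
                                                 "INHIBIT_RORGT"),
                                     seed = 1L,
                                     params = th17_default_params(),
                                     c17_dose = 100, cx_dose = 100,
                                     t_end = 144, step = 0.12) {
  variant <- match.arg(variant)
  abort_if(!is.numeric(n_sets) || n_sets < 0 || n_sets != floor(n_sets),
           "n_sets must be a non-negative integer")
  if (n_sets == 0) {
    rep0 <- data.frame(set = integer(), th17_established = logical(),
                       switched = logical(), time_to_switch = numeric(),
                       error = character(), stringsAsFactors = FALSE)
    return(structure(rep0, class = c("switch_report", "data.frame"),
                     n_switched = 0L, n_not_switched = 0L,
                     variant = variant, design = NULL))
  }
  design <- lhs_sample(ranges, n = max(2, n_sets), seed = seed)
  rows <- design$values[seq_len(n_sets), , drop = FALSE]
  out <- data.frame(set = seq_len(n_sets), th17_established = NA,
                    switched = NA, time_to_switch = NA_real_,
                    error = "", stringsAsFactors = FALSE)
  for (i in seq_len(n_sets)) {
    pi <- params
    pi[colnames(rows)] <- as.list(rows[i, ])
    res <- tryCatch({
      pl <- th17_pipeline(pi, variant, c17_dose, cx_dose, t_end, step)
      est <- pl$call17$label == "TH17"
      sw <- est && pl$callx$label == "EX_TH17"
      list(est = est, sw = sw,
           tts = if (sw) time_to_switch(pl$trajx, pl$baselines) else NA_real_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      out$th17_established[i] <- FALSE
      out$switched[i] <- FALSE
    } else {
      out$th17_established[i] <- res$est
      out$switched[i] <- res$sw
      out$time_to_switch[i] <- res$tts
    }
  }
  structure(out, class = c("switch_report", "data.frame"),
            n_switched = sum(out$switched, na.rm = TRUE),
            n_not_switched = sum(!out$switched, na.rm = TRUE),
            variant = variant, design = design)
}

#' @export
print.switch_report <- function(x, ...) {
  cat("<switch_report> ", attr(x, "variant"), ": ",
      attr(x, "n_switched"), " switched / ",
      attr(x, "n_not_switched"), " not switched (n = ", nrow(x), ")\n",
      sep = "")
  invisible(x)
}

#' Robustness of the phenotype switch to the CX dose
#'
#' Polarises one parameter set to a stable Th17 state, then applies each
#' CX concentration as a separate SET intervention and asks whether every
#' dose still drives the switch.
#'
#' @param params parameter set, default [th17_default_params()] (which
#'   switches at the reference dose under `PROMOTE_TBET`).
#' @param cx_values CX doses; default ten log-spaced values in
#'   \[10, 10000\].
#' @param variant model variant, default `"PROMOTE_TBET"`.
#' @param t_end,step solve horizon and output step per stage.
#' @param keep_trajectories return the post-CX trajectories too.
#' @return list with `all_switched` (flag), `calls` (data.frame `cx`,
#'   `label`, `switched`) and optionally `trajectories`.
#' @export
robustness_sweep <- function(params = th17_default_params(),
                             cx_values = 10^seq(1, 4, length.out = 10),
                             variant = "PROMOTE_TBET",
                             t_end = 144, step = 0.12,
                             keep_trajectories = FALSE) {
  abort_if(length(cx_values) == 0, "cx_values must be non-empty")
  doc <- build_th17_model(params, variant)
  baselines <- c(get_value(doc, "T"), get_value(doc, "R"))
  traj0 <- solve_model(doc, t_end, step)
  snap0 <- snapshot_from_trajectory(doc, traj0, "auto")
  stim17 <- apply_interventions(
    snap0, list(intervention("C17", "species_initial", "SET", 100)))
  traj17 <- solve_model(stim17, t_end, step)
  call17 <- classify_phenotype(traj17, baselines, eval_time = "end")
  abort_if(call17$label != "TH17",
           "parameter set failed to polarise to Th17 before the sweep")
  snap17 <- snapshot_from_trajectory(stim17, traj17, "auto")
  models <- intervention_sweep(snap17, "CX", cx_values)
  calls <- data.frame(cx = cx_values, label = NA_character_,
                      switched = NA, stringsAsFactors = FALSE)
  trajs <- if (keep_trajectories) vector("list", length(models)) else NULL
  for (i in seq_along(models)) {
    tr <- solve_model(models[[i]], t_end, step)
    cl <- classify_phenotype(tr, baselines, history = "TH17",
                             eval_time = "end")
    calls$label[i] <- cl$label
    calls$switched[i] <- cl$label == "EX_TH17"
    if (keep_trajectories) trajs[[i]] <- tr
  }
  out <- list(all_switched = all(calls$switched), calls = calls)
  if (keep_trajectories) out$trajectories <- trajs
  out
}
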