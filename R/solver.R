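# Deterministic integration of a model_document's reaction network.
#
# The kinetic laws are compiled once into a vector-valued derivative
# function; integration is adaptive embedded Dormand-Prince 5(4) with
# PI step-size control, while the *output* grid is fixed at the caller's
# step (the grid is sampling, not integration: internal steps always land
# exactly on grid times, subdividing adaptively in between).

#' Compile a model's ODE right-hand side
#'
#' Builds `d[conc]/dt` for every non-boundary species as the
#' stoichiometry-weighted sum of reaction rates divided by the compartment
#' size. Boundary species and parameters enter as constants.
#'
#' @param doc a `model_document`.
#' @return a list with `state_ids`, `y0` (initial concentrations) and
#'   `rhs(t, y)`.
#' @keywords internal
compile_odes <- function(doc) {
  validate_model(doc)
  sp <- doc$species
  dyn <- sp$id[!sp$boundary]
  abort_if(length(dyn) == 0, "model has no non-boundary species")
  bnd <- sp[sp$boundary, , drop = FALSE]
  vol <- doc$compartments$size[match(sp$compartment, doc$compartments$id)]
  vol[is.na(vol)] <- 1
  names(vol) <- sp$id

  # symbolic net-rate expression per dynamic species
  terms <- stats::setNames(vector("list", length(dyn)), dyn)
  for (rx in doc$reactions) {
    law <- rx$kinetic_law
    contribute <- function(df, sign) {
      for (i in seq_len(NROW(df))) {
        sid <- df$species[i]
        if (!sid %in% dyn) next
        coef <- sign * df$stoich[i] / vol[[sid]]
        term <- if (coef == 1) law else call("*", coef, law)
        terms[[sid]] <<- if (is.null(terms[[sid]])) term else {
          call("+", terms[[sid]], term)
        }
      }
    }
    contribute(rx$reactants, -1)
    contribute(rx$products, +1)
  }
  dexprs <- lapply(terms, function(e) if (is.null(e)) 0 else e)
  # inline every constant (parameters, compartment sizes, boundary species)
  # and compile d/dt into a plain function of (t, y) for speed
  const <- c(stats::setNames(as.list(doc$parameters$value), doc$parameters$id),
             stats::setNames(as.list(doc$compartments$size),
                             doc$compartments$id),
             stats::setNames(as.list(bnd$initial), bnd$id))
  dexprs <- lapply(dexprs, substitute_symbols, values = const)
  assigns <- lapply(seq_along(dyn), function(i) {
    call("<-", as.name(dyn[i]), call("[[", quote(y), i))
  })
  fn_body <- as.call(c(quote(`{`), assigns,
                       list(as.call(c(quote(c), dexprs)))))
  rhs <- eval(call("function", as.pairlist(alist(t = , y = )), fn_body),
              envir = baseenv())
  list(state_ids = dyn,
       y0 = sp$initial[!sp$boundary],
       boundary = stats::setNames(bnd$initial, bnd$id),
       rhs = compiler::cmpfun(rhs))
}

# Dormand-Prince 5(4) Butcher tableau
DP_A <- matrix(0, 7, 7)
DP_A[2, 1] <- 1 / 5
DP_A[3, 1:2] <- c(3 / 40, 9 / 40)
DP_A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
DP_A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
DP_A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
                  -5103 / 18656)
DP_A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
DP_B5 <- DP_A[7, 1:7]
DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
           187 / 2100, 1 / 40)
DP_C <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

#' Integrate a model's ODE system on a fixed output grid
#'
#' Adaptive Dormand-Prince 5(4) integration with relative tolerance `1e-8`
#' and absolute tolerance `1e-10`; results are reported on the fixed grid
#' `0, step, 2*step, ..., t_end`. Boundary species are held at their
#' initial concentration and included in the output.
#'
#' @param doc a `model_document` whose reactions define a closed ODE system.
#' @param t_end end time (> 0), model time units.
#' @param step output grid spacing (> 0).
#' @param rtol,atol integration tolerances.
#' @return a `trajectory`: list with `times`, `values` (matrix, one column
#'   per species) and `meta`.
#' @examples
#' doc <- model_document("decay",
#'   species = data.frame(id = "S", compartment = "cell", initial = 1,
#'                        boundary = FALSE),
#'   reactions = list(list(id = "deg",
#'     reactants = data.frame(species = "S", stoich = 1),
#'     products = data.frame(species = character(), stoich = numeric()),
#'     kinetic_law = quote(1 * S))))
#' tr <- solve_model(doc, t_end = 1, step = 0.25)
#' tr$values[nrow(tr$values), "S"]  # ~ exp(-1)
#' @export
solve_model <- function(doc, t_end, step, rtol = 1e-8, atol = 1e-10) {
  abort_if(!is_scalar_num(t_end) || t_end <= 0, "t_end must be > 0")
  abort_if(!is_scalar_num(step) || step <= 0, "step must be > 0")
  sys <- compile_odes(doc)
  times <- seq(0, by = step, length.out = floor(t_end / step) + 1)
  n <- length(sys$y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n,
                dimnames = list(NULL, sys$state_ids))
  y <- sys$y0
  out[1, ] <- y
  f <- sys$rhs
  k1 <- f(0, y)
  abort_if(any(!is.finite(k1)), "non-finite derivative at t = 0")
  h <- step # initial guess, adapted immediately
  for (gi in seq_along(times)[-1]) {
    t0 <- times[gi - 1]
    t1 <- times[gi]
    t <- t0
    while (t < t1 - 1e-12 * t1) {
      h <- min(h, t1 - t)
      repeat {
        ks <- matrix(0, 7, n)
        ks[1, ] <- k1
        for (s in 2:7) {
          ys <- y + h * drop(DP_A[s, 1:(s - 1), drop = FALSE] %*%
                               ks[1:(s - 1), , drop = FALSE])
          ks[s, ] <- f(t + DP_C[s] * h, ys)
        }
        y5 <- y + h * drop(DP_B5 %*% ks)
        y4 <- y + h * drop(DP_B4 %*% ks)
        if (any(!is.finite(y5))) {
          h <- h / 2
          abort_if(h < 1e-14 * max(1, t),
                   "integration failure (non-finite state) near t = ",
                   signif(t, 6))
          next
        }
        sc <- atol + rtol * pmax(abs(y), abs(y5))
        err <- sqrt(mean(((y5 - y4) / sc)^2))
        if (err <= 1 || h <= 1e-14 * max(1, t)) {
          t <- t + h
          y <- y5
          k1 <- ks[7, ] # FSAL
          fac <- if (err > 0) 0.9 * err^(-0.2) else 5
          h <- h * min(5, max(0.2, fac))
          break
        }
        h <- h * max(0.2, 0.9 * err^(-0.2))
        abort_if(h < 1e-14 * max(1, t),
                 "integration failure (step underflow) at t = ",
                 signif(t, 6))
      }
    }
    out[gi, ] <- y
  }
  abort_if(any(!is.finite(out)), "non-finite values in trajectory")
  if (length(sys$boundary) > 0) {
    bmat <- matrix(rep(sys$boundary, each = length(times)),
                   nrow = length(times),
                   dimnames = list(NULL, names(sys$boundary)))
    out <- cbind(out, bmat)
  }
  trajectory(times, out,
             meta = list(step = step, method = "dopri5",
                         model_id = doc$model_id, rtol = rtol, atol = atol))
}

#' Construct a trajectory object
#'
#' @param times ascending numeric vector starting at 0.
#' @param values numeric matrix, one named column per species.
#' @param meta list of solver metadata.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(times, values, meta = list()) {
  values <- as.matrix(values)
  abort_if(length(times) != nrow(values),
           "times and values have different lengths")
  abort_if(any(diff(times) <= 0), "times must be strictly increasing")
  abort_if(any(!is.finite(values)), "trajectory contains non-finite values")
  abort_if(is.null(colnames(values)), "trajectory columns must be named")
  structure(list(times = as.numeric(times), values = values, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [",
      x$times[1], ", ", x$times[length(x$times)], "], species: ",
      paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as a solver-style CSV
#'
#' Dialect: comma separated, `.` decimal, mandatory header whose first
#' column is literally `time` followed by species ids.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV file with a `time` column and one column per species.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  abort_if(!"time" %in% names(df), "trajectory CSV must have a 'time' column")
  vals <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  trajectory(df$time, vals, meta = list(source = path))
}

#' Detect the earliest steady-state time of a trajectory
#'
#' Windowed sup-norm criterion: the earliest grid time `t*` such that, for
#' every species, the trajectory within `[t*, t* + window]` stays within
#' `rel_tol * max(|x(t*)|, floor)` of `x(t*)`, with `floor = 1e-9`.
#'
#' @param traj a `trajectory`.
#' @param window look-ahead window, same time units as the trajectory;
#'   must be shorter than the trajectory's span.
#' @param rel_tol relative tolerance.
#' @return the steady-state time, or `NA` if none is found.
#' @export
detect_steady_state <- function(traj, window, rel_tol = 1e-4) {
  span <- traj$times[length(traj$times)] - traj$times[1]
  abort_if(!is_scalar_num(window) || window <= 0 || window >= span,
           "window must lie strictly inside the trajectory span")
  floor_ <- 1e-9
  times <- traj$times
  vals <- traj$values
  last_start <- max(which(times <= times[length(times)] - window))
  for (i in seq_len(last_start)) {
    in_win <- times >= times[i] & times <= times[i] + window
    ref <- vals[i, ]
    tol <- rel_tol * pmax(abs(ref), floor_)
    dev <- abs(sweep(vals[in_win, , drop = FALSE], 2, ref, "-"))
    if (all(dev <= rep(tol, each = nrow(dev)))) return(times[i])
  }
  NA_real_
}

# value of every species at a given time (exact grid match required)
trajectory_row <- function(traj, at_time) {
  idx <- which(abs(traj$times - at_time) <= 1e-9 * max(1, abs(at_time)))
  abort_if(length(idx) == 0, "time ", at_time, " not on the trajectory grid")
  stats::setNames(traj$values[idx[1], ], colnames(traj$values))
}
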