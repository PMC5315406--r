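# Sensitivity statistics on solver responses joined to a sampling design.

#' Partial rank correlation coefficients for an LHS design
#'
#' For each designed target `x_j`, all design columns and the response are
#' rank-transformed; the PRCC is the correlation of the residuals after
#' linearly regressing `rank(x_j)` and `rank(y)` on the ranks of all other
#' targets. Significance uses the t approximation
#' `t = prcc * sqrt((n - 2 - (k - 1)) / (1 - prcc^2))` with
#' `n - 2 - (k - 1)` degrees of freedom (the `k - 1` other targets are the
#' controlled variables).
#'
#' @param design a `sample_set` from [lhs_sample()] with `n >= k + 3` rows.
#' @param responses data.frame of response measures aligned row-for-row
#'   with the design.
#' @param response name of the response column to analyse.
#' @param bonferroni multiply p-values by the number of targets (capped at
#'   1). Default `FALSE`: raw per-target p-values.
#' @return a `sensitivity_result` data.frame with columns `target`,
#'   `statistic` (PRCC in \[-1, 1\]), `p_value`, `note`.
#' @export
prcc <- function(design, responses, response, bonferroni = FALSE) {
  abort_if(!inherits(design, "sample_set"), "design must be a sample_set")
  abort_if(design$technique != "LHS", "PRCC requires an LHS design")
  X <- design$values
  n <- nrow(X)
  k <- ncol(X)
  abort_if(n < k + 3, "PRCC needs n >= k + 3 rows (have n = ", n,
           ", k = ", k, ")")
  y <- response_vector(design, responses, response)
  rY <- rank(y)
  rX <- apply(X, 2, rank)
  stat <- p <- rep(NA_real_, k)
  note <- rep("", k)
  dfree <- n - 2 - (k - 1)
  for (j in seq_len(k)) {
    if (length(unique(X[, j])) < 2) {
      note[j] <- "constant column: PRCC undefined"
      next
    }
    Z <- cbind(1, rX[, -j, drop = FALSE])
    rxj <- stats::lsfit(Z, rX[, j], intercept = FALSE)$residuals
    ryj <- stats::lsfit(Z, rY, intercept = FALSE)$residuals
    if (stats::sd(rxj) == 0 || stats::sd(ryj) == 0) {
      note[j] <- "degenerate residuals: PRCC undefined"
      next
    }
    r <- stats::cor(rxj, ryj)
    stat[j] <- r
    tval <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
    p[j] <- 2 * stats::pt(-abs(tval), df = dfree)
  }
  if (bonferroni) p <- pmin(1, p * k)
  sensitivity_result(
    data.frame(target = design$targets, statistic = stat, p_value = p,
               note = note, stringsAsFactors = FALSE),
    technique = "LHS", statistic = "PRCC", response = response)
}

response_vector <- function(design, responses, response) {
  responses <- as.data.frame(responses)
  abort_if(nrow(responses) != nrow(design$values),
           "responses have ", nrow(responses), " rows, design has ",
           nrow(design$values))
  abort_if(!response %in% names(responses),
           "no response column '", response, "'")
  y <- responses[[response]]
  abort_if(!is.numeric(y), "response must be numeric")
  abort_if(any(!is.finite(y)), "response contains non-finite values")
  y
}

sensitivity_result <- function(df, technique, statistic, response) {
  structure(df, class = c("sensitivity_result", "data.frame"),
            technique = technique, statistic = statistic,
            response = response)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", attr(x, "statistic"), " (",
      attr(x, "technique"), ") for response '", attr(x, "response"),
      "'\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' eFAST first-order and total-order sensitivity indices
#'
#' Per factor-of-interest block and resample curve, the response's Fourier
#' spectrum over the search-curve index is computed. The first-order index
#' `Si` is the variance at the factor's frequency and its first `M`
#' harmonics divided by total variance; the total-order index `STi` is one
#' minus the share of variance in the complementary low-frequency band
#' (frequencies up to `omega_max / 2`). Indices are averaged over curves;
#' each real factor's per-curve `Si`/`STi` samples are compared with the
#' dummy factor's by a two-sample t test.
#'
#' @param design a `sample_set` from [efast_sample()].
#' @param responses data.frame aligned row-for-row with the design.
#' @param response name of the response column.
#' @return a `sensitivity_result` data.frame with columns `target`, `Si`,
#'   `STi`, `p_Si_vs_dummy`, `p_STi_vs_dummy`, `note`.
#' @export
efast_indices <- function(design, responses, response) {
  abort_if(!inherits(design, "sample_set"), "design must be a sample_set")
  abort_if(design$technique != "EFAST" || is.null(design$efast_meta),
           "efast_indices requires an EFAST design with efast_meta")
  em <- design$efast_meta
  y <- response_vector(design, responses, response)
  targets <- design$targets
  k <- length(targets)
  si <- sti <- matrix(NA_real_, nrow = k, ncol = em$curves,
                      dimnames = list(targets, NULL))
  note <- rep("", k)
  for (b in em$blocks) {
    yb <- y[b$rows]
    if (stats::var(yb) == 0) {
      note[match(b$factor, targets)] <- "zero response variance in block"
      next
    }
    sp <- fourier_power(yb)
    v_total <- sum(sp)
    wmax <- em$omega_max
    harmonics <- (seq_len(em$M)) * wmax
    harmonics <- harmonics[harmonics <= length(sp)]
    v_first <- sum(sp[harmonics])
    low_band <- seq_len(max(1, floor(wmax / 2)))
    v_comp <- sum(sp[low_band])
    i <- match(b$factor, targets)
    si[i, b$curve] <- v_first / v_total
    sti[i, b$curve] <- 1 - v_comp / v_total
  }
  has_dummy <- isTRUE(em$include_dummy) && "dummy" %in% targets
  p_si <- p_sti <- rep(NA_real_, k)
  if (has_dummy && em$curves >= 2) {
    d <- match("dummy", targets)
    for (i in seq_len(k)) {
      if (i == d || anyNA(si[i, ])) next
      p_si[i] <- safe_t_test(si[i, ], si[d, ])
      p_sti[i] <- safe_t_test(sti[i, ], sti[d, ])
    }
  }
  sensitivity_result(
    data.frame(target = targets,
               Si = rowMeans(si), STi = rowMeans(sti),
               p_Si_vs_dummy = p_si, p_STi_vs_dummy = p_sti,
               note = note, stringsAsFactors = FALSE),
    technique = "EFAST", statistic = "Si/STi", response = response)
}

safe_t_test <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

# one-sided amplitude spectrum at integer frequencies 1 .. (n-1)/2;
# power_w approximates the variance contributed by frequency w
fourier_power <- function(y) {
  n <- length(y)
  s <- pi * (2 * seq_len(n) - n - 1) / n
  wmax <- (n - 1) %/% 2
  w <- seq_len(wmax)
  A <- (2 / n) * as.vector(cos(outer(w, s)) %*% y)
  B <- (2 / n) * as.vector(sin(outer(w, s)) %*% y)
  (A^2 + B^2) / 2
}

#' Response curves for a local one-at-a-time design
#'
#' @param design a `sample_set` from [local_sweep()].
#' @param responses data.frame aligned row-for-row with the design.
#' @param response name of the response column.
#' @return named list, one element per target: data.frame of sorted
#'   `(value, response)` pairs, with attribute `max_deviation` — the
#'   largest absolute deviation of the response from the baseline-value
#'   response.
#' @export
local_curves <- function(design, responses, response) {
  abort_if(!inherits(design, "sample_set") || design$technique != "LOCAL",
           "local_curves requires a LOCAL design")
  y <- response_vector(design, responses, response)
  out <- list()
  for (j in seq_along(design$targets)) {
    tid <- design$targets[j]
    idx <- which(design$local_meta$factor == tid)
    vals <- design$values[idx, j]
    ord <- order(vals)
    df <- data.frame(value = vals[ord], response = y[idx][ord])
    baseline_val <- design$ranges$baseline[j]
    base_resp <- df$response[which.min(abs(df$value - baseline_val))]
    attr(df, "baseline_value") <- baseline_val
    attr(df, "baseline_response") <- base_resp
    attr(df, "max_deviation") <- max(abs(df$response - base_resp))
    out[[tid]] <- df
  }
  out
}

#' Bar plot of a sensitivity result
#'
#' Minimal static rendering of PRCC or Si/STi values per target.
#'
#' @param height a `sensitivity_result`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_sensitivity <- function(height, ...) {
  if (identical(attr(height, "statistic"), "PRCC")) {
    graphics::barplot(height$statistic, names.arg = height$target,
                      ylim = c(-1, 1), ylab = "PRCC", las = 2, ...)
  } else {
    m <- t(as.matrix(height[, c("Si", "STi")]))
    graphics::barplot(m, beside = TRUE, names.arg = height$target,
                      ylim = c(0, 1), ylab = "Si / STi", las = 2,
                      legend.text = c("Si", "STi"), ...)
  }
  invisible(height)
}
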