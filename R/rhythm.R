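#' Construct a luminescence trace
#'
#' A bioluminescence recording: photomultiplier counts at strictly
#' increasing time points (hours; typically one reading every 10 minutes).
#'
#' @param time_h Numeric vector of times in hours, strictly increasing.
#' @param counts Numeric vector of luminescence counts, same length.
#' @param id Optional trace identifier.
#' @return Tibble of class `luminescence_trace` with columns `time_h`,
#'   `counts` (and attribute `id`).
#' @export
luminescence_trace <- function(time_h, counts, id = NULL) {
  stopifnot(length(time_h) == length(counts))
  if (any(diff(time_h) <= 0)) stop("time must be strictly increasing",
                                   call. = FALSE)
  out <- tibble::tibble(time_h = time_h, counts = counts)
  class(out) <- c("luminescence_trace", class(out))
  attr(out, "id") <- id
  out
}

restore_trace <- function(out, template) {
  class(out) <- c("luminescence_trace", setdiff(class(out),
                                                "luminescence_trace"))
  attr(out, "id") <- attr(template, "id")
  out
}

#' Read a delimited luminescence trace
#'
#' Expects columns `time_h` and `counts` (tab- or comma-delimited).
#'
#' @param path File path.
#' @param id Optional trace id (defaults to the file name).
#' @return A `luminescence_trace`.
#' @export
read_trace <- function(path, id = basename(path)) {
  df <- suppressMessages(readr::read_delim(path, show_col_types = FALSE))
  stopifnot(all(c("time_h", "counts") %in% names(df)))
  luminescence_trace(df$time_h, df$counts, id = id)
}

#' Subtract the photomultiplier background
#'
#' Removes a constant per-channel background level (measured by averaging a
#' blank recording). Negative values are retained (no flooring at zero).
#'
#' @param trace A `luminescence_trace`.
#' @param background Background level in counts.
#' @return Corrected `luminescence_trace`.
#' @export
background_correct <- function(trace, background) {
  out <- trace
  out$counts <- trace$counts - background
  restore_trace(out, trace)
}

#' Discard the initial transient
#'
#' Removes all points recorded before `hours` (points with
#' `time_h >= hours` are kept; the boundary point is retained). Time is not
#' re-zeroed.
#'
#' @param trace A `luminescence_trace`.
#' @param hours Hours to discard from the start of the recording (default
#'   10).
#' @return Trimmed `luminescence_trace`.
#' @export
trim_initial <- function(trace, hours = 10) {
  keep <- trace$time_h >= hours
  if (!any(keep)) stop("empty-result error: trace shorter than ", hours,
                       " h", call. = FALSE)
  restore_trace(trace[keep, ], trace)
}

#' Subtract a centered running-average baseline
#'
#' Detrends the trace by subtracting a centered running mean whose window
#' spans `window_h` hours (default 24, about one circadian period). Near the
#' edges the window shrinks symmetrically to the available points.
#'
#' @param trace A `luminescence_trace`.
#' @param window_h Window width in hours.
#' @return Detrended `luminescence_trace` with an extra column `baseline`.
#' @export
baseline_subtract <- function(trace, window_h = 24) {
  t <- trace$time_h; y <- trace$counts
  W <- running_mean_operator(t, window_h)
  base <- as.vector(W %*% y)
  out <- trace
  out$counts <- y - base
  out$baseline <- base
  out <- restore_trace(out, trace)
  attr(out, "detrend_window") <- window_h
  out
}

# Linear operator of the centered running mean with symmetric edge
# shrinkage; row i averages the points within the largest half-width
# available on both sides of t[i] (up to window/2).
running_mean_operator <- function(t, window_h) {
  n <- length(t)
  half <- window_h / 2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- min(half, t[i] - t[1], t[n] - t[i])
    ix <- which(t >= t[i] - h & t <= t[i] + h)
    W[i, ix] <- 1 / length(ix)
  }
  W
}

#' Fit a damped sine wave to a detrended trace
#'
#' Least-squares fit of \eqn{A e^{-d t} \sin(2\pi t / T + \varphi)} to the
#' detrended counts. When the trace was detrended by [baseline_subtract()],
#' the model is passed through the same running-average subtraction before
#' comparison with the data, so the detrending operator introduces no period
#' bias (it is linear, and data and model are filtered identically).
#' Starting values come from the periodogram peak (period) and the trace's
#' spread (amplitude); the phase start is chosen from a coarse grid.
#' Goodness of fit is the percent variance explained,
#' `100 * (1 - SS_res / SS_tot)` on the detrended trace; traces with
#' goodness below 80% (or a failed fit) are flagged arrhythmic.
#'
#' @param trace A detrended `luminescence_trace`.
#' @param period_range Admissible period window in hours for the periodogram
#'   seed.
#' @param gof_threshold Rhythmicity threshold on goodness of fit (percent).
#' @param detrend_window Width (hours) of the running-average window the
#'   trace was detrended with, applied to the model as well; taken from the
#'   trace's `detrend_window` attribute when present, `NULL` for a plain
#'   damped-sine fit.
#' @return Object of class `damped_sine_fit`: `period_h`, `amplitude`,
#'   `phase_rad`, `damping_per_h`, `goodness`, `rhythmic`, `converged`,
#'   `fitted`, `trace`.
#' @export
fit_damped_sine <- function(trace, period_range = c(15, 40),
                            gof_threshold = 80,
                            detrend_window = attr(trace, "detrend_window")) {
  t <- trace$time_h; y <- trace$counts
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  fail <- function(msg) {
    structure(list(period_h = NA_real_, amplitude = NA_real_,
                   phase_rad = NA_real_, damping_per_h = NA_real_,
                   goodness = 0, rhythmic = FALSE, converged = FALSE,
                   diagnostic = msg, fitted = rep(NA_real_, n),
                   trace = trace),
              class = "damped_sine_fit")
  }
  if (ss_tot <= 0) return(fail("constant trace"))
  T0 <- periodogram_period(t, y, period_range)
  A0 <- stats::sd(y) * sqrt(2)
  # coarse phase grid at the seed period
  phases <- seq(0, 2 * pi, length.out = 9)[-9]
  sse <- vapply(phases, function(ph) {
    sum((y - A0 * sin(2 * pi * t / T0 + ph))^2)
  }, numeric(1))
  ph0 <- phases[which.min(sse)]
  df <- data.frame(t = t, y = y)
  if (!is.null(detrend_window)) {
    W <- running_mean_operator(t, detrend_window)
    dsine <- function(t, A, d, T, phi) {
      m <- A * exp(-d * t) * sin(2 * pi * t / T + phi)
      m - as.vector(W %*% m)
    }
  } else {
    dsine <- function(t, A, d, T, phi) {
      A * exp(-d * t) * sin(2 * pi * t / T + phi)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dsine(t, A, d, T, phi),
      data = df,
      start = list(A = A0, d = 0.01, T = T0, phi = ph0),
      lower = c(A = 0, d = -0.2, T = period_range[1], phi = -2 * pi),
      upper = c(A = Inf, d = 1, T = period_range[2], phi = 4 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  fitted <- stats::predict(fit)
  gof <- 100 * (1 - sum((y - fitted)^2) / ss_tot)
  phase <- cf[["phi"]] %% (2 * pi)
  structure(list(period_h = cf[["T"]], amplitude = cf[["A"]],
                 phase_rad = phase, damping_per_h = cf[["d"]],
                 goodness = gof, rhythmic = gof >= gof_threshold,
                 converged = TRUE, diagnostic = NA_character_,
                 fitted = fitted, trace = trace),
            class = "damped_sine_fit")
}

periodogram_period <- function(t, y, period_range) {
  dt <- stats::median(diff(t))
  sp <- stats::spec.pgram(stats::ts(y, deltat = dt), plot = FALSE,
                          detrend = TRUE, taper = 0)
  per <- 1 / sp$freq
  ok <- per >= period_range[1] & per <= period_range[2]
  if (!any(ok)) return(mean(period_range))
  per[ok][which.max(sp$spec[ok])]
}

#' @export
print.damped_sine_fit <- function(x, ...) {
  if (x$converged) {
    cat("<damped_sine_fit> T = ", signif(x$period_h, 5), " h, goodness = ",
        signif(x$goodness, 4), "% (",
        if (x$rhythmic) "rhythmic" else "arrhythmic", ")\n", sep = "")
  } else {
    cat("<damped_sine_fit> failed: ", x$diagnostic, " (arrhythmic)\n",
        sep = "")
  }
  invisible(x)
}

#' @method tidy damped_sine_fit
#' @export
tidy.damped_sine_fit <- function(x, ...) {
  tibble::tibble(term = c("period_h", "amplitude", "phase_rad",
                          "damping_per_h"),
                 estimate = c(x$period_h, x$amplitude, x$phase_rad,
                              x$damping_per_h))
}

#' @method glance damped_sine_fit
#' @export
glance.damped_sine_fit <- function(x, ...) {
  tibble::tibble(period_h = x$period_h, amplitude = x$amplitude,
                 phase_rad = x$phase_rad, damping_per_h = x$damping_per_h,
                 goodness = x$goodness, rhythmic = x$rhythmic,
                 converged = x$converged)
}

#' Fit a one-phase exponential decay
#'
#' Normalizes the trace to its first reading, then fits
#' \eqn{y = (y_0 - p)\,e^{-k (t - t_1)} + p} by least squares (seeded from a
#' log-linear regression) and reports the half-life \eqn{t_{1/2} = \ln 2 / k}.
#'
#' @param trace A `luminescence_trace` (background-corrected).
#' @param normalize Divide by the first reading so the trace starts at 1.
#' @return Object of class `decay_fit`: `rate_per_h` (k), `plateau`, `y0`,
#'   `half_life_h`, `fitted`, `trace`.
#' @export
fit_one_phase_decay <- function(trace, normalize = TRUE) {
  t <- trace$time_h - trace$time_h[1]
  y <- trace$counts
  if (normalize) {
    if (y[1] == 0) stop("cannot normalize: first reading is zero", call. = FALSE)
    y <- y / y[1]
  }
  p0 <- max(0, min(y) - 0.05 * abs(min(y)))
  pos <- y - p0 > 1e-9
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos] - p0) ~ t[pos]))[2]
    max(1e-4, -sl)
  } else 0.1
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ (y0 - p) * exp(-k * t) + p, data = df,
    start = list(y0 = y[1], p = p0, k = k0),
    lower = c(y0 = -Inf, p = -Inf, k = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  cf <- stats::coef(fit)
  structure(list(rate_per_h = cf[["k"]], plateau = cf[["p"]],
                 y0 = cf[["y0"]], half_life_h = log(2) / cf[["k"]],
                 fitted = stats::predict(fit),
                 trace = luminescence_trace(trace$time_h, y,
                                            attr(trace, "id"))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> t1/2 = ", signif(x$half_life_h, 5), " h (k = ",
      signif(x$rate_per_h, 4), "/h, plateau ", signif(x$plateau, 3), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("rate_per_h", "plateau", "y0", "half_life_h"),
                 estimate = c(x$rate_per_h, x$plateau, x$y0, x$half_life_h))
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rate_per_h = x$rate_per_h, plateau = x$plateau,
                 y0 = x$y0, half_life_h = x$half_life_h)
}

#' Scale detrended traces for heat-map display
#'
#' Per trace: z-score, then linear rescale so the largest absolute value is
#' 1, giving rows bounded in \[-1, 1\]. Constant traces become all-zero
#' rows.
#'
#' @param traces A list of detrended `luminescence_trace`s (equal lengths)
#'   or a numeric matrix (rows = traces).
#' @return Numeric matrix of the same shape, entries in \[-1, 1\].
#' @export
heatmap_scale <- function(traces) {
  if (is.list(traces) && !is.matrix(traces)) {
    m <- do.call(rbind, lapply(traces, function(tr) tr$counts))
  } else {
    m <- as.matrix(traces)
  }
  t(apply(m, 1L, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) return(rep(0, length(r)))
    z <- (r - mean(r)) / s
    z / max(abs(z))
  }))
}
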