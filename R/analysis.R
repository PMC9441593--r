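# Analysis: exponential fits, the length-constant fit, peak/charge metrics,
# and I-V tables.  All fits are deterministic: initial values come from a
# log-linear regression, refined by Levenberg-Marquardt least squares.

fit_result <- function(ok, model, amplitude = NA_real_, tau = NA_real_,
                       offset = NA_real_, t0 = NA_real_, rss = NA_real_,
                       r2 = NA_real_, window = c(NA_real_, NA_real_),
                       message = "") {
  structure(list(ok = ok, model = model, amplitude = amplitude, tau = tau,
                 offset = offset, t0 = t0, rss = rss, r2 = r2,
                 window = window, message = message),
            class = "mf_fit")
}

#' @export
print.mf_fit <- function(x, ...) {
  if (x$ok) {
    cat("<mf_fit ", x$model, "> tau/lambda = ", format(x$tau, digits = 5),
        ", amplitude = ", format(x$amplitude, digits = 5),
        ", R^2 = ", format(x$r2, digits = 4), "\n", sep = "")
  } else {
    cat("<mf_fit ", x$model, "> FAILED: ", x$message, "\n", sep = "")
  }
  invisible(x)
}

.r2 <- function(y, fitted) {
  ss <- sum((y - mean(y))^2)
  if (ss == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss
}

#' Fit a single decaying exponential
#'
#' Fits `y = A * exp(-(t - t0)/tau) + C` (offset optional) over a window.
#' Initialization is deterministic: the offset starts at the tail mean and
#' `A`, `tau` come from a log-linear regression of `y - C`.
#'
#' @param t,y trace samples.
#' @param window `c(t_lo, t_hi)`; defaults to the full trace.
#' @param with_offset fit a constant offset `C` (otherwise `C = 0`).
#' @return an `mf_fit`; on failure (non-convergence, `tau <= 0`, degenerate
#'   data) an explicit failure result, never an error.
#' @export
fit_single_exponential <- function(t, y, window = range(t),
                                   with_offset = TRUE) {
  sel <- t >= window[1] & t <= window[2]
  tt <- t[sel] - window[1]
  yy <- y[sel]
  model <- if (with_offset) "single_exp_with_offset" else "single_exp"
  if (length(tt) < 10) {
    return(fit_result(FALSE, model, window = window,
                      message = "fewer than 10 samples in window"))
  }
  c0 <- if (with_offset) mean(yy[tt >= max(tt) * 0.9]) else 0
  z <- yy - c0
  sgn <- if (abs(min(z)) > abs(max(z))) -1 else 1
  z <- z * sgn
  pos <- z > max(z) * 1e-3
  if (sum(pos) < 5 || max(z) <= 0) {
    return(fit_result(FALSE, model, window = window,
                      message = "degenerate (non-decaying) data"))
  }
  lf <- lm(log(z[pos]) ~ tt[pos])
  tau0 <- as.numeric(-1 / coef(lf)[2])
  a0 <- as.numeric(exp(coef(lf)[1])) * sgn
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
  fit <- tryCatch({
    if (with_offset) {
      minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + C,
                        start = list(A = a0, tau = tau0, C = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(yy ~ A * exp(-tt / tau),
                        start = list(A = a0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(FALSE, model, window = window,
                      message = "nonlinear fit did not converge"))
  }
  cf <- coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    return(fit_result(FALSE, model, window = window,
                      message = "fitted tau not positive"))
  }
  fit_result(TRUE, model, amplitude = cf[["A"]], tau = cf[["tau"]],
             offset = if (with_offset) cf[["C"]] else 0, t0 = window[1],
             rss = sum(resid(fit)^2), r2 = .r2(yy, fitted(fit)),
             window = window)
}

# mono-exponential approach to a plateau: y = A * (1 - exp(-(t - t0)/tau)),
# used for activation time constants (fit from 10% of peak to the peak).
fit_exp_rise <- function(t, y, window = range(t)) {
  sel <- t >= window[1] & t <= window[2]
  tt <- t[sel]
  yy <- y[sel]
  if (length(tt) < 6) {
    return(fit_result(FALSE, "exp_rise", window = window,
                      message = "too few samples"))
  }
  a0 <- max(yy)
  z <- 1 - yy / a0
  pos <- z > 1e-4
  tau0 <- if (sum(pos) >= 3) {
    as.numeric(-1 / coef(lm(log(z[pos]) ~ tt[pos]))[2])
  } else {
    diff(range(tt)) / 3
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * (1 - exp(-(tt - t0) / tau)),
                      start = list(A = a0, tau = tau0, t0 = window[1]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    return(fit_result(FALSE, "exp_rise", window = window,
                      message = "rise fit failed"))
  }
  cf <- coef(fit)
  fit_result(TRUE, "exp_rise", amplitude = cf[["A"]], tau = cf[["tau"]],
             t0 = cf[["t0"]], rss = sum(resid(fit)^2),
             r2 = .r2(yy, fitted(fit)), window = window)
}

#' Fit the length constant of amplitude decay with distance
#'
#' Fits `A * exp(-x/lambda)` to peak amplitudes versus path distance.
#'
#' @param distance_um increasing distances, um (>= 4 points).
#' @param amplitude_mv peak amplitudes, mV.
#' @return an `mf_fit` with `tau` holding lambda (um) and `r2` the fit R^2;
#'   an explicit failure result for degenerate input.
#' @export
#' @examples
#' x <- seq(100, 1500, by = 150)
#' fit_distance_constant(x, 12 * exp(-x / 300))$tau
fit_distance_constant <- function(distance_um, amplitude_mv) {
  if (length(distance_um) < 4 || is.unsorted(distance_um, strictly = TRUE)) {
    return(fit_result(FALSE, "length_constant",
                      message = "need >= 4 strictly increasing distances"))
  }
  if (any(amplitude_mv <= 0) || any(diff(amplitude_mv) >= 0)) {
    return(fit_result(FALSE, "length_constant",
                      message = "amplitudes must be positive and decreasing"))
  }
  lf <- lm(log(amplitude_mv) ~ distance_um)
  lam0 <- as.numeric(-1 / coef(lf)[2])
  a0 <- as.numeric(exp(coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(amplitude_mv ~ A * exp(-distance_um / lambda),
                      start = list(A = a0, lambda = lam0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(FALSE, "length_constant", message = "fit failed"))
  }
  cf <- coef(fit)
  fit_result(TRUE, "length_constant", amplitude = cf[["A"]],
             tau = cf[["lambda"]],
             r2 = .r2(amplitude_mv, fitted(fit)))
}

#' Peak and charge of a presynaptic Ca2+ current transient
#'
#' Baseline is the mean current over the 1 ms preceding stimulus onset; the
#' peak is the magnitude of the largest inward (negative) excursion of the
#' baseline-subtracted trace within the window, and the charge is the
#' trapezoidal integral of the baseline-subtracted inward current over the
#' window (1 pA * ms = 1 fC, reported positive for net inward transfer).
#'
#' @param t time, ms.
#' @param i_pa current, pA (inward negative).
#' @param stim_onset stimulus onset, ms.
#' @param window_len window length after onset, ms.
#' @return list of class `mf_ca_metrics`: `peak_pa`, `charge_fc`,
#'   `baseline_pa`, `t_peak_ms`, `window`.
#' @export
peak_and_charge <- function(t, i_pa, stim_onset, window_len = 10) {
  if (stim_onset - 1 < min(t) || stim_onset + window_len > max(t) + 1e-9) {
    stop("window error: trace must cover [onset - 1, onset + window_len]")
  }
  base_sel <- t >= stim_onset - 1 & t < stim_onset
  baseline <- mean(i_pa[base_sel])
  sel <- t >= stim_onset & t <= stim_onset + window_len
  tt <- t[sel]
  z <- i_pa[sel] - baseline
  peak <- max(0, -min(z))
  t_peak <- tt[which.min(z)]
  charge <- -sum(diff(tt) * (z[-1] + z[-length(z)]) / 2)
  structure(list(peak_pa = peak, charge_fc = charge, baseline_pa = baseline,
                 t_peak_ms = t_peak,
                 window = c(stim_onset, stim_onset + window_len)),
            class = "mf_ca_metrics")
}

#' @export
print.mf_ca_metrics <- function(x, ...) {
  cat("<mf_ca_metrics> peak ", format(x$peak_pa, digits = 5), " pA, charge ",
      format(x$charge_fc, digits = 5), " fC (baseline ",
      format(x$baseline_pa, digits = 3), " pA)\n", sep = "")
  invisible(x)
}

#' Peak-current I-V table from a clamp characterization
#'
#' @param char a data.frame from [characterize_channel()] (columns `v_test`,
#'   `i_peak_pa`, ...).
#' @return the input with an attribute `v_at_peak_inward`: the test potential
#'   of maximal inward current.
#' @export
iv_table <- function(char) {
  structure(char[, c("v_test", "i_peak_pa")],
            v_at_peak_inward = char$v_test[which.min(char$i_peak_pa)])
}
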