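#' Acquisition parameters for the saturation-recovery FLASH readout
#'
#' Bundles the pulse-sequence constants entering the SR-FLASH signal equation:
#' repetition time between readout pulses, pre-pulse delay from the saturation
#' pulse to the central k-space line, flip angle, the index of the readout
#' pulse acquiring the k-space centre, and the longitudinal relaxivity of the
#' contrast agent.
#'
#' Defaults correspond to a 3T turbo-FLASH perfusion protocol
#' (TR/TE 2.20/1.07 ms, flip angle 12 degrees, PD 100 ms, 48 phase-encode
#' lines per frame with the centre reached after 24 pulses) and gadobutrol
#' relaxivity of about 5 per mM per second at 3T.
#'
#' @param tr repetition time between successive alpha pulses, seconds.
#' @param pd pre-pulse delay: saturation pulse to central k-space line, seconds.
#' @param flip_angle readout flip angle, degrees (0 < alpha < 90).
#' @param n_center number of readout pulses up to and including the central
#'   k-space line (the exponent index of the transient FLASH term).
#' @param r1_relaxivity longitudinal relaxivity r1, per mM per second.
#' @param te echo time, seconds; used only when rendering synthetic signal
#'   (the T2*-attenuation term), not by the conversion itself.
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq <- acquisition_params()
#' acq$pd
acquisition_params <- function(tr = 0.0022, pd = 0.100, flip_angle = 12,
                               n_center = 24, r1_relaxivity = 5.0,
                               te = 0.00107) {
  stopifnot(is.numeric(tr), is.numeric(pd), is.numeric(flip_angle),
            is.numeric(n_center), is.numeric(r1_relaxivity))
  if (tr <= 0) stop("'tr' must be > 0")
  if (pd <= 0) stop("'pd' must be > 0")
  if (flip_angle <= 0 || flip_angle >= 90)
    stop("'flip_angle' must lie strictly between 0 and 90 degrees")
  if (n_center < 1) stop("'n_center' must be >= 1")
  if (r1_relaxivity <= 0) stop("'r1_relaxivity' must be > 0")
  if (te < 0) stop("'te' must be >= 0")
  structure(list(tr = tr, pd = pd, flip_angle = flip_angle,
                 n_center = as.integer(n_center),
                 r1_relaxivity = r1_relaxivity, te = te),
            class = "acq_params")
}

new_perfusion_curve <- function(times, values, region, subclass) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(!is.finite(values))) stop("'values' must be finite")
  structure(list(times = times, values = values, region = as.character(region)),
            class = c(subclass, "perfusion_curve"))
}

#' Signal-intensity time curve
#'
#' A time-stamped signal-intensity curve for one region of interest (the
#' arterial input function sampled in the left-ventricular blood pool, or one
#' myocardial segment).
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values signal intensities, arbitrary scanner units, non-negative.
#' @param region region label, e.g. `"aif"` or `"seg03"`.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(times, values, region = "aif") {
  if (any(values < 0)) stop("signal 'values' must be non-negative")
  new_perfusion_curve(times, values, region, "signal_curve")
}

#' Contrast-agent concentration time curve
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values gadolinium concentration, mM.
#' @param region region label, e.g. `"aif"` or `"seg03"`.
#' @param saturated optional logical vector flagging samples whose signal sat
#'   at/above the SR-FLASH plateau and was clipped during inversion.
#' @return An object of class `conc_curve`.
#' @export
conc_curve <- function(times, values, region = "aif", saturated = NULL) {
  x <- new_perfusion_curve(times, values, region, "conc_curve")
  if (!is.null(saturated)) {
    stopifnot(is.logical(saturated), length(saturated) == length(x$values))
    attr(x, "saturated") <- saturated
  }
  x
}

#' Fraction of clipped (saturated) samples in a concentration curve
#' @param curve a `conc_curve`.
#' @return fraction in \[0, 1\]; 0 when no saturation metadata is attached.
#' @export
saturation_fraction <- function(curve) {
  s <- attr(curve, "saturated")
  if (is.null(s) || !length(s)) return(0)
  mean(s)
}

curve_dt <- function(curve, tol = 1e-8) {
  d <- diff(curve$times)
  if (!length(d)) stop("curve has fewer than 2 samples")
  dt <- d[1]
  if (any(abs(d - dt) > tol * max(dt, 1)))
    stop("curve is not uniformly sampled")
  dt
}

is_uniform <- function(curve, tol = 1e-8) {
  ok <- try(curve_dt(curve, tol), silent = TRUE)
  !inherits(ok, "try-error")
}

#' @export
print.perfusion_curve <- function(x, ...) {
  cat(sprintf("<%s> region '%s': %d samples, t = [%g, %g] s, range [%.4g, %.4g]\n",
              class(x)[1], x$region, length(x$times),
              min(x$times), max(x$times), min(x$values), max(x$values)))
  sf <- saturation_fraction(x)
  if (sf > 0) cat(sprintf("  %.1f%% of samples flagged saturated\n", 100 * sf))
  invisible(x)
}

#' @export
as.data.frame.perfusion_curve <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, region = x$region,
             stringsAsFactors = FALSE)
}

#' @export
plot.perfusion_curve <- function(x, ...,
                                 xlab = "time (s)",
                                 ylab = if (inherits(x, "conc_curve"))
                                   "[Gd] (mM)" else "signal (a.u.)") {
  graphics::plot(x$times, x$values, type = "o", pch = 16, cex = 0.6,
                 xlab = xlab, ylab = ylab, main = x$region, ...)
  invisible(x)
}
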