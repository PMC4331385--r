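# Tissue impulse responses (Fermi, distributed-parameter) and their forward
# convolution models. All internal kinetics are in seconds and mL/s/mL; MBF is
# carried in mL/min/mL (the reporting unit) and converted by a single /60 at
# the convolution boundary.

#' Fermi model parameters
#'
#' @param mbf myocardial blood flow, mL/min per mL tissue (> 0).
#' @param tau0 shoulder width of the Fermi function, seconds (>= 0).
#' @param k_decay wash-out decay rate, per second (>= 0).
#' @return object of class `fermi_params`.
#' @export
fermi_params <- function(mbf, tau0, k_decay) {
  if (mbf <= 0) stop("'mbf' must be > 0")
  if (tau0 < 0) stop("'tau0' must be >= 0")
  if (k_decay < 0) stop("'k_decay' must be >= 0")
  structure(list(mbf = mbf, tau0 = tau0, k_decay = k_decay),
            class = "fermi_params")
}

#' Distributed-parameter (two-region, one-barrier) model parameters
#'
#' @param mbf myocardial blood flow, mL/min per mL tissue (> 0).
#' @param t_overall mean overall transit time T, seconds.
#' @param t_cap mean capillary transit time Tc, seconds (0 < Tc <= T).
#' @param t_int mean interstitial (extravascular-extracellular) transit time
#'   Te, seconds (> 0).
#' @return object of class `dp_params`.
#' @export
dp_params <- function(mbf, t_overall, t_cap, t_int) {
  if (mbf <= 0) stop("'mbf' must be > 0")
  if (t_cap <= 0) stop("'t_cap' must be > 0")
  if (t_overall < t_cap) stop("'t_cap' must not exceed 't_overall'")
  if (t_int <= 0) stop("'t_int' must be > 0")
  structure(list(mbf = mbf, t_overall = t_overall, t_cap = t_cap,
                 t_int = t_int),
            class = "dp_params")
}

#' Fermi tissue impulse response
#'
#' \deqn{R(t) = 1 / (\exp[(t-\tau_0)k] + 1)}
#' Used exactly as printed, un-normalised: \eqn{R(0) = 1/(e^{-\tau_0 k}+1)}
#' is not forced to 1; the fitted MBF is the amplitude multiplying R.
#'
#' @param t time, seconds (vectorised, t >= 0).
#' @param p a [fermi_params()] object.
#' @return dimensionless response values, non-increasing in t.
#' @export
fermi_response <- function(t, p) {
  1 / (exp((t - p$tau0) * p$k_decay) + 1)
}

#' Distributed-parameter transfer function (Laplace domain)
#'
#' \deqn{R(s) = (1 - \exp[-s(T + s T_c T_e)/(1 + s T_e)]) / s}
#' evaluated for complex frequency \eqn{s = i 2\pi f}. At \eqn{s = 0} the
#' removable singularity is replaced by its limit \eqn{T}: the DC gain of the
#' residue function equals the mean overall transit time, i.e. the area under
#' \eqn{R(t)} is \eqn{T}.
#'
#' @param s complex frequency (vectorised; may contain 0).
#' @param p a [dp_params()] object.
#' @return complex transfer values.
#' @export
dp_transfer <- function(s, p) {
  s <- as.complex(s)
  out <- complex(length.out = length(s))
  z <- Mod(s) == 0
  if (any(!z)) {
    ss <- s[!z]
    out[!z] <- (1 - exp(-ss * (p$t_overall + ss * p$t_cap * p$t_int) /
                          (1 + ss * p$t_int))) / ss
  }
  out[z] <- complex(real = p$t_overall)
  out
}

# Smallest even highly-composite FFT length >= target.
.fft_size <- function(target) {
  m <- stats::nextn(max(8, ceiling(target)), c(2, 3, 5))
  while (m %% 2L) m <- stats::nextn(m + 1L, c(2, 3, 5))
  m
}

# Inverse-FFT of the DP transfer function on an M-point grid with spacing dt.
# The residue function is discontinuous (unit jump at t = 0 and a drop of
# E' = exp(-(T-Tc)/Te) at t = Tc), so direct frequency truncation rings.
# The jumps are carried by an analytic reference with matching high-frequency
# behaviour, (1 - E' e^(-s Tc))/(s + 1/Te), whose time form is exact; only
# the smooth O(1/s^2) remainder goes through the inverse FFT.
.dp_impulse_fft <- function(p, m, dt) {
  half <- 0:(m / 2)
  s <- 2i * pi * half / (m * dt)
  lam <- min(1 / p$t_int, 0.5 / dt)   # keep the reference resolvable on the grid
  ep <- exp(-(p$t_overall - p$t_cap) / p$t_int)
  h <- (1 - exp(-s * (p$t_overall + s * p$t_cap * p$t_int) /
                  (1 + s * p$t_int))) / s
  h[1] <- p$t_overall                  # removable singularity: DC gain is T
  h <- h - (1 - ep * exp(-s * p$t_cap)) / (s + lam)
  h[m / 2 + 1] <- Re(h[m / 2 + 1])     # real Nyquist bin
  hf <- c(h, Conj(h[(m / 2):2]))       # conjugate-symmetric full spectrum
  r <- Re(stats::fft(hf, inverse = TRUE)) / (m * dt)
  t <- (0:(m - 1)) * dt
  r + exp(-lam * t) - ep * exp(-lam * pmax(t - p$t_cap, 0)) * (t >= p$t_cap)
}

#' Distributed-parameter impulse response by numerical Laplace inversion
#'
#' Evaluates [dp_transfer()] on an FFT frequency grid and inverse-transforms
#' to obtain \eqn{R(t)} on a uniform time grid. Intended for validation and
#' plotting; the forward model reuses the same inversion internally.
#'
#' @param p a [dp_params()] object.
#' @param t_grid uniform time grid starting at 0, seconds. Must span at least
#'   \eqn{T + 5 T_e} so the interstitial tail is contained.
#' @param pad_factor zero-padding factor controlling wrap-around aliasing
#'   (default 2).
#' @return numeric vector of \eqn{R(t)} values on `t_grid`.
#' @export
dp_impulse_numeric <- function(p, t_grid, pad_factor = 2) {
  if (length(t_grid) < 4) stop("'t_grid' too short")
  dt <- diff(t_grid)[1]
  if (any(abs(diff(t_grid) - dt) > 1e-8 * dt))
    stop("'t_grid' must be uniform")
  span <- max(t_grid)
  if (span < p$t_overall + 5 * p$t_int)
    stop("window too short: grid must span T + 5*Te")
  n <- length(t_grid)
  m <- .fft_size(pad_factor * n)
  r <- .dp_impulse_fft(p, m, dt)
  r[seq_len(n)]
}

# Exact discrete causal convolution of two equal-step sequences via FFT
# zero-padded linear convolution; returns the first length(a) samples.
.causal_conv <- function(a, r, dt) {
  n <- length(a)
  stopifnot(length(r) >= n)
  m <- .fft_size(2 * n)
  out <- stats::fft(stats::fft(c(a, numeric(m - n))) *
                      stats::fft(c(r[seq_len(n)], numeric(m - n))),
                    inverse = TRUE) / m
  Re(out[seq_len(n)]) * dt
}

#' Forward Fermi model: tissue curve from AIF and parameters
#'
#' Discrete causal convolution
#' \deqn{C_t(t) = (MBF/60)\sum_\tau R(\tau)\,C_a(t-\tau)\,\Delta t,}
#' with MBF converted from per-minute to per-second once at this boundary.
#'
#' @param aif a uniformly sampled [conc_curve()] (the arterial input).
#' @param p a [fermi_params()] object.
#' @return a [conc_curve()] of modelled tissue concentration on the AIF grid.
#' @export
fermi_forward <- function(aif, p) {
  dt <- curve_dt(aif)
  r <- fermi_response(aif$times - aif$times[1], p)
  v <- .causal_conv(aif$values, r, dt) * (p$mbf / 60)
  conc_curve(aif$times, v, region = "model")
}

# Internal DP impulse grid: long enough to contain the interstitial tail
# (T + 6 Te) so frequency-sampling aliasing is negligible, and at least
# 2x the curve length.
.dp_impulse_for <- function(p, n, dt) {
  m <- .fft_size(max(2 * n, (p$t_overall + 6 * p$t_int) / dt + 1))
  .dp_impulse_fft(p, m, dt)
}

#' Forward distributed-parameter model: tissue curve from AIF and parameters
#'
#' The DP residue function is obtained by inverse-FFT of the Laplace-domain
#' transfer function on an internal grid sized to contain the interstitial
#' tail (at least \eqn{T + 6T_e} and twice the curve length, suppressing
#' circular wrap), then convolved causally with the AIF as in
#' [fermi_forward()].
#'
#' @param aif a uniformly sampled [conc_curve()].
#' @param p a [dp_params()] object.
#' @return a [conc_curve()] of modelled tissue concentration on the AIF grid.
#' @export
dp_forward <- function(aif, p) {
  dt <- curve_dt(aif)
  n <- length(aif$values)
  r <- .dp_impulse_for(p, n, dt)
  v <- .causal_conv(aif$values, r, dt) * (p$mbf / 60)
  conc_curve(aif$times, v, region = "model")
}

#' Microvascular parameters derived from a distributed-parameter fit
#'
#' Given fitted DP parameters and a haematocrit, derives
#' \deqn{MPF = MBF(1-hct),\quad v_b = MBF\,T_c/60,\quad
#'       v_e = F(T-T_c)/60,\quad v_d = F\,T/60,\quad
#'       PS = F(T-T_c)/T_e,\quad E = 1-e^{-PS/MPF},}
#' where the flow \eqn{F} used for \eqn{v_e, v_d, PS} is the myocardial
#' plasma flow under the default `flow_convention = "mpf"` or whole-blood
#' MBF under `"mbf"`; \eqn{v_b} always uses whole-blood MBF. Transit times in
#' seconds are converted to volumes by a single /60 against the per-minute
#' flows. Note \eqn{v_d = v_b + v_e} holds exactly only under the `"mbf"`
#' convention.
#'
#' @param p a [dp_params()] object.
#' @param hct haematocrit fraction in \[0, 1); 0.45 is the conventional
#'   assumed value.
#' @param flow_convention `"mpf"` (plasma flow for ve, vd, PS; default) or
#'   `"mbf"` (whole-blood flow throughout).
#' @return object of class `microvascular_profile`: list with `vb`, `ve`,
#'   `vd` (mL/mL), `ps`, `mpf` (mL/min/mL), `extraction`, `hct`.
#' @export
#' @examples
#' microvascular_profile(dp_params(1, 20, 6, 40), hct = 0.45)
microvascular_profile <- function(p, hct = 0.45,
                                  flow_convention = c("mpf", "mbf")) {
  flow_convention <- match.arg(flow_convention)
  if (hct < 0 || hct >= 1) stop("'hct' must lie in [0, 1)")
  mpf <- p$mbf * (1 - hct)
  fl <- if (flow_convention == "mpf") mpf else p$mbf
  vb <- p$mbf * p$t_cap / 60
  ve <- fl * (p$t_overall - p$t_cap) / 60
  vd <- fl * p$t_overall / 60
  ps <- fl * (p$t_overall - p$t_cap) / p$t_int
  extraction <- 1 - exp(-ps / mpf)
  structure(list(vb = vb, ve = ve, vd = vd, ps = ps, mpf = mpf,
                 extraction = extraction, hct = hct,
                 flow_convention = flow_convention),
            class = "microvascular_profile")
}

#' @export
print.microvascular_profile <- function(x, ...) {
  cat("<microvascular_profile>\n")
  cat(sprintf("  vb = %.4g mL/mL   ve = %.4g mL/mL   vd = %.4g mL/mL\n",
              x$vb, x$ve, x$vd))
  cat(sprintf("  PS = %.4g mL/min/mL   MPF = %.4g mL/min/mL   E = %.3f\n",
              x$ps, x$mpf, x$extraction))
  cat(sprintf("  (hct = %.2f, flow convention '%s' for ve/vd/PS)\n",
              x$hct, x$flow_convention))
  invisible(x)
}
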