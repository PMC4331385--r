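# Methods for fitted deconvolution models.

#' @export
print.mbf_fit <- function(x, ...) {
  cat(sprintf("<mbf_fit> %s model, %s\n",
              toupper(x$model),
              if (x$converged) "converged" else "NON-CONVERGENT"))
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  MBF = %.3f mL/min/mL | SSE = %.4g over frames %d-%d",
              x$coefficients[["mbf"]], x$sse,
              x$window_used[1], x$window_used[2]))
  if (x$saturation_fraction > 0)
    cat(sprintf(" | %.0f%% AIF samples saturated", 100 * x$saturation_fraction))
  cat("\n")
  invisible(x)
}

#' Extract fitted kinetic coefficients
#' @param object an `mbf_fit`.
#' @param ... unused.
#' @return named numeric vector; MBF in mL/min/mL, times in seconds, decay
#'   rate per second.
#' @export
coef.mbf_fit <- function(object, ...) object$coefficients

#' @export
fitted.mbf_fit <- function(object, ...) object$fitted_values

#' Residuals of a deconvolution fit
#' @param object an `mbf_fit`.
#' @param ... unused.
#' @return observed minus fitted tissue concentration over the fitted window.
#' @export
residuals.mbf_fit <- function(object, ...) {
  win <- seq.int(object$window_used[1], object$window_used[2])
  object$tissue$values[win] - object$fitted_values[win]
}

#' Predict a tissue curve from a fitted model
#' @param object an `mbf_fit`.
#' @param newdata optional [conc_curve()] AIF; defaults to the training AIF.
#' @param ... unused.
#' @return a [conc_curve()] of predicted tissue concentration.
#' @export
predict.mbf_fit <- function(object, newdata = NULL, ...) {
  aif <- if (is.null(newdata)) object$aif else newdata
  if (object$model == "fermi") fermi_forward(aif, object$params)
  else dp_forward(aif, object$params)
}

#' Summarise a deconvolution fit
#'
#' For DP fits the summary also derives the microvascular profile
#' ([microvascular_profile()]) at the given haematocrit.
#'
#' @param object an `mbf_fit`.
#' @param hct haematocrit for the microvascular derivation (default 0.45).
#' @param flow_convention passed to [microvascular_profile()].
#' @param ... unused.
#' @return object of class `summary.mbf_fit`.
#' @export
summary.mbf_fit <- function(object, hct = 0.45,
                            flow_convention = c("mpf", "mbf"), ...) {
  out <- list(fit = object)
  if (object$model == "dp")
    out$microvascular <- microvascular_profile(object$params, hct = hct,
                                               flow_convention = match.arg(flow_convention))
  win <- seq.int(object$window_used[1], object$window_used[2])
  obs <- object$tissue$values[win]
  out$r_squared <- if (object$sse_null > 0) 1 - object$sse / sum((obs - mean(obs))^2) else NA_real_
  class(out) <- "summary.mbf_fit"
  out
}

#' @export
print.summary.mbf_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared (window): %.4f\n", x$r_squared))
  if (!is.null(x$microvascular)) print(x$microvascular)
  invisible(x)
}

#' Plot a deconvolution fit
#' @param x an `mbf_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mbf_fit <- function(x, ...) {
  t <- x$tissue$times
  graphics::plot(t, x$tissue$values, pch = 16, cex = 0.6,
                 xlab = "time (s)", ylab = "[Gd] (mM)",
                 main = sprintf("%s fit (%s)", toupper(x$model), x$tissue$region),
                 ...)
  graphics::lines(t, x$fitted_values, col = "red3", lwd = 2)
  graphics::abline(v = t[x$window_used[2]], lty = 3, col = "grey40")
  graphics::legend("topright", bty = "n", lwd = c(NA, 2), pch = c(16, NA),
                   col = c("black", "red3"), legend = c("measured", "model"))
  invisible(x)
}

#' Simulate noisy tissue replicates from a fitted model
#'
#' Draws Gaussian noise around the fitted tissue curve, with standard
#' deviation given as a fraction of the fitted peak (matching the additive
#' noise model of the synthetic generator).
#'
#' @param object an `mbf_fit`.
#' @param nsim number of replicate curves.
#' @param seed optional integer seed.
#' @param noise_sd noise SD as a fraction of the fitted tissue peak.
#' @param ... unused.
#' @return list of [conc_curve()] replicates.
#' @export
simulate.mbf_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdv <- noise_sd * max(object$fitted_values)
  lapply(seq_len(nsim), function(i) {
    conc_curve(object$tissue$times,
               object$fitted_values + stats::rnorm(length(object$fitted_values), 0, sdv),
               region = object$tissue$region)
  })
}
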