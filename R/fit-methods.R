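#' @export
print.saxs_ensemble_fit <- function(x, ...) {
  cat("Weighted SAXS ensemble fit\n")
  cat(sprintf("  members: %s\n", paste(x$member_ids, collapse = ", ")))
  cat(sprintf("  weights: %s\n",
              paste(format(x$weights, digits = 3), collapse = ", ")))
  cat(sprintf("  chi2 = %.4g, scale = %.4g (%d weight vectors searched)\n",
              x$chi2, x$scale, x$n_evaluated))
  invisible(x)
}

#' @export
summary.saxs_ensemble_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(weights = stats::setNames(object$weights,
                                        paste0("w[", object$member_ids, "]")),
              chi2 = object$chi2, scale = object$scale,
              n_points = length(object$exp_curve$q),
              n_members = length(object$weights),
              n_evaluated = object$n_evaluated,
              step = object$step,
              resid_summary = summary(res))
  class(out) <- "summary.saxs_ensemble_fit"
  out
}

#' @export
print.summary.saxs_ensemble_fit <- function(x, ...) {
  cat("Weighted SAXS ensemble fit\n\n")
  cat("Grid-quantized weights (step =", x$step, "):\n")
  print(x$weights)
  cat(sprintf("\nReduced chi2: %.4g over %d q points (scale c = %.4g)\n",
              x$chi2, x$n_points, x$scale))
  cat(sprintf("%d weight vectors evaluated for %d members\n",
              x$n_evaluated, x$n_members))
  cat("\nError-normalized residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.saxs_ensemble_fit <- function(object, ...) {
  stats::setNames(object$weights, paste0("w[", object$member_ids, "]"))
}

#' @export
fitted.saxs_ensemble_fit <- function(object, ...) {
  object$scale * object$combined$I
}

#' @export
residuals.saxs_ensemble_fit <- function(object,
                                        type = c("normalized", "raw"),
                                        ...) {
  type <- match.arg(type)
  r <- stats::fitted(object) - object$exp_curve$I
  if (type == "normalized") r <- r / object$exp_curve$sigma
  r
}

#' Predicted ensemble intensity
#'
#' Returns the scaled combined intensity c * sum_i w_i I_i. With
#' `newcurves`, the fitted weights and scale are applied to a new set of
#' member curves (same member count and order, arbitrary q grid).
#'
#' @param object a `saxs_ensemble_fit`.
#' @param newcurves optional list of [saxs_curve]s replacing the member
#'   curves.
#' @param ... unused.
#' @return a [saxs_curve] of predicted intensities.
#' @export
predict.saxs_ensemble_fit <- function(object, newcurves = NULL, ...) {
  if (is.null(newcurves))
    return(saxs_curve(object$combined$q, stats::fitted(object)))
  if (length(newcurves) != length(object$weights))
    stop("newcurves must match the fitted member count")
  q <- newcurves[[1]]$q
  M <- vapply(newcurves, `[[`, numeric(length(q)), "I")
  saxs_curve(q, object$scale * as.numeric(matrix(M, ncol = length(newcurves))
                                          %*% object$weights))
}

#' Simulate replicate experimental curves from a fitted ensemble
#'
#' Draws `nsim` synthetic curves I_fit(q) + N(0, sigma(q)) using the
#' experimental errors, mirroring the generative model the fit assumes.
#'
#' @param object a `saxs_ensemble_fit`.
#' @param nsim number of replicates (default 1).
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of [saxs_curve]s with the experimental sigma attached.
#' @export
simulate.saxs_ensemble_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object)
  sg <- object$exp_curve$sigma
  lapply(seq_len(nsim), function(k)
    saxs_curve(object$exp_curve$q, mu + stats::rnorm(length(mu), 0, sg),
               sigma = sg))
}

#' Plot an ensemble fit
#'
#' Two-panel base-graphics display: log-intensity overlay of the
#' experimental curve and the scaled ensemble curve, and the
#' error-normalized residuals.
#'
#' @param x a `saxs_ensemble_fit`.
#' @param ... passed to the upper-panel plot.
#' @return `x`, invisibly.
#' @export
plot.saxs_ensemble_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  q <- x$exp_curve$q
  graphics::plot(q, x$exp_curve$I, log = "y", pch = 16, cex = 0.5,
                 xlab = "q (1/A)", ylab = "I(q)", ...)
  graphics::lines(q, stats::fitted(x), col = "red3", lwd = 2)
  graphics::legend("topright", c("experimental", "ensemble"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "red3"), bty = "n")
  graphics::plot(q, stats::residuals(x), type = "h",
                 xlab = "q (1/A)", ylab = "(c I_fit - I_exp) / sigma")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
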