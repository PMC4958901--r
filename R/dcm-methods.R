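#' @export
print.dcm <- function(x, ...) {
  cat("Dynamic causal model fit: model", x$spec$id,
      sprintf("(%s, family %s)\n", x$spec$linearity, x$spec$family))
  cat(sprintf("  %d free parameters, %d regions, %d volumes\n",
              length(x$theta), x$spec$regions$n, nrow(x$data)))
  cat(sprintf("  free energy F = %.2f (accuracy %.2f, complexity %.2f)\n",
              x$F, x$accuracy, x$complexity))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Posterior means of a fitted model
#'
#' @param object a \code{dcm} fit
#' @param natural report self-connections in Hz and haemodynamic parameters
#'   in their natural units (rather than the internal log-scalings)
#' @param ... ignored
#' @export
coef.dcm <- function(object, natural = TRUE, ...) {
  th <- object$theta
  if (natural) th <- setNames(theta_natural(th, object$priors$table), names(th))
  th
}

#' @export
vcov.dcm <- function(object, ...) object$Sigma

#' @export
fitted.dcm <- function(object, ...) object$fitted

#' @export
residuals.dcm <- function(object, ...) object$residuals

#' @export
logLik.dcm <- function(object, ...) {
  structure(object$F, df = length(object$theta), class = "logLik",
            nobs = length(object$data))
}

#' Summarize a fitted dynamic causal model
#'
#' Reports, per free parameter, the posterior mean, posterior SD and the
#' conditional probability of a non-zero value (sign-aware Gaussian mass).
#'
#' @param object a \code{dcm} fit
#' @param ... ignored
#' @export
summary.dcm <- function(object, ...) {
  sdv <- sqrt(pmax(diag(object$Sigma), 0))
  tab <- data.frame(parameter = names(object$theta),
                    estimate = theta_natural(object$theta, object$priors$table),
                    mean = as.numeric(object$theta), sd = sdv,
                    Pp = conditional_probability(object$theta, pmax(sdv, 1e-12)),
                    row.names = NULL)
  out <- list(model = object$spec$id, F = object$F, accuracy = object$accuracy,
              complexity = object$complexity, lambda = object$lambda,
              converged = object$converged, iterations = object$iterations,
              parameters = tab)
  class(out) <- "summary.dcm"
  out
}

#' @export
print.summary.dcm <- function(x, digits = 3, ...) {
  cat("Model", x$model, " F =", format(x$F, digits = 8), "\n")
  cat("Noise precisions:", paste(signif(x$lambda, 3), collapse = " "), "\n\n")
  tab <- x$parameters
  tab$estimate <- signif(tab$estimate, digits)
  tab$sd <- signif(tab$sd, digits)
  tab$Pp <- round(tab$Pp, 3)
  print(tab[, c("parameter", "estimate", "sd", "Pp")], row.names = FALSE)
  invisible(x)
}

#' Predict the BOLD response of a fitted model
#'
#' Re-runs the deterministic forward model at the posterior mean, optionally
#' under new inputs or acquisition.
#'
#' @param object a \code{dcm} fit
#' @param inputs optional new \code{\link{dcm_inputs}}
#' @param acq optional new \code{\link{acquisition}}
#' @param ... ignored
#' @export
predict.dcm <- function(object, inputs = object$inputs, acq = object$acq, ...) {
  y <- fast_predict(object$spec, object$theta, object$priors$table,
                    inputs$u, inputs$dt, volume_sample_bins(acq),
                    object$constants, object$control$bound)
  if (is.null(y)) stop("forward model diverged at the posterior mean")
  colnames(y) <- object$spec$regions$names
  y
}

#' Simulate BOLD series from the posterior of a fitted model
#'
#' Draws parameter vectors from the Gaussian posterior, runs the forward
#' model, and adds observation noise at the estimated per-region precision.
#'
#' @param object a \code{dcm} fit
#' @param nsim number of simulated series
#' @param seed optional RNG seed
#' @param noise add Gaussian observation noise
#' @param ... ignored
#' @return list of n_volumes x n matrices
#' @export
simulate.dcm <- function(object, nsim = 1, seed = NULL, noise = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(nsim, object$theta, object$Sigma)
  if (nsim == 1) draws <- matrix(draws, nrow = 1)
  sdv <- sqrt(1 / object$lambda)
  bins <- volume_sample_bins(object$acq)
  lapply(seq_len(nsim), function(s) {
    y <- fast_predict(object$spec, draws[s, ], object$priors$table,
                      object$inputs$u, object$inputs$dt, bins,
                      object$constants, object$control$bound)
    if (is.null(y)) return(NULL)
    if (noise) y <- y + matrix(rnorm(length(y), sd = rep(sdv, each = nrow(y))),
                               nrow(y), ncol(y))
    colnames(y) <- object$spec$regions$names
    y
  })
}

#' Plot observed against fitted BOLD per region
#'
#' @param x a \code{dcm} fit
#' @param regions subset of region names to draw
#' @param ... passed to \code{matplot}
#' @export
plot.dcm <- function(x, regions = x$spec$regions$names, ...) {
  t_s <- (seq_len(nrow(x$data)) - 1) * x$acq$TR
  old <- graphics::par(mfrow = c(length(regions), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (r in regions) {
    graphics::matplot(t_s, cbind(x$data[, r], x$fitted[, r]), type = "l",
                      lty = c(1, 1), col = c("grey50", "firebrick"),
                      xlab = "time (s)", ylab = "BOLD (%)", main = r, ...)
  }
  invisible(x)
}
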