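## Post-selection parameter synthesis: Bayesian model averaging (across
## models, within subject, by sampling the mixture of Gaussian posteriors),
## Bayesian parameter averaging (across subjects, precision-weighted), and
## the conditional probability that a parameter is non-zero.

## align a fit's posterior onto a union parameter vector; absent = fixed at 0
union_parameters <- function(fits) {
  Reduce(union, lapply(fits, function(f) names(f$theta)))
}

#' Bayesian model averaging for one subject
#'
#' Mixture over a subset of fitted models: models are drawn according to
#' their probability and parameter vectors sampled from each Gaussian
#' posterior. Parameters excluded by a model's masks contribute exactly zero
#' when that model is drawn.
#'
#' @param fits named list of \code{dcm} fits (one per model) for one
#'   subject-session
#' @param model_probs probabilities over \code{subset} (normalized
#'   internally); typically random-effects expected frequencies
#' @param subset model ids to average over (default: all of \code{fits})
#' @param nsamp number of mixture samples
#' @param seed RNG seed
#' @return object of class \code{dcm_bma} with per-parameter \code{mean},
#'   \code{sd}, \code{Pp}, the \code{samples} matrix and provenance
#' @export
bma <- function(fits, model_probs, subset = names(fits), nsamp = 1e4, seed = 1) {
  if (!length(subset)) stop("subset must be non-empty")
  if (!all(subset %in% names(fits)))
    stop("missing inversion for model(s): ",
         paste(setdiff(subset, names(fits)), collapse = ", "))
  fits <- fits[subset]
  if (is.null(names(model_probs))) names(model_probs) <- subset
  w <- model_probs[subset]
  if (anyNA(w)) stop("model_probs must cover the subset")
  w <- w / sum(w)
  pars <- union_parameters(fits)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, nsamp, w))
  samples <- matrix(0, nsamp, length(pars), dimnames = list(NULL, pars))
  row0 <- 0L
  for (m in seq_along(fits)) {
    if (counts[m] == 0) next
    f <- fits[[m]]
    sd0 <- sqrt(pmax(diag(f$Sigma), 0))
    if (all(sd0 < 1e-14)) {
      draw <- matrix(rep(f$theta, each = counts[m]), counts[m],
                     dimnames = list(NULL, names(f$theta)))
    } else {
      draw <- MASS::mvrnorm(counts[m], f$theta, f$Sigma)
      if (counts[m] == 1) draw <- matrix(draw, 1, dimnames = list(NULL, names(f$theta)))
    }
    samples[row0 + seq_len(counts[m]), colnames(draw)] <- draw
    row0 <- row0 + counts[m]
  }
  samples <- samples[sample.int(nsamp), , drop = FALSE]   # shuffle model blocks
  mu <- colMeans(samples)
  sdv <- apply(samples, 2, sd)
  pp <- vapply(pars, function(p) {
    s <- samples[, p]
    max(mean(s > 0), mean(s < 0))
  }, 0)
  structure(list(mean = mu, sd = sdv, Pp = pp, samples = samples,
                 models = subset, weights = w, nsamp = nsamp, seed = seed),
            class = "dcm_bma")
}

#' @export
print.dcm_bma <- function(x, digits = 3, ...) {
  cat("Bayesian model average over", length(x$models), "models (",
      paste(x$models, collapse = ", "), ")\n")
  tab <- data.frame(parameter = names(x$mean), mean = signif(x$mean, digits),
                    sd = signif(x$sd, digits), Pp = round(x$Pp, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bayesian parameter averaging across subjects
#'
#' Precision-weighted combination of Gaussian posteriors: group precision is
#' the sum of subject precisions, group mean the precision-weighted mean.
#'
#' @param posteriors list (one per subject) of either \code{dcm} fits or
#'   lists with \code{mean} and \code{sd} (or \code{cov}) over a common
#'   parameterization
#' @return list of class \code{dcm_bpa} with group \code{mean}, \code{sd}
#'   and per-parameter conditional probability \code{Pp}
#' @export
bpa <- function(posteriors) {
  if (length(posteriors) < 1) stop("need at least one subject posterior")
  get_ms <- function(p) {
    if (inherits(p, "dcm")) list(mean = p$theta, var = pmax(diag(p$Sigma), 0))
    else if (!is.null(p$sd)) list(mean = p$mean, var = p$sd^2)
    else list(mean = p$mean, var = pmax(diag(p$cov), 0))
  }
  ms <- lapply(posteriors, get_ms)
  nms <- names(ms[[1]]$mean)
  if (is.null(nms)) nms <- paste0("p", seq_along(ms[[1]]$mean))
  for (m in ms) if (length(m$mean) != length(nms))
    stop("subjects must share a common parameterization")
  prec <- sapply(ms, function(m) {
    if (any(m$var <= 0)) stop("zero-precision (infinite variance) input")
    1 / m$var
  })
  prec <- matrix(prec, nrow = length(nms))
  wsum <- sapply(ms, function(m) m$mean / m$var)
  wsum <- matrix(wsum, nrow = length(nms))
  gprec <- rowSums(prec)
  gmean <- rowSums(wsum) / gprec
  gsd <- sqrt(1 / gprec)
  structure(list(mean = setNames(gmean, nms), sd = setNames(gsd, nms),
                 Pp = setNames(conditional_probability(gmean, gsd), nms),
                 n_subjects = length(posteriors)),
            class = "dcm_bpa")
}

#' Conditional probability that a parameter is non-zero
#'
#' Sign-aware one-sided Gaussian mass: the posterior probability on the same
#' side of zero as the mean, \code{max(P(theta > 0), P(theta < 0))}. A zero
#' SD is reported as indistinguishable from 1 (with a warning-free flag via
#' the returned attribute).
#'
#' @param mean posterior mean(s)
#' @param sd posterior SD(s), non-negative
#' @param two_sided if \code{TRUE}, report the mass outside
#'   \code{[-threshold, threshold]} instead
#' @param threshold half-width used when \code{two_sided}
#' @export
conditional_probability <- function(mean, sd, two_sided = FALSE, threshold = 0) {
  stopifnot(all(sd >= 0))
  degenerate <- sd == 0
  sd[degenerate] <- .Machine$double.eps
  pp <- if (two_sided) {
    pnorm(-threshold, mean, sd) + pnorm(threshold, mean, sd, lower.tail = FALSE)
  } else {
    pmax(pnorm(0, mean, sd, lower.tail = FALSE), pnorm(0, mean, sd))
  }
  pp[degenerate] <- 1
  if (any(degenerate)) attr(pp, "degenerate") <- TRUE
  pp
}

#' Per-subject drug-minus-placebo parameter changes
#'
#' Elementwise difference of averaged posterior means between two matched
#' sessions, for the monitored connectivity parameters.
#'
#' @param placebo,drug subjects x parameters matrices of averaged posterior
#'   means (matching dimnames), or lists of \code{dcm_bma} objects
#' @param parameters optional subset of parameter names
#' @return subjects x parameters matrix of differences (drug - placebo)
#' @export
delta_parameters <- function(placebo, drug, parameters = NULL) {
  to_mat <- function(x) {
    if (is.list(x) && !is.data.frame(x) && inherits(x[[1]], "dcm_bma"))
      x <- do.call(rbind, lapply(x, `[[`, "mean"))
    as.matrix(x)
  }
  P <- to_mat(placebo)
  D <- to_mat(drug)
  if (!identical(dim(P), dim(D)) || !identical(colnames(P), colnames(D)))
    stop("session parameterizations do not match")
  if (!is.null(parameters)) {
    if (!all(parameters %in% colnames(P)))
      stop("unknown parameter(s): ",
           paste(setdiff(parameters, colnames(P)), collapse = ", "))
    P <- P[, parameters, drop = FALSE]
    D <- D[, parameters, drop = FALSE]
  }
  D - P
}
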