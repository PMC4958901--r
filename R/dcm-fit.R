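## Variational-Laplace inversion: Gauss-Newton/EM ascent on the free energy
## F = accuracy - KL(posterior || prior), with a Gaussian (Laplace) posterior
## over the packed parameter vector and per-region noise precisions updated
## in closed form under a Gamma hyperprior.

#' Inversion settings
#'
#' @param max_iter maximum EM iterations
#' @param tol free-energy convergence tolerance (nats); iteration stops when
#'   the change stays below it for \code{tol_runs} consecutive iterations
#' @param tol_runs consecutive small-change iterations required
#' @param fd_step forward-difference step for the prediction Jacobian
#' @param max_tries damping increases attempted per iteration when a step
#'   lowers the free energy or destabilizes the dynamics
#' @param bound divergence bound on neural states
#' @param verbose print the free-energy trace
#' @export
dcm_control <- function(max_iter = 128L, tol = 1e-2, tol_runs = 3L,
                        fd_step = 1e-3, max_tries = 6L, bound = 16,
                        verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol = tol, tol_runs = as.integer(tol_runs),
       fd_step = fd_step, max_tries = as.integer(max_tries),
       bound = bound, verbose = verbose)
}

## integer index encoding of the parameter table for the C++ fast path
block_codes <- c(self = 0L, A = 1L, B = 2L, C = 3L, D = 4L,
                 hemo.decay = 5L, hemo.transit = 6L, hemo.epsilon = 7L)
hemo_base <- c(decay = 0.64, transit = 2, epsilon = 1)

pack_table <- function(tab) {
  list(block = unname(block_codes[tab$block]), i = as.integer(tab$i),
       j = as.integer(tab$j), k = as.integer(tab$k))
}

## unvalidated hot-path prediction from a packed parameter vector
fast_predict <- function(spec, theta, tab, u, dt, sample_bins, constants, bound,
                         pk = pack_table(tab)) {
  res <- cpp_predict_packed(as.numeric(theta), pk$block, pk$i, pk$j, pk$k,
                            spec$regions$n, u, dt, as.integer(sample_bins),
                            constants, hemo_base, bound)
  if (isTRUE(res$diverged)) return(NULL)
  res$y
}

#' Free energy of a Gaussian posterior
#'
#' Accuracy minus complexity: the expected Gaussian log-likelihood of the
#' residuals (with the optional Jacobian trace correction for posterior
#' uncertainty) minus the closed-form Gaussian Kullback-Leibler divergence
#' from the prior. A singular posterior covariance is regularized with a
#' logged jitter.
#'
#' @param posterior list with \code{mean} and \code{cov}
#' @param prior list with \code{mean} and \code{cov} (or a \code{dcm_priors},
#'   whose diagonal covariance is used)
#' @param residuals n_volumes x n_regions residual matrix
#' @param lambda per-region noise precisions
#' @param J optional stacked Jacobian (rows ordered region-block by region)
#' @return list with \code{F}, \code{accuracy}, \code{complexity},
#'   \code{jitter}
#' @export
free_energy <- function(posterior, prior, residuals, lambda, J = NULL) {
  if (inherits(prior, "dcm_priors"))
    prior <- list(mean = prior$mean, cov = diag(prior$var, length(prior$var)))
  residuals <- as.matrix(residuals)
  nvol <- nrow(residuals)
  nreg <- ncol(residuals)
  stopifnot(length(lambda) == nreg)
  sse <- colSums(residuals^2)
  acc <- sum(-0.5 * lambda * sse + 0.5 * nvol * log(lambda) - 0.5 * nvol * log(2 * pi))
  if (!is.null(J)) {
    JS <- J %*% posterior$cov
    tr <- rowSums(JS * J)                      # diag(J Sigma J^T)
    w <- rep(lambda, each = nvol)
    acc <- acc - 0.5 * sum(w * tr)
  }
  sc <- safe_chol(posterior$cov)
  cov_reg <- posterior$cov + diag(sc$jitter, nrow(posterior$cov))
  cmp <- kl_gaussian(posterior$mean, cov_reg, prior$mean, prior$cov)
  list(F = acc - cmp, accuracy = acc, complexity = cmp, jitter = sc$jitter)
}

#' Invert a network model to a region time-series
#'
#' Fits one candidate model to one subject-session by expectation-maximization
#' with Gauss-Newton updates on a local linearization of the forward model.
#' Steps are accepted only when they increase the free energy; rejected steps
#' are halved. Per-region Gaussian noise precisions are re-estimated in closed
#' form each iteration. The optimization is deterministic given its settings.
#'
#' @param spec a \code{dcm_model}
#' @param data n_volumes x n_regions matrix (or data.frame with a
#'   \code{time_s} column plus one column per region) of observed BOLD
#' @param inputs a \code{\link{dcm_inputs}} spanning the acquisition
#' @param acq an \code{\link{acquisition}}
#' @param priors a \code{\link{default_priors}} object
#' @param control a \code{\link{dcm_control}}
#' @param constants shared balloon constants
#' @return an object of class \code{dcm}: posterior mean and covariance over
#'   the packed parameters, per-region noise precisions, the free energy
#'   \code{F} with its iteration trace, fitted values and residuals
#' @export
dcm <- function(spec, data, inputs, acq, priors = default_priors(spec),
                control = dcm_control(), constants = balloon_constants()) {
  nm <- spec$regions$names
  if (is.data.frame(data)) {
    if (!all(nm %in% names(data)))
      stop("data must contain one column per region: ", paste(nm, collapse = ", "))
    data <- as.matrix(data[, nm, drop = FALSE])
  }
  if (nrow(data) != acq$n_volumes)
    stop("data has ", nrow(data), " volumes but acquisition declares ", acq$n_volumes)
  if (anyNA(data)) stop("time-series must be complete (no missing volumes)")
  bins <- volume_sample_bins(acq)
  if (inputs$n_bins < max(bins)) stop("inputs do not span the acquisition window")

  tab <- priors$table
  p <- nrow(tab)
  mu0 <- as.numeric(priors$mean)
  P0 <- diag(1 / as.numeric(priors$var), p)
  S0 <- diag(as.numeric(priors$var), p)
  nvol <- nrow(data)
  nreg <- ncol(data)
  a0 <- priors$noise$a0
  b0 <- priors$noise$b0

  pk <- pack_table(tab)
  predict_y <- function(theta)
    fast_predict(spec, theta, tab, inputs$u, inputs$dt, bins, constants,
                 control$bound, pk = pk)

  jacobian <- function(theta) {
    res <- cpp_jacobian_packed(as.numeric(theta), pk$block, pk$i, pk$j, pk$k,
                               spec$regions$n, inputs$u, inputs$dt,
                               as.integer(bins), constants, hemo_base,
                               control$bound, control$fd_step)
    if (isTRUE(res$diverged))
      stop("Jacobian evaluation diverged",
           if (res$param > 0) paste0(" for ", tab$name[res$param]) else "")
    res
  }

  theta <- mu0
  y0 <- predict_y(theta)
  if (is.null(y0)) stop("forward model diverges at the prior mean")
  r <- data - y0
  lambda <- pmin(pmax(nvol / (colSums(r^2) + 1e-8), 1e-6), 1e8)
  Sigma <- S0
  fe <- free_energy(list(mean = theta, cov = Sigma), priors, r, lambda)
  F_curr <- fe$F
  F_trace <- F_curr
  converged <- FALSE
  small_runs <- 0L
  grad_norm <- NA_real_
  nu <- 0                        # Levenberg-Marquardt damping

  for (iter in seq_len(control$max_iter)) {
    J <- jacobian(theta)$J
    W <- rep(lambda, each = nvol)
    JtL <- t(J * W)
    P <- JtL %*% J + P0
    Sigma <- chol2inv(safe_chol(P)$chol)
    g <- JtL %*% as.numeric(r) - P0 %*% (theta - mu0)
    grad_norm <- sqrt(sum(g^2))

    # noise precision update (Gamma hyperprior, closed form), then re-baseline
    # the free energy under the new precisions before judging the step
    JS <- J %*% Sigma
    trJ <- rowSums(JS * J)
    tr_reg <- colSums(matrix(trJ, nvol, nreg))
    sse <- colSums(r^2)
    lambda <- pmin(pmax((nvol / 2 + a0) / (sse / 2 + tr_reg / 2 + b0), 1e-6), 1e8)
    F_curr <- free_energy(list(mean = theta, cov = Sigma), priors, r, lambda, J = J)$F

    # damped Gauss-Newton step; rejected steps raise the damping, which bends
    # the update towards the gradient and shortens it
    accepted <- FALSE
    for (h in seq_len(control$max_tries)) {
      P_try <- P + diag(nu * diag(P), nrow(P))
      step <- as.numeric(chol2inv(safe_chol(P_try)$chol) %*% g)
      cand <- theta + step
      y1 <- predict_y(cand)
      if (!is.null(y1)) {
        r1 <- data - y1
        fe1 <- free_energy(list(mean = cand, cov = Sigma), priors, r1, lambda, J = J)
        if (fe1$F > F_curr - 1e-9) {
          theta <- cand; y0 <- y1; r <- r1; F_new <- fe1$F
          accepted <- TRUE
          nu <- if (nu < 1e-3) 0 else nu / 4
          break
        }
      }
      nu <- max(nu * 8, 1e-2)
    }
    if (!accepted) F_new <- F_curr       # no improving step found: keep iterate
    if (control$verbose)
      cat(sprintf("iter %3d  F = %.4f  (damping %.3g)\n", iter, F_new, nu))
    F_trace <- c(F_trace, F_new)
    if (accepted && abs(F_new - F_curr) < control$tol) small_runs <- small_runs + 1L
    else if (accepted) small_runs <- 0L
    else small_runs <- small_runs + 1L   # stalled iteration
    F_curr <- F_new
    if (small_runs >= control$tol_runs) { converged <- TRUE; break }
  }

  # final posterior covariance at the optimum
  J <- jacobian(theta)$J
  W <- rep(lambda, each = nvol)
  P <- t(J * W) %*% J + P0
  Sigma <- chol2inv(safe_chol(P)$chol)
  fe <- free_energy(list(mean = theta, cov = Sigma), priors, r, lambda, J = J)
  names(theta) <- tab$name
  dimnames(Sigma) <- list(tab$name, tab$name)

  structure(list(spec = spec, theta = theta, Sigma = Sigma, lambda = lambda,
                 F = fe$F, accuracy = fe$accuracy, complexity = fe$complexity,
                 F_trace = F_trace, converged = converged,
                 iterations = length(F_trace) - 1L, grad_norm = grad_norm,
                 data = data, fitted = y0, residuals = r,
                 inputs = inputs, acq = acq, priors = priors,
                 constants = constants, control = control),
            class = "dcm")
}

#' Free energies of every model in a space for one session
#'
#' Convenience wrapper that inverts each candidate model to the same data and
#' collects the free energies, the row of an evidence matrix.
#'
#' @param data,inputs,acq as in \code{\link{dcm}}
#' @param space a \code{dcm_model_space}
#' @param control a \code{\link{dcm_control}}
#' @param keep_fits return the full \code{dcm} objects as well
#' @export
fit_model_space <- function(data, inputs, acq, space = enumerate_models(),
                            control = dcm_control(), keep_fits = FALSE) {
  fits <- lapply(space, function(sp) dcm(sp, data, inputs, acq, control = control))
  Fv <- vapply(fits, `[[`, 0, "F")
  if (keep_fits) list(F = Fv, fits = fits) else Fv
}
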