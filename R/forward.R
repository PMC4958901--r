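## Deterministic generative forward model: neural dynamics with bilinear and
## activity-gated coupling, observed through the balloon-Windkessel model.

#' Shared balloon-model constants
#'
#' Fixed haemodynamic constants: vasodilatory autoregulation rate, Grubb's
#' vessel stiffness exponent, resting oxygen extraction fraction, resting
#' venous blood volume fraction, and the field-dependent BOLD signal
#' coefficients (frequency offset \code{theta0}, intravascular relaxation
#' slope \code{r0}, echo time \code{TE}). Per-region decay, transit and
#' epsilon live in \code{\link{hemodynamic_params}}.
#'
#' @param gamma autoregulatory feedback rate (1/s)
#' @param alpha Grubb exponent (dimensionless)
#' @param E0 resting oxygen extraction fraction
#' @param V0 resting venous volume fraction
#' @param theta0 frequency offset at the outer surface of magnetized vessels (1/s)
#' @param r0 intravascular relaxation rate slope (1/s)
#' @param TE echo time (s)
#' @export
balloon_constants <- function(gamma = 0.32, alpha = 0.32, E0 = 0.4, V0 = 0.04,
                              theta0 = 40.3, r0 = 25, TE = 0.03) {
  stopifnot(gamma > 0, alpha > 0, alpha < 1, E0 > 0, E0 < 1, V0 > 0, TE > 0)
  list(gamma = gamma, alpha = alpha, E0 = E0, V0 = V0,
       theta0 = theta0, r0 = r0, TE = TE)
}

#' Per-region haemodynamic parameters
#'
#' @param n number of regions (recycled if scalars given)
#' @param decay vasodilatory signal decay rate (1/s)
#' @param transit mean venous transit time (s)
#' @param epsilon intra/extravascular signal ratio (dimensionless)
#' @param constants shared constants from \code{\link{balloon_constants}}
#' @export
hemodynamic_params <- function(n, decay = 0.64, transit = 2, epsilon = 1,
                               constants = balloon_constants()) {
  decay <- rep_len(decay, n); transit <- rep_len(transit, n)
  epsilon <- rep_len(epsilon, n)
  if (any(decay <= 0) || any(transit <= 0) || any(epsilon <= 0))
    stop("decay, transit and epsilon must all be positive")
  structure(list(decay = decay, transit = transit, epsilon = epsilon,
                 constants = constants), class = "hemodynamic_params")
}

#' Coupling parameters of the neural state equation
#'
#' \code{A} holds average coupling rates (Hz; negative diagonal), \code{B}
#' the per-input bilinear changes, \code{C} driving gains and \code{D} the
#' per-source-region non-linear gating gains. Entries outside the model's
#' masks must be exactly zero.
#'
#' @param A n x n matrix (row = target, column = source)
#' @param B n x n x m array (slice per input channel), or NULL for none
#' @param C n x m driving gain matrix
#' @param D n x n x n array (slice per gating source region), or NULL
#' @param spec optional \code{dcm_model} whose masks are enforced
#' @export
coupling_params <- function(A, B = NULL, C, D = NULL, spec = NULL) {
  n <- nrow(A)
  m <- ncol(C)
  if (is.null(B)) B <- array(0, c(n, n, m))
  if (is.null(D)) D <- array(0, c(n, n, n))
  stopifnot(ncol(A) == n, nrow(C) == n, dim(B)[1] == n, dim(B)[3] == m,
            all(dim(D) == n))
  if (any(diag(A) >= 0)) stop("self-connections (diagonal of A) must be negative")
  if (!is.null(spec)) {
    msk <- spec$masks
    offdiag <- !diag(TRUE, n)
    if (any(A[!msk$A & offdiag] != 0)) stop("A has entries outside the model mask")
    if (any(B[!msk$B] != 0)) stop("B has entries outside the model mask")
    if (any(C[!msk$C] != 0)) stop("C has entries outside the model mask")
    if (any(D[!msk$D] != 0)) stop("D has entries outside the model mask")
  }
  structure(list(A = A, B = B, C = C, D = D), class = "coupling_params")
}

#' Input time-courses on the microtime grid
#'
#' @param u n_bins x m matrix of input channels (piecewise constant per bin)
#' @param dt microtime step (s)
#' @export
dcm_inputs <- function(u, dt) {
  u <- as.matrix(u)
  stopifnot(dt > 0, is.numeric(u))
  structure(list(u = u, dt = dt, n_bins = nrow(u), channels = colnames(u)),
            class = "dcm_inputs")
}

#' Acquisition metadata
#'
#' @param TR repetition time (s)
#' @param n_volumes number of volumes
#' @param microtime_bins microtime bins per TR (integration resolution)
#' @export
acquisition <- function(TR = 2, n_volumes, microtime_bins = 16L) {
  stopifnot(TR > 0, n_volumes >= 1, microtime_bins >= 1)
  list(TR = TR, n_volumes = as.integer(n_volumes),
       microtime_bins = as.integer(microtime_bins),
       dt = TR / microtime_bins)
}

#' Integrate the neural state equation
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' \code{dz/dt = (A + sum_j u_j B_j + sum_k z_k D_k) z + C u} with inputs held
#' constant within each microtime bin.
#'
#' @param spec a \code{dcm_model} (masks are enforced on \code{params})
#' @param params a \code{\link{coupling_params}} object
#' @param inputs a \code{\link{dcm_inputs}} object
#' @param z0 initial neural state (default rest, all zero)
#' @param bound divergence bound on |z|; exceeding it raises an error naming
#'   the offending parameters
#' @return n_bins x n matrix of neural states at bin-start times
#' @export
simulate_neural <- function(spec, params, inputs, z0 = NULL, bound = 16) {
  n <- spec$regions$n
  if (is.null(z0)) z0 <- numeric(n)
  coupling_params(params$A, params$B, params$C, params$D, spec = spec)
  res <- cpp_simulate_neural(params$A, as.numeric(params$B), params$C,
                             as.numeric(params$D), inputs$u, inputs$dt,
                             z0, bound)
  if (isTRUE(res$diverged)) {
    stop("neural dynamics diverged at t = ", round((res$bin - 1) * inputs$dt, 3),
         " s (|z| > ", bound, "); A diagonal = ",
         paste(round(diag(params$A), 3), collapse = ", "),
         "; max |off-diagonal A| = ",
         round(max(abs(params$A - diag(diag(params$A)))), 3))
  }
  z <- res$z
  colnames(z) <- spec$regions$names
  z
}

volume_sample_bins <- function(acq) {
  # volume i is read at t = (i-1) * TR, i.e. microtime bin (i-1)*bins_per_TR + 1
  as.integer((seq_len(acq$n_volumes) - 1L) * acq$microtime_bins + 1L)
}

#' Integrate the balloon observation model and emit BOLD
#'
#' Per region, the vasodilatory signal, inflow, venous volume and
#' deoxyhaemoglobin states are integrated (RK4, same microtime grid as the
#' neural states) and the static non-linear BOLD equation is read out at each
#' volume time, in percent signal change.
#'
#' @param z n_bins x n neural state matrix (microtime grid)
#' @param hemo a \code{\link{hemodynamic_params}}
#' @param acq an \code{\link{acquisition}}; \code{n_bins} must span it
#' @param dt microtime step of \code{z} (defaults to \code{acq$dt})
#' @return n_volumes x n matrix of BOLD percent signal change
#' @export
simulate_bold <- function(z, hemo, acq, dt = acq$dt) {
  z <- as.matrix(z)
  bins <- volume_sample_bins(acq)
  if (nrow(z) < max(bins)) stop("neural series does not span the acquisition window")
  cs <- hemo$constants
  res <- cpp_simulate_bold(z, dt, hemo$decay, cs$gamma, hemo$transit, cs$alpha,
                           cs$E0, cs$V0, hemo$epsilon, cs$theta0, cs$r0, cs$TE,
                           bins)
  if (isTRUE(res$diverged)) stop("balloon model diverged; check parameters")
  y <- res$y
  colnames(y) <- colnames(z)
  y
}

#' Predict a region time-series from a full parameter set
#'
#' Composition of \code{\link{simulate_neural}} and
#' \code{\link{simulate_bold}}; deterministic given its arguments.
#'
#' @inheritParams simulate_neural
#' @param hemo a \code{\link{hemodynamic_params}}
#' @param acq an \code{\link{acquisition}}
#' @return n_volumes x n matrix of predicted BOLD (percent)
#' @export
predict_timeseries <- function(spec, params, hemo, inputs, acq) {
  z <- simulate_neural(spec, params, inputs)
  simulate_bold(z, hemo, acq, dt = inputs$dt)
}
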