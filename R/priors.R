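## Priors over the free parameters of one model. Off-diagonal couplings,
## bilinear and gating gains are zero-mean Gaussians in Hz; self-connections
## are parameterized as a_ii = -0.5 * exp(theta) so that any draw is
## intrinsically stable, with a liberal variance relative to the couplings;
## haemodynamic decay/transit/epsilon are log-normal scalings of the standard
## balloon constants.

prior_defaults <- function() {
  list(var_self = 1 / 2,      # log-scaling of the -0.5 Hz self-connection
       var_offdiag = 1 / 4,   # average coupling (Hz^2); liberal, see vignette
       var_b = 1 / 16,        # bilinear modulation (Hz^2)
       var_c = 1,             # driving gains
       var_d = 1 / 16,        # non-linear gating gains
       var_hemo = 0.0625,     # log-scalings of decay/transit/epsilon
       noise_a0 = 1e-2,       # Gamma hyperprior on region noise precision
       noise_b0 = 1e-4)
}

#' Build the free-parameter table of a model
#'
#' One row per free parameter with its block, matrix indices and prior
#' moments. The packing order is: self-connections, off-diagonal A, B, C, D,
#' then per-region decay/transit/epsilon log-scalings.
#'
#' @keywords internal
param_table <- function(spec, config = prior_defaults()) {
  nm <- spec$regions$names
  n <- spec$regions$n
  m <- spec$masks
  rows <- list()
  add <- function(name, block, i, j, k, pv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, block = block, i = i, j = j, k = k,
      prior_mean = 0, prior_var = pv, stringsAsFactors = FALSE)
  }
  for (r in seq_len(n)) add(paste0("self.", nm[r]), "self", r, r, 0L, config$var_self)
  offd <- which(m$A & !diag(TRUE, n), arr.ind = TRUE)
  if (nrow(offd)) for (q in seq_len(nrow(offd)))
    add(paste0("A.", nm[offd[q, 2]], "->", nm[offd[q, 1]]), "A",
        offd[q, 1], offd[q, 2], 0L, config$var_offdiag)
  for (ch in seq_len(dim(m$B)[3])) {
    idx <- which(m$B[, , ch], arr.ind = TRUE)
    if (nrow(idx)) for (q in seq_len(nrow(idx)))
      add(paste0("B.", dimnames(m$B)[[3]][ch], ".", nm[idx[q, 2]], "->", nm[idx[q, 1]]),
          "B", idx[q, 1], idx[q, 2], ch, config$var_b)
  }
  for (ch in seq_len(ncol(m$C))) {
    idx <- which(m$C[, ch])
    for (r in idx)
      add(paste0("C.", colnames(m$C)[ch], "->", nm[r]), "C", r, ch, 0L, config$var_c)
  }
  for (g in seq_len(n)) {
    idx <- which(m$D[, , g], arr.ind = TRUE)
    if (nrow(idx)) for (q in seq_len(nrow(idx)))
      add(paste0("D.", nm[g], ".", nm[idx[q, 2]], "->", nm[idx[q, 1]]), "D",
          idx[q, 1], idx[q, 2], g, config$var_d)
  }
  for (r in seq_len(n)) {
    add(paste0("hemo.decay.", nm[r]), "hemo.decay", r, 0L, 0L, config$var_hemo)
    add(paste0("hemo.transit.", nm[r]), "hemo.transit", r, 0L, 0L, config$var_hemo)
    add(paste0("hemo.epsilon.", nm[r]), "hemo.epsilon", r, 0L, 0L, config$var_hemo)
  }
  do.call(rbind, rows)
}

#' Default priors for a model specification
#'
#' @param spec a \code{dcm_model}
#' @param config list of prior variances and noise hyperparameters
#'   (see \code{stopdcm:::prior_defaults})
#' @return object of class \code{dcm_priors} with mean/variance per free
#'   parameter and the per-region noise-precision hyperprior
#' @export
default_priors <- function(spec, config = prior_defaults()) {
  tab <- param_table(spec, config)
  structure(list(table = tab,
                 mean = setNames(tab$prior_mean, tab$name),
                 var = setNames(tab$prior_var, tab$name),
                 noise = list(a0 = config$noise_a0, b0 = config$noise_b0),
                 config = config),
            class = "dcm_priors")
}

#' Prior variance of a named parameter
#'
#' Parameters excluded by the model's masks are fixed at zero: their prior
#' variance is exactly 0.
#'
#' @param priors a \code{dcm_priors}
#' @param name parameter name(s)
#' @export
prior_variance <- function(priors, name) {
  out <- priors$var[name]
  out[is.na(out)] <- 0
  setNames(as.numeric(out), name)
}

#' Draw coupling/haemodynamic parameters from the prior
#'
#' By default the draw is restricted to the stable domain (all eigenvalues
#' of A with negative real part) by rejection, mirroring priors chosen to
#' keep the optimizer away from unstable excursions; the Gaussian prior used
#' by the inversion itself is untruncated.
#'
#' @param spec a \code{dcm_model}
#' @param priors a \code{dcm_priors}
#' @param constants shared balloon constants
#' @param stable reject draws whose A matrix is unstable
#' @param max_tries rejection budget before erroring
#' @return list with elements \code{theta}, \code{coupling}
#'   (\code{\link{coupling_params}}) and \code{hemo}
#' @export
prior_draw <- function(spec, priors = default_priors(spec),
                       constants = balloon_constants(), stable = TRUE,
                       max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    theta <- rnorm(nrow(priors$table), priors$table$prior_mean,
                   sqrt(priors$table$prior_var))
    names(theta) <- priors$table$name
    out <- c(list(theta = theta),
             theta_to_params(spec, theta, priors$table, constants))
    if (!stable) return(out)
    ev <- eigen(out$coupling$A, only.values = TRUE)$values
    if (all(Re(ev) < 0)) return(out)
  }
  stop("no stable draw within ", max_tries, " tries")
}

## map a packed parameter vector to coupling + haemodynamic parameters
theta_to_params <- function(spec, theta, tab, constants = balloon_constants()) {
  n <- spec$regions$n
  nm <- spec$regions$names
  n_inputs <- dim(spec$masks$B)[3]
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  B <- array(0, c(n, n, n_inputs), dimnames = dimnames(spec$masks$B))
  C <- matrix(0, n, n_inputs, dimnames = dimnames(spec$masks$C))
  D <- array(0, c(n, n, n), dimnames = dimnames(spec$masks$D))
  decay <- rep(0, n); transit <- rep(0, n); epsilon <- rep(0, n)
  for (q in seq_len(nrow(tab))) {
    v <- theta[q]
    switch(tab$block[q],
      self = { A[tab$i[q], tab$j[q]] <- -0.5 * exp(v) },
      A = { A[tab$i[q], tab$j[q]] <- v },
      B = { B[tab$i[q], tab$j[q], tab$k[q]] <- v },
      C = { C[tab$i[q], tab$j[q]] <- v },
      D = { D[tab$i[q], tab$j[q], tab$k[q]] <- v },
      hemo.decay = { decay[tab$i[q]] <- v },
      hemo.transit = { transit[tab$i[q]] <- v },
      hemo.epsilon = { epsilon[tab$i[q]] <- v })
  }
  hemo <- hemodynamic_params(n, decay = 0.64 * exp(decay),
                             transit = 2 * exp(transit),
                             epsilon = 1 * exp(epsilon),
                             constants = constants)
  list(coupling = coupling_params(A, B, C, D), hemo = hemo)
}

## natural-units report of a packed parameter vector (self/hemo transformed)
theta_natural <- function(theta, tab) {
  out <- theta
  sel <- tab$block == "self"
  out[sel] <- -0.5 * exp(theta[sel])
  out[tab$block == "hemo.decay"] <- 0.64 * exp(theta[tab$block == "hemo.decay"])
  out[tab$block == "hemo.transit"] <- 2 * exp(theta[tab$block == "hemo.transit"])
  out[tab$block == "hemo.epsilon"] <- exp(theta[tab$block == "hemo.epsilon"])
  out
}
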