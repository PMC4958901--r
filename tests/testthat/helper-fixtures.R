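# Shared fixtures built in code: small acquisition grids, diagonal coupling
# sets, and reduced inversion settings used throughout the suite.

test_acq <- function(n_volumes = 60, microtime_bins = 8, TR = 2)
  acquisition(TR = TR, n_volumes = n_volumes, microtime_bins = microtime_bins)

# impulse input: one microtime bin of the task channel
impulse_inputs <- function(acq, bin = 5L, channel = 1L, value = 1) {
  nb <- acq$n_volumes * acq$microtime_bins
  u <- matrix(0, nb, 2, dimnames = list(NULL, c("task", "stop")))
  u[bin, channel] <- value
  dcm_inputs(u, acq$dt)
}

# decoupled coupling set: diagonal A, unit drive into chosen regions
diag_coupling <- function(spec, self = -0.5, drive = "preSMA", gain = 1) {
  n <- spec$regions$n
  nm <- spec$regions$names
  A <- diag(self, n)
  dimnames(A) <- list(nm, nm)
  C <- matrix(0, n, 2, dimnames = list(nm, c("task", "stop")))
  C[drive, "task"] <- gain
  coupling_params(A, C = C)
}

# reduced settings used for inversion-heavy tests
fast_control <- function(max_iter = 24L) dcm_control(max_iter = max_iter)

small_cohort_config <- function(...) {
  cohort_config(n_volumes = 100L, microtime_bins = 4L, ...)
}

nonlinear_presma_ids <- c("NAp", "NBp", "NCp", "NDp")
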