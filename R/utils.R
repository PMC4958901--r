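#' @useDynLib stopdcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef dnorm lm median pbeta pf pnorm pt qnorm quantile
#'   rbinom rexp rgamma rnorm runif sd setNames t.test var vcov aov
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw from a Dirichlet distribution
#'
#' Gamma-ratio sampler used by the random-effects model-selection routines.
#'
#' @param n number of draws
#' @param alpha concentration vector
#' @return n x length(alpha) matrix of frequency vectors
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  g / rowSums(g)
}

#' Ex-Gaussian random deviates
#'
#' Sum of a normal and an exponential component; the standard description of
#' skewed reaction-time distributions. Mean is \code{mu + tau}.
#'
#' @param n number of deviates
#' @param mu,sigma normal component mean and SD (ms)
#' @param tau exponential component mean (ms)
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

## KL divergence between two multivariate Gaussians KL(N0 || N1), closed form.
kl_gaussian <- function(mu0, S0, mu1, S1) {
  d <- length(mu0)
  ch1 <- chol(S1)
  ch0 <- chol(S0)
  logdet1 <- 2 * sum(log(diag(ch1)))
  logdet0 <- 2 * sum(log(diag(ch0)))
  S1inv <- chol2inv(ch1)
  dm <- mu1 - mu0
  0.5 * (sum(S1inv * S0) + sum(dm * (S1inv %*% dm)) - d + logdet1 - logdet0)
}

## symmetrize + jitter a covariance until Cholesky succeeds; returns list
safe_chol <- function(S, max_tries = 8L) {
  S <- (S + t(S)) / 2
  jit <- 0
  for (i in seq_len(max_tries)) {
    ch <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = jit))
    jit <- if (jit == 0) 1e-10 * mean(diag(S)) else jit * 10
  }
  stop("covariance matrix could not be factorized even after regularization")
}

read_tsv_strict <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
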