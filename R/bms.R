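## Group-level Bayesian model selection over a subjects x models matrix of
## free energies: fixed-effects posteriors, the variational Dirichlet
## random-effects scheme with Monte-Carlo exceedance probabilities, the
## Bayesian omnibus risk protecting against the all-frequencies-equal null,
## family-level inference, and the three-step selection hierarchy.

as_evidence_matrix <- function(E) {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("evidence matrix must be finite")
  if (nrow(E) < 1 || ncol(E) < 2)
    stop("evidence matrix needs >= 1 subject and >= 2 models")
  if (is.null(colnames(E))) colnames(E) <- paste0("m", seq_len(ncol(E)))
  E
}

#' Fixed-effects Bayesian model selection
#'
#' Posterior model probabilities under the assumption that one common model
#' generated every subject's data: a softmax over the per-model summed free
#' energies with a uniform model prior. Invariant to adding a constant to all
#' free energies.
#'
#' @param E subjects x models matrix of free energies (nats)
#' @return named per-model posterior probability vector
#' @export
ffx_bms <- function(E) {
  E <- as_evidence_matrix(E)
  s <- colSums(E)
  s <- s - max(s)
  p <- exp(s) / sum(exp(s))
  setNames(p, colnames(E))
}

#' Random-effects Bayesian model selection
#'
#' Variational update of a Dirichlet posterior over population model
#' frequencies (uniform prior, alpha0 = 1 per model by default), with
#' exceedance probabilities estimated by seeded Monte-Carlo sampling of the
#' fitted Dirichlet.
#'
#' @param E subjects x models matrix of free energies
#' @param alpha0 Dirichlet prior counts (scalar or per model)
#' @param nsamp Monte-Carlo samples for the exceedance probabilities
#' @param seed RNG seed for the sampler
#' @param tol,max_iter convergence control of the variational iteration
#' @return list with \code{alpha} (Dirichlet counts),
#'   \code{expected_frequencies}, \code{xp}, the posterior assignment matrix
#'   \code{g}, and bookkeeping needed by \code{\link{protected_xp}}
#' @export
rfx_bms <- function(E, alpha0 = 1, nsamp = 1e6, seed = 1, tol = 1e-8,
                    max_iter = 512L) {
  E <- as_evidence_matrix(E)
  K <- ncol(E)
  N <- nrow(E)
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0 + N / K
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(lg - apply(lg, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    trace <- c(trace, delta)
    alpha <- alpha_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("random-effects update did not converge; last deltas: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = " "))
  xp <- dirichlet_exceedance(alpha, nsamp = nsamp, seed = seed)
  list(alpha = setNames(alpha, colnames(E)), alpha0 = alpha0,
       expected_frequencies = setNames(alpha / sum(alpha), colnames(E)),
       xp = setNames(xp, colnames(E)), g = g, E = E, iterations = it)
}

## P(r_k is the largest frequency) by chunked Dirichlet sampling
dirichlet_exceedance <- function(alpha, nsamp = 1e6, seed = 1,
                                 group = NULL, chunk = 1e5) {
  K <- if (is.null(group)) length(alpha) else length(unique(group))
  counts <- numeric(K)
  done <- 0
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  while (done < nsamp) {
    nb <- min(chunk, nsamp - done)
    r <- rdirichlet(nb, alpha)
    if (!is.null(group)) {
      r <- t(rowsum(t(r), group = group))   # reordered as sort(unique(group))
    }
    w <- max.col(r, ties.method = "first")
    counts <- counts + tabulate(w, nbins = K)
    done <- done + nb
  }
  counts / nsamp
}

## free energy of the random-effects frequency model (variational bound)
rfx_free_energy <- function(E, alpha, alpha0, g) {
  K <- ncol(E)
  Elogr <- digamma(alpha) - digamma(sum(alpha))
  eterm <- sum(g * E) + sum(sweep(g, 2, Elogr, `*`))
  ent_m <- -sum(g[g > 0] * log(g[g > 0]))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * Elogr)
  eterm + ent_m - kl_dir
}

## free energy of the null: every model equally frequent a priori
null_free_energy <- function(E) {
  K <- ncol(E)
  sum(apply(E - log(K), 1, logsumexp))
}

#' Protected exceedance probabilities and Bayesian omnibus risk
#'
#' The Bayesian omnibus risk (BOR) is the posterior probability of the null
#' hypothesis that all model frequencies are equal, computed from the free
#' energies of the null and the random-effects frequency model. Exceedance
#' probabilities are then shrunk towards chance:
#' \code{pxp = xp * (1 - bor) + bor / K}.
#'
#' @inheritParams rfx_bms
#' @param rfx optional precomputed \code{\link{rfx_bms}} result
#' @return list with \code{pxp}, \code{xp}, \code{bor}, and the two free
#'   energies \code{F_rfx} and \code{F_null} for audit
#' @export
protected_xp <- function(E, alpha0 = 1, nsamp = 1e6, seed = 1, rfx = NULL) {
  if (is.null(rfx)) rfx <- rfx_bms(E, alpha0 = alpha0, nsamp = nsamp, seed = seed)
  E <- rfx$E
  K <- ncol(E)
  F1 <- rfx_free_energy(E, rfx$alpha, rfx$alpha0, rfx$g)
  F0 <- null_free_energy(E)
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- rfx$xp * (1 - bor) + bor / K
  list(pxp = pxp, xp = rfx$xp, bor = bor, F_rfx = F1, F_null = F0, rfx = rfx)
}

#' Family-level random-effects model selection
#'
#' Runs the random-effects scheme with the Dirichlet prior mass uniform over
#' families (divided equally among each family's members), then aggregates
#' frequencies within family. Family exceedance probabilities are the
#' probability that a family's summed frequency exceeds every other
#' family's.
#'
#' @param E subjects x models free-energy matrix
#' @param partition model -> family map: named character vector or factor
#'   covering the columns of \code{E}
#' @param prior_correction divide each family's prior mass equally among its
#'   members (the default); \code{FALSE} leaves a uniform per-model prior,
#'   so larger families carry more prior mass
#' @param nsamp,seed Monte-Carlo control
#' @return list with family-level \code{expected_frequencies}, \code{xp},
#'   \code{pxp}, \code{bor} and the underlying model-level result
#' @export
family_bms <- function(E, partition, prior_correction = TRUE, nsamp = 1e6,
                       seed = 1) {
  E <- as_evidence_matrix(E)
  if (!is.null(names(partition))) partition <- partition[colnames(E)]
  if (anyNA(partition) || length(partition) != ncol(E))
    stop("partition must cover every model column")
  fam <- factor(partition)
  sizes <- table(fam)
  if (any(sizes == 0)) stop("empty family in partition")
  alpha0 <- if (prior_correction) as.numeric(1 / sizes[fam]) else rep(1, ncol(E))
  rfx <- rfx_bms(E, alpha0 = alpha0, nsamp = nsamp, seed = seed)
  fam_freq <- tapply(rfx$expected_frequencies, fam, sum)
  fam_xp <- dirichlet_exceedance(rfx$alpha, nsamp = nsamp, seed = seed,
                                 group = fam)
  names(fam_xp) <- levels(fam)
  F1 <- rfx_free_energy(rfx$E, rfx$alpha, rfx$alpha0, rfx$g)
  F0 <- null_free_energy(rfx$E)
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- fam_xp * (1 - bor) + bor / nlevels(fam)
  list(families = levels(fam), sizes = as.integer(sizes),
       expected_frequencies = fam_freq[levels(fam)], xp = fam_xp, pxp = pxp,
       bor = bor, F_rfx = F1, F_null = F0, model_level = rfx)
}

#' Three-step hierarchical model selection
#'
#' Step 1 compares the 12 linear to the 8 non-linear models (family-level
#' random effects); step 2 compares, among the non-linear models, the two
#' gating sources (preSMA vs IFG); step 3 compares the four non-linear
#' preSMA models individually, with protected exceedance probabilities and
#' the Bayesian omnibus risk. With a single subject the random-effects
#' machinery is degenerate: a warning is raised and fixed-effects posteriors
#' are reported instead.
#'
#' @param E subjects x models free-energy matrix with model-id column names
#' @param space the \code{dcm_model_space} the columns refer to
#' @param xp_threshold exceedance probability treated as decisive
#' @param nsamp,seed Monte-Carlo control
#' @return object of class \code{dcm_selection} with per-step results and a
#'   decision trail
#' @export
hierarchical_selection <- function(E, space = enumerate_models(),
                                   xp_threshold = 0.9, nsamp = 1e6, seed = 1) {
  E <- as_evidence_matrix(E)
  ids <- colnames(E)
  missing <- setdiff(names(space), ids)
  if (length(missing))
    stop("evidence matrix must cover the full model space; missing: ",
         paste(missing, collapse = ", "))
  linearity <- vapply(space, `[[`, "", "linearity")[ids]
  gating <- vapply(space, `[[`, "", "gating_source")[ids]

  if (nrow(E) == 1) {
    warning("single subject: random-effects selection is degenerate; ",
            "reporting fixed-effects posteriors")
    p <- ffx_bms(E)
    step1 <- tapply(p, linearity, sum)
    nl <- gating != "none"
    step2 <- tapply(p[nl], gating[nl], sum)
    presma <- nl & gating == "preSMA"
    out <- list(method = "ffx", step1 = step1, step2 = step2,
                step3 = list(posterior = p[presma] / sum(p[presma])),
                trail = "single-subject fallback: fixed-effects posteriors")
    class(out) <- "dcm_selection"
    return(out)
  }

  step1 <- family_bms(E, setNames(linearity, ids), nsamp = nsamp, seed = seed)
  win1 <- names(which.max(step1$xp))
  nl_ids <- ids[gating != "none"]
  step2 <- family_bms(E[, nl_ids, drop = FALSE],
                      setNames(gating[nl_ids], nl_ids), nsamp = nsamp, seed = seed)
  win2 <- names(which.max(step2$xp))
  presma_ids <- ids[gating == "preSMA"]
  step3 <- protected_xp(E[, presma_ids, drop = FALSE], nsamp = nsamp, seed = seed)
  win3 <- names(which.max(step3$xp))

  fmt <- function(tag, win, xp)
    sprintf("%s: winner %s (XP = %.4f, %s threshold %.2f)", tag, win, max(xp),
            if (max(xp) > xp_threshold) "exceeds" else "below", xp_threshold)
  trail <- c(fmt("step 1 (linear vs non-linear)", win1, step1$xp),
             fmt("step 2 (gating source)", win2, step2$xp),
             fmt("step 3 (non-linear preSMA families)", win3, step3$xp),
             sprintf("step 3 BOR = %.4f", step3$bor))

  out <- list(method = "rfx", step1 = step1, step2 = step2, step3 = step3,
              winners = c(step1 = win1, step2 = win2, step3 = win3),
              xp_threshold = xp_threshold, trail = trail)
  class(out) <- "dcm_selection"
  out
}

#' @export
print.dcm_selection <- function(x, ...) {
  cat("Hierarchical model selection (", x$method, ")\n", sep = "")
  for (line in x$trail) cat(" ", line, "\n")
  if (x$method == "rfx") {
    cat("\nStep 3 (non-linear preSMA models):\n")
    tab <- data.frame(model = names(x$step3$xp), XP = round(x$step3$xp, 4),
                      pXP = round(x$step3$pxp, 4))
    print(tab, row.names = FALSE)
    cat("BOR =", round(x$step3$bor, 4), "\n")
  }
  invisible(x)
}

#' Outlier sensitivity of model selection
#'
#' Flags subjects whose monitored parameter values lie beyond a z-score
#' threshold from the group mean, repeats the selection without them, and
#' reports the change in the top-two summed-evidence gap and in the
#' exceedance probabilities.
#'
#' @param E subjects x models free-energy matrix
#' @param parameter_table subjects x parameters numeric table aligned with
#'   the rows of \code{E}
#' @param z_threshold flagging threshold in group SD units
#' @param nsamp,seed Monte-Carlo control
#' @export
outlier_sensitivity <- function(E, parameter_table, z_threshold = 2,
                                nsamp = 1e5, seed = 1) {
  E <- as_evidence_matrix(E)
  P <- as.matrix(parameter_table)
  if (nrow(P) != nrow(E)) stop("parameter table must align with subjects")
  z <- scale(P)
  z[is.nan(z)] <- 0
  flagged <- which(apply(abs(z) > z_threshold, 1, any))
  if (length(flagged) == nrow(E)) stop("all subjects flagged as outliers")

  top2_gap <- function(M) {
    s <- sort(colSums(M), decreasing = TRUE)
    s[1] - s[2]
  }
  full <- rfx_bms(E, nsamp = nsamp, seed = seed)
  if (length(flagged) == 0) {
    return(list(flagged = integer(0), z = z, delta_F_full = top2_gap(E),
                delta_F_reduced = top2_gap(E), xp_full = full$xp,
                xp_reduced = full$xp, changed = FALSE))
  }
  Ered <- E[-flagged, , drop = FALSE]
  red <- rfx_bms(Ered, nsamp = nsamp, seed = seed)
  list(flagged = flagged, z = z,
       delta_F_full = top2_gap(E), delta_F_reduced = top2_gap(Ered),
       xp_full = full$xp, xp_reduced = red$xp, changed = TRUE)
}

#' Read / write an evidence matrix as TSV
#'
#' Rows are subjects (first column \code{subject}), remaining columns models.
#'
#' @param E matrix to write
#' @param path file path
#' @export
write_evidence_matrix <- function(E, path) {
  df <- data.frame(subject = rownames(E) %||% paste0("sub-", seq_len(nrow(E))),
                   E, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_evidence_matrix
#' @export
read_evidence_matrix <- function(path) {
  df <- read_tsv_strict(path)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df[[1]]
  E
}
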