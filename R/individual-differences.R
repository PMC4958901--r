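## Individual-differences statistics: baseline-vs-change correlation for
## SSRT, multiple regression of drug-induced connectivity change on disease
## severity and plasma drug level, and the paired session comparison of the
## balloon-model haemodynamic parameters.

#' Correlation between baseline SSRT and its drug-induced change
#'
#' Pearson correlation (two-sided) between placebo-session SSRT and the
#' improvement, placebo minus drug.
#'
#' @param ssrt_placebo,ssrt_drug paired per-subject SSRT values (ms)
#' @return list with \code{r}, \code{p}, \code{n}, \code{change}
#' @export
baseline_change_correlation <- function(ssrt_placebo, ssrt_drug) {
  stopifnot(length(ssrt_placebo) == length(ssrt_drug))
  ok <- stats::complete.cases(ssrt_placebo, ssrt_drug)
  x <- ssrt_placebo[ok]
  change <- x - ssrt_drug[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(change) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, change, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), change = change)
}

#' Regress drug-induced connectivity change on severity and drug level
#'
#' Ordinary least squares of a drug-minus-placebo connectivity change on
#' UPDRS-III motor score and plasma drug level, both predictors and response
#' z-scored, so the coefficients are standardized betas. Zero-order Pearson
#' correlations are reported alongside.
#'
#' @param covariates data.frame with columns \code{updrs}, \code{drug_level}
#'   and the response column named by \code{response}
#' @param response name of the dependent Delta-connectivity column
#' @return object of class \code{delta_regression}: per-predictor
#'   standardized beta, t, p, and zero-order r with its p
#' @export
regress_deltas <- function(covariates, response) {
  need <- c("updrs", "drug_level", response)
  if (!all(need %in% names(covariates)))
    stop("covariates must contain columns: ", paste(need, collapse = ", "))
  df <- covariates[stats::complete.cases(covariates[, need]), need]
  X <- as.matrix(df[, c("updrs", "drug_level")])
  y <- df[[response]]
  if (nrow(df) < 4) stop("too few complete cases for two predictors")
  qrX <- qr(cbind(1, scale(X)))
  if (qrX$rank < 3) {
    cors <- abs(stats::cor(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X), collapse = ", "))
  }
  zx <- scale(X)
  zy <- as.numeric(scale(y))
  fit <- lm(zy ~ zx)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  rownames(co) <- colnames(X)
  zero_order <- t(vapply(colnames(X), function(v) {
    ct <- stats::cor.test(X[, v], y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }, c(r = 0, p = 0)))
  structure(list(response = response, n = nrow(df),
                 beta = setNames(co[, "Estimate"], rownames(co)),
                 t = setNames(co[, "t value"], rownames(co)),
                 p = setNames(co[, "Pr(>|t|)"], rownames(co)),
                 zero_order = zero_order, fit = fit),
            class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  cat("Multiple regression of", x$response, "( n =", x$n, ")\n")
  for (v in names(x$beta)) {
    cat(sprintf("  %-10s beta = %6.3f, t = %6.3f, p = %.4f;  r = %6.3f, p = %.4f\n",
                v, x$beta[v], x$t[v], x$p[v],
                x$zero_order[v, "r"], x$zero_order[v, "p"]))
  }
  invisible(x)
}

#' Paired session comparison of haemodynamic parameters
#'
#' Extracts per-subject posterior means of the balloon-model decay, transit
#' and epsilon parameters (region-averaged, natural units) from two matched
#' sessions and reports a paired t-test per parameter plus a
#' repeated-measures omnibus F for the session effect.
#'
#' @param session_a,session_b named lists of \code{dcm} fits (same subjects,
#'   same order; names are subject ids), or subjects x 3 matrices with
#'   columns decay, transit, epsilon
#' @return object of class \code{hemo_comparison}
#' @export
compare_hemodynamics <- function(session_a, session_b) {
  extract <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) {
      m <- as.matrix(x)
      stopifnot(all(c("decay", "transit", "epsilon") %in% colnames(m)))
      return(m[, c("decay", "transit", "epsilon")])
    }
    t(vapply(x, function(f) {
      est <- theta_natural(f$theta, f$priors$table)
      blk <- f$priors$table$block
      c(decay = mean(est[blk == "hemo.decay"]),
        transit = mean(est[blk == "hemo.transit"]),
        epsilon = mean(est[blk == "hemo.epsilon"]))
    }, c(decay = 0, transit = 0, epsilon = 0)))
  }
  A <- extract(session_a)
  B <- extract(session_b)
  if (nrow(A) != nrow(B)) stop("sessions must contain matched subjects")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("subject ids differ between sessions")
  n <- nrow(A)
  per_param <- lapply(c("decay", "transit", "epsilon"), function(p) {
    d <- B[, p] - A[, p]
    if (all(abs(d) < 1e-14)) return(list(parameter = p, t = 0, p_value = 1,
                                         mean_diff = 0))
    tt <- t.test(d)
    list(parameter = p, t = unname(tt$statistic), p_value = tt$p.value,
         mean_diff = mean(d))
  })
  # omnibus repeated-measures session effect across the three parameters
  d_all <- B - A
  if (all(abs(d_all) < 1e-14)) {
    omnibus <- list(F = 0, df1 = 1, df2 = n - 1, p_value = 1)
  } else {
    long <- data.frame(
      value = c(A, B),
      session = factor(rep(c("a", "b"), each = n * 3)),
      parameter = factor(rep(rep(c("decay", "transit", "epsilon"), each = n), 2)),
      subject = factor(rep(seq_len(n), 6)))
    fit <- aov(value ~ session * parameter + Error(subject / (session * parameter)),
               data = long)
    tab <- summary(fit)[["Error: subject:session"]][[1]]
    omnibus <- list(F = tab["session", "F value"], df1 = tab["session", "Df"],
                    df2 = tab["Residuals", "Df"], p_value = tab["session", "Pr(>F)"])
  }
  structure(list(per_parameter = per_param, omnibus = omnibus, n = n),
            class = "hemo_comparison")
}

#' @export
print.hemo_comparison <- function(x, ...) {
  cat("Haemodynamic parameters, paired session comparison ( n =", x$n, ")\n")
  for (pp in x$per_parameter)
    cat(sprintf("  %-8s mean diff = %8.4f, t = %7.3f, p = %.4f\n",
                pp$parameter, pp$mean_diff, pp$t, pp$p_value))
  cat(sprintf("  omnibus session effect: F(%d,%d) = %.3f, p = %.4f\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p_value))
  invisible(x)
}
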