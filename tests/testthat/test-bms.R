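# Selection oracles: closed-form softmax for fixed effects, the analytic
# Beta tail for two-model random effects, conservation and shift invariance,
# and the behaviour of the omnibus-risk-protected exceedance probabilities
# under null and decisive evidence.

test_that("fixed-effects posteriors match the closed-form softmax", {
  # 1 subject, 2 models, dF = 5: winner posterior = 1 / (1 + exp(-5))
  E <- matrix(c(5, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  p <- ffx_bms(E)
  expect_lt(abs(p["a"] - 1 / (1 + exp(-5))), 1e-12)
  # equal evidence: uniform
  E2 <- matrix(3, 4, 3)
  expect_true(all(abs(ffx_bms(E2) - 1 / 3) < 1e-12))
  # shift invariance
  set.seed(2)
  E3 <- matrix(rnorm(12), 4, 3)
  expect_lt(max(abs(ffx_bms(E3) - ffx_bms(E3 + 1000))), 1e-12)
  # general case against a direct softmax computed in the test
  s <- colSums(E3)
  expect_lt(max(abs(ffx_bms(E3) - exp(s - max(s)) / sum(exp(s - max(s))))), 1e-12)
})

test_that("two-model random-effects exceedance matches the analytic Beta tail", {
  set.seed(4)
  E <- matrix(rnorm(20, sd = 2), 10, 2)
  r <- rfx_bms(E, nsamp = 2e5, seed = 7)
  beta_tail <- pbeta(0.5, r$alpha[2], r$alpha[1])    # P(r1 > 0.5)
  expect_lt(abs(r$xp[1] - beta_tail), 0.01)
  # symmetric rows give XP = (0.5, 0.5)
  Esym <- matrix(1.3, 8, 2)
  rsym <- rfx_bms(Esym, nsamp = 2e5, seed = 8)
  expect_lt(max(abs(rsym$xp - 0.5)), 0.01)
})

test_that("unanimous evidence concentrates the exceedance probability", {
  E <- matrix(0, 10, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  E[, 1] <- 3                     # every subject: dF = +3 for model 1
  r <- rfx_bms(E, nsamp = 1e5, seed = 1)
  expect_gt(r$xp["m1"], 0.9)
  # oracle: high-count Dirichlet sampling of the same posterior
  xp_ref <- stopdcm:::dirichlet_exceedance(r$alpha, nsamp = 1e6, seed = 99)
  expect_lt(max(abs(r$xp - xp_ref)), 0.01)
})

test_that("probability vectors conserve mass and respect monotonicity", {
  set.seed(11)
  E <- matrix(rnorm(60), 12, 5)
  r <- rfx_bms(E, nsamp = 1e5, seed = 3)
  px <- protected_xp(E, nsamp = 1e5, seed = 3, rfx = r)
  expect_lt(abs(sum(ffx_bms(E)) - 1), 1e-6)
  expect_lt(abs(sum(r$expected_frequencies) - 1), 1e-6)
  expect_lt(abs(sum(r$xp) - 1), 1e-6)
  expect_lt(abs(sum(px$pxp) - 1), 1e-6)
  expect_identical(unname(px$pxp), unname(px$xp * (1 - px$bor) + px$bor / 5))
  # per-subject row shifts leave everything unchanged
  E2 <- E + matrix(rnorm(12, sd = 50), 12, 5)[, rep(1, 5)]
  r2 <- rfx_bms(E2, nsamp = 1e5, seed = 3)
  px2 <- protected_xp(E2, nsamp = 1e5, seed = 3, rfx = r2)
  expect_lt(max(abs(r2$expected_frequencies - r$expected_frequencies)), 1e-8)
  expect_lt(abs(px2$bor - px$bor), 1e-8)
  # raising one model's evidence never lowers its expected frequency
  E3 <- E; E3[4, 2] <- E3[4, 2] + 2
  r3 <- rfx_bms(E3, nsamp = 1e4, seed = 3)
  expect_gte(r3$expected_frequencies[2], r$expected_frequencies[2] - 1e-10)
})

test_that("null cohorts raise the omnibus risk; decisive cohorts suppress it", {
  K <- 4
  bors <- numeric(20)
  pxp_dev <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    E <- matrix(rnorm(10 * K, sd = 0.3), 10, K)    # i.i.d. noise around equality
    px <- protected_xp(E, nsamp = 2e4, seed = s)
    bors[s] <- px$bor
    pxp_dev[s] <- max(abs(px$pxp - 1 / K))
  }
  expect_gt(mean(bors), 0.8)
  expect_true(all(pxp_dev < 0.1))
  # strong unanimous evidence: BOR < 0.05 and pXP ~ XP
  E <- matrix(0, 20, K); E[, 2] <- 10
  px <- protected_xp(E, nsamp = 2e4, seed = 5)
  expect_lt(px$bor, 0.05)
  expect_lt(max(abs(px$pxp - px$xp)), 0.05)
  expect_true(is.finite(px$F_rfx) && is.finite(px$F_null))
})

test_that("family inference aggregates evidence with equal prior mass per family", {
  # symmetric families: uniform family XPs
  set.seed(21)
  shift <- matrix(rnorm(10, sd = 2), 10, 4)[, rep(1, 4)]
  E <- matrix(0, 10, 4, dimnames = list(NULL, paste0("m", 1:4))) + shift
  fam <- setNames(c("f1", "f1", "f2", "f2"), colnames(E))
  fb <- family_bms(E, fam, nsamp = 2e5, seed = 2)
  expect_lt(max(abs(fb$xp - 0.5)), 0.02)
  # duplicating a model inside a family leaves family XP unchanged (prior
  # mass correction): compare 2-vs-1 with duplicated copy against 1-vs-1
  set.seed(22)
  base <- matrix(rnorm(16, sd = 1.5), 8, 2,
                 dimnames = list(NULL, c("a", "b")))
  dup <- cbind(base[, "a", drop = FALSE], base)
  colnames(dup) <- c("a1", "a2", "b")
  f1 <- family_bms(base, c(a = "A", b = "B"), nsamp = 2e5, seed = 3)
  f2 <- family_bms(dup, c(a1 = "A", a2 = "A", b = "B"), nsamp = 2e5, seed = 3)
  expect_lt(abs(f1$xp["A"] - f2$xp["A"]), 0.02)
  # without the correction the duplicated family draws extra prior mass
  f3 <- family_bms(dup, c(a1 = "A", a2 = "A", b = "B"),
                   prior_correction = FALSE, nsamp = 2e5, seed = 3)
  expect_gt(f3$expected_frequencies["A"], f2$expected_frequencies["A"])
  # the 20-model manifest partitions into 4 families of 5
  space <- enumerate_models()
  fam20 <- vapply(space, `[[`, "", "family")
  expect_identical(as.integer(table(fam20)), rep(5L, 4))
  expect_error(family_bms(base, c(a = "A", b = NA)), "cover")
})

test_that("hierarchical selection recovers structure from synthetic evidence", {
  # build an evidence matrix with the signature of an NCp cohort
  space <- enumerate_models()
  ids <- names(space)
  set.seed(31)
  E <- matrix(rnorm(12 * 20, sd = 0.5), 12, 20, dimnames = list(NULL, ids))
  lin <- vapply(space, function(m) m$linearity == "linear", TRUE)
  E[, lin] <- E[, lin] - 8
  E[, "NAi"] <- E[, "NAi"] - 4; E[, "NBi"] <- E[, "NBi"] - 4
  E[, "NCi"] <- E[, "NCi"] - 4; E[, "NDi"] <- E[, "NDi"] - 4
  E[, "NCp"] <- E[, "NCp"] + 3
  sel <- hierarchical_selection(E, space, nsamp = 5e4, seed = 2)
  expect_identical(unname(sel$winners["step1"]), "nonlinear")
  expect_identical(unname(sel$winners["step2"]), "preSMA")
  expect_identical(unname(sel$winners["step3"]), "NCp")
  expect_gt(sel$step3$xp["NCp"], 0.9)
  # degenerate single-subject input falls back to fixed effects with warning
  expect_warning(s1 <- hierarchical_selection(E[1, , drop = FALSE], space),
                 "single subject")
  expect_identical(s1$method, "ffx")
  expect_lt(abs(sum(s1$step1) - 1), 1e-6)
})

test_that("outlier flagging and re-selection report the evidence shift", {
  set.seed(41)
  E <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  pars <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("d1", "d2")))
  # no outliers: reselection identical
  r0 <- outlier_sensitivity(E, pars, z_threshold = 10)
  expect_length(r0$flagged, 0)
  expect_identical(r0$xp_full, r0$xp_reduced)
  # threshold = Inf flags nothing even with an extreme subject
  pars2 <- pars; pars2[3, 1] <- mean(pars[, 1]) + 10 * sd(pars[, 1])
  expect_length(outlier_sensitivity(E, pars2, z_threshold = Inf)$flagged, 0)
  # planted extreme subject is flagged at z = 2 and the dF shift is reported
  r2 <- outlier_sensitivity(E, pars2, z_threshold = 2)
  expect_true(3 %in% r2$flagged)
  expect_true(is.finite(r2$delta_F_reduced - r2$delta_F_full))
  expect_error(outlier_sensitivity(E[1:2, ], pars2[1:2, ] * 0 + c(1, 100),
                                   z_threshold = 0.1), "all subjects")
})

test_that("evidence matrices round-trip through TSV", {
  E <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), c("m1", "m2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_matrix(E, path)
  E2 <- read_evidence_matrix(path)
  expect_equal(E2, E, tolerance = 1e-12)
})
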