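# Synthetic study generator: layout, determinism, noise calibration, and
# end-to-end recoverability of the planted structure at reduced scale.

test_that("the default design yields 19 x 2 + 20 x 1 = 58 subject-sessions on disk", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_volumes = 60L, microtime_bins = 4L)   # desk-scale window
  coh <- generate_cohort(cfg, seed = 1, dir = dir)
  expect_length(coh$sessions, 58)
  folders <- list.dirs(dir, recursive = FALSE)
  expect_length(folders, 58)
  expect_true(all(file.exists(file.path(folders, "timeseries.tsv"))))
  expect_true(all(file.exists(file.path(folders, "events.tsv"))))
  expect_true(file.exists(file.path(dir, "covariates.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # drug level is zero on placebo sessions, positive on drug sessions
  cov <- coh$covariates
  expect_true(all(cov$drug_level[cov$session == "placebo"] == 0))
  expect_true(all(cov$drug_level[cov$session == "drug"] >= 147 &
                  cov$drug_level[cov$session == "drug"] <= 516))
  # round-trip: the written time-series reload to the in-memory data
  ts <- read_timeseries(file.path(folders[1], "timeseries.tsv"),
                        regions = c("preSMA", "IFG", "STN", "M1"))
  key <- basename(folders[1])
  expect_equal(unname(ts$data), unname(coh$sessions[[key]]$data),
               tolerance = 1e-12)
})

test_that("regenerating with the same seed reproduces identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 2L, n_controls = 2L, n_volumes = 50L,
                       microtime_bins = 4L)
  generate_cohort(cfg, seed = 9, dir = d1)
  generate_cohort(cfg, seed = 9, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_cohort(cfg, seed = 10, dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, f1[2]))),
                         unname(tools::md5sum(file.path(d3, f1[2])))))
})

test_that("empirical SNR of emitted series is within 10% of the configured value", {
  for (snr in c(0.5, 1, 2)) {
    cfg <- cohort_config(n_patients = 0L, n_controls = 3L, n_volumes = 300L,
                         microtime_bins = 4L, snr = snr)
    coh <- generate_cohort(cfg, seed = 11)
    for (s in coh$sessions) {
      emp <- apply(s$clean, 2, sd) / apply(s$data - s$clean, 2, sd)
      expect_true(all(abs(emp / snr - 1) < 0.1),
                  info = paste("snr", snr, s$subject))
    }
  }
})

test_that("the miniature fixture generates quickly and is deterministic", {
  t0 <- proc.time()
  f1 <- fixture_small(seed = 4)
  elapsed <- (proc.time() - t0)[["elapsed"]]
  expect_lt(elapsed, 5)
  expect_length(f1$sessions, 6)     # 2 patients x 2 sessions + 2 controls
  f2 <- fixture_small(seed = 4)
  expect_identical(f1$sessions[[1]]$data, f2$sessions[[1]]$data)
  # an inversion on the fixture completes promptly (smoke test)
  ses <- f1$sessions[["sub-03_ses-single"]]
  t0 <- proc.time()
  fit <- dcm(enumerate_models()[["NCp"]], ses$data, ses$inputs, ses$acq,
             control = fast_control(max_iter = 16))
  expect_lt((proc.time() - t0)[["elapsed"]], 30)
  expect_true(is.finite(fit$F))
})

test_that("every session is traceable to a manifest row that regenerates it", {
  cfg <- cohort_config(n_patients = 1L, n_controls = 1L, n_volumes = 50L,
                       microtime_bins = 4L)
  coh <- generate_cohort(cfg, seed = 21)
  expect_identical(names(coh$manifest), names(coh$sessions))
  for (key in names(coh$sessions)) {
    m <- coh$manifest[[key]]
    s <- coh$sessions[[key]]
    expect_identical(m$model_id, s$model_id)
    # re-simulating the manifest parameters reproduces the clean series
    spec <- enumerate_models()[[m$model_id]]
    theta <- unlist(m$theta)[names(s$theta)]
    y <- stopdcm:::fast_predict(spec, theta, stopdcm:::param_table(spec),
                                s$inputs$u, s$inputs$dt,
                                stopdcm:::volume_sample_bins(s$acq),
                                balloon_constants(), 16)
    expect_equal(unname(y), unname(s$clean), tolerance = 1e-12)
  }
})

test_that("a homogeneous patient group leaves family C dominant on placebo", {
  # subgroup fraction 0: all patients generated from NCp; the family
  # comparison over the non-linear preSMA models should favour C
  cfg <- cohort_config(n_patients = 4L, n_controls = 0L, subgroup_fraction = 0,
                       n_volumes = 120L, microtime_bins = 4L)
  coh <- generate_cohort(cfg, seed = 31)
  pla <- grep("ses-placebo", names(coh$sessions), value = TRUE)
  space <- enumerate_models()[nonlinear_presma_ids]
  E <- cohort_evidence(coh, sessions = pla, space = space,
                       control = fast_control())
  fam <- setNames(c("A", "B", "C", "D"), nonlinear_presma_ids)
  fb <- family_bms(E, fam, nsamp = 1e4, seed = 1)
  expect_identical(names(which.max(fb$xp)), "C")
})

test_that("planted drug effects on connectivity are recovered through inversion", {
  # constant +0.3 Hz drug effect on IFG->STN; deltas of the NCp posterior
  # means across sessions should recover it within 0.1 on average
  cfg <- cohort_config(n_patients = 19L, n_controls = 0L,
                       subgroup_fraction = 0, drug_effect_ifg_stn = 0.3,
                       updrs_effect = 0, plasma_effect = 0, delta_noise = 0,
                       n_volumes = 600L, microtime_bins = 4L)
  coh <- generate_cohort(cfg, seed = 41)
  spec <- enumerate_models()[["NCp"]]
  est <- sapply(sprintf("sub-%02d", 1:19), function(sid) {
    vapply(c("placebo", "drug"), function(ses) {
      s <- coh$sessions[[paste0(sid, "_ses-", ses)]]
      fit <- dcm(spec, s$data, s$inputs, s$acq, control = fast_control())
      fit$theta[["A.IFG->STN"]]
    }, 0)
  })
  deltas <- est["drug", ] - est["placebo", ]
  expect_lt(abs(mean(deltas) - 0.3), 0.1)
})

test_that("planted covariate associations survive the full delta-regression path", {
  # three seeded reduced cohorts: the recovered UPDRS and drug-level
  # regressions should carry the planted positive signs
  sign_ok <- 0L
  for (s in 1:3) {
    cfg <- cohort_config(n_patients = 12L, n_controls = 0L,
                         subgroup_fraction = 0, updrs_effect = 0.2,
                         plasma_effect = 0.15, n_volumes = 100L,
                         microtime_bins = 4L)
    coh <- generate_cohort(cfg, seed = 50 + s)
    spec <- enumerate_models()[["NCp"]]
    tab <- t(sapply(sprintf("sub-%02d", 1:12), function(sid) {
      vapply(c("placebo", "drug"), function(ses) {
        ss <- coh$sessions[[paste0(sid, "_ses-", ses)]]
        fit <- dcm(spec, ss$data, ss$inputs, ss$acq, control = fast_control())
        av <- bma(setNames(list(fit), "NCp"), model_probs = c(NCp = 1),
                  nsamp = 2000, seed = 1)
        c(av$mean[["A.IFG->STN"]], av$mean[["D.preSMA.IFG->STN"]])[
          if (ses == "placebo") 1:2 else 1:2]
      }, c(0, 0)) |> as.numeric()
    }))
    colnames(tab) <- c("a_pla", "d_pla", "a_drug", "d_drug")
    cov <- coh$covariates[coh$covariates$session == "drug", ]
    d <- data.frame(updrs = cov$updrs, drug_level = cov$drug_level,
                    delta_a = tab[, "a_drug"] - tab[, "a_pla"],
                    delta_d = tab[, "d_drug"] - tab[, "d_pla"])
    f1 <- regress_deltas(d, "delta_a")
    f2 <- regress_deltas(d, "delta_d")
    if (f1$beta["updrs"] > 0 && f2$beta["drug_level"] > 0) sign_ok <- sign_ok + 1L
  }
  expect_gte(sign_ok, 2L)
})

test_that("infeasible windows are rejected", {
  expect_error(generate_cohort(cohort_config(n_volumes = 5L), seed = 1),
               "too short")
})
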