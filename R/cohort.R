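## Synthetic crossover-study generator with ground truth. Controls are
## generated from the non-linear family-C model (NCp); a configurable
## subgroup of patients lacks the preSMA->IFG average coupling on placebo
## (model NAp) and has it restored on drug; drug-session changes in the
## IFG->STN coupling and the preSMA gating gain carry planted linear
## associations with disease severity and plasma drug level. Behavioural
## stop-signal sessions are simulated per subject with race parameters tied
## to group and session.

#' Cohort configuration
#'
#' Defaults emulate the study design: 19 patients in a two-session
#' (placebo/drug) crossover plus 20 single-session controls, TR 2 s, and a
#' full 480-trial stop-signal session (360/80/40) whose events drive the
#' network. \code{n_volumes} defaults to the 1200 s the task occupies.
#'
#' @param n_patients,n_controls group sizes
#' @param TR repetition time (s)
#' @param n_volumes imaging volumes per session (the event schedule is
#'   truncated to the trials that fit the window)
#' @param microtime_bins integration bins per TR
#' @param snr signal-to-noise ratio sd(signal)/sd(noise) per region
#' @param subgroup_fraction fraction of patients missing preSMA->IFG on
#'   placebo (generated from NAp)
#' @param restore_strength preSMA->IFG coupling restored on drug (Hz)
#' @param drug_effect_ifg_stn constant drug-session shift of the IFG->STN
#'   coupling (Hz), applied to every patient
#' @param updrs_effect planted drug-session change in IFG->STN coupling per
#'   SD of UPDRS (Hz)
#' @param plasma_effect planted drug-session change in the preSMA gating
#'   gain per SD of plasma level (Hz)
#' @param coupling_jitter between-subject SD of coupling parameters (Hz)
#' @param hemo_jitter between-subject SD of haemodynamic log-scalings
#' @param delta_noise SD of the unexplained part of the planted drug effects
#' @param updrs_mean,updrs_sd UPDRS-III motor score distribution (points)
#' @param plasma_range plasma atomoxetine range on drug (ng/ml)
#' @param true_values named ground-truth coupling values (Hz) shared by the
#'   generating models; see \code{stopdcm:::true_values_default}
#' @export
cohort_config <- function(n_patients = 19L, n_controls = 20L, TR = 2,
                          n_volumes = 600L, microtime_bins = 16L, snr = 1,
                          subgroup_fraction = 0.5, restore_strength = 0.35,
                          drug_effect_ifg_stn = 0,
                          updrs_effect = 0.15, plasma_effect = 0.1,
                          coupling_jitter = 0.05, hemo_jitter = 0.1,
                          delta_noise = 0.03,
                          updrs_mean = 25.87, updrs_sd = 8.94,
                          plasma_range = c(147, 516),
                          true_values = true_values_default()) {
  stopifnot(snr > 0, subgroup_fraction >= 0, subgroup_fraction <= 1)
  as.list(environment())
}

## ground-truth coupling values shared by the generating models (Hz),
## calibrated so neural excursions stay physiological (peak BOLD ~5-7%)
## while the family structure and the gating remain identifiable at SNR 1
true_values_default <- function() {
  c(`A.preSMA->STN` = 0.2, `A.IFG->STN` = 0.3, `A.STN->M1` = 0.3,
    `A.preSMA->IFG` = 0.3,
    `C.task->preSMA` = 0.45, `C.task->IFG` = 0.45, `C.stop->preSMA` = 0.45,
    `D.preSMA.IFG->STN` = 0.4)
}

## packed true parameter vector for a spec: zeros (prior means) overwritten
## by the named values admitted by the model's masks
true_theta <- function(spec, values) {
  tab <- param_table(spec)
  theta <- setNames(numeric(nrow(tab)), tab$name)
  hit <- intersect(names(values), names(theta))
  theta[hit] <- values[hit]
  theta
}

session_race <- function(group, session, stop_mu, cfg) {
  race_params(stop_mu = stop_mu,
              p_go_omission = if (group == "control") 0.02 else 0.05)
}

#' Generate a complete synthetic study
#'
#' @param config a \code{\link{cohort_config}}
#' @param seed master seed; every random draw derives from it
#' @param dir optional output directory; when given, one folder per
#'   subject-session is written with \code{timeseries.tsv}, \code{events.tsv}
#'   and \code{behaviour.tsv}, plus cohort-level \code{covariates.tsv} and
#'   \code{manifest.json}
#' @param space model space used to instantiate the generating models
#' @return object of class \code{dcm_cohort}: \code{sessions} (in-memory
#'   list with data matrix, inputs, acquisition and truth per
#'   subject-session), \code{covariates} data.frame, \code{manifest}, and
#'   \code{dir} if written
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1, dir = NULL,
                            space = enumerate_models()) {
  cfg <- config
  acq <- acquisition(TR = cfg$TR, n_volumes = cfg$n_volumes,
                     microtime_bins = cfg$microtime_bins)
  window_s <- cfg$n_volumes * cfg$TR
  if (window_s < 25) stop("acquisition window too short for the event schedule")
  constants <- balloon_constants()

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  n_pat <- cfg$n_patients
  n_con <- cfg$n_controls
  n_sub <- n_pat + n_con
  sub_seed <- sample.int(2^30, n_sub * 4)
  dim(sub_seed) <- c(n_sub, 4)

  # covariates and subject-level truth
  updrs <- rnorm(n_pat, cfg$updrs_mean, cfg$updrs_sd)
  plasma <- runif(n_pat, cfg$plasma_range[1], cfg$plasma_range[2])
  n_subgroup <- round(cfg$subgroup_fraction * n_pat)
  subgroup <- rep(FALSE, n_pat)
  if (n_pat > 0 && n_subgroup > 0)
    subgroup[sample.int(n_pat, n_subgroup)] <- TRUE
  session_order <- if (n_pat > 0) sample(c("placebo_first", "drug_first"),
                                         n_pat, replace = TRUE) else character(0)
  stop_mu_pla <- 203 + rnorm(n_pat, 0, 25)       # mean stop latency ~224 ms
  improvement <- 0.5 * ((stop_mu_pla + 20) - 224) - 4 + rnorm(n_pat, 0, 12)
  stop_mu_drug <- pmax(stop_mu_pla - improvement, 40)
  stop_mu_con <- 150 + rnorm(n_con, 0, 20)       # mean stop latency ~171 ms

  z_or_zero <- function(x) if (length(x) > 1 && sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  z_updrs <- z_or_zero(updrs)
  z_plasma <- z_or_zero(plasma)

  sessions <- list()
  manifest <- list()
  make_session <- function(subject, group, session, model_id, theta, race,
                           seeds) {
    trials <- build_session(seed = seeds[1])
    record <- simulate_session(trials, race, seed = seeds[2])
    keep <- record$onset_s + 1 <= window_s
    events <- data.frame(onset = record$onset_s[keep], duration = 1,
                         trial_type = record$outcome[keep])
    inputs <- build_dcm_inputs(events, dt = acq$dt,
                               n_bins = acq$n_volumes * acq$microtime_bins)
    spec <- space[[model_id]]
    y <- fast_predict(spec, theta, param_table(spec), inputs$u, inputs$dt,
                      volume_sample_bins(acq), constants, bound = 16)
    if (is.null(y)) stop("generating model diverged for ", subject)
    if (max(abs(y)) > 20)
      stop("generating parameters produce unphysiological BOLD (",
           round(max(abs(y)), 1), "% peak) for ", subject)
    set.seed(seeds[3])
    noise_sd <- apply(y, 2, sd) / cfg$snr
    noise_sd[noise_sd == 0] <- 1e-6
    noisy <- y + matrix(rnorm(length(y), sd = rep(noise_sd, each = nrow(y))),
                        nrow(y), ncol(y))
    colnames(noisy) <- spec$regions$names
    ssrt <- estimate_ssrt(record)
    list(subject = subject, group = group, session = session,
         model_id = model_id, theta = theta, race = race,
         noise_sd = noise_sd, data = noisy, clean = y, inputs = inputs,
         acq = acq, record = record, events = events, ssrt = ssrt$ssrt)
  }

  base <- cfg$true_values
  for (i in seq_len(n_pat)) {
    sid <- sprintf("sub-%02d", i)
    jit_seed <- sub_seed[i, 4]
    set.seed(jit_seed)
    jit <- rnorm(length(base), 0, cfg$coupling_jitter)
    hjit <- rnorm(12, 0, cfg$hemo_jitter)
    subj_vals <- base + jit

    pla_vals <- subj_vals
    pla_model <- if (subgroup[i]) "NAp" else "NCp"
    theta_pla <- true_theta(space[[pla_model]], pla_vals)
    drug_vals <- subj_vals
    if (subgroup[i]) drug_vals["A.preSMA->IFG"] <- cfg$restore_strength
    drug_vals["A.IFG->STN"] <- drug_vals["A.IFG->STN"] +
      cfg$drug_effect_ifg_stn +
      cfg$updrs_effect * z_updrs[i] + rnorm(1, 0, cfg$delta_noise)
    drug_vals["D.preSMA.IFG->STN"] <- drug_vals["D.preSMA.IFG->STN"] +
      cfg$plasma_effect * z_plasma[i] + rnorm(1, 0, cfg$delta_noise)
    theta_drug <- true_theta(space[["NCp"]], drug_vals)
    hemo_names <- grep("^hemo\\.", names(theta_pla), value = TRUE)
    theta_pla[hemo_names] <- hjit
    theta_drug[grep("^hemo\\.", names(theta_drug))] <- hjit

    sessions[[paste0(sid, "_ses-placebo")]] <- make_session(
      sid, "patient", "placebo", pla_model, theta_pla,
      session_race("patient", "placebo", stop_mu_pla[i], cfg),
      sub_seed[i, 1:3])
    sessions[[paste0(sid, "_ses-drug")]] <- make_session(
      sid, "patient", "drug", "NCp", theta_drug,
      session_race("patient", "drug", stop_mu_drug[i], cfg),
      sub_seed[i, 1:3] + 7L)
  }
  for (j in seq_len(n_con)) {
    sid <- sprintf("sub-%02d", n_pat + j)
    set.seed(sub_seed[n_pat + j, 4])
    jit <- rnorm(length(base), 0, cfg$coupling_jitter)
    hjit <- rnorm(12, 0, cfg$hemo_jitter)
    theta <- true_theta(space[["NCp"]], base + jit)
    theta[grep("^hemo\\.", names(theta))] <- hjit
    sessions[[paste0(sid, "_ses-single")]] <- make_session(
      sid, "control", "single", "NCp", theta,
      session_race("control", "single", stop_mu_con[j], cfg),
      sub_seed[n_pat + j, 1:3])
  }

  cov_rows <- lapply(sessions, function(s) {
    i <- as.integer(sub("sub-(\\d+).*", "\\1", s$subject))
    data.frame(subject = s$subject, group = s$group, session = s$session,
               model_id = s$model_id,
               updrs = if (s$group == "patient") updrs[i] else NA_real_,
               drug_level = if (s$group == "patient" && s$session == "drug")
                 plasma[i] else 0,
               session_order = if (s$group == "patient") session_order[i]
                 else NA_character_,
               ssrt_ms = s$ssrt)
  })
  covariates <- do.call(rbind, c(cov_rows, list(make.row.names = FALSE)))

  manifest <- lapply(sessions, function(s) {
    list(subject = s$subject, group = s$group, session = s$session,
         model_id = s$model_id, theta = as.list(s$theta),
         race = unclass(s$race), noise_sd = as.numeric(s$noise_sd),
         ssrt_ms = s$ssrt)
  })

  out <- structure(list(sessions = sessions, covariates = covariates,
                        manifest = manifest, config = cfg, seed = seed,
                        acq = acq, dir = dir),
                   class = "dcm_cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' @export
print.dcm_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$sessions), "subject-sessions (",
      x$config$n_patients, "patients x 2,", x$config$n_controls,
      "controls x 1 )\n")
  cat("  ", x$acq$n_volumes, "volumes at TR", x$acq$TR, "s, SNR",
      x$config$snr, "\n")
  invisible(x)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$sessions)) {
    s <- cohort$sessions[[key]]
    sdir <- file.path(dir, key)
    dir.create(sdir, showWarnings = FALSE)
    ts <- data.frame(time_s = (seq_len(nrow(s$data)) - 1) * s$acq$TR, s$data,
                     check.names = FALSE)
    write_tsv(ts, file.path(sdir, "timeseries.tsv"))
    write_tsv(s$events, file.path(sdir, "events.tsv"))
    write_tsv(s$record, file.path(sdir, "behaviour.tsv"))
  }
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Miniature study for fast tests
#'
#' Two patients (two sessions each) plus two controls at 120 volumes;
#' generates in a few seconds and exercises every pipeline stage.
#'
#' @param seed master seed
#' @param dir optional output directory
#' @param n_volumes window length (volumes)
#' @export
fixture_small <- function(seed = 1, dir = NULL, n_volumes = 120L) {
  cfg <- cohort_config(n_patients = 2L, n_controls = 2L,
                       n_volumes = as.integer(n_volumes), microtime_bins = 8L)
  generate_cohort(cfg, seed = seed, dir = dir)
}

#' Evidence matrix for a set of cohort sessions
#'
#' Inverts each model of a space to each selected subject-session and
#' collects the free energies.
#'
#' @param cohort a \code{\link{generate_cohort}} result
#' @param sessions names of \code{cohort$sessions} entries (default: all)
#' @param space model space (or a subset of one)
#' @param control inversion settings
#' @export
cohort_evidence <- function(cohort, sessions = names(cohort$sessions),
                            space = enumerate_models(),
                            control = dcm_control()) {
  E <- matrix(NA_real_, length(sessions), length(space),
              dimnames = list(sessions, names(space)))
  for (s in sessions) {
    ses <- cohort$sessions[[s]]
    E[s, ] <- fit_model_space(ses$data, ses$inputs, ses$acq, space = space,
                              control = control)
  }
  E
}
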