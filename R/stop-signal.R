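## Stop-signal task engine: trial-list construction (360 Go / 80 Stop /
## 40 NoGo per session, 2.5 s stimulus onset asynchrony), simulation under
## the independent race model with an adaptive +/-50 ms staircase holding
## successful inhibition near 50%, and the integration-method SSRT estimator
## with max-RT replacement of Go omissions.

#' Build one session's trial list
#'
#' @param seed RNG seed controlling the randomized order
#' @param n_go,n_stop,n_nogo trial counts per session
#' @param soa stimulus onset asynchrony (ms)
#' @return data.frame of class \code{trial_list}: trial, type, onset_s
#' @export
build_session <- function(seed = 1, n_go = 360L, n_stop = 80L, n_nogo = 40L,
                          soa = 2500) {
  types <- c(rep("go", n_go), rep("stop", n_stop), rep("nogo", n_nogo))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  types <- sample(types)
  out <- data.frame(trial = seq_along(types), type = types,
                    onset_s = (seq_along(types) - 1) * soa / 1000)
  class(out) <- c("trial_list", "data.frame")
  out
}

#' Race-model parameters
#'
#' Independent-race generative model of stop-signal behaviour: ex-Gaussian
#' go-RT and stop-latency distributions (ms), a go-omission probability and
#' a stop-trigger-failure probability.
#'
#' @param go_mu,go_sigma,go_tau go finishing-time ex-Gaussian parameters (ms)
#' @param stop_mu,stop_sigma,stop_tau stop-latency ex-Gaussian parameters
#'   (ms); the true SSRT distribution has mean \code{stop_mu + stop_tau}
#' @param p_go_omission probability that the go process never finishes
#' @param p_trigger_failure probability the stop process fails to launch
#' @export
race_params <- function(go_mu = 450, go_sigma = 60, go_tau = 80,
                        stop_mu = 180, stop_sigma = 30, stop_tau = 20,
                        p_go_omission = 0.02, p_trigger_failure = 0.02) {
  stopifnot(go_mu > 0, go_sigma >= 0, go_tau > 0, stop_mu >= 0,
            stop_sigma >= 0, stop_tau > 0,
            p_go_omission >= 0, p_go_omission < 1,
            p_trigger_failure >= 0, p_trigger_failure < 1)
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 stop_mu = stop_mu, stop_sigma = stop_sigma, stop_tau = stop_tau,
                 p_go_omission = p_go_omission,
                 p_trigger_failure = p_trigger_failure),
            class = "race_params")
}

#' True mean stop latency of a race model
#' @param race a \code{\link{race_params}}
#' @export
true_ssrt <- function(race) race$stop_mu + race$stop_tau

#' Simulate one session under the independent race model
#'
#' On each stop trial the go and stop processes race: a response occurs iff
#' the go finishing time is below SSD + stop latency (or the stop trigger
#' fails). After a successful stop the stop-signal delay increases by the
#' staircase step; after a failed stop it decreases, bounded below at the
#' floor. NoGo trials are races at SSD = 0.
#'
#' @param trials a \code{\link{build_session}} trial list
#' @param race a \code{\link{race_params}}
#' @param seed RNG seed
#' @param ssd_start initial stop-signal delay (ms)
#' @param ssd_step staircase increment (ms)
#' @param ssd_floor lower bound on SSD (ms)
#' @return data.frame of class \code{behavioural_record}: trial, type,
#'   onset_s, ssd_ms (NA on go trials), rt_ms (NA when no response),
#'   outcome in \{go_correct, go_omission, stop_correct, stop_incorrect,
#'   nogo_correct, nogo_incorrect\}
#' @export
simulate_session <- function(trials, race, seed = 1, ssd_start = 250,
                             ssd_step = 50, ssd_floor = 0) {
  if (race$go_sigma == 0 && race$stop_sigma == 0)
    warning("degenerate race: both processes are (near) deterministic")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nt <- nrow(trials)
  go_rt <- rexgauss(nt, race$go_mu, race$go_sigma, race$go_tau)
  go_rt <- pmax(go_rt, 1)
  stop_lat <- rexgauss(nt, race$stop_mu, race$stop_sigma, race$stop_tau)
  stop_lat <- pmax(stop_lat, 1)
  omitted <- runif(nt) < race$p_go_omission
  trig_fail <- runif(nt) < race$p_trigger_failure

  ssd <- ssd_start
  ssd_ms <- rep(NA_real_, nt)
  rt_ms <- rep(NA_real_, nt)
  outcome <- character(nt)
  for (i in seq_len(nt)) {
    type <- trials$type[i]
    if (type == "go") {
      if (omitted[i]) outcome[i] <- "go_omission"
      else { rt_ms[i] <- go_rt[i]; outcome[i] <- "go_correct" }
    } else {
      delay <- if (type == "stop") ssd else 0
      ssd_ms[i] <- delay
      responded <- !omitted[i] &&
        (trig_fail[i] || go_rt[i] < delay + (if (is.finite(stop_lat[i])) stop_lat[i] else Inf))
      if (responded) rt_ms[i] <- go_rt[i]
      if (type == "stop") {
        outcome[i] <- if (responded) "stop_incorrect" else "stop_correct"
        ssd <- if (responded) max(ssd - ssd_step, ssd_floor) else ssd + ssd_step
      } else {
        outcome[i] <- if (responded) "nogo_incorrect" else "nogo_correct"
      }
    }
  }
  out <- data.frame(trial = trials$trial, type = trials$type,
                    onset_s = trials$onset_s, ssd_ms = ssd_ms, rt_ms = rt_ms,
                    outcome = outcome)
  class(out) <- c("behavioural_record", "data.frame")
  out
}

#' Integration-method SSRT with omission adjustment
#'
#' The response rate on stop trials, p = P(respond | stop), indexes the
#' go-RT distribution: omitted go trials are assigned the maximum observed
#' go RT (or, with \code{adjustment = "renorm"}, dropped with the quantile
#' re-normalized), and SSRT is the n-th ranked go RT with
#' n = ceiling(p * N), minus the mean stop-signal delay. NoGo trials are
#' excluded throughout.
#'
#' @param record a \code{\link{simulate_session}} behavioural record
#' @param adjustment go-omission handling: \code{"max_rt"} replacement
#'   (default) or \code{"renorm"}
#' @return list of class \code{ssrt_estimate}: \code{ssrt} (ms),
#'   \code{p_respond}, \code{mean_ssd}, \code{nth_rt}, \code{n_go},
#'   \code{n_omission}, \code{reliable}
#' @export
estimate_ssrt <- function(record, adjustment = c("max_rt", "renorm")) {
  adjustment <- match.arg(adjustment)
  stops <- record[record$type == "stop", ]
  if (nrow(stops) == 0) stop("no stop trials: SSRT undefined")
  gos <- record[record$type == "go", ]
  go_rts <- gos$rt_ms[!is.na(gos$rt_ms)]
  if (length(go_rts) == 0) stop("no scorable go RTs: SSRT undefined")
  n_omit <- sum(is.na(gos$rt_ms))
  p <- mean(stops$outcome == "stop_incorrect")
  reliable <- p > 0 && p < 1
  if (adjustment == "max_rt" && n_omit > 0) {
    go_rts <- c(go_rts, rep(max(go_rts), n_omit))
  }
  go_sorted <- sort(go_rts)
  N <- length(go_sorted)
  nth <- min(max(ceiling(p * N), 1L), N)
  nth_rt <- go_sorted[nth]
  mean_ssd <- mean(stops$ssd_ms)
  structure(list(ssrt = nth_rt - mean_ssd, p_respond = p, mean_ssd = mean_ssd,
                 nth_rt = nth_rt, n_go = N, n_omission = n_omit,
                 adjustment = adjustment, reliable = reliable),
            class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("SSRT (integration method): %.1f ms\n", x$ssrt))
  cat(sprintf("  P(respond | stop) = %.3f, mean SSD = %.1f ms, nth go RT = %.1f ms\n",
              x$p_respond, x$mean_ssd, x$nth_rt))
  if (!x$reliable) cat("  WARNING: response rate at boundary; estimate unreliable\n")
  invisible(x)
}

#' Build DCM input functions from an event table
#'
#' Channel \code{task} is an indicator over all trial events (1 s boxcars by
#' default); channel \code{stop} carries contrast weights on the same
#' boxcars (successful stops positive, go trials negative under the default
#' +1/-1 contrast). No serial orthogonalization is applied. Events
#' overlapping at microtime resolution are summed.
#'
#' @param events data.frame with \code{onset}, \code{duration},
#'   \code{trial_type} (BIDS-events-style); a behavioural record is
#'   converted automatically (events of 1 s duration at trial onsets)
#' @param dt microtime step (s)
#' @param n_bins length of the microtime grid (must cover the events)
#' @param contrast named weights mapping trial types to the stopping channel
#' @param mean_center subtract each channel's mean (off by default: indicator
#'   inputs are left uncentred)
#' @return a \code{\link{dcm_inputs}} with channels \code{task}, \code{stop}
#' @export
build_dcm_inputs <- function(events, dt, n_bins,
                             contrast = c(stop_correct = 1, go_correct = -1),
                             mean_center = FALSE) {
  if (inherits(events, "behavioural_record")) {
    events <- data.frame(onset = events$onset_s, duration = 1,
                         trial_type = events$outcome)
  }
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  u <- matrix(0, n_bins, 2, dimnames = list(NULL, c("task", "stop")))
  if (nrow(events)) {
    if (any(events$onset < 0) ||
        any(events$onset + events$duration > n_bins * dt + 1e-9))
      stop("events fall outside the acquisition window")
    overlaps <- 0L
    for (i in seq_len(nrow(events))) {
      first <- floor(events$onset[i] / dt) + 1
      len <- ceiling(events$duration[i] / dt)
      bins <- first:min(first + len - 1, n_bins)
      if (any(u[bins, "task"] != 0)) overlaps <- overlaps + 1L
      u[bins, "task"] <- u[bins, "task"] + 1
      w <- unname(contrast[events$trial_type[i]])
      if (is.na(w)) w <- 0
      u[bins, "stop"] <- u[bins, "stop"] + w
    }
    if (overlaps > 0)
      message(overlaps, " event(s) overlap at microtime resolution; summed")
  }
  if (mean_center) u <- sweep(u, 2, colMeans(u))
  dcm_inputs(u, dt)
}
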