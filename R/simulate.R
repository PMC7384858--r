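#' Ground-truth configuration for the synthetic session generator
#'
#' Encodes the statistical structure the analyses assume: per-condition
#' latent subspaces with a controllable degree of sharing, condition gains
#' (observation activity ~1/3.5 of execution by default), Poisson spiking
#' around smooth latent trajectories, task event-time distributions, and
#' EMG bursts confined to execution.
#'
#' @param n_neurons neurons in the simulated population
#' @param k_latent latent dimensionality per condition (<= n_neurons)
#' @param rho_exe_obs,rho_obs_nogo subspace overlap (0 to 1) between the
#'   execution/observation and observation/NoGo loading subspaces; every
#'   principal angle between the two subspaces is planted at
#'   `acos(sqrt(rho))`, so for isotropic latents the alignment index of one
#'   condition in the other's subspace equals `rho`
#' @param gains named condition gains (dimensionless); default observation
#'   gain is 1/3.5 of execution
#' @param amplitude per-neuron modulation scale, spikes/s: latent loadings
#'   are orthonormal (entries of order 1/sqrt(N)), so rates use
#'   `amplitude * sqrt(N) * W z`, keeping a neuron's typical modulation
#'   depth at `amplitude` regardless of population size
#' @param baseline_mean,baseline_sdlog lognormal per-neuron baseline rate
#'   parameters (spikes/s; median = `baseline_mean`)
#' @param trials_per_grasp named trial counts per condition (per grasp)
#' @param rt_median,mt_median named (execution, observation) medians of the
#'   lognormal reaction/movement-time distributions, ms; observation uses
#'   the slower human (experimenter) timing
#' @param rt_cv,mt_cv coefficients of variation; 0 collapses the
#'   distribution onto its median
#' @param emg generate EMG traces?
#' @param n_muscles number of EMG channels (<= 12)
#' @param emg_rate EMG sampling rate, Hz
#' @param emg_burst execution burst amplitude as a multiple of baseline SD
#' @param emg_trial_gain_sdlog lognormal SD of per-trial EMG amplitude gain
#'   (models electrode/posture nonstationarity; 0 = stationary null)
#' @param n_dead_muscles channels simulated as flat/noisy (no task burst)
#' @param seed required integer seed; identical seeds give identical bundles
#' @return an object of class `ground_truth_config`
#' @export
ground_truth_config <- function(n_neurons = 40, k_latent = 3,
                                rho_exe_obs = 0.5, rho_obs_nogo = 0.3,
                                gains = c(execution = 1,
                                          observation = 1 / 3.5,
                                          nogo = 0.25),
                                amplitude = 15,
                                baseline_mean = 8, baseline_sdlog = 0.4,
                                trials_per_grasp = c(execution = 20,
                                                     observation = 20,
                                                     nogo = 14),
                                rt_median = c(execution = 310,
                                              observation = 442),
                                mt_median = c(execution = 306,
                                              observation = 430),
                                rt_cv = 0.12, mt_cv = 0.12,
                                emg = TRUE, n_muscles = 12, emg_rate = 500,
                                emg_burst = 4, emg_trial_gain_sdlog = 0.2,
                                n_dead_muscles = 0,
                                seed) {
  if (missing(seed)) stop("seed is required")
  cfg <- as.list(environment())
  if (cfg$rho_exe_obs < 0 || cfg$rho_exe_obs > 1 ||
      cfg$rho_obs_nogo < 0 || cfg$rho_obs_nogo > 1)
    stop("subspace overlaps rho must lie in [0, 1]")
  if (any(cfg$gains < 0)) stop("condition gains must be non-negative")
  if (any(cfg$trials_per_grasp < 1)) stop("at least 1 trial per condition")
  if (cfg$k_latent > cfg$n_neurons)
    stop("k_latent must not exceed n_neurons")
  if (cfg$baseline_mean <= 0) stop("baseline rates must be positive")
  if (cfg$n_muscles > 12) stop("at most 12 muscles")
  structure(cfg, class = "ground_truth_config")
}

# Haar-ish random orthonormal N x k basis (sign-fixed QR)
random_orthonormal <- function(n, k) {
  qrd <- qr(matrix(stats::rnorm(n * k), n, k))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), k, k)
}

# basis orthogonal to span(W), k columns
orthogonal_complement_basis <- function(w, k) {
  n <- nrow(w)
  g <- matrix(stats::rnorm(n * k), n, k)
  g <- g - w %*% crossprod(w, g)
  qr.Q(qr(g))
}

# Rotate an orthonormal basis away from `w` by angle theta (all principal
# angles equal theta), randomizing within-subspace orientation.
rotated_basis <- function(w, w_perp, theta) {
  k <- ncol(w)
  q1 <- random_orthonormal(k, k)
  q2 <- random_orthonormal(k, k)
  cos(theta) * (w %*% q1) + sin(theta) * (w_perp %*% q2)
}

#' Sample task event times for simulated trials
#'
#' Reaction and movement times are lognormal with positive support; NoGo
#' trials carry only the pre-movement events. A coefficient of variation of
#' zero degenerates every trial to the configured medians.
#'
#' @param config a [ground_truth_config()]
#' @param condition "execution", "observation" or "nogo"
#' @param n_trials number of trials to sample
#' @param seed integer seed
#' @return list of named event vectors (trial-relative ms; LCDon at 600)
#' @export
sample_event_times <- function(config, condition, n_trials, seed) {
  with_seed(seed, {
    timing_cond <- if (condition == "execution") "execution" else "observation"
    sdlog_rt <- sqrt(log(1 + config$rt_cv^2))
    sdlog_mt <- sqrt(log(1 + config$mt_cv^2))
    lapply(seq_len(n_trials), function(i) {
      lcd <- 600
      obj <- lcd + 300
      go <- obj + 800 + stats::runif(1, -40, 40)
      ev <- c(LCDon = lcd, ObjCue = obj, GoNogo = go)
      if (condition != "nogo") {
        rt <- stats::rlnorm(1, log(config$rt_median[timing_cond]), sdlog_rt)
        mt <- stats::rlnorm(1, log(config$mt_median[timing_cond]), sdlog_mt)
        hpr <- go + rt
        do_ <- hpr + mt
        ho <- do_ + 120 + abs(stats::rnorm(1, 30, 10))
        hoff <- ho + 700 + abs(stats::rnorm(1, 50, 20))
        hpn <- hoff + 250 + abs(stats::rnorm(1, 30, 10))
        ev <- c(ev, HPR = hpr, DO = do_, HO = ho, HOFF = hoff, HPN = hpn)
      }
      ev
    })
  })
}

# Latent trajectories: sums of Gaussian bumps anchored to task events so the
# multi-alignment has event-locked structure to recover. Units ~O(1).
latent_traj <- function(tgrid, events, condition, k, grasp_amp) {
  if (condition == "nogo") {
    centers <- events["GoNogo"] + c(100, 250, 420)
    sds <- c(80, 100, 140)
  } else {
    centers <- c(events["GoNogo"] + 100, events["HPR"] + 60,
                 events["DO"] + 120)
    sds <- c(100, 120, 160)
  }
  z <- matrix(0, k, length(tgrid))
  for (j in seq_len(k)) {
    jj <- ((j - 1L) %% 3L) + 1L
    ctr <- centers[jj] + 40 * ((j - 1L) %/% 3L)
    z[j, ] <- grasp_amp[j] * exp(-(tgrid - ctr)^2 / (2 * sds[jj]^2))
  }
  z
}

#' Generate a synthetic recording session
#'
#' Builds a [session_bundle()] whose statistical structure matches the
#' analyses' assumptions: per condition c, neuron rates follow
#' `lambda(t) = max(0, b + g_c * A * W_c z(t))` with orthonormal loading
#' bases `W_c` planted at controlled principal angles
#' (`acos(sqrt(rho))`) between conditions, inhomogeneous-Poisson spikes
#' (1 ms resolution), event times drawn per [sample_event_times()], and EMG
#' with execution-only bursts. All randomness flows from `config$seed`.
#'
#' @param config a [ground_truth_config()]
#' @return list with `bundle` (a `session_bundle`) and `truth` (a
#'   ground-truth record: loading bases per condition, planted angles,
#'   baselines, per-trial latent/event draws, per-trial spike tallies)
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "ground_truth_config"))
  with_seed(config$seed, {
    n <- config$n_neurons
    k <- config$k_latent
    b <- stats::rlnorm(n, log(config$baseline_mean), config$baseline_sdlog)

    w_exe <- random_orthonormal(n, k)
    w_perp1 <- orthogonal_complement_basis(w_exe, k)
    th1 <- acos(sqrt(config$rho_exe_obs))
    w_obs <- rotated_basis(w_exe, w_perp1, th1)
    w_perp2 <- orthogonal_complement_basis(w_obs, k)
    th2 <- acos(sqrt(config$rho_obs_nogo))
    w_nogo <- rotated_basis(w_obs, w_perp2, th2)
    w <- list(execution = w_exe, observation = w_obs, nogo = w_nogo)

    # grasp-specific latent amplitude patterns (PG reference, WHG varied)
    grasp_amp <- list(PG = rep(1, k),
                      WHG = 0.6 + stats::runif(k, 0, 0.8))

    span_len <- 7000
    muscles <- if (config$emg)
      paste0("muscle", seq_len(config$n_muscles)) else NULL
    muscle_gain <- if (config$emg) stats::runif(config$n_muscles, 0.7, 1.3)
    dead <- if (config$emg && config$n_dead_muscles > 0)
      seq_len(config$n_dead_muscles) else integer(0)

    trials <- list()
    tallies <- list()
    expected <- list()
    ev_record <- list()
    trial_no <- 0L
    ev_seed_i <- 0L
    for (cond in CONDITIONS) {
      n_tr <- unname(config$trials_per_grasp[cond])
      if (is.na(n_tr) || n_tr < 1) next
      for (g in GRASPS) {
        ev_seed_i <- ev_seed_i + 1L
        evs <- sample_event_times(config, cond, n_tr,
                                  derive_seed(config$seed, ev_seed_i))
        for (i in seq_len(n_tr)) {
          trial_no <- trial_no + 1L
          t0 <- (trial_no - 1L) * span_len
          ev <- evs[[i]] + t0
          span <- c(t0, t0 + span_len)
          tgrid <- seq(t0 + 0.5, t0 + span_len - 0.5, by = 1)  # bin centers
          z <- latent_traj(tgrid, ev, cond, k, grasp_amp[[g]])
          lam <- rectify(b + config$gains[cond] * config$amplitude *
                           sqrt(n) * (w[[cond]] %*% z))
          counts <- matrix(stats::rpois(length(lam), lam * 1e-3),
                           nrow = n)
          spikes <- lapply(seq_len(n), function(ni) {
            ci <- counts[ni, ]
            hits <- which(ci > 0L)
            if (!length(hits)) return(numeric(0))
            tt <- rep(tgrid[hits], ci[hits]) +
              stats::runif(sum(ci[hits]), -0.5, 0.5)
            sort(tt)
          })
          emg <- NULL
          if (config$emg) {
            n_samp <- span_len * config$emg_rate / 1000
            ts <- t0 + (seq_len(n_samp) - 0.5) * (1000 / config$emg_rate)
            gain_tr <- stats::rlnorm(1, 0, config$emg_trial_gain_sdlog)
            emg <- matrix(0, config$n_muscles, n_samp)
            for (m in seq_len(config$n_muscles)) {
              if (m %in% dead) next    # dead channel: flat zero trace
              sdv <- rep(gain_tr * muscle_gain[m], n_samp)
              if (cond == "execution") {
                ctr <- (ev["GoNogo"] + ev["DO"]) / 2
                wid <- (ev["DO"] - ev["GoNogo"]) / 2 + 100
                burst <- config$emg_burst *
                  exp(-(ts - ctr)^2 / (2 * (wid / 2)^2))
                sdv <- sdv * (1 + burst)
              }
              emg[m, ] <- stats::rnorm(n_samp, 0, sdv)
            }
          }
          trials[[trial_no]] <- list(
            trial = trial_no, condition = cond, grasp = g,
            outcome = "correct", span = span, events = ev,
            spikes = spikes, emg = emg)
          tallies[[trial_no]] <- rowSums(counts)
          expected[[trial_no]] <- rowSums(lam) * 1e-3
          ev_record[[trial_no]] <- ev
        }
      }
    }

    neurons <- data.frame(
      neuron_id = sprintf("n%03d", seq_len(n)),
      area = "M1", identity = "PTN", subject = "synthetic",
      stringsAsFactors = FALSE)
    bundle <- session_bundle(
      session_id = paste0("synthetic-seed", config$seed),
      neurons = neurons, trials = trials,
      emg_muscles = muscles,
      emg_rate = if (config$emg) config$emg_rate else NULL)
    truth <- structure(
      list(config = config, W = w,
           planted_angle_exe_obs = th1, planted_angle_obs_nogo = th2,
           baselines = b, grasp_amp = grasp_amp,
           spike_counts = do.call(rbind, tallies),
           expected_counts = do.call(rbind, expected),
           event_times = ev_record,
           muscle_gain = muscle_gain,
           dead_muscles = dead,
           contaminated = integer(0)),
      class = "ground_truth_record")
    list(bundle = bundle, truth = truth)
  })
}

#' Inject EMG contamination into passive trials
#'
#' Adds a movement-like EMG burst (white noise scaled to a stated multiple
#' of the trial's baseline-interval SD, shaped over the Reaction window) to
#' selected observation or NoGo trials, recording the contaminated indices
#' as ground truth. Targeting an execution trial is an error. Amplitude 0
#' leaves the bundle unchanged.
#'
#' @param bundle a `session_bundle` with EMG
#' @param trial_idx trial indices to contaminate
#' @param amplitude burst size as a multiple of the baseline-interval SD
#' @param seed integer seed for the injected noise
#' @return the modified bundle with `contaminated` updated
#' @export
inject_emg_contamination <- function(bundle, trial_idx, amplitude, seed = 1L) {
  stopifnot(inherits(bundle, "session_bundle"), amplitude >= 0)
  if (is.null(bundle$emg_muscles)) stop("bundle has no EMG")
  pos <- match(trial_idx, vapply(bundle$trials, `[[`, 0L, "trial"))
  if (anyNA(pos)) stop("unknown trial index")
  with_seed(seed, {
    for (p in pos) {
      tr <- bundle$trials[[p]]
      if (tr$condition == "execution")
        stop("trial ", tr$trial, " is an execution trial; only observation ",
             "or NoGo trials can be contaminated")
      if (amplitude == 0) next
      rate <- bundle$emg_rate
      ts <- tr$span[1] + (seq_len(ncol(tr$emg)) - 0.5) * (1000 / rate)
      go <- tr$events["GoNogo"]
      win <- ts >= go & ts < go + 300
      base <- ts >= tr$events["LCDon"] & ts < tr$events["ObjCue"]
      shape <- exp(-(ts[win] - (go + 150))^2 / (2 * 75^2))
      for (m in seq_len(nrow(tr$emg))) {
        sd_b <- stats::sd(tr$emg[m, base])
        tr$emg[m, win] <- tr$emg[m, win] +
          stats::rnorm(sum(win), 0, amplitude * sd_b) * shape
      }
      bundle$trials[[p]] <- tr
      bundle$contaminated <- sort(unique(c(bundle$contaminated,
                                           as.integer(tr$trial))))
    }
  })
  bundle
}
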