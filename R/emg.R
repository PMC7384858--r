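# Butterworth design via analog prototype + bilinear transform. No signal-
# processing dependency is available, so the classical design is done here;
# coefficients are validated in the tests against an independent reference.

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth filter by bilinear transform of the analog
#' prototype. `order` is the overall filter order (a band-pass of order 4
#' has 4 poles, i.e. prototype order 2), matching how band-pass orders are
#' conventionally reported.
#'
#' @param order overall filter order (even for band-pass)
#' @param cutoff cutoff frequency in Hz (length 2 for band-pass)
#' @param fs sampling rate, Hz
#' @param type "low", "high" or "pass"
#' @return list with numerator `b` and denominator `a` coefficients
#' @export
butter_coeffs <- function(order, cutoff, fs, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  if (type == "pass") {
    if (length(cutoff) != 2L || order %% 2L != 0L)
      stop("band-pass needs two cutoffs and an even order")
    np <- order / 2L
  } else {
    if (length(cutoff) != 1L) stop("low/high-pass needs one cutoff")
    np <- order
  }
  # analog lowpass prototype poles (unit cutoff)
  kk <- seq_len(np)
  p <- exp(1i * pi * (2 * kk + np - 1) / (2 * np))
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff)
    pa <- p * wc; za <- complex(0); ka <- wc^np
  } else if (type == "high") {
    wc <- warp(cutoff)
    pa <- wc / p; za <- rep(0 + 0i, np)
    ka <- 1 / Re(prod(-p))      # so that H_hp(infinity) = 1
  } else {
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    pa <- c((p * bw + sqrt((p * bw)^2 - 4 * w0^2)) / 2,
            (p * bw - sqrt((p * bw)^2 - 4 * w0^2)) / 2)
    za <- rep(0 + 0i, np)
    ka <- bw^np
  }
  nz <- length(za); npl <- length(pa)
  zd <- (1 + za / fs2) / (1 - za / fs2)
  pd <- (1 + pa / fs2) / (1 - pa / fs2)
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  zd_all <- c(zd, rep(-1 + 0i, npl - nz))
  b <- Re(kd * poly_from_roots(zd_all))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# single-pass IIR filter using stats::filter (convolution FIR part +
# recursive AR part); zero initial conditions
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)[-seq_len(nb - 1)]
  if (length(a) > 1L)
    v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters the signal forward and backward so the net phase response is
#' zero. The ends are padded by odd reflection; the pad length is scaled
#' to several times the filter's slowest time constant (estimated from
#' its pole radii) so start-up transients — which for a 0.5 Hz corner
#' last hundreds of samples — decay inside the padding rather than
#' contaminating the signal.
#'
#' @param b,a filter coefficients from [butter_coeffs()]
#' @param x numeric signal
#' @return filtered signal, same length
#' @export
filtfilt_bw <- function(b, a, x) {
  n <- length(x)
  r_max <- max(Mod(polyroot(rev(a))))
  tau <- if (r_max < 1) -1 / log(r_max) else 50
  npad <- min(max(3L * (max(length(a), length(b)) - 1L),
                  ceiling(6 * tau)), n - 1L)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

emg_timestamps <- function(tr, rate) {
  tr$span[1] + (seq_len(ncol(tr$emg)) - 0.5) * (1000 / rate)
}

# [lo, hi) Reaction window for a trial: Go->HPR on Go trials (the
# experimenter's HPR on observation), a fixed 0-300 ms post-cue on NoGo,
# or the fixed variant everywhere when reaction_def = "fixed300".
reaction_window <- function(tr, reaction_def = c("hpr", "fixed300")) {
  reaction_def <- match.arg(reaction_def)
  go <- unname(tr$events["GoNogo"])
  if (tr$condition == "nogo" || reaction_def == "fixed300")
    return(c(go, go + 300))
  c(go, unname(tr$events["HPR"]))
}

#' Rectified band-passed EMG envelope means per interval
#'
#' For every trial and muscle: rectify the raw trace, band-pass it with a
#' zero-phase 4th-order Butterworth (0.5-30 Hz), and average the result
#' over the Baseline (LCDon to ObjCue) and Reaction (Go to HPR for
#' execution/observation; 0-300 ms post-cue for NoGo) intervals.
#'
#' @param bundle a `session_bundle` with EMG
#' @param band band-pass corner frequencies, Hz
#' @param order overall filter order
#' @param reaction_def "hpr" (Go to HPR on Go trials) or "fixed300"
#'   (0-300 ms post-cue in every condition)
#' @param block_ms sub-interval block length (ms) for the block-mean
#'   samples that the exclusion t-tests operate on; trailing partial
#'   blocks are dropped
#' @return data.frame: trial, condition, grasp, muscle, baseline, reaction
#'   (interval means); attribute `"blocks"` holds the long block-mean
#'   table (trial, condition, grasp, muscle, interval, block, value)
#' @export
envelope_quant <- function(bundle, band = c(0.5, 30), order = 4,
                           reaction_def = "hpr", block_ms = 100) {
  if (is.null(bundle$emg_muscles)) stop("bundle has no EMG")
  rate <- bundle$emg_rate
  stopifnot(rate > 60)
  co <- butter_coeffs(order, band, rate, "pass")
  bl_n <- max(1L, round(block_ms * rate / 1000))
  rows <- list()
  blocks <- list()
  for (tr in session_trials(bundle)) {
    if (is.null(tr$emg)) next
    ts <- emg_timestamps(tr, rate)
    bw_ <- c(unname(tr$events["LCDon"]), unname(tr$events["ObjCue"]))
    rw <- reaction_window(tr, reaction_def)
    if (rw[2] > max(ts) || bw_[1] < min(ts))
      stop("trial ", tr$trial, ": interval outside EMG trace")
    ib <- which(ts >= bw_[1] & ts < bw_[2])
    ir <- which(ts >= rw[1] & ts < rw[2])
    block_means <- function(env, idx) {
      nb <- length(idx) %/% bl_n
      if (nb < 1L) return(numeric(0))
      colMeans(matrix(env[idx[seq_len(nb * bl_n)]], bl_n, nb))
    }
    for (m in seq_len(nrow(tr$emg))) {
      env <- filtfilt_bw(co$b, co$a, abs(tr$emg[m, ]))
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr$trial, condition = tr$condition, grasp = tr$grasp,
        muscle = bundle$emg_muscles[m],
        baseline = mean(env[ib]), reaction = mean(env[ir]),
        stringsAsFactors = FALSE)
      for (iv in c("baseline", "reaction")) {
        bm <- block_means(env, if (iv == "baseline") ib else ir)
        if (!length(bm)) next
        blocks[[length(blocks) + 1L]] <- data.frame(
          trial = tr$trial, condition = tr$condition, grasp = tr$grasp,
          muscle = bundle$emg_muscles[m], interval = iv,
          block = seq_along(bm), value = bm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "blocks") <- do.call(rbind, blocks)
  out
}

#' Flag noisy EMG channels
#'
#' A channel is noisy for the session when its mean execution envelope
#' during the reach does not exceed its mean baseline envelope (a working
#' electrode must see the execution burst).
#'
#' @param envelopes output of [envelope_quant()]
#' @return character vector of flagged muscle names (possibly empty); if
#'   every channel is flagged a warning is raised
#' @export
flag_noisy_channels <- function(envelopes) {
  ex <- envelopes[envelopes$condition == "execution", ]
  if (!nrow(ex)) stop("need at least one execution trial")
  agg_r <- tapply(ex$reaction, ex$muscle, mean)
  agg_b <- tapply(ex$baseline, ex$muscle, mean)
  flagged <- names(agg_r)[agg_r <= agg_b]
  if (length(flagged) == length(agg_r))
    warning("all EMG channels flagged noisy; distances not interpretable")
  flagged
}

#' Per-trial EMG distances from mean baseline
#'
#' Per muscle, envelope means are z-scored against the mean and SD of the
#' baseline interval across trials (within condition); each trial's
#' distance is the Euclidean norm of its M-muscle z-vector. The session
#' summary is the median across trials.
#'
#' @param envelopes output of [envelope_quant()]
#' @param interval "reaction" or "baseline" (which interval to score)
#' @param condition condition label to score
#' @param exclude_muscles channels to drop (e.g. from
#'   [flag_noisy_channels()])
#' @return data.frame (trial, condition, grasp, distance) with attribute
#'   `median`; zero-baseline-SD muscles are dropped with a warning
#' @export
trial_distances <- function(envelopes, interval = c("reaction", "baseline"),
                            condition = "observation",
                            exclude_muscles = character(0)) {
  interval <- match.arg(interval)
  df <- envelopes[envelopes$condition == condition &
                    !envelopes$muscle %in% exclude_muscles, ]
  if (length(unique(df$trial)) < 2L)
    stop("need at least 2 trials for baseline statistics")
  out <- NULL
  for (m in unique(df$muscle)) {
    dm <- df[df$muscle == m, ]
    mu <- mean(dm$baseline); sdv <- stats::sd(dm$baseline)
    if (!is.finite(sdv) || sdv == 0) {
      warning("muscle ", m, " has zero baseline SD; dropped")
      next
    }
    z <- (dm[[interval]] - mu) / sdv
    add <- data.frame(trial = dm$trial, condition = dm$condition,
                      grasp = dm$grasp, z2 = z^2)
    out <- if (is.null(out)) add else {
      out$z2 <- out$z2 + add$z2[match(out$trial, add$trial)]
      out
    }
  }
  if (is.null(out)) stop("no usable muscles")
  res <- data.frame(trial = out$trial, condition = out$condition,
                    grasp = out$grasp, distance = sqrt(out$z2),
                    stringsAsFactors = FALSE)
  attr(res, "median") <- stats::median(res$distance)
  attr(res, "interval") <- interval
  res
}

#' Iterative EMG-based trial exclusion
#'
#' For one passive condition: per muscle, a one-sided t-test
#' ("unbalanced": the two intervals contribute unequal sample counts)
#' compares the 100-ms block means of the rectified band-passed envelope
#' between the baseline and Reaction intervals, pooled across the
#' remaining trials, asking whether Reaction EMG exceeds baseline. Since
#' genuine movement leakage recruits several muscles at once, an
#' across-muscle Stouffer combination of the per-muscle statistics joins
#' the test family; all tests are Bonferroni-corrected together. While
#' any corrected test is significant at `alpha`, one trial is removed —
#' the one with the largest mean Reaction envelope on the most
#' significant muscle, or, when the pooled test leads, the largest
#' across-muscle z-scored Reaction mean — and all tests rerun; the loop
#' stops when nothing is significant or fewer than 3 trials remain
#' (flagged). Removal order is deterministic given identical inputs.
#'
#' @param envelopes output of [envelope_quant()] (must carry the
#'   `"blocks"` attribute)
#' @param condition "observation" or "nogo"
#' @param alpha family-wise significance level (default 0.05)
#' @param exclude_muscles channels to ignore
#' @param max_iter safety cap on removals
#' @return an `exclusion_report`: removed trial indices (in removal order),
#'   per-iteration minimum corrected p-values, iterations run, `exhausted`
#'   flag, remaining trial count
#' @export
iterative_exclusion <- function(envelopes, condition, alpha = 0.05,
                                exclude_muscles = character(0),
                                max_iter = 100L) {
  stopifnot(condition %in% c("observation", "nogo"))
  blocks <- attr(envelopes, "blocks")
  if (is.null(blocks))
    stop("envelopes lack the 'blocks' attribute; use envelope_quant()")
  df <- envelopes[envelopes$condition == condition &
                    !envelopes$muscle %in% exclude_muscles, ]
  bl <- blocks[blocks$condition == condition &
                 !blocks$muscle %in% exclude_muscles, ]
  trials_left <- unique(df$trial)
  if (length(trials_left) < 3L) stop("need at least 3 trials")
  muscles <- unique(df$muscle)
  removed <- integer(0)
  pvals <- numeric(0)
  exhausted <- FALSE
  n_tests <- length(muscles) + 1L        # per-muscle family + pooled
  for (it in seq_len(max_iter)) {
    sub <- bl[bl$trial %in% trials_left, ]
    p_m <- vapply(muscles, function(m) {
      dm <- sub[sub$muscle == m, ]
      x <- dm$value[dm$interval == "reaction"]
      y <- dm$value[dm$interval == "baseline"]
      sdy <- stats::sd(y)
      if (sdy == 0)
        return(if (mean(x) > mean(y)) 0 else 1)
      # t standardized by baseline variability only: under H0 both
      # intervals share sigma, so this is calibrated; under contamination
      # the reaction variance is inflated by the very outliers under test
      # and a Welch denominator would saturate (t ~ sqrt(k)), never
      # triggering the stopping rule
      tt <- (mean(x) - mean(y)) /
        (sdy * sqrt(1 / length(x) + 1 / length(y)))
      stats::pt(tt, df = length(y) - 1, lower.tail = FALSE)
    }, numeric(1))
    # Stouffer pooling across muscles (independent channels under H0):
    # movement leakage raises every muscle a little, which no single
    # per-muscle test may catch
    z_m <- stats::qnorm(pmin(pmax(p_m, 1e-15), 1 - 1e-15),
                        lower.tail = FALSE)
    p_pool <- stats::pnorm(sum(z_m) / sqrt(length(z_m)),
                           lower.tail = FALSE)
    p_adj <- pmin(c(p_m, pooled = p_pool) * n_tests, 1)
    pvals <- c(pvals, min(p_adj))
    if (min(p_adj) >= alpha) break
    lead <- which.min(p_adj)
    dfl <- df[df$trial %in% trials_left, ]
    if (lead <= length(muscles)) {
      dm <- dfl[dfl$muscle == muscles[lead], ]
      victim <- dm$trial[which.max(dm$reaction)]
    } else {
      # pooled test leads: largest across-muscle z-scored Reaction mean
      zsum <- rep(0, length(trials_left))
      names(zsum) <- as.character(sort(trials_left))
      for (m in muscles) {
        dm <- dfl[dfl$muscle == m, ]
        mu <- mean(dm$baseline); sdv <- stats::sd(dm$baseline)
        if (!is.finite(sdv) || sdv == 0) next
        zsum[as.character(dm$trial)] <- zsum[as.character(dm$trial)] +
          (dm$reaction - mu) / sdv
      }
      victim <- as.integer(names(zsum)[which.max(zsum)])
    }
    removed <- c(removed, victim)
    trials_left <- setdiff(trials_left, victim)
    if (length(trials_left) < 3L) { exhausted <- TRUE; break }
  }
  structure(list(condition = condition, removed = removed,
                 iterations = length(pvals), p_values = pvals,
                 alpha = alpha, exhausted = exhausted,
                 n_remaining = length(trials_left),
                 excluded_muscles = exclude_muscles),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> ", x$condition, ": removed ",
      length(x$removed), " trial(s)",
      if (length(x$removed)) paste0(" [",
                                    paste(x$removed, collapse = ", "), "]"),
      "; ", x$n_remaining, " remaining",
      if (x$exhausted) " (stopped: trials exhausted)", "\n", sep = "")
  invisible(x)
}

#' Minimum-trial gating after exclusion
#'
#' Applies the downstream inclusion floors: units lose observation
#' analyses below 10 observation trials per grasp, and NoGo analyses below
#' 7 NoGo trials per grasp.
#'
#' @param bundle a `session_bundle` (post-exclusion)
#' @param min_obs,min_nogo per-grasp trial floors
#' @return list of logicals `observation_ok`, `nogo_ok` (per grasp)
#' @export
trial_floor_check <- function(bundle, min_obs = 10L, min_nogo = 7L) {
  cnt <- function(cond, g) length(session_trials(bundle, cond, g))
  list(observation_ok = stats::setNames(
         vapply(GRASPS, function(g) cnt("observation", g) >= min_obs,
                logical(1)), GRASPS),
       nogo_ok = stats::setNames(
         vapply(GRASPS, function(g) cnt("nogo", g) >= min_nogo,
                logical(1)), GRASPS))
}

#' Median split of trials by EMG distance
#'
#' Splits a condition's trials (per grasp) at the median of their
#' Reaction-interval distances, before any EMG-based exclusion. With an odd
#' trial count the median trial joins the low half; exact ties are broken
#' deterministically by trial index.
#'
#' @param distances output of [trial_distances()]
#' @return list per grasp with `low` and `high` integer trial-index sets
#' @export
median_split <- function(distances) {
  out <- list()
  for (g in unique(distances$grasp)) {
    d <- distances[distances$grasp == g, ]
    if (nrow(d) < 4L) stop("need at least 4 trials per grasp for a split")
    ord <- order(d$distance, d$trial)
    n_low <- ceiling(nrow(d) / 2)
    out[[g]] <- list(low = sort(d$trial[ord[seq_len(n_low)]]),
                     high = sort(d$trial[ord[-seq_len(n_low)]]))
  }
  out
}
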