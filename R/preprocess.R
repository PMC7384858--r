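#' Construct a rate tensor
#'
#' Neurons x timepoints firing-rate matrix with its binning, alignment and
#' normalization metadata. The time axis is in ms relative to the canonical
#' Go/NoGo cue (t = 0) unless stated otherwise; bins are half-open
#' `[t, t + bin_width)` and `time_axis` holds left bin edges.
#'
#' @param values numeric matrix, neurons x timepoints (spikes/s or
#'   normalized units)
#' @param time_axis numeric vector of left bin edges (ms)
#' @param bin_width bin width (ms)
#' @param alignment e.g. `"single:GoNogo"` or `"multi:(Go,HPR,DO)"`
#' @param normalization `NULL`, or a record of the normalization applied
#' @param neuron_ids character vector of neuron ids (rownames)
#' @param condition,grasp labels carried for bookkeeping
#' @param canonical named numeric of canonical event times on this axis
#'   (e.g. LCDon, ObjCue, GoNogo = 0, HPR, DO, HO)
#' @return an object of class `rate_tensor`
#' @export
rate_tensor <- function(values, time_axis, bin_width, alignment = "single:GoNogo",
                        normalization = NULL, neuron_ids = NULL,
                        condition = NULL, grasp = NULL, canonical = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(time_axis), bin_width > 0)
  if (!is.null(neuron_ids)) rownames(values) <- neuron_ids
  structure(list(values = values, time_axis = as.numeric(time_axis),
                 bin_width = bin_width, alignment = alignment,
                 normalization = normalization,
                 condition = condition, grasp = grasp,
                 canonical = canonical),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  cat("<rate_tensor> ", nrow(x$values), " neurons x ", ncol(x$values),
      " bins (", x$bin_width, " ms), align ", x$alignment,
      if (!is.null(x$condition)) paste0(", ", x$condition),
      if (!is.null(x$grasp)) paste0("/", x$grasp),
      if (!is.null(x$normalization)) ", normalized", "\n", sep = "")
  invisible(x)
}

#' Slice a rate tensor to a time window
#'
#' @param tensor a `rate_tensor`
#' @param window length-2 numeric, `[lo, hi)` on the tensor's time axis (ms)
#' @return a `rate_tensor` restricted to bins whose left edge lies in the
#'   window
#' @export
slice_tensor <- function(tensor, window) {
  keep <- tensor$time_axis >= window[1] & tensor$time_axis < window[2]
  if (!any(keep)) stop("window [", window[1], ", ", window[2],
                       ") outside tensor time axis")
  tensor$values <- tensor$values[, keep, drop = FALSE]
  tensor$time_axis <- tensor$time_axis[keep]
  tensor
}

#' Bin spike times into counts
#'
#' Half-open bins `[t, t + bin_width)`: a spike exactly on a boundary falls
#' in the bin starting there. Spike times must already be aligned so that
#' the window is expressed relative to the alignment event.
#'
#' @param spikes numeric vector of (aligned) spike times, ms
#' @param window length-2 numeric `c(start, end)`, ms; the window length
#'   must be a positive multiple of `bin_width`
#' @param bin_width bin width, ms
#' @return integer vector of counts, one per bin; attribute `edges` holds
#'   left bin edges
#' @export
bin_spikes <- function(spikes, window, bin_width) {
  stopifnot(bin_width > 0)
  if (window[2] <= window[1]) stop("empty binning window")
  edges <- seq(window[1], window[2], by = bin_width)
  if (length(edges) < 2L) stop("window shorter than one bin")
  nb <- length(edges) - 1L
  counts <- integer(nb)
  sp <- spikes[spikes >= window[1] & spikes < edges[nb + 1L]]
  if (length(sp)) {
    ix <- findInterval(sp, edges)           # [edge_i, edge_{i+1})
    ix <- ix[ix >= 1L & ix <= nb]
    tb <- tabulate(ix, nbins = nb)
    counts <- tb
  }
  structure(counts, edges = edges[seq_len(nb)])
}

#' Gaussian-kernel smoothing of a binned rate
#'
#' Discrete Gaussian kernel of the given standard deviation, truncated at
#' +/- 4 SD and normalized to unit sum; near the edges the kernel is
#' renormalized over its valid support so constants are preserved
#' everywhere and interior mass is conserved.
#'
#' @param rates numeric vector (one neuron) or matrix (neurons x bins)
#' @param sd kernel standard deviation, ms
#' @param bin_width bin width of `rates`, ms
#' @return smoothed object of the same shape
#' @export
smooth_gaussian <- function(rates, sd, bin_width) {
  stopifnot(sd > 0, bin_width > 0)
  r <- ceiling(4 * sd / bin_width)
  k <- stats::dnorm((-r:r) * bin_width, sd = sd)
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    full <- stats::convolve(x, rev(k), type = "open")
    wsum <- stats::convolve(rep(1, n), rev(k), type = "open")
    (full / wsum)[(r + 1):(r + n)]
  }
  if (is.matrix(rates)) t(apply(rates, 1L, smooth1)) else smooth1(rates)
}

# Mean canonical event times (ms relative to Go/NoGo = 0) across execution
# and observation correct Go trials, both grasps: HPR = mean RT, DO = mean
# RT+MT, HO likewise; LCDon/ObjCue as mean negative offsets from Go.
#' Canonical event times for a session
#'
#' @param bundle a `session_bundle`
#' @return named numeric: LCDon, ObjCue, GoNogo (= 0), HPR, DO, HO on the
#'   Go-relative canonical timeline
#' @export
canonical_events <- function(bundle) {
  trs <- session_trials(bundle, condition = c("execution", "observation"))
  trs <- Filter(function(tr) all(c("GoNogo", "HPR", "DO") %in%
                                   names(tr$events)), trs)
  if (!length(trs)) stop("no Go trials with GoNogo/HPR/DO events")
  rel <- function(ev) vapply(trs, function(tr)
    unname(tr$events[ev] - tr$events["GoNogo"]), numeric(1))
  ho <- vapply(trs, function(tr)
    if ("HO" %in% names(tr$events))
      unname(tr$events["HO"] - tr$events["GoNogo"]) else NA_real_, numeric(1))
  c(LCDon = mean(rel("LCDon")), ObjCue = mean(rel("ObjCue")), GoNogo = 0,
    HPR = mean(rel("HPR")), DO = mean(rel("DO")),
    HO = mean(ho, na.rm = TRUE))
}

psth_aligned <- function(trials, n_neurons, event, window, bin_width) {
  mats <- lapply(trials, function(tr) {
    t0 <- unname(tr$events[event])
    vapply(tr$spikes, function(sp)
      as.numeric(bin_spikes(sp - t0, window, bin_width)),
      numeric(round(diff(window) / bin_width)))
  })
  counts <- Reduce(`+`, mats) / length(mats)
  t(counts) * (1000 / bin_width)          # neurons x bins, spikes/s
}

#' Multi-event aligned trial-average rate tensor
#'
#' Firing rates are averaged separately aligned to the Go cue, homepad
#' release (HPR) and displacement onset (DO), then stitched on a canonical
#' timeline where Go = 0 and HPR/DO sit at their session-mean times. Each
#' canonical segment is owned by its nearest event (boundaries at midpoints
#' between canonical event times); across each boundary the two aligned
#' estimates are blended by a short linear crossfade so the stitched trace
#' is continuous. Trials missing a required event are skipped with a
#' warning. Smoothing is applied per aligned segment before stitching.
#'
#' @param bundle a `session_bundle`
#' @param condition "execution", "observation" or "nogo"; NoGo trials have
#'   no movement events and are singly aligned to the NoGo cue
#' @param grasp "PG" or "WHG" (NULL = both pooled)
#' @param bin_width bin width, ms (default 10)
#' @param smooth_sd Gaussian kernel SD, ms (default 50); NULL disables
#' @param canonical canonical event map from [canonical_events()]; computed
#'   from the session when NULL
#' @param window canonical timeline span, ms relative to Go; default from
#'   canonical LCDon - 300 to canonical HO + 700
#' @param blend crossfade half-width at each stitch boundary, ms
#' @return a `rate_tensor` on the canonical timeline
#' @export
multi_align <- function(bundle, condition, grasp = NULL, bin_width = 10,
                        smooth_sd = 50, canonical = NULL, window = NULL,
                        blend = 50) {
  canonical <- canonical %||% canonical_events(bundle)
  window <- window %||% c(floor((canonical["LCDon"] - 300) / bin_width),
                          ceiling((canonical["HO"] + 700) / bin_width)) *
    bin_width
  trials <- session_trials(bundle, condition = condition, grasp = grasp)
  if (!length(trials)) stop("no trials for condition ", condition)
  n_neurons <- nrow(bundle$neurons)
  taxis <- seq(window[1], window[2] - bin_width, by = bin_width)

  single_align <- condition == "nogo"
  if (!single_align) {
    need <- c("GoNogo", "HPR", "DO")
    ok <- vapply(trials, function(tr) all(need %in% names(tr$events)),
                 logical(1))
    if (any(!ok))
      warning(sum(!ok), " trial(s) missing Go/HPR/DO skipped in multi_align")
    trials <- trials[ok]
    if (!length(trials)) stop("no trials with all of Go/HPR/DO")
  }

  pad <- if (is.null(smooth_sd)) 0 else ceiling(4 * smooth_sd / bin_width) *
    bin_width
  seg_psth <- function(event, seg) {
    w <- c(seg[1] - pad - canonical[event], seg[2] + pad - canonical[event])
    m <- psth_aligned(trials, n_neurons, event, w, bin_width)
    if (!is.null(smooth_sd)) m <- smooth_gaussian(m, smooth_sd, bin_width)
    npad <- pad / bin_width
    m[, (npad + 1):(ncol(m) - npad), drop = FALSE]
  }

  if (single_align) {
    vals <- seg_psth("GoNogo", window)
    return(rate_tensor(vals, taxis, bin_width, alignment = "single:GoNogo",
                       neuron_ids = bundle$neurons$neuron_id,
                       condition = condition, grasp = grasp,
                       canonical = canonical))
  }

  b1 <- unname((canonical["GoNogo"] + canonical["HPR"]) / 2)
  b2 <- unname((canonical["HPR"] + canonical["DO"]) / 2)
  b1 <- round(b1 / bin_width) * bin_width
  b2 <- round(b2 / bin_width) * bin_width
  go <- seg_psth("GoNogo", c(window[1], b1 + blend))
  hp <- seg_psth("HPR", c(b1 - blend, b2 + blend))
  do_ <- seg_psth("DO", c(b2 - blend, window[2]))

  nb <- length(taxis)
  vals <- matrix(0, n_neurons, nb)
  wts <- numeric(nb)
  place <- function(acc, seg, lo) {
    i0 <- round((lo - window[1]) / bin_width)
    idx <- (i0 + 1):(i0 + ncol(seg))
    list(idx = idx, seg = seg)
  }
  ramp <- function(n, up) if (up) seq(0, 1, length.out = n) else
    seq(1, 0, length.out = n)
  add_seg <- function(seg, lo, w_left_up = NULL, w_right_down = NULL) {
    p <- place(NULL, seg, lo)
    w <- rep(1, ncol(seg))
    nb_bl <- round(2 * blend / bin_width)
    if (!is.null(w_left_up) && w_left_up)  w[seq_len(nb_bl)] <-
        ramp(nb_bl, TRUE)
    if (!is.null(w_right_down) && w_right_down)
      w[(ncol(seg) - nb_bl + 1):ncol(seg)] <- ramp(nb_bl, FALSE)
    vals[, p$idx] <<- vals[, p$idx] + sweep(seg, 2L, w, `*`)
    wts[p$idx] <<- wts[p$idx] + w
  }
  add_seg(go, window[1], w_left_up = FALSE, w_right_down = TRUE)
  add_seg(hp, b1 - blend, w_left_up = TRUE, w_right_down = TRUE)
  add_seg(do_, b2 - blend, w_left_up = TRUE, w_right_down = FALSE)
  vals <- sweep(vals, 2L, pmax(wts, 1e-12), `/`)
  # residual gaps (possible with very narrow windows): linear interpolation
  if (any(wts < 1e-9)) {
    for (i in seq_len(n_neurons))
      vals[i, wts < 1e-9] <- stats::approx(taxis[wts >= 1e-9],
                                           vals[i, wts >= 1e-9],
                                           xout = taxis[wts < 1e-9],
                                           rule = 2)$y
  }
  rate_tensor(vals, taxis, bin_width, alignment = "multi:(Go,HPR,DO)",
              neuron_ids = bundle$neurons$neuron_id,
              condition = condition, grasp = grasp, canonical = canonical)
}

#' Baseline-correct rate tensors
#'
#' Subtracts, per neuron, a single scalar baseline: the mean rate in the
#' 250 ms before LCDon averaged across all supplied conditions. Negative
#' values after correction are meaningful (suppression below baseline).
#'
#' @param tensors a `rate_tensor` or list of them (same neurons, same axis)
#' @param window baseline window, ms relative to the canonical LCDon
#' @return object(s) of the same shape with `baseline` attribute recording
#'   the subtracted vector
#' @export
baseline_correct <- function(tensors, window = c(-250, 0)) {
  single <- inherits(tensors, "rate_tensor")
  if (single) tensors <- list(tensors)
  base_per <- lapply(tensors, function(tt) {
    if (is.null(tt$canonical) || is.na(tt$canonical["LCDon"]))
      stop("tensor lacks canonical LCDon time")
    w <- tt$canonical["LCDon"] + window
    keep <- tt$time_axis >= w[1] & tt$time_axis < w[2]
    if (!any(keep)) stop("baseline window outside tensor data span")
    rowMeans(tt$values[, keep, drop = FALSE])
  })
  base <- Reduce(`+`, base_per) / length(base_per)
  out <- lapply(tensors, function(tt) {
    tt$values <- tt$values - base
    attr(tt, "baseline") <- base
    tt
  })
  if (single) out[[1]] else out
}

#' Soft-normalize rate tensors
#'
#' `range_soft` (population-average / subspace pipeline): each neuron's
#' rates are divided by its firing-rate range across all times and all
#' supplied conditions plus a small constant (default 5 spikes/s), bounding
#' normalized rates inside (-1, 1). `absmax_soft` (epoch-correlation
#' pipeline): division by the maximum absolute value across all supplied
#' epoch x condition means plus the constant.
#'
#' @param tensors a `rate_tensor`/matrix or list of them (baseline-corrected)
#' @param mode "range_soft" or "absmax_soft"
#' @param constant soft constant, spikes/s (> 0, default 5)
#' @return normalized object(s) with a `normalization` record; silent
#'   neurons (zero range) are divided by the constant alone
#' @export
soft_normalize <- function(tensors, mode = c("range_soft", "absmax_soft"),
                           constant = 5) {
  mode <- match.arg(mode)
  stopifnot(constant > 0)
  single <- !is.list(tensors) || inherits(tensors, "rate_tensor")
  if (single) tensors <- list(tensors)
  getv <- function(x) if (inherits(x, "rate_tensor")) x$values else
    as.matrix(x)
  allv <- do.call(cbind, lapply(tensors, getv))
  denom <- if (mode == "range_soft")
    apply(allv, 1L, function(r) diff(range(r))) + constant
  else
    apply(abs(allv), 1L, max) + constant
  out <- lapply(tensors, function(x) {
    if (inherits(x, "rate_tensor")) {
      x$values <- x$values / denom
      x$normalization <- list(mode = mode, constant = constant,
                              denominator = denom)
      x
    } else getv(x) / denom
  })
  if (single) out[[1]] else out
}

# epochs ----------------------------------------------------------------

#' Canonical epoch definitions
#'
#' Two canonical sets: `"anova"` (Baseline: LCDon-ObjCue; Reach: HPR-DO;
#' GraspHold: 0-700 ms from HO) used for unit classification, and
#' `"correlation"`, the eight task periods (PreLCD, Pres, ObjectCue,
#' EarlyReact, LateReact, EarlyReach, LateReach, Hold). Event-spanned
#' epochs are resolved per trial; Early/Late Reach are the first and second
#' halves of each trial's HPR-DO interval.
#'
#' @param set "anova" or "correlation"
#' @return named list; each element is `list(anchor, offsets)` or
#'   `list(from, to)` or `list(span_halves = ...)`
#' @export
canonical_epochs <- function(set = c("anova", "correlation")) {
  set <- match.arg(set)
  if (set == "anova")
    list(Baseline  = list(from = "LCDon", to = "ObjCue"),
         Reach     = list(from = "HPR", to = "DO"),
         GraspHold = list(anchor = "HO", offsets = c(0, 700)))
  else
    list(PreLCD    = list(anchor = "LCDon", offsets = c(-250, 0)),
         Pres      = list(from = "LCDon", to = "ObjCue"),
         ObjectCue = list(anchor = "GoNogo", offsets = c(-500, 0)),
         EarlyReact = list(anchor = "GoNogo", offsets = c(0, 150)),
         LateReact  = list(anchor = "GoNogo", offsets = c(150, 300)),
         EarlyReach = list(span_halves = c("HPR", "DO"), half = 1L),
         LateReach  = list(span_halves = c("HPR", "DO"), half = 2L),
         Hold       = list(anchor = "HO", offsets = c(0, 700)))
}

# Absolute [lo, hi) window of an epoch on one trial, or NULL if unresolvable
epoch_window <- function(ep, events) {
  if (!is.null(ep$anchor)) {
    if (!ep$anchor %in% names(events)) return(NULL)
    return(unname(events[ep$anchor] + ep$offsets))
  }
  if (!is.null(ep$from)) {
    if (!all(c(ep$from, ep$to) %in% names(events))) return(NULL)
    return(unname(c(events[ep$from], events[ep$to])))
  }
  ev <- ep$span_halves
  if (!all(ev %in% names(events))) return(NULL)
  lo <- unname(events[ev[1]]); hi <- unname(events[ev[2]])
  mid <- (lo + hi) / 2
  if (ep$half == 1L) c(lo, mid) else c(mid, hi)
}

#' Trial-level epoch mean rates
#'
#' Mean firing rate (spikes/s) of every neuron in every resolvable epoch of
#' every selected trial. Epochs a trial cannot resolve (e.g. movement
#' epochs on NoGo) are omitted for that trial.
#'
#' @param bundle a `session_bundle`
#' @param epochs epoch definition list, see [canonical_epochs()]
#' @param condition,grasp trial filters
#' @return long data.frame: trial, condition, grasp, epoch, neuron, rate
#' @export
trial_epoch_rates <- function(bundle, epochs = canonical_epochs("anova"),
                              condition = NULL, grasp = NULL) {
  trials <- session_trials(bundle, condition = condition, grasp = grasp)
  n_neurons <- nrow(bundle$neurons)
  rows <- list()
  for (tr in trials) {
    for (en in names(epochs)) {
      w <- epoch_window(epochs[[en]], tr$events)
      if (is.null(w) || w[2] <= w[1]) next
      dur <- (w[2] - w[1]) / 1000
      cnt <- vapply(tr$spikes, function(sp)
        sum(sp >= w[1] & sp < w[2]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr$trial, condition = tr$condition, grasp = tr$grasp,
        epoch = en, neuron = seq_len(n_neurons), rate = cnt / dur,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Trial-averaged epoch rates
#'
#' Averages [trial_epoch_rates()] across trials, separately per condition
#' and grasp.
#'
#' @inheritParams trial_epoch_rates
#' @return data.frame: condition, grasp, epoch, neuron, rate (mean across
#'   trials), n_trials
#' @export
epoch_average <- function(bundle, epochs = canonical_epochs("correlation"),
                          condition = NULL, grasp = NULL) {
  df <- trial_epoch_rates(bundle, epochs, condition, grasp)
  if (is.null(df)) stop("no resolvable epochs")
  agg <- stats::aggregate(rate ~ condition + grasp + epoch + neuron, df, mean)
  n <- stats::aggregate(rate ~ condition + grasp + epoch + neuron, df, length)
  agg$n_trials <- n$rate
  agg
}

#' Per-trial behaviour metrics
#'
#' Reaction time (Go cue to homepad release) and movement time (homepad
#' release to displacement onset) for every correct Go trial, with
#' per-session medians by condition and grasp. NoGo trials, having no
#' movement, are excluded.
#'
#' @param bundle a `session_bundle`
#' @return list with `trials` (trial, condition, grasp, RT, MT) and
#'   `medians` (condition, grasp, median_RT, median_MT, n)
#' @export
compute_behaviour <- function(bundle) {
  trs <- session_trials(bundle, condition = c("execution", "observation"))
  rows <- lapply(trs, function(tr) {
    ev <- tr$events
    if (!all(c("GoNogo", "HPR", "DO") %in% names(ev))) return(NULL)
    rt <- unname(ev["HPR"] - ev["GoNogo"])
    mt <- unname(ev["DO"] - ev["HPR"])
    if (rt <= 0 || mt <= 0)
      stop("trial ", tr$trial, ": non-positive RT/MT interval")
    data.frame(trial = tr$trial, condition = tr$condition, grasp = tr$grasp,
               RT = rt, MT = mt, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no Go trials with RT/MT events")
  med <- do.call(rbind, lapply(split(tab, list(tab$condition, tab$grasp),
                                     drop = TRUE), function(d)
    data.frame(condition = d$condition[1], grasp = d$grasp[1],
               median_RT = stats::median(d$RT), median_MT = stats::median(d$MT),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(med) <- NULL
  list(trials = tab, medians = med)
}
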