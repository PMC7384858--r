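#' Construct a session bundle
#'
#' A `session_bundle` is the universal input record for every analysis in the
#' package: spike times per neuron per trial, task-event timestamps, trial
#' labels, and (optionally) multichannel EMG for one recording session.
#' All times are in milliseconds on a common session clock.
#'
#' @param session_id character scalar identifying the session.
#' @param neurons data.frame with columns `neuron_id`, `area` ("M1" or "F5"),
#'   `identity` ("PTN" or "UID"), `subject`.
#' @param trials list of trial records. Each record is a list with elements
#'   `trial` (unique integer index), `condition` ("execution", "observation"
#'   or "nogo"), `grasp` ("PG" or "WHG"), `outcome` ("correct" or "error"),
#'   `span` (numeric length-2, recorded start/end on the session clock),
#'   `events` (named numeric, subset of LCDon, ObjCue, GoNogo, HPR, DO, HO,
#'   HOFF, HPN), `spikes` (list of numeric spike-time vectors, one per
#'   neuron), and optionally `emg` (muscles x samples matrix starting at
#'   `span[1]`).
#' @param emg_muscles character vector of muscle names (<= 12) or `NULL` when
#'   the session has no EMG.
#' @param emg_rate EMG sampling rate in Hz (required when EMG present).
#' @param contaminated integer vector of trial indices with known injected
#'   EMG contamination (ground truth bookkeeping; empty for real data).
#' @param validate check all invariants before returning.
#' @return an object of class `session_bundle`.
#' @seealso [validate_session()], [read_session()], [write_session()]
#' @export
session_bundle <- function(session_id, neurons, trials, emg_muscles = NULL,
                           emg_rate = NULL, contaminated = integer(0),
                           validate = TRUE) {
  b <- structure(
    list(session_id = as.character(session_id),
         neurons = as.data.frame(neurons, stringsAsFactors = FALSE),
         trials = trials,
         emg_muscles = emg_muscles,
         emg_rate = emg_rate,
         spike_unit = "ms",
         contaminated = as.integer(contaminated)),
    class = "session_bundle")
  if (validate) validate_session(b)
  b
}

#' Sub-population label for each neuron
#'
#' M1 neurons split by antidromic identification (M1-PTN vs M1-UID); F5
#' pools PTNs and UIDs into a single population.
#'
#' @param bundle a `session_bundle`
#' @return character vector, one of "M1-PTN", "M1-UID", "F5" per neuron
#' @export
neuron_population <- function(bundle) {
  ifelse(bundle$neurons$area == "F5", "F5",
         paste0("M1-", bundle$neurons$identity))
}

#' Validate a session bundle
#'
#' Checks every structural invariant: unique trial indices, legal condition
#' and grasp labels, task-ordered strictly increasing event times, absence of
#' movement events on NoGo trials, spike times inside the recorded span, and
#' EMG shape/finiteness. Violations raise an error naming the offending
#' trial; nothing is silently coerced.
#'
#' @param bundle a `session_bundle`
#' @return the bundle, invisibly
#' @export
validate_session <- function(bundle) {
  stopifnot(inherits(bundle, "session_bundle"))
  nr <- bundle$neurons
  req <- c("neuron_id", "area", "identity", "subject")
  if (!all(req %in% names(nr)))
    stop("neurons table must have columns: ", paste(req, collapse = ", "))
  if (!all(nr$area %in% c("M1", "F5")))
    stop("neuron area must be 'M1' or 'F5'")
  if (!all(nr$identity %in% c("PTN", "UID")))
    stop("neuron identity must be 'PTN' or 'UID'")
  n_neurons <- nrow(nr)

  idx <- vapply(bundle$trials, function(tr) as.integer(tr$trial), integer(1))
  if (anyDuplicated(idx)) stop("trial indices must be unique")

  for (tr in bundle$trials) {
    lab <- paste0("trial ", tr$trial)
    if (!tr$condition %in% CONDITIONS)
      stop(lab, ": condition must be one of ",
           paste(CONDITIONS, collapse = ", "))
    if (!tr$grasp %in% GRASPS)
      stop(lab, ": grasp must be 'PG' or 'WHG'")
    if (!tr$outcome %in% c("correct", "error"))
      stop(lab, ": outcome must be 'correct' or 'error'")
    if (length(tr$span) != 2L || tr$span[2] <= tr$span[1])
      stop(lab, ": span must be an increasing length-2 vector")
    ev <- tr$events
    if (!all(names(ev) %in% EVENT_ORDER))
      stop(lab, ": unknown event name(s): ",
           paste(setdiff(names(ev), EVENT_ORDER), collapse = ", "))
    if (tr$condition == "nogo" && any(MOVEMENT_EVENTS %in% names(ev)))
      stop(lab, ": NoGo trial carries movement event(s): ",
           paste(intersect(names(ev), MOVEMENT_EVENTS), collapse = ", "))
    ord <- ev[EVENT_ORDER[EVENT_ORDER %in% names(ev)]]
    if (length(ord) > 1L && any(diff(unname(ord)) <= 0))
      stop(lab, ": event times must be strictly increasing in task order")
    if (length(ev) && (any(ev < tr$span[1]) || any(ev > tr$span[2])))
      stop(lab, ": event times outside recorded span")
    if (length(tr$spikes) != n_neurons)
      stop(lab, ": expected ", n_neurons, " spike lists, found ",
           length(tr$spikes))
    for (sp in tr$spikes) {
      if (length(sp) &&
          (any(sp < tr$span[1]) || any(sp > tr$span[2])))
        stop(lab, ": spike times outside recorded span")
    }
    if (!is.null(tr$emg)) {
      if (is.null(bundle$emg_muscles))
        stop(lab, ": trial has EMG but bundle declares no muscles")
      if (nrow(tr$emg) != length(bundle$emg_muscles))
        stop(lab, ": EMG trace count (", nrow(tr$emg),
             ") != muscle count (", length(bundle$emg_muscles), ")")
      if (any(!is.finite(tr$emg)))
        stop(lab, ": EMG contains non-finite samples")
    }
  }
  if (!is.null(bundle$emg_muscles)) {
    if (length(bundle$emg_muscles) > 12L)
      stop("at most 12 EMG muscles supported")
    if (is.null(bundle$emg_rate) || bundle$emg_rate <= 60)
      stop("EMG sampling rate must be set and exceed 60 Hz")
  }
  invisible(bundle)
}

#' @export
print.session_bundle <- function(x, ...) {
  n_tr <- length(x$trials)
  conds <- table(vapply(x$trials, `[[`, "", "condition"))
  cat("<session_bundle> ", x$session_id, "\n",
      "  neurons: ", nrow(x$neurons), "  trials: ", n_tr, " (",
      paste(names(conds), conds, sep = "=", collapse = ", "), ")\n",
      "  EMG: ",
      if (is.null(x$emg_muscles)) "none" else
        paste0(length(x$emg_muscles), " muscles @ ", x$emg_rate, " Hz"),
      "\n", sep = "")
  invisible(x)
}

# helpers ---------------------------------------------------------------

trial_field <- function(bundle, field) {
  vapply(bundle$trials, function(tr) as.character(tr[[field]]), character(1))
}

#' Select correct trials by condition/grasp
#'
#' @param bundle a `session_bundle`
#' @param condition,grasp optional label filters (NULL = all)
#' @param outcome outcome filter; error trials are excluded from every
#'   analysis by default
#' @return list of trial records
#' @export
session_trials <- function(bundle, condition = NULL, grasp = NULL,
                           outcome = "correct") {
  keep <- vapply(bundle$trials, function(tr) {
    (is.null(condition) || tr$condition %in% condition) &&
      (is.null(grasp) || tr$grasp %in% grasp) &&
      (is.null(outcome) || tr$outcome %in% outcome)
  }, logical(1))
  bundle$trials[keep]
}

#' Drop trials from a session by trial index
#'
#' @param bundle a `session_bundle`
#' @param trial_idx integer trial indices to remove
#' @return the reduced bundle
#' @export
drop_trials <- function(bundle, trial_idx) {
  keep <- !vapply(bundle$trials, function(tr) tr$trial %in% trial_idx,
                  logical(1))
  bundle$trials <- bundle$trials[keep]
  bundle
}

# I/O -------------------------------------------------------------------

#' Write a session bundle to disk
#'
#' The native on-disk form is a single JSON document mirroring the in-memory
#' structure (neuron table, per-trial events/spikes, optional EMG block).
#' Writing the same bundle twice produces identical logical content on
#' re-read.
#'
#' @param bundle a valid `session_bundle`
#' @param path output file path (".json")
#' @return `path`, invisibly
#' @export
write_session <- function(bundle, path) {
  validate_session(bundle)
  trials <- lapply(bundle$trials, function(tr) {
    out <- list(trial = tr$trial, condition = tr$condition,
                grasp = tr$grasp, outcome = tr$outcome,
                span = tr$span,
                events = as.list(tr$events),
                spikes = lapply(tr$spikes, as.numeric))
    if (!is.null(tr$emg)) out$emg <- tr$emg
    out
  })
  doc <- list(format = "mirrorpop-session", version = 1L,
              session_id = bundle$session_id,
              spike_unit = bundle$spike_unit,
              neurons = bundle$neurons,
              emg_muscles = bundle$emg_muscles,
              emg_rate = bundle$emg_rate,
              contaminated = bundle$contaminated,
              trials = trials)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; every invariant is re-checked on load, so a
#' file describing e.g. a NoGo trial with a movement event is rejected with
#' an error naming the trial.
#'
#' @param path path to a session JSON written by [write_session()]
#' @return a validated `session_bundle`
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mirrorpop-session"))
    stop("schema error: not a mirrorpop session file (missing format tag)")
  for (req in c("session_id", "neurons", "trials"))
    if (is.null(doc[[req]])) stop("schema error: missing group '", req, "'")
  neurons <- do.call(rbind, lapply(doc$neurons, function(n)
    data.frame(neuron_id = n$neuron_id, area = n$area,
               identity = n$identity, subject = n$subject,
               stringsAsFactors = FALSE)))
  n_neurons <- nrow(neurons)
  trials <- lapply(doc$trials, function(tr) {
    out <- list(trial = as.integer(tr$trial), condition = tr$condition,
                grasp = tr$grasp, outcome = tr$outcome,
                span = as.numeric(unlist(tr$span)),
                events = unlist(tr$events) %||% stats::setNames(numeric(0),
                                                                character(0)),
                spikes = lapply(tr$spikes, function(s) as.numeric(unlist(s))))
    if (length(out$spikes) == 0L && n_neurons > 0L)
      out$spikes <- rep(list(numeric(0)), n_neurons)
    if (!is.null(tr$emg))
      out$emg <- do.call(rbind, lapply(tr$emg, function(r)
        as.numeric(unlist(r))))
    out
  })
  session_bundle(doc$session_id, neurons, trials,
                 emg_muscles = if (is.null(doc$emg_muscles)) NULL else
                   as.character(unlist(doc$emg_muscles)),
                 emg_rate = doc$emg_rate,
                 contaminated = as.integer(unlist(doc$contaminated)))
}

#' Export the trial event table as CSV
#'
#' One row per trial with columns session_id, trial, condition, grasp, the
#' eight task events (NA where absent), and outcome.
#'
#' @param bundle a `session_bundle`
#' @param path output CSV path
#' @return the event table, invisibly
#' @export
write_event_csv <- function(bundle, path) {
  rows <- lapply(bundle$trials, function(tr) {
    ev <- stats::setNames(rep(NA_real_, length(EVENT_ORDER)), EVENT_ORDER)
    ev[names(tr$events)] <- tr$events
    cbind(data.frame(session_id = bundle$session_id, trial = tr$trial,
                     condition = tr$condition, grasp = tr$grasp,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(ev)),
          data.frame(outcome = tr$outcome, stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Load deposited trial-averaged rate matrices
#'
#' Adapter for externally deposited, already trial-averaged population rate
#' matrices, exported as plain CSV: one file per
#' `<population>_<condition>_<grasp>.csv`, first column `time_ms` (common
#' multi-aligned timeline), remaining columns one neuron each. A sidecar
#' `meta.json` may set `bin_width` and `normalized`. The core pipeline never
#' requires this adapter; if the deposit is absent the caller is expected to
#' fall back to synthetic mode.
#'
#' @param path directory containing the CSV export
#' @return named list of [rate_tensor()] objects, flagged as
#'   already-normalized when the deposit says so
#' @export
load_deposited_rates <- function(path) {
  if (!dir.exists(path))
    stop("deposit not found: ", path,
         " (pipeline can continue in synthetic mode)")
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files))
    stop("adapter error: no rate CSVs under ", path, "; found files: ",
         paste(list.files(path), collapse = ", "))
  meta_path <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  out <- list()
  for (f in files) {
    key <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("adapter error: cannot parse '", basename(f),
           "' as <population>_<condition>_<grasp>.csv")
    tab <- utils::read.csv(f, check.names = FALSE)
    if (names(tab)[1] != "time_ms")
      stop("adapter error: first column of ", basename(f),
           " must be time_ms; found: ", paste(names(tab), collapse = ", "))
    vals <- t(as.matrix(tab[, -1, drop = FALSE]))
    out[[key]] <- rate_tensor(
      values = vals, time_axis = tab$time_ms,
      bin_width = meta$bin_width %||%
        stats::median(diff(tab$time_ms)),
      alignment = "multi:(Go,HPR,DO)",
      normalization = if (isTRUE(meta$normalized)) "deposited" else NULL,
      neuron_ids = rownames(vals) %||% colnames(tab)[-1],
      condition = parts[length(parts) - 1L],
      grasp = parts[length(parts)])
  }
  dims <- vapply(out, function(tt) nrow(tt$values), integer(1))
  pops <- vapply(names(out), function(k)
    paste(utils::head(strsplit(k, "_")[[1]], -2L), collapse = "_"), "")
  for (p in unique(pops))
    if (length(unique(dims[pops == p])) != 1L)
      stop("adapter error: inconsistent neuron counts within population ", p)
  out
}
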