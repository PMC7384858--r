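# Shared fixtures: everything is generated in code at test time.

# A small, fast synthetic session for structural tests.
small_session <- function(seed = 11, ...) {
  defaults <- list(
    n_neurons = 12, k_latent = 3, emg = FALSE, n_muscles = 6,
    trials_per_grasp = c(execution = 6, observation = 6, nogo = 5),
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  generate_session(do.call(ground_truth_config, args))
}

# Hand-built minimal bundle (1 neuron, explicit events) for arithmetic
# tests where every number is chosen by the test.
manual_bundle <- function(trials, n_neurons = 1L, emg_muscles = NULL,
                          emg_rate = NULL) {
  neurons <- data.frame(neuron_id = sprintf("n%02d", seq_len(n_neurons)),
                        area = "M1", identity = "PTN", subject = "t",
                        stringsAsFactors = FALSE)
  session_bundle("manual", neurons, trials, emg_muscles = emg_muscles,
                 emg_rate = emg_rate)
}

manual_trial <- function(trial, condition = "execution", grasp = "PG",
                         events, span = c(0, 8000),
                         spikes = list(numeric(0)), emg = NULL,
                         outcome = "correct") {
  list(trial = trial, condition = condition, grasp = grasp,
       outcome = outcome, span = span, events = events, spikes = spikes,
       emg = emg)
}

# Noise-free planted activity matrices (T x N) built from a ground-truth
# record: X_c = (g_c * A * sqrt(N) * W_c z)^T with shared latent z.
planted_activity <- function(truth, condition, tgrid = seq(0, 1, by = 0.01)) {
  k <- truth$config$k_latent
  z <- vapply(seq_len(k), function(j)
    sin(2 * pi * (j + 1) * tgrid + j), numeric(length(tgrid)))
  t(truth$W[[condition]] %*% t(z))
}

# Synthetic envelope table (as produced by envelope_quant) with fully
# controlled baseline/reaction values.
manual_envelopes <- function(baseline, reaction, condition = "observation",
                             grasp = "PG") {
  # baseline, reaction: trials x muscles matrices
  stopifnot(identical(dim(baseline), dim(reaction)))
  m <- ncol(baseline)
  do.call(rbind, lapply(seq_len(m), function(mi)
    data.frame(trial = seq_len(nrow(baseline)), condition = condition,
               grasp = grasp, muscle = paste0("m", mi),
               baseline = baseline[, mi], reaction = reaction[, mi],
               stringsAsFactors = FALSE)))
}
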