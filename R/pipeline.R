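#' Pipeline configuration
#'
#' Collects stage toggles, stage parameters (defaults are the analysis
#' defaults used throughout the package) and the master seed for the
#' end-to-end pipeline. Every stochastic stage receives a seed derived
#' deterministically from the master seed.
#'
#' @param input "synthetic" (generate a session), or a path to a session
#'   JSON file
#' @param out_dir output directory for artifacts and the manifest
#' @param seed master seed
#' @param stages character subset of
#'   `c("simulate", "preprocess", "emg_gate", "classify", "correlate",
#'   "subspace", "decode")`
#' @param generator a [ground_truth_config()] for synthetic input (seed is
#'   overridden by the derived stage seed unless supplied explicitly)
#' @param bin_width,smooth_sd,norm_constant preprocessing parameters (ms,
#'   ms, spikes/s)
#' @param emg_alpha,min_obs_trials,min_nogo_trials EMG gating parameters
#' @param k,n_null,boot_n,boot_fraction subspace parameters
#' @param decode_conditions,decode_bins_window decoding condition set and
#'   Go-relative window (ms)
#' @param cv_splits,resamples,permutations,cluster_min decoding
#'   cross-validation and significance parameters
#' @param shuffles correlation shuffle count
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input = "synthetic", out_dir = tempfile("mpop"),
                            seed = 1L,
                            stages = c("simulate", "preprocess", "emg_gate",
                                       "classify", "correlate", "subspace",
                                       "decode"),
                            generator = NULL,
                            bin_width = 10, smooth_sd = 50,
                            norm_constant = 5,
                            emg_alpha = 0.05, min_obs_trials = 10L,
                            min_nogo_trials = 7L,
                            k = 3, n_null = 10000L, boot_n = 1000L,
                            boot_fraction = 0.5,
                            decode_conditions = c("execution", "observation",
                                                  "nogo"),
                            decode_bins_window = c(-1000, 1000),
                            cv_splits = 10L, resamples = 50L,
                            permutations = 50L, cluster_min = 5L,
                            shuffles = 1000L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

write_artifact <- function(obj, path) {
  if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                            force = TRUE, null = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load) a
#' session, preprocess to normalized rate tensors, EMG-gate passive
#' trials, classify units, correlate conditions, run the subspace suite,
#' and decode — writing each stage's artifacts under `out_dir` together
#' with a manifest of md5 content hashes. Identical config and seed give
#' identical manifests for the deterministic stages.
#'
#' @param config a [pipeline_config()]
#' @return list: `manifest` (data.frame file/md5), `results` (in-memory
#'   stage outputs), invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = file.path(config$out_dir, "pipeline.log"),
        append = TRUE)
  }
  res <- list()
  artifacts <- character(0)
  st <- function(name) name %in% config$stages
  # serialize the configuration alongside the outputs for auditability
  cfg_ser <- config
  cfg_ser$out_dir <- NULL                # location-independent record
  cfg_ser$generator <- if (!is.null(config$generator))
    unclass(config$generator)
  artifacts <- c(artifacts, write_artifact(
    unclass(cfg_ser), file.path(config$out_dir, "config.json")))

  # --- input -----------------------------------------------------------
  if (identical(config$input, "synthetic")) {
    if (!st("simulate")) stop("synthetic input requires the simulate stage")
    gen <- config$generator %||%
      ground_truth_config(seed = derive_seed(config$seed, 1L))
    log_line("simulate: seed ", gen$seed, ", ", gen$n_neurons, " neurons")
    sim <- generate_session(gen)
    bundle <- sim$bundle
    res$truth <- sim$truth
    ev_path <- file.path(config$out_dir, "events.csv")
    write_event_csv(bundle, ev_path)
    artifacts <- c(artifacts, ev_path)
  } else {
    log_line("load: ", config$input)
    bundle <- read_session(config$input)
  }

  # --- emg gate --------------------------------------------------------
  if (st("emg_gate") && !is.null(bundle$emg_muscles)) {
    env <- envelope_quant(bundle)
    noisy <- flag_noisy_channels(env)
    gates <- list()
    for (cond in c("observation", "nogo")) {
      rep_c <- iterative_exclusion(env, cond, alpha = config$emg_alpha,
                                   exclude_muscles = noisy)
      gates[[cond]] <- rep_c
      bundle <- drop_trials(bundle, rep_c$removed)
      log_line("emg_gate ", cond, ": removed ",
               length(rep_c$removed), " trial(s)")
    }
    res$emg_gate <- list(noisy_channels = noisy, reports = gates,
                         floors = trial_floor_check(
                           bundle, config$min_obs_trials,
                           config$min_nogo_trials))
    artifacts <- c(artifacts, write_artifact(
      list(noisy_channels = noisy,
           removed = lapply(gates, `[[`, "removed")),
      file.path(config$out_dir, "emg_gate.json")))
  }

  # --- preprocess ------------------------------------------------------
  tensors <- NULL
  if (st("preprocess")) {
    canon <- canonical_events(bundle)
    tensors <- list()
    for (cond in CONDITIONS) {
      if (!length(session_trials(bundle, cond))) next
      tensors[[cond]] <- list()
      for (g in GRASPS)
        tensors[[cond]][[g]] <- multi_align(
          bundle, cond, g, bin_width = config$bin_width,
          smooth_sd = config$smooth_sd, canonical = canon)
    }
    flat <- unlist(tensors, recursive = FALSE)
    flat <- baseline_correct(flat)
    flat <- soft_normalize(flat, "range_soft", config$norm_constant)
    for (nm in names(flat)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      tensors[[parts[1]]][[parts[2]]] <- flat[[nm]]
    }
    res$tensors <- tensors
    res$behaviour <- compute_behaviour(bundle)
    artifacts <- c(artifacts, write_artifact(
      res$behaviour$medians, file.path(config$out_dir, "behaviour.csv")))
    log_line("preprocess: ", length(flat), " tensors on canonical timeline")
  }

  # --- classify --------------------------------------------------------
  if (st("classify")) {
    res$units <- classify_units(bundle, min_trials = min(
      config$min_obs_trials, 10L))
    artifacts <- c(artifacts, write_artifact(
      res$units, file.path(config$out_dir, "unit_classification.csv")))
    log_line("classify: ", sum(res$units$is_MN), " MNs of ",
             nrow(res$units))
  }

  # --- correlate -------------------------------------------------------
  if (st("correlate")) {
    vecs <- epoch_vectors(bundle, constant = config$norm_constant)
    corr <- lapply(names(vecs), function(en) {
      v <- vecs[[en]]
      ec <- epoch_corr(v$exe, v$obs)
      sn <- shuffle_null(v$exe, v$obs, n = config$shuffles,
                         seed = derive_seed(config$seed, 20L))
      data.frame(epoch = en, r = ec$r, p_parametric = ec$p,
                 null95 = sn$threshold95, significant = sn$significant)
    })
    res$correlation <- do.call(rbind, corr)
    if (!is.null(tensors)) {
      ct_exe <- multi_align(bundle, "execution", bin_width = 50,
                            smooth_sd = NULL)
      ct_obs <- multi_align(bundle, "observation", bin_width = 50,
                            smooth_sd = NULL)
      res$cross_temporal <- cross_temporal(ct_exe, ct_obs)
    }
    artifacts <- c(artifacts, write_artifact(
      res$correlation, file.path(config$out_dir, "epoch_correlations.csv")))
    log_line("correlate: ", sum(res$correlation$significant),
             " significant epoch(s)")
  }

  # --- subspace --------------------------------------------------------
  if (st("subspace")) {
    if (is.null(tensors)) stop("subspace stage requires preprocess")
    res$subspace <- condition_projection_suite(
      tensors, k = config$k, n_null = config$n_null,
      seed = derive_seed(config$seed, 30L))
    res$cross_grasp <- bootstrap_cross_grasp(
      tensors, k = config$k, fraction = config$boot_fraction,
      n = config$boot_n, seed = derive_seed(config$seed, 31L),
      window = unname(c(tensors$execution$PG$canonical["HPR"] - 50,
                        tensors$execution$PG$canonical["HO"] + 500)))
    summ <- lapply(res$subspace, function(gr)
      list(movement_obs = gr$movement$observation,
           obs_exe = gr$observation$execution,
           obs_nogo = gr$observation$nogo))
    artifacts <- c(artifacts, write_artifact(
      summ, file.path(config$out_dir, "subspace.json")))
    log_line("subspace: PG obs-in-movement a = ",
             sprintf("%.3f", res$subspace$PG$movement$observation$a),
             " (p = ", res$subspace$PG$movement$observation$p, ")")
  }

  # --- decode ----------------------------------------------------------
  if (st("decode")) {
    pseudo <- build_pseudopopulation(
      bundle, conditions = config$decode_conditions,
      window = config$decode_bins_window,
      seed = derive_seed(config$seed, 40L))
    res$decoding <- decode_timecourse(
      pseudo, cv_splits = config$cv_splits, resamples = config$resamples,
      permutations = config$permutations, cluster_min = config$cluster_min,
      seed = derive_seed(config$seed, 41L))
    acc <- data.frame(time = res$decoding$time_axis,
                      accuracy = res$decoding$accuracy,
                      significant = res$decoding$significant)
    artifacts <- c(artifacts, write_artifact(
      acc, file.path(config$out_dir, "decoding.csv")))
    log_line("decode: ",
             if (is.null(res$decoding$clusters)) "no clusters" else
               paste0(nrow(res$decoding$clusters), " cluster(s)"))
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  res$bundle <- bundle
  invisible(list(manifest = manifest, results = res))
}
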