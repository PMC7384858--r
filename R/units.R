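#' Two-way ANOVA task-modulation test for one neuron, one condition
#'
#' Trial-level epoch mean rates (spikes/s, so unequal epoch durations do
#' not bias the test) enter a 2-way ANOVA with factors EPOCH (Baseline,
#' Reach, GraspHold) and GRASP (PG, WHG), followed by post-hoc paired
#' t-tests of each task epoch against baseline within each grasp. The
#' neuron is modulated when the epoch main effect or the interaction is
#' significant at `alpha` AND at least one post-hoc comparison is.
#'
#' @param rates data.frame with columns `trial`, `grasp`, `epoch`
#'   (levels Baseline/Reach/GraspHold) and `rate`, one condition
#' @param alpha significance level
#' @param holm apply a Holm correction across the four post-hoc tests
#'   (default FALSE: uncorrected, each at `alpha`)
#' @return list: `p_epoch`, `p_grasp`, `p_interaction`, `posthoc`
#'   (data.frame grasp/epoch/p), `modulated`, `testable`
#' @export
anova_modulation <- function(rates, alpha = 0.05, holm = FALSE) {
  stopifnot(all(c("trial", "grasp", "epoch", "rate") %in% names(rates)))
  rates$epoch <- factor(rates$epoch,
                        levels = c("Baseline", "Reach", "GraspHold"))
  rates$grasp <- factor(rates$grasp)
  if (stats::var(rates$rate) == 0)
    return(list(p_epoch = NA_real_, p_grasp = NA_real_,
                p_interaction = NA_real_, posthoc = NULL,
                modulated = FALSE, testable = FALSE))
  fit <- stats::lm(rate ~ epoch * grasp, data = rates)
  an <- stats::anova(fit)
  p <- stats::setNames(an[["Pr(>F)"]], rownames(an))
  ph <- list()
  for (g in levels(rates$grasp)) {
    base <- rates[rates$grasp == g & rates$epoch == "Baseline", ]
    for (ep in c("Reach", "GraspHold")) {
      task <- rates[rates$grasp == g & rates$epoch == ep, ]
      common <- intersect(base$trial, task$trial)
      if (length(common) < 3L) next
      pv <- tryCatch(stats::t.test(
        task$rate[match(common, task$trial)],
        base$rate[match(common, base$trial)], paired = TRUE)$p.value,
        error = function(e) NA_real_)
      ph[[length(ph) + 1L]] <- data.frame(grasp = g, epoch = ep, p = pv,
                                          stringsAsFactors = FALSE)
    }
  }
  ph <- do.call(rbind, ph)
  p_ph <- ph$p
  if (holm && length(p_ph)) p_ph <- stats::p.adjust(p_ph, "holm")
  main_sig <- isTRUE(p["epoch"] < alpha) || isTRUE(p["epoch:grasp"] < alpha)
  post_sig <- any(p_ph < alpha, na.rm = TRUE)
  list(p_epoch = unname(p["epoch"]), p_grasp = unname(p["grasp"]),
       p_interaction = unname(p["epoch:grasp"]), posthoc = ph,
       modulated = main_sig && post_sig, testable = TRUE)
}

#' Mirror-neuron category by sign of maximum modulation
#'
#' For one neuron and grasp: in each condition, the deviation with the
#' largest absolute value of (task-epoch mean - baseline mean) over
#' {Reach, GraspHold} gives the condition's sign (F = facilitation,
#' S = suppression); the execution/observation pair maps to one of F-F,
#' F-S, S-F, S-S. An exact tie in absolute deviation resolves to the
#' earlier epoch (Reach).
#'
#' @param epoch_means_exe,epoch_means_obs named numeric with elements
#'   `Baseline`, `Reach`, `GraspHold` (trial-averaged rates, one grasp)
#' @return category string ("F-F", "F-S", "S-F" or "S-S")
#' @export
mn_category <- function(epoch_means_exe, epoch_means_obs) {
  sign_of <- function(m) {
    dev <- m[c("Reach", "GraspHold")] - m["Baseline"]
    pick <- which.max(abs(dev))       # ties -> first, i.e. Reach
    if (dev[pick] >= 0) "F" else "S"
  }
  paste(sign_of(epoch_means_exe), sign_of(epoch_means_obs), sep = "-")
}

#' Classify all units of a session
#'
#' Runs the modulation ANOVA per neuron in execution and observation;
#' neurons modulated in both are mirror neurons (MNs) and receive an
#' F/S category per grasp. Neurons below the trial floor (10 per grasp per
#' condition) are untestable and flagged.
#'
#' @param bundle a `session_bundle`
#' @param alpha significance level
#' @param min_trials per-grasp per-condition trial floor
#' @param holm Holm-correct the post-hoc family
#' @return data.frame, one row per neuron: p-values per condition,
#'   modulation flags, `is_MN`, and `category_PG` / `category_WHG`
#'   (NA unless an MN)
#' @export
classify_units <- function(bundle, alpha = 0.05, min_trials = 10L,
                           holm = FALSE) {
  er <- trial_epoch_rates(bundle, canonical_epochs("anova"),
                          condition = c("execution", "observation"))
  n_neurons <- nrow(bundle$neurons)
  res <- vector("list", n_neurons)
  for (ni in seq_len(n_neurons)) {
    d <- er[er$neuron == ni, ]
    row <- list(neuron_id = bundle$neurons$neuron_id[ni],
                area = bundle$neurons$area[ni],
                identity = bundle$neurons$identity[ni])
    mods <- list()
    for (cond in c("execution", "observation")) {
      dc <- d[d$condition == cond, ]
      counts <- table(unique(dc[, c("trial", "grasp")])$grasp)
      enough <- length(counts) == 2L && all(counts >= min_trials)
      mods[[cond]] <- if (enough)
        anova_modulation(dc, alpha = alpha, holm = holm)
      else list(p_epoch = NA_real_, p_grasp = NA_real_,
                p_interaction = NA_real_, modulated = FALSE,
                testable = FALSE)
      row[[paste0("p_epoch_", cond)]] <- mods[[cond]]$p_epoch
      row[[paste0("p_grasp_", cond)]] <- mods[[cond]]$p_grasp
      row[[paste0("p_interaction_", cond)]] <- mods[[cond]]$p_interaction
      row[[paste0("modulated_", cond)]] <- mods[[cond]]$modulated
      row[[paste0("testable_", cond)]] <- mods[[cond]]$testable
    }
    row$is_MN <- mods$execution$modulated && mods$observation$modulated
    for (g in GRASPS) {
      cat_g <- NA_character_
      if (row$is_MN) {
        m_of <- function(cond) {
          dg <- d[d$condition == cond & d$grasp == g, ]
          tapply(dg$rate, factor(dg$epoch,
                                 c("Baseline", "Reach", "GraspHold")), mean)
        }
        cat_g <- mn_category(m_of("execution"), m_of("observation"))
      }
      row[[paste0("category_", g)]] <- cat_g
    }
    res[[ni]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
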