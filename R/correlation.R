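#' Cross-condition epoch correlation
#'
#' Pearson correlation between the paired execution and observation
#' population vectors of one task epoch (length N neurons x C grasps,
#' absmax-soft-normalized upstream), with the two-sided parametric
#' p-value. Zero variance in either vector makes r undefined; it is
#' reported as NA, never as zero.
#'
#' @param exe,obs numeric vectors of equal length >= 3
#' @param method "pearson" (default) or "spearman" (provided, untested
#'   against any reference)
#' @return list: `r`, `p`, `n`, `defined`
#' @export
epoch_corr <- function(exe, obs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(exe) == length(obs), length(exe) >= 3L)
  if (stats::sd(exe) == 0 || stats::sd(obs) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(exe),
                defined = FALSE))
  ct <- stats::cor.test(exe, obs, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(exe),
       defined = TRUE)
}

#' Shuffle null for an epoch correlation
#'
#' Permutes the entries of the observation vector (destroying within-unit
#' pairing across the full N x C vector) and recomputes r, `n` times. The
#' observed correlation is significant when it exceeds the null's 95th
#' percentile.
#'
#' @param exe,obs the paired epoch vectors
#' @param n number of shuffles (default 1000)
#' @param seed integer seed
#' @param within_grasp permute within grasp blocks instead of the full
#'   vector; requires `grasp_block` (a factor of the same length)
#' @param grasp_block optional blocking factor for `within_grasp = TRUE`
#' @return list: `r` (observed), `null` (length n), `threshold95`,
#'   `significant`, `p_perm` (proportion of null >= observed)
#' @export
shuffle_null <- function(exe, obs, n = 1000L, seed = 1L,
                         within_grasp = FALSE, grasp_block = NULL) {
  obs_r <- epoch_corr(exe, obs)$r
  null <- with_seed(seed, vapply(seq_len(n), function(i) {
    perm <- if (within_grasp) {
      stopifnot(!is.null(grasp_block))
      idx <- seq_along(obs)
      for (g in unique(grasp_block)) {
        sel <- which(grasp_block == g)
        idx[sel] <- sel[sample.int(length(sel))]
      }
      obs[idx]
    } else obs[sample.int(length(obs))]
    suppressWarnings(stats::cor(exe, perm))
  }, numeric(1)))
  thr <- stats::quantile(null, 0.95, names = FALSE, na.rm = TRUE)
  list(r = obs_r, null = null, threshold95 = thr,
       significant = isTRUE(obs_r > thr),
       p_perm = mean(null >= obs_r, na.rm = TRUE))
}

#' Cross-temporal correlation matrix
#'
#' Correlates the execution population vector at timepoint t1 with the
#' observation vector at every t2 (Pearson, across neurons), in both
#' orders, and averages across the diagonal (i.e. M(t1, t2) with
#' M(t2, t1)) so the result is symmetric. Inputs should be unsmoothed
#' 50 ms binned, multi-aligned PSTHs (kernel smoothing would induce
#' trivial short-lag correlations). Zero-variance timepoints give NA
#' entries and are flagged.
#'
#' @param exe,obs N x T matrices (or `rate_tensor`s) on a common timeline
#' @return list of class `cross_temporal`: `values` (T x T, symmetric),
#'   `undefined` (logical T, timepoints with zero variance), `time_axis`
#' @export
cross_temporal <- function(exe, obs) {
  taxis <- NULL
  if (inherits(exe, "rate_tensor")) { taxis <- exe$time_axis
                                      exe <- exe$values }
  if (inherits(obs, "rate_tensor")) obs <- obs$values
  stopifnot(identical(dim(exe), dim(obs)))
  sd0 <- apply(exe, 2L, stats::sd) == 0 | apply(obs, 2L, stats::sd) == 0
  m1 <- suppressWarnings(stats::cor(exe, obs))   # (t_exe, t_obs)
  m2 <- t(m1)
  vals <- (m1 + m2) / 2
  vals[sd0, ] <- NA_real_
  vals[, sd0] <- NA_real_
  structure(list(values = vals, undefined = sd0, time_axis = taxis,
                 bin_width = 50),
            class = "cross_temporal")
}

#' Paired epoch vectors for the correlation analysis
#'
#' Stacks the per-neuron, per-grasp epoch means of two conditions into the
#' paired R^(N*C) vectors the epoch correlation operates on, after absmax
#' soft-normalization across all epochs and conditions.
#'
#' @param bundle a `session_bundle`
#' @param conditions length-2 character (default execution vs observation)
#' @param constant soft-normalization constant (spikes/s)
#' @param baseline_window ms relative to LCDon for baseline correction
#' @return list per epoch: list(exe, obs, grasp_block)
#' @export
epoch_vectors <- function(bundle, conditions = c("execution", "observation"),
                          constant = 5, baseline_window = c(-250, 0)) {
  eps <- canonical_epochs("correlation")
  ea <- epoch_average(bundle, eps, condition = conditions)
  # baseline correction: subtract the PreLCD mean across conditions
  base <- stats::aggregate(rate ~ neuron,
                           ea[ea$epoch == "PreLCD", ], mean)
  ea$rate <- ea$rate - base$rate[match(ea$neuron, base$neuron)]
  # absmax soft-normalization across all epochs and conditions
  mx <- stats::aggregate(abs(rate) ~ neuron, ea, max)
  ea$rate <- ea$rate / (mx[[2]][match(ea$neuron, mx$neuron)] + constant)
  out <- list()
  for (en in names(eps)) {
    d <- ea[ea$epoch == en, ]
    vecs <- lapply(conditions, function(cc) {
      dd <- d[d$condition == cc, ]
      dd <- dd[order(dd$grasp, dd$neuron), ]
      dd$rate
    })
    blocks <- d[d$condition == conditions[1], ]
    blocks <- blocks[order(blocks$grasp, blocks$neuron), ]
    if (length(vecs[[1]]) && length(vecs[[1]]) == length(vecs[[2]]))
      out[[en]] <- list(exe = vecs[[1]], obs = vecs[[2]],
                        grasp_block = blocks$grasp)
  }
  out
}
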