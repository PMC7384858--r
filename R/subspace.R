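#' Fit a PCA subspace to population activity
#'
#' Columns (neurons) of the T x N activity matrix are centred by their
#' time-mean; the basis is the top-k eigenvectors of the resulting
#' covariance across neurons. Column signs are fixed so each axis's
#' largest-magnitude coordinate is positive, making the fit deterministic.
#'
#' @param x T x N matrix (time x neurons) or a `rate_tensor` (transposed
#'   internally); typically soft-normalized rates
#' @param k number of axes (default 3; three dimensions typically capture
#'   over 90% of peri-movement execution variance)
#' @param window optional canonical-time window to slice a `rate_tensor`
#' @return an object of class `subspace_model`: orthonormal `v` (N x k),
#'   `eigenvalues` (all), `var_frac` (fraction captured per axis),
#'   `center`, `k`
#' @export
fit_subspace <- function(x, k = 3, window = NULL) {
  meta <- list()
  if (inherits(x, "rate_tensor")) {
    if (!is.null(window)) x <- slice_tensor(x, window)
    meta <- list(condition = x$condition, grasp = x$grasp, window = window)
    x <- t(x$values)
  }
  x <- as.matrix(x)
  tt <- nrow(x); n <- ncol(x)
  if (tt <= k) stop("need more timepoints than axes (T > k)")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  cv <- crossprod(xc) / (tt - 1)
  ee <- eigen(cv, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  rk <- sum(ev > max(ev) * 1e-10)
  if (rk < k)
    stop("data rank ", rk, " below requested k = ", k,
         "; achievable k = ", rk)
  v <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  structure(c(list(v = v, k = k, eigenvalues = ev,
                   var_frac = ev[seq_len(k)] / sum(ev),
                   center = ctr, n_neurons = n), meta),
            class = "subspace_model")
}

#' @export
print.subspace_model <- function(x, ...) {
  cat("<subspace_model> k = ", x$k, ", ", x$n_neurons, " neurons; ",
      "captured variance ", sprintf("%.1f%%", 100 * sum(x$var_frac)),
      "\n", sep = "")
  invisible(x)
}

cov_of <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  crossprod(xc) / (nrow(x) - 1)
}

#' Variance-alignment index of target activity in a reference subspace
#'
#' The ratio of the variance of the (centred) target data captured by the
#' reference basis to the maximum variance any k axes could capture:
#' `a = tr(V_ref' C V_ref) / sum(top-k eigenvalues of C)` with C the
#' target covariance. a = 1 when target and reference data overlap
#' perfectly, 0 when fully orthogonal; a is invariant to global rescaling
#' of the data and to the covariance denominator convention.
#'
#' @param target T x N matrix or `rate_tensor` (the projected condition)
#' @param reference a `subspace_model` (or plain orthonormal N x k matrix)
#' @param window optional window to slice a `rate_tensor` target
#' @return object of class `alignment_result`: `a`, `numerator`,
#'   `denominator`, `k`
#' @export
alignment_index <- function(target, reference, window = NULL) {
  if (inherits(target, "rate_tensor")) {
    if (!is.null(window)) target <- slice_tensor(target, window)
    target <- t(target$values)
  }
  v <- if (inherits(reference, "subspace_model")) reference$v else
    as.matrix(reference)
  if (ncol(target) != nrow(v))
    stop("target has ", ncol(target), " neurons but reference basis has ",
         nrow(v), "; neuron sets must match")
  k <- ncol(v)
  cv <- cov_of(target)
  num <- sum(diag(crossprod(v, cv %*% v)))
  den <- sum(eigen(cv, symmetric = TRUE, only.values = TRUE)$values[
    seq_len(k)])
  structure(list(a = num / den, numerator = num, denominator = den, k = k),
            class = "alignment_result")
}

#' Random-orthonormal null distribution for the alignment index
#'
#' Draws `n` Haar-uniform orthonormal N x k bases (QR of standard Gaussian
#' matrices with sign correction) and computes each basis's alignment with
#' the target covariance. The p-value is the proportion of null values
#' strictly greater than the observed alignment (resolution 1/n).
#'
#' @param target T x N matrix or `rate_tensor`
#' @param k subspace dimension
#' @param n number of draws (default 10000)
#' @param seed integer seed
#' @param observed optional observed alignment (an `alignment_result` or
#'   scalar) to compute a p-value against
#' @param window optional window to slice a `rate_tensor`
#' @return list: `null` (length n), `mean`, `q95`, and when `observed`
#'   given, `a` and `p`
#' @export
random_orthonormal_null <- function(target, k = 3, n = 10000L, seed = 1L,
                                    observed = NULL, window = NULL) {
  if (inherits(target, "rate_tensor")) {
    if (!is.null(window)) target <- slice_tensor(target, window)
    target <- t(target$values)
  }
  cv <- cov_of(target)
  nn <- nrow(cv)
  stopifnot(nn >= k)
  den <- sum(eigen(cv, symmetric = TRUE, only.values = TRUE)$values[
    seq_len(k)])
  null <- with_seed(seed, vapply(seq_len(n), function(i) {
    q <- random_orthonormal(nn, k)
    sum((cv %*% q) * q) / den
  }, numeric(1)))
  out <- list(null = null, mean = mean(null),
              q95 = stats::quantile(null, 0.95, names = FALSE), k = k)
  if (!is.null(observed)) {
    a <- if (inherits(observed, "alignment_result")) observed$a else observed
    out$a <- a
    out$p <- mean(null > a)
  }
  out
}

#' Bootstrap comparison of cross-grasp alignment between conditions
#'
#' Repeatedly subsamples a fraction of the neurons (without replacement);
#' on each identical neuron subset, fits the subspace on one grasp and
#' computes the other grasp's alignment, separately within execution and
#' observation. The one-sided p-value is the proportion of execution draws
#' whose alignment exceeds the paired observation draw (a priori: grasps
#' separate more during execution).
#'
#' @param x_by named list `list(execution = list(PG = , WHG = ),
#'   observation = ...)` of T x N matrices or `rate_tensor`s
#' @param fit_grasp,target_grasp which grasp defines the axes and which is
#'   projected
#' @param k subspace dimension
#' @param fraction neuron subsample fraction (default 0.5)
#' @param n bootstrap draws (default 1000)
#' @param seed integer seed
#' @param window optional window for `rate_tensor` inputs
#' @return list of class `cross_grasp_bootstrap`: `a_execution`,
#'   `a_observation` (paired draws), `p`, `n_discarded` (rank-deficient
#'   subsets resampled)
#' @export
bootstrap_cross_grasp <- function(x_by, fit_grasp = "PG",
                                  target_grasp = "WHG", k = 3,
                                  fraction = 0.5, n = 1000L, seed = 1L,
                                  window = NULL) {
  as_mat <- function(x) {
    if (inherits(x, "rate_tensor")) {
      if (!is.null(window)) x <- slice_tensor(x, window)
      t(x$values)
    } else as.matrix(x)
  }
  conds <- c("execution", "observation")
  mats <- lapply(x_by[conds], function(g) lapply(g, as_mat))
  nn <- ncol(mats$execution[[fit_grasp]])
  m <- floor(nn * fraction)
  if (m < 2 * k) stop("subsample of ", m, " neurons cannot support k = ", k,
                      " axes; need at least 2k neurons")
  draws <- matrix(NA_real_, n, 2, dimnames = list(NULL, conds))
  n_disc <- 0L
  with_seed(seed, {
    i <- 1L
    while (i <= n) {
      idx <- if (m == nn) seq_len(nn) else sample.int(nn, m)
      ok <- TRUE
      vals <- numeric(2)
      for (ci in seq_along(conds)) {
        fit_x <- mats[[conds[ci]]][[fit_grasp]][, idx, drop = FALSE]
        tgt_x <- mats[[conds[ci]]][[target_grasp]][, idx, drop = FALSE]
        res <- tryCatch({
          mdl <- fit_subspace(fit_x, k = k)
          alignment_index(tgt_x, mdl)$a
        }, error = function(e) NA_real_)
        if (is.na(res)) { ok <- FALSE; break }
        vals[ci] <- res
      }
      if (!ok) { n_disc <- n_disc + 1L; next }
      draws[i, ] <- vals
      i <- i + 1L
    }
  })
  structure(list(a_execution = draws[, "execution"],
                 a_observation = draws[, "observation"],
                 p = mean(draws[, "execution"] > draws[, "observation"]),
                 fit_grasp = fit_grasp, target_grasp = target_grasp,
                 fraction = fraction, k = k, n_discarded = n_disc),
            class = "cross_grasp_bootstrap")
}

#' Project activity onto a fitted subspace
#'
#' Low-dimensional trajectory of population activity on a subspace's
#' axes, for plotting condition trajectories in state space. The
#' reference model's own centering is applied.
#'
#' @param tensor a `rate_tensor` (or T x N matrix)
#' @param model a `subspace_model` over the same neurons
#' @param window optional canonical-time window
#' @param dims which axes to return (default first 2, as plotted)
#' @return data.frame with `time` (if known) and one column per axis
#' @export
project_trajectory <- function(tensor, model, window = NULL, dims = 1:2) {
  taxis <- NULL
  if (inherits(tensor, "rate_tensor")) {
    if (!is.null(window)) tensor <- slice_tensor(tensor, window)
    taxis <- tensor$time_axis
    x <- t(tensor$values)
  } else x <- as.matrix(tensor)
  if (ncol(x) != nrow(model$v))
    stop("neuron count mismatch with the reference basis")
  sc <- sweep(x, 2L, model$center) %*% model$v[, dims, drop = FALSE]
  out <- as.data.frame(sc)
  names(out) <- paste0("pc", dims)
  if (!is.null(taxis)) out <- cbind(time = taxis, out)
  out
}

#' Movement- and observation-subspace projection suite
#'
#' For each grasp runs the two standard analyses: (1) movement subspace —
#' axes fit on execution activity from 50 ms before HPR to 500 ms after
#' HO; observation activity over the same window is projected and its
#' alignment tested against a random-orthonormal null. (2) observation
#' subspace — axes fit on observation activity 100-400 ms after the Go
#' cue; execution and NoGo activity over that window are projected, each
#' with its own null. NoGo analyses are skipped (with a note) when the
#' NoGo tensor is absent.
#'
#' @param tensors named list of normalized `rate_tensor`s per condition,
#'   each itself a named list per grasp, e.g.
#'   `list(execution = list(PG = , WHG = ), observation = , nogo = )`;
#'   execution/observation multi-aligned, NoGo Go-aligned, common canonical
#'   times
#' @param k subspace dimension (default 3)
#' @param n_null random-orthonormal null draws (default 10000)
#' @param seed integer seed
#' @return nested list per grasp: `movement$observation` and
#'   `observation$execution` / `observation$nogo`, each holding `a`, `p`,
#'   `null` summary and the fitted models
#' @export
condition_projection_suite <- function(tensors, k = 3, n_null = 10000L,
                                       seed = 1L) {
  canon <- tensors$execution[[1]]$canonical
  mov_win <- unname(c(canon["HPR"] - 50, canon["HO"] + 500))
  obs_win <- c(100, 400)
  out <- list()
  si <- 0L
  for (g in names(tensors$execution)) {
    res_g <- list()
    # movement subspace: execution-fit, observation projected
    mdl_exe <- fit_subspace(tensors$execution[[g]], k = k, window = mov_win)
    a_obs <- alignment_index(tensors$observation[[g]], mdl_exe,
                             window = mov_win)
    si <- si + 1L
    nl <- random_orthonormal_null(tensors$observation[[g]], k = k,
                                  n = n_null,
                                  seed = derive_seed(seed, si),
                                  observed = a_obs, window = mov_win)
    res_g$movement <- list(model = mdl_exe,
                           observation = list(a = a_obs$a, p = nl$p,
                                              null_mean = nl$mean,
                                              null_q95 = nl$q95))
    # observation subspace: observation-fit over Go+100..Go+400
    mdl_obs <- fit_subspace(tensors$observation[[g]], k = k,
                            window = obs_win)
    proj <- list()
    for (cond in c("execution", "nogo")) {
      if (is.null(tensors[[cond]]) || is.null(tensors[[cond]][[g]])) {
        proj[[cond]] <- list(skipped = TRUE)
        next
      }
      a_c <- alignment_index(tensors[[cond]][[g]], mdl_obs,
                             window = obs_win)
      si <- si + 1L
      nl_c <- random_orthonormal_null(tensors[[cond]][[g]], k = k,
                                      n = n_null,
                                      seed = derive_seed(seed, si),
                                      observed = a_c, window = obs_win)
      proj[[cond]] <- list(a = a_c$a, p = nl_c$p, null_mean = nl_c$mean,
                           null_q95 = nl_c$q95)
    }
    res_g$observation <- c(list(model = mdl_obs), proj)
    out[[g]] <- res_g
  }
  out
}
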