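#' Build a pseudo-population tensor
#'
#' Neurons recorded non-simultaneously are combined by sampling, for each
#' unit independently, `n_trials` trials per condition; spike counts are
#' binned (50 ms non-overlapping, singly aligned to the Go/NoGo cue) into
#' a trials x neurons x bins tensor with balanced condition labels. Units
#' below the trial floor are excluded with a message.
#'
#' @param bundle a `session_bundle`
#' @param conditions condition set (default all three)
#' @param n_trials pseudo-trials per condition (default 10)
#' @param bin_width bin width, ms (default 50)
#' @param window ms relative to the Go/NoGo cue
#' @param seed master seed; per-unit streams are derived deterministically
#' @return list: `x` ((n_trials * n_conditions) x N x B array), `labels`
#'   (condition factor), `time_axis`, `excluded_units`
#' @export
build_pseudopopulation <- function(bundle,
                                   conditions = c("execution",
                                                  "observation", "nogo"),
                                   n_trials = 10L, bin_width = 50,
                                   window = c(-1000, 1000), seed = 1L) {
  n_neurons <- nrow(bundle$neurons)
  nb <- round(diff(window) / bin_width)
  labels <- factor(rep(conditions, each = n_trials), levels = conditions)
  trials_by_cond <- lapply(conditions, function(cc)
    session_trials(bundle, condition = cc))
  names(trials_by_cond) <- conditions
  enough <- vapply(trials_by_cond, function(trs) length(trs) >= n_trials,
                   logical(1))
  if (any(!enough))
    stop("conditions below the ", n_trials, "-trial floor: ",
         paste(conditions[!enough], collapse = ", "))
  x <- array(0, dim = c(length(labels), n_neurons, nb))
  for (ni in seq_len(n_neurons)) {
    with_seed(derive_seed(seed, ni), {
      row <- 0L
      for (cc in conditions) {
        trs <- trials_by_cond[[cc]]
        pick <- sample.int(length(trs), n_trials)
        for (ti in pick) {
          tr <- trs[[ti]]
          row <- row + 1L
          go <- unname(tr$events["GoNogo"])
          x[row, ni, ] <- as.numeric(
            bin_spikes(tr$spikes[[ni]] - go, window, bin_width))
        }
      }
    })
  }
  list(x = x, labels = labels,
       time_axis = seq(window[1], window[2] - bin_width, by = bin_width),
       bin_width = bin_width, excluded_units = character(0))
}

#' Maximum-correlation-coefficient classifier
#'
#' Features are z-scored with training-set statistics only; each class
#' template is the mean training vector, and a test vector is assigned the
#' class whose template it correlates with most (Pearson). Ties resolve to
#' the earlier class in factor order; a zero-variance test vector has no
#' defined correlation, is predicted NA and scored incorrect downstream.
#'
#' @param train n_train x N matrix
#' @param labels factor of training labels
#' @param test n_test x N matrix
#' @return factor of predicted labels (NA where undefined)
#' @export
max_corr_classify <- function(train, labels, test) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1          # constant feature: centred to 0 either way
  zs <- function(m) sweep(sweep(m, 2L, mu), 2L, sdv, `/`)
  ztr <- zs(train); zte <- zs(test)
  templ <- t(vapply(levels(labels), function(l)
    colMeans(ztr[labels == l, , drop = FALSE]), numeric(ncol(train))))
  pred <- rep(NA_integer_, nrow(zte))
  for (i in seq_len(nrow(zte))) {
    v <- zte[i, ]
    if (stats::sd(v) == 0) next
    rs <- suppressWarnings(apply(templ, 1L, stats::cor, y = v))
    rs[is.na(rs)] <- -Inf
    pred[i] <- which.max(rs)
  }
  factor(levels(labels)[pred], levels = levels(labels))
}

balanced_splits <- function(labels, cv_splits) {
  split_of <- integer(length(labels))
  for (l in levels(labels)) {
    sel <- which(labels == l)
    split_of[sel] <- sample(rep(seq_len(cv_splits),
                                length.out = length(sel)))
  }
  split_of
}

# One cross-validated accuracy pass over a trials x N matrix with a given
# split assignment. Algebraically identical to looping max_corr_classify()
# over folds (asserted in the test suite), but fully vectorized across
# folds (fold statistics by subtracting held-out sums from totals; one
# matrix product for all test-vs-template correlations) so the
# permutation null stays affordable.
cv_pass <- function(m, labels, split_of, cv_splits) {
  n <- nrow(m); p <- ncol(m)
  lab_i <- as.integer(labels)
  lv <- levels(labels)
  nl <- length(lv)
  # per-fold training mean/sd via totals minus held-out sums
  s_f <- matrix(0, cv_splits, p)
  q_f <- matrix(0, cv_splits, p)
  sp <- rowsum(m, split_of)
  qp <- rowsum(m * m, split_of)
  s_f[as.integer(rownames(sp)), ] <- sp
  q_f[as.integer(rownames(qp)), ] <- qp
  n_te <- tabulate(split_of, nbins = cv_splits)
  n_tr <- n - n_te
  mu <- (rep(colSums(m), each = cv_splits) - s_f) / n_tr
  vv <- ((rep(colSums(m * m), each = cv_splits) - q_f) - n_tr * mu^2) /
    (n_tr - 1)
  sdv <- sqrt(pmax(vv, 0))
  sdv[sdv == 0] <- 1
  # per-fold, per-class training templates
  grp <- (split_of - 1L) * nl + lab_i
  cs_g <- matrix(0, cv_splits * nl, p)
  cg <- rowsum(m, grp)
  cs_g[as.integer(rownames(cg)), ] <- cg
  cn_g <- tabulate(grp, nbins = cv_splits * nl)
  cs_tot <- matrix(0, nl, p)
  ct <- rowsum(m, lab_i)
  cs_tot[as.integer(rownames(ct)), ] <- ct
  cn_tot <- tabulate(lab_i, nbins = nl)
  fold_of_g <- rep(seq_len(cv_splits), each = nl)
  class_of_g <- rep(seq_len(nl), times = cv_splits)
  templ <- (cs_tot[class_of_g, , drop = FALSE] - cs_g) /
    (cn_tot[class_of_g] - cn_g)
  # z-score templates and test rows with their fold's training stats
  tz <- (templ - mu[fold_of_g, , drop = FALSE]) /
    sdv[fold_of_g, , drop = FALSE]
  vz <- (m - mu[split_of, , drop = FALSE]) / sdv[split_of, , drop = FALSE]
  rcn <- function(x) {
    xc <- x - rowMeans(x)
    nr <- sqrt(rowSums(xc * xc))
    list(x = xc / ifelse(nr == 0, 1, nr), bad = nr == 0)
  }
  tt <- rcn(tz); vv_ <- rcn(vz)
  r_all <- vv_$x %*% t(tt$x)              # n x (cv_splits * nl)
  # each test row compares only against its own fold's templates
  cols <- matrix(rep((split_of - 1L) * nl, nl) +
                   rep(seq_len(nl), each = n), n, nl)
  r_own <- matrix(r_all[cbind(rep(seq_len(n), nl), as.vector(cols))],
                  n, nl)
  bad_templ <- matrix(tt$bad[as.vector(cols)], n, nl)
  r_own[bad_templ] <- -Inf
  pred <- max.col(r_own, ties.method = "first")
  mean(!vv_$bad & pred == lab_i)
}

cv_accuracy <- function(m, labels, cv_splits, resamples) {
  acc <- numeric(resamples)
  for (r in seq_len(resamples))
    acc[r] <- cv_pass(m, labels, balanced_splits(labels, cv_splits),
                      cv_splits)
  mean(acc)
}

#' Time-resolved pseudo-population decoding
#'
#' Per 50 ms bin: 10-fold cross-validated accuracy of the
#' maximum-correlation classifier, averaged over resampled split
#' assignments. A permutation null repeats the identical procedure with
#' condition labels shuffled before splitting; a bin is pointwise
#' significant when its observed accuracy exceeds every null value
#' (minimum attainable p ~ 1/permutations), and truly significant only
#' inside a cluster of at least `cluster_min` consecutive significant
#' bins.
#'
#' @param pseudo output of [build_pseudopopulation()]
#' @param cv_splits cross-validation splits (default 10)
#' @param resamples split-assignment resamples (default 50)
#' @param permutations label-shuffle null size (default 50)
#' @param cluster_min minimum run of significant bins (default 5)
#' @param seed integer seed
#' @return object of class `decoding_result`: per-bin `accuracy`, `null`
#'   (permutations x bins), `significant`, `clusters` (start/end bins),
#'   `chance`
#' @export
decode_timecourse <- function(pseudo, cv_splits = 10L, resamples = 50L,
                              permutations = 50L, cluster_min = 5L,
                              seed = 1L) {
  x <- pseudo$x; labels <- pseudo$labels
  nb <- dim(x)[3]
  n <- dim(x)[1]
  if (n %% cv_splits != 0L)
    stop("trial count ", n, " not divisible into ", cv_splits, " splits")
  accuracy <- numeric(nb)
  null <- matrix(NA_real_, permutations, nb)
  with_seed(seed, {
    for (b in seq_len(nb))
      accuracy[b] <- cv_accuracy(x[, , b, drop = TRUE], labels,
                                 cv_splits, resamples)
    for (p in seq_len(permutations)) {
      lab_p <- sample(labels)
      for (b in seq_len(nb))
        null[p, b] <- cv_accuracy(x[, , b, drop = TRUE], lab_p,
                                  cv_splits, resamples)
    }
  })
  sig <- accuracy > apply(null, 2L, max)
  runs <- rle(sig)
  clusters <- NULL
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= cluster_min
  if (any(keep))
    clusters <- data.frame(start = starts[keep], end = ends[keep])
  structure(list(accuracy = accuracy, null = null,
                 significant = sig & vapply(seq_len(nb), function(b) {
                   any(!is.null(clusters)) &&
                     any(clusters$start <= b & clusters$end >= b)
                 }, logical(1)),
                 pointwise_significant = sig,
                 clusters = clusters,
                 chance = 1 / nlevels(labels),
                 time_axis = pseudo$time_axis,
                 cluster_min = cluster_min),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", length(x$accuracy), " bins; peak accuracy ",
      sprintf("%.2f", max(x$accuracy)), " (chance ",
      sprintf("%.2f", x$chance), "); ",
      if (is.null(x$clusters)) "no significant clusters" else
        paste0(nrow(x$clusters), " significant cluster(s)"),
      "\n", sep = "")
  invisible(x)
}
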