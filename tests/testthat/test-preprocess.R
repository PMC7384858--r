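test_that("bin_spikes uses half-open bins and conserves counts", {
  expect_equal(as.numeric(bin_spikes(numeric(0), c(0, 100), 10)), rep(0, 10))
  # spike exactly on a boundary belongs to the bin starting there
  b <- bin_spikes(c(20), c(0, 100), 10)
  expect_equal(which(b == 1), 3L)
  # window end is exclusive
  expect_equal(sum(bin_spikes(c(100), c(0, 100), 10)), 0)
  # 1000 uniform spikes over 1 s in 10 ms bins: total conserved and
  # equal to an independent histogram
  set.seed(41)
  sp <- runif(1000, 0, 1000)
  counts <- as.numeric(bin_spikes(sp, c(0, 1000), 10))
  expect_equal(sum(counts), 1000)
  oracle <- as.numeric(table(cut(sp, seq(0, 1000, 10), right = FALSE)))
  expect_equal(counts, oracle)
  expect_error(bin_spikes(sp, c(100, 100), 10), "empty")
})

test_that("smooth_gaussian is unit-area, preserves constants and shape", {
  expect_equal(smooth_gaussian(rep(7, 50), sd = 50, bin_width = 10),
               rep(7, 50), tolerance = 1e-12)
  # single-bin pulse far from edges reproduces the sampled Gaussian
  x <- rep(0, 201); x[101] <- 1
  y <- smooth_gaussian(x, sd = 50, bin_width = 10)
  r <- 4 * 50 / 10
  k <- dnorm((-r:r) * 10, sd = 50); k <- k / sum(k)
  expect_equal(y[(101 - r):(101 + r)], k, tolerance = 1e-10)
  expect_equal(sum(y), 1, tolerance = 1e-6)   # interior mass conserved
  # matrix input smooths each row
  m <- rbind(x, rep(3, 201))
  ym <- smooth_gaussian(m, 50, 10)
  expect_equal(ym[1, ], y, ignore_attr = TRUE)
  expect_equal(ym[2, ], rep(3, 201), ignore_attr = TRUE)
})

test_that("multi_align equals single alignment when events sit at canonical times", {
  # zero RT/MT variability and matched execution/observation timing, so
  # every trial's HPR/DO sits exactly at the canonical times
  sim <- small_session(seed = 42, rt_cv = 0, mt_cv = 0, n_neurons = 6,
                       rt_median = c(execution = 310, observation = 310),
                       mt_median = c(execution = 306, observation = 306))
  b <- sim$bundle
  # remove the Go-delay jitter as well so all events are canonical
  for (i in seq_along(b$trials)) {
    sh <- 1700 - (b$trials[[i]]$events["GoNogo"] - b$trials[[i]]$span[1])
    b$trials[[i]]$events <- b$trials[[i]]$events + sh
    b$trials[[i]]$spikes <- lapply(b$trials[[i]]$spikes, function(s) s + sh)
  }
  canon <- canonical_events(b)
  mt <- multi_align(b, "execution", "PG", canonical = canon)
  # reference: plain Go-aligned average through the same bin/smooth path
  trials <- session_trials(b, "execution", "PG")
  w <- range(mt$time_axis) + c(0, mt$bin_width)
  pad <- 4 * 50
  ref <- Reduce(`+`, lapply(trials, function(tr) {
    t(vapply(tr$spikes, function(sp)
      as.numeric(bin_spikes(sp - tr$events["GoNogo"],
                            w + c(-pad, pad), 10)),
      numeric(as.integer(diff(w) / 10) + 2 * pad / 10)))
  })) / length(trials) * 100
  ref <- smooth_gaussian(ref, 50, 10)[, (pad / 10 + 1):(pad / 10 + ncol(mt$values)), drop = FALSE]
  expect_equal(unname(mt$values), unname(ref), tolerance = 1e-8)
})

test_that("multi_align recovers event-locked structure under timing jitter", {
  # one neuron whose rate is a bump locked to DO, with jittered RT/MT
  set.seed(43)
  n_tr <- 60
  trials <- lapply(seq_len(n_tr), function(i) {
    go <- 1700 + (i - 1) * 8000
    rt <- rlnorm(1, log(310), 0.25)
    do_ <- go + rt + rlnorm(1, log(306), 0.25)
    ev <- c(LCDon = go - 1100, ObjCue = go - 800, GoNogo = go,
            HPR = go + rt, DO = do_, HO = do_ + 150)
    # deterministic dense spikes under a bump at DO (80 sp/s peak, sd 40)
    tg <- seq(go - 1500, go + 2500, by = 1)
    lam <- 80 * exp(-(tg - do_)^2 / (2 * 40^2))
    sp <- tg[runif(length(tg)) < lam * 1e-3]
    manual_trial(i, events = ev, span = c(go - 2000, go + 3000),
                 spikes = list(sp))
  })
  b <- manual_bundle(trials)
  canon <- canonical_events(b)
  mt <- multi_align(b, "execution", canonical = canon)
  # Go-only aligned reference for comparison
  go_psth <- Reduce(`+`, lapply(trials, function(tr) {
    as.numeric(bin_spikes(tr$spikes[[1]] - tr$events["GoNogo"],
                          range(mt$time_axis) + c(0, 10), 10))
  })) / n_tr * 100
  go_psth <- smooth_gaussian(go_psth, 50, 10)
  peak_multi <- mt$time_axis[which.max(mt$values[1, ])]
  peak_go <- mt$time_axis[which.max(go_psth)]
  expect_lt(abs(peak_multi - canon["DO"]), 20 + 1e-9)  # within ~1-2 bins
  # multi-alignment concentrates the bump: higher, sharper peak
  expect_gt(max(mt$values[1, ]), max(go_psth) * 1.15)
})

test_that("baseline correction subtracts a cross-condition scalar", {
  sim <- small_session(seed = 44, n_neurons = 5)
  canon <- canonical_events(sim$bundle)
  t_exe <- multi_align(sim$bundle, "execution", canonical = canon)
  t_obs <- multi_align(sim$bundle, "observation", canonical = canon)
  bc <- baseline_correct(list(t_exe, t_obs))
  base <- attr(bc[[1]], "baseline")
  # adding a constant to all conditions leaves the output unchanged
  t_exe2 <- t_exe; t_exe2$values <- t_exe2$values + 3
  t_obs2 <- t_obs; t_obs2$values <- t_obs2$values + 3
  bc2 <- baseline_correct(list(t_exe2, t_obs2))
  expect_equal(bc2[[1]]$values, bc[[1]]$values, tolerance = 1e-12)
  # a tensor equal to its baseline everywhere maps to zero
  t_flat <- t_exe
  t_flat$values <- matrix(base, nrow = 5, ncol = ncol(t_flat$values))
  expect_equal(max(abs(baseline_correct(t_flat)$values)), 0,
               tolerance = 1e-12)
  # planted baselines recovered within a few Poisson SEs
  n_trials <- length(session_trials(sim$bundle, "execution")) +
    length(session_trials(sim$bundle, "observation"))
  se <- sqrt(sim$truth$baselines / (0.25 * n_trials))
  expect_true(all(abs(base - sim$truth$baselines) < 4 * se + 1))
})

test_that("soft normalization matches its formula and bounds", {
  taxis <- seq(0, 990, 10)
  vals <- rbind(c(rep(0, 50), rep(45, 50)),   # range 45, peak 45
                rep(0, 100))                  # silent neuron
  tt <- rate_tensor(vals, taxis, 10, canonical = c(LCDon = 250))
  out <- soft_normalize(tt, "range_soft", 5)
  expect_equal(max(out$values[1, ]), 45 / 50)
  expect_equal(out$values[2, ], rep(0, 100))
  # strict (-1, 1) bound on arbitrary input
  set.seed(45)
  rnd <- rate_tensor(matrix(rnorm(300, sd = 40), 3), seq(0, 990, 10), 10)
  expect_lt(max(abs(soft_normalize(rnd, "range_soft", 5)$values)), 1)
  expect_lt(max(abs(soft_normalize(rnd, "absmax_soft", 5)$values)), 1)
  # absmax mode divides by max |value| + constant
  m <- matrix(c(-10, 5, 0, 2), 2)
  nm <- soft_normalize(m, "absmax_soft", 5)
  expect_equal(nm[1, ], c(-10, 0) / 15)
})

test_that("epoch averages honour their definitions", {
  # regular 100 sp/s spike train, epoch boundaries on the 10 ms grid
  ev <- c(LCDon = 600, ObjCue = 900, GoNogo = 1700, HPR = 2010, DO = 2330,
          HO = 2450, HOFF = 3200, HPN = 3500)
  sp <- seq(5, 7995, by = 10)
  b <- manual_bundle(list(
    manual_trial(1, events = ev, spikes = list(sp)),
    manual_trial(2, events = ev + c(0, 0, 0, 40, 40, 40, 40, 40),
                 spikes = list(sp))))
  ea <- epoch_average(b, canonical_epochs("anova"))
  expect_equal(unique(ea$rate), 100)
  eac <- epoch_average(b, canonical_epochs("correlation"))
  expect_setequal(unique(eac$epoch),
                  c("PreLCD", "Pres", "ObjectCue", "EarlyReact", "LateReact",
                    "EarlyReach", "LateReach", "Hold"))
  expect_equal(unique(round(eac$rate, 6)), 100)

  # NoGo trials resolve only cue-anchored epochs
  bn <- manual_bundle(list(manual_trial(
    1, condition = "nogo",
    events = c(LCDon = 600, ObjCue = 900, GoNogo = 1700),
    spikes = list(sp))))
  ean <- trial_epoch_rates(bn, canonical_epochs("anova"))
  expect_setequal(unique(ean$epoch), "Baseline")
})

test_that("behaviour table computes RT/MT and excludes NoGo", {
  ev <- c(LCDon = 100, ObjCue = 400, GoNogo = 1000, HPR = 1310, DO = 1616,
          HO = 1750, HOFF = 2500, HPN = 2800)
  b <- manual_bundle(list(
    manual_trial(1, events = ev),
    manual_trial(2, condition = "nogo",
                 events = c(LCDon = 100, ObjCue = 400, GoNogo = 1000))))
  beh <- compute_behaviour(b)
  expect_equal(beh$trials$RT, 310)
  expect_equal(beh$trials$MT, 306)
  expect_false(any(beh$trials$trial == 2))

  # session medians track the generator's configured RT at scale
  cfg <- ground_truth_config(n_neurons = 1, k_latent = 1,
                             trials_per_grasp = c(execution = 500,
                                                  observation = 1, nogo = 1),
                             emg = FALSE, seed = 46)
  sim <- generate_session(cfg)
  beh2 <- compute_behaviour(sim$bundle)
  med <- beh2$medians[beh2$medians$condition == "execution", ]
  rts <- beh2$trials$RT[beh2$trials$condition == "execution"]
  sem <- 1.2533 * sd(rts) / sqrt(length(rts))
  expect_lt(abs(median(rts) - 310), 3 * sem + 1)
  expect_true(all(med$median_RT > 0))
})
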