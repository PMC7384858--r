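# Reference Butterworth coefficients computed independently with
# scipy.signal.butter(2, [0.5, 30], btype="bandpass", fs=...), i.e. a
# 4-pole band-pass. Frozen here as the oracle for the filter design.
SCIPY_BP_500 <- list(
  b = c(0.027038151622029133, 0, -0.054076303244058266, 0,
        0.027038151622029133),
  a = c(1, -3.4798185583411847, 4.552763170902945, -2.66508472511209,
        0.5921445264591205))
SCIPY_BP_1000 <- list(
  b = c(0.007577051052700954, 0, -0.015154102105401909, 0,
        0.007577051052700954),
  a = c(1, -3.737998486467213, 5.245551135756502, -3.2769692621168645,
        0.7694169221529442))

test_that("Butterworth design matches the independent reference", {
  for (cs in list(list(fs = 500, ref = SCIPY_BP_500),
                  list(fs = 1000, ref = SCIPY_BP_1000))) {
    co <- butter_coeffs(4, c(0.5, 30), cs$fs, "pass")
    expect_equal(co$b, cs$ref$b, tolerance = 1e-10)
    expect_equal(co$a, cs$ref$a, tolerance = 1e-10)
  }
  expect_error(butter_coeffs(3, c(0.5, 30), 500, "pass"), "even order")
})

test_that("zero-phase band-pass removes DC, passes the band, keeps phase", {
  co <- butter_coeffs(4, c(0.5, 30), 500, "pass")
  n <- 4000; t <- (0:(n - 1)) / 500
  # DC rejected
  expect_lt(max(abs(filtfilt_bw(co$b, co$a, rep(3, n))[500:3500])), 1e-3)
  # 5 Hz sine passed with ~unit gain, zero phase (filtfilt squares |H|)
  x <- sin(2 * pi * 5 * t)
  y <- filtfilt_bw(co$b, co$a, x)
  mid <- 500:3500
  expect_equal(sd(y[mid]) / sd(x[mid]), 1, tolerance = 0.02)
  expect_gt(cor(x[mid], y[mid]), 0.999)
  # 100 Hz strongly attenuated
  x2 <- sin(2 * pi * 100 * t)
  y2 <- filtfilt_bw(co$b, co$a, x2)
  expect_lt(sd(y2[mid]) / sd(x2[mid]), 0.05)
})

test_that("envelope means separate a planted Reaction burst from baseline", {
  rate <- 500
  ev <- c(LCDon = 600, ObjCue = 900, GoNogo = 1700, HPR = 2010, DO = 2330,
          HO = 2450, HOFF = 3200, HPN = 3500)
  mk_trial <- function(i, cond, burst) {
    ns <- 8000 * rate / 1000
    ts <- (seq_len(ns) - 0.5) / rate * 1000
    set.seed(100 + i)
    sdv <- rep(1, ns)
    if (burst) sdv[ts >= 1700 & ts < 2400] <- 6
    emg <- rbind(rnorm(ns, 0, sdv),     # muscle with burst (when asked)
                 rep(0.5, ns))          # pure-DC channel
    evs <- if (cond == "nogo") ev[1:3] else ev
    manual_trial(i, condition = cond, events = evs, emg = emg,
                 spikes = list(numeric(0)))
  }
  b <- manual_bundle(c(lapply(1:4, mk_trial, cond = "execution",
                              burst = TRUE),
                       lapply(5:8, mk_trial, cond = "nogo", burst = FALSE)),
                     emg_muscles = c("burst", "dc"), emg_rate = rate)
  env <- envelope_quant(b)
  exe_burst <- env[env$condition == "execution" & env$muscle == "burst", ]
  expect_true(all(exe_burst$reaction > exe_burst$baseline))
  # DC offset is removed by the 0.5 Hz high-pass
  dc <- env[env$muscle == "dc", ]
  expect_lt(max(abs(c(dc$baseline, dc$reaction))), 0.05)
  # zero trace gives (near-)zero envelope
  b0 <- b
  for (i in seq_along(b0$trials)) b0$trials[[i]]$emg[] <- 0
  env0 <- envelope_quant(b0)
  expect_equal(max(abs(c(env0$baseline, env0$reaction))), 0)
  # flat/dc channel flagged noisy, burst channel retained
  expect_true("dc" %in% flag_noisy_channels(env))
  expect_false("burst" %in% flag_noisy_channels(env))
})

test_that("generator's dead channels are flagged exactly", {
  sim <- small_session(seed = 51, emg = TRUE, n_muscles = 12,
                       n_dead_muscles = 2,
                       trials_per_grasp = c(execution = 8, observation = 8,
                                            nogo = 5))
  env <- envelope_quant(sim$bundle)
  flagged <- flag_noisy_channels(env)
  expect_setequal(flagged, sim$bundle$emg_muscles[sim$truth$dead_muscles])
})

test_that("trial distances follow the z-norm arithmetic", {
  # 2 muscles, 5 trials; baseline columns have known mean/sd
  base <- cbind(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  # trial 1 reaction identical to baseline mean on both muscles -> 0
  # trial 2 at +3 SD on muscle 1, at mean on muscle 2 -> 3
  s1 <- sd(base[, 1]); s2 <- sd(base[, 2])
  reac <- rbind(c(3, 30),
                c(3 + 3 * s1, 30),
                c(3 + 4 * s1, 30 + 3 * s2),
                c(3, 30 - 2 * s2),
                c(3 + s1, 30 + s2))
  env <- manual_envelopes(base, reac)
  d <- trial_distances(env, "reaction", "observation")
  expect_equal(d$distance[1], 0, tolerance = 1e-12)
  expect_equal(d$distance[2], 3, tolerance = 1e-12)
  expect_equal(d$distance[3], 5, tolerance = 1e-12)
  expect_equal(d$distance[5], sqrt(2), tolerance = 1e-12)
  # zero-SD muscle dropped with a warning
  env2 <- manual_envelopes(cbind(base[, 1], rep(7, 5)), reac)
  expect_warning(d2 <- trial_distances(env2, "reaction", "observation"),
                 "zero baseline SD")
  expect_equal(d2$distance[2], 3, tolerance = 1e-12)
})

test_that("baseline-interval distances follow a chi distribution under the null", {
  set.seed(52)
  m <- 8; n_tr <- 600
  env <- manual_envelopes(matrix(rnorm(n_tr * m), n_tr, m),
                          matrix(rnorm(n_tr * m), n_tr, m))
  d <- trial_distances(env, "baseline", "observation")
  expect_equal(median(d$distance), sqrt(qchisq(0.5, df = m)),
               tolerance = 0.05)
})

test_that("iterative exclusion removes planted contamination deterministically", {
  sim <- small_session(seed = 53, emg = TRUE, n_muscles = 12,
                       trials_per_grasp = c(execution = 8, observation = 15,
                                            nogo = 5))
  obs_idx <- as.integer(mirrorpop:::trial_field(sim$bundle, "trial")[
    mirrorpop:::trial_field(sim$bundle, "condition") == "observation"])
  targets <- obs_idx[c(3, 11, 22)]
  b <- inject_emg_contamination(sim$bundle, targets, amplitude = 10,
                                seed = 54)
  env <- envelope_quant(b)
  rep1 <- iterative_exclusion(env, "observation")
  rep2 <- iterative_exclusion(env, "observation")
  expect_identical(rep1, rep2)              # order-deterministic
  expect_true(all(targets %in% rep1$removed))
  # the most contaminated trial (all at 10 SD) is removed first
  expect_true(rep1$removed[1] %in% targets)
  expect_lte(length(setdiff(rep1$removed, targets)), 1)
  # by the stopping rule, the final corrected p is non-significant unless
  # the trial floor stopped the loop
  expect_true(rep1$exhausted ||
                rev(rep1$p_values)[1] >= rep1$alpha)
  # re-running on the gated session removes nothing further
  keep <- env$trial %in% setdiff(unique(env$trial), rep1$removed)
  env_kept <- env[keep, ]
  attr(env_kept, "blocks") <-
    attr(env, "blocks")[attr(env, "blocks")$trial %in%
                          setdiff(unique(env$trial), rep1$removed), ]
  rep3 <- iterative_exclusion(env_kept, "observation")
  expect_length(rep3$removed, 0)
  expect_error(iterative_exclusion(env, "execution"), "observation")
})

test_that("median split halves trials by distance with deterministic ties", {
  d <- data.frame(trial = 1:4, condition = "observation", grasp = "PG",
                  distance = c(1, 2, 3, 4))
  sp <- median_split(d)
  expect_equal(sp$PG$low, c(1, 2))
  expect_equal(sp$PG$high, c(3, 4))
  # odd count: median trial joins the low half
  d5 <- data.frame(trial = 1:5, condition = "observation", grasp = "PG",
                   distance = c(5, 1, 3, 2, 4))
  sp5 <- median_split(d5)
  expect_equal(sp5$PG$low, sort(d5$trial[order(d5$distance)][1:3]))
  # exact ties broken by trial index
  dt <- data.frame(trial = c(4, 2, 3, 1), condition = "observation",
                   grasp = "PG", distance = c(1, 1, 1, 1))
  spt <- median_split(dt)
  expect_equal(spt$PG$low, c(1, 2))
  expect_equal(spt$PG$high, c(3, 4))
  # contaminated half lands in the high set
  dd <- data.frame(trial = 1:10, condition = "observation", grasp = "PG",
                   distance = c(rep(1, 5), rep(9, 5)) + (1:10) / 100)
  expect_setequal(median_split(dd)$PG$high, 6:10)
})
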