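test_that("compute_fret implements the corrected-intensity formula", {
  tr <- list(donor = c(100, 0, 100), acceptor = c(100, 50, 300),
             frame_interval = 0.1)
  ft <- compute_fret(tr, crosstalk = 0.105, gamma = 1)
  expect_equal(ft$fret[1], (100 - 10.5) / 200)   # 0.4475
  expect_equal(ft$fret[2], 1)                    # no donor signal
  ft2 <- compute_fret(tr, crosstalk = 0, gamma = 1)
  expect_equal(ft2$fret[3], 0.75)                # IA = 3 ID

  # scale invariance: c * (ID, IA) leaves E unchanged for any c > 0
  set.seed(5)
  for (c_scale in c(0.01, 1, 7, 1000)) {
    d <- runif(20, 10, 500); a <- runif(20, 10, 500)
    e1 <- compute_fret(list(donor = d, acceptor = a, frame_interval = 0.1))
    e2 <- compute_fret(list(donor = c_scale * d, acceptor = c_scale * a,
                            frame_interval = 0.1))
    expect_equal(e1$fret, e2$fret, tolerance = 1e-12)
  }

  # non-positive total: undefined, flagged, not silently zero
  ft3 <- compute_fret(list(donor = c(0, 10), acceptor = c(0, 10),
                           frame_interval = 0.1))
  expect_true(is.na(ft3$fret[1]))
  expect_false(ft3$defined[1])
  expect_true(ft3$defined[2])
})

test_that("change-point scan localizes a constructed bleach step", {
  set.seed(8)
  noise_sd <- 80
  x <- c(rnorm(200, 500, noise_sd), rnorm(200, 100, noise_sd))  # 5-sigma step
  cp <- find_change_point(x)
  expect_true(cp$frame >= 198 && cp$frame <= 202)
  # oracle: independent exhaustive scan of the same statistic
  best <- -Inf; kbest <- NA
  for (k in 5:395) {
    m1 <- mean(x[1:k]); m2 <- mean(x[(k + 1):400])
    sp <- sqrt((sum((x[1:k] - m1)^2) + sum((x[(k + 1):400] - m2)^2)) / 398)
    tt <- abs(m1 - m2) / (sp * sqrt(1 / k + 1 / (400 - k)))
    if (tt > best) { best <- tt; kbest <- k }
  }
  expect_equal(cp$frame, kbest)
  expect_equal(cp$tstat, best, tolerance = 1e-9)
})

test_that("bleach detection counts steps and ignores flat noise", {
  set.seed(9)
  # flat noisy trace: no events
  flat <- list(donor = rnorm(300, 400, 30), acceptor = rnorm(300, 300, 30),
               frame_interval = 0.1)
  ev <- detect_bleach_events(flat)
  expect_equal(ev$donor_steps, 0)
  expect_equal(ev$acceptor_steps, 0)
  expect_equal(ev$first_bleach_frame, 301L)

  # all-constant trace: no events, no steps
  const <- list(donor = rep(400, 100), acceptor = rep(300, 100),
                frame_interval = 0.1)
  evc <- detect_bleach_events(const)
  expect_equal(evc$donor_steps + evc$acceptor_steps, 0)

  # acceptor bleach at frame 200, donor bleach at frame 400
  em <- emission_params()
  ph <- photophysics_params()
  p <- simulate_state_path(build_rate_matrix(ref_kp(0)), 60,
                           start_state = 1, seed = 10)
  tr <- render_trace(p, em, ph, seed = 11,
                     bleach_times = list(donor = 40, acceptor = 20))
  ev2 <- detect_bleach_events(tr)
  expect_equal(ev2$donor_steps, 1)
  expect_equal(ev2$acceptor_steps, 1)
  expect_true(abs(ev2$acceptor_bleach_frame - 201) <= 3)
  expect_true(abs(ev2$donor_bleach_frame - 401) <= 3)

  # two acceptor steps (second fluorophore): counted as 2
  tr2 <- render_trace(p, em, ph, seed = 12,
                      bleach_times = list(donor = 50, acceptor = 30),
                      artifacts = list(extra_acceptor_step = 10))
  ev3 <- detect_bleach_events(tr2)
  expect_gte(ev3$acceptor_steps, 2)
})

test_that("selection applies the published criteria with reason codes", {
  em <- emission_params(); ph <- photophysics_params()
  p0 <- simulate_state_path(build_rate_matrix(ref_kp(0)), 60,
                            start_state = 1, seed = 20)
  mk <- function(seed, bleach, artifacts = NULL)
    render_trace(p0, em, ph, seed = seed, bleach_times = bleach,
                 artifacts = artifacts)
  traces <- list(
    mk(1, list(donor = 15, acceptor = 40)),                 # 15 s: too short
    mk(2, list(donor = 50, acceptor = 30),
       artifacts = list(extra_acceptor_step = 10)),         # double acceptor
    mk(3, list(donor = 50, acceptor = Inf),
       artifacts = list(drift_rate = 0.02)),                # drifting total
    mk(4, list(donor = 45, acceptor = 55)),                 # ideal
    mk(5, list(donor = 50, acceptor = 25)))                 # ideal
  for (i in seq_along(traces)) {
    traces[[i]]$trace_id <- i; traces[[i]]$movie_id <- 1L
  }
  ts <- structure(list(traces = traces, movie_id = rep(1L, 5),
                       condition = list(conc = 0), frame_interval = 0.1,
                       seed = 1), class = "trace_set")
  sel <- select_traces(ts)
  expect_equal(length(sel$traces), 2)
  rej <- attr(sel, "rejections")
  expect_setequal(rej$reason[rej$trace_id == 1], "too_short")
  expect_setequal(rej$reason[rej$trace_id == 2], "multi_step_acceptor")
  expect_setequal(rej$reason[rej$trace_id == 3], "unstable_total")

  # ideal noiseless 60-s trace with both bleaches observed is accepted
  em0 <- emission_params(noise_sd = 0)
  tr <- render_trace(p0, em0, ph, bleach_times = list(donor = 50, acceptor = 30))
  tr$trace_id <- 1L; tr$movie_id <- 1L
  ts1 <- structure(list(traces = list(tr), movie_id = 1L,
                        condition = list(conc = 0), frame_interval = 0.1,
                        seed = 1), class = "trace_set")
  expect_equal(length(select_traces(ts1)$traces), 1)

  # idempotence
  sel2 <- select_traces(sel)
  expect_equal(length(sel2$traces), length(sel$traces))
  expect_equal(nrow(attr(sel2, "rejections")), 0)
})

test_that("per-movie histograms are normalized and aggregate with SEM", {
  # all frames at exactly 0.52: one occupied bin at density 1/bin_width
  tr2 <- list(frame_interval = 0.1, trace_id = 1L, movie_id = 1L)
  ch <- smfretkin:::fret_to_channels(0.52, 500, 0.105, 1.1)
  tr2$donor <- rep(ch$donor, 400); tr2$acceptor <- rep(ch$acceptor, 400)
  tr2$bleach <- list(donor_bleach_frame = NA_integer_,
                     acceptor_bleach_frame = NA_integer_,
                     donor_steps = 1L, acceptor_steps = 1L,
                     first_bleach_frame = 401L)
  tr2$usable_frames <- 400L
  ts <- structure(list(traces = list(tr2), movie_id = 1L,
                       condition = list(conc = 0), frame_interval = 0.1,
                       seed = 1, crosstalk = 0.105, gamma = 1.1),
                  class = "trace_set", selected = TRUE)
  h <- compile_histograms(ts)[[1]]
  expect_equal(sum(h$density * 0.02), 1, tolerance = 1e-9)
  expect_equal(sum(h$density > 0), 1)
  expect_equal(max(h$density), 1 / 0.02)

  # five identical movies aggregate with zero SEM everywhere
  hs <- rep(list(h), 5)
  agg <- aggregate_histograms(hs)
  expect_equal(agg$density, h$density)
  expect_equal(agg$sem, rep(0, length(h$density)))
  expect_equal(agg$n_movies, 5)

  # histograms integrate to 1 on realistic simulated input
  ts2 <- simulate_experiment(ref_kp(0.3), n_movies = 2, traces_per_movie = 20,
                             duration = 40, seed = 41)
  sel <- select_traces(ts2)
  for (hh in compile_histograms(sel))
    expect_equal(sum(hh$density * 0.02), 1, tolerance = 1e-9)
})

test_that("two-state occupancies are reflected in histogram mass", {
  # concentration chosen so theta = 0.5: occupancies (0.25, 0.5, 0.25)
  em <- emission_params()
  ts <- simulate_experiment(kinetic_params(1, 0.46, 0.46), em,
                            photophysics_params(donor_bleach_mean = 1e6,
                                                acceptor_bleach_mean = 1e6),
                            n_movies = 1, traces_per_movie = 30,
                            duration = 40, seed = 51)
  # bypass bleach-dependent selection: no bleaching in this set
  vals <- unlist(lapply(ts$traces, function(tr) compute_fret(tr)$fret[1:200]))
  lo <- mean(vals < 0.34); hi <- mean(vals > 0.46)
  expect_lt(abs(lo - 0.25), 0.07)
  expect_lt(abs(hi - 0.25), 0.07)
})
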