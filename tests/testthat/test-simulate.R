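test_that("Gillespie paths are reproducible, contiguous and step-wise valid", {
  Q <- build_rate_matrix(ref_kp(0.3))
  p1 <- simulate_state_path(Q, 60, seed = 7)
  p2 <- simulate_state_path(Q, 60, seed = 7)
  expect_identical(p1, p2)
  expect_equal(p1$start[1], 0)
  expect_equal(p1$end[nrow(p1)], 60)
  expect_equal(p1$start[-1], p1$end[-nrow(p1)])   # contiguous
  # consecutive states differ by exactly one binding step
  if (nrow(p1) > 1) expect_true(all(abs(diff(p1$state)) == 1))

  # all rates zero: a single segment spans the whole duration
  Q0 <- matrix(0, 3, 3, dimnames = dimnames(Q))
  p0 <- simulate_state_path(Q0, 10, start_state = 2, seed = 1)
  expect_equal(nrow(p0), 1)
  expect_equal(p0$end - p0$start, 10)

  Qbad <- Q; Qbad[1, 2] <- -1
  expect_error(simulate_state_path(Qbad, 10), "off-diagonal")
})

test_that("Gillespie dwell times match the exit rates of Q", {
  kp <- ref_kp(0.3)
  Q <- build_rate_matrix(kp)
  set.seed(99)
  # accumulate >= 10,000 complete RAA dwells (and per-state dwells for KS)
  dwells <- list(`1` = numeric(0), `2` = numeric(0), `3` = numeric(0))
  while (length(dwells[["3"]]) < 10000) {
    p <- simulate_state_path(Q, 5000)
    inner <- p[-c(1, nrow(p)), , drop = FALSE]   # complete dwells only
    for (s in 1:3)
      dwells[[as.character(s)]] <-
        c(dwells[[as.character(s)]],
          inner$end[inner$state == s] - inner$start[inner$state == s])
  }
  d3 <- dwells[["3"]][1:10000]
  # empirical mean dwell in RAA = 1/(2 koff) within 3 standard errors
  mu <- 1 / (2 * kp$koff)
  expect_lt(abs(mean(d3) - mu), 3 * sd(d3) / sqrt(length(d3)))
  # dwell distributions are exponential at the exit rates (KS, alpha 0.001)
  lam <- -diag(Q)
  for (s in 1:3) {
    d <- dwells[[as.character(s)]]
    d <- d[seq_len(min(length(d), 10000))]
    ks <- suppressWarnings(ks.test(d, "pexp", lam[s]))
    expect_gt(ks$p.value, 0.001)
  }
  # long-run state frequencies match the stationary distribution
  p <- simulate_state_path(Q, 20000, seed = 123)
  occ <- vapply(1:3, function(s) sum(p$end[p$state == s] - p$start[p$state == s]), 0) / 20000
  expect_equal(occ, unname(stationary_distribution(Q)), tolerance = 0.03)
})

test_that("zero-noise rendering round-trips through compute_fret exactly", {
  em <- emission_params(noise_sd = 0)
  ph <- photophysics_params()
  Q <- build_rate_matrix(ref_kp(0.3))
  p <- simulate_state_path(Q, 30, seed = 5)
  tr <- render_trace(p, em, ph, bleach_times = list(donor = Inf, acceptor = Inf))
  ft <- compute_fret(tr, crosstalk = em$crosstalk, gamma = em$gamma)
  truth <- tr$truth$fret
  expect_equal(ft$fret, truth, tolerance = 1e-12)

  # single-state path: every frame equals the state mean exactly
  p1 <- simulate_state_path(build_rate_matrix(ref_kp(0)), 20,
                            start_state = 1, seed = 1)
  tr1 <- render_trace(p1, em, ph, bleach_times = list(donor = Inf, acceptor = Inf))
  ft1 <- compute_fret(tr1, em$crosstalk, em$gamma)
  expect_equal(ft1$fret, rep(em$state_means[1], 200), tolerance = 1e-12)
})

test_that("acceptor bleach zeroes FRET and donor bleach kills both channels", {
  em <- emission_params()
  ph <- photophysics_params(background_level = 0)
  p <- simulate_state_path(build_rate_matrix(ref_kp(0)), 60,
                           start_state = 1, seed = 2)
  tr <- render_trace(p, em, ph, seed = 3,
                     bleach_times = list(donor = 50, acceptor = 30))
  ft <- compute_fret(tr, em$crosstalk, em$gamma)
  expect_lt(abs(mean(ft$fret[302:499])), 0.03)       # FRET ~ 0 after 30 s
  expect_gt(mean(tr$donor[302:499]), 200)             # donor persists
  post <- c(tr$donor[502:600], tr$acceptor[502:600])  # both at background
  expect_lt(abs(mean(post)), 3 * em$noise_sd / sqrt(99) * 3 + 1)
})

test_that("default channel noise gives the configured FRET-domain width", {
  em <- emission_params()
  ph <- photophysics_params()
  p <- simulate_state_path(build_rate_matrix(ref_kp(0)), 500,
                           start_state = 1, seed = 11)
  tr <- render_trace(p, em, ph, seed = 12,
                     bleach_times = list(donor = Inf, acceptor = Inf))
  ft <- compute_fret(tr, em$crosstalk, em$gamma)
  # numeric propagation oracle of channel noise through the FRET formula
  set.seed(13)
  ch <- smfretkin:::fret_to_channels(em$state_means[1], em$total_intensity,
                                     em$crosstalk, em$gamma)
  idn <- ch$donor + rnorm(2e5, 0, em$noise_sd)
  ian <- ch$acceptor + rnorm(2e5, 0, em$noise_sd)
  oracle_sd <- sd((ian - em$crosstalk * em$gamma * idn) /
                    (em$gamma * idn + ian))
  expect_equal(sd(ft$fret), oracle_sd, tolerance = 0.1)
  # and the design target of ~0.055 FRET units
  expect_equal(oracle_sd, 0.055, tolerance = 0.1)
})

test_that("simulate_experiment is deterministic and concentration-sensitive", {
  kp <- ref_kp(0.3)
  a <- simulate_experiment(kp, n_movies = 2, traces_per_movie = 3,
                           duration = 10, seed = 21)
  b <- simulate_experiment(kp, n_movies = 2, traces_per_movie = 3,
                           duration = 10, seed = 21)
  expect_identical(a, b)
  expect_equal(length(a$traces), 6)
  expect_equal(a$movie_id, rep(1:2, each = 3))

  em <- emission_params()
  apo <- simulate_experiment(ref_kp(0), em, n_movies = 1,
                             traces_per_movie = 8, duration = 20, seed = 31)
  sat <- simulate_experiment(ref_kp(1000), em, n_movies = 1,
                             traces_per_movie = 8, duration = 20, seed = 32)
  mean_fret <- function(ts) {
    mean(unlist(lapply(ts$traces, function(tr) {
      ev <- detect_bleach_events(tr)
      n <- min(ev$first_bleach_frame - 1, 100)
      if (n < 5) return(NULL)
      compute_fret(tr)$fret[1:n]
    })), na.rm = TRUE)
  }
  delta <- mean_fret(apo) - mean_fret(sat)
  expect_equal(delta, em$state_means[1] - em$state_means[3], tolerance = 0.05)
})

test_that("trace sets round-trip through TSV + JSON storage", {
  ts <- simulate_experiment(ref_kp(0.3), n_movies = 2, traces_per_movie = 2,
                            duration = 5, seed = 77)
  dir <- withr::local_tempdir()
  write_trace_set(ts, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- read_trace_set(dir)
  expect_equal(length(back$traces), 4)
  expect_equal(back$condition$conc, 0.3)
  expect_equal(back$traces[[1]]$donor, ts$traces[[1]]$donor, tolerance = 1e-9)
})
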