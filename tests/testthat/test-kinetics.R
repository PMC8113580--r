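test_that("the truncated-exponential MLE matches its closed form", {
  set.seed(81)
  td <- 0.2
  lam_true <- 0.9
  t3 <- td + rexp(4000, lam_true)
  # dwell sequences: state 3 dwells each ending with an observed exit to 2
  dss <- lapply(t3, function(t) make_dwells(c(3, 2), c(t, 1), dead_time = td))
  sc <- scheme_spec("linear", "free")
  base <- c(r12 = 0.6, r21 = 0.46, r23 = 0.3, r32 = 1)
  # 1-D likelihood in the r32 direction under the plain conditional form
  nll <- function(r32) {
    r <- base; r["r32"] <- r32
    -dwell_loglik(dss, sc, r, dead_time = td, missed_events = "conditional")
  }
  opt <- optimize(nll, c(0.01, 20), tol = 1e-10)
  closed_form <- 1 / (mean(t3) - td)
  expect_equal(opt$minimum, closed_form, tolerance = 1e-6)
})

test_that("the per-dwell density integrates to one over [dead_time, Inf)", {
  set.seed(82)
  sc <- scheme_spec("linear", "free")
  for (mode in c("first_order", "conditional")) {
    for (i in 1:10) {
      r <- setNames(runif(4, 0.1, 3), c("r12", "r21", "r23", "r32"))
      td <- runif(1, 0, 0.5)
      for (st in 1:3) {
        total <- 0
        for (nx in setdiff(1:3, st)) {
          # a two-dwell sequence's loglik is the first dwell's full density
          # plus the follower's survivor term; subtracting the follower's
          # lone survivor loglik isolates the per-dwell density
          follower <- dwell_loglik(make_dwells(nx, 10, dead_time = td),
                                   sc, r, dead_time = td,
                                   missed_events = mode)
          f <- Vectorize(function(t) {
            ds <- make_dwells(c(st, nx), c(t, 10), dead_time = td)
            exp(dwell_loglik(ds, sc, r, dead_time = td,
                             missed_events = mode) - follower)
          })
          total <- total + integrate(f, td, Inf, rel.tol = 1e-9)$value
        }
        expect_equal(total, 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("rates are recovered from exponential dwells without dead time", {
  set.seed(83)
  kp <- ref_kp(0.3)
  Q <- build_rate_matrix(kp)
  # dwell sequences straight from Gillespie paths, no merging, no dead time
  dss <- lapply(1:150, function(i) {
    p <- simulate_state_path(Q, 50)
    make_dwells(p$state, p$end - p$start, dead_time = 0)
  })
  n_dwells <- sum(vapply(dss, nrow, 0L))
  expect_gt(n_dwells, 5000)
  sc <- scheme_spec("linear", "independent_sites", conc = 0.3)
  fit <- fit_rates(dss, sc, dead_time = 0)
  # numeric optimum within ~2 SE of the truth
  expect_lt(abs(fit$rates["kon"] - kp$kon), 3 * fit$se["kon"])
  expect_lt(abs(fit$rates["koff"] - kp$koff), 3 * fit$se["koff"])
  expect_equal(unname(fit$rates["kon"]), kp$kon, tolerance = 0.1)
  expect_equal(unname(fit$rates["koff"]), kp$koff, tolerance = 0.1)
})

test_that("constrained fits enforce the 2:1 structure; free fits recover it", {
  set.seed(84)
  kp <- ref_kp(0.3)
  Q <- build_rate_matrix(kp)
  dss <- lapply(1:300, function(i) {
    p <- simulate_state_path(Q, 60)
    nf <- floor(60 / 0.1)
    mid <- (seq_len(nf) - 0.5) * 0.1
    lab <- p$state[findInterval(mid, p$start)]
    it <- make_idealized(lab)
    extract_dwells(it, dead_time = 0.2)
  })
  dss <- dss[vapply(dss, nrow, 0L) > 1]
  sc <- scheme_spec("linear", "independent_sites", conc = 0.3)
  fit <- fit_rates(dss, sc, dead_time = 0.2)
  # the constraint builds the 2:1 ratios in exactly
  Qf <- smfretkin:::scheme_rate_matrix(sc, fit$rates)
  expect_equal(Qf["R", "RA"] / Qf["RA", "RAA"], 2)
  expect_equal(Qf["RAA", "RA"] / Qf["RA", "R"], 2)
  # parameter recovery within 15%
  expect_equal(unname(fit$rates["kon"]), kp$kon, tolerance = 0.15)
  expect_equal(unname(fit$rates["koff"]), kp$koff, tolerance = 0.15)
  expect_equal(fit$kd, kp$koff / kp$kon, tolerance = 0.15)

  # the free linear fit finds the 2:1 structure without being told
  scf <- scheme_spec("linear", "free", conc = 0.3)
  ff <- fit_rates(dss, scf, dead_time = 0.2)
  expect_gt(ff$rates["r12"] / ff$rates["r23"], 1.6)
  expect_lt(ff$rates["r12"] / ff$rates["r23"], 2.4)
  expect_gt(ff$rates["r32"] / ff$rates["r21"], 1.6)
  expect_lt(ff$rates["r32"] / ff$rates["r21"], 2.4)
})

test_that("loglik is invariant to sequence order and censoring is honored", {
  set.seed(85)
  Q <- build_rate_matrix(ref_kp(0.3))
  dss <- lapply(1:20, function(i) {
    p <- simulate_state_path(Q, 30)
    make_dwells(p$state, p$end - p$start, dead_time = 0)
  })
  sc <- scheme_spec("linear", "independent_sites", conc = 0.3)
  r <- c(kon = 1, koff = 0.46)
  ll1 <- dwell_loglik(dss, sc, r, dead_time = 0)
  ll2 <- dwell_loglik(rev(dss), sc, r, dead_time = 0)
  expect_equal(ll1, ll2, tolerance = 1e-12)

  # dropping censored dwells changes the likelihood by exactly their terms
  ll3 <- dwell_loglik(dss, sc, r, dead_time = 0, include_censored = FALSE)
  expect_false(isTRUE(all.equal(ll1, ll3)))

  # dwells below the dead time violate the contract
  bad <- make_dwells(c(1, 2), c(0.05, 1), dead_time = 0.2)
  expect_error(dwell_loglik(bad, sc, r, dead_time = 0.2), "dead time")
  expect_error(dwell_loglik(dss, sc, c(kon = -1, koff = 1), dead_time = 0),
               "positive")
})

test_that("estimation bias shrinks as the data volume grows", {
  set.seed(86)
  Q <- build_rate_matrix(ref_kp(0.3))
  sc <- scheme_spec("linear", "independent_sites", conc = 0.3)
  est <- vapply(c(15, 120), function(n_tr) {
    dss <- lapply(seq_len(n_tr), function(i) {
      p <- simulate_state_path(Q, 40)
      make_dwells(p$state, p$end - p$start, dead_time = 0)
    })
    fit <- fit_rates(dss, sc, dead_time = 0, n_starts = 2)
    unname(fit$rates["kon"])
  }, 0)
  expect_lte(abs(est[2] - 1.0), abs(est[1] - 1.0) + 0.05)
  expect_equal(est[2], 1.0, tolerance = 0.1)
})

test_that("Kd is the rate ratio and needs the independent-sites constraint", {
  set.seed(87)
  dss <- lapply(1:50, function(i) {
    p <- simulate_state_path(build_rate_matrix(ref_kp(0.3)), 40)
    make_dwells(p$state, p$end - p$start, dead_time = 0)
  })
  sc <- scheme_spec("linear", "independent_sites", conc = 0.3)
  fit <- fit_rates(dss, sc, dead_time = 0)
  expect_equal(fit$kd, unname(fit$rates["koff"] / fit$rates["kon"]))
  kdr <- dissociation_constant(fit)
  expect_equal(kdr$kd, fit$kd)
  expect_true(is.finite(kdr$se))

  ff <- fit_rates(dss, scheme_spec("linear", "free"), dead_time = 0)
  expect_error(dissociation_constant(ff), "independent-sites")

  # Kd invariances on the parameter container
  expect_equal(kinetic_params(1, 0.46, 1)$koff / kinetic_params(1, 0.46, 1)$kon,
               0.46)
  expect_equal(kinetic_params(10, 4.6, 1)$koff / kinetic_params(10, 4.6, 1)$kon,
               0.46)
})

test_that("scheme comparison flags boundary-pinned triangular rates", {
  set.seed(88)
  Q <- build_rate_matrix(ref_kp(0.3))
  dss <- lapply(1:150, function(i) {
    p <- simulate_state_path(Q, 60)
    make_dwells(p$state, p$end - p$start, dead_time = 0)
  })
  schemes <- list(
    linear_constrained = scheme_spec("linear", "independent_sites", conc = 0.3),
    linear_free = scheme_spec("linear", "free", conc = 0.3),
    triangular = scheme_spec("triangular", "free", conc = 0.3))
  tab <- compare_schemes(dss, schemes, dead_time = 0, n_starts = 3)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_par, c(2, 4, 6))
  # triangular on linear-truth data: direct rates driven to the boundary
  tri <- tab[tab$scheme == "triangular", ]
  expect_true(grepl("r13|r31", tri$pinned_rates))
  expect_false(tri$converged)
  # free linear nests the constrained model: LR statistic small under truth
  lr <- 2 * (tab$loglik[tab$scheme == "linear_free"] -
               tab$loglik[tab$scheme == "linear_constrained"])
  expect_gte(lr, -1e-6)
  expect_lt(lr, qchisq(0.999, df = 2))
  # identical schemes produce identical rows
  tab2 <- compare_schemes(dss, list(a = schemes$linear_free,
                                    b = schemes$linear_free),
                          dead_time = 0, n_starts = 1)
  expect_equal(tab2$loglik[1], tab2$loglik[2], tolerance = 1e-6)
})
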