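test_that("generated models satisfy detailed balance by construction", {
  for (seed in 1:10) {
    m <- generate_ladder_rates(generator_spec(seed = seed, n_steps = sample(1:4, 1)))
    res <- detailed_balance_residuals(m)
    expect_true(all(res$residual < 1e-12))
    expect_true(all(m$transitions$k_forward > 0))
    expect_true(all(m$transitions$k_backward > 0))
  }
})

test_that("generation is deterministic and honours pinned rates", {
  sp <- generator_spec(seed = 42, n_steps = 4,
                       fixed = list(k_O3C3 = 3, k_O4C4 = 3,
                                    k_C3O3 = 2.0e2, k_C4O4 = 2.0e2))
  m1 <- generate_ladder_rates(sp)
  m2 <- generate_ladder_rates(sp)
  expect_identical(m1$transitions, m2$transitions)
  tr <- m1$transitions
  expect_identical(tr$k_backward[tr$edge == "C3O3"], 3)
  expect_identical(tr$k_backward[tr$edge == "C4O4"], 3)
  expect_identical(tr$k_forward[tr$edge == "C3O3"], 2.0e2)
  expect_identical(tr$k_forward[tr$edge == "C4O4"], 2.0e2)
  # and the pinned model still balances exactly
  expect_true(all(detailed_balance_residuals(m1)$residual < 1e-12))

  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_ladder_rates(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("inconsistent pins on a balance-closed rate are rejected", {
  sp <- generator_spec(seed = 1, n_steps = 2, fixed = list(k_O2O1 = 123.45))
  expect_error(generate_ladder_rates(sp), "over-constrains cycle C1-C2-O2-O1")
  expect_error(generate_ladder_rates(generator_spec(seed = 1, fixed = list(k_X9Y9 = 1))),
               "does not name")
})

test_that("a frozen ensemble never transitions and stays put", {
  m <- build_ladder_model(0, list(C0O0 = c(0, 0)), balance_tol = Inf)
  ens <- gillespie_ensemble(m, jump_protocol(0, 1), n_channels = 50, seed = 3,
                            n_bins = 10, p0 = c(1, 0))
  seg <- ens$segments[[1]]
  expect_true(all(seg$counts_forward == 0))
  expect_true(all(seg$counts_backward == 0))
  expect_true(all(seg$occupancy["C0", ] == 50))
})

test_that("ensembles are reproducible by seed", {
  m <- demo_ladder_model()
  pr <- jump_protocol(7.5, 0.5)
  e1 <- gillespie_ensemble(m, pr, n_channels = 200, seed = 5, n_bins = 20)
  e2 <- gillespie_ensemble(m, pr, n_channels = 200, seed = 5, n_bins = 20)
  e3 <- gillespie_ensemble(m, pr, n_channels = 200, seed = 6, n_bins = 20)
  expect_identical(e1$segments, e2$segments)
  expect_false(identical(e1$segments, e3$segments))
})

test_that("two-state ensembles track the analytic relaxation", {
  k1 <- 2; km1 <- 1
  m <- two_state(k1, km1)
  N <- 10000
  ens <- gillespie_ensemble(m, jump_protocol(0, 3), n_channels = N, seed = 11,
                            n_bins = 60, p0 = c(1, 0))
  seg <- ens$segments[[1]]
  ts <- seg$bin_edges
  p_inf <- k1 / (k1 + km1)
  p_open <- p_inf * (1 - exp(-(k1 + km1) * ts))
  obs <- seg$occupancy["O0", ] / N
  se <- sqrt(pmax(p_open * (1 - p_open), 1e-12) / N)
  expect_gte(mean(abs(obs - p_open) <= 3 * se), 0.99)
})

test_that("event counts at equilibrium balance on every edge", {
  m <- two_state(2, 1)
  st <- stationary_distribution(m, 0)$probability
  ens <- gillespie_ensemble(m, jump_protocol(0, 50), n_channels = 2000, seed = 8,
                            n_bins = 10, p0 = st)
  seg <- ens$segments[[1]]
  fwd <- sum(seg$counts_forward)
  bwd <- sum(seg$counts_backward)
  expect_lt(abs(fwd - bwd), 3 * sqrt(fwd + bwd))
})

test_that("empirical flux estimates carry Poisson errors and zero maps to zero", {
  m <- build_ladder_model(0, list(C0O0 = c(0, 0)), balance_tol = Inf)
  ens <- gillespie_ensemble(m, jump_protocol(0, 1), n_channels = 10, seed = 1,
                            n_bins = 4, p0 = c(1, 0))
  ef <- empirical_flux(ens)
  expect_true(all(ef$f_net == 0))
  expect_true(all(ef$se_net == 0))

  m2 <- demo_ladder_model()
  ens2 <- gillespie_ensemble(m2, jump_protocol(7.5, 0.5), n_channels = 500,
                             seed = 2, n_bins = 24)
  ef2 <- empirical_flux(ens2)
  expect_true(all(ef2$f_uni_forward >= 0))
  expect_true(all(ef2$f_uni_backward <= 0))
  expect_equal(ef2$f_net, ef2$f_uni_forward + ef2$f_uni_backward)
})

test_that("ensemble occupancies converge to the deterministic trajectory", {
  m <- demo_ladder_model()
  pr <- jump_protocol(7.5, 1)
  dev_at <- function(N) {
    ens <- gillespie_ensemble(m, pr, n_channels = N, seed = 4, n_bins = 40)
    seg <- ens$segments[[1]]
    P <- propagate(m, stationary_distribution(m, 0), 7.5, seg$bin_edges)
    det <- t(as.matrix(P[, m$states$label]))
    max(abs(seg$occupancy / N - det))
  }
  d_small <- dev_at(1000)
  d_large <- dev_at(100000)
  # root-N convergence: two decades in N shrink the error by roughly 10x
  expect_lt(d_large, d_small / 3)
})
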