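test_that("net flux densities vanish at equilibrium and follow the defining formula", {
  m <- generate_ladder_rates(generator_spec(seed = 4, n_steps = 4))
  st <- stationary_distribution(m, 1.5)
  traj <- propagate(m, st, 1.5, make_time_grid(2, 101))
  fd <- flux_density(traj, m)
  expect_lt(max(abs(fd$f_net)), 1e-12)
  # opposed unidirectional components are equal and opposite at equilibrium
  expect_lt(max(abs(fd$f_uni_forward + fd$f_uni_backward)), 1e-12)
  expect_true(all(fd$f_uni_forward >= 0))
  expect_true(all(fd$f_uni_backward <= 0))

  # direct substitution: equal occupancies, k_open = 1, k_close = 2
  m2 <- two_state(1, 2)
  traj2 <- propagate(m2, c(0.5, 0.5), 0, c(0, 0.001))
  fd2 <- flux_density(traj2, m2)
  expect_equal(fd2$f_net[fd2$t == 0], 1 * 0.5 - 2 * 0.5)
})

test_that("unidirectional components sum to the net density on every edge", {
  m <- demo_ladder_model()
  tr <- run_protocol(m, default_protocol(), n_points = 201)
  fd <- flux_density(tr, m)
  expect_lt(max(abs(fd$f_net - (fd$f_uni_forward + fd$f_uni_backward))), 1e-12)
})

test_that("total net flux matches the analytic two-state transfer", {
  k1 <- 2; km1 <- 0.5
  m <- two_state(k1, km1)
  p0 <- c(1, 0)
  traj <- propagate(m, p0, 0, make_time_grid(40, 401))
  fd <- flux_density(traj, m)
  tot <- total_net_flux(fd, method = "spectral")
  p_inf <- k1 / (k1 + km1)
  # t_end = 40 s is ~100 relaxation times: F = delta P_open
  expect_equal(tot$F_total, p_inf - 0, tolerance = 1e-10)
})

test_that("Simpson and spectral integration agree, and Simpson converges", {
  m <- generate_ladder_rates(generator_spec(seed = 12, n_steps = 4))
  p0 <- stationary_distribution(m, 0)
  run_tot <- function(n) {
    traj <- propagate(m, p0, 7.5, make_time_grid(5, n))
    fd <- flux_density(traj, m)
    list(sp = total_net_flux(fd, method = "spectral"),
         si = total_net_flux(fd, method = "simpson"))
  }
  r <- run_tot(2001)
  expect_lt(max(abs(r$sp$F_total - r$si$F_total)), 1e-6)

  # refining the grid 4x shrinks the Simpson error by >= an order of magnitude
  r4 <- run_tot(8001)
  err1 <- max(abs(r$si$F_total - r$sp$F_total))
  err4 <- max(abs(r4$si$F_total - r4$sp$F_total))
  expect_lt(err4, err1 / 10)
})

test_that("integrated fluxes reproduce occupancy changes at every state", {
  for (seed in c(6, 23)) {
    m <- generate_ladder_rates(generator_spec(seed = seed, n_steps = 4))
    tr <- run_protocol(m, default_protocol(), n_points = 401)
    segs <- attr(tr, "segments")
    tot <- total_net_flux(flux_density(tr, m), method = "spectral")
    st <- attr(tot, "segment_totals")
    for (s in seq_along(segs)) {
      div <- flux_divergence_check(st[[s]], segs[[s]])
      expect_lt(attr(div, "max_residual"), 1e-6)
      # global conservation: residuals cancel
      expect_lt(abs(sum(div$residual)), 1e-9)
    }
  }

  # stationary trajectory: totals and residuals vanish
  m <- demo_ladder_model()
  st7 <- stationary_distribution(m, 7.5)
  traj <- propagate(m, st7, 7.5, make_time_grid(1, 101))
  tot0 <- total_net_flux(flux_density(traj, m))
  expect_lt(max(abs(tot0$F_total)), 1e-12)
  expect_lt(attr(flux_divergence_check(tot0, traj), "max_residual"), 1e-12)
})

test_that("at saturating ligand the initial C0 occupancy drains through its two edges", {
  m <- demo_ladder_model()
  p0 <- stationary_distribution(m, 0)
  traj <- propagate(m, p0, 750, make_time_grid(5, 401))
  tot <- total_net_flux(flux_density(traj, m))
  out_c0 <- tot$F_total[tot$edge == "C0C1"] + tot$F_total[tot$edge == "C0O0"]
  expect_equal(out_c0, p0$probability[p0$state == "C0"], tolerance = 1e-6)
})

test_that("integration rejects end times beyond the grid", {
  m <- two_state()
  traj <- propagate(m, c(1, 0), 0, make_time_grid(1, 41))
  fd <- flux_density(traj, m)
  expect_error(total_net_flux(fd, t_end = 2), "grid")
})
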