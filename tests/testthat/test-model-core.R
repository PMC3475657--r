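test_that("ladder builder produces the expected topology", {
  m4 <- generate_ladder_rates(generator_spec(seed = 11, n_steps = 4))
  expect_equal(nrow(m4$states), 10)
  expect_equal(nrow(m4$transitions), 13)
  expect_equal(sum(m4$transitions$kind == "isomerization"), 5)
  expect_equal(sum(m4$transitions$kind == "binding_closed"), 4)
  expect_equal(sum(m4$transitions$kind == "binding_open"), 4)
  expect_true(all(m4$transitions$ligand_dependent ==
                    (m4$transitions$kind != "isomerization")))

  m0 <- two_state()
  expect_equal(nrow(m0$states), 2)
  expect_equal(nrow(m0$transitions), 1)

  m2 <- generate_ladder_rates(generator_spec(seed = 5, n_steps = 2))
  expect_equal(nrow(m2$states), 6)
  expect_equal(nrow(m2$transitions), 7)
})

test_that("builder rejects invalid rate tables with informative errors", {
  rates <- demo_ladder_model()$transitions[, c("edge", "k_forward", "k_backward")]
  expect_error(build_ladder_model(4, rates[-3, ]), "C2C3")
  bad <- rates
  bad$k_forward[1] <- -1
  expect_error(build_ladder_model(4, bad), "Negative")
  unbalanced <- rates
  unbalanced$k_forward[unbalanced$edge == "C1O1"] <-
    2 * unbalanced$k_forward[unbalanced$edge == "C1O1"]
  expect_error(build_ladder_model(4, unbalanced), "Detailed balance")
})

test_that("detailed-balance residuals are computed per square cycle", {
  m <- generate_ladder_rates(generator_spec(seed = 3, n_steps = 2))
  res <- detailed_balance_residuals(m)
  expect_equal(nrow(res), 2)
  expect_true(all(res$residual < 1e-10))

  # doubling one rate of a 1-step ladder makes that cycle residual exactly 1
  m1 <- generate_ladder_rates(generator_spec(seed = 3, n_steps = 1))
  r <- m1$transitions[, c("edge", "k_forward", "k_backward")]
  r$k_forward[r$edge == "C0C1"] <- 2 * r$k_forward[r$edge == "C0C1"]
  skel <- build_ladder_model(1, r, balance_tol = Inf)
  res1 <- detailed_balance_residuals(skel)
  expect_equal(res1$residual, 1.0)

  expect_equal(nrow(detailed_balance_residuals(two_state())), 0)

  # a zero rate in the denominator product reports an infinite residual
  r2 <- m1$transitions[, c("edge", "k_forward", "k_backward")]
  r2$k_forward[r2$edge == "C0O0"] <- 0
  m_zero <- build_ladder_model(1, r2, balance_tol = Inf)
  expect_true(is.infinite(detailed_balance_residuals(m_zero)$residual))
})

test_that("rate matrix follows the column-generator convention", {
  m <- two_state(k_open = 1, k_close = 2)
  expect_equal(unname(rate_matrix(m, 0)), matrix(c(-1, 1, 2, -2), 2))

  # columns sum to zero for arbitrary models and concentrations
  for (seed in 1:5) {
    mod <- generate_ladder_rates(generator_spec(seed = seed, n_steps = 4))
    for (L in c(0, 0.075, 7.5)) {
      Q <- rate_matrix(mod, L)
      expect_lt(max(abs(colSums(Q))), 1e-12 * max(1, max(abs(Q))))
      expect_true(all(diag(Q) <= 0))
    }
  }

  # at L = 0 binding-direction entries vanish and the unliganded block is
  # the two-state generator
  mod <- generate_ladder_rates(generator_spec(seed = 9, n_steps = 4))
  Q0 <- rate_matrix(mod, 0)
  binding <- mod$transitions[mod$transitions$ligand_dependent, ]
  for (j in seq_len(nrow(binding))) {
    expect_identical(Q0[binding$to[j], binding$from[j]], 0)
  }
  iso0 <- mod$transitions[mod$transitions$edge == "C0O0", ]
  expect_equal(unname(Q0[c("C0", "O0"), c("C0", "O0")]),
               matrix(c(-iso0$k_forward, iso0$k_forward,
                        iso0$k_backward, -iso0$k_backward), 2))
  expect_error(rate_matrix(mod, -1), ">= 0")
})

test_that("model JSON round trip is bit-identical", {
  m <- generate_ladder_rates(generator_spec(seed = 21, n_steps = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_ladder_model(m, path)
  m2 <- read_ladder_model(path)
  expect_identical(m2$transitions, m$transitions)
  expect_identical(m2$states, m$states)
  expect_identical(m2$name, m$name)
})

test_that("shipped demo config matches the in-code demo model", {
  path <- system.file("extdata", "c4l_o4l_demo.json", package = "gatingflux")
  expect_true(nzchar(path))
  m <- read_ladder_model(path)
  expect_identical(m$transitions, demo_ladder_model()$transitions)
})
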