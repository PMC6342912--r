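test_that("Fermi probability is symmetric, monotone, and overflow-safe", {
  expect_identical(fermi_probability(2, 2, K = 0.1), 0.5)
  expect_equal(fermi_probability(1, 2, K = 0.1), 1 / (1 + exp(-10)))
  set.seed(1)
  for (x in runif(20, -8, 8)) {
    expect_equal(fermi_probability(x, 0, 0.1) + fermi_probability(0, x, 0.1), 1)
  }
  # |p_i - p_j| / K up to 1000 stays finite and ordered
  w_hi <- fermi_probability(100, 0, K = 0.1)
  w_lo <- fermi_probability(0, 100, K = 0.1)
  expect_true(is.finite(w_hi) && w_hi >= 0 && w_hi < 1e-300)
  expect_equal(w_lo, 1)
  diffs <- fermi_probability(seq(-3, 3, 0.5), 0, 0.1)
  expect_true(all(diff(diffs) < 0))  # decreasing in focal advantage
  expect_error(fermi_probability(1, 2, K = 0), "K must")
  expect_error(dynamics_config(K = -1), "K must")
})

test_that("a scripted elementary step reproduces the hand-computed outcome", {
  p <- game_params(T = 1.3, S = -0.1)
  mem <- memory_config("none")
  dyn <- dynamics_config()
  st <- make_uniform_lattice(3, "C")
  st$strategies[1, 2] <- 0L  # a defector above the centre site

  # focal = centre (2,2) = 0-based row-major index 4; neighbor = up (1,2)
  u_focal <- 4.5 / 9
  u_up <- 0.1
  p_i <- 3 * 1 + (-0.1)  # C with 3 C + 1 D
  p_j <- 4 * 1.3         # the D sees 4 C (its up neighbor wraps to row 3)
  W <- 1 / (1 + exp((p_i - p_j) / 0.1))
  step <- elementary_step(st, p, mem, dyn, u = c(u_focal, u_up, W - 1e-9))
  expect_identical(step$state$strategies[2, 2], 0L)  # adopted D
  expect_equal(step$event$W, W)
  expect_true(step$event$adopted)

  step2 <- elementary_step(st, p, mem, dyn, u = c(u_focal, u_up, W + 1e-9))
  expect_identical(step2$state$strategies[2, 2], 1L)  # draw too high
  expect_false(step2$event$adopted)

  # same-strategy pair: the adoption draw is consumed but nothing changes
  step3 <- elementary_step(st, p, mem, dyn, u = c(u_focal, 0.9, 0))
  expect_identical(step3$state$strategies, st$strategies)
  expect_null(step3$event)
})

test_that("imitation cannot introduce an absent strategy", {
  p <- game_params(T = 1.9, S = -0.9)
  all_d <- make_uniform_lattice(10, "D")
  run <- run_game(all_d, p,
                  dyn = dynamics_config(relaxation_steps = 20,
                                        measure_steps = 0,
                                        stop_at_absorption = FALSE))
  expect_true(all(run$final_state$strategies == 0L))
  all_c <- make_uniform_lattice(10, "C")
  run_c <- run_game(all_c, p,
                    dyn = dynamics_config(relaxation_steps = 5,
                                          measure_steps = 5))
  expect_identical(run_c$rho_stationary, 1)
  expect_true(run_c$absorbed)
})

test_that("one Monte Carlo step keeps exact cooperator bookkeeping", {
  p <- game_params(T = 1.3, S = -0.1)
  mem <- memory_config("averaged", alpha = 0.5)
  dyn <- dynamics_config()
  set.seed(21)
  st <- prefill_histories(lattice_random(6), p, mem)
  before <- sum(st$strategies)
  out <- monte_carlo_step(st, p, mem, dyn)
  after <- sum(out$state$strategies)
  ev <- out$events
  expect_lte(nrow(ev), 36)
  gained <- sum(ev$adopted & ev$s_j == "C")
  lost <- sum(ev$adopted & ev$s_j == "D")
  expect_identical(after - before, gained - lost)
  expect_identical(out$state$time, 1L)
  # history bounds respected
  expect_true(all(lengths(out$state$payoff_history) <= mem$capacity))
  expect_true(all(lengths(out$state$strategy_history) <= mem$lag))
})

test_that("compiled runs are bit-identical to the pure-R path on one stream", {
  p <- game_params(1.3, -0.1)
  for (mem in list(memory_config("none"),
                   memory_config("averaged", alpha = 0.8),
                   memory_config("delayed", tau = 2))) {
    st <- lattice_random(6, seed = 42)
    per <- if (mem$variant == "delayed") 5 else 3
    set.seed(7)
    u <- runif(per * 36 * 4)
    dyn <- dynamics_config(relaxation_steps = 4, measure_steps = 0)
    s <- prefill_histories(st, p, mem)
    for (k in 1:4) {
      out <- monte_carlo_step(s, p, mem, dyn,
                              u = u[((k - 1) * per * 36 + 1):(k * per * 36)])
      s <- out$state
    }
    cpp <- run_game(st, p, mem, dyn, uniforms = u)
    expect_identical(cpp$final_state$strategies, s$strategies)
    expect_equal(cpp$trajectory$rho_c[4], rho_c(s))
  }
})

test_that("seeded runs are exactly reproducible", {
  p <- game_params(1.1, -0.3)
  st <- lattice_random(20, seed = 8)
  dyn <- dynamics_config(relaxation_steps = 30, measure_steps = 20)
  a <- run_game(st, p, memory_config("averaged", alpha = 0.5), dyn, seed = 5)
  b <- run_game(st, p, memory_config("averaged", alpha = 0.5), dyn, seed = 5)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_state$strategies, b$final_state$strategies)
  c <- run_game(st, p, memory_config("averaged", alpha = 0.5), dyn, seed = 6)
  expect_false(identical(a$final_state$strategies, c$final_state$strategies))
})

test_that("tidy and glance summarise a run", {
  run <- run_game(lattice_random(15, seed = 1), game_params(0.5, 0.5),
                  dyn = dynamics_config(relaxation_steps = 50,
                                        measure_steps = 20), seed = 2)
  tr <- tidy(run)
  expect_named(tr, c("mcs", "rho_c"))
  expect_lte(nrow(tr), 70)
  g <- glance(run)
  expect_identical(nrow(g), 1L)
  expect_identical(g$variant, "none")
  expect_true(g$rho_stationary >= 0 && g$rho_stationary <= 1)
})
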