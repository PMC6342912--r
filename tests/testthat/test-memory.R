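test_that("memory length matches direct enumeration of the weight cutoff", {
  expect_identical(memory_length(0), 0L)
  expect_identical(memory_length(0.5), 6L)    # 0.5^6 = 0.015625 >= 0.01
  expect_identical(memory_length(0.95), 89L)
  for (alpha in c(0.1, 0.3, 0.5, 0.8, 0.9, 0.95, 0.99)) {
    M <- memory_length(alpha)
    expect_identical(M, oracle_memory_length(alpha))
    expect_gte(alpha^M, 0.01)       # inclusive cutoff
    expect_lt(alpha^(M + 1), 0.01)
  }
  # non-decreasing in alpha
  Ms <- vapply(seq(0, 0.99, 0.01), memory_length, integer(1))
  expect_true(all(diff(Ms) >= 0))
  expect_error(memory_length(1), "alpha")
  expect_error(memory_length(0.5, threshold = 0), "threshold")
})

test_that("averaged payoff reproduces the finite-sum oracle", {
  expect_equal(averaged_payoff(c(2.3, 9, 9), alpha = 0), 2.3)
  expect_equal(averaged_payoff(rep(1, 7), alpha = 0.5, M = 6), 1)
  expect_equal(averaged_payoff(c(1, 0, 0, 0, 0, 0, 0), alpha = 0.5, M = 6),
               1 / 1.984375)
  set.seed(42)
  for (alpha in c(0, 0.5, 0.8, 0.95)) {
    M <- memory_length(alpha)
    for (k in 1:250) {
      n <- sample(1:(M + 5), 1)
      h <- runif(n, -4, 8)
      expect_equal(averaged_payoff(h, alpha, M), oracle_averaged(h, alpha, M),
                   tolerance = 1e-12)
    }
  }
  expect_error(averaged_payoff(numeric(0), 0.5), "empty")
})

test_that("averaged payoff is a convex combination of the entries used", {
  set.seed(7)
  for (rep in 1:100) {
    alpha <- runif(1, 0, 0.99)
    M <- memory_length(alpha)
    h <- runif(sample(1:20, 1), -4, 8)
    used <- h[seq_len(min(length(h), M + 1))]
    out <- averaged_payoff(h, alpha, M)
    expect_gte(out, min(used) - 1e-12)
    expect_lte(out, max(used) + 1e-12)
  }
  # weight normalization: a constant history maps to itself
  for (alpha in c(0, 0.5, 0.8, 0.9, 0.95, 0.99)) {
    M <- memory_length(alpha)
    expect_equal(averaged_payoff(rep(3.7, M + 1), alpha, M), 3.7,
                 tolerance = 1e-12)
  }
})

test_that("delay acceptance follows exp(-tau/s) with the fixed scale", {
  expect_equal(delay_acceptance(100), 0.01)
  expect_identical(delay_acceptance(0), 1)
  expect_equal(delay_acceptance(50), 0.1)
  expect_equal(delay_scale(), -100 / log(0.01))
  nus <- delay_acceptance(0:200)
  expect_true(all(diff(nus) < 0))  # strictly decreasing
  expect_error(delay_acceptance(-1), "non-negative")
})

test_that("effective payoff applies the configured variant rule", {
  h <- c(3.1, 0.2, -1, 5)
  expect_identical(effective_payoff(h, memory_config("none")), 3.1)
  cfg0 <- memory_config("delayed", tau = 0)
  expect_identical(effective_payoff(h, cfg0, u = 0), 3.1)
  expect_identical(effective_payoff(h, cfg0, u = 0.9999), 3.1)
  cfg3 <- memory_config("delayed", tau = 3)
  expect_identical(effective_payoff(h, cfg3, u = cfg3$nu - 1e-9), 5)
  expect_identical(effective_payoff(h, cfg3, u = cfg3$nu + 1e-9), 3.1)
  # shorter history: the oldest entry substitutes
  expect_identical(effective_payoff(h[1:2], cfg3, u = 0), 0.2)
  expect_error(effective_payoff(numeric(0), cfg3), "empty")
})

test_that("memoryless limits coincide: none, alpha = 0, tau = 0", {
  set.seed(3)
  for (rep in 1:50) {
    h <- runif(sample(1:10, 1), -4, 8)
    u <- runif(1)
    vals <- c(effective_payoff(h, memory_config("none")),
              effective_payoff(h, memory_config("averaged", alpha = 0)),
              effective_payoff(h, memory_config("delayed", tau = 0), u = u))
    expect_identical(vals[2], vals[1])
    expect_identical(vals[3], vals[1])
  }
})

test_that("empirical acceptance frequency matches nu over 1e5 draws", {
  set.seed(99)
  cfg <- memory_config("delayed", tau = 7)
  h <- c(1, rep(0, 7))  # picking the past returns 0, the present returns 1
  n <- 1e5
  picks <- vapply(seq_len(n), function(i) effective_payoff(h, cfg),
                  numeric(1))
  frac_past <- mean(picks == 0)
  se <- sqrt(cfg$nu * (1 - cfg$nu) / n)
  expect_lt(abs(frac_past - cfg$nu), 3 * se)
})

test_that("memory configuration derives window, capacity and lag", {
  avg <- memory_config("averaged", alpha = 0.5)
  expect_identical(avg$M, 6L)
  expect_identical(avg$capacity, 6L)
  expect_identical(avg$lag, 3L)  # middle of the averaging window
  del <- memory_config("delayed", tau = 3)
  expect_identical(del$capacity, 3L)
  expect_identical(del$lag, 3L)
  expect_equal(del$nu, exp(-3 / delay_scale()))
  none <- memory_config("none")
  expect_identical(none$capacity, 0L)
  expect_identical(none$lag, 0L)
  # alpha -> 1 limit: capacity capped by the configured window
  big <- memory_config("averaged", alpha = 1, max_window = 100)
  expect_identical(big$M, 99L)
  expect_error(memory_config("averaged", alpha = 1.2), "alpha")
  expect_error(memory_config("delayed", tau = -1), "tau")
})
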