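test_that("mass normalization puts species on a mole-proportional scale", {
  tc <- pts_timecourse(
    times = c(0, 10),
    intensities = cbind(A = c(58.2, 29.1), P = c(70.1, 35.05)),
    masses = c(A = 58.2, P = 70.1)
  )
  norm <- normalize_densitometry(tc)
  # intensity equal to the mass -> unit abundance; half the mass -> 0.5
  expect_equal(unname(norm$intensities[1, ]), c(1, 1))
  expect_equal(unname(norm$intensities[2, ]), c(0.5, 0.5))
  # zero intensity stays zero
  tc0 <- pts_timecourse(c(0, 10), cbind(A = c(0, 1), P = c(0, 2)),
                        c(A = 50, P = 60))
  expect_equal(unname(normalize_densitometry(tc0)$intensities[1, "A"]), 0)
})

test_that("time course construction rejects invalid inputs", {
  expect_error(pts_timecourse(c(0, 10), cbind(A = c(1, 2)), c(B = 50)),
               "mass.*A")
  expect_error(pts_timecourse(c(10, 5), cbind(A = c(1, 2)), c(A = 50)),
               "increasing")
  expect_error(pts_timecourse(c(0, 10), cbind(A = c(-1, 2)), c(A = 50)),
               "non-negative")
})

test_that("splice yield follows P = 100x/(100+x) and its limits", {
  eq <- splice_yield(1, 1)
  expect_equal(eq$x, 100)
  expect_equal(eq$P, 50)
  expect_equal(splice_yield(0, 1)$P, 0)
  expect_equal(splice_yield(3, 1)$P, 75)
  expect_error(splice_yield(0, 0), "undefined")
  # monotone increasing in SP at fixed precursor, bounded below 100
  sp <- seq(0.01, 50, length.out = 50)
  P <- vapply(sp, function(s) splice_yield(s, 1)$P, numeric(1))
  expect_true(all(diff(P) > 0))
  expect_true(all(P >= 0 & P < 100))
})

test_that("half-life conversion reproduces printed rate/half-life pairs", {
  expect_equal(round(half_life(0.1387), 1), 5.0)
  expect_equal(round(half_life(0.0913), 1), 7.6)
  expect_equal(half_life(log(2)), 1.0)
  expect_error(half_life(0), "> 0")
  expect_error(half_life(-1), "> 0")
})

test_that("closed-form three-state profiles match the ODE oracle", {
  times <- c(0, 1, 5, 10, 50)
  prof <- three_state_profiles(0.1, 0.05, 0.2, 1, times)
  ode <- ode_three_state(0.1, 0.05, 0.2, 1, times)
  expect_lt(max(abs(as.matrix(prof[, c("A", "BI", "P")]) -
                    as.matrix(ode[, c("A", "BI", "P")]))), 1e-8)
  # initial condition and absorbing end state
  expect_equal(unname(unlist(prof[1, c("A", "BI", "P")])), c(1, 0, 0))
  late <- three_state_profiles(0.1, 0.05, 0.2, 0.7, 1e6)
  expect_equal(late$P, 0.7, tolerance = 1e-9)
  expect_lt(late$A + late$BI, 1e-9)
})

test_that("closed form agrees with the ODE oracle over random rate draws", {
  set.seed(101)
  for (i in 1:100) {
    k <- 10^stats::runif(3, -3, 0)
    tmax <- 10 / min(k)
    times <- seq(0, tmax, length.out = 20)
    prof <- three_state_profiles(k[1], k[2], k[3], 1, times)
    ode <- ode_three_state(k[1], k[2], k[3], 1, times)
    expect_lt(max(abs(as.matrix(prof[, 2:4]) - as.matrix(ode[, 2:4]))), 1e-8)
    # conservation at every point
    expect_lt(max(abs(rowSums(prof[, 2:4]) - 1)), 1e-10)
    # eigenvalue realness and ordering hold by construction
    p <- sum(k)
    expect_gte(p^2 - 4 * k[1] * k[3], 0)
  }
})

test_that("repeated-eigenvalue limit is continuous with the generic form", {
  # p^2 -> 4 k1 k3 when k2 -> 0 and k1 = k3
  k <- 0.05
  t <- c(0, 5, 20, 100)
  exact <- three_state_profiles(k, 1e-24, k, 1, t)       # a == b branch
  nearby <- three_state_profiles(k * (1 + 1e-6), 1e-24, k, 1, t)
  expect_equal(as.matrix(exact[, 2:4]), as.matrix(nearby[, 2:4]),
               tolerance = 1e-4)
  ode <- ode_three_state(k, 1e-24, k, 1, t)
  expect_lt(max(abs(as.matrix(exact[, 2:4]) - as.matrix(ode[, 2:4]))), 1e-7)
})

test_that("single-exponential fit recovers generating parameters", {
  t <- c(2, 5, 10, 20, 40, 80, 160)
  y <- 0.30 * (1 - exp(-0.05 * t))
  tc <- pts_timecourse(t, cbind(P = y), c(P = 70), normalized = TRUE)
  fit <- fit_single_exponential(tc)
  expect_equal(fit$k_total, 0.05, tolerance = 1e-3)
  expect_equal(fit$P_max, 0.30, tolerance = 1e-3)
  expect_equal(fit$t_half_s, log(2) / fit$k_total)
  # all-zero and flat traces are rejected
  tc0 <- pts_timecourse(t, cbind(P = rep(0, 7)), c(P = 70), normalized = TRUE)
  expect_error(fit_single_exponential(tc0), "zero")
})

test_that("three-state global fit round-trips generator truth", {
  gen <- generate_pts_gel(0.05, 0.01, 0.1, active_fraction = 1,
                          noise_sd = 0, seed = 1)
  fit <- fit_three_state(scale_to_limiting_total(gen$timecourse))
  expect_equal(fit$k1, 0.05, tolerance = 1e-3)
  expect_equal(fit$k3, 0.1, tolerance = 1e-3)
  expect_equal(fit$P_max, 1, tolerance = 1e-3)
  # derived eigen-quantities satisfy their algebraic identities
  expect_equal(fit$p, fit$k1 + fit$k2 + fit$k3)
  expect_equal(fit$a * fit$b, fit$k1 * fit$k3, tolerance = 1e-10)
  expect_true(fit$a >= fit$b && fit$b > 0)
})

test_that("three-state fit with noise recovers k1, k3 and P_max", {
  gen <- generate_pts_gel(0.05, 0.01, 0.1, active_fraction = 1,
                          noise_sd = 0.05, seed = 11,
                          times = c(2, 5, 10, 20, 30, 60, 120, 300, 600))
  fit <- fit_three_state(scale_to_limiting_total(gen$timecourse))
  expect_lt(abs(fit$k1 / 0.05 - 1), 0.10)
  expect_lt(abs(fit$k3 / 0.1 - 1), 0.10)
  expect_lt(abs(fit$P_max - 1), 0.02)
})

test_that("three-state fit requires the intermediate trace", {
  gen <- generate_pts_gel(0.05, 0.01, 0.1, active_fraction = 1,
                          noise_sd = 0, seed = 1)
  tc <- gen$timecourse
  tc2 <- pts_timecourse(tc$times, tc$intensities[, c("A", "P")],
                        tc$masses[c("A", "P")])
  expect_error(fit_three_state(tc2), "BI")
})
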