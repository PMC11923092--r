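true_rates <- list(ka = 1e5, kd = 1e-2, kf = 1e-2, ku = 1e-3)

test_that("trace/determinant exponents equal the 2x2 rate-matrix eigenvalues", {
  set.seed(7)
  for (i in 1:25) {
    r <- list(ka = 10^runif(1, 3, 6), kd = 10^runif(1, -4, -1),
              kf = 10^runif(1, -4, -1), ku = 10^runif(1, -5, -2))
    C <- 10^runif(1, -9, -6)
    got <- bli_eigenvalues(r$ka, r$kd, r$kf, r$ku, C)
    want <- eigen_two_step(r$ka, r$kd, r$kf, r$ku, C)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("association fit recovers eigenvalue sum from a simulated trace", {
  C <- 100e-9
  tr <- two_step_sensorgram(true_rates, C)
  a <- tr[tr$phase == "association", ]
  fit <- fit_association(a$time, a$response, conc = C)
  ev <- eigen_two_step(true_rates$ka, true_rates$kd, true_rates$kf,
                       true_rates$ku, C)
  expect_lt(abs((fit$sigma1 + fit$sigma2) / sum(ev) - 1), 0.005)
  # Y(0) = 0 by the D = -(E+F) constraint
  expect_equal(fit$D, -(fit$E + fit$F))
  expect_gte(fit$sigma1, fit$sigma2)
})

test_that("1:1 binding limit collapses to a single exponent", {
  r <- list(ka = 1e5, kd = 1e-2, kf = 0, ku = 0)
  C <- 100e-9
  tr <- two_step_sensorgram(r, C)
  a <- tr[tr$phase == "association", ]
  fit <- fit_association(a$time, a$response, conc = C)
  expect_true(fit$mono)
  expect_lt(abs(fit$sigma1 / (r$ka * C + r$kd) - 1), 0.01)
})

test_that("dissociation fit recovers C = 0 eigenvalue sum and product", {
  tr <- two_step_sensorgram(true_rates, 100e-9)
  d <- tr[tr$phase == "dissociation", ]
  fit <- fit_dissociation(d$time, d$response, t0 = 500, conc = 100e-9)
  ev0 <- eigen_two_step(true_rates$ka, true_rates$kd, true_rates$kf,
                        true_rates$ku, 0)
  expect_lt(abs((fit$sigma1 + fit$sigma2) / sum(ev0) - 1), 0.005)
  expect_lt(abs((fit$sigma1 * fit$sigma2) / prod(ev0) - 1), 0.005)
  expect_error(fit_dissociation(d$time, rep(0, nrow(d)), t0 = 500), "flat")
})

test_that("non-dissociating locked complex gives a vanishing slow exponent", {
  r <- list(ka = 1e5, kd = 1e-2, kf = 1e-2, ku = 0)
  tr <- two_step_sensorgram(r, 100e-9)
  d <- tr[tr$phase == "dissociation", ]
  fit <- fit_dissociation(d$time, d$response, t0 = 500, conc = 100e-9)
  # gamma1 * gamma2 = kd * ku = 0 in this limit
  expect_lt(fit$sigma2 / fit$sigma1, 1e-2)
})

test_that("eigenvalue regressions invert the forward eigenvalue computation", {
  # exact sigma/gamma values, no trace fitting: the regressions alone must
  # recover the generating rates
  conc <- c(200, 100, 50, 25, 12.5, 6.25, 3.125) * 1e-9
  mkfit <- function(ev, conc, phase) {
    structure(list(phase = phase, sigma1 = ev[1], sigma2 = ev[2],
                   E = -0.5, F = -0.5, D = 1, conc = conc, mono = FALSE,
                   residual_norm = 0), class = "bli_phasefit")
  }
  af <- lapply(conc, function(C)
    mkfit(eigen_two_step(1e5, 1e-2, 1e-2, 1e-3, C), C, "association"))
  df <- lapply(conc, function(C)
    mkfit(eigen_two_step(1e5, 1e-2, 1e-2, 1e-3, 0), C, "dissociation"))
  rc <- extract_rate_constants(af, df)
  expect_lt(abs(rc$ka / 1e5 - 1), 1e-3)
  expect_lt(abs(rc$kd / 1e-2 - 1), 1e-3)
  expect_lt(abs(rc$kf / 1e-2 - 1), 1e-3)
  expect_lt(abs(rc$ku / 1e-3 - 1), 1e-3)
  # by construction of kf, gamma identities hold exactly
  g <- eigen_two_step(1e5, 1e-2, 1e-2, 1e-3, 0)
  expect_equal(rc$kd + rc$kf + rc$ku, sum(g), tolerance = 1e-9)
  # concentration-independent sigmas are a model violation
  af_flat <- lapply(conc, function(C)
    mkfit(eigen_two_step(1e5, 1e-2, 1e-2, 1e-3, 50e-9), C, "association"))
  expect_error(extract_rate_constants(af_flat, df), "not positive")
})

test_that("equilibrium and macroscopic constants follow their identities", {
  rc <- macroscopic_rates(equilibrium_constants(true_rates))
  expect_equal(rc$Ka1, 1e7)
  expect_equal(rc$Ka2, 10)
  expect_equal(rc$Ka, 1.1e8)
  expect_equal(rc$Kd, 1 / 1.1e8)
  expect_equal(rc$kon, 5e4)
  expect_equal(rc$koff, 5e-4)
  # Kd < koff/kon for finite Ka2; equality only as Ka2 -> infinity
  expect_lt(rc$Kd, rc$koff / rc$kon)
  expect_equal(rc$koff / rc$kon, 1 / (rc$Ka1 * rc$Ka2))
  # 1:1 limit kf -> 0
  rc2 <- equilibrium_constants(list(ka = 1e5, kd = 1e-2, kf = 1e-12, ku = 1e-3))
  expect_equal(rc2$Kd, 1e-2 / 1e5, tolerance = 1e-8)
  # kd -> 0 pushes kon towards ka; kf = kd halves it
  expect_equal(macroscopic_rates(list(ka = 1e5, kd = 1e-9, kf = 1, ku = 1))$kon,
               1e5, tolerance = 1e-8)
  expect_equal(macroscopic_rates(list(ka = 1e5, kd = 0.3, kf = 0.3, ku = 1))$kon,
               5e4)
})

test_that("noiseless end-to-end recovery is better than 1%", {
  sim <- generate_sensorgrams(true_rates, noise_sd = 0, seed = 1)
  fits <- fit_all_phases(sim$sensorgrams)
  rc <- extract_rate_constants(fits$assoc, fits$dissoc)
  for (nm in names(true_rates)) {
    expect_lt(abs(rc[[nm]] / true_rates[[nm]] - 1), 0.01)
  }
})

test_that("noisy end-to-end recovery with refinement is within 10%", {
  sim <- generate_sensorgrams(true_rates, noise_sd = 0.005, seed = 1)
  rc <- analyze_sensorgrams(sim$sensorgrams, t0 = 500, refine = TRUE)
  for (nm in names(true_rates)) {
    expect_lt(abs(rc[[nm]] / true_rates[[nm]] - 1), 0.10)
  }
})

test_that("steady-state isotherm fit recovers Kd and passes through Ymax/2", {
  conc <- c(200, 100, 50, 25, 12.5, 6.25, 3.125) * 1e-9
  kd_true <- 12e-9
  y <- 1 * conc / (kd_true + conc)
  fit <- fit_steady_state(conc, y)
  expect_equal(fit$Kd, kd_true, tolerance = 1e-6)
  expect_equal(fit$Ymax, 1, tolerance = 1e-6)
  # half-saturation property of the fitted curve
  expect_equal(fit$Ymax * fit$Kd / (fit$Kd + fit$Kd), fit$Ymax / 2)
  # 2% noise: Kd within 10%
  set.seed(21)
  y_noisy <- y + rnorm(length(y), sd = 0.02)
  fit2 <- fit_steady_state(conc, y_noisy)
  expect_lt(abs(fit2$Kd / kd_true - 1), 0.10)
  # proportional responses leave Kd unidentifiable
  expect_error(fit_steady_state(conc, 5e6 * conc), "unidentifiable")
})

test_that("model validation flags two-step vs shuffled or 1:1 data", {
  sim <- generate_sensorgrams(true_rates, noise_sd = 0, seed = 1)
  fits <- fit_all_phases(sim$sensorgrams)
  v <- validate_biphasic_model(fits$assoc)
  expect_true(v$pass)
  expect_gt(v$r2_sum, 0.999)
  expect_gt(v$r2_prod, 0.999)
  # shuffling sigma across concentrations must fail the linearity check
  shuffled <- fits$assoc
  set.seed(5)
  perm <- c(4, 1, 5, 7, 2, 6, 3)
  for (i in seq_along(shuffled)) {
    shuffled[[i]]$sigma1 <- fits$assoc[[perm[i]]]$sigma1
    shuffled[[i]]$sigma2 <- fits$assoc[[perm[i]]]$sigma2
  }
  expect_false(validate_biphasic_model(shuffled)$pass)
  # 1:1 data: all traces mono-exponential
  sim11 <- generate_sensorgrams(list(ka = 1e5, kd = 1e-2, kf = 0, ku = 0),
                                noise_sd = 0, seed = 1)
  fits11 <- fit_all_phases(sim11$sensorgrams)
  v11 <- validate_biphasic_model(fits11$assoc)
  expect_false(v11$pass)
})

test_that("exponent ordering is stable under amplitude sign flips", {
  C <- 100e-9
  tr <- two_step_sensorgram(true_rates, C)
  a <- tr[tr$phase == "association", ]
  up <- fit_association(a$time, a$response, conc = C)
  down <- fit_association(a$time, -a$response, conc = C)
  expect_equal(up$sigma1, down$sigma1, tolerance = 1e-6)
  expect_equal(up$sigma2, down$sigma2, tolerance = 1e-6)
  expect_gte(down$sigma1, down$sigma2)
})
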