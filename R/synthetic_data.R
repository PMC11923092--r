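#' Generate a synthetic PTS gel-densitometry time course
#'
#' Produces band-intensity tables emulating Coomassie densitometry of a PTS
#' reaction: species amounts follow the closed-form three-state solution
#' scaled by the active precursor fraction, the inactive remainder stays as
#' unreacted precursor, intensities are amount x molecular mass x gain, and
#' noise is multiplicative log-normal (densitometry error scales with band
#' intensity).
#'
#' @param k1,k2,k3 True three-state rates (1/s).
#' @param active_fraction Fraction of precursor competent to splice (P_max).
#' @param masses Named numeric vector of masses (kDa) for `A`, `BI`, `P`.
#' @param times Sampling times (s).
#' @param noise_sd Log-normal noise s.d. as a fraction (default 0.05 = 5%).
#' @param gain Arbitrary densitometry gain.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with `timecourse` (a [pts_timecourse()], raw intensity scale)
#'   and `truth` (the generating parameters).
#' @export
generate_pts_gel <- function(k1, k2, k3, active_fraction = 0.3,
                             masses = c(A = 58.2, BI = 128.3, P = 70.1),
                             times = c(5, 10, 20, 30, 60, 120, 300, 600, 1200),
                             noise_sd = 0.05, gain = 100, seed = 1) {
  stopifnot(all(c("A", "BI", "P") %in% names(masses)))
  set.seed(seed)
  prof <- three_state_profiles(k1, k2, k3, active_fraction, times)
  # the inactive precursor fraction never reacts and adds to the A band
  amounts <- cbind(A = prof$A + (1 - active_fraction),
                   BI = prof$BI, P = prof$P)
  intens <- sweep(amounts, 2, masses[colnames(amounts)], "*") * gain
  if (noise_sd > 0) {
    sdlog <- sqrt(log(1 + noise_sd^2))
    intens <- intens * matrix(
      stats::rlnorm(length(intens), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow = nrow(intens))
  }
  list(
    timecourse = pts_timecourse(times, intens, masses),
    truth = list(k1 = k1, k2 = k2, k3 = k3,
                 active_fraction = active_fraction, noise_sd = noise_sd,
                 gain = gain, seed = seed)
  )
}

#' Generate synthetic biphasic BLI sensorgrams
#'
#' Simulates the two-step conformational-change model at each analyte
#' concentration of a dilution series using the exact linear-system solution,
#' with the response taken as a linear combination of encounter and locked
#' complex, plus additive Gaussian noise.
#'
#' @param rates Named list with true `ka`, `kd`, `kf`, `ku`.
#' @param concentrations Analyte concentrations (M); default the seven-point
#'   2-fold dilution series 200, 100, 50, 25, 12.5, 6.25, 3.125 nM.
#' @param t_assoc,t_dissoc Phase durations (s); defaults 500 s each.
#' @param dt Sampling interval (s).
#' @param alpha,beta Response coefficients of the two bound species.
#' @param noise_sd Additive noise s.d. as a fraction of the maximum response
#'   (default 0.005 = 0.5%).
#' @param seed Integer seed.
#' @return List with `sensorgrams` (list of data frames, one per
#'   concentration, each with `time`, `response`, `phase` and attribute
#'   `conc`) and `truth`.
#' @export
generate_sensorgrams <- function(rates,
                                 concentrations = c(200, 100, 50, 25, 12.5,
                                                    6.25, 3.125) * 1e-9,
                                 t_assoc = 500, t_dissoc = 500, dt = 1,
                                 alpha = 1, beta = 1, noise_sd = 0.005,
                                 seed = 1) {
  set.seed(seed)
  traces <- lapply(concentrations, function(C) {
    tr <- two_step_sensorgram(rates, C, C0 = 1, t_assoc = t_assoc,
                              t_dissoc = t_dissoc, dt = dt,
                              alpha = alpha, beta = beta)
    tr
  })
  ymax <- max(vapply(traces, function(tr) max(tr$response), numeric(1)))
  traces <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (noise_sd > 0) {
      tr$response <- tr$response +
        stats::rnorm(nrow(tr), sd = noise_sd * ymax)
    }
    attr(tr, "conc") <- concentrations[i]
    tr
  })
  list(sensorgrams = traces,
       truth = c(rates, list(concentrations = concentrations,
                             alpha = alpha, beta = beta,
                             noise_sd = noise_sd, seed = seed)))
}

#' Generate a synthetic SEC chromatogram
#'
#' Sum of Gaussian peaks on a linear baseline with additive noise, emulating
#' a bimodal aggregate (void-volume) plus monomer elution profile.
#'
#' @param peaks Data frame with columns `center` (mL), `width` (Gaussian
#'   s.d., mL, > 0) and `area` (mAU mL).
#' @param V0,Vt Column constants (mL).
#' @param volume_range Elution range sampled (mL); default `c(V0*0.8, Vt)`.
#' @param n_points Number of samples.
#' @param baseline Constant baseline offset (mAU).
#' @param noise_sd Additive noise s.d. (mAU).
#' @param seed Integer seed.
#' @return List with `volume`, `absorbance`, `V0`, `Vt`, and `truth`
#'   (including the true area percentages).
#' @export
generate_chromatogram <- function(peaks, V0 = 8, Vt = 24,
                                  volume_range = NULL, n_points = 600,
                                  baseline = 0, noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "area") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  set.seed(seed)
  if (is.null(volume_range)) volume_range <- c(V0 * 0.8, Vt)
  v <- seq(volume_range[1], volume_range[2], length.out = n_points)
  y <- rep(baseline, n_points)
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$area[i] * stats::dnorm(v, peaks$center[i], peaks$width[i])
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, sd = noise_sd)
  list(volume = v, absorbance = y, V0 = V0, Vt = Vt,
       truth = list(peaks = peaks,
                    area_percent = 100 * peaks$area / sum(peaks$area),
                    baseline = baseline, noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic thermal-shift melt curve
#'
#' Four-parameter logistic transition followed by a linear post-peak
#' fluorescence quench (aggregation of dye-protein complexes), with additive
#' Gaussian noise. Temperatures run 10-90 deg C in 1 deg C steps by default.
#'
#' @param T_M Melting temperature (deg C).
#' @param b Hill coefficient (1/deg C), > 0.
#' @param Ymin,Ymax Plateau fluorescence values.
#' @param quench_onset Temperature (deg C) past which fluorescence decays
#'   linearly; `Inf` disables the quench.
#' @param quench_slope Fractional decay per deg C past the onset.
#' @param temperature Sampling temperatures (deg C).
#' @param noise_sd Additive noise s.d. as a fraction of `Ymax`.
#' @param seed Integer seed.
#' @return List with `temperature`, `fluorescence` and `truth`.
#' @export
generate_melt_curve <- function(T_M = 61.4, b = 0.25, Ymin = 0.05, Ymax = 1,
                                quench_onset = Inf, quench_slope = 0.02,
                                temperature = seq(10, 90, by = 1),
                                noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  y <- Ymin + (Ymax - Ymin) / (1 + 10^((T_M - temperature) * b))
  past <- temperature > quench_onset
  if (any(past)) {
    y_onset <- Ymin + (Ymax - Ymin) / (1 + 10^((T_M - quench_onset) * b))
    y[past] <- y_onset * pmax(1 - quench_slope * (temperature[past] - quench_onset), 0)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd * Ymax)
  list(temperature = temperature, fluorescence = y,
       truth = list(T_M = T_M, b = b, Ymin = Ymin, Ymax = Ymax,
                    quench_onset = quench_onset, quench_slope = quench_slope,
                    noise_sd = noise_sd, seed = seed))
}
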