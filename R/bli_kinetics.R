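#' Eigen-exponents of the two-step conformational-change binding model
#'
#' For the scheme N + C <-> N.C <-> NC (bimolecular encounter with rates
#' ka, kd followed by unimolecular folding/locking with rates kf, ku) under
#' pseudo-first-order conditions (constant analyte concentration C), the
#' bound species obey a linear 2x2 system whose decay exponents satisfy
#' sum = ka*C + kd + kf + ku and product = ka*C*(kf + ku) + kd*ku.
#' Dissociation exponents are the C = 0 case.
#'
#' @param ka Association rate, 1/(M s).
#' @param kd Complex dissociation rate, 1/s.
#' @param kf Folding (locking) rate, 1/s.
#' @param ku Unfolding rate, 1/s.
#' @param C Analyte concentration, M (0 for dissociation).
#' @return Numeric vector `c(sigma1, sigma2)` with `sigma1 >= sigma2 >= 0`.
#' @export
bli_eigenvalues <- function(ka, kd, kf, ku, C) {
  tr <- ka * C + kd + kf + ku
  det <- ka * C * (kf + ku) + kd * ku
  disc <- tr^2 - 4 * det
  q <- sqrt(max(disc, 0))
  c(sigma1 = (tr + q) / 2, sigma2 = (tr - q) / 2)
}

# right-hand-side matrix and forcing of the pseudo-first-order two-step system
# state x = ([N.C], [NC]); d x/dt = M x + b with
# M = [[-(kaC+kd+kf), -(kaC-ku)], [kf, -ku]], b = (ka*C*C0, 0)
bli_system <- function(ka, kd, kf, ku, C, C0) {
  M <- matrix(c(-(ka * C + kd + kf), kf,
                -(ka * C - ku),      -ku), nrow = 2)
  list(M = M, b = c(ka * C * C0, 0))
}

#' Closed-form sensorgram of the two-step binding model
#'
#' Exact solution of the linearized two-step scheme at constant analyte
#' concentration, reported as the instrument response
#' Y = alpha*[N.C] + beta*[NC]. Association starts from empty sensor;
#' dissociation continues from the association end point with C = 0.
#'
#' @param rates Named list or vector with `ka`, `kd`, `kf`, `ku`.
#' @param C Analyte concentration (M) during association.
#' @param C0 Immobilized ligand amount (response-capacity units; default 1).
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s).
#' @param alpha,beta Response coefficients of the encounter and locked
#'   complexes (nm per unit concentration).
#' @return Data frame with `time`, `response`, `phase`
#'   (`"association"`/`"dissociation"`); time is global, dissociation starts
#'   at `t0 = t_assoc`.
#' @export
two_step_sensorgram <- function(rates, C, C0 = 1, t_assoc = 500,
                                t_dissoc = 500, dt = 1,
                                alpha = 1, beta = 1) {
  ka <- rates[["ka"]]; kd <- rates[["kd"]]
  kf <- rates[["kf"]]; ku <- rates[["ku"]]

  # x(t) = V e^{L t} V^-1 x0 + V phi(L, t) V^-1 b with
  # phi(l, t) = (e^{l t} - 1)/l (:= t at l = 0, so singular M — the 1:1
  # limit kf = ku = 0 — needs no special case)
  solve_linear <- function(M, b, x0, t) {
    eg <- eigen(M)
    V <- eg$vectors
    lam <- eg$values
    c0 <- solve(V, x0)
    cb <- solve(V, b)
    phi <- function(l, tt) if (abs(l) * tt < 1e-12) tt else (exp(l * tt) - 1) / l
    X <- vapply(t, function(tt) {
      Re(V %*% (c0 * exp(lam * tt) +
                cb * vapply(lam, phi, complex(1), tt = tt)))
    }, numeric(2))
    t(X)
  }

  t1 <- seq(0, t_assoc, by = dt)
  sys1 <- bli_system(ka, kd, kf, ku, C, C0)
  X1 <- solve_linear(sys1$M, sys1$b, c(0, 0), t1)

  t2 <- seq(dt, t_dissoc, by = dt)
  sys0 <- bli_system(ka, kd, kf, ku, 0, C0)
  X2 <- solve_linear(sys0$M, sys0$b, X1[nrow(X1), ], t2)

  data.frame(
    time = c(t1, t_assoc + t2),
    response = c(X1 %*% c(alpha, beta), X2 %*% c(alpha, beta)),
    phase = rep(c("association", "dissociation"), c(length(t1), length(t2)))
  )
}

# variable-projection biexponential fit: for fixed exponents the amplitudes are
# linear, so optimize only (log s1, log s2) and solve amplitudes by lm.
# model = "association": Y = E (e^{-s1 t} - 1) + F (e^{-s2 t} - 1)  (Y(0) = 0)
# model = "dissociation": Y = E e^{-s1 t} + F e^{-s2 t}
fit_biexp <- function(t, y, model = c("association", "dissociation")) {
  model <- match.arg(model)
  basis <- function(s) {
    B <- cbind(exp(-s[1] * t), exp(-s[2] * t))
    if (model == "association") B <- B - 1
    B
  }
  rss <- function(par) {
    s <- exp(par)
    B <- basis(s)
    fit <- stats::lm.fit(B, y)
    sum(fit$residuals^2)
  }
  # the varpro objective is cheap in the 2 exponents, so locate the global
  # basin on a log grid spanning rates resolvable on this time window, then
  # refine locally; biexponentials with nearby exponents are ill-conditioned
  # and a single local search routinely stalls on noisy traces
  span <- max(t) - min(t)
  lo <- log(0.2 / span)          # slower components are indistinguishable from a drift
  hi <- log(200 / span)          # faster ones decay within the first samples
  grid <- seq(lo, hi, length.out = 25)
  pairs <- expand.grid(g1 = grid, g2 = grid)
  pairs <- pairs[pairs$g1 >= pairs$g2, ]
  vals <- apply(pairs, 1, rss)
  keep <- order(vals)[1:4]
  opts <- lapply(keep, function(i) {
    tryCatch(stats::optim(as.numeric(pairs[i, ]), rss, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-14)),
             error = function(e) NULL)
  })
  opts <- Filter(Negate(is.null), opts)
  if (length(opts) == 0) stop("fit failure: biexponential optimizer diverged")
  best <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  s <- sort(exp(best$par), decreasing = TRUE)   # sigma1 >= sigma2
  B <- basis(s)
  amp <- stats::lm.fit(B, y)$coefficients
  list(s1 = s[1], s2 = s[2], E = unname(amp[1]), F = unname(amp[2]),
       rss = best$value)
}

# single-exponential fallback used when the two exponents are unresolvable
fit_monoexp <- function(t, y, model) {
  basis <- function(s) {
    B <- matrix(exp(-s * t), ncol = 1)
    if (model == "association") B <- B - 1
    B
  }
  rss <- function(lp) {
    B <- basis(exp(lp))
    sum(stats::lm.fit(B, y)$residuals^2)
  }
  opt <- stats::optimize(rss, interval = log(c(1e-8, 1e3)))
  s <- exp(opt$minimum)
  amp <- stats::lm.fit(basis(s), y)$coefficients
  list(s1 = s, s2 = NA_real_, E = unname(amp[1]), F = 0, rss = opt$objective)
}

#' Fit the biphasic association phase of a sensorgram
#'
#' Fits Y = D + E exp(-sigma1 t) + F exp(-sigma2 t) with the constraint
#' D = -(E + F), so the fitted curve passes through zero at the phase start.
#' Time is measured from the start of association. If the two exponents are
#' unresolvable (ratio < 1.05) the fit degrades to a single exponential and
#' is flagged `mono = TRUE`.
#'
#' @param time Times (s) of the association segment, measured from its start.
#' @param response Baseline-corrected responses (nm).
#' @param conc Analyte concentration (M), carried through for regressions.
#' @return A list of class `bli_phasefit` with `sigma1 >= sigma2`, amplitudes
#'   `D`, `E`, `F`, the concentration, `mono` flag and residual norm.
#' @export
fit_association <- function(time, response, conc = NA_real_) {
  if (length(time) < 20) stop("association segment needs >= 20 points")
  t <- time - time[1]
  fit <- fit_biexp(t, response, "association")
  mono <- FALSE
  # a slow exponent that barely decays within the window is unresolvable:
  # its basis function degenerates to a ramp and the amplitude diverges
  if (!is.finite(fit$s2) || fit$s2 <= 0 || fit$s1 / fit$s2 < 1.05 ||
      fit$s2 * (max(t) - min(t)) < 0.05 ||
      abs(fit$E + fit$F) > 10 * max(abs(response)) ||
      abs(fit$F) < 1e-10 * max(abs(response))) {
    fit <- fit_monoexp(t, response, "association")
    mono <- TRUE
  }
  structure(
    list(phase = "association", sigma1 = fit$s1, sigma2 = fit$s2,
         E = fit$E, F = fit$F, D = -(fit$E + fit$F), conc = conc,
         mono = mono, residual_norm = sqrt(fit$rss)),
    class = "bli_phasefit"
  )
}

#' Fit the biphasic dissociation phase of a sensorgram
#'
#' Fits Y = E exp(-gamma1 (t - t0)) + F exp(-gamma2 (t - t0)) with both
#' amplitudes free (the response coefficients of the two bound species are
#' not separately identifiable).
#'
#' @param time Times (s) of the dissociation segment.
#' @param response Responses (nm).
#' @param t0 Dissociation start time (s); default is the first sample time.
#' @param conc Analyte concentration of the preceding association (M).
#' @return A `bli_phasefit` with `gamma1 >= gamma2` stored as
#'   `sigma1`/`sigma2`.
#' @export
fit_dissociation <- function(time, response, t0 = time[1], conc = NA_real_) {
  if (length(time) < 20) stop("dissociation segment needs >= 20 points")
  if (max(abs(response)) < .Machine$double.eps^0.5) {
    stop("fit failure: flat dissociation trace")
  }
  t <- time - t0
  fit <- fit_biexp(t, response, "dissociation")
  mono <- FALSE
  if (!is.finite(fit$s2) || fit$s2 < 0 || (fit$s2 > 0 && fit$s1 / fit$s2 < 1.05)) {
    fit <- fit_monoexp(t, response, "dissociation")
    mono <- TRUE
  }
  structure(
    list(phase = "dissociation", sigma1 = fit$s1, sigma2 = fit$s2,
         E = fit$E, F = fit$F, D = 0, conc = conc, mono = mono,
         residual_norm = sqrt(fit$rss)),
    class = "bli_phasefit"
  )
}

#' Extract microscopic rate constants from phase fits across concentrations
#'
#' Implements the eigenvalue regressions of the two-step model: the slope of
#' (sigma1 + sigma2) against C gives ka; the slope of sigma1*sigma2/ka against
#' C gives kf + ku; the concentration-independent dissociation exponents give
#' kd = mean(gamma1 + gamma2) - (kf + ku) and ku = mean(gamma1 * gamma2)/kd,
#' and finally kf = mean(gamma1 + gamma2) - (kd + ku). Regressions are
#' ordinary least squares with a free intercept.
#'
#' @param assoc_fits List of association `bli_phasefit`s, one per analyte
#'   concentration (at least 3 distinct concentrations).
#' @param dissoc_fits List of dissociation `bli_phasefit`s.
#' @param weighting `"amplitude"` (default) weights each trace's exponent
#'   estimates by its squared fitted amplitude in the concentration
#'   regressions and the dissociation-exponent means — the sampling error of
#'   a fitted exponent scales inversely with the trace's signal-to-noise
#'   ratio, so low-concentration traces carry proportionally less weight —
#'   or `"none"` for unweighted regressions and plain means.
#' @return A list of class `bli_rates` with `ka`, `kd`, `kf`, `ku` and the
#'   two regression summaries (`slope`, `intercept`, `r_squared`).
#' @export
extract_rate_constants <- function(assoc_fits, dissoc_fits,
                                   weighting = c("amplitude", "none")) {
  weighting <- match.arg(weighting)
  # traces whose fit degraded to a single exponential carry no usable
  # eigenvalue pair; drop them from the regressions
  ok_a <- !vapply(assoc_fits, `[[`, logical(1), "mono")
  ok_d <- !vapply(dissoc_fits, `[[`, logical(1), "mono")
  if (sum(ok_a) < 3 || sum(ok_d) < 1) {
    stop("model inconsistency: too few resolvable biphasic traces (",
         sum(ok_a), " association, ", sum(ok_d), " dissociation)")
  }
  assoc_fits <- assoc_fits[ok_a]
  dissoc_fits <- dissoc_fits[ok_d]
  C <- vapply(assoc_fits, `[[`, numeric(1), "conc")
  if (length(unique(C)) < 3) stop("need >= 3 distinct analyte concentrations")
  s_sum <- vapply(assoc_fits, function(f) f$sigma1 + f$sigma2, numeric(1))
  s_prod <- vapply(assoc_fits, function(f) f$sigma1 * f$sigma2, numeric(1))
  amp2 <- function(fits) vapply(fits, function(f) (f$E + f$F)^2, numeric(1))
  w_a <- if (weighting == "amplitude") amp2(assoc_fits) else rep(1, length(C))
  w_d <- if (weighting == "amplitude") amp2(dissoc_fits)
         else rep(1, length(dissoc_fits))

  reg_sum <- stats::lm(s_sum ~ C, weights = w_a)
  ka <- unname(stats::coef(reg_sum)[2])
  if (!is.finite(ka) || ka <= 0) {
    stop("model inconsistency: slope of sigma1+sigma2 vs C is not positive (",
         signif(ka, 4), ")")
  }
  reg_prod <- stats::lm(I(s_prod / ka) ~ C, weights = w_a)
  kf_plus_ku <- unname(stats::coef(reg_prod)[2])
  if (!is.finite(kf_plus_ku) || kf_plus_ku <= 0) {
    stop("model inconsistency: slope of sigma1*sigma2/ka vs C is not positive")
  }

  g_sum <- stats::weighted.mean(
    vapply(dissoc_fits, function(f) f$sigma1 + f$sigma2, numeric(1)), w_d)
  g_prod <- stats::weighted.mean(
    vapply(dissoc_fits, function(f) f$sigma1 * f$sigma2, numeric(1)), w_d)
  kd <- g_sum - kf_plus_ku
  if (!is.finite(kd) || kd <= 0) {
    stop("model inconsistency: derived kd = (gamma1+gamma2) - (kf+ku) = ",
         signif(kd, 4), " <= 0")
  }
  ku <- g_prod / kd
  kf <- g_sum - (kd + ku)
  if (ku <= 0 || kf <= 0) {
    stop("model inconsistency: derived kf or ku not positive (kf = ",
         signif(kf, 4), ", ku = ", signif(ku, 4), ")")
  }
  r2 <- r_squared
  structure(
    list(ka = ka, kd = kd, kf = kf, ku = ku,
         regressions = list(
           sigma_sum = list(slope = ka,
                            intercept = unname(stats::coef(reg_sum)[1]),
                            r_squared = r2(reg_sum)),
           sigma_prod = list(slope = kf_plus_ku,
                             intercept = unname(stats::coef(reg_prod)[1]),
                             r_squared = r2(reg_prod)))),
    class = "bli_rates"
  )
}

#' Refine microscopic rates by a global closed-form fit across all traces
#'
#' The per-trace phase fits and eigenvalue regressions estimate each decay
#' exponent from a single trace, which is imprecise for the weakly expressed
#' exponents (small-amplitude components and exponents slower than the phase
#' window). This refinement step keeps the same closed-form biexponential
#' model but ties all exponents across every association and dissociation
#' segment to a single (ka, kd, kf, ku) set through the model's eigenvalue
#' structure, with each segment's amplitudes profiled out by linear least
#' squares. The result is the least-squares rate set given all traces at
#' once; the regression estimates serve as the starting point.
#'
#' @param assoc_segments List with one element per concentration, each a list
#'   with `time` (from the association start), `response`, and `conc` (M).
#' @param dissoc_segments Same structure for the dissociation segments, with
#'   `time` measured from the dissociation start.
#' @param init Named list/vector of starting rates (`ka`, `kd`, `kf`, `ku`),
#'   typically from [extract_rate_constants()].
#' @return A list of class `bli_rates` with the refined `ka`, `kd`, `kf`,
#'   `ku` and the total residual norm.
#' @export
refine_rate_constants <- function(assoc_segments, dissoc_segments, init) {
  seg_rss <- function(tr, lam, assoc) {
    B <- cbind(exp(-lam[1] * tr$time), exp(-lam[2] * tr$time))
    if (assoc) B <- B - 1
    sum(stats::lm.fit(B, tr$response)$residuals^2)
  }
  total_rss <- function(par) {
    k <- exp(par)
    tot <- 0
    for (tr in assoc_segments) {
      tot <- tot + seg_rss(tr, bli_eigenvalues(k[1], k[2], k[3], k[4], tr$conc),
                           assoc = TRUE)
    }
    g <- bli_eigenvalues(k[1], k[2], k[3], k[4], 0)
    for (tr in dissoc_segments) tot <- tot + seg_rss(tr, g, assoc = FALSE)
    tot
  }
  start <- log(c(init$ka, init$kd, init$kf, init$ku))
  best <- stats::optim(start, total_rss, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  k <- exp(best$par)
  structure(list(ka = k[1], kd = k[2], kf = k[3], ku = k[4],
                 residual_norm = sqrt(best$value), refined = TRUE),
            class = "bli_rates")
}

#' Full BLI analysis of a sensorgram set
#'
#' Convenience pipeline: per-trace phase fits, eigenvalue regressions,
#' optional global refinement, equilibrium and macroscopic constants.
#'
#' @param sensorgrams List of data frames with `time`, `response`, `phase`
#'   and a `conc` attribute (as produced by [generate_sensorgrams()]).
#' @param t0 Dissociation start time (s).
#' @param refine Run [refine_rate_constants()] after the regressions.
#' @return A `bli_rates` list completed with equilibrium and macroscopic
#'   constants, plus `phase_fits` and `diagnostics`.
#' @export
analyze_sensorgrams <- function(sensorgrams, t0 = NULL, refine = TRUE) {
  assoc_fits <- list(); dissoc_fits <- list()
  assoc_segs <- list(); dissoc_segs <- list()
  for (i in seq_along(sensorgrams)) {
    tr <- sensorgrams[[i]]
    conc <- attr(tr, "conc")
    a <- tr[tr$phase == "association", ]
    d <- tr[tr$phase == "dissociation", ]
    t0_i <- if (is.null(t0)) max(a$time) else t0
    assoc_fits[[i]] <- fit_association(a$time, a$response, conc = conc)
    dissoc_fits[[i]] <- fit_dissociation(d$time, d$response, t0 = t0_i,
                                         conc = conc)
    assoc_segs[[i]] <- list(time = a$time - a$time[1], response = a$response,
                            conc = conc)
    dissoc_segs[[i]] <- list(time = d$time - t0_i, response = d$response,
                             conc = conc)
  }
  rates <- extract_rate_constants(assoc_fits, dissoc_fits)
  diag <- validate_biphasic_model(assoc_fits)
  if (refine) {
    reg <- rates$regressions
    rates <- refine_rate_constants(assoc_segs, dissoc_segs, rates)
    rates$regressions <- reg
  }
  rates <- macroscopic_rates(equilibrium_constants(rates))
  rates$phase_fits <- list(association = assoc_fits,
                           dissociation = dissoc_fits)
  rates$diagnostics <- diag
  rates
}

#' Equilibrium constants of the two-step binding model
#'
#' Completes a rate-constant set with Ka1 = ka/kd, Ka2 = kf/ku, the overall
#' association constant Ka = Ka1 (1 + Ka2) and the dissociation constant
#' Kd = 1/Ka.
#'
#' @param rates A `bli_rates` object or named list with `ka`, `kd`, `kf`, `ku`.
#' @return The input completed with `Ka1` (1/M), `Ka2` (dimensionless),
#'   `Ka` (1/M) and `Kd` (M).
#' @export
equilibrium_constants <- function(rates) {
  with(rates, {
    stopifnot(ka > 0, kd > 0, kf > 0, ku > 0)
    rates$Ka1 <- ka / kd
    rates$Ka2 <- kf / ku
    rates$Ka <- rates$Ka1 * (1 + rates$Ka2)
    rates$Kd <- 1 / rates$Ka
    rates
  })
}

#' Macroscopic on- and off-rates of the two-step binding model
#'
#' kon = ka*kf/(kd + kf) and koff = kd*ku/(kd + kf); their ratio
#' koff/kon = 1/(Ka1*Ka2) exceeds the overall Kd whenever the locking
#' equilibrium is finite.
#'
#' @param rates Named list with `ka`, `kd`, `kf`, `ku`.
#' @return The input completed with `kon` (1/(M s)) and `koff` (1/s).
#' @export
macroscopic_rates <- function(rates) {
  rates$kon <- rates$ka * rates$kf / (rates$kd + rates$kf)
  rates$koff <- rates$kd * rates$ku / (rates$kd + rates$kf)
  rates
}

#' Steady-state affinity from equilibrium responses
#'
#' Fits the binding isotherm Y = Ymax * X / (Kd + X) to average plateau
#' responses across analyte concentrations.
#'
#' @param conc Analyte concentrations (M), at least 4.
#' @param response Average steady-state responses (nm), typically the mean
#'   over the final seconds of the association phase.
#' @return List of class `bli_steadystate` with `Kd` (M), `Ymax` (nm) and the
#'   residual norm.
#' @export
fit_steady_state <- function(conc, response) {
  if (length(conc) < 4) stop("need >= 4 concentrations")
  # curvature check: a pure proportionality leaves Kd unidentifiable
  ratio <- response / conc
  if (stats::sd(ratio) / mean(ratio) < 1e-6) {
    stop("Kd unidentifiable: responses proportional to concentration")
  }
  fit <- minpack.lm::nlsLM(
    response ~ ymax * conc / (kd + conc),
    start = list(ymax = max(response) * 1.5, kd = stats::median(conc)),
    lower = c(1e-12, 1e-15),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
  )
  cf <- stats::coef(fit)
  structure(
    list(Kd = unname(cf["kd"]), Ymax = unname(cf["ymax"]),
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "bli_steadystate"
  )
}

#' Diagnose whether phase fits are consistent with the two-step model
#'
#' Under the two-step model both the sum and the product of the association
#' exponents are linear in analyte concentration. Reports the R-squared of
#' both regressions and flags the model check as passed when both exceed the
#' threshold; traces that collapsed to single exponentials are reported.
#'
#' @param assoc_fits List of association `bli_phasefit`s across >= 3
#'   concentrations.
#' @param r2_threshold Minimum R-squared for a pass (default 0.99).
#' @return List with `r2_sum`, `r2_prod`, `n_mono`, and logical `pass`.
#' @export
validate_biphasic_model <- function(assoc_fits, r2_threshold = 0.99) {
  C <- vapply(assoc_fits, `[[`, numeric(1), "conc")
  if (length(unique(C)) < 3) stop("need >= 3 distinct analyte concentrations")
  n_mono <- sum(vapply(assoc_fits, `[[`, logical(1), "mono"))
  if (n_mono == length(assoc_fits)) {
    return(list(r2_sum = NA_real_, r2_prod = NA_real_, n_mono = n_mono,
                pass = FALSE, note = "all traces mono-exponential (1:1 model?)"))
  }
  s_sum <- vapply(assoc_fits, function(f) f$sigma1 + ifelse(f$mono, 0, f$sigma2),
                  numeric(1))
  s_prod <- vapply(assoc_fits, function(f) ifelse(f$mono, NA_real_,
                                                  f$sigma1 * f$sigma2),
                   numeric(1))
  r2_sum <- r_squared(stats::lm(s_sum ~ C))
  ok <- is.finite(s_prod)
  r2_prod <- if (sum(ok) >= 3) r_squared(stats::lm(s_prod[ok] ~ C[ok]))
             else NA_real_
  slope_sum <- unname(stats::coef(stats::lm(s_sum ~ C))[2])
  pass <- is.finite(r2_sum) && is.finite(r2_prod) &&
    r2_sum >= r2_threshold && r2_prod >= r2_threshold && slope_sum > 0
  list(r2_sum = r2_sum, r2_prod = r2_prod, n_mono = n_mono, pass = pass)
}
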