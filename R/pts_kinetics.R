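#' Build a protein trans-splicing time course
#'
#' Container for densitometric time-course data of a PTS reaction: per-species
#' band intensities at each sampled time, together with the molecular masses
#' needed to convert intensities to mole-proportional abundances.
#'
#' @param times Numeric vector of sampling times in seconds, non-negative and
#'   strictly increasing.
#' @param intensities Numeric matrix (or data frame) with one column per
#'   species and one row per time point; all values must be non-negative.
#' @param masses Named numeric vector of molecular masses in kDa, one entry per
#'   species column. All masses must be positive.
#' @param normalized Logical; `TRUE` once intensities have been divided by the
#'   species masses (mole-proportional scale).
#'
#' @return An object of class `pts_timecourse`.
#' @export
pts_timecourse <- function(times, intensities, masses, normalized = FALSE) {
  times <- as.numeric(times)
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities))) {
    stop("intensity matrix must have species column names")
  }
  if (length(times) != nrow(intensities)) {
    stop("length(times) must equal nrow(intensities)")
  }
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  species <- colnames(intensities)
  missing_mass <- setdiff(species, names(masses))
  if (length(missing_mass) > 0) {
    stop("no molecular mass given for species: ",
         paste(missing_mass, collapse = ", "))
  }
  masses <- masses[species]
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all species masses must be positive and finite")
  }
  structure(
    list(times = times, intensities = intensities, masses = masses,
         normalized = isTRUE(normalized)),
    class = "pts_timecourse"
  )
}

#' @export
print.pts_timecourse <- function(x, ...) {
  cat("PTS time course:", length(x$times), "time points,",
      ncol(x$intensities), "species (",
      paste(colnames(x$intensities), collapse = ", "), ")\n")
  cat("  scale:", if (x$normalized) "mole-proportional" else "raw intensity", "\n")
  invisible(x)
}

#' Convert band intensities to mole-proportional abundances
#'
#' Coomassie staining intensity is proportional to protein mass, so within a
#' lane the band intensity of each species must be divided by its molecular
#' weight before species can be compared on a molar scale.
#'
#' @param tc A [pts_timecourse()].
#' @return A `pts_timecourse` with mass-normalized intensities
#'   (`normalized = TRUE`).
#' @export
normalize_densitometry <- function(tc) {
  stopifnot(inherits(tc, "pts_timecourse"))
  if (tc$normalized) return(tc)
  norm <- sweep(tc$intensities, 2, tc$masses, "/")
  pts_timecourse(tc$times, norm, tc$masses, normalized = TRUE)
}

#' Rescale a time course to the limiting-precursor total
#'
#' Kinetic fits expect abundances as fractions of the total limiting
#' precursor. Because the scheme conserves A + BI + P, the per-lane row sum
#' over those species estimates that total; its mean over lanes divides the
#' whole table, making the trace dimensionless and robust to lane-to-lane
#' noise.
#'
#' @param tc A [pts_timecourse()] containing species `A`, `BI` and `P`.
#' @return A normalized `pts_timecourse` on the fraction scale.
#' @export
scale_to_limiting_total <- function(tc) {
  stopifnot(inherits(tc, "pts_timecourse"))
  tc <- normalize_densitometry(tc)
  need <- c("A", "BI", "P")
  if (!all(need %in% colnames(tc$intensities))) {
    stop("scaling requires species A, BI and P")
  }
  total <- mean(rowSums(tc$intensities[, need, drop = FALSE]))
  if (total <= 0) stop("limiting-precursor total is zero")
  pts_timecourse(tc$times, tc$intensities / total, tc$masses,
                 normalized = TRUE)
}

#' Splice yield from product and limiting-precursor abundances
#'
#' The percent ratio of splice product to the precursor supplied in limiting
#' amount, x = 100 * SP / A, is converted to the splice yield
#' P = 100 * x / (100 + x), algebraically equal to 100 * SP / (SP + A).
#'
#' @param sp Mole-proportional abundance of splice product (>= 0).
#' @param precursor Mole-proportional abundance of the limiting precursor
#'   remaining (>= 0).
#' @return A list with `x` (percent ratio) and `P` (percent yield in [0, 100)).
#' @export
splice_yield <- function(sp, precursor) {
  if (sp < 0 || precursor < 0) stop("abundances must be non-negative")
  if (sp == 0 && precursor == 0) {
    stop("splice yield undefined: both product and precursor are zero")
  }
  x <- 100 * sp / precursor   # Inf when precursor fully consumed
  P <- 100 * sp / (sp + precursor)
  list(x = x, P = P)
}

#' Half-life of a first-order process
#'
#' @param k First-order rate constant in 1/s; must be positive.
#' @return Half-life ln(2)/k in seconds.
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("rate constant must be > 0")
  log(2) / k
}

#' Fit a pseudo-first-order splice-product time course
#'
#' Fits P(t) = P_max * (1 - exp(-k_total * t)) by nonlinear least squares.
#' Abundances should be normalized so that the limiting precursor total is 1;
#' P_max is then the fraction of precursor competent to splice.
#'
#' @param tc A normalized [pts_timecourse()] (or raw; normalized internally).
#' @param species Column name of the splice product trace (default `"P"`).
#' @return A list of class `pts_expfit` with `k_total` (1/s), `P_max`,
#'   `t_half_s`, `residual_norm`, and the fitted values.
#' @export
fit_single_exponential <- function(tc, species = "P") {
  stopifnot(inherits(tc, "pts_timecourse"))
  tc <- normalize_densitometry(tc)
  if (!species %in% colnames(tc$intensities)) {
    stop("species '", species, "' not present in time course")
  }
  t <- tc$times
  y <- tc$intensities[, species]
  if (length(t) < 4) stop("at least 4 time points required")
  if (all(y == 0)) stop("fit failure: product trace is identically zero")
  if (max(y) <= min(y)) {
    stop("fit failure: product trace shows no increase over time")
  }
  # start values: plateau from the tail, rate from the half-rise time
  pmax0 <- max(y)
  t_half0 <- t[which(y >= pmax0 / 2)[1]]
  k0 <- if (is.na(t_half0) || t_half0 <= 0) 1 / max(t[t > 0]) else log(2) / t_half0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ pmax * (1 - exp(-k * t)),
      start = list(pmax = pmax0, k = k0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
    ),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             " (starts pmax=", signif(pmax0, 3),
                             ", k=", signif(k0, 3), ")")
  )
  cf <- stats::coef(fit)
  structure(
    list(k_total = unname(cf["k"]), P_max = unname(cf["pmax"]),
         t_half_s = log(2) / unname(cf["k"]),
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         fitted = stats::fitted(fit), times = t),
    class = "pts_expfit"
  )
}

# eigen-quantities of the three-state scheme A -> BI -> SP with BI -> A reversal
# p = k1+k2+k3; q = sqrt(p^2 - 4 k1 k3) (real: p^2 - 4k1k3 >= (k1-k3)^2 >= 0);
# a = (p+q)/2, b = (p-q)/2 so that a*b = k1*k3.
three_state_eigen <- function(k1, k2, k3) {
  p <- k1 + k2 + k3
  disc <- p^2 - 4 * k1 * k3
  q <- sqrt(max(disc, 0))
  list(p = p, q = q, a = (p + q) / 2, b = (p - q) / 2)
}

#' Closed-form species trajectories of the three-state splicing scheme
#'
#' Evaluates the analytical solution of the linear scheme
#' A <-> BI -> SP (rates k1 forward, k2 reverse, k3 product formation) with
#' initial condition ([A], [BI], [P]) = (P_max, 0, 0). When the two
#' eigenvalues coincide (p^2 = 4 k1 k3) the repeated-eigenvalue limit with
#' t*exp(-a t) terms is used; the switchover is |a - b| < 1e-9 * a.
#'
#' @param k1,k2,k3 Positive rate constants (1/s): complex formation, complex
#'   dissociation/reversal, and splice-product formation.
#' @param P_max Active precursor fraction in (0, 1].
#' @param times Numeric vector of times (s).
#' @return Data frame with columns `time`, `A`, `BI`, `P`.
#' @export
three_state_profiles <- function(k1, k2, k3, P_max, times) {
  if (any(c(k1, k2, k3) <= 0)) stop("rate constants must be positive")
  if (P_max <= 0 || P_max > 1) stop("P_max must lie in (0, 1]")
  eg <- three_state_eigen(k1, k2, k3)
  a <- eg$a; b <- eg$b
  t <- as.numeric(times)
  if (abs(a - b) < 1e-9 * a) {
    # repeated eigenvalue: A = (1 + (a - k1) t) e^{-at}, BI = k1 t e^{-at}
    ea <- exp(-a * t)
    A  <- P_max * (1 + (a - k1) * t) * ea
    BI <- P_max * k1 * t * ea
    P  <- P_max - A - BI
  } else {
    ea <- exp(-a * t); eb <- exp(-b * t)
    A  <- P_max * ((k1 * (a - k3)) / (a * (a - b)) * ea +
                   (k1 * (k3 - b)) / (b * (a - b)) * eb)
    BI <- P_max * (k1 / (a - b)) * (eb - ea)
    P  <- P_max * ((k1 * k3) / (a * b) +
                   (k1 * k3) / (a * (a - b)) * ea -
                   (k1 * k3) / (b * (a - b)) * eb)
  }
  data.frame(time = t, A = A, BI = BI, P = P)
}

#' Global three-state fit of precursor, intermediate and product traces
#'
#' Fits a single parameter set (k1, k2, k3, P_max) to the joint residuals of
#' the limiting precursor `A`, branched intermediate `BI` and splice product
#' `P` traces against the closed-form three-state solution. Rates are
#' optimized on the log scale (positivity by construction) with multiple
#' log-spaced starts.
#'
#' @param tc A [pts_timecourse()] containing columns `A`, `BI` and `P` at
#'   six or more time points.
#' @param n_starts Number of log-spaced multi-start initializations.
#' @param inactive_offset If `TRUE`, the inactive precursor fraction
#'   (1 - P_max) is modelled as a constant additive offset on the `A` trace;
#'   use when the data are scaled to the full precursor total and the
#'   splice-incompetent fraction co-migrates with intact precursor.
#' @return A list of class `pts_threestatefit` with `k1`, `k2`, `k3`, `P_max`,
#'   derived `p`, `q`, `a`, `b`, and `residual_norm`.
#' @export
fit_three_state <- function(tc, n_starts = 5, inactive_offset = FALSE) {
  stopifnot(inherits(tc, "pts_timecourse"))
  tc <- normalize_densitometry(tc)
  need <- c("A", "BI", "P")
  absent <- setdiff(need, colnames(tc$intensities))
  if (length(absent) > 0) {
    stop("three-state fit requires species traces: ",
         paste(absent, collapse = ", "))
  }
  t <- tc$times
  if (length(t) < 6) stop("at least 6 time points required")
  Y <- tc$intensities[, need]

  obj <- function(par) {
    k <- exp(par[1:3])
    pmax <- stats::plogis(par[4])
    pred <- three_state_profiles(k[1], k[2], k[3], pmax, t)
    if (inactive_offset) pred$A <- pred$A + (1 - pmax)
    sum((pred$A - Y[, "A"])^2) + sum((pred$BI - Y[, "BI"])^2) +
      sum((pred$P - Y[, "P"])^2)
  }

  # crude scale for the rates: inverse of the product half-rise time
  p_trace <- Y[, "P"]
  t_half0 <- t[which(p_trace >= max(p_trace) / 2)[1]]
  k_scale <- if (is.na(t_half0) || t_half0 <= 0) 1 / max(t[t > 0]) else log(2) / t_half0
  pmax0 <- max(Y[, "A"][1], max(p_trace), 1e-3)
  pmax0 <- min(pmax0, 0.999)

  starts <- lapply(seq_len(n_starts), function(i) {
    mult <- 10^((i - (n_starts + 1) / 2) / 2)   # log-spaced around k_scale
    c(log(k_scale * mult), log(k_scale * mult / 3), log(k_scale * mult),
      stats::qlogis(pmax0))
  })
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, obj, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("fit failure: no start converged (", n_starts, " starts tried)")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  k <- exp(best$par[1:3])
  pmax <- stats::plogis(best$par[4])
  eg <- three_state_eigen(k[1], k[2], k[3])
  structure(
    list(k1 = k[1], k2 = k[2], k3 = k[3], P_max = pmax,
         p = eg$p, q = eg$q, a = eg$a, b = eg$b,
         residual_norm = sqrt(best$value)),
    class = "pts_threestatefit"
  )
}
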