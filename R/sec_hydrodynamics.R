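#' SEC partition coefficient
#'
#' Kav = (Ve - V0) / (Vt - V0), the normalized elution position between the
#' void volume (blue-dextran marker) and total bed volume (acetone marker).
#' Values outside (0, 1] are returned as-is — elution at or before the void
#' volume gives Kav <= 0 and signals an excluded (aggregated) species.
#'
#' @param Ve Elution volume (mL).
#' @param V0 Void volume (mL).
#' @param Vt Total bed volume (mL); must exceed `V0`.
#' @return Kav (dimensionless).
#' @export
partition_coefficient <- function(Ve, V0, Vt) {
  if (Vt <= V0) stop("total volume Vt must exceed void volume V0")
  (Ve - V0) / (Vt - V0)
}

#' Calibrate Stokes radius against SEC standards
#'
#' Ordinary least squares of the standards' Stokes radii on
#' sqrt(-log10(Kav)), the classical linearization for globular proteins on
#' size-exclusion media. An optional molecular-weight calibration (linear in
#' log10 MW vs Kav) can be fitted from the same standards.
#'
#' @param standards Data frame with columns `name`, `rst` (Stokes radius, Å),
#'   `ve` (elution volume, mL) and optionally `mw` (kDa).
#' @param V0,Vt Column constants (mL).
#' @return List of class `sec_calibration` with `slope`, `intercept` (Å), the
#'   standards table augmented with `kav`, the column constants, and — when
#'   `mw` is supplied — `mw_slope`, `mw_intercept` for log10(MW) vs Kav.
#' @export
calibrate_stokes <- function(standards, V0, Vt) {
  stopifnot(is.data.frame(standards), nrow(standards) >= 2,
            all(c("rst", "ve") %in% names(standards)))
  kav <- partition_coefficient(standards$ve, V0, Vt)
  bad <- which(kav <= 0 | kav >= 1)
  if (length(bad) > 0) {
    nm <- if ("name" %in% names(standards)) standards$name[bad] else bad
    stop("standard(s) with Kav outside (0, 1): ", paste(nm, collapse = ", "))
  }
  x <- sqrt(-log10(kav))
  fit <- stats::lm(standards$rst ~ x)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              standards = cbind(standards, kav = kav),
              V0 = V0, Vt = Vt,
              r_squared = r_squared(fit),
              log_base = 10)
  if ("mw" %in% names(standards)) {
    mwfit <- stats::lm(log10(standards$mw) ~ kav)
    out$mw_slope <- unname(stats::coef(mwfit)[2])
    out$mw_intercept <- unname(stats::coef(mwfit)[1])
  }
  structure(out, class = "sec_calibration")
}

#' Stokes radius from an elution volume
#'
#' Applies the calibration line R_ST = intercept + slope * sqrt(-log10 Kav).
#' Elution at or before the void volume (Kav <= 0) is not on the calibrated
#' range; the largest calibrated radius is then returned as a lower bound
#' with `lower_bound = TRUE` (such species are larger than anything the
#' column resolves).
#'
#' @param Ve Elution volume (mL).
#' @param calibration A [calibrate_stokes()] result.
#' @return List with `rst` (Å), `kav`, and `lower_bound` flag.
#' @export
stokes_radius <- function(Ve, calibration) {
  stopifnot(inherits(calibration, "sec_calibration"))
  kav <- partition_coefficient(Ve, calibration$V0, calibration$Vt)
  if (kav <= 0) {
    return(list(rst = max(calibration$standards$rst), kav = kav,
                lower_bound = TRUE))
  }
  if (kav >= 1) kav <- 1   # fully included: R_ST -> intercept
  rst <- calibration$intercept + calibration$slope * sqrt(-log10(kav))
  list(rst = rst, kav = kav, lower_bound = FALSE)
}

#' Apparent molecular weight from an elution volume
#'
#' Applies the log-linear MW calibration (log10 MW vs Kav) fitted from
#' globular standards.
#'
#' @param Ve Elution volume (mL).
#' @param calibration A [calibrate_stokes()] result fitted with `mw` values.
#' @return Apparent molecular weight (kDa).
#' @export
apparent_mw <- function(Ve, calibration) {
  stopifnot(inherits(calibration, "sec_calibration"))
  if (is.null(calibration$mw_slope)) {
    stop("calibration has no molecular-weight component; supply 'mw' standards")
  }
  kav <- partition_coefficient(Ve, calibration$V0, calibration$Vt)
  10^(calibration$mw_intercept + calibration$mw_slope * kav)
}

# linear baseline through the medians of the first and last `frac` of the trace
subtract_baseline <- function(volume, absorbance, frac = 0.05) {
  n <- length(volume)
  k <- max(2, floor(frac * n))
  head_ix <- seq_len(k); tail_ix <- seq(n - k + 1, n)
  x1 <- stats::median(volume[head_ix]); y1 <- stats::median(absorbance[head_ix])
  x2 <- stats::median(volume[tail_ix]); y2 <- stats::median(absorbance[tail_ix])
  slope <- (y2 - y1) / (x2 - x1)
  absorbance - (y1 + slope * (volume - x1))
}

#' Aggregate/monomer quantification of a bimodal chromatogram
#'
#' Subtracts a linear baseline, locates the two largest peaks on a lightly
#' smoothed trace, places the boundary at the inter-peak minimum (unless
#' boundaries are given), and integrates each region by the trapezoidal
#' rule. The peak in the void region (left of `void_limit`, defaulting to the
#' void volume) is labelled aggregate. Percentages are area fractions and are
#' invariant under uniform rescaling of the trace.
#'
#' @param volume Elution volumes (mL), ascending.
#' @param absorbance A280 trace (mAU).
#' @param V0 Void volume (mL); used to label the aggregate peak.
#' @param boundaries Optional numeric vector of interior peak boundaries (mL);
#'   auto-detected at the inter-peak minimum when `NULL`.
#' @param smooth_window Running-mean window (points) for peak detection.
#' @param baseline Subtract a linear baseline first (default TRUE).
#' @return List of class `sec_fractions` with `aggregate_percent`,
#'   `monomer_percent`, `boundary`, and per-peak areas.
#' @export
integrate_fractions <- function(volume, absorbance, V0 = NULL,
                                boundaries = NULL, smooth_window = 5,
                                baseline = TRUE) {
  stopifnot(length(volume) == length(absorbance), all(diff(volume) > 0))
  y <- if (baseline) subtract_baseline(volume, absorbance) else absorbance
  y <- pmax(y, 0)
  if (max(y) <= 0) stop("no detectable peak in chromatogram")

  trapz <- function(x, f) sum(diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)

  if (is.null(boundaries)) {
    ys <- as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
    # local maxima above 5% of the global maximum
    is_max <- which(diff(sign(diff(ys))) < 0) + 1
    is_max <- is_max[ys[is_max] > 0.05 * max(ys)]
    if (length(is_max) == 0) stop("no detectable peak in chromatogram")
    if (length(is_max) == 1) {
      agg <- !is.null(V0) && volume[is_max] <= V0 + 0.02 * (max(volume) - min(volume))
      total <- trapz(volume, y)
      return(structure(list(
        aggregate_percent = if (agg) 100 else 0,
        monomer_percent = if (agg) 0 else 100,
        boundary = NA_real_,
        areas = stats::setNames(total, if (agg) "aggregate" else "monomer")),
        class = "sec_fractions"))
    }
    top2 <- is_max[order(ys[is_max], decreasing = TRUE)][1:2]
    top2 <- sort(top2)
    valley <- top2[1] + which.min(ys[top2[1]:top2[2]]) - 1
    boundaries <- volume[valley]
  }
  b <- boundaries[1]
  left <- volume <= b
  # include the boundary point in both regions for a continuous split
  a_area <- trapz(volume[left], y[left])
  m_area <- trapz(volume[!left | volume == b], y[!left | volume == b])
  total <- a_area + m_area
  structure(list(
    aggregate_percent = 100 * a_area / total,
    monomer_percent = 100 * m_area / total,
    boundary = b,
    areas = c(aggregate = a_area, monomer = m_area)),
    class = "sec_fractions")
}

#' Fit aggregation or disaggregation kinetics of SEC fractions
#'
#' Models the monomer (or aggregate) percentage over time either as a
#' one-phase exponential M(t) = M_inf + (M0 - M_inf) exp(-k t) — appropriate
#' for aggregate resolution and for the post-lag phase of re-aggregation —
#' or as a logistic M(t) = M_inf + (M0 - M_inf)/(1 + exp(k (t - t_mid)))
#' capturing the nucleation lag. Both models' AIC are reported so the lag
#' phase can be detected by model comparison.
#'
#' @param time Times (any consistent unit), >= 5 points.
#' @param fraction Fraction values (percent).
#' @param model `"one_phase_exponential"` or `"logistic"`.
#' @return List of class `sec_aggfit` with `k`, `plateau` (M_inf), `M0`,
#'   `t_mid` (logistic only), `aic`, `aic_alternative` (the other model) and
#'   residual norm.
#' @export
fit_aggregation_kinetics <- function(time, fraction,
                                     model = c("one_phase_exponential",
                                               "logistic")) {
  model <- match.arg(model)
  if (length(time) < 5) stop("need >= 5 time points")
  if (stats::sd(fraction) < 1e-12) {
    stop("rate unidentifiable: fraction is constant over time")
  }
  span <- max(time) - min(time)
  fit_one <- function(which) {
    m0 <- fraction[1]; minf <- fraction[length(fraction)]
    if (which == "one_phase_exponential") {
      minpack.lm::nlsLM(
        fraction ~ minf + (m0 - minf) * exp(-k * time),
        start = list(minf = minf, m0 = m0, k = 2 / span),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
    } else {
      minpack.lm::nlsLM(
        fraction ~ minf + (m0 - minf) / (1 + exp(k * (time - tmid))),
        start = list(minf = minf, m0 = m0, k = 4 / span,
                     tmid = stats::median(time)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
    }
  }
  fit <- tryCatch(fit_one(model),
                  error = function(e) stop("fit failure: ", conditionMessage(e)))
  other <- setdiff(c("one_phase_exponential", "logistic"), model)
  aic_alt <- tryCatch(stats::AIC(fit_one(other)), error = function(e) NA_real_)
  cf <- stats::coef(fit)
  structure(
    list(model = model, k = unname(cf["k"]), plateau = unname(cf["minf"]),
         M0 = unname(cf["m0"]),
         t_mid = if (model == "logistic") unname(cf["tmid"]) else NA_real_,
         aic = stats::AIC(fit), aic_alternative = aic_alt,
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "sec_aggfit"
  )
}
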