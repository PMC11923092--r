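#' Kyte-Doolittle hydropathy scale
#'
#' Named vector of per-residue hydropathy values for the 20 standard amino
#' acids (one-letter codes). Range -4.5 (Arg) to 4.5 (Ile).
#'
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(kyte_doolittle))
  if (length(bad) > 0) {
    stop("non-standard residue(s) '", paste(res[bad], collapse = ""),
         "' at position(s) ", paste(bad, collapse = ", "))
  }
  res
}

#' Mean net charge of a protein sequence
#'
#' |#(K, R) - #(D, E)| / length, with histidine treated as neutral and
#' terminal charges ignored (the convention of charge-hydrophobicity plots).
#'
#' @param sequence Amino-acid string (20 standard one-letter codes).
#' @return Mean net charge R >= 0.
#' @export
mean_net_charge <- function(sequence) {
  res <- check_sequence(sequence)
  abs(sum(res %in% c("K", "R")) - sum(res %in% c("D", "E"))) / length(res)
}

#' Mean hydrophobicity of a protein sequence
#'
#' Kyte-Doolittle values rescaled to [0, 1] via (kd + 4.5)/9, averaged over a
#' sliding window of `window` residues and then over window positions (the
#' charge-hydrophobicity plot convention).
#'
#' @param sequence Amino-acid string.
#' @param window Sliding-window width (default 5).
#' @return Mean hydrophobicity H in [0, 1].
#' @export
mean_hydrophobicity <- function(sequence, window = 5) {
  res <- check_sequence(sequence)
  if (length(res) < window) {
    stop("sequence shorter than the ", window, "-residue window")
  }
  h <- (kyte_doolittle[res] + 4.5) / 9
  win_means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  mean(win_means, na.rm = TRUE)
}

#' Charge-hydrophobicity classification
#'
#' Places a protein in the mean-net-charge (R) vs mean-hydrophobicity (H)
#' plane relative to the empirical boundary R* = 2.785 H - 1.151 separating
#' natively unfolded from compact proteins. Points with R above the line fall
#' on the disordered side.
#'
#' @param R Mean net charge ([mean_net_charge()]).
#' @param H Mean hydrophobicity in [0, 1] ([mean_hydrophobicity()]).
#' @return List with `classification` (`"disordered-side"`, `"ordered-side"`
#'   or `"boundary"`), `boundary_R` (the line's R at this H), and `distance`
#'   (signed perpendicular distance, positive on the disordered side).
#' @export
uversky_classify <- function(R, H) {
  if (H < 0 || H > 1) stop("H must lie in [0, 1]")
  if (R < 0) stop("R must be non-negative")
  r_star <- 2.785 * H - 1.151
  dist <- (R - r_star) / sqrt(1 + 2.785^2)
  cls <- if (abs(R - r_star) < 1e-12) "boundary"
         else if (R > r_star) "disordered-side" else "ordered-side"
  list(classification = cls, boundary_R = r_star, distance = dist)
}

#' Full charge-hydrophobicity profile of a sequence
#'
#' @param sequence Amino-acid string.
#' @param window Hydrophobicity sliding-window width.
#' @return List with `R`, `H`, and the [uversky_classify()] result fields.
#' @export
sequence_profile <- function(sequence, window = 5) {
  R <- mean_net_charge(sequence)
  H <- mean_hydrophobicity(sequence, window)
  c(list(R = R, H = H), uversky_classify(R, H))
}

#' Fit a thermal-shift melt curve
#'
#' Truncates the fluorescence trace at its global maximum (fluorescence of
#' dye-protein complexes quenches after aggregation sets in past the
#' transition), normalizes to the maximum, and fits the four-parameter
#' logistic Y = Ymin + (Ymax - Ymin) / (1 + 10^((T_M - X) * b)) by nonlinear
#' least squares. `b > 0` (increasing sigmoid) is enforced by bound. With
#' replicates, the truncation point is taken from the mean curve and applied
#' identically to all replicates.
#'
#' @param temperature Temperatures (deg C), ascending.
#' @param fluorescence Fluorescence values (arbitrary units).
#' @param replicate Optional replicate id vector; the mean curve is fitted.
#' @return List of class `melt_fit` with `T_M` (deg C), `b` (1/deg C),
#'   `Ymin`, `Ymax` (normalized units), `truncation_temp`, residual norm.
#' @export
fit_melt_curve <- function(temperature, fluorescence, replicate = NULL) {
  if (!is.null(replicate)) {
    agg <- stats::aggregate(fluorescence,
                            by = list(temperature = temperature), FUN = mean)
    temperature <- agg$temperature
    fluorescence <- agg$x
  }
  ord <- order(temperature)
  temperature <- temperature[ord]; fluorescence <- fluorescence[ord]
  if (length(temperature) < 10) stop("need >= 10 points across the transition")

  imax <- which.max(fluorescence)
  trunc_T <- temperature[imax]
  x <- temperature[1:imax]
  y <- fluorescence[1:imax] / fluorescence[imax]
  if (length(x) < 10) stop("no sigmoidal transition detectable before the maximum")
  if (max(y) - min(y) < 0.05) {
    stop("no sigmoidal transition detectable (flat trace)")
  }

  # start values: midpoint crossing and a decade-per-10-degrees slope
  y_mid <- (min(y) + max(y)) / 2
  tm0 <- x[which(y >= y_mid)[1]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ymin + (ymax - ymin) / (1 + 10^((tm - x) * b)),
      start = list(ymin = min(y), ymax = max(y), tm = tm0, b = 0.1),
      lower = c(-Inf, -Inf, min(x), 1e-6),
      upper = c(Inf, Inf, max(x), 10),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf["ymax"] <= cf["ymin"]) stop("fit failure: inverted transition")
  structure(
    list(T_M = unname(cf["tm"]), b = unname(cf["b"]),
         Ymin = unname(cf["ymin"]), Ymax = unname(cf["ymax"]),
         truncation_temp = trunc_T,
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "melt_fit"
  )
}
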