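#' Indentation from base position, force and cantilever stiffness
#'
#' The indentation of the sample is the base travel past contact minus the
#' cantilever deflection: `h = (z - z_contact) - F / k_cant`, clipped at 0
#' before contact. With z in um, F in uN and k in N/m the deflection term
#' `F / k_cant` is already in um.
#'
#' @param curve A [force_record()] or [segmented_curve][segment_phases()];
#'   only the loading phase is used when segmented.
#' @param z_contact Contact position in um.
#' @return Numeric vector of indentations in um (same length as the
#'   loading phase).
#' @export
compute_indentation <- function(curve, z_contact) {
  seg <- as_segmented(curve)
  rec <- seg$record
  k <- rec$meta$k_cant
  if (is.null(k) || !is.finite(k) || k <= 0)
    stop_tenomech("configuration_error", "k_cant missing from record meta")
  i <- seg$load
  pmax((rec$z[i] - z_contact) - rec$F[i] / k, 0)
}

# Closed-form linear Hertz estimator on an indentation window.
# h um, F uN, R um; returns E (Pa), rmse (uN), n in-window points.
# E_hat = sum(F g) / sum(g^2) with g = (4/3) sqrt(R) h^1.5 (SI).
hertz_lsq <- function(h_um, F_uN, R_um, h_max = 1) {
  keep <- h_um >= 0 & h_um <= h_max
  n <- sum(keep)
  if (n < 10) return(NULL)
  g <- (4 / 3) * sqrt(R_um * .UM) * (h_um[keep] * .UM)^1.5   # m^2
  FN <- F_uN[keep] * .UN
  den <- sum(g^2)
  E <- if (den > 0) sum(FN * g) / den else 0
  rmse <- sqrt(mean((FN - E * g)^2)) / .UN
  list(E_eff = E, rmse = rmse, n_points = n, h_top = max(h_um[keep]),
       F_top = max(F_uN[keep]))
}

#' Fit the Hertzian spherical contact model over an indentation window
#'
#' Least-squares fit of `F = (4/3) * E_eff * sqrt(R_tip) * h^(3/2)` on the
#' samples with `0 <= h <= h_max`. The model is linear in `E_eff`, so the
#' estimator is closed form: `E_eff = sum(F g) / sum(g^2)` with
#' `g = (4/3) sqrt(R) h^(3/2)`. Curves whose deepest in-window indentation
#' falls short of `h_max` are fitted over the available range with a
#' warning when it reaches at least `0.8 * h_max`, and rejected below that.
#'
#' The Poisson-ratio term is absorbed into `E_eff` (the instrument
#' convention for an "effective" modulus); set `nu` to apply the
#' `1 / (1 - nu^2)` correction and report a true Young's modulus instead.
#'
#' @param h Indentation in um.
#' @param F Force in uN.
#' @param R_tip Tip (bead) radius in um.
#' @param h_max Fit window upper edge in um. Default 1.
#' @param z_contact Contact position to record in the result (um); optional.
#' @param nu Optional Poisson ratio; `NULL` (default) reports the
#'   effective modulus with no correction.
#' @return An object of class `hertz_fit`: `z_contact`, `E_eff` (Pa),
#'   `h_window` (um), `rmse` (uN), `n_points`.
#' @examples
#' rec <- simulate_elastic_curve(1300, probe_config())
#' h <- compute_indentation(rec, 5)
#' fit_hertz(h, rec$F, R_tip = 37.5)$E_eff
#' @export
fit_hertz <- function(h, F, R_tip, h_max = 1, z_contact = NA_real_,
                      nu = NULL) {
  if (!is.finite(R_tip) || R_tip <= 0)
    stop_tenomech("invalid_parameter", "R_tip must be positive")
  h_reach <- suppressWarnings(max(c(h[h <= h_max], 0)))
  fit <- hertz_lsq(h, F, R_tip, h_max)
  if (is.null(fit))
    stop_tenomech("insufficient_depth",
                  "fewer than 10 samples inside the %g um window", h_max)
  if (fit$h_top < 0.8 * h_max)
    stop_tenomech("insufficient_depth",
                  "maximum indentation %.2f um below 0.8 x window", fit$h_top)
  if (fit$h_top < 0.98 * h_max)
    warning(sprintf("fit window truncated at %.2f um (< %g um)",
                    fit$h_top, h_max), call. = FALSE)
  E <- fit$E_eff
  if (!is.null(nu)) E <- E / (1 - nu^2)
  structure(list(z_contact = z_contact, E_eff = E,
                 h_window = c(0, fit$h_top), rmse = fit$rmse,
                 n_points = fit$n_points),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E_eff %.4g Pa | contact %.3f um | window 0..%.2f um | rmse %.3g uN (n=%d)\n",
    x$E_eff, x$z_contact, x$h_window[2], x$rmse, x$n_points))
  invisible(x)
}

#' Detect the contact point of a loading curve
#'
#' Grid search over candidate contact positions along the loading phase,
#' each scored by the residual of the closed-form Hertz fit over the
#' `h_max` indentation window. For every candidate the pre-contact force
#' baseline (mean force at `z < z_contact`) is subtracted before
#' indentation and fit are computed. The candidate with the smallest
#' residual wins; ties break to the smallest contact position.
#'
#' @param curve A [force_record()] or segmented curve.
#' @param h_max Fit window in um. Default 1.
#' @param resolution Grid spacing in um. Default 0.01 (10 nm).
#' @return A `hertz_fit` whose `z_contact` is the detected contact point
#'   and whose `E_eff`/`rmse` are the fit achieved there.
#' @section Errors:
#' `no_contact` if the force never exceeds 3x the pre-contact noise sd;
#' `insufficient_depth` if no candidate reaches 0.8 x `h_max` of
#' indentation with at least 10 window samples.
#' @examples
#' rec <- simulate_elastic_curve(1300, probe_config())
#' detect_contact_point(rec)$z_contact
#' @export
detect_contact_point <- function(curve, h_max = 1, resolution = 0.01) {
  seg <- as_segmented(curve)
  rec <- seg$record
  k <- rec$meta$k_cant
  R <- rec$meta$R_tip
  i <- seg$load
  z <- rec$z[i]; F <- rec$F[i]

  n0 <- max(5L, min(20L, length(F) %/% 10))
  base0 <- mean(F[seq_len(n0)])
  noise_sd <- sd(F[seq_len(n0)])
  if (!(max(F - base0) > 3 * noise_sd))
    stop_tenomech("no_contact",
                  "force never exceeds 3x the baseline noise sd")

  cand <- seq(z[1], max(z) - 0.8 * h_max, by = resolution)
  if (!length(cand))
    stop_tenomech("insufficient_depth",
                  "loading range too short for a %g um window", h_max)
  best <- NULL
  depth_reached <- FALSE
  for (zc in cand) {
    pre <- z < zc
    base <- if (sum(pre) >= 5) mean(F[pre]) else base0
    Fc <- F - base
    h <- pmax((z - zc) - Fc / k, 0)
    fit <- hertz_lsq(h, Fc, R, h_max)
    if (is.null(fit) || fit$h_top < 0.8 * h_max) next
    depth_reached <- TRUE
    # a candidate whose window holds no force signal (pre-contact only)
    # would fit E = 0 with zero residual; require the fitted model
    # amplitude at the window top to rise above the noise floor
    Fhat_top <- fit$E_eff * (4 / 3) * sqrt(R * .UM) *
      (fit$h_top * .UM)^1.5 / .UN
    if (!(Fhat_top > 3 * noise_sd)) next
    if (is.null(best) || fit$rmse < best$rmse) {
      best <- fit; best$z_contact <- zc
    }
  }
  if (is.null(best)) {
    if (depth_reached)
      stop_tenomech("no_contact",
                    "no candidate fit rises above the noise floor")
    stop_tenomech("insufficient_depth",
                  "no candidate contact point reaches 0.8 x %g um", h_max)
  }
  structure(list(z_contact = best$z_contact, E_eff = best$E_eff,
                 h_window = c(0, best$h_top), rmse = best$rmse,
                 n_points = best$n_points),
            class = "hertz_fit")
}

#' Per-construct effective modulus
#'
#' Averages the effective Young's moduli of the (nominally five) indents
#' performed along one construct. A warning is raised when the number of
#' sites differs from five.
#'
#' @param fits List of `hertz_fit` objects, or a numeric vector of moduli
#'   in Pa.
#' @param construct_id Construct identifier.
#' @param day Culture day.
#' @return An object of class `construct_modulus` with `site_values`,
#'   `mean_E` (Pa), `construct_id`, `day`.
#' @examples
#' construct_modulus(c(1000, 2000, 3000, 4000, 5000), "c1", 0)$mean_E
#' @export
construct_modulus <- function(fits, construct_id = NA, day = NA) {
  values <- if (is.numeric(fits)) fits
            else vapply(fits, function(f) f$E_eff, numeric(1))
  if (!length(values))
    stop_tenomech("invalid_parameter", "no site values supplied")
  if (length(values) != 5L)
    warning(sprintf("construct %s: %d sites instead of 5",
                    construct_id, length(values)), call. = FALSE)
  structure(list(site_values = values, mean_E = mean(values),
                 construct_id = construct_id, day = day),
            class = "construct_modulus")
}

#' Empirical CDF of construct moduli with the plotting-position convention
#'
#' Sorted values are assigned probabilities `p_i = (i - 0.5) / n`, so the
#' middle value of an odd-sized sample sits exactly at CDF 0.5; the median
#' is read off at 0.5 (by linear interpolation between plotting positions
#' for even n).
#'
#' @param values Numeric vector of per-construct mean moduli (Pa), or a
#'   list of `construct_modulus` objects.
#' @return A list of class `modulus_cdf`: `value` (sorted), `p`, `median`.
#' @examples
#' modulus_cdf(c(2, 1, 3))$median      # 2
#' modulus_cdf(c(1, 2, 3, 4))$median   # 2.5
#' @export
modulus_cdf <- function(values) {
  if (is.list(values) && !is.numeric(values))
    values <- vapply(values, function(v) v$mean_E, numeric(1))
  if (!length(values))
    stop_tenomech("invalid_parameter", "no values supplied")
  v <- sort(values)
  n <- length(v)
  p <- (seq_len(n) - 0.5) / n
  med <- if (n == 1L) v
         else if (length(unique(v)) == 1L) v[1]
         else approx(p, v, xout = 0.5, rule = 2, ties = "ordered")$y
  structure(list(value = v, p = p, median = med), class = "modulus_cdf")
}

#' @export
print.modulus_cdf <- function(x, ...) {
  cat(sprintf("<modulus_cdf> n = %d, median = %.4g\n",
              length(x$value), x$median))
  invisible(x)
}

#' One-call indentation analysis of a curve
#'
#' Convenience wrapper: segments the record, detects the contact point and
#' returns the Hertz fit over the 1-um window.
#'
#' @inheritParams detect_contact_point
#' @return A `hertz_fit`.
#' @export
analyze_indent <- function(curve, h_max = 1, resolution = 0.01) {
  detect_contact_point(as_segmented(curve), h_max = h_max,
                       resolution = resolution)
}
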