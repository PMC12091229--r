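#' Indentation probe configuration
#'
#' Describes the spherical-tipped cantilever probe and acquisition settings
#' used to simulate (and interpret) indentation records. The defaults follow
#' the experimental protocol: a bead of 50-100 um diameter (tip radius
#' 25-50 um, default 37.5 um), the cantilever base driven at 10 um/s.
#' The cantilever stiffness is not reported by the instrument class's
#' typical publications at this softness; the default 0.5 N/m is a typical
#' value and is always recorded in the file header so the analysis never
#' assumes it.
#'
#' @param R_tip Sphere (bead) radius in um. Default 37.5.
#' @param k_cant Cantilever stiffness in N/m. Default 0.5.
#' @param speed Base displacement rate in um/s. Default 10.
#' @param rate Sampling frequency in Hz. Default 1000.
#' @param z_contact True contact position of the sample surface along the
#'   base-displacement axis, in um. Default 5.
#' @param noise_sd Force noise standard deviation in nN. Default 0 (noiseless).
#' @param seed Integer seed for the force noise; `NULL` leaves the global
#'   RNG untouched.
#'
#' @return An object of class `probe_config` (a named list).
#' @examples
#' probe_config(R_tip = 25, noise_sd = 1, seed = 7)
#' @export
probe_config <- function(R_tip = 37.5, k_cant = 0.5, speed = 10,
                         rate = 1000, z_contact = 5, noise_sd = 0,
                         seed = NULL) {
  num <- c(R_tip = R_tip, k_cant = k_cant, speed = speed, rate = rate,
           z_contact = z_contact)
  if (any(!is.finite(num)) || any(num <= 0))
    stop_tenomech("invalid_parameter",
                  "probe parameters must be positive and finite")
  if (noise_sd < 0)
    stop_tenomech("invalid_parameter", "noise_sd must be >= 0")
  structure(list(R_tip = R_tip, k_cant = k_cant, speed = speed,
                 rate = rate, z_contact = z_contact, noise_sd = noise_sd,
                 seed = seed),
            class = "probe_config")
}

#' Standard linear solid material
#'
#' Three-element viscoelastic model used to simulate stress relaxation of
#' the constructs: an instantaneous effective modulus `E0`, a long-time
#' modulus `E_inf` and a single relaxation time `tau`. The hold-phase force
#' of a rigid hold decays as `F(t) = F_max * (alpha + (1 - alpha) *
#' exp(-t / tau))` with `alpha = E_inf / E0`, so the 10-s relaxation
#' percentage is `100 * (1 - alpha) * (1 - exp(-10 / tau))`.
#'
#' @param E0 Instantaneous effective modulus in Pa.
#' @param E_inf Long-time effective modulus in Pa; `0 < E_inf <= E0`.
#' @param tau Relaxation time constant in s.
#'
#' @return An object of class `sls_material`.
#' @seealso [sls_for_relaxation()] to choose `alpha` for a target
#'   relaxation percentage.
#' @examples
#' sls_material(E0 = 2000, E_inf = 1300, tau = 2)
#' @export
sls_material <- function(E0, E_inf, tau) {
  if (!is.finite(E0) || E0 <= 0)
    stop_tenomech("invalid_parameter", "E0 must be positive")
  if (!is.finite(E_inf) || E_inf <= 0 || E_inf > E0)
    stop_tenomech("invalid_parameter", "E_inf must satisfy 0 < E_inf <= E0")
  if (!is.finite(tau) || tau <= 0)
    stop_tenomech("invalid_parameter", "tau must be positive")
  structure(list(E0 = E0, E_inf = E_inf, tau = tau, alpha = E_inf / E0),
            class = "sls_material")
}

#' Standard linear solid matching a target relaxation percentage
#'
#' Inverts the rigid-hold closed form
#' `100 * (1 - alpha) * (1 - exp(-t_eval / tau))` for `alpha`,
#' returning an [sls_material()]
#' whose analytic relaxation percentage at `t_eval` seconds equals
#' `r_target`.
#'
#' @param r_target Target relaxation percentage (0-100).
#' @param tau Relaxation time constant in s. Default 2.
#' @param E0 Instantaneous modulus in Pa. Default 2000.
#' @param t_eval Evaluation time in s. Default 10.
#' @return An `sls_material`.
#' @examples
#' m <- sls_for_relaxation(35)    # alpha ~ 0.648 at tau = 2
#' m$alpha
#' @export
sls_for_relaxation <- function(r_target, tau = 2, E0 = 2000, t_eval = 10) {
  decay <- 1 - exp(-t_eval / tau)
  alpha <- 1 - (r_target / 100) / decay
  if (alpha <= 0 || alpha > 1)
    stop_tenomech("invalid_parameter",
                  "relaxation target %.1f%% unreachable at tau = %g s",
                  r_target, tau)
  sls_material(E0 = E0, E_inf = alpha * E0, tau = tau)
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf(
    "<probe_config> R_tip %.3g um | k %.3g N/m | %.3g um/s @ %g Hz | contact %.3g um | noise %.3g nN\n",
    x$R_tip, x$k_cant, x$speed, x$rate, x$z_contact, x$noise_sd))
  invisible(x)
}

#' @export
print.sls_material <- function(x, ...) {
  cat(sprintf("<sls_material> E0 %.4g Pa | E_inf %.4g Pa (alpha %.3f) | tau %.3g s\n",
              x$E0, x$E_inf, x$alpha, x$tau))
  invisible(x)
}

# Hertz force in N for indentation h_m (m), modulus E (Pa), radius R_m (m).
# Prefactor convention: F = (4/3) * E_eff * sqrt(R) * h^(3/2), with the
# Poisson term absorbed into E_eff.
hertz_force <- function(E, R_m, h_m) {
  (4 / 3) * E * sqrt(R_m) * pmax(h_m, 0)^1.5
}
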