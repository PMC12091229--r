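# Newton solve of the compliance-coupled contact equation, vectorised over
# samples: find h >= 0 (um) with h + B * h^1.5 = d, where d = z - z_contact
# is the base travel past contact and B * h^1.5 is the cantilever
# deflection F/k expressed in um.
solve_indentation <- function(d_um, B) {
  h <- pmax(d_um, 0)
  if (B > 0) {
    for (i in 1:60) {
      f <- h + B * h^1.5 - d_um
      df <- 1 + 1.5 * B * sqrt(h)
      h_new <- pmax(h - f / df, 0)
      if (max(abs(h_new - h)) < 1e-13) { h <- h_new; break }
      h <- h_new
    }
  }
  pmax(h, 0)
}

#' Simulate a purely elastic spherical-indentation curve
#'
#' Generates the force record of a Hertzian indentation: the cantilever
#' base advances at constant speed; before contact the force is zero (plus
#' noise); past contact the force follows
#' `F = (4/3) * E_eff * sqrt(R_tip) * h^(3/2)` with the indentation `h`
#' solved self-consistently against the cantilever deflection,
#' `h = z - z_contact - F / k_cant`. Gaussian force noise of standard
#' deviation `noise_sd` (nN) is added when requested; identical seeds give
#' bit-identical records.
#'
#' @param E_eff Effective Young's modulus in Pa (Poisson term absorbed).
#' @param probe A [probe_config()].
#' @param max_depth Maximum indentation in um; must be >= 1 so the 1-um
#'   fit window is reachable. Default 2.
#' @param label Text label stored in the record metadata.
#' @return A [force_record()] whose metadata also carries the simulation
#'   ground truth (`E_true`, `z_contact`, `speed`, `noise_sd`).
#' @examples
#' rec <- simulate_elastic_curve(1300, probe_config())
#' max(rec$F)   # uN
#' @export
simulate_elastic_curve <- function(E_eff, probe, max_depth = 2,
                                   label = "elastic") {
  stopifnot(inherits(probe, "probe_config"))
  if (!is.finite(E_eff) || E_eff <= 0)
    stop_tenomech("invalid_parameter", "E_eff must be positive")
  if (max_depth < 1)
    stop_tenomech("invalid_parameter",
                  "max_depth must be >= 1 um (fit window)")
  R_m <- probe$R_tip * .UM
  A <- (4 / 3) * E_eff * sqrt(R_m)            # N per m^1.5
  B <- A * .UM^1.5 / probe$k_cant / .UM       # deflection um per h_um^1.5
  F_target <- hertz_force(E_eff, R_m, max_depth * .UM)
  z_end <- probe$z_contact + max_depth + F_target / probe$k_cant / .UM
  t <- seq(0, z_end / probe$speed, by = 1 / probe$rate)
  if (length(t) < 100)
    stop_tenomech("invalid_parameter",
                  "fewer than 100 samples; increase rate or depth")
  z <- probe$speed * t
  h <- solve_indentation(z - probe$z_contact, B)
  F <- A * (h * .UM)^1.5 / .UN                # uN
  if (probe$noise_sd > 0)
    F <- F + with_seed(probe$seed %||% stop_tenomech(
      "invalid_parameter", "noisy simulation requires a seed"),
      rnorm(length(F), 0, probe$noise_sd * 1e-3))
  meta <- list(k_cant = probe$k_cant, R_tip = probe$R_tip,
               rate = probe$rate, label = label,
               z_contact = probe$z_contact, speed = probe$speed,
               noise_sd = probe$noise_sd, E_true = E_eff)
  force_record(t, z, F, meta, phase = rep("load", length(t)))
}

#' Simulate a stress-relaxation record (ramp - hold - retract)
#'
#' Loads to `depth` um at the probe speed (elastic response at the
#' instantaneous modulus `E0`), holds for `hold_s` seconds, then retracts.
#' Two hold models are available:
#'
#' * `mode = "rigid"` (default): the tip position is frozen and the hold
#'   force follows the closed form
#'   `F(t) = F_max * (alpha + (1 - alpha) * exp(-t / tau))`,
#'   `alpha = E_inf / E0`. This is the analytically testable reference.
#' * `mode = "compliant"`: the *base* is frozen (open-loop hold, as in the
#'   experiment) and `h(t) = z - z_contact - F(t) / k_cant` is enforced by
#'   per-step fixed-point iteration against a standard-linear-solid
#'   hereditary force update, so the tip creeps forward as the force
#'   decays.
#'
#' @param mat An [sls_material()].
#' @param probe A [probe_config()].
#' @param hold_s Hold duration in s; default 10 (the evaluation time of
#'   the relaxation percentage).
#' @param depth Target indentation in um. Default 2.
#' @param mode `"rigid"` or `"compliant"`.
#' @param retract_s Unloading ramp duration in s (0 disables). Default 0.5.
#' @param label Text label stored in the metadata.
#' @return A [force_record()] with per-sample `phase` annotations
#'   (`load`/`hold`/`unload`) and the simulation ground truth in `meta`.
#' @examples
#' rec <- simulate_relaxation_record(sls_for_relaxation(35), probe_config())
#' relaxation_percentage(segment_phases(rec))$r_relax
#' @export
simulate_relaxation_record <- function(mat, probe, hold_s = 10, depth = 2,
                                       mode = c("rigid", "compliant"),
                                       retract_s = 0.5,
                                       label = "relaxation") {
  stopifnot(inherits(mat, "sls_material"), inherits(probe, "probe_config"))
  mode <- match.arg(mode)
  if (hold_s < 10)
    stop_tenomech("invalid_parameter", "hold_s must be >= 10 s")
  dt <- 1 / probe$rate
  R_m <- probe$R_tip * .UM
  alpha <- mat$alpha

  # Loading ramp: elastic at E0, compliance-coupled.
  A0 <- (4 / 3) * mat$E0 * sqrt(R_m)
  B0 <- A0 * .UM^1.5 / probe$k_cant / .UM
  F_target <- hertz_force(mat$E0, R_m, depth * .UM)
  z_hold <- probe$z_contact + depth + F_target / probe$k_cant / .UM
  t_ramp <- seq(0, z_hold / probe$speed, by = dt)
  z_ramp <- probe$speed * t_ramp
  h_ramp <- solve_indentation(z_ramp - probe$z_contact, B0)
  F_ramp <- A0 * (h_ramp * .UM)^1.5 / .UN
  n_ramp <- length(t_ramp)
  F_max <- F_ramp[n_ramp]
  h_max <- h_ramp[n_ramp]

  n_hold <- ceiling(hold_s / dt)
  t_hold <- t_ramp[n_ramp] + dt * seq_len(n_hold)
  z_hold_v <- rep(z_ramp[n_ramp], n_hold)
  if (mode == "rigid") {
    F_hold <- F_max * (alpha + (1 - alpha) * exp(-(t_hold - t_ramp[n_ramp]) / mat$tau))
    h_hold <- rep(h_max, n_hold)
  } else {
    # SLS hereditary update on g(h) = (4/3) sqrt(R) h^1.5, base frozen.
    g <- function(h_um) (4 / 3) * sqrt(R_m) * (h_um * .UM)^1.5
    decay <- exp(-dt / mat$tau)
    half <- exp(-dt / (2 * mat$tau))
    Q <- (mat$E0 - mat$E_inf) * g(h_max)   # Maxwell-arm force at ramp end
    # (ramp treated as fast relative to tau: instantaneous response at E0)
    h_prev <- h_max
    F_hold <- numeric(n_hold); h_hold <- numeric(n_hold)
    d_um <- z_ramp[n_ramp] - probe$z_contact
    for (i in seq_len(n_hold)) {
      h_i <- h_prev
      for (it in 1:80) {
        Q_i <- Q * decay + (mat$E0 - mat$E_inf) * half * (g(h_i) - g(h_prev))
        F_i <- mat$E_inf * g(h_i) + Q_i
        h_new <- max(d_um - (F_i / probe$k_cant) / .UM, 0)
        if (abs(h_new - h_i) < 1e-12) { h_i <- h_new; break }
        h_i <- h_new
      }
      Q <- Q * decay + (mat$E0 - mat$E_inf) * half * (g(h_i) - g(h_prev))
      F_hold[i] <- (mat$E_inf * g(h_i) + Q) / .UN
      h_hold[i] <- h_i
      h_prev <- h_i
    }
  }

  t <- c(t_ramp, t_hold)
  z <- c(z_ramp, z_hold_v)
  F <- c(F_ramp, F_hold)
  phase <- c(rep("load", n_ramp), rep("hold", n_hold))

  if (retract_s > 0) {
    n_un <- max(4L, ceiling(retract_s / dt))
    t_un <- t_hold[n_hold] + dt * seq_len(n_un)
    z_un <- z_hold_v[n_hold] - probe$speed * dt * seq_len(n_un)
    # schematic unload: force falls with the long-time elastic response
    h_un <- pmax(h_max - probe$speed * dt * seq_len(n_un), 0)
    F_end <- F[length(F)]
    F_un <- F_end * (h_un / h_max)^1.5
    t <- c(t, t_un); z <- c(z, z_un); F <- c(F, F_un)
    phase <- c(phase, rep("unload", n_un))
  }

  if (probe$noise_sd > 0)
    F <- F + with_seed(probe$seed %||% stop_tenomech(
      "invalid_parameter", "noisy simulation requires a seed"),
      rnorm(length(F), 0, probe$noise_sd * 1e-3))

  meta <- list(k_cant = probe$k_cant, R_tip = probe$R_tip,
               rate = probe$rate, label = label,
               z_contact = probe$z_contact, speed = probe$speed,
               noise_sd = probe$noise_sd,
               E0 = mat$E0, E_inf = mat$E_inf, tau = mat$tau,
               alpha = alpha)
  force_record(t, z, F, meta, phase = phase)
}
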