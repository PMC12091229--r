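#' Stress-relaxation percentage over a hold
#'
#' Computes the relaxation statistic
#' `r_relax = 100 * (F_max - F_t) / F_max`,
#' where `F_max` is the peak force at the end of the indentation ramp
#' (maximum within `onset_window` seconds of the hold onset) and `F_t` the
#' force read at exactly `t_eval` seconds after hold onset, by linear
#' interpolation on the hold samples. A higher percentage indicates more
#' liquid-like behaviour; a smaller one more solid, elastic-like
#' behaviour. Negative values (force creeping upward) are reported with a
#' warning, never clipped.
#'
#' @param curve A [force_record()] or [segmented_curve][segment_phases()]
#'   with a hold phase at least `t_eval` long.
#' @param t_eval Evaluation time after hold onset in s. Default 10.
#' @param onset_window Half-width of the peak-force search window around
#'   the hold onset, in s. Default 0.1.
#' @param smooth_window Optional averaging half-width (s) applied around
#'   `t_eval` for noisy data; 0 (default) reads the interpolated
#'   instantaneous value.
#' @return An object of class `relaxation_stat`: `F_max` (uN), `F_10s`
#'   (uN), `r_relax` (percent), `hold_duration` (s).
#' @examples
#' rec <- simulate_relaxation_record(sls_for_relaxation(35), probe_config())
#' relaxation_percentage(rec)$r_relax
#' @export
relaxation_percentage <- function(curve, t_eval = 10, onset_window = 0.1,
                                  smooth_window = 0) {
  seg <- as_segmented(curve)
  rec <- seg$record
  if (!length(seg$hold))
    stop_tenomech("insufficient_hold", "record has no hold phase")
  t <- rec$t; F <- rec$F
  th <- t[seg$hold]; Fh <- F[seg$hold]
  t0 <- th[1]
  dt <- median(diff(th))
  hold_dur <- th[length(th)] - t0
  if (hold_dur < t_eval - 2 * dt)
    stop_tenomech("insufficient_hold",
                  "hold lasts %.2f s, shorter than t_eval = %g s",
                  hold_dur, t_eval)

  peak_win <- abs(t - t0) <= onset_window
  F_max <- max(F[peak_win])
  if (!is.finite(F_max) || F_max <= 0)
    stop_tenomech("no_contact", "peak force at hold onset is not positive")

  t_target <- min(t0 + t_eval, th[length(th)])
  F_t <- if (smooth_window > 0) {
    mean(Fh[abs(th - t_target) <= smooth_window])
  } else {
    approx(th, Fh, xout = t_target, rule = 2)$y
  }
  r <- 100 * (F_max - F_t) / F_max
  if (r < 0)
    warning(sprintf("negative relaxation (%.2f%%): force rose during hold", r),
            call. = FALSE)
  structure(list(F_max = F_max, F_10s = F_t, r_relax = r,
                 hold_duration = hold_dur),
            class = "relaxation_stat")
}

#' @export
print.relaxation_stat <- function(x, ...) {
  cat(sprintf(
    "<relaxation_stat> F_max %.4g uN -> F_t %.4g uN over %.3g s hold: r_relax %.2f%%\n",
    x$F_max, x$F_10s, x$hold_duration, x$r_relax))
  invisible(x)
}

#' Recover standard-linear-solid parameters from a hold phase
#'
#' Nonlinear least-squares fit of
#' `F(t) = F_max * (alpha + (1 - alpha) * exp(-t / tau))`
#' to the hold-phase force, validating the relaxation simulator. A hold
#' that does not decay is flagged degenerate: `alpha = 1`, `tau = NA`.
#'
#' @param curve A record or segmented curve with a hold phase.
#' @return A list of class `sls_fit`: `alpha` (the implied
#'   `E_inf / E0`), `tau` (s), `F_max` (uN), `degenerate` flag.
#' @examples
#' rec <- simulate_relaxation_record(sls_material(2000, 1300, 2),
#'                                   probe_config())
#' fit_sls_inverse(rec)$alpha      # ~0.65
#' @export
fit_sls_inverse <- function(curve) {
  seg <- as_segmented(curve)
  if (!length(seg$hold))
    stop_tenomech("insufficient_hold", "record has no hold phase")
  th <- seg$record$t[seg$hold]
  Fh <- seg$record$F[seg$hold]
  tt <- th - th[1]
  F0 <- Fh[1]; F_end <- mean(tail(Fh, max(3L, length(Fh) %/% 20)))
  drop <- (F0 - F_end) / F0
  if (!is.finite(drop) || drop < 1e-4) {
    warning("hold force does not decay; degenerate fit with alpha = 1",
            call. = FALSE)
    return(structure(list(alpha = 1, tau = NA_real_, F_max = F0,
                          degenerate = TRUE), class = "sls_fit"))
  }
  a0 <- max(min(F_end / F0, 0.99), 0.01)
  # crude tau start: time to cover half the decay
  half_level <- F0 * (a0 + (1 - a0) / 2)
  t_half <- tt[which(Fh <= half_level)[1]]
  tau0 <- if (is.finite(t_half) && t_half > 0) t_half / log(2) else max(tt) / 5
  dat <- data.frame(tt = tt, Fh = Fh)
  fit <- minpack.lm::nlsLM(
    Fh ~ Fm * (a + (1 - a) * exp(-tt / tau)), data = dat,
    start = list(Fm = F0, a = a0, tau = tau0),
    lower = c(Fm = 0, a = 0, tau = 1e-6),
    upper = c(Fm = Inf, a = 1, tau = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(alpha = unname(cf["a"]), tau = unname(cf["tau"]),
                 F_max = unname(cf["Fm"]), degenerate = FALSE),
            class = "sls_fit")
}

#' Per-construct relaxation statistic
#'
#' Mean of the site-level relaxation percentages of one construct, the
#' same five-site aggregation contract as [construct_modulus()].
#'
#' @param stats List of `relaxation_stat` objects or numeric percentages.
#' @param construct_id,day Identifiers carried through.
#' @return A list with `site_values`, `mean_r`, `construct_id`, `day`.
#' @export
construct_relaxation <- function(stats, construct_id = NA, day = NA) {
  values <- if (is.numeric(stats)) stats
            else vapply(stats, function(s) s$r_relax, numeric(1))
  if (!length(values))
    stop_tenomech("invalid_parameter", "no site values supplied")
  if (length(values) != 5L)
    warning(sprintf("construct %s: %d sites instead of 5",
                    construct_id, length(values)), call. = FALSE)
  list(site_values = values, mean_r = mean(values),
       construct_id = construct_id, day = day)
}
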