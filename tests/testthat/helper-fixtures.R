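# Shared fixtures for the test suite. Everything is generated in code;
# small sampling rates keep individual records above the 100-sample floor
# while staying fast.

noiseless_probe <- function(...) {
  probe_config(R_tip = 37.5, k_cant = 0.5, speed = 10, rate = 1000,
               z_contact = 5, noise_sd = 0, ...)
}

# Full enumeration oracle for the two-sided Mann-Whitney test:
# p = P(min(U_A, U_B) <= observed) over all C(N, nA) group labelings.
mw_enumerate <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_min <- function(idx) {
    ua <- sum(r[idx]) - na * (na + 1) / 2
    min(ua, na * nb - ua)
  }
  u_obs <- u_min(seq_len(na))
  labelings <- utils::combn(na + nb, na)
  u_all <- apply(labelings, 2, u_min)
  mean(u_all <= u_obs)
}

# Analytic rigid-hold relaxation percentage of an SLS material.
sls_relax_pct <- function(alpha, tau, t_eval = 10) {
  100 * (1 - alpha) * (1 - exp(-t_eval / tau))
}
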