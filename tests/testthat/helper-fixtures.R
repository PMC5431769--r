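# shared fixtures: small, fast configurations used across test files

default_reg <- function(...) regulation_params(...)

# a mini-ensemble configuration at the published trap conditions
mini_cfg <- function(pca = 5, duration_s = 10)
  trap_config(k_trap = 0.038, n_motors = 14, atp_uM = 100, pca = pca,
              duration_s = duration_s)

# clean (noise-free) trace with rectangular pulses, for detector arithmetic
pulse_trace <- function(disp_nm, dur_ms, t_start_s = 1, duration_s = 3,
                        sample_hz = 4000, k_trap = 0.04) {
  t <- seq_len(duration_s * sample_hz) / sample_hz
  x <- numeric(length(t))
  for (i in seq_along(disp_nm)) {
    idx <- t >= t_start_s[i] & t < t_start_s[i] + dur_ms[i] / 1000
    x[idx] <- disp_nm[i]
  }
  structure(data.frame(t_s = t, x_nm = x, f_pN = k_trap * x),
            class = c("trap_trace", "data.frame"))
}

# analytic steady state of the 3-state cycle (detached -> bound_ADP ->
# rigor -> detached): stationary distribution pi with pi Q = 0, sum(pi) = 1
cycle_steady_state <- function(k_attach, k_adp_rate, k_det) {
  Q <- rbind(c(-k_attach, k_attach, 0),
             c(0, -k_adp_rate, k_adp_rate),
             c(k_det, 0, -k_det))
  A <- rbind(t(Q)[1:2, ], rep(1, 3))
  solve(A, c(0, 0, 1))
}
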