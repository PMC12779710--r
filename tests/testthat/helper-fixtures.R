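# Small network and trial fixtures built in code.

tiny_config <- function(..., seed = 1L) {
  network_config(n_e = 8L, n_i = 2L, n_channels = 4L,
                 p_ee = 0.5, p_ei = 0.5, p_ie = 0.5, p_ii = 0.5,
                 i_scale = 2, input_frac = 0.5, seed = seed, ...)
}

tiny_profile <- function() {
  channel_profile(baseline = 0.2, delta = c(0.05, 0.04, -0.05, -0.04),
                  cv = 0.3)
}

tiny_trial <- function(T_len = 136L, ...) {
  make_trial(tiny_profile(), T_len = T_len, block_len = 68L,
             change_window = c(30L, 100L), ...)
}

# hand-rolled scalar ALIF iteration, independent of the package internals;
# used as the oracle for the step/simulate recurrences
scalar_alif_oracle <- function(I_seq, params = alif_params()) {
  alpha <- exp(-params$dt / params$tau_m)
  rho <- exp(-params$dt / params$tau_a)
  v <- params$E_m
  a <- 0
  refrac <- 0L
  spikes <- integer(length(I_seq))
  for (t in seq_along(I_seq)) {
    z_prev <- if (t == 1L) 0 else spikes[t - 1L]
    v <- params$E_m + alpha * (v - params$E_m) + I_seq[t] -
      z_prev * (params$v_th - params$E_m)
    a_thr <- rho * a + z_prev
    A <- params$v_th + params$beta * a_thr
    if (refrac > 0L) {
      spikes[t] <- 0L
      refrac <- refrac - 1L
    } else if (v > A) {
      spikes[t] <- 1L
      refrac <- params$t_refrac
    }
    a <- a_thr
  }
  spikes
}
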