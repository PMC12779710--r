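#' ALIF neuron and simulation constants
#'
#' All constants of the adaptive leaky integrate-and-fire unit and of the
#' discrete-time simulation. The decay factors `alpha = exp(-dt/tau_m)` and
#' `rho = exp(-dt/tau_a)` are always recomputed from the stored fields, never
#' cached, so editing a time constant cannot leave a stale decay behind.
#'
#' The printed membrane recurrence is implemented in leak-to-rest form,
#' `v' = E_m + alpha (v - E_m) + I - z_prev (v_th - E_m)`, which is the only
#' reading consistent with the resting potential (-70.6 mV), threshold
#' (-50.4 mV) and initialisation (-65 mV) all being negative voltages;
#' `leak_to_rest = FALSE` switches to the literal decay-toward-zero form for
#' comparison. The pseudo-derivative is normalised by
#' `v_eff = |v_th - E_m| = 20.2 mV` by default (`pd_norm = "gap"`); with
#' `pd_norm = "vth"` it uses `|v_th|` instead.
#'
#' @param E_m resting potential (mV).
#' @param v_th baseline spike threshold (mV); must exceed `E_m`.
#' @param tau_m,tau_a membrane / adaptation time constants (ms).
#' @param beta adaptation coupling: threshold is `v_th + beta * a` (mV per
#'   unit of the dimensionless trace `a`).
#' @param gamma_pd pseudo-derivative amplitude.
#' @param dt time step (ms).
#' @param t_refrac refractory period (ms); spikes are forced to 0 for
#'   `t_refrac` steps after each spike.
#' @param v_init_mean,v_init_sd normal initialisation of membrane potentials.
#' @param leak_to_rest leak toward `E_m` (default) or toward 0 mV.
#' @param pd_norm normalising voltage of the pseudo-derivative.
#' @return An object of class `alif_params`.
#' @export
alif_params <- function(E_m = -70.6, v_th = -50.4, tau_m = 20, tau_a = 100,
                        beta = 0.16, gamma_pd = 0.3, dt = 1, t_refrac = 4L,
                        v_init_mean = -65, v_init_sd = 5,
                        leak_to_rest = TRUE, pd_norm = c("gap", "vth")) {
  pd_norm <- match.arg(pd_norm)
  stopifnot(v_th > E_m, dt > 0, t_refrac >= 0, tau_m > 0, tau_a > 0)
  structure(list(E_m = E_m, v_th = v_th, tau_m = tau_m, tau_a = tau_a,
                 beta = beta, gamma_pd = gamma_pd, dt = dt,
                 t_refrac = as.integer(t_refrac),
                 v_init_mean = v_init_mean, v_init_sd = v_init_sd,
                 leak_to_rest = isTRUE(leak_to_rest), pd_norm = pd_norm),
            class = "alif_params")
}

#' @rdname alif_params
#' @param params an `alif_params` object.
#' @export
alif_alpha <- function(params) exp(-params$dt / params$tau_m)

#' @rdname alif_params
#' @export
alif_rho <- function(params) exp(-params$dt / params$tau_a)

#' @rdname alif_params
#' @export
alif_v_eff <- function(params) {
  if (params$pd_norm == "gap") abs(params$v_th - params$E_m)
  else abs(params$v_th)
}

# flat list handed to the compiled core; decays derived here, on every call
cpp_pars <- function(params) {
  list(E_m = params$E_m, v_th = params$v_th,
       alpha = alif_alpha(params), rho = alif_rho(params),
       beta = params$beta, gamma_pd = params$gamma_pd,
       v_eff = alif_v_eff(params), t_refrac = params$t_refrac,
       leak_to_rest = params$leak_to_rest)
}

#' Initial neuron state
#'
#' @param n number of units.
#' @param params an [alif_params()].
#' @param v optional membrane potentials; drawn from
#'   `Normal(v_init_mean, v_init_sd)` when missing.
#' @return A list with `v`, adaptation trace `a` (zeros), and
#'   `refrac_count` (zeros).
#' @export
alif_state <- function(n, params, v = NULL) {
  if (is.null(v)) v <- rnorm(n, params$v_init_mean, params$v_init_sd)
  list(v = v, a = numeric(n), refrac_count = integer(n))
}

#' One simulation step (reference implementation)
#'
#' Advances the network by one time step. The membrane integrates leak,
#' recurrent input from the previous step's spikes, external input spikes,
#' and the post-spike reset `-(v_th - E_m)`. The adaptive threshold at this
#' step is `v_th + beta * (rho * a + z_prev)`; a unit spikes when its new
#' potential strictly exceeds it, unless refractory. Spiking reloads the
#' refractory counter and increments the adaptation trace.
#'
#' This pure-R step is the readable reference; [simulate_trial()] runs the
#' identical recurrence in compiled code.
#'
#' @param state list with `v`, `a`, `refrac_count` (see [alif_state()]).
#' @param z_prev spike vector from the previous step.
#' @param x_t input-channel spike vector at this step.
#' @param weights a `weight_set` (uses `W_rec`, `W_in`).
#' @param params an [alif_params()].
#' @return `list(state = <new state>, z = <spike vector>)`.
#' @export
alif_step <- function(state, z_prev, x_t, weights, params) {
  alpha <- alif_alpha(params)
  rho <- alif_rho(params)
  I <- drop(crossprod(weights$W_rec, z_prev))
  if (!is.null(weights$W_in)) I <- I + drop(crossprod(weights$W_in, x_t))
  v <- if (params$leak_to_rest) {
    params$E_m + alpha * (state$v - params$E_m) + I -
      z_prev * (params$v_th - params$E_m)
  } else {
    alpha * state$v + I - z_prev * (params$v_th - params$E_m)
  }
  if (any(!is.finite(v)))
    stop("non-finite membrane potential at unit(s) ",
         paste(which(!is.finite(v)), collapse = ", "))
  a_thr <- rho * state$a + z_prev
  A <- params$v_th + params$beta * a_thr
  refractory <- state$refrac_count > 0L
  z <- as.numeric(v > A)
  z[refractory] <- 0
  refrac <- pmax(state$refrac_count - 1L, 0L)
  refrac[z == 1] <- params$t_refrac
  list(state = list(v = v, a = a_thr, refrac_count = refrac), z = z, A = A)
}

#' Simulate one trial
#'
#' Initialises membrane potentials from `Normal(v_init_mean, v_init_sd)`
#' (adaptation and refractory counters at zero) and iterates the ALIF
#' recurrence for `ncol(input_spikes)` steps in compiled code, returning the
#' full spike raster and the linear readout series.
#'
#' @param weights a complete `weight_set`.
#' @param input_spikes channels x T binary matrix.
#' @param params an [alif_params()].
#' @param v_init optional vector of initial potentials (for reproducibility
#'   or oracle comparisons); drawn from the ambient RNG when missing.
#' @param record_state also return membrane potentials and thresholds.
#' @return `list(z = units x T raster, y = outputs x T readout,
#'   rate = mean population rate in spikes/ms, ...)`.
#' @export
simulate_trial <- function(weights, input_spikes, params = alif_params(),
                           v_init = NULL, record_state = FALSE) {
  stopifnot(inherits(weights, "weight_set"), ncol(input_spikes) > 0)
  n <- length(weights$sign)
  if (nrow(input_spikes) != nrow(weights$W_in))
    stop("input_spikes rows must match the number of channels")
  if (is.null(v_init)) v_init <- rnorm(n, params$v_init_mean, params$v_init_sd)
  out <- .cpp_simulate(weights$W_in, weights$W_rec, weights$W_out,
                       input_spikes, v_init, cpp_pars(params),
                       FALSE, record_state)
  if (any(!is.finite(out$y)))
    stop("non-finite readout encountered during simulation")
  out$v_init <- v_init
  class(out) <- "snn_sim"
  out
}

#' Linear readout of a spike raster
#'
#' Per-millisecond weighted sum of spikes for each output unit; there is no
#' output nonlinearity. For a one-hot (two-column) readout the predicted
#' label at each step is the argmax over the two series.
#'
#' @param raster units x T binary spike matrix.
#' @param W_out units x outputs weight matrix.
#' @param encoding `"single"` or `"one_hot"`; must match `ncol(W_out)`.
#' @return outputs x T matrix; for one-hot, the per-ms predicted label is
#'   attached as attribute `"label"`.
#' @export
readout <- function(raster, W_out, encoding = c("single", "one_hot")) {
  encoding <- match.arg(encoding)
  K <- if (encoding == "one_hot") 2L else 1L
  if (ncol(W_out) != K)
    stop("encoding '", encoding, "' needs ", K, " output column(s), got ",
         ncol(W_out))
  if (nrow(raster) != nrow(W_out))
    stop("raster rows must match output weight rows")
  y <- crossprod(W_out, raster)
  if (encoding == "one_hot")
    attr(y, "label") <- as.integer(y[2L, ] > y[1L, ])
  y
}
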