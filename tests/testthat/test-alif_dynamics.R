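params_default <- alif_params()

one_unit_weights <- function(w_in = 2) {
  cfg <- network_config(n_e = 1L, n_i = 0L, n_channels = 1L,
                        p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0)
  structure(list(W_rec = matrix(0, 1, 1), mask_rec = matrix(FALSE, 1, 1),
                 sign = 1L, is_e = TRUE, config = cfg,
                 W_in = matrix(w_in, 1, 1), mask_in = matrix(w_in != 0, 1, 1),
                 W_out = matrix(0, 1, 1), mask_out = matrix(FALSE, 1, 1),
                 input_pool = TRUE, output_pool = FALSE,
                 receives_input = w_in != 0, ee_blocked = FALSE),
            class = "weight_set")
}

test_that("resting potential with no input is a fixed point", {
  ws <- one_unit_weights(0)
  st <- alif_state(1, params_default, v = params_default$E_m)
  for (t in 1:20) {
    out <- alif_step(st, 0, 0, ws, params_default)
    st <- out$state
    expect_identical(out$z, 0)
    expect_equal(st$v, params_default$E_m)
  }
})

test_that("membrane decays toward rest by exactly alpha per step", {
  ws <- one_unit_weights(0)
  v0 <- -55
  st <- alif_state(1, params_default, v = v0)
  alpha <- alif_alpha(params_default)
  for (t in 1:10) {
    st <- alif_step(st, 0, 0, ws, params_default)$state
    expect_equal(st$v - params_default$E_m,
                 alpha^t * (v0 - params_default$E_m), tolerance = 1e-12)
  }
})

test_that("constant drive reproduces the scalar brute-force spike times", {
  # 2 mV per step from rest: first spike when the integrated drive crosses
  # the threshold gap, then reset/refractory shape the ISI pattern
  T_len <- 300L
  oracle <- scalar_alif_oracle(rep(2, T_len), params_default)
  expect_gt(sum(oracle), 0)
  ws <- one_unit_weights(2)
  x <- matrix(1, 1, T_len)
  sim <- simulate_trial(ws, x, params_default, v_init = params_default$E_m)
  expect_equal(drop(sim$z), as.numeric(oracle))
  # and the pure-R step agrees, step by step
  st <- alif_state(1, params_default, v = params_default$E_m)
  z_prev <- 0
  for (t in seq_len(50)) {
    out <- alif_step(st, z_prev, 1, ws, params_default)
    st <- out$state
    z_prev <- out$z
    expect_equal(out$z, as.numeric(oracle[t]))
  }
})

test_that("spikes are forced to zero through the refractory period", {
  set.seed(31)
  ws <- one_unit_weights(5)
  x <- matrix(1, 1, 400)
  sim <- simulate_trial(ws, x, params_default,
                        v_init = params_default$E_m)
  times <- which(drop(sim$z) == 1)
  expect_gt(length(times), 2)
  expect_true(all(diff(times) > params_default$t_refrac))
})

test_that("two-neuron relay matches a hand-iterated recurrence", {
  # unit 1 driven to spike; a strong synapse onto unit 2 makes it follow
  cfg <- network_config(n_e = 2L, n_i = 0L, n_channels = 1L,
                        p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0)
  W_rec <- matrix(c(0, 25, 0, 0), 2, 2, byrow = TRUE)  # 1 -> 2 at 25 mV
  ws <- structure(list(W_rec = W_rec, mask_rec = W_rec != 0,
                       sign = c(1L, 1L), is_e = c(TRUE, TRUE), config = cfg,
                       W_in = matrix(c(25, 0), 1, 2),
                       mask_in = matrix(c(TRUE, FALSE), 1, 2),
                       W_out = matrix(0, 2, 1),
                       mask_out = matrix(FALSE, 2, 1),
                       input_pool = c(TRUE, FALSE),
                       output_pool = c(FALSE, TRUE),
                       receives_input = c(TRUE, FALSE), ee_blocked = FALSE),
                  class = "weight_set")
  x <- matrix(0, 1, 30)
  x[1, c(3, 15)] <- 1   # two input spikes, 25 mV each: immediate spikes
  sim <- simulate_trial(ws, x, params_default,
                        v_init = c(params_default$E_m, params_default$E_m))
  # hand iteration: unit 1 spikes at 3 and 15; unit 2 receives 25 mV one
  # step later and spikes at 4 and 16
  expect_equal(which(sim$z[1, ] == 1), c(3L, 15L))
  expect_equal(which(sim$z[2, ] == 1), c(4L, 16L))
})

test_that("a silent network stays silent", {
  cfg <- tiny_config(seed = 8)
  ws <- build_network(cfg)
  ws$W_in[] <- 0; ws$mask_in[] <- FALSE
  x <- matrix(0, cfg$n_channels, 200)
  sim <- simulate_trial(ws, x, params_default,
                        v_init = rep(params_default$E_m, 10))
  expect_equal(sum(sim$z), 0)
  expect_true(all(sim$y == 0))
})

test_that("adaptation raises the threshold and decays geometrically", {
  ws <- one_unit_weights(3)
  x <- matrix(1, 1, 200)
  sim <- simulate_trial(ws, x, params_default,
                        v_init = params_default$E_m, record_state = TRUE)
  expect_true(all(sim$A >= params_default$v_th))
  # between spikes the threshold excess decays by rho each step
  rho <- alif_rho(params_default)
  z <- drop(sim$z)
  A <- drop(sim$A)
  quiet <- which(z == 0)[-1]
  quiet <- quiet[z[quiet - 1] == 0 & quiet > 10]
  excess <- A - params_default$v_th
  expect_equal(excess[quiet], rho * excess[quiet - 1], tolerance = 1e-10)
})

test_that("every simulated raster respects the refractory invariant", {
  set.seed(41)
  ws <- build_network(tiny_config(seed = 41))
  ws$W_in <- ws$W_in * 40   # force vigorous spiking
  tr <- tiny_trial()
  sim <- simulate_trial(ws, tr$spikes, params_default)
  expect_gt(sum(sim$z), 10)
  for (i in seq_len(nrow(sim$z))) {
    times <- which(sim$z[i, ] == 1)
    if (length(times) > 1)
      expect_true(all(diff(times) > params_default$t_refrac))
  }
})

test_that("readout is a per-ms weighted sum and is linear", {
  raster <- matrix(0, 3, 6)
  raster[1, 3] <- 1
  W_out <- matrix(c(0.5, 0, 0), 3, 1)
  y <- readout(raster, W_out)
  expect_equal(drop(y), c(0, 0, 0.5, 0, 0, 0))
  # all-zero output weights give an identically zero series
  expect_true(all(readout(raster, matrix(0, 3, 1)) == 0))
  # additivity over rasters disjoint in time
  r2 <- matrix(0, 3, 6); r2[2, 5] <- 1
  W <- matrix(c(0.5, -1, 2), 3, 1)
  expect_equal(readout(raster + r2, W),
               readout(raster, W) + readout(r2, W))
})

test_that("one-hot readout decodes the argmax label", {
  raster <- matrix(0, 2, 4)
  raster[1, 1:2] <- 1
  raster[2, 3:4] <- 1
  W_out <- matrix(c(1, 0, 0, 1), 2, 2)
  y <- readout(raster, W_out, "one_hot")
  expect_equal(attr(y, "label"), c(0L, 0L, 1L, 1L))
  expect_error(readout(raster, W_out, "single"), "output column")
})

test_that("compiled and pure-R recurrences agree on a random network", {
  set.seed(55)
  ws <- build_network(tiny_config(seed = 55))
  ws$W_in <- ws$W_in * 30
  x <- matrix(rbinom(4 * 100, 1, 0.3), 4, 100)
  v0 <- rnorm(10, -60, 4)
  sim <- simulate_trial(ws, x, params_default, v_init = v0)
  st <- alif_state(10, params_default, v = v0)
  z_prev <- numeric(10)
  for (t in 1:100) {
    out <- alif_step(st, z_prev, x[, t], ws, params_default)
    st <- out$state
    z_prev <- out$z
    expect_equal(out$z, unname(sim$z[, t]))
  }
})
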