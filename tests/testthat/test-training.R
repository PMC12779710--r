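test_that("task loss is the mean squared readout-target deviation", {
  y <- rbind(rep(0.5, 10))
  expect_equal(task_loss(y, y), 0)
  expect_equal(task_loss(rbind(rep(0, 10)), rbind(rep(1, 10))), 1)
  expect_equal(task_loss(rbind(c(1, 0)), rbind(c(0, 0))), 0.5)
  # one-hot averages over both output rows
  expect_equal(task_loss(matrix(0, 2, 4), matrix(c(1, 0), 2, 4)), 0.5)
  expect_error(task_loss(rbind(1:3), rbind(1:4)), "dimensions")
})

test_that("rate loss is the squared deviation from the target rate", {
  r <- matrix(0, 10, 100)
  r[, 1:2] <- 1   # 20 of 1000 slots -> 0.020 spikes/ms
  expect_equal(rate_loss(r, 0.020), 0)
  r2 <- matrix(0, 10, 100)
  r2[, 1:3] <- 1  # 0.030 spikes/ms
  expect_equal(rate_loss(r2, 0.020), 1e-4)
})

test_that("pseudo-derivative has the stated peak, hinge, and refractory zero", {
  p <- alif_params()
  v_eff <- alif_v_eff(p)
  expect_equal(v_eff, abs(p$v_th - p$E_m))
  expect_equal(pseudo_derivative(-50.4, -50.4, 0, p), p$gamma_pd / v_eff)
  # support ends exactly one normalising voltage away from threshold
  expect_equal(pseudo_derivative(-50.4 + v_eff, -50.4, 0, p), 0)
  expect_equal(pseudo_derivative(-50.4 - v_eff - 1, -50.4, 0, p), 0)
  expect_equal(pseudo_derivative(-50.4, -50.4, 3, p), 0)
  # halfway down the hinge
  expect_equal(pseudo_derivative(-50.4 - v_eff / 2, -50.4, 0, p),
               0.5 * p$gamma_pd / v_eff)
  # alternative normalisation uses |v_th|
  p2 <- alif_params(pd_norm = "vth")
  expect_equal(alif_v_eff(p2), 50.4)
})

test_that("surrogate-graph gradients match finite differences on a toy", {
  # 5-unit toy, 10-step trial, continuous relaxation of the spike so the
  # graph is differentiable end to end
  set.seed(7)
  cfg <- network_config(n_e = 4, n_i = 1, n_channels = 3, p_ee = 0.6,
                        p_ei = 0.6, p_ie = 0.6, p_ii = 0.6,
                        input_frac = 0.4, i_scale = 2)
  ws <- build_network(cfg)
  pars <- pushpull:::cpp_pars(alif_params())
  x <- matrix(rbinom(30, 1, 0.5), 3, 10)
  target <- rbind(rep(c(0, 1), length.out = 10))
  v0 <- rnorm(5, -60, 3)
  g <- pushpull:::.cpp_bptt(ws$W_in, ws$W_rec, ws$W_out, x, v0, target,
                            pars, 1, 1, 5000, 0.02, TRUE)
  lossfun <- function(w) pushpull:::.cpp_bptt(w$W_in, w$W_rec, w$W_out, x,
                                              v0, target, pars, 1, 1, 5000,
                                              0.02, TRUE)$loss
  eps <- 1e-5
  for (layer in c("W_rec", "W_in", "W_out")) {
    for (i in which(ws[[layer]] != 0)) {
      w1 <- ws; w1[[layer]][i] <- w1[[layer]][i] + eps
      w2 <- ws; w2[[layer]][i] <- w2[[layer]][i] - eps
      fd <- (lossfun(w1) - lossfun(w2)) / (2 * eps)
      an <- g[[sub("W_", "dW_", layer)]][i]
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("zero learning rate leaves weights unchanged", {
  set.seed(12)
  ws <- build_network(tiny_config(seed = 12))
  opt <- adam_init(ws, lr = 0)
  batch <- replicate(2, tiny_trial(), simplify = FALSE)
  res <- batch_update(batch, ws, opt)
  expect_identical(res$weights$W_rec, ws$W_rec)
  expect_identical(res$weights$W_in, ws$W_in)
  expect_identical(res$weights$W_out, ws$W_out)
  expect_gte(res$record$E_task, 0)
})

test_that("structurally absent connections never acquire weight", {
  set.seed(13)
  ws <- build_network(tiny_config(seed = 13))
  masked_rec <- !ws$mask_rec
  masked_in <- !ws$mask_in
  opt <- adam_init(ws, lr = 0.05)
  for (u in 1:5) {
    batch <- replicate(2, tiny_trial(), simplify = FALSE)
    res <- batch_update(batch, ws, opt)
    ws <- res$weights
    opt <- res$opt
    # slots outside the *original* mask can only become active by rewiring,
    # which updates the mask; anything off the current mask must be zero
    expect_true(all(ws$W_rec[!ws$mask_rec] == 0))
    expect_true(all(ws$W_in[!ws$mask_in] == 0))
    expect_true(all(ws$W_out[!ws$mask_out] == 0))
    expect_true(all(diag(ws$W_rec) == 0))
  }
  expect_silent(validate_weight_set(ws))
})

test_that("Dale's law and class counts survive training updates", {
  set.seed(14)
  ws <- build_network(tiny_config(seed = 14))
  ws$W_in <- ws$W_in * 20  # drive spiking so gradients flow
  ws$mask_in <- ws$W_in != 0
  count_classes <- function(w) {
    pre_e <- matrix(w$is_e, 10, 10)
    c(rec_e = sum(w$mask_rec & pre_e), rec_i = sum(w$mask_rec & !pre_e),
      inp = sum(w$mask_in), out = sum(w$mask_out))
  }
  n0 <- count_classes(ws)
  opt <- adam_init(ws, lr = 0.1)  # deliberately large: provoke crossings
  rewired <- 0L
  for (u in 1:8) {
    batch <- replicate(2, tiny_trial(), simplify = FALSE)
    res <- batch_update(batch, ws, opt)
    ws <- res$weights
    opt <- res$opt
    rewired <- rewired + nrow(res$events)
    expect_identical(count_classes(ws), n0)
    expect_silent(validate_weight_set(ws))
  }
  expect_gt(rewired, 0)   # the large step must have caused some crossings
})

test_that("rewiring prunes crossings and conserves counts on a toy matrix", {
  set.seed(15)
  ws <- build_network(tiny_config(seed = 15))
  # force two sign crossings by hand: one e slot negative, one i positive
  e_slots <- which(ws$mask_rec & matrix(ws$is_e, 10, 10))
  i_slots <- which(ws$mask_rec & matrix(!ws$is_e, 10, 10))
  ws$W_rec[e_slots[1]] <- -0.1
  ws$W_rec[i_slots[1]] <- 0.2
  n_e_active <- length(e_slots)
  n_i_active <- length(i_slots)
  res <- deepr_rewire(ws)
  w2 <- res$weights
  expect_equal(nrow(res$events), 2L)
  expect_equal(w2$W_rec[e_slots[1]], 0)
  expect_equal(w2$W_rec[i_slots[1]], 0)
  pre_e <- matrix(w2$is_e, 10, 10)
  expect_equal(sum(w2$mask_rec & pre_e), n_e_active)
  expect_equal(sum(w2$mask_rec & !pre_e), n_i_active)
  expect_silent(validate_weight_set(w2))
})

test_that("rewiring is the identity when nothing crossed zero", {
  ws <- build_network(tiny_config(seed = 16))
  res <- deepr_rewire(ws)
  expect_identical(res$weights$W_rec, ws$W_rec)
  expect_equal(nrow(res$events), 0L)
})

test_that("rewiring is skipped entirely without Dale enforcement", {
  cfg <- tiny_config(seed = 17, dale_enforced = FALSE)
  ws <- build_network(cfg)
  e_slots <- which(ws$mask_rec & matrix(ws$is_e, 10, 10))
  ws$W_rec[e_slots[1]] <- -0.5   # a crossing that must be left alone
  res <- deepr_rewire(ws)
  expect_identical(res$weights$W_rec, ws$W_rec)
})

test_that("blocked e-e slots are never regrown", {
  cfg <- tiny_config(seed = 18, remove_ee = TRUE)
  set.seed(18)
  ws <- build_network(cfg)
  ee <- outer(ws$is_e, ws$is_e, `&`)
  expect_true(all(ws$W_rec[ee] == 0))
  # prune every e connection; regrowth must avoid the e-e block
  e_active <- which(ws$mask_rec & matrix(ws$is_e, 10, 10))
  ws$W_rec[e_active] <- -1e-6
  res <- deepr_rewire(ws)
  expect_true(all(res$weights$W_rec[ee] == 0))
  expect_silent(validate_weight_set(res$weights))
})

test_that("zero updates return the initial weights only", {
  set.seed(19)
  fit <- train_network(tiny_config(seed = 19), n_updates = 0L,
                       batch_size = 2L, n_unique = 2L, T_len = 136L,
                       change_window = c(30L, 100L))
  expect_length(fit$snapshots, 1L)
  expect_identical(fit$weights$W_rec, fit$snapshots[[1]]$W_rec)
})

test_that("rate-only training pulls the population rate toward its target", {
  set.seed(20)
  fit <- train_network(
    network_config(n_e = 16, n_i = 4, seed = 20),
    mode = "rate_only", n_updates = 250L, batch_size = 4L, n_unique = 12L,
    T_len = 340L, change_window = c(60L, 280L),
    lr = 5e-3, snapshot_every = 50L)
  last <- fit$losses[241:250, ]
  # from a silent start the population rate climbs toward the 20 Hz target
  expect_lt(mean(last$E_rate), 0.9 * fit$losses$E_rate[1L])
  expect_gt(mean(last$rate), 0.002)
})
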