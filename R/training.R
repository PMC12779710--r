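#' Task loss
#'
#' Mean over all timesteps (and, for one-hot targets, over both output
#' units) of the squared difference between the readout and the binary
#' target.
#'
#' @param y_pred outputs x T matrix (or length-T vector).
#' @param y_target same shape as `y_pred`.
#' @return scalar mean squared error.
#' @export
task_loss <- function(y_pred, y_target) {
  y_pred <- rbind(y_pred)
  y_target <- rbind(y_target)
  if (!identical(dim(y_pred), dim(y_target)))
    stop("prediction and target dimensions differ")
  mean((y_pred - y_target)^2)
}

#' Rate loss
#'
#' Squared deviation of a trial's mean population spike rate from the
#' target rate (default 0.020 spikes/ms, i.e. 20 Hz). This is the naive,
#' unscaled quantity; during training it is weighted by `lambda_rate`
#' (see [train_network()]).
#'
#' @param raster units x T binary spike matrix.
#' @param target_rate target rate in spikes/ms.
#' @return scalar squared deviation in (spikes/ms)^2.
#' @export
rate_loss <- function(raster, target_rate = 0.020) {
  stopifnot(target_rate >= 0)
  (mean(raster) - target_rate)^2
}

#' Spike pseudo-derivative
#'
#' Surrogate for the derivative of the spike nonlinearity, used in place of
#' the Heaviside derivative during backpropagation:
#' `psi = (gamma_pd / v_eff) * max(0, 1 - |v - A| / v_eff)`, and 0 during
#' the refractory period. `v_eff` is the normalising voltage
#' (see [alif_params()]; `|v_th - E_m| = 20.2` mV by default).
#'
#' @param v membrane potentials (mV).
#' @param A adaptive thresholds (mV).
#' @param refrac_count remaining refractory steps per unit.
#' @param params an [alif_params()].
#' @return per-unit surrogate gradient (1/mV).
#' @export
pseudo_derivative <- function(v, A, refrac_count, params = alif_params()) {
  v_eff <- alif_v_eff(params)
  psi <- (params$gamma_pd / v_eff) * pmax(0, 1 - abs(v - A) / v_eff)
  psi[refrac_count > 0] <- 0
  psi
}

mode_weights <- function(mode) {
  switch(mode,
         dual = c(task = 1, rate = 1),
         task_only = c(task = 1, rate = 0),
         rate_only = c(task = 0, rate = 1),
         stop("unknown training mode: ", mode))
}

trial_target_matrix <- function(trial, encoding) {
  if (encoding == "one_hot")
    rbind(1 - trial$target, trial$target)
  else
    rbind(trial$target)
}

#' Adam optimizer state
#'
#' First/second moment accumulators for the three weight layers, with the
#' usual bias-corrected update. Moments are created at zero and reset only
#' at slots pruned or regrown by [deepr_rewire()].
#'
#' @param weights a `weight_set`.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam hyperparameters.
#' @return An object of class `adam_state`.
#' @export
adam_init <- function(weights, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zero_like <- function(W) array(0, dim = dim(W))
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
                 m = list(W_in = zero_like(weights$W_in),
                          W_rec = zero_like(weights$W_rec),
                          W_out = zero_like(weights$W_out)),
                 v = list(W_in = zero_like(weights$W_in),
                          W_rec = zero_like(weights$W_rec),
                          W_out = zero_like(weights$W_out))),
            class = "adam_state")
}

adam_apply <- function(weights, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (layer in c("W_in", "W_rec", "W_out")) {
    g <- grads[[layer]]
    opt$m[[layer]] <- opt$beta1 * opt$m[[layer]] + (1 - opt$beta1) * g
    opt$v[[layer]] <- opt$beta2 * opt$v[[layer]] + (1 - opt$beta2) * g^2
    step <- opt$lr * (opt$m[[layer]] / bc1) /
      (sqrt(opt$v[[layer]] / bc2) + opt$eps)
    weights[[layer]] <- weights[[layer]] - step
  }
  list(weights = weights, opt = opt)
}

# draw replacement weights for regrown connections of one sign class
draw_init_weight <- function(n, layer, positive, cfg) {
  if (n == 0L) return(numeric(0))
  if (layer == "W_in")
    return(runif(n, cfg$input_w_min, cfg$input_w_max))
  draw <- rlnorm(n, cfg$lognormal_mu, cfg$lognormal_sigma)
  if (positive) draw else -cfg$i_scale * draw
}

#' DEEP R sparsity-preserving rewiring
#'
#' After a gradient update under Dale's law, any active connection whose
#' weight has crossed zero (or reached exactly zero) is pruned, and for each
#' pruned connection a replacement slot is drawn uniformly from the
#' currently inactive slots of the same layer and presynaptic sign class
#' (never the diagonal, never a blocked e->e slot, and only onto the pool
#' that keeps input-receiving and output-projecting units disjoint). The
#' replacement weight is drawn from the layer's initial distribution, so
#' per-class active connection counts are conserved. Optimizer moments at
#' pruned and regrown slots are reset.
#'
#' Skipped entirely when Dale's law is not enforced.
#'
#' @param weights a `weight_set` after a gradient step.
#' @param opt the matching [adam_init()] state (or NULL).
#' @return `list(weights, opt, events)` where `events` is a data frame with
#'   one row per rewired connection (layer, pruned slot, regrown slot, new
#'   weight).
#' @export
deepr_rewire <- function(weights, opt = NULL) {
  cfg <- weights$config
  events <- list()
  if (!isTRUE(cfg$dale_enforced))
    return(list(weights = weights, opt = opt,
                events = rewire_events(NULL)))
  n <- length(weights$sign)

  rewire_layer <- function(layer, sign_of_slot, allowed) {
    W <- weights[[layer]]
    mask <- weights[[paste0("mask_", sub("W_", "", layer))]]
    active <- which(mask)
    if (!length(active)) return(invisible(NULL))
    crossed <- active[W[active] * sign_of_slot[active] <= 0]
    for (cls in c(1, -1)) {
      pr <- crossed[sign_of_slot[crossed] == cls]
      if (!length(pr)) next
      W[pr] <- 0
      mask[pr] <- FALSE
      pool <- which(!mask & allowed & sign_of_slot == cls)
      k <- min(length(pr), length(pool))
      if (k < length(pr))
        warning("no free slot to regrow ", length(pr) - k,
                " pruned connection(s) in ", layer)
      grown <- if (k > 0) pool[sample.int(length(pool), k)] else integer(0)
      neww <- draw_init_weight(k, layer, cls > 0, cfg)
      W[grown] <- neww
      mask[grown] <- TRUE
      if (!is.null(opt)) {
        touched <- c(pr, grown)
        opt$m[[layer]][touched] <<- 0
        opt$v[[layer]][touched] <<- 0
      }
      events[[length(events) + 1L]] <<- data.frame(
        layer = rep(layer, length(pr)),
        pruned = pr,
        regrown = c(grown, rep(NA_integer_, length(pr) - k)),
        new_weight = c(neww, rep(NA_real_, length(pr) - k)),
        stringsAsFactors = FALSE)
    }
    weights[[layer]] <<- W
    weights[[paste0("mask_", sub("W_", "", layer))]] <<- mask
    invisible(NULL)
  }

  # input layer: all slots are the positive class; regrow only onto the
  # input-eligible pool
  sign_in <- matrix(1, nrow(weights$W_in), n)
  allowed_in <- matrix(rep(weights$input_pool, each = nrow(weights$W_in)),
                       nrow(weights$W_in), n) & TRUE
  rewire_layer("W_in", sign_in, allowed_in)

  # recurrent layer: class = presynaptic sign; never the diagonal or a
  # blocked e->e slot
  sign_rec <- matrix(weights$sign, n, n)
  allowed_rec <- matrix(TRUE, n, n)
  diag(allowed_rec) <- FALSE
  if (isTRUE(weights$ee_blocked))
    allowed_rec[outer(weights$is_e, weights$is_e, `&`)] <- FALSE
  rewire_layer("W_rec", sign_rec, allowed_rec)

  # output layer: class = source sign; regrow only on the output pool
  K <- ncol(weights$W_out)
  sign_out <- matrix(weights$sign, n, K)
  allowed_out <- matrix(weights$output_pool, n, K)
  rewire_layer("W_out", sign_out, allowed_out)

  list(weights = weights, opt = opt,
       events = rewire_events(do.call(rbind, events)))
}

rewire_events <- function(df) {
  if (is.null(df) || !nrow(df))
    df <- data.frame(layer = character(0), pruned = integer(0),
                     regrown = integer(0), new_weight = numeric(0),
                     stringsAsFactors = FALSE)
  df
}

mask_grads <- function(grads, weights) {
  grads$W_in[!weights$mask_in] <- 0
  grads$W_rec[!weights$mask_rec] <- 0
  grads$W_out[!weights$mask_out] <- 0
  grads
}

#' One batch update
#'
#' Accumulates the dual loss and its gradient over a batch of trials by
#' reverse-mode backpropagation through the unrolled spiking dynamics (with
#' the pseudo-derivative standing in for the Heaviside derivative), takes
#' one Adam step on the batch-mean gradient, and applies the Dale/rewiring
#' pass. Gradients at structurally absent connections are zeroed, so masked
#' slots never move.
#'
#' @param batch list of `snn_trial`s.
#' @param weights a `weight_set`.
#' @param opt an [adam_init()] state.
#' @param mode `"dual"`, `"task_only"` or `"rate_only"`.
#' @param params an [alif_params()].
#' @param lambda_rate scale applied to the rate loss inside the total loss.
#' @param rate_target target rate (spikes/ms).
#' @return `list(weights, opt, record, events)`; `record` is a one-row data
#'   frame with the batch-mean task loss, naive rate loss, scaled total
#'   loss, and mean population rate.
#' @export
batch_update <- function(batch, weights, opt, mode = "dual",
                         params = alif_params(), lambda_rate = 1250,
                         rate_target = 0.020) {
  w <- mode_weights(mode)
  n <- length(weights$sign)
  grads <- list(W_in = 0 * weights$W_in, W_rec = 0 * weights$W_rec,
                W_out = 0 * weights$W_out)
  e_task <- e_rate <- e_tot <- rates <- numeric(length(batch))
  for (b in seq_along(batch)) {
    trial <- batch[[b]]
    target <- trial_target_matrix(trial, weights$config$output_encoding)
    v_init <- rnorm(n, params$v_init_mean, params$v_init_sd)
    res <- .cpp_bptt(weights$W_in, weights$W_rec, weights$W_out,
                     trial$spikes, v_init, target, cpp_pars(params),
                     w[["task"]], w[["rate"]], lambda_rate, rate_target,
                     FALSE)
    if (any(!is.finite(res$dW_rec)))
      stop("non-finite gradient in batch trial ", b)
    grads$W_in <- grads$W_in + res$dW_in
    grads$W_rec <- grads$W_rec + res$dW_rec
    grads$W_out <- grads$W_out + res$dW_out
    e_task[b] <- res$E_task
    e_rate[b] <- res$E_rate
    e_tot[b] <- res$loss
    rates[b] <- res$rate
  }
  nb <- length(batch)
  grads <- lapply(grads, function(g) g / nb)
  grads <- mask_grads(grads, weights)
  upd <- adam_apply(weights, grads, opt)
  rw <- deepr_rewire(upd$weights, upd$opt)
  record <- data.frame(E_task = mean(e_task), E_rate = mean(e_rate),
                       E_total = mean(e_tot), rate = mean(rates),
                       n_rewired = nrow(rw$events))
  list(weights = rw$weights, opt = rw$opt, record = record,
       events = rw$events)
}

#' Train a network
#'
#' Runs the full batch loop: builds (or accepts) a network, generates (or
#' accepts) a shuffled trial stream, and performs `n_updates` batch updates
#' under the requested loss mode, snapshotting the weights every
#' `snapshot_every` batches (one "epoch") for retroactive circuit analysis.
#'
#' The total loss is `E_task + lambda_rate * E_rate`; `lambda_rate`
#' (default 5000) brings the initial rate-loss contribution to the same
#' order as the initial task loss, and the naive unscaled rate loss is
#' always logged alongside.
#'
#' @param config a [network_config()] (ignored if `weights` given).
#' @param mode `"dual"`, `"task_only"` or `"rate_only"`.
#' @param n_updates number of batch updates.
#' @param batch_size trials per batch (30 at full scale).
#' @param profile a [channel_profile()].
#' @param params an [alif_params()].
#' @param weights optional pre-built `weight_set`.
#' @param dataset optional output of [make_dataset()]; generated when
#'   missing (`n_unique` unique trials).
#' @param n_unique unique trials when generating the dataset.
#' @param label_high label attached to high entropy (see [make_trial()]).
#' @param T_len,block_len,change_window trial geometry, forwarded to
#'   [make_trial()].
#' @param lr,beta1,beta2,eps Adam settings.
#' @param lambda_rate rate-loss scale in the total loss.
#' @param rate_target target rate (spikes/ms).
#' @param snapshot_every batches per epoch snapshot.
#' @param seed optional seed for the whole run.
#' @param verbose print epoch summaries.
#' @return An object of class `snn_training`: final `weights`, `snapshots`
#'   (list of weight sets, index 1 = initial), `losses` (one row per
#'   batch), `rewire_count`, and the run settings.
#' @export
train_network <- function(config = network_config(), mode = "dual",
                          n_updates = 100L, batch_size = 30L,
                          profile = channel_profile(),
                          params = alif_params(),
                          weights = NULL, dataset = NULL, n_unique = 600L,
                          label_high = 1L, T_len = 4080L, block_len = 68L,
                          change_window = c(500L, 3500L),
                          lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          lambda_rate = 1250, rate_target = 0.020,
                          snapshot_every = 100L, seed = NULL,
                          verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- build_network(config)
  config <- weights$config
  if (is.null(dataset))
    dataset <- make_dataset(profile, n_unique = n_unique,
                            total = n_updates * batch_size,
                            label_high = label_high, T_len = T_len,
                            block_len = block_len,
                            change_window = change_window)
  if (length(dataset$stream) < n_updates * batch_size)
    stop("dataset stream shorter than n_updates * batch_size")
  opt <- adam_init(weights, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
  snapshots <- list(weights)
  losses <- vector("list", n_updates)
  rewired <- 0L
  for (u in seq_len(n_updates)) {
    idx <- dataset$stream[((u - 1L) * batch_size + 1L):(u * batch_size)]
    res <- batch_update(dataset$trials[idx], weights, opt, mode = mode,
                        params = params, lambda_rate = lambda_rate,
                        rate_target = rate_target)
    weights <- res$weights
    opt <- res$opt
    rewired <- rewired + nrow(res$events)
    losses[[u]] <- cbind(batch = u, res$record)
    if (u %% snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- weights
      if (verbose) {
        recent <- do.call(rbind, losses[(u - snapshot_every + 1L):u])
        message(sprintf(
          "epoch %d: task %.4f rate %.3g total %.4f pop rate %.4f",
          u %/% snapshot_every, mean(recent$E_task), mean(recent$E_rate),
          mean(recent$E_total), mean(recent$rate)))
      }
    }
  }
  losses <- do.call(rbind, losses)
  losses$epoch <- (losses$batch - 1L) %/% snapshot_every + 1L
  structure(list(weights = weights, snapshots = snapshots, losses = losses,
                 rewire_count = rewired, mode = mode, config = config,
                 params = params, profile = profile,
                 lambda_rate = lambda_rate, rate_target = rate_target,
                 label_high = label_high, T_len = T_len,
                 block_len = block_len, change_window = change_window,
                 batch_size = batch_size, snapshot_every = snapshot_every),
            class = "snn_training")
}

#' @export
print.snn_training <- function(x, ...) {
  nb <- nrow(x$losses)
  cat(sprintf("snn_training: %s mode, %d batch updates of %d trials\n",
              x$mode, nb, x$batch_size))
  if (nb) {
    first <- x$losses[x$losses$epoch == 1L, ]
    last <- x$losses[x$losses$epoch == max(x$losses$epoch), ]
    cat(sprintf("  task loss %.3f -> %.3f; naive rate loss %.2e -> %.2e\n",
                mean(first$E_task), mean(last$E_task),
                mean(first$E_rate), mean(last$E_rate)))
  }
  cat(sprintf("  %d connections rewired; %d snapshots\n",
              x$rewire_count, length(x$snapshots)))
  invisible(x)
}
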