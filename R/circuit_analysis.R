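#' Classify units and channels by label modulation
#'
#' For every recurrent unit, pools all evaluation trials and compares the
#' mean firing rate over timesteps where the target is 1 against timesteps
#' where it is 0; the preferred label is the one with the higher rate.
#' Silent units (no spikes across the evaluation set) and exact ties are
#' left unclassified (`NA`). The same procedure, applied to the input
#' channel spike trains, yields per-channel preferred labels.
#'
#' @param weights a `weight_set` (typically trained).
#' @param trials list of evaluation `snn_trial`s covering both label
#'   states.
#' @param params an [alif_params()].
#' @param rasters optional precomputed list of units x T rasters matching
#'   `trials`; simulated when missing.
#' @return An object of class `modulation_profile`: `unit_pref` (0/1/NA per
#'   unit), `unit_rate0`, `unit_rate1`, and the channel equivalents, plus
#'   the rasters used (for downstream jitter analysis).
#' @export
classify_modulation <- function(weights, trials, params = alif_params(),
                                rasters = NULL) {
  stopifnot(length(trials) >= 1L)
  n <- length(weights$sign)
  if (is.null(rasters))
    rasters <- lapply(trials, function(tr)
      simulate_trial(weights, tr$spikes, params)$z)
  sum1 <- sum0 <- numeric(n)
  csum1 <- csum0 <- numeric(nrow(trials[[1L]]$spikes))
  t1 <- t0 <- 0
  for (k in seq_along(trials)) {
    lab <- trials[[k]]$target == 1L
    if (any(lab)) {
      sum1 <- sum1 + rowSums(rasters[[k]][, lab, drop = FALSE])
      csum1 <- csum1 + rowSums(trials[[k]]$spikes[, lab, drop = FALSE])
      t1 <- t1 + sum(lab)
    }
    if (any(!lab)) {
      sum0 <- sum0 + rowSums(rasters[[k]][, !lab, drop = FALSE])
      csum0 <- csum0 + rowSums(trials[[k]]$spikes[, !lab, drop = FALSE])
      t0 <- t0 + sum(!lab)
    }
  }
  if (t1 == 0 || t0 == 0)
    stop("evaluation trials must contain timesteps of both labels")
  rate1 <- sum1 / t1
  rate0 <- sum0 / t0
  pref <- ifelse(rate1 > rate0, 1L, ifelse(rate0 > rate1, 0L, NA_integer_))
  pref[sum1 + sum0 == 0] <- NA_integer_
  crate1 <- csum1 / t1
  crate0 <- csum0 / t0
  cpref <- ifelse(crate1 > crate0, 1L,
                  ifelse(crate0 > crate1, 0L, NA_integer_))
  cpref[csum1 + csum0 == 0] <- NA_integer_
  structure(list(unit_pref = pref, unit_rate0 = rate0, unit_rate1 = rate1,
                 channel_pref = cpref, channel_rate0 = crate0,
                 channel_rate1 = crate1, rasters = rasters),
            class = "modulation_profile")
}

#' Construct a modulation profile from given labels
#'
#' Convenience constructor used by null calibrations and toy tests, where
#' unit labels are assigned directly rather than measured from activity.
#'
#' @param unit_pref per-unit preferred label (0, 1, or NA).
#' @param channel_pref optional per-channel preferred label.
#' @return A `modulation_profile`.
#' @export
modulation_profile <- function(unit_pref, channel_pref = NULL) {
  structure(list(unit_pref = as.integer(unit_pref),
                 channel_pref = if (is.null(channel_pref)) NULL
                                else as.integer(channel_pref)),
            class = "modulation_profile")
}

#' Cross- versus within-modulation weight ratios
#'
#' Partitions the active recurrent connections between classified units by
#' (presynaptic label, postsynaptic label): "within" pairs share the
#' preferred label, "across" pairs differ. For each connection class
#' (e->e, e->i, i->e, i->i) and pooled by presynaptic identity (all-e,
#' all-i), reports the mean absolute weight in each partition and the
#' across/within ratio. Because a profile measured at the end of training
#' depends only on unit identities, the ratio can be evaluated
#' retroactively on any stored weight snapshot.
#'
#' Ratios use absolute weights throughout, so a strengthening inhibitory
#' projection yields a ratio above 1. Empty partitions give `NA`.
#'
#' @param weights a `weight_set` (or a bare recurrent matrix plus `is_e`).
#' @param profile a [modulation_profile()].
#' @param is_e logical vector of excitatory identity; taken from `weights`
#'   when it is a `weight_set`.
#' @return A data frame with one row per class (`ee`, `ei`, `ie`, `ii`,
#'   `pooled_e`, `pooled_i`): counts, mean |weight| within and across, and
#'   their ratio.
#' @export
cross_within_ratio <- function(weights, profile, is_e = NULL) {
  if (inherits(weights, "weight_set")) {
    W <- weights$W_rec
    mask <- weights$mask_rec
    is_e <- weights$is_e
  } else {
    W <- weights
    mask <- W != 0
    if (is.null(is_e)) stop("is_e required when passing a bare matrix")
  }
  pref <- profile$unit_pref
  n <- length(pref)
  idx <- which(mask)
  pre <- (idx - 1L) %% n + 1L
  post <- (idx - 1L) %/% n + 1L
  keep <- !is.na(pref[pre]) & !is.na(pref[post])
  idx <- idx[keep]; pre <- pre[keep]; post <- post[keep]
  w <- abs(W[idx])
  within <- pref[pre] == pref[post]
  cls_list <- list(
    ee = is_e[pre] & is_e[post],
    ei = is_e[pre] & !is_e[post],
    ie = !is_e[pre] & is_e[post],
    ii = !is_e[pre] & !is_e[post],
    pooled_e = is_e[pre],
    pooled_i = !is_e[pre])
  rows <- lapply(names(cls_list), function(nm) {
    sel <- cls_list[[nm]]
    mw <- if (any(sel & within)) mean(w[sel & within]) else NA_real_
    ma <- if (any(sel & !within)) mean(w[sel & !within]) else NA_real_
    data.frame(class = nm,
               n_within = sum(sel & within), n_across = sum(sel & !within),
               mean_within = mw, mean_across = ma,
               ratio = ma / mw, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Input-layer modulation weight ratio
#'
#' Mean nonzero input weight from '1'-modulated channels divided by the
#' mean from '0'-modulated channels, separately for excitatory and
#' inhibitory targets. A ratio below 1 onto inhibitory units means the
#' '0'-preferring channels drive inhibition harder, the input-layer half of
#' the push-pull arrangement.
#'
#' @param weights a `weight_set`.
#' @param profile a [modulation_profile()] with `channel_pref` filled in.
#' @return A data frame with rows `onto_e` and `onto_i`: mean weights from
#'   each channel group and their '1'/'0' ratio (`NA` when a group is
#'   empty).
#' @export
input_modulation_ratio <- function(weights, profile) {
  cpref <- profile$channel_pref
  if (is.null(cpref)) stop("profile carries no channel labels")
  W <- weights$W_in
  mask <- weights$mask_in
  one_rows <- which(cpref == 1L)
  zero_rows <- which(cpref == 0L)
  grp_mean <- function(rows, cols) {
    sel <- mask[rows, cols, drop = FALSE]
    if (!any(sel)) return(NA_real_)
    mean(W[rows, cols, drop = FALSE][sel])
  }
  rows <- lapply(c(onto_e = TRUE, onto_i = FALSE), function(e_target) {
    cols <- which(weights$is_e == e_target)
    m1 <- grp_mean(one_rows, cols)
    m0 <- grp_mean(zero_rows, cols)
    data.frame(mean_from_1 = m1, mean_from_0 = m0, ratio = m1 / m0)
  })
  out <- do.call(rbind, rows)
  out$target <- c("onto_e", "onto_i")
  out[, c("target", "mean_from_1", "mean_from_0", "ratio")]
}

#' Persistence of the strongest connections
#'
#' Fraction of the connections in the top-`q` quantile of absolute initial
#' weight that are still in the top-`q` quantile of absolute final weight.
#' Quantile membership is rank-based over each state's active connections,
#' so the fraction is exactly 1 when the weights are unchanged and has
#' expectation `q` when final ranks are independent of initial ranks.
#'
#' @param W_init,W_final weight matrices of identical shape (zeros =
#'   inactive).
#' @param q top quantile (0.1 = top decile, 0.25 = top quartile).
#' @return scalar fraction in \[0, 1\].
#' @export
top_quantile_persistence <- function(W_init, W_final, q = 0.1) {
  stopifnot(identical(dim(W_init), dim(W_final)), q > 0, q <= 1)
  act_i <- which(W_init != 0)
  act_f <- which(W_final != 0)
  if (length(act_i) < 1 / q)
    stop("fewer active initial connections than 1/q")
  n_top_i <- max(1L, round(q * length(act_i)))
  n_top_f <- max(1L, round(q * length(act_f)))
  top_i <- act_i[order(abs(W_init[act_i]), decreasing = TRUE)][seq_len(n_top_i)]
  top_f <- act_f[order(abs(W_final[act_f]),
                       decreasing = TRUE)][seq_len(n_top_f)]
  length(intersect(top_i, top_f)) / length(top_i)
}

#' Mean and SD of nonzero weights per connection class
#'
#' Tabulates each layer's active weights split by presynaptic/postsynaptic
#' identity (in->e, in->i, e->e, e->i, i->e, i->i, e->out, i->out),
#' mirroring the layout of the weight-change tables. With a
#' [modulation_profile()] supplied, the recurrent classes are further split
#' by modulation pairing ('0'->'0', '1'->'1', '0'->'1', '1'->'0').
#'
#' @param weights a `weight_set`.
#' @param profile optional `modulation_profile` for the pairing split.
#' @return A data frame with columns class, (pairing,) n, mean, sd.
#' @export
weight_summary <- function(weights, profile = NULL) {
  is_e <- weights$is_e
  cls <- function(W, rows, cols, mask) {
    sel <- mask[rows, cols, drop = FALSE]
    w <- W[rows, cols, drop = FALSE][sel]
    data.frame(n = length(w),
               mean = if (length(w)) mean(w) else NA_real_,
               sd = if (length(w) > 1) sd(w) else
                 if (length(w) == 1) 0 else NA_real_)
  }
  out <- rbind(
    cbind(class = "in_e", cls(weights$W_in, seq_len(nrow(weights$W_in)),
                              which(is_e), weights$mask_in)),
    cbind(class = "in_i", cls(weights$W_in, seq_len(nrow(weights$W_in)),
                              which(!is_e), weights$mask_in)),
    cbind(class = "ee", cls(weights$W_rec, which(is_e), which(is_e),
                            weights$mask_rec)),
    cbind(class = "ei", cls(weights$W_rec, which(is_e), which(!is_e),
                            weights$mask_rec)),
    cbind(class = "ie", cls(weights$W_rec, which(!is_e), which(is_e),
                            weights$mask_rec)),
    cbind(class = "ii", cls(weights$W_rec, which(!is_e), which(!is_e),
                            weights$mask_rec)),
    cbind(class = "e_out", cls(weights$W_out, which(is_e),
                               seq_len(ncol(weights$W_out)),
                               weights$mask_out)),
    cbind(class = "i_out", cls(weights$W_out, which(!is_e),
                               seq_len(ncol(weights$W_out)),
                               weights$mask_out)))
  if (is.null(profile)) return(out)
  pref <- profile$unit_pref
  pairs <- expand.grid(pre_lab = c(0L, 1L), post_lab = c(0L, 1L))
  rec_cls <- list(ee = c(TRUE, TRUE), ei = c(TRUE, FALSE),
                  ie = c(FALSE, TRUE), ii = c(FALSE, FALSE))
  rows <- list()
  for (nm in names(rec_cls)) {
    for (p in seq_len(nrow(pairs))) {
      pre_sel <- which(is_e == rec_cls[[nm]][1L] &
                         !is.na(pref) & pref == pairs$pre_lab[p])
      post_sel <- which(is_e == rec_cls[[nm]][2L] &
                          !is.na(pref) & pref == pairs$post_lab[p])
      r <- cls(weights$W_rec, pre_sel, post_sel, weights$mask_rec)
      rows[[length(rows) + 1L]] <-
        cbind(class = nm,
              pairing = sprintf("%d_to_%d", pairs$pre_lab[p],
                                pairs$post_lab[p]), r)
    }
  }
  list(by_class = out, by_modulation = do.call(rbind, rows))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper over [stats::ks.test()] returning the D statistic and the
#' asymptotic p-value, as used for all weight- and rate-distribution
#' comparisons.
#'
#' @param sample_a,sample_b numeric vectors (nonempty).
#' @return `list(statistic = D, p.value = p)`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be nonempty")
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
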