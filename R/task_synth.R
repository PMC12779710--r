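#' Drifting-dot stimulus parameters
#'
#' Parameters of the random-dot kinematogram whose motion entropy the
#' network must report: 460 white dots on a black background drifting at
#' 10 px/ms, each living 1000 ms before being replaced at a random
#' position. At low entropy all dots share one cardinal direction; at high
#' entropy only 15% do, and the rest move in arbitrary directions.
#'
#' The dot generator documents the stimulus and supports tests; the network
#' itself is driven by the calibrated channel model ([channel_profile()]),
#' which stands in for the convolutional front-end that converted these
#' videos to firing rates.
#'
#' @param n_dots number of dots.
#' @param speed drift speed (px/ms).
#' @param lifetime dot lifetime (ms).
#' @param coherent_fraction_high,coherent_fraction_low fraction of dots
#'   sharing the cardinal direction at high / low motion entropy.
#' @param frame_size square frame side (px).
#' @return An object of class `dot_stimulus_params`.
#' @export
dot_stimulus_params <- function(n_dots = 460L, speed = 10, lifetime = 1000L,
                                coherent_fraction_high = 0.15,
                                coherent_fraction_low = 1.0,
                                frame_size = 120L) {
  stopifnot(lifetime > 0, n_dots >= 0,
            coherent_fraction_high > 0, coherent_fraction_high <= 1,
            coherent_fraction_low > 0, coherent_fraction_low <= 1)
  structure(list(n_dots = as.integer(n_dots), speed = speed,
                 lifetime = as.integer(lifetime),
                 coherent_fraction_high = coherent_fraction_high,
                 coherent_fraction_low = coherent_fraction_low,
                 cardinal_directions = c(0, 90, 180, 270),
                 frame_size = as.integer(frame_size)),
            class = "dot_stimulus_params")
}

#' Generate a drifting-dot stimulus
#'
#' Simulates dot positions over time on a toroidal frame. Dots start at
#' uniform positions with uniform remaining lifetimes; each millisecond
#' every dot is displaced by `speed` px along its direction, and expired
#' dots are replaced at random positions with a fresh direction draw. The
#' coherent subset (re-drawn per dot at spawn with the entropy-dependent
#' coherent fraction) moves along the trial's cardinal direction; the rest
#' move along independent uniform angles.
#'
#' @param params a [dot_stimulus_params()].
#' @param entropy_seq integer vector over time, 1 = high entropy, 0 = low.
#' @return A list with `x`, `y` (dots x T position matrices), `age`
#'   (dots x T), `coherent` (dots x T logical) and the trial's cardinal
#'   direction in degrees.
#' @export
generate_dot_video <- function(params, entropy_seq) {
  T_len <- length(entropy_seq)
  nd <- params$n_dots
  sz <- params$frame_size
  card <- sample(params$cardinal_directions, 1L)
  card_rad <- card * pi / 180
  out_x <- matrix(NA_real_, nd, T_len)
  out_y <- matrix(NA_real_, nd, T_len)
  out_age <- matrix(NA_integer_, nd, T_len)
  out_coh <- matrix(NA, nd, T_len)
  if (nd == 0L)
    return(list(x = out_x, y = out_y, age = out_age, coherent = out_coh,
                cardinal = card))
  coh_frac <- function(level)
    if (level == 1L) params$coherent_fraction_high
    else params$coherent_fraction_low
  x <- runif(nd, 0, sz)
  y <- runif(nd, 0, sz)
  age <- sample.int(params$lifetime, nd, replace = TRUE) - 1L
  coherent <- runif(nd) < coh_frac(entropy_seq[1L])
  theta <- ifelse(coherent, card_rad, runif(nd, 0, 2 * pi))
  for (t in seq_len(T_len)) {
    expired <- age >= params$lifetime
    if (any(expired)) {
      k <- sum(expired)
      x[expired] <- runif(k, 0, sz)
      y[expired] <- runif(k, 0, sz)
      age[expired] <- 0L
      coherent[expired] <- runif(k) < coh_frac(entropy_seq[t])
      theta[expired] <- ifelse(coherent[expired], card_rad,
                               runif(k, 0, 2 * pi))
    }
    x <- (x + params$speed * cos(theta)) %% sz
    y <- (y + params$speed * sin(theta)) %% sz
    age <- age + 1L
    out_x[, t] <- x; out_y[, t] <- y
    out_age[, t] <- age; out_coh[, t] <- coherent
  }
  list(x = out_x, y = out_y, age = out_age, coherent = out_coh,
       cardinal = card)
}

#' Calibrated input-channel rate model
#'
#' Parametric model of the 16 Poisson input channels that replace the
#' convolutional front-end. Each channel c fires at a block-wise constant
#' rate whose entropy-conditional means differ by the calibration value
#' `delta[c]` (high-entropy mean minus low-entropy mean, spikes/ms). The
#' default `delta` is the measured per-channel table (8 positive, 8
#' negative, mean |delta| = 0.021 spikes/ms); `baseline` is the grand mean
#' rate (0.18 spikes/ms, the high-entropy group mean) to which `+/- delta/2`
#' is applied; `cv` is the coefficient of variation of the gamma-distributed
#' block-to-block rate variability.
#'
#' @param baseline per-channel (or scalar) baseline rate, spikes/ms.
#' @param delta per-channel high-minus-low rate difference, spikes/ms.
#' @param cv block-rate coefficient of variation (0 = deterministic rates).
#' @return An object of class `channel_profile`.
#' @export
channel_profile <- function(baseline = 0.18,
                            delta = c(0.0163, 0.0002, 0.0192, 0.0874,
                                      -0.0176, -0.0163, -0.0063, -0.0170,
                                      0.0284, 0.0033, 0.0180, -0.0395,
                                      -0.0336, -0.0118, -0.0166, 0.0071),
                            cv = 0.45) {
  n_ch <- length(delta)
  baseline <- rep_len(baseline, n_ch)
  stopifnot(all(baseline >= 0), cv >= 0)
  structure(list(baseline = baseline, delta = delta, cv = cv,
                 n_channels = n_ch),
            class = "channel_profile")
}

#' Block-wise channel rates for an entropy sequence
#'
#' For each 68-ms block and channel, draws a firing rate from a gamma
#' distribution whose mean is `baseline + delta/2` when the block is high
#' entropy and `baseline - delta/2` when low (the block's level is the
#' entropy at its first millisecond), with coefficient of variation `cv`.
#' Rates are constant within a block; negative calibrated means are clipped
#' to 0 with a warning.
#'
#' @param profile a [channel_profile()].
#' @param entropy_seq per-ms entropy levels (1 = high, 0 = low); its length
#'   must be a multiple of `block_len`.
#' @param block_len block length in ms (68).
#' @return channels x blocks rate matrix (spikes/ms).
#' @export
make_channel_rates <- function(profile, entropy_seq, block_len = 68L) {
  T_len <- length(entropy_seq)
  if (T_len %% block_len != 0)
    stop("trial length must be a multiple of the block length")
  n_blocks <- T_len %/% block_len
  starts <- seq(1L, T_len, by = block_len)
  level <- entropy_seq[starts]
  means <- outer(profile$delta / 2, ifelse(level == 1L, 1, -1)) +
    matrix(profile$baseline, profile$n_channels, n_blocks)
  if (any(means < 0)) {
    warning("negative calibrated mean rate clipped to 0")
    means[means < 0] <- 0
  }
  if (profile$cv <= 0) return(means)
  shape <- 1 / profile$cv^2
  rates <- matrix(rgamma(length(means), shape = shape,
                         scale = pmax(means, 0) / shape),
                  profile$n_channels, n_blocks)
  rates[means == 0] <- 0
  rates
}

#' Poisson spikes from block rates
#'
#' Expands each block rate to its `block_len` milliseconds and draws
#' independent Bernoulli(rate * dt) spikes per millisecond (dt = 1 ms).
#' Probabilities above 1 are clipped with a warning.
#'
#' @param rates channels x blocks rate matrix (spikes/ms) or channels x T
#'   per-ms rates when `block_len = 1`.
#' @param block_len ms per block.
#' @return channels x (blocks * block_len) binary spike matrix.
#' @export
poissonize <- function(rates, block_len = 68L) {
  stopifnot(all(rates >= 0))
  p <- rates[, rep(seq_len(ncol(rates)), each = block_len), drop = FALSE]
  if (any(p > 1)) {
    warning("spike probability rate*dt > 1 clipped to 1")
    p[p > 1] <- 1
  }
  spikes <- matrix(as.numeric(runif(length(p)) < p), nrow(p), ncol(p))
  spikes
}

#' Construct one task trial
#'
#' Builds a complete 4080-ms episode: a uniformly chosen initial entropy
#' level, with probability `change_prob` a single entropy change at a
#' uniform time in `change_window`, the per-ms binary target derived from
#' the label map, and the calibrated Poisson channel spikes. Rates change
#' at the first block boundary at or after the change time; the target
#' flips at the exact millisecond.
#'
#' @param profile a [channel_profile()].
#' @param label_high the output label (0 or 1) attached to the high-entropy
#'   level; low entropy gets the complementary label. Swapping this value
#'   realises the label-swap experiments.
#' @param change_prob probability that the trial contains an entropy change.
#' @param T_len trial duration (ms); multiple of `block_len`.
#' @param block_len rate block length (ms).
#' @param change_window inclusive ms range of possible change times.
#' @return An object of class `snn_trial`: `spikes` (channels x T),
#'   `target` (length-T 0/1 vector), `entropy` (length-T levels),
#'   `change_time` (ms or NA), `label_high`.
#' @export
make_trial <- function(profile, label_high = 1L, change_prob = 0.5,
                       T_len = 4080L, block_len = 68L,
                       change_window = c(500L, 3500L)) {
  stopifnot(change_prob >= 0, change_prob <= 1)
  start_level <- sample(c(0L, 1L), 1L)
  change_time <- NA_integer_
  entropy <- rep(start_level, T_len)
  if (runif(1) < change_prob) {
    change_time <- sample(seq(change_window[1L], change_window[2L]), 1L)
    entropy[seq(change_time, T_len)] <- 1L - start_level
  }
  label_of <- function(level) ifelse(level == 1L, label_high, 1L - label_high)
  target <- label_of(entropy)
  rates <- make_channel_rates(profile, entropy, block_len)
  spikes <- poissonize(rates, block_len)
  structure(list(spikes = spikes, target = as.integer(target),
                 entropy = entropy, change_time = change_time,
                 label_high = as.integer(label_high),
                 rates = rates, T_len = T_len, block_len = block_len),
            class = "snn_trial")
}

#' Build a shuffled training stream of repeated unique trials
#'
#' Generates `n_unique` distinct trials and an index stream of length
#' `total` in which every unique trial appears `floor(total/n_unique)` or
#' `ceiling(total/n_unique)` times, in shuffled order. Consecutive slices
#' of the stream form the training batches.
#'
#' @param profile a [channel_profile()].
#' @param n_unique number of distinct trials (600 at full scale).
#' @param total total stream length (300000 = 30 x 10000 at full scale).
#' @param ... forwarded to [make_trial()].
#' @return `list(trials = <list of snn_trial>, stream = <integer indices>)`.
#' @export
make_dataset <- function(profile, n_unique = 600L, total = 300000L, ...) {
  trials <- replicate(n_unique, make_trial(profile, ...), simplify = FALSE)
  reps <- rep(total %/% n_unique, n_unique)
  extra <- total - sum(reps)
  if (extra > 0) {
    bump <- sample.int(n_unique, extra)
    reps[bump] <- reps[bump] + 1L
  }
  stream <- rep.int(seq_len(n_unique), reps)
  stream <- stream[sample.int(length(stream))]
  list(trials = trials, stream = stream)
}
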