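toy_profile_weights <- function() {
  # 4 units: 2 e (1, 2) and 2 i (3, 4); labels 0, 1, 0, 1
  cfg <- network_config(n_e = 2, n_i = 2, n_channels = 2,
                        p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0)
  W <- matrix(0, 4, 4)
  W[1, 2] <- 1   # e 0 -> e 1  : across
  W[2, 1] <- 2   # e 1 -> e 0  : across
  W[3, 4] <- -3  # i 0 -> i 1  : across
  W[4, 3] <- -4  # i 1 -> i 0  : across
  W[1, 3] <- 5   # e 0 -> i 0  : within
  W[3, 1] <- -6  # i 0 -> e 0  : within
  ws <- structure(list(W_rec = W, mask_rec = W != 0,
                       sign = c(1L, 1L, -1L, -1L),
                       is_e = c(TRUE, TRUE, FALSE, FALSE), config = cfg),
                  class = "weight_set")
  list(ws = ws, prof = modulation_profile(c(0L, 1L, 0L, 1L)))
}

test_that("cross/within ratios match hand-enumerated values on a toy", {
  tp <- toy_profile_weights()
  r <- cross_within_ratio(tp$ws, tp$prof)
  # e connections: within = {5}, across = {1, 2}; i: within = {6}, across
  # = {3, 4} (absolute weights)
  expect_equal(r$ratio[r$class == "pooled_e"], mean(c(1, 2)) / 5)
  expect_equal(r$ratio[r$class == "pooled_i"], mean(c(3, 4)) / 6)
  expect_true(is.na(r$mean_within[r$class == "ee"]))  # no within e-e pair
  expect_true(is.na(r$ratio[r$class == "ee"]))
  expect_equal(r$mean_across[r$class == "ii"], 3.5)
})

test_that("unclassified units are excluded from ratio partitions", {
  tp <- toy_profile_weights()
  prof <- modulation_profile(c(0L, NA, 0L, 1L))
  r <- cross_within_ratio(tp$ws, prof)
  # unit 2's connections (1->2, 2->1) drop out
  expect_equal(r$n_within[r$class == "pooled_e"] +
                 r$n_across[r$class == "pooled_e"], 1L)
})

test_that("random labels give pooled ratios near one", {
  set.seed(30)
  ws <- build_network(network_config(seed = 30))
  ratios_e <- ratios_i <- numeric(100)
  for (k in 1:100) {
    pref <- sample(c(0L, 1L), 300, replace = TRUE)
    r <- cross_within_ratio(ws, modulation_profile(pref))
    ratios_e[k] <- r$ratio[r$class == "pooled_e"]
    ratios_i[k] <- r$ratio[r$class == "pooled_i"]
  }
  expect_equal(mean(ratios_e), 1, tolerance = 0.02)
  expect_equal(mean(ratios_i), 1, tolerance = 0.02)
})

test_that("modulation classification recovers constructed preferences", {
  cfg <- tiny_config(seed = 31)
  ws <- build_network(cfg)
  T_len <- 136L
  tr <- tiny_trial(change_prob = 1)
  lab1 <- tr$target == 1L
  # synthetic rasters: unit 1 spikes only under label 1, unit 2 only under
  # label 0, unit 3 at 0.02 vs 0.01, unit 4 silent
  z <- matrix(0, 10, T_len)
  z[1, lab1] <- 1
  z[2, !lab1] <- 1
  set.seed(31)
  z[3, lab1] <- rbinom(sum(lab1), 1, 0.4)
  z[3, !lab1] <- rbinom(sum(!lab1), 1, 0.1)
  prof <- classify_modulation(ws, list(tr), rasters = list(z))
  expect_equal(prof$unit_pref[1], 1L)
  expect_equal(prof$unit_pref[2], 0L)
  expect_equal(prof$unit_pref[3], 1L)
  expect_true(is.na(prof$unit_pref[4]))
  expect_equal(prof$unit_rate1[1], 1)
  expect_equal(prof$unit_rate0[1], 0)
  # channels with positive delta fire more under the high-entropy label
  expect_length(prof$channel_pref, 4L)
})

test_that("classification requires both label states", {
  ws <- build_network(tiny_config(seed = 32))
  tr <- tiny_trial(change_prob = 0)
  z <- matrix(0, 10, 136)
  expect_error(classify_modulation(ws, list(tr), rasters = list(z)),
               "both labels")
})

test_that("input modulation ratio reflects constructed weight asymmetry", {
  cfg <- tiny_config(seed = 33)
  ws <- build_network(cfg)
  ws$W_in[] <- 0
  ws$W_in[1, 1:8] <- 0.4   # channel 1 ('1'-pref) onto e units
  ws$W_in[3, 1:8] <- 0.2   # channel 3 ('0'-pref) onto e units
  ws$W_in[1, 9:10] <- 0.1
  ws$W_in[3, 9:10] <- 0.2
  ws$mask_in <- ws$W_in != 0
  prof <- modulation_profile(rep(1L, 10),
                             channel_pref = c(1L, NA, 0L, NA))
  r <- input_modulation_ratio(ws, prof)
  expect_equal(r$ratio[r$target == "onto_e"], 2)
  expect_equal(r$ratio[r$target == "onto_i"], 0.5)
  # identical weights everywhere -> both ratios 1
  ws$W_in[ws$mask_in] <- 0.3
  r1 <- input_modulation_ratio(ws, prof)
  expect_equal(r1$ratio, c(1, 1))
})

test_that("top-quantile persistence is 1 under identity, ~q under permutation", {
  set.seed(34)
  W <- matrix(0, 50, 50)
  idx <- sample(length(W), 600)
  W[idx] <- rlnorm(600, -0.64, 0.51)
  expect_equal(top_quantile_persistence(W, W, 0.1), 1)
  # random permutation of weights over the same slots
  overlaps <- replicate(200, {
    W2 <- W
    W2[idx] <- W[sample(idx)]
    top_quantile_persistence(W, W2, 0.1)
  })
  expect_equal(mean(overlaps), 0.1, tolerance = 0.08)
  expect_true(all(overlaps >= 0 & overlaps <= 1))
  expect_error(top_quantile_persistence(W, W, 1e-4), "fewer active")
})

test_that("weight summaries report per-class means of nonzero weights", {
  set.seed(35)
  ws <- build_network(network_config(n_e = 80, n_i = 20, seed = 35))
  s <- weight_summary(ws)
  expect_setequal(s$class, c("in_e", "in_i", "ee", "ei", "ie", "ii",
                             "e_out", "i_out"))
  ln_mean <- exp(-0.64 + 0.51^2 / 2)
  expect_equal(s$mean[s$class == "ee"], ln_mean, tolerance = 0.15)
  expect_lt(s$mean[s$class == "ie"], 0)
  expect_equal(s$mean[s$class == "ii"], -10 * ln_mean, tolerance = 1.5)
  # single-connection class: mean equals the weight, sd 0
  tp <- toy_profile_weights()
  tp$ws$W_in <- matrix(0, 2, 4); tp$ws$mask_in <- tp$ws$W_in != 0
  tp$ws$W_out <- matrix(0, 4, 1); tp$ws$mask_out <- tp$ws$W_out != 0
  s2 <- weight_summary(tp$ws)
  expect_equal(s2$mean[s2$class == "ei"], 5)
  expect_equal(s2$sd[s2$class == "ei"], 0)
  # modulation split covers all four pairings
  s3 <- weight_summary(tp$ws, tp$prof)
  expect_equal(nrow(s3$by_modulation), 16L)
  expect_equal(s3$by_modulation$mean[s3$by_modulation$class == "ee" &
                 s3$by_modulation$pairing == "0_to_1"], 1)
})

test_that("KS comparison returns the expected extremes", {
  x <- rnorm(50)
  r <- ks_compare(x, x)
  expect_equal(r$statistic, 0)
  r2 <- ks_compare(1:50, 101:150)   # disjoint supports
  expect_equal(r2$statistic, 1)
  expect_lt(r2$p.value, 1e-10)
  expect_error(ks_compare(numeric(0), 1:3), "nonempty")
})

test_that("ratios are retroactively computable on stored snapshots", {
  set.seed(36)
  fit <- train_network(tiny_config(seed = 36), mode = "rate_only",
                       n_updates = 10L, batch_size = 2L, n_unique = 4L,
                       profile = tiny_profile(),
                       T_len = 136L, change_window = c(30L, 100L),
                       snapshot_every = 5L, lr = 5e-3)
  prof <- modulation_profile(sample(c(0L, 1L), 10, replace = TRUE))
  r_snap <- cross_within_ratio(fit$snapshots[[1]], prof)
  r_direct <- cross_within_ratio(fit$snapshots[[1]]$W_rec, prof,
                                 is_e = fit$snapshots[[1]]$is_e)
  expect_equal(r_snap$ratio, r_direct$ratio)
})
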