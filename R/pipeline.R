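#' Scale presets
#'
#' Two bundled configurations: `paper_scale()` is the full protocol
#' (240 e + 60 i units, 4080-ms trials, 600 unique trials, batches of 30,
#' 10,000 updates) and `desk_scale()` is a reduced protocol sized for a
#' workstation CPU (48 e + 12 i units, 1020-ms trials of 15 blocks, change
#' window 125-875 ms, 100 unique trials, batches of 10, 2000 updates,
#' learning rate 5e-3 to compensate for the shorter schedule). Both return
#' a plain list understood by [run_pipeline()] and [train_network()].
#'
#' @param variant one of `"default"`, `"one_hot"`, `"no_dale"`,
#'   `"weak_inh"`, `"no_ee"`.
#' @param seed integer seed recorded in the configuration.
#' @return A named list of sections: `network`, `task`, `train`.
#' @export
paper_scale <- function(variant = "default", seed = 1L) {
  scale_config(variant, seed,
               n_e = 240L, n_i = 60L, T_len = 4080L, n_blocks = 60L,
               change_window = c(500L, 3500L), n_unique = 600L,
               batch_size = 30L, n_updates = 10000L, lr = 1e-3,
               snapshot_every = 100L, n_eval = 60L)
}

#' @rdname paper_scale
#' @export
desk_scale <- function(variant = "default", seed = 1L) {
  scale_config(variant, seed,
               n_e = 48L, n_i = 12L, T_len = 1020L, n_blocks = 15L,
               change_window = c(125L, 875L), n_unique = 100L,
               batch_size = 10L, n_updates = 3000L, lr = 5e-3,
               snapshot_every = 100L, n_eval = 40L)
}

scale_config <- function(variant, seed, n_e, n_i, T_len, n_blocks,
                         change_window, n_unique, batch_size, n_updates,
                         lr, snapshot_every, n_eval) {
  variant <- match.arg(variant,
                       c("default", "one_hot", "no_dale", "weak_inh",
                         "no_ee"))
  net <- network_config(
    n_e = n_e, n_i = n_i, seed = seed,
    i_scale = if (variant %in% c("weak_inh", "no_dale")) 1.5 else 10,
    dale_enforced = variant != "no_dale",
    remove_ee = variant == "no_ee",
    output_encoding = if (variant == "one_hot") "one_hot" else "single")
  list(variant = variant, seed = as.integer(seed), network = net,
       task = list(T_len = as.integer(T_len), block_len = 68L,
                   n_blocks = as.integer(n_blocks),
                   change_window = as.integer(change_window),
                   n_unique = as.integer(n_unique), label_high = 1L),
       train = list(batch_size = as.integer(batch_size),
                    n_updates = as.integer(n_updates), lr = lr,
                    lambda_rate = 1250, rate_target = 0.020,
                    snapshot_every = as.integer(snapshot_every),
                    mode = "dual"),
       analyze = list(n_eval = as.integer(n_eval)))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
    net <- config$network
    config$network <- do.call(network_config, net[!vapply(net, is.null,
                                                          logical(1))])
  }
  stopifnot(is.list(config), !is.null(config$network))
  config
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

manifest_add <- function(manifest, files) {
  for (f in files)
    manifest$files[[basename(f)]] <-
      list(path = f, md5 = unname(tools::md5sum(f)))
  manifest
}

#' Run the full pipeline
#'
#' Orchestrates the stages `init` (construct and persist the network),
#' `dataset` (evaluation trials), `train`, `analyze` (modulation
#' classification, cross/within and input-layer ratios, weight summaries,
#' top-weight persistence) and `jitter` (spike-time perturbation), writing
#' every artifact plus a manifest with checksums and seeds to `out_dir`.
#' Later stages reload persisted artifacts, so a run can be resumed stage
#' by stage.
#'
#' @param config a list from [desk_scale()]/[paper_scale()], or a path to a
#'   JSON/YAML file with the same structure.
#' @param stages character subset of
#'   `c("init", "dataset", "train", "analyze", "jitter")`, executed in
#'   canonical order.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return The run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = desk_scale(),
                         stages = c("init", "dataset", "train", "analyze",
                                    "jitter"),
                         out_dir = tempfile("snn_run_"), verbose = FALSE) {
  config <- read_run_config(config)
  stages <- match.arg(stages, c("init", "dataset", "train", "analyze",
                                "jitter"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- alif_params()
  profile <- channel_profile()
  if (config$network$n_channels != profile$n_channels)
    profile <- channel_profile(
      delta = rep_len(profile$delta, config$network$n_channels))
  manifest <- list(config = strip_classes(config),
                   seed = config$seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("pushpull")),
                   files = list())
  say <- function(...) if (verbose) message(sprintf(...))
  need <- function(path, stage)
    if (!file.exists(path))
      stop("missing artifact '", basename(path), "': run stage '", stage,
           "' first")

  weights_dir <- file.path(out_dir, "weights_init")
  trained_dir <- file.path(out_dir, "weights_trained")

  if ("init" %in% stages) {
    say("stage init")
    set.seed(config$seed)
    ws <- build_network(config$network)
    save_weights(ws, weights_dir)
    manifest$stages$init <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest <- manifest_add(manifest,
                             list.files(weights_dir, full.names = TRUE))
  }

  if ("dataset" %in% stages || "analyze" %in% stages ||
      "jitter" %in% stages) {
    # evaluation set: fixed, seeded, balanced across initial entropy level
    set.seed(config$seed + 1000L)
    n_eval <- config$analyze$n_eval
    eval_trials <- balanced_eval_trials(profile, n_eval, config$task)
  }
  if ("dataset" %in% stages) {
    say("stage dataset (%d evaluation trials)", length(eval_trials))
    manifest$stages$dataset <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  }

  if ("train" %in% stages) {
    need(file.path(weights_dir, "weights.json"), "init")
    say("stage train (%d updates)", config$train$n_updates)
    ws <- load_weights(weights_dir)
    set.seed(config$seed + 2000L)
    fit <- train_network(weights = ws, mode = config$train$mode,
                         n_updates = config$train$n_updates,
                         batch_size = config$train$batch_size,
                         profile = profile, params = params,
                         n_unique = config$task$n_unique,
                         label_high = config$task$label_high,
                         T_len = config$task$T_len,
                         block_len = config$task$block_len,
                         change_window = config$task$change_window,
                         lr = config$train$lr,
                         lambda_rate = config$train$lambda_rate,
                         rate_target = config$train$rate_target,
                         snapshot_every = config$train$snapshot_every,
                         verbose = verbose)
    save_weights(fit$weights, trained_dir)
    write.csv(fit$losses, file.path(out_dir, "losses.csv"),
              row.names = FALSE)
    manifest$stages$train <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest$rewire_count <- fit$rewire_count
    manifest <- manifest_add(manifest, c(
      list.files(trained_dir, full.names = TRUE),
      file.path(out_dir, "losses.csv")))
  }

  if ("analyze" %in% stages) {
    need(file.path(trained_dir, "weights.json"), "train")
    say("stage analyze")
    ws0 <- load_weights(weights_dir)
    ws1 <- load_weights(trained_dir)
    set.seed(config$seed + 3000L)
    prof <- classify_modulation(ws1, eval_trials, params)
    ratios <- cross_within_ratio(ws1, prof)
    ratios0 <- cross_within_ratio(ws0, prof)
    inratio <- input_modulation_ratio(ws1, prof)
    summ <- weight_summary(ws1)
    persist <- data.frame(
      q = c(0.1, 0.25),
      persistence = c(
        top_quantile_persistence(ws0$W_rec, ws1$W_rec, 0.1),
        top_quantile_persistence(ws0$W_rec, ws1$W_rec, 0.25)))
    write.csv(cbind(state = "trained", ratios),
              file.path(out_dir, "cross_within_ratios.csv"),
              row.names = FALSE)
    write.csv(cbind(state = "initial", ratios0),
              file.path(out_dir, "cross_within_ratios_initial.csv"),
              row.names = FALSE)
    write.csv(inratio, file.path(out_dir, "input_modulation_ratio.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(out_dir, "weight_summary.csv"),
              row.names = FALSE)
    write.csv(persist, file.path(out_dir, "persistence.csv"),
              row.names = FALSE)
    raster_dir <- file.path(out_dir, "eval_rasters")
    dir.create(raster_dir, showWarnings = FALSE)
    for (k in seq_along(prof$rasters))
      save_raster(prof$rasters[[k]],
                  file.path(raster_dir, sprintf("raster_%03d.csv", k)))
    headline <- list(
      i_cross_within = ratios$ratio[ratios$class == "pooled_i"],
      e_cross_within = ratios$ratio[ratios$class == "pooled_e"],
      input_ratio_onto_e = inratio$ratio[inratio$target == "onto_e"],
      input_ratio_onto_i = inratio$ratio[inratio$target == "onto_i"])
    jsonlite::write_json(headline, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$analyze <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest <- manifest_add(manifest, file.path(out_dir, c(
      "cross_within_ratios.csv", "cross_within_ratios_initial.csv",
      "input_modulation_ratio.csv", "weight_summary.csv",
      "persistence.csv", "summary.json")))
  }

  if ("jitter" %in% stages) {
    need(file.path(trained_dir, "weights.json"), "train")
    say("stage jitter")
    ws1 <- load_weights(trained_dir)
    raster_dir <- file.path(out_dir, "eval_rasters")
    rasters <- if (dir.exists(raster_dir)) {
      lapply(sort(list.files(raster_dir, pattern = "\\.csv$",
                             full.names = TRUE)), load_raster)
    } else {
      set.seed(config$seed + 3000L)
      lapply(eval_trials, function(tr)
        simulate_trial(ws1, tr$spikes, params)$z)
    }
    set.seed(config$seed + 4000L)
    jt <- evaluate_jittered(ws1, eval_trials, rasters, jitter_config())
    write.csv(jt, file.path(out_dir, "jitter_losses.csv"),
              row.names = FALSE)
    manifest$stages$jitter <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest <- manifest_add(manifest,
                             file.path(out_dir, "jitter_losses.csv"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

# evaluation trials balanced over the initial entropy level
balanced_eval_trials <- function(profile, n_eval, task) {
  trials <- vector("list", n_eval)
  for (k in seq_len(n_eval)) {
    repeat {
      tr <- make_trial(profile, label_high = task$label_high,
                       change_prob = 0.5, T_len = task$T_len,
                       block_len = task$block_len,
                       change_window = task$change_window)
      if (tr$entropy[1L] == k %% 2L) break   # alternate initial levels
    }
    trials[[k]] <- tr
  }
  trials
}
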