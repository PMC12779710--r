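#' Save and load a weight set
#'
#' Weights are persisted as plain-text sparse triplets (one CSV per layer:
#' row, col, weight) plus a JSON sidecar holding the network configuration,
#' sign vector and pool membership. The round trip is bit-exact: values are
#' written with full double precision.
#'
#' @param ws a `weight_set`.
#' @param dir directory to write into (created if needed).
#' @return `save_weights` returns the directory invisibly; `load_weights`
#'   returns the reconstructed `weight_set`.
#' @export
save_weights <- function(ws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_triplets <- function(W, path) {
    idx <- which(W != 0, arr.ind = TRUE)
    df <- data.frame(row = idx[, 1L], col = idx[, 2L],
                     weight = sprintf("%.17g", W[idx]))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_triplets(ws$W_in, file.path(dir, "W_in.csv"))
  write_triplets(ws$W_rec, file.path(dir, "W_rec.csv"))
  write_triplets(ws$W_out, file.path(dir, "W_out.csv"))
  meta <- list(config = unclass(ws$config), sign = ws$sign,
               input_pool = ws$input_pool, output_pool = ws$output_pool,
               ee_blocked = isTRUE(ws$ee_blocked),
               dims = list(n = length(ws$sign),
                           n_channels = nrow(ws$W_in),
                           n_out = ncol(ws$W_out)))
  jsonlite::write_json(meta, file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_weights
#' @export
load_weights <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "weights.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  class(cfg) <- "network_config"
  n <- meta$dims$n
  read_triplets <- function(path, nr, nc) {
    df <- read.csv(path, colClasses = c("integer", "integer", "character"))
    W <- matrix(0, nr, nc)
    if (nrow(df)) W[cbind(df$row, df$col)] <- as.numeric(df$weight)
    W
  }
  W_in <- read_triplets(file.path(dir, "W_in.csv"), meta$dims$n_channels, n)
  W_rec <- read_triplets(file.path(dir, "W_rec.csv"), n, n)
  W_out <- read_triplets(file.path(dir, "W_out.csv"), n, meta$dims$n_out)
  is_e <- meta$sign > 0
  structure(list(W_rec = W_rec, mask_rec = W_rec != 0,
                 sign = as.integer(meta$sign), is_e = is_e, config = cfg,
                 W_in = W_in, mask_in = W_in != 0,
                 W_out = W_out, mask_out = W_out != 0,
                 input_pool = meta$input_pool,
                 output_pool = meta$output_pool,
                 receives_input = colSums(W_in != 0) > 0,
                 ee_blocked = isTRUE(meta$ee_blocked)),
            class = "weight_set")
}

#' Save and load a spike raster
#'
#' Rasters are persisted as sparse (unit, time) CSV pairs with a small JSON
#' header carrying the dimensions.
#'
#' @param z units x T binary matrix.
#' @param path CSV path; a `.json` sidecar is written next to it.
#' @export
save_raster <- function(z, path) {
  idx <- which(z != 0, arr.ind = TRUE)
  write.csv(data.frame(unit = idx[, 1L], time = idx[, 2L]), path,
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_units = nrow(z), T_len = ncol(z)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_raster
#' @export
load_raster <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  z <- matrix(0, hdr$n_units, hdr$T_len)
  if (nrow(df)) z[cbind(df$unit, df$time)] <- 1
  z
}
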