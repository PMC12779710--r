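#' Sample the recurrent weight matrix
#'
#' Draws the sparse signed recurrent connectivity. Each ordered pair
#' (pre j, post i), j != i, is connected independently with the probability
#' of its (pre-type, post-type) class. Excitatory weights are log-normal
#' draws; inhibitory weights are the negated draws scaled by `i_scale`.
#' Entry `W_rec[j, i]` is the synapse from presynaptic unit j to
#' postsynaptic unit i; the diagonal is structurally zero.
#'
#' @param config a [network_config()].
#' @return A partial `weight_set` holding `W_rec`, its mask, and the per-unit
#'   sign vector (+1 excitatory, -1 inhibitory; units 1..n_e are excitatory).
#' @export
sample_recurrent_weights <- function(config) {
  validate_network_config(config)
  n <- config$n_e + config$n_i
  is_e <- c(rep(TRUE, config$n_e), rep(FALSE, config$n_i))
  pmat <- matrix(0, n, n)
  pmat[is_e,  is_e]  <- config$p_ee
  pmat[is_e,  !is_e] <- config$p_ei
  pmat[!is_e, is_e]  <- config$p_ie
  pmat[!is_e, !is_e] <- config$p_ii
  mask <- matrix(runif(n * n) < pmat, n, n)
  diag(mask) <- FALSE
  W <- matrix(0, n, n)
  idx <- which(mask)
  if (length(idx)) {
    draw <- rlnorm(length(idx), config$lognormal_mu, config$lognormal_sigma)
    pre_e <- is_e[(idx - 1L) %% n + 1L]
    W[idx] <- ifelse(pre_e, draw, -config$i_scale * draw)
  }
  structure(list(W_rec = W, mask_rec = mask,
                 sign = ifelse(is_e, 1L, -1L), is_e = is_e,
                 config = config),
            class = "weight_set")
}

#' Build input and output layers
#'
#' Completes a `weight_set` begun by [sample_recurrent_weights()]. Units are
#' partitioned (seeded by the ambient RNG) into an input-eligible pool of
#' fraction `input_frac` and a complementary output-eligible pool, so that
#' no unit that receives input can project to the output. Input channels
#' are treated as excitatory afferents: they connect to pool units with
#' probability `p_ee` (onto e units) or `p_ei` (onto i units) and uniform
#' weights on `[input_w_min, input_w_max]`. Output connectivity reuses the
#' recurrent statistics: probability `p_ee` from e units and `p_ie` from i
#' units, weights drawn from the recurrent initial distribution with the
#' source unit's sign.
#'
#' @param weights partial `weight_set` from [sample_recurrent_weights()].
#' @param config the same [network_config()].
#' @return A complete `weight_set` with `W_in` (channels x units), `W_out`
#'   (units x outputs), masks, and the pool bookkeeping.
#' @export
build_io_layers <- function(weights, config) {
  stopifnot(inherits(weights, "weight_set"))
  n <- length(weights$sign)
  is_e <- weights$is_e
  C <- config$n_channels
  n_in_pool <- round(config$input_frac * n)
  input_pool <- rep(FALSE, n)
  input_pool[sample.int(n, n_in_pool)] <- TRUE

  p_onto <- ifelse(is_e, config$p_ee, config$p_ei)
  mask_in <- matrix(FALSE, C, n)
  for (i in which(input_pool))
    mask_in[, i] <- runif(C) < p_onto[i]
  W_in <- matrix(0, C, n)
  W_in[mask_in] <- runif(sum(mask_in), config$input_w_min, config$input_w_max)
  mask_in <- mask_in & W_in != 0          # degenerate bounds: no input at all
  W_in[!mask_in] <- 0

  receives_input <- colSums(mask_in) > 0L
  # units outside the input pool are output-eligible; input-pool units that
  # happened to draw no input connection stay reserved for input. If nothing
  # receives input at all (degenerate bounds), every unit is eligible.
  output_pool <- if (any(mask_in)) !input_pool else rep(TRUE, n)
  if (!any(output_pool))
    stop("output-eligible pool is empty: every unit receives input; ",
         "reduce input_frac or input connection probabilities")

  K <- if (config$output_encoding == "one_hot") 2L else 1L
  p_out <- ifelse(is_e, config$p_ee, config$p_ie)
  mask_out <- matrix(FALSE, n, K)
  for (i in which(output_pool))
    mask_out[i, ] <- runif(K) < p_out[i]
  W_out <- matrix(0, n, K)
  idx <- which(mask_out)
  if (length(idx)) {
    draw <- rlnorm(length(idx), config$lognormal_mu, config$lognormal_sigma)
    pre_e <- is_e[(idx - 1L) %% n + 1L]
    W_out[idx] <- ifelse(pre_e, draw, -config$i_scale * draw)
  }

  weights$W_in <- W_in
  weights$mask_in <- mask_in
  weights$W_out <- W_out
  weights$mask_out <- mask_out
  weights$input_pool <- input_pool
  weights$output_pool <- output_pool
  weights$receives_input <- receives_input
  weights
}

#' Apply a structural variant
#'
#' Applies the ablation flags of the configuration to a constructed
#' `weight_set`: `remove_ee` zeroes the e->e block of the recurrent matrix
#' and marks it non-regrowable; `dale_enforced = FALSE` records that sign
#' constraints (and hence rewiring) are dropped during training while the
#' initial signs are kept.
#'
#' @param weights a complete `weight_set`.
#' @param config the [network_config()] carrying the variant flags.
#' @return The transformed `weight_set`.
#' @export
apply_variant <- function(weights, config) {
  stopifnot(inherits(weights, "weight_set"))
  weights$config <- config
  if (config$remove_ee) {
    ee <- outer(weights$is_e, weights$is_e, `&`)
    weights$W_rec[ee] <- 0
    weights$mask_rec[ee] <- FALSE
    weights$ee_blocked <- TRUE
  } else {
    weights$ee_blocked <- FALSE
  }
  weights
}

#' Construct a complete network
#'
#' Convenience wrapper: [sample_recurrent_weights()], [build_io_layers()],
#' [apply_variant()] in order, optionally under a fixed seed.
#'
#' @param config a [network_config()]; its `seed` field (if set) seeds the
#'   construction.
#' @return A `weight_set`.
#' @examples
#' ws <- build_network(network_config(n_e = 40, n_i = 10, seed = 1))
#' summary(ws$W_rec[ws$mask_rec])
#' @export
build_network <- function(config = network_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ws <- sample_recurrent_weights(config)
  ws <- build_io_layers(ws, config)
  apply_variant(ws, config)
}

#' Check the structural invariants of a weight set
#'
#' Verifies sign homogeneity under Dale's law, an exactly-zero recurrent
#' diagonal, mask/nonzero agreement in every layer, and disjointness of
#' input-receiving and output-projecting units. Used throughout the test
#' suite and after every training batch in debug runs.
#'
#' @param ws a `weight_set`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_weight_set <- function(ws) {
  stopifnot(inherits(ws, "weight_set"))
  n <- length(ws$sign)
  if (any(diag(ws$W_rec) != 0)) stop("recurrent diagonal must be zero")
  if (!identical(unname(ws$W_rec != 0), unname(ws$mask_rec)))
    stop("recurrent nonzeros disagree with mask")
  if (!is.null(ws$W_in)) {
    if (!identical(unname(ws$W_in != 0), unname(ws$mask_in)))
      stop("input nonzeros disagree with mask")
    if (!identical(unname(ws$W_out != 0), unname(ws$mask_out)))
      stop("output nonzeros disagree with mask")
    rec_out <- rowSums(ws$W_out != 0) > 0
    if (any(ws$receives_input & rec_out))
      stop("a unit both receives input and projects to output")
  }
  if (isTRUE(ws$config$dale_enforced)) {
    sgn <- matrix(ws$sign, n, n)
    bad <- ws$W_rec * sgn < 0
    if (any(bad)) stop("Dale violation in recurrent weights")
    if (!is.null(ws$W_out)) {
      sgn_out <- matrix(ws$sign, n, ncol(ws$W_out))
      if (any(ws$W_out * sgn_out < 0)) stop("Dale violation in output weights")
      if (any(ws$W_in < 0)) stop("negative input weight")
    }
  }
  invisible(TRUE)
}

#' @export
print.weight_set <- function(x, ...) {
  n <- length(x$sign)
  cat(sprintf("weight_set: %d units (%d e, %d i)\n",
              n, sum(x$is_e), sum(!x$is_e)))
  if (!is.null(x$W_in))
    cat(sprintf("  input  %d x %d, %d active\n",
                nrow(x$W_in), n, sum(x$mask_in)))
  cat(sprintf("  recur  %d x %d, %d active (density %.3f)\n",
              n, n, sum(x$mask_rec), sum(x$mask_rec) / (n * (n - 1))))
  if (!is.null(x$W_out))
    cat(sprintf("  output %d x %d, %d active\n",
                n, ncol(x$W_out), sum(x$mask_out)))
  invisible(x)
}
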