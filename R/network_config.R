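#' Network construction parameters
#'
#' Bundles every constant that defines the architecture of the recurrent
#' spiking network: population sizes, per-class connection probabilities,
#' the log-normal weight distribution of excitatory synapses, the inhibitory
#' magnitude multiplier, input-weight bounds, and the structural variant
#' flags used in the ablation experiments.
#'
#' Defaults follow mouse-neocortex statistics: 240 excitatory and 60
#' inhibitory units (4:1), connection probabilities
#' p(e->e) = 0.160, p(e->i) = 0.205, p(i->e) = 0.252, p(i->i) = 0.284,
#' excitatory weights log-normal with log-mean -0.64 and log-sd 0.51
#' (arithmetic mean 0.6005 mV), inhibitory weights drawn from the same
#' distribution, negated and scaled by `i_scale` (10 by default; 1.5 for the
#' weak-inhibition variant). Input weights are uniform on
#' `[input_w_min, input_w_max]` (default \[0, 0.4\] mV).
#'
#' @param n_e,n_i number of excitatory / inhibitory units.
#' @param n_channels number of input channels.
#' @param p_ee,p_ei,p_ie,p_ii connection probabilities by
#'   (presynaptic, postsynaptic) type, each in \[0, 1\].
#' @param lognormal_mu,lognormal_sigma log-space parameters of the
#'   excitatory weight distribution (mV).
#' @param i_scale positive multiplier applied to inhibitory weight
#'   magnitudes relative to excitatory draws.
#' @param input_w_min,input_w_max bounds of the uniform input-weight
#'   distribution (mV).
#' @param input_frac fraction of units eligible to receive input; the
#'   complementary pool is eligible to project to the output, enforcing the
#'   constraint that no unit both receives input and drives the output.
#' @param dale_enforced keep each unit's outgoing weights sign-homogeneous
#'   during training (Dale's law) and rewire pruned connections.
#' @param remove_ee zero the e->e block at construction and forbid its
#'   regrowth (recurrent-excitation ablation).
#' @param output_encoding `"single"` (one readout unit reporting the label
#'   level) or `"one_hot"` (two readout units, argmax decodes the label).
#' @param seed optional integer; when given, construction is reproducible.
#'
#' @return An object of class `network_config`.
#' @seealso [build_network()]
#' @export
network_config <- function(n_e = 240L, n_i = 60L, n_channels = 16L,
                           p_ee = 0.160, p_ei = 0.205,
                           p_ie = 0.252, p_ii = 0.284,
                           lognormal_mu = -0.64, lognormal_sigma = 0.51,
                           i_scale = 10, input_w_min = 0, input_w_max = 0.4,
                           input_frac = 0.5,
                           dale_enforced = TRUE, remove_ee = FALSE,
                           output_encoding = c("single", "one_hot"),
                           seed = NULL) {
  output_encoding <- match.arg(output_encoding)
  cfg <- list(n_e = as.integer(n_e), n_i = as.integer(n_i),
              n_channels = as.integer(n_channels),
              p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              i_scale = i_scale,
              input_w_min = input_w_min, input_w_max = input_w_max,
              input_frac = input_frac,
              dale_enforced = isTRUE(dale_enforced),
              remove_ee = isTRUE(remove_ee),
              output_encoding = output_encoding,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$n_e < 0L || cfg$n_i < 0L || cfg$n_e + cfg$n_i < 1L)
    stop("need at least one unit (n_e + n_i >= 1)")
  probs <- c(cfg$p_ee, cfg$p_ei, cfg$p_ie, cfg$p_ii)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (!is.finite(cfg$lognormal_sigma) || cfg$lognormal_sigma <= 0)
    stop("lognormal_sigma must be positive")
  if (!is.finite(cfg$i_scale) || cfg$i_scale <= 0)
    stop("i_scale must be positive")
  if (cfg$input_w_max < cfg$input_w_min)
    stop("input_w_max must be >= input_w_min")
  if (cfg$input_frac < 0 || cfg$input_frac > 1)
    stop("input_frac must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("Recurrent SNN configuration\n")
  cat(sprintf("  units: %d e + %d i, %d input channels, %s output\n",
              x$n_e, x$n_i, x$n_channels, x$output_encoding))
  cat(sprintf("  p(e>e)=%.3f p(e>i)=%.3f p(i>e)=%.3f p(i>i)=%.3f\n",
              x$p_ee, x$p_ei, x$p_ie, x$p_ii))
  cat(sprintf("  e weights ~ lognormal(%.2f, %.2f), i = -%g x draw\n",
              x$lognormal_mu, x$lognormal_sigma, x$i_scale))
  cat(sprintf("  input weights ~ U[%g, %g] on %.0f%% of units\n",
              x$input_w_min, x$input_w_max, 100 * x$input_frac))
  cat(sprintf("  Dale enforced: %s; e->e removed: %s\n",
              x$dale_enforced, x$remove_ee))
  invisible(x)
}
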