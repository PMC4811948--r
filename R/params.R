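#' Temporal-memory network parameters
#'
#' Bundles and validates the parameters of the sequence-memory network.
#' Defaults follow the full-scale simulation configuration: 2048
#' mini-columns of 32 cells, 40 active columns per input (2% sparsity),
#' an NMDA threshold of 15 connected synapses, up to 128 basal segments
#' per cell and 40 synapses per segment, and permanences in `[0, 1]`
#' with a connection threshold of 0.5.
#'
#' @param n_columns Number of mini-columns (N).
#' @param cells_per_column Cells per mini-column (M).
#' @param k Active columns per input; inputs of a different size are
#'   processed with a warning.
#' @param theta_activate Connected-synapse threshold for an NMDA spike;
#'   a segment is active when *more than* `theta_activate` connected
#'   synapses have active presynaptic cells (strict inequality).
#' @param theta_match Minimum positive-permanence overlap for a bursting
#'   column to reinforce its best-matching segment instead of growing a
#'   new one.
#' @param max_segments_per_cell Basal segment budget per cell; when full,
#'   the least recently active segment is evicted.
#' @param max_synapses_per_segment Synapse budget per segment.
#' @param sample_size New synapses grown per learning event (subsampling
#'   of the previously active cells).
#' @param perm_connected Permanence above which a synapse is connected.
#' @param perm_init Initial permanence of grown synapses; below
#'   `perm_connected` so that a new pattern only takes effect after
#'   several presentations.
#' @param p_plus Permanence increment for synapses with active
#'   presynaptic cells on a reinforced segment.  Rates for this model
#'   family are tuned per dataset in practice, typically below 0.1; the
#'   default sits at that canonical upper value.
#' @param p_minus Permanence decrement applied to every positive synapse
#'   of a reinforced segment (the punishment half of the Hebbian rule).
#' @param p_decay Decay applied to every positive synapse of a segment
#'   that was active while its cell did not subsequently become active:
#'   the punishment that retires segments reinforced by chance and
#'   obsolete branch predictions.  Kept several-fold smaller than
#'   `p_plus` so that genuinely recurring contexts always win, but large
#'   enough that a stale prediction dies after a few dozen exposures.
#' @param seed Integer seed for the network's private random stream
#'   (segment growth, winner choice, tie-breaking).
#' @param apical_enabled Model the apical (top-down feedback) dendritic
#'   channel; off by default.
#' @param apical_inputs Size of the feedback axon space the apical
#'   segments synapse onto.
#' @return A validated list of class `tm_params`.
#' @export
tm_params <- function(n_columns = 2048L, cells_per_column = 32L, k = 40L,
                      theta_activate = 15L, theta_match = 8L,
                      max_segments_per_cell = 128L,
                      max_synapses_per_segment = 40L, sample_size = 30L,
                      perm_connected = 0.5, perm_init = 0.21,
                      p_plus = 0.1, p_minus = 0.01, p_decay = 0.02,
                      seed = 42L, apical_enabled = FALSE,
                      apical_inputs = 2048L) {
  p <- list(n_columns = as.integer(n_columns),
            cells_per_column = as.integer(cells_per_column),
            k = as.integer(k),
            theta_activate = as.integer(theta_activate),
            theta_match = as.integer(theta_match),
            max_segments_per_cell = as.integer(max_segments_per_cell),
            max_synapses_per_segment = as.integer(max_synapses_per_segment),
            sample_size = as.integer(sample_size),
            perm_connected = as.numeric(perm_connected),
            perm_init = as.numeric(perm_init),
            p_plus = as.numeric(p_plus),
            p_minus = as.numeric(p_minus),
            p_decay = as.numeric(p_decay),
            seed = as.integer(seed),
            apical_enabled = isTRUE(apical_enabled),
            apical_inputs = as.integer(apical_inputs))
  validate_tm_params(p)
  structure(p, class = "tm_params")
}

validate_tm_params <- function(p) {
  check_count(p$n_columns, "n_columns", 1L)
  check_count(p$cells_per_column, "cells_per_column", 1L)
  check_count(p$k, "k", 1L)
  check_count(p$theta_activate, "theta_activate", 1L)
  check_count(p$theta_match, "theta_match", 1L)
  check_count(p$max_segments_per_cell, "max_segments_per_cell", 1L)
  check_count(p$max_synapses_per_segment, "max_synapses_per_segment", 1L)
  check_count(p$sample_size, "sample_size", 1L)
  if (p$k > p$n_columns)
    stop("`k` must not exceed `n_columns`", call. = FALSE)
  if (!(p$theta_match <= p$theta_activate &&
        p$theta_activate <= p$max_synapses_per_segment))
    stop("need theta_match <= theta_activate <= max_synapses_per_segment",
         call. = FALSE)
  for (f in c("perm_connected", "perm_init")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be in [0, 1]", f), call. = FALSE)
  }
  for (f in c("p_plus", "p_minus", "p_decay")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf(
    "<tm_params> %d columns x %d cells, k=%d, theta=%d (match %d)\n",
    x$n_columns, x$cells_per_column, x$k, x$theta_activate, x$theta_match))
  invisible(x)
}

#' First-order control parameters
#'
#' Returns a copy of `params` with one cell per column (`M = 1`), the
#' control network that cannot carry temporal context and therefore
#' cannot disambiguate high-order sequences.  All other parameters are
#' unchanged; idempotent.
#'
#' @param params A [tm_params()] object.
#' @return A `tm_params` object with `cells_per_column = 1`.
#' @export
first_order_params <- function(params) {
  stopifnot(inherits(params, "tm_params"))
  params$cells_per_column <- 1L
  validate_tm_params(params)
  params
}
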