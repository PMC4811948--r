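# Shared fixtures and independent reference implementations ("oracles")
# used across the suite.  Oracles are deliberately naive: exhaustive
# enumeration and dense per-segment counting, never the package's own
# code paths.

# Exhaustive false-match probability: enumerate every a-subset of
# {1..n}, count those sharing >= theta elements with the synapse set
# {1..s}.  Only feasible for small n; that is the point.
oracle_false_match <- function(n, a, s, theta) {
  if (theta > min(s, a)) return(0)
  pats <- utils::combn(n, a)
  hits <- colSums(pats <= s) >= theta
  mean(hits)
}

# Dense per-segment prediction oracle over a tm_segments() snapshot:
# a cell is predictive iff one of its segments has more than theta
# connected synapses onto active cells.
oracle_predictions <- function(segdf, active_cells, theta, perm_connected) {
  if (nrow(segdf) == 0L) return(integer(0))
  pred <- integer(0)
  for (sg in unique(segdf$segment)) {
    d <- segdf[segdf$segment == sg, ]
    n_on <- sum(d$permanence > perm_connected & d$presyn %in% active_cells)
    if (n_on > theta) pred <- c(pred, d$cell[1L])
  }
  sort(unique(pred))
}

# Small network configuration used by most unit tests: 12 columns of
# 3 cells, 4 active columns, low thresholds so tiny patterns register.
tiny_params <- function(...) {
  args <- modifyList(
    list(n_columns = 12L, cells_per_column = 3L, k = 4L,
         theta_activate = 2L, theta_match = 2L,
         max_segments_per_cell = 8L, max_synapses_per_segment = 10L,
         sample_size = 4L, seed = 99L),
    list(...))
  do.call(tm_params, args)
}

# Drive a network with a fixed symbol sequence (one tm_step per symbol,
# warnings about |W| != k silenced); returns per-step results.
drive <- function(net, enc_map, symbols, learn = TRUE) {
  lapply(symbols, function(s)
    suppressWarnings(tm_step(net, enc_map[[s]], learn = learn)))
}
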