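#' Exact false-match probability of a dendritic segment
#'
#' Probability that a *random* sparse pattern of `a` active cells in a
#' population of `n` cells activates at least `theta` of the `s` synapses
#' on a dendritic segment, i.e. triggers a spurious NMDA spike.  This is
#' the hypergeometric tail
#' \deqn{\sum_{b=\theta}^{s} \binom{s}{b}\binom{n-s}{a-b} / \binom{n}{a}.}
#'
#' The sum is evaluated in the log domain (log-binomials combined with
#' log-sum-exp), which keeps relative error below ~1e-11 even for values
#' of order 1e-20 that would underflow or lose all precision in a naive
#' floating-point sum.  Terms outside the hypergeometric support
#' (`a - b < 0` or `a - b > n - s`) contribute zero.
#'
#' @param n Population size (positive integer).
#' @param a Number of active cells in the population, `0 <= a <= n`.
#' @param s Number of synapses on the segment, `0 <= s <= n`.
#' @param theta NMDA spike threshold (integer, >= 1): minimum number of
#'   synapses that must fall on active cells for the segment to fire.
#' @return A probability in `[0, 1]`.
#' @examples
#' false_match_probability(200000, 2000, 10, 10)   # ~9.8e-21
#' false_match_probability(1024, 20, 15, 8)
#' @export
false_match_probability <- function(n, a, s, theta) {
  check_count(n, "n", min = 1L)
  check_count(a, "a", min = 0L)
  check_count(s, "s", min = 0L)
  check_count(theta, "theta", min = 1L)
  if (a > n) stop("`a` must not exceed `n`", call. = FALSE)
  if (s > n) stop("`s` must not exceed `n`", call. = FALSE)
  b <- seq.int(theta, length.out = max(0L, s - theta + 1L))
  b <- b[a - b >= 0 & a - b <= n - s]
  if (length(b) == 0L) return(0)
  log_terms <- lchoose(s, b) + lchoose(n - s, a - b) - lchoose(n, a)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(p, 1)
}

#' Noise tolerance of an oversampled segment
#'
#' A segment storing `s` synapses for a pattern but needing only `theta`
#' coincident inputs still fires when up to `s - theta` of the stored
#' cells are silenced; the tolerated fraction is `(s - theta) / s`.
#' With s = 20 and theta = 10 a segment recognizes its pattern even when
#' half of the pattern's cells are inactive or changed.
#'
#' @inheritParams false_match_probability
#' @return Fraction in `[0, 1]` of the stored pattern that may be missing.
#' @export
noise_tolerance <- function(s, theta) {
  check_count(s, "s", min = 1L)
  check_count(theta, "theta", min = 1L)
  if (theta > s) stop("`theta` must not exceed `s`", call. = FALSE)
  (s - theta) / s
}

#' Number of patterns one neuron can store
#'
#' With a fixed synapse budget and a fixed number of synapses allocated
#' per stored pattern, a neuron recognizes
#' `floor(total_synapses / synapses_per_pattern)` independent patterns
#' (e.g. 6000 synapses at 20 per pattern: about 300 patterns).
#'
#' @param total_synapses Total synapse budget of the neuron (positive).
#' @param synapses_per_pattern Synapses allocated per stored pattern
#'   (positive).
#' @return Integer pattern count.
#' @export
patterns_per_neuron <- function(total_synapses, synapses_per_pattern) {
  check_count(total_synapses, "total_synapses", min = 1L)
  check_count(synapses_per_pattern, "synapses_per_pattern", min = 1L)
  total_synapses %/% synapses_per_pattern
}

#' Transition capacity of a sequence-memory network
#'
#' The network stores transitions, not whole sequences.  Capacity is the
#' expected duty cycle of one neuron (cells per column divided by the
#' column sparsity) times the number of patterns each neuron recognizes
#' on its basal dendrites, rounded down.  For 32 cells per column, 2%
#' column sparsity, and 200 patterns per cell this is 320,000
#' transitions, and it scales linearly in `patterns_per_cell`.
#'
#' @param cells_per_column Cells per mini-column (positive integer).
#' @param column_sparsity Fraction of columns active per input, in (0, 1].
#' @param patterns_per_cell Patterns recognizable per neuron (positive).
#' @return Integer transition count.
#' @export
transition_capacity <- function(cells_per_column, column_sparsity,
                                patterns_per_cell) {
  check_count(cells_per_column, "cells_per_column", min = 1L)
  check_count(patterns_per_cell, "patterns_per_cell", min = 1L)
  if (!is.numeric(column_sparsity) || length(column_sparsity) != 1L ||
      is.na(column_sparsity) || column_sparsity <= 0 || column_sparsity > 1)
    stop("`column_sparsity` must be a single value in (0, 1]", call. = FALSE)
  x <- (cells_per_column / column_sparsity) * patterns_per_cell
  # guard against 0.02-style binary round-off before flooring
  floor(x + 1e-9)
}

#' Number of distinct context representations of one input
#'
#' With `active_columns` columns active per input and one cell active per
#' column, an input can be represented in
#' `cells_per_column ^ active_columns` distinct ways (e.g. 32^40), each
#' encoding a different temporal context.  The result exceeds double
#' precision for realistic parameters, so it is computed with exact
#' big-integer arithmetic and returned as a decimal string.
#'
#' @param active_columns Number of active columns per input (>= 1).
#' @param cells_per_column Cells per mini-column (>= 1).
#' @return Exact count as a decimal character string.
#' @examples
#' representation_count(2, 3)  # "9"
#' @export
representation_count <- function(active_columns, cells_per_column) {
  check_count(active_columns, "active_columns", min = 1L)
  check_count(cells_per_column, "cells_per_column", min = 1L)
  big_pow(cells_per_column, active_columns)
}

#' Monte-Carlo false-match probability of a shared segment
#'
#' When synapse sets recognizing `stored_sets` different patterns are
#' mixed on one dendritic segment, the segment fires whenever at least
#' `theta` synapses of the pooled (union) set fall on active cells, which
#' adds error beyond the single-pattern rate.  The overlap of a uniform
#' random `a`-of-`n` pattern with a fixed synapse set is exactly
#' hypergeometric, so each Monte-Carlo trial draws that overlap directly.
#'
#' Also reported is the probability that at least one of the stored sets
#' would have fired had each been on its own segment,
#' `1 - (1 - p1)^stored_sets` with `p1` from
#' [false_match_probability()]: the no-mixing baseline against which the
#' mixing penalty can be read off.
#'
#' @inheritParams false_match_probability
#' @param stored_sets Number of independently stored synapse sets mixed
#'   on the segment (>= 1).
#' @param trials Number of Monte-Carlo trials (>= 1).
#' @param seed Integer seed for reproducibility.
#' @return A list with `estimate`, `stderr`, `union_size` (number of
#'   distinct synapses after mixing), `separate_bound`
#'   (`1 - (1 - p1)^stored_sets`), and `trials`.
#' @export
shared_segment_false_match <- function(n, a, s, theta, stored_sets = 1L,
                                       trials = 100000L, seed = 1L) {
  check_count(n, "n", min = 1L)
  check_count(a, "a", min = 0L)
  check_count(s, "s", min = 1L)
  check_count(theta, "theta", min = 1L)
  check_count(stored_sets, "stored_sets", min = 1L)
  check_count(trials, "trials", min = 1L)
  if (a > n) stop("`a` must not exceed `n`", call. = FALSE)
  if (stored_sets * s > n)
    stop("stored_sets * s exceeds the population size", call. = FALSE)
  p1 <- false_match_probability(n, a, s, theta)
  if (theta > a) {
    return(list(estimate = 0, stderr = 0, union_size = NA_integer_,
                separate_bound = 0, trials = trials))
  }
  est <- with_seed(seed, {
    sets <- replicate(stored_sets, sample.int(n, s), simplify = FALSE)
    u <- length(unique(unlist(sets)))
    overlap <- stats::rhyper(trials, m = u, n = n - u, k = a)
    c(mean(overlap >= theta), u)
  })
  p <- est[[1L]]
  list(estimate = p,
       stderr = sqrt(p * (1 - p) / trials),
       union_size = as.integer(est[[2L]]),
       separate_bound = 1 - (1 - p1)^stored_sets,
       trials = as.integer(trials))
}

#' Table of false-match probabilities over a parameter grid
#'
#' Evaluates [false_match_probability()] over the cross product of
#' population specifications `(n, a)` and segment specifications
#' `(s, theta)`, in the style of supplementary error tables.
#'
#' @param n,a Equal-length vectors of population sizes and active-cell
#'   counts (recycled against each other pairwise).
#' @param s,theta Equal-length vectors of synapse counts and thresholds
#'   (pairwise).
#' @return A data.frame with columns `n`, `a`, `s`, `theta`, `p_false`,
#'   one row per (population, segment) combination.
#' @export
error_table <- function(n, a, s, theta) {
  if (length(n) == 0L || length(s) == 0L)
    stop("parameter grids must be non-empty", call. = FALSE)
  pop <- data.frame(n = n, a = a)
  seg <- data.frame(s = s, theta = theta)
  grid <- merge(pop, seg, by = NULL)  # cross join
  grid$p_false <- mapply(false_match_probability,
                         grid$n, grid$a, grid$s, grid$theta)
  grid[order(grid$n, grid$a, grid$s, grid$theta), , drop = FALSE]
}

#' Write an error table to CSV
#'
#' @param table Data frame from [error_table()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_error_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != floor(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(x)
}

# Evaluate expr with a private RNG stream; global RNG state untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Minimal exact big-integer power; little-endian base-1e6 limbs so that
# schoolbook products and their partial sums stay well below 2^53.
big_pow <- function(base, exponent) {
  limb <- 1e6
  to_limbs <- function(v) {
    out <- numeric(0)
    while (v > 0 || length(out) == 0L) {
      out <- c(out, v %% limb)
      v <- v %/% limb
    }
    out
  }
  mul <- function(x, y) {
    res <- numeric(length(x) + length(y))
    for (i in seq_along(x)) {
      idx <- i:(i + length(y) - 1L)
      res[idx] <- res[idx] + x[i] * y
    }
    carry <- 0
    for (i in seq_along(res)) {
      v <- res[i] + carry
      carry <- floor(v / limb)
      res[i] <- v - carry * limb
    }
    stopifnot(carry == 0)
    while (length(res) > 1L && res[length(res)] == 0) res <- res[-length(res)]
    res
  }
  out <- to_limbs(1)
  b <- to_limbs(base)
  e <- exponent
  while (e > 0) {
    if (e %% 2 == 1) out <- mul(out, b)
    e <- e %/% 2
    if (e > 0) b <- mul(b, b)
  }
  paste0(out[length(out)],
         paste(sprintf("%06.0f", rev(out[-length(out)])), collapse = ""))
}
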