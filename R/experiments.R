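#' Exact-match prediction accuracy for one transition
#'
#' Scores a prediction 1 only when the predicted column set equals the
#' next input's column set exactly.  Exact set equality (rather than
#' containment) penalizes over-broad union predictions, so a first-order
#' network that predicts "D or F" after an ambiguous context scores 0 on
#' that transition; this is what separates it from the high-order
#' network on branching sequences.
#'
#' @param predicted_columns Integer vector: columns predicted for this
#'   step (from the previous [tm_step()]).
#' @param actual_next Integer vector: the columns of the input that
#'   actually arrived (non-empty).
#' @return 0 or 1.
#' @export
prediction_accuracy <- function(predicted_columns, actual_next) {
  if (length(actual_next) == 0L)
    stop("`actual_next` must be non-empty", call. = FALSE)
  as.numeric(length(predicted_columns) > 0L &&
               setequal(predicted_columns, actual_next))
}

# Stream a range of elements through a network, scoring each arrival
# against the prediction made at the previous step.
run_stream_segment <- function(net, symbols, enc, learn = TRUE,
                               prev_prediction = integer(0)) {
  n <- length(symbols)
  raw <- numeric(n)
  pred <- prev_prediction
  for (t in seq_len(n)) {
    w <- enc$map[[symbols[t]]]
    raw[t] <- prediction_accuracy(pred, w)
    res <- tm_step(net, w, learn = learn)
    pred <- res$predicted_columns
  }
  list(raw = raw, prediction = pred)
}

#' Run the online sequence-learning experiment
#'
#' Streams a synthetic high-order symbol stream through a fresh network
#' with learning on, scoring every arrival against the previous step's
#' prediction under the exact-match rule.  With the default stream
#' (ceiling 50%, sequence pool swapped at element 3000) the high-order
#' network's accuracy climbs to the ceiling, collapses at the swap, and
#' recovers as the new structure is learned.
#'
#' @param params A [tm_params()] object.
#' @param spec An [stream_spec()] object.
#' @param learn Learning flag (accuracy stays at 0 when off).
#' @param encoding_seed Seed for the symbol encoder (defaults to
#'   `spec$seed + 1`).
#' @param return_network Also return the trained network.
#' @return An `htm_accuracy_trace`: list with `raw` (0/1 per element),
#'   `smoothed` (200-step moving average, length `n - 199`), `window`,
#'   `ceiling` (ground-truth predictable fraction), `predictable`,
#'   `params`, `spec`, and optionally `network`.
#' @export
run_online_experiment <- function(params = tm_params(),
                                  spec = stream_spec(),
                                  learn = TRUE, encoding_seed = NULL,
                                  return_network = FALSE) {
  stopifnot(inherits(params, "tm_params"), inherits(spec, "htm_stream_spec"))
  if (is.null(encoding_seed)) encoding_seed <- spec$seed + 1L
  stream <- make_stream(spec)
  enc <- sdr_encoding(attr(stream, "alphabet"), params$n_columns,
                      params$k, seed = encoding_seed)
  net <- htm_network(params)
  seg <- run_stream_segment(net, stream$symbol, enc, learn = learn)
  trace <- accuracy_trace(seg$raw, stream$predictable, params, spec)
  if (return_network) {
    trace$network <- net
    trace$encoding <- enc
    trace$stream <- stream
    trace$last_prediction <- seg$prediction
  }
  trace
}

accuracy_trace <- function(raw, predictable, params, spec, window = 200L) {
  structure(list(raw = raw,
                 smoothed = moving_average(raw, window),
                 window = as.integer(window),
                 ceiling = mean(predictable),
                 predictable = predictable,
                 params = params, spec = spec),
            class = "htm_accuracy_trace")
}

#' Trailing moving average
#'
#' @param x Numeric vector.
#' @param window Window length `w`; the result has length
#'   `length(x) - w + 1`, element `i` averaging `x[i:(i + w - 1)]`.
#' @return Numeric vector of window means.
#' @export
moving_average <- function(x, window = 200L) {
  check_count(window, "window", min = 1L)
  if (length(x) < window) return(numeric(0))
  as.numeric(stats::filter(x, rep(1 / window, window),
                           sides = 1))[window:length(x)]
}

#' Converged accuracy of a trace
#'
#' Mean raw correctness over the `window` elements ending at `at`
#' (default: the last pre-swap element, or the end of the run for
#' swap-free streams).
#'
#' @param trace An `htm_accuracy_trace`.
#' @param at Last element of the evaluation window.
#' @param window Number of elements averaged (default 500).
#' @return Mean accuracy in `[0, 1]`.
#' @export
converged_accuracy <- function(trace, at = NULL, window = 500L) {
  stopifnot(inherits(trace, "htm_accuracy_trace"))
  if (is.null(at))
    at <- if (!is.null(trace$spec$swap_at))
      min(trace$spec$swap_at, length(trace$raw)) else length(trace$raw)
  stopifnot(at >= window)
  mean(trace$raw[(at - window + 1L):at])
}

#' First element at which the moving average reaches the ceiling
#'
#' @param trace An `htm_accuracy_trace`.
#' @param tol How close (in accuracy) to the ceiling counts as reached.
#' @return The element index at the end of the first qualifying window,
#'   or `NA` if never reached.
#' @export
steps_to_ceiling <- function(trace, tol = 0.03) {
  stopifnot(inherits(trace, "htm_accuracy_trace"))
  hit <- which(trace$smoothed >= trace$ceiling - tol)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] + trace$window - 1L
}

#' @export
print.htm_accuracy_trace <- function(x, ...) {
  cat(sprintf(
    "<htm_accuracy_trace> %d elements, ceiling %.2f, final MA %.3f\n",
    length(x$raw), x$ceiling,
    if (length(x$smoothed)) x$smoothed[length(x$smoothed)] else NA))
  invisible(x)
}

#' @export
plot.htm_accuracy_trace <- function(x, ...) {
  n <- length(x$raw)
  plot(NA, xlim = c(1, n), ylim = c(0, 1), xlab = "element",
       ylab = sprintf("prediction accuracy (%d-step MA)", x$window), ...)
  graphics::abline(h = x$ceiling, lty = 2, col = "grey40")
  if (!is.null(x$spec$swap_at) && x$spec$swap_at <= n)
    graphics::abline(v = x$spec$swap_at, lty = 3, col = "grey40")
  if (length(x$smoothed))
    graphics::lines(seq.int(x$window, n), x$smoothed, col = "red")
  invisible(x)
}

#' Write an accuracy trace as CSV
#'
#' Columns `step,raw,smoothed` (smoothed is `NA` for the first
#' `window - 1` steps).
#'
#' @param trace An `htm_accuracy_trace`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$raw)
  smoothed <- c(rep(NA_real_, trace$window - 1L), trace$smoothed)
  utils::write.csv(data.frame(step = seq_len(n), raw = trace$raw,
                              smoothed = smoothed[seq_len(n)]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run the lesion-robustness experiment
#'
#' Trains a network to stable performance on a swap-free stream, then
#' for each cell-death fraction: clones the trained network, kills that
#' fraction of cells uniformly at random, measures accuracy immediately
#' after the lesion, lets the network keep learning, and measures the
#' recovered accuracy.  Oversampled segments (more synapses than the
#' NMDA threshold) make performance nearly immune to 40% cell death;
#' beyond that it drops and then recovers through relearning.
#'
#' @param params A [tm_params()] object.
#' @param spec An [stream_spec()] object; its swap is disabled and its
#'   `total_elements` must cover
#'   `train_steps + measure_steps + relearn_steps`.
#' @param fractions Cell-death fractions to test.
#' @param train_steps Elements of pre-lesion training.
#' @param measure_steps Window for the immediate post-lesion accuracy.
#' @param relearn_steps Further learning steps before the recovered
#'   accuracy is measured (over the final 500).
#' @return A data.frame (class `htm_lesion_result`) with one row per
#'   fraction: `fraction`, `pre_accuracy`, `immediate_accuracy`,
#'   `recovered_accuracy`.
#' @export
run_lesion_experiment <- function(params = tm_params(),
                                  spec = stream_spec(swap_at = NULL),
                                  fractions = c(0, 0.4, 0.6),
                                  train_steps = 3000L,
                                  measure_steps = 500L,
                                  relearn_steps = 2500L,
                                  encoding_seed = NULL) {
  stopifnot(inherits(params, "tm_params"), inherits(spec, "htm_stream_spec"))
  stopifnot(all(fractions >= 0 & fractions <= 1))
  if (is.null(encoding_seed)) encoding_seed <- spec$seed + 1L
  spec$swap_at <- NULL
  need <- train_steps + measure_steps + relearn_steps
  if (spec$total_elements < need) spec$total_elements <- as.integer(need)
  stream <- make_stream(spec)
  enc <- sdr_encoding(attr(stream, "alphabet"), params$n_columns,
                      params$k, seed = encoding_seed)
  net <- htm_network(params)
  tr <- run_stream_segment(net, stream$symbol[seq_len(train_steps)], enc)
  pre <- mean(tr$raw[(train_steps - 499L):train_steps])
  after <- (train_steps + 1L):(train_steps + measure_steps)
  relearn <- (train_steps + measure_steps + 1L):need
  out <- data.frame(fraction = fractions, pre_accuracy = pre,
                    immediate_accuracy = NA_real_,
                    recovered_accuracy = NA_real_)
  for (i in seq_along(fractions)) {
    netf <- tm_clone(net)
    tm_lesion(netf, fractions[i])
    seg1 <- run_stream_segment(netf, stream$symbol[after], enc,
                               prev_prediction = tr$prediction)
    out$immediate_accuracy[i] <- mean(seg1$raw)
    seg2 <- run_stream_segment(netf, stream$symbol[relearn], enc,
                               prev_prediction = seg1$prediction)
    out$recovered_accuracy[i] <-
      mean(seg2$raw[(length(seg2$raw) - 499L):length(seg2$raw)])
  }
  class(out) <- c("htm_lesion_result", "data.frame")
  out
}

#' Worked examples: two crossing sequences and apical feedback
#'
#' Trains the sequences ABCD and XBCY on a small network with disjoint
#' idealized column codes and verifies the signature behaviors of the
#' sequence memory: after training, ABC predicts exactly D's columns and
#' XBC exactly Y's; the ambiguous probe B,C (started with a burst)
#' predicts the union of D and Y; the two context representations of C
#' share no cells; and with a constant feedback pattern F present while
#' ABCD was learned, F alone depolarizes the whole B'C'D' chain, F plus
#' input B yields the single-cell-per-column representation B', and F
#' plus an input from the unrelated sequence makes all its columns burst.
#'
#' @param seed Network seed.
#' @param reps Training presentations per sequence.
#' @return A list of class `htm_worked_examples`: per-check `pass` flags
#'   with details, and `all_pass`.
#' @export
worked_example_suite <- function(seed = 7L, reps = 40L) {
  p <- tm_params(n_columns = 64L, cells_per_column = 6L, k = 8L,
                 theta_activate = 6L, theta_match = 6L,
                 max_segments_per_cell = 32L,
                 max_synapses_per_segment = 32L, sample_size = 8L,
                 seed = seed, apical_enabled = TRUE, apical_inputs = 256L)
  # idealized illustration encoding: disjoint 8-column blocks per symbol
  symbols <- c("A", "B", "C", "D", "X", "Y")
  enc_map <- split(seq_len(48L), rep(seq_along(symbols), each = 8L))
  names(enc_map) <- symbols
  feedback <- 101L:124L
  net <- htm_network(p)
  seqs <- list(c("A", "B", "C", "D"), c("X", "B", "C", "Y"))
  # phase 1: learn both sequences through the basal channel
  for (r in seq_len(reps)) {
    for (s in seq_along(seqs)) {
      tm_reset(net)
      for (sym in seqs[[s]])
        tm_step(net, enc_map[[sym]], learn = TRUE)
    }
  }
  # phase 2: replay the already-learned ABCD under constant feedback so
  # its winner cells grow apical synapses to the feedback pattern
  for (r in seq_len(reps)) {
    tm_reset(net)
    for (sym in seqs[[1L]])
      tm_step(net, enc_map[[sym]], learn = TRUE, feedback = feedback)
  }
  probe <- function(syms) {
    tm_reset(net)
    acts <- vector("list", length(syms))
    pred <- NULL
    for (i in seq_along(syms)) {
      res <- tm_step(net, enc_map[[syms[i]]], learn = FALSE)
      acts[[i]] <- res$active_cells
      pred <- res$predicted_columns
    }
    list(active = acts, predicted_columns = pred)
  }
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- list(name = name, pass = isTRUE(pass),
                                           detail = detail)
  }
  abc <- probe(c("A", "B", "C"))
  add("ABC predicts exactly D",
      setequal(abc$predicted_columns, enc_map$D),
      sprintf("%d predicted columns", length(abc$predicted_columns)))
  xbc <- probe(c("X", "B", "C"))
  add("XBC predicts exactly Y",
      setequal(xbc$predicted_columns, enc_map$Y),
      sprintf("%d predicted columns", length(xbc$predicted_columns)))
  bc <- probe(c("B", "C"))
  add("ambiguous BC predicts D and Y",
      setequal(bc$predicted_columns, c(enc_map$D, enc_map$Y)),
      sprintf("%d predicted columns", length(bc$predicted_columns)))
  c1 <- abc$active[[3L]]
  c2 <- xbc$active[[3L]]
  add("context representations of C are disjoint",
      length(intersect(c1, c2)) == 0L,
      sprintf("|C'| = %d, |C''| = %d, shared %d",
              length(c1), length(c2), length(intersect(c1, c2))))
  add("one active cell per column on learned sequences",
      length(c1) == length(enc_map$C) && length(c2) == length(enc_map$C))
  # apical feedback: whole-sequence depolarization
  chain <- sort(unique(c(abc$active[[2L]], abc$active[[3L]],
                         tm_predictions(net, abc$active[[3L]]))))
  depol <- apical_overlay(net, feedback)
  add("feedback alone depolarizes the B'C'D' chain",
      setequal(depol, chain),
      sprintf("%d depolarized vs %d chain cells", length(depol),
              length(chain)))
  tm_reset(net)
  suppressWarnings(tm_step(net, integer(0), learn = FALSE,
                           feedback = feedback))
  resb <- tm_step(net, enc_map$B, learn = FALSE, feedback = feedback)
  add("feedback then B gives sparse B' representation",
      length(resb$active_cells) == length(enc_map$B) &&
        all(resb$active_cells %in% chain),
      sprintf("%d active cells", length(resb$active_cells)))
  tm_reset(net)
  suppressWarnings(tm_step(net, integer(0), learn = FALSE,
                           feedback = feedback))
  resx <- tm_step(net, enc_map$X, learn = FALSE, feedback = feedback)
  add("feedback then unrelated input bursts (anomaly)",
      length(resx$burst_columns) == length(enc_map$X),
      sprintf("%d of %d columns burst", length(resx$burst_columns),
              length(enc_map$X)))
  structure(list(checks = checks,
                 all_pass = all(vapply(checks, `[[`, TRUE, "pass"))),
            class = "htm_worked_examples")
}

#' @export
print.htm_worked_examples <- function(x, ...) {
  for (chk in x$checks)
    cat(sprintf("[%s] %s%s\n", if (chk$pass) "PASS" else "FAIL", chk$name,
                if (nzchar(chk$detail)) paste0(" (", chk$detail, ")") else ""))
  cat(if (x$all_pass) "all checks passed\n" else "SOME CHECKS FAILED\n")
  invisible(x)
}
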