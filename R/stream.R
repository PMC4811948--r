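#' Specification of a synthetic high-order symbol stream
#'
#' Defines the stream used in the online-learning simulations: a pool of
#' paired six-element sequences embedded among random filler symbols.
#' The two members of a pair share their three interior elements and
#' differ in the first element and the last two (pattern
#' `X A B C D E` / `Y A B C F G`), so the final transitions can only be
#' predicted with high-order (more than one step of) temporal context.
#' Each block is one sequence followed by `noise_gap` filler symbols
#' drawn independently and uniformly from a disjoint filler alphabet.
#'
#' With sequences of length 6 and `noise_gap = 4`, 5 of every 10
#' transitions are deterministic given full history, so the best possible
#' average prediction accuracy (the stream's ceiling) is 50%.
#'
#' @param n_pairs Number of sequence pairs in the pool (default 2, i.e.
#'   4 sequences).
#' @param noise_gap Filler symbols between sequence instances.
#' @param noise_alphabet_size Size of the disjoint filler alphabet.
#' @param total_elements Stream length in symbols.
#' @param swap_at Element index after which the embedded sequences are
#'   replaced by freshly generated pairs over new symbols (applied at the
#'   first block boundary at or after `swap_at`); `NULL` for no swap.
#' @param seed Integer seed driving sequence choice and filler draws.
#' @return An object of class `htm_stream_spec`.
#' @export
stream_spec <- function(n_pairs = 2L, noise_gap = 4L,
                        noise_alphabet_size = 50L, total_elements = 6000L,
                        swap_at = 3000L, seed = 1L) {
  check_count(n_pairs, "n_pairs", min = 1L)
  check_count(noise_gap, "noise_gap", min = 0L)
  check_count(noise_alphabet_size, "noise_alphabet_size", min = 1L)
  check_count(total_elements, "total_elements", min = 1L)
  if (!is.null(swap_at)) check_count(swap_at, "swap_at", min = 1L)
  structure(list(n_pairs = as.integer(n_pairs),
                 seq_len = 6L,
                 noise_gap = as.integer(noise_gap),
                 noise_alphabet_size = as.integer(noise_alphabet_size),
                 total_elements = as.integer(total_elements),
                 swap_at = if (is.null(swap_at)) NULL else as.integer(swap_at),
                 seed = as.integer(seed)),
            class = "htm_stream_spec")
}

# One pool of paired high-order sequences.  Pair p contributes symbols
# <tag>p.1 / <tag>p.2 (distinct first elements), <tag>p.i1..i3 (shared
# interior), and <tag>p.{d1,e1,d2,e2} (distinct last two per member).
make_sequence_pool <- function(n_pairs, tag) {
  pool <- vector("list", 2L * n_pairs)
  for (p in seq_len(n_pairs)) {
    nm <- function(x) sprintf("%s%d.%s", tag, p, x)
    interior <- c(nm("a"), nm("b"), nm("c"))
    pool[[2L * p - 1L]] <- c(nm("x"), interior, nm("d"), nm("e"))
    pool[[2L * p]]      <- c(nm("y"), interior, nm("f"), nm("g"))
  }
  pool
}

#' Generate a synthetic high-order stream
#'
#' Emits blocks of one embedded sequence (chosen uniformly at random from
#' the pool) followed by `noise_gap` independent filler symbols, until
#' `total_elements` symbols have been produced.  At the first block
#' boundary at or after `swap_at` the sequence pool is replaced with
#' freshly named pairs, modelling a change in the temporal statistics of
#' the world.  Each element carries a ground-truth `predictable` flag:
#' `TRUE` for within-sequence elements after the first (deterministic
#' given full history), `FALSE` for sequence starts and fillers.
#'
#' @param spec An [stream_spec()] object.
#' @return An object of class `htm_stream`: a data.frame with columns
#'   `step`, `symbol`, `predictable`, plus attributes `spec` and
#'   `alphabet` (all symbols that can occur, fillers included).
#' @export
make_stream <- function(spec) {
  stopifnot(inherits(spec, "htm_stream_spec"))
  pool_pre <- make_sequence_pool(spec$n_pairs, "S")
  pool_post <- make_sequence_pool(spec$n_pairs, "T")
  fillers <- sprintf("n%02d", seq_len(spec$noise_alphabet_size))
  total <- spec$total_elements
  sym <- character(total)
  pred <- logical(total)
  with_seed(spec$seed, {
    t <- 0L
    swapped <- FALSE
    pool <- pool_pre
    while (t < total) {
      if (!swapped && !is.null(spec$swap_at) && t + 1L >= spec$swap_at) {
        pool <- pool_post
        swapped <- TRUE
      }
      s <- pool[[sample.int(length(pool), 1L)]]
      take <- min(length(s), total - t)
      sym[t + seq_len(take)] <- s[seq_len(take)]
      pred[t + seq_len(take)] <- c(FALSE, rep(TRUE, take - 1L))
      t <- t + take
      gap <- min(spec$noise_gap, total - t)
      if (gap > 0L) {
        sym[t + seq_len(gap)] <- fillers[sample.int(length(fillers), gap,
                                                    replace = TRUE)]
        t <- t + gap
      }
    }
  })
  alphabet <- c(unlist(pool_pre), unlist(pool_post), fillers)
  alphabet <- unique(alphabet)
  structure(data.frame(step = seq_len(total), symbol = sym,
                       predictable = pred, stringsAsFactors = FALSE),
            spec = spec, alphabet = alphabet,
            class = c("htm_stream", "data.frame"))
}

#' Ground-truth accuracy ceiling of a stream
#'
#' Fraction of elements whose arrival is deterministic given full
#' history; no predictor can average better than this under exact-match
#' scoring.
#'
#' @param stream An [make_stream()] object.
#' @return A fraction in `[0, 1]`.
#' @export
stream_ceiling <- function(stream) mean(stream$predictable)

#' Read and write streams as CSV
#'
#' The on-disk format is `step,symbol,predictable` with a header row;
#' round-trips are lossless.
#'
#' @param stream An `htm_stream` (or compatible data.frame).
#' @param path File path.
#' @return `write_stream` the path invisibly; `read_stream` an
#'   `htm_stream` data.frame.
#' @export
write_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[, c("step", "symbol", "predictable")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e)
      stop(sprintf("malformed stream file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  if (!identical(names(df), c("step", "symbol", "predictable")))
    stop(sprintf("malformed stream file '%s': expected header %s",
                 path, "step,symbol,predictable"), call. = FALSE)
  df$step <- suppressWarnings(as.integer(df$step))
  df$predictable <- as.logical(df$predictable)
  bad <- which(is.na(df$step) | is.na(df$predictable))
  if (length(bad))
    stop(sprintf("malformed stream file '%s' at line %d", path, bad[1L] + 1L),
         call. = FALSE)
  structure(df, class = c("htm_stream", "data.frame"))
}

#' @export
print.htm_stream <- function(x, ...) {
  cat(sprintf("<htm_stream> %d elements, ceiling %.3f\n",
              nrow(x), mean(x$predictable)))
  invisible(x)
}
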