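#' Deterministic symbol-to-SDR encoding
#'
#' Maps each symbol of an alphabet to a fixed, randomly drawn set of `k`
#' active mini-columns out of `n_columns` (e.g. 40 of 2048, a 2% sparse
#' code).  The mapping is drawn once from a seeded generator, so the same
#' `(alphabet, n_columns, k, seed)` always yields byte-identical column
#' sets, across calls and across runs.
#'
#' @param alphabet Character vector of distinct symbols.
#' @param n_columns Total number of mini-columns.
#' @param k Active columns per symbol, `1 <= k <= n_columns`.
#' @param seed Integer seed for the column draws.
#' @return An object of class `htm_encoding`: a list with the parameters
#'   and `map`, a named list of sorted 1-based column index vectors.
#' @export
sdr_encoding <- function(alphabet, n_columns = 2048L, k = 40L, seed = 1L) {
  stopifnot(is.character(alphabet), length(alphabet) >= 1L)
  if (anyDuplicated(alphabet))
    stop("alphabet symbols must be distinct", call. = FALSE)
  check_count(n_columns, "n_columns", min = 1L)
  check_count(k, "k", min = 1L)
  if (k > n_columns) stop("`k` must not exceed `n_columns`", call. = FALSE)
  map <- with_seed(seed, {
    out <- vector("list", length(alphabet))
    for (i in seq_along(alphabet)) out[[i]] <- sort(sample.int(n_columns, k))
    out
  })
  names(map) <- alphabet
  structure(list(alphabet = alphabet, n_columns = as.integer(n_columns),
                 k = as.integer(k), seed = as.integer(seed), map = map),
            class = "htm_encoding")
}

#' Encode one symbol as a set of active columns
#'
#' @param enc An [sdr_encoding()] object.
#' @param symbol A single symbol present in the encoding's alphabet.
#' @return Sorted integer vector of `k` active column indices (1-based).
#' @export
encode_symbol <- function(enc, symbol) {
  stopifnot(inherits(enc, "htm_encoding"))
  cols <- enc$map[[as.character(symbol)]]
  if (is.null(cols))
    stop(sprintf("symbol '%s' is not in the encoding alphabet", symbol),
         call. = FALSE)
  cols
}

#' @export
print.htm_encoding <- function(x, ...) {
  cat(sprintf("<htm_encoding> %d symbols, %d of %d columns active, seed %d\n",
              length(x$alphabet), x$k, x$n_columns, x$seed))
  invisible(x)
}

#' Serialize / restore an encoding as JSON
#'
#' @param enc An [sdr_encoding()] object.
#' @param path File path.
#' @return `write_encoding` the path invisibly; `read_encoding` the
#'   restored `htm_encoding`.
#' @export
write_encoding <- function(enc, path) {
  stopifnot(inherits(enc, "htm_encoding"))
  jsonlite::write_json(
    list(n_columns = enc$n_columns, k = enc$k, seed = enc$seed,
         map = enc$map),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- lapply(x$map, as.integer)
  structure(list(alphabet = names(map), n_columns = as.integer(x$n_columns),
                 k = as.integer(x$k), seed = as.integer(x$seed), map = map),
            class = "htm_encoding")
}
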