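MODEL_FORMAT <- "htmseq-model-1"

pool_dump <- function(pool) {
  segs <- which(pool$seg_alive[seq_len(pool$n_seg)])
  list(n_seg = pool$n_seg,
       segments = lapply(segs, function(s) {
         ids <- pool_seg_synapses(pool, s)
         list(id = s, owner = pool$seg_owner[s],
              last_used = pool$seg_last_used[s],
              pre = pool$syn_pre[ids], perm = pool$syn_perm[ids])
       }))
}

pool_restore <- function(pool, dump) {
  # rebuild alive segments under fresh ids; returns old-id -> new-id map
  id_map <- integer(dump$n_seg)
  for (s in dump$segments) {
    new <- pool_grow_segment(pool, as.integer(s$owner), as.integer(s$pre),
                             as.numeric(s$perm), as.numeric(s$last_used))
    pool$seg_last_used[new] <- as.numeric(s$last_used)
    id_map[as.integer(s$id)] <- new
  }
  id_map
}

#' Save / load a network
#'
#' Serializes the complete network — parameters, every live segment and
#' synapse permanence, lesion mask, dynamic state, and the private RNG
#' state — as JSON.  A reloaded network continues exactly where the
#' saved one left off: subsequent trajectories are identical.
#'
#' @param net An [htm_network()] object.
#' @param path File path.
#' @return `save_model` the path invisibly; `load_model` the restored
#'   network.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "htm_network"))
  obj <- list(format = MODEL_FORMAT,
              params = unclass(net$p),
              step = net$step,
              lesioned = which(net$lesioned),
              rng_state = net$rng_state,
              state = list(active = net$active, winners = net$winners,
                           pi = net$pi, pi_basal = net$pi_basal,
                           pi_apical = net$pi_apical,
                           active_segments = net$active_segments,
                           pos_seg = net$pos_seg, pos_cnt = net$pos_cnt),
              basal = pool_dump(net$basal),
              apical = if (is.null(net$apical)) NULL
                       else pool_dump(net$apical))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, MODEL_FORMAT))
    stop(sprintf("unsupported model format '%s' (expected '%s')",
                 obj$format, MODEL_FORMAT), call. = FALSE)
  params <- do.call(tm_params, obj$params)
  net <- htm_network(params)
  net$step <- as.integer(obj$step)
  net$lesioned[as.integer(obj$lesioned)] <- TRUE
  net$rng_state <- as.integer(obj$rng_state)
  map <- pool_restore(net$basal, obj$basal)
  if (!is.null(obj$apical) && !is.null(net$apical))
    pool_restore(net$apical, obj$apical)
  iv <- function(x) if (is.null(x)) integer(0) else as.integer(x)
  net$active <- iv(obj$state$active)
  net$winners <- iv(obj$state$winners)
  net$pi <- iv(obj$state$pi)
  net$pi_basal <- iv(obj$state$pi_basal)
  net$pi_apical <- iv(obj$state$pi_apical)
  net$pi_mask <- {
    m <- logical(net$n_cells)
    m[net$pi] <- TRUE
    m
  }
  remap <- function(ids) {
    ids <- iv(ids)
    out <- map[ids]
    out[!is.na(out) & out > 0L]
  }
  net$active_segments <- remap(obj$state$active_segments)
  pos <- iv(obj$state$pos_seg)
  cnt <- iv(obj$state$pos_cnt)
  keep <- map[pos] > 0L
  net$pos_seg <- map[pos[keep]]
  net$pos_cnt <- cnt[keep]
  net
}
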