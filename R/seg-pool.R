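# Mutable store for one dendritic channel (basal or apical): segments,
# their synapses, and the inverted presynaptic index used to score
# overlaps against the (small) set of active sources each step.
#
# Layout: flat parallel arrays with capacity doubling (atomic vectors
# sub-assigned in place), plus three ragged indices kept as hashed
# environments so that appends touch only one small vector:
#   seg_syn[[segment]]   synapse ids (may contain dead ones, filtered)
#   pre_index[[source]]  synapse ids (may contain dead ones, filtered)
#   cell_segs[[owner]]   alive segment ids; cell_nseg[owner] its length
#
# Not exported; the network object owns one pool per channel.

pool_new <- function(n_sources, n_owner_cells, cap_seg = 256L,
                     cap_syn = 4096L) {
  # parent = baseenv() so assignments can be eval()ed inside the pool
  pool <- new.env(parent = baseenv())
  pool$n_sources <- as.integer(n_sources)
  pool$n_owner <- as.integer(n_owner_cells)
  pool$n_seg <- 0L
  pool$seg_owner <- integer(cap_seg)
  pool$seg_alive <- logical(cap_seg)
  pool$seg_last_used <- numeric(cap_seg)
  pool$seg_nsyn <- integer(cap_seg)
  pool$n_syn <- 0L
  pool$syn_seg <- integer(cap_syn)
  pool$syn_pre <- integer(cap_syn)
  pool$syn_perm <- numeric(cap_syn)
  pool$syn_alive <- logical(cap_syn)
  pool$seg_syn <- new.env(hash = TRUE, parent = emptyenv())
  pool$pre_index <- new.env(hash = TRUE, parent = emptyenv(),
                            size = max(29L, n_sources))
  pool$cell_segs <- new.env(hash = TRUE, parent = emptyenv())
  pool$cell_nseg <- integer(n_owner_cells)
  pool
}

ragged_get <- function(e, key) {
  get0(key, envir = e, ifnotfound = integer(0))
}

ragged_append <- function(e, key, ids) {
  assign(key, c(get0(key, envir = e, ifnotfound = NULL), ids), envir = e)
}


# In-place sub-assignment on a pool array.  `pool$x[i] <- v` inside a
# function forces R to copy the whole array on every write; evaluating
# the assignment inside the pool environment keeps it O(length(i)).
.pq <- list(
  syn_seg = quote(syn_seg[.i] <- .v),
  syn_pre = quote(syn_pre[.i] <- .v),
  syn_perm = quote(syn_perm[.i] <- .v),
  syn_alive = quote(syn_alive[.i] <- .v),
  seg_owner = quote(seg_owner[.i] <- .v),
  seg_alive = quote(seg_alive[.i] <- .v),
  seg_last_used = quote(seg_last_used[.i] <- .v),
  seg_nsyn = quote(seg_nsyn[.i] <- .v),
  cell_nseg = quote(cell_nseg[.i] <- .v))

pool_set <- function(pool, q, i, v) {
  pool$.i <- i
  pool$.v <- v
  eval(q, pool)
  invisible()
}

pool_reserve_seg <- function(pool, extra = 1L) {
  need <- pool$n_seg + extra
  cap <- length(pool$seg_owner)
  if (need <= cap) return(invisible())
  new_cap <- max(need, 2L * cap)
  length(pool$seg_owner) <- new_cap
  length(pool$seg_alive) <- new_cap
  length(pool$seg_last_used) <- new_cap
  length(pool$seg_nsyn) <- new_cap
  pool$seg_owner[(cap + 1L):new_cap] <- 0L
  pool$seg_alive[(cap + 1L):new_cap] <- FALSE
  pool$seg_last_used[(cap + 1L):new_cap] <- 0
  pool$seg_nsyn[(cap + 1L):new_cap] <- 0L
  invisible()
}

pool_reserve_syn <- function(pool, extra) {
  need <- pool$n_syn + extra
  cap <- length(pool$syn_seg)
  if (need <= cap) return(invisible())
  new_cap <- max(need, 2L * cap)
  length(pool$syn_seg) <- new_cap
  length(pool$syn_pre) <- new_cap
  length(pool$syn_perm) <- new_cap
  length(pool$syn_alive) <- new_cap
  pool$syn_alive[(cap + 1L):new_cap] <- FALSE
  invisible()
}

# Append synapses to an existing segment; sources must be new to it.
pool_add_synapses <- function(pool, seg, sources, perm) {
  n <- length(sources)
  if (n == 0L) return(invisible())
  pool_reserve_syn(pool, n)
  ids <- pool$n_syn + seq_len(n)
  pool$n_syn <- pool$n_syn + n
  pool_set(pool, .pq$syn_seg, ids, seg)
  pool_set(pool, .pq$syn_pre, ids, sources)
  pool_set(pool, .pq$syn_perm, ids, perm)
  pool_set(pool, .pq$syn_alive, ids, TRUE)
  pool_set(pool, .pq$seg_nsyn, seg, pool$seg_nsyn[seg] + n)
  ragged_append(pool$seg_syn, as.character(seg), ids)
  keys <- as.character(sources)
  for (i in seq_len(n)) ragged_append(pool$pre_index, keys[i], ids[i])
  invisible(ids)
}

# Create a segment on `owner` with synapses to `sources` at `perm`.
pool_grow_segment <- function(pool, owner, sources, perm, now) {
  pool_reserve_seg(pool)
  seg <- pool$n_seg + 1L
  pool$n_seg <- seg
  pool_set(pool, .pq$seg_owner, seg, owner)
  pool_set(pool, .pq$seg_alive, seg, TRUE)
  pool_set(pool, .pq$seg_last_used, seg, now)
  pool_set(pool, .pq$seg_nsyn, seg, 0L)
  ragged_append(pool$cell_segs, as.character(owner), seg)
  pool_set(pool, .pq$cell_nseg, owner, pool$cell_nseg[owner] + 1L)
  pool_add_synapses(pool, seg, sources, perm)
  seg
}

pool_kill_segment <- function(pool, seg) {
  if (!pool$seg_alive[seg]) return(invisible())
  key <- as.character(seg)
  ids <- ragged_get(pool$seg_syn, key)
  ids <- ids[pool$syn_alive[ids]]
  pool_set(pool, .pq$syn_alive, ids, FALSE)
  pool_set(pool, .pq$seg_alive, seg, FALSE)
  pool_set(pool, .pq$seg_nsyn, seg, 0L)
  if (exists(key, envir = pool$seg_syn)) rm(list = key,
                                            envir = pool$seg_syn)
  owner <- pool$seg_owner[seg]
  okey <- as.character(owner)
  keep <- ragged_get(pool$cell_segs, okey)
  assign(okey, keep[keep != seg], envir = pool$cell_segs)
  pool_set(pool, .pq$cell_nseg, owner, pool$cell_nseg[owner] - 1L)
  invisible()
}

# Alive segment ids owned by one cell.
pool_cell_segments <- function(pool, cell) {
  ragged_get(pool$cell_segs, as.character(cell))
}

# Alive synapse ids of one segment.
pool_seg_synapses <- function(pool, seg) {
  ids <- ragged_get(pool$seg_syn, as.character(seg))
  ids[pool$syn_alive[ids]]
}

# Presynaptic sources currently on one segment.
pool_seg_sources <- function(pool, seg) {
  pool$syn_pre[pool_seg_synapses(pool, seg)]
}

# Score all segments against the active source set.  Returns segments
# with >= 1 positive-permanence synapse on active sources (`pos`), and
# the connected-synapse counts (`conn`), as parallel id/count vectors.
pool_overlaps <- function(pool, active_sources, conn_thresh) {
  empty <- list(pos_seg = integer(0), pos_cnt = integer(0),
                conn_seg = integer(0), conn_cnt = integer(0))
  if (length(active_sources) == 0L || pool$n_seg == 0L) return(empty)
  ids <- unlist(mget(as.character(active_sources), envir = pool$pre_index,
                     ifnotfound = list(integer(0))), use.names = FALSE)
  if (length(ids) == 0L) return(empty)
  ids <- ids[pool$syn_alive[ids]]
  if (length(ids) == 0L) return(empty)
  segs <- pool$syn_seg[ids]
  pos_tab <- tabulate(segs, nbins = pool$n_seg)
  pos_seg <- which(pos_tab > 0L)
  conn_ids <- ids[pool$syn_perm[ids] > conn_thresh]
  if (length(conn_ids)) {
    conn_tab <- tabulate(pool$syn_seg[conn_ids], nbins = pool$n_seg)
    conn_seg <- which(conn_tab > 0L)
    conn_cnt <- conn_tab[conn_seg]
  } else {
    conn_seg <- integer(0)
    conn_cnt <- integer(0)
  }
  list(pos_seg = pos_seg, pos_cnt = pos_tab[pos_seg],
       conn_seg = conn_seg, conn_cnt = conn_cnt)
}

# Destroy specific synapses of a segment (bookkeeping only; the caller
# picks which).  Used to make room on a full segment before growth.
pool_destroy_synapses <- function(pool, seg, ids) {
  if (length(ids) == 0L) return(invisible())
  pool_set(pool, .pq$syn_alive, ids, FALSE)
  pool_set(pool, .pq$seg_nsyn, seg, pool$seg_nsyn[seg] - length(ids))
  if (pool$seg_nsyn[seg] == 0L) pool_kill_segment(pool, seg)
  invisible()
}

# Free space on a full segment by removing its weakest synapses,
# sparing those whose presynaptic source is currently relevant
# (active_mask); without this, segments clogged with synapses onto
# dead or obsolete sources could never re-learn after a lesion.
pool_make_room <- function(pool, seg, n_needed, active_mask) {
  if (n_needed <= 0L) return(0L)
  ids <- pool_seg_synapses(pool, seg)
  cand <- ids[!active_mask[pool$syn_pre[ids]]]
  if (length(cand) == 0L) return(0L)
  cand <- cand[order(pool$syn_perm[cand])]
  kill <- cand[seq_len(min(n_needed, length(cand)))]
  pool_destroy_synapses(pool, seg, kill)
  length(kill)
}

# Hebbian permanence update for one reinforced segment (active source
# synapses +p_plus, every positive synapse -p_minus), clipped to [0, 1];
# synapses whose permanence reaches 0 are removed, empty segments die.
pool_reinforce <- function(pool, seg, active_mask, p_plus, p_minus) {
  ids <- pool_seg_synapses(pool, seg)
  if (length(ids) == 0L) return(invisible())
  act <- active_mask[pool$syn_pre[ids]]
  perm <- pool$syn_perm[ids] - p_minus
  perm[act] <- perm[act] + p_plus
  pool_commit_perms(pool, seg, ids, perm)
}

# Small decay on every positive synapse of a mistakenly active segment.
pool_decay <- function(pool, seg, p_decay) {
  ids <- pool_seg_synapses(pool, seg)
  if (length(ids) == 0L) return(invisible())
  pool_commit_perms(pool, seg, ids, pool$syn_perm[ids] - p_decay)
}

pool_commit_perms <- function(pool, seg, ids, perm) {
  dead <- perm <= 0
  perm <- pmin(1, pmax(0, perm))
  pool_set(pool, .pq$syn_perm, ids, perm)
  if (any(dead)) {
    pool_set(pool, .pq$syn_alive, ids[dead], FALSE)
    pool_set(pool, .pq$seg_nsyn, seg, pool$seg_nsyn[seg] - sum(dead))
    if (pool$seg_nsyn[seg] == 0L) pool_kill_segment(pool, seg)
  }
  invisible()
}
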