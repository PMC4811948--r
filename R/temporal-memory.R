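#' Create a sequence-memory network
#'
#' Builds an empty temporal-memory network: `n_columns` mini-columns of
#' `cells_per_column` cells, each cell able to grow basal (and optionally
#' apical) dendritic segments.  Cells are indexed 1-based; the cell `i`
#' of column `j` has flat id `(j - 1) * M + i`.  Segments and synapses
#' are created online by learning; nothing is pre-wired.
#'
#' The network owns a private random stream seeded from `params$seed`,
#' so identical `(params, input stream)` yield identical activity and
#' permanence trajectories.
#'
#' @param params A [tm_params()] object.
#' @return An object of class `htm_network` (an environment; functions
#'   such as [tm_step()] mutate it in place).
#' @export
htm_network <- function(params = tm_params()) {
  stopifnot(inherits(params, "tm_params"))
  net <- new.env(parent = emptyenv())
  net$p <- params
  net$n_cells <- params$n_columns * params$cells_per_column
  net$lesioned <- logical(net$n_cells)
  net$basal <- pool_new(net$n_cells, net$n_cells)
  net$apical <- if (params$apical_enabled)
    pool_new(params$apical_inputs, net$n_cells) else NULL
  net$step <- 0L
  net$rng_state <- with_seed(params$seed,
                             get(".Random.seed", envir = globalenv()))
  tm_reset(net)
  class(net) <- "htm_network"
  net
}

#' Reset the dynamic state of a network
#'
#' Clears activity, predictions, and the per-step segment bookkeeping
#' while keeping everything the network has learned.  Used to start an
#' independent probe (the continuous-stream experiments never reset).
#'
#' @param net An [htm_network()] object.
#' @return The network, invisibly.
#' @export
tm_reset <- function(net) {
  net$active <- integer(0)
  net$winners <- integer(0)
  net$pi <- integer(0)
  net$pi_basal <- integer(0)
  net$pi_apical <- integer(0)
  net$pi_mask <- logical(net$n_cells)
  net$active_segments <- integer(0)
  net$pos_seg <- integer(0)
  net$pos_cnt <- integer(0)
  invisible(net)
}

#' @export
print.htm_network <- function(x, ...) {
  cat(sprintf(
    "<htm_network> %d x %d cells, %d basal segments, %d synapses, step %d\n",
    x$p$n_columns, x$p$cells_per_column,
    sum(x$basal$seg_alive[seq_len(x$basal$n_seg)]),
    sum(x$basal$syn_alive[seq_len(x$basal$n_syn)]), x$step))
  invisible(x)
}

with_net_rng <- function(net, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  assign(".Random.seed", net$rng_state, envir = globalenv())
  res <- expr
  net$rng_state <- get(".Random.seed", envir = globalenv())
  res
}

resample <- function(x, size) {
  if (size >= length(x)) return(x[sample.int(length(x), length(x))])
  x[sample.int(length(x), size)]
}

column_of <- function(cell, M) (cell - 1L) %/% M + 1L

column_cells <- function(col, M) ((col - 1L) * M + 1L):(col * M)

#' Advance the network by one time step
#'
#' Runs one full cycle of the sequence memory on an input (the set of
#' winning columns selected by feedforward inhibition): activation of
#' cells in the winning columns (predicted cells fire alone, unpredicted
#' columns burst), Hebbian learning on the segments responsible for the
#' previous step's predictions, and computation of the new predictive
#' state for the next input.
#'
#' @param net An [htm_network()] object (mutated in place).
#' @param input_columns Integer vector of active (winning) column
#'   indices; normally of length `params$k` (a warning is emitted
#'   otherwise and the input is processed anyway).
#' @param learn Apply the plasticity rules this step.
#' @param feedback Optional integer vector of active feedback axons for
#'   the apical channel (requires `apical_enabled`); apically recognized
#'   cells are depolarized and treated as predicted alongside basally
#'   predicted ones.
#' @return A list: `active_cells`, `winner_cells`, `predicted_cells`
#'   (cells depolarized for the *next* step), `predicted_columns` (the
#'   network's prediction for the next input), `burst_columns`, and
#'   `burst_fraction`.
#' @export
tm_step <- function(net, input_columns, learn = TRUE, feedback = NULL) {
  stopifnot(inherits(net, "htm_network"))
  p <- net$p
  M <- p$cells_per_column
  W <- unique(as.integer(input_columns))
  if (length(W) && (min(W) < 1L || max(W) > p$n_columns))
    stop("input columns out of range", call. = FALSE)
  if (length(W) != p$k)
    warning(sprintf("input has %d columns, expected k = %d",
                    length(W), p$k), call. = FALSE)
  if (!is.null(feedback) && is.null(net$apical))
    feedback <- NULL  # apical channel disabled: no-op
  with_net_rng(net, {
    prev_active <- net$active
    prev_winners <- net$winners
    prev_active_seg <- net$active_segments
    prev_pos_seg <- net$pos_seg
    prev_pos_cnt <- net$pos_cnt
    net$step <- net$step + 1L
    now <- net$step

    ## -- activation --------------------------------------------------
    active <- integer(0)
    pred_active <- integer(0)   # cells activated through a prediction
    burst_cols <- integer(0)
    for (j in W) {
      cells <- column_cells(j, M)
      live <- cells[!net$lesioned[cells]]
      predicted <- live[net$pi_mask[live]]
      if (length(predicted)) {
        active <- c(active, predicted)
        pred_active <- c(pred_active, predicted)
      } else {
        active <- c(active, live)
        burst_cols <- c(burst_cols, j)
      }
    }

    ## -- learning ----------------------------------------------------
    winners <- pred_active
    apical_learners <- pred_active  # winners with a basal learning event
    if (learn) {
      active_prev_mask <- logical(net$n_cells)
      active_prev_mask[prev_active] <- TRUE
      # correctly predicted cells: reinforce every segment that was
      # active at t-1 and caused the prediction
      if (length(prev_active_seg) && length(pred_active)) {
        pa_mask <- logical(net$n_cells)
        pa_mask[pred_active] <- TRUE
        sel <- prev_active_seg[pa_mask[net$basal$seg_owner[prev_active_seg]]]
        for (seg in sel) {
          pool_reinforce(net$basal, seg, active_prev_mask,
                         p$p_plus, p$p_minus)
          pool_set(net$basal, .pq$seg_last_used, seg, now)
        }
      }
      # bursting columns: best sub-threshold match is reinforced and
      # topped up; with no match, a new segment is grown
      if (length(burst_cols)) {
        pos_owner <- net$basal$seg_owner[prev_pos_seg]
        pos_col <- column_of(pos_owner, M)
        for (j in burst_cols) {
          idx <- which(pos_col == j & !net$lesioned[pos_owner])
          best <- 0L
          if (length(idx)) {
            cnt <- prev_pos_cnt[idx]
            mx <- max(cnt)
            if (mx >= p$theta_match) {
              cand <- idx[cnt == mx]
              best <- prev_pos_seg[if (length(cand) > 1L)
                cand[sample.int(length(cand), 1L)] else cand]
            }
          }
          if (best > 0L) {
            pool_reinforce(net$basal, best, active_prev_mask,
                           p$p_plus, p$p_minus)
            if (net$basal$seg_alive[best]) {
              pool_set(net$basal, .pq$seg_last_used, best, now)
              # new synapses subsample the previous winner cells: the
              # nascent sparse context representation, so segments
              # track the code that will be active once learned
              src <- pool_seg_sources(net$basal, best)
              desired <- p$sample_size - sum(active_prev_mask[src])
              avail <- setdiff(prev_winners,
                               c(src, net$basal$seg_owner[best]))
              desired <- min(desired, length(avail))
              if (desired > 0L) {
                new_src <- resample(avail, desired)
                # one synapse per presynaptic column: when a column's
                # context cell is redesignated (winner churn, cell
                # death), the new synapse replaces the obsolete one
                # instead of accumulating alongside it
                old_syn <- pool_seg_synapses(net$basal, best)
                stale <- old_syn[column_of(net$basal$syn_pre[old_syn], M)
                                 %in% column_of(new_src, M) &
                                   !active_prev_mask[
                                     net$basal$syn_pre[old_syn]]]
                pool_destroy_synapses(net$basal, best, stale)
                room <- p$max_synapses_per_segment -
                  net$basal$seg_nsyn[best]
                if (room < desired)
                  room <- room + pool_make_room(net$basal, best,
                                                desired - room,
                                                active_prev_mask)
                if (room > 0L)
                  pool_add_synapses(net$basal, best,
                                    resample(new_src, min(desired, room)),
                                    p$perm_init)
              }
              winners <- c(winners, net$basal$seg_owner[best])
              apical_learners <- c(apical_learners,
                                   net$basal$seg_owner[best])
            }
          } else {
            owner <- grow_segment(net, j, prev_winners, now)
            if (length(owner)) {
              winners <- c(winners, owner)
              if (net$basal$cell_nseg[owner] > 0L)
                apical_learners <- c(apical_learners, owner)
            }
          }
        }
      }
      # decay segments that predicted a cell that did not become active
      if (length(prev_active_seg)) {
        a_mask <- logical(net$n_cells)
        a_mask[active] <- TRUE
        pun <- prev_active_seg[!a_mask[net$basal$seg_owner[prev_active_seg]]]
        for (seg in pun) pool_decay(net$basal, seg, p$p_decay)
      }
      # apical channel: cells that anchored a basal learning event this
      # step learn the current feedback pattern on their apical dendrites
      if (!is.null(feedback) && length(feedback) && length(apical_learners))
        apical_learn(net, unique(apical_learners), as.integer(feedback), now)
    }

    ## -- prediction for the next step --------------------------------
    ov <- pool_overlaps(net$basal, active, p$perm_connected)
    act_idx <- ov$conn_cnt > p$theta_activate
    active_segs <- ov$conn_seg[act_idx]
    if (length(active_segs)) {
      keep <- net$basal$seg_alive[active_segs] &
        !net$lesioned[net$basal$seg_owner[active_segs]]
      active_segs <- active_segs[keep]
      pool_set(net$basal, .pq$seg_last_used, active_segs, now)
    }
    pi_basal <- unique(net$basal$seg_owner[active_segs])
    pi_apical <- integer(0)
    if (!is.null(feedback) && length(feedback))
      pi_apical <- apical_depolarized(net, as.integer(feedback))
    pi <- union(pi_basal, pi_apical)

    net$active <- active
    net$winners <- unique(winners)
    net$active_segments <- active_segs
    net$pos_seg <- ov$pos_seg
    net$pos_cnt <- ov$pos_cnt
    net$pi <- pi
    net$pi_basal <- pi_basal
    net$pi_apical <- pi_apical
    net$pi_mask <- {
      m <- logical(net$n_cells)
      m[pi] <- TRUE
      m
    }

    list(active_cells = sort(active),
         winner_cells = sort(unique(winners)),
         predicted_cells = sort(pi),
         predicted_columns = sort(unique(column_of(pi, M))),
         burst_columns = sort(burst_cols),
         burst_fraction = if (length(W)) length(burst_cols) / length(W)
                          else 0)
  })
}

# Handle a bursting column with no matching segment: pick a winner cell
# (random live cell among those with the fewest segments) and, if the
# previous step produced winner cells, grow a new segment on it that
# subsamples them.  The winner is designated even when nothing can be
# grown yet, so the sparse context code exists from the first exposure.
# Returns the winner cell id, or integer(0) if the column is fully dead.
grow_segment <- function(net, col, prev_winners, now) {
  p <- net$p
  cells <- column_cells(col, p$cells_per_column)
  live <- cells[!net$lesioned[cells]]
  if (length(live) == 0L) return(integer(0))
  nseg <- net$basal$cell_nseg[live]
  cand <- live[nseg == min(nseg)]
  owner <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
  sources <- setdiff(prev_winners, owner)
  if (length(sources) == 0L) return(owner)
  if (net$basal$cell_nseg[owner] >= p$max_segments_per_cell) {
    segs <- pool_cell_segments(net$basal, owner)
    oldest <- segs[which.min(net$basal$seg_last_used[segs])]
    pool_kill_segment(net$basal, oldest)
  }
  sources <- resample(sources,
                      min(p$sample_size, p$max_synapses_per_segment,
                          length(sources)))
  pool_grow_segment(net$basal, owner, sources, p$perm_init, now)
  owner
}

#' Predictive cells for a given activity pattern (read-only)
#'
#' Scores every basal segment against an arbitrary set of active cells
#' and returns the cells that would enter the predictive state, without
#' touching the network's own state.  Intended for inspection and for
#' cross-checking against reference implementations.
#'
#' @param net An [htm_network()] object.
#' @param active_cells Integer vector of active cell ids.
#' @return Sorted integer vector of predictive cell ids.
#' @export
tm_predictions <- function(net, active_cells) {
  stopifnot(inherits(net, "htm_network"))
  ov <- pool_overlaps(net$basal, as.integer(active_cells),
                      net$p$perm_connected)
  segs <- ov$conn_seg[ov$conn_cnt > net$p$theta_activate]
  segs <- segs[net$basal$seg_alive[segs]]
  owners <- net$basal$seg_owner[segs]
  sort(unique(owners[!net$lesioned[owners]]))
}

#' Inactivate a random fraction of cells
#'
#' Marks `floor(fraction * N * M)` uniformly sampled cells dead.  Dead
#' cells are never active, never predictive, are skipped as learning
#' targets, and (being permanently silent) no longer contribute to any
#' segment's overlap.  Lesions accumulate; the sample is drawn from all
#' cells with the network's private random stream.
#'
#' @param net An [htm_network()] object.
#' @param fraction Fraction of all cells to kill, in `[0, 1]`.
#' @return Integer vector of the newly killed cell ids, invisibly.
#' @export
tm_lesion <- function(net, fraction) {
  stopifnot(inherits(net, "htm_network"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  n_kill <- floor(fraction * net$n_cells)
  killed <- with_net_rng(net, sample.int(net$n_cells, n_kill))
  net$lesioned[killed] <- TRUE
  # purge dead cells from the live state
  net$active <- net$active[!net$lesioned[net$active]]
  net$winners <- net$winners[!net$lesioned[net$winners]]
  net$pi <- net$pi[!net$lesioned[net$pi]]
  net$pi_basal <- net$pi_basal[!net$lesioned[net$pi_basal]]
  net$pi_apical <- net$pi_apical[!net$lesioned[net$pi_apical]]
  net$pi_mask[killed] <- FALSE
  invisible(sort(killed))
}

#' Deep-copy a network
#'
#' @param net An [htm_network()] object.
#' @return An independent copy; stepping one never affects the other.
#' @export
tm_clone <- function(net) {
  stopifnot(inherits(net, "htm_network"))
  copy_env <- function(e, parent = emptyenv()) {
    list2env(as.list.environment(e, all.names = TRUE),
             envir = new.env(hash = TRUE, parent = parent))
  }
  copy_pool <- function(pool) {
    out <- copy_env(pool, parent = baseenv())
    out$seg_syn <- copy_env(pool$seg_syn)
    out$pre_index <- copy_env(pool$pre_index)
    out$cell_segs <- copy_env(pool$cell_segs)
    out
  }
  out <- copy_env(net)
  out$basal <- copy_pool(net$basal)
  if (!is.null(net$apical)) out$apical <- copy_pool(net$apical)
  class(out) <- "htm_network"
  out
}

#' Manually add a dendritic segment (for inspection and testing)
#'
#' @param net An [htm_network()] object.
#' @param cell Owner cell id.
#' @param presyn Integer vector of presynaptic cell ids (apical: feedback
#'   axon ids), distinct, not equal to `cell` for the basal channel.
#' @param perms Permanence(s) in `[0, 1]`, recycled over `presyn`.
#' @param channel `"basal"` or `"apical"`.
#' @return The new segment id, invisibly.
#' @export
tm_add_segment <- function(net, cell, presyn, perms,
                           channel = c("basal", "apical")) {
  stopifnot(inherits(net, "htm_network"))
  channel <- match.arg(channel)
  pool <- if (channel == "basal") net$basal else net$apical
  if (is.null(pool)) stop("apical channel is disabled", call. = FALSE)
  presyn <- as.integer(presyn)
  if (anyDuplicated(presyn))
    stop("at most one synapse per presynaptic cell", call. = FALSE)
  if (channel == "basal" && cell %in% presyn)
    stop("no synapse to the owner cell itself", call. = FALSE)
  if (length(presyn) > net$p$max_synapses_per_segment)
    stop("segment exceeds max_synapses_per_segment", call. = FALSE)
  perms <- rep_len(as.numeric(perms), length(presyn))
  stopifnot(all(perms >= 0 & perms <= 1))
  seg <- pool_grow_segment(pool, as.integer(cell), presyn, perms, net$step)
  invisible(seg)
}

#' Snapshot of all synapses
#'
#' @param net An [htm_network()] object.
#' @param channel `"basal"` or `"apical"`.
#' @return A data.frame with one row per live synapse: `segment`, `cell`
#'   (owner), `column`, `presyn`, `permanence`.
#' @export
tm_segments <- function(net, channel = c("basal", "apical")) {
  stopifnot(inherits(net, "htm_network"))
  channel <- match.arg(channel)
  pool <- if (channel == "basal") net$basal else net$apical
  if (is.null(pool))
    return(data.frame(segment = integer(0), cell = integer(0),
                      column = integer(0), presyn = integer(0),
                      permanence = numeric(0)))
  ids <- which(pool$syn_alive[seq_len(pool$n_syn)])
  segs <- pool$syn_seg[ids]
  owners <- pool$seg_owner[segs]
  data.frame(segment = segs, cell = owners,
             column = column_of(owners, net$p$cells_per_column),
             presyn = pool$syn_pre[ids],
             permanence = pool$syn_perm[ids])
}

## -- apical channel ---------------------------------------------------

# Cells whose apical segments recognize the feedback pattern.
apical_depolarized <- function(net, feedback) {
  ov <- pool_overlaps(net$apical, feedback, net$p$perm_connected)
  segs <- ov$conn_seg[ov$conn_cnt > net$p$theta_activate]
  segs <- segs[net$apical$seg_alive[segs]]
  owners <- unique(net$apical$seg_owner[segs])
  sort(owners[!net$lesioned[owners]])
}

# Winner cells learn the currently active feedback axons with the same
# reinforce-or-grow rule as the basal channel.
apical_learn <- function(net, winners, feedback, now) {
  p <- net$p
  fb_mask <- logical(p$apical_inputs)
  fb_mask[feedback] <- TRUE
  for (w in winners) {
    segs <- pool_cell_segments(net$apical, w)
    best <- 0L
    best_cnt <- -1L
    for (seg in segs) {
      cnt <- sum(fb_mask[pool_seg_sources(net$apical, seg)])
      if (cnt > best_cnt) {
        best <- seg
        best_cnt <- cnt
      }
    }
    if (best > 0L && best_cnt >= p$theta_match) {
      pool_reinforce(net$apical, best, fb_mask, p$p_plus, p$p_minus)
      if (net$apical$seg_alive[best]) {
        pool_set(net$apical, .pq$seg_last_used, best, now)
        avail <- setdiff(feedback, pool_seg_sources(net$apical, best))
        desired <- min(p$sample_size - best_cnt, length(avail))
        if (desired > 0L) {
          room <- p$max_synapses_per_segment - net$apical$seg_nsyn[best]
          if (room < desired)
            room <- room + pool_make_room(net$apical, best,
                                          desired - room, fb_mask)
          if (room > 0L)
            pool_add_synapses(net$apical, best,
                              resample(avail, min(desired, room)),
                              p$perm_init)
        }
      }
    } else {
      if (net$apical$cell_nseg[w] >= p$max_segments_per_cell) {
        segs <- pool_cell_segments(net$apical, w)
        oldest <- segs[which.min(net$apical$seg_last_used[segs])]
        pool_kill_segment(net$apical, oldest)
      }
      sources <- resample(feedback,
                          min(p$sample_size, p$max_synapses_per_segment,
                              length(feedback)))
      pool_grow_segment(net$apical, w, sources, p$perm_init, now)
    }
  }
  invisible()
}

#' Apical depolarization from a feedback pattern
#'
#' Scores the apical segments against a feedback pattern and reports
#' which cells become depolarized, without running a feedforward step.
#' With a constant feedback pattern that was present while a sequence
#' was learned, all cells of that sequence's chain are depolarized
#' simultaneously, priming the network to interpret the next inputs as
#' part of the expected sequence.
#'
#' @param net An [htm_network()] object with the apical channel enabled.
#' @param feedback Integer vector of active feedback axon ids.
#' @return Sorted integer vector of depolarized cell ids (empty when the
#'   apical channel is disabled).
#' @export
apical_overlay <- function(net, feedback) {
  stopifnot(inherits(net, "htm_network"))
  if (is.null(net$apical)) return(integer(0))
  apical_depolarized(net, as.integer(feedback))
}
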