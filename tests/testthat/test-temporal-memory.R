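# Cell flat ids for column j of a network with M cells per column.
cells_of <- function(j, M) ((j - 1L) * M + 1L):(j * M)

test_that("predicted cells fire alone while unpredicted columns burst", {
  p <- tiny_params()
  net <- htm_network(p)
  M <- p$cells_per_column
  # one connected segment: cell 2 of column 5 recognizes columns 1:4's
  # first cells
  src <- vapply(1:4, function(j) cells_of(j, M)[1L], integer(1))
  tm_add_segment(net, cells_of(5, M)[2L], src, 0.9)
  r1 <- suppressWarnings(tm_step(net, 1:4, learn = FALSE))
  expect_true(5L %in% r1$predicted_columns)
  expect_setequal(r1$burst_columns, 1:4)   # nothing predicted those
  r2 <- suppressWarnings(tm_step(net, c(5L, 9L), learn = FALSE))
  # column 5 fires its single predicted cell, column 9 bursts whole
  expect_true(cells_of(5, M)[2L] %in% r2$active_cells)
  expect_length(intersect(r2$active_cells, cells_of(5, M)), 1L)
  expect_setequal(intersect(r2$active_cells, cells_of(9, M)), cells_of(9, M))
  expect_identical(r2$burst_columns, 9L)
  # empty input: nothing active
  r3 <- suppressWarnings(tm_step(net, integer(0), learn = FALSE))
  expect_length(r3$active_cells, 0L)
})

test_that("segment activation uses the strict NMDA threshold", {
  p <- tiny_params(theta_activate = 3L, theta_match = 2L)
  net <- htm_network(p)
  M <- p$cells_per_column
  srcs <- vapply(1:4, function(j) cells_of(j, M)[1L], integer(1))
  tm_add_segment(net, cells_of(6, M)[1L], srcs[1:3], 0.9)  # exactly theta
  tm_add_segment(net, cells_of(7, M)[1L], srcs[1:4], 0.9)  # theta + 1
  pi <- tm_predictions(net, srcs)
  expect_false(cells_of(6, M)[1L] %in% pi)  # ||D~ o A|| > theta is strict
  expect_true(cells_of(7, M)[1L] %in% pi)
  # unconnected synapses do not count
  tm_add_segment(net, cells_of(8, M)[1L], srcs, 0.4)
  expect_false(cells_of(8, M)[1L] %in% tm_predictions(net, srcs))
  # no segments at all: no predictions
  expect_length(tm_predictions(htm_network(p), srcs), 0L)
})

test_that("reinforcement rewards active synapses and punishes the rest", {
  p <- tiny_params(p_plus = 0.05, p_minus = 0.01, p_decay = 0.002)
  net <- htm_network(p)
  M <- p$cells_per_column
  ctx <- vapply(1:4, function(j) cells_of(j, M)[1L], integer(1))
  target <- cells_of(6, M)[1L]
  seg <- tm_add_segment(net, target, c(ctx[1:3], cells_of(5, M)[1L]), 0.5)
  suppressWarnings(tm_step(net, 1:4))          # ctx active, target predicted
  suppressWarnings(tm_step(net, 6L))           # prediction comes true
  d <- tm_segments(net)
  d <- d[d$segment == seg, ]
  # active presynapses: +p_plus - p_minus; inactive: -p_minus (column 5
  # was not part of the input)
  expect_equal(d$permanence[match(ctx[1:3], d$presyn)], rep(0.54, 3))
  expect_equal(d$permanence[match(cells_of(5, M)[1L], d$presyn)], 0.49)
})

test_that("zero learning rates freeze all permanences", {
  p <- tiny_params(p_plus = 0, p_minus = 0, p_decay = 0)
  net <- htm_network(p)
  M <- p$cells_per_column
  ctx <- vapply(1:4, function(j) cells_of(j, M)[1L], integer(1))
  seg <- tm_add_segment(net, cells_of(6, M)[1L], ctx, 0.7)
  before <- tm_segments(net)
  suppressWarnings(tm_step(net, 1:4))
  suppressWarnings(tm_step(net, 6L))
  suppressWarnings(tm_step(net, c(2L, 3L, 7L, 8L)))
  after <- tm_segments(net)
  after <- after[after$segment == seg, ]
  expect_equal(after$permanence[order(after$presyn)],
               before$permanence[order(before$presyn)])
})

test_that("a bursting column reinforces its best sub-threshold match", {
  p <- tiny_params(theta_activate = 9L, theta_match = 2L,
                   max_synapses_per_segment = 12L,
                   p_plus = 0.05, p_minus = 0.01)
  net <- htm_network(p)
  M <- p$cells_per_column
  ctx <- unlist(lapply(1:4, function(j) cells_of(j, M)[1:2]))  # 8 cells
  weak <- tm_add_segment(net, cells_of(6, M)[1L], ctx[1:3], 0.3)
  strong <- tm_add_segment(net, cells_of(6, M)[2L], ctx[1:7], 0.3)
  r1 <- suppressWarnings(tm_step(net, 1:4))     # columns 1:4 burst
  suppressWarnings(tm_step(net, 6L))            # column 6 bursts, matches
  d <- tm_segments(net)
  perm_strong <- d$permanence[d$segment == strong & d$presyn %in% ctx[1:7]]
  perm_weak <- d$permanence[d$segment == weak & d$presyn %in% ctx[1:3]]
  expect_true(all(perm_strong > 0.3))  # argmax overlap (7 vs 3) reinforced
  expect_true(all(perm_weak == 0.3))
})

test_that("mistaken predictions decay their responsible segments", {
  p <- tiny_params(p_decay = 0.004)
  net <- htm_network(p)
  M <- p$cells_per_column
  ctx <- vapply(1:4, function(j) cells_of(j, M)[1L], integer(1))
  seg <- tm_add_segment(net, cells_of(6, M)[1L], ctx, 0.8)
  suppressWarnings(tm_step(net, 1:4))           # segment fires, predicts 6
  suppressWarnings(tm_step(net, c(7L, 8L)))     # but 6 never arrives
  d <- tm_segments(net)
  expect_equal(d$permanence[d$segment == seg], rep(0.8 - 0.004, 4))
})

test_that("segment growth subsamples previous winners at perm_init", {
  p <- tm_params(n_columns = 64L, cells_per_column = 4L, k = 40L,
                 theta_activate = 10L, theta_match = 5L,
                 sample_size = 30L, max_synapses_per_segment = 40L,
                 seed = 7L)
  net <- htm_network(p)
  suppressWarnings(tm_step(net, 1:40))   # all burst; winners designated
  suppressWarnings(tm_step(net, 25:64))  # grows onto the 40 winners
  d <- tm_segments(net)
  ns <- table(d$segment)
  expect_true(all(ns == 30L))            # min(sample_size, |winners|)
  expect_true(all(d$permanence == p$perm_init))
  # few winners available: segment size limited by supply
  p2 <- tiny_params(sample_size = 9L)
  net2 <- htm_network(p2)
  suppressWarnings(tm_step(net2, 1:4))   # 4 winners
  suppressWarnings(tm_step(net2, 5:8))
  d2 <- tm_segments(net2)
  expect_true(all(table(d2$segment) <= 4L))
})

test_that("tiny networks match the dense prediction oracle", {
  p <- tm_params(n_columns = 8L, cells_per_column = 3L, k = 3L,
                 theta_activate = 2L, theta_match = 2L,
                 max_synapses_per_segment = 8L, sample_size = 4L,
                 seed = 123L)
  set.seed(42)
  for (rep in 1:20) {
    net <- htm_network(p)
    for (s in seq_len(sample(3:10, 1))) {
      owner <- sample.int(24L, 1)
      presyn <- sample(setdiff(1:24, owner), sample(2:6, 1))
      tm_add_segment(net, owner, presyn, runif(length(presyn)))
    }
    active <- sample.int(24L, sample(3:9, 1))
    expect_identical(
      tm_predictions(net, active),
      oracle_predictions(tm_segments(net), active,
                         p$theta_activate, p$perm_connected))
  }
})

test_that("every step keeps permanences and budgets within bounds", {
  p <- tiny_params(max_segments_per_cell = 3L,
                   max_synapses_per_segment = 6L, sample_size = 6L)
  net <- htm_network(p)
  set.seed(1)
  for (t in 1:150) {
    suppressWarnings(tm_step(net, sample.int(p$n_columns, p$k)))
    if (t %% 30 == 0) {
      d <- tm_segments(net)
      expect_true(all(d$permanence > 0 & d$permanence <= 1))
      # no duplicate presynaptic cell on a segment, none onto the owner
      per_seg <- split(d, d$segment)
      expect_true(all(vapply(per_seg, function(x)
        !anyDuplicated(x$presyn) && !(x$cell[1] %in% x$presyn),
        logical(1))))
      expect_true(all(table(d$segment) <= 6L))
      seg_per_cell <- table(unique(d[c("segment", "cell")])$cell)
      expect_true(all(seg_per_cell <= 3L))
    }
  }
})

test_that("winning columns are cleanly partitioned: predicted or bursting", {
  p <- tiny_params()
  net <- htm_network(p)
  M <- p$cells_per_column
  set.seed(2)
  for (t in 1:80) {
    W <- sample.int(p$n_columns, p$k)
    r <- suppressWarnings(tm_step(net, W))
    per_col <- split(r$active_cells, column_of_cells <- (r$active_cells - 1L) %/% M + 1L)
    for (j in names(per_col)) {
      jj <- as.integer(j)
      n_active <- length(per_col[[j]])
      if (jj %in% r$burst_columns) {
        expect_identical(n_active, M)
      } else {
        expect_lt(n_active, M + 1L)
        expect_gte(n_active, 1L)
      }
    }
    expect_setequal(unique((r$active_cells - 1L) %/% M + 1L), W)
  }
})

test_that("identical seeds give identical trajectories", {
  run_once <- function() {
    p <- tiny_params(seed = 31L)
    net <- htm_network(p)
    set.seed(77)  # drives the input choice only
    out <- list()
    for (t in 1:60)
      out[[t]] <- suppressWarnings(
        tm_step(net, sample.int(p$n_columns, p$k)))$active_cells
    list(trace = out, segments = tm_segments(net))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$trace, b$trace)
  expect_identical(a$segments, b$segments)
})

test_that("lesioned cells drop out of every computation", {
  p <- tiny_params(seed = 8L)
  net <- htm_network(p)
  set.seed(3)
  for (t in 1:40) suppressWarnings(tm_step(net, sample.int(p$n_columns, p$k)))
  killed <- tm_lesion(net, 0.3)
  expect_length(killed, floor(0.3 * net$n_cells))
  for (t in 1:40) {
    r <- suppressWarnings(tm_step(net, sample.int(p$n_columns, p$k)))
    expect_length(intersect(r$active_cells, killed), 0L)
    expect_length(intersect(r$predicted_cells, killed), 0L)
  }
  # total lesion: silence
  net2 <- htm_network(p)
  tm_lesion(net2, 1)
  r <- suppressWarnings(tm_step(net2, 1:4))
  expect_length(r$active_cells, 0L)
  expect_error(tm_lesion(net2, 1.2), "fraction")
})

test_that("a zero-fraction lesion leaves behavior untouched", {
  p <- tiny_params(seed = 12L)
  a <- htm_network(p)
  b <- htm_network(p)
  tm_lesion(b, 0)
  set.seed(5)
  W <- replicate(30, sample.int(p$n_columns, p$k), simplify = FALSE)
  for (w in W) {
    ra <- suppressWarnings(tm_step(a, w))
    rb <- suppressWarnings(tm_step(b, w))
    expect_identical(ra$active_cells, rb$active_cells)
    expect_identical(ra$predicted_cells, rb$predicted_cells)
  }
})

test_that("clones evolve independently of their source", {
  p <- tiny_params(seed = 14L)
  net <- htm_network(p)
  set.seed(6)
  for (t in 1:20) suppressWarnings(tm_step(net, sample.int(p$n_columns, p$k)))
  snap <- tm_segments(net)
  cl <- tm_clone(net)
  for (t in 1:20) suppressWarnings(tm_step(cl, sample.int(p$n_columns, p$k)))
  expect_identical(tm_segments(net), snap)     # original untouched
  expect_gt(nrow(tm_segments(cl)), nrow(snap)) # clone kept learning
})

test_that("manual segments validate their invariants", {
  net <- htm_network(tiny_params())
  expect_error(tm_add_segment(net, 5L, c(7L, 7L), 0.5), "one synapse")
  expect_error(tm_add_segment(net, 5L, c(5L, 9L), 0.5), "owner")
  expect_error(tm_add_segment(net, 5L, 7:20, 0.5), "max_synapses")
  expect_error(tm_add_segment(net, 5L, 7L, 0.5, channel = "apical"),
               "disabled")
})
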