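test_that("tree count equals spots minus links, including at annotation scale", {
  # forest with the published annotation arithmetic: 278 rooted tracks
  # carrying 13,888 spots connected by 13,610 links
  n_trees <- 278L
  n_spots <- 13888L
  lens <- rep(n_spots %/% n_trees, n_trees)
  lens[seq_len(n_spots %% n_trees)] <- lens[1] + 1L
  id0 <- cumsum(c(0L, lens[-n_trees]))
  spots <- data.frame(
    id = seq_len(n_spots),
    t = unlist(lapply(lens, seq_len)) - 1L,
    z = 1, y = 1, x = rep(seq_len(n_trees) * 10, lens), radius = 2)
  links <- data.frame(
    source_id = setdiff(seq_len(n_spots), id0 + 1L) - 1L,
    target_id = setdiff(seq_len(n_spots), id0 + 1L))
  big <- lineage_forest(spots, links)
  expect_identical(count_trees(big), n_trees)
  expect_identical(nrow(big$links), n_spots - n_trees)

  single <- lineage_forest(data.frame(id = 1, t = 0, z = 0, y = 0, x = 0,
                                      radius = 1))
  expect_identical(count_trees(single), 1L)

  # simulated forest: agrees with an independent connected-component count
  f <- get_small_recording()$forest
  expect_identical(count_trees(f), nrow(f$spots) - nrow(f$links))
  expect_identical(count_trees(f), bf_count_components(f))
})

test_that("malformed forests are rejected with the offending record named", {
  spots <- data.frame(id = 1:2, t = 0:1, z = 0, y = 0, x = 0, radius = 1)
  expect_error(lineage_forest(spots, data.frame(source_id = 1,
                                                target_id = 9)),
               "unknown target id 9")
  expect_error(lineage_forest(spots, data.frame(source_id = c(1, 1),
                                                target_id = c(2, 2))),
               "more than one parent")
  expect_error(lineage_forest(data.frame(id = 1, t = 0, z = 0, y = 0,
                                         x = 0, radius = -1)),
               "radius")
  expect_error(lineage_forest(data.frame(id = c(3, 3), t = 0, z = 0,
                                         y = 0, x = 0, radius = 1)),
               "duplicate spot id")
  # links must advance time by exactly one step
  spots3 <- data.frame(id = 1:2, t = c(0, 2), z = 0, y = 0, x = 0,
                       radius = 1)
  expect_error(lineage_forest(spots3, data.frame(source_id = 1,
                                                 target_id = 2)),
               "dt = 2")
  # three children are rejected
  spots4 <- data.frame(id = 1:4, t = c(0, 1, 1, 1), z = 0, y = 0,
                       x = 0:3, radius = 1)
  expect_error(lineage_forest(spots4,
                              data.frame(source_id = 1, target_id = 2:4)),
               "more than two children")
})

test_that("divisions are counted at the parent's time point", {
  f <- two_track_forest()
  d <- divisions_per_timepoint(f)
  expect_identical(unname(d[c("0", "1", "2")]), c(0L, 1L, 0L))
  # chain forest: no divisions anywhere
  chain <- lineage_forest(
    data.frame(id = 1:4, t = 0:3, z = 0, y = 0, x = 0, radius = 1),
    data.frame(source_id = 1:3, target_id = 2:4))
  expect_true(all(divisions_per_timepoint(chain) == 0L))
  # simulated burst: counts match the generator's event log exactly
  rec <- get_small_recording()
  d <- divisions_per_timepoint(rec$forest)
  ev <- rec$events[rec$events$event == "division", ]
  expect_identical(sum(d), nrow(ev))
  for (tt in names(d)) {
    expect_identical(unname(d[tt]), sum(ev$t == as.integer(tt)))
  }
  # nonzero only inside the burst window [2, 6)
  nz <- as.integer(names(d)[d > 0])
  expect_true(all(nz >= 2 & nz < 6))
})

test_that("time reduction keeps trees, re-links across gaps and composes", {
  # 55 annotated time points decimated by 2 keep 28
  chain55 <- lineage_forest(
    data.frame(id = 1:55, t = 0:54, z = 0, y = 0, x = 0, radius = 1),
    data.frame(source_id = 1:54, target_id = 2:55))
  red <- reduce_time(chain55, 2, 0)
  expect_identical(nrow(red$spots), 28L)
  expect_identical(max(red$spots$t), 27L)
  expect_identical(count_trees(red), 1L)

  # division at an odd (removed) time point re-attaches to the ancestor
  f <- two_track_forest()  # division at t = 1
  red <- reduce_time(f, 2, 0)
  expect_identical(count_trees(red), count_trees(f))
  expect_identical(sort(red$spots$id), c(1L, 3L, 4L, 6L, 7L))
  # ancestor 4 now has the two grandchildren as direct children
  ch <- sort(red$links$target_id[red$links$source_id == 4L])
  expect_identical(ch, c(6L, 7L))
  d <- divisions_per_timepoint(red)
  expect_identical(unname(d["0"]), 1L)

  # per-tree spot count halves (rounded up) in a division-free forest
  rec <- get_small_recording()
  nodiv <- simulate_recording(simulation_config(
    grid = voxel_grid(c(8, 32, 32)), n_timepoints = 9, n_replicates = 1,
    n_initial = 6, seed = 3, division_profile = rep(0, 9),
    apoptosis_prob = 0))$forest
  red <- reduce_time(nodiv, 2, 0)
  expect_identical(count_trees(red), count_trees(nodiv))
  expect_identical(nrow(red$spots), 6L * 5L)  # ceil(9 / 2) per tree

  # composition: two rounds of halving equal one round of keep-every-4
  f <- rec$forest
  r22 <- reduce_time(reduce_time(f, 2, 0), 2, 0)
  r4 <- reduce_time(f, 4, 0)
  expect_identical(sort(r22$spots$id), sort(r4$spots$id))
  expect_identical(r22$spots$t[order(r22$spots$id)],
                   r4$spots$t[order(r4$spots$id)])

  # offset validation
  expect_error(reduce_time(f, 1, 0), "keep_every")
  expect_error(reduce_time(f, 2, 2), "offset")
})

test_that("time reduction preserves ancestry through removed frames", {
  # brute-force oracle: in the reduced forest, a link a -> b must
  # correspond to a directed ancestor path a ->* b in the original
  f <- get_small_recording()$forest
  red <- reduce_time(f, 2, 0)
  children_of <- split(f$links$target_id, f$links$source_id)
  descendants <- function(id) {
    out <- integer(0)
    frontier <- id
    while (length(frontier) > 0) {
      nb <- unlist(children_of[as.character(frontier)], use.names = FALSE)
      out <- c(out, nb)
      frontier <- nb
    }
    out
  }
  for (k in seq_len(nrow(red$links))) {
    a <- red$links$source_id[k]
    b <- red$links$target_id[k]
    expect_true(b %in% descendants(a))
  }
  expect_identical(count_trees(red), count_trees(f))
})
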