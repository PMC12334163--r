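test_that("forward linking follows nearest-neighbour semantics", {
  # one spot per frame moving 2 um: a single two-spot track
  sp <- data.frame(id = 1:2, t = 0:1, z = 5, y = 5, x = c(5, 7),
                   radius = 2)
  f <- link_forward(sp)
  expect_identical(nrow(f$links), 1L)
  expect_identical(count_trees(f), 1L)

  # a parent with three equidistant in-range children keeps only two
  sp3 <- data.frame(id = 1:4, t = c(0, 1, 1, 1), z = 5,
                    y = c(5, 2, 5, 8), x = c(5, 5, 8, 5), radius = 2)
  f3 <- link_forward(sp3)
  expect_identical(nrow(f3$links), 2L)
  expect_identical(sum(f3$links$source_id == 1), 2L)

  # beyond d_max nothing links
  far <- data.frame(id = 1:2, t = 0:1, z = 5, y = 5, x = c(5, 11),
                    radius = 2)
  expect_identical(nrow(link_forward(far)$links), 0L)
  expect_identical(nrow(link_forward(
    far, params = linking_params(d_max = 7))$links), 1L)

  # an empty interior frame breaks tracks: no link may span two steps
  gap <- data.frame(id = 1:2, t = c(0, 2), z = 0, y = 0, x = 0,
                    radius = 1)
  fg <- link_forward(gap)
  expect_identical(nrow(fg$links), 0L)
  expect_identical(count_trees(fg), 2L)
})

test_that("flow priors resolve crossing cells that plain linking cannot", {
  # two cells crossing: A moves +3 in x, B moves -3; they end 3 um
  # apart from each other's origin, closer than to their own
  sp <- data.frame(id = 1:4, t = c(0, 0, 1, 1), z = 5, y = 5,
                   x = c(5, 8, 8, 5), radius = 1)
  truth <- data.frame(source_id = 1:2, target_id = 3:4)
  gt <- lineage_forest(sp, truth)
  # without flow, nearest-neighbour linking swaps the pair
  f_plain <- link_forward(sp, NULL, linking_params(d_max = 5))
  key <- function(l) paste(l$source_id, l$target_id, collapse = ";")
  expect_false(key(f_plain$links[order(f_plain$links$source_id), ]) ==
                 key(truth))
  # with the exact flow, the ground truth is recovered
  f_flow <- link_forward(sp, gt_flow_sampler(gt), linking_params())
  got <- f_flow$links[order(f_flow$links$source_id), ]
  expect_identical(key(got), key(truth))
  # and the flow-guided result is the minimum-total-distance assignment
  # of predicted origins to parents (exhaustive oracle)
  pred_origin <- cbind(c(5, 5), c(5, 5), c(8, 5) - c(3, -3))
  parents <- sp[sp$t == 0, ]
  d <- sqrt(outer(pred_origin[, 1], parents$z, `-`)^2 +
              outer(pred_origin[, 2], parents$y, `-`)^2 +
              outer(pred_origin[, 3], parents$x, `-`)^2)
  oracle <- bf_min_assignment(d)
  expect_identical(got$source_id[order(got$target_id)],
                   parents$id[oracle$assignment])
})

test_that("linking output is a valid forest and recall grows with d_max", {
  rec <- get_small_recording()
  f <- rec$forest
  recalls <- vapply(c(1, 2, 5), function(dm) {
    pred <- link_forward(f$spots, NULL, linking_params(d_max = dm))
    validate_forest(pred)
    linking_scores(f, pred)["recall"]
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("well-separated tracks with exact flow are recovered perfectly", {
  # three cells > 2 * d_max apart, drifting; complete detections
  set.seed(21)
  base <- data.frame(z = c(5, 5, 5), y = c(5, 30, 55), x = c(5, 30, 55))
  rows <- list(); links <- list(); id <- 0
  prev <- NULL
  for (tt in 0:5) {
    step <- matrix(rnorm(9, sd = 1), 3)
    base <- base + step
    ids <- id + 1:3; id <- id + 3
    rows[[tt + 1]] <- data.frame(id = ids, t = tt, z = base$z,
                                 y = base$y, x = base$x, radius = 2)
    if (!is.null(prev)) {
      links[[tt]] <- data.frame(source_id = prev, target_id = ids)
    }
    prev <- ids
  }
  gt <- lineage_forest(do.call(rbind, rows), do.call(rbind, links))
  pred <- link_forward(gt$spots, gt_flow_sampler(gt), linking_params())
  sc <- linking_scores(gt, pred)
  expect_identical(unname(sc), c(1, 1))
})

test_that("backtracking reverses ancestry and interpolates over gaps", {
  # stationary cell, complete detections: reaches t = 0, zero-length
  # links, nothing interpolated
  det <- data.frame(id = 1:5, t = 0:4, z = 5, y = 5, x = 5, radius = 2)
  path <- backtrack(5L, detections = det)
  expect_identical(path$status, "complete")
  expect_identical(min(path$spots$t), 0L)
  expect_identical(path$n_interpolated, 0L)
  expect_identical(sort(path$spots$id), 1:5)

  # constant motion +2 um/frame with exact flow; the t = 2 detection is
  # missing; budget 1 interpolates it at the predicted position
  det2 <- data.frame(id = 1:5, t = 0:4, z = 5, y = 5,
                     x = 5 + 2 * (0:4), radius = 2)
  flow <- function(pos, t) cbind(0, 0, rep(2, nrow(pos)))
  path <- backtrack(5L, detections = det2[det2$t != 2, ], flow = flow,
                    params = backtrack_params(max_interpolation = 1))
  expect_identical(path$status, "complete")
  expect_identical(path$n_interpolated, 1L)
  interp <- path$spots[path$spots$interpolated, ]
  expect_identical(interp$t, 2L)
  expect_equal(interp$x, 9, tolerance = 1e-9)
  expect_equal(interp$z, 5, tolerance = 1e-9)

  # nearest detection 6 um from the prediction with vicinity 5 and
  # budget 0: truncated, path stays at the seed
  det3 <- data.frame(id = 1:2, t = 0:1, z = 5, y = 5, x = c(11, 5),
                     radius = 2)
  path <- backtrack(2L, detections = det3,
                    params = backtrack_params(vicinity_radius = 5,
                                              max_interpolation = 0))
  expect_identical(path$status, "truncated")
  expect_identical(nrow(path$spots), 1L)

  # exhausting the budget mid-way truncates without raising
  det4 <- det2[det2$t %in% c(0, 4), ]  # three consecutive gaps
  path <- backtrack(5L, detections = det4, flow = flow,
                    params = backtrack_params(max_interpolation = 2))
  expect_identical(path$status, "truncated")
  expect_identical(path$n_interpolated, 2L)
  expect_identical(min(path$spots$t), 2L)
})

test_that("backtracking through a division follows the seed's own chain", {
  f <- two_track_forest()  # 4 -> 5 -> {6, 7}
  path <- backtrack(7L, detections = f$spots)
  expect_identical(path$status, "complete")
  expect_identical(sort(path$spots$id), c(4L, 5L, 7L))
})

test_that("block-matching flow recovers known translations", {
  set.seed(31)
  grid <- voxel_grid(c(8, 32, 32))
  # textured frame
  spots <- data.frame(id = 1:25, t = 0,
                      z = runif(25, 1, 8), y = runif(25, 1, 8.9),
                      x = runif(25, 1, 6.9), radius = 1.2, amp = 1000)
  frame0 <- regentrack:::render_scene(spots, grid, c(0.6, 0.3, 0.3))

  # identical frames: zero field
  fl <- estimate_flow_block_matching(frame0, frame0, grid)
  expect_true(all(fl$displacement == 0))

  # one-voxel shift in y: interior blocks report ~ (0, 0.31, 0) um
  frame1 <- frame0
  frame1[, 2:32, ] <- frame0[, 1:31, ]
  fl <- estimate_flow_block_matching(frame1, frame0, grid,
                                     block_halfsize = 3,
                                     search_radius = 2)
  mid <- fl$displacement[4, 12:20, 12:20, ]
  dim(mid) <- c(81, 3)
  expect_lt(mean(abs(mid[, 2] - 0.31)), 0.1)
  expect_lt(mean(abs(mid[, 1])), 0.1)

  # uniform drift of 2 um in x between rendered frames
  spots2 <- spots
  spots2$x <- spots2$x + 2
  frame2 <- regentrack:::render_scene(spots2, grid, c(0.6, 0.3, 0.3))
  fl <- estimate_flow_block_matching(frame2, frame0, grid,
                                     block_halfsize = 4,
                                     search_radius = 4)
  sampled <- flow_at(fl, cbind(spots2$z, spots2$y, spots2$x))
  err <- sqrt(rowSums(sweep(sampled, 2, c(0, 0, 2))^2))
  expect_lt(mean(err), 0.5)
})
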