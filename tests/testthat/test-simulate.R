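test_that("simulation is deterministic and obeys its schedules", {
  cfg <- simulation_config(grid = voxel_grid(c(8, 32, 32)),
                           n_timepoints = 6, n_replicates = 2,
                           n_initial = 8, seed = 11,
                           division_profile = rep(0, 6))
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$movie$data, r2$movie$data)
  expect_identical(r1$forest$spots, r2$forest$spots)
  expect_identical(r1$events, r2$events)

  # all-zero division profile: per-time-point counts never increase
  counts <- table(factor(r1$forest$spots$t, levels = 0:5))
  expect_true(all(diff(as.integer(counts)) <= 0))
  expect_true(all(divisions_per_timepoint(r1$forest) == 0))

  # burst window: divisions only inside it, totals match the event log
  rec <- get_small_recording()  # burst over [2, 6), apoptosis ~ 0
  d <- divisions_per_timepoint(rec$forest)
  nz <- as.integer(names(d)[d > 0])
  expect_gt(length(nz), 0)
  expect_true(all(nz >= 2 & nz < 6))
  expect_identical(sum(d), sum(rec$events$event == "division"))

  # forest invariants hold and spot positions sit inside the volume
  f <- rec$forest
  expect_identical(nrow(f$spots) - nrow(f$links), count_trees(f))
  ext <- (rec$movie$grid$shape - 1) * rec$movie$grid$voxel_size
  expect_true(all(f$spots$z >= 0 & f$spots$z <= ext[1]))
  expect_true(all(f$spots$x >= 0 & f$spots$x <= ext[3]))
})

test_that("overcrowded placement errors out", {
  expect_error(simulate_recording(simulation_config(
    grid = voxel_grid(c(6, 16, 16)), n_timepoints = 2, n_replicates = 1,
    n_initial = 200, seed = 1, division_profile = rep(0, 2))),
    "overcrowding")
})

test_that("imaging stages follow their closed forms", {
  grid <- voxel_grid(c(5, 4, 4))
  vol <- array(100, dim = grid$shape)
  # infinite attenuation length is the identity
  expect_identical(depth_attenuate(vol, grid, Inf), vol)
  # a slice at z = L is dimmed by exactly 1/e relative to z = 0
  att <- depth_attenuate(vol, grid, 1.24)
  expect_equal(att[2, 1, 1] / att[1, 1, 1], exp(-1), tolerance = 1e-12)
  expect_error(depth_attenuate(vol - 200, grid, 10), "non-negative")

  # bleaching trajectory: exponential with one multiplicative recovery
  expos <- 0:100
  m <- bleach_multiplier(expos, 0.01, 50, 0.4)
  expect_equal(m[1], 1)
  expect_equal(m[31], exp(-0.01 * 30), tolerance = 1e-12)
  expect_equal(m[81], exp(-0.01 * 80) * 1.4, tolerance = 1e-12)
  # the recovery step is exactly (1 + A)-fold on top of the exponential
  expect_equal(m[51] / m[50], exp(-0.01) * 1.4, tolerance = 1e-12)

  # averaging n replicates cuts noise variance by about n
  scene <- array(500, dim = c(10, 40, 40))
  set.seed(99)
  reps <- replicate(4, add_noise(scene, 10, 50), simplify = FALSE)
  v1 <- var(as.vector(reps[[1]] - scene))
  v4 <- var(as.vector((reps[[1]] + reps[[2]] + reps[[3]] + reps[[4]]) / 4
                      - scene))
  expect_lt(abs(v4 / v1 - 1 / 4), 0.15 / 4)
})

test_that("mean intensity decreases monotonically with depth pre-noise", {
  rec <- get_small_recording()
  cfg <- rec$config
  # same-radius nuclei at increasing depth: rendered peaks must decay
  spots <- data.frame(id = 1:4, t = 0, z = c(0, 3, 6, 9), y = 7,
                      x = c(2, 5, 8, 11), radius = 1.5,
                      amp = 1000)
  grid <- voxel_grid(c(9, 48, 48))
  sc <- regentrack:::render_scene(spots, grid, cfg$psf_sigma)
  sc <- depth_attenuate(sc, grid, 6)
  idx <- regentrack:::um_to_voxel(cbind(spots$z, spots$y, spots$x), grid)
  peaks <- sc[idx]
  expect_true(all(diff(peaks) < 0))
})

test_that("probability maps peak at nucleus centres and stay in [0, 1]", {
  grid <- voxel_grid(c(10, 40, 40))
  empty <- lineage_forest(data.frame(id = integer(0), t = integer(0),
                                     z = numeric(0), y = numeric(0),
                                     x = numeric(0), radius = numeric(0)))
  expect_true(all(render_probability_map(empty, grid, 0) == 0))

  one <- lineage_forest(data.frame(id = 1, t = 0, z = 5.0, y = 6.2,
                                   x = 6.2, radius = 2))
  pm <- render_probability_map(one, grid, 0)
  expect_true(max(pm) <= 1 && min(pm) >= 0)
  peak <- which(pm == max(pm), arr.ind = TRUE)
  true_vox <- regentrack:::um_to_voxel(matrix(c(5.0, 6.2, 6.2), 1), grid)
  expect_true(all(abs(peak[1, ] - true_vox) <= 1))

  # two nuclei 10 um apart: two local maxima, centre values >= 0.99
  two <- lineage_forest(data.frame(id = 1:2, t = 0, z = 5, y = 6,
                                   x = c(1.5, 11.5), radius = 2.5))
  pm <- render_probability_map(two, grid, 0)
  idx <- regentrack:::um_to_voxel(cbind(c(5, 5), c(6, 6), c(1.5, 11.5)),
                                  grid)
  expect_true(all(pm[idx] >= 0.99))
  sp <- extract_centers(pm, grid, detection_params(threshold = 0.5), 0)
  expect_identical(nrow(sp), 2L)
})

test_that("ground-truth flow reproduces per-cell displacements", {
  # stationary cells, no noise: zero field
  grid <- voxel_grid(c(6, 20, 20))
  spots <- data.frame(id = 1:4, t = rep(0:1, each = 2),
                      z = c(2, 4, 2, 4), y = c(2, 4, 2, 4),
                      x = c(1, 3, 1, 3), radius = 1)
  links <- data.frame(source_id = 1:2, target_id = 3:4)
  f0 <- lineage_forest(spots, links)
  fl <- ground_truth_flow(f0, grid, 1, noise_sd = 0)
  expect_true(all(fl$displacement == 0))

  # uniform translation by (0, 2, 0): constant field
  spots2 <- spots
  spots2$y[3:4] <- spots2$y[3:4] + 2
  f1 <- lineage_forest(spots2, links)
  fl <- ground_truth_flow(f1, grid, 1, noise_sd = 0)
  expect_true(all(fl$displacement[, , , 1] == 0))
  expect_true(all(fl$displacement[, , , 2] == 2))
  expect_true(all(fl$displacement[, , , 3] == 0))

  # mixed motion: the field at each cell equals that cell's displacement
  rec <- get_small_recording()
  f <- rec$forest
  sampler <- gt_flow_sampler(f)
  for (tt in c(3, 7)) {
    cur <- f$spots[f$spots$t == tt, ]
    par_id <- f$links$source_id[match(cur$id, f$links$target_id)]
    keep <- !is.na(par_id)
    cur <- cur[keep, ]
    par <- f$spots[match(par_id[keep], f$spots$id), ]
    got <- sampler(cbind(cur$z, cur$y, cur$x), tt)
    expect_equal(got[, 1], cur$z - par$z, tolerance = 1e-9)
    expect_equal(got[, 2], cur$y - par$y, tolerance = 1e-9)
    expect_equal(got[, 3], cur$x - par$x, tolerance = 1e-9)
  }

  # the rasterised field agrees with the sampler at cell positions
  fl <- ground_truth_flow(f, voxel_grid(c(10, 48, 48)), 3, noise_sd = 0)
  cur <- f$spots[f$spots$t == 3, ][1:3, ]
  pos <- cbind(cur$z, cur$y, cur$x)
  expect_equal(flow_at(fl, pos), unname(sampler(pos, 3)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("replicates are independent realisations of one scene", {
  rec <- get_small_recording()
  a <- rec$movie$data[3, 1, , , ]
  b <- rec$movie$data[3, 2, , , ]
  expect_false(identical(a, b))
  # but they share the underlying scene: strong correlation
  expect_gt(cor(as.vector(a), as.vector(b)), 0.5)
})
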