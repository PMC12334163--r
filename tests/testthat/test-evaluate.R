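mk_forest <- function(spots, links = NULL) lineage_forest(spots, links)

test_that("spot matching resolves candidates one-to-one per time point", {
  gt <- data.frame(id = 1:3, t = 0, z = 0, y = 0, x = c(0, 10, 20),
                   radius = 2)
  # identical sets: all TP
  m <- match_spots(gt, gt)
  expect_identical(c(m$tp, m$ns, m$fn, m$fp), c(3L, 0L, 0L, 0L))

  # one prediction centred between two close ground-truth spots,
  # inside both radii: one TP, the other needs a vertex split (NS)
  gt2 <- data.frame(id = 1:2, t = 0, z = 0, y = 0, x = c(0, 2),
                    radius = 2)
  pr2 <- data.frame(id = 10, t = 0, z = 0, y = 0, x = 1, radius = 2)
  m <- match_spots(gt2, pr2)
  expect_identical(c(m$tp, m$ns, m$fn, m$fp), c(1L, 1L, 0L, 0L))

  # prediction beyond the ground-truth radius: FN plus FP
  pr3 <- data.frame(id = 10, t = 0, z = 0, y = 0, x = 5, radius = 2)
  m <- match_spots(gt2[1, ], pr3)
  expect_identical(c(m$tp, m$ns, m$fn, m$fp), c(0L, 0L, 1L, 1L))

  # assignment is minimum-total-distance: a prediction inside two
  # spheres pairs with the closer centre
  gt4 <- data.frame(id = 1:2, t = 0, z = 0, y = 0, x = c(0, 3),
                    radius = 3)
  pr4 <- data.frame(id = 10:11, t = 0, z = 0, y = 0, x = c(0.4, 2.9),
                    radius = 2)
  m <- match_spots(gt4, pr4)
  expect_identical(m$pairs$pred_id[match(1:2, m$pairs$gt_id)], c(10L, 11L))
})

test_that("precision and recall use the stated formulas and conventions", {
  expect_equal(unname(detection_scores(3, 1, 2)), c(0.75, 0.6))
  expect_equal(unname(detection_scores(5, 0, 0)), c(1, 1))
  # 0/0 convention
  expect_equal(unname(detection_scores(0, 0, 5)), c(1, 0))
  expect_equal(unname(detection_scores(0, 0, 0)), c(1, 1))
})

test_that("AOGM decomposition matches hand-computed edit costs", {
  # 5-spot chain-with-division ground truth
  gt <- two_track_forest()
  expect_identical(aogm(gt, gt)$cost, 0)

  # prediction missing one interior non-dividing spot (id 2) and its
  # two incident links: FN = 1, EA = 2, cost 10 + 2 * 1.5 = 13
  chain <- mk_forest(
    data.frame(id = 1:3, t = 0:2, z = 0, y = 0, x = c(0, 1, 2),
               radius = 2),
    data.frame(source_id = 1:2, target_id = 2:3))
  pred <- mk_forest(chain$spots[-2, ])
  a <- aogm(chain, pred)
  expect_identical(unname(a$counts), c(0L, 1L, 0L, 0L, 2L, 0L))
  expect_identical(a$cost, 13)
  # ... normalising: TRA = 1 - 13 / (3 * 10 + 2 * 1.5)
  expect_equal(tra_score(chain, pred), 1 - 13 / 33, tolerance = 1e-12)

  # a spurious unlinked extra spot costs exactly w_fp = 1
  plus <- chain$spots
  plus <- rbind(plus, data.frame(id = 99, t = 1, z = 50, y = 50, x = 50,
                                 radius = 2, intensity = 0,
                                 label = NA_character_,
                                 interpolated = FALSE))
  a <- aogm(chain, mk_forest(plus, chain$links))
  expect_identical(a$cost, 1)

  # a division link counted with wrong semantics costs w_ec
  div_spots <- data.frame(id = 1:4, t = c(0, 1, 1, 2), z = 0, y = 0,
                          x = c(0, -2, 2, -2), radius = 2)
  gt_div <- mk_forest(div_spots,
                      data.frame(source_id = c(1, 1, 2),
                                 target_id = c(2, 3, 4)))
  pred_nodiv <- mk_forest(div_spots,
                          data.frame(source_id = c(1, 2),
                                     target_id = c(2, 4)))
  a <- aogm(gt_div, pred_nodiv)
  # link 1->2 is a division link in gt but not in pred: EC; 1->3 absent:
  # EA
  expect_identical(unname(a$counts["ec"]), 1L)
  expect_identical(unname(a$counts["ea"]), 1L)
})

test_that("DET and TRA are normalised into [0, 1] with the stated anchors", {
  gt <- two_track_forest()
  expect_identical(det_score(gt, gt), 1)
  expect_identical(tra_score(gt, gt), 1)
  empty <- mk_forest(gt$spots[0, ])
  expect_identical(det_score(gt, empty), 0)
  expect_identical(tra_score(gt, empty), 0)
  expect_error(det_score(empty, gt), "empty ground truth")
  # adding a false positive never raises TRA
  jit <- gt
  extra <- gt$spots[1, ]
  extra$id <- 99L; extra$x <- extra$x + 40
  with_fp <- mk_forest(rbind(gt$spots, extra), gt$links)
  expect_lte(tra_score(gt, with_fp), tra_score(gt, gt))
})

test_that("linking scores count matched-endpoint link images", {
  gt <- two_track_forest()
  expect_equal(unname(linking_scores(gt, gt)), c(1, 1))
  # a reversed-parent division: the wrong link is an FP and the true
  # link an FN
  sp <- data.frame(id = 1:4, t = c(0, 0, 1, 1), z = 0, y = 0,
                   x = c(0, 6, 0, 6), radius = 2)
  gt2 <- mk_forest(sp, data.frame(source_id = c(1, 2),
                                  target_id = c(3, 4)))
  pr2 <- mk_forest(sp, data.frame(source_id = c(1, 2),
                                  target_id = c(4, 3)))
  sc <- linking_scores(gt2, pr2)
  expect_equal(unname(sc), c(0, 0))
  one_right <- mk_forest(sp, data.frame(source_id = 1, target_id = 3))
  expect_equal(unname(linking_scores(gt2, one_right)), c(1, 0.5))
})

test_that("proofreading effort is the raw cost and adds over unions", {
  chain <- mk_forest(
    data.frame(id = 1:3, t = 0:2, z = 0, y = 0, x = c(0, 1, 2),
               radius = 2),
    data.frame(source_id = 1:2, target_id = 2:3))
  pred <- mk_forest(chain$spots[-2, ])
  expect_identical(proofreading_effort(chain, chain), 0)
  e1 <- proofreading_effort(chain, pred)
  # disjoint duplicated experiment: exactly twice the effort
  shift_ids <- function(f, k, dx) {
    sp <- f$spots; sp$id <- sp$id + k; sp$x <- sp$x + dx
    ln <- f$links + k
    mk_forest(sp, ln)
  }
  gt2 <- mk_forest(rbind(chain$spots, shift_ids(chain, 100L, 50)$spots),
                   rbind(chain$links, chain$links + 100L))
  pr2 <- mk_forest(rbind(pred$spots, shift_ids(pred, 100L, 50)$spots),
                   rbind(pred$links, pred$links + 100L))
  expect_identical(proofreading_effort(gt2, pr2), 2 * e1)
})

test_that("depth-stratified scores bin by ground-truth depth", {
  # all spots shallow, perfect prediction: one bin at 1/1
  gt <- data.frame(id = 1:4, t = 0, z = c(1, 2, 3, 4), y = 0,
                   x = c(0, 10, 20, 30), radius = 2)
  tab <- depth_stratified_scores(gt, gt)
  expect_identical(nrow(tab), 1L)
  expect_equal(c(tab$precision, tab$recall), c(1, 1))

  # predictions missing below 20 um: full recall shallow, zero deep
  gt2 <- data.frame(id = 1:6, t = 0, z = c(2, 7, 12, 17, 22, 27), y = 0,
                    x = seq(0, 50, 10), radius = 2)
  pred2 <- gt2[gt2$z < 20, ]
  tab <- depth_stratified_scores(gt2, pred2)
  expect_identical(nrow(tab), 6L)
  expect_equal(tab$recall, c(1, 1, 1, 1, 0, 0))
  # empty bins are omitted
  gt3 <- gt2[gt2$z %in% c(2, 27), ]
  tab <- depth_stratified_scores(gt3, gt3)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$z_min, c(0, 25))
})

test_that("the AOGM agrees with brute force on random small instances", {
  # spot check here (the acceptance suite runs the large sweep)
  for (seed in 1:25) {
    inst <- random_instance(seed)
    got <- aogm(inst$gt, inst$pred)
    want <- bf_aogm(inst$gt, inst$pred)
    expect_identical(got$counts, want$counts)
    expect_equal(got$cost, want$cost, tolerance = 1e-12)
  }
})
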