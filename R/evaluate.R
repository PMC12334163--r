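#' Edit-operation weights of the tracking metric
#'
#' Costs of the elementary edit operations that transform a computed
#' track graph into the reference graph: splitting a computed vertex
#' that covers several reference nuclei (NS), adding a missing vertex
#' (FN), deleting a spurious vertex (FP), deleting a redundant edge
#' (ED), adding a missing edge (EA) and correcting an edge's division
#' semantics (EC). Defaults follow the Cell Tracking Challenge
#' reference implementation.
#'
#' @param w_ns,w_fn,w_fp,w_ed,w_ea,w_ec non-negative costs.
#' @return Object of class `aogm_weights`.
#' @export
aogm_weights <- function(w_ns = 5, w_fn = 10, w_fp = 1, w_ed = 1,
                         w_ea = 1.5, w_ec = 1) {
  w <- c(w_ns = w_ns, w_fn = w_fn, w_fp = w_fp, w_ed = w_ed,
         w_ea = w_ea, w_ec = w_ec)
  if (any(w < 0)) stop("weights must be non-negative")
  structure(as.list(w), class = "aogm_weights")
}

#' Match predicted spots to ground-truth spots
#'
#' Per time point, a predicted spot is a candidate match of a
#' ground-truth spot when its centre lies inside the ground-truth
#' sphere (distance at most the ground-truth radius — the point-cloud
#' counterpart of the Cell Tracking Challenge's mask-overlap test).
#' Candidates are resolved into a one-to-one matching of maximum
#' cardinality and minimum total distance (linear sum assignment).
#' Matched pairs are TP. An unmatched ground-truth spot still covered
#' by some already-matched predicted spot counts as NS (that prediction
#' would have to be split); remaining unmatched ground truth is FN;
#' unmatched predictions are FP.
#'
#' @param gt,pred spots data.frames (need columns id, t, z, y, x,
#'   radius).
#' @return List with `pairs` (data.frame gt_id, pred_id, dist, t),
#'   counts `tp`, `ns`, `fn`, `fp`, and per-spot status tables
#'   `gt_status` (id, t, z, status in TP/NS/FN) and `pred_status`
#'   (id, t, z, status in TP/FP).
#' @export
match_spots <- function(gt, pred) {
  times <- sort(unique(c(gt$t, pred$t)))
  pair_list <- list()
  gt_status <- character(nrow(gt))
  pred_status <- character(nrow(pred))
  big <- 1e7
  for (tt in times) {
    gi <- which(gt$t == tt)
    pi <- which(pred$t == tt)
    if (length(gi) == 0) {
      pred_status[pi] <- "FP"
      next
    }
    if (length(pi) == 0) {
      gt_status[gi] <- "FN"
      next
    }
    G <- gt[gi, , drop = FALSE]
    P <- pred[pi, , drop = FALSE]
    d <- sqrt(outer(G$z, P$z, `-`)^2 + outer(G$y, P$y, `-`)^2 +
                outer(G$x, P$x, `-`)^2)
    allowed <- d <= G$radius
    cost <- ifelse(allowed, d, big)
    if (nrow(cost) <= ncol(cost)) {
      sol <- as.integer(clue::solve_LSAP(cost))
      g_of <- seq_len(nrow(cost)); p_of <- sol
    } else {
      sol <- as.integer(clue::solve_LSAP(t(cost)))
      g_of <- sol; p_of <- seq_len(ncol(cost))
    }
    ok <- allowed[cbind(g_of, p_of)]
    g_match <- g_of[ok]; p_match <- p_of[ok]
    gt_status[gi] <- "FN"
    gt_status[gi[g_match]] <- "TP"
    pred_status[pi] <- "FP"
    pred_status[pi[p_match]] <- "TP"
    # unmatched GT covered by a matched prediction: needs a vertex split
    un_g <- setdiff(seq_len(nrow(cost)), g_match)
    if (length(un_g) > 0 && length(p_match) > 0) {
      covered <- rowSums(allowed[un_g, p_match, drop = FALSE]) > 0
      gt_status[gi[un_g[covered]]] <- "NS"
    }
    if (length(g_match) > 0) {
      pair_list[[length(pair_list) + 1]] <- data.frame(
        gt_id = G$id[g_match], pred_id = P$id[p_match],
        dist = d[cbind(g_match, p_match)], t = tt)
    }
  }
  pairs <- if (length(pair_list) > 0) {
    do.call(rbind, pair_list)
  } else {
    data.frame(gt_id = integer(0), pred_id = integer(0),
               dist = numeric(0), t = integer(0))
  }
  list(pairs = pairs,
       tp = nrow(pairs),
       ns = sum(gt_status == "NS"),
       fn = sum(gt_status == "FN"),
       fp = sum(pred_status == "FP"),
       gt_status = data.frame(id = gt$id, t = gt$t, z = gt$z,
                              status = gt_status),
       pred_status = data.frame(id = pred$id, t = pred$t, z = pred$z,
                                status = pred_status))
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with the
#' empty-versus-empty convention 0/0 = 1.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
detection_scores <- function(tp, fp, fn) {
  safe <- function(num, den) if (den == 0) 1 else num / den
  c(precision = safe(tp, tp + fp), recall = safe(tp, tp + fn))
}

# division links: links whose source has exactly two children
division_link_flags <- function(links) {
  if (nrow(links) == 0) return(logical(0))
  deg <- table(links$source_id)
  as.vector(deg[as.character(links$source_id)] == 2L)
}

#' Acyclic-oriented-graph matching decomposition and cost
#'
#' Counts the edit operations needed to turn the predicted lineage
#' forest into the ground truth, given the per-time-point vertex
#' matching of [match_spots()]: vertex operations NS, FN, FP; edge
#' operations over matched vertex pairs — ED (predicted links whose
#' endpoint images are not a ground-truth link), EA (ground-truth links
#' with no predicted counterpart) and EC (corresponding links whose
#' division semantics differ; a link is a division link when its source
#' has two children). The weighted sum of the counts is the raw AOGM
#' cost.
#'
#' @param gt,pred `lineage_forest` objects on a shared time axis.
#' @param weights an [aogm_weights()].
#' @param matching optional precomputed [match_spots()] result.
#' @return List with `counts` (named vector ns, fn, fp, ed, ea, ec),
#'   `cost`, and the `matching`.
#' @export
aogm <- function(gt, pred, weights = aogm_weights(), matching = NULL) {
  if (is.null(matching)) matching <- match_spots(gt$spots, pred$spots)
  map <- stats::setNames(matching$pairs$gt_id, matching$pairs$pred_id)
  gl <- gt$links
  pl <- pred$links
  gt_key <- paste(gl$source_id, gl$target_id)
  ps_img <- map[as.character(pl$source_id)]
  pt_img <- map[as.character(pl$target_id)]
  both_matched <- !is.na(ps_img) & !is.na(pt_img)
  pred_key_img <- paste(ps_img, pt_img)
  corresponds <- both_matched & (pred_key_img %in% gt_key)
  ed <- sum(both_matched & !corresponds)
  ea <- nrow(gl) - sum(corresponds)
  # division semantics of corresponding link pairs
  gt_div <- stats::setNames(division_link_flags(gl), gt_key)
  pred_div <- division_link_flags(pl)
  ec <- sum(corresponds &
              (pred_div != as.vector(gt_div[pred_key_img])), na.rm = TRUE)
  counts <- c(ns = matching$ns, fn = matching$fn, fp = matching$fp,
              ed = ed, ea = ea, ec = ec)
  cost <- weights$w_ns * counts["ns"] + weights$w_fn * counts["fn"] +
    weights$w_fp * counts["fp"] + weights$w_ed * counts["ed"] +
    weights$w_ea * counts["ea"] + weights$w_ec * counts["ec"]
  list(counts = counts, cost = unname(cost), matching = matching)
}

#' Normalised detection and tracking scores
#'
#' Both scores normalise a graph-edit cost by the cost of building the
#' reference from nothing, clipped into [0, 1]:
#' `TRA = 1 - min(AOGM, AOGM0) / AOGM0` with
#' `AOGM0 = w_fn * |V_gt| + w_ea * |E_gt|`; `DET` is identical with the
#' vertex-only cost and `AOGM0 = w_fn * |V_gt|`.
#'
#' @param gt,pred `lineage_forest` objects.
#' @param weights an [aogm_weights()].
#' @param matching optional precomputed [match_spots()] result.
#' @return A number in [0, 1].
#' @export
det_score <- function(gt, pred, weights = aogm_weights(),
                      matching = NULL) {
  if (nrow(gt$spots) == 0) stop("DET is undefined for empty ground truth")
  if (is.null(matching)) matching <- match_spots(gt$spots, pred$spots)
  cost <- weights$w_ns * matching$ns + weights$w_fn * matching$fn +
    weights$w_fp * matching$fp
  ref <- weights$w_fn * nrow(gt$spots)
  1 - min(cost, ref) / ref
}

#' @rdname det_score
#' @export
tra_score <- function(gt, pred, weights = aogm_weights(),
                      matching = NULL) {
  if (nrow(gt$spots) == 0) stop("TRA is undefined for empty ground truth")
  a <- aogm(gt, pred, weights, matching)
  ref <- weights$w_fn * nrow(gt$spots) + weights$w_ea * nrow(gt$links)
  1 - min(a$cost, ref) / ref
}

#' Proofreading effort estimate
#'
#' The raw (un-normalised) AOGM cost: a proxy, in arbitrary units, for
#' the human work needed to correct the computed tracks. Unlike the
#' normalised scores it grows with dataset size at fixed per-frame
#' quality, and it is additive over disjoint unions.
#'
#' @inheritParams det_score
#' @return Non-negative number.
#' @export
proofreading_effort <- function(gt, pred, weights = aogm_weights(),
                                matching = NULL) {
  aogm(gt, pred, weights, matching)$cost
}

#' Linking precision and recall
#'
#' A predicted link is a true positive when both endpoints are matched
#' and their images form a ground-truth link. Precision divides by the
#' predicted links, recall by the ground-truth links (0/0 = 1).
#'
#' @param gt,pred `lineage_forest` objects.
#' @param matching optional precomputed [match_spots()] result.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
linking_scores <- function(gt, pred, matching = NULL) {
  if (is.null(matching)) matching <- match_spots(gt$spots, pred$spots)
  map <- stats::setNames(matching$pairs$gt_id, matching$pairs$pred_id)
  gl <- gt$links
  pl <- pred$links
  gt_key <- paste(gl$source_id, gl$target_id)
  ps_img <- map[as.character(pl$source_id)]
  pt_img <- map[as.character(pl$target_id)]
  tp <- sum(!is.na(ps_img) & !is.na(pt_img) &
              paste(ps_img, pt_img) %in% gt_key)
  safe <- function(num, den) if (den == 0) 1 else num / den
  c(precision = safe(tp, nrow(pl)), recall = safe(tp, nrow(gl)))
}

#' Linking performance isolated from detection (TRA on GT)
#'
#' Re-links the ground-truth spots with the forward linker (perfect
#' detections) and scores the resulting forest against the ground
#' truth, isolating the linker's contribution from detection errors.
#'
#' @param gt ground-truth `lineage_forest`.
#' @param flow flow prior as in [link_forward()].
#' @param params a [linking_params()].
#' @param weights an [aogm_weights()].
#' @return List with `linking` (precision/recall), `tra`, and the
#'   relinked `forest`.
#' @export
tra_on_gt <- function(gt, flow = NULL, params = linking_params(),
                      weights = aogm_weights()) {
  pred <- link_forward(gt$spots, flow, params)
  matching <- match_spots(gt$spots, pred$spots)
  list(linking = linking_scores(gt, pred, matching),
       tra = tra_score(gt, pred, weights, matching),
       forest = pred)
}

#' Depth-stratified detection scores
#'
#' Bins spots by depth (`[0, w), [w, 2w), ...` um from the first z
#' slice) and reports per-bin detection precision and recall: recall
#' over the ground-truth spots of the bin, precision with false
#' positives binned by the predicted spot's own depth. Bins without
#' ground-truth spots are omitted.
#'
#' @param gt,pred spots data.frames or `lineage_forest` objects.
#' @param bin_width bin width in um (default 5).
#' @param matching optional precomputed [match_spots()] result.
#' @return data.frame with columns `z_min, z_max, n_gt, tp, fn, ns, fp,
#'   precision, recall`.
#' @export
depth_stratified_scores <- function(gt, pred, bin_width = 5,
                                    matching = NULL) {
  if (inherits(gt, "lineage_forest")) gt <- gt$spots
  if (inherits(pred, "lineage_forest")) pred <- pred$spots
  if (is.null(matching)) matching <- match_spots(gt, pred)
  gs <- matching$gt_status
  ps <- matching$pred_status
  gs$bin <- floor(gs$z / bin_width)
  ps$bin <- floor(ps$z / bin_width)
  bins <- sort(unique(gs$bin))
  out <- lapply(bins, function(b) {
    g <- gs[gs$bin == b, ]
    tp <- sum(g$status == "TP")
    fn <- sum(g$status == "FN")
    ns <- sum(g$status == "NS")
    fp <- sum(ps$status == "FP" & ps$bin == b)
    sc <- detection_scores(tp, fp, fn)
    data.frame(z_min = b * bin_width, z_max = (b + 1) * bin_width,
               n_gt = nrow(g), tp = tp, fn = fn, ns = ns, fp = fp,
               precision = sc["precision"], recall = sc["recall"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full evaluation report of a predicted forest
#'
#' @param gt,pred `lineage_forest` objects.
#' @param weights an [aogm_weights()].
#' @param depth_bin optional bin width (um) for a depth-stratified
#'   table.
#' @return Object of class `evaluation_report`: DET, TRA, detection and
#'   linking precision/recall, AOGM counts and cost, proofreading
#'   effort, and (optionally) the per-depth-bin table.
#' @export
evaluate_tracking <- function(gt, pred, weights = aogm_weights(),
                              depth_bin = NULL) {
  matching <- match_spots(gt$spots, pred$spots)
  a <- aogm(gt, pred, weights, matching)
  det_pr <- detection_scores(matching$tp, matching$fp, matching$fn)
  link_pr <- linking_scores(gt, pred, matching)
  rep <- list(
    det = det_score(gt, pred, weights, matching),
    tra = tra_score(gt, pred, weights, matching),
    detection = det_pr,
    linking = link_pr,
    aogm_counts = a$counts,
    aogm_cost = a$cost,
    effort = a$cost,
    depth_table = if (!is.null(depth_bin)) {
      depth_stratified_scores(gt$spots, pred$spots, depth_bin, matching)
    })
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("DET %.3f  TRA %.3f  det P/R %.3f/%.3f  link P/R %.3f/%.3f  effort %.1f\n",
              x$det, x$tra, x$detection["precision"],
              x$detection["recall"], x$linking["precision"],
              x$linking["recall"], x$effort))
  cat("AOGM counts:", paste(names(x$aogm_counts), x$aogm_counts,
                            sep = "=", collapse = " "), "\n")
  if (!is.null(x$depth_table)) {
    cat("depth-stratified scores:\n")
    print(x$depth_table, digits = 3)
  }
  invisible(x)
}

#' Acquisition trade-off experiment
#'
#' Runs the full pipeline for each acquisition condition derived from a
#' master recording: subsample the movie, reduce the ground truth,
#' detect nuclei, build a flow prior, link, and score (detection and
#' CTC-style scores against the reduced ground truth; linking
#' precision/recall in TRA-on-GT mode; proofreading effort). Repeats
#' are independent realisations: when `master` is a
#' `simulation_config`, each repeat simulates a fresh recording with a
#' child seed; a fixed `recording` is evaluated once per repeat (the
#' pipeline itself is deterministic).
#'
#' @param master a `recording` (see [simulate_recording()]) or a
#'   `simulation_config`.
#' @param conditions list of [acquisition_condition()]s.
#' @param detector_params [detection_params()].
#' @param link_params [linking_params()].
#' @param flow `"ground_truth"` (flow sampled from the reduced
#'   ground-truth displacements), `"estimate"` (block matching between
#'   consecutive frames) or `"none"`.
#' @param weights [aogm_weights()].
#' @param n_repeats number of repeats averaged.
#' @param seed base seed; repeat r simulates with child seed
#'   `child_seed(seed, r)`.
#' @param depth_bin bin width (um) for the per-condition depth table.
#' @param radii,snr_half detector scale range and SNR calibration, see
#'   [blob_response()].
#' @return Object of class `tradeoff_table`: a data.frame with one row
#'   per condition (image settings, relative exposure, DET, TRA,
#'   detection precision/recall, linking precision/recall, proofreading
#'   effort, number of time points), averaged over repeats; per-repeat,
#'   per-condition summaries and depth tables in `attr(, "repeats")`.
#' @export
run_tradeoff_experiment <- function(master,
                                    conditions = standard_conditions(),
                                    detector_params = detection_params(),
                                    link_params = linking_params(),
                                    flow = c("ground_truth", "estimate",
                                             "none"),
                                    weights = aogm_weights(),
                                    n_repeats = 3, seed = 1,
                                    depth_bin = NULL, radii = NULL,
                                    snr_half = 8) {
  flow <- match.arg(flow)
  rep_rows <- vector("list", n_repeats)
  rep_reports <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rec <- if (inherits(master, "simulation_config")) {
      cfg <- master
      cfg$seed <- child_seed(seed, r)
      simulate_recording(cfg)
    } else if (inherits(master, "recording")) {
      master
    } else {
      stop("master must be a recording or a simulation_config")
    }
    rows <- lapply(conditions, function(cond) {
      ms <- subsample_movie(rec$movie, cond)
      gt_c <- reduce_forest(rec$forest, cond)
      pred_spots <- detect_nuclei(ms, detector_params, radii, snr_half)
      flow_prior <- switch(flow,
        ground_truth = gt_flow_sampler(gt_c),
        estimate = block_flow_sampler(ms),
        none = NULL)
      pred <- link_forward(pred_spots, flow_prior, link_params)
      report <- evaluate_tracking(gt_c, pred, weights, depth_bin)
      on_gt <- tra_on_gt(gt_c, flow_prior, link_params, weights)
      row <- data.frame(
        condition = cond$name,
        xy_um = ms$grid$voxel_size[2], z_um = ms$grid$voxel_size[1],
        t_min = ms$grid$time_interval, averaging = cond$n_average,
        exposure = relative_exposure(cond),
        det = report$det, tra = report$tra,
        det_precision = unname(report$detection["precision"]),
        det_recall = unname(report$detection["recall"]),
        link_precision = unname(on_gt$linking["precision"]),
        link_recall = unname(on_gt$linking["recall"]),
        effort = report$effort,
        n_timepoints = n_timepoints(ms),
        row.names = NULL)
      list(summary = row, depth_table = report$depth_table)
    })
    rep_rows[[r]] <- do.call(rbind, c(lapply(rows, `[[`, "summary"),
                                      list(make.row.names = FALSE)))
    rep_reports[[r]] <- rows
  }
  avg <- rep_rows[[1]]
  num_cols <- c("det", "tra", "det_precision", "det_recall",
                "link_precision", "link_recall", "effort")
  for (cc in num_cols) {
    avg[[cc]] <- Reduce(`+`, lapply(rep_rows, `[[`, cc)) / n_repeats
  }
  structure(avg, class = c("tradeoff_table", "data.frame"),
            repeats = rep_reports)
}

# lazily estimated block-matching flow for a (single-replicate) movie
block_flow_sampler <- function(m, block_halfsize = 5, search_radius = 5) {
  cache <- new.env(parent = emptyenv())
  function(pos, t) {
    key <- as.character(t)
    if (is.null(cache[[key]])) {
      cache[[key]] <- estimate_flow_block_matching(
        movie_frame(m, t + 1L, 1), movie_frame(m, t, 1), m$grid,
        block_halfsize, search_radius)
    }
    flow_at(cache[[key]], pos)
  }
}

#' @export
print.tradeoff_table <- function(x, ...) {
  cat("Acquisition trade-off experiment",
      sprintf("(equal relative exposure %.3g)\n", x$exposure[1]))
  df <- as.data.frame(x)
  df$exposure <- NULL
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}
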