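#' Labelled point cloud of nuclei
#'
#' A set of nucleus positions with categorical labels, from either a
#' post-fixation stained volume (`source = "fixed"`) or the last frame
#' of a live recording (`source = "live"`).
#'
#' @param points n x 3 matrix or data.frame of (z, y, x) positions, um.
#' @param labels character vector of length n (recycled), e.g.
#'   `"marker+"` / `"marker-"`.
#' @param source `"fixed"` or `"live"`.
#' @return Object of class `labelled_cloud`: list with `points` (n x 3
#'   matrix), `labels`, `source`.
#' @export
labelled_cloud <- function(points, labels = NA_character_,
                           source = c("fixed", "live")) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3 (z, y, x)")
  if (nrow(points) < 1) stop("a cloud needs at least one point")
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  colnames(points) <- c("z", "y", "x")
  structure(list(points = points,
                 labels = rep_len(as.character(labels), nrow(points)),
                 source = match.arg(source)),
            class = "labelled_cloud")
}

# least-squares rigid fit (Kabsch): R minimising sum |R f + t - l|^2
fit_rigid <- function(f, l) {
  mf <- colMeans(f); ml <- colMeans(l)
  H <- t(sweep(f, 2, mf)) %*% sweep(l, 2, ml)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(A = R, t = as.numeric(ml - R %*% mf))
}

fit_affine <- function(f, l) {
  coef <- stats::lsfit(f, l, intercept = TRUE)$coefficients
  list(A = t(coef[-1, , drop = FALSE]), t = as.numeric(coef[1, ]))
}

apply_transform <- function(trans, p) {
  sweep(p %*% t(trans$A), 2, trans$t, `+`)
}

#' Register a fixed stained cloud onto a live cloud
#'
#' Iterative-closest-point registration of the post-fixation nuclei
#' onto the nuclei of the last live frame: nearest-neighbour
#' correspondences and least-squares transform fits are alternated
#' until the mean residual stabilises. Initialisation is centroid
#' alignment plus a principal-axes rotation (the sign-ambiguous axis
#' orientations are disambiguated by trying the four proper rotations
#' and keeping the best). A trimming fraction discards the worst
#' correspondences from each fit, which absorbs outliers such as
#' fixation-distorted or unmatched nuclei.
#'
#' @param fixed,live `labelled_cloud`s (or n x 3 matrices).
#' @param mode `"rigid"` (rotation + translation) or `"affine"`
#'   (accommodates uniform tissue distortion from mounting/fixation).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change of the mean residual (um).
#' @param trim fraction in [0, 1) of the worst correspondences excluded
#'   from each transform fit.
#' @return List with `A` (3 x 3 linear part), `t` (translation, um),
#'   `residuals` (per fixed point, distance to its nearest live point
#'   after transformation), `mean_residual`, `inlier_residual` (mean
#'   over the kept fraction), `converged`, `iterations`, `mode`.
#' @export
register_clouds <- function(fixed, live, mode = c("rigid", "affine"),
                            max_iter = 50, tol = 1e-9, trim = 0) {
  mode <- match.arg(mode)
  f <- if (inherits(fixed, "labelled_cloud")) fixed$points else
    as.matrix(fixed)
  l <- if (inherits(live, "labelled_cloud")) live$points else
    as.matrix(live)
  need <- if (mode == "affine") 4 else 3
  if (nrow(f) < need || nrow(l) < need) {
    stop(mode, " registration needs at least ", need, " points")
  }
  if (trim < 0 || trim >= 1) stop("trim must be in [0, 1)")

  nn_dist <- function(p) {
    # for each row of p, index and distance of the nearest row of l
    idx <- integer(nrow(p)); dd <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      d2 <- colSums((t(l) - p[i, ])^2)
      idx[i] <- which.min(d2)
      dd[i] <- sqrt(d2[idx[i]])
    }
    list(idx = idx, dist = dd)
  }

  # principal-axes initialisation (proper rotations only)
  init_candidates <- list(diag(3))
  if (nrow(f) > 3) {
    ef <- eigen(stats::cov(f), symmetric = TRUE)$vectors
    el <- eigen(stats::cov(l), symmetric = TRUE)$vectors
    if (det(ef) < 0) ef[, 3] <- -ef[, 3]
    if (det(el) < 0) el[, 3] <- -el[, 3]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      S <- diag(c(s1, s2, s1 * s2))
      init_candidates[[length(init_candidates) + 1]] <-
        el %*% S %*% t(ef)
    }
  }
  mf <- colMeans(f); ml <- colMeans(l)
  best_init <- NULL; best_cost <- Inf
  for (R0 in init_candidates) {
    tr <- list(A = R0, t = as.numeric(ml - R0 %*% mf))
    cost <- mean(nn_dist(apply_transform(tr, f))$dist)
    if (cost < best_cost) {
      best_cost <- cost
      best_init <- tr
    }
  }

  trans <- best_init
  prev <- Inf
  converged <- FALSE
  iter <- 0
  n_keep <- max(need, ceiling((1 - trim) * nrow(f)))
  while (iter < max_iter) {
    iter <- iter + 1
    fp <- apply_transform(trans, f)
    nn <- nn_dist(fp)
    keep <- order(nn$dist)[seq_len(n_keep)]
    fit <- if (mode == "rigid") {
      fit_rigid(f[keep, , drop = FALSE], l[nn$idx[keep], , drop = FALSE])
    } else {
      fit_affine(f[keep, , drop = FALSE], l[nn$idx[keep], , drop = FALSE])
    }
    trans <- fit
    cur <- mean(nn_dist(apply_transform(trans, f))$dist)
    if (is.finite(prev) && abs(prev - cur) < tol) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  fp <- apply_transform(trans, f)
  nn <- nn_dist(fp)
  keep <- order(nn$dist)[seq_len(n_keep)]
  list(A = trans$A, t = trans$t, residuals = nn$dist,
       mean_residual = mean(nn$dist),
       inlier_residual = mean(nn$dist[keep]),
       converged = converged, iterations = iter, mode = mode)
}

#' Transfer stain labels onto live spots
#'
#' Maps each fixed (stained) nucleus through the registration transform
#' and assigns its label to the nearest live spot within the accept
#' radius; assignments are one-to-one, resolved greedily in ascending
#' distance, and unmatched fixed points are reported.
#'
#' @param transform result of [register_clouds()] (or any list with
#'   `A`, `t`).
#' @param fixed a `labelled_cloud` of stained nuclei.
#' @param live_spots spots data.frame of the last live frame.
#' @param accept_radius maximum match distance in um (default 5, the
#'   linking gate).
#' @return List with `spots` (live spots, `label` filled in for matched
#'   spots), `matches` (data.frame fixed_index, spot_id, dist) and
#'   `unmatched_fixed` (indices into the fixed cloud).
#' @export
transfer_labels <- function(transform, fixed, live_spots,
                            accept_radius = 5) {
  fp <- apply_transform(transform, fixed$points)
  lp <- cbind(live_spots$z, live_spots$y, live_spots$x)
  d <- sqrt(outer(fp[, 1], lp[, 1], `-`)^2 +
              outer(fp[, 2], lp[, 2], `-`)^2 +
              outer(fp[, 3], lp[, 3], `-`)^2)
  cand <- which(d <= accept_radius, arr.ind = TRUE)
  out_spots <- live_spots
  matches <- data.frame(fixed_index = integer(0), spot_id = integer(0),
                        dist = numeric(0))
  if (nrow(cand) > 0) {
    ord <- order(d[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    f_taken <- logical(nrow(fp))
    s_taken <- logical(nrow(lp))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (f_taken[i] || s_taken[j]) next
      f_taken[i] <- TRUE
      s_taken[j] <- TRUE
      out_spots$label[j] <- fixed$labels[i]
      matches <- rbind(matches,
                       data.frame(fixed_index = i,
                                  spot_id = live_spots$id[j],
                                  dist = d[i, j]))
    }
  }
  list(spots = out_spots, matches = matches,
       unmatched_fixed = setdiff(seq_len(nrow(fp)), matches$fixed_index))
}

#' Progenitors and division history of labelled terminal cells
#'
#' Walks each labelled terminal spot (a spot at the forest's final time
#' point) up its parent chain to the root, groups labelled cells by
#' shared root (clone) and reports, per clone: the progenitor's
#' position at its first time point, the number of divisions in the
#' clone's tree, and how many of the clone's terminal descendants are
#' labelled versus unlabelled.
#'
#' @param forest a `lineage_forest`.
#' @param labelled_ids spot ids of the labelled terminal cells; all
#'   must exist in the forest.
#' @return List with `clones` (one row per progenitor: root_id, root_t,
#'   root z/y/x, n_divisions, n_labelled, n_unlabelled_terminal) and
#'   `paths` (one row per labelled cell: labelled_id, root_id,
#'   divisions_on_path).
#' @export
progenitor_analysis <- function(forest, labelled_ids) {
  validate_forest(forest)
  spots <- forest$spots
  links <- forest$links
  missing_ids <- setdiff(labelled_ids, spots$id)
  if (length(missing_ids) > 0) {
    stop("labelled spot id ", missing_ids[1], " is not in the forest")
  }
  parent_of <- stats::setNames(links$source_id, links$target_id)
  out_deg <- table(links$source_id)
  is_div <- stats::setNames(spots$id %in%
                              as.integer(names(out_deg)[out_deg == 2L]),
                            spots$id)
  root_and_divs <- function(id) {
    divs <- 0L
    repeat {
      p <- parent_of[as.character(id)]
      if (is.na(p)) return(c(root = unname(id), divs = divs))
      id <- unname(p)
      if (is_div[as.character(id)]) divs <- divs + 1L
    }
  }
  t_max <- max(spots$t)
  walk <- vapply(labelled_ids, root_and_divs, c(root = 0, divs = 0))
  paths <- data.frame(labelled_id = labelled_ids,
                      root_id = as.integer(walk["root", ]),
                      divisions_on_path = as.integer(walk["divs", ]))
  # root of every terminal spot, for unlabelled-descendant counts
  terminals <- spots$id[spots$t == t_max]
  term_roots <- vapply(terminals,
                       function(id) root_and_divs(id)["root"], numeric(1))
  # divisions per tree
  children_of <- split(links$target_id, factor(links$source_id,
                                               levels = spots$id))
  tree_divisions <- function(root) {
    n <- 0L
    frontier <- root
    while (length(frontier) > 0) {
      n <- n + sum(is_div[as.character(frontier)])
      frontier <- unlist(children_of[as.character(frontier)],
                         use.names = FALSE)
    }
    n
  }
  roots <- sort(unique(paths$root_id))
  clones <- do.call(rbind, lapply(roots, function(rt) {
    rs <- spots[spots$id == rt, ]
    n_lab <- sum(paths$root_id == rt)
    n_term <- sum(term_roots == rt)
    data.frame(root_id = rt, root_t = rs$t, root_z = rs$z,
               root_y = rs$y, root_x = rs$x,
               n_divisions = tree_divisions(rt),
               n_labelled = n_lab,
               n_unlabelled_terminal = n_term - n_lab)
  }))
  rownames(clones) <- NULL
  list(clones = clones, paths = paths)
}
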