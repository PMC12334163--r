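# Shared fixtures (built in code, cached across test files) and
# independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# the packaged benchmark recording (li-synth, seed 42)
get_fixture <- function() {
  memo("fixture", simulate_recording(li_synth_config()))
}

# small, fast recording for unit tests
get_small_recording <- function() {
  memo("small_rec", simulate_recording(simulation_config(
    grid = voxel_grid(c(10, 48, 48)), n_timepoints = 10,
    n_replicates = 2, n_initial = 12, seed = 7,
    division_profile = division_schedule(10, 2, 6, 0.1, 0))))
}

# detections of a fixture condition, cached: list(movie, gt, spots)
get_fixture_detection <- function(which) {
  memo(paste0("det_", which), {
    rec <- get_fixture()
    cond <- switch(which,
      master = acquisition_condition("master-avg", n_average = 4),
      standard_conditions()[[which]])
    ms <- subsample_movie(rec$movie, cond)
    gt <- reduce_forest(rec$forest, cond)
    list(movie = ms, gt = gt, spots = detect_nuclei(ms))
  })
}

# a hand-sized forest: one dividing track plus one plain track
#
#        1 (t0) -> 2 (t1) -> 3 (t2)        [chain]
#        4 (t0) -> 5 (t1) -+-> 6 (t2)      [division at t1]
#                          +-> 7 (t2)
two_track_forest <- function() {
  spots <- data.frame(
    id = 1:7, t = c(0L, 1L, 2L, 0L, 1L, 2L, 2L),
    z = 5, y = c(10, 10, 10, 30, 30, 28, 32),
    x = c(10, 12, 14, 10, 12, 14, 14), radius = 2)
  links <- data.frame(source_id = c(1L, 2L, 4L, 5L, 5L),
                      target_id = c(2L, 3L, 5L, 6L, 7L))
  lineage_forest(spots, links)
}

# independent tree count: connected components by undirected traversal
bf_count_components <- function(forest) {
  ids <- forest$spots$id
  if (length(ids) == 0) return(0L)
  adj <- split(c(forest$links$target_id, forest$links$source_id),
               c(forest$links$source_id, forest$links$target_id))
  seen <- stats::setNames(logical(length(ids)), ids)
  n <- 0L
  for (id in ids) {
    if (seen[as.character(id)]) next
    n <- n + 1L
    frontier <- id
    while (length(frontier) > 0) {
      seen[as.character(frontier)] <- TRUE
      nb <- unlist(adj[as.character(frontier)], use.names = FALSE)
      frontier <- unique(nb[!seen[as.character(nb)]])
    }
  }
  n
}

# all one-to-one matchings between index sets, restricted to allowed
# pairs (logical matrix); returns list of 2-column index matrices
enumerate_matchings <- function(allowed) {
  ng <- nrow(allowed); np <- ncol(allowed)
  out <- list(matrix(integer(0), 0, 2))
  rec <- function(g, used_p, acc) {
    if (g > ng) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    rec(g + 1L, used_p, acc)  # leave g unmatched
    for (p in seq_len(np)) {
      if (allowed[g, p] && !used_p[p]) {
        u <- used_p; u[p] <- TRUE
        rec(g + 1L, u, rbind(acc, c(g, p)))
      }
    }
  }
  rec(1L, logical(np), matrix(integer(0), 0, 2))
  out
}

# exhaustive AOGM: enumerate candidate matchings per time point, take
# the maximum-cardinality minimum-total-distance one, then count the
# edit operations from first principles
bf_aogm <- function(gt, pred, weights = aogm_weights()) {
  gs <- gt$spots; ps <- pred$spots
  times <- sort(unique(c(gs$t, ps$t)))
  pairs <- NULL
  ns <- fn <- fp <- 0L
  for (tt in times) {
    G <- gs[gs$t == tt, , drop = FALSE]
    P <- ps[ps$t == tt, , drop = FALSE]
    if (nrow(G) == 0) {
      fp <- fp + nrow(P)
      next
    }
    if (nrow(P) == 0) {
      fn <- fn + nrow(G)
      next
    }
    d <- sqrt(outer(G$z, P$z, `-`)^2 + outer(G$y, P$y, `-`)^2 +
                outer(G$x, P$x, `-`)^2)
    allowed <- d <= G$radius
    ms <- enumerate_matchings(allowed)
    card <- vapply(ms, nrow, integer(1))
    ms <- ms[card == max(card)]
    cost <- vapply(ms, function(m) {
      if (nrow(m) == 0) 0 else sum(d[m])
    }, numeric(1))
    m <- ms[[which.min(cost)]]
    matched_g <- m[, 1]; matched_p <- m[, 2]
    if (nrow(m) > 0) {
      pairs <- rbind(pairs, data.frame(gt_id = G$id[matched_g],
                                       pred_id = P$id[matched_p]))
    }
    un_g <- setdiff(seq_len(nrow(G)), matched_g)
    for (g in un_g) {
      if (length(matched_p) > 0 && any(allowed[g, matched_p])) {
        ns <- ns + 1L
      } else {
        fn <- fn + 1L
      }
    }
    fp <- fp + (nrow(P) - nrow(m))
  }
  map <- if (is.null(pairs)) {
    stats::setNames(integer(0), character(0))
  } else {
    stats::setNames(pairs$gt_id, pairs$pred_id)
  }
  gl <- gt$links; pl <- pred$links
  is_div <- function(links) {
    if (nrow(links) == 0) return(logical(0))
    tab <- table(links$source_id)
    as.vector(tab[as.character(links$source_id)] == 2L)
  }
  g_div <- is_div(gl); p_div <- is_div(pl)
  gt_keys <- paste(gl$source_id, gl$target_id)
  ed <- ec <- 0L
  matched_gt_link <- rep(FALSE, nrow(gl))
  for (k in seq_len(nrow(pl))) {
    a <- map[as.character(pl$source_id[k])]
    b <- map[as.character(pl$target_id[k])]
    if (is.na(a) || is.na(b)) next
    hit <- which(gt_keys == paste(a, b))
    if (length(hit) == 0) {
      ed <- ed + 1L
    } else {
      matched_gt_link[hit] <- TRUE
      if (p_div[k] != g_div[hit]) ec <- ec + 1L
    }
  }
  ea <- sum(!matched_gt_link)
  counts <- c(ns = ns, fn = fn, fp = fp, ed = ed, ea = ea, ec = ec)
  cost <- sum(unlist(weights[c("w_ns", "w_fn", "w_fp", "w_ed", "w_ea",
                               "w_ec")]) * counts)
  list(counts = counts, cost = cost)
}

# random small gt/pred forest pair for AOGM property testing
random_instance <- function(seed) {
  set.seed(seed)
  n_t <- sample(2:3, 1)
  spots <- NULL
  links <- NULL
  id <- 0L
  prev_ids <- integer(0)
  for (tt in 0:(n_t - 1)) {
    n <- sample(1:3, 1)
    ids <- id + seq_len(n)
    id <- id + n
    spots <- rbind(spots, data.frame(
      id = ids, t = tt, z = runif(n, 0, 12), y = runif(n, 0, 12),
      x = runif(n, 0, 12), radius = runif(n, 1.5, 3)))
    if (tt > 0) {
      for (b in ids) {
        if (length(prev_ids) > 0 && runif(1) < 0.8) {
          # respect the two-children cap
          load <- table(factor(links$source_id, levels = prev_ids))
          open <- prev_ids[load < 2]
          if (length(open) > 0) {
            src <- open[sample.int(length(open), 1)]
            links <- rbind(links, data.frame(source_id = src,
                                             target_id = b))
          }
        }
      }
    }
    prev_ids <- ids
  }
  if (nrow(spots) > 8) {
    keep <- spots$id[seq_len(8)]
    spots <- spots[spots$id %in% keep, ]
    links <- links[links$source_id %in% keep & links$target_id %in% keep, ]
  }
  gt <- lineage_forest(spots, links)
  # perturb into a prediction: jitter, drop, add, relink
  ps <- spots
  ps$z <- ps$z + rnorm(nrow(ps), 0, 0.7)
  ps$y <- ps$y + rnorm(nrow(ps), 0, 0.7)
  ps$x <- ps$x + rnorm(nrow(ps), 0, 0.7)
  drop <- runif(nrow(ps)) < 0.2
  ps <- ps[!drop, , drop = FALSE]
  pl <- links
  if (!is.null(pl)) {
    pl <- pl[pl$source_id %in% ps$id & pl$target_id %in% ps$id, ,
             drop = FALSE]
    pl <- pl[runif(nrow(pl)) > 0.15, , drop = FALSE]
  }
  if (runif(1) < 0.4) {
    ps <- rbind(ps, data.frame(id = max(spots$id) + 1L,
                               t = sample(0:(n_t - 1), 1),
                               z = runif(1, 0, 12), y = runif(1, 0, 12),
                               x = runif(1, 0, 12), radius = 2))
  }
  pred <- lineage_forest(ps, pl)
  list(gt = gt, pred = pred)
}

# minimum-total-distance complete assignment by enumeration (for the
# linking oracle on tiny instances)
bf_min_assignment <- function(d) {
  np <- ncol(d)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(np))) {
    cost <- sum(d[cbind(seq_len(nrow(d)), p[seq_len(nrow(d))])])
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}
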