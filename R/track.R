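#' Linking and backtracking parameters
#'
#' @param d_max maximum linking distance in um (default 5) between a
#'   candidate parent and the flow-predicted origin of a spot.
#' @param max_children maximum links out of one spot (default 2,
#'   allowing divisions).
#' @return `linking_params` / `backtrack_params` objects.
#' @export
linking_params <- function(d_max = 5, max_children = 2) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (max_children < 1) stop("max_children must be >= 1")
  structure(list(d_max = d_max, max_children = as.integer(max_children)),
            class = "linking_params")
}

#' @rdname linking_params
#' @param vicinity_radius um; a detection within this distance of the
#'   predicted position is linked (default 5, the linking gate).
#' @param max_interpolation budget of *consecutive* interpolated time
#'   points before the trace is truncated.
#' @param window_halfsize um; half-size of the local box around the
#'   predicted position in which detections are searched (or computed,
#'   when tracing on image volumes).
#' @export
backtrack_params <- function(vicinity_radius = 5, max_interpolation = 3,
                             window_halfsize = 10) {
  if (vicinity_radius <= 0 || max_interpolation < 0 ||
      window_halfsize <= 0) {
    stop("invalid backtrack parameters")
  }
  structure(list(vicinity_radius = vicinity_radius,
                 max_interpolation = as.integer(max_interpolation),
                 window_halfsize = window_halfsize),
            class = "backtrack_params")
}

#' Nearest-neighbour forward linking into a lineage forest
#'
#' For each spot at time t+1 the predicted origin is its position minus
#' the flow displacement sampled there (or the position itself without
#' a flow prior). Candidate parents are the spots at time t within
#' `d_max` of the predicted origin; candidate pairs are assigned
#' greedily in ascending distance order, each child accepting at most
#' one parent and each parent at most `max_children` children (so that
#' dividing cells can keep both daughters). Unmatched spots start new
#' trees.
#'
#' @param spots spots data.frame (unique ids). The time axis is the
#'   consecutive integer range spanned by the spots; a frame with no
#'   detections simply breaks the tracks crossing it (links never span
#'   more than one step).
#' @param flow optional flow prior: `NULL`, a [flow_field()], a list of
#'   flow fields indexed by `as.character(t)`, or a
#'   `function(pos, t)` returning displacements (um) — e.g.
#'   [gt_flow_sampler()].
#' @param params a [linking_params()].
#' @return A `lineage_forest` over the given spots.
#' @export
link_forward <- function(spots, flow = NULL, params = linking_params()) {
  if (nrow(spots) == 0) return(lineage_forest(spots))
  times <- seq(min(spots$t), max(spots$t))
  sampler <- as_flow_sampler(flow)
  src <- integer(0); tgt <- integer(0)
  for (t in times[-length(times)]) {
    A <- spots[spots$t == t, , drop = FALSE]
    B <- spots[spots$t == t + 1, , drop = FALSE]
    if (nrow(A) == 0 || nrow(B) == 0) next
    posB <- cbind(B$z, B$y, B$x)
    pred <- posB - sampler(posB, t + 1)
    posA <- cbind(A$z, A$y, A$x)
    # candidate pairs within d_max of the predicted origin
    d2 <- outer(rowSums(pred^2), rowSums(posA^2), `+`) -
      2 * pred %*% t(posA)
    d2 <- pmax(d2, 0)
    cand <- which(d2 <= params$d_max^2, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    dd <- sqrt(d2[cand])
    ord <- order(dd, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    child_taken <- logical(nrow(B))
    parent_load <- integer(nrow(A))
    for (k in seq_len(nrow(cand))) {
      b <- cand[k, 1]; a <- cand[k, 2]
      if (child_taken[b] || parent_load[a] >= params$max_children) next
      child_taken[b] <- TRUE
      parent_load[a] <- parent_load[a] + 1L
      src <- c(src, A$id[a])
      tgt <- c(tgt, B$id[b])
    }
  }
  lineage_forest(spots, data.frame(source_id = src, target_id = tgt))
}

#' Trace a selected cell backward in time
#'
#' Starting from a seed spot at time t, the tracer iterates towards
#' t = 0. At each step the cell's previous position is predicted by
#' subtracting the flow displacement sampled at the current position;
#' detections near the prediction are looked up (from a supplied spot
#' table, or computed by running the blob detector on a local window of
#' the image volume). If a detection lies within the vicinity radius,
#' the trace links to the closest one and the interpolation counter
#' resets; otherwise a new spot is interpolated at the predicted
#' position (flagged `interpolated`) and the counter increments. The
#' trace stops at t = 0 (`status = "complete"`) or when the next step
#' would exceed the budget of consecutive interpolations
#' (`status = "truncated"`).
#'
#' @param seed a one-row spots data.frame (the selected cell), or a spot
#'   id present in `detections`.
#' @param detections spots data.frame of detections over time (e.g.
#'   output of [detect_nuclei()] or ground-truth spots). Either this or
#'   `movie` must be given.
#' @param movie a `movie` to detect in on the fly (replicate 1).
#' @param flow flow prior as in [link_forward()]; required in practice
#'   for moving tissue, `NULL` means zero flow.
#' @param detector_params [detection_params()] for on-the-fly detection.
#' @param params a [backtrack_params()].
#' @param snr_half passed to [blob_response()] in movie mode.
#' @return Object of class `backtrack_path`: list with `spots` (ordered
#'   seed first, earliest last), `links` (parent -> child rows), `status`
#'   (`"complete"` or `"truncated"`) and `n_interpolated`.
#' @export
backtrack <- function(seed, detections = NULL, movie = NULL, flow = NULL,
                      detector_params = detection_params(),
                      params = backtrack_params(), snr_half = 8) {
  if (is.null(detections) && is.null(movie)) {
    stop("supply detections or a movie to trace in")
  }
  if (!is.data.frame(seed)) {
    if (is.null(detections)) stop("a seed id needs a detections table")
    seed <- detections[match(seed, detections$id), , drop = FALSE]
    if (nrow(seed) == 0 || anyNA(seed$id)) stop("seed id not found")
  }
  seed <- lineage_forest(seed)$spots  # normalise columns
  sampler <- as_flow_sampler(flow)
  w <- params$window_halfsize
  next_id <- max(c(seed$id, detections$id, 0L)) + 1L

  path <- list(seed)
  src <- integer(0); tgt <- integer(0)
  cur <- seed
  interp <- 0L
  n_interp <- 0L
  status <- "complete"
  while (cur$t >= 1) {
    pos <- cbind(cur$z, cur$y, cur$x)
    pred <- as.numeric(pos - sampler(pos, cur$t))
    tm1 <- cur$t - 1L
    cand <- if (!is.null(detections)) {
      D <- detections[detections$t == tm1, , drop = FALSE]
      D[abs(D$z - pred[1]) <= w & abs(D$y - pred[2]) <= w &
          abs(D$x - pred[3]) <= w, , drop = FALSE]
    } else {
      local_detect(movie, tm1, pred, w, detector_params, snr_half)
    }
    hit <- NULL
    if (nrow(cand) > 0) {
      d <- sqrt((cand$z - pred[1])^2 + (cand$y - pred[2])^2 +
                  (cand$x - pred[3])^2)
      if (min(d) <= params$vicinity_radius) {
        hit <- cand[order(d, cand$id)[1], , drop = FALSE]
      }
    }
    if (!is.null(hit)) {
      if (is.null(detections)) {
        hit$id <- next_id
        next_id <- next_id + 1L
      }
      nxt <- lineage_forest(hit)$spots
      interp <- 0L
    } else {
      if (interp + 1L > params$max_interpolation) {
        status <- "truncated"
        break
      }
      interp <- interp + 1L
      n_interp <- n_interp + 1L
      nxt <- cur
      nxt$id <- next_id
      next_id <- next_id + 1L
      nxt$z <- pred[1]; nxt$y <- pred[2]; nxt$x <- pred[3]
      nxt$intensity <- 0
      nxt$interpolated <- TRUE
    }
    nxt$t <- tm1
    src <- c(src, nxt$id)
    tgt <- c(tgt, cur$id)
    path[[length(path) + 1]] <- nxt
    cur <- nxt
  }
  structure(list(spots = do.call(rbind, path),
                 links = data.frame(source_id = src, target_id = tgt),
                 status = status, n_interpolated = n_interp),
            class = "backtrack_path")
}

#' @export
print.backtrack_path <- function(x, ...) {
  cat("backtrack_path: ", nrow(x$spots), " spots down to t = ",
      min(x$spots$t), " (", x$status, ", ", x$n_interpolated,
      " interpolated)\n", sep = "")
  invisible(x)
}

# run the blob detector on a window around `center` (um) of frame t
local_detect <- function(m, t, center, halfsize, params, snr_half) {
  grid <- m$grid
  lo <- um_to_voxel(matrix(center - halfsize, 1), grid)
  hi <- um_to_voxel(matrix(center + halfsize, 1), grid)
  vol <- movie_frame(m, t + 1L, 1)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                   drop = FALSE]
  sub_grid <- voxel_grid(dim(vol), grid$voxel_size, grid$time_interval)
  sp <- extract_centers(blob_response(vol, sub_grid, snr_half = snr_half),
                        params = params, t = t)
  off <- (as.numeric(lo) - 1) * grid$voxel_size
  sp$z <- sp$z + off[1]; sp$y <- sp$y + off[2]; sp$x <- sp$x + off[3]
  sp
}

# cross-correlation by FFT: c(d) = sum_v A(v) * W(v + d), A zero-padded
# to the shape of W; valid for d in 0 .. dim(W) - dim(A) per axis
xcorr3 <- function(A, W) {
  dW <- dim(W)
  Ap <- array(0, dW)
  Ap[seq_len(dim(A)[1]), seq_len(dim(A)[2]), seq_len(dim(A)[3])] <- A
  Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(W), inverse = TRUE)) /
    prod(dW)
}

#' Block-matching flow estimation between two frames
#'
#' Classical stand-in for a learned flow model: the later frame is
#' tiled into blocks; each block is matched against the earlier frame
#' within a search radius by maximising the normalised cross-correlation
#' (computed via FFT), and the winning per-block displacement (um, from
#' t-1 to t) is written into a piecewise-constant voxel field.
#' Zero-variance blocks or windows yield zero displacement.
#'
#' @param frame_t,frame_t_minus_1 equal-shaped 3D arrays `(z, y, x)`.
#' @param grid matching `voxel_grid`.
#' @param block_halfsize um; blocks are `2 * halfsize` wide per axis
#'   (at least 1 voxel).
#' @param search_radius um; maximum displacement searched per axis.
#' @return A [flow_field()].
#' @export
estimate_flow_block_matching <- function(frame_t, frame_t_minus_1, grid,
                                         block_halfsize = 5,
                                         search_radius = 5) {
  if (!identical(dim(frame_t), dim(frame_t_minus_1))) {
    stop("frames must have equal shape")
  }
  dims <- dim(frame_t)
  vs <- grid$voxel_size
  bs <- pmax(1L, as.integer(round(2 * block_halfsize / vs)))
  bs <- pmin(bs, dims)
  sr <- pmax(0L, as.integer(round(search_radius / vs)))
  disp <- array(0, dim = c(dims, 3))
  starts <- lapply(1:3, function(a) {
    last <- max(dims[a] - bs[a] + 1L, 1L)
    unique(c(seq(1L, last, by = bs[a]), last))
  })
  for (z0 in starts[[1]]) for (y0 in starts[[2]]) for (x0 in starts[[3]]) {
    b_end <- pmin(c(z0, y0, x0) + bs - 1L, dims)
    b_rng <- Map(seq, c(z0, y0, x0), b_end)
    A <- frame_t[b_rng[[1]], b_rng[[2]], b_rng[[3]], drop = FALSE]
    w_lo <- pmax(c(z0, y0, x0) - sr, 1L)
    w_hi <- pmin(b_end + sr, dims)
    W <- frame_t_minus_1[w_lo[1]:w_hi[1], w_lo[2]:w_hi[2],
                         w_lo[3]:w_hi[3], drop = FALSE]
    dA <- dim(A); dW <- dim(W)
    nA <- prod(dA)
    varA <- stats::var(as.vector(A)) * (nA - 1)
    best_shift <- c(0, 0, 0)
    if (varA > 0) {
      num <- xcorr3(A - mean(A), W)
      s1 <- xcorr3(array(1, dA), W)
      s2 <- xcorr3(array(1, dA), W^2)
      denom2 <- pmax(s2 - s1^2 / nA, 0)
      valid <- dW - dA  # max offset per axis
      ncc <- num[1:(valid[1] + 1), 1:(valid[2] + 1), 1:(valid[3] + 1),
                 drop = FALSE] /
        sqrt(pmax(denom2[1:(valid[1] + 1), 1:(valid[2] + 1),
                         1:(valid[3] + 1), drop = FALSE] * varA, 1e-12))
      ncc[denom2[1:(valid[1] + 1), 1:(valid[2] + 1), 1:(valid[3] + 1),
                 drop = FALSE] <= 1e-9] <- -Inf
      if (any(is.finite(ncc))) {
        q <- which(ncc == max(ncc), arr.ind = TRUE)[1, ] - 1L
        # matched block in t-1 starts at w_lo + q; displacement t-1 -> t
        best_shift <- (c(z0, y0, x0) - (w_lo + q)) * vs
      }
    }
    for (k in 1:3) {
      disp[b_rng[[1]], b_rng[[2]], b_rng[[3]], k] <- best_shift[k]
    }
  }
  flow_field(disp, grid)
}
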