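#' Centre-detection parameters
#'
#' @param threshold probability threshold applied to the response map
#'   (default 0.7; the division-candidate mode uses 0.8).
#' @param r_min,r_max admissible nucleus radius bounds in um (defaults
#'   1 and 5); the estimated radius is clamped into this interval.
#' @param d_sup suppression distance in um (default 3): of two
#'   candidate centres closer than `d_sup` (centre-to-centre), only the
#'   higher-valued one is kept.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(threshold = 0.7, r_min = 1, r_max = 5,
                             d_sup = 3) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (!(r_min > 0 && r_min <= r_max)) stop("need 0 < r_min <= r_max")
  if (d_sup <= 0) stop("d_sup must be > 0")
  structure(list(threshold = threshold, r_min = r_min, r_max = r_max,
                 d_sup = d_sup), class = "detection_params")
}

# circular shift of a 3D array by one voxel along one axis
shift3 <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 - by) %% n) + 1
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Gaussian smoothing of a 3D volume by FFT, sigma per axis in voxels.
# Returns the smoothed volume (circular boundary conditions).
fft_gauss_smooth <- function(vol_f, dims, sigma_vox) {
  h <- lapply(1:3, function(a) {
    n <- dims[a]
    k <- 0:(n - 1)
    f <- pmin(k, n - k) / n
    exp(-2 * pi^2 * sigma_vox[a]^2 * f^2)
  })
  H <- h[[1]] %o% h[[2]] %o% h[[3]]
  Re(stats::fft(vol_f * H, inverse = TRUE)) / prod(dims)
}

# scale-normalised negative Laplacian-of-Gaussian response at one scale
log_response <- function(vol_f, dims, sigma_um, voxel_size) {
  sm <- fft_gauss_smooth(vol_f, dims, sigma_um / voxel_size)
  lap <- array(0, dims)
  for (a in 1:3) {
    lap <- lap + (shift3(sm, a, 1) + shift3(sm, a, -1) - 2 * sm) /
      voxel_size[a]^2
  }
  -sigma_um^2 * lap
}

#' Multi-scale blob response of an image volume
#'
#' Classical stand-in for a trained nucleus detector: the
#' scale-normalised Laplacian-of-Gaussian response is computed over
#' scales spanning the admissible radius range, maximised over scale,
#' converted to a robust signal-to-noise ratio (using the median and
#' MAD of the response over the volume as the background reference) and
#' squashed into a pseudo-probability
#' `p = 1 - 2^(-snr / snr_half)` in [0, 1). A volume with zero dynamic
#' range yields an all-zero map.
#'
#' @param volume 3D array `(z, y, x)` of non-negative intensities.
#' @param grid matching `voxel_grid`.
#' @param radii blob radii (um) defining the scale range; defaults to
#'   four geometrically spaced radii over `[r_min, r_max]` = [1, 5] um.
#'   The LoG scale of a radius-r blob is `r / sqrt(3)`.
#' @param snr_half signal-to-noise ratio at which the pseudo-probability
#'   reaches 1/2 (default 8).
#' @return Object of class `blob_map`: list with `p` (the [0, 1]
#'   response), `best_radius` (per-voxel argmax radius, um), `stack`
#'   (the raw per-scale responses, used for plateau-free peak
#'   localisation) and `grid`. [extract_centers()] accepts it directly.
#' @export
blob_response <- function(volume, grid, radii = NULL, snr_half = 8) {
  if (any(volume < 0)) stop("volume must be non-negative")
  if (is.null(radii)) radii <- exp(seq(log(1), log(5), length.out = 4))
  dims <- dim(volume)
  zero <- structure(list(p = array(0, dims),
                         best_radius = array(radii[1], dims),
                         stack = NULL, radii = radii, grid = grid),
                    class = "blob_map")
  if (max(volume) == min(volume)) return(zero)
  vol_f <- stats::fft(volume)
  raw <- vector("list", length(radii))
  pst <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    resp <- log_response(vol_f, dims, radii[k] / sqrt(3),
                         grid$voxel_size)
    med <- stats::median(resp)
    mad <- stats::median(abs(resp - med)) * 1.4826
    raw[[k]] <- resp
    pst[[k]] <- if (mad == 0) {
      array(0, dims)
    } else {
      1 - 2^(-pmax((resp - med) / mad, 0) / snr_half)
    }
  }
  p <- array(0, dims)
  best_r <- array(radii[1], dims)
  for (k in seq_along(radii)) {
    upd <- pst[[k]] > p
    p[upd] <- pst[[k]][upd]
    best_r[upd] <- radii[k]
  }
  if (max(p) == 0) return(zero)
  structure(list(p = p, best_radius = best_r, stack = raw,
                 radii = radii, grid = grid), class = "blob_map")
}

#' Extract nucleus centres from a probability map
#'
#' Finds local maxima (26-neighbourhood) with value at or above the
#' threshold, refines each peak to sub-voxel precision by a per-axis
#' quadratic fit, estimates each candidate's radius from the
#' best-responding blob scale (clamped into `[r_min, r_max]`), and
#' suppresses candidates closer than `d_sup` um to a stronger one
#' (greedy non-maximum suppression in descending value order; ties
#' broken towards the smaller z, y, x index).
#'
#' @param map a `blob_map` from [blob_response()], or a plain 3D array
#'   of values in [0, 1] (e.g. a ground-truth probability map, in which
#'   case the radius is estimated as `sqrt(r_min * r_max)`).
#' @param grid `voxel_grid`; taken from the `blob_map` when omitted.
#' @param params a [detection_params()].
#' @param t time index stamped on the returned spots.
#' @return Spots data.frame (id, t, z, y, x, radius, intensity = map
#'   value, label, interpolated), sorted by descending value.
#' @export
extract_centers <- function(map, grid = NULL, params = detection_params(),
                            t = 0L) {
  if (inherits(map, "blob_map")) {
    p <- map$p
    best_r <- map$best_radius
    if (is.null(grid)) grid <- map$grid
  } else {
    p <- map
    best_r <- NULL
    if (is.null(grid)) stop("grid is required for a plain array map")
  }
  if (any(!is.finite(p))) stop("probability map contains non-finite values")
  dims <- dim(p)

  local_maxima <- function(a, thr_arr) {
    is_max <- array(TRUE, dims)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      nb <- shift3(shift3(shift3(a, 1, dz), 2, dy), 3, dx)
      is_max <- is_max & (a >= nb)
    }
    which(is_max & thr_arr >= params$threshold, arr.ind = TRUE)
  }
  # scale-space maxima: crowded nuclei that merge at coarse scales stay
  # separable at their own scale, so maxima are pooled over scales.
  # Maxima are located on the raw per-scale responses (which never
  # plateau) and thresholded on the [0, 1] map.
  # sub-voxel localisation: per-axis quadratic fit through the peak
  # and its two neighbours (offset clamped to half a voxel)
  refine <- function(a, cand) {
    off <- matrix(0, nrow(cand), 3)
    for (ax in 1:3) {
      lo <- cand; lo[, ax] <- pmax(lo[, ax] - 1L, 1L)
      hi <- cand; hi[, ax] <- pmin(hi[, ax] + 1L, dims[ax])
      f0 <- a[cand]; fm <- a[lo]; fp <- a[hi]
      den <- fm - 2 * f0 + fp
      o <- ifelse(abs(den) > 1e-12, 0.5 * (fm - fp) / den, 0)
      off[, ax] <- pmin(pmax(o, -0.5), 0.5) * grid$voxel_size[ax]
    }
    off
  }
  if (inherits(map, "blob_map") && !is.null(map$stack)) {
    cand <- NULL; offs <- NULL
    for (a in map$stack) {
      ck <- local_maxima(a, p)
      if (nrow(ck) > 0) {
        cand <- rbind(cand, ck)
        offs <- rbind(offs, refine(a, ck))
      }
    }
    if (!is.null(cand)) {
      dup <- duplicated(cand)
      cand <- cand[!dup, , drop = FALSE]
      offs <- offs[!dup, , drop = FALSE]
    }
  } else {
    cand <- local_maxima(p, p)
    offs <- refine(p, cand)
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(empty_spots(t))
  }
  val <- p[cand]
  # descending value; ties towards smaller (z, y, x)
  ord <- order(-val, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  val <- val[ord]
  pos <- voxel_to_um(cand, grid) + offs[ord, , drop = FALSE]
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (i == 1) {
      keep[1] <- TRUE
      next
    }
    kept_pos <- pos[keep, , drop = FALSE]
    d2 <- colSums((t(kept_pos) - pos[i, ])^2)
    keep[i] <- min(d2) >= params$d_sup^2
  }
  cand <- cand[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  val <- val[keep]
  radius <- if (is.null(best_r)) {
    rep(sqrt(params$r_min * params$r_max), length(val))
  } else {
    pmin(pmax(best_r[cand], params$r_min), params$r_max)
  }
  data.frame(id = seq_along(val), t = as.integer(t), z = pos[, 1],
             y = pos[, 2], x = pos[, 3], radius = radius, intensity = val,
             label = NA_character_, interpolated = FALSE)
}

empty_spots <- function(t = integer(0)) {
  data.frame(id = integer(0), t = integer(0), z = numeric(0),
             y = numeric(0), x = numeric(0), radius = numeric(0),
             intensity = numeric(0), label = character(0),
             interpolated = logical(0))
}

#' Detect nuclei in every frame of a movie
#'
#' Runs [blob_response()] and [extract_centers()] on each frame
#' (replicate 1, which after [subsample_movie()] is the averaged image)
#' and stacks the per-frame spots with ids unique across the movie.
#'
#' @param m a `movie`.
#' @param params [detection_params()].
#' @param radii,snr_half passed to [blob_response()].
#' @return Spots data.frame over all time points (t = 0-based frame
#'   index).
#' @export
detect_nuclei <- function(m, params = detection_params(), radii = NULL,
                          snr_half = 8) {
  out <- vector("list", n_timepoints(m))
  offset <- 0L
  for (t in seq_len(n_timepoints(m))) {
    bm <- blob_response(movie_frame(m, t, 1), m$grid, radii, snr_half)
    sp <- extract_centers(bm, params = params, t = t - 1L)
    sp$id <- sp$id + offset
    offset <- offset + nrow(sp)
    out[[t]] <- sp
  }
  do.call(rbind, out)
}

#' Metaphase-like division candidates
#'
#' Flags bright, compact nuclei: the multi-scale blob response is
#' restricted to the compact half of the radius range and weighted by
#' robustly normalised brightness, then thresholded at 0.8 (the
#' division-detection threshold) with the usual centre extraction.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param grid `voxel_grid`.
#' @param params [detection_params()]; default threshold 0.8.
#' @param snr_half passed to [blob_response()].
#' @param t time index stamped on the spots.
#' @return Spots data.frame of division candidates.
#' @export
detect_division_candidates <- function(volume, grid,
                                       params = detection_params(
                                         threshold = 0.8),
                                       snr_half = 8, t = 0L) {
  radii <- exp(seq(log(params$r_min),
                   log((params$r_min + params$r_max) / 2),
                   length.out = 3))
  bm <- blob_response(volume, grid, radii, snr_half)
  q <- stats::quantile(volume, c(0.5, 0.999))
  bright <- if (q[2] > q[1]) {
    pmin(pmax((volume - q[1]) / (q[2] - q[1]), 0), 1)
  } else array(0, dim(volume))
  bm$p <- bm$p * bright
  extract_centers(bm, params = params, t = t)
}
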