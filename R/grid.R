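#' Voxel grid calibration
#'
#' Describes the sampling of an image volume: the number of voxels per
#' axis, the physical voxel size and the time interval between frames.
#' Axis order is `(z, y, x)` throughout the package, positions are in
#' micrometres and the physical position of a voxel centre is
#' `(index - 1) * voxel_size` (0-based centre-of-voxel convention; the
#' first z slice is the coverslip-proximal one).
#'
#' @param shape integer vector `(n_z, n_y, n_x)`.
#' @param voxel_size numeric vector `(z, y, x)` in micrometres; defaults
#'   to the standard confocal calibration 1.24 x 0.31 x 0.31 um.
#' @param time_interval minutes between frames (default 10).
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(1.24, 0.31, 0.31),
                       time_interval = 10) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape <= 0)) {
    stop("shape must be three positive integers (n_z, n_y, n_x)")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three positive numbers (z, y, x) in um")
  }
  if (!is.finite(time_interval) || time_interval <= 0) {
    stop("time_interval must be positive")
  }
  structure(list(shape = shape, voxel_size = voxel_size,
                 time_interval = as.numeric(time_interval)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid: ", paste(x$shape, collapse = " x "),
      " voxels (z y x), ", paste(x$voxel_size, collapse = " x "),
      " um, dt = ", x$time_interval, " min\n", sep = "")
  invisible(x)
}

# physical um positions (z,y,x matrix) of 1-based voxel indices
voxel_to_um <- function(idx, grid) {
  sweep(as.matrix(idx) - 1, 2, grid$voxel_size, `*`)
}

# nearest 1-based voxel index of physical positions, clamped to the grid
um_to_voxel <- function(pos, grid) {
  idx <- round(sweep(as.matrix(pos), 2, grid$voxel_size, `/`)) + 1
  idx <- pmax(idx, 1)
  sweep_max <- matrix(grid$shape, nrow(idx), 3, byrow = TRUE)
  matrix(as.integer(pmin(idx, sweep_max)), ncol = 3,
         dimnames = list(NULL, c("z", "y", "x")))
}

#' Time-lapse movie container
#'
#' A movie holds the intensity data of a recording as a 5D array indexed
#' `[t, replicate, z, y, x]` together with its `voxel_grid` calibration.
#' Replicates are repeated scans of the same z slice at the same time
#' point (independent noise realisations of the same scene).
#'
#' @param data 5D numeric array with dimensions
#'   `(n_t, n_replicates, n_z, n_y, n_x)`.
#' @param grid a `voxel_grid` whose shape matches the three trailing
#'   dimensions.
#' @return Object of class `movie` with elements `data` and `grid`.
#' @export
movie <- function(data, grid) {
  d <- dim(data)
  if (length(d) != 5) stop("movie data must be a 5D array (t, rep, z, y, x)")
  if (!identical(as.integer(d[3:5]), grid$shape)) {
    stop("movie shape ", paste(d[3:5], collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  }
  structure(list(data = data, grid = grid), class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat("movie: ", d[1], " time points, ", d[2], " replicate(s), ",
      paste(d[3:5], collapse = " x "), " voxels (z y x)\n", sep = "")
  print(x$grid)
  invisible(x)
}

n_timepoints <- function(m) dim(m$data)[1]
n_replicates <- function(m) dim(m$data)[2]

# one [z, y, x] volume
movie_frame <- function(m, t, replicate = 1) {
  array(m$data[t, replicate, , , ], dim = dim(m$data)[3:5])
}

#' Flow field between two consecutive frames
#'
#' Stores, for every voxel, the displacement (in micrometres, axis order
#' z, y, x) of the moving tissue from time `t - 1` to time `t`. The
#' backward-prediction convention used by the trackers is
#' `pos(t - 1) ~ pos(t) - flow_t(pos(t))`: the field is sampled at the
#' later position.
#'
#' @param displacement 4D array `(n_z, n_y, n_x, 3)`, micrometres.
#' @param grid matching `voxel_grid`.
#' @return Object of class `flow_field`.
#' @export
flow_field <- function(displacement, grid) {
  d <- dim(displacement)
  if (length(d) != 4 || d[4] != 3) {
    stop("displacement must be an (n_z, n_y, n_x, 3) array")
  }
  if (!identical(as.integer(d[1:3]), grid$shape)) stop("shape mismatch")
  if (any(!is.finite(displacement))) stop("flow must be finite")
  structure(list(displacement = displacement, grid = grid),
            class = "flow_field")
}

#' Sample a flow field at physical positions
#'
#' Nearest-voxel lookup of the displacement vectors.
#'
#' @param flow a `flow_field`.
#' @param pos n x 3 matrix of positions (z, y, x) in micrometres.
#' @return n x 3 matrix of displacements in micrometres.
#' @export
flow_at <- function(flow, pos) {
  idx <- um_to_voxel(pos, flow$grid)
  out <- matrix(0, nrow(idx), 3, dimnames = list(NULL, c("z", "y", "x")))
  for (k in 1:3) {
    out[, k] <- flow$displacement[cbind(idx, k)]
  }
  out
}

# Resolve a user-supplied flow prior into a sampler function(pos, t) ->
# n x 3 displacement matrix. Accepts NULL (zero flow), a single
# flow_field (used for every t), a list of flow_field indexed by
# as.character(t), or a function(pos, t).
as_flow_sampler <- function(flow) {
  if (is.null(flow)) {
    return(function(pos, t) matrix(0, nrow(as.matrix(pos)), 3))
  }
  if (inherits(flow, "flow_field")) {
    return(function(pos, t) flow_at(flow, pos))
  }
  if (is.list(flow)) {
    return(function(pos, t) {
      f <- flow[[as.character(t)]]
      if (is.null(f)) stop("no flow field supplied for t = ", t)
      flow_at(f, pos)
    })
  }
  if (is.function(flow)) return(flow)
  stop("flow must be NULL, a flow_field, a list of flow_field, ",
       "or a function(pos, t)")
}
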