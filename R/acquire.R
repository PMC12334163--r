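#' Acquisition conditions derived from a master recording
#'
#' An acquisition condition describes how a high-resolution master
#' recording (full z and t sampling, several imaging replicates per
#' slice) is subsampled into a lower-exposure variant: the fraction of
#' z slices and time points kept, the fraction of pixels kept per
#' lateral axis, and how many replicates are averaged. Because the
#' master's replicates were actually scanned, the relative light
#' exposure of a derived dataset is the product
#' `z_keep * t_keep * xy_keep^2 * n_average / master_replicates`.
#'
#' @param name condition name.
#' @param z_keep,t_keep,xy_keep kept fraction of z slices, time points
#'   and pixels per lateral axis; each 1 or 1/2.
#' @param n_average number of replicates averaged (1, 2 or 4).
#' @param master_replicates replicates available in the master.
#' @return Object of class `acquisition_condition`.
#' @export
acquisition_condition <- function(name, z_keep = 1, t_keep = 1,
                                  xy_keep = 1, n_average = 1,
                                  master_replicates = 4) {
  fr <- c(z_keep, t_keep, xy_keep)
  if (!all(fr %in% c(1, 0.5))) {
    stop("z_keep, t_keep and xy_keep must each be 1 or 1/2")
  }
  if (n_average > master_replicates) {
    stop("cannot average ", n_average, " of ", master_replicates,
         " replicates")
  }
  structure(list(name = name, z_keep = z_keep, t_keep = t_keep,
                 xy_keep = xy_keep, n_average = as.integer(n_average),
                 master_replicates = as.integer(master_replicates)),
            class = "acquisition_condition")
}

#' @export
print.acquisition_condition <- function(x, ...) {
  cat(sprintf("%s: z %.2g, t %.2g, xy %.2g, avg %d/%d (exposure %.3g)\n",
              x$name, x$z_keep, x$t_keep, x$xy_keep, x$n_average,
              x$master_replicates, relative_exposure(x)))
  invisible(x)
}

#' The five standard equal-exposure conditions
#'
#' The benchmark set of acquisition variants, all derived from a
#' 4-replicate master and all corresponding to exactly one quarter of
#' the master's light exposure:
#' \describe{
#'   \item{#1 Standard}{half z, half t, 4 replicates averaged}
#'   \item{#2 Improved Z}{full z, half t, 2 replicates averaged}
#'   \item{#3 Improved T}{half z, full t, 2 replicates averaged}
#'   \item{#4 Improved Z+T}{full z and t, half xy, 4 replicates averaged}
#'   \item{#5 Improved Z+T}{full z and t, single replicate}
#' }
#'
#' @param master_replicates replicates in the master recording.
#' @return Named list of five [acquisition_condition()]s.
#' @export
standard_conditions <- function(master_replicates = 4) {
  conds <- list(
    acquisition_condition("#1 Standard", z_keep = 0.5, t_keep = 0.5,
                          n_average = 4,
                          master_replicates = master_replicates),
    acquisition_condition("#2 Improved Z", t_keep = 0.5, n_average = 2,
                          master_replicates = master_replicates),
    acquisition_condition("#3 Improved T", z_keep = 0.5, n_average = 2,
                          master_replicates = master_replicates),
    acquisition_condition("#4 Improved Z+T", xy_keep = 0.5, n_average = 4,
                          master_replicates = master_replicates),
    acquisition_condition("#5 Improved Z+T", n_average = 1,
                          master_replicates = master_replicates))
  stats::setNames(conds, vapply(conds, `[[`, "", "name"))
}

#' Relative light exposure of an acquisition condition
#'
#' Fraction of the master recording's total illumination that the
#' subsampled dataset corresponds to:
#' `z_keep * t_keep * xy_keep^2 * n_average / master_replicates`.
#'
#' @param cond an [acquisition_condition()].
#' @return A number in (0, 1].
#' @export
relative_exposure <- function(cond) {
  cond$z_keep * cond$t_keep * cond$xy_keep^2 *
    cond$n_average / cond$master_replicates
}

#' Subsample a master movie into an acquisition condition
#'
#' Decimation keeps even indices (the 1st, 3rd, ... plane, time point or
#' pixel), replicate averaging takes the arithmetic mean of the first
#' `n_average` replicates (rounded half-up to integer intensities), and
#' the calibration metadata is updated (voxel size doubled on decimated
#' axes, time interval doubled when t is decimated). The result always
#' has a single replicate. Ground-truth annotations are in physical um,
#' so only the time axis of a forest needs reducing alongside; see
#' [reduce_forest()].
#'
#' @param m master `movie`.
#' @param cond an [acquisition_condition()]; the movie must carry
#'   `master_replicates` replicates.
#' @return A `movie` with one replicate.
#' @export
subsample_movie <- function(m, cond) {
  d <- dim(m$data)
  if (d[2] != cond$master_replicates) {
    stop("movie has ", d[2], " replicates but the condition expects ",
         cond$master_replicates)
  }
  keep_idx <- function(n, frac) {
    if (frac == 1) seq_len(n) else seq(1, n, by = 2)
  }
  ti <- keep_idx(d[1], cond$t_keep)
  zi <- keep_idx(d[3], cond$z_keep)
  yi <- keep_idx(d[4], cond$xy_keep)
  xi <- keep_idx(d[5], cond$xy_keep)
  ri <- seq_len(cond$n_average)
  sub <- m$data[ti, ri, zi, yi, xi, drop = FALSE]
  if (length(ri) > 1) {
    sub <- colMeans(aperm(sub, c(2, 1, 3, 4, 5)), dims = 1)
    sub <- floor(sub + 0.5)  # round half-up
    dim(sub) <- c(length(ti), 1, length(zi), length(yi), length(xi))
  }
  vs <- m$grid$voxel_size * c(ifelse(cond$z_keep < 1, 2, 1),
                              ifelse(cond$xy_keep < 1, 2, 1),
                              ifelse(cond$xy_keep < 1, 2, 1))
  grid <- voxel_grid(c(length(zi), length(yi), length(xi)), vs,
                     m$grid$time_interval * ifelse(cond$t_keep < 1, 2, 1))
  movie(sub, grid)
}

#' Reduce a ground-truth forest to match an acquisition condition
#'
#' Positions are physical (um) and are not moved by spatial decimation;
#' only temporal decimation changes the annotations, via
#' [reduce_time()].
#'
#' @param forest ground-truth `lineage_forest`.
#' @param cond an [acquisition_condition()].
#' @return A `lineage_forest`.
#' @export
reduce_forest <- function(forest, cond) {
  if (cond$t_keep == 1) forest else reduce_time(forest, 2L, 0L)
}
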