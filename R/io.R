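#' Read and write spot and link tables
#'
#' Spots are stored as comma-separated text with a header row and
#' columns `id,t,z,y,x,radius,intensity,label,interpolated`; links as
#' `source_id,target_id`. Positions are micrometres, decimal point `.`,
#' UTF-8. `read_forest()` / `write_forest()` combine the two tables into
#' a validated [lineage_forest()].
#'
#' @param path file path.
#' @param spots,links data.frames in the layout above.
#' @return `read_spots_csv` and `read_links_csv` return data.frames;
#'   `read_forest` returns a `lineage_forest`.
#' @name forest_io
NULL

#' @rdname forest_io
#' @export
read_spots_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "t", "z", "y", "x", "radius")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("spots file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$intensity)) df$intensity <- 0
  if (is.null(df$label)) df$label <- NA_character_
  if (is.null(df$interpolated)) df$interpolated <- FALSE
  df$interpolated <- as.logical(df$interpolated)
  df
}

#' @rdname forest_io
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname forest_io
#' @export
read_links_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(df))) {
    stop("links file ", path, " needs columns source_id, target_id")
  }
  df
}

#' @rdname forest_io
#' @export
write_links_csv <- function(links, path) {
  utils::write.csv(links, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname forest_io
#' @param spots_path,links_path file paths of the two tables.
#' @export
read_forest <- function(spots_path, links_path) {
  spots <- read_spots_csv(spots_path)
  links <- read_links_csv(links_path)
  lineage_forest(spots, links)
}

#' @rdname forest_io
#' @param forest a `lineage_forest`.
#' @export
write_forest <- function(forest, spots_path, links_path) {
  sp <- forest$spots
  sp$label[is.na(sp$label)] <- ""
  write_spots_csv(sp, spots_path)
  write_links_csv(forest$links, links_path)
  invisible(forest)
}

#' Export and import tracklet text (Cell Tracking Challenge layout)
#'
#' Decomposes the forest into maximal unbranched tracklets and writes
#' one line per tracklet: `L B E P` (tracklet label, begin time, end
#' time, parent tracklet label; 0 for root tracklets), space separated.
#' This is the plain-text track format used by the Cell Tracking
#' Challenge. The import returns the tracklet table; spot positions are
#' not part of this format, so only the track topology round-trips.
#'
#' @param forest a `lineage_forest`.
#' @param path output file.
#' @return `write_ctc_tracks` returns `path` invisibly;
#'   `read_ctc_tracks` returns a data.frame with columns
#'   `label, begin, end, parent`.
#' @export
write_ctc_tracks <- function(forest, path) {
  validate_forest(forest)
  tl <- forest_tracklets(forest)
  writeLines(sprintf("%d %d %d %d", tl$label, tl$begin, tl$end, tl$parent),
             path)
  invisible(path)
}

#' @rdname write_ctc_tracks
#' @export
read_ctc_tracks <- function(path) {
  df <- utils::read.table(path, col.names = c("label", "begin", "end",
                                              "parent"))
  if (anyDuplicated(df$label)) stop("duplicate tracklet label in ", path)
  bad <- df$parent != 0 & !(df$parent %in% df$label)
  if (any(bad)) {
    stop("tracklet ", df$label[which(bad)[1]], " references unknown parent ",
         df$parent[which(bad)[1]])
  }
  df
}

#' Write and read a movie as per-frame multi-page TIFF files
#'
#' Each time point and replicate is one 16-bit multi-page TIFF (one page
#' per z slice) named `t{TTT}_r{R}.tif`; the physical calibration is
#' stored alongside in `calibration.yaml`. Intensities are clamped to
#' [0, 65535] and rounded on write.
#'
#' @param m a `movie`.
#' @param dir directory (created if needed).
#' @return `write_movie` returns `dir` invisibly; `read_movie` returns a
#'   `movie`.
#' @export
write_movie <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(m$data)
  for (t in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      vol <- movie_frame(m, t, r)
      vol <- pmin(pmax(round(vol), 0), 65535)
      pages <- lapply(seq_len(d[3]), function(z) {
        matrix(vol[z, , ], d[4], d[5]) / 65535
      })
      tiff::writeTIFF(pages, file.path(dir, sprintf("t%03d_r%d.tif",
                                                    t - 1L, r)),
                      bits.per.sample = 16L, compression = "none")
    }
  }
  yaml::write_yaml(list(
    n_timepoints = d[1], n_replicates = d[2],
    shape = as.integer(d[3:5]),
    voxel_size_um = as.numeric(m$grid$voxel_size),
    time_interval_min = m$grid$time_interval
  ), file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir) {
  cal_path <- file.path(dir, "calibration.yaml")
  if (!file.exists(cal_path)) stop("no calibration.yaml in ", dir)
  cal <- yaml::read_yaml(cal_path)
  grid <- voxel_grid(cal$shape, cal$voxel_size_um, cal$time_interval_min)
  d <- c(cal$n_timepoints, cal$n_replicates, cal$shape)
  data <- array(0, dim = d)
  for (t in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      f <- file.path(dir, sprintf("t%03d_r%d.tif", t - 1L, r))
      if (!file.exists(f)) stop("missing frame file ", f)
      pages <- tiff::readTIFF(f, all = TRUE)
      for (z in seq_len(d[3])) {
        data[t, r, z, , ] <- round(pages[[z]] * 65535)
      }
    }
  }
  movie(data, grid)
}
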