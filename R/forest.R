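#' Lineage forests of tracked nuclei
#'
#' A lineage forest is the standard container for cell-tracking results:
#' a set of *spots* (one point-plus-radius annotation of a nucleus at one
#' time point) connected by directed parent-to-child *links* between
#' consecutive time points. Each tree of the forest is the clonal descent
#' of one cell, branching where the cell divides; a spot therefore has at
#' most one parent and at most two children.
#'
#' @param spots data.frame with columns `id` (unique positive integer),
#'   `t` (non-negative integer time index), `z`, `y`, `x` (physical
#'   position in micrometres), `radius` (micrometres, > 0). Optional
#'   columns `intensity` (>= 0, default 0), `label` (character tag,
#'   default `NA`) and `interpolated` (logical, default `FALSE`) are
#'   filled in when absent.
#' @param links data.frame with integer columns `source_id`, `target_id`
#'   referring to spot ids; every link must step forward by exactly one
#'   time index.
#' @param validate if `TRUE` (default) the structural invariants are
#'   checked and violations raise an error.
#'
#' @return An object of class `lineage_forest`: a list with elements
#'   `spots` and `links` (both data.frames as described above).
#'
#' @examples
#' spots <- data.frame(id = 1:3, t = c(0L, 1L, 1L),
#'                     z = 0, y = 0, x = c(0, -2, 2), radius = 2)
#' links <- data.frame(source_id = c(1L, 1L), target_id = c(2L, 3L))
#' fr <- lineage_forest(spots, links)
#' count_trees(fr)
#' divisions_per_timepoint(fr)
#' @export
lineage_forest <- function(spots, links = NULL, validate = TRUE) {
  spots <- as.data.frame(spots)
  required <- c("id", "t", "z", "y", "x", "radius")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0) {
    stop("spots table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(spots$intensity)) spots$intensity <- rep(0, nrow(spots))
  if (is.null(spots$label)) spots$label <- rep(NA_character_, nrow(spots))
  if (is.null(spots$interpolated)) {
    spots$interpolated <- rep(FALSE, nrow(spots))
  }
  spots$id <- as.integer(spots$id)
  spots$t <- as.integer(spots$t)
  spots$label <- as.character(spots$label)
  spots$interpolated <- as.logical(spots$interpolated)
  spots <- spots[c(required, "intensity", "label", "interpolated")]

  if (is.null(links)) {
    links <- data.frame(source_id = integer(0), target_id = integer(0))
  }
  links <- as.data.frame(links)
  if (!all(c("source_id", "target_id") %in% names(links))) {
    stop("links table needs columns source_id, target_id")
  }
  links$source_id <- as.integer(links$source_id)
  links$target_id <- as.integer(links$target_id)
  links <- links[c("source_id", "target_id")]

  forest <- structure(list(spots = spots, links = links),
                      class = "lineage_forest")
  if (validate) validate_forest(forest)
  forest
}

#' Check the structural invariants of a lineage forest
#'
#' Verifies spot validity (unique ids, finite positions, radius > 0,
#' t >= 0), link validity (existing endpoints, no self links, exactly one
#' time step forward), the degree constraints (at most one parent, at
#' most two children per spot) and, implied by the unit time step,
#' acyclicity.
#'
#' @param forest a `lineage_forest`.
#' @return `forest`, invisibly. Violations raise an error naming the
#'   offending spot or link.
#' @export
validate_forest <- function(forest) {
  spots <- forest$spots
  links <- forest$links
  if (anyDuplicated(spots$id)) {
    stop("duplicate spot id: ", spots$id[duplicated(spots$id)][1])
  }
  if (nrow(spots) > 0) {
    if (any(spots$id <= 0 | is.na(spots$id))) stop("spot ids must be positive")
    if (any(is.na(spots$t) | spots$t < 0)) {
      stop("negative or missing time index for spot id ",
           spots$id[which(is.na(spots$t) | spots$t < 0)[1]])
    }
    bad_pos <- !is.finite(spots$z) | !is.finite(spots$y) | !is.finite(spots$x)
    if (any(bad_pos)) stop("non-finite position for spot id ",
                           spots$id[which(bad_pos)[1]])
    bad_r <- !is.finite(spots$radius) | spots$radius <= 0
    if (any(bad_r)) stop("non-positive radius for spot id ",
                         spots$id[which(bad_r)[1]])
  }
  if (nrow(links) > 0) {
    si <- match(links$source_id, spots$id)
    ti <- match(links$target_id, spots$id)
    if (anyNA(si)) stop("link references unknown source id ",
                        links$source_id[which(is.na(si))[1]])
    if (anyNA(ti)) stop("link references unknown target id ",
                        links$target_id[which(is.na(ti))[1]])
    if (any(links$source_id == links$target_id)) {
      stop("self link at spot id ",
           links$source_id[which(links$source_id == links$target_id)[1]])
    }
    dt <- spots$t[ti] - spots$t[si]
    if (any(dt != 1L)) {
      k <- which(dt != 1L)[1]
      stop("link ", links$source_id[k], " -> ", links$target_id[k],
           " does not advance time by one step (dt = ", dt[k], ")")
    }
    if (anyDuplicated(links$target_id)) {
      stop("spot id ", links$target_id[duplicated(links$target_id)][1],
           " has more than one parent")
    }
    n_children <- table(links$source_id)
    if (any(n_children > 2)) {
      stop("spot id ", names(n_children)[which(n_children > 2)[1]],
           " has more than two children")
    }
  }
  invisible(forest)
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat("lineage_forest: ", nrow(x$spots), " spots, ", nrow(x$links),
      " links, ", count_trees(x), " trees",
      if (nrow(x$spots) > 0) {
        paste0(", t in [", min(x$spots$t), ", ", max(x$spots$t), "]")
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of lineage trees in a forest
#'
#' A tree is one rooted lineage: the clonal descent of a cell present at
#' the start of its track. For a valid forest (at most one parent per
#' spot, acyclic) the number of trees equals the number of root spots,
#' which in turn equals `nrow(spots) - nrow(links)`.
#'
#' @param forest a `lineage_forest`.
#' @return Non-negative integer count of rooted trees.
#' @export
count_trees <- function(forest) {
  validate_forest(forest)
  sum(!(forest$spots$id %in% forest$links$target_id))
}

#' Number of cell divisions at each time point
#'
#' A division is a spot with exactly two outgoing links; the dividing
#' cell is counted at the time point where it divides (the parent's
#' time index).
#'
#' @param forest a `lineage_forest`.
#' @return Named integer vector over the full time range of the forest
#'   (names are time indices as characters); zero where no division
#'   occurs. Empty forest gives an empty vector.
#' @export
divisions_per_timepoint <- function(forest) {
  validate_forest(forest)
  spots <- forest$spots
  if (nrow(spots) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tt <- seq(min(spots$t), max(spots$t))
  out <- stats::setNames(integer(length(tt)), as.character(tt))
  if (nrow(forest$links) > 0) {
    deg <- table(forest$links$source_id)
    div_ids <- as.integer(names(deg)[deg == 2L])
    div_t <- spots$t[match(div_ids, spots$id)]
    cnt <- table(factor(div_t, levels = tt))
    out[] <- as.integer(cnt)
  }
  out
}

#' Reduce the temporal resolution of a lineage forest
#'
#' Keeps only spots at time points `offset, offset + keep_every, ...`,
#' re-indexes the kept time points to consecutive integers, and relinks
#' each kept spot to its nearest kept descendants reachable through the
#' removed time points. A division falling on a removed time point is
#' thereby re-attached as two links from the retained ancestor, so the
#' at-most-two-children invariant and (whenever every tree intersects
#' the kept time points) the tree count are preserved.
#'
#' @param forest a `lineage_forest`.
#' @param keep_every keep one time point in `keep_every` (integer >= 2).
#' @param offset index of the first kept time point
#'   (`0 <= offset < keep_every`).
#' @return A `lineage_forest` on the re-indexed time axis.
#' @export
reduce_time <- function(forest, keep_every, offset = 0L) {
  validate_forest(forest)
  keep_every <- as.integer(keep_every)
  offset <- as.integer(offset)
  if (is.na(keep_every) || keep_every < 2L) stop("keep_every must be >= 2")
  if (is.na(offset) || offset < 0L || offset >= keep_every) {
    stop("offset must satisfy 0 <= offset < keep_every")
  }
  spots <- forest$spots
  links <- forest$links
  kept <- spots$t >= offset & (spots$t - offset) %% keep_every == 0L
  new_spots <- spots[kept, , drop = FALSE]
  new_spots$t <- (new_spots$t - offset) %/% keep_every

  children_of <- split(links$target_id, factor(links$source_id,
                                               levels = spots$id))
  kept_set <- spots$id[kept]
  is_kept <- stats::setNames(kept, spots$id)

  # nearest kept descendants of a kept spot, searching through removed frames
  descend <- function(id) {
    out <- integer(0)
    frontier <- children_of[[as.character(id)]]
    while (length(frontier) > 0) {
      hit <- is_kept[as.character(frontier)]
      out <- c(out, frontier[hit])
      miss <- frontier[!hit]
      frontier <- if (length(miss) > 0) {
        unlist(children_of[as.character(miss)], use.names = FALSE)
      } else integer(0)
    }
    out
  }

  src <- integer(0); tgt <- integer(0)
  for (id in kept_set) {
    d <- descend(id)
    if (length(d) > 2) {
      stop("spot id ", id, " has ", length(d),
           " retained descendants after reduction; cannot keep the ",
           "two-children invariant")
    }
    src <- c(src, rep.int(id, length(d)))
    tgt <- c(tgt, d)
  }
  lineage_forest(new_spots,
                 data.frame(source_id = src, target_id = tgt))
}

# internal: maximal unbranched tracklets of a forest.
# Returns a data.frame with one row per tracklet: label, begin, end,
# parent (0 for roots), plus the ordered spot ids of each tracklet.
forest_tracklets <- function(forest) {
  spots <- forest$spots
  links <- forest$links
  parent_of <- stats::setNames(links$source_id, links$target_id)
  children_of <- split(links$target_id,
                       factor(links$source_id, levels = spots$id))
  out_deg <- lengths(children_of)[as.character(spots$id)]
  # tracklet starts: roots, and children of dividing spots
  roots <- spots$id[!(spots$id %in% links$target_id)]
  div_children <- links$target_id[
    links$source_id %in% spots$id[out_deg == 2L]]
  starts <- sort(unique(c(roots, div_children)))
  t_of <- stats::setNames(spots$t, spots$id)
  rows <- vector("list", length(starts))
  start_label <- stats::setNames(seq_along(starts), starts)
  for (k in seq_along(starts)) {
    id <- starts[k]
    chain <- id
    repeat {
      ch <- children_of[[as.character(id)]]
      if (length(ch) != 1L) break
      id <- ch
      chain <- c(chain, id)
    }
    rows[[k]] <- list(label = k, begin = unname(t_of[as.character(chain[1])]),
                      end = unname(t_of[as.character(id)]),
                      start_id = chain[1], end_id = id, ids = chain)
  }
  # parent tracklet: tracklet containing the parent spot of this start
  end_label <- stats::setNames(seq_along(starts),
                               vapply(rows, function(r) r$end_id, integer(1)))
  df <- data.frame(
    label = vapply(rows, function(r) r$label, numeric(1)),
    begin = vapply(rows, function(r) r$begin, numeric(1)),
    end = vapply(rows, function(r) r$end, numeric(1)),
    parent = vapply(rows, function(r) {
      p <- parent_of[as.character(r$start_id)]
      if (is.na(p)) 0 else unname(end_label[as.character(p)])
    }, numeric(1))
  )
  attr(df, "ids") <- lapply(rows, function(r) r$ids)
  df
}
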