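#' Division schedule profiles
#'
#' Builds a per-time-point division probability profile with the three
#' phases seen in regenerating epithelia: a quiescent phase after
#' wounding, a proliferation burst, and a decline back to sparse
#' divisions.
#'
#' @param n_timepoints length of the profile.
#' @param burst_start,burst_end time indices (0-based) delimiting the
#'   burst; divisions at `burst_start <= t < burst_end` occur with
#'   probability `burst_rate` per cell per frame.
#' @param burst_rate,decline_rate per-cell per-frame division
#'   probabilities during the burst and during the decline phase
#'   (`t >= burst_end`).
#' @return Numeric vector of length `n_timepoints`, values in [0, 1].
#' @export
division_schedule <- function(n_timepoints, burst_start = 15,
                              burst_end = 35, burst_rate = 0.03,
                              decline_rate = 0.008) {
  t <- seq_len(n_timepoints) - 1
  p <- numeric(n_timepoints)
  p[t >= burst_start & t < burst_end] <- burst_rate
  p[t >= burst_end] <- decline_rate
  p
}

#' Configuration of the synthetic recording generator
#'
#' Collects every parameter of the simulated master acquisition. The
#' defaults are the packaged benchmark configuration (`"li-synth"`):
#' a 60-frame, 4-replicate recording on a 20 x 192 x 192 voxel grid at
#' the standard confocal calibration (1.24 um z step, 0.31 um pixels,
#' 10-minute intervals) with about 150 nuclei migrating towards a wound
#' plane, a quiescence/burst/decline division schedule, sparse
#' apoptosis with pyknotic brightening, depth-dependent signal
#' attenuation, photobleaching with one heat-shock recovery, and
#' Poisson plus Gaussian read noise per imaging replicate.
#'
#' @param grid `voxel_grid` of one frame.
#' @param n_timepoints number of frames.
#' @param n_replicates imaging replicates per z slice per frame.
#' @param n_initial initial cell count.
#' @param placement_margin minimum distance (um) of initial nuclei from
#'   the volume faces.
#' @param radius_mean,radius_sd,radius_range nucleus radius distribution
#'   (um); draws are clamped to `radius_range`.
#' @param motility_sd standard deviation (um/frame) of the persistent
#'   random-walk velocity.
#' @param persistence autocorrelation of the random-walk velocity
#'   between frames (0 = white noise, 1 = straight lines).
#' @param drift_speed directed migration speed (um/frame) towards the
#'   wound plane at the distal (`x = max`) face.
#' @param wound_arrest distance (um) from the wound plane within which
#'   migration arrests (the drift ramps down linearly to zero), so
#'   that arriving cells stop instead of compacting against the face.
#' @param division_profile per-time-point per-cell division probability
#'   (length `n_timepoints`); see [division_schedule()].
#' @param cycle_refractory minimum number of frames after its birth
#'   before a daughter cell may divide again (a short minimum cell
#'   cycle; 6 frames = 1 h at the default interval).
#' @param apoptosis_prob per-cell per-frame apoptosis probability.
#' @param pyknotic_factor intensity multiplier of the condensed nucleus
#'   in a cell's final frame before apoptotic removal.
#' @param attenuation_length depth attenuation length (um): signal is
#'   scaled by `exp(-z / attenuation_length)`.
#' @param bleach_rate photobleaching rate per exposure (one exposure =
#'   one replicate scan of the volume).
#' @param recovery_timepoints,recovery_amplitudes heat-shock recovery:
#'   at each listed time point the bleaching multiplier gains a factor
#'   `1 + amplitude` (re-induced fluorophore expression).
#' @param psf_sigma Gaussian point-spread sigmas (z, y, x) in um, added
#'   in quadrature to the nucleus profile.
#' @param base_intensity peak nucleus intensity (arbitrary units) before
#'   attenuation and bleaching.
#' @param background constant background intensity.
#' @param poisson_gain intensity units per detected photon; shot noise
#'   is Poisson in photons.
#' @param read_noise_sd Gaussian read noise sd (intensity units).
#' @param min_separation minimum centre-to-centre distance (um) between
#'   initially placed nuclei.
#' @param oscillation_amplitude,oscillation_period_min optional
#'   sinusoidal tissue oscillation along y (um, minutes); off (0) by
#'   default.
#' @param seed RNG seed making the whole recording deterministic.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(grid = voxel_grid(c(20, 192, 192)),
                              n_timepoints = 60,
                              n_replicates = 4,
                              n_initial = 150,
                              placement_margin = 2,
                              radius_mean = 2.5,
                              radius_sd = 0.25,
                              radius_range = c(1.5, 4),
                              motility_sd = 0.4,
                              persistence = 0.6,
                              drift_speed = 0.15,
                              wound_arrest = 5,
                              division_profile = division_schedule(n_timepoints),
                              cycle_refractory = 6,
                              apoptosis_prob = 0.002,
                              pyknotic_factor = 3,
                              attenuation_length = 15,
                              bleach_rate = 0.0015,
                              recovery_timepoints = 30,
                              recovery_amplitudes = 0.3,
                              psf_sigma = c(1.0, 0.35, 0.35),
                              base_intensity = 6000,
                              background = 100,
                              poisson_gain = 10,
                              read_noise_sd = 50,
                              min_separation = 3,
                              oscillation_amplitude = 0,
                              oscillation_period_min = 390,
                              seed = 42) {
  cfg <- list(grid = grid, n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              n_initial = as.integer(n_initial),
              placement_margin = placement_margin,
              radius_mean = radius_mean, radius_sd = radius_sd,
              radius_range = radius_range,
              motility_sd = motility_sd, persistence = persistence,
              drift_speed = drift_speed,
              wound_arrest = wound_arrest,
              division_profile = division_profile,
              cycle_refractory = as.integer(cycle_refractory),
              apoptosis_prob = apoptosis_prob,
              pyknotic_factor = pyknotic_factor,
              attenuation_length = attenuation_length,
              bleach_rate = bleach_rate,
              recovery_timepoints = recovery_timepoints,
              recovery_amplitudes = recovery_amplitudes,
              psf_sigma = psf_sigma,
              base_intensity = base_intensity, background = background,
              poisson_gain = poisson_gain, read_noise_sd = read_noise_sd,
              min_separation = min_separation,
              oscillation_amplitude = oscillation_amplitude,
              oscillation_period_min = oscillation_period_min,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg$grid, "voxel_grid"))
  if (cfg$n_timepoints < 1) stop("n_timepoints must be >= 1")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(cfg$division_profile) != cfg$n_timepoints) {
    stop("division_profile must have length n_timepoints")
  }
  probs <- c(cfg$division_profile, cfg$apoptosis_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  lens <- c(cfg$radius_mean, cfg$attenuation_length, cfg$psf_sigma,
            cfg$min_separation, cfg$radius_range)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (cfg$cycle_refractory < 0) stop("cycle_refractory must be >= 0")
  if (length(cfg$recovery_timepoints) != length(cfg$recovery_amplitudes)) {
    stop("recovery_timepoints and recovery_amplitudes must match")
  }
  invisible(cfg)
}

#' The packaged benchmark configuration
#'
#' Shorthand for the default [simulation_config()], the fixed fixture
#' (`"li-synth"`, seed 42) used by the package's own evaluation.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
li_synth_config <- function(...) simulation_config(...)

#' Photobleaching multiplier
#'
#' Closed-form bleaching trajectory: intensity is scaled by
#' `exp(-rate * exposures)`, with a multiplicative step increase
#' `1 + amplitude` at each heat-shock recovery exposure (re-induction of
#' the fluorophore).
#'
#' @param exposures cumulative number of exposures (vectorised).
#' @param rate bleaching rate per exposure.
#' @param recovery_exposures,recovery_amplitudes exposure counts at
#'   which recovery occurs, and the amplitude of each recovery.
#' @return Numeric vector of multipliers.
#' @export
bleach_multiplier <- function(exposures, rate,
                              recovery_exposures = numeric(0),
                              recovery_amplitudes = numeric(0)) {
  out <- exp(-rate * exposures)
  for (j in seq_along(recovery_exposures)) {
    out <- out * ifelse(exposures >= recovery_exposures[j],
                        1 + recovery_amplitudes[j], 1)
  }
  out
}

#' Imaging-model stages
#'
#' The individually callable stages of the synthetic imaging model.
#' `depth_attenuate()` scales each z slice by `exp(-z / length)`
#' (z measured in um from the coverslip-proximal first slice);
#' `add_noise()` draws one noise realisation: Poisson shot noise in
#' photons (`intensity / poisson_gain` photons per voxel) plus Gaussian
#' read noise. `add_noise` consumes the current RNG stream.
#'
#' @param volume 3D array `(z, y, x)` of non-negative intensities.
#' @param grid `voxel_grid` giving the z calibration.
#' @param attenuation_length attenuation length in um; `Inf` disables
#'   attenuation.
#' @return Array of the same shape.
#' @export
depth_attenuate <- function(volume, grid, attenuation_length) {
  if (any(volume < 0)) stop("intensities must be non-negative")
  if (!is.finite(attenuation_length)) return(volume)
  z_um <- (seq_len(dim(volume)[1]) - 1) * grid$voxel_size[1]
  volume * exp(-z_um / attenuation_length)
}

#' @rdname depth_attenuate
#' @param poisson_gain,read_noise_sd see [simulation_config()].
#' @export
add_noise <- function(volume, poisson_gain = 20, read_noise_sd = 60) {
  if (any(volume < 0)) stop("intensities must be non-negative")
  n <- length(volume)
  noisy <- stats::rpois(n, as.vector(volume) / poisson_gain) * poisson_gain +
    stats::rnorm(n, 0, read_noise_sd)
  array(pmax(noisy, 0), dim = dim(volume))
}

# render Gaussian nuclei into a (z,y,x) volume. spots: data.frame with
# z,y,x,radius and an `amp` column (peak intensity). The intensity
# profile of one nucleus has per-axis sd sqrt((radius/2)^2 + psf^2):
# the nominal radius sits at two profile sds, so neighbouring nuclei at
# epithelial packing distances stay resolvable, as real
# chromatin-filled nuclei are.
render_scene <- function(spots, grid, psf_sigma = c(0, 0, 0)) {
  vol <- array(0, dim = grid$shape)
  if (nrow(spots) == 0) return(vol)
  vs <- grid$voxel_size
  ax_um <- lapply(1:3, function(a) (seq_len(grid$shape[a]) - 1) * vs[a])
  for (i in seq_len(nrow(spots))) {
    p <- c(spots$z[i], spots$y[i], spots$x[i])
    sd_ax <- sqrt((spots$radius[i] / 2)^2 + psf_sigma^2)
    rng <- lapply(1:3, function(a) {
      which(abs(ax_um[[a]] - p[a]) <= 3.5 * sd_ax[a])
    })
    if (any(lengths(rng) == 0)) next
    g <- lapply(1:3, function(a) {
      exp(-(ax_um[[a]][rng[[a]]] - p[a])^2 / (2 * sd_ax[a]^2))
    })
    patch <- spots$amp[i] * (g[[1]] %o% g[[2]] %o% g[[3]])
    vol[rng[[1]], rng[[2]], rng[[3]]] <-
      vol[rng[[1]], rng[[2]], rng[[3]]] + patch
  }
  vol
}

#' Render the ground-truth detection probability map of one frame
#'
#' Stand-in for a trained detector's probability output: each nucleus
#' contributes a Gaussian bump of its own radius (value 1 at the centre,
#' `exp(-d^2 / (2 radius^2))` at distance d); overlapping nuclei combine
#' by the maximum, so values stay in [0, 1] and the background is 0.
#'
#' @param forest `lineage_forest` with ground-truth spots.
#' @param grid `voxel_grid` of the frame.
#' @param t time index (0-based, matching spot `t`).
#' @return 3D array `(z, y, x)` of values in [0, 1].
#' @export
render_probability_map <- function(forest, grid, t) {
  spots <- forest$spots[forest$spots$t == t, , drop = FALSE]
  vol <- array(0, dim = grid$shape)
  if (nrow(spots) == 0) return(vol)
  vs <- grid$voxel_size
  ax_um <- lapply(1:3, function(a) (seq_len(grid$shape[a]) - 1) * vs[a])
  for (i in seq_len(nrow(spots))) {
    p <- c(spots$z[i], spots$y[i], spots$x[i])
    r <- spots$radius[i]
    rng <- lapply(1:3, function(a) which(abs(ax_um[[a]] - p[a]) <= 3.5 * r))
    if (any(lengths(rng) == 0)) next
    g <- lapply(1:3, function(a) {
      exp(-(ax_um[[a]][rng[[a]]] - p[a])^2 / (2 * r^2))
    })
    patch <- g[[1]] %o% g[[2]] %o% g[[3]]
    cur <- vol[rng[[1]], rng[[2]], rng[[3]]]
    vol[rng[[1]], rng[[2]], rng[[3]]] <- pmax(cur, patch)
  }
  vol
}

#' Ground-truth flow between consecutive frames
#'
#' Stand-in for a learned flow model: at each voxel the displacement
#' (um, from `t - 1` to `t`) of the nearest tracked cell that exists at
#' both time points, optionally perturbed by isotropic Gaussian noise.
#' `gt_flow_sampler()` returns the equivalent position-wise sampler
#' `function(pos, t)` without rasterising a field, which the trackers
#' accept directly as a flow prior.
#'
#' @param forest ground-truth `lineage_forest`.
#' @param grid `voxel_grid`.
#' @param t time index >= 1.
#' @param noise_sd sd (um) of Gaussian noise added per component; drawn
#'   from the current RNG stream.
#' @return `ground_truth_flow` returns a [flow_field()];
#'   `gt_flow_sampler` a function.
#' @export
ground_truth_flow <- function(forest, grid, t, noise_sd = 0) {
  if (t < 1) stop("flow is defined for t >= 1")
  mv <- moving_spot_displacements(forest, t)
  disp <- array(0, dim = c(grid$shape, 3))
  if (nrow(mv) > 0) {
    d2z <- lapply(seq_len(nrow(mv)), function(j) {
      ((seq_len(grid$shape[1]) - 1) * grid$voxel_size[1] - mv$z[j])^2
    })
    d2y <- lapply(seq_len(nrow(mv)), function(j) {
      ((seq_len(grid$shape[2]) - 1) * grid$voxel_size[2] - mv$y[j])^2
    })
    d2x <- lapply(seq_len(nrow(mv)), function(j) {
      ((seq_len(grid$shape[3]) - 1) * grid$voxel_size[3] - mv$x[j])^2
    })
    best <- array(Inf, dim = grid$shape)
    best_j <- array(1L, dim = grid$shape)
    for (j in seq_len(nrow(mv))) {
      d2 <- outer(outer(d2z[[j]], d2y[[j]], `+`), d2x[[j]], `+`)
      upd <- d2 < best
      best[upd] <- d2[upd]
      best_j[upd] <- j
    }
    for (k in 1:3) {
      comp <- c("dz", "dy", "dx")[k]
      disp[, , , k] <- mv[[comp]][best_j]
    }
  }
  if (noise_sd > 0) {
    disp <- disp + stats::rnorm(length(disp), 0, noise_sd)
  }
  flow_field(disp, grid)
}

#' @rdname ground_truth_flow
#' @export
gt_flow_sampler <- function(forest) {
  force(forest)
  function(pos, t) {
    pos <- as.matrix(pos)
    mv <- moving_spot_displacements(forest, t)
    out <- matrix(0, nrow(pos), 3)
    if (nrow(mv) == 0) return(out)
    for (i in seq_len(nrow(pos))) {
      d2 <- (mv$z - pos[i, 1])^2 + (mv$y - pos[i, 2])^2 +
        (mv$x - pos[i, 3])^2
      j <- which.min(d2)
      out[i, ] <- c(mv$dz[j], mv$dy[j], mv$dx[j])
    }
    out
  }
}

# spots at time t that have a parent at t-1, with their displacements
moving_spot_displacements <- function(forest, t) {
  spots <- forest$spots
  links <- forest$links
  cur <- spots[spots$t == t, , drop = FALSE]
  pi <- links$source_id[match(cur$id, links$target_id)]
  has_parent <- !is.na(pi)
  cur <- cur[has_parent, , drop = FALSE]
  par <- spots[match(pi[has_parent], spots$id), , drop = FALSE]
  data.frame(z = cur$z, y = cur$y, x = cur$x,
             dz = cur$z - par$z, dy = cur$y - par$y, dx = cur$x - par$x)
}

#' Simulate a synthetic master recording with known ground truth
#'
#' Generates a lineage forest (cells migrating towards the wound plane
#' at the distal x face, dividing according to the division schedule,
#' occasionally undergoing apoptosis with pyknotic brightening), renders
#' the noiseless scene per frame, applies depth attenuation and
#' photobleaching, and draws `n_replicates` independent noise
#' realisations per frame. Everything is deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return Object of class `recording`: a list with elements `movie`
#'   (a [movie()], integer intensities), `forest` (the ground-truth
#'   [lineage_forest()]; spot `intensity` holds the rendered peak
#'   intensity after attenuation and bleaching), `events` (data.frame
#'   `cell_id, event, t, parent_cell` logging births, divisions and
#'   apoptoses) and `config`.
#' @export
simulate_recording <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  sim <- simulate_lineage(config)
  forest <- sim$forest
  events <- sim$events
  grid <- config$grid
  d <- c(config$n_timepoints, config$n_replicates, grid$shape)
  data <- array(0L, dim = d)
  for (t0 in 0:(config$n_timepoints - 1)) {
    sp <- forest$spots[forest$spots$t == t0, , drop = FALSE]
    sp$amp <- sp$intensity / exp(-sp$z / config$attenuation_length)
    scene <- render_scene(sp, grid, config$psf_sigma)
    scene <- depth_attenuate(scene, grid, config$attenuation_length)
    scene <- scene + config$background
    for (r in seq_len(config$n_replicates)) {
      noisy <- add_noise(scene, config$poisson_gain, config$read_noise_sd)
      data[t0 + 1, r, , , ] <- as.integer(round(pmin(noisy, 65535)))
    }
  }
  structure(list(movie = movie(data, grid), forest = forest,
                 events = events, config = config),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("synthetic recording (seed ", x$config$seed, ")\n", sep = "")
  print(x$movie)
  print(x$forest)
  invisible(x)
}

# push pairs of points closer than min_sep apart (symmetric, along the
# connecting axis, to 3% beyond the minimum so contacts are not left
# sitting exactly on the boundary), several relaxation sweeps;
# deterministic
resolve_overlaps <- function(P, min_sep, bounds = NULL, n_iter = 40) {
  target <- 1.03 * min_sep
  clamp <- function(M) {
    if (is.null(bounds)) return(M)
    M <- pmax(M, 0)
    pmin(M, matrix(bounds, nrow(M), 3, byrow = TRUE))
  }
  for (it in seq_len(n_iter)) {
    d2 <- as.matrix(stats::dist(P))^2
    diag(d2) <- Inf
    bad <- which(d2 < min_sep^2 & upper.tri(d2), arr.ind = TRUE)
    if (nrow(bad) == 0) break
    for (k in seq_len(nrow(bad))) {
      i <- bad[k, 1]; j <- bad[k, 2]
      v <- P[j, ] - P[i, ]
      d <- sqrt(sum(v^2))
      v <- if (d > 1e-9) v / d else c(1, 0, 0)
      push <- (target - min(d, target)) / 2
      P[i, ] <- P[i, ] - v * push
      P[j, ] <- P[j, ] + v * push
    }
    # clamping inside the sweep so wall contacts get re-resolved
    # sideways instead of being recreated after the loop
    P <- clamp(P)
  }
  P
}

# cell behaviour + ground-truth forest; uses the current RNG stream
simulate_lineage <- function(config) {
  grid <- config$grid
  extent <- (grid$shape - 1) * grid$voxel_size  # um, (z, y, x)
  m <- config$placement_margin
  if (any(extent <= 2 * m)) stop("volume too small for placement margin")

  draw_radius <- function(n) {
    pmin(pmax(stats::rnorm(n, config$radius_mean, config$radius_sd),
              config$radius_range[1]), config$radius_range[2])
  }

  # initial placement with minimum separation (rejection sampling)
  n0 <- config$n_initial
  pos <- matrix(NA_real_, n0, 3)
  placed <- 0
  tries <- 0
  max_tries <- 2000 * n0
  while (placed < n0) {
    cand <- m + stats::runif(3) * (extent - 2 * m)
    ok <- placed == 0 ||
      min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)) >=
      config$min_separation^2
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
    tries <- tries + 1
    if (tries > max_tries) {
      stop("overcrowding: cannot place ", n0, " cells at minimum ",
           "separation ", config$min_separation, " um")
    }
  }

  n_tp <- config$n_timepoints
  cells <- data.frame(cell_id = seq_len(n0), z = pos[, 1], y = pos[, 2],
                      x = pos[, 3], radius = draw_radius(n0),
                      vz = 0, vy = 0, vx = 0, prev_spot = NA_integer_,
                      refractory = 0L)
  next_cell <- n0 + 1
  next_spot <- 1L

  spot_rows <- vector("list", n_tp)
  link_src <- integer(0)
  link_tgt <- integer(0)
  ev_cell <- integer(0); ev_name <- character(0); ev_t <- integer(0)
  ev_parent <- integer(0)
  log_event <- function(cell, name, t, parent = NA_integer_) {
    ev_cell <<- c(ev_cell, cell); ev_name <<- c(ev_name, name)
    ev_t <<- c(ev_t, t); ev_parent <<- c(ev_parent, parent)
  }
  for (cid in cells$cell_id) log_event(cid, "birth", 0L)

  bleach_t <- bleach_multiplier(
    (0:(n_tp - 1)) * config$n_replicates, config$bleach_rate,
    config$recovery_timepoints * config$n_replicates,
    config$recovery_amplitudes)
  osc_shift <- if (config$oscillation_amplitude > 0) {
    config$oscillation_amplitude *
      sin(2 * pi * (0:(n_tp - 1)) * grid$time_interval /
            config$oscillation_period_min)
  } else numeric(n_tp)

  clamp_pos <- function(p) pmin(pmax(p, 0), extent)

  for (t0 in 0:(n_tp - 1)) {
    nc <- nrow(cells)
    if (nc == 0) break
    # decide fates for the transition t0 -> t0 + 1
    last_tp <- t0 == n_tp - 1
    u <- stats::runif(nc)
    divides <- !last_tp & cells$refractory == 0L &
      u < config$division_profile[t0 + 1]
    dies <- !last_tp & !divides &
      stats::runif(nc) < config$apoptosis_prob

    # record spots at t0 (apoptotic cells render pyknotic: condensed,
    # brighter)
    amp <- config$base_intensity * bleach_t[t0 + 1] *
      ifelse(dies, config$pyknotic_factor, 1)
    peak <- amp * exp(-cells$z / config$attenuation_length)
    ids <- seq.int(next_spot, length.out = nc)
    next_spot <- next_spot + nc
    spot_rows[[t0 + 1]] <- data.frame(
      id = ids, t = t0, z = cells$z, y = cells$y, x = cells$x,
      radius = cells$radius * ifelse(dies, 0.7, 1),
      intensity = peak,
      label = ifelse(dies, "apoptotic", NA_character_),
      interpolated = FALSE)
    has_prev <- !is.na(cells$prev_spot)
    link_src <- c(link_src, cells$prev_spot[has_prev])
    link_tgt <- c(link_tgt, ids[has_prev])
    cells$prev_spot <- ids
    if (last_tp) break

    for (k in which(dies)) log_event(cells$cell_id[k], "apoptosis", t0)

    # movement of surviving, non-dividing cells: persistent random walk
    # plus drift towards the wound plane (distal x face)
    keep <- !dies & !divides
    surv <- cells[keep, , drop = FALSE]
    ph <- config$persistence
    ns <- nrow(surv)
    if (ns > 0) {
      nz <- stats::rnorm(ns, 0, config$motility_sd * sqrt(1 - ph^2))
      ny <- stats::rnorm(ns, 0, config$motility_sd * sqrt(1 - ph^2))
      nx <- stats::rnorm(ns, 0, config$motility_sd * sqrt(1 - ph^2))
      surv$vz <- ph * surv$vz + nz
      surv$vy <- ph * surv$vy + ny
      surv$vx <- ph * surv$vx + nx
      dy_osc <- osc_shift[t0 + 2] - osc_shift[t0 + 1]
      # migration arrests on arrival at the wound face
      dist_to_wound <- extent[3] - surv$x
      drift <- config$drift_speed *
        pmin(1, pmax(dist_to_wound, 0) / config$wound_arrest)
      newp <- clamp_pos(cbind(surv$z + surv$vz,
                              surv$y + surv$vy + dy_osc,
                              surv$x + surv$vx + drift))
      surv$z <- newp[, 1]; surv$y <- newp[, 2]; surv$x <- newp[, 3]
      surv$refractory <- pmax(surv$refractory - 1L, 0L)
    }

    # divisions: two daughters displaced +-1 radius along a random axis
    dau_list <- list()
    for (k in which(divides)) {
      parent <- cells[k, ]
      log_event(parent$cell_id, "division", t0)
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      off <- axis * parent$radius
      p1 <- clamp_pos(c(parent$z, parent$y, parent$x) + off)
      p2 <- clamp_pos(c(parent$z, parent$y, parent$x) - off)
      dd <- data.frame(cell_id = c(next_cell, next_cell + 1L),
                       z = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                       x = c(p1[3], p2[3]),
                       radius = draw_radius(2),
                       vz = parent$vz, vy = parent$vy, vx = parent$vx,
                       prev_spot = parent$prev_spot,
                       refractory = config$cycle_refractory)
      log_event(next_cell, "birth", t0 + 1L, parent$cell_id)
      log_event(next_cell + 1L, "birth", t0 + 1L, parent$cell_id)
      next_cell <- next_cell + 2L
      dau_list[[length(dau_list) + 1]] <- dd
    }
    cells <- rbind(surv, do.call(rbind, c(dau_list, list(NULL))))
    rownames(cells) <- NULL
    # epithelial packing: nuclei cannot interpenetrate, so overlapping
    # neighbours are pushed apart towards the minimum separation
    if (nrow(cells) > 1) {
      P <- resolve_overlaps(cbind(cells$z, cells$y, cells$x),
                            config$min_separation, bounds = extent)
      cells$z <- P[, 1]; cells$y <- P[, 2]; cells$x <- P[, 3]
    }
  }

  forest <- lineage_forest(do.call(rbind, spot_rows),
                           data.frame(source_id = link_src,
                                      target_id = link_tgt))
  events <- data.frame(cell_id = ev_cell, event = ev_name, t = ev_t,
                       parent_cell = ev_parent)
  list(forest = forest, events = events)
}
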