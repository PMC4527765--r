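#' Specification for a simulated mask movie
#'
#' Describes one simulated migrating, deforming cell rendered as a binary
#' mask per frame. The cell is a star-shaped radial blob: a radius profile
#' over angle, perturbed each frame by persistent protrusion/retraction
#' bumps (which survive into following frames and so register as protrusion
#' or retraction pixels) and by non-persistent boundary roughness (which
#' registers as short-lived pixels), while the cell centre advances at a
#' constant nominal speed.
#'
#' @param n_frames Number of frames.
#' @param grid_size Side of the square pixel grid.
#' @param base_radius Resting cell radius in pixels.
#' @param speed_px_per_frame Nominal centre displacement per frame (px).
#' @param protrusion_rate Expected number of new boundary pixels per frame
#'   contributed by persistent outward bumps.
#' @param retraction_rate Expected number of boundary pixels removed per
#'   frame by persistent inward bumps.
#' @param shape_noise Standard deviation (px) of the non-persistent smooth
#'   boundary roughness.
#' @param gap_frames Integer frame indices to emit as unsegmentable gaps.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `mask_sim_spec`.
#' @export
mask_sim_spec <- function(n_frames = 20, grid_size = 96, base_radius = 12,
                          speed_px_per_frame = 0, protrusion_rate = 0,
                          retraction_rate = 0, shape_noise = 0,
                          gap_frames = integer(), seed = 1) {
  stopifnot(n_frames >= 1, grid_size >= 8, base_radius >= 2,
            speed_px_per_frame >= 0, protrusion_rate >= 0,
            retraction_rate >= 0, shape_noise >= 0)
  structure(
    list(n_frames = as.integer(n_frames), grid_size = as.integer(grid_size),
         base_radius = base_radius,
         speed_px_per_frame = speed_px_per_frame,
         protrusion_rate = protrusion_rate,
         retraction_rate = retraction_rate,
         shape_noise = shape_noise,
         gap_frames = as.integer(gap_frames), seed = as.integer(seed)),
    class = "mask_sim_spec"
  )
}

# Render a star-shaped cell: pixel is foreground iff its distance to the
# centre is <= the radius profile at its angle (linear interpolation over
# the angular grid).
render_blob <- function(center, radii, grid_size) {
  n_theta <- length(radii)
  xs <- matrix(rep(seq_len(grid_size), each = grid_size), grid_size)  # col
  ys <- matrix(rep(seq_len(grid_size), times = grid_size), grid_size) # row
  dy <- ys - center[1]
  dx <- xs - center[2]
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  pos <- theta / (2 * pi) * n_theta         # in [0, n_theta)
  i0 <- floor(pos)
  w <- pos - i0
  r_at <- radii[(i0 %% n_theta) + 1] * (1 - w) +
    radii[((i0 + 1) %% n_theta) + 1] * w
  dist <= r_at
}

# Smooth periodic bump profile of unit height centred at angular index m
# with half-width hw (in index units).
bump_profile <- function(n_theta, m, hw) {
  d <- abs(seq_len(n_theta) - m)
  d <- pmin(d, n_theta - d)
  pmax(1 - d / hw, 0)
}

#' Simulate a mask movie of a migrating, deforming cell
#'
#' Generates `n_frames` binary masks of one simply-connected (star-shaped)
#' cell. The centre of area advances by approximately
#' `speed_px_per_frame` pixels per frame along the grid diagonal of
#' available space (horizontally), persistent boundary bumps appear at the
#' stated protrusion/retraction pixel rates and relax slowly back to the
#' resting radius, and a non-persistent smooth roughness term adds
#' short-lived boundary pixels. With all rates and noise zero the cell is
#' rigid: successive masks are exact translates when the speed is integer.
#'
#' @param spec A [mask_sim_spec].
#' @param pixel_size_um,frame_interval_min Calibration passed to the
#'   returned sequence.
#' @return A [mask_sequence] with gap frames as specified.
#' @export
generate_mask_sequence <- function(spec, pixel_size_um = 0.21,
                                   frame_interval_min = 5) {
  stopifnot(inherits(spec, "mask_sim_spec"))
  g <- spec$grid_size
  margin <- spec$base_radius * 1.7 + 3 * spec$shape_noise + 2
  x_start <- margin
  x_end <- x_start + (spec$n_frames - 1) * spec$speed_px_per_frame
  if (x_end + margin > g || 2 * margin > g) {
    stop("cell would exit the grid: enlarge grid_size or reduce speed/frames")
  }
  set.seed(spec$seed)

  n_theta <- 180L
  radii <- rep(spec$base_radius, n_theta)      # persistent radius profile
  hw <- n_theta / 24                           # bump half-width, ~15 degrees
  # One triangular bump of amplitude a adds ~ a * r * (angular width)/2
  # pixels; calibrate amplitude so a single bump moves ~6 px of boundary.
  bump_amp <- 6 / (spec$base_radius * (2 * hw * 2 * pi / n_theta) / 2)
  bump_amp <- min(bump_amp, spec$base_radius / 3)
  px_per_bump <- bump_amp * spec$base_radius * (2 * hw * 2 * pi / n_theta) / 2
  relax <- 0.15

  frames <- vector("list", spec$n_frames)
  gaps <- seq_len(spec$n_frames) %in% spec$gap_frames
  cy <- g / 2
  for (t in seq_len(spec$n_frames)) {
    cx <- x_start + (t - 1) * spec$speed_px_per_frame
    if (t > 1) {
      # persistent shape evolution: relax toward base, then add new bumps
      radii <- spec$base_radius + (1 - relax) * (radii - spec$base_radius)
      n_pro <- if (spec$protrusion_rate > 0)
        stats::rpois(1, spec$protrusion_rate / px_per_bump) else 0L
      n_ret <- if (spec$retraction_rate > 0)
        stats::rpois(1, spec$retraction_rate / px_per_bump) else 0L
      for (b in seq_len(n_pro)) {
        radii <- radii + bump_amp *
          bump_profile(n_theta, stats::runif(1, 1, n_theta), hw)
      }
      for (b in seq_len(n_ret)) {
        radii <- radii - bump_amp *
          bump_profile(n_theta, stats::runif(1, 1, n_theta), hw)
      }
      radii <- pmax(radii, 2)
    }
    r_frame <- radii
    if (spec$shape_noise > 0) {
      rough <- stats::rnorm(12, 0, spec$shape_noise)
      ang <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
      wave <- rep(0, n_theta)
      for (k in seq_len(6)) {
        wave <- wave + rough[2 * k - 1] * cos(k * ang) +
          rough[2 * k] * sin(k * ang)
      }
      r_frame <- pmax(r_frame + wave / sqrt(6), 2)
    }
    frames[[t]] <- if (gaps[t]) {
      matrix(FALSE, g, g)
    } else {
      render_blob(c(cy, cx), r_frame, g)
    }
  }
  mask_sequence(frames, pixel_size_um, frame_interval_min,
                gap_flags = gaps, cell_id = sprintf("sim%d", spec$seed))
}

#' Specification for a simulated observation table
#'
#' Describes a synthetic per-cell per-frame feature table with planted
#' ground truth. Two independent latent processes drive the table: a latent
#' Cell Speed (heavy-tailed and positive: cell-level lognormal means with
#' within-cell AR(1) fluctuations on the log scale, persistence decreasing
#' with cell mean speed) and a latent membrane-activity residual
#' ("latent CMD", Gaussian, independent of speed). Dynamic Cell Area is
#' `k * speed + m + latentCMD`. Each synthetic feature is a planted
#' transform of one or both latents plus Gaussian noise, with the planted
#' archetype recorded as ground truth. Protrusion/retraction pixel counts
#' are split from the Dynamic Cell Area with a speed-dependent imbalance so
#' that slow cells tend to grow and fast cells to shrink.
#'
#' @param n_cells Number of cell trajectories.
#' @param frames_per_cell Frames per trajectory.
#' @param archetype_plan Data frame with columns `feature`, `process`
#'   (`"speed"`, `"cmd"`, `"both"` or `"none"`), `shape` (one of
#'   `"linear_increase"`, `"linear_decrease"`, `"plateau_early"`,
#'   `"plateau_late"`, `"weak_nonmonotone"`, `"null"`) and `effect`
#'   (effect size in units of `noise_sd`; must be non-negative). Defaults
#'   to [default_archetype_plan()].
#' @param n_features Number of features when `archetype_plan` is built by
#'   default (150).
#' @param noise_sd Feature noise standard deviation.
#' @param k,m Slope (um^2 per um/min) and intercept (um^2) of the planted
#'   linear speed to Dynamic Cell Area relationship.
#' @param cmd_sd Standard deviation (um^2) of the latent CMD.
#' @param speed_meanlog,speed_sdlog_cell,speed_sdlog_within Parameters of
#'   the latent log-speed model: cell-level mean `~ N(speed_meanlog,
#'   speed_sdlog_cell^2)`; within-cell AR(1) innovations scaled to
#'   stationary sd `speed_sdlog_within`.
#' @param cells_per_experiment Cells per pseudo-experiment label.
#' @param seed Integer seed.
#' @return A list of class `table_sim_spec`.
#' @export
table_sim_spec <- function(n_cells = 100, frames_per_cell = 50,
                           archetype_plan = NULL, n_features = 150,
                           noise_sd = 1, k = 400, m = 150, cmd_sd = 50,
                           speed_meanlog = log(0.15),
                           speed_sdlog_cell = 0.35,
                           speed_sdlog_within = 0.45,
                           cells_per_experiment = 10, seed = 1) {
  if (is.null(archetype_plan)) {
    archetype_plan <- default_archetype_plan(n_features, 0, 0, 0)
  }
  stopifnot(is.data.frame(archetype_plan),
            all(c("feature", "process", "shape", "effect") %in%
                  names(archetype_plan)),
            noise_sd > 0, n_cells >= 1, frames_per_cell >= 1)
  if (any(archetype_plan$effect < 0)) stop("effect sizes must be non-negative")
  bad <- !archetype_plan$process %in% c("speed", "cmd", "both", "none")
  if (any(bad)) stop("unknown process in archetype_plan")
  structure(
    list(n_cells = as.integer(n_cells),
         frames_per_cell = as.integer(frames_per_cell),
         archetype_plan = archetype_plan,
         n_features = nrow(archetype_plan),
         noise_sd = noise_sd, k = k, m = m, cmd_sd = cmd_sd,
         speed_meanlog = speed_meanlog,
         speed_sdlog_cell = speed_sdlog_cell,
         speed_sdlog_within = speed_sdlog_within,
         cells_per_experiment = as.integer(cells_per_experiment),
         seed = as.integer(seed)),
    class = "table_sim_spec"
  )
}

#' Default planted-feature plan
#'
#' Builds an archetype plan with `n_speed` speed-linked, `n_cmd` CMD-linked
#' and `n_both` dual-linked linear features (increase/decrease alternating),
#' the remainder null.
#'
#' @param n_features Total number of features.
#' @param n_speed,n_cmd,n_both Counts of planted features per class.
#' @param effect Effect size in noise standard deviations.
#' @param shapes Shapes cycled over the planted features.
#' @return Data frame usable as `archetype_plan`.
#' @export
default_archetype_plan <- function(n_features = 150, n_speed = 5, n_cmd = 5,
                                   n_both = 5, effect = 5,
                                   shapes = c("linear_increase",
                                              "linear_decrease")) {
  n_planted <- n_speed + n_cmd + n_both
  stopifnot(n_planted <= n_features)
  proc <- c(rep("speed", n_speed), rep("cmd", n_cmd), rep("both", n_both),
            rep("none", n_features - n_planted))
  shape <- c(rep_len(shapes, n_planted),
             rep("null", n_features - n_planted))
  data.frame(
    feature = sprintf("F%03d", seq_len(n_features)),
    process = proc, shape = shape,
    effect = c(rep(effect, n_planted), rep(0, n_features - n_planted)),
    stringsAsFactors = FALSE
  )
}

# Archetype response curves on the quantile scale u in (0,1).
archetype_transform <- function(u, shape) {
  switch(shape,
    linear_increase = u,
    linear_decrease = -u,
    plateau_early = pmin(u, 0.4) / 0.4,
    plateau_late = pmax(u - 0.6, 0) / 0.4,
    weak_nonmonotone = 1 - 2 * abs(u - 0.5),
    null = rep(0, length(u)),
    stop("unknown archetype shape: ", shape)
  )
}

#' Simulate an observation table with planted feature-process structure
#'
#' @param spec A [table_sim_spec].
#' @return A list with `table` (data.frame: index columns, process columns,
#'   feature columns, `valid` flag), `truth` (the archetype plan) and
#'   `latents` (data.frame with the latent speed and latent CMD per
#'   observation).
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_sim_spec"))
  set.seed(spec$seed)
  nc <- spec$n_cells; nf <- spec$frames_per_cell
  n <- nc * nf

  cell_mu <- stats::rnorm(nc, spec$speed_meanlog, spec$speed_sdlog_cell)
  # persistence decreases with cell mean speed (fast cells are transient)
  u_cell <- (rank(cell_mu, ties.method = "first") - 0.5) / nc
  rho <- pmin(pmax(0.65 - 0.45 * u_cell, 0.05), 0.9)

  speed <- numeric(n); cell_id <- character(n); frame <- integer(n)
  for (c_i in seq_len(nc)) {
    e <- stats::rnorm(nf, 0, spec$speed_sdlog_within * sqrt(1 - rho[c_i]^2))
    z <- numeric(nf)
    z[1] <- stats::rnorm(1, 0, spec$speed_sdlog_within)
    if (nf >= 2) for (t in 2:nf) z[t] <- rho[c_i] * z[t - 1] + e[t]
    idx <- ((c_i - 1) * nf + 1):(c_i * nf)
    speed[idx] <- exp(cell_mu[c_i] + z)
    cell_id[idx] <- sprintf("cell%03d", c_i)
    frame[idx] <- seq_len(nf)
  }
  cmd_latent <- stats::rnorm(n, 0, spec$cmd_sd)
  dca <- spec$k * speed + spec$m + cmd_latent
  dca <- pmax(dca, 0)

  # pixel split of the dynamic area: slow cells protrude more than they
  # retract, fast cells the reverse; ~10% of dynamic pixels short-lived
  px2 <- 0.21^2
  dca_px <- round(dca / px2)
  u_speed <- (rank(speed, ties.method = "first") - 0.5) / n
  frac_prot <- pmin(pmax(0.55 - 0.18 * u_speed +
                           stats::rnorm(n, 0, 0.12), 0.05), 0.95)
  short_px <- round(0.10 * dca_px)
  prot_px <- round((dca_px - short_px) * frac_prot)
  retr_px <- dca_px - short_px - prot_px

  experiment <- sprintf("exp%02d",
                        (match(cell_id, unique(cell_id)) - 1) %/%
                          spec$cells_per_experiment + 1)

  plan <- spec$archetype_plan
  u_cmd <- (rank(cmd_latent, ties.method = "first") - 0.5) / n
  feat <- matrix(stats::rnorm(n * nrow(plan), 0, spec$noise_sd), n,
                 nrow(plan))
  colnames(feat) <- plan$feature
  for (j in seq_len(nrow(plan))) {
    if (plan$process[j] == "none" || plan$effect[j] == 0) next
    amp <- plan$effect[j] * spec$noise_sd
    if (plan$process[j] %in% c("speed", "both")) {
      feat[, j] <- feat[, j] + amp * archetype_transform(u_speed, plan$shape[j])
    }
    if (plan$process[j] %in% c("cmd", "both")) {
      feat[, j] <- feat[, j] + amp * archetype_transform(u_cmd, plan$shape[j])
    }
  }

  tab <- data.frame(
    experiment_id = experiment, cell_trace_id = cell_id,
    frame_number = frame,
    position_x = stats::runif(n, 0, 1024), position_y = stats::runif(n, 0, 1024),
    cell_speed = speed,
    protrusion_pixels = as.integer(prot_px),
    retraction_pixels = as.integer(retr_px),
    short_lived_pixels = as.integer(short_px),
    dynamic_cell_area = dca,
    valid = TRUE,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(feat))
  list(table = tab, truth = plan,
       latents = data.frame(speed = speed, cmd = cmd_latent))
}
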