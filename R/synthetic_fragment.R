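#' Parameters for the synthetic tumor-fragment simulator
#'
#' Collects and validates every knob of the fragment simulator. Defaults
#' reproduce the geometry and acquisition cadence of the assay the package
#' analyzes: fragments 150--300 um in diameter (default 200 um), imaged in
#' 10 um z-slices every 3--4 h over roughly five days, with a thin ring of
#' loading damage at the perimeter, an optional inward-advancing kill front
#' (condition-dependent), TIL arrivals on the fragment surface that infiltrate
#' inward, live->dying->dead dye transitions, photobleaching of the green
#' channel, and additive background plus signal-dependent Gaussian noise.
#'
#' @param fragment_diameter fragment diameter, um.
#' @param voxel_size named numeric \code{c(dx=, dy=, dz=)}, um. Axial slices
#'   default to 10 um; lateral sampling defaults to 5 um.
#' @param time_points acquisition times, hours since the start of perfusion.
#' @param perimeter_damage_depth depth of the loading-damage ring, um; these
#'   voxels enter the dying state at t = 0.
#' @param kill_front_speed inward speed of the killing front, um/h (0 = none).
#' @param dying_duration residence time in the green+APC co-positive "dying"
#'   state before the green signal is lost and the voxel is "dead", hours.
#' @param til_surface_rate TIL arrival rate per um^2 of fragment surface per h.
#' @param til_infiltration_speed inward migration speed of TILs, um/h.
#' @param til_radius rendered radius of one TIL, um (red channel footprint).
#' @param til_kill_radius radius around a TIL within which tumor voxels begin
#'   dying on contact, um; 0 disables contact killing.
#' @param til_death_rate exponential hazard for a TIL to die (become
#'   red+APC co-positive), 1/h.
#' @param green_bleach_rate exponential photobleaching rate of the green
#'   channel, 1/h (signal scales as exp(-rate * t)).
#' @param base_intensities named per-channel mean signal, arbitrary units.
#' @param background_level named per-channel additive background mean.
#' @param noise_sd named per-channel Gaussian background standard deviation.
#' @param noise_dispersion signal-proportional dispersion: the noise SD of a
#'   voxel with signal S is \code{sqrt(noise_sd^2 + (noise_dispersion*S)^2)}.
#' @param shape_perturbation amplitude of the smooth random radial
#'   perturbation of the spheroid, as a fraction of the radius.
#' @param grid_dim optional fixed field of view \code{c(nz, ny, nx)}; when
#'   given, the fragment must fit with at least a 2-voxel margin. When NULL
#'   the grid is sized automatically around the fragment.
#' @param margin_voxels lateral/axial margin used when sizing the grid.
#' @param seed integer random seed; identical params + seed give bit-identical
#'   output.
#' @return an object of class \code{simulation_params}.
#' @seealso [simulate_fragment()], [apply_condition()]
#' @export
simulation_params <- function(fragment_diameter = 200,
                              voxel_size = c(dx = 5, dy = 5, dz = 10),
                              time_points = seq(0, 105, by = 3.5),
                              perimeter_damage_depth = 3,
                              kill_front_speed = 0.2,
                              dying_duration = 48,
                              til_surface_rate = 1e-5,
                              til_infiltration_speed = 2,
                              til_radius = 7,
                              til_kill_radius = 8,
                              til_death_rate = 0.02,
                              green_bleach_rate = 0.01,
                              base_intensities = c(live_green = 2000,
                                                   til_red = 2000,
                                                   dead_apc = 2000),
                              background_level = c(live_green = 200,
                                                   til_red = 200,
                                                   dead_apc = 200),
                              noise_sd = c(live_green = 60, til_red = 60,
                                           dead_apc = 60),
                              noise_dispersion = 0.05,
                              shape_perturbation = 0.10,
                              grid_dim = NULL,
                              margin_voxels = 3,
                              seed = 1L) {
  p <- list(fragment_diameter = fragment_diameter,
            voxel_size = expand_voxel_size(voxel_size),
            time_points = as.numeric(time_points),
            perimeter_damage_depth = perimeter_damage_depth,
            kill_front_speed = kill_front_speed,
            dying_duration = dying_duration,
            til_surface_rate = til_surface_rate,
            til_infiltration_speed = til_infiltration_speed,
            til_radius = til_radius,
            til_kill_radius = til_kill_radius,
            til_death_rate = til_death_rate,
            green_bleach_rate = green_bleach_rate,
            base_intensities = expand_channel_vec(base_intensities),
            background_level = expand_channel_vec(background_level),
            noise_sd = expand_channel_vec(noise_sd),
            noise_dispersion = noise_dispersion,
            shape_perturbation = shape_perturbation,
            grid_dim = grid_dim,
            margin_voxels = margin_voxels,
            seed = as.integer(seed))
  class(p) <- "simulation_params"
  validate_simulation_params(p)
  p
}

expand_voxel_size <- function(v) {
  if (is.null(names(v))) names(v) <- c("dx", "dy", "dz")[seq_along(v)]
  stopifnot(all(c("dx", "dy", "dz") %in% names(v)))
  v[c("dx", "dy", "dz")]
}

expand_channel_vec <- function(v) {
  if (is.null(names(v))) {
    if (length(v) == 1L) v <- rep(v, 3)
    if (length(v) != 3L)
      stop_config("per-channel values must be named or of length 1 or 3")
    names(v) <- TK_CHANNELS
  }
  if (!all(TK_CHANNELS %in% names(v)))
    stop_config("per-channel values must name all of: ",
                paste(TK_CHANNELS, collapse = ", "))
  v[TK_CHANNELS]
}

validate_simulation_params <- function(p) {
  if (!is_scalar_number(p$fragment_diameter) || p$fragment_diameter <= 0)
    stop_config("fragment_diameter must be a positive number (um)")
  if (any(p$voxel_size <= 0)) stop_config("voxel sizes must be positive")
  if (length(p$time_points) == 0)
    stop_config("time_points must not be empty")
  if (any(p$time_points < 0) || is.unsorted(p$time_points))
    stop_config("time_points must be non-negative and increasing")
  rates <- c(perimeter_damage_depth = p$perimeter_damage_depth,
             kill_front_speed = p$kill_front_speed,
             dying_duration = p$dying_duration,
             til_surface_rate = p$til_surface_rate,
             til_infiltration_speed = p$til_infiltration_speed,
             til_radius = p$til_radius,
             til_kill_radius = p$til_kill_radius,
             til_death_rate = p$til_death_rate,
             green_bleach_rate = p$green_bleach_rate,
             noise_dispersion = p$noise_dispersion,
             shape_perturbation = p$shape_perturbation)
  bad <- names(rates)[!vapply(rates, is_scalar_number, logical(1)) | rates < 0]
  if (length(bad))
    stop_config("negative or non-numeric rate parameter(s): ",
                paste(bad, collapse = ", "))
  if (any(p$base_intensities < 0) || any(p$background_level < 0) ||
      any(p$noise_sd < 0))
    stop_config("intensity, background and noise parameters must be >= 0")
  if (!is.null(p$grid_dim) && length(p$grid_dim) != 3)
    stop_config("grid_dim must be c(nz, ny, nx)")
  invisible(p)
}

#' Named condition presets for the perfusion experiment
#'
#' Maps a treatment condition to multipliers on the killing kinetics:
#' isotype-control TILs neither form a kill front nor kill on contact (only
#' perimeter loading damage remains), anti-PD-1 gives the base potency, and
#' anti-CTLA4 doubles the front speed. TIL surface arrival (retention) also
#' rises with checkpoint blockade. The multipliers are package choices, not
#' measured quantities.
#'
#' @param params a \code{simulation_params} object.
#' @param condition one of \code{TK_CONDITIONS}.
#' @return modified \code{simulation_params}.
#' @export
apply_condition <- function(params, condition) {
  condition <- match.arg(condition, TK_CONDITIONS)
  preset <- switch(condition,
    isotype    = list(kill = 0, til = 1,   contact = FALSE),
    anti_PD1   = list(kill = 1, til = 2,   contact = TRUE),
    anti_CTLA4 = list(kill = 2, til = 3,   contact = TRUE))
  params$kill_front_speed <- params$kill_front_speed * preset$kill
  params$til_surface_rate <- params$til_surface_rate * preset$til
  if (!preset$contact) params$til_kill_radius <- 0
  params$condition <- condition
  validate_simulation_params(params)
  params
}

# ---- geometry ---------------------------------------------------------------

# Builds the voxel grid and the perturbed-spheroid fragment: per-voxel radial
# coordinate r, local surface radius R(dir) and radial depth R(dir) - r (um).
# Uses the RNG (shape perturbation); callers wrap in with_seed().
build_geometry <- function(p) {
  vs <- p$voxel_size
  R0 <- p$fragment_diameter / 2
  s <- p$shape_perturbation
  Rmax <- R0 * (1 + s)

  if (is.null(p$grid_dim)) {
    nz <- 2L * as.integer(ceiling(Rmax / vs["dz"] + p$margin_voxels)) + 1L
    ny <- 2L * as.integer(ceiling(Rmax / vs["dy"] + p$margin_voxels)) + 1L
    nx <- 2L * as.integer(ceiling(Rmax / vs["dx"] + p$margin_voxels)) + 1L
  } else {
    nz <- as.integer(p$grid_dim[1]); ny <- as.integer(p$grid_dim[2])
    nx <- as.integer(p$grid_dim[3])
    half <- c(nz / 2 * vs["dz"], ny / 2 * vs["dy"], nx / 2 * vs["dx"])
    need <- Rmax + 2 * c(vs["dz"], vs["dy"], vs["dx"])
    if (any(half < need))
      stop_config("fragment larger than the field of view: needs half-extent ",
                  paste(round(need, 1), collapse = "/"), " um (z/y/x), grid ",
                  "provides ", paste(round(half, 1), collapse = "/"))
  }

  cz <- (nz + 1) / 2; cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  z <- ((1:nz) - cz) * vs["dz"]
  y <- ((1:ny) - cy) * vs["dy"]
  x <- ((1:nx) - cx) * vs["dx"]
  # full coordinate arrays, dim (nz, ny, nx)
  Z <- array(z, dim = c(nz, ny, nx))
  Y <- array(rep(y, each = nz), dim = c(nz, ny, nx))
  X <- array(rep(x, each = nz * ny), dim = c(nz, ny, nx))
  r <- sqrt(Z^2 + Y^2 + X^2)

  if (s > 0) {
    coef <- rnorm(8)
    pert_fun <- make_pert_fun(coef, s)
  } else {
    pert_fun <- function(u) rep(0, nrow(u))
  }
  eps <- 1e-9
  u <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) / pmax(as.vector(r), eps)
  R_local <- array(R0 * (1 + pert_fun(u)), dim = c(nz, ny, nx))
  depth <- R_local - r
  inside <- depth >= 0

  list(dim = c(nz, ny, nx), voxel_size = vs, R0 = R0,
       coords = list(z = z, y = y, x = x), r = r, R_local = R_local,
       depth = depth, inside = inside, n_inside = sum(inside),
       pert_fun = function(u) R0 * (1 + pert_fun(u)))
}

# Smooth random radial perturbation from low-order direction polynomials,
# rescaled so the maximum amplitude equals `s`.
make_pert_fun <- function(coef, s) {
  basis <- function(u) {
    cbind(u[, 1], u[, 2], u[, 3],
          u[, 1] * u[, 2], u[, 2] * u[, 3], u[, 1] * u[, 3],
          u[, 1]^2 - u[, 2]^2, u[, 2]^2 - u[, 3]^2)
  }
  # normalize on a reference direction sample (deterministic grid)
  th <- seq(0, pi, length.out = 24); ph <- seq(0, 2 * pi, length.out = 48)
  g <- expand.grid(th = th, ph = ph)
  ref <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  scale <- max(abs(basis(ref) %*% coef), 1e-12)
  function(u) as.vector(basis(u) %*% coef) / scale * s
}

# ---- TIL arrivals -----------------------------------------------------------

# Poisson stream of TILs landing on the fragment surface; each infiltrates
# radially inward and may die (exponential hazard). Uses the RNG.
seed_tils <- function(p, geom) {
  t_max <- max(p$time_points)
  area <- 4 * pi * geom$R0^2
  n <- rpois(1, p$til_surface_rate * area * t_max)
  if (n == 0)
    return(data.frame(t_arrive = numeric(0), t_die = numeric(0),
                      ux = numeric(0), uy = numeric(0), uz = numeric(0),
                      R_dir = numeric(0)))
  t_arrive <- sort(runif(n, 0, t_max))
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  t_die <- t_arrive + if (p$til_death_rate > 0)
    rexp(n, p$til_death_rate) else Inf
  data.frame(t_arrive = t_arrive, t_die = t_die,
             ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3],
             R_dir = geom$pert_fun(dirs))
}

# Radial depth of TIL i at time t (um below the local surface), capped at the
# center; TILs stop moving when they die.
til_depth_at <- function(tils, p, t) {
  tt <- pmin(t, tils$t_die)
  d <- p$til_infiltration_speed * pmax(tt - tils$t_arrive, 0)
  pmin(d, tils$R_dir)
}

# Cartesian centers (um) of TILs at time t.
til_centers_at <- function(tils, p, t) {
  rad <- tils$R_dir - til_depth_at(tils, p, t)
  cbind(x = tils$ux * rad, y = tils$uy * rad, z = tils$uz * rad)
}

# Mark voxels within `radius` um of any of the given centers.
mark_balls <- function(geom, centers, radius) {
  out <- array(FALSE, dim = geom$dim)
  if (nrow(centers) == 0 || radius <= 0) return(out)
  vs <- geom$voxel_size
  co <- geom$coords
  nz <- geom$dim[1]; ny <- geom$dim[2]; nx <- geom$dim[3]
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, "x"]; cy <- centers[i, "y"]; cz <- centers[i, "z"]
    iz <- which(abs(co$z - cz) <= radius)
    iy <- which(abs(co$y - cy) <= radius)
    ix <- which(abs(co$x - cx) <= radius)
    if (!length(iz) || !length(iy) || !length(ix)) next
    dz2 <- (co$z[iz] - cz)^2
    dy2 <- (co$y[iy] - cy)^2
    dx2 <- (co$x[ix] - cx)^2
    d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    sub <- out[iz, iy, ix, drop = FALSE]
    sub[d2 <= radius^2] <- TRUE
    out[iz, iy, ix] <- sub
  }
  out
}

# ---- death kinetics ---------------------------------------------------------

# Per-voxel dying-onset times: perimeter damage at t = 0, the inward kill
# front, and TIL contact foci (first observation time within til_kill_radius
# of an arrived, live TIL). Inf = never; voxels outside the fragment are NA.
death_onsets <- function(p, geom, tils) {
  onset <- array(Inf, dim = geom$dim)
  d <- geom$depth
  onset[geom$inside & d <= p$perimeter_damage_depth] <- 0
  if (p$kill_front_speed > 0) {
    front <- (d - p$perimeter_damage_depth) / p$kill_front_speed
    sel <- geom$inside & d > p$perimeter_damage_depth
    onset[sel] <- front[sel]
  }
  if (p$til_kill_radius > 0 && nrow(tils) > 0) {
    for (t in p$time_points) {
      act <- tils[tils$t_arrive <= t & tils$t_die > t, , drop = FALSE]
      if (nrow(act) == 0) next
      hit <- mark_balls(geom, til_centers_at(act, p, t), p$til_kill_radius)
      sel <- geom$inside & hit & onset > t
      onset[sel] <- t
    }
  }
  onset[!geom$inside] <- NA_real_
  onset
}

# State code at time t: 0 outside, 1 live, 2 dying, 3 dead.
states_at <- function(onset, p, t) {
  st <- array(0L, dim = dim(onset))
  inside <- !is.na(onset)
  st[inside] <- 1L
  st[inside & onset <= t] <- 2L
  st[inside & onset + p$dying_duration <= t] <- 3L
  st
}

# ---- rendering --------------------------------------------------------------

render_channels <- function(p, geom, st, tils, t) {
  base <- p$base_intensities
  g <- array(0, dim = geom$dim)
  a <- array(0, dim = geom$dim)
  r <- array(0, dim = geom$dim)
  bleach <- exp(-p$green_bleach_rate * t)
  g[st == 1L | st == 2L] <- base["live_green"] * bleach
  a[st == 2L | st == 3L] <- base["dead_apc"]

  til_mask <- array(FALSE, dim = geom$dim)
  if (nrow(tils) > 0) {
    arrived <- tils[tils$t_arrive <= t, , drop = FALSE]
    if (nrow(arrived) > 0) {
      til_mask <- mark_balls(geom, til_centers_at(arrived, p, t), p$til_radius)
      r[til_mask] <- base["til_red"]
      dead_tils <- arrived[arrived$t_die <= t, , drop = FALSE]
      if (nrow(dead_tils) > 0) {
        dead_mask <- mark_balls(geom, til_centers_at(dead_tils, p, t),
                                p$til_radius)
        a[dead_mask] <- pmax(a[dead_mask], base["dead_apc"])
      }
    }
  }
  list(channels = list(live_green = g, til_red = r, dead_apc = a),
       til_mask = til_mask)
}

add_noise <- function(ch, p) {
  out <- ch
  for (nm in TK_CHANNELS) {
    v <- ch[[nm]]
    s <- sqrt(p$noise_sd[nm]^2 + (p$noise_dispersion * v)^2)
    v <- v + p$background_level[nm]
    if (any(s > 0)) v <- v + rnorm(length(v), 0, s)
    v <- round(pmin(pmax(v, 0), 65535))
    out[[nm]] <- array(v, dim = dim(ch[[nm]]))
  }
  out
}

# ---- main entry -------------------------------------------------------------

#' Simulate a tumor fragment under TIL perfusion
#'
#' Generates one three-channel z-stack per acquisition timepoint together with
#' the per-voxel ground-truth state labels the renderer used. The fragment is
#' a spheroid with a smooth random radial perturbation; death spreads from a
#' perimeter damage ring, an inward kill front, and TIL contact foci; voxels
#' pass live -> dying (green+APC co-positive) -> dead (APC only, green lost).
#' Output is a pure function of the parameter object (including its seed).
#'
#' @param params a [simulation_params()] object.
#' @param fragment_id identifier stamped on every stack and truth row.
#' @return object of class \code{fragment_simulation}: list with
#'   \itemize{
#'     \item \code{stacks}: list of [channel_stack()] objects, one per
#'       timepoint (noisy rendered intensities, integer-valued);
#'     \item \code{truth}: list with \code{summary} (data.frame: time_h,
#'       n_live, n_dying, n_dead, true_fraction, n_til_voxels,
#'       max_til_depth_um), \code{labels} (list of state arrays; 0 outside,
#'       1 live, 2 dying, 3 dead) and \code{til_masks};
#'     \item \code{n_fragment_voxels}, \code{equivalent_diameter_um},
#'       \code{params}.
#'   }
#'   The true dying fraction is n_dying / (n_live + n_dying + n_dead), whose
#'   denominator is the constant initial fragment voxel count.
#' @export
simulate_fragment <- function(params, fragment_id = "fragment") {
  stopifnot(inherits(params, "simulation_params"))
  validate_simulation_params(params)
  p <- params
  with_seed(p$seed, {
    geom <- build_geometry(p)
    tils <- seed_tils(p, geom)
    onset <- death_onsets(p, geom, tils)

    stacks <- vector("list", length(p$time_points))
    labels <- vector("list", length(p$time_points))
    til_masks <- vector("list", length(p$time_points))
    rows <- vector("list", length(p$time_points))

    for (i in seq_along(p$time_points)) {
      t <- p$time_points[i]
      st <- states_at(onset, p, t)
      rend <- render_channels(p, geom, st, tils, t)
      noisy <- add_noise(rend$channels, p)
      stacks[[i]] <- channel_stack(noisy, voxel_size = p$voxel_size,
                                   time_h = t, fragment_id = fragment_id)
      labels[[i]] <- st
      til_masks[[i]] <- rend$til_mask
      arrived <- tils[tils$t_arrive <= t, , drop = FALSE]
      rows[[i]] <- data.frame(
        fragment_id = fragment_id, time_h = t,
        n_live = sum(st == 1L), n_dying = sum(st == 2L),
        n_dead = sum(st == 3L),
        true_fraction = sum(st == 2L) / geom$n_inside,
        n_til_voxels = sum(rend$til_mask),
        max_til_depth_um = if (nrow(arrived)) max(til_depth_at(arrived, p, t))
                           else 0)
    }

    vvol <- prod(p$voxel_size)
    out <- list(stacks = stacks,
                truth = list(summary = do.call(rbind, rows), labels = labels,
                             til_masks = til_masks),
                n_fragment_voxels = geom$n_inside,
                equivalent_diameter_um =
                  (6 * geom$n_inside * vvol / pi)^(1 / 3),
                fragment_id = fragment_id,
                params = p)
    class(out) <- "fragment_simulation"
    out
  })
}

#' @export
print.fragment_simulation <- function(x, ...) {
  cat("<fragment_simulation>", x$fragment_id, "\n")
  cat("  grid:", paste(dim(x$stacks[[1]]$channels[[1]]), collapse = " x "),
      "(nz x ny x nx),", length(x$stacks), "timepoints\n")
  cat("  fragment voxels:", x$n_fragment_voxels,
      sprintf("(equivalent diameter %.0f um)\n", x$equivalent_diameter_um))
  cat(sprintf("  final true dying fraction: %.3f\n",
              utils::tail(x$truth$summary$true_fraction, 1)))
  invisible(x)
}

#' Write simulator ground truth as CSV
#'
#' @param sims list of \code{fragment_simulation} objects (or one).
#' @param path output CSV path.
#' @export
write_truth_csv <- function(sims, path) {
  if (inherits(sims, "fragment_simulation")) sims <- list(sims)
  tab <- do.call(rbind, lapply(sims, function(s) {
    d <- s$truth$summary
    d$condition <- s$params$condition %||% NA_character_
    d
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
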