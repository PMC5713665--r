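# Synthetic inputs: QA phantoms (sphere/ellipsoid scaler measurement sets),
# stand-in off-axis-ratio profiles, and randomized test plans. Everything
# is deterministic under a seed, so the engine is fully testable without
# vendor data.

#' Specify a QA phantom
#'
#' @param shape \code{"sphere"} or \code{"ellipsoid"}.
#' @param parameters radius (mm) for a sphere, or the three semi-axes (mm)
#'   for an ellipsoid.
#' @param center phantom centre (frame mm).
#' @param n_directions number of scaler directions to generate.
#' @param seed integer seed fixing the direction jitter.
#' @return object of class \code{pfx_phantom_spec}.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid"), parameters = 80,
                         center = FRAME_CENTER, n_directions = 24,
                         seed = 1L) {
  shape <- match.arg(shape)
  parameters <- as.numeric(parameters)
  if (shape == "sphere" && length(parameters) != 1)
    stop("a sphere takes a single radius")
  if (shape == "ellipsoid" && length(parameters) != 3)
    stop("an ellipsoid takes three semi-axes")
  if (any(parameters <= 0)) stop("phantom dimensions must be positive")
  if (n_directions < 6) stop("need at least 6 directions")
  structure(list(shape = shape, parameters = parameters,
                 center = as.numeric(center),
                 n_directions = as.integer(n_directions),
                 seed = as.integer(seed)),
            class = "pfx_phantom_spec")
}

#' Exact analytic surface of a QA phantom
#'
#' Wraps a phantom spec as a surface with the same query interface as a
#' fitted skull surface (\code{\link{radius_at}}, \code{\link{ray_entry}},
#' \code{\link{trace_beam}}, the dose engine), but with the exact
#' sphere/ellipsoid radial function instead of a spherical-harmonic fit.
#' Useful as a fit-error-free reference in QA and closed-form checks.
#'
#' @param spec a \code{pfx_phantom_spec}.
#' @return object of class \code{pfx_phantom_surface}.
#' @export
phantom_surface <- function(spec) {
  stopifnot(inherits(spec, "pfx_phantom_spec"))
  structure(list(spec = spec, center = spec$center,
                 fit_residuals = numeric(0)),
            class = "pfx_phantom_surface")
}

#' @export
radius_at.pfx_phantom_surface <- function(surface, direction) {
  phantom_radius(surface$spec, direction)
}

# analytic radius of the phantom surface along unit directions (n x 3)
phantom_radius <- function(spec, directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  if (spec$shape == "sphere") {
    rep(spec$parameters, nrow(directions))
  } else {
    ax <- spec$parameters
    1 / sqrt((directions[, 1] / ax[1])^2 + (directions[, 2] / ax[2])^2 +
             (directions[, 3] / ax[3])^2)
  }
}

# scaler direction layout: quasi-uniform cover of the superior hemisphere
# plus an equatorial band, with a small seeded jitter (mimics hand-placed
# scaler probe positions); a stand-in for the instrument's standard set
scaler_directions <- function(n, seed) {
  n_band <- max(6L, round(n / 4))
  n_hemi <- n - n_band
  i <- seq_len(n_hemi) - 0.5
  z <- i / n_hemi                      # superior hemisphere, z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  hemi <- cbind(r * cos(phi), r * sin(phi), z)
  band_phi <- 2 * pi * (seq_len(n_band) - 1) / n_band
  band <- cbind(cos(band_phi), sin(band_phi), -0.15)
  band <- band / sqrt(rowSums(band^2))
  dirs <- rbind(hemi, band)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jitter <- matrix(stats::rnorm(3 * n, sd = 0.02), n, 3)
  dirs <- dirs + jitter
  dirs / sqrt(rowSums(dirs^2))
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate skull-scaler measurements of a QA phantom
#'
#' Radii are exact analytic distances from the phantom centre to its
#' surface along the generated directions; the direction set is
#' deterministic under the spec's seed.
#'
#' @param spec a \code{pfx_phantom_spec}.
#' @return a \code{pfx_scaler_measurements}.
#' @export
#' @examples
#' m <- make_scaler_measurements(phantom_spec("sphere", 80))
#' range(m$radii)  # 80 80
make_scaler_measurements <- function(spec) {
  stopifnot(inherits(spec, "pfx_phantom_spec"))
  dirs <- scaler_directions(spec$n_directions, spec$seed)
  scaler_measurements(dirs, phantom_radius(spec, dirs), spec$center)
}

#' Default off-axis-ratio profile for a collimator size
#'
#' A documented stand-in for vendor beam profiles: unity over a flat core
#' of radius collimator/2 at the focus, a smooth cosine penumbra of the
#' given width falling to zero, and a zero tail. Strictly non-increasing.
#'
#' @param collimator collimator size (16, 8 or 4 mm).
#' @param penumbra_mm penumbra width (mm), default 2.
#' @param step_mm radial sampling step of the table (mm).
#' @return list with \code{radius_mm} and \code{oar} vectors.
#' @export
make_default_oar <- function(collimator, penumbra_mm = 2, step_mm = 0.25) {
  if (!collimator %in% COLLIMATOR_SIZES)
    stop("collimator must be one of ", paste(COLLIMATOR_SIZES, collapse = ", "))
  core <- collimator / 2
  rmax <- core + penumbra_mm + 2
  r <- seq(0, rmax, by = step_mm)
  v <- ifelse(r <= core, 1,
              ifelse(r >= core + penumbra_mm, 0,
                     0.5 * (1 + cos(pi * (r - core) / penumbra_mm))))
  list(radius_mm = r, oar = round(v, 6))
}

#' Bell-shaped off-axis-ratio profile for a collimator size
#'
#' A Gaussian radial profile with its 50% level at collimator/2 (FWHM
#' equal to the nominal collimator size), tabulated to 4 half-widths.
#' This is the profile family used by the shipped default machine file:
#' unlike a flat-topped profile it keeps the single-shot dose maximum at
#' the focus, and it is closer in shape to measured beam profiles.
#'
#' @param collimator collimator size (16, 8 or 4 mm).
#' @param step_mm radial sampling step of the table (mm).
#' @return list with \code{radius_mm} and \code{oar} vectors.
#' @export
make_bell_oar <- function(collimator, step_mm = 0.25) {
  if (!collimator %in% COLLIMATOR_SIZES)
    stop("collimator must be one of ", paste(COLLIMATOR_SIZES, collapse = ", "))
  r50 <- collimator / 2
  r <- seq(0, 4 * r50, by = step_mm)
  v <- exp(-log(2) * (r / r50)^2)
  v <- round(v, 7)
  v[1] <- 1
  list(radius_mm = r, oar = v)
}

#' Write the default machine-definition file
#'
#' Emits the YAML machine definition used as the package default: the
#' true Perfexion sector/ring layout counts (8 sectors of 24 sources, 5
#' rings) with plausible placeholder angles, distances and beam tables,
#' all overridable. Used to (re)generate the shipped file.
#'
#' @param path output path.
#' @param dose_rate_gy_min calibration dose rate (Gy/min).
#' @param oar_style \code{"bell"} (Gaussian profiles, the shipped
#'   default; see \code{\link{make_bell_oar}}) or \code{"flat-core"}
#'   (flat core + cosine penumbra; see \code{\link{make_default_oar}}).
#' @return the path, invisibly.
#' @export
write_default_machine <- function(path, dose_rate_gy_min = 3,
                                  oar_style = c("bell", "flat-core")) {
  oar_style <- match.arg(oar_style)
  oar_fun <- if (oar_style == "bell") make_bell_oar else make_default_oar
  vsfd_base <- c(433, 419, 404, 389, 374)  # per ring, mm
  doc <- list(
    schema = "pfx-machine/1",
    geometry = list(
      sector_azimuths = seq(0, 315, by = 45),
      ring_polar_angles = c(35, 47.5, 60, 72.5, 85),
      ring_occupancy = c(4L, 5L, 6L, 5L, 4L),
      ring_physical_distance = vsfd_base),
    beam_data = list(
      output_factors = list(c16 = 1.0, c8 = 0.92, c4 = 0.81),
      vsfd = list(c16 = vsfd_base, c8 = vsfd_base + 1.5,
                  c4 = vsfd_base + 3),
      oar_profiles = list(c16 = oar_fun(16), c8 = oar_fun(8),
                          c4 = oar_fun(4))),
    calibration = list(dose_rate_gy_min = dose_rate_gy_min,
                       r_cal_mm = 80, mu_per_mm = 0.0065))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' Generate a randomized test plan inside a phantom
#'
#' Shot positions are drawn uniformly inside the phantom with a 20 mm
#' margin to its surface, gamma angles from \code{gamma_set}, sector
#' states at random (never all blocked); durations are set so each shot
#' delivers approximately prescription/n_shots at its own focus.
#' Deterministic under \code{seed}.
#'
#' @param n_shots number of shots (>= 1).
#' @param phantom a \code{pfx_phantom_spec}.
#' @param seed integer seed.
#' @param machine a \code{pfx_machine} used to set durations.
#' @param prescription prescription list (\code{dose_gy}, \code{isodose_pct}).
#' @param gamma_set gamma angles sampled from, degrees.
#' @param all_open_16 force every sector of every shot to 16 mm (the
#'   canonical calibration-closure configuration).
#' @return a \code{pfx_plan}; the phantom's fitted surface is attached as
#'   attribute \code{"surface"} and its measurements as
#'   \code{"measurements"}.
#' @export
make_plan <- function(n_shots, phantom = phantom_spec("sphere", 80),
                      seed = 1L, machine = load_machine(),
                      prescription = list(dose_gy = 20, isodose_pct = 50),
                      gamma_set = c(70, 90, 110), all_open_16 = FALSE) {
  if (n_shots < 1) stop("n_shots must be >= 1")
  meas <- make_scaler_measurements(phantom)
  degree <- if (phantom$shape == "sphere") 2 else 4
  if ((degree + 1)^2 > phantom$n_directions)
    degree <- floor(sqrt(phantom$n_directions)) - 1
  surface <- fit_skull(meas, degree = degree)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  margin <- 20
  shots <- vector("list", n_shots)
  for (i in seq_len(n_shots)) {
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      p <- phantom$center + u * (min(phantom$parameters) - margin)
      rel <- p - phantom$center
      if (vnorm(rel) < 1e-9 ||
          vnorm(rel) < phantom_radius(phantom, unitize(rel)) - margin) break
    }
    p <- round(p, 2)
    gamma <- sample(gamma_set, 1)
    if (all_open_16) {
      states <- rep("16", 8)
      gamma <- 90
      p <- round(phantom$center, 2)
    } else {
      states <- sample(c("16", "8", "4", "blocked"), 8, replace = TRUE,
                       prob = c(0.4, 0.25, 0.25, 0.1))
      if (all(states == "blocked")) states[sample(8, 3)] <- "16"
    }
    sh <- shot(p, gamma_angle = gamma, sector_states = states, weight = 1)
    rate <- shot_dose_rate(p, sh, surface, machine)
    sh$duration <- round((prescription$dose_gy / n_shots) / rate, 4)
    sh$weight <- NULL
    sh$id <- sprintf("shot-%02d", i)
    shots[[i]] <- sh
  }
  ctr <- round(rowMeans(vapply(shots, `[[`, numeric(3), "position")), 2)
  pl <- plan(shots, prescription = prescription,
             grid_spec = list(origin = ctr - 25, spacing = c(2, 2, 2),
                              dims = c(26L, 26L, 26L)),
             identifier = sprintf("synthetic-%s-%d", phantom$shape, seed))
  attr(pl, "surface") <- surface
  attr(pl, "measurements") <- meas
  pl
}
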