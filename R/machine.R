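# Virtual Perfexion machine model: 192 Co-60 sources in 8 sectors x 5 rings,
# collimator-size output factors, per-(collimator, ring) virtual
# source-to-focus distances and off-axis-ratio profiles, and the calibration
# constants of the point dose-rate model.

N_SOURCES <- 192L
N_SECTORS <- 8L
N_RINGS <- 5L
COLLIMATOR_SIZES <- c(16L, 8L, 4L)

coll_key <- function(size) paste0("c", size)

#' Load a machine-definition file
#'
#' Reads a YAML machine definition with sections \code{geometry},
#' \code{beam_data} and \code{calibration} and returns a validated
#' \code{pfx_machine} object. Optional fields absent from the file are
#' filled from documented defaults: \code{mu_per_mm = 0.0065},
#' \code{r_cal_mm = 80}, \code{dose_rate_gy_min = 3}. OAR profiles may be
#' given once per collimator (applied to every ring) or per ring.
#'
#' All lengths are millimetres, dose rates Gy/min, angles degrees.
#'
#' @param path path to a machine-definition YAML file. The default is the
#'   machine file shipped with the package, whose geometric values are
#'   plausible placeholders (vendor beam data is proprietary); every value
#'   can be overridden by supplying your own file.
#' @return an object of class \code{pfx_machine} with elements
#'   \code{geometry} (source table plus ring/sector layout),
#'   \code{beam_data} (output factors, vSFD, OAR profiles) and
#'   \code{calibration}.
#' @export
#' @examples
#' mach <- load_machine()
#' nrow(mach$geometry$sources)  # 192
load_machine <- function(path = default_machine_path()) {
  if (!file.exists(path)) stop("machine-definition file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (sec in c("geometry", "beam_data", "calibration")) {
    if (is.null(raw[[sec]])) stop("machine file is missing section '", sec, "'")
  }
  geom <- build_geometry(raw$geometry)
  beam <- build_beam_data(raw$beam_data)
  cal <- build_calibration(raw$calibration)
  opts <- build_options(raw$options)
  structure(list(geometry = geom, beam_data = beam, calibration = cal,
                 options = opts, source = path),
            class = "pfx_machine")
}

#' Path to the default machine-definition file
#' @return file path of the YAML machine definition shipped with the package.
#' @export
default_machine_path <- function() {
  system.file("extdata", "machine_default.yaml", package = "pfxverify",
              mustWork = TRUE)
}

build_geometry <- function(g) {
  need <- c("sector_azimuths", "ring_polar_angles", "ring_occupancy",
            "ring_physical_distance")
  for (k in need) if (is.null(g[[k]])) stop("geometry is missing '", k, "'")
  az <- as.numeric(g$sector_azimuths)
  polar <- as.numeric(g$ring_polar_angles)
  occ <- as.integer(g$ring_occupancy)
  phys <- as.numeric(g$ring_physical_distance)
  if (length(az) != N_SECTORS) stop("expected ", N_SECTORS, " sector azimuths, got ", length(az))
  if (length(polar) != N_RINGS) stop("expected ", N_RINGS, " ring polar angles, got ", length(polar))
  if (length(occ) != N_RINGS || length(phys) != N_RINGS)
    stop("ring_occupancy and ring_physical_distance must have ", N_RINGS, " entries")
  if (sum(occ) != 24L)
    stop("ring_occupancy must sum to 24 sources per sector, got ", sum(occ))
  if (any(phys <= 0)) stop("physical source-to-focus distances must be positive")

  # lay the sources out: within each sector the ring occupancy is spread
  # symmetrically over the 45 degree wedge, identically for every sector,
  # so the full set is invariant under 45 degree rotations about the z axis
  rows <- vector("list", N_SECTORS * N_RINGS)
  k <- 0L
  for (s in seq_len(N_SECTORS)) {
    for (r in seq_len(N_RINGS)) {
      n <- occ[r]
      offs <- (seq_len(n) - (n + 1) / 2) * (45 / n)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sector_index = s, ring_index = r,
        azimuth_deg = az[s] + offs,
        polar_deg = polar[r],
        physical_distance = phys[r])
    }
  }
  src <- do.call(rbind, rows)
  dirs <- dir_from_angles(src$polar_deg, src$azimuth_deg)
  src$dx <- dirs[, 1]; src$dy <- dirs[, 2]; src$dz <- dirs[, 3]
  n_src <- nrow(src)
  if (n_src != N_SOURCES)
    stop("machine model must contain ", N_SOURCES, " sources, got ", n_src)
  bad <- abs(1 - sqrt(src$dx^2 + src$dy^2 + src$dz^2)) >= 1e-12
  if (any(bad)) stop("non-unit source direction produced (internal error)")
  list(sources = src, sector_azimuths = az, ring_polar_angles = polar,
       ring_occupancy = occ, ring_physical_distance = phys)
}

build_beam_data <- function(b) {
  if (is.null(b$output_factors)) stop("beam_data is missing 'output_factors'")
  of <- b$output_factors
  ofs <- vapply(COLLIMATOR_SIZES, function(s) {
    v <- of[[coll_key(s)]]
    if (is.null(v)) stop("output factor missing for collimator ", s, " mm")
    as.numeric(v)
  }, numeric(1))
  names(ofs) <- coll_key(COLLIMATOR_SIZES)
  if (ofs[["c16"]] != 1)
    stop("output factor of the 16 mm collimator must be exactly 1 (got ",
         ofs[["c16"]], "); all factors are normalized to it")
  if (any(ofs <= 0 | ofs > 1)) stop("output factors must lie in (0, 1]")

  if (is.null(b$vsfd)) stop("beam_data is missing 'vsfd'")
  vsfd <- matrix(NA_real_, length(COLLIMATOR_SIZES), N_RINGS,
                 dimnames = list(coll_key(COLLIMATOR_SIZES), NULL))
  for (s in COLLIMATOR_SIZES) {
    v <- as.numeric(b$vsfd[[coll_key(s)]])
    if (length(v) == 1) v <- rep(v, N_RINGS)
    if (length(v) != N_RINGS)
      stop("vsfd for collimator ", s, " mm must have 1 or ", N_RINGS, " values")
    vsfd[coll_key(s), ] <- v
  }
  if (any(!is.finite(vsfd)) || any(vsfd <= 0))
    stop("all virtual source-to-focus distances must be positive")

  if (is.null(b$oar_profiles)) stop("beam_data is missing 'oar_profiles'")
  oar <- vector("list", length(COLLIMATOR_SIZES))
  names(oar) <- coll_key(COLLIMATOR_SIZES)
  for (s in COLLIMATOR_SIZES) {
    p <- b$oar_profiles[[coll_key(s)]]
    if (is.null(p)) stop("OAR profile missing for collimator ", s, " mm")
    # either one table for all rings, or a list of per-ring tables
    if (!is.null(p$radius_mm)) {
      tab <- validate_oar_table(p, s)
      oar[[coll_key(s)]] <- rep(list(tab), N_RINGS)
    } else {
      if (length(p) != N_RINGS)
        stop("per-ring OAR profiles for collimator ", s, " mm must have ",
             N_RINGS, " tables")
      oar[[coll_key(s)]] <- lapply(p, validate_oar_table, size = s)
    }
  }
  list(output_factors = ofs, vsfd = vsfd, oar_profiles = oar)
}

validate_oar_table <- function(p, size) {
  r <- as.numeric(p$radius_mm)
  v <- as.numeric(p$oar)
  if (length(r) != length(v) || length(r) < 2)
    stop("OAR table for collimator ", size, " mm must pair >= 2 radii with ratios")
  if (any(diff(r) <= 0))
    stop("OAR table radii for collimator ", size, " mm must be strictly increasing")
  if (r[1] != 0 || v[1] != 1)
    stop("OAR table for collimator ", size, " mm must start at (0, 1)")
  if (any(diff(v) > 1e-12))
    stop("OAR table for collimator ", size, " mm must be non-increasing")
  if (any(v < 0)) stop("OAR values must be non-negative")
  list(radius_mm = r, oar = v)
}

build_calibration <- function(cal) {
  dose_rate <- if (is.null(cal$dose_rate_gy_min)) 3 else as.numeric(cal$dose_rate_gy_min)
  r_cal <- if (is.null(cal$r_cal_mm)) 80 else as.numeric(cal$r_cal_mm)
  mu <- if (is.null(cal$mu_per_mm)) 0.0065 else as.numeric(cal$mu_per_mm)
  if (!is.finite(dose_rate) || dose_rate <= 0)
    stop("calibration dose rate must be positive")
  if (!is.finite(mu) || mu <= 0)
    stop("linear attenuation coefficient mu must be positive, got ", mu)
  if (!is.finite(r_cal) || r_cal <= 0) stop("calibration depth must be positive")
  list(dose_rate = dose_rate, r_cal = r_cal, mu = mu)
}

# optional machine-file switches. ssd_convention selects how the
# source-to-surface distance entering the OAR divergence scaling is read:
# "entry" (default): SSD = vSFD - focus depth, a per-beam constant;
# "point-projection": SSD = vSFD - axial depth of the calculation point's
# projection, the alternative (per-point) reading.
build_options <- function(o) {
  conv <- if (is.null(o$ssd_convention)) "entry" else o$ssd_convention
  if (!conv %in% c("entry", "point-projection"))
    stop("ssd_convention must be 'entry' or 'point-projection', got '",
         conv, "'")
  list(ssd_convention = conv, ssd_per_point = conv == "point-projection")
}

#' @export
print.pfx_machine <- function(x, ...) {
  cat("Virtual Gamma Knife Perfexion machine model\n")
  cat(sprintf("  sources: %d (8 sectors x 5 rings, occupancy %s)\n",
              nrow(x$geometry$sources),
              paste(x$geometry$ring_occupancy, collapse = "/")))
  cat(sprintf("  output factors: 16mm=%.3g 8mm=%.3g 4mm=%.3g\n",
              x$beam_data$output_factors[["c16"]],
              x$beam_data$output_factors[["c8"]],
              x$beam_data$output_factors[["c4"]]))
  cat(sprintf("  calibration: %.4g Gy/min at %g mm depth, mu = %g /mm\n",
              x$calibration$dose_rate, x$calibration$r_cal, x$calibration$mu))
  invisible(x)
}

#' Beam axis of one source for a given shot
#'
#' Expresses a source's beam axis in frame coordinates for a shot at
#' \code{shot_position} with the given gamma (head-tilt) angle. The machine
#' frame is rotated about the frame's lateral (x) axis by
#' \code{gamma_angle - 90} degrees (90 degrees is the identity: head axis
#' aligned with the machine axis) and translated so the machine focus
#' coincides with the shot position.
#'
#' @param source one row of the machine source table (or any list with
#'   \code{dx, dy, dz, physical_distance}).
#' @param shot_position frame point (mm), length 3.
#' @param gamma_angle degrees, in (0, 180).
#' @return list with \code{origin} (source position, frame mm) and unit
#'   \code{direction} pointing from the source toward the focus.
#' @export
beam_axis <- function(source, shot_position, gamma_angle = 90) {
  stopifnot(length(shot_position) == 3, all(is.finite(shot_position)))
  if (!is.finite(gamma_angle) || gamma_angle <= 0 || gamma_angle >= 180)
    stop("gamma angle must lie in (0, 180) degrees, got ", gamma_angle)
  d <- c(source$dx, source$dy, source$dz)
  R <- rot_x(gamma_angle - 90)
  d_frame <- as.numeric(R %*% d)
  origin <- shot_position + source$physical_distance * d_frame
  list(origin = origin, direction = unitize(-d_frame))
}

# rotated source directions (n x 3) and origins for a whole shot at once
beam_axes_matrix <- function(sources, shot_position, gamma_angle) {
  R <- rot_x(gamma_angle - 90)
  d <- as.matrix(sources[, c("dx", "dy", "dz")]) %*% t(R)
  origins <- sweep(d * sources$physical_distance, 2, shot_position, "+")
  list(origins = origins, directions = -d)
}

# linear interpolation on an OAR table, clamped to the last value beyond it
oar_lookup <- function(table, r) {
  stats::approx(table$radius_mm, table$oar, xout = abs(r), rule = 2,
                ties = "ordered")$y
}
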