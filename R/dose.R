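# Point dose-rate model and its sums over sources, sectors and shots.
#
# The dose rate at a point P from one source is
#
#   (dD/dt)_i(P) = (dD/dt)_cal,16 * 1/192 * OF_c
#                  * exp(-mu * (d - df - R_cal))
#                  * (1 - df / vSFD_i)^-2
#                  * OAR(OAD_f / (1 - df / SSD_i))
#
# where d is the focus depth along the beam axis, df the signed axial
# offset of P from the focus, R_cal the calibration depth, vSFD_i the
# (collimator, ring)-specific virtual source-to-focus distance, OAD_f the
# off-axis distance of P at the focus depth, and SSD_i the virtual
# source-to-surface distance. The off-axis ratio argument is the
# divergence-scaled off-axis distance.

# scale at which 1 - df/ssd is considered degenerate (point at the
# virtual source); clamped for numerical safety in grid sweeps
DIVERGENCE_EPS <- 1e-9

# vectorized kernel over points; df, oad_f vectors, the rest scalars
source_rate_kernel <- function(df, oad_f, depth_focus, ssd, vsfd, of,
                               oar_table, cal, clamp_divergence = TRUE) {
  atten <- exp(-cal$mu * (depth_focus - df - cal$r_cal))
  invsq <- (1 - df / vsfd)^(-2)
  div <- 1 - df / ssd
  if (clamp_divergence) {
    div <- pmax(div, DIVERGENCE_EPS)
  } else if (any(div <= 0)) {
    stop("calculation point lies at or beyond the virtual source ",
         "(1 - df/SSD <= 0): geometrically invalid")
  }
  oar <- oar_lookup(oar_table, oad_f / div)
  cal$dose_rate / N_SOURCES * of * atten * invsq * oar
}

#' Dose rate at a point from a single source
#'
#' Evaluates the per-source dose-rate model for one source of a shot. The
#' sector of the source selects the collimator size (hence output factor,
#' vSFD and OAR profile, together with the source's ring).
#'
#' @param P calculation point (frame mm).
#' @param source one row of the machine source table.
#' @param shot a \code{pfx_shot}.
#' @param surface a \code{pfx_skull_surface}.
#' @param machine a \code{pfx_machine}.
#' @return dose rate in Gy/min.
#' @export
source_dose_rate <- function(P, source, shot, surface, machine) {
  state <- shot$sector_states[source$sector_index]
  if (state == "blocked")
    stop("source ", source$sector_index, "/", source$ring_index,
         " sits in a blocked sector; callers must skip blocked sectors")
  size <- as.integer(state)
  ray <- beam_axis(source, shot$position, shot$gamma_angle)
  trace <- trace_beam(surface, ray, shot$position)
  vsfd <- unname(machine$beam_data$vsfd[coll_key(size), source$ring_index])
  proj <- project_point(P, ray, trace, vsfd)
  ssd <- if (isTRUE(machine$options$ssd_per_point))
    vsfd - (trace$depth_focus - proj$df) else proj$ssd
  source_rate_kernel(proj$df, proj$oad_f, trace$depth_focus, ssd, vsfd,
                     machine$beam_data$output_factors[[coll_key(size)]],
                     machine$beam_data$oar_profiles[[coll_key(size)]][[source$ring_index]],
                     machine$calibration, clamp_divergence = FALSE)
}

# Trace all 192 beams of a shot once; returns a per-source table reused for
# every calculation point. Beams in blocked sectors are dropped; beams that
# enter through no tissue degrade to zero contribution with a warning.
shot_traces <- function(shot, surface, machine) {
  src <- machine$geometry$sources
  axes <- beam_axes_matrix(src, shot$position, shot$gamma_angle)
  states <- shot$sector_states[src$sector_index]
  keep <- which(states != "blocked")
  if (length(keep) == 0) {
    warning("all sectors blocked: shot contributes no dose")
    return(NULL)
  }
  out <- vector("list", length(keep))
  n_missed <- 0L
  for (j in seq_along(keep)) {
    i <- keep[j]
    ray <- list(origin = axes$origins[i, ], direction = axes$directions[i, ])
    tr <- tryCatch(trace_beam(surface, ray, shot$position),
                   error = function(e) NULL)
    if (is.null(tr)) { n_missed <- n_missed + 1L; next }
    size <- as.integer(states[i])
    out[[j]] <- list(ray = ray, trace = tr, size = size,
                     ring = src$ring_index[i],
                     vsfd = unname(machine$beam_data$vsfd[coll_key(size), src$ring_index[i]]),
                     of = machine$beam_data$output_factors[[coll_key(size)]],
                     oar = machine$beam_data$oar_profiles[[coll_key(size)]][[src$ring_index[i]]])
  }
  if (n_missed > 0)
    warning(n_missed, " beam(s) enter through no tissue; ",
            "their contribution is taken as zero")
  out[!vapply(out, is.null, logical(1))]
}

# sum the kernel over pre-computed traces for an n x 3 matrix of points
sum_traces_at <- function(P, traces, cal, ssd_per_point = FALSE) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  total <- numeric(nrow(P))
  for (tb in traces) {
    proj <- project_point(P, tb$ray, tb$trace, tb$vsfd)
    ssd <- if (ssd_per_point) tb$vsfd - (tb$trace$depth_focus - proj$df)
           else proj$ssd
    total <- total + source_rate_kernel(proj$df, proj$oad_f,
                                        tb$trace$depth_focus, ssd,
                                        tb$vsfd, tb$of, tb$oar, cal)
  }
  total
}

#' Dose rate at a point from one shot
#'
#' Sums the per-source dose rate over all sources in non-blocked sectors.
#' Blocked sectors contribute zero; beams that do not pass through tissue
#' before the focus contribute zero with a warning.
#'
#' @param P calculation point (frame mm), length 3 or n x 3 matrix.
#' @param shot a \code{pfx_shot}.
#' @param surface a \code{pfx_skull_surface}.
#' @param machine a \code{pfx_machine}.
#' @return dose rate in Gy/min (vector when P is a matrix).
#' @export
shot_dose_rate <- function(P, shot, surface, machine) {
  traces <- shot_traces(shot, surface, machine)
  if (is.null(traces)) {
    n <- if (is.null(dim(P))) 1L else nrow(P)
    return(numeric(n))
  }
  sum_traces_at(P, traces, machine$calibration,
                isTRUE(machine$options$ssd_per_point))
}

#' Irradiation time needed to deliver a dose
#'
#' @param dose dose to deliver (Gy).
#' @param dose_rate dose rate at the point of interest (Gy/min).
#' @return time in minutes, \code{dose / dose_rate}.
#' @export
shot_time <- function(dose, dose_rate) {
  if (any(dose_rate <= 0)) stop("dose rate must be positive")
  dose / dose_rate
}

# resolve shot durations: explicit durations win; otherwise convert weights
# using duration = weight * prescription dose / focus dose rate
resolve_durations <- function(plan, surface, machine) {
  vapply(plan$shots, function(sh) {
    if (!is.null(sh$duration)) return(sh$duration)
    if (is.null(sh$weight))
      stop("shot ", sh$id, " has neither a duration nor a weight")
    rate <- shot_dose_rate(sh$position, sh, surface, machine)
    shot_time(sh$weight * plan$prescription$dose_gy, rate)
  }, numeric(1))
}

#' Compute the 3D dose grid of a plan
#'
#' Evaluates the total dose (Gy) of all shots on the plan's grid. Per-shot
#' beam traces are computed once (192 per shot) and reused for every
#' voxel. Shots with explicit durations use them; otherwise durations are
#' derived from shot weights via the prescription.
#'
#' @param plan a \code{pfx_plan}.
#' @param surface a \code{pfx_skull_surface}.
#' @param machine a \code{pfx_machine}.
#' @return object of class \code{pfx_dose_grid}: 3D \code{values} array
#'   (Gy), \code{origin} (mm), \code{spacing} (mm), \code{dims}.
#' @export
compute_dose_grid <- function(plan, surface, machine) {
  gs <- plan$grid_spec
  ax <- lapply(1:3, function(k) gs$origin[k] + gs$spacing[k] * (seq_len(gs$dims[k]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  durations <- resolve_durations(plan, surface, machine)
  dose <- numeric(nrow(pts))
  for (i in seq_along(plan$shots)) {
    traces <- shot_traces(plan$shots[[i]], surface, machine)
    if (is.null(traces)) next
    dose <- dose + durations[i] *
      sum_traces_at(pts, traces, machine$calibration,
                    isTRUE(machine$options$ssd_per_point))
  }
  if (any(!is.finite(dose))) {
    bad <- which(!is.finite(dose))[1]
    stop("non-finite dose at voxel with linear index ", bad,
         " (frame position ", paste(round(pts[bad, ], 2), collapse = ", "), ")")
  }
  structure(list(values = array(dose, dim = gs$dims), origin = gs$origin,
                 spacing = gs$spacing, dims = gs$dims),
            class = "pfx_dose_grid")
}

#' Frame coordinates of a voxel index
#' @param grid a \code{pfx_dose_grid}.
#' @param idx integer voxel index, length 3 (1-based).
#' @return frame point (mm).
#' @export
voxel_center <- function(grid, idx) {
  grid$origin + grid$spacing * (idx - 1)
}

#' @export
print.pfx_dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$dims, collapse = "x"),
              paste(x$spacing, collapse = ", "),
              paste(x$origin, collapse = ", ")))
  cat(sprintf("  dose range %.4g - %.4g Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Write a dose grid as a detached-header NRRD file
#'
#' Writes an ASCII-encoded NRRD (text, single file) recording the grid
#' origin and spacing in the header.
#'
#' @param grid a \code{pfx_dose_grid}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_nrrd <- function(grid, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# dose grid (Gy), frame coordinates in mm",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %s", paste(grid$dims, collapse = " ")),
           "space: right-anterior-superior",
           sprintf("space origin: (%.10g,%.10g,%.10g)", grid$origin[1],
                   grid$origin[2], grid$origin[3]),
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   grid$spacing[1], grid$spacing[2], grid$spacing[3]),
           "encoding: ascii",
           "")
  writeLines(hdr, con)
  writeLines(format(as.numeric(grid$values), digits = 17, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' Read a dose grid written by \code{write_nrrd}
#' @param path NRRD file path.
#' @return a \code{pfx_dose_grid}.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header")
  hdr <- lines[seq_len(blank - 1)]
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) == 0) stop("NRRD header missing field '", key, "'")
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (get_field("encoding") != "ascii") stop("only ascii encoding is supported")
  dims <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  origin <- as.numeric(strsplit(gsub("[()]", "", get_field("space origin")), ",")[[1]])
  sd <- get_field("space directions")
  nums <- regmatches(sd, gregexpr("-?[0-9.]+(e[-+]?[0-9]+)?", sd))[[1]]
  m <- matrix(as.numeric(nums), 3, 3, byrow = TRUE)
  spacing <- diag(m)
  vals <- as.numeric(lines[(blank + 1):length(lines)])
  structure(list(values = array(vals, dim = dims), origin = origin,
                 spacing = spacing, dims = dims),
            class = "pfx_dose_grid")
}

#' Dump a dose grid as CSV voxel rows
#'
#' One row per voxel: \code{i,j,k,x_mm,y_mm,z_mm,dose_gy}.
#'
#' @param grid a \code{pfx_dose_grid}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  idx <- expand.grid(i = seq_len(grid$dims[1]), j = seq_len(grid$dims[2]),
                     k = seq_len(grid$dims[3]), KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(idx,
                   x_mm = grid$origin[1] + grid$spacing[1] * (idx$i - 1),
                   y_mm = grid$origin[2] + grid$spacing[2] * (idx$j - 1),
                   z_mm = grid$origin[3] + grid$spacing[3] * (idx$k - 1),
                   dose_gy = as.numeric(grid$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
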