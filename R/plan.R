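# Treatment plan containers and their structured-text (YAML) round-trip.
# Plan files carry sections patient / prescription / grid / shots; scaler
# measurements may be embedded or supplied as a separate two-column table.

#' Construct a shot
#'
#' @param position frame point (mm), length 3.
#' @param gamma_angle head-tilt angle (degrees), default 90.
#' @param sector_states character vector of length 8, each one of
#'   \code{"16"}, \code{"8"}, \code{"4"} or \code{"blocked"}.
#' @param duration minutes (optional if \code{weight} is given).
#' @param weight dimensionless shot weight (optional).
#' @param id shot identifier.
#' @return object of class \code{pfx_shot}.
#' @export
shot <- function(position, gamma_angle = 90,
                 sector_states = rep("16", 8),
                 duration = NULL, weight = NULL, id = NULL) {
  stopifnot(length(position) == 3, all(is.finite(position)))
  sector_states <- as.character(sector_states)
  if (length(sector_states) != 8)
    stop("a shot needs exactly 8 sector states, got ", length(sector_states))
  bad <- !sector_states %in% c("16", "8", "4", "blocked")
  if (any(bad))
    stop("invalid sector state(s): ", paste(sector_states[bad], collapse = ", "))
  if (!is.null(duration) && duration < 0) stop("shot duration must be >= 0")
  if (is.null(duration) && is.null(weight))
    stop("a shot needs a duration or a weight")
  structure(list(id = id, position = as.numeric(position),
                 gamma_angle = gamma_angle, sector_states = sector_states,
                 duration = duration, weight = weight),
            class = "pfx_shot")
}

#' Construct a plan
#'
#' @param shots list of \code{pfx_shot}.
#' @param prescription list with \code{dose_gy} and \code{isodose_pct}
#'   (prescription dose and the relative isodose level it is given to).
#' @param grid_spec list with \code{origin} (mm), \code{spacing} (mm per
#'   axis), \code{dims} (voxels per axis).
#' @param identifier plan identifier string.
#' @return object of class \code{pfx_plan}.
#' @export
plan <- function(shots, prescription = list(dose_gy = 20, isodose_pct = 50),
                 grid_spec = NULL, identifier = "plan") {
  if (length(shots) < 1) stop("a plan needs at least one shot")
  stopifnot(all(vapply(shots, inherits, logical(1), "pfx_shot")))
  for (i in seq_along(shots))
    if (is.null(shots[[i]]$id)) shots[[i]]$id <- sprintf("shot-%02d", i)
  ids <- vapply(shots, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate shot ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (is.null(grid_spec)) {
    ctr <- rowMeans(vapply(shots, `[[`, numeric(3), "position"))
    grid_spec <- list(origin = ctr - 25, spacing = c(2, 2, 2),
                      dims = c(26L, 26L, 26L))
  }
  grid_spec$origin <- as.numeric(grid_spec$origin)
  grid_spec$spacing <- as.numeric(grid_spec$spacing)
  grid_spec$dims <- as.integer(grid_spec$dims)
  if (any(grid_spec$spacing <= 0)) stop("grid spacing must be positive")
  if (any(grid_spec$dims < 1)) stop("grid dims must be >= 1")
  structure(list(identifier = identifier, shots = shots,
                 prescription = prescription, grid_spec = grid_spec),
            class = "pfx_plan")
}

#' @export
print.pfx_plan <- function(x, ...) {
  cat(sprintf("Plan '%s': %d shot(s), %g Gy to the %g%% isodose\n",
              x$identifier, length(x$shots), x$prescription$dose_gy,
              x$prescription$isodose_pct))
  for (sh in x$shots)
    cat(sprintf("  %s at (%.1f, %.1f, %.1f) gamma %g [%s]%s\n", sh$id,
                sh$position[1], sh$position[2], sh$position[3],
                sh$gamma_angle, paste(sh$sector_states, collapse = ","),
                if (!is.null(sh$duration)) sprintf(" %.3f min", sh$duration)
                else sprintf(" w=%.3f", sh$weight)))
  invisible(x)
}

#' Write a plan to a YAML file
#'
#' Doubles are written with 17 significant digits so that a written plan
#' reads back bit-identically.
#'
#' @param plan a \code{pfx_plan}.
#' @param path output path.
#' @param measurements optional \code{pfx_scaler_measurements} to embed.
#' @return the path, invisibly.
#' @export
write_plan <- function(plan, path, measurements = NULL) {
  stopifnot(inherits(plan, "pfx_plan"))
  doc <- list(
    schema = "pfx-plan/1",
    patient = list(identifier = plan$identifier),
    prescription = plan$prescription,
    grid = list(origin = plan$grid_spec$origin,
                spacing = plan$grid_spec$spacing,
                dims = plan$grid_spec$dims),
    shots = lapply(plan$shots, function(sh) {
      out <- list(id = sh$id, position = sh$position,
                  gamma_angle = sh$gamma_angle,
                  sector_states = as.list(sh$sector_states))
      if (!is.null(sh$duration)) out$duration_min <- sh$duration
      if (!is.null(sh$weight)) out$weight <- sh$weight
      out
    }))
  if (!is.null(measurements)) {
    d <- measurements$directions
    doc$skull_scaler <- list(
      center = measurements$center,
      directions = lapply(seq_len(nrow(d)), function(i) as.numeric(d[i, ])),
      radii_mm = measurements$radii)
  }
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' Read a plan from a YAML file
#'
#' @param path plan file path.
#' @return a \code{pfx_plan}; if the file embeds skull-scaler
#'   measurements they are attached as attribute \code{"measurements"}.
#' @export
read_plan <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$shots) || length(doc$shots) == 0)
    stop("plan file has no shots")
  shots <- lapply(doc$shots, function(s) {
    shot(position = as.numeric(s$position),
         gamma_angle = as.numeric(s$gamma_angle),
         sector_states = unlist(s$sector_states),
         duration = if (!is.null(s$duration_min)) as.numeric(s$duration_min),
         weight = if (!is.null(s$weight)) as.numeric(s$weight),
         id = s$id)
  })
  pl <- plan(shots,
             prescription = list(dose_gy = as.numeric(doc$prescription$dose_gy),
                                 isodose_pct = as.numeric(doc$prescription$isodose_pct)),
             grid_spec = list(origin = as.numeric(doc$grid$origin),
                              spacing = as.numeric(doc$grid$spacing),
                              dims = as.integer(doc$grid$dims)),
             identifier = doc$patient$identifier)
  if (!is.null(doc$skull_scaler)) {
    sc <- doc$skull_scaler
    dirs <- do.call(rbind, lapply(sc$directions, as.numeric))
    attr(pl, "measurements") <- scaler_measurements(dirs,
                                                    as.numeric(sc$radii_mm),
                                                    as.numeric(sc$center))
  }
  pl
}

#' Read scaler measurements from a two-column angle table
#'
#' Whitespace/comma separated text with a header row
#' \code{polar_deg azimuth_deg radius_mm}: direction given as polar angle
#' from the frame +z axis and azimuth from +x, degrees; radius in mm.
#'
#' @param path table path.
#' @param center scaler centre (frame mm).
#' @return a \code{pfx_scaler_measurements}.
#' @export
read_scaler_table <- function(path, center = FRAME_CENTER) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#")
  need <- c("polar_deg", "azimuth_deg", "radius_mm")
  if (!all(need %in% names(df)))
    stop("scaler table needs columns: ", paste(need, collapse = ", "))
  dirs <- dir_from_angles(df$polar_deg, df$azimuth_deg)
  scaler_measurements(dirs, df$radius_mm, center)
}

#' Write scaler measurements as a two-column angle table
#' @param measurements a \code{pfx_scaler_measurements}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scaler_table <- function(measurements, path) {
  d <- measurements$directions
  df <- data.frame(
    polar_deg = acos(pmin(1, pmax(-1, d[, 3]))) * 180 / pi,
    azimuth_deg = atan2(d[, 2], d[, 1]) * 180 / pi,
    radius_mm = measurements$radii)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
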