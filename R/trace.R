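# Per-beam tissue depths and per-point projections feeding the dose model.
#
# Each source contributes one beam axis per shot. The beam is traced once
# through the skull surface along the source-to-focus axis; off-axis
# calculation points are handled purely by orthogonal projection onto that
# axis (no second surface trace).

#' Trace one beam through the skull surface
#'
#' @param surface a \code{pfx_skull_surface}.
#' @param ray list with \code{origin} and unit \code{direction}
#'   (source toward focus), e.g. from \code{\link{beam_axis}}.
#' @param focus shot focus position (frame mm); must lie inside the
#'   surface and on the ray.
#' @return list of class \code{pfx_beam_trace}: \code{entry_point} (frame
#'   mm, on the skull surface), \code{t_entry} and \code{t_focus} (mm ray
#'   parameters from the source), \code{depth_focus} (mm of tissue from
#'   entry to focus along the axis).
#' @export
trace_beam <- function(surface, ray, focus) {
  entry <- ray_entry(surface, ray)
  t_focus <- sum((focus - ray$origin) * ray$direction)
  if (is.null(entry) || entry$t >= t_focus)
    stop("beam does not intersect the skull surface before the focus ",
         "(beam enters through no tissue)")
  structure(list(entry_point = entry$point, t_entry = entry$t,
                 t_focus = t_focus, depth_focus = t_focus - entry$t),
            class = "pfx_beam_trace")
}

#' Project a calculation point onto a beam axis
#'
#' Computes the quantities of the point dose-rate model for an arbitrary
#' calculation point P relative to one traced beam:
#' \itemize{
#'   \item \code{df}: signed difference between the focus depth and the
#'     axial depth of P's orthogonal projection onto the beam axis;
#'     positive when P projects proximal to the focus (shallower, nearer
#'     the source).
#'   \item \code{oad_f}: perpendicular (off-axis) distance from P to the
#'     beam axis, mm.
#'   \item \code{ssd}: source-to-surface distance of this beam, the
#'     distance from the virtual source to the skull entry point along the
#'     axis, \code{vsfd - depth_focus} (a per-beam constant).
#' }
#'
#' @param P calculation point (frame mm), length 3 or n x 3 matrix.
#' @param ray the beam axis used for \code{trace}.
#' @param trace a \code{pfx_beam_trace} for this ray.
#' @param vsfd virtual source-to-focus distance of this beam (mm).
#' @return list with \code{df}, \code{oad_f}, \code{ssd} (vectors when P
#'   is a matrix).
#' @export
project_point <- function(P, ray, trace, vsfd) {
  stopifnot(inherits(trace, "pfx_beam_trace"), vsfd > 0)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  rel <- sweep(P, 2, ray$origin)
  t_P <- as.numeric(rel %*% ray$direction)
  df <- trace$t_focus - t_P
  perp <- rel - outer(t_P, ray$direction)
  oad_f <- sqrt(rowSums(perp^2))
  list(df = df, oad_f = oad_f, ssd = vsfd - trace$depth_focus)
}
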