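# Skull-surface reconstruction from skull-scaler measurements.
#
# The scaler yields radial distances from the instrument centre along a set
# of directions. The surface is represented as a real spherical-harmonic
# expansion r(theta, phi) fitted by least squares, giving a smooth, closed,
# star-shaped surface that can be queried for radii and ray intersections.

#' Construct a skull-scaler measurement set
#'
#' @param directions n x 3 matrix of unit vectors from the scaler centre.
#' @param radii measured radial distances (mm), one per direction.
#' @param center frame point (mm) of the scaler instrument centre.
#' @return object of class \code{pfx_scaler_measurements}.
#' @export
scaler_measurements <- function(directions, radii,
                                center = FRAME_CENTER) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, length(radii) == nrow(directions),
            length(center) == 3)
  if (nrow(directions) < 6)
    stop("at least 6 scaler measurements are required, got ", nrow(directions))
  if (any(radii <= 0)) stop("all scaler radii must be positive")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("measurement directions must be unit vectors")
  structure(list(directions = directions, radii = as.numeric(radii),
                 center = as.numeric(center)),
            class = "pfx_scaler_measurements")
}

# Real spherical-harmonic design matrix for unit directions (n x 3).
# Orthonormal real basis; Condon-Shortley phase cancelled so that
# the m = 0, l = 0 column is the constant 1/sqrt(4 pi).
sh_basis <- function(directions, degree, even_only = FALSE) {
  n <- nrow(directions)
  z <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  degrees <- if (even_only) seq(0, degree, by = 2) else 0:degree
  cols <- list()
  labels <- character(0)
  for (l in degrees) {
    P <- pracma::legendre(l, z)           # (l+1) x n, orders m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in 0:l) {
      nf <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      pl <- P[m + 1, ] * (-1)^m           # undo Condon-Shortley phase
      if (m == 0) {
        cols[[length(cols) + 1]] <- nf * pl
        labels <- c(labels, sprintf("Y%d_0", l))
      } else {
        cols[[length(cols) + 1]] <- sqrt(2) * nf * pl * cos(m * phi)
        cols[[length(cols) + 1]] <- sqrt(2) * nf * pl * sin(m * phi)
        labels <- c(labels, sprintf("Y%d_%dc", l, m), sprintf("Y%d_%ds", l, m))
      }
    }
  }
  A <- do.call(cbind, cols)
  colnames(A) <- labels
  A
}

#' Fit a skull surface to scaler measurements
#'
#' Least-squares expansion of the measured radius over direction in real
#' spherical harmonics up to the given degree. The fitted surface is
#' checked for positivity on a dense direction grid; a surface that dips
#' to a non-positive radius anywhere is rejected as implausible.
#'
#' @param measurements a \code{pfx_scaler_measurements} object.
#' @param degree maximum spherical-harmonic degree (default 4).
#' @param even_only use only even degrees (enforces antipodal symmetry).
#' @return object of class \code{pfx_skull_surface} with the coefficient
#'   vector, per-measurement \code{fit_residuals} (mm) and the centre.
#' @export
#' @examples
#' m <- make_scaler_measurements(phantom_spec("sphere", 80))
#' s <- fit_skull(m, degree = 2)
#' radius_at(s, c(0, 0, 1))  # 80
fit_skull <- function(measurements, degree = 4, even_only = FALSE) {
  stopifnot(inherits(measurements, "pfx_scaler_measurements"))
  A <- sh_basis(measurements$directions, degree, even_only)
  n_coef <- ncol(A)
  n_meas <- nrow(A)
  if (n_meas < n_coef)
    stop("underdetermined fit: degree ", degree, " needs at least ", n_coef,
         " measurements, got ", n_meas)
  qr_A <- qr(A)
  if (qr_A$rank < n_coef)
    stop("measurement directions are degenerate: design matrix rank ",
         qr_A$rank, " < ", n_coef, " coefficients")
  coef <- qr.coef(qr_A, measurements$radii)
  resid <- measurements$radii - as.numeric(A %*% coef)
  surf <- structure(list(coef = coef, degree = degree, even_only = even_only,
                         center = measurements$center, fit_residuals = resid),
                    class = "pfx_skull_surface")
  probe <- rbind(fibonacci_directions(800), measurements$directions)
  if (any(radius_at(surf, probe) <= 0))
    stop("fitted surface has non-positive radius in some direction; ",
         "the measurement set does not define a plausible closed surface")
  surf
}

#' Evaluate a surface's radial function
#'
#' @param surface a \code{pfx_skull_surface} (spherical-harmonic fit) or a
#'   \code{pfx_phantom_surface} (exact analytic phantom).
#' @param direction unit vector (length 3) or n x 3 matrix of unit vectors.
#' @return radius (mm) about the surface centre, one value per direction.
#' @export
radius_at <- function(surface, direction) UseMethod("radius_at")

#' @export
radius_at.pfx_skull_surface <- function(surface, direction) {
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  A <- sh_basis(direction, surface$degree, surface$even_only)
  as.numeric(A %*% surface$coef)
}

#' @export
print.pfx_skull_surface <- function(x, ...) {
  cat(sprintf("Skull surface: spherical-harmonic fit, degree %d%s\n",
              x$degree, if (x$even_only) " (even only)" else ""))
  cat(sprintf("  centre (%g, %g, %g) mm, rms residual %.4g mm\n",
              x$center[1], x$center[2], x$center[3],
              sqrt(mean(x$fit_residuals^2))))
  invisible(x)
}

# signed "outside" function along a ray: positive outside the surface
surface_gap <- function(surface, pts) {
  rel <- sweep(pts, 2, surface$center)
  d <- sqrt(rowSums(rel^2))
  dirs <- rel / pmax(d, 1e-12)
  small <- d < 1e-9   # at the centre any direction gives a point inside
  if (any(small)) dirs[small, ] <- rep(c(0, 0, 1), each = sum(small))
  d - radius_at(surface, dirs)
}

#' First entry point of a ray into the skull surface
#'
#' Marches along the ray in fixed steps to bracket the first outside-to-
#' inside crossing of the surface, then refines the crossing by root
#' finding. The surface is star-shaped about the scaler centre, so the
#' crossing is a sign change of (distance from centre - fitted radius).
#'
#' @param surface a \code{pfx_skull_surface}.
#' @param ray list with \code{origin} (frame mm) and unit \code{direction}.
#' @param step bracketing step (mm).
#' @param tol positional tolerance of the refined crossing (mm).
#' @param max_range how far to march (mm); default covers any cranial setup.
#' @return list with \code{point} (frame mm) and ray parameter \code{t}
#'   (mm from the ray origin), or \code{NULL} if the ray never enters.
#'   Errors if the ray origin is already inside the surface.
#' @export
ray_entry <- function(surface, ray, step = 2, tol = 1e-9, max_range = 600) {
  stopifnot(!is.null(surface$center))
  o <- ray$origin
  u <- ray$direction
  if (abs(vnorm(u) - 1) > 1e-9) stop("ray direction must be a unit vector")
  ts <- seq(0, max_range, by = step)
  pts <- cbind(o[1] + ts * u[1], o[2] + ts * u[2], o[3] + ts * u[3])
  g <- surface_gap(surface, pts)
  if (g[1] <= 0)
    stop("ray origin lies inside the skull surface; sources must be external")
  below <- which(g <= 0)
  if (length(below) == 0) return(NULL)
  i <- below[1]
  f <- function(t) surface_gap(surface, matrix(o + t * u, ncol = 3))
  root <- stats::uniroot(f, lower = ts[i - 1], upper = ts[i],
                         f.lower = g[i - 1], f.upper = g[i],
                         tol = tol)$root
  list(point = o + root * u, t = root)
}
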