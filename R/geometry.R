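# Small 3-vector helpers shared across the package. Points are length-3
# numeric vectors (or n x 3 matrices) in Leksell-style frame coordinates,
# millimetres, right-handed, frame centre at (100, 100, 100):
# x lateral, y anterior-posterior, z superior-inferior.

FRAME_CENTER <- c(100, 100, 100)

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about the frame lateral (x) axis
#'
#' @param angle_deg rotation angle in degrees (right-handed about +x).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' Rotation matrix about the machine (z) axis
#' @param angle_deg rotation angle in degrees (right-handed about +z).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

# direction (n x 3) from polar angle (from +z) and azimuth, degrees
dir_from_angles <- function(polar_deg, azimuth_deg) {
  th <- polar_deg * pi / 180
  ph <- azimuth_deg * pi / 180
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# quasi-uniform directions on the sphere (Fibonacci spiral); n x 3 matrix
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
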