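# Shared fixtures, built once per test run. Everything is generated in
# code; the only file input is the machine definition shipped with the
# package.

.fx <- new.env(parent = emptyenv())

default_machine <- function() {
  if (is.null(.fx$machine)) .fx$machine <- load_machine()
  .fx$machine
}

# degree-2 fit of an exact sphere phantom (cached per radius)
sphere_surface <- function(radius = 80, n_directions = 24, seed = 1) {
  key <- sprintf("sph-%g-%d-%d", radius, n_directions, seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- fit_skull(make_scaler_measurements(
      phantom_spec("sphere", radius, n_directions = n_directions,
                   seed = seed)), degree = 2)
  .fx[[key]]
}

ellipsoid_spec <- function(n_directions = 60, seed = 2)
  phantom_spec("ellipsoid", c(90, 75, 80), n_directions = n_directions,
               seed = seed)

ellipsoid_surface <- function() {
  if (is.null(.fx$ell)) .fx$ell <- fit_skull(
    make_scaler_measurements(ellipsoid_spec()), degree = 4)
  .fx$ell
}

centered_shot <- function(states = rep("16", 8), gamma = 90, duration = 1)
  shot(c(100, 100, 100), gamma_angle = gamma, sector_states = states,
       duration = duration)

frame_center <- c(100, 100, 100)

# write a modified copy of the default machine YAML and load it
load_modified_machine <- function(modify) {
  doc <- yaml::read_yaml(default_machine_path())
  doc <- modify(doc)
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  path
}

# analytic smallest positive root of the ray-ellipsoid (or sphere)
# quadratic |diag(1/ax) (o + t u - c)|^2 = 1
ray_quadric_entry <- function(origin, direction, center, semi_axes) {
  if (length(semi_axes) == 1) semi_axes <- rep(semi_axes, 3)
  o <- (origin - center) / semi_axes
  u <- direction / semi_axes
  a <- sum(u^2); b <- 2 * sum(o * u); cc <- sum(o^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  pos <- roots[roots > 0]
  if (length(pos) == 0) NULL else pos[1]
}
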