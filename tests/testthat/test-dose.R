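test_that("the per-source rate reduces to rate/192 in the calibration condition", {
  mach <- default_machine()
  s <- sphere_surface(80)
  sh <- centered_shot()
  for (i in c(1, 40, 96, 150, 192)) {
    src <- mach$geometry$sources[i, ]
    r <- source_dose_rate(frame_center, src, sh, s, mach)
    expect_equal(r, mach$calibration$dose_rate / 192, tolerance = 1e-9)
  }
})

test_that("phantom size changes the focus rate by pure attenuation", {
  mach <- default_machine()
  sh <- centered_shot()
  r80 <- shot_dose_rate(frame_center, sh, sphere_surface(80), mach)
  r90 <- shot_dose_rate(frame_center, sh, sphere_surface(90), mach)
  expect_equal(r90 / r80, exp(-0.0065 * 10), tolerance = 1e-9)
})

test_that("focus rate ratios across collimator sizes equal the output factors exactly", {
  mach <- default_machine()
  s <- sphere_surface(80)
  r16 <- shot_dose_rate(frame_center, centered_shot(rep("16", 8)), s, mach)
  r8 <- shot_dose_rate(frame_center, centered_shot(rep("8", 8)), s, mach)
  r4 <- shot_dose_rate(frame_center, centered_shot(rep("4", 8)), s, mach)
  expect_equal(r4 / r16, 0.81, tolerance = 1e-12)
  expect_equal(r8 / r16, 0.92, tolerance = 1e-12)
})

test_that("blocked sectors contribute nothing", {
  mach <- default_machine()
  s <- sphere_surface(80)
  all_blocked <- centered_shot(rep("blocked", 8))
  expect_warning(r0 <- shot_dose_rate(frame_center, all_blocked, s, mach),
                 "blocked")
  expect_identical(r0, 0)
  one_blocked <- centered_shot(c("blocked", rep("16", 7)))
  r <- shot_dose_rate(frame_center, one_blocked, s, mach)
  expect_equal(r, 7 / 8 * mach$calibration$dose_rate, tolerance = 1e-9)
  src_blocked <- mach$geometry$sources[1, ]  # sector 1
  expect_error(source_dose_rate(frame_center, src_blocked, one_blocked,
                                s, mach), "blocked")
})

test_that("calibration closure holds for any phantom radius matching r_cal", {
  for (R in c(70, 95)) {
    path <- load_modified_machine(function(doc) {
      doc$calibration$r_cal_mm <- R
      doc
    })
    mach <- load_machine(path)
    s <- sphere_surface(R)
    r <- shot_dose_rate(frame_center, centered_shot(), s, mach)
    expect_equal(r, mach$calibration$dose_rate, tolerance = 1e-9)
  }
})

test_that("log focus rate is linear in phantom radius with slope -mu", {
  mach <- default_machine()
  sh <- centered_shot()
  radii <- seq(60, 100, by = 10)
  lr <- vapply(radii, function(R)
    log(shot_dose_rate(frame_center, sh, sphere_surface(R), mach)),
    numeric(1))
  fit <- stats::lm(lr ~ radii)
  expect_equal(unname(stats::coef(fit)[2]), -mach$calibration$mu,
               tolerance = 1e-8)
  expect_lt(max(abs(stats::resid(fit))), 1e-10)
})

test_that("shot time is dose over rate and linear in both", {
  expect_identical(shot_time(4, 2), 2)
  expect_identical(shot_time(0, 2), 0)
  expect_identical(shot_time(4, 2) / shot_time(4, 4), 2)
  expect_error(shot_time(4, 0), "positive")
  expect_error(shot_time(4, -1), "positive")
})

test_that("a centred calibration shot delivers the prescription to the focus voxel", {
  mach <- default_machine()
  s <- sphere_surface(80)
  rx <- 20
  duration <- rx / mach$calibration$dose_rate
  sh <- centered_shot(duration = duration)
  pl <- plan(list(sh),
             prescription = list(dose_gy = rx, isodose_pct = 50),
             grid_spec = list(origin = frame_center - 8,
                              spacing = c(2, 2, 2), dims = c(9L, 9L, 9L)))
  g <- compute_dose_grid(pl, s, mach)
  focus_voxel <- g$values[5, 5, 5]
  expect_equal(focus_voxel, rx, tolerance = 1e-9)
  expect_true(all(is.finite(g$values)) && all(g$values >= 0))
})

test_that("dose grids superpose over shots", {
  mach <- default_machine()
  s <- sphere_surface(80)
  gs <- list(origin = frame_center - 10, spacing = c(2.5, 2.5, 2.5),
             dims = c(9L, 9L, 9L))
  shA <- shot(frame_center + c(4, 0, 0), 90, rep("16", 8), duration = 1.2,
              id = "A")
  shB <- shot(frame_center - c(0, 5, 0), 110,
              c("8", "8", "4", "16", "blocked", "16", "8", "4"),
              duration = 0.7, id = "B")
  gA <- compute_dose_grid(plan(list(shA), grid_spec = gs), s, mach)
  gB <- compute_dose_grid(plan(list(shB), grid_spec = gs), s, mach)
  gAB <- compute_dose_grid(plan(list(shA, shB), grid_spec = gs), s, mach)
  expect_lt(max(abs(gAB$values - (gA$values + gB$values))),
            1e-12 * max(gAB$values))
})

test_that("no point out-doses the focus of a single centred shot", {
  mach <- default_machine()
  s <- sphere_surface(80)
  sh <- centered_shot()
  r_focus <- shot_dose_rate(frame_center, sh, s, mach)
  set.seed(21)
  u <- matrix(rnorm(300), 100, 3)
  u <- u / sqrt(rowSums(u^2))
  # points 50 mm off the focus in random directions (still inside)
  P <- sweep(50 * u, 2, frame_center, "+")
  expect_true(all(shot_dose_rate(P, sh, s, mach) <= r_focus))
})

test_that("the dose field is invariant under 45-degree rotation of phantom and points", {
  mach <- default_machine()
  spec <- ellipsoid_spec(n_directions = 60, seed = 5)
  meas <- make_scaler_measurements(spec)
  surf <- fit_skull(meas, degree = 4)
  Rz <- rot_z(45)
  meas_rot <- scaler_measurements(meas$directions %*% t(Rz), meas$radii,
                                  meas$center)
  surf_rot <- fit_skull(meas_rot, degree = 4)
  sh <- centered_shot(rep("8", 8))
  set.seed(7)
  P <- sweep(matrix(rnorm(90, sd = 8), 30, 3), 2, frame_center, "+")
  P_rot <- sweep(sweep(P, 2, frame_center) %*% t(Rz), 2, frame_center, "+")
  d1 <- shot_dose_rate(P, sh, surf, mach)
  d2 <- shot_dose_rate(P_rot, sh, surf_rot, mach)
  expect_lt(max(abs(d2 / d1 - 1)), 1e-6)
})

test_that("weighted shots resolve durations through the prescription", {
  mach <- default_machine()
  s <- sphere_surface(80)
  sh <- shot(frame_center, 90, rep("16", 8), weight = 0.5)
  pl <- plan(list(sh), prescription = list(dose_gy = 18, isodose_pct = 50))
  dur <- resolve_durations(pl, s, mach)
  rate <- shot_dose_rate(frame_center, sh, s, mach)
  expect_equal(dur, 0.5 * 18 / rate, tolerance = 1e-12)
})

test_that("dose grids round-trip through NRRD and dump to CSV", {
  mach <- default_machine()
  s <- sphere_surface(80)
  pl <- plan(list(centered_shot(duration = 1.5)),
             grid_spec = list(origin = frame_center - 6,
                              spacing = c(3, 3, 3), dims = c(5L, 5L, 5L)))
  g <- compute_dose_grid(pl, s, mach)
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(g, f)
  g2 <- read_nrrd(f)
  expect_equal(g2$values, g$values, tolerance = 1e-15)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), prod(g$dims))
  expect_equal(df$dose_gy, as.numeric(g$values))
})
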