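make_tables <- function(ratios, base_dose = 10, time = 1.5) {
  n <- length(ratios)
  ids <- sprintf("shot-%02d", seq_len(n))
  list(computed = data.frame(shot_id = ids,
                             focus_dose_gy = base_dose * ratios,
                             time_min = time * ratios),
       reference = data.frame(shot_id = ids,
                              focus_dose_gy = rep(base_dose, n),
                              time_min = rep(time, n)))
}

test_that("identical computed and reference values verify cleanly", {
  tb <- make_tables(rep(1, 5))
  v <- verify_plan(tb$computed, tb$reference)
  expect_true(all(v$records$ratio == 1))
  expect_true(all(v$records$flag == "pass"))
  expect_identical(v$summary$sd, 0)
  expect_identical(v$summary$plan_flag, "pass")
})

test_that("tolerance and action limits flag deviations, boundaries inclusive", {
  eps <- 1e-9
  cases <- list(list(r = 1.02, flag = "pass"),
                list(r = 0.98, flag = "pass"),
                list(r = 1.03 - eps, flag = "pass"),
                list(r = 1.04, flag = "tolerance"),
                list(r = 0.96, flag = "tolerance"),
                list(r = 1.05 - eps, flag = "tolerance"),
                list(r = 1.06, flag = "action"),
                list(r = 0.94, flag = "action"))
  for (cs in cases) {
    tb <- make_tables(cs$r)
    v <- verify_plan(tb$computed, tb$reference)
    expect_identical(v$records$flag, cs$flag)
  }
  # deviations exactly at a limit fall in the less severe category
  expect_identical(ratio_flag(1 + TOLERANCE_LIMIT * (1 - 1e-14)), "pass")
  expect_identical(ratio_flag(1 + ACTION_LIMIT * (1 - 1e-14)), "tolerance")
})

test_that("summary statistics match an independent recomputation", {
  tb <- make_tables(c(0.98, 1.00, 1.02))
  v <- verify_plan(tb$computed, tb$reference)
  expect_equal(v$summary$average, 1.0, tolerance = 1e-12)
  expect_equal(v$summary$max, 1.02, tolerance = 1e-12)
  expect_equal(v$summary$min, 0.98, tolerance = 1e-12)
  set.seed(13)
  ratios <- 1 + rnorm(20, sd = 0.03)
  tb <- make_tables(ratios)
  v <- verify_plan(tb$computed, tb$reference)
  expect_lt(abs(v$summary$average - mean(v$records$ratio)), 1e-12)
  expect_lt(abs(v$summary$sd - stats::sd(v$records$ratio)), 1e-12)
  expect_lt(abs(v$summary$max - max(v$records$ratio)), 1e-12)
  expect_lt(abs(v$summary$min - min(v$records$ratio)), 1e-12)
  expect_true(v$summary$min <= v$summary$average &&
              v$summary$average <= v$summary$max)
  # flags partition the shots
  expect_true(all(v$records$flag %in% c("pass", "tolerance", "action")))
})

test_that("mismatched ids and non-positive references are errors", {
  tb <- make_tables(rep(1, 3))
  bad_ref <- tb$reference
  bad_ref$shot_id[2] <- "shot-99"
  expect_error(verify_plan(tb$computed, bad_ref), "shot-99")
  neg_ref <- tb$reference
  neg_ref$focus_dose_gy[1] <- 0
  expect_error(verify_plan(tb$computed, neg_ref), "positive")
})

test_that("maximum-dose localization picks the argmax with a stable tie rule", {
  g <- structure(list(values = array(0, c(3, 3, 3)), origin = c(0, 0, 0),
                      spacing = c(1, 1, 1), dims = c(3L, 3L, 3L)),
                 class = "pfx_dose_grid")
  expect_error(max_dose_location(g), "zero")
  g$values[2, 3, 1] <- 5
  loc <- max_dose_location(g)
  expect_identical(loc$index, c(2L, 3L, 1L))
  expect_identical(loc$point, c(1, 2, 0))
  # two equal maxima: the smaller row-major linear index wins
  g$values[] <- 0
  g$values[1, 2, 3] <- 7   # row-major index (1-1)*9 + (2-1)*3 + 3 = 6
  g$values[2, 1, 1] <- 7   # row-major index (2-1)*9 + 1 = 10
  loc <- max_dose_location(g)
  expect_identical(loc$index, c(1L, 2L, 3L))
})

test_that("isodose masks threshold, nest, and match brute-force counts", {
  mach <- default_machine()
  s <- sphere_surface(80)
  pl <- plan(list(centered_shot(duration = 2)),
             grid_spec = list(origin = frame_center - 12,
                              spacing = c(2, 2, 2), dims = c(13L, 13L, 13L)))
  g <- compute_dose_grid(pl, s, mach)
  m100 <- isodose_mask(g, 100)
  expect_identical(which(m100), which(g$values == max(g$values)))
  masks <- lapply(default_isodose_levels(), isodose_mask, grid = g)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i + 1]] <= masks[[i]]))  # higher level nested
  brute <- sum(as.numeric(g$values) >= 0.5 * max(g$values))
  expect_identical(sum(isodose_mask(g, 50)), brute)
  expect_error(isodose_mask(g, 0), "percent")
  expect_error(isodose_mask(g, 101), "percent")
})

test_that("the HTML report lists every shot, highlights actions, and is reproducible", {
  tb <- make_tables(c(1.00, 1.04, 1.08))
  v <- verify_plan(tb$computed, tb$reference)
  mach <- default_machine()
  s <- sphere_surface(80)
  pl <- plan(list(centered_shot(duration = 2)),
             grid_spec = list(origin = frame_center - 10,
                              spacing = c(2, 2, 2), dims = c(11L, 11L, 11L)))
  g <- compute_dose_grid(pl, s, mach)
  f1 <- withr::local_tempfile(fileext = ".html")
  render_report(v, f1, grid = g)
  html <- readLines(f1)
  expect_length(grep("<tr class=\"(pass|tolerance|action)\">", html), 3)
  expect_length(grep("<tr class=\"action\">", html), 1)
  expect_length(grep("class=\"summary\"", html), 1)
  expect_length(grep("data:image/png;base64", html), 3)
  # regenerating from identical inputs differs only in the timestamp line
  f2 <- withr::local_tempfile(fileext = ".html")
  Sys.sleep(1.1)
  render_report(v, f2, grid = g)
  strip <- function(x) x[!grepl("class=\"timestamp\"", x)]
  expect_identical(strip(readLines(f1)), strip(readLines(f2)))
})

test_that("the file-based pipeline verifies a synthetic plan end to end", {
  pl <- make_plan(3, phantom_spec("sphere", 80), seed = 31)
  meas <- attr(pl, "measurements")
  plan_f <- withr::local_tempfile(fileext = ".yaml")
  write_plan(pl, plan_f, measurements = meas)
  # reference = computed values with small perturbations, one per flag class
  surface <- attr(pl, "surface")
  computed <- compute_focus_table(pl, surface, default_machine())
  ref <- data.frame(shot_id = computed$shot_id,
                    focus_dose_gy = computed$focus_dose_gy / c(1.00, 1.04, 1.06),
                    time_min = computed$time_min)
  ref_f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ref, ref_f, row.names = FALSE)
  report_f <- withr::local_tempfile(fileext = ".html")
  grid_f <- withr::local_tempfile(fileext = ".nrrd")
  res <- run_verification(plan_f, reference_path = ref_f,
                          report_path = report_f, grid_path = grid_f,
                          fit_degree = 2)
  expect_identical(res$verification$records$flag,
                   c("pass", "tolerance", "action"))
  expect_identical(res$verification$summary$plan_flag, "action")
  expect_true(file.exists(report_f))
  g <- read_nrrd(grid_f)
  expect_identical(g$dims, pl$grid_spec$dims)
  # computed times agree with the plan durations
  durs <- vapply(pl$shots, `[[`, numeric(1), "duration")
  expect_equal(res$computed$time_min, durs, tolerance = 1e-12)
})
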