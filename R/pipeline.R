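# End-to-end verification: files in, verification report out. This is the
# surface the command-line wrapper drives.

#' Run a full plan verification from files
#'
#' Loads the machine model, plan and skull-scaler measurements, fits the
#' skull surface, computes per-shot focus doses and times, compares them
#' against the reference file, and (optionally) computes the plan dose
#' grid and writes the HTML report.
#'
#' @param plan_path plan YAML file (may embed scaler measurements).
#' @param machine_path machine-definition YAML (default: shipped model).
#' @param skull_path scaler-measurement table; optional if the plan file
#'   embeds the measurements.
#' @param reference_path reference CSV (\code{shot_id,focus_dose_gy,time_min});
#'   optional — without it only computed values are returned.
#' @param report_path write an HTML report here (optional; needs a reference).
#' @param grid_path write the dose grid as NRRD here (optional).
#' @param fit_degree spherical-harmonic degree of the skull fit.
#' @param compute_grid compute the 3D dose grid (done anyway when
#'   \code{grid_path} or \code{report_path} is given).
#' @return list with \code{computed} (per-shot table), \code{verification}
#'   (a \code{pfx_verification}, when a reference was given), \code{grid}
#'   (when computed), \code{surface}, \code{machine}, \code{plan}.
#' @export
run_verification <- function(plan_path,
                             machine_path = default_machine_path(),
                             skull_path = NULL,
                             reference_path = NULL,
                             report_path = NULL,
                             grid_path = NULL,
                             fit_degree = 4,
                             compute_grid = FALSE) {
  machine <- load_machine(machine_path)
  pl <- read_plan(plan_path)
  meas <- if (!is.null(skull_path)) read_scaler_table(skull_path)
          else attr(pl, "measurements")
  if (is.null(meas))
    stop("no skull-scaler measurements: supply skull_path or embed them ",
         "in the plan file")
  if ((fit_degree + 1)^2 > nrow(meas$directions)) {
    fit_degree <- floor(sqrt(nrow(meas$directions))) - 1
    message("reducing skull fit degree to ", fit_degree,
            " for ", nrow(meas$directions), " measurements")
  }
  surface <- fit_skull(meas, degree = fit_degree)
  computed <- compute_focus_table(pl, surface, machine)

  verification <- NULL
  if (!is.null(reference_path))
    verification <- verify_plan(computed, read_reference(reference_path))

  grid <- NULL
  if (compute_grid || !is.null(grid_path) || !is.null(report_path))
    grid <- compute_dose_grid(pl, surface, machine)
  if (!is.null(grid_path)) write_nrrd(grid, grid_path)
  if (!is.null(report_path)) {
    if (is.null(verification))
      stop("a reference file is required to render a report")
    render_report(verification, report_path, grid = grid,
                  title = sprintf("Plan verification: %s", pl$identifier))
  }
  list(computed = computed, verification = verification, grid = grid,
       surface = surface, machine = machine, plan = pl)
}
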