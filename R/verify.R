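# Comparison of computed against reference (planning-system) results:
# per-shot focus doses and times with clinical tolerance (3%) and action
# (5%) limits, dose-maximum localization, isodose masks, and the HTML
# verification report.

TOLERANCE_LIMIT <- 0.03
ACTION_LIMIT <- 0.05

#' Locate the maximum-dose voxel
#'
#' @param grid a \code{pfx_dose_grid}.
#' @return list with \code{index} (1-based voxel index, length 3),
#'   \code{point} (frame mm) and \code{dose} (Gy). Ties are broken by the
#'   smallest linear index.
#' @export
max_dose_location <- function(grid) {
  stopifnot(inherits(grid, "pfx_dose_grid"))
  if (all(grid$values == 0)) stop("dose grid is identically zero")
  mx <- max(grid$values)
  cand <- arrayInd(which(grid$values == mx), grid$dims)
  # tie-break: smallest row-major linear index
  rowmaj <- (cand[, 1] - 1) * grid$dims[2] * grid$dims[3] +
    (cand[, 2] - 1) * grid$dims[3] + cand[, 3]
  idx <- as.integer(cand[which.min(rowmaj), ])
  list(index = idx, point = voxel_center(grid, idx), dose = mx)
}

#' Isodose mask at a relative level
#'
#' @param grid a \code{pfx_dose_grid}.
#' @param level_percent isodose level as percent of the grid maximum,
#'   in (0, 100].
#' @return logical array of the grid's dimensions: voxels with dose at or
#'   above the level.
#' @export
isodose_mask <- function(grid, level_percent) {
  stopifnot(inherits(grid, "pfx_dose_grid"))
  if (level_percent <= 0 || level_percent > 100)
    stop("isodose level must lie in (0, 100] percent")
  grid$values >= (level_percent / 100) * max(grid$values)
}

#' Default isodose level set
#' @return the standard comparison levels, percent of maximum dose.
#' @export
default_isodose_levels <- function() c(12.5, 25, 50, 75, 90)

#' Compute the per-shot focus-dose table of a plan
#'
#' For each shot: the dose rate at its own focus, the focus dose delivered
#' by the shot (rate times duration) and the shot time. This is the
#' "computed" side of the plan verification.
#'
#' @param plan a \code{pfx_plan}.
#' @param surface a \code{pfx_skull_surface}.
#' @param machine a \code{pfx_machine}.
#' @return data.frame with \code{shot_id}, \code{dose_rate_gy_min},
#'   \code{focus_dose_gy}, \code{time_min}.
#' @export
compute_focus_table <- function(plan, surface, machine) {
  durations <- resolve_durations(plan, surface, machine)
  rates <- vapply(plan$shots, function(sh)
    shot_dose_rate(sh$position, sh, surface, machine), numeric(1))
  data.frame(shot_id = vapply(plan$shots, `[[`, character(1), "id"),
             dose_rate_gy_min = rates,
             focus_dose_gy = rates * durations,
             time_min = durations,
             stringsAsFactors = FALSE)
}

#' Read a reference-results file
#'
#' CSV with header \code{shot_id,focus_dose_gy,time_min}: per-shot focus
#' doses and times exported from the planning system.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shot_id", "focus_dose_gy", "time_min")
  if (!all(need %in% names(df)))
    stop("reference file needs columns: ", paste(need, collapse = ", "))
  df
}

ratio_flag <- function(ratio) {
  dev <- abs(ratio - 1)
  ifelse(dev <= TOLERANCE_LIMIT, "pass",
         ifelse(dev <= ACTION_LIMIT, "tolerance", "action"))
}

#' Verify computed focus doses against reference values
#'
#' Joins the computed and reference per-shot tables on shot id, forms the
#' computed/reference dose ratios, and flags each shot against the
#' clinical tolerance (3%) and action (5%) limits; a deviation of
#' exactly 3% (5%) falls in the less severe category. Also returns
#' summary statistics of the ratios and a plan-level worst-case flag.
#'
#' @param computed data.frame from \code{\link{compute_focus_table}} (or
#'   with the same \code{shot_id,focus_dose_gy,time_min} columns).
#' @param reference data.frame from \code{\link{read_reference}}.
#' @return list of class \code{pfx_verification}: \code{records}
#'   (per-shot data.frame with ratio, time ratio and flag),
#'   \code{summary} (mean/sd/max/min of the dose ratios and the
#'   plan-level flag).
#' @export
verify_plan <- function(computed, reference) {
  if (!setequal(computed$shot_id, reference$shot_id) ||
      anyDuplicated(computed$shot_id) || anyDuplicated(reference$shot_id)) {
    only_c <- setdiff(computed$shot_id, reference$shot_id)
    only_r <- setdiff(reference$shot_id, computed$shot_id)
    stop("shot ids do not match; computed-only: [",
         paste(only_c, collapse = ", "), "], reference-only: [",
         paste(only_r, collapse = ", "), "]")
  }
  reference <- reference[match(computed$shot_id, reference$shot_id), ]
  if (any(reference$focus_dose_gy <= 0))
    stop("reference focus doses must be positive")
  ratio <- computed$focus_dose_gy / reference$focus_dose_gy
  time_ratio <- computed$time_min / reference$time_min
  records <- data.frame(
    shot_id = computed$shot_id,
    computed_focus_dose_gy = computed$focus_dose_gy,
    reference_focus_dose_gy = reference$focus_dose_gy,
    ratio = ratio,
    computed_time_min = computed$time_min,
    reference_time_min = reference$time_min,
    time_ratio = time_ratio,
    flag = ratio_flag(ratio),
    stringsAsFactors = FALSE)
  summary <- list(average = mean(ratio),
                  sd = if (length(ratio) > 1) stats::sd(ratio) else 0,
                  max = max(ratio), min = min(ratio),
                  plan_flag = c("pass", "tolerance", "action")[
                    max(match(records$flag, c("pass", "tolerance", "action")))])
  structure(list(records = records, summary = summary),
            class = "pfx_verification")
}

#' @export
print.pfx_verification <- function(x, ...) {
  cat(sprintf("Plan verification: %d shot(s), ratio %.3f +/- %.3f [%.3f, %.3f], %s\n",
              nrow(x$records), x$summary$average, x$summary$sd,
              x$summary$min, x$summary$max, toupper(x$summary$plan_flag)))
  print(x$records, digits = 4)
  invisible(x)
}

# mid-plane isodose overlay figure, returned as a base64 data URI
midplane_figure <- function(grid, plane = c("axial", "sagittal", "coronal"),
                            levels = default_isodose_levels()) {
  plane <- match.arg(plane)
  k <- switch(plane, axial = 3, sagittal = 1, coronal = 2)
  mid <- ceiling(grid$dims[k] / 2)
  slice <- switch(plane,
                  axial = grid$values[, , mid],
                  sagittal = grid$values[mid, , ],
                  coronal = grid$values[, mid, ])
  ax <- lapply(1:3, function(a) grid$origin[a] + grid$spacing[a] *
                 (seq_len(grid$dims[a]) - 1))
  xy <- switch(plane, axial = ax[c(1, 2)], sagittal = ax[c(2, 3)],
               coronal = ax[c(1, 3)])
  lab <- switch(plane, axial = c("x (mm)", "y (mm)"),
                sagittal = c("y (mm)", "z (mm)"), coronal = c("x (mm)", "z (mm)"))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, width = 480, height = 480)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  graphics::contour(xy[[1]], xy[[2]], slice,
                    levels = levels / 100 * max(grid$values),
                    labels = paste0(levels, "%"),
                    xlab = lab[1], ylab = lab[2],
                    main = sprintf("%s mid-plane isodoses", plane),
                    col = grDevices::hcl.colors(length(levels), "Zissou 1"))
  graphics::par(op)
  grDevices::dev.off()
  raw <- readBin(tmp, "raw", n = file.info(tmp)$size)
  unlink(tmp)
  paste0("data:image/png;base64,", jsonlite::base64_enc(raw))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the verification report as a self-contained HTML document
#'
#' Per-shot table with tolerance/action flags highlighted, a summary row,
#' and (when a dose grid is supplied) isodose-overlay figures for the
#' axial, sagittal and coronal mid-planes. Regenerating the report from
#' identical inputs reproduces it byte-identically apart from the
#' timestamp line.
#'
#' @param verification a \code{pfx_verification}.
#' @param path output HTML path.
#' @param grid optional \code{pfx_dose_grid} for the isodose figures.
#' @param title report title.
#' @return the path, invisibly.
#' @export
render_report <- function(verification, path, grid = NULL,
                          title = "Plan verification report") {
  stopifnot(inherits(verification, "pfx_verification"))
  rec <- verification$records
  if (nrow(rec) == 0) stop("no verification records to report")
  s <- verification$summary
  row_html <- vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    sprintf(paste0("<tr class=\"%s\"><td>%s</td><td>%.4f</td><td>%.4f</td>",
                   "<td>%.4f</td><td>%.3f</td><td>%.3f</td>",
                   "<td class=\"flag\">%s</td></tr>"),
            r$flag, html_escape(r$shot_id), r$computed_focus_dose_gy,
            r$reference_focus_dose_gy, r$ratio, r$computed_time_min,
            r$reference_time_min, toupper(r$flag))
  }, character(1))
  figs <- ""
  if (!is.null(grid)) {
    uris <- vapply(c("axial", "sagittal", "coronal"), midplane_figure,
                   character(1), grid = grid)
    figs <- paste0("<h2>Isodose overlays (12.5/25/50/75/90% of maximum)</h2>\n",
                   paste(sprintf("<img alt=\"%s\" src=\"%s\"/>",
                                 names(uris), uris), collapse = "\n"))
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>",
    "body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:0.3em 0.8em;text-align:right}",
    "tr.pass td.flag{background:#cfc}",
    "tr.tolerance td.flag{background:#ffd27f}",
    "tr.action td.flag{background:#f99;font-weight:bold}",
    "tr.summary td{font-weight:bold}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    sprintf("<p class=\"timestamp\">generated: %s</p>",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("<p>Plan-level flag: <strong>%s</strong>. Limits: tolerance &plusmn;%g%%, action &plusmn;%g%%.</p>",
            toupper(s$plan_flag), 100 * TOLERANCE_LIMIT, 100 * ACTION_LIMIT),
    "<table>",
    "<tr><th>shot</th><th>computed dose (Gy)</th><th>reference dose (Gy)</th><th>ratio</th><th>computed time (min)</th><th>reference time (min)</th><th>flag</th></tr>",
    row_html,
    sprintf(paste0("<tr class=\"summary\"><td>all shots</td><td></td><td></td>",
                   "<td>%.4f (sd %.4f, range %.4f&ndash;%.4f)</td><td></td><td></td>",
                   "<td class=\"flag\">%s</td></tr>"),
            s$average, s$sd, s$min, s$max, toupper(s$plan_flag)),
    "</table>",
    figs,
    "</body></html>")
  ok <- tryCatch({ writeLines(html, path); TRUE },
                 error = function(e) stop("cannot write report to ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}
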