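#' Study-level configuration
#'
#' Collects every tunable of the measurement pipeline with the defaults the
#' package documents: the RGB dye threshold, the 0.0013028 mm/pixel
#' calibration with the 7.18 mm complete-penetration cap, a quartic fit,
#' 5 px marker bins, three thickness stations, exclusion of delaminated
#' specimens from the statistics, and a 0.05 significance level.
#'
#' @param threshold A [dye_threshold()].
#' @param calibration A [calibration_spec()].
#' @param degree Maximum interface-fit degree.
#' @param bin_width Marker bin width in pixels.
#' @param n_thickness_stations Stations for cement-thickness measurement.
#' @param delamination_policy `"exclude"` (drop delaminated specimens from
#'   the statistics, count them separately) or `"assign_cap"` (enter them
#'   at the cap distance).
#' @param alpha Significance level for the normality gate.
#' @param seed RNG seed used by any stochastic step.
#' @return An object of class `study_config`.
#' @export
study_config <- function(threshold = dye_threshold(),
                         calibration = calibration_spec(),
                         degree = 4,
                         bin_width = 5,
                         n_thickness_stations = 3,
                         delamination_policy = c("exclude", "assign_cap"),
                         alpha = 0.05,
                         seed = 1L) {
  delamination_policy <- match.arg(delamination_policy)
  stopifnot(inherits(threshold, "dye_threshold"),
            inherits(calibration, "calibration_spec"),
            degree >= 1, bin_width > 0, n_thickness_stations >= 1,
            alpha > 0, alpha < 1)
  structure(list(threshold = threshold, calibration = calibration,
                 degree = degree, bin_width = bin_width,
                 n_thickness_stations = n_thickness_stations,
                 delamination_policy = delamination_policy,
                 alpha = alpha, seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  threshold: R <= %g, G <= %g, %g <= B <= %g\n",
              x$threshold$r_max, x$threshold$g_max,
              x$threshold$b_min, x$threshold$b_max))
  cat(sprintf("  calibration: %g mm/pixel, cap %g mm\n",
              x$calibration$mm_per_pixel, x$calibration$cap_mm))
  cat(sprintf("  degree %g, bin_width %g px, %d thickness stations\n",
              x$degree, x$bin_width, x$n_thickness_stations))
  cat(sprintf("  delamination policy: %s; alpha %g; seed %d\n",
              x$delamination_policy, x$alpha, x$seed))
  invisible(x)
}

require_field <- function(metadata, field) {
  val <- metadata[[field]]
  if (is.null(val) || length(val) == 0L || (is.atomic(val) && anyNA(val)))
    stop("specimen metadata is missing required field '", field, "'",
         call. = FALSE)
  val
}

#' Measure one specimen image
#'
#' Runs the full three-stage measurement on a single cross-section image:
#' dye thresholding, marker placement along the die--cement interface, and
#' quartic curve fit with calibrated arc-length penetration. A specimen
#' flagged as delaminated in its metadata is not measured and reports
#' `status = "delaminated"`.
#'
#' @param image An `H x W x 3` raster array or an image file path.
#' @param metadata Named list (or one-row data frame) with `specimen_id`,
#'   `group`, `margin_row`, `margin_col`, optional `center_row`/`center_col`
#'   (die-center landmark) and optional `delaminated` (0/1).
#' @param config A [study_config()].
#' @param overlay_path Optional path; when given, the image annotated with
#'   markers and the fitted curve is written there as PNG.
#' @return A list with `result` (a [penetration_result()]), `trace`, `curve`
#'   (or `NULL`), and `row` (a one-row data frame ready for the results
#'   CSV).
#' @export
run_specimen <- function(image, metadata, config = study_config(),
                         overlay_path = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.data.frame(metadata)) metadata <- as.list(metadata[1L, ])
  specimen_id <- require_field(metadata, "specimen_id")
  group <- require_field(metadata, "group")
  delaminated <- isTRUE(metadata$delaminated == 1) || isTRUE(metadata$delaminated)

  trace <- marker_trace(); curve <- NULL
  if (delaminated) {
    res <- penetration_result(NA_real_, NA_real_, FALSE, "delaminated")
  } else {
    img <- as_raster_image(image)
    margin <- c(require_field(metadata, "margin_row"),
                require_field(metadata, "margin_col"))
    center <- NULL
    if (!is.null(metadata$center_row) && !is.null(metadata$center_col) &&
        !anyNA(c(metadata$center_row, metadata$center_col)))
      center <- c(metadata$center_row, metadata$center_col)

    mask <- classify_dye_pixels(img, config$threshold)
    trace <- extract_interface_markers(mask, margin, config$bin_width)
    res <- measure_penetration(trace, config$calibration, die_center = center,
                               degree = config$degree)
    if (n_markers(trace) >= 2L) {
      curve <- fit_interface_curve(trace, degree = config$degree)
      if (curve$degree_used < config$degree)
        warning("specimen ", specimen_id, ": fit degree reduced to ",
                curve$degree_used, call. = FALSE)
    }
    if (!is.null(overlay_path)) {
      out <- render_markers(img, trace)
      if (!is.null(curve)) out <- render_overlay(out, curve)
      write_raster(out, overlay_path)
    }
  }
  list(result = res, trace = trace, curve = curve,
       row = data.frame(specimen_id = specimen_id, group = group,
                        status = res$status,
                        arc_length_px = res$arc_length_px,
                        penetration_mm = res$penetration_mm,
                        capped = res$capped,
                        degree_used = res$degree_used,
                        row.names = NULL))
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest must be a non-empty data frame or CSV path")
  for (fld in c("specimen_id", "group", "image_path", "margin_row", "margin_col"))
    if (!fld %in% names(manifest))
      stop("manifest is missing required column '", fld, "'")
  manifest
}

#' Run a full study from a manifest
#'
#' Measures every specimen listed in the manifest, assembles the per-group
#' penetration values according to the delamination policy, and runs the
#' statistical workflow (normality gate, Kruskal-Wallis,
#' Dunn-Bonferroni, group summaries). Optionally writes `results.csv`
#' (per-specimen rows plus group summaries) and `stats.json` to an output
#' directory.
#'
#' Specimens whose trace reaches complete penetration enter the statistics
#' at the cap distance; delaminated specimens are excluded (default) or
#' entered at the cap, per `config$delamination_policy`.
#'
#' @param manifest A data frame or CSV path with columns `specimen_id`,
#'   `group`, `image_path`, `margin_row`, `margin_col`, optional
#'   `center_row`, `center_col`, `delaminated` (0/1). At least 2 groups are
#'   required.
#' @param config A [study_config()].
#' @param output_dir Optional directory for `results.csv` and `stats.json`.
#' @param images Optional named list mapping `image_path` values to
#'   in-memory raster arrays (used by the simulation workflow to avoid
#'   round-tripping through disk).
#' @return A list with `results` (per-specimen data frame), `study` (a
#'   [group_study()]) and `report` (a [study_report()]).
#' @export
run_study <- function(manifest, config = study_config(), output_dir = NULL,
                      images = NULL) {
  stopifnot(inherits(config, "study_config"))
  manifest <- read_manifest(manifest)
  if (length(unique(manifest$group)) < 2L)
    stop("a study needs at least 2 groups for statistical comparison")

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    md <- as.list(manifest[i, ])
    img <- if (!is.null(images) && md$image_path %in% names(images))
      images[[md$image_path]] else md$image_path
    t0 <- proc.time()[["elapsed"]]
    sp <- run_specimen(img, md, config)
    message(sprintf("specimen %s (%s): %s, %.4f mm [%.2f s]",
                    md$specimen_id, md$group, sp$result$status,
                    sp$result$penetration_mm,
                    proc.time()[["elapsed"]] - t0))
    rows[[i]] <- sp$row
  }
  results <- do.call(rbind, rows)

  cap <- config$calibration$cap_mm
  groups <- list(); delam <- integer(0); comp <- integer(0)
  for (g in unique(results$group)) {
    sub <- results[results$group == g, ]
    vals <- sub$penetration_mm[sub$status != "delaminated"]
    n_delam <- sum(sub$status == "delaminated")
    if (config$delamination_policy == "assign_cap")
      vals <- c(vals, rep(cap, n_delam))
    groups[[g]] <- vals
    delam[g] <- n_delam
    comp[g] <- sum(sub$status == "complete_penetration")
  }
  study <- group_study(groups, delaminated_counts = delam,
                       complete_penetration_counts = comp)
  report <- study_report(study, alpha = config$alpha)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(shapiro_p = as.list(report$shapiro_p),
           nonparametric = report$nonparametric,
           omnibus = report$omnibus,
           pairwise = report$pairwise,
           summary = report$summary),
      file.path(output_dir, "stats.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(results = results, study = study, report = report)
}
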