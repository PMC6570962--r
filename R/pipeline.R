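#' Run the full batch analysis workflow
#'
#' Orchestrates discovery, loading, preprocessing (contrast stretch, red
#' channel, threshold), particle capture, shape measurement, classification
#' and reporting for every image under `input_root`. Per sub-directory it
#' writes a raw measurement CSV and the indexed QC overlays; at the root of
#' `output_root` it writes one CSV per parameter per analysed class and
#' (when both classes are analysed) the pelleted-fraction summary.
#'
#' @param input_root Directory of raw images (sub-directories at any depth
#'   are analysed and reported separately).
#' @param output_root Directory for all outputs (mirrors the input layout).
#' @param um_per_px Calibration, um per pixel.
#' @param suffix Image file suffix to analyse (case-insensitive).
#' @param mode `"both"`, `"pellets"` or `"dispersed"`.
#' @param pellet_min_area,dispersed_min_area Class cut-offs in um^2
#'   (defaults 500 and 95; see [mpd_class_config()]).
#' @param threshold `"auto"` (per-image isodata) or a fixed grey cutoff.
#' @param connectivity 4 or 8 (default 8).
#' @param border_policy `"exclude_all"` (default) drops particles touching
#'   the image edge; `"keep_all"` retains them.
#' @param contrast_saturation Fraction of pixels saturated by the contrast
#'   stretch (default 0.05).
#' @param qc_flags Optional data frame or CSV path of visually rejected
#'   calls (columns `image`, `index`) to remove from all reports.
#' @param overlays Write QC overlay images (default TRUE).
#' @param verbose Log per-image progress to stderr.
#' @return An `mpd_run` object: counts, per-sub-directory pelleted
#'   fractions, all reported rows, paths of every file written, and any
#'   warnings collected.
#' @export
run_pipeline <- function(input_root, output_root, um_per_px,
                         suffix = "png", mode = c("both", "pellets",
                                                  "dispersed"),
                         pellet_min_area = 500, dispersed_min_area = 95,
                         threshold = "auto", connectivity = 8,
                         border_policy = c("exclude_all", "keep_all"),
                         contrast_saturation = 0.05, qc_flags = NULL,
                         overlays = TRUE, verbose = TRUE) {
  mode <- match.arg(mode)
  border_policy <- match.arg(border_policy)
  cal <- mpd_calibration(um_per_px)
  config <- mpd_class_config(pellet_min_area, dispersed_min_area, mode)
  groups <- discover_images(input_root, suffix)
  root_norm <- normalizePath(input_root)

  all_rows <- NULL
  files_written <- character(0)
  warnings <- character(0)
  n_images <- 0L
  n_artefacts <- 0L
  artefact_area <- 0
  n_border_excluded <- 0L
  classes_in_mode <- switch(mode, both = c("pellet", "dispersed"),
                            pellets = "pellet", dispersed = "dispersed")

  rows_by_subdir <- list()
  for (subdir in names(groups)) {
    sub_rows <- NULL
    for (path in groups[[subdir]]) {
      rel <- sub("^/*", "", substring(path, nchar(root_norm) + 1L))
      record <- load_image(path, subdir = subdir)
      grey <- to_red_channel(
        enhance_contrast(record$raster, contrast_saturation))
      mask <- binarize(grey, threshold, cal)
      particles <- label_particles(mask, connectivity, trace = FALSE,
                                   source = rel)
      kept <- apply_border_policy(particles, border_policy)
      n_border_excluded <- n_border_excluded +
        (length(particles) - length(kept))
      # classify on area first: area needs only the pixel count, so
      # artefacts and out-of-mode particles are never traced or measured
      areas <- vapply(kept, function(p) area_um2(p, cal), numeric(1))
      cls <- if (length(areas)) classify_area(areas, config) else character(0)
      n_artefacts <- n_artefacts + sum(cls == "artefact")
      artefact_area <- artefact_area + sum(areas[cls == "artefact"])
      keep_particles <- kept[cls %in% classes_in_mode]
      rows <- NULL
      for (p in keep_particles) {
        m <- particle_metrics(trace_particle(p), cal, config)
        m$image <- rel
        rows <- rbind(rows, m)
      }
      n_images <- n_images + 1L
      if (verbose)
        message(sprintf("[%s] %d particle(s) reported (%d border-excluded)",
                        rel, if (is.null(rows)) 0L else nrow(rows),
                        length(particles) - length(kept)))
      if (overlays) {
        files_written <- c(files_written, render_qc_overlays(
          record, keep_particles,
          if (is.null(rows)) character(0) else rows$class,
          out_dir = file.path(output_root, subdir), mode = mode))
      }
      sub_rows <- rbind(sub_rows, rows)
    }
    if (is.null(sub_rows)) sub_rows <- .empty_rows()
    if (nrow(sub_rows) > 0L) sub_rows$subdir <- subdir
    rows_by_subdir[[subdir]] <- sub_rows
  }

  all_rows <- do.call(rbind, lapply(rows_by_subdir, function(r)
    if (nrow(r) > 0L) r else NULL))
  if (is.null(all_rows))
    all_rows <- cbind(.empty_rows(), data.frame(subdir = character()))
  rownames(all_rows) <- NULL

  if (!is.null(qc_flags)) {
    n_before <- nrow(all_rows)
    all_rows <- drop_flagged(all_rows, qc_flags)   # errors on unknown flags
    n_qc_dropped <- n_before - nrow(all_rows)
    if (verbose && n_qc_dropped > 0L)
      message(sprintf("%d particle(s) removed by QC flags", n_qc_dropped))
  }

  for (subdir in names(groups)) {
    sub_rows <- all_rows[all_rows$subdir == subdir, , drop = FALSE]
    raw_path <- file.path(output_root, subdir, "raw_data.csv")
    write_raw_csv(sub_rows, raw_path)
    files_written <- c(files_written, raw_path)
  }
  files_written <- c(files_written,
                     write_parameter_tables(all_rows, output_root, mode))

  fractions <- NULL
  if (mode == "both") {
    fractions <- data.frame(subdir = names(groups),
                            pellet_fraction_pct = NA_real_,
                            stringsAsFactors = FALSE)
    for (i in seq_along(groups)) {
      rows_d <- all_rows[all_rows$subdir == names(groups)[i], , drop = FALSE]
      frac <- withCallingHandlers(
        pellet_fraction(rows_d),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      fractions$pellet_fraction_pct[i] <- frac
    }
    frac_path <- file.path(output_root, "pellet_fraction.csv")
    write_pellet_fraction_csv(fractions, frac_path)
    files_written <- c(files_written, frac_path)
  }

  class_counts <- table(factor(all_rows$class,
                               levels = c("pellet", "dispersed")))
  structure(list(
    input_root = input_root, output_root = output_root,
    calibration = cal, config = config, mode = mode,
    threshold = threshold, connectivity = connectivity,
    border_policy = border_policy,
    n_images = n_images,
    n_pellets = as.integer(class_counts[["pellet"]]),
    n_dispersed = as.integer(class_counts[["dispersed"]]),
    n_artefacts = n_artefacts,
    artefact_area_um2 = artefact_area,
    n_border_excluded = n_border_excluded,
    rows = all_rows,
    fractions = fractions,
    files_written = files_written,
    warnings = warnings
  ), class = "mpd_run")
}

#' @export
print.mpd_run <- function(x, ...) {
  cat("Fungal macromorphology analysis run\n")
  cat(sprintf("  input:  %s\n  output: %s\n", x$input_root, x$output_root))
  cat(sprintf("  calibration: %g um/px, mode: %s\n",
              x$calibration$um_per_px, x$mode))
  cat(sprintf("  images analysed: %d\n", x$n_images))
  cat(sprintf("  pellets: %d, dispersed: %d\n", x$n_pellets, x$n_dispersed))
  cat(sprintf("  artefacts removed: %d (%.1f um^2 total)\n",
              x$n_artefacts, x$artefact_area_um2))
  cat(sprintf("  border-excluded particles: %d\n", x$n_border_excluded))
  if (!is.null(x$fractions)) {
    cat("  pelleted fraction by sub-directory:\n")
    for (i in seq_len(nrow(x$fractions)))
      cat(sprintf("    %s: %s%%\n", x$fractions$subdir[i],
                  formatC(x$fractions$pellet_fraction_pct[i], digits = 1,
                          format = "f")))
  }
  cat(sprintf("  files written: %d\n", length(x$files_written)))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("    ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.mpd_run <- function(object, ...) {
  rows <- object$rows
  out <- list(run = object)
  if (nrow(rows) > 0L) {
    out$by_class <- do.call(rbind, lapply(split(rows, rows$class), function(g)
      data.frame(class = g$class[1L], n = nrow(g),
                 mean_area_um2 = mean(g$area_um2),
                 mean_diameter_um = mean(g$feret_max_um),
                 mean_aspect_ratio = mean(g$aspect_ratio),
                 mean_solidity = mean(g$solidity),
                 mean_morphology_number = mean(g$morphology_number))))
    rownames(out$by_class) <- NULL
  }
  class(out) <- "summary.mpd_run"
  out
}

#' @export
print.summary.mpd_run <- function(x, ...) {
  print(x$run)
  if (!is.null(x$by_class)) {
    cat("\nPer-class descriptor means:\n")
    print(x$by_class, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
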