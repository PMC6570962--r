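#' Discover input images under a directory tree
#'
#' Walks `input_root` at any nesting depth and returns every file whose name
#' ends with `suffix` (case-insensitive), grouped by its immediate containing
#' sub-directory. Files sitting directly in the root form the implicit group
#' `"."`. Groups and the files inside them are ordered lexicographically so
#' that particle indices are reproducible across runs.
#'
#' @param input_root Directory containing the raw images.
#' @param suffix File extension to match, with or without the leading dot
#'   (e.g. `"jpg"`, `".png"`).
#' @return A named list; names are sub-directory paths relative to
#'   `input_root`, values are character vectors of absolute file paths.
#' @export
discover_images <- function(input_root, suffix) {
  if (!dir.exists(input_root))
    stop(sprintf("input root '%s' does not exist", input_root), call. = FALSE)
  suffix <- sub("^\\.", "", suffix)
  if (!nzchar(suffix)) stop("suffix must be non-empty", call. = FALSE)
  files <- list.files(input_root, recursive = TRUE, full.names = FALSE)
  pat <- paste0("\\.", suffix, "$")
  files <- files[grepl(pat, files, ignore.case = TRUE)]
  if (length(files) == 0L)
    stop(sprintf("no input: no files with suffix '%s' found under '%s'",
                 suffix, input_root), call. = FALSE)
  subdir <- dirname(files)
  files <- files[order(subdir, basename(files), method = "radix")]
  subdir <- dirname(files)
  groups <- split(file.path(normalizePath(input_root), files), subdir)
  groups[order(names(groups), method = "radix")]
}

#' Load one raster image as an 8-bit RGB record
#'
#' Reads a JPEG, PNG or TIFF file and returns a row-major 8-bit RGB array.
#' Greyscale sources are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @param subdir Sub-directory label carried through to reports
#'   (relative to the analysis input root); defaults to `"."`.
#' @return An object of class `mpd_image`: a list with `path`, `subdir` and
#'   `raster`, the latter an integer array `height x width x 3` in 0..255.
#' @export
load_image <- function(path, subdir = ".") {
  if (!file.exists(path))
    stop(sprintf("image file '%s' does not exist", path), call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("cannot decode image '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  a <- EBImage::imageData(img)  # width-major, values in [0, 1]
  if (length(dim(a)) == 2L) {
    g <- t(a)
    a <- array(c(g, g, g), c(dim(g), 3L))
  } else {
    nch <- dim(a)[3]
    if (nch == 2L) {                  # grey + alpha
      g <- t(a[, , 1L])
      a <- array(c(g, g, g), c(dim(g), 3L))
    } else {
      a <- aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    }
  }
  if (any(dim(a)[1:2] < 1L))
    stop(sprintf("image '%s' has a zero-sized raster", path), call. = FALSE)
  raster <- array(as.integer(a * 255 + 0.5), dim(a))
  structure(list(path = path, subdir = subdir, raster = raster),
            class = "mpd_image")
}

# Shared per-particle report columns and their printed precision:
# 2 decimals for calibrated um/um^2 quantities, 4 for dimensionless ones.
.raw_columns <- c("image", "index", "class", "area_um2", "feret_max_um",
                  "feret_min_um", "aspect_ratio", "solidity",
                  "morphology_number")

.round_measurements <- function(rows) {
  for (col in c("area_um2", "feret_max_um", "feret_min_um"))
    if (col %in% names(rows)) rows[[col]] <- round(rows[[col]], 2)
  for (col in c("aspect_ratio", "solidity", "morphology_number", "value"))
    if (col %in% names(rows)) rows[[col]] <- round(rows[[col]], 4)
  rows
}

.empty_rows <- function() {
  data.frame(image = character(), index = integer(), class = character(),
             area_um2 = numeric(), feret_max_um = numeric(),
             feret_min_um = numeric(), aspect_ratio = numeric(),
             solidity = numeric(), morphology_number = numeric(),
             stringsAsFactors = FALSE)
}

#' Write the per-sub-directory raw measurement CSV
#'
#' One CSV per analysed sub-directory, holding every reported particle of the
#' images it contains. Rows are ordered by source image and then ascending
#' particle index, matching the numbering drawn on the QC overlays.
#'
#' @param rows Data frame of per-particle measurements (columns `image`,
#'   `index`, `class`, `area_um2`, `feret_max_um`, `feret_min_um`,
#'   `aspect_ratio`, `solidity`, `morphology_number`).
#' @param path Output CSV path; parent directories are created.
#' @return The output path, invisibly.
#' @export
write_raw_csv <- function(rows, path) {
  if (nrow(rows) == 0L) rows <- .empty_rows()
  missing_cols <- setdiff(.raw_columns, names(rows))
  if (length(missing_cols))
    stop("raw rows are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rows <- rows[order(rows$image, rows$index, method = "radix"), .raw_columns,
               drop = FALSE]
  rows <- .round_measurements(rows)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write root-level per-parameter result tables
#'
#' Extracts each reported parameter (diameter, area, aspect ratio, solidity,
#' morphology number) into its own CSV per analysed class, pooled over the
#' whole input tree. Every particle of a class appears exactly once in each
#' of that class's tables.
#'
#' @param all_rows Data frame of per-particle rows with a `subdir` column in
#'   addition to the raw-report columns.
#' @param output_root Directory receiving the tables.
#' @param mode Which classes to extract: `"pellets"`, `"dispersed"` or
#'   `"both"`.
#' @return Character vector of the written file paths.
#' @export
write_parameter_tables <- function(all_rows, output_root,
                                   mode = c("both", "pellets", "dispersed")) {
  mode <- match.arg(mode)
  classes <- switch(mode, both = c("pellet", "dispersed"),
                    pellets = "pellet", dispersed = "dispersed")
  params <- c(diameter = "feret_max_um", area = "area_um2",
              aspect_ratio = "aspect_ratio", solidity = "solidity",
              morphology_number = "morphology_number")
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  if (nrow(all_rows) == 0L) {
    all_rows <- cbind(.empty_rows(), data.frame(subdir = character()))
  }
  paths <- character(0)
  for (cls in classes) {
    sub <- all_rows[all_rows$class == cls, , drop = FALSE]
    for (p in names(params)) {
      tab <- data.frame(subdir = sub$subdir, image = sub$image,
                        index = sub$index, value = sub[[params[[p]]]],
                        stringsAsFactors = FALSE)
      tab <- .round_measurements(tab)
      if (params[[p]] %in% c("feret_max_um", "area_um2"))
        tab$value <- round(sub[[params[[p]]]], 2)
      path <- file.path(output_root, sprintf("%s_%s.csv", cls, p))
      write.csv(tab, path, row.names = FALSE)
      paths <- c(paths, path)
    }
  }
  paths
}

#' Write the pelleted-fraction summary CSV
#'
#' One file for the whole run, listing every analysed sub-directory with the
#' percentage of its total fungal area contributed by pellets.
#'
#' @param fractions Data frame with columns `subdir` and
#'   `pellet_fraction_pct` (percentages in \[0, 100\], `NA` where a
#'   directory had no fungal area).
#' @param path Output CSV path.
#' @return The output path, invisibly.
#' @export
write_pellet_fraction_csv <- function(fractions, path) {
  stopifnot(all(c("subdir", "pellet_fraction_pct") %in% names(fractions)))
  bad <- !is.na(fractions$pellet_fraction_pct) &
    (fractions$pellet_fraction_pct < 0 | fractions$pellet_fraction_pct > 100)
  if (any(bad))
    stop("pellet fractions must lie in [0, 100]", call. = FALSE)
  fractions$pellet_fraction_pct <- round(fractions$pellet_fraction_pct, 2)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(fractions, path, row.names = FALSE)
  invisible(path)
}
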