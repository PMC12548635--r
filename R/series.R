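#' Per-slice spatial metadata record
#'
#' A `slice_record` holds the spatial metadata of one single-frame CT slice:
#' its patient-space origin, in-plane orientation and pixel spacing, plus the
#' instance and acquisition counters that DICOM importers use to group slices
#' into sub-volumes. The pixel grid is optional; geometry-only records are
#' first-class so spacing audits can run without image data.
#'
#' @param specimen_id Specimen label (e.g. `"W584"`).
#' @param instance_index Integer slice counter (DICOM Instance Number).
#' @param acquisition_index Integer acquisition counter; importers split a
#'   series into sub-volumes where this changes.
#' @param position_mm Numeric length-3, slice-center origin in mm, patient
#'   space (DICOM Image Position (Patient)).
#' @param row_dir,col_dir Unit length-3 in-plane direction cosines.
#' @param pixel_spacing_mm Numeric length-2 `(row, column)` spacing in mm.
#' @param stated_spacing_mm Scalar spacing the metadata claims for the series
#'   (Spacing Between Slices if present, else Slice Thickness), or `NA`.
#' @param n_rows,n_cols Integer grid dimensions.
#' @param pixels Optional integer matrix (`n_rows` x `n_cols`) of intensities.
#' @return An object of class `slice_record`.
#' @export
slice_record <- function(specimen_id, instance_index, acquisition_index,
                         position_mm, row_dir, col_dir, pixel_spacing_mm,
                         stated_spacing_mm = NA_real_, n_rows = 16L,
                         n_cols = 16L, pixels = NULL) {
  stopifnot(length(position_mm) == 3L, length(row_dir) == 3L,
            length(col_dir) == 3L, length(pixel_spacing_mm) == 2L)
  if (abs(sqrt(sum(row_dir^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(col_dir^2)) - 1) > 1e-6) {
    stop("row_dir and col_dir must be unit vectors", call. = FALSE)
  }
  if (abs(sum(row_dir * col_dir)) > 1e-6) {
    stop("row_dir and col_dir must be orthogonal", call. = FALSE)
  }
  if (any(pixel_spacing_mm <= 0)) {
    stop("pixel_spacing_mm must be strictly positive", call. = FALSE)
  }
  if (!is.na(stated_spacing_mm) && stated_spacing_mm <= 0) {
    stop("stated_spacing_mm must be strictly positive when present",
         call. = FALSE)
  }
  structure(
    list(specimen_id = specimen_id,
         instance_index = as.integer(instance_index),
         acquisition_index = as.integer(acquisition_index),
         position_mm = as.numeric(position_mm),
         row_dir = as.numeric(row_dir),
         col_dir = as.numeric(col_dir),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         stated_spacing_mm = as.numeric(stated_spacing_mm),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixels = pixels),
    class = "slice_record"
  )
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Assemble an ordered series geometry from slice records
#'
#' Slices are sorted by the scalar projection of their origin onto the slice
#' normal (the cross product of the first slice's in-plane directions); exact
#' ties are broken by instance index. Ordering is geometric, not by instance
#' number, because that is how volume importers reconstruct a stack.
#'
#' @param records List of [slice_record()] objects (>= 2).
#' @param specimen_id Optional specimen label; defaults to the first record's.
#' @return An object of class `series_geometry` with elements `slices`
#'   (sorted records), `normal`, `offsets_mm` (sorted projections),
#'   `gaps_mm` (consecutive offset differences, length `n_slices - 1`) and
#'   `stated_spacing_mm`.
#' @export
series_geometry <- function(records, specimen_id = NULL) {
  if (length(records) < 2L) {
    stop("series too small: need at least 2 slices", call. = FALSE)
  }
  normal <- .cross3(records[[1L]]$row_dir, records[[1L]]$col_dir)
  normal <- normal / sqrt(sum(normal^2))
  for (r in records) {
    nr <- .cross3(r$row_dir, r$col_dir)
    nr <- nr / sqrt(sum(nr^2))
    ang <- acos(pmin(1, pmax(-1, sum(nr * normal))))
    if (ang > 1e-3) {
      stop("non-parallel slices: orientation deviates by ",
           format(ang), " rad", call. = FALSE)
    }
  }
  offsets <- vapply(records, function(r) sum(r$position_mm * normal),
                    numeric(1L))
  inst <- vapply(records, function(r) r$instance_index, integer(1L))
  ord <- order(offsets, inst)
  offsets <- offsets[ord]
  records <- records[ord]
  gaps <- diff(offsets)
  if (any(gaps <= 0)) {
    stop("duplicate slice positions: zero gap in sorted offsets",
         call. = FALSE)
  }
  if (is.null(specimen_id)) specimen_id <- records[[1L]]$specimen_id
  stated <- vapply(records, function(r) r$stated_spacing_mm, numeric(1L))
  stated <- stated[is.finite(stated)]
  structure(
    list(specimen_id = specimen_id,
         slices = records,
         normal = normal,
         offsets_mm = offsets,
         gaps_mm = gaps,
         stated_spacing_mm = if (length(stated)) stated[1L] else NA_real_),
    class = "series_geometry"
  )
}

#' @export
print.series_geometry <- function(x, ...) {
  cat("<series_geometry> ", x$specimen_id, ": ", length(x$slices),
      " slices, extent ",
      format(max(x$offsets_mm) - min(x$offsets_mm)), " mm",
      if (is.finite(x$stated_spacing_mm))
        paste0(", stated spacing ", format(x$stated_spacing_mm), " mm"),
      "\n", sep = "")
  gp <- table(round(x$gaps_mm, 3L))
  cat("  gaps (rounded to 1e-3):",
      paste(sprintf("%s mm x%d", names(gp), as.integer(gp)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Load a single-frame DICOM series as an ordered geometry
#'
#' Reads every DICOM file in `directory`, extracts per-slice geometry tags and
#' assembles a [series_geometry()]. Slices are sorted along the slice normal;
#' the stated spacing is taken from Spacing Between Slices when present,
#' falling back to Slice Thickness (the two can legitimately differ, and
#' volume geometry is governed by spacing).
#'
#' @param directory Path to a directory containing one series, one slice per
#'   file.
#' @param read_pixels Read pixel grids as well as geometry? Default `TRUE`.
#' @return A `series_geometry`.
#' @export
load_series <- function(directory, read_pixels = TRUE) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) {
    stop("series too small: found ", length(files), " file(s) in ",
         directory, call. = FALSE)
  }
  records <- lapply(files, function(f) {
    d <- dcm_read_file(f, read_pixels = read_pixels)
    if (is.null(d$position) || is.null(d$orientation) ||
        length(d$position) != 3L || length(d$orientation) != 6L) {
      stop("incomplete geometry: missing position/orientation tags in ",
           basename(f), call. = FALSE)
    }
    stated <- if (!is.null(d$spacing_between_slices)) {
      d$spacing_between_slices[1L]
    } else if (!is.null(d$slice_thickness)) {
      d$slice_thickness[1L]
    } else {
      NA_real_
    }
    slice_record(
      specimen_id = if (is.null(d$specimen_id)) "" else d$specimen_id,
      instance_index = if (is.null(d$instance_number)) 0L else
        d$instance_number,
      acquisition_index = if (is.null(d$acquisition_number)) 1L else
        d$acquisition_number,
      position_mm = d$position,
      row_dir = d$orientation[1:3],
      col_dir = d$orientation[4:6],
      pixel_spacing_mm = if (is.null(d$pixel_spacing)) c(1, 1) else
        d$pixel_spacing,
      stated_spacing_mm = stated,
      n_rows = if (is.null(d$n_rows)) 0L else d$n_rows,
      n_cols = if (is.null(d$n_cols)) 0L else d$n_cols,
      pixels = d$pixels
    )
  })
  series_geometry(records)
}

#' Write a synthetic series to disk as single-frame DICOM files
#'
#' Realizes a [synthetic_series_spec()] as one standards-conformant Explicit
#' VR Little Endian DICOM file per slice. Slice origins follow the spec's
#' sub-volume gap pattern exactly; the acquisition-number tag increments per
#' sub-volume; the spacing tags carry the spec's *stated* spacing, which need
#' not match the geometry (that mismatch is the audit's subject).
#'
#' @param spec A [synthetic_series_spec()].
#' @param directory Output directory (created if needed).
#' @param shuffle Write files in a random slice order (exercises geometric
#'   sorting on re-load). Uses the spec's seed.
#' @return Invisibly, the vector of written file paths.
#' @export
write_series <- function(spec, directory, shuffle = FALSE) {
  stopifnot(inherits(spec, "synthetic_series_spec"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2L) != 0L) {
    stop("directory not writable: ", directory, call. = FALSE)
  }
  built <- make_series(spec)
  geom <- built$geometry
  n <- length(geom$slices)
  series_uid <- paste0(DCM_UID_IMPL, ".", abs(spec$seed) %% 100000L)
  order_idx <- seq_len(n)
  if (shuffle) {
    order_idx <- withr::with_seed(spec$seed, sample.int(n))
  }
  paths <- character(n)
  for (j in order_idx) {
    s <- geom$slices[[j]]
    path <- file.path(directory, sprintf("slice_%04d.dcm", j))
    dcm_write_file(path, list(
      specimen_id = s$specimen_id,
      instance_number = s$instance_index,
      acquisition_number = s$acquisition_index,
      position = s$position_mm,
      orientation = c(s$row_dir, s$col_dir),
      pixel_spacing = s$pixel_spacing_mm,
      slice_thickness = spec$stated_spacing_mm,
      spacing_between_slices = spec$stated_spacing_mm,
      n_rows = s$n_rows, n_cols = s$n_cols,
      pixels = s$pixels,
      series_uid = series_uid,
      sop_uid = paste0(series_uid, ".", j)
    ))
    paths[j] <- path
  }
  invisible(paths)
}
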