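# Synthetic inputs: phantom CT series with injected sub-volume spacing
# structure, and repeated-measurement tables with the statistical structure
# the validation pipeline assumes. Every pipeline stage is testable from
# these generators alone, with no external scan downloads.

#' Specification of a synthetic sub-volume CT series
#'
#' Describes a stack of `n_volumes` acquisition blocks of
#' `slices_per_volume` slices each, with gap `within_gap_mm` inside a block
#' and `between_gap_mm` between blocks — the geometry that makes importers
#' emit an inconsistent-spacing warning when the two gaps differ. The stated
#' spacing carried in the metadata tags is independent of the geometry, so
#' metadata mismatches can be injected deliberately.
#'
#' @param specimen_id Label for the series.
#' @param n_volumes Number of sub-volumes, V >= 1.
#' @param slices_per_volume Slices per sub-volume, m >= 1 (V*m >= 2).
#' @param within_gap_mm Intra-volume gap w > 0, mm.
#' @param between_gap_mm Inter-volume gap b > 0, mm (unused when V = 1).
#' @param stated_spacing_mm Spacing claimed by the metadata tags, mm.
#' @param pixel_spacing_mm Length-2 in-plane spacing, mm.
#' @param n_rows,n_cols Pixel grid dimensions.
#' @param phantom `"NONE"` (zero pixels) or `"ELLIPSOID_WITH_FIDUCIALS"`
#'   (a bright ellipsoid plus two point fiducials at known physical
#'   positions).
#' @param fiducial_positions_mm Optional 2 x 3 matrix of physical fiducial
#'   positions; defaults to two points near the axis at 25% and 75% of the
#'   stack extent.
#' @param seed Integer seed governing any randomized realization detail
#'   (e.g. shuffled write order in [write_series()]).
#' @return A `synthetic_series_spec`.
#' @export
synthetic_series_spec <- function(specimen_id = "SYN001",
                                  n_volumes = 1L,
                                  slices_per_volume = 10L,
                                  within_gap_mm = 0.60,
                                  between_gap_mm = 0.50,
                                  stated_spacing_mm = within_gap_mm,
                                  pixel_spacing_mm = c(0.5, 0.5),
                                  n_rows = 32L, n_cols = 32L,
                                  phantom = c("NONE",
                                              "ELLIPSOID_WITH_FIDUCIALS"),
                                  fiducial_positions_mm = NULL,
                                  seed = 1L) {
  phantom <- match.arg(phantom)
  V <- as.integer(n_volumes)
  m <- as.integer(slices_per_volume)
  stopifnot(V >= 1L, m >= 1L, V * m >= 2L,
            within_gap_mm > 0, between_gap_mm > 0, stated_spacing_mm > 0,
            all(pixel_spacing_mm > 0), n_rows >= 1L, n_cols >= 1L)
  spec <- structure(
    list(specimen_id = specimen_id, n_volumes = V, slices_per_volume = m,
         within_gap_mm = within_gap_mm, between_gap_mm = between_gap_mm,
         stated_spacing_mm = stated_spacing_mm,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         phantom = phantom,
         fiducial_positions_mm = fiducial_positions_mm,
         seed = as.integer(seed)),
    class = "synthetic_series_spec"
  )
  if (phantom == "ELLIPSOID_WITH_FIDUCIALS") {
    if (is.null(spec$fiducial_positions_mm)) {
      spec$fiducial_positions_mm <- .default_fiducials(spec)
    }
    .check_fiducials(spec)
  }
  spec
}

#' Preset emulating the study's canonical multi-volume specimen
#'
#' 51 sub-volumes of 6 slices, 0.60 mm gaps within a sub-volume and 0.50 mm
#' between them, with metadata claiming a uniform 0.60 mm — the geometry
#' whose regularized spacing is 0.58360656 mm.
#'
#' @param ... Overrides passed to [synthetic_series_spec()].
#' @return A `synthetic_series_spec`.
#' @export
w584_series_spec <- function(...) {
  args <- utils::modifyList(
    list(specimen_id = "W584", n_volumes = 51L, slices_per_volume = 6L,
         within_gap_mm = 0.60, between_gap_mm = 0.50,
         stated_spacing_mm = 0.60),
    list(...))
  do.call(synthetic_series_spec, args)
}

#' Gap pattern of a sub-volume series spec
#' @param spec A [synthetic_series_spec()].
#' @return Numeric vector of the V*m - 1 consecutive gaps.
#' @export
series_gap_pattern <- function(spec) {
  V <- spec$n_volumes
  m <- spec$slices_per_volume
  per_vol <- rep(spec$within_gap_mm, m - 1L)
  gaps <- numeric(0L)
  for (v in seq_len(V)) {
    gaps <- c(gaps, per_vol)
    if (v < V) gaps <- c(gaps, spec$between_gap_mm)
  }
  gaps
}

# coronal-style orientation: slices advance along +y (posterior)
.series_axes <- function() {
  list(row_dir = c(1, 0, 0), col_dir = c(0, 0, -1), normal = c(0, 1, 0))
}

.series_offsets <- function(spec) {
  c(0, cumsum(series_gap_pattern(spec)))
}

.default_fiducials <- function(spec) {
  ax <- .series_axes()
  offs <- .series_offsets(spec)
  extent <- max(offs)
  mid_r <- (spec$n_rows - 1L) / 2 * spec$pixel_spacing_mm[1L]
  mid_c <- (spec$n_cols - 1L) / 2 * spec$pixel_spacing_mm[2L]
  center <- mid_r * ax$col_dir + mid_c * ax$row_dir
  rbind(center + 0.25 * extent * ax$normal,
        center + 0.75 * extent * ax$normal)
}

.fiducial_voxels <- function(spec) {
  ax <- .series_axes()
  offs <- .series_offsets(spec)
  t(apply(spec$fiducial_positions_mm, 1L, function(p) {
    k <- which.min(abs(offs - sum(p * ax$normal))) - 1L
    p_in <- p - offs[k + 1L] * ax$normal
    i <- round(sum(p_in * ax$col_dir) / spec$pixel_spacing_mm[1L])
    j <- round(sum(p_in * ax$row_dir) / spec$pixel_spacing_mm[2L])
    c(row = i, col = j, slice = k)
  }))
}

.check_fiducials <- function(spec) {
  ax <- .series_axes()
  offs <- .series_offsets(spec)
  tol <- spec$within_gap_mm / 2
  axial <- apply(spec$fiducial_positions_mm, 1L,
                 function(p) sum(p * ax$normal))
  if (any(axial < min(offs) - tol | axial > max(offs) + tol)) {
    stop("fiducial out of bounds", call. = FALSE)
  }
  vox <- .fiducial_voxels(spec)
  n_slices <- spec$n_volumes * spec$slices_per_volume
  ok <- vox[, 1L] >= 0 & vox[, 1L] < spec$n_rows &
    vox[, 2L] >= 0 & vox[, 2L] < spec$n_cols &
    vox[, 3L] >= 0 & vox[, 3L] < n_slices
  if (!all(ok)) stop("fiducial out of bounds", call. = FALSE)
  invisible(vox)
}

#' Build a synthetic series geometry (and phantom pixels) in memory
#'
#' Realizes a [synthetic_series_spec()] as a [series_geometry()] whose slice
#' origins follow the V/m/w/b gap pattern exactly and whose
#' acquisition-number tag increments per sub-volume. With the fiducial
#' phantom, pixel grids hold a bright ellipsoid (intensity 1000) plus two
#' point fiducials (intensity 32000) whose true physical positions are
#' returned as ground truth. Fully deterministic given the spec.
#'
#' @param spec A [synthetic_series_spec()].
#' @return List with `geometry` (a `series_geometry`) and `ground_truth`
#'   (list: `gap_pattern_mm`, `n_volumes`, `slices_per_volume`,
#'   `within_gap_mm`, `between_gap_mm`, and for fiducial phantoms
#'   `fiducial_positions_mm`, `fiducial_voxels`,
#'   `fiducial_distance_mm` between the voxel-snapped markers under the true
#'   geometry).
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_series_spec"))
  ax <- .series_axes()
  offs <- .series_offsets(spec)
  n <- length(offs)
  V <- spec$n_volumes
  m <- spec$slices_per_volume

  fid_vox <- NULL
  if (spec$phantom == "ELLIPSOID_WITH_FIDUCIALS") {
    fid_vox <- .check_fiducials(spec)
  }

  records <- vector("list", n)
  for (k in seq_len(n)) {
    pixels <- NULL
    if (spec$phantom == "ELLIPSOID_WITH_FIDUCIALS") {
      pixels <- .phantom_slice(spec, offs, k, fid_vox)
    }
    records[[k]] <- slice_record(
      specimen_id = spec$specimen_id,
      instance_index = k,
      acquisition_index = ((k - 1L) %/% m) + 1L,
      position_mm = offs[k] * ax$normal,
      row_dir = ax$row_dir, col_dir = ax$col_dir,
      pixel_spacing_mm = spec$pixel_spacing_mm,
      stated_spacing_mm = spec$stated_spacing_mm,
      n_rows = spec$n_rows, n_cols = spec$n_cols,
      pixels = pixels
    )
  }
  geometry <- series_geometry(records, specimen_id = spec$specimen_id)

  gt <- list(gap_pattern_mm = series_gap_pattern(spec),
             n_volumes = V, slices_per_volume = m,
             within_gap_mm = spec$within_gap_mm,
             between_gap_mm = if (V > 1L) spec$between_gap_mm else NA_real_)
  if (!is.null(fid_vox)) {
    gt$fiducial_positions_mm <- spec$fiducial_positions_mm
    gt$fiducial_voxels <- fid_vox
    d_vox <- fid_vox[2L, ] - fid_vox[1L, ]
    gt$fiducial_distance_mm <- sqrt(
      (d_vox[1L] * spec$pixel_spacing_mm[1L])^2 +
      (d_vox[2L] * spec$pixel_spacing_mm[2L])^2 +
      (offs[fid_vox[2L, 3L] + 1L] - offs[fid_vox[1L, 3L] + 1L])^2)
  }
  list(geometry = geometry, ground_truth = gt)
}

.phantom_slice <- function(spec, offs, k, fid_vox) {
  extent <- max(offs)
  rows <- seq_len(spec$n_rows) - 1L
  cols <- seq_len(spec$n_cols) - 1L
  # ellipsoid centered mid-grid / mid-stack, semi-axes 40% of each extent
  cr <- (spec$n_rows - 1L) / 2
  cc <- (spec$n_cols - 1L) / 2
  a_r <- 0.4 * spec$n_rows * spec$pixel_spacing_mm[1L]
  a_c <- 0.4 * spec$n_cols * spec$pixel_spacing_mm[2L]
  a_z <- max(0.4 * extent, spec$within_gap_mm)
  dz2 <- ((offs[k] - extent / 2) / a_z)^2
  dr2 <- (((rows - cr) * spec$pixel_spacing_mm[1L]) / a_r)^2
  dc2 <- (((cols - cc) * spec$pixel_spacing_mm[2L]) / a_c)^2
  inside <- outer(dr2, dc2, "+") + dz2 <= 1
  pix <- matrix(0L, spec$n_rows, spec$n_cols)
  pix[inside] <- 1000L
  for (f in seq_len(nrow(fid_vox))) {
    if (fid_vox[f, 3L] == k - 1L) {
      pix[fid_vox[f, 1L] + 1L, fid_vox[f, 2L] + 1L] <- 32000L
    }
  }
  pix
}

#' Specification of a synthetic repeated-measurement study
#'
#' Emulates the validation study's design: three specimen groups measured
#' repeatedly with calipers (`Original`), on CT models under one or two
#' assigned slice spacings, and once with an articulated-arm digitizer
#' (`Microscribe`). Group 1 is scanned at 0.75 mm (correctly assigned);
#' groups 2 and 3 each carry a correctly-assigned and a misassigned CT
#' modality (true spacings 0.60 and 0.58360656 mm respectively, the
#' misassignment swapping the two).
#'
#' Per specimen, the true distance D is drawn uniformly from
#' `true_distance_range_mm`; caliper replicates are `Normal(D, sd)`; CT
#' replicates under assigned spacing \eqn{s_a} when the truth is \eqn{s_t}
#' are `Normal(D * sqrt((1-f) + f (s_a/s_t)^2), sd)` with `f` the axial
#' fraction; the Microscribe value is `Normal(D + offset, sd)`.
#'
#' The defaults are the study conditions: 10 + 5 + 5 specimens, 10
#' replicates, distances spanning the published 113-153 mm range, a fully
#' axial measurement (f = 1), and noise levels (caliper 0.4 mm, CT 0.3 mm,
#' Microscribe 0.3 mm with a +0.5 mm offset) chosen to reproduce the
#' published interval widths of roughly 1-3 mm; the study itself publishes
#' no variance components, so these are model assumptions, all
#' configurable.
#'
#' @param n_group1,n_group2,n_group3 Specimens per group.
#' @param true_distance_range_mm Length-2 range for the uniform draw of D.
#' @param axial_fraction Share of squared distance along the slice axis.
#' @param true_spacing_mm Named numeric: true spacing per group.
#' @param assigned_spacing_mm Named list: per group, named numeric of CT
#'   modality -> assigned spacing.
#' @param noise_sd_mm Named numeric: `Original`, `CT`, `Microscribe` sds.
#' @param microscribe_offset_mm Systematic digitizer offset, mm.
#' @param replicates Replicates per repeated modality (>= 2).
#' @param seed Integer master seed; per-specimen substreams are derived
#'   deterministically, so adding specimens never perturbs earlier ones.
#' @return A `synthetic_measurement_spec`.
#' @export
synthetic_measurement_spec <- function(
    n_group1 = 10L, n_group2 = 5L, n_group3 = 5L,
    true_distance_range_mm = c(110, 155),
    axial_fraction = 1,
    true_spacing_mm = c(G1 = 0.75, G2 = 0.60, G3 = 0.58360656),
    assigned_spacing_mm = list(
      G1 = c(CT_0.75 = 0.75),
      G2 = c(CT_0.60 = 0.60, CT_0.58 = 0.58360656),
      G3 = c(CT_0.58 = 0.58360656, CT_0.60 = 0.60)),
    noise_sd_mm = c(Original = 0.4, CT = 0.3, Microscribe = 0.3),
    microscribe_offset_mm = 0.5,
    replicates = 10L,
    seed = 1L) {
  stopifnot(all(noise_sd_mm >= 0), replicates >= 2L,
            all(true_spacing_mm > 0),
            all(unlist(assigned_spacing_mm) > 0),
            axial_fraction >= 0, axial_fraction <= 1,
            length(true_distance_range_mm) == 2L,
            true_distance_range_mm[1L] <= true_distance_range_mm[2L])
  structure(
    list(n_specimens = c(G1 = as.integer(n_group1),
                         G2 = as.integer(n_group2),
                         G3 = as.integer(n_group3)),
         true_distance_range_mm = true_distance_range_mm,
         axial_fraction = axial_fraction,
         true_spacing_mm = true_spacing_mm,
         assigned_spacing_mm = assigned_spacing_mm,
         noise_sd_mm = noise_sd_mm,
         microscribe_offset_mm = microscribe_offset_mm,
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "synthetic_measurement_spec"
  )
}

.specimen_seed <- function(master, idx) {
  # deterministic substream per specimen, kept inside 32-bit integer range
  as.integer((as.double(master) * 7919 + 104729 * idx) %% 2147483647)
}

#' Generate a synthetic repeated-measurement table
#'
#' @param spec A [synthetic_measurement_spec()].
#' @return A validated measurement table (long-format data.frame:
#'   `specimen_id`, `group`, `modality`, `replicate`, `distance_mm`) plus a
#'   `"ground_truth"` attribute (data.frame of per-specimen true distances).
#' @export
make_measurement_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_measurement_spec"))
  rows <- list()
  truths <- list()
  idx <- 0L
  for (grp in names(spec$n_specimens)) {
    for (i in seq_len(spec$n_specimens[[grp]])) {
      idx <- idx + 1L
      sp_id <- sprintf("SYN%03d", idx)
      withr::with_seed(.specimen_seed(spec$seed, idx), {
        D <- stats::runif(1L, spec$true_distance_range_mm[1L],
                          spec$true_distance_range_mm[2L])
        reps <- spec$replicates
        add <- function(modality, values) {
          rows[[length(rows) + 1L]] <<- data.frame(
            specimen_id = sp_id, group = grp, modality = modality,
            replicate = seq_along(values), distance_mm = values,
            stringsAsFactors = FALSE)
        }
        add("Original", stats::rnorm(reps, D, spec$noise_sd_mm[["Original"]]))
        s_t <- spec$true_spacing_mm[[grp]]
        f <- spec$axial_fraction
        for (md in names(spec$assigned_spacing_mm[[grp]])) {
          s_a <- spec$assigned_spacing_mm[[grp]][[md]]
          mu <- D * sqrt((1 - f) + f * (s_a / s_t)^2)
          add(md, stats::rnorm(reps, mu, spec$noise_sd_mm[["CT"]]))
        }
        add("Microscribe",
            stats::rnorm(1L, D + spec$microscribe_offset_mm,
                         spec$noise_sd_mm[["Microscribe"]]))
        truths[[length(truths) + 1L]] <- data.frame(
          specimen_id = sp_id, group = grp, true_distance_mm = D,
          true_spacing_mm = s_t, stringsAsFactors = FALSE)
      })
    }
  }
  tab <- do.call(rbind, rows)
  validate_measurement_table(tab)
  attr(tab, "ground_truth") <- do.call(rbind, truths)
  tab
}
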