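# Shared fixture builders for the test suite. Everything is generated in
# code; no binary files ship with the package.

# random sub-volume series spec under a fixed RNG state
random_series_spec <- function(id = "RND") {
  V <- sample(1:8, 1L)
  m <- if (V == 1L) sample(2:12, 1L) else sample(1:12, 1L)
  if (V * m < 2L) m <- 2L
  synthetic_series_spec(
    specimen_id = id,
    n_volumes = V, slices_per_volume = m,
    within_gap_mm = runif(1L, 0.3, 1.2),
    between_gap_mm = runif(1L, 0.3, 1.2),
    stated_spacing_mm = runif(1L, 0.3, 1.2),
    seed = sample.int(1e6, 1L)
  )
}

# closed-form regularized spacing of a V x m / w / b series
closed_form_spacing <- function(spec) {
  V <- spec$n_volumes
  m <- spec$slices_per_volume
  (V * (m - 1L) * spec$within_gap_mm +
     (V - 1L) * spec$between_gap_mm) / (V * m - 1L)
}

# minimal geometry built directly from slice records, offsets given in mm
geometry_from_offsets <- function(offsets, acq = NULL, stated = NA_real_,
                                  id = "GEO") {
  if (is.null(acq)) acq <- rep(1L, length(offsets))
  records <- lapply(seq_along(offsets), function(i) {
    slice_record(
      specimen_id = id, instance_index = i, acquisition_index = acq[i],
      position_mm = c(0, offsets[i], 0),
      row_dir = c(1, 0, 0), col_dir = c(0, 0, -1),
      pixel_spacing_mm = c(0.5, 0.5), stated_spacing_mm = stated
    )
  })
  series_geometry(records, specimen_id = id)
}
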