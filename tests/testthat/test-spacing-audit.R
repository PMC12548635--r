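test_that("gap profiling clusters with the absolute tolerance", {
  g <- geometry_from_offsets(cumsum(c(0, rep(0.75, 9))))
  p <- profile_gaps(g)
  expect_equal(nrow(p$distinct_gaps), 1L)
  expect_equal(p$distinct_gaps$count, 9L)
  expect_equal(p$dominant_gap_mm, 0.75, tolerance = 1e-12)

  # counts from the 51x6 pattern: 51*5 intra gaps, 50 inter gaps
  w <- make_series(w584_series_spec())$geometry
  pw <- profile_gaps(w)
  expect_equal(pw$distinct_gaps$value, c(0.50, 0.60), tolerance = 1e-6)
  expect_equal(pw$distinct_gaps$count, c(50L, 255L))
  expect_equal(pw$dominant_gap_mm, 0.60, tolerance = 1e-6)

  # 0.6 and 0.6005 merge under the 1e-3 tolerance; 0.5 stays separate
  g3 <- geometry_from_offsets(cumsum(c(0, 0.6, 0.6005, 0.5)))
  p3 <- profile_gaps(g3)
  expect_equal(nrow(p3$distinct_gaps), 2L)
  expect_equal(p3$distinct_gaps$count, c(1L, 2L))
})

test_that("dominant-gap ties break toward the smaller value", {
  g <- geometry_from_offsets(cumsum(c(0, 0.5, 0.5, 0.7, 0.7)))
  expect_equal(profile_gaps(g)$dominant_gap_mm, 0.5, tolerance = 1e-12)
})

test_that("sub-volume detection recovers runs from acquisition tags and from gaps", {
  g <- geometry_from_offsets(cumsum(c(0, rep(0.6, 9))))
  s <- detect_subvolumes(g)
  expect_equal(nrow(s$runs), 1L)
  expect_equal(s$runs$n_slices, 10L)
  expect_length(s$between_gaps_mm, 0L)

  w <- make_series(w584_series_spec())$geometry
  sw <- detect_subvolumes(w)
  expect_equal(nrow(sw$runs), 51L)
  expect_true(all(sw$runs$n_slices == 6L))
  expect_equal(sw$between_gaps_mm, rep(0.5, 50L), tolerance = 1e-6)

  # no acquisition tags: split where a gap leaves the dominant cluster
  g2 <- geometry_from_offsets(cumsum(c(0, 0.6, 0.6, 0.5, 0.6, 0.6)))
  s2 <- detect_subvolumes(g2)
  expect_equal(s2$runs$n_slices, c(3L, 3L))
  expect_equal(s2$between_gaps_mm, 0.5, tolerance = 1e-9)

  # a 1-slice run reports its within-gap as absent
  g3 <- geometry_from_offsets(c(0, 0.6, 1.2, 1.7),
                              acq = c(1L, 1L, 1L, 2L))
  s3 <- detect_subvolumes(g3)
  expect_equal(s3$runs$n_slices, c(3L, 1L))
  expect_true(is.na(s3$runs$within_gap_mm[2L]))
})

test_that("regularized spacing is the mean gap and matches the closed form", {
  w <- make_series(w584_series_spec())$geometry
  expect_equal(round(regularized_spacing(w), 8L), 0.58360656)

  g <- geometry_from_offsets(cumsum(c(0, rep(0.62, 7))))
  expect_equal(regularized_spacing(g), 0.62, tolerance = 1e-12)

  spec <- synthetic_series_spec("V3", 3L, 4L, 0.6, 0.5)
  g3 <- make_series(spec)$geometry
  expect_equal(regularized_spacing(g3), 6.4 / 11, tolerance = 1e-12)

  expect_error(
    regularized_spacing(list(offsets_mm = 0)), "undefined spacing")
})

test_that("regularized spacing equals the mean-gap oracle and closed form over random specs", {
  withr::local_seed(8351)
  for (i in 1:100) {
    spec <- random_series_spec()
    g <- make_series(spec)$geometry
    reg <- regularized_spacing(g)
    expect_equal(reg, mean(g$gaps_mm), tolerance = 1e-12)
    expect_equal(reg, closed_form_spacing(spec), tolerance = 1e-12)
    expect_gte(reg, min(g$gaps_mm) - 1e-12)
    expect_lte(reg, max(g$gaps_mm) + 1e-12)
  }
})

test_that("regularized spacing is strictly increasing in the between-volume gap", {
  bs <- seq(0.3, 0.9, by = 0.1)
  vals <- vapply(bs, function(b) {
    regularized_spacing(make_series(
      synthetic_series_spec("M", 5L, 4L, 0.6, b))$geometry)
  }, numeric(1L))
  expect_true(all(diff(vals) > 0))
})

test_that("audit flags inconsistency and metadata mismatch correctly", {
  u <- make_series(synthetic_series_spec("U", 1L, 10L, 0.75,
                                         stated_spacing_mm = 0.75))$geometry
  a <- audit(u)
  expect_equal(a$status, "UNIFORM")
  expect_true(a$metadata_match)
  expect_equal(a$relative_discrepancy, 0, tolerance = 1e-9)

  w <- make_series(w584_series_spec())$geometry
  aw <- audit(w)
  expect_equal(aw$status, "INCONSISTENT")
  expect_equal(round(aw$regularized_spacing_mm, 8L), 0.58360656)
  expect_false(aw$metadata_match)
  expect_equal(aw$relative_discrepancy, (0.58360656 - 0.60) / 0.60,
               tolerance = 1e-6)

  u6 <- make_series(synthetic_series_spec("U6", 1L, 10L, 0.60,
                                          stated_spacing_mm = 0.60))$geometry
  expect_true(audit(u6)$metadata_match)
  expect_equal(audit(u6)$status, "UNIFORM")

  # a single deviant gap is enough to flag INCONSISTENT
  g1 <- geometry_from_offsets(cumsum(c(0, rep(0.6, 8), 0.5)),
                              stated = 0.6)
  expect_equal(audit(g1)$status, "INCONSISTENT")
})

test_that("sub-volume recovery works with tags and, when gaps differ, without", {
  withr::local_seed(5150)
  for (i in 1:20) {
    spec <- random_series_spec()
    g <- make_series(spec)$geometry
    s <- detect_subvolumes(g)
    expect_equal(nrow(s$runs), spec$n_volumes)
    expect_true(all(s$runs$n_slices == spec$slices_per_volume))
    # strip acquisition tags: recovery still works when |w - b| > tolerance
    if (abs(spec$within_gap_mm - spec$between_gap_mm) > 1e-3 &&
        spec$slices_per_volume >= 2L) {
      g2 <- g
      g2$slices <- lapply(g2$slices, function(s) {
        s$acquisition_index <- 1L
        s
      })
      s2 <- detect_subvolumes(g2)
      expect_equal(nrow(s2$runs), spec$n_volumes)
    }
  }
})

test_that("specimen triage table encodes the collection's group boundaries", {
  expect_equal(expected_group("W100")$stated_spacing_mm, 0.75)
  expect_false(expected_group("W100")$error_expected)
  expect_equal(expected_group("W100")$corrected_basis, "STATED")

  w584 <- expected_group("W584")
  expect_equal(w584$stated_spacing_mm, 0.60)
  expect_true(w584$error_expected)
  expect_equal(w584$corrected_basis, "REGULARIZED")

  w670 <- expected_group("W670")
  expect_equal(w670$stated_spacing_mm, 0.60)
  expect_false(w670$error_expected)

  # boundaries
  expect_false(expected_group("W487")$error_expected)
  expect_true(expected_group("W488")$error_expected)
  expect_true(expected_group("W669")$error_expected)

  expect_error(expected_group("W0"), "unknown specimen")
  expect_error(expected_group("W986"), "unknown specimen")
  expect_error(expected_group("X12"), "unknown specimen")
})

test_that("regularization produces an arithmetic offset sequence and is idempotent", {
  u <- make_series(synthetic_series_spec("U", 1L, 8L, 0.7))$geometry
  ru <- regularize_geometry(u)
  expect_equal(ru$offsets_mm, u$offsets_mm, tolerance = 1e-12)

  w <- make_series(w584_series_spec())$geometry
  rw <- regularize_geometry(w)
  s <- regularized_spacing(w)
  expect_equal(rw$offsets_mm, w$offsets_mm[1L] + (0:305) * s,
               tolerance = 1e-9)
  expect_equal(rw$offsets_mm, regularize_geometry(rw)$offsets_mm,
               tolerance = 1e-12)
  # slice count and in-plane metadata preserved
  expect_length(rw$slices, 306L)
  expect_equal(rw$slices[[1L]]$pixel_spacing_mm,
               w$slices[[1L]]$pixel_spacing_mm)
})

test_that("audit serializes to the documented JSON and CSV schemas", {
  w <- make_series(w584_series_spec())$geometry
  a <- audit(w)
  js <- jsonlite::fromJSON(audit_json(a))
  expect_equal(js$specimen_id, "W584")
  expect_equal(js$status, "INCONSISTENT")
  expect_equal(js$regularized_spacing_mm, 0.58360656)
  expect_equal(js$n_subvolumes, 51L)
  row <- audit_summary_row(a)
  expect_equal(names(row)[1:4],
               c("specimen_id", "status", "stated_spacing_mm",
                 "regularized_spacing_mm"))

  f <- withr::local_tempfile(fileext = ".nhdr")
  write_nrrd_header(w, f)
  lines <- readLines(f)
  expect_equal(lines[1L], "NRRD0004")
  expect_true(any(grepl("0.58360656", lines, fixed = TRUE)))
})
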