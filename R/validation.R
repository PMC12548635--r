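# Repeated-measures validation statistics: paired t-tests with Bonferroni
# adjustment, 99% prediction intervals for a single future observation, and
# inclusion audits of one-shot digitizer measurements against those
# intervals. This is the machinery used to decide which slice spacing of a
# scan group faithfully represents the physical specimens.

MODALITY_LEVELS <- c("CT_0.58", "CT_0.60", "CT_0.75", "Original",
                     "Microscribe")

#' Validate a long-format repeated-measurement table
#'
#' The table holds repeated landmark-distance measurements per specimen and
#' modality: `specimen_id`, `group` (`G1`/`G2`/`G3`), `modality` (one of
#' `r paste(MODALITY_LEVELS, collapse = ", ")`), `replicate` (>= 1),
#' `distance_mm` (> 0). Microscribe is a one-shot digitizer: exactly one
#' replicate per specimen; every other modality needs >= 2 replicates.
#'
#' @param table A data.frame in the schema above.
#' @return The table, invisibly, after validation.
#' @export
validate_measurement_table <- function(table) {
  required <- c("specimen_id", "group", "modality", "replicate",
                "distance_mm")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0L) stop("measurement table is empty", call. = FALSE)
  bad_mod <- setdiff(unique(table$modality), MODALITY_LEVELS)
  if (length(bad_mod)) {
    stop("unknown modality: ", paste(bad_mod, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$distance_mm)) || any(table$distance_mm <= 0)) {
    stop("distance_mm must be finite and positive", call. = FALSE)
  }
  key <- paste(table$specimen_id, table$modality, table$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (specimen, modality, replicate) rows", call. = FALSE)
  }
  counts <- stats::aggregate(replicate ~ specimen_id + modality,
                             data = table, FUN = length)
  ms <- counts$modality == "Microscribe"
  if (any(counts$replicate[ms] != 1L)) {
    stop("Microscribe must have exactly 1 replicate per specimen",
         call. = FALSE)
  }
  if (any(counts$replicate[!ms] < 2L)) {
    stop("non-Microscribe modalities need >= 2 replicates", call. = FALSE)
  }
  invisible(table)
}

#' Read / write a measurement table as CSV
#'
#' @param path CSV path (header required, UTF-8, decimal point).
#' @return `read_measurement_table()` returns the validated data.frame.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  tab
}

#' @rdname read_measurement_table
#' @param table A measurement table.
#' @export
write_measurement_table <- function(table, path) {
  validate_measurement_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paired t-test on replicate-paired samples
#'
#' The t statistic on differences \eqn{d_i = x_i - y_i} paired by replicate
#' order: \eqn{t = \bar d / (s_d/\sqrt n)}, df = n - 1, two-sided p from the
#' t distribution. If the differences have zero variance but nonzero mean
#' the statistic is reported as signed infinity with p = 0; identical
#' samples are a degenerate pairing and raise an error.
#'
#' @param sample_1,sample_2 Equal-length numeric vectors (n >= 2), paired by
#'   position.
#' @return List with `statistic`, `df`, `p`.
#' @export
paired_t <- function(sample_1, sample_2) {
  n <- length(sample_1)
  if (n != length(sample_2) || n < 2L) {
    stop("samples must have equal length >= 2", call. = FALSE)
  }
  d <- sample_1 - sample_2
  if (all(d == 0)) stop("degenerate pairing: all differences zero",
                        call. = FALSE)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(statistic = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(statistic = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1L))
}

#' Bonferroni adjustment over m comparisons
#'
#' `min(1, m * p)` elementwise. The study design runs 40 within-specimen
#' comparisons (10 + 15 + 15 across the three groups), and that is the
#' default `m` in [run_validation()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons in the family; `>= length(p_values)`.
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p_values, m = length(p_values)) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("invalid probability: p outside [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("m must be >= number of p-values", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Significance label for an adjusted p-value
#'
#' `ns` if p > 0.05; `*` if p <= 0.05; `**` if <= 0.01; `***` if <= 0.001;
#' `****` if <= 0.0001 (most extreme applicable label).
#'
#' @param p_adj Numeric vector of adjusted p-values.
#' @return Character vector of labels.
#' @export
significance_label <- function(p_adj) {
  if (any(!is.na(p_adj) & (p_adj < 0 | p_adj > 1))) {
    stop("invalid probability: p outside [0, 1]", call. = FALSE)
  }
  vapply(p_adj, function(p) {
    if (is.na(p)) NA_character_
    else if (p <= 1e-4) "****"
    else if (p <= 1e-3) "***"
    else if (p <= 1e-2) "**"
    else if (p <= 0.05) "*"
    else "ns"
  }, character(1L))
}

#' Prediction interval for a single future observation
#'
#' The interval from an intercept-only normal model expected to contain one
#' future observation at the stated confidence:
#' \deqn{\bar x \pm t_{(1+c)/2,\,n-1}\; s \sqrt{1 + 1/n}}
#' — wider than the confidence interval for the mean by the factor
#' \eqn{\sqrt{1 + 1/n}}.
#'
#' @param sample Numeric vector, n >= 2.
#' @param confidence Coverage probability in (0, 1). Default 0.99.
#' @return A `prediction_interval`: list with `mean_mm`, `sd_mm`, `n`,
#'   `confidence`, `lower_mm`, `upper_mm`, `degenerate` (TRUE when the
#'   sample has zero spread, collapsing the interval to a point).
#' @export
prediction_interval <- function(sample, confidence = 0.99) {
  n <- length(sample)
  if (n < 2L) stop("insufficient sample: n < 2", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  m <- mean(sample)
  s <- stats::sd(sample)
  degenerate <- s == 0
  if (degenerate) {
    warning("zero-variance sample: degenerate prediction interval",
            call. = FALSE)
    half <- 0
  } else {
    half <- stats::qt((1 + confidence) / 2, df = n - 1L) * s *
      sqrt(1 + 1 / n)
  }
  structure(
    list(mean_mm = m, sd_mm = s, n = n, confidence = confidence,
         lower_mm = m - half, upper_mm = m + half, degenerate = degenerate),
    class = "prediction_interval"
  )
}

#' Inclusion audit of a probe value against a prediction interval
#'
#' Closed-interval membership; `signed_exceedance_mm` is 0 when included,
#' the distance beyond the nearer limit otherwise (positive above the upper
#' limit, negative below the lower).
#'
#' @param probe_mm Scalar probe measurement (e.g. a one-shot digitizer
#'   value).
#' @param interval A [prediction_interval()] or any list with `lower_mm` and
#'   `upper_mm`.
#' @return List with `probe_value_mm`, `included`, `signed_exceedance_mm`.
#' @export
inclusion_audit <- function(probe_mm, interval) {
  lo <- interval$lower_mm
  hi <- interval$upper_mm
  included <- probe_mm >= lo && probe_mm <= hi
  exceed <- if (included) 0 else if (probe_mm > hi) probe_mm - hi
            else probe_mm - lo
  list(probe_value_mm = probe_mm, included = included,
       signed_exceedance_mm = exceed)
}

#' Run the full measurement-validation pipeline on a table
#'
#' Three stages, mirroring the published report layout:
#' \enumerate{
#'   \item all within-specimen pairs of repeated modalities get a paired
#'     t-test, Bonferroni-adjusted over `m` comparisons;
#'   \item each specimen x repeated-modality cell gets a prediction interval
#'     for a single future observation;
#'   \item the specimen's one-shot Microscribe value is probed against every
#'     interval.
#' }
#' Degenerate pairings (identical samples) are recorded with `NA` statistics
#' and the run continues; specimens without a Microscribe value are excluded
#' from the inclusion audit with a warning.
#'
#' @param table A measurement table (see [validate_measurement_table()]).
#' @param confidence Prediction-interval coverage. Default 0.99.
#' @param m Comparison-family size for the Bonferroni adjustment, or
#'   `"auto"` (the number of comparisons actually run).
#' @return List of class `validation_run` with data.frames `comparisons`,
#'   `intervals`, `inclusions` and a `summary` list (`n_comparisons`,
#'   `n_inclusions_true`, `n_inclusions_total`, per-modality inclusion
#'   counts, per group x modality exceedance ranges).
#' @export
run_validation <- function(table, confidence = 0.99, m = "auto") {
  validate_measurement_table(table)
  table$modality <- factor(table$modality, levels = MODALITY_LEVELS)
  specimens <- unique(table$specimen_id)

  comparisons <- list()
  intervals <- list()
  inclusions <- list()
  for (sp in specimens) {
    sub <- table[table$specimen_id == sp, ]
    grp <- sub$group[1L]
    mods <- intersect(MODALITY_LEVELS, as.character(unique(sub$modality)))
    rep_mods <- setdiff(mods, "Microscribe")
    reps <- lapply(rep_mods, function(md) {
      r <- sub[sub$modality == md, ]
      r$distance_mm[order(r$replicate)]
    })
    names(reps) <- rep_mods

    if (length(rep_mods) >= 2L) {
      prs <- utils::combn(rep_mods, 2L)
      for (j in seq_len(ncol(prs))) {
        m1 <- prs[1L, j]; m2 <- prs[2L, j]
        res <- tryCatch(paired_t(reps[[m1]], reps[[m2]]),
                        error = function(e) {
                          warning("specimen ", sp, " ", m1, " vs ", m2,
                                  ": ", conditionMessage(e), call. = FALSE)
                          list(statistic = NA_real_,
                               df = length(reps[[m1]]) - 1L, p = NA_real_)
                        })
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          group = grp, specimen_id = sp, modality_1 = m1, modality_2 = m2,
          n1 = length(reps[[m1]]), n2 = length(reps[[m2]]),
          statistic = res$statistic, df = res$df, p = res$p,
          stringsAsFactors = FALSE)
      }
    }

    for (md in rep_mods) {
      pi <- withCallingHandlers(
        prediction_interval(reps[[md]], confidence),
        warning = function(w) invokeRestart("muffleWarning"))
      intervals[[length(intervals) + 1L]] <- data.frame(
        group = grp, specimen_id = sp, modality = md,
        mean_mm = pi$mean_mm, sd_mm = pi$sd_mm, n = pi$n,
        confidence = confidence, lower_mm = pi$lower_mm,
        upper_mm = pi$upper_mm, degenerate = pi$degenerate,
        stringsAsFactors = FALSE)
    }

    probe <- sub$distance_mm[sub$modality == "Microscribe"]
    if (length(probe) == 1L) {
      for (md in rep_mods) {
        pi <- intervals[[length(intervals) - length(rep_mods) +
                           match(md, rep_mods)]]
        ia <- inclusion_audit(probe, pi)
        inclusions[[length(inclusions) + 1L]] <- data.frame(
          group = grp, specimen_id = sp, reference_modality = md,
          probe_value_mm = probe, lower_mm = pi$lower_mm,
          upper_mm = pi$upper_mm, included = ia$included,
          signed_exceedance_mm = ia$signed_exceedance_mm,
          stringsAsFactors = FALSE)
      }
    } else {
      warning("specimen ", sp,
              " has no Microscribe value; excluded from inclusion audit",
              call. = FALSE)
    }
  }

  comparisons <- do.call(rbind, comparisons)
  intervals <- do.call(rbind, intervals)
  inclusions <- if (length(inclusions)) do.call(rbind, inclusions) else NULL

  if (!is.null(comparisons)) {
    m_eff <- if (identical(m, "auto")) nrow(comparisons) else m
    comparisons$p_adj <- adjust_p(comparisons$p, m_eff)
    comparisons$significance <- significance_label(comparisons$p_adj)
  }

  structure(
    list(comparisons = comparisons, intervals = intervals,
         inclusions = inclusions,
         summary = summarize_validation(comparisons, inclusions)),
    class = "validation_run"
  )
}

summarize_validation <- function(comparisons, inclusions) {
  out <- list(
    n_comparisons = if (is.null(comparisons)) 0L else nrow(comparisons),
    n_inclusions_total = if (is.null(inclusions)) 0L else nrow(inclusions),
    n_inclusions_true = if (is.null(inclusions)) 0L else
      sum(inclusions$included)
  )
  if (!is.null(inclusions)) {
    by_mod <- stats::aggregate(included ~ reference_modality,
                               data = inclusions,
                               FUN = function(x) c(sum(x), length(x)))
    out$inclusions_by_modality <- stats::setNames(
      lapply(seq_len(nrow(by_mod)), function(i) {
        list(n_true = unname(by_mod$included[i, 1L]),
             n_total = unname(by_mod$included[i, 2L]))
      }), by_mod$reference_modality)
    excl <- inclusions[!inclusions$included, , drop = FALSE]
    if (nrow(excl)) {
      key <- paste(excl$group, excl$reference_modality, sep = ":")
      out$exceedance_ranges <- lapply(split(excl, key), function(d) {
        list(min_mm = min(d$signed_exceedance_mm),
             max_mm = max(d$signed_exceedance_mm),
             n_excluded = nrow(d))
      })
    }
  }
  out
}

#' @export
print.validation_run <- function(x, ...) {
  s <- x$summary
  cat("<validation_run> ", s$n_comparisons, " paired comparisons; ",
      s$n_inclusions_true, "/", s$n_inclusions_total,
      " probe inclusions TRUE\n", sep = "")
  if (!is.null(s$inclusions_by_modality)) {
    for (md in names(s$inclusions_by_modality)) {
      im <- s$inclusions_by_modality[[md]]
      cat(sprintf("  %-10s %d/%d included\n", md, im$n_true, im$n_total))
    }
  }
  invisible(x)
}

#' Write the three validation reports to a directory
#'
#' Emits `comparisons.csv` (paired-test rows), `intervals.csv` (prediction
#' interval + inclusion rows) and `summary.json`.
#'
#' @param run A [run_validation()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_validation_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(run$intervals, file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)
  if (!is.null(run$inclusions)) {
    utils::write.csv(run$inclusions, file.path(out_dir, "inclusions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Audit the packaged printed prediction intervals
#'
#' The package ships the published per-specimen prediction intervals and
#' one-shot Microscribe values for the 20 validation skulls as a plain-text
#' fixture. This function re-runs the inclusion audit on those printed
#' limits and returns the computed verdicts next to the printed ones.
#'
#' @param path Fixture CSV; defaults to the packaged copy.
#' @return A data.frame with one row per specimen x reference modality:
#'   printed limits, computed `included`, `signed_exceedance_mm`, and the
#'   printed verdict in `included_printed`.
#' @export
audit_printed_intervals <- function(path = system.file(
  "extdata", "printed_prediction_intervals.csv", package = "ctspacing")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    inclusion_audit(tab$microscribe_mm[i],
                    list(lower_mm = tab$lower_mm[i],
                         upper_mm = tab$upper_mm[i]))
  })
  tab$included <- vapply(res, `[[`, logical(1L), "included")
  tab$signed_exceedance_mm <- vapply(res, `[[`, numeric(1L),
                                     "signed_exceedance_mm")
  tab
}

#' Reproduce the published validation tables from the raw measurement file
#'
#' Runs the complete pipeline (paired t-tests over 40 comparisons,
#' 99% prediction intervals, Microscribe inclusion audit) on the study's raw
#' repeated PR-BA distance file. That file is distributed as supplementary
#' data alongside the study and is not redistributable here, so the caller
#' must supply the path to a local copy (long-format CSV in the
#' [validate_measurement_table()] schema).
#'
#' @param path Path to the raw measurement CSV.
#' @param confidence Prediction-interval coverage. Default 0.99.
#' @param m Bonferroni family size. Default 40, the study's comparison
#'   count.
#' @return A [run_validation()] result.
#' @export
reproduce_supplementary <- function(path, confidence = 0.99, m = 40L) {
  if (!file.exists(path)) {
    stop("raw measurement file not found: ", path,
         "\nDownload the study's raw PR-BA distance table and pass its ",
         "local path.", call. = FALSE)
  }
  run_validation(read_measurement_table(path), confidence = confidence,
                 m = m)
}
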