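# Band-assignment knowledge and second-derivative intensity ratios.
#
# Peak intensity convention: on a second-derivative spectrum an absorbance
# maximum is a *negative* lobe, so intensity is the magnitude of the local
# minimum located inside the search window. Magnitudes keep all ratios
# positive.

#' Load a band assignment table
#'
#' The packaged table maps literature band centers (cm^-1) to vibrational
#' modes and biomolecule classes for the lipid (3000-2800), protein
#' (1800-1500) and carbohydrate/nucleic-acid (1200-900) regions of
#' fibroblast mid-IR spectra. A user table in the same CSV format
#' (`center_cm1, mode, assignment, note`) may be supplied instead.
#'
#' @param path CSV path; default the packaged table.
#' @param match_tolerance maximum |query - center| for a match, in cm^-1.
#'   Default 8, the nominal instrument resolution.
#' @return object of class `band_table`.
#' @export
band_table <- function(path = NULL, match_tolerance = 8) {
  path <- path %||% system.file("extdata", "band_assignments.csv",
                                package = "ftirfp", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("center_cm1", "mode", "assignment")
  if (!all(need %in% names(df)) || nrow(df) == 0) {
    abort("ftirfp_format_error",
          sprintf("%s: band table needs nonempty columns %s",
                  path, paste(need, collapse = ", ")))
  }
  if (!"note" %in% names(df)) df$note <- ""
  if (match_tolerance <= 0) {
    abort("ftirfp_validation_error", "match_tolerance must be positive")
  }
  if (any(df$center_cm1 < 600 | df$center_cm1 > 4000)) {
    abort("ftirfp_validation_error", "band centers must lie in 600-4000 cm^-1")
  }
  structure(list(entries = df, match_tolerance = match_tolerance),
            class = "band_table")
}

#' Assign a wavenumber to the nearest literature band
#'
#' Returns the nearest table entry within the match tolerance, or `NULL` when
#' nothing is close enough. Distance ties break toward the lower wavenumber.
#'
#' @param wavenumber query in cm^-1.
#' @param table a [band_table()].
#' @return one-row data.frame (`center_cm1`, `mode`, `assignment`, `note`) or
#'   `NULL`.
#' @export
assign_band <- function(wavenumber, table = band_table()) {
  d <- abs(table$entries$center_cm1 - wavenumber)
  ok <- which(d <= table$match_tolerance)
  if (length(ok) == 0) return(NULL)
  dmin <- min(d[ok])
  cand <- ok[d[ok] <= dmin + 1e-12]
  pick <- cand[which.min(table$entries$center_cm1[cand])]
  table$entries[pick, , drop = FALSE]
}

#' Peak intensity of a second-derivative spectrum near a target band
#'
#' Locates the local minimum below zero nearest the target inside the closed
#' window `target +/- search_halfwidth` and returns its magnitude (AU cm^2).
#' The magnitude is read from the vertex of a least-squares parabola fitted
#' over up to 3 grid points on each side of the located minimum, which
#' suppresses point noise while leaving the value of a smooth band minimum
#' essentially unchanged; the reported wavenumber is the grid point of the
#' located minimum. Window endpoints count as candidate minima only if the
#' adjacent interior point is higher.
#'
#' @param spec an `ftir_spectrum` holding second-derivative values.
#' @param target_cm1 literature band center in cm^-1.
#' @param search_halfwidth half-width of the search window (default 15 cm^-1,
#'   wide enough to track group-dependent shifts of ~9 cm^-1 without
#'   capturing neighboring bands).
#' @return list with `intensity` (magnitude, >= 0), `wavenumber` (grid point
#'   of the located minimum) and `target`.
#' @export
peak_intensity <- function(spec, target_cm1, search_halfwidth = 15) {
  x <- spec$wavenumbers; y <- spec$absorbance
  lo <- target_cm1 - search_halfwidth; hi <- target_cm1 + search_halfwidth
  if (lo < min(x) - 1e-9 || hi > max(x) + 1e-9) {
    abort("ftirfp_range_error",
          sprintf("search window [%g, %g] not covered by the grid [%g, %g]",
                  lo, hi, min(x), max(x)))
  }
  keep <- which(x >= lo - 1e-9 & x <= hi + 1e-9)
  xs <- x[keep]; ys <- y[keep]
  m <- length(ys)
  if (m < 3) abort("ftirfp_range_error", "search window holds fewer than 3 grid points")
  i <- 2:(m - 1)
  local_min <- i[ys[i] < ys[i - 1] & ys[i] <= ys[i + 1] & ys[i] < 0]
  if (ys[1] < ys[2] && ys[1] < 0) local_min <- c(1L, local_min)
  if (ys[m] < ys[m - 1] && ys[m] < 0) local_min <- c(local_min, m)
  if (length(local_min) == 0) {
    abort("ftirfp_no_peak_error",
          sprintf("no second-derivative minimum below 0 in [%g, %g] cm^-1", lo, hi))
  }
  j <- local_min[which.min(abs(xs[local_min] - target_cm1))]
  val <- ys[j]
  fit_lo <- max(1L, j - 3L); fit_hi <- min(m, j + 3L)
  if (fit_hi - fit_lo >= 2) {
    dx <- xs[fit_lo:fit_hi] - xs[j]
    fit <- stats::lm.fit(cbind(1, dx, dx^2), ys[fit_lo:fit_hi])$coefficients
    if (is.finite(fit[3]) && fit[3] > 0) {
      vertex <- fit[1] - fit[2]^2 / (4 * fit[3])
      if (is.finite(vertex) && vertex < 0) val <- vertex
    }
  }
  list(intensity = abs(unname(val)), wavenumber = xs[j], target = target_cm1)
}

# Band targets of the intensity ratios (cm^-1).
ratio_targets <- list(
  ch2_asym = 2922, ch3_asym = 2959, ch2_sym = 2851,
  carbonyl = 1747, olefinic = 3013
)

#' CH2/CH3 intensity ratio
#'
#' Ratio of the second-derivative peak intensities of the CH2 asymmetric
#' stretch (~2922 cm^-1) and the CH3 asymmetric stretch (~2959 cm^-1),
#' a readout of lipid acyl chain length.
#'
#' @inheritParams peak_intensity
#' @return dimensionless ratio (positive scalar).
#' @export
ch2_ch3_ratio <- function(spec, search_halfwidth = 15) {
  num <- peak_intensity(spec, ratio_targets$ch2_asym, search_halfwidth)
  den <- peak_intensity(spec, ratio_targets$ch3_asym, search_halfwidth)
  if (den$intensity == 0) abort("ftirfp_degenerate_error", "zero CH3 intensity")
  num$intensity / den$intensity
}

#' Carbonyl / total lipid intensity ratio
#'
#' Ester C=O stretch intensity (~1747 cm^-1) over the sum of the saturated
#' CH2 band intensities (~2922 and ~2851 cm^-1); a lipid peroxidation
#' readout.
#'
#' @inheritParams peak_intensity
#' @param allow_zero return 0 instead of failing when no carbonyl minimum is
#'   found (the band may genuinely vanish); default FALSE.
#' @return dimensionless ratio.
#' @export
carbonyl_total_lipid_ratio <- function(spec, search_halfwidth = 15,
                                       allow_zero = FALSE) {
  num <- tryCatch(peak_intensity(spec, ratio_targets$carbonyl, search_halfwidth),
                  ftirfp_no_peak_error = function(e) {
                    if (allow_zero) list(intensity = 0) else stop(e)
                  })
  d1 <- peak_intensity(spec, ratio_targets$ch2_asym, search_halfwidth)
  d2 <- peak_intensity(spec, ratio_targets$ch2_sym, search_halfwidth)
  den <- d1$intensity + d2$intensity
  if (den == 0) abort("ftirfp_degenerate_error", "zero total-lipid intensity")
  num$intensity / den
}

#' Unsaturated / saturated intensity ratio
#'
#' Olefinic =C-H stretch intensity (~3013 cm^-1) over the sum of the
#' saturated CH2 band intensities (~2922 and ~2851 cm^-1); declines with
#' lipid peroxidation. Requires a grid extending above 3013 cm^-1, so it must
#' be computed on the full-range second derivative, not a 3000-2800 crop.
#'
#' @inheritParams carbonyl_total_lipid_ratio
#' @return dimensionless ratio.
#' @export
unsat_sat_ratio <- function(spec, search_halfwidth = 15, allow_zero = FALSE) {
  num <- tryCatch(peak_intensity(spec, ratio_targets$olefinic, search_halfwidth),
                  ftirfp_no_peak_error = function(e) {
                    if (allow_zero) list(intensity = 0) else stop(e)
                  })
  d1 <- peak_intensity(spec, ratio_targets$ch2_asym, search_halfwidth)
  d2 <- peak_intensity(spec, ratio_targets$ch2_sym, search_halfwidth)
  den <- d1$intensity + d2$intensity
  if (den == 0) abort("ftirfp_degenerate_error", "zero total-lipid intensity")
  num$intensity / den
}

#' Compute all three lipid ratios for every spectrum of a set
#'
#' Rows are full-range second-derivative spectra. Per-sample failures (e.g. a
#' flat spectrum with no locatable peaks) are recorded in the `error` column
#' without aborting the batch.
#'
#' @param set an `ftir_spectra_set` of second derivatives.
#' @param search_halfwidth see [peak_intensity()].
#' @return data.frame with one row per spectrum: `sample_id`, `group`,
#'   `replicate`, `ch2_ch3`, `carbonyl_total_lipid`, `unsat_sat`, `error`
#'   (NA when all ratios computed).
#' @export
compute_ratios <- function(set, search_halfwidth = 15) {
  n <- n_spectra(set)
  ch2ch3 <- carb <- unsat <- rep(NA_real_, n)
  err <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- set_row(set, i)
    tryCatch({
      ch2ch3[i] <- ch2_ch3_ratio(s, search_halfwidth)
      carb[i] <- carbonyl_total_lipid_ratio(s, search_halfwidth)
      unsat[i] <- unsat_sat_ratio(s, search_halfwidth)
    }, ftirfp_error = function(e) {
      err[i] <<- conditionMessage(e)
    })
  }
  data.frame(sample_id = set$sample_ids, group = set$groups,
             replicate = set$replicates, ch2_ch3 = ch2ch3,
             carbonyl_total_lipid = carb, unsat_sat = unsat,
             error = err, row.names = NULL)
}
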