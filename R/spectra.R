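#' Construct a single spectrum
#'
#' A spectrum couples a strictly monotone wavenumber grid (cm^-1) with
#' absorbance values (arbitrary units, AU) and sample metadata. Grids are
#' canonicalized to ascending order on construction; a descending input (the
#' usual orientation of spectrometer text exports) is reversed together with
#' its absorbance values.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   monotone in either direction, length >= 2.
#' @param absorbance numeric vector of absorbance values (AU), same length.
#' @param sample_id character scalar identifying the sample.
#' @param group character scalar group label (e.g. "control", "DM1_1000").
#' @param replicate positive integer replicate index.
#' @return An object of class `ftir_spectrum`: a list with fields
#'   `wavenumbers` (ascending), `absorbance`, `sample_id`, `group`,
#'   `replicate`.
#' @export
spectrum <- function(wavenumbers, absorbance, sample_id = "sample",
                     group = "unlabeled", replicate = 1L) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    abort("ftirfp_validation_error", "wavenumbers and absorbance differ in length")
  }
  if (length(wavenumbers) < 2) {
    abort("ftirfp_validation_error", "a spectrum needs at least 2 points")
  }
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    abort("ftirfp_validation_error", "non-finite values in spectrum")
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    abort("ftirfp_validation_error",
          "wavenumbers must be strictly monotone (duplicate or unordered values found)")
  }
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_id = as.character(sample_id), group = as.character(group),
         replicate = as.integer(replicate)),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %s (group %s, replicate %d): %d points, %.1f-%.1f cm^-1\n",
              x$sample_id, x$group, x$replicate, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a set of spectra on a shared grid
#'
#' @param grid ascending numeric wavenumber grid (cm^-1).
#' @param matrix numeric matrix, one row per spectrum, `length(grid)` columns.
#' @param sample_ids character vector, one per row.
#' @param groups character vector of group labels, one per row.
#' @param replicates integer vector of replicate indices, one per row.
#' @param provenance optional list recording how the set was produced.
#' @return An object of class `ftir_spectra_set`.
#' @export
spectra_set <- function(grid, matrix, sample_ids, groups = NULL,
                        replicates = NULL, provenance = list()) {
  grid <- as.numeric(grid)
  matrix <- base::as.matrix(matrix)
  if (any(diff(grid) <= 0)) {
    abort("ftirfp_validation_error", "set grid must be strictly ascending")
  }
  if (ncol(matrix) != length(grid)) {
    abort("ftirfp_validation_error", "matrix columns must match grid length")
  }
  n <- nrow(matrix)
  if (n < 1) abort("ftirfp_validation_error", "a spectra set needs at least 1 row")
  groups <- as.character(groups %||% rep("unlabeled", n))
  replicates <- as.integer(replicates %||% rep(1L, n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n || length(groups) != n || length(replicates) != n) {
    abort("ftirfp_validation_error", "per-row metadata must match the number of rows")
  }
  if (any(!nzchar(groups))) abort("ftirfp_validation_error", "empty group label")
  dimnames(matrix) <- NULL
  structure(
    list(grid = grid, matrix = matrix, sample_ids = sample_ids,
         groups = groups, replicates = replicates, provenance = provenance),
    class = "ftir_spectra_set"
  )
}

#' @export
print.ftir_spectra_set <- function(x, ...) {
  cat(sprintf("<ftir_spectra_set> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              nrow(x$matrix), length(x$grid), min(x$grid), max(x$grid)))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set an `ftir_spectra_set`.
#' @return integer row count.
#' @export
n_spectra <- function(set) nrow(set$matrix)

# Extract row i of a set as an ftir_spectrum.
set_row <- function(set, i) {
  spectrum(set$grid, set$matrix[i, ], sample_id = set$sample_ids[i],
           group = set$groups[i], replicate = set$replicates[i])
}

# Stack spectra (shared grid within 1e-6 cm^-1 absolute) into a set.
#' Combine spectra sharing a common grid into a set
#'
#' Grids must agree within 1e-6 cm^-1 (absolute), the tolerance of text
#' round-trips.
#'
#' @param spectra list of `ftir_spectrum` objects.
#' @return an `ftir_spectra_set`.
#' @export
bind_spectra <- function(spectra) {
  if (length(spectra) < 1) abort("ftirfp_validation_error", "no spectra to bind")
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (length(s$wavenumbers) != length(grid) ||
        any(abs(s$wavenumbers - grid) > 1e-6)) {
      abort("ftirfp_validation_error",
            sprintf("spectrum %s is not on the shared grid", s$sample_id))
    }
  }
  spectra_set(
    grid = grid,
    matrix = do.call(rbind, lapply(spectra, function(s) s$absorbance)),
    sample_ids = vapply(spectra, function(s) s$sample_id, character(1)),
    groups = vapply(spectra, function(s) s$group, character(1)),
    replicates = vapply(spectra, function(s) s$replicate, integer(1))
  )
}
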