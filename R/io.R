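# Readers/writers for the text formats the pipeline touches.

#' Read a two-column wavenumber/absorbance text export
#'
#' Parses Bruker-style DPT exports: one `wavenumber<sep>absorbance` pair per
#' line, separated by comma, tab or whitespace. Lines that are empty or start
#' with `#` are skipped. Descending grids (the usual export orientation) are
#' reversed to ascending.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file stem.
#' @param group,replicate metadata attached to the returned spectrum.
#' @return an `ftir_spectrum`.
#' @export
read_two_column <- function(path, sample_id = NULL, group = "unlabeled",
                            replicate = 1L) {
  if (!file.exists(path)) abort("ftirfp_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) < 2) {
    abort("ftirfp_format_error", sprintf("%s: need at least 2 data lines", path))
  }
  xs <- numeric(length(keep)); ys <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    tok <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) != 2 || any(is.na(vals))) {
      abort("ftirfp_parse_error",
            sprintf("%s: line %d does not parse as two numbers: '%s'", path, i, lines[i]))
    }
    xs[j] <- vals[1]; ys[j] <- vals[2]
  }
  sid <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  spectrum(xs, ys, sample_id = sid, group = group, replicate = replicate)
}

#' Read a wide CSV of spectra plus optional sample metadata
#'
#' The CSV holds one wavenumber column (first) and one column per sample, with
#' a header row of sample ids. The optional metadata CSV has columns
#' `sample_id`, `group`, `replicate`; samples without metadata get group
#' `"unlabeled"` and replicate 1. Metadata rows naming unknown samples are
#' dropped with a warning.
#'
#' @param path wide CSV path.
#' @param metadata_path optional metadata CSV path.
#' @return an `ftir_spectra_set`.
#' @export
read_spectra_csv <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) abort("ftirfp_io_error", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl("[A-Za-z]", first)) {
    abort("ftirfp_format_error", sprintf("%s: missing header row of sample ids", path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) abort("ftirfp_format_error", sprintf("%s: need >= 2 columns", path))
  grid <- as.numeric(df[[1]])
  mat <- t(base::as.matrix(df[, -1, drop = FALSE]))
  ids <- colnames(df)[-1]
  d <- diff(grid)
  if (all(d < 0)) {
    grid <- rev(grid)
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  } else if (!all(d > 0)) {
    abort("ftirfp_validation_error", sprintf("%s: wavenumbers not strictly monotone", path))
  }
  groups <- rep("unlabeled", length(ids))
  reps <- rep(1L, length(ids))
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "replicate")
    if (!all(need %in% names(md))) {
      abort("ftirfp_format_error",
            sprintf("%s: metadata needs columns %s", metadata_path, paste(need, collapse = ", ")))
    }
    unknown <- setdiff(md$sample_id, ids)
    if (length(unknown) > 0) {
      warning(sprintf("metadata rows ignored (sample_id not in %s): %s",
                      basename(path), paste(unknown, collapse = ", ")))
    }
    m <- match(ids, md$sample_id)
    hit <- !is.na(m)
    groups[hit] <- md$group[m[hit]]
    reps[hit] <- as.integer(md$replicate[m[hit]])
  }
  spectra_set(grid, mat, sample_ids = ids, groups = groups, replicates = reps)
}

#' Write a spectra set as wide CSV (plus metadata CSV)
#'
#' Inverse of [read_spectra_csv()]; values are written with full double
#' precision so a write/read round trip reproduces the set to ~1e-16.
#'
#' @param set an `ftir_spectra_set`.
#' @param path output CSV path.
#' @param metadata_path optional path for the sample metadata CSV.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path, metadata_path = NULL) {
  rows <- vapply(seq_along(set$grid), function(j) {
    paste(formatC(c(set$grid[j], set$matrix[, j]), format = "g", digits = 17),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(c("wavenumber", set$sample_ids), collapse = ","), rows), path)
  if (!is.null(metadata_path)) {
    utils::write.csv(
      data.frame(sample_id = set$sample_ids, group = set$groups,
                 replicate = set$replicates),
      metadata_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports AFFN-encoded `##XYPOINTS=` / `##XYDATA=` blocks of plain (X, Y)
#' pairs. Compressed encodings (SQZ/DIF/DIFDUP/PAC letter codes) are rejected
#' explicitly.
#'
#' @param path JCAMP-DX file path.
#' @inheritParams read_two_column
#' @return an `ftir_spectrum`.
#' @export
read_jcamp_xy <- function(path, sample_id = NULL, group = "unlabeled",
                          replicate = 1L) {
  if (!file.exists(path)) abort("ftirfp_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  start <- grep("^##(XYPOINTS|XYDATA)\\s*=", lines)
  if (length(start) == 0) {
    abort("ftirfp_format_error",
          sprintf("%s: no ##XYPOINTS/##XYDATA block found", path))
  }
  start <- start[1]
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body)) & !grepl("^\\$\\$", body)]
  if (any(grepl("[A-DF-Za-df-z%@]", body))) {
    abort("ftirfp_unsupported_error",
          sprintf("%s: compressed JCAMP encodings (SQZ/DIF/DIFDUP) are unsupported", path))
  }
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,;\t ]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) next
    if (length(vals) %% 2 != 0) {
      abort("ftirfp_parse_error",
            sprintf("%s: data line is not (X,Y) pairs: '%s'", path, ln))
    }
    xs <- c(xs, vals[seq(1, length(vals), by = 2)])
    ys <- c(ys, vals[seq(2, length(vals), by = 2)])
  }
  title <- sub("^##TITLE=\\s*", "", grep("^##TITLE=", lines, value = TRUE)[1])
  sid <- sample_id %||%
    (if (!is.na(title) && nzchar(title)) title else sub("\\.[^.]*$", "", basename(path)))
  spectrum(xs, ys, sample_id = sid, group = group, replicate = replicate)
}

#' Resample a spectrum or set onto a target wavenumber grid
#'
#' Linear interpolation; no extrapolation. The target grid must lie inside the
#' source span. Either a target grid or an even spacing (in cm^-1, generating
#' a grid across the source span) can be given.
#'
#' @param x an `ftir_spectrum` or `ftir_spectra_set`.
#' @param target_grid ascending numeric target grid.
#' @param spacing_cm1 alternative: grid spacing in cm^-1.
#' @return object of the same class as `x`, on the target grid.
#' @export
resample_to_grid <- function(x, target_grid = NULL, spacing_cm1 = NULL) {
  src <- if (inherits(x, "ftir_spectrum")) x$wavenumbers else x$grid
  if (is.null(target_grid)) {
    if (is.null(spacing_cm1)) {
      abort("ftirfp_validation_error", "give target_grid or spacing_cm1")
    }
    target_grid <- seq(min(src), max(src), by = spacing_cm1)
  }
  target_grid <- as.numeric(target_grid)
  if (min(target_grid) < min(src) - 1e-9 || max(target_grid) > max(src) + 1e-9) {
    abort("ftirfp_range_error",
          sprintf("target grid [%.6g, %.6g] extends beyond source span [%.6g, %.6g]",
                  min(target_grid), max(target_grid), min(src), max(src)))
  }
  if (inherits(x, "ftir_spectrum")) {
    if (isTRUE(all.equal(target_grid, src, tolerance = 0))) return(x)
    a <- stats::approx(src, x$absorbance, xout = target_grid, method = "linear")$y
    spectrum(target_grid, a, sample_id = x$sample_id, group = x$group,
             replicate = x$replicate)
  } else if (inherits(x, "ftir_spectra_set")) {
    mat <- t(apply(x$matrix, 1, function(r) {
      stats::approx(src, r, xout = target_grid, method = "linear")$y
    }))
    spectra_set(target_grid, mat, sample_ids = x$sample_ids, groups = x$groups,
                replicates = x$replicates, provenance = x$provenance)
  } else {
    abort("ftirfp_validation_error", "x must be an ftir_spectrum or ftir_spectra_set")
  }
}
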