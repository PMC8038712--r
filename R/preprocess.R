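# Spectral preprocessing: baseline correction, total-area normalization,
# Savitzky-Golay second derivative, region selection.

#' Preprocessing configuration
#'
#' @param baseline baseline method: `"rubberband"` (lower convex hull,
#'   default), `"linear"` (line through the endpoints) or `"none"`.
#' @param normalization `"area"` (total |A| trapezoidal area scaled to 1,
#'   default) or `"none"`.
#' @param sg_half_width Savitzky-Golay points per side; window length is
#'   `2 * sg_half_width + 1`. Default 3 (7-point window).
#' @param sg_polyorder polynomial order of the local fit, default 4; must be
#'   smaller than the window length and at least `derivative_order`.
#' @param derivative_order derivative order, default 2.
#' @param regions list of `c(low, high)` wavenumber pairs (cm^-1) analyzed
#'   downstream. Defaults to the lipid, protein and carbohydrate/nucleic-acid
#'   windows 3000-2800, 1800-1500 and 1200-900 cm^-1.
#' @param abs_area logical; normalize by the integral of |A| (default TRUE).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(baseline = "rubberband",
                              normalization = "area",
                              sg_half_width = 3L,
                              sg_polyorder = 4L,
                              derivative_order = 2L,
                              regions = list(c(2800, 3000), c(1500, 1800), c(900, 1200)),
                              abs_area = TRUE) {
  baseline <- match.arg(baseline, c("rubberband", "linear", "none"))
  normalization <- match.arg(normalization, c("area", "none"))
  sg_half_width <- as.integer(sg_half_width)
  sg_polyorder <- as.integer(sg_polyorder)
  derivative_order <- as.integer(derivative_order)
  if (sg_half_width < 1) abort("ftirfp_validation_error", "sg_half_width must be >= 1")
  if (2L * sg_half_width + 1L <= sg_polyorder) {
    abort("ftirfp_validation_error",
          "SG window length (2*half_width + 1) must exceed sg_polyorder")
  }
  if (derivative_order > sg_polyorder) {
    abort("ftirfp_validation_error", "derivative_order must be <= sg_polyorder")
  }
  regions <- lapply(regions, function(r) {
    r <- sort(as.numeric(r))
    if (length(r) != 2 || r[1] >= r[2]) {
      abort("ftirfp_validation_error", "each region must be a (low, high) pair with low < high")
    }
    r
  })
  structure(list(baseline = baseline, normalization = normalization,
                 sg_half_width = sg_half_width, sg_polyorder = sg_polyorder,
                 derivative_order = derivative_order, regions = regions,
                 abs_area = abs_area),
            class = "preprocess_config")
}

# Lower convex hull baseline of (x, y), evaluated at every x.
# grDevices::chull gives the full hull; the two arcs between the leftmost and
# rightmost vertices are both x-monotone, and the lower hull is the pointwise
# minimum of their linear interpolants.
rubberband_baseline <- function(x, y) {
  h <- grDevices::chull(x, y)
  i_left <- which.min(x[h]); i_right <- which.max(x[h])
  wrap <- function(from, to) {
    if (from <= to) h[from:to] else h[c(from:length(h), 1:to)]
  }
  arc1 <- wrap(i_left, i_right)
  arc2 <- rev(wrap(i_right, i_left))
  interp <- function(idx) {
    idx <- idx[order(x[idx])]
    if (length(idx) < 2) return(rep(y[idx], length(x)))
    stats::approx(x[idx], y[idx], xout = x, method = "linear", rule = 2)$y
  }
  pmin(interp(arc1), interp(arc2))
}

#' Baseline-correct a spectrum
#'
#' `"rubberband"` subtracts the lower convex hull of the (wavenumber,
#' absorbance) points, evaluated at every grid point; `"linear"` subtracts the
#' straight line through the first and last points; `"none"` returns the input
#' unchanged.
#'
#' @param spec an `ftir_spectrum`.
#' @param method `"rubberband"`, `"linear"` or `"none"`.
#' @return baseline-corrected `ftir_spectrum`.
#' @export
baseline_correct <- function(spec, method = "rubberband") {
  method <- match.arg(method, c("rubberband", "linear", "none"))
  if (method == "none") return(spec)
  x <- spec$wavenumbers; y <- spec$absorbance
  if (method == "linear") {
    n <- length(x)
    base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  } else {
    if (length(x) < 3) {
      abort("ftirfp_validation_error", "rubberband baseline needs >= 3 points")
    }
    base <- rubberband_baseline(x, y)
  }
  out <- spec
  out$absorbance <- y - base
  out
}

#' Normalize a spectrum to unit total area
#'
#' Scales the spectrum so the trapezoidal integral of |A| over the full grid
#' equals 1. The output is the input times a positive scalar, so band shapes
#' and all intensity ratios are preserved.
#'
#' @param spec an `ftir_spectrum`.
#' @param abs_area integrate |A| (default) rather than signed A.
#' @return normalized `ftir_spectrum`.
#' @export
area_normalize <- function(spec, abs_area = TRUE) {
  y <- if (abs_area) abs(spec$absorbance) else spec$absorbance
  a <- trapz(spec$wavenumbers, y)
  if (!is.finite(a) || abs(a) < 1e-300) {
    abort("ftirfp_degenerate_error",
          sprintf("spectrum %s has zero total area; cannot normalize", spec$sample_id))
  }
  out <- spec
  out$absorbance <- spec$absorbance / a
  out
}

# Central-window SG derivative coefficients, scaled by grid spacing h and
# derivative order: coefficients from signal::sgolay carry the 1/ts^m scaling.
sg_kernel <- function(half_width, polyorder, deriv, h) {
  n <- 2L * half_width + 1L
  F <- signal::sgolay(p = polyorder, n = n, m = deriv, ts = h)
  F[half_width + 1L, ]
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Local least-squares polynomial fit over a sliding window of
#' `2 * half_width + 1` points, returning the second-derivative estimate
#' d2A/dlambda2 in AU cm^2 at every interior point with a full window. The
#' output grid is trimmed by `half_width` points on each side. The grid must
#' be uniform (resample first if not); derivative values are scaled by the
#' true grid spacing, not per-index units.
#'
#' @param spec an `ftir_spectrum` on a uniform grid.
#' @param half_width points per side (default 3).
#' @param polyorder local polynomial order (default 4).
#' @param deriv derivative order (default 2).
#' @return `ftir_spectrum` of derivative values on the trimmed grid.
#' @export
sg_second_derivative <- function(spec, half_width = 3L, polyorder = 4L,
                                 deriv = 2L) {
  x <- spec$wavenumbers; y <- spec$absorbance
  half_width <- as.integer(half_width)
  if (!is_uniform_grid(x)) {
    abort("ftirfp_validation_error",
          "grid is not uniform; resample_to_grid() before differentiating")
  }
  n <- length(x)
  w <- 2L * half_width + 1L
  if (w > n) abort("ftirfp_validation_error", "SG window longer than the spectrum")
  if (w <= polyorder) {
    abort("ftirfp_validation_error", "SG window must exceed polyorder")
  }
  h <- (x[n] - x[1]) / (n - 1)
  k <- sg_kernel(half_width, polyorder, deriv, h)
  d <- sg_apply(y, k, half_width)
  out <- spec
  out$wavenumbers <- x[(half_width + 1L):(n - half_width)]
  out$absorbance <- d
  out
}

# Apply a centered SG kernel to y, returning only full-window outputs.
sg_apply <- function(y, kernel, half_width) {
  filt <- stats::filter(y, rev(kernel), method = "convolution", sides = 2)
  as.numeric(filt[(half_width + 1L):(length(y) - half_width)])
}

#' Restrict a spectrum or set to a wavenumber region
#'
#' Keeps points with `low <= wavenumber <= high` (closed interval). The bounds
#' may be given in either order.
#'
#' @param x an `ftir_spectrum` or `ftir_spectra_set`.
#' @param low,high region bounds in cm^-1.
#' @return object of the same class restricted to the region.
#' @export
select_region <- function(x, low, high) {
  b <- sort(c(low, high))
  grid <- if (inherits(x, "ftir_spectrum")) x$wavenumbers else x$grid
  keep <- which(grid >= b[1] - 1e-9 & grid <= b[2] + 1e-9)
  if (length(keep) == 0) {
    abort("ftirfp_range_error",
          sprintf("region [%g, %g] does not overlap the grid [%g, %g]",
                  b[1], b[2], min(grid), max(grid)))
  }
  if (inherits(x, "ftir_spectrum")) {
    out <- x
    out$wavenumbers <- grid[keep]
    out$absorbance <- x$absorbance[keep]
    out
  } else {
    spectra_set(grid[keep], x$matrix[, keep, drop = FALSE],
                sample_ids = x$sample_ids, groups = x$groups,
                replicates = x$replicates, provenance = x$provenance)
  }
}

#' Run the preprocessing pipeline on a spectra set
#'
#' Applies, in order, baseline correction, total-area normalization and the
#' Savitzky-Golay second derivative to every row. Region selection is *not*
#' performed here: the derivative is computed on the full grid so that window
#' edges fall outside the analysis regions, and regions are cropped afterwards
#' with [select_region()]. The applied configuration is recorded in the result
#' provenance.
#'
#' @param set an `ftir_spectra_set`.
#' @param config a [preprocess_config()].
#' @return preprocessed `ftir_spectra_set` (second derivatives when
#'   `derivative_order > 0`).
#' @export
preprocess_pipeline <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  rows <- lapply(seq_len(n_spectra(set)), function(i) {
    s <- set_row(set, i)
    tryCatch({
      s <- baseline_correct(s, config$baseline)
      if (config$normalization == "area") s <- area_normalize(s, config$abs_area)
      if (config$derivative_order > 0) {
        s <- sg_second_derivative(s, config$sg_half_width, config$sg_polyorder,
                                  config$derivative_order)
      }
      s
    }, ftirfp_error = function(e) {
      abort(class(e)[1], sprintf("sample %s: %s", s$sample_id, conditionMessage(e)))
    })
  })
  out <- bind_spectra(rows)
  out$provenance <- c(set$provenance,
                      list(preprocess = unclass(config)))
  out
}
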