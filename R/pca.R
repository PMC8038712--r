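# Region-restricted PCA with group-discrimination readouts: per-PC side
# tables, quadrant membership, loading peak extraction.

#' Principal component analysis of a spectra set
#'
#' Column-mean-centered PCA (no variance scaling — area normalization already
#' puts spectra on a common scale) by singular value decomposition. Loadings
#' are returned one row per component, unit norm; a deterministic sign
#' convention flips each component so the loading element largest in absolute
#' value is positive, making score signs reproducible across platforms.
#'
#' @param set an `ftir_spectra_set` (typically a preprocessed region).
#' @param k number of components to retain (default 4).
#' @return an object of class `ftir_pca`: list with `scores` (n x k),
#'   `loadings` (k x n_points, rows unit norm), `explained_variance_pct`
#'   (percent of total variance per retained PC), `grid`, `labels`,
#'   `sample_ids`, `centering_mean`.
#' @export
spectra_pca <- function(set, k = 4L) {
  X <- set$matrix
  n <- nrow(X)
  if (n < 2) abort("ftirfp_validation_error", "PCA needs at least 2 spectra")
  k <- as.integer(k)
  kmax <- min(n - 1L, ncol(X))
  if (k > kmax) {
    abort("ftirfp_validation_error",
          sprintf("k = %d exceeds the maximum rank %d", k, kmax))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-300) {
    abort("ftirfp_degenerate_error", "zero-variance matrix: all spectra identical")
  }
  sv <- svd(Xc, nu = kmax, nv = kmax)
  ev <- sv$d^2
  ev_pct <- 100 * ev / sum(ev)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])     # k x p, rows unit norm
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    if (loadings[j, which.max(abs(loadings[j, ]))] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_pct = ev_pct[seq_len(k)],
         grid = set$grid, labels = set$groups, sample_ids = set$sample_ids,
         centering_mean = mu),
    class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d samples, %d PCs; explained variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", x$explained_variance_pct), collapse = ", ")))
  invisible(x)
}

#' Per-group side table for one principal component
#'
#' For each group, the fraction of samples whose score on the component is
#' strictly positive. "Clean separation" is true when every group is
#' sign-homogeneous, i.e. a bipartition of groups exists such that every
#' sample's score sign matches its group's side. A score of exactly zero
#' counts as the nonpositive side.
#'
#' @param pca an `ftir_pca`.
#' @param pc_index component (1-based).
#' @return list with `table` (data.frame: group, n, fraction_positive, side)
#'   and `clean_separation` (logical).
#' @export
pc_side_separation <- function(pca, pc_index) {
  if (pc_index < 1 || pc_index > ncol(pca$scores)) {
    abort("ftirfp_validation_error", "pc_index out of range")
  }
  s <- pca$scores[, pc_index]
  groups <- unique(pca$labels)
  frac <- vapply(groups, function(g) mean(s[pca$labels == g] > 0), numeric(1))
  n <- vapply(groups, function(g) sum(pca$labels == g), integer(1))
  clean <- all(frac == 0 | frac == 1)
  list(
    table = data.frame(group = groups, n = n, fraction_positive = frac,
                       side = ifelse(frac >= 0.5, "positive", "negative"),
                       row.names = NULL),
    clean_separation = clean,
    pc_index = pc_index
  )
}

#' Quadrant membership on a pair of principal components
#'
#' Standard mathematical quadrants on the (pc_i, pc_j) score plane:
#' Q1 = (+, +), Q2 = (-, +), Q3 = (-, -), Q4 = (+, -). Samples with a zero
#' score on either axis are flagged on-axis and excluded from group purity.
#'
#' @param pca an `ftir_pca`.
#' @param pc_i,pc_j component indices (1-based).
#' @return list with `pc_pair`, `samples` (data.frame: sample_id, group,
#'   score_i, score_j, quadrant, on_axis) and `group_summary` (data.frame:
#'   group, majority_quadrant, purity).
#' @export
quadrant_assign <- function(pca, pc_i = 1L, pc_j = 2L) {
  k <- ncol(pca$scores)
  if (pc_i < 1 || pc_i > k || pc_j < 1 || pc_j > k) {
    abort("ftirfp_validation_error", "component index out of range")
  }
  si <- pca$scores[, pc_i]; sj <- pca$scores[, pc_j]
  on_axis <- si == 0 | sj == 0
  quad <- ifelse(si > 0 & sj > 0, "Q1",
          ifelse(si < 0 & sj > 0, "Q2",
          ifelse(si < 0 & sj < 0, "Q3", "Q4")))
  quad[on_axis] <- NA_character_
  samples <- data.frame(sample_id = pca$sample_ids, group = pca$labels,
                        score_i = si, score_j = sj, quadrant = quad,
                        on_axis = on_axis, row.names = NULL)
  groups <- unique(pca$labels)
  gs <- do.call(rbind, lapply(groups, function(g) {
    q <- quad[pca$labels == g & !on_axis]
    if (length(q) == 0) {
      return(data.frame(group = g, majority_quadrant = NA_character_,
                        purity = NA_real_))
    }
    tab <- table(q)
    data.frame(group = g, majority_quadrant = names(tab)[which.max(tab)],
               purity = max(tab) / length(q))
  }))
  list(pc_pair = c(pc_i, pc_j), samples = samples, group_summary = gs)
}

#' Extract dominant peaks of a loading profile
#'
#' Local maxima of the loading row are reported as positive-side peaks, local
#' minima as negative-side peaks; only extrema with
#' `|value| >= min_prominence * max(|loading|)` are kept, sorted by |value|
#' descending. On second-derivative spectra an absorbance band appears as a
#' loading *minimum* on the side of the groups it characterizes.
#'
#' @param pca an `ftir_pca` whose grid is uniform.
#' @param pc_index component (1-based).
#' @param min_prominence relative threshold in (0, 1], default 0.1.
#' @return data.frame with columns `wavenumber`, `loading`, `side`
#'   ("positive"/"negative"); zero rows for a flat loading.
#' @export
loading_peaks <- function(pca, pc_index, min_prominence = 0.1) {
  if (pc_index < 1 || pc_index > nrow(pca$loadings)) {
    abort("ftirfp_validation_error", "pc_index out of range")
  }
  v <- pca$loadings[pc_index, ]
  g <- pca$grid
  vmax <- max(abs(v))
  empty <- data.frame(wavenumber = numeric(0), loading = numeric(0),
                      side = character(0))
  if (vmax < 1e-300) return(empty)
  n <- length(v)
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  is_min <- v[i] < v[i - 1] & v[i] <= v[i + 1]
  idx <- i[is_max | is_min]
  if (length(idx) == 0) return(empty)
  out <- data.frame(wavenumber = g[idx], loading = v[idx],
                    side = ifelse(is_max[match(idx, i)], "positive", "negative"))
  out <- out[abs(out$loading) >= min_prominence * vmax, , drop = FALSE]
  out <- out[order(-abs(out$loading)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
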