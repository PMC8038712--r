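# Nonparametric test battery: normality screen, Kruskal-Wallis omnibus,
# Dunn-type many-to-one rank post hoc, Mann-Whitney U, Welch's t.
#
# All p-values are two-sided; significance is called at p <= alpha.

test_result <- function(test_name, statistic, df = NA_real_, p_value,
                        comparison = "omnibus", adjusted = FALSE,
                        alpha = 0.05, note = NA_character_) {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, comparison = comparison, adjusted = adjusted,
         alpha = alpha, significant = is.finite(p_value) && p_value <= alpha,
         note = note),
    class = "ftir_test_result")
}

#' @export
print.ftir_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g%s\n", x$test_name,
              paste(x$comparison, collapse = " vs "), x$statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Kruskal-Wallis omnibus rank test
#'
#' Midrank-based H with tie correction, referred to the chi-square
#' distribution with k - 1 degrees of freedom (wraps
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return an `ftir_test_result` with fields `statistic` (H), `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) abort("ftirfp_validation_error", "need >= 2 groups")
  if (any(lengths(groups) < 1)) abort("ftirfp_validation_error", "empty group")
  vals <- unlist(groups)
  if (length(vals) < 3) abort("ftirfp_validation_error", "total n must be >= 3")
  if (length(unique(vals)) == 1) {
    abort("ftirfp_degenerate_error", "all observations identical: H undefined")
  }
  kt <- stats::kruskal.test(groups)
  test_result("kruskal_wallis", unname(kt$statistic), unname(kt$parameter),
              kt$p.value, comparison = "omnibus", alpha = alpha)
}

#' Dunn-type many-to-one rank comparisons against a control group
#'
#' Rank analogue of a many-to-one ("Dunnett-style") post hoc after a
#' Kruskal-Wallis omnibus: for each treatment group i,
#' `z = (Rbar_i - Rbar_c) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_c))` on pooled
#' midranks, where `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties.
#' Two-sided normal p per comparison, family-adjusted over the m = k - 1
#' comparisons.
#'
#' @param groups list of numeric vectors.
#' @param control_index index of the control group within `groups`.
#' @param adjustment `"bonferroni"` (default), `"sidak"` or `"none"`.
#' @param alpha significance level.
#' @return list of `ftir_test_result`, one per treatment group, each carrying
#'   the unadjusted statistic and the adjusted p-value (`adjusted = TRUE`
#'   unless `adjustment = "none"`).
#' @export
manytoone_rank_posthoc <- function(groups, control_index = 1L,
                                   adjustment = c("bonferroni", "sidak", "none"),
                                   alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  k <- length(groups)
  if (k < 2) abort("ftirfp_validation_error", "need >= 2 groups")
  if (control_index < 1 || control_index > k) {
    abort("ftirfp_validation_error", "control_index out of range")
  }
  if (length(groups[[control_index]]) == 0) {
    abort("ftirfp_validation_error", "control group is empty")
  }
  gnames <- names(groups) %||% paste0("group", seq_len(k))
  if (is.null(names(groups))) names(groups) <- gnames
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)  # midranks
  sizes <- lengths(groups)
  idx_end <- cumsum(sizes); idx_start <- idx_end - sizes + 1L
  rbar <- vapply(seq_len(k), function(i) mean(r[idx_start[i]:idx_end[i]]), numeric(1))
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  m <- k - 1L
  treat <- setdiff(seq_len(k), control_index)
  out <- lapply(treat, function(i) {
    se <- sqrt(var_base * (1 / sizes[[i]] + 1 / sizes[[control_index]]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[control_index]) / se
    p <- 2 * stats::pnorm(-abs(z))
    p_adj <- switch(adjustment,
                    bonferroni = min(1, m * p),
                    sidak = 1 - (1 - p)^m,
                    none = p)
    test_result("manytoone_rank", unname(z), p_value = p_adj,
                comparison = c(gnames[i], gnames[control_index]),
                adjusted = adjustment != "none", alpha = alpha,
                note = sprintf("unadjusted p = %.6g; adjustment = %s", p, adjustment))
  })
  names(out) <- gnames[treat]
  out
}

#' Mann-Whitney U test for two independent samples
#'
#' Reports `U = min(U_x, U_y)` on midranks. `method = "exact"` uses the exact
#' null distribution (admissible for tie-free samples with both sizes <= 8;
#' with ties it falls back to the normal approximation with a recorded
#' notice); `"normal"` uses the tie-corrected normal approximation with
#' continuity correction; `"auto"` (default) picks exact when admissible.
#' Wraps [stats::wilcox.test()].
#'
#' @param x,y numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param alpha significance level.
#' @return an `ftir_test_result` with `statistic` = U.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    abort("ftirfp_validation_error", "both samples must be nonempty")
  }
  n1 <- length(x); n2 <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  note <- NA_character_
  want_exact <- switch(method,
                       exact = TRUE,
                       normal = FALSE,
                       auto = !has_ties && n1 <= 8 && n2 <= 8)
  if (want_exact && has_ties) {
    note <- "ties present: exact distribution inapplicable, fell back to normal approximation"
    want_exact <- FALSE
  }
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(ux, n1 * n2 - ux)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = want_exact, correct = TRUE)
  )
  test_result("mann_whitney_u", u, p_value = min(1, wt$p.value),
              comparison = c("x", "y"), alpha = alpha, note = note)
}

#' Welch's t-test for unequal variances
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with Welch-Satterthwaite
#' degrees of freedom; wraps [stats::t.test()].
#'
#' @param x,y numeric samples, each with n >= 2.
#' @param alpha significance level.
#' @return an `ftir_test_result` with `statistic` = t and fractional `df`.
#' @export
welch_t <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) {
    abort("ftirfp_validation_error", "both samples need n >= 2")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_result("welch_t", 0, df = length(x) + length(y) - 2,
                         p_value = 1, comparison = c("x", "y"), alpha = alpha))
    }
    abort("ftirfp_degenerate_error", "both samples have zero variance")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result("welch_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, comparison = c("x", "y"), alpha = alpha)
}

#' D'Agostino K-squared normality screen
#'
#' Omnibus normality test combining z-transforms of sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983):
#' `K2 = Z1^2 + Z2^2`, referred to chi-square with 2 df. Carries a
#' parametric/nonparametric recommendation at `alpha`; with n < 8 the
#' transforms are unreliable and an "insufficient n" result with no
#' recommendation is returned.
#'
#' @param values numeric sample.
#' @param alpha significance level.
#' @return an `ftir_test_result` with an extra `recommendation` field
#'   (`"parametric"`, `"nonparametric"` or `NA`).
#' @export
normality_screen <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 8) {
    res <- test_result("dagostino_k2", NA_real_, p_value = NA_real_,
                       comparison = "normality", alpha = alpha,
                       note = sprintf("insufficient n (%d < 8): no recommendation", n))
    res$recommendation <- NA_character_
    res$significant <- NA
    return(res)
  }
  x <- values - mean(values)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  if (m2 == 0) abort("ftirfp_degenerate_error", "zero variance sample")
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  b2s <- m4 / m2^2
  xk <- (b2s - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  res <- test_result("dagostino_k2", k2, df = 2, p_value = p,
                     comparison = "normality", alpha = alpha)
  res$recommendation <- if (p <= alpha) "nonparametric" else "parametric"
  res
}

#' Run the full statistical battery on a ratio table
#'
#' For each ratio column: a normality screen on the pooled values, the
#' Kruskal-Wallis omnibus across groups, many-to-one rank comparisons against
#' the control group, and pairwise Mann-Whitney U tests.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param control group label used as the many-to-one control; default the
#'   first group encountered.
#' @param adjustment post hoc family adjustment, see
#'   [manytoone_rank_posthoc()].
#' @param alpha significance level.
#' @param pool_replicates if `FALSE`, replicate rows are averaged per sample
#'   before testing; default `TRUE` (replicates enter as observations).
#' @return tidy data.frame: `ratio`, `test`, `comparison`, `statistic`, `df`,
#'   `p_value`, `adjusted`, `significant`.
#' @export
ratio_stats <- function(ratios, control = NULL,
                        adjustment = "bonferroni", alpha = 0.05,
                        pool_replicates = TRUE) {
  ratios <- ratios[is.na(ratios$error), , drop = FALSE]
  if (!pool_replicates) {
    agg <- stats::aggregate(
      ratios[c("ch2_ch3", "carbonyl_total_lipid", "unsat_sat")],
      by = list(sample_id = ratios$sample_id, group = ratios$group),
      FUN = mean)
    ratios <- agg
  }
  groups_order <- unique(ratios$group)
  control <- control %||% groups_order[1]
  if (!control %in% groups_order) {
    abort("ftirfp_validation_error", sprintf("control group '%s' not present", control))
  }
  rows <- list()
  add <- function(ratio, tr, comparison) {
    rows[[length(rows) + 1]] <<- data.frame(
      ratio = ratio, test = tr$test_name, comparison = comparison,
      statistic = tr$statistic, df = if (is.null(tr$df)) NA_real_ else tr$df,
      p_value = tr$p_value, adjusted = tr$adjusted,
      significant = isTRUE(tr$significant))
  }
  for (rc in c("ch2_ch3", "carbonyl_total_lipid", "unsat_sat")) {
    vals <- split(ratios[[rc]], factor(ratios$group, levels = groups_order))
    ns <- normality_screen(unlist(vals), alpha = alpha)
    add(rc, ns, "pooled")
    kw <- tryCatch(kruskal_wallis(vals, alpha = alpha),
                   ftirfp_degenerate_error = function(e) NULL)
    if (!is.null(kw)) add(rc, kw, "omnibus")
    ph <- manytoone_rank_posthoc(vals, control_index = match(control, groups_order),
                                 adjustment = adjustment, alpha = alpha)
    for (tr in ph) add(rc, tr, paste(tr$comparison, collapse = " vs "))
    combos <- utils::combn(groups_order, 2, simplify = FALSE)
    for (cb in combos) {
      mw <- mann_whitney_u(vals[[cb[1]]], vals[[cb[2]]], alpha = alpha)
      add(rc, mw, paste(cb, collapse = " vs "))
    }
  }
  do.call(rbind, rows)
}
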