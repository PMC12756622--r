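#' Z-score normalization of a variable table
#'
#' Standardizes each numeric column to mean 0 and sample standard deviation
#' 1 (n-1 denominator), so that variables measured on different scales and
#' units carry equal weight in ordination. Constant columns cannot be
#' standardized and error with the offending column name.
#'
#' @param table A data frame.
#' @param cols Columns to standardize; default all numeric columns.
#' @return The table with the selected columns standardized.
#' @export
zscore_normalize <- function(table, cols = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, logical(1L))]
  for (col in cols) {
    x <- table[[col]]
    if (!is.numeric(x)) stop(sprintf("column '%s' is not numeric", col),
                             call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column '%s' is constant and cannot be standardized", col),
           call. = FALSE)
    table[[col]] <- (x - mean(x)) / s
  }
  table
}

#' Dunn's post hoc test on mean ranks
#'
#' Pairwise z tests on Kruskal-Wallis mean ranks with the standard tie
#' correction: for groups i, j with mean ranks Ri, Rj,
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))`, where
#' `T = sum(t^3 - t)` over tie groups. Two-sided p values are adjusted with
#' [stats::p.adjust()] (Holm by default).
#'
#' @param x Numeric response.
#' @param g Grouping factor (>= 2 groups with >= 2 observations each).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust = "holm") {
  g <- factor(g)
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  N <- length(x)
  r <- rank(x)
  rb <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) *
                 (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rb[[i]] - rb[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust))
}

# compact letter display by insert-and-absorb over a significance relation
cld_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[k]; b <- sig_pairs$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets))
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          length(new_sets[[i]]) < length(new_sets[[j]]))
        keep[i] <- FALSE
    sets <- unique(new_sets[keep])
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (gname in sets[[i]])
      out[gname] <- paste0(out[gname], letters[i])
  out
}

#' Group comparisons for a variable table
#'
#' Orchestrates the routine trial statistics: per variable, a Shapiro-Wilk
#' normality screen (logged, not gating), a Kruskal-Wallis test across
#' groups, and - when the omnibus test is significant at `alpha` - Dunn's
#' post hoc test with multiplicity adjustment, summarized as compact
#' significance letters (groups sharing a letter do not differ at `alpha`).
#' Degenerate variables (constant, or groups with fewer than 2 observations)
#' are skipped with a warning.
#'
#' @param table Data frame of samples x variables.
#' @param variables Character vector of numeric response columns.
#' @param group Name of the grouping column.
#' @param alpha Significance threshold; default 0.05.
#' @param p_adjust Dunn's test adjustment method; default `"holm"`.
#' @return A list with `tests` (per-variable Shapiro p, Kruskal-Wallis
#'   statistic and p) and `groups` (per variable x group: n, mean, sd,
#'   significance letter).
#' @export
group_tests <- function(table, variables, group, alpha = 0.05,
                        p_adjust = "holm") {
  stopifnot(is.data.frame(table), group %in% names(table),
            all(variables %in% names(table)))
  g <- factor(table[[group]])
  tests <- NULL; groups_out <- NULL
  for (v in variables) {
    x <- table[[v]]
    ok <- is.finite(x)
    if (nlevels(droplevels(g[ok])) < 2L || any(table(droplevels(g[ok])) < 2L) ||
        stats::sd(x[ok]) == 0) {
      warning(sprintf("variable '%s' skipped: degenerate groups", v),
              call. = FALSE)
      next
    }
    sw <- tryCatch(stats::shapiro.test(x[ok])$p.value,
                   error = function(e) NA_real_)
    kw <- stats::kruskal.test(x[ok], g[ok])
    lev <- levels(droplevels(g[ok]))
    if (kw$p.value <= alpha) {
      dn <- dunn_test(x[ok], g[ok], p_adjust = p_adjust)
      letters_v <- cld_letters(lev, dn[dn$p_adj <= alpha, , drop = FALSE])
    } else {
      letters_v <- stats::setNames(rep("a", length(lev)), lev)
    }
    tests <- rbind(tests, data.frame(
      variable = v, shapiro_p = sw,
      kw_statistic = unname(kw$statistic), kw_p = kw$p.value))
    groups_out <- rbind(groups_out, data.frame(
      variable = v, group = lev,
      n = as.integer(table(droplevels(g[ok]))[lev]),
      mean = as.numeric(tapply(x[ok], droplevels(g[ok]), mean)[lev]),
      sd = as.numeric(tapply(x[ok], droplevels(g[ok]), stats::sd)[lev]),
      letter = unname(letters_v[lev])))
  }
  list(tests = tests, groups = groups_out)
}

#' Principal component analysis on a standardized table
#'
#' Runs PCA on the z-scored variables ([zscore_normalize()]), equivalent to
#' a correlation-matrix PCA of the raw table.
#'
#' @param table Data frame.
#' @param variables Numeric columns entering the ordination.
#' @return A [stats::prcomp] object (scores in `$x`, loadings in
#'   `$rotation`, explained variance via `summary()`).
#' @export
run_pca <- function(table, variables) {
  z <- zscore_normalize(table[, variables, drop = FALSE])
  stats::prcomp(as.matrix(z), center = FALSE, scale. = FALSE)
}
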