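# Spatially corrected correlation, model-II regression, latitudinal fits,
# and rank-based group comparisons.

#' F-ratio of a correlation coefficient
#'
#' The quantity r^2 / (1 - r^2), reported alongside the modified t-test
#' (it equals the F statistic divided by its numerator degrees of freedom
#' scaling, i.e. before multiplication by df).
#'
#' @param r Pearson correlation in [-1, 1].
#' @return nonnegative numeric.
#' @export
f_ratio <- function(r) {
  if (any(abs(r) > 1)) stop("correlation must lie in [-1, 1]")
  r^2 / (1 - r^2)
}

#' Modified t-test of association between two spatial variables
#'
#' Pearson correlation with spatial autocorrelation-corrected degrees of
#' freedom. The effective sample size (ESS) follows the moment correction
#' of Clifford-Richardson-Hemon/Dutilleul: pairwise great-circle distances
#' between unit centroids are binned into distance classes (number of
#' classes by Sturges' rule); per class, sample autocorrelations of x and
#' of y are estimated; their products (negative products truncated at 0)
#' build the trace correction, giving `ess = min(n, 1 + n^2 / trace)`. The
#' test statistic `(ess - 2) * r^2 / (1 - r^2)` is referred to
#' F(1, ess - 2).
#'
#' @param x,y numeric vectors of per-unit values.
#' @param coords two-column matrix or data.frame of centroid (lat, lon) in
#'   decimal degrees.
#' @param nclass number of distance classes; default Sturges' rule on the
#'   number of pairs.
#' @return object of class `"modified_ttest"`: list with `r`, `f_ratio`
#'   (= r^2/(1-r^2)), `ess`, `df` (= ess - 2), `F_stat` (df-scaled),
#'   `p`, `n`, `nclass`, `degenerate`.
#' @export
modified_ttest <- function(x, y, coords, nclass = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  coords <- as.matrix(coords)[ok, , drop = FALSE]
  n <- length(x)
  if (n < 10) stop("need at least 10 units with both values")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")

  r <- cor(x, y)
  degenerate <- FALSE
  if (1 - r^2 < 1e-12) {
    r <- sign(r) * sqrt(1 - 1e-12)
    degenerate <- TRUE
  }

  # great-circle distances between centroids; coords are (lat, lon)
  d <- geosphere::distm(coords[, c(2, 1)], fun = geosphere::distHaversine)
  iu <- upper.tri(d)
  dv <- d[iu]
  if (is.null(nclass)) nclass <- ceiling(1 + log2(length(dv)))
  br <- seq(0, max(dv) * (1 + 1e-9), length.out = nclass + 1)
  cls <- cut(dv, br, include.lowest = TRUE, labels = FALSE)

  xc <- x - mean(x); yc <- y - mean(y)
  s2x <- mean(xc^2); s2y <- mean(yc^2)
  px <- tcrossprod(xc)[iu]
  py <- tcrossprod(yc)[iu]
  npair <- tabulate(cls, nbins = nclass)
  rho_x <- vapply(seq_len(nclass), function(k)
    if (npair[k] == 0) 0 else mean(px[cls == k]) / s2x, numeric(1))
  rho_y <- vapply(seq_len(nclass), function(k)
    if (npair[k] == 0) 0 else mean(py[cls == k]) / s2y, numeric(1))
  tr <- n + sum(2 * npair * pmax(0, rho_x * rho_y))
  ess <- min(n, 1 + n^2 / tr)
  df <- ess - 2
  fr <- f_ratio(r)
  if (df > 0) {
    F_stat <- df * fr
    p <- pf(F_stat, 1, df, lower.tail = FALSE)
  } else {
    F_stat <- NA_real_
    p <- NA_real_
  }
  structure(list(r = r, f_ratio = fr, ess = ess, df = df, F_stat = F_stat,
                 p = p, n = n, nclass = nclass, degenerate = degenerate),
            class = "modified_ttest")
}

#' @export
print.modified_ttest <- function(x, ...) {
  cat("Modified t-test of spatial association\n")
  cat(sprintf("  correlation coefficient = %.3f, Fstat = %.3f\n",
              x$r, x$f_ratio))
  cat(sprintf("  effective sample size = %.3f (n = %d), df = %.3f\n",
              x$ess, x$n, x$df))
  cat(sprintf("  F(1, df) = %.3f, p = %.4g\n", x$F_stat, x$p))
  if (x$degenerate) cat("  [degenerate: |r| ~ 1, statistic capped]\n")
  if (x$df <= 0) cat("  [ess <= 2: p undefined]\n")
  invisible(x)
}

#' Reduced major axis (model II geometric mean) regression
#'
#' Symmetric regression for the case where both variables carry error:
#' slope = sign(r) * sd(y) / sd(x), intercept through the means.
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance.
#' @return object of class `"rma_fit"`: list with `slope`, `intercept`,
#'   `r2`, `kind = "rma"`, `n`.
#' @export
rma_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (r == 0) slope <- sd(y) / sd(x)  # sign undefined at exactly r = 0
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r2 = r^2, kind = "rma", n = length(x)),
            class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("Reduced major axis regression (n = %d)\n", x$n))
  cat(sprintf("  slope = %.5g, intercept = %.5g, r2 = %.4f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Latitudinal fit of an assemblage variable
#'
#' Quadratic: ordinary least squares of `values ~ lat + lat^2` (the
#' equator-peaked diversity gradient is a quadratic function of latitude).
#' Lowess: locally weighted linear regression with tricube weights and the
#' given span, evaluated at the sorted latitudes.
#'
#' @param values per-unit variable.
#' @param latitudes centroid latitudes in decimal degrees.
#' @param kind "quadratic" or "lowess".
#' @param span lowess span in (0, 1]; default 0.5.
#' @return for "quadratic", a list (class `"latitude_fit"`) with
#'   `coefficients` (intercept, lat, lat2), `r2`, `fitted`; for "lowess", a
#'   list with `x` (sorted latitudes), `y` (curve) and `span`.
#' @export
latitude_fit <- function(values, latitudes, kind = c("quadratic", "lowess"),
                         span = 0.5) {
  kind <- match.arg(kind)
  ok <- is.finite(values) & is.finite(latitudes)
  values <- values[ok]; latitudes <- latitudes[ok]
  if (length(values) < 5) stop("need at least 5 observations")
  if (kind == "lowess") {
    if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
    lo <- lowess(latitudes, values, f = span, iter = 0)
    return(structure(list(kind = "lowess", x = lo$x, y = lo$y, span = span),
                     class = "latitude_fit"))
  }
  fit <- lm(values ~ latitudes + I(latitudes^2))
  # direct r2; a constant response is defined as r2 = 0, not the 0/0 ratio
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  structure(list(kind = "quadratic",
                 coefficients = setNames(coef(fit),
                                         c("intercept", "lat", "lat2")),
                 r2 = r2, fitted = fitted(fit)),
            class = "latitude_fit")
}

#' @export
print.latitude_fit <- function(x, ...) {
  if (x$kind == "quadratic") {
    cat(sprintf("Quadratic latitudinal fit: r2 = %.4f\n", x$r2))
    print(x$coefficients)
  } else {
    cat(sprintf("Lowess latitudinal fit (span = %.2f, %d points)\n",
                x$span, length(x$x)))
  }
  invisible(x)
}

#' Rank-based group comparisons
#'
#' Two groups: Wilcoxon rank-sum test (exact when the combined sample size
#' is at most 20 and there are no ties, otherwise normal approximation
#' with tie correction). More than two groups with `pairwise = TRUE`: all
#' pairwise Mann-Whitney tests with Holm adjustment.
#'
#' @param groups named list of numeric vectors, each nonempty.
#' @param alternative "two.sided", "less" or "greater" (the one-tailed
#'   direction refers to the first group of each pair).
#' @param pairwise compare all pairs when more than two groups.
#' @return data.frame with one row per comparison: `group1`, `group2`,
#'   `n1`, `n2`, `W`, `p`, `p_adj`, `method`.
#' @export
rank_compare <- function(groups, alternative = c("two.sided", "less",
                                                 "greater"),
                         pairwise = FALSE) {
  alternative <- match.arg(alternative)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  pairs <- if (length(groups) == 2 || !pairwise) {
    if (length(groups) > 2) stop("more than two groups requires pairwise = TRUE")
    list(names(groups))
  } else {
    combn(names(groups), 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = alternative, exact = exact,
                  correct = !exact))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               W = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "holm")
  out[c("group1", "group2", "n1", "n2", "W", "p", "p_adj", "method")]
}
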