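## Spatial congruence of invasive and non-invasive richness surfaces:
## Dutilleul's modified test (effective degrees of freedom under spatial
## autocorrelation) and loess residual hot spots.

#' Drop grid cells empty of both alien groups
#'
#' Cells where neither invasive nor non-invasive species were recorded
#' are removed to reduce the influence of uninvaded cells.  Idempotent;
#' the number of removed cells is attached as attribute `n_dropped`.
#'
#' @param grid data frame with columns `richness_invasive` and
#'   `richness_noninvasive`.
#' @return the filtered grid.
#' @export
drop_empty_cells <- function(grid) {
  stopifnot(all(c("richness_invasive", "richness_noninvasive") %in%
                  names(grid)))
  empty <- grid$richness_invasive == 0 & grid$richness_noninvasive == 0
  if (all(empty)) stop("all grid cells are empty of both alien groups")
  out <- grid[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(empty)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged).  Constant input is
#' flagged rather than returning `NA` silently.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return the rank correlation.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

# Moran's I of centred values z for a 0/1 adjacency matrix A
moran_i <- function(z, A) {
  n <- length(z)
  s <- sum(A)
  if (s == 0) return(NA_real_)
  (n / s) * drop(z %*% A %*% z) / sum(z^2)
}

#' Dutilleul's modified test of correlation under spatial autocorrelation
#'
#' Tests the correlation between two variables observed at spatial
#' locations, replacing the sample size by an effective sample size that
#' accounts for the spatial autocorrelation of both variables
#' (Dutilleul 1993).  The spatial correlation structure of each variable
#' is estimated by Moran's I over equal-width distance classes on the
#' range of pairwise distances; the estimated correlation matrices
#' \eqn{\Sigma_X, \Sigma_Y} give the effective sample size
#' \deqn{\hat M = 1 + tr(B\Sigma_X) tr(B\Sigma_Y) / tr(B\Sigma_X B\Sigma_Y)}
#' with \eqn{B} the centring matrix, and the correlation is tested with
#' \eqn{F = r^2 (\hat M - 2) / (1 - r^2)} on \eqn{(1, \hat M - 2)}
#' degrees of freedom.  With `method = "spearman"` (default, matching a
#' rank correlation) the correction is applied to the rank-transformed
#' data; `method = "pearson"` uses the raw values.
#'
#' Distance classes without pairs are dropped (merged into their
#' neighbours' complement) with a warning.
#'
#' @param x,y numeric vectors.
#' @param coords two-column matrix or data frame of planar centroid
#'   coordinates.
#' @param n_classes number of equal-width distance classes.
#' @param method `"spearman"` or `"pearson"`.
#' @return list of class `phynat_dutilleul`: `r`, `effective_df`
#'   (\eqn{\hat M - 2}), `effective_n`, `F`, `p`, `method`, `n`.
#' @export
dutilleul_test <- function(x, y, coords, n_classes = 13,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- length(x)
  stopifnot(length(y) == n, nrow(coords) == n, n >= 10)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  u <- if (method == "spearman") rank(x) else as.numeric(x)
  v <- if (method == "spearman") rank(y) else as.numeric(y)
  r <- cor(u, v)
  D <- as.matrix(dist(coords))
  dmax <- max(D)
  brk <- seq(0, dmax, length.out = n_classes + 1)
  cls <- matrix(cut(D, breaks = c(-1e-9, brk[-1]), labels = FALSE), n, n)
  diag(cls) <- 0L
  zu <- u - mean(u)
  zv <- v - mean(v)
  Sx <- diag(1, n)
  Sy <- diag(1, n)
  empty <- 0L
  for (k in seq_len(n_classes)) {
    A <- (cls == k) * 1
    if (sum(A) == 0) { empty <- empty + 1L; next }
    Ix <- moran_i(zu, A)
    Iy <- moran_i(zv, A)
    Sx[A == 1] <- Ix
    Sy[A == 1] <- Iy
  }
  if (empty > 0) {
    warning(empty, " empty distance class(es) dropped")
  }
  # trace identities with the centring matrix B = I - J/n, all O(n^2):
  # tr(B S)      = tr(S) - sum(S)/n
  # tr(B Sx B Sy)= sum(dc(Sx) * Sy), dc = double centring
  tr_bx <- sum(diag(Sx)) - sum(Sx) / n
  tr_by <- sum(diag(Sy)) - sum(Sy) / n
  rm_x <- rowMeans(Sx); gm_x <- mean(Sx)
  dcx <- Sx - outer(rm_x, rep(1, n)) - outer(rep(1, n), rm_x) + gm_x
  tr_bxy <- sum(dcx * Sy)
  m_hat <- 1 + tr_bx * tr_by / tr_bxy
  df <- m_hat - 2
  if (!is.finite(df) || df <= 0) {
    warning("degenerate effective sample size; reporting undefined test")
    out <- list(r = r, effective_df = NA_real_, effective_n = m_hat,
                F = NA_real_, p = NA_real_, method = method, n = n)
    class(out) <- "phynat_dutilleul"
    return(out)
  }
  Fstat <- r^2 * df / (1 - r^2)
  p <- pf(Fstat, 1, df, lower.tail = FALSE)
  out <- list(r = r, effective_df = df, effective_n = m_hat, F = Fstat,
              p = p, method = method, n = n)
  class(out) <- "phynat_dutilleul"
  out
}

#' @export
print.phynat_dutilleul <- function(x, ...) {
  cat(sprintf(
    "Modified (Dutilleul) correlation test [%s]\n  r = %.3f, F = %.3g, df = 1, %.3g, p = %.4g  (n = %d)\n",
    x$method, x$r, x$F, x$effective_df, x$p, x$n))
  invisible(x)
}

#' Loess fit of one richness surface on another
#'
#' Local second-degree polynomial regression with tricube weights over
#' the `ceiling(span * n)` nearest x-neighbours of each point
#' ([stats::loess()], gaussian family, no robustness iterations), plus a
#' pseudo-R-squared (`1 - SS_res / SS_tot`).
#'
#' @param x predictor vector.
#' @param y response vector.
#' @param span smoothing parameter in `(0, 1]` (fraction of points in
#'   each local neighbourhood).
#' @param degree local polynomial degree.
#' @return list with `fitted`, `residuals`, `pseudo_r2`, and the `loess`
#'   `model` object.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2) {
  n <- length(x)
  stopifnot(length(y) == n, degree >= 0)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (ceiling(span * n) < degree + 2) {
    stop("span too small: local neighbourhood of ", ceiling(span * n),
         " points cannot identify a degree-", degree, " polynomial")
  }
  fit <- loess(y ~ x, span = span, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct"))
  fitted <- predict(fit, newdata = data.frame(x = x))
  res <- y - fitted
  list(fitted = fitted, residuals = res,
       pseudo_r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       model = fit)
}

#' Residual hot spots of invasive richness
#'
#' Residuals from a loess regression of invasive on non-invasive alien
#' richness, per grid cell.  Positive residuals mark cells with more
#' invasive richness than predicted from non-invasive richness.
#'
#' @param grid a cleaned grid (see [drop_empty_cells()]).
#' @param span,degree loess parameters.
#' @return data frame `x`, `y`, `richness_invasive`,
#'   `richness_noninvasive`, `fitted`, `residual`; attribute `pseudo_r2`.
#' @export
residual_hotspots <- function(grid, span = 0.75, degree = 2) {
  fit <- loess_fit(grid$richness_noninvasive, grid$richness_invasive,
                   span = span, degree = degree)
  out <- data.frame(x = grid$x, y = grid$y,
                    richness_invasive = grid$richness_invasive,
                    richness_noninvasive = grid$richness_noninvasive,
                    fitted = fit$fitted, residual = fit$residuals)
  attr(out, "pseudo_r2") <- fit$pseudo_r2
  out
}
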