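#' Direct least-squares ellipse fit
#'
#' Fits the conic `Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0` to 2D points by the
#' stabilized direct least-squares method (Fitzgibbon's ellipse-specific
#' constraint `4AC - B^2 = 1`, solved via the Halir-Flusser block
#' decomposition). The fit is deterministic and non-iterative, passes exactly
#' through five points in general position, and has zero residual for points
#' lying exactly on an ellipse.
#'
#' @param points n x 2 matrix of (x, y) points, n >= 5, not all collinear.
#' @return an object of class `fitted_ellipse`: list with `center` (x, y),
#'   semi-axes `a >= b > 0`, orientation `theta` (radians, angle of the major
#'   axis in `[0, pi)`), eccentricity `e = sqrt(1 - b^2/a^2)`, and the conic
#'   coefficients `conic`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 41)[-41]
#' fit_ellipse(cbind(2 * cos(t), sin(t)))
#' @export
fit_ellipse <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 2L) stop("'points' must be an n x 2 matrix")
  if (nrow(P) < 5L) stop("ellipse fitting needs at least 5 points")
  if (!all(is.finite(P))) stop("non-finite points")
  # normalize for conditioning
  ctr <- colMeans(P)
  sc <- max(stats::sd(P[, 1]), stats::sd(P[, 2]))
  if (!is.finite(sc) || sc < 1e-12) stop("degenerate point set")
  x <- (P[, 1] - ctr[1]) / sc
  y <- (P[, 2] - ctr[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point set (collinear or coincident points)"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok))
    stop("no elliptical solution for these points")
  a1 <- vecs[, ok[1L]]
  co <- c(a1, drop(Tm %*% a1))
  # undo normalization: substitute x -> (x - cx)/s, y -> (y - cy)/s
  A <- co[1] / sc^2; B <- co[2] / sc^2; C <- co[3] / sc^2
  D <- co[4] / sc - (2 * A * ctr[1] + B * ctr[2])
  E <- co[5] / sc - (2 * C * ctr[2] + B * ctr[1])
  F <- co[6] + A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 -
       co[4] * ctr[1] / sc - co[5] * ctr[2] / sc
  conic_to_ellipse(c(A, B, C, D, E, F))
}

conic_to_ellipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  if (B^2 - 4 * A * C >= 0)
    stop("conic is not an ellipse")
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  center <- drop(solve(-2 * M, c(D, E)))
  F0 <- F + (D * center[1] + E * center[2]) / 2
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -F0 / ev$values
  if (any(ax2 <= 0))
    stop("degenerate (imaginary or point) ellipse")
  ax <- sqrt(ax2)
  i_major <- which.max(ax)              # major axis <-> smaller eigenvalue
  a <- max(ax); b <- min(ax)
  theta <- atan2(ev$vectors[2, i_major], ev$vectors[1, i_major]) %% pi
  structure(list(center = c(x = center[1], y = center[2]),
                 a = a, b = b, theta = theta,
                 e = sqrt(1 - b^2 / a^2), conic = co),
            class = "fitted_ellipse")
}

#' @export
print.fitted_ellipse <- function(x, ...) {
  cat(sprintf(
    "Fitted ellipse: center (%.4g, %.4g), a = %.6g, b = %.6g, theta = %.4g rad, e = %.6g\n",
    x$center[1], x$center[2], x$a, x$b, x$theta, x$e))
  invisible(x)
}

#' Ellipse through manually clicked hinge-pouch fold points
#'
#' Alternative, expression-independent delimitation of the wing pouch: the
#' ellipse is fitted by least squares to points clicked on the hinge-pouch
#' (HP) folds of a DAPI-stained disc, rather than derived from the reporter
#' pattern itself.
#'
#' @param fold_points n x 2 matrix of clicked points, n >= 5.
#' @return a `fitted_ellipse`.
#' @export
fit_hp_ellipse <- function(fold_points) {
  fit_ellipse(fold_points)
}

#' Sample points on a fitted ellipse boundary
#'
#' @param ellipse a `fitted_ellipse` (or list with `center`, `a`, `b`,
#'   `theta`).
#' @param n number of boundary points.
#' @return n x 2 matrix of (x, y) points.
#' @export
ellipse_boundary <- function(ellipse, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  cbind(x = ellipse$center[1] + ellipse$a * cos(t) * ct - ellipse$b * sin(t) * st,
        y = ellipse$center[2] + ellipse$a * cos(t) * st + ellipse$b * sin(t) * ct)
}
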