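# shared fixtures and independent oracles, built in code at test time

random_config <- function(k = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(2 * k), k, 2)
}

as_config <- function(xy, id = "w", labels = NULL, ...) {
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(xy)))
  landmark_config(xy, labels, wing_id = id, landmark_set = "SYM10", ...)
}

# brute-force Procrustes oracle: dense rotation grid x reflection, with the
# analytic optimal scale at each angle; independent of the SVD route
grid_disparity_oracle <- function(X, Y, n_angles = 36000) {
  std <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  X <- std(X); Y <- std(Y)
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  best <- Inf
  for (refl in c(1, -1)) {
    Yr <- Y %*% diag(c(1, refl))
    c1 <- sum(X * Yr)
    c2 <- sum(X[, 1] * Yr[, 2] - X[, 2] * Yr[, 1])
    tr <- pmax(c1 * cos(th) + c2 * sin(th), 0)
    best <- min(best, 1 - max(tr)^2)
  }
  best
}

# rasterize a filled ellipse into a 0/1 matrix (independent of the package's
# phantom generator)
raster_ellipse <- function(a, b, theta = 0, center = NULL,
                           shape = c(512L, 512L)) {
  nr <- shape[1]; nc <- shape[2]
  if (is.null(center)) center <- c(nc / 2, nr / 2)
  gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  gy <- matrix(seq_len(nr), nr, nc)
  ct <- cos(theta); st <- sin(theta)
  u <- (gx - center[1]) * ct + (gy - center[2]) * st
  v <- -(gx - center[1]) * st + (gy - center[2]) * ct
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nr, nc)
}

# points exactly on an ellipse boundary
ellipse_points <- function(a, b, theta = 0, center = c(0, 0), n = 200) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(theta); st <- sin(theta)
  cbind(center[1] + a * cos(t) * ct - b * sin(t) * st,
        center[2] + a * cos(t) * st + b * sin(t) * ct)
}

apply_similarity <- function(xy, angle = 0, scale = 1, shift = c(0, 0),
                             reflect = FALSE) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (reflect) R <- R %*% diag(c(-1, 1))
  sweep(scale * (xy %*% R), 2, shift, `+`)
}
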