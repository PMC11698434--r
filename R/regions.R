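#' Partition a pattern mask into intervein regions
#'
#' Vein polylines (ordered anterior to posterior) partition the foreground of
#' the mask into intervein regions: everything anterior of the first vein,
#' the bands between consecutive veins, and everything posterior of the last
#' vein. Each polyline is extended beyond its endpoints along its terminal
#' segment directions until it exits the mask bounding box, since manual
#' clicks rarely reach the pattern edge. A pixel is assigned by counting the
#' veins it lies strictly posterior of; pixels exactly on a vein go to the
#' anterior-side region (deterministic sub-pixel tie-break).
#'
#' @param mask 0/1 matrix.
#' @param veins named list of vein polylines (n x 2 matrices of (x, y) click
#'   points), in anterior-to-posterior order, e.g.
#'   `list(L2 = ..., L3 = ..., L4 = ..., L5 = ...)`.
#' @return integer matrix of the mask shape: 0 = background, k = region
#'   index (1 = most anterior). Attribute `region_names` holds the region
#'   labels, `"M-<first>"`, `"<i>-<i+1>"`, ..., `"<last>-M"`.
#' @export
segment_mask_by_veins <- function(mask, veins) {
  mask <- as.matrix(mask)
  if (!length(veins)) stop("at least one vein polyline is required")
  vnames <- names(veins)
  if (is.null(vnames)) vnames <- paste0("V", seq_along(veins))
  fg <- mask_coords(mask)
  if (!nrow(fg)) stop("empty mask")
  bbox <- c(0, ncol(mask) + 1, 0, nrow(mask) + 1)   # xmin,xmax,ymin,ymax
  post_count <- integer(nrow(fg))
  for (i in seq_along(veins)) {
    pl <- clean_polyline(veins[[i]], vnames[i])
    pl <- extend_polyline(pl, bbox)
    side <- polyline_side(fg, pl)
    post_sign <- vein_posterior_sign(i, veins, vnames, pl)
    post_count <- post_count + as.integer(side * post_sign > 0)
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[cbind(fg[, 2], fg[, 1])] <- post_count + 1L
  k <- length(veins)
  rn <- c(paste0("M-", vnames[1L]),
          if (k > 1L) paste0(vnames[-k], "-", vnames[-1L]),
          paste0(vnames[k], "-M"))
  attr(lab, "region_names") <- rn
  lab
}

clean_polyline <- function(pl, name) {
  pl <- as.matrix(pl)
  if (ncol(pl) != 2L || nrow(pl) < 2L)
    stop(sprintf("vein '%s': polyline needs at least 2 points", name))
  keep <- c(TRUE, rowSums((pl[-1L, , drop = FALSE] -
                           pl[-nrow(pl), , drop = FALSE])^2) > 1e-18)
  pl <- pl[keep, , drop = FALSE]
  if (nrow(pl) < 2L)
    stop(sprintf("vein '%s': degenerate polyline (coincident points), cannot separate the mask",
                 name))
  pl
}

# prepend/append points along the terminal segment directions, long enough
# to exit the bounding box
extend_polyline <- function(pl, bbox) {
  span <- sqrt((bbox[2] - bbox[1])^2 + (bbox[4] - bbox[3])^2) * 2
  d1 <- pl[1L, ] - pl[2L, ]
  dn <- pl[nrow(pl), ] - pl[nrow(pl) - 1L, ]
  d1 <- d1 / sqrt(sum(d1^2)); dn <- dn / sqrt(sum(dn^2))
  rbind(pl[1L, ] + span * d1, pl, pl[nrow(pl), ] + span * dn)
}

# signed side of each point w.r.t. its nearest polyline segment:
# positive = left of the oriented polyline (image coordinates, y down)
polyline_side <- function(pts, pl) {
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  side <- numeric(n)
  for (k in seq_len(nrow(pl) - 1L)) {
    a <- pl[k, ]; b <- pl[k + 1L, ]
    e <- b - a
    len2 <- sum(e^2)
    rel_x <- pts[, 1] - a[1]; rel_y <- pts[, 2] - a[2]
    t <- pmin(pmax((rel_x * e[1] + rel_y * e[2]) / len2, 0), 1)
    dx <- rel_x - t * e[1]; dy <- rel_y - t * e[2]
    d2 <- dx^2 + dy^2
    cr <- e[1] * rel_y - e[2] * rel_x
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    side[upd] <- cr[upd]
  }
  sign(side)
}

# which side sign is posterior for vein i: the side holding the next vein's
# click centroid (or, for the last vein, the opposite of the previous vein's
# side). A single vein defaults to "posterior = left of the oriented
# polyline".
vein_posterior_sign <- function(i, veins, vnames, pl_ext) {
  if (length(veins) == 1L) return(1)
  ref_idx <- if (i < length(veins)) i + 1L else i - 1L
  ref <- matrix(colMeans(as.matrix(veins[[ref_idx]])), ncol = 2)
  s <- polyline_side(ref, pl_ext)
  if (s == 0)
    stop(sprintf("vein '%s' coincides with its neighbor; cannot orient regions",
                 vnames[i]))
  if (i < length(veins)) s else -s
}

#' Absolute and relative intervein region areas from a labeled map
#'
#' Counts pixels per region of a partition produced by
#' [segment_mask_by_veins()]. Relative areas divide by the total foreground,
#' so they sum to exactly 1: the partition assigns every foreground pixel to
#' exactly one region.
#'
#' @param labelmap labeled region map from [segment_mask_by_veins()].
#' @return a `region_area_table`: data.frame with columns `region`,
#'   `absolute_area` (pixels), `relative_area`; attribute `reference` is
#'   `"pattern"`.
#' @export
relative_region_areas <- function(labelmap) {
  rn <- attr(labelmap, "region_names")
  if (is.null(rn)) stop("'labelmap' must come from segment_mask_by_veins()")
  total <- sum(labelmap > 0)
  if (total == 0) stop("empty labelmap")
  counts <- vapply(seq_along(rn), function(k) sum(labelmap == k), numeric(1))
  structure(
    data.frame(region = rn, absolute_area = counts,
               relative_area = counts / total, stringsAsFactors = FALSE),
    reference = "pattern", class = c("region_area_table", "data.frame"))
}

#' @export
print.region_area_table <- function(x, ...) {
  cat(sprintf("Intervein region areas (reference: %s)\n", attr(x, "reference")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Intervein region areas within a fitted ellipse
#'
#' Vein-independent variant: the pouch is modeled as the ellipse (e.g. fitted
#' through the hinge-pouch folds), rasterized, and partitioned by the vein
#' polylines. Relative areas are taken with respect to the true ellipse area
#' `pi * a * b`, so they sum to the rasterized/true area ratio (within ~1%).
#'
#' @param ellipse a `fitted_ellipse`.
#' @param veins named list of vein polylines as in [segment_mask_by_veins()].
#' @param min_semi_axis rasterization detail: the ellipse is scaled so its
#'   minor semi-axis spans at least this many pixels (default 150).
#' @return a `region_area_table` with attribute `reference = "ellipse"`;
#'   absolute areas are in the ellipse's own squared units.
#' @export
ellipse_region_areas <- function(ellipse, veins, min_semi_axis = 150) {
  a <- ellipse$a; b <- ellipse$b
  f <- max(1, min_semi_axis / b)
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  cx <- ellipse$center[1] * f; cy <- ellipse$center[2] * f
  af <- a * f; bf <- b * f
  xr <- floor(cx - af - 2):ceiling(cx + af + 2)
  yr <- floor(cy - af - 2):ceiling(cy + af + 2)
  gx <- matrix(xr, length(yr), length(xr), byrow = TRUE)
  gy <- matrix(yr, length(yr), length(xr))
  u <- (gx - cx) * ct + (gy - cy) * st
  v <- -(gx - cx) * st + (gy - cy) * ct
  inside <- (u / af)^2 + (v / bf)^2 <= 1
  mask <- matrix(as.integer(inside), length(yr), length(xr))
  # veins into the shifted, scaled raster frame
  veins_r <- lapply(veins, function(p) {
    p <- as.matrix(p) * f
    cbind(p[, 1] - xr[1] + 1, p[, 2] - yr[1] + 1)
  })
  names(veins_r) <- names(veins)
  fg <- mask_coords(mask)
  bbox <- c(0, ncol(mask) + 1, 0, nrow(mask) + 1)
  for (i in seq_along(veins_r)) {
    pl <- extend_polyline(clean_polyline(veins_r[[i]], names(veins_r)[i]), bbox)
    s <- polyline_side(fg, pl)
    if (all(s >= 0) || all(s <= 0))
      stop(sprintf("vein '%s' does not cross the ellipse", names(veins_r)[i]))
  }
  lab <- segment_mask_by_veins(mask, veins_r)
  rn <- attr(lab, "region_names")
  counts <- vapply(seq_along(rn), function(k) sum(lab == k), numeric(1))
  structure(
    data.frame(region = rn, absolute_area = counts / f^2,
               relative_area = counts / (pi * af * bf),
               stringsAsFactors = FALSE),
    reference = "ellipse", class = c("region_area_table", "data.frame"))
}

#' Area of a simple polygon
#'
#' Absolute shoelace area; independent of vertex orientation. Used for
#' adult-wing region areas measured on annotation polygons (e.g. the wing
#' blade outline between veins).
#'
#' @param vertices n x 2 matrix (n >= 3) of polygon vertices in order.
#' @return non-negative area in squared coordinate units.
#' @export
polygon_area <- function(vertices) {
  P <- as.matrix(vertices)
  n <- nrow(P)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(P))) stop("non-finite vertices")
  if (polygon_self_intersects(P))
    stop("polygon is self-intersecting")
  abs(signed_loop_area(P))
}

polygon_self_intersects <- function(P) {
  n <- nrow(P)
  seg <- function(i) rbind(P[i, ], P[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next        # adjacent through closure
      if (segments_cross(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# proper crossing test (shared endpoints of adjacent edges excluded by caller)
segments_cross <- function(s1, s2) {
  d1 <- s1[2, ] - s1[1, ]; d2 <- s2[2, ] - s2[1, ]
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE)
  r <- s2[1, ] - s1[1, ]
  t <- (r[1] * d2[2] - r[2] * d2[1]) / den
  u <- (r[1] * d1[2] - r[2] * d1[1]) / den
  t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
}
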