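#' Construct a landmark configuration for one wing
#'
#' A landmark configuration is an ordered, labeled set of 2D points digitized
#' on a single wing. Coordinates follow image convention: the origin is the
#' top-left corner, `x` is the column and `y` the row, with `y` increasing
#' downward. All geometry in the package shares this convention.
#'
#' @param coords numeric matrix with two columns (x, y), one row per landmark.
#' @param labels character vector of unique landmark labels, e.g.
#'   `c("1A", ..., "5A", "1P", ..., "5P")` for the 10-point symmetric set.
#' @param wing_id identifier of the wing.
#' @param cohort one of `"control"`, `"impaired"`.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param landmark_set one of `"ML"` (margin landmarks), `"VL"` (vein
#'   landmarks), `"SYM10"` (10-point AP-paired set), `"EXT26"` (extended
#'   26-point set).
#' @return an object of class `landmark_config`.
#' @examples
#' w <- template_wing()
#' w
#' @export
landmark_config <- function(coords, labels, wing_id = "wing",
                            cohort = c("control", "impaired"),
                            sex = c("unknown", "male", "female"),
                            landmark_set = c("SYM10", "ML", "VL", "EXT26")) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("'coords' must have two columns (x, y)")
  if (!all(is.finite(coords)))
    stop("landmark coordinates must be finite")
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("length(labels) must equal nrow(coords)")
  if (anyDuplicated(labels))
    stop("landmark labels must be unique")
  cohort <- match.arg(cohort)
  sex <- match.arg(sex)
  landmark_set <- match.arg(landmark_set)
  dimnames(coords) <- list(labels, c("x", "y"))
  structure(
    list(wing_id = as.character(wing_id), coords = coords, cohort = cohort,
         sex = sex, landmark_set = landmark_set),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("Landmark configuration '%s' (%s, %s): %d landmarks [%s]\n",
              x$wing_id, x$cohort, x$sex, nrow(x$coords), x$landmark_set))
  print(round(x$coords, 4))
  invisible(x)
}

#' @export
as.matrix.landmark_config <- function(x, ...) x$coords

n_landmarks <- function(config) nrow(config$coords)

#' Bundle landmark configurations into a cohort
#'
#' All configurations in a cohort must share one landmark set with identical
#' labels in identical order, so that pairwise shape comparison is defined
#' label-wise.
#'
#' @param configurations list of [landmark_config] objects.
#' @param name cohort name.
#' @return an object of class `wing_cohort`.
#' @export
wing_cohort <- function(configurations, name = "cohort") {
  if (!length(configurations))
    stop("a wing cohort needs at least one configuration")
  if (!all(vapply(configurations, inherits, logical(1), "landmark_config")))
    stop("all elements must be landmark_config objects")
  ref <- rownames(configurations[[1L]]$coords)
  sets <- unique(vapply(configurations, function(cf) cf$landmark_set, character(1)))
  if (length(sets) != 1L)
    stop("all configurations must share one landmark_set; found: ",
         paste(sets, collapse = ", "))
  for (cf in configurations) {
    if (!identical(rownames(cf$coords), ref))
      stop(sprintf("configuration '%s' has labels differing from the cohort's",
                   cf$wing_id))
  }
  structure(list(configurations = configurations, name = as.character(name)),
            class = "wing_cohort")
}

#' @export
print.wing_cohort <- function(x, ...) {
  cat(sprintf("Wing cohort '%s': %d configurations, %d landmarks [%s]\n",
              x$name, length(x$configurations),
              nrow(x$configurations[[1L]]$coords),
              x$configurations[[1L]]$landmark_set))
  invisible(x)
}

#' @export
length.wing_cohort <- function(x) length(x$configurations)

#' Anterior/posterior landmark pairing scheme
#'
#' The pairing scheme declares, for each anterior landmark, its posterior
#' counterpart with respect to the AP axis. The axis itself is the line
#' through the midpoints of two designated pairs, by default the pairs on
#' veins L2 and L5: on the adult wing, vein L2 is taken as the counterpart of
#' vein L5 and vein L3 of vein L4.
#'
#' @param anterior character vector of anterior labels.
#' @param posterior character vector of posterior counterpart labels, same
#'   length and order as `anterior`.
#' @param axis_pairs indices (into the pair list) of the two pairs whose
#'   midpoints define the AP axis. Default: pairs 2 and 5.
#' @return an object of class `paired_scheme`.
#' @export
paired_scheme <- function(anterior, posterior, axis_pairs = c(2L, 5L)) {
  anterior <- as.character(anterior)
  posterior <- as.character(posterior)
  if (length(anterior) != length(posterior))
    stop("'anterior' and 'posterior' must have the same length")
  if (length(anterior) < 2L)
    stop("a pairing scheme needs at least two pairs")
  if (any(duplicated(c(anterior, posterior))))
    stop("labels in the pairing must be disjoint and unique")
  axis_pairs <- as.integer(axis_pairs)
  if (length(axis_pairs) != 2L || any(axis_pairs < 1L) ||
      any(axis_pairs > length(anterior)) || axis_pairs[1] == axis_pairs[2])
    stop("'axis_pairs' must be two distinct pair indices")
  structure(list(anterior = anterior, posterior = posterior,
                 axis_pairs = axis_pairs),
            class = "paired_scheme")
}

#' Default 10-point symmetric pairing scheme
#'
#' Pairs `iA` with `iP` for i in 1..5; the AP axis is defined by the midpoints
#' of pairs 2 (vein L2/L5 proxy) and 5.
#' @return a [paired_scheme].
#' @export
sym10_scheme <- function() {
  paired_scheme(paste0(1:5, "A"), paste0(1:5, "P"), axis_pairs = c(2L, 5L))
}

#' @export
print.paired_scheme <- function(x, ...) {
  cat("AP pairing scheme:",
      paste(sprintf("%s<->%s", x$anterior, x$posterior), collapse = " "), "\n")
  cat("axis pairs:", paste(x$axis_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a pairing scheme against a configuration
#'
#' Checks that every label named by the scheme exists in the configuration and
#' that the two axis-pair midpoints are distinct, so the AP axis is defined.
#'
#' @param config a [landmark_config].
#' @param scheme a [paired_scheme].
#' @return a list with elements `ok` (logical), `missing` (labels named by the
#'   scheme but absent from the configuration) and `degenerate_axis` (TRUE if
#'   the two axis midpoints coincide). Never throws for an invalid pairing;
#'   failures are carried in the report.
#' @export
validate_paired_scheme <- function(config, scheme) {
  stopifnot(inherits(config, "landmark_config"), inherits(scheme, "paired_scheme"))
  lab <- rownames(config$coords)
  wanted <- c(scheme$anterior, scheme$posterior)
  missing <- setdiff(wanted, lab)
  degenerate <- FALSE
  if (!length(missing)) {
    m <- axis_midpoints(config, scheme)
    degenerate <- sqrt(sum((m[1, ] - m[2, ])^2)) < 1e-12
  }
  list(ok = !length(missing) && !degenerate,
       missing = missing, degenerate_axis = degenerate)
}

axis_midpoints <- function(config, scheme) {
  xy <- config$coords
  i <- scheme$axis_pairs
  rbind(
    (xy[scheme$anterior[i[1]], ] + xy[scheme$posterior[i[1]], ]) / 2,
    (xy[scheme$anterior[i[2]], ] + xy[scheme$posterior[i[2]], ]) / 2
  )
}

#' Signed area of the ordered landmark loop
#'
#' Shoelace sum over the landmarks treated as a closed loop. Used for
#' chirality normalization: wings are digitized without recording left/right,
#' so configurations whose loop area is negative are mirror-flipped to share
#' one handedness.
#'
#' Plain matrices are traversed in stored order. For a [landmark_config]
#' whose labels follow the AP-paired convention (`1A..kA, 1P..kP`) the
#' boundary loop is traversed instead — anterior labels in order, then
#' posterior labels reversed — because the stored order runs both rows in the
#' same direction and would self-cancel on a symmetric wing.
#'
#' @param config a [landmark_config] or a two-column matrix.
#' @return signed scalar area (image coordinates: y down).
#' @export
signed_loop_area <- function(config) {
  xy <- if (inherits(config, "landmark_config")) {
    lab <- rownames(config$coords)
    ant <- grep("^[0-9]+A$", lab, value = TRUE)
    post <- grep("^[0-9]+P$", lab, value = TRUE)
    if (length(ant) && length(ant) == length(post) &&
        length(ant) + length(post) == length(lab))
      config$coords[c(ant, rev(post)), , drop = FALSE]
    else config$coords
  } else as.matrix(config)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Normalize configuration chirality
#'
#' Reflects the configuration about the vertical axis through its centroid if
#' the signed area of its ordered landmark loop is negative, so that all wings
#' in an analysis share one handedness regardless of unrecorded wing side.
#'
#' @param config a [landmark_config].
#' @return the configuration, reflected if needed.
#' @export
normalize_chirality <- function(config) {
  if (signed_loop_area(config) >= 0) return(config)
  xy <- config$coords
  xy[, 1] <- 2 * mean(xy[, 1]) - xy[, 1]
  config$coords <- xy
  config
}

#' Intersection of a crossvein line with the wing margin
#'
#' Four of the ten margin landmarks are constructed by extending the line
#' defined by the anterior (or posterior) crossvein and intersecting it with
#' the wing-margin outline. The infinite line through the crossvein segment is
#' intersected with every segment of the margin polyline; if several
#' intersections exist the one nearest the crossvein midpoint is returned.
#'
#' @param crossvein 2x2 matrix: the two crossvein endpoints (rows).
#' @param margin n x 2 matrix (n >= 2): the margin polyline, in either
#'   direction of travel.
#' @return length-2 numeric vector (x, y): the constructed margin landmark.
#' @export
crossvein_margin_point <- function(crossvein, margin) {
  crossvein <- as.matrix(crossvein); margin <- as.matrix(margin)
  if (nrow(crossvein) != 2L || any(!is.finite(crossvein)))
    stop("'crossvein' must be a 2x2 matrix of finite endpoints")
  d <- crossvein[2, ] - crossvein[1, ]
  if (sqrt(sum(d^2)) < 1e-12)
    stop("crossvein endpoints must be distinct")
  if (nrow(margin) < 2L)
    stop("margin polyline needs at least two points")
  p0 <- crossvein[1, ]
  hits <- list()
  for (k in seq_len(nrow(margin) - 1L)) {
    a <- margin[k, ]; b <- margin[k + 1L, ]
    e <- b - a
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-14) next            # parallel segment
    # solve p0 + t d = a + u e with u in [0, 1]
    u <- ((a[1] - p0[1]) * d[2] - (a[2] - p0[2]) * d[1]) / den
    if (u >= 0 && u <= 1) hits[[length(hits) + 1L]] <- a + u * e
  }
  if (!length(hits))
    stop("crossvein line does not intersect the margin polyline; ",
         "check the annotation")
  mid <- colMeans(crossvein)
  dist2 <- vapply(hits, function(p) sum((p - mid)^2), numeric(1))
  hits[[which.min(dist2)]]
}
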