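#' Anterior-posterior axis of a landmark configuration
#'
#' The AP axis is the line through the midpoints of the two designated axis
#' pairs of the pairing scheme — by default the midpoint between landmarks 2A
#' and 2P and the midpoint between 5A and 5P.
#'
#' @param config a [landmark_config].
#' @param scheme a [paired_scheme] valid on `config`.
#' @return an object of class `axis_line`: list with `origin` (point on the
#'   line) and `direction` (unit 2-vector).
#' @export
ap_axis <- function(config, scheme = sym10_scheme()) {
  v <- validate_paired_scheme(config, scheme)
  if (length(v$missing))
    stop("configuration is missing scheme labels: ",
         paste(v$missing, collapse = ", "))
  m <- axis_midpoints(config, scheme)
  d <- m[2, ] - m[1, ]
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("degenerate AP axis: the two axis-pair midpoints coincide")
  structure(list(origin = m[1, ], direction = d / len), class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("AP axis: origin (%.4g, %.4g), direction (%.4g, %.4g)\n",
              x$origin[1], x$origin[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Reflect points across an axis line
#'
#' Mirror image across the line: for each point, the perpendicular through it
#' is taken and the point is mapped to the opposite side at equal distance.
#' An isometric involution: applying it twice returns the input.
#'
#' @param p length-2 vector or n x 2 matrix of points.
#' @param axis an `axis_line` from [ap_axis()].
#' @return reflected point(s), same shape as the input.
#' @export
reflect_across_axis <- function(p, axis) {
  vec <- is.null(dim(p))
  P <- if (vec) matrix(p, ncol = 2) else as.matrix(p)
  u <- axis$direction
  rel <- sweep(P, 2, axis$origin)
  along <- rel %*% u                    # component along the axis
  proj <- along %*% t(u)                # projection onto the axis direction
  refl <- sweep(2 * proj - rel, 2, axis$origin, `+`)
  if (vec) drop(refl) else refl
}

#' Symmetrized (anteriorized or posteriorized) configuration
#'
#' Builds the hypothetical mirror-symmetric wing: for `"anteriorized"`, each
#' posterior landmark iP is replaced by the reflection of its anterior
#' counterpart iA across the configuration's own AP axis (and conversely for
#' `"posteriorized"`). Labels and point order are preserved, so Procrustes
#' correspondence with the original remains label-wise; landmarks not named
#' by the scheme are left unchanged. The axis is always computed from the
#' original configuration. The operation is idempotent per side: reflected
#' pairs have their midpoints on the original axis.
#'
#' @param config a [landmark_config].
#' @param scheme a [paired_scheme].
#' @param side `"anteriorized"` or `"posteriorized"`.
#' @return a [landmark_config] with the same labels and order.
#' @export
symmetrize <- function(config, scheme = sym10_scheme(),
                       side = c("anteriorized", "posteriorized")) {
  side <- match.arg(side)
  axis <- ap_axis(config, scheme)
  out <- config
  if (side == "anteriorized") {
    src <- scheme$anterior; dst <- scheme$posterior
  } else {
    src <- scheme$posterior; dst <- scheme$anterior
  }
  out$coords[dst, ] <- reflect_across_axis(config$coords[src, , drop = FALSE],
                                           axis)
  out$wing_id <- paste0(config$wing_id, "_",
                        substr(side, 1, 4))
  out
}

#' AP symmetry scores of one wing
#'
#' The wing is compared, by Procrustes disparity, with its anteriorized and
#' with its posteriorized image. A perfectly mirror-symmetric wing scores
#' (0, 0); larger values indicate more AP asymmetry. Scores are invariant
#' under similarity transforms of the input.
#'
#' @param config a [landmark_config].
#' @param scheme a [paired_scheme].
#' @return named numeric vector `c(d_anteriorized=, d_posteriorized=)`.
#' @export
symmetry_scores <- function(config, scheme = sym10_scheme()) {
  c(d_anteriorized =
      superimpose(config, symmetrize(config, scheme, "anteriorized"))$disparity,
    d_posteriorized =
      superimpose(config, symmetrize(config, scheme, "posteriorized"))$disparity)
}

#' Per-wing symmetry scores for a cohort
#'
#' @param cohort a [wing_cohort].
#' @param scheme a [paired_scheme].
#' @return data.frame with columns `wing_id`, `cohort`, `d_anteriorized`,
#'   `d_posteriorized`.
#' @export
cohort_symmetry_scores <- function(cohort, scheme = sym10_scheme()) {
  stopifnot(inherits(cohort, "wing_cohort"))
  sc <- t(vapply(cohort$configurations, symmetry_scores, numeric(2),
                 scheme = scheme))
  data.frame(
    wing_id = vapply(cohort$configurations, `[[`, character(1), "wing_id"),
    cohort = vapply(cohort$configurations, `[[`, character(1), "cohort"),
    d_anteriorized = sc[, 1], d_posteriorized = sc[, 2],
    stringsAsFactors = FALSE)
}

#' Compare AP symmetry between two cohorts
#'
#' Computes per-wing anteriorized and posteriorized symmetry scores for both
#' cohorts and compares each score type across cohorts with the gated
#' two-sample procedure ([gated_two_sample_test()]).
#'
#' @param controls,impaired [wing_cohort] objects sharing one landmark set.
#' @param scheme a [paired_scheme].
#' @param alpha significance level for the gates and tests.
#' @return list with `scores` (combined per-wing score table), and
#'   `test_anteriorized`, `test_posteriorized` (gated test reports).
#' @export
cohort_symmetry_comparison <- function(controls, impaired,
                                       scheme = sym10_scheme(), alpha = 0.05) {
  stopifnot(inherits(controls, "wing_cohort"), inherits(impaired, "wing_cohort"))
  if (controls$configurations[[1L]]$landmark_set !=
      impaired$configurations[[1L]]$landmark_set)
    stop("cohorts use different landmark sets")
  sa <- cohort_symmetry_scores(controls, scheme)
  sb <- cohort_symmetry_scores(impaired, scheme)
  sa$group <- controls$name; sb$group <- impaired$name
  scores <- rbind(sa, sb)
  list(
    scores = scores,
    test_anteriorized = gated_two_sample_test(
      sa$d_anteriorized, sb$d_anteriorized, alpha = alpha,
      group_names = c(controls$name, impaired$name)),
    test_posteriorized = gated_two_sample_test(
      sa$d_posteriorized, sb$d_posteriorized, alpha = alpha,
      group_names = c(controls$name, impaired$name))
  )
}
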