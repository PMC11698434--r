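#' Procrustes superimposition of two landmark configurations
#'
#' Both configurations are standardized (centered on their centroid, scaled to
#' unit root-sum-of-squares size); the second is then mapped by the similarity
#' transform (translation, uniform scale, orthogonal map) minimizing the sum
#' of squared distances to the first. The orthogonal map may be an improper
#' rotation: reflections are permitted, which together with chirality
#' normalization makes results robust to unrecorded wing side. The disparity
#' is the minimized sum of squared point distances; it is zero iff the two
#' configurations are similarity-equivalent, and — because both inputs are
#' standardized — symmetric in its arguments.
#'
#' @param ref,other [landmark_config] objects (or plain k x 2 matrices) with
#'   the same landmarks in the same order.
#' @return an object of class `procrustes_fit` with elements `aligned_ref`
#'   (standardized first configuration), `aligned_other` (transformed second
#'   configuration), `disparity`, `rotation` (the 2x2 orthogonal matrix),
#'   `scale`, and `labels`.
#' @examples
#' w <- template_wing()
#' superimpose(w, w)$disparity   # 0
#' @export
superimpose <- function(ref, other) {
  lab <- NULL
  if (inherits(ref, "landmark_config") && inherits(other, "landmark_config")) {
    if (ref$landmark_set != other$landmark_set)
      stop("configurations have different landmark sets")
    if (!identical(rownames(ref$coords), rownames(other$coords)))
      stop("label order mismatch between configurations")
    lab <- rownames(ref$coords)
  }
  X <- standardize_config(as.matrix(ref))
  Y <- standardize_config(as.matrix(other))
  if (nrow(X) != nrow(Y)) stop("configurations differ in landmark count")
  if (nrow(X) < 3L) stop("at least 3 landmarks are required")
  # orthogonal map (reflections allowed) and scale minimizing |X - s Y R|^2
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sc <- sum(s$d)                       # both inputs have unit norm
  aligned <- sc * (Y %*% R)
  disp <- sum((X - aligned)^2)
  structure(list(aligned_ref = X, aligned_other = aligned,
                 disparity = max(disp, 0), rotation = R, scale = sc,
                 labels = lab),
            class = "procrustes_fit")
}

standardize_config <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite coordinates")
  X <- sweep(X, 2, colMeans(X))
  size <- sqrt(sum(X^2))
  if (size < 1e-12)
    stop("degenerate configuration: all landmarks coincide (zero centroid size)")
  X / size
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes superimposition: %d landmarks, disparity = %.6g\n",
              nrow(x$aligned_ref), x$disparity))
  invisible(x)
}

#' All-pairs Procrustes disparities within or across cohorts
#'
#' With one cohort, computes the disparity of every unordered pair within it
#' (n(n-1)/2 values); with two, every ordered cross pair with the reference
#' taken from the first cohort (n1 x n2 values — e.g. 52 controls against 20
#' recruitment-impaired wings give 1040 comparisons). Disparity symmetry makes
#' the cross-pair order immaterial; it is fixed for reproducibility.
#'
#' @param a a [wing_cohort].
#' @param b optional second [wing_cohort]; `NULL` for within-cohort pairs.
#' @return an object of class `disparity_set`: a data.frame with columns
#'   `ref_id`, `other_id`, `disparity`, plus attributes `pairing`
#'   (`"within_cohort"` or `"cross_cohort"`) and `group_names`.
#' @export
pairwise_disparities <- function(a, b = NULL) {
  stopifnot(inherits(a, "wing_cohort"))
  ca <- a$configurations
  if (is.null(b)) {
    n <- length(ca)
    if (n < 2L) stop("within-cohort comparison needs at least 2 configurations")
    idx <- utils::combn(n, 2L)
    res <- data.frame(
      ref_id = vapply(idx[1, ], function(i) ca[[i]]$wing_id, character(1)),
      other_id = vapply(idx[2, ], function(i) ca[[i]]$wing_id, character(1)),
      disparity = vapply(seq_len(ncol(idx)), function(k)
        superimpose(ca[[idx[1, k]]], ca[[idx[2, k]]])$disparity, numeric(1)),
      stringsAsFactors = FALSE)
    pairing <- "within_cohort"
    groups <- c(a$name, a$name)
  } else {
    stopifnot(inherits(b, "wing_cohort"))
    cb <- b$configurations
    if (!length(ca) || !length(cb)) stop("empty cohort")
    grid <- expand.grid(i = seq_along(ca), j = seq_along(cb))
    res <- data.frame(
      ref_id = vapply(grid$i, function(i) ca[[i]]$wing_id, character(1)),
      other_id = vapply(grid$j, function(j) cb[[j]]$wing_id, character(1)),
      disparity = mapply(function(i, j)
        superimpose(ca[[i]], cb[[j]])$disparity, grid$i, grid$j),
      stringsAsFactors = FALSE)
    pairing <- "cross_cohort"
    groups <- c(a$name, b$name)
  }
  structure(res, pairing = pairing, group_names = groups,
            class = c("disparity_set", "data.frame"))
}

#' @export
print.disparity_set <- function(x, ...) {
  cat(sprintf("Disparity set (%s, %s vs %s): %d values, median %.4g\n",
              attr(x, "pairing"), attr(x, "group_names")[1],
              attr(x, "group_names")[2], nrow(x), stats::median(x$disparity)))
  invisible(x)
}

#' Average aligned landmark matrices over a set of superimpositions
#'
#' Element-wise arithmetic mean of the standardized reference matrices and of
#' the aligned second matrices across a list of Procrustes fits; used to
#' visualize the average control and average experimental landmark positions
#' after all pairwise comparisons.
#'
#' @param results non-empty list of `procrustes_fit` objects sharing one
#'   landmark count.
#' @return list with matrices `mean_ref` and `mean_other`.
#' @export
mean_aligned_shape <- function(results) {
  if (!length(results)) stop("empty result list")
  k <- nrow(results[[1L]]$aligned_ref)
  for (r in results)
    if (nrow(r$aligned_ref) != k) stop("landmark counts differ across results")
  mr <- Reduce(`+`, lapply(results, `[[`, "aligned_ref")) / length(results)
  mo <- Reduce(`+`, lapply(results, `[[`, "aligned_other")) / length(results)
  dimnames(mr) <- dimnames(results[[1L]]$aligned_ref)
  dimnames(mo) <- dimnames(mr)
  list(mean_ref = mr, mean_other = mo)
}

#' Per-landmark displacement between averaged aligned shapes
#'
#' Euclidean distance between corresponding landmarks of the two averaged
#' matrices, with landmarks displaced more than twice the average distance
#' flagged (strict inequality), identifying which landmarks drive a shape
#' difference.
#'
#' @param avg_ref,avg_other k x 2 matrices.
#' @param labels optional landmark labels (default from `avg_ref` rownames).
#' @return a data.frame with columns `label`, `distance`, `flagged`, plus
#'   attribute `mean_distance`.
#' @export
landmark_displacements <- function(avg_ref, avg_other, labels = NULL) {
  avg_ref <- as.matrix(avg_ref); avg_other <- as.matrix(avg_other)
  if (!identical(dim(avg_ref), dim(avg_other)))
    stop("averaged matrices differ in dimension")
  if (is.null(labels)) labels <- rownames(avg_ref)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(avg_ref)))
  if (length(labels) != nrow(avg_ref)) stop("label length mismatch")
  d <- sqrt(rowSums((avg_ref - avg_other)^2))
  m <- mean(d)
  out <- data.frame(label = labels, distance = unname(d),
                    flagged = unname(d > 2 * m), stringsAsFactors = FALSE)
  attr(out, "mean_distance") <- m
  out
}
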