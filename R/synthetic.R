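#' Template wing: exactly mirror-symmetric 10-point configuration
#'
#' A fixed landmark configuration with the 10-point AP-paired layout
#' (labels 1A..5A, 1P..5P), exactly mirror-symmetric about the x-axis, which
#' is therefore its AP axis (the pair-2 and pair-5 midpoints both lie on it).
#' Proportions loosely follow an adult wing: span 5 units along the AP axis,
#' half-height up to 1.3. Its ordered landmark loop has positive signed area
#' (canonical chirality). Symmetry scores of the template are exactly (0, 0).
#'
#' @param scheme a [paired_scheme] with 5 pairs (default [sym10_scheme()]).
#' @return a [landmark_config].
#' @export
template_wing <- function(scheme = sym10_scheme()) {
  if (length(scheme$anterior) != 5L)
    stop("the template is defined for a 5-pair (10-point) scheme")
  x <- c(0.0, 1.5, 3.0, 4.2, 5.0)
  h <- c(1.0, 1.3, 1.1, 0.7, 0.25)
  coords <- rbind(cbind(x, -h),     # anterior: 1A..5A (y up = smaller y)
                  cbind(x, h))      # posterior: 1P..5P
  cfg <- landmark_config(coords, c(scheme$anterior, scheme$posterior),
                         wing_id = "template", cohort = "control",
                         sex = "unknown", landmark_set = "SYM10")
  cfg
}

centroid_size <- function(config) {
  X <- as.matrix(config)
  sqrt(sum(sweep(X, 2, colMeans(X))^2))
}

#' Generate a synthetic wing cohort with controllable AP asymmetry
#'
#' Each wing is the [template_wing()] with its posterior landmarks displaced
#' outward from their mirror positions (away from the AP axis) by a fraction
#' `asym * w_i` of their axis distance, with weights `w = (1:5)/5` so the
#' displacement is maximal at pair 5 — mimicking the posterior-margin (L5-M)
#' localization of the asymmetry seen in real wings — plus isotropic Gaussian
#' landmark noise with standard deviation `noise_sd` in units of the template
#' centroid size. Fully deterministic under `seed`.
#'
#' @param n cohort size, >= 1.
#' @param asym asymmetry factor >= 0; 0 gives (noisy) mirror-symmetric wings.
#' @param noise_sd landmark noise SD relative to centroid size
#'   (default 0.002, the digitization-error scale of wing landmark data:
#'   roughly a pixel on a high-resolution wing image).
#' @param seed integer seed (required).
#' @param cohort cohort label for the configurations.
#' @param sex sex label.
#' @param name cohort name.
#' @param scheme pairing scheme (default [sym10_scheme()]).
#' @return a [wing_cohort]; the ground-truth `asym` and `noise_sd` are stored
#'   as attributes.
#' @export
generate_wing_cohort <- function(n, asym = 0, noise_sd = 0.002, seed,
                                 cohort = c("control", "impaired"),
                                 sex = "unknown", name = NULL,
                                 scheme = sym10_scheme()) {
  cohort <- match.arg(cohort)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  if (asym < 0) stop("'asym' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (missing(seed)) stop("'seed' is required")
  if (is.null(name)) name <- cohort
  tmpl <- template_wing(scheme)
  cs <- centroid_size(tmpl)
  w <- seq_len(5) / 5
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  configs <- lapply(seq_len(n), function(i) {
    xy <- tmpl$coords
    post <- scheme$posterior
    xy[post, 2] <- xy[post, 2] * (1 + asym * w)   # outward from the y=0 axis
    xy <- xy + matrix(stats::rnorm(length(xy), sd = noise_sd * cs),
                      nrow(xy), 2)
    landmark_config(xy, rownames(tmpl$coords),
                    wing_id = sprintf("%s_%03d", name, i), cohort = cohort,
                    sex = sex, landmark_set = "SYM10")
  })
  out <- wing_cohort(configs, name = name)
  attr(out, "asym") <- asym
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Generate a two-channel wing-disc phantom with known ground truth
#'
#' Builds a synthetic disc image pair emulating a confocal projection: the
#' pattern channel is a filled ellipse of known semi-axes (a reporter-like
#' domain), and the intervein channel is the same ellipse carrying dark vein
#' stripes perpendicular to the major axis at positions given by
#' `vein_fractions` (fractions of the major-axis extent, anterior to
#' posterior). Additive Gaussian noise is applied to both channels. The
#' ground truth — exact eccentricity, per-region pixel counts from the
#' generator's own coordinate-comparison labeling (a code path independent of
#' the analysis modules), and vein positions — is returned alongside, with
#' vein-polyline annotations in the shared annotation format.
#'
#' @param shape image dimensions `c(rows, cols)` (default 512 x 512).
#' @param a,b ellipse semi-axes in pixels, `a >= b > 0` (defaults 200, 120,
#'   i.e. eccentricity 0.8).
#' @param theta major-axis orientation in radians (default 0).
#' @param center ellipse center (x, y); default image center.
#' @param vein_fractions strictly increasing values in (0, 1) placing the
#'   vein stripes across the major-axis extent (default 0.2, 0.4, 0.6, 0.8).
#' @param vein_names names for the veins (default L2..L5 when there are 4).
#' @param pattern_intensity,intervein_intensity foreground intensities
#'   (defaults 200, 180).
#' @param vein_halfwidth half-width of the dark vein stripes in pixels.
#' @param noise_sd additive Gaussian noise SD (default 10).
#' @param seed integer seed (required).
#' @return list with `channels` (matrices `pattern`, `intervein`),
#'   `annotations` (vein polylines, background ROI corner), `ground_truth`
#'   (`eccentricity`, `region_fractions`, `region_counts`, `vein_positions`),
#'   and `params`.
#' @export
generate_disc_phantom <- function(shape = c(512L, 512L), a = 200, b = 120,
                                  theta = 0, center = NULL,
                                  vein_fractions = c(0.2, 0.4, 0.6, 0.8),
                                  vein_names = NULL,
                                  pattern_intensity = 200,
                                  intervein_intensity = 180,
                                  vein_halfwidth = 5,
                                  noise_sd = 10, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (a < b || b <= 0) stop("semi-axes must satisfy a >= b > 0")
  if (is.unsorted(vein_fractions, strictly = TRUE) ||
      any(vein_fractions <= 0) || any(vein_fractions >= 1))
    stop("'vein_fractions' must be strictly increasing within (0, 1)")
  nr <- shape[1]; nc <- shape[2]
  if (is.null(center)) center <- c(nc / 2, nr / 2)
  if (center[1] - a < 1 || center[1] + a > nc ||
      center[2] - a < 1 || center[2] + a > nr)
    stop("ellipse exceeds image bounds")
  if (is.null(vein_names))
    vein_names <- if (length(vein_fractions) == 4L) paste0("L", 2:5)
                  else paste0("V", seq_along(vein_fractions))
  ct <- cos(theta); st <- sin(theta)
  gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  gy <- matrix(seq_len(nr), nr, nc)
  u <- (gx - center[1]) * ct + (gy - center[2]) * st   # along major axis
  v <- -(gx - center[1]) * st + (gy - center[2]) * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  # ground-truth labeling by direct coordinate comparison (independent of
  # the vein-polyline partition used by the analysis)
  u_veins <- (2 * vein_fractions - 1) * a
  region_of <- matrix(0L, nr, nc)
  region_of[inside] <- 1L +
    rowSums(outer(u[inside], u_veins, `>`))
  counts <- vapply(seq_len(length(u_veins) + 1L),
                   function(k) sum(region_of == k), numeric(1))
  k <- length(vein_names)
  region_names <- c(paste0("M-", vein_names[1L]),
                    if (k > 1L) paste0(vein_names[-k], "-", vein_names[-1L]),
                    paste0(vein_names[k], "-M"))
  names(counts) <- region_names
  # channels
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  pattern <- matrix(0, nr, nc)
  pattern[inside] <- pattern_intensity
  stripe <- inside & (abs(outer_min_dist(u, u_veins)) <= vein_halfwidth)
  intervein <- matrix(0, nr, nc)
  intervein[inside] <- intervein_intensity
  intervein[stripe] <- 0
  if (noise_sd > 0) {
    pattern <- pmax(pattern + matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                     nr, nc), 0)
    intervein <- pmax(intervein + matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                         nr, nc), 0)
  }
  # vein click annotations: a few points along each stripe, inside the pattern
  veins <- lapply(seq_along(u_veins), function(i) {
    uv <- u_veins[i]
    vmax <- b * sqrt(max(1 - (uv / a)^2, 0)) * 0.9
    vv <- seq(-vmax, vmax, length.out = 5)
    cbind(x = center[1] + uv * ct - vv * st,
          y = center[2] + uv * st + vv * ct)
  })
  names(veins) <- vein_names
  list(
    channels = list(pattern = pattern, intervein = intervein),
    annotations = list(veins = veins,
                       background_roi = c(2, 2)),
    ground_truth = list(
      eccentricity = sqrt(1 - b^2 / a^2),
      region_counts = counts,
      region_fractions = counts / sum(counts),
      vein_positions = u_veins,
      a = a, b = b, theta = theta, center = center),
    params = list(shape = shape, a = a, b = b, theta = theta,
                  center = center, vein_fractions = vein_fractions,
                  pattern_intensity = pattern_intensity,
                  intervein_intensity = intervein_intensity,
                  vein_halfwidth = vein_halfwidth,
                  noise_sd = noise_sd, seed = seed)
  )
}

# distance from each u value to the nearest vein position
outer_min_dist <- function(u, u_veins) {
  d <- abs(u - u_veins[1])
  for (uv in u_veins[-1]) d <- pmin(d, abs(u - uv))
  d
}
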