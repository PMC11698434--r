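#' Analysis run configuration
#'
#' Collects every tunable parameter of the two end-to-end analyses, with the
#' package's standard defaults: binarization at 20% of the pattern maximum,
#' alpha 0.05, 200 px nominal nuclear area, projection blocks of 5 planes,
#' 30 px background ROI.
#'
#' @param binarize_fraction threshold fraction of the pattern maximum.
#' @param min_component_px,blur_kernel mask cleanup parameters.
#' @param alpha significance level for the gated tests.
#' @param nucleus_px nominal nuclear area in pixels.
#' @param projection_group z-planes per maximum-projection block.
#' @param background_roi_size side of the square background region.
#' @param power_reps Monte-Carlo repetitions for Mann-Whitney power.
#' @param seed integer seed for every stochastic step (required).
#' @param scheme a [paired_scheme] for the symmetry analysis.
#' @return a list of class `run_config`.
#' @export
run_config <- function(binarize_fraction = 0.20, min_component_px = 64,
                       blur_kernel = 5, alpha = 0.05, nucleus_px = 200,
                       projection_group = 5, background_roi_size = 30,
                       power_reps = 2000, seed = 1L,
                       scheme = sym10_scheme()) {
  stopifnot(binarize_fraction > 0, binarize_fraction < 1,
            min_component_px >= 0, blur_kernel >= 1,
            alpha > 0, alpha < 1, nucleus_px > 0, power_reps >= 100)
  structure(list(binarize_fraction = binarize_fraction,
                 min_component_px = min_component_px,
                 blur_kernel = blur_kernel, alpha = alpha,
                 nucleus_px = nucleus_px, projection_group = projection_group,
                 background_roi_size = background_roi_size,
                 power_reps = power_reps, seed = as.integer(seed),
                 scheme = scheme),
            class = "run_config")
}

config_sexes <- function(controls, impaired) {
  sx <- function(ch) vapply(ch$configurations, `[[`, character(1), "sex")
  sa <- sx(controls); sb <- sx(impaired)
  if (all(c(sa, sb) == "unknown")) return(NULL)
  intersect(unique(sa), unique(sb))
}

subset_cohort <- function(cohort, sex) {
  keep <- vapply(cohort$configurations, function(cf) cf$sex == sex, logical(1))
  wing_cohort(cohort$configurations[keep],
              name = paste(cohort$name, sex, sep = "_"))
}

#' End-to-end adult-wing shape and symmetry analysis
#'
#' For a control and a recruitment-impaired cohort: chirality normalization;
#' within-control and cross-cohort Procrustes disparities; average aligned
#' landmarks over all cross-cohort superimpositions with the per-landmark
#' displacement report (landmarks displaced more than twice the average are
#' flagged); per-wing AP symmetry scores; and gated two-sample tests
#' comparing (i) within-control vs cross-cohort disparity distributions and
#' (ii) the symmetry scores across cohorts. Sexes are analyzed separately
#' when the sex field is annotated, pooled otherwise with a logged note.
#' With an output directory, every table is written as CSV (deterministic
#' full-precision formatting) along with a run log.
#'
#' @param controls,impaired [wing_cohort] objects.
#' @param config a [run_config].
#' @param outdir optional output directory for CSV results.
#' @return (invisibly when writing) a list per analysis group with elements
#'   `within`, `cross`, `mean_shape`, `displacements`, `symmetry`, `tests`.
#' @export
run_wing_analysis <- function(controls, impaired, config = run_config(),
                              outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("wingsym %s | R %s", as.character(utils::packageVersion("wingsym")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed=%d alpha=%g power_reps=%d", config$seed,
                   config$alpha, config$power_reps))
  sexes <- config_sexes(controls, impaired)
  groups <- if (is.null(sexes)) {
    log <- c(log, "sex not annotated: cohorts pooled across sexes")
    list(pooled = list(a = controls, b = impaired))
  } else {
    stats::setNames(lapply(sexes, function(s)
      list(a = subset_cohort(controls, s), b = subset_cohort(impaired, s))),
      sexes)
  }
  out <- lapply(names(groups), function(g) {
    a <- groups[[g]]$a; b <- groups[[g]]$b
    a$configurations <- lapply(a$configurations, normalize_chirality)
    b$configurations <- lapply(b$configurations, normalize_chirality)
    within <- pairwise_disparities(a)
    fits <- list()
    for (ca in a$configurations)
      for (cb in b$configurations)
        fits[[length(fits) + 1L]] <- superimpose(ca, cb)
    cross <- data.frame(
      ref_id = rep(vapply(a$configurations, `[[`, character(1), "wing_id"),
                   each = length(b)),
      other_id = rep(vapply(b$configurations, `[[`, character(1), "wing_id"),
                     times = length(a)),
      disparity = vapply(fits, `[[`, numeric(1), "disparity"),
      stringsAsFactors = FALSE)
    ms <- mean_aligned_shape(fits)
    disp <- landmark_displacements(ms$mean_ref, ms$mean_other)
    sym <- cohort_symmetry_comparison(a, b, scheme = config$scheme,
                                      alpha = config$alpha)
    tests <- rbind(
      cbind(comparison = "disparity_within_vs_cross",
            report_row(gated_two_sample_test(
              within$disparity, cross$disparity, alpha = config$alpha,
              group_names = c("within_control", "cross")), config)),
      cbind(comparison = "symmetry_anteriorized",
            report_row(sym$test_anteriorized, config)),
      cbind(comparison = "symmetry_posteriorized",
            report_row(sym$test_posteriorized, config)))
    list(within = within, cross = cross, mean_shape = ms,
         displacements = disp, symmetry = sym$scores, tests = tests)
  })
  names(out) <- names(groups)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(out)) {
      r <- out[[g]]
      write_csv_full(as.data.frame(r$within), file.path(outdir,
        sprintf("disparities_within_control_%s.csv", g)))
      write_csv_full(r$cross, file.path(outdir,
        sprintf("disparities_cross_%s.csv", g)))
      ms <- data.frame(label = rownames(r$mean_shape$mean_ref),
                       ref_x = r$mean_shape$mean_ref[, 1],
                       ref_y = r$mean_shape$mean_ref[, 2],
                       other_x = r$mean_shape$mean_other[, 1],
                       other_y = r$mean_shape$mean_other[, 2])
      write_csv_full(ms, file.path(outdir, sprintf("mean_shape_%s.csv", g)))
      write_csv_full(r$displacements, file.path(outdir,
        sprintf("displacements_%s.csv", g)))
      write_csv_full(r$symmetry, file.path(outdir,
        sprintf("symmetry_scores_%s.csv", g)))
      write_csv_full(r$tests, file.path(outdir, sprintf("tests_%s.csv", g)))
    }
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  invisible(out)
}

# one CSV row per gated test, with a seeded post-hoc power estimate
report_row <- function(test, config) {
  df <- as.data.frame(test)
  df$power <- NA_real_
  if (!isTRUE(test$degenerate)) {
    d_obs <- observed_cohens_d(test)
    n <- min(test$n)
    df$power <- if (identical(test$test_used, "mann_whitney"))
      mwu_power_mc(d_obs, n, alpha = test$alpha, reps = config$power_reps,
                   seed = config$seed)
    else t_test_power(d_obs, n, alpha = test$alpha)
  }
  df
}

observed_cohens_d <- function(test) {
  pooled <- sqrt(((test$n[1] - 1) * test$sds[1]^2 +
                  (test$n[2] - 1) * test$sds[2]^2) / (sum(test$n) - 2))
  if (pooled == 0) return(0)
  abs(test$means[1] - test$means[2]) / pooled
}

#' End-to-end wing-disc pattern analysis
#'
#' For a batch of disc images with vein annotations: background subtraction
#' (when a background ROI is annotated), binarization at the configured
#' fraction of the pattern maximum, mask cleanup, intervein region areas from
#' the vein polylines, pattern eccentricity via the convex-envelope ellipse
#' fit, the hinge-pouch-ellipse region variant when fold points are
#' annotated, and an optional two-channel overlap/nuclei estimate. When discs
#' carry cohort labels, eccentricity and each region's relative area are
#' compared across cohorts with the gated test.
#'
#' @param discs list of disc entries: each a list with `id`, optional
#'   `cohort` (`"control"`/`"impaired"`), `pattern` (matrix or image path),
#'   optional `overlap_with` (second mask/matrix for the overlap estimate),
#'   and `annotations` (list or JSON path with `veins`, optional `hp_folds`,
#'   optional `background_roi`).
#' @param config a [run_config].
#' @param outdir optional output directory for CSV results.
#' @return list with `region_areas`, `eccentricity`, `overlap` data frames
#'   and `tests` (NULL without cohort labels).
#' @export
run_disc_analysis <- function(discs, config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"), length(discs) > 0)
  area_rows <- list(); ecc_rows <- list(); overlap_rows <- list()
  for (d in discs) {
    id <- if (is.null(d$id)) stop("disc entry without an id") else d$id
    res <- tryCatch({
      ann <- if (is.character(d$annotations)) read_annotations(d$annotations)
             else d$annotations
      if (is.null(ann$veins) || !length(ann$veins))
        stop("missing vein annotation")
      img <- if (is.character(d$pattern)) read_image(d$pattern) else d$pattern
      if (length(dim(img)) == 3L)
        img <- project_stack(img)
      if (!is.null(ann$background_roi))
        img <- subtract_background(img, ann$background_roi,
                                   roi_size = config$background_roi_size)
      mask <- binarize_pattern(img, fraction = config$binarize_fraction)
      mask <- preprocess_mask(mask, min_component_px = config$min_component_px,
                              blur_kernel = config$blur_kernel,
                              keep_largest = TRUE)
      lab <- segment_mask_by_veins(mask, ann$veins)
      areas <- relative_region_areas(lab)
      ell <- fit_ellipse(hull_points(mask))
      out <- list(areas = cbind(image_id = id,
                                cohort = d$cohort %||% NA_character_,
                                as.data.frame(areas),
                                reference = "pattern"),
                  ecc = data.frame(image_id = id,
                                   cohort = d$cohort %||% NA_character_,
                                   xc = ell$center[1], yc = ell$center[2],
                                   a = ell$a, b = ell$b, theta = ell$theta,
                                   eccentricity = ell$e,
                                   stringsAsFactors = FALSE))
      if (!is.null(ann$hp_folds)) {
        hp <- fit_hp_ellipse(ann$hp_folds)
        out$areas <- rbind(out$areas,
          cbind(image_id = id, cohort = d$cohort %||% NA_character_,
                as.data.frame(ellipse_region_areas(hp, ann$veins)),
                reference = "ellipse"))
      }
      if (!is.null(d$overlap_with)) {
        m2 <- if (is.character(d$overlap_with)) read_image(d$overlap_with)
              else d$overlap_with
        out$overlap <- data.frame(
          image_id = id,
          nuclei = overlap_nuclei_estimate(mask, as.matrix(m2) > 0,
                                           nucleus_px = config$nucleus_px),
          stringsAsFactors = FALSE)
      }
      out
    }, error = function(e)
      stop(sprintf("disc '%s': %s", id, conditionMessage(e)), call. = FALSE))
    area_rows[[length(area_rows) + 1L]] <- res$areas
    ecc_rows[[length(ecc_rows) + 1L]] <- res$ecc
    if (!is.null(res$overlap))
      overlap_rows[[length(overlap_rows) + 1L]] <- res$overlap
  }
  region_areas <- do.call(rbind, area_rows)
  eccentricity <- do.call(rbind, ecc_rows)
  overlap <- if (length(overlap_rows)) do.call(rbind, overlap_rows)
  tests <- disc_cohort_tests(region_areas, eccentricity, config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    names(region_areas)[names(region_areas) == "absolute_area"] <-
      "absolute_area_px2"
    names(region_areas)[names(region_areas) == "relative_area"] <-
      "relative_area_fraction_of_reference"
    write_csv_full(region_areas, file.path(outdir, "region_areas.csv"))
    write_csv_full(eccentricity, file.path(outdir, "eccentricity.csv"))
    if (!is.null(overlap))
      write_csv_full(overlap, file.path(outdir, "overlap_nuclei.csv"))
    if (!is.null(tests))
      write_csv_full(tests, file.path(outdir, "tests.csv"))
  }
  invisible(list(region_areas = region_areas, eccentricity = eccentricity,
                 overlap = overlap, tests = tests))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

disc_cohort_tests <- function(region_areas, eccentricity, config) {
  if (all(is.na(eccentricity$cohort))) return(NULL)
  grp <- function(df, col) split(df[[col]], df$cohort)
  rows <- list()
  g <- grp(eccentricity, "eccentricity")
  if (length(g) == 2L && all(lengths(g) >= 3L))
    rows[["eccentricity"]] <- cbind(
      comparison = "eccentricity",
      report_row(gated_two_sample_test(g[[1]], g[[2]], alpha = config$alpha,
                                       group_names = names(g)), config))
  pat <- region_areas[region_areas$reference == "pattern", , drop = FALSE]
  for (rg in unique(pat$region)) {
    sub <- pat[pat$region == rg, , drop = FALSE]
    g <- split(sub$relative_area, sub$cohort)
    if (length(g) == 2L && all(lengths(g) >= 3L))
      rows[[rg]] <- cbind(
        comparison = paste0("relative_area_", rg),
        report_row(gated_two_sample_test(g[[1]], g[[2]], alpha = config$alpha,
                                         group_names = names(g)), config))
  }
  if (length(rows)) do.call(rbind, rows)
}
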