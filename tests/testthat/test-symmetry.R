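sch <- sym10_scheme()

test_that("the AP axis passes through the pair-2 and pair-5 midpoints", {
  xy <- rbind(`1A` = c(-1, 1), `2A` = c(0, 1), `3A` = c(1, 1),
              `4A` = c(2, 1), `5A` = c(4, 1),
              `1P` = c(-1, -1), `2P` = c(0, -1), `3P` = c(1, -1),
              `4P` = c(2, -1), `5P` = c(4, -1))
  ax <- ap_axis(landmark_config(xy, rownames(xy)), sch)
  expect_equal(unname(ax$origin), c(0, 0))
  expect_equal(abs(unname(ax$direction)), c(1, 0))
  # mirror-symmetric about y = x -> axis is y = x
  xy2 <- xy
  xy2[6:10, ] <- xy[6:10, c(2, 1)]    # posterior = anterior mirrored in y=x
  xy2[1:5, ] <- cbind(c(-1, 0, 1, 2, 4) + 0.3, c(-1, 0, 1, 2, 4) - 0.3)
  xy2[6:10, ] <- cbind(c(-1, 0, 1, 2, 4) - 0.3, c(-1, 0, 1, 2, 4) + 0.3)
  ax2 <- ap_axis(landmark_config(xy2, rownames(xy)), sch)
  expect_equal(abs(unname(ax2$direction)), c(1, 1) / sqrt(2))
  # coincident axis landmarks -> degenerate
  xy3 <- xy
  xy3[c(2, 7, 5, 10), ] <- 0
  expect_error(ap_axis(landmark_config(xy3, rownames(xy)), sch), "degenerate")
})

test_that("reflection across the axis is an isometric involution", {
  xaxis <- structure(list(origin = c(0, 0), direction = c(1, 0)),
                     class = "axis_line")
  expect_equal(reflect_across_axis(c(1, 2), xaxis), c(1, -2))
  expect_equal(reflect_across_axis(c(3, 0), xaxis), c(3, 0))  # on the axis
  set.seed(5)
  oblique <- structure(list(origin = c(2, -1),
                            direction = c(cos(0.7), sin(0.7))),
                       class = "axis_line")
  P <- matrix(rnorm(40), 20, 2)
  R <- reflect_across_axis(P, oblique)
  expect_equal(reflect_across_axis(R, oblique), P, tolerance = 1e-12)
  # distances to the line are preserved
  d_line <- function(p) abs((p[, 1] - 2) * sin(0.7) - (p[, 2] + 1) * cos(0.7))
  expect_equal(d_line(R), d_line(P), tolerance = 1e-12)
})

test_that("symmetrization replaces the opposite side and is idempotent", {
  tw <- template_wing()
  # symmetric template: anteriorized equals the original
  ant <- symmetrize(tw, sch, "anteriorized")
  expect_equal(ant$coords, tw$coords, tolerance = 1e-12)
  # displace 5P: anteriorization puts it back at reflect(5A)
  bumped <- tw
  bumped$coords["5P", 2] <- bumped$coords["5P", 2] + 0.3
  ant2 <- symmetrize(bumped, sch, "anteriorized")
  ax <- ap_axis(bumped, sch)
  expect_equal(unname(ant2$coords["5P", ]),
               unname(reflect_across_axis(bumped$coords["5A", ], ax)))
  # idempotence per side
  once <- symmetrize(bumped, sch, "anteriorized")
  twice <- symmetrize(once, sch, "anteriorized")
  expect_equal(twice$coords, once$coords, tolerance = 1e-12)
  # labels and order preserved
  expect_identical(rownames(ant2$coords), rownames(tw$coords))
})

test_that("symmetrized wings are exactly mirror-symmetric about the original axis", {
  set.seed(9)
  for (s in 1:5) {
    cf <- generate_wing_cohort(1, asym = 0.3, noise_sd = 0.01,
                               seed = s)$configurations[[1]]
    ax <- ap_axis(cf, sch)
    for (side in c("anteriorized", "posteriorized")) {
      sym <- symmetrize(cf, sch, side)
      mids <- (sym$coords[sch$anterior, ] + sym$coords[sch$posterior, ]) / 2
      # pair midpoints lie on the axis
      rel <- sweep(mids, 2, ax$origin)
      perp <- rel[, 1] * ax$direction[2] - rel[, 2] * ax$direction[1]
      expect_true(all(abs(perp) < 1e-9))
    }
  }
})

test_that("symmetry scores: zero for symmetric wings, positive for displaced ones", {
  tw <- template_wing()
  expect_equal(unname(symmetry_scores(tw, sch)), c(0, 0), tolerance = 1e-12)
  bumped <- tw
  bumped$coords["3P", ] <- bumped$coords["3P", ] + c(0, 0.4)
  sc <- symmetry_scores(bumped, sch)
  expect_gt(sc["d_anteriorized"], 0)
})

test_that("symmetry scores are invariant under similarity transforms", {
  cf <- generate_wing_cohort(1, asym = 0.25, noise_sd = 0.01,
                             seed = 3)$configurations[[1]]
  base <- symmetry_scores(cf, sch)
  tr <- cf
  tr$coords <- apply_similarity(cf$coords, angle = 1.2, scale = 3.7,
                                shift = c(10, -4))
  expect_equal(symmetry_scores(tr, sch), base, tolerance = 1e-9)
})

test_that("with zero noise the anteriorized score increases strictly with asymmetry", {
  scores <- vapply(c(0, 0.05, 0.1, 0.2), function(a)
    symmetry_scores(generate_wing_cohort(1, asym = a, noise_sd = 0,
                                         seed = 1)$configurations[[1]],
                    sch)["d_anteriorized"], numeric(1))
  expect_equal(scores[1], 0, tolerance = 1e-12)
  expect_true(all(diff(scores) > 0))
})

test_that("cohort symmetry comparison detects a true asymmetry difference and is direction-aware", {
  ctrl <- generate_wing_cohort(50, asym = 0.2, seed = 21, name = "ctrl")
  imp <- generate_wing_cohort(50, asym = 0.1, seed = 22, cohort = "impaired",
                              name = "imp")
  cmp <- cohort_symmetry_comparison(ctrl, imp, sch)
  t1 <- cmp$test_anteriorized
  expect_lt(t1$p_value, 0.05)
  expect_gt(t1$medians[1], t1$medians[2])   # impaired wings more symmetric
  # swapping the cohorts swaps the direction but not the p-value
  cmp2 <- cohort_symmetry_comparison(imp, ctrl, sch)
  expect_equal(cmp2$test_anteriorized$p_value, t1$p_value)
  expect_lt(cmp2$test_anteriorized$medians[1],
            cmp2$test_anteriorized$medians[2])
})

test_that("clone cohorts give all-zero scores and a degenerate (flagged) test", {
  tw <- template_wing()
  mk <- function(nm) wing_cohort(lapply(1:5, function(i) {
    cf <- tw; cf$wing_id <- paste0(nm, i); cf
  }), name = nm)
  cmp <- cohort_symmetry_comparison(mk("a"), mk("b"), sch)
  expect_true(all(abs(cmp$scores$d_anteriorized) < 1e-12))
  expect_true(cmp$test_anteriorized$degenerate)
  expect_true(is.na(cmp$test_anteriorized$p_value))
})
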