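test_that("self-registration returns the identity", {
  pair <- small_pair_identity()
  res <- register_baseline(pair$primary, pair$primary)
  expect_lt(max(abs(coef(res$transform)[1:3])), 0.1)
  expect_lt(max(abs(coef(res$transform)[4:6])), 0.1)
  # a perfectly sharp self-pair loses NMI quickly away from exact identity,
  # so the value is checked loosely; the parameters above are the real bound
  expect_gt(res$metric_value, 0.9)
})

test_that("baseline recovers translations and rotations within half a voxel", {
  ctr <- small_center(small_spec())
  tt <- rigid_transform(3, -2, 4, center = ctr)
  pair <- generate_phantom_pair(small_spec(true_transform = tt))
  res <- register_baseline(pair$primary, pair$secondary)
  err <- decompose_difference(res$transform, tt, center = ctr)
  expect_lt(abs(err$dt_lr), 0.5 * 1.074)
  expect_lt(abs(err$dt_ap), 0.5 * 1.074)
  expect_lt(abs(err$dt_cc), 0.5 * 1.0)

  rr <- rigid_transform(rz = 2, center = ctr)
  pair2 <- generate_phantom_pair(small_spec(true_transform = rr))
  res2 <- register_baseline(pair2$primary, pair2$secondary)
  err2 <- decompose_difference(res2$transform, rr, center = ctr)
  expect_lt(abs(err2$dr_axial), 0.5)
})

test_that("non-overlapping volumes are rejected up front", {
  pair <- small_pair_identity()
  far <- image_volume(pair$primary$voxels, pair$primary$spacing,
                      pair$primary$origin + c(500, 500, 500))
  expect_error(register_baseline(pair$primary, far), "overlap")
})

test_that("contour-focused refinement is a fixed point at the optimum", {
  pair <- small_pair_identity()
  lv <- select_landmark_levels(pair$truth$lesion_levels, 4)
  cm <- extract_landmark_mask(pair$primary, lv, pair$truth$level_boundaries)
  init <- rigid_transform(center = mask_centroid(cm))
  res <- register_contour_focused(pair$primary, pair$secondary, cm,
                                  init = init)
  expect_lt(max(abs(coef(res$transform) - coef(init))), 0.05)
  v_init <- masked_nmi(pair$primary, pair$secondary, init, cm)
  expect_lt(abs(res$metric_value - v_init), 1e-6)
})

test_that("refinement never returns a worse masked NMI than its start", {
  ctr <- small_center(small_spec())
  set.seed(81)
  for (i in 1:3) {
    tt <- random_small_transform(max_t = 4, max_r = 2, center = ctr)
    pair <- generate_phantom_pair(small_spec(true_transform = tt,
                                             noise_sd = 15, seed = 100 + i))
    fit <- run_arir_workflow(pair$primary, pair$secondary,
                             phantom_annot(pair))
    expect_gte(fit$nmi_arir, fit$nmi_baseline - 1e-9)
  }
})

test_that("contour focus shields the registration from off-target anatomy", {
  # an anterior soft-tissue mass moves 14 mm between the scans: whole-image
  # NMI is pulled off the spine, the contour-restricted metric is not
  ctr <- c(51.015, 51.015, 80)
  tt <- rigid_transform(2, -1.5, 3, 1, 0, -1, center = ctr)
  spec <- phantom_spec(true_transform = tt, noise_sd = 15, seed = 4,
                       distractor_shift_mm = 14)
  pair <- generate_phantom_pair(spec)
  fit <- run_arir_workflow(pair$primary, pair$secondary, phantom_annot(pair))
  e_contour <- decompose_difference(fit$transform, tt,
                                    center = fit$transform$center)
  e_base <- decompose_difference(fit$baseline$transform, tt,
                                 center = fit$transform$center)
  # the refined registration meets the protocol accuracy ...
  expect_lt(max(abs(c(e_contour$dt_lr, e_contour$dt_ap, e_contour$dt_cc))), 1)
  expect_lt(max(abs(c(e_contour$dr_axial, e_contour$dr_coronal,
                      e_contour$dr_sagittal))), 1)
  # ... and its worst error component (mm or degree) improves on the
  # whole-image alignment, which the moving mass visibly biases
  worst <- function(e) max(abs(c(e$dt_lr, e$dt_ap, e$dt_cc,
                                 e$dr_axial, e$dr_coronal, e$dr_sagittal)))
  expect_lt(worst(e_contour), worst(e_base))
})

test_that("the workflow is deterministic and equivariant to extra shifts", {
  ctr <- small_center(small_spec())
  tt <- rigid_transform(1.5, -1, 2, 0.5, 0, -0.5, center = ctr)
  pair <- generate_phantom_pair(small_spec(true_transform = tt, noise_sd = 10,
                                           seed = 9))
  fit1 <- run_arir_workflow(pair$primary, pair$secondary, phantom_annot(pair))
  fit2 <- run_arir_workflow(pair$primary, pair$secondary, phantom_annot(pair))
  expect_identical(coef(fit1$transform), coef(fit2$transform))
  expect_identical(fit1$nmi_arir, fit2$nmi_arir)

  # same anatomy under truth E o T: recovered transform shifts by E
  extra <- rigid_transform(tz = 2)
  tt2 <- compose(extra, tt, center = ctr)
  pair2 <- generate_phantom_pair(small_spec(true_transform = tt2,
                                            noise_sd = 10, seed = 9))
  fit3 <- run_arir_workflow(pair2$primary, pair2$secondary,
                            phantom_annot(pair2))
  gap <- decompose_difference(fit3$transform,
                              compose(extra, fit1$transform,
                                      center = fit1$transform$center),
                              center = fit1$transform$center)
  # two independent recoveries each contribute their own sub-voxel error
  expect_lt(gap$dt_abs, 0.75)
  expect_lt(max(abs(c(gap$dr_axial, gap$dr_coronal, gap$dr_sagittal))), 0.75)
})

test_that("workflow errors are labeled with their stage", {
  pair <- small_pair_identity()
  bad_ann <- list(lesion_levels = c(1L, 3L),
                  level_boundaries = pair$truth$level_boundaries)
  expect_error(run_arir_workflow(pair$primary, pair$secondary, bad_ann),
               "\\[contour\\]")
})
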