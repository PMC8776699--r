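eval_fixture <- function() {
  pair <- small_pair_identity()
  lv <- select_landmark_levels(pair$truth$lesion_levels, 4)
  cm <- extract_landmark_mask(pair$primary, lv, pair$truth$level_boundaries)
  list(pair = pair, cm = cm)
}

test_that("evaluate_case reports zero deltas for coincident transforms", {
  fx <- eval_fixture()
  t0 <- rigid_transform(center = mask_centroid(fx$cm))
  ce <- evaluate_case(fx$pair$primary, fx$pair$secondary, fx$cm,
                      t0, t0, t0, case_id = "c0")
  expect_equal(ce$delta_nmi_arir, 0)
  expect_equal(ce$delta_nmi_hrir, 0)
  expect_equal(ce$error$dt_abs, 0)
  expect_equal(ce$error$dr_axial, 0)
  expect_true(all(c(ce$nmi_baseline, ce$nmi_arir, ce$nmi_hrir) >= 0 &
                    c(ce$nmi_baseline, ce$nmi_arir, ce$nmi_hrir) <= 1))
})

test_that("an aligned A-RIR beats an offset baseline on the contour", {
  fx <- eval_fixture()
  truth <- rigid_transform(center = mask_centroid(fx$cm))
  off <- rigid_transform(ty = 2, center = mask_centroid(fx$cm))
  ce <- evaluate_case(fx$pair$primary, fx$pair$secondary, fx$cm,
                      off, truth, truth)
  expect_gt(ce$delta_nmi_arir, 0)
})

test_that("transform error fields follow the 3-4-5 construction", {
  fx <- eval_fixture()
  base <- rigid_transform(center = mask_centroid(fx$cm))
  arir <- rigid_transform(3, 4, 0, center = mask_centroid(fx$cm))
  ce <- evaluate_case(fx$pair$primary, fx$pair$secondary, fx$cm,
                      base, arir, base)
  expect_equal(ce$error$dt_abs, 5)
})

test_that("swapping the A-RIR and H-RIR arms mirrors the evaluation", {
  fx <- eval_fixture()
  ctr <- mask_centroid(fx$cm)
  base <- rigid_transform(ty = 1, center = ctr)
  ta <- rigid_transform(0.5, -0.3, 0.2, 0.1, 0, -0.2, center = ctr)
  th <- rigid_transform(-0.2, 0.4, -0.1, 0, 0.15, 0.1, center = ctr)
  a <- evaluate_case(fx$pair$primary, fx$pair$secondary, fx$cm, base, ta, th)
  b <- evaluate_case(fx$pair$primary, fx$pair$secondary, fx$cm, base, th, ta)
  expect_equal(a$delta_nmi_arir, b$delta_nmi_hrir)
  expect_equal(a$delta_nmi_hrir, b$delta_nmi_arir)
  # negation is first-order in the relative rotation angle
  ang <- (abs(a$error$dr_axial) + abs(a$error$dr_coronal) +
            abs(a$error$dr_sagittal)) * pi / 180
  expect_lt(max(abs(c(a$error$dt_lr + b$error$dt_lr,
                      a$error$dt_ap + b$error$dt_ap,
                      a$error$dt_cc + b$error$dt_cc))),
            ang * a$error$dt_abs + 1e-9)
})

test_that("perturbation losses vanish at zero and are positive at the optimum", {
  fx <- eval_fixture()
  truth <- rigid_transform(center = mask_centroid(fx$cm))
  zero <- perturbation_sensitivity(fx$pair$primary, fx$pair$secondary, truth,
                                   fx$cm, translations_mm = 0,
                                   rotations_deg = 0)
  expect_true(all(zero$loss == 0))

  tab <- perturbation_sensitivity(fx$pair$primary, fx$pair$secondary, truth,
                                  fx$cm)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$loss > 0))
})

test_that("losses are nearly symmetric close to a smooth optimum", {
  # smoothness premise: on sharp piecewise data the loss is V-shaped at a
  # grid-aligned optimum, so the check runs on lightly smoothed volumes
  fx <- eval_fixture()
  prim <- spinefuse:::blur_volume(fx$pair$primary)
  sec <- spinefuse:::blur_volume(fx$pair$secondary)
  truth <- rigid_transform(center = mask_centroid(fx$cm))
  big <- perturbation_sensitivity(prim, sec, truth,
                                  fx$cm, translations_mm = c(-1, 1),
                                  rotations_deg = numeric(0))
  small <- perturbation_sensitivity(prim, sec, truth,
                                    fx$cm, translations_mm = c(-0.1, 0.1),
                                    rotations_deg = numeric(0))
  for (ax in unique(big$axis)) {
    asym1 <- abs(diff(big$loss[big$axis == ax]))
    asym01 <- abs(diff(small$loss[small$axis == ax]))
    expect_lte(asym01, 10 * asym1 + 1e-9)
  }
})
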