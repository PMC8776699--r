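test_that("elementary transforms act as expected", {
  expect_equal(transform_points(rigid_transform(), c(10, 20, 30)),
               c(10, 20, 30))
  expect_equal(transform_points(rigid_transform(tz = 5), c(0, 0, 0)),
               c(0, 0, 5))
  # 90 degree axial rotation about the origin maps x onto y
  p <- transform_points(rigid_transform(rz = 90), c(1, 0, 0))
  expect_lt(abs(p[1]), 1e-9)
  expect_lt(abs(p[2] - 1), 1e-9)
  expect_identical(p[3], 0)
  expect_error(rigid_transform(tx = NaN), "finite")
  expect_error(rigid_transform(center = c(1, 2)), "finite")
})

test_that("rotation matrices are proper and stay proper under composition", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_small_transform(max_r = 30)
    b <- random_small_transform(max_r = 30)
    R <- rotation_matrix(compose(a, b))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("compose matches sequential application and handles translations", {
  expect_equal(coef(compose(rigid_transform(1, 2, 3),
                            rigid_transform(4, 5, 6))),
               c(tx = 5, ty = 7, tz = 9, rx = 0, ry = 0, rz = 0))
  set.seed(21)
  a <- random_small_transform(center = c(5, -3, 8))
  b <- random_small_transform(center = c(-2, 7, 1))
  pts <- matrix(runif(300, -50, 50), ncol = 3)
  expect_lt(max(abs(transform_points(compose(a, b), pts) -
                      transform_points(a, transform_points(b, pts)))), 1e-9)
  expect_lt(max(abs(transform_points(compose(a, rigid_transform()), pts) -
                      transform_points(a, pts))), 1e-9)
  expect_lt(max(abs(transform_points(compose(invert(a), a), pts) - pts)),
            1e-9)
})

test_that("invert is the functional inverse and a round-trip involution", {
  expect_equal(coef(invert(rigid_transform())), coef(rigid_transform()))
  expect_equal(coef(invert(rigid_transform(1, -2, 3)))[1:3],
               c(tx = -1, ty = 2, tz = -3))
  set.seed(31)
  pts <- matrix(runif(60, -40, 40), ncol = 3)
  for (i in 1:20) {
    t <- random_small_transform(center = c(10, 0, -5))
    expect_lt(max(abs(transform_points(invert(t), transform_points(t, pts)) -
                        pts)), 1e-9)
    expect_equal(coef(invert(invert(t))), coef(t), tolerance = 1e-9)
  }
})

test_that("decompose_difference reports the registration-to-registration gap", {
  z <- decompose_difference(rigid_transform(1, 2, 3, 0.5, -0.2, 0.1),
                            rigid_transform(1, 2, 3, 0.5, -0.2, 0.1))
  expect_equal(unlist(z), c(dt_lr = 0, dt_ap = 0, dt_cc = 0, dt_abs = 0,
                            dr_axial = 0, dr_coronal = 0, dr_sagittal = 0),
               tolerance = 1e-12)
  e <- decompose_difference(rigid_transform(3, 4, 0), rigid_transform())
  expect_equal(e$dt_abs, 5.0)
  expect_equal(e$dt_abs, sqrt(e$dt_ap^2 + e$dt_lr^2 + e$dt_cc^2))
  expect_gte(e$dt_abs, max(abs(e$dt_ap), abs(e$dt_lr), abs(e$dt_cc)))

  # recomposing the decomposed error onto t_b recovers t_a
  set.seed(41)
  pts <- matrix(runif(60, -30, 30), ncol = 3)
  for (i in 1:15) {
    t_a <- random_small_transform(max_r = 1, center = c(2, 4, 6))
    t_b <- random_small_transform(max_r = 1, center = c(2, 4, 6))
    d <- decompose_difference(t_a, t_b)
    rec <- compose(t_b, rigid_transform(d$dt_lr, d$dt_ap, d$dt_cc,
                                        d$dr_sagittal, d$dr_coronal,
                                        d$dr_axial, center = t_a$center))
    expect_lt(max(abs(transform_points(rec, pts) -
                        transform_points(t_a, pts))), 1e-6)
  }
})

test_that("decompose_difference is antisymmetric in translation sign", {
  a <- rigid_transform(2, -1, 4)
  b <- rigid_transform(-3, 5, 0.5)
  d1 <- decompose_difference(a, b)
  d2 <- decompose_difference(b, a)
  expect_equal(c(d1$dt_lr, d1$dt_ap, d1$dt_cc),
               -c(d2$dt_lr, d2$dt_ap, d2$dt_cc))
  expect_equal(d1$dt_abs, d2$dt_abs)
  # with rotations present the negation holds to first order: the deviation
  # |(I - R^T) d| is bounded by the total rotation angle times |d|
  set.seed(51)
  for (i in 1:10) {
    a <- random_small_transform(max_r = 1)
    b <- random_small_transform(max_r = 1)
    d1 <- decompose_difference(a, b)
    d2 <- decompose_difference(b, a)
    ang <- (abs(d1$dr_axial) + abs(d1$dr_coronal) + abs(d1$dr_sagittal)) *
      pi / 180
    expect_lt(max(abs(c(d1$dt_lr + d2$dt_lr, d1$dt_ap + d2$dt_ap,
                        d1$dt_cc + d2$dt_cc))),
              ang * d1$dt_abs + 1e-9)
    expect_equal(d1$dt_abs, d2$dt_abs, tolerance = 1e-12)
  }
})

test_that("transform JSON serialization round-trips losslessly", {
  t <- rigid_transform(1.23456789012345, -2.3456789012345e-3, 3.14159265358979,
                       0.123456789012345, -4.56789012345678, 9.87654321098765,
                       center = c(51.4159, 47.1234, 80.0001))
  f <- tempfile(fileext = ".json")
  write_transform(t, f)
  t2 <- read_transform(f)
  expect_equal(coef(t2), coef(t), tolerance = 1e-12)
  expect_equal(t2$center, t$center, tolerance = 1e-12)
  expect_identical(t2$frame, "LPS")
})
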