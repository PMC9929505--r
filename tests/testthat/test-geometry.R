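reference_levers <- function() {
  lever_set(inlever = c(0, 1, 0), outlever_distal = c(2, 0, 0),
            apodeme_axis = c(1, 0, 0), gamma0_deg = 90, theta0_deg = 51)
}

test_that("apodeme angle is linear in the opening angle with slope -1", {
  lv <- reference_levers()
  expect_equal(apodeme_angle(51, lv), 90)    # identity at the reference pose
  expect_equal(apodeme_angle(105, lv), 36)
  expect_equal(apodeme_angle(35, lv), 106)
  th <- seq(30, 110, by = 5)
  expect_equal(diff(apodeme_angle(th, lv)) / diff(th), rep(-1, length(th) - 1))
})

test_that("effective levers follow the projected cross products", {
  # hand-worked case: R = z, Li = (1,1,1), A = x, gamma = 90 deg
  fr <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  lv <- lever_set(inlever = c(1, 1, 1), outlever_distal = c(2, 0, 0),
                  apodeme_axis = c(1, 0, 0), gamma0_deg = 90, theta0_deg = 51)
  res <- effective_levers(51, lv, fr)
  expect_equal(res$inlever_eff, sqrt(2), tolerance = 1e-12)
  expect_equal(res$outlever_eff, 2)

  # MA falls by 1/sin(36 deg) = 1.70 between gamma = 90 and gamma = 36 deg
  lv2 <- reference_levers()
  ma <- effective_levers(c(51, 105), lv2, fr)$mechanical_advantage
  expect_equal(ma[1] / ma[2], 1 / sin(36 * pi / 180), tolerance = 1e-12)
  expect_equal(round(ma[1] / ma[2], 1), 1.7)

  # the effective inlever peaks where gamma = 90 and is symmetric about it
  th <- seq(11, 91, by = 1)  # gamma from 130 down to 50 deg
  ie <- effective_levers(th, lv2, fr)$inlever_eff
  expect_equal(th[which.max(ie)], 51)
  expect_equal(effective_levers(51 - 20, lv2, fr)$inlever_eff,
               effective_levers(51 + 20, lv2, fr)$inlever_eff,
               tolerance = 1e-12)
})

test_that("apodeme displacement matches the closed form and its components", {
  fr <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  lv <- lever_set(inlever = c(1, 1, 1), outlever_distal = c(2, 0, 0),
                  apodeme_axis = c(1, 0, 0), gamma0_deg = 90, theta0_deg = 51)
  expect_equal(apodeme_displacement(51, lv, fr)$delta, 0)
  # closing by 30 deg: [cos 90 - cos 120] * sqrt(2) = 0.7071
  d <- apodeme_displacement(51 - 30, lv, fr)
  expect_equal(d$delta, 0.5 * sqrt(2), tolerance = 1e-6)
  # closing by 40 deg: |lateral| / longitudinal = (1 - sin 50) / cos 50 ~ 1/3
  d40 <- apodeme_displacement(51 - 40, lv, fr)
  expect_equal(abs(d40$lateral) / d40$longitudinal,
               (1 - sin(50 * pi / 180)) / cos(50 * pi / 180),
               tolerance = 1e-12)
  expect_equal(abs(d40$lateral) / d40$longitudinal, 1 / 3, tolerance = 0.1)
})

test_that("virtual work links apodeme displacement to the effective inlever", {
  # d(delta)/d(theta in radians) = -inlever_eff, by central difference
  for (seed in 1:5) {
    app <- random_apparatus(seed)
    th <- seq(app$theta_range[1] + 2, app$theta_range[2] - 2, length.out = 9)
    h <- 1e-4  # degrees
    dd <- (apodeme_displacement(th + h, app$levers, app$frame)$delta -
             apodeme_displacement(th - h, app$levers, app$frame)$delta) /
      (2 * h * pi / 180)
    ie <- effective_levers(th, app$levers, app$frame)$inlever_eff
    expect_equal(dd, -ie, tolerance = 1e-6)
  }
})

test_that("moment arms are invariant to the reference point along the axis", {
  app <- random_apparatus(42)
  fr2 <- joint_frame(app$frame$centre + 3.7 * app$frame$axis, app$frame$axis)
  th <- seq(app$theta_range[1], app$theta_range[2], length.out = 7)
  expect_equal(effective_levers(th, app$levers, app$frame),
               effective_levers(th, app$levers, fr2), tolerance = 1e-9)
  expect_equal(apodeme_displacement(th, app$levers, app$frame),
               apodeme_displacement(th, app$levers, fr2), tolerance = 1e-9)
})

test_that("gape is twice the signed distance to the sagittal plane", {
  p0 <- c(0, 0, 0)
  nrm <- c(0, 1, 0)
  expect_equal(gape(c(1, 0, 2), p0, nrm), 0)
  expect_equal(gape(c(0.3, 1.8, -1), p0, nrm), 3.6)    # printed maximum gape
  expect_equal(gape(c(0, -0.65, 0), p0, nrm), -1.3)    # printed overlap
  expect_error(gape(c(0, 1, 0), p0, c(0, 2, 0)), "unit")
})

test_that("degenerate and invalid geometry is rejected", {
  fr <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  lv_bad <- lever_set(inlever = c(0, 1, 0), outlever_distal = c(0, 0, 3),
                      apodeme_axis = c(1, 0, 0), gamma0_deg = 90,
                      theta0_deg = 51)
  expect_error(effective_levers(51, lv_bad, fr), "degenerate")
  expect_error(joint_frame(c(0, 0, 0), c(0, 0, 0)), "zero")
  expect_error(lever_set(c(0, 1, 0), c(2, 0, 0), c(1, 0, 0),
                         gamma0_deg = 181, theta0_deg = 51), "gamma0")
})

test_that("the rotation-axis sign convention follows the dorso-ventral axis", {
  fr <- joint_frame(c(0, 0, 0), c(0, 0, -1), dv_axis = c(0, 0, 1))
  expect_equal(fr$axis, c(0, 0, 1))
})
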