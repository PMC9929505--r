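test_that("landmark normalization centres, scales and mirrors correctly", {
  # an already-normalized left pose passes through unchanged
  df <- data.frame(
    pose = "p1", hemisphere = "left",
    landmark = c("joint_centre", "head_rear", "inlever", "outlever_distal",
                 "outlever_proximal", "apodeme_com"),
    x = c(0, -1, 0.1, 0.5, 0.3, 0.4),
    y = c(0, 0, 0.2, -0.3, -0.2, 0.05),
    z = c(0, 0, 0.05, 0.1, 0.1, 0.02))
  p <- normalize_landmarks(df)[[1]]
  expect_equal(p$head_length, 1)
  expect_equal(p$vectors$inlever, c(0.1, 0.2, 0.05))
  expect_equal(p$apodeme_com, c(0.4, 0.05, 0.02))

  # right-hemisphere poses are mirrored across the sagittal plane
  df_r <- df
  df_r$hemisphere <- "right"
  pr <- normalize_landmarks(df_r)[[1]]
  expect_equal(pr$vectors$inlever, c(0.1, -0.2, 0.05))

  # rigid whole-head translation leaves normalized vectors unchanged
  df_t <- df
  df_t[, c("x", "y", "z")] <- df_t[, c("x", "y", "z")] +
    rep(c(3.2, -1.5, 0.7), each = nrow(df))
  pt <- normalize_landmarks(df_t)[[1]]
  expect_equal(pt$vectors, p$vectors, tolerance = 1e-12)

  # missing landmarks are reported with pose and landmark name
  expect_error(normalize_landmarks(df[df$landmark != "inlever", ]),
               "pose 'p1'.*'inlever'")
})

test_that("the rotation axis is recovered exactly from rigid rotations", {
  ps <- make_pose_series(c(20, 40, 60), axis = c(0, 0, 1))
  est <- estimate_rotation_axis(normalize_landmarks(ps$landmarks))
  expect_equal(abs(sum(est$axis * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_lt(est$residual, 1e-10)
  expect_equal(est$n_poses, 3)
})

test_that("axis estimation is invariant to uniform scaling of the landmarks", {
  ps <- make_pose_series(c(30, 55, 80), axis = c(0.2, 0.1, 1))
  est1 <- estimate_rotation_axis(normalize_landmarks(ps$landmarks))
  scaled <- ps$landmarks
  scaled[, c("x", "y", "z")] <- scaled[, c("x", "y", "z")] * 2.5
  est2 <- estimate_rotation_axis(normalize_landmarks(scaled))
  expect_equal(est1$axis, est2$axis, tolerance = 1e-5)
})

test_that("identical poses make the axis unidentifiable", {
  ps <- make_pose_series(c(40, 70))
  dup <- ps$landmarks
  dup$pose[dup$pose == "pose_02"] <- "pose_01b"
  dup[dup$pose == "pose_01b", c("x", "y", "z")] <-
    ps$landmarks[ps$landmarks$pose == "pose_01", c("x", "y", "z")]
  expect_error(estimate_rotation_axis(normalize_landmarks(dup)),
               "unidentifiable")
  expect_error(estimate_rotation_axis(normalize_landmarks(ps$landmarks)[1]),
               ">= 2")
})

test_that("the fitted axis beats random axes on noise-free poses", {
  ps <- make_pose_series(c(25, 50, 75), axis = c(0.3, -0.2, 1))
  poses <- normalize_landmarks(ps$landmarks)
  est <- estimate_rotation_axis(poses)
  obj <- function(axis) {
    sum(sapply(c("inlever", "outlever_distal", "outlever_proximal"),
               function(nm) {
      ang <- sapply(poses, function(p) {
        v <- p$vectors[[nm]]
        acos(sum(v * axis) / sqrt(sum(v^2))) * 180 / pi
      })
      sum((ang - mean(ang))^2)
    }))
  }
  set.seed(11)
  best <- obj(est$axis)
  for (i in 1:100) {
    a <- rnorm(3)
    expect_gte(obj(a / sqrt(sum(a^2))), best - 1e-9)
  }
})

test_that("axis recovery stays within 3 degrees under 1% landmark noise", {
  hits <- 0
  for (i in 1:30) {
    ps <- make_pose_series(c(20, 40, 60), axis = c(0, 0, 1), noise = 0.01,
                           seed = 400 + i)
    est <- estimate_rotation_axis(normalize_landmarks(ps$landmarks))
    ang <- acos(pmin(1, abs(sum(est$axis * c(0, 0, 1))))) * 180 / pi
    hits <- hits + (ang < 3)
  }
  expect_gte(hits, 27)   # the full 200-draw check lives in the acceptance suite
})

test_that("the displacement axis reproduces collinear paths exactly", {
  s <- seq(-0.1, 0.1, length.out = 6)
  coms <- cbind(-s, 0, 0)        # pure posterior displacement, normalized units
  res <- displacement_axis(coms, mean_head_length = 3.5)
  expect_equal(res$r2, 1)
  expect_equal(res$displacements, (s - mean(s)) * 3.5, tolerance = 1e-12)

  # a noisy line still loads > 0.9 of the variance on the first component
  set.seed(21)
  noisy <- coms + matrix(rnorm(18, sd = 0.05 * diff(range(s))), ncol = 3)
  resn <- displacement_axis(noisy, 3.5)
  expect_gt(resn$r2, 0.9)

  # the angle to a supplied apodeme main axis is reported
  expect_equal(displacement_axis(coms, 3.5, apodeme_axis = c(1, 0, 0))$apodeme_angle_deg,
               0, tolerance = 1e-9)
  expect_error(displacement_axis(coms[1:2, ], 3.5), ">= 3")
})

test_that("PCA displacements match the model displacement on a symmetric arc", {
  # attachment point on a circular arc; for an arc straddling gamma0 = 90 deg
  # symmetrically, the first principal direction is the apodeme axis and the
  # scores equal Delta(theta) exactly
  app <- make_reference_apparatus()
  th <- seq(51 - 35, 51 + 35, length.out = 10)    # 70 deg span, gamma 55-125
  gam <- apodeme_angle(th, app$levers) * pi / 180
  r <- 0.6454 / 3.5                                # projected inlever, normalized
  arc <- cbind(r * cos(gam), r * sin(gam), 0)
  res <- displacement_axis(arc, mean_head_length = 3.5)
  delta <- apodeme_displacement(th, app$levers, app$frame)$delta
  delta_c <- delta - mean(delta)
  err <- abs(res$displacements - delta_c)
  expect_lt(max(err) / diff(range(delta_c)), 0.02)
})
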