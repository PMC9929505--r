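test_that("all factors at their maxima give sigma_max * A_phys * MA_max", {
  # gamma = 90 at theta0, fibre at L_opt, zero pennation, single population
  fr <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  lv <- lever_set(inlever = c(0, 0.5, 0), outlever_distal = c(2, 0, 0),
                  apodeme_axis = c(1, 0, 0), gamma0_deg = 90, theta0_deg = 60)
  app <- bite_apparatus(
    fr, lv,
    muscle_architecture(1.8, fibre_population(0, 0.9)),
    force_length_params(1.5, 0.9, 6),
    theta_range = c(40, 80))
  expect_equal(bite_force(60, app), 1.5 * (1.8 / 0.9) * 0.5 / 2,
               tolerance = 1e-12)
})

test_that("the forward model equals an independent brute-force composition", {
  for (seed in 1:100) {
    app <- random_apparatus(seed)
    set.seed(seed + 5000)
    th <- runif(3, app$theta_range[1], app$theta_range[2])
    expect_equal(bite_force(th, app),
                 vapply(th, oracle_bite_force, numeric(1), app = app),
                 tolerance = 1e-9)
  }
})

test_that("bite force equals the factored torque balance", {
  # single population: F * |Lo,eff| = sigma A cos(phi) * |Li,eff|
  set.seed(7)
  fr <- joint_frame(c(0, 0, 0), c(0.1, -0.2, 1))
  lv <- lever_set(inlever = c(0.1, 0.6, 0.1), outlever_distal = c(2, -0.5, 0.2),
                  apodeme_axis = c(1, 0.2, -0.1), gamma0_deg = 80, theta0_deg = 55)
  pop <- fibre_population(28, 1.6, 0.5)
  app <- bite_apparatus(fr, lv, muscle_architecture(3.2, pop),
                        force_length_params(1.1, 1.0, 5),
                        theta_range = c(35, 75))
  th <- seq(36, 74, length.out = 11)
  lev <- effective_levers(th, lv, fr)
  delta <- apodeme_displacement(th, lv, fr)$delta
  lf <- fibre_length(delta, pop)
  phi <- pennation_angle(delta, 28, 2.1)
  lhs <- bite_force(th, app) * lev$outlever_eff
  rhs <- stress(lf, app$physiology) * app$a_phys * cos(phi * pi / 180) *
    lev$inlever_eff
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("the reference apparatus reproduces the printed peak bite force", {
  app <- make_reference_apparatus()
  th <- seq(35, 105, by = 0.25)
  f <- bite_force(th, app)
  expect_equal(max(f), 1.4, tolerance = 0.15)
  expect_lt(th[which.max(f)], 65)   # peak at small opening angles
  expect_error(bite_force(110, app), "admissible range")
})

test_that("sensor projection recovers the bite force from measurements", {
  fr <- joint_frame(c(0, 0, 0), c(0, 0, 1))
  lo <- c(1, 0, 0)             # bite force direction: Lo x R = (0, -1, 0)
  mk <- function(alpha_deg, gcal = 1, gbite = 1) {
    a <- alpha_deg * pi / 180
    bite_measurement(theta_deg = 60, force_measured = 0.5, outlever = lo,
                     sensor_axis = c(sin(a), -cos(a), 0),
                     plate_moment_cal = gcal, plate_moment_bite = gbite)
  }
  expect_equal(measured_to_bite(mk(0), fr), 0.5)
  expect_equal(measured_to_bite(mk(60), fr), 1.0, tolerance = 1e-12)
  expect_equal(measured_to_bite(mk(0, gcal = 1.25, gbite = 1), fr), 0.625)
  # monotone decreasing in alpha on [0, 90)
  f <- vapply(c(0, 20, 40, 60, 75), function(a) measured_to_bite(mk(a), fr),
              numeric(1))
  expect_true(all(diff(f) > 0))  # recovered force grows as cos(alpha) shrinks
  expect_error(measured_to_bite(mk(89), fr), "perpendicular")
})

test_that("non-distal stimulated bites rescale by the effective outlever ratio", {
  expect_equal(stimulated_rescale(2, 1.5, 1.5), 2)
  expect_equal(stimulated_rescale(2, 1.2, 1.5), 2 * 0.8)
  expect_equal(stimulated_rescale(2, 0.75, 1.5), 1)
  expect_error(stimulated_rescale(2, 0, 1.5), "> 0")
})

test_that("the minimal model combines its proxies into 8.25 kPa/um", {
  # F = 0.55 * 1 * 0.3 Hw Hl * 50 Sl kPa; per unit Hw Hl Sl that is 8.25
  inp <- minimal_model_inputs(1, 1, 1, 10, 55e-6)
  expect_equal(minimal_max_force(inp) / 10 * 1000, 8.25)
  # Sl = 10 um: prefactor 82.5 -> approximately 83 kPa * Hw * Hl
  expect_lte(abs(minimal_max_force(inp) * 1000 - 83), 0.5)
  expect_equal(sarcomere_stress(3), 150)
  expect_error(sarcomere_stress(2.9), "\\[3, 17\\]")
  expect_error(minimal_model_inputs(1, 1, 1, 18, 1) |> minimal_max_force(),
               "\\[3, 17\\]")
  # linear in each of Hw, Hl, Sl
  base <- minimal_max_force(minimal_model_inputs(2, 3, 1, 8, 1))
  expect_equal(minimal_max_force(minimal_model_inputs(4, 3, 1, 8, 1)), 2 * base)
  expect_equal(minimal_max_force(minimal_model_inputs(2, 6, 1, 8, 1)), 2 * base)
  expect_equal(minimal_max_force(minimal_model_inputs(2, 3, 1, 16, 1)), 2 * base)
})

test_that("allometric bounds give the printed weight-specific forces", {
  expect_equal(round(allometric_bound(55e-6, 20), -2), 500)
  expect_equal(round(allometric_bound(55e-6, 50), -2), 1300)
  expect_equal(allometric_bound(1, 20), 20)
  expect_error(allometric_bound(0, 20), "> 0")
})
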