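# Independent brute-force oracle for the forward model and a random
# apparatus generator for property-style tests. The oracle re-derives every
# quantity from the defining equations with its own (scalar, explicit)
# arithmetic; it shares no code with the package internals.

oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

oracle_norm <- function(v) sqrt(sum(v * v))

# forward model composed step by step from the defining relations
oracle_bite_force <- function(theta_deg, app) {
  d2r <- pi / 180
  r <- app$frame$axis / oracle_norm(app$frame$axis)
  lv <- app$levers
  proj_in <- oracle_norm(oracle_cross(r, lv$inlever))
  proj_out <- oracle_norm(oracle_cross(r, lv$outlever_distal))
  proj_apo <- oracle_norm(oracle_cross(r, lv$apodeme_axis))
  gamma <- (lv$theta0_deg - theta_deg + lv$gamma0_deg) * d2r
  ma <- sin(gamma) * proj_in * proj_apo / proj_out
  delta <- (cos(lv$gamma0_deg * d2r) - cos(gamma)) * proj_in * proj_apo
  phys <- app$physiology
  ref_l0 <- app$muscle$populations[[app$muscle$reference]]$fibre_length0
  a_total <- app$muscle$volume / phys$l_opt
  force <- 0
  for (pop in app$muscle$populations) {
    lt0 <- pop$fibre_length0 + pop$filament_length
    phi0 <- pop$phi0_deg * d2r
    lf <- sqrt((cos(phi0) * lt0 - delta)^2 + (sin(phi0) * lt0)^2) -
      pop$filament_length
    phi <- atan2(sin(phi0), cos(phi0) - delta / lt0)
    l_opt_pop <- phys$l_opt * pop$fibre_length0 / ref_l0
    sigma <- phys$sigma_max * exp(-phys$beta * (1 - lf / l_opt_pop)^2)
    force <- force + pop$number_fraction * a_total * sigma * cos(phi)
  }
  ma * force
}

# a random but physically admissible apparatus; pure function of the seed
random_apparatus <- function(seed) {
  set.seed(seed)
  rand_unit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  axis <- rand_unit()
  # keep lever and apodeme projections well away from degeneracy
  ok_vec <- function(len) {
    repeat {
      v <- len * rand_unit()
      if (oracle_norm(oracle_cross(axis, v)) > 0.3 * len) return(v)
    }
  }
  theta0 <- runif(1, 40, 70)
  pops <- list(fibre_population(
    phi0_deg = runif(1, 5, 40),
    fibre_length0 = runif(1, 1.2, 2.0),
    filament_length = runif(1, 0.3, 0.8),
    number_fraction = 0.8
  ), fibre_population(
    phi0_deg = runif(1, 5, 40),
    fibre_length0 = runif(1, 1.2, 2.2),
    filament_length = 0,
    number_fraction = 0.2
  ))
  bite_apparatus(
    frame = joint_frame(runif(3, -1, 1), axis),
    levers = lever_set(
      inlever = ok_vec(runif(1, 0.3, 0.7)),
      outlever_distal = ok_vec(runif(1, 1.5, 2.5)),
      apodeme_axis = ok_vec(1),
      gamma0_deg = runif(1, 70, 110),
      theta0_deg = theta0
    ),
    muscle = muscle_architecture(runif(1, 2, 5), pops),
    physiology = force_length_params(runif(1, 0.5, 2), runif(1, 0.7, 1.3),
                                     runif(1, 2, 12)),
    theta_range = c(theta0 - 25, theta0 + 25)
  )
}
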