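test_that("same seed gives a bit-identical trajectory", {
  ff <- force_field(4)
  st <- init_chain(ff)
  r1 <- langevin_run(st, ff, 2000, seed = 42, draw_velocities = TRUE)
  r2 <- langevin_run(st, ff, 2000, seed = 42, draw_velocities = TRUE)
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$obs, r2$obs)
  r3 <- langevin_run(st, ff, 2000, seed = 43, draw_velocities = TRUE)
  expect_false(identical(r1$state$positions, r3$state$positions))
})

test_that("zero-friction integration conserves energy (symplectic bound)", {
  ff <- force_field(2)
  st <- chain_state(matrix(c(0, 0, 0, 0, 0, 1.7), 2, 3, byrow = TRUE))
  r <- langevin_run(st, ff, 1e5, dt = 0.1, gamma = 0, sample_every = 10)
  E <- r$epot + r$ekin
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("thermostatted velocities satisfy equipartition", {
  ff <- force_field(2)
  st <- init_chain(ff)
  # record z velocity variance through kinetic energy of a long run
  r <- langevin_run(st, ff, 3e5, temperature = 300, dt = 0.5, gamma = 0.01,
                    sample_every = 10, draw_velocities = TRUE, seed = 2)
  # mean kinetic energy per degree of freedom = kT/2
  dof <- 3 * 2
  Tk <- mean(r$ekin) / (0.5 * dof * kB_kcal)
  blocks <- split(r$ekin, cut(seq_along(r$ekin), 20))
  se <- sd(vapply(blocks, mean, 0)) / sqrt(20) / (0.5 * dof * kB_kcal)
  expect_lt(abs(Tk - 300), 3 * se + 1)
})

test_that("interior-bead kinetic temperature stays within 2% of target", {
  ff <- force_field(8)
  st <- init_chain(ff, 8)
  r <- langevin_run(st, ff, 1e6, temperature = 300, dt = 0.5, gamma = 0.01,
                    mode = "isometric", sample_every = 10,
                    draw_velocities = TRUE, seed = 1)
  Tk <- mean(r$ekin) / (0.5 * 3 * r$n_free * kB_kcal)
  expect_lt(abs(Tk - 300) / 300, 0.02)
})

test_that("annealing runs the scheduled segments and relaxes energy", {
  ff <- force_field(6)
  st <- init_chain(ff)
  # zero-step schedule leaves the state untouched
  st2 <- anneal(st, ff, list(c(300, 0)))
  expect_identical(st2$positions, st$positions)

  # cooling from a hot equilibrated state lowers the potential energy in
  # most seeded repeats
  hot <- langevin_run(st, ff, 5000, temperature = 700, gamma = 0.01,
                      draw_velocities = TRUE, seed = 3)$state
  V0 <- chain_potential(hot, ff)
  wins <- 0
  for (s in 1:20) {
    cooled <- anneal(hot, ff, list(c(500, 2000), c(300, 2000), c(120, 2000)),
                     seed = s, draw_velocities = TRUE)
    if (chain_potential(cooled, ff) <= V0) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("annealed equilibration agrees with direct equilibration", {
  ff <- force_field(2)
  st <- init_chain(ff)
  run_mean_epot <- function(state, seed) {
    r <- langevin_run(state, ff, 4e4, temperature = 300, gamma = 0.01,
                      sample_every = 10, seed = seed)
    bl <- split(r$epot, cut(seq_along(r$epot), 20))
    m <- vapply(bl, mean, 0)
    c(mean(m), sd(m) / sqrt(20))
  }
  annealed <- anneal(st, ff, list(c(600, 4000), c(300, 4000)), seed = 5,
                     draw_velocities = TRUE)
  direct <- langevin_run(st, ff, 3e4, temperature = 300, gamma = 0.01,
                         draw_velocities = TRUE, seed = 6)$state
  a <- run_mean_epot(annealed, 7)
  d <- run_mean_epot(direct, 8)
  expect_lt(abs(a[1] - d[1]), 3 * sqrt(a[2]^2 + d[2]^2) + 1e-3)
})

test_that("isometric dimer reproduces the deterministic bond force", {
  ff <- force_field(2)
  p <- quick_protocol("isometric", 1, n_prod = 2000, n_replicas = 1)
  for (x in c(1.3, 1.5, 1.9)) {
    s <- sample_isometric(ff, x, p, seed = 1)
    expect_equal(s$mean, morse_dUdr(x, 80, 2, 1.5), tolerance = 1e-10)
    expect_equal(s$stderr, 0)
  }
  expect_error(sample_isometric(ff, -1, p), "must lie")
  expect_error(sample_isometric(ff, 10, p), "must lie")
})

test_that("isometric trimer matches the quadrature oracle", {
  ff <- force_field(3)
  p <- quick_protocol("isometric", 1, n_prod = 40000, n_replicas = 4)
  for (x in c(2.2, 2.6, 3.0)) {
    s <- sample_isometric(ff, x, p, seed = 17)
    orc <- oracle_fbar_isometric(ff, x, beta300)
    expect_lt(abs(s$mean - orc), 3 * sqrt(s$stderr^2 + 1e-3^2))
  }
})

test_that("isometric mean force vanishes at the free-energy minimum", {
  ff <- force_field(3)
  xmin <- optimize(function(x) -log(oracle_Z_isometric(ff, x, beta300)),
                   c(2, 3.4))$minimum
  # dt = 0.25 fs keeps the O(dt^2) configurational bias below the noise floor
  p <- quick_protocol("isometric", 1, n_prod = 60000, n_replicas = 4,
                      timestep = 0.25)
  s <- sample_isometric(ff, xmin, p, seed = 23)
  expect_lt(abs(s$mean), 3 * s$stderr + 3e-3)
})

test_that("isotensional dimer matches the orientational quadrature oracle", {
  ff <- force_field(2)
  p <- quick_protocol("isotensional", 1, n_prod = 50000, n_replicas = 4)
  s0 <- sample_isotensional(ff, 0, p, seed = 31)
  expect_lt(abs(s0$mean), 3 * s0$stderr)  # isotropy at zero force
  means <- c()
  for (f in c(1, 3, 6)) {
    s <- sample_isotensional(ff, f, p, seed = 31)
    orc <- oracle_xbar_isotensional(ff, f, beta300)
    expect_lt(abs(s$mean - orc), 3 * s$stderr + 1e-3)
    means <- c(means, s$mean)
  }
  expect_true(all(diff(means) > 0))  # extension grows with force
  expect_error(sample_isotensional(ff, -1, p), ">= 0")
})

test_that("finite-difference isotensional response is non-negative", {
  ff <- force_field(2)
  p <- quick_protocol("isotensional", 1, n_prod = 40000, n_replicas = 4)
  s1 <- sample_isotensional(ff, 2, p, seed = 41)
  s2 <- sample_isotensional(ff, 3, p, seed = 42)
  kappa <- (s2$mean - s1$mean) / 1
  expect_gt(kappa, -3 * sqrt(s1$stderr^2 + s2$stderr^2))
})

test_that("sweep derives distinct reproducible seeds and aggregates replicas", {
  seeds <- outer(1:3, 1:2, function(i, j) derive_seed(99, i, j))
  expect_equal(length(unique(as.vector(seeds))), 6)

  ff <- force_field(2)
  p <- quick_protocol("isometric", c(1.4, 1.6, 1.8), n_prod = 2000,
                      n_replicas = 2, seed = 9)
  c1 <- stretch_sweep(ff, p)
  c2 <- stretch_sweep(ff, p)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # single grid point reduces to the single-point sampler
  p1 <- quick_protocol("isometric", 1.6, n_prod = 2000, n_replicas = 1,
                       seed = 9)
  s <- sample_isometric(ff, 1.6, p1, seed = derive_seed(9, 1, 1))
  c3 <- stretch_sweep(ff, p1)
  expect_equal(c3$mean, s$mean)
})

test_that("bond breaking is flagged, not fatal", {
  ff <- force_field(2)
  p <- quick_protocol("isotensional", 1, n_prod = 5000, n_replicas = 1)
  # pulling beyond the Morse inflection force dissociates the bond
  s <- sample_isotensional(ff, 90, p, seed = 3)
  expect_true(s$broken)
  p2 <- quick_protocol("isotensional", c(1, 90), n_prod = 5000,
                       n_replicas = 1)
  cv <- stretch_sweep(ff, p2)
  expect_false(cv$flag[1])
  expect_true(cv$flag[2])
})

test_that("curves round-trip through the annotated CSV dialect", {
  ff <- force_field(2)
  p <- quick_protocol("isometric", c(1.4, 1.6), n_prod = 2000, n_replicas = 2)
  cv <- stretch_sweep(ff, p)
  path <- tempfile(fileext = ".csv")
  write_curve(cv, path)
  cv2 <- read_curve(path)
  expect_equal(as.data.frame(cv2), as.data.frame(cv), tolerance = 1e-15)
  m <- attr(cv2, "meta")
  expect_equal(m$mode, "isometric")
  expect_equal(m$temperature, 300)
})

test_that("protocols round-trip through YAML", {
  p <- stretch_protocol("isotensional", c(0.5, 1, 2), temperature = 320,
                        n_equil = 1000, n_prod = 5000, n_replicas = 3,
                        seed = 77)
  path <- tempfile(fileext = ".yaml")
  write_protocol(p, path)
  p2 <- read_protocol(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
})

test_that("protocol construction validates its grid and steps", {
  expect_error(stretch_protocol("isometric", c(2, 1)), "increasing")
  expect_error(stretch_protocol("isometric", 1, timestep = 0), "timestep")
  expect_error(stretch_protocol("isometric", 1, n_prod = 0), "n_prod")
})
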