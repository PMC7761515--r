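test_that("single-term potentials match their closed forms", {
  # Morse
  expect_equal(morse_energy(1.5, 80, 2, 1.5), 0)
  expect_equal(morse_energy(log(2), 1, 1, 0), 0.25)
  expect_lt(abs(morse_energy(1.5 + 20 / 2, 80, 2, 1.5) - 80), 1e-8 * 80)
  # bend
  expect_equal(bend_energy(pi / 2, 2, pi / 2), 0)
  expect_equal(bend_energy(pi, 2, pi / 2), pi^2 / 4)
  expect_equal(bend_energy(runif(1, 0, pi), 0, 1.9), 0)
  # torsion
  phis <- seq(-pi, pi, length.out = 11)
  expect_equal(torsion_energy(phis, c(0, 0, 0, 0)), rep(0, 11))
  expect_equal(torsion_energy(phis, c(1, 0, 0, 0)), rep(1, 11))
  expect_equal(torsion_energy(pi / 2, c(0, 1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(0, c(0, 1, 0, 0)), 1)
  # periodicity and evenness
  expect_equal(torsion_energy(0.7, c(1, 2, -0.5, 3)),
               torsion_energy(-0.7, c(1, 2, -0.5, 3)))
  expect_equal(torsion_energy(0.7, c(1, 2, -0.5, 3)),
               torsion_energy(0.7 + 2 * pi, c(1, 2, -0.5, 3)))
})

test_that("single-term potentials reject out-of-domain input", {
  expect_error(morse_energy(-0.1, 80, 2, 1.5), "r must be")
  expect_error(bend_energy(-0.1, 60, 1.9), "0, pi")
  expect_error(bend_energy(3.2, 60, 1.9), "0, pi")
  expect_equal(torsion_energy(1, numeric(0)), 0)
})

test_that("Morse energy is monotone on each side of r0 and bounded by D", {
  rs_right <- seq(1.5, 6, by = 0.05)
  rs_left <- seq(1.5, 0.4, by = -0.05)
  u_r <- morse_energy(rs_right, 80, 2, 1.5)
  u_l <- morse_energy(rs_left, 80, 2, 1.5)
  expect_true(all(diff(u_r) > 0))
  expect_true(all(diff(u_l) > 0))
  expect_true(all(u_r <= 80))
})

test_that("alpha_from_stiffness reproduces the Morse well curvature", {
  Ks <- 640; D <- 80
  a <- alpha_from_stiffness(Ks, D)
  expect_equal(a, sqrt(Ks / (2 * D)))
  # numerical curvature of the Morse well at r0 equals Ks
  h <- 1e-4
  curv <- (morse_energy(1.5 + h, D, a, 1.5) - 2 * morse_energy(1.5, D, a, 1.5) +
             morse_energy(1.5 - h, D, a, 1.5)) / h^2
  expect_equal(curv, Ks, tolerance = 1e-6)
  expect_error(alpha_from_stiffness(-1, 80))
})

test_that("total potential equals an independent term-by-term summation", {
  set.seed(101)
  ff <- force_field(4)
  for (rep in 1:5) {
    st <- random_state(ff)
    expect_equal(chain_potential(st, ff), r_chain_potential(st$positions, ff),
                 tolerance = 1e-10)
  }
  # equilibrium zigzag with torsion switched off has zero energy
  ff0 <- force_field(6, torsion_K = c(0, 0, 0, 0))
  expect_equal(chain_potential(init_chain(ff0), ff0), 0, tolerance = 1e-18)
})

test_that("potential is invariant under rigid motions", {
  set.seed(7)
  ff <- force_field(6)
  st <- random_state(ff)
  V <- chain_potential(st, ff)
  for (rep in 1:5) {
    R <- random_rotation()
    shift <- matrix(rep(runif(3, -5, 5), each = 6), 6, 3)
    st2 <- chain_state(st$positions %*% R + shift)
    expect_equal(chain_potential(st2, ff), V, tolerance = 1e-9 * max(1, abs(V)))
  }
})

test_that("analytic forces match central finite differences", {
  set.seed(11)
  ff <- force_field(5)
  h <- 1e-5
  for (rep in 1:5) {
    st <- random_state(ff)
    Fm <- chain_forces(st, ff)
    num <- Fm * 0
    for (i in 1:5) for (k in 1:3) {
      pp <- st$positions; pp[i, k] <- pp[i, k] + h
      pm <- st$positions; pm[i, k] <- pm[i, k] - h
      num[i, k] <- -(chain_potential(chain_state(pp), ff) -
                       chain_potential(chain_state(pm), ff)) / (2 * h)
    }
    expect_lt(max(abs(Fm - num)) / max(abs(num)), 1e-6)
    # no net force, no net torque
    expect_lt(max(abs(colSums(Fm))), 1e-9)
    tq <- c(sum(st$positions[, 2] * Fm[, 3] - st$positions[, 3] * Fm[, 2]),
            sum(st$positions[, 3] * Fm[, 1] - st$positions[, 1] * Fm[, 3]),
            sum(st$positions[, 1] * Fm[, 2] - st$positions[, 2] * Fm[, 1]))
    expect_lt(max(abs(tq)), 1e-9)
  }
  # equilibrium geometry: forces vanish
  ff0 <- force_field(6, torsion_K = c(0, 0, 0, 0))
  expect_lt(max(abs(chain_forces(init_chain(ff0), ff0))), 1e-10)
})

test_that("overlapping consecutive beads are a domain error", {
  ff <- force_field(3)
  pos <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1.5), 3, 3, byrow = TRUE)
  expect_error(chain_potential(chain_state(pos), ff), "overlapping")
})

test_that("force-field construction enforces its invariants", {
  expect_error(force_field(1), "n_beads")
  expect_error(force_field(4, bond_D = -1), "bond_D")
  expect_error(force_field(4, bond_alpha = 0), "bond_alpha")
  expect_error(force_field(4, masses = c(1, 2)), "masses")
  expect_error(force_field(4, masses = -14), "masses")
  expect_error(force_field(4, bend_K = -5), "bend_K")
  expect_error(force_field(6, torsion_K = list(c(1, 2))), "per dihedral")
  # counts: N-1 bonds, N-2 bends, N-3 torsions via the torsion list length
  ff <- force_field(8)
  expect_length(ff$torsion_K, 5)
  expect_length(force_field(3)$torsion_K, 0)
})

test_that("force field and chain geometry round-trip through files", {
  ff <- force_field(5, masses = c(15, 14, 16, 14, 15), bond_D = 75,
                    bond_alpha = 1.8, torsion_K = c(1, -2, 0.5))
  yml <- tempfile(fileext = ".yaml")
  write_force_field(ff, yml)
  ff2 <- read_force_field(yml)
  expect_equal(unclass(ff2), unclass(ff), tolerance = 1e-12)

  st <- init_chain(ff, 5.2)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(st, xyz)
  st2 <- read_xyz(xyz)
  expect_equal(st2$positions, st$positions, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("init_chain places uniform bonds with the ends on the z axis", {
  for (N in c(5, 8)) for (x in c(3.5, 6.5, 9)) {
    ff <- force_field(N)
    st <- init_chain(ff, x)
    bonds <- sqrt(rowSums(diff(st$positions)^2))
    expect_equal(st$positions[1, ], c(0, 0, 0))
    expect_equal(st$positions[N, ], c(0, 0, x))
    if (x <= (N - 1) * ff$bond_r0 * 0.98)
      expect_equal(bonds, rep(ff$bond_r0, N - 1), tolerance = 1e-9)
  }
})
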