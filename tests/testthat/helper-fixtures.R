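# shared fixtures and independent reference implementations

beta300 <- 1 / (kB_kcal * 300)

quick_protocol <- function(mode, grid, n_equil = 4000, n_prod = 30000,
                           n_replicas = 4, seed = 1, ...) {
  stretch_protocol(mode, grid, n_equil = n_equil, n_prod = n_prod,
                   n_replicas = n_replicas, seed = seed, ...)
}

# independent term-by-term chain potential, written only from the single-term
# closed forms and plain R geometry (the oracle for the compiled evaluation)
r_chain_potential <- function(pos, ff) {
  N <- nrow(pos)
  V <- 0
  for (i in 1:(N - 1)) {
    r <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
    V <- V + morse_energy(r, ff$bond_D, ff$bond_alpha, ff$bond_r0)
  }
  if (N >= 3 && ff$bend_K > 0) for (j in 2:(N - 1)) {
    a <- pos[j - 1, ] - pos[j, ]; b <- pos[j + 1, ] - pos[j, ]
    ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    V <- V + bend_energy(acos(max(min(ca, 1), -1)), ff$bend_K, ff$bend_theta0)
  }
  if (N >= 4 && length(ff$torsion_K)) for (t in 1:(N - 3)) {
    b1 <- pos[t + 1, ] - pos[t, ]
    b2 <- pos[t + 2, ] - pos[t + 1, ]
    b3 <- pos[t + 3, ] - pos[t + 2, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    phi <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
    V <- V + torsion_energy(phi, ff$torsion_K[[t]])
  }
  V
}

# random mildly-perturbed chain state (avoids degenerate geometries)
random_state <- function(ff, amp = 0.2) {
  st <- init_chain(ff)
  st$positions <- st$positions +
    matrix(runif(3 * ff$n_beads, -amp, amp), ff$n_beads, 3)
  st
}

random_rotation <- function() {
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  Rx %*% Rz
}

# analytic Morse force magnitude dU/dr
morse_dUdr <- function(r, D, alpha, r0) {
  e <- exp(-alpha * (r - r0))
  2 * D * alpha * e * (1 - e)
}

convex_toy <- function(k = 4, x_max = 4, n = 801) {
  toy_free_energy(k = k,
                  bumps = data.frame(center = numeric(0),
                                     height = numeric(0),
                                     width = numeric(0)),
                  x_max = x_max, n = n)
}

bump_toy <- function(k = 4, center = 2, height = 3, width = 0.25,
                     x_max = 4, n = 1601) {
  toy_free_energy(k = k, bumps = data.frame(center = center, height = height,
                                            width = width),
                  x_max = x_max, n = n)
}
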