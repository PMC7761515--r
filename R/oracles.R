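#' Quadrature partition functions for tiny chains
#'
#' Deterministic brute-force references for the sampler and the transform
#' toolkit, limited to dimers and trimers.  `oracle_Z_isometric` computes
#' the configurational partition function with the end-to-end VECTOR held
#' at (0, 0, x): for a dimer there are no remaining degrees of freedom and
#' `Z(x) = exp(-beta U_bond(x))`; for a trimer the middle bead is
#' integrated in cylindrical coordinates about the pinned-end axis
#' (azimuthal symmetry reduces the integral to 2D, done with adaptive 2D
#' quadrature).  Momentum and hbar/N! prefactors are x-independent, cancel
#' in all energy differences, and are dropped throughout.
#'
#' @param ff `force_field` with 2 or 3 beads.
#' @param x end-to-end distance, Angstrom.
#' @param beta inverse temperature, mol/kcal.
#' @return the configurational Z(x) (arbitrary constant normalization).
#' @export
oracle_Z_isometric <- function(ff, x, beta) {
  N <- ff$n_beads
  if (N > 3) stop("quadrature oracle supports N <= 3 only")
  if (length(x) > 1) return(vapply(x, oracle_Z_isometric, 0, ff = ff, beta = beta))
  if (N == 2) return(exp(-beta * morse_energy(x, ff$bond_D, ff$bond_alpha, ff$bond_r0)))
  # trimer: middle bead at (rho, 0, z), ends at (0,0,0) and (0,0,x)
  rng <- bond_range(ff, beta)
  U <- function(rho, z) {
    r1 <- sqrt(rho^2 + z^2)
    r2 <- sqrt(rho^2 + (x - z)^2)
    u <- morse_energy(pmax(r1, 1e-12), ff$bond_D, ff$bond_alpha, ff$bond_r0) +
      morse_energy(pmax(r2, 1e-12), ff$bond_D, ff$bond_alpha, ff$bond_r0)
    if (ff$bend_K > 0) {
      # angle at the middle bead between the vectors to the two pinned ends
      a1 <- -rho; a3 <- -z
      b1 <- -rho; b3 <- x - z
      ca <- (a1 * b1 + a3 * b3) / (r1 * r2)
      ca <- pmin(pmax(ca, -1), 1)
      u <- u + 0.5 * ff$bend_K * (acos(ca) - ff$bend_theta0)^2
    }
    u
  }
  integrand <- function(rho, z) rho * exp(-beta * U(rho, z))
  2 * pi * pracma::integral2(integrand, 0, rng[2], x / 2 - rng[2], x / 2 + rng[2],
                             reltol = 1e-10)$Q
}

# log configurational partition function; avoids underflow of Z itself
oracle_lnZ <- function(ff, x, beta) {
  if (ff$n_beads == 2)
    return(-beta * morse_energy(x, ff$bond_D, ff$bond_alpha, ff$bond_r0))
  log(oracle_Z_isometric(ff, x, beta))
}

# bond-length window outside which exp(-beta U_bond) is negligible
bond_range <- function(ff, beta, cut = 30) {
  Ucut <- min(cut / beta, 0.96 * ff$bond_D)
  s <- sqrt(Ucut / ff$bond_D)
  rlo <- max(ff$bond_r0 - log1p(s) / ff$bond_alpha, 1e-6)
  rhi <- ff$bond_r0 - log(1 - s) / ff$bond_alpha
  c(rlo, rhi)
}

#' Helmholtz curve and mean force from the quadrature oracle
#'
#' `oracle_F_curve` tabulates `F(x) = -k_BT ln Z(x)` on a grid (optionally
#' anchored to 0 at the first point); `oracle_fbar_isometric` returns the
#' mean constraint force `dF/dx` by central differencing of the quadrature
#' F, the deterministic reference for the isometric sampler.
#'
#' @param ff `force_field` (N <= 3).
#' @param xs grid of end-to-end distances.
#' @param beta inverse temperature.
#' @param anchor subtract the value at the first grid point.
#' @return an `energy_curve` (kind "helmholtz").
#' @export
oracle_F_curve <- function(ff, xs, beta, anchor = TRUE) {
  lnZ <- log(oracle_Z_isometric(ff, xs, beta))
  Fv <- -lnZ / beta
  if (anchor) Fv <- Fv - Fv[1]
  energy_curve(xs, Fv, 0,
               meta = list(kind = "helmholtz", reference = if (anchor) xs[1] else NA,
                           temperature = 1 / (beta * kB_kcal),
                           n_beads = ff$n_beads, oracle = TRUE))
}

#' @param x end-to-end distance (vectorized).
#' @param h central-difference step, Angstrom.
#' @rdname oracle_F_curve
#' @export
oracle_fbar_isometric <- function(ff, x, beta, h = 1e-3) {
  (log(oracle_Z_isometric(ff, x - h, beta)) -
     log(oracle_Z_isometric(ff, x + h, beta))) / (2 * h * beta)
}

#' Isotensional quadrature references
#'
#' Two distinct references are provided, and the distinction matters for
#' small chains.  `oracle_Delta_isotensional` evaluates the scalar
#' transform-convention partition function
#' \deqn{\Delta(f) = \beta f \int_0^{x_{max}} Z(x)\, e^{\beta f x} dx,}
#' the object the free-energy transform toolkit is built on
#' (`oracle_G_isotensional` is `-k_BT ln Delta`).  `oracle_xbar_isotensional`
#' instead predicts what the 3D constant-force simulation actually
#' measures: the mean z-projection of the end-to-end vector under the full
#' orientational measure `d^3x Z(|x|) e^{beta f z}`.  Writing z = x cos
#' theta, the angular integral is analytic and
#' \deqn{\bar z(f) = \frac{\int x Z(x) [x\cosh(u) - \sinh(u)/(\beta f)] dx}
#'                       {\int x Z(x) \sinh(u)/(\beta f)\, dx}, \quad u = \beta f x.}
#' The two conventions differ by orientational-entropy terms of order
#' k_BT ln(beta f x); they agree in the stiff, strongly-stretched limit.
#'
#' @param ff `force_field` (N <= 3).
#' @param f applied force, kcal/mol/A (> 0 for Delta; >= 0 for xbar).
#' @param beta inverse temperature.
#' @param x_max upper integration limit (default: the bond-break length).
#' @return `oracle_Delta_isotensional`: Delta(f); `oracle_G_isotensional`:
#'   -k_BT ln Delta(f); `oracle_xbar_isotensional`: mean z-extension, A.
#' @export
oracle_Delta_isotensional <- function(ff, f, beta,
                                      x_max = (ff$n_beads - 1) * r_break(ff)) {
  if (any(f <= 0)) stop("f must be > 0")
  if (length(f) > 1)
    return(vapply(f, oracle_Delta_isotensional, 0, ff = ff, beta = beta,
                  x_max = x_max))
  x_lo <- 1e-6
  lw <- function(x) oracle_lnZ(ff, x, beta) + beta * f * x
  grid <- seq(x_lo, x_max, length.out = 400)
  lws <- lw(grid)
  keep <- is.finite(lws)
  M <- max(lws[keep])
  ig <- if (ff$n_beads == 2) {
    function(x) {
      v <- exp(lw(x) - M)
      v[!is.finite(v)] <- 0
      v
    }
  } else {
    grid <- grid[keep & lws > M - 300]
    x_lo <- min(grid); x_max <- max(grid)
    sf <- splinefun(grid, lw(grid) - M, method = "monoH.FC")
    function(x) exp(sf(x))
  }
  I <- pracma::quadgk(ig, x_lo, x_max, tol = 1e-12)
  beta * f * exp(M) * I
}

#' @rdname oracle_Delta_isotensional
#' @export
oracle_G_isotensional <- function(ff, f, beta,
                                  x_max = (ff$n_beads - 1) * r_break(ff)) {
  -log(oracle_Delta_isotensional(ff, f, beta, x_max)) / beta
}

#' @rdname oracle_Delta_isotensional
#' @export
oracle_xbar_isotensional <- function(ff, f, beta,
                                     x_max = (ff$n_beads - 1) * r_break(ff)) {
  if (any(f < 0)) stop("f must be >= 0")
  n_grid <- if (ff$n_beads == 2) 600 else 200
  grid <- seq(1e-6, x_max, length.out = n_grid)
  lnZ <- oracle_lnZ(ff, grid, beta)  # table built once, shared across f
  keep <- is.finite(lnZ) & (lnZ > max(lnZ[is.finite(lnZ)]) - 200)
  grid <- grid[keep]; lnZ <- lnZ[keep]
  lxZ <- splinefun(grid, lnZ, method = "monoH.FC")
  one <- function(fi) {
    if (fi == 0) return(0)  # isotropy
    bf <- beta * fi
    lw <- lnZ + bf * grid + log(grid)
    M <- max(lw)
    # restrict to the region carrying weight (peaked integrands upset the
    # adaptive rule when the support is a sliver of the interval)
    supp <- range(grid[lw > M - 80])
    # angular integral done analytically: d^3x -> 2 pi x dx dz, |z| <= x
    den_ig <- function(x) {
      uu <- bf * x
      exp(lxZ(x) + log(x) + uu - M) * (1 - exp(-2 * uu)) / 2
    }
    num_ig <- function(x) {
      uu <- bf * x
      exp(lxZ(x) + log(x) + uu - M) * bf *
        (x * (1 + exp(-2 * uu)) / (2 * bf) - (1 - exp(-2 * uu)) / (2 * bf^2))
    }
    den <- pracma::quadgk(den_ig, supp[1], supp[2], tol = 1e-12)
    num <- pracma::quadgk(num_ig, supp[1], supp[2], tol = 1e-12)
    num / den
  }
  vapply(f, one, 0)
}

#' Parametric non-convex toy free energies
#'
#' Generates an analytically known Helmholtz-like curve
#' \deqn{F(x) = \tfrac12 k x^2 + \sum_b h_b \exp(-(x - c_b)^2 / 2 w_b^2)}
#' on `[0, x_max]`: a convex quadratic backbone plus Gaussian concave bumps
#' that stand in for the curvature anomalies of small-chain stretching.
#' With no bumps F is convex everywhere; a sufficiently tall, narrow bump
#' makes `F'' < 0` on a computable interval, so the force curve
#' `fbar = F'` acquires a negative-slope stretch and the Legendre-Fenchel
#' conjugate a kink.
#'
#' @param k quadratic stiffness, kcal/mol/A^2.
#' @param bumps data.frame with columns `center`, `height`, `width` (one
#'   row per bump; zero rows for a convex toy).
#' @param x_max domain end, Angstrom.
#' @param n number of tabulation points.
#' @return a list with the tabulated `curve` (an `energy_curve`), analytic
#'   functions `F`, `Fprime`, `Fsecond`, and the parameters.
#' @export
toy_free_energy <- function(k = 4, bumps = data.frame(center = 2, height = 3,
                                                      width = 0.25),
                            x_max = 4, n = 801) {
  bumps <- as.data.frame(bumps)
  Ffun <- function(x) {
    v <- 0.5 * k * x^2
    for (b in seq_len(nrow(bumps)))
      v <- v + bumps$height[b] * exp(-(x - bumps$center[b])^2 /
                                       (2 * bumps$width[b]^2))
    v
  }
  Fp <- function(x) {
    v <- k * x
    for (b in seq_len(nrow(bumps)))
      v <- v - bumps$height[b] * (x - bumps$center[b]) / bumps$width[b]^2 *
        exp(-(x - bumps$center[b])^2 / (2 * bumps$width[b]^2))
    v
  }
  Fs <- function(x) {
    v <- rep(k, length(x))
    for (b in seq_len(nrow(bumps))) {
      t <- (x - bumps$center[b]) / bumps$width[b]
      v <- v + bumps$height[b] / bumps$width[b]^2 * (t^2 - 1) *
        exp(-t^2 / 2)
    }
    v
  }
  xs <- seq(0, x_max, length.out = n)
  list(curve = energy_curve(xs, Ffun(xs), 0,
                            meta = list(kind = "helmholtz", reference = 0,
                                        toy = TRUE)),
       F = Ffun, Fprime = Fp, Fsecond = Fs,
       params = list(k = k, bumps = bumps, x_max = x_max))
}

#' @param params the list returned by `toy_free_energy`.
#' @param n number of tabulation points for the derivative curve.
#' @rdname toy_free_energy
#' @export
toy_F_prime <- function(params, n = 801) {
  xs <- seq(0, params$params$x_max, length.out = n)
  data.frame(control = xs, mean = params$Fprime(xs), stderr = 0)
}

#' Equal-area (Maxwell) force level of a toy anomaly
#'
#' For each bump of a toy free energy, finds by root-finding on the
#' analytic `F'` the force level `f*` at which the horizontal line cuts
#' equal areas out of the van-der-Waals-like loop of `F'`: the common
#' tangent condition `F(x2) - F(x1) = f* (x2 - x1)` with
#' `F'(x1) = F'(x2) = f*`.  This `f*` is dual to the Legendre-Fenchel kink
#' force, and `(x1, x2)` to the maximizer jump there.
#'
#' @param toy list from [toy_free_energy()].
#' @param bump which bump (row index).
#' @return list with `f` (the equal-area level) and `x_lo`, `x_hi` (the
#'   two outer extensions sharing that force).
#' @export
toy_maxwell_force <- function(toy, bump = 1) {
  p <- toy$params
  b <- p$bumps[bump, ]
  # window around this bump, bounded by neighbours
  ctr <- sort(p$bumps$center)
  pos <- match(b$center, ctr)
  lo <- if (pos > 1) (ctr[pos - 1] + b$center) / 2 else 0
  hi <- if (pos < length(ctr)) (ctr[pos + 1] + b$center) / 2 else p$x_max
  xs <- seq(lo, hi, length.out = 4001)
  fp <- toy$Fprime(xs)
  # local extrema of F' bracketing the S-loop
  d <- diff(fp)
  imax <- which(d[-1] < 0 & d[-length(d)] >= 0) + 1
  imin <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1
  if (length(imax) == 0 || length(imin) == 0)
    stop("no S-loop in F' inside the bump window (bump too weak)")
  f_hi <- fp[imax[1]]; f_lo <- fp[imin[length(imin)]]
  roots_at <- function(f) {
    g <- fp - f
    sc <- which(g[-1] * g[-length(g)] <= 0)
    r <- vapply(sc, function(i)
      uniroot(function(x) toy$Fprime(x) - f, c(xs[i], xs[i + 1]),
              tol = 1e-12)$root, 0)
    sort(unique(r))
  }
  areas <- function(f) {
    r <- roots_at(f)
    if (length(r) < 2) return(NA_real_)
    x1 <- r[1]; x2 <- r[length(r)]
    (toy$F(x2) - toy$F(x1)) - f * (x2 - x1)
  }
  eps <- 1e-6 * (f_hi - f_lo)
  fstar <- uniroot(areas, c(f_lo + eps, f_hi - eps), tol = 1e-12)$root
  r <- roots_at(fstar)
  list(f = fstar, x_lo = r[1], x_hi = r[length(r)])
}

#' Lower convex hull of a tabulated free energy
#'
#' Independent convex-envelope construction: the lower convex hull of the
#' (x, F) point set by an Andrew monotone-chain scan, evaluated back on the
#' original grid as a piecewise-linear function.  Used as the reference
#' that the biconjugate (double Legendre-Fenchel transform) must reproduce.
#'
#' @param F an `energy_curve` with >= 3 points.
#' @return an `energy_curve` tabulating the hull on the same grid.
#' @export
convex_envelope_hull <- function(F) {
  xs <- F$control; ys <- F$value
  n <- length(xs)
  if (n < 3) stop("need at least 3 points")
  hull <- c(1, 2)
  for (i in 3:n) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies on or above the chord a--i
      cr <- (xs[b] - xs[a]) * (ys[i] - ys[a]) -
        (ys[b] - ys[a]) * (xs[i] - xs[a])
      if (cr >= 0) break
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  hv <- approx(xs[hull], ys[hull], xout = xs)$y
  energy_curve(xs, hv, 0,
               meta = c(curve_meta(F)[setdiff(names(curve_meta(F)),
                                              "envelope")],
                        list(envelope = "lower_hull")))
}

#' Hull vertex indices (internal helper exposed for diagnostics)
#' @noRd
hull_vertices <- function(F) {
  xs <- F$control; ys <- F$value
  n <- length(xs)
  hull <- c(1, 2)
  for (i in 3:n) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cr <- (xs[b] - xs[a]) * (ys[i] - ys[a]) -
        (ys[b] - ys[a]) * (xs[i] - xs[a])
      if (cr >= 0) break
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  hull
}

#' Run the oracle cross-check suite
#'
#' Quick deterministic consistency checks among independent code paths:
#' the two Delta routes (direct quadrature vs the exact transform over the
#' tabulated F), hull vs biconjugate on random toys, and the equal-area vs
#' kink duality.  Returns a data.frame of pass/fail rows; used by the
#' `verify` CLI subcommand.
#'
#' @param seed seed for the random toy parameters.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
verify_oracles <- function(seed = 1) {
  set.seed(seed)
  beta <- 1 / (kB_kcal * 300)
  ff2 <- force_field(2)
  rows <- list()
  note <- function(check, pass, detail)
    rows[[length(rows) + 1]] <<- data.frame(check = check, pass = pass,
                                            detail = detail)
  # Delta route consistency on the dimer
  xs <- seq(0.9, 2.6, length.out = 6001)
  Fo <- oracle_F_curve(ff2, xs, beta, anchor = FALSE)
  fs <- seq(1, 10, length.out = 10)
  g1 <- oracle_G_isotensional(ff2, fs, beta, x_max = max(xs))
  g2 <- exact_gibbs(Fo, fs, beta, x_lo = min(xs), x_max = max(xs))
  dev <- max(abs(g1 - g2) / pmax(abs(g1), 1e-8))
  note("delta_routes_dimer", dev <= 1e-6, sprintf("max rel dev %.2e", dev))
  # hull vs biconjugate on random toys
  worst <- 0
  for (i in 1:10) {
    toy <- toy_free_energy(k = runif(1, 2, 6),
                           bumps = data.frame(center = runif(1, 1.2, 2.8),
                                              height = runif(1, 1, 4),
                                              width = runif(1, 0.15, 0.4)),
                           x_max = 4, n = 601)
    h <- convex_envelope_hull(toy$curve)
    b <- biconjugate(toy$curve)
    scale <- max(abs(toy$curve$value))
    worst <- max(worst, max(abs(h$value - b$value)) / scale)
  }
  note("hull_vs_biconjugate", worst <= 1e-6, sprintf("max scaled dev %.2e", worst))
  # Maxwell equal-area force vs LF kink force
  toy <- toy_free_energy(k = 4, bumps = data.frame(center = 2, height = 3,
                                                   width = 0.25),
                         x_max = 4, n = 2001)
  mx <- toy_maxwell_force(toy)
  lf <- legendre_fenchel(toy$curve, f_grid = seq(0.5, 16, length.out = 800))
  kerr <- if (nrow(lf$kinks) == 1) abs(lf$kinks$f - mx$f) else Inf
  note("maxwell_vs_kink", kerr <= 1e-3, sprintf("kink force error %.2e", kerr))
  do.call(rbind, rows)
}
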