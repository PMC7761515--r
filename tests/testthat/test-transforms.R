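test_that("pointwise Legendre transform matches closed forms", {
  xs <- seq(0, 3, length.out = 301)
  Fq <- energy_curve(xs, 0.5 * xs^2, meta = list(kind = "helmholtz"))
  lg <- legendre(Fq)
  i <- which.min(abs(lg$x - 1))
  expect_equal(lg$f[i], 1, tolerance = 1e-8)
  expect_equal(lg$G[i], -0.5, tolerance = 1e-8)
  # linear F: f = c everywhere, G = 0
  Fl <- energy_curve(xs, 2.5 * xs, meta = list(kind = "helmholtz"))
  ll <- legendre(Fl)
  expect_equal(ll$f, rep(2.5, length(ll$f)), tolerance = 1e-10)
  expect_lt(max(abs(ll$G)), 1e-9)
  expect_error(legendre(Fq[1:2, ]), "3 grid points")
})

test_that("Legendre output is not one-to-one for non-convex F", {
  toy <- bump_toy()
  lg <- legendre(toy$curve)
  expect_true(any(diff(lg$f) < 0))  # several x share the same force
})

test_that("Legendre-Fenchel conjugate of a quadratic is f^2/2k", {
  k <- 2
  xs <- seq(0, 4, length.out = 801)
  Fq <- energy_curve(xs, 0.5 * k * xs^2, meta = list(kind = "helmholtz"))
  fg <- seq(0.2, 7, length.out = 150)
  lf <- legendre_fenchel(Fq, f_grid = fg)
  scale <- max(abs(lf$neg_G))
  expect_lt(max(abs(lf$neg_G - fg^2 / (2 * k))), 1e-3 * scale)
  expect_equal(nrow(lf$kinks), 0)
  # agrees with the pointwise Legendre route on convex F
  lg <- legendre(Fq)
  Gi <- approx(lg$f, lg$G, xout = fg)$y
  expect_lt(max(abs(-lf$neg_G - Gi), na.rm = TRUE), 1e-3 * scale)
  expect_error(legendre_fenchel(Fq, f_grid = numeric(0)), "non-empty")
})

test_that("Legendre-Fenchel equals dense brute-force maximization", {
  toy <- bump_toy(n = 401)
  fg <- seq(0.5, 14, length.out = 120)
  lf <- legendre_fenchel(toy$curve, f_grid = fg)
  dense_x <- seq(0, 4, length.out = 4001)  # 10x finer grid
  dense_F <- toy$F(dense_x)
  brute <- vapply(fg, function(f) max(f * dense_x - dense_F), 0)
  h <- 4 / 400
  tol <- h^2 / 8 * max(abs(toy$Fsecond(dense_x))) + 1e-9
  expect_lt(max(abs(lf$neg_G - brute)), tol)
})

test_that("the conjugate is convex with a monotone maximizer for random toys", {
  set.seed(5)
  for (rep in 1:10) {
    toy <- toy_free_energy(k = runif(1, 2, 6),
                           bumps = data.frame(center = runif(1, 1.2, 2.8),
                                              height = runif(1, 0.5, 4),
                                              width = runif(1, 0.15, 0.4)),
                           x_max = 4, n = 601)
    lf <- legendre_fenchel(toy$curve, f_grid = seq(1e-3, 20,
                                                   length.out = 300))
    scale <- max(abs(lf$neg_G))
    expect_gt(min(diff(diff(lf$neg_G))), -1e-9 * scale)
    expect_gt(min(diff(lf$argmax_x)), -1e-8 * 4)
  }
})

test_that("exact transform reproduces the free-segment closed form", {
  L <- 3; beta <- beta300
  xs <- seq(0, L, length.out = 501)
  F0 <- energy_curve(xs, rep(0, 501), meta = list(kind = "helmholtz"))
  for (f in c(0.5, 2, 5)) {
    expect_equal(exact_gibbs(F0, f, beta),
                 -log(exp(beta * f * L) - 1) / beta, tolerance = 1e-10)
  }
  expect_error(exact_gibbs(F0, 0, beta), "f > 0")
  expect_error(exact_gibbs(F0, 1, -2), "beta")
})

test_that("exact transform shifts by exactly c when F shifts by c", {
  xs <- seq(0, 3, length.out = 301)
  F0 <- energy_curve(xs, 0.4 * xs^2, meta = list(kind = "helmholtz"))
  F1 <- energy_curve(xs, 0.4 * xs^2 + 2.5, meta = list(kind = "helmholtz"))
  expect_equal(exact_gibbs(F1, 1.5, beta300),
               exact_gibbs(F0, 1.5, beta300) + 2.5, tolerance = 1e-10)
})

test_that("the saddle-point gap shrinks monotonically with beta", {
  toy <- convex_toy(k = 1, x_max = 6, n = 2001)
  f0 <- 2
  lfv <- max(f0 * toy$curve$control - toy$curve$value)
  gaps <- vapply(c(1, 10, 100), function(m)
    abs(exact_gibbs(toy$curve, f0, beta300 * m) - (-lfv)), 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("biconjugate is the convex envelope", {
  set.seed(9)
  # convex F: involution
  toy0 <- convex_toy()
  b0 <- biconjugate(toy0$curve)
  expect_lt(max(abs(b0$value - toy0$curve$value)), 1e-9)
  # random non-convex toys: matches the independent hull construction
  for (rep in 1:10) {
    toy <- toy_free_energy(k = runif(1, 2, 6),
                           bumps = data.frame(center = runif(1, 1.2, 2.8),
                                              height = runif(1, 1, 4),
                                              width = runif(1, 0.15, 0.4)),
                           x_max = 4, n = 401)
    h <- convex_envelope_hull(toy$curve)
    b <- biconjugate(toy$curve)
    scale <- max(abs(toy$curve$value))
    expect_lt(max(abs(h$value - b$value)), 1e-6 * scale)
    expect_lt(max(b$value - toy$curve$value), 1e-9 * scale)
    # the envelope differs from F exactly on the anomaly
    expect_gt(max(toy$curve$value - b$value), 0)
  }
})

test_that("F and its envelope share the same conjugate", {
  toy <- bump_toy(n = 801)
  fg <- seq(0.5, 14, length.out = 200)
  lf1 <- legendre_fenchel(toy$curve, f_grid = fg)
  lf2 <- legendre_fenchel(biconjugate(toy$curve), f_grid = fg)
  scale <- max(abs(lf1$neg_G))
  expect_lt(max(abs(lf1$neg_G - lf2$neg_G)), 1e-6 * scale)
})

test_that("force-elongation from the conjugate is monotone and jumps at kinks", {
  # smooth conjugate: -G_LF = f^2/2 gives x = f, no kinks
  fs <- seq(0.1, 4, length.out = 100)
  xs <- seq(0, 5, length.out = 1001)
  Fq <- energy_curve(xs, 0.5 * xs^2, meta = list(kind = "helmholtz"))
  lfq <- legendre_fenchel(Fq, f_grid = fs)
  feq <- force_elongation_from_G(lfq)
  expect_lt(max(abs(feq$x - feq$f)), 5e-3)
  expect_equal(nrow(attr(feq, "kinks")), 0)

  toy <- bump_toy(n = 1601)
  lf <- legendre_fenchel(toy$curve, f_grid = seq(0.5, 16, length.out = 800))
  fe <- force_elongation_from_G(lf)
  expect_true(all(diff(fe$x) > -1e-9))
  kk <- attr(fe, "kinks")
  expect_equal(nrow(kk), 1)
  mx <- toy_maxwell_force(toy)
  expect_lt(abs(kk$jump - (mx$x_hi - mx$x_lo)), 5e-3)
})

test_that("kink detection counts the anomalies", {
  xs <- seq(0, 4, length.out = 801)
  Fq <- energy_curve(xs, 0.5 * 4 * xs^2, meta = list(kind = "helmholtz"))
  expect_equal(nrow(legendre_fenchel(Fq)$kinks), 0)
  one <- bump_toy(n = 1201)
  lf1 <- legendre_fenchel(one$curve, f_grid = seq(0.5, 16, length.out = 600))
  expect_equal(nrow(lf1$kinks), 1)
  two <- toy_free_energy(k = 4, bumps = data.frame(center = c(1.3, 2.8),
                                                   height = c(2.5, 2.5),
                                                   width = c(0.15, 0.15)),
                         x_max = 4, n = 2001)
  lf2 <- legendre_fenchel(two$curve, f_grid = seq(0.5, 16, length.out = 800))
  expect_equal(nrow(lf2$kinks), 2)
})

test_that("the LF kink force equals the equal-area (Maxwell) level", {
  toy <- bump_toy(n = 2001)
  mx <- toy_maxwell_force(toy)
  lf <- legendre_fenchel(toy$curve, f_grid = seq(0.5, 16, length.out = 800))
  expect_equal(nrow(lf$kinks), 1)
  expect_lt(abs(lf$kinks$f - mx$f), 1e-3)
})

test_that("transform results round-trip through CSV with a kink summary", {
  toy <- bump_toy(n = 801)
  lf <- legendre_fenchel(toy$curve, f_grid = seq(0.5, 16, length.out = 400))
  path <- tempfile(fileext = ".csv")
  write_transform(lf, path)
  r <- lfstretch:::read_annotated_csv(path)
  expect_equal(r$df$f, lf$f, tolerance = 1e-15)
  expect_equal(r$df$neg_G, lf$neg_G, tolerance = 1e-15)
  expect_equal(sum(r$df$is_kink == "TRUE" | r$df$is_kink == TRUE), 1)
  kj <- jsonlite::read_json(sub("\\.csv$", ".kinks.json", path),
                            simplifyVector = TRUE)
  expect_equal(kj$n_kinks, 1)
})
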