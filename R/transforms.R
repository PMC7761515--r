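#' Pointwise Legendre transform of a Helmholtz curve
#'
#' Computes the classical Legendre construction `G(f(x)) = F(x) - f(x) x`
#' with `f(x) = F'(x)` from the three-point non-uniform first-difference
#' stencil, at every interior grid point.  No convexity is assumed: when F
#' is non-convex the returned (f, G) set is not one-to-one in f -- several
#' extensions map to the same force -- which is exactly the failure mode
#' that motivates the Legendre-Fenchel transform for small chains.
#'
#' @param F an `energy_curve` (Helmholtz, >= 3 points).
#' @return a data.frame with columns `x`, `f` (= F'(x)) and `G`.
#' @export
legendre <- function(F) {
  xs <- F$control; ys <- F$value
  n <- length(xs)
  if (n < 3) stop("need at least 3 grid points")
  i <- 2:(n - 1)
  h1 <- xs[i] - xs[i - 1]; h2 <- xs[i + 1] - xs[i]
  fp <- -h2 / (h1 * (h1 + h2)) * ys[i - 1] +
    (h2 - h1) / (h1 * h2) * ys[i] +
    h1 / (h2 * (h1 + h2)) * ys[i + 1]
  data.frame(x = xs[i], f = fp, G = ys[i] - fp * xs[i])
}

# discrete conjugate sup_x [f x - y(x)] over the tabulated grid, for one f.
# The value is the exact grid maximum (convex in f by construction); the
# argmax is refined by a quadratic through the three bracketing points.
conj_point <- function(xs, ys, f) {
  vals <- f * xs - ys
  i <- which.max(vals)
  xstar <- xs[i]
  if (i > 1 && i < length(xs)) {
    x3 <- xs[(i - 1):(i + 1)]; y3 <- vals[(i - 1):(i + 1)]
    d1 <- (y3[2] - y3[1]) / (x3[2] - x3[1])
    d2 <- (y3[3] - y3[2]) / (x3[3] - x3[2])
    curv <- (d2 - d1) / (x3[3] - x3[1])
    if (curv < 0) {  # concave bracket: vertex of the Newton-form parabola
      xv <- (x3[1] + x3[2]) / 2 - d1 / (2 * curv)
      xstar <- min(max(xv, x3[1]), x3[3])
    }
  }
  c(value = vals[i], argmax = xstar, index = i)
}

#' Legendre-Fenchel transform of a Helmholtz curve
#'
#' Computes `-G_LF(f) = max_x [f x - F(x)]` over the tabulated x grid for
#' every force in `f_grid`.  The conjugate value is the exact discrete
#' maximum, so the output is convex in f to machine precision (a maximum of
#' affine functions); the maximizer is additionally refined by a local
#' quadratic through the three bracketing grid points, which sharpens the
#' location of kinks without touching the convex values.  Kinks -- forces
#' where the maximizer jumps, the dual image of a non-convex stretch of
#' F -- are detected and reported.
#'
#' @param F an `energy_curve` tabulating the Helmholtz energy on a bounded
#'   x grid.
#' @param f_grid forces at which to evaluate the conjugate; default spans
#'   `[1e-6, max forward-difference slope of F]` with 200 points.
#' @param kink_tol maximizer jump threshold, as a fraction of the x range,
#'   above which a kink is recorded.
#' @return an object of class `lf_transform`: list with `f`, `neg_G`
#'   (values of -G_LF, kcal/mol), `argmax_x`, `kinks` (data.frame), and
#'   `meta` (method, x range, the input table).
#' @export
legendre_fenchel <- function(F, f_grid = NULL, kink_tol = 0.02) {
  xs <- F$control; ys <- F$value
  if (is.null(f_grid)) {
    slopes <- diff(ys) / diff(xs)
    f_grid <- seq(1e-6, max(slopes), length.out = 200)
  }
  if (length(f_grid) == 0) stop("f_grid must be non-empty")
  res <- vapply(f_grid, function(f) conj_point(xs, ys, f), c(0, 0, 0))
  tr <- structure(list(f = as.numeric(f_grid), neg_G = res[1, ],
                       argmax_x = res[2, ],
                       meta = list(method = "legendre_fenchel",
                                   x_min = min(xs), x_max = max(xs),
                                   F_control = xs, F_value = ys,
                                   temperature = curve_meta(F)$temperature,
                                   n_beads = curve_meta(F)$n_beads)),
                  class = "lf_transform")
  tr$kinks <- detect_kinks(tr, tol = kink_tol)
  tr
}

#' @export
print.lf_transform <- function(x, ...) {
  cat(sprintf("Legendre-Fenchel transform: %d forces in [%g, %g], x in [%g, %g]\n",
              length(x$f), min(x$f), max(x$f), x$meta$x_min, x$meta$x_max))
  nk <- if (is.null(x$kinks)) 0 else nrow(x$kinks)
  if (nk > 0) {
    cat(sprintf("  %d kink(s) (non-differentiable points of -G_LF):\n", nk))
    print(x$kinks, row.names = FALSE)
  } else cat("  no kinks detected (conjugate differentiable on the grid)\n")
  invisible(x)
}

#' @export
plot.lf_transform <- function(x, ...) {
  graphics::plot(x$f, x$neg_G, type = "l", xlab = "f (kcal/mol/A)",
                 ylab = "-G_LF(f) (kcal/mol)", ...)
  if (!is.null(x$kinks) && nrow(x$kinks))
    graphics::abline(v = x$kinks$f, lty = 3)
  invisible(x)
}

#' @export
summary.lf_transform <- function(object, ...) {
  d2 <- second_diff(object$f, object$neg_G)$d2
  cat("Legendre-Fenchel transform summary\n")
  cat(sprintf("  forces: %d points in [%g, %g]\n", length(object$f),
              min(object$f), max(object$f)))
  cat(sprintf("  min discrete 2nd difference of -G_LF: %.3g (convex if >= 0)\n",
              min(d2)))
  cat(sprintf("  maximizer range: [%g, %g] A\n", min(object$argmax_x),
              max(object$argmax_x)))
  cat(sprintf("  kinks: %d\n", if (is.null(object$kinks)) 0 else nrow(object$kinks)))
  invisible(object)
}

#' Detect kinks (non-differentiable points) of a Legendre-Fenchel conjugate
#'
#' A non-convex stretch of F is mapped by the Legendre-Fenchel transform
#' into a force at which `-G_LF` is non-differentiable and the maximizer
#' jumps across the anomaly.  Kinks are detected as jumps of the recorded
#' maximizer between adjacent forces exceeding `tol * (x range)`; each kink
#' force is then refined from the two flanking maximizers x1, x2 via the
#' common-tangent (equal-area) condition
#' `f* = (F(x2) - F(x1)) / (x2 - x1)`.
#'
#' @param result an `lf_transform`.
#' @param tol maximizer jump threshold as a fraction of the x range.
#' @return data.frame with columns `f` (refined kink force), `f_grid`
#'   (bracketing grid force), `x_lo`, `x_hi` (flanking maximizers) and
#'   `jump` (their gap) -- zero rows when the conjugate is differentiable.
#' @export
detect_kinks <- function(result, tol = 0.02) {
  xr <- result$meta$x_max - result$meta$x_min
  jmp <- diff(result$argmax_x)
  idx <- which(jmp > tol * xr)
  if (length(idx) == 0)
    return(data.frame(f = numeric(0), f_grid = numeric(0),
                      x_lo = numeric(0), x_hi = numeric(0),
                      jump = numeric(0)))
  # merge runs of consecutive indices (one kink can straddle several grid steps)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  out <- lapply(runs, function(r) {
    i0 <- min(r); i1 <- max(r) + 1
    x1 <- result$argmax_x[i0]; x2 <- result$argmax_x[i1]
    Fi <- splinefun(result$meta$F_control, result$meta$F_value,
                    method = "monoH.FC")
    fstar <- (Fi(x2) - Fi(x1)) / (x2 - x1)
    data.frame(f = fstar, f_grid = (result$f[i0] + result$f[i1]) / 2,
               x_lo = x1, x_hi = x2, jump = x2 - x1)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exact integral transform from Helmholtz to Gibbs energy
#'
#' Evaluates the exact finite-size relation between the two stretching
#' energies,
#' \deqn{e^{-\beta G(f)} = \beta f \int_0^{x_{max}} e^{-\beta (F(x) - f x)} dx,}
#' by adaptive quadrature over the monotone-cubic interpolation of the
#' tabulated F.  The integrand maximum is factored out before
#' exponentiating, so integrals spanning hundreds of k_BT are computed
#' without overflow, and reintroduced analytically in the log.  The
#' `beta f` prefactor contributes `-k_BT ln(beta f)` to G; it diverges
#' logarithmically as f -> 0, so `f > 0` is required.  Adding a constant c
#' to F shifts G by exactly +c.
#'
#' @param F an `energy_curve` (Helmholtz) tabulated from its reference up
#'   to the unfolded length.
#' @param f force(s), kcal/mol/A, strictly positive.
#' @param beta inverse temperature 1/(k_B T), mol/kcal.
#' @param x_lo,x_max integration limits (default: the tabulated range).
#' @return Gibbs energy value(s), kcal/mol, on the same additive scale as F.
#' @export
exact_gibbs <- function(F, f, beta, x_lo = min(F$control),
                        x_max = max(F$control)) {
  if (any(f <= 0)) stop("exact_gibbs requires f > 0 (beta*f prefactor)")
  if (beta <= 0) stop("beta must be > 0")
  xs <- F$control; ys <- F$value
  Fi <- splinefun(xs, ys, method = "monoH.FC")
  vapply(f, function(fi) {
    grid <- seq(x_lo, x_max, length.out = 512)
    M <- max(-beta * (Fi(grid) - fi * grid))
    ig <- function(x) exp(-beta * (Fi(x) - fi * x) - M)
    I <- pracma::quadgk(ig, x_lo, x_max, tol = 1e-12)
    if (!is.finite(I) || I <= 0) stop("non-finite integrand in exact_gibbs")
    -(log(beta * fi) + M + log(I)) / beta
  }, 0)
}

# discrete conjugate of a tabulated function, generic helper:
# returns sup_s [t s - v(s)] over the (s, v) table for each t
conj_table <- function(s, v, t_grid) {
  res <- vapply(t_grid, function(t) conj_point(s, v, t), c(0, 0, 0))
  list(value = res[1, ], argmax = res[2, ], index = as.integer(res[3, ]))
}

#' Biconjugate (convex envelope) of a Helmholtz curve
#'
#' Applies the Legendre-Fenchel transform twice:
#' `F**(x) = max_f [f x + G_LF(f)]`.  The result is the convex envelope of
#' F -- the largest convex function below it: `F** <= F` pointwise, with
#' equality wherever F is locally convex and on the envelope.  `F** = F`
#' exactly when F is convex (the transform is an involution there), and
#' `F** != F` precisely on the non-convex anomalies responsible for
#' ensemble inequivalence; both share the same conjugate, `(F**)* = F*`.
#' The internal force grid spans all hull slopes (including negative ones),
#' so the discrete double conjugate coincides with the lower convex hull of
#' the tabulated points.
#'
#' @param F an `energy_curve` on a bounded grid.
#' @param n_f size of the internal force grid.
#' @return an `energy_curve` tabulating F** on the same x grid.
#' @export
biconjugate <- function(F, n_f = 4001) {
  xs <- F$control; ys <- F$value
  slopes <- diff(ys) / diff(xs)
  pad <- 1e-6 + 0.05 * (max(slopes) - min(slopes))
  f_grid <- seq(min(slopes) - pad, max(slopes) + pad, length.out = n_f)
  c1 <- conj_table(xs, ys, f_grid)        # F*(f), scan for active vertices
  # F* is piecewise linear in f; its exact breakpoints are the secant slopes
  # between consecutive active maximizers, and the second conjugation attains
  # its sup there, so conjugating on those forces reproduces the hull exactly
  J <- sort(unique(c1$index))
  fb <- if (length(J) >= 2) diff(ys[J]) / diff(xs[J]) else numeric(0)
  f2 <- sort(unique(c(min(f_grid), fb, max(f_grid))))
  v2 <- conj_table(xs, ys, f2)$value      # exact F* at the breakpoints
  c2 <- conj_table(f2, v2, xs)            # F**(x)
  energy_curve(xs, c2$value, 0,
               meta = c(curve_meta(F)[setdiff(names(curve_meta(F)), "kind")],
                        list(kind = curve_meta(F)$kind %||% "helmholtz",
                             envelope = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Force-elongation relation from the Legendre-Fenchel conjugate
#'
#' Differentiates the conjugate: `x_LF(f) = d(-G_LF)/df`, using one-sided
#' differences so kinks are not smoothed across.  By convexity the result
#' is monotone non-decreasing; at each kink `x_LF` jumps by the maximizer
#' gap, the Maxwell-construction gap bridging the non-convex anomaly of F.
#'
#' @param result an `lf_transform`.
#' @return a data.frame with columns `f` and `x` (midpoint forces and
#'   one-sided slopes of -G_LF), with the kink table attached as attribute
#'   `kinks`.
#' @export
force_elongation_from_G <- function(result) {
  f <- result$f; v <- result$neg_G
  if (length(f) < 2) stop("need at least 2 forces")
  slopes <- diff(v) / diff(f)          # subgradient slopes, non-decreasing
  mid <- (f[-1] + f[-length(f)]) / 2
  out <- data.frame(f = mid, x = slopes)
  attr(out, "kinks") <- result$kinks
  out
}
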