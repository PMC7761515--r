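#' Free-energy curve container
#'
#' An `energy_curve` tabulates a free energy against its control variable:
#' Helmholtz F(x) against end-to-end distance, or Gibbs G(f) against force.
#' Values are differences relative to the reference control point, which
#' maps to exactly 0.
#'
#' @param control strictly increasing grid.
#' @param value energy values, kcal/mol, zero at the reference point.
#' @param value_err propagated standard errors (0 if exact).
#' @param meta named list; should include `kind` ("helmholtz" or "gibbs"),
#'   `reference`, and where known `temperature` and `n_beads`.
#' @return object of classes `energy_curve`, `data.frame`.
#' @export
energy_curve <- function(control, value, value_err = 0, meta = list()) {
  if (any(diff(control) <= 0)) stop("control grid must be strictly increasing")
  if (length(value) != length(control)) stop("value/control length mismatch")
  df <- data.frame(control = as.numeric(control), value = as.numeric(value),
                   value_err = rep_len(as.numeric(value_err), length(control)))
  structure(df, meta = meta, class = c("energy_curve", "data.frame"))
}

#' @export
print.energy_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("energy_curve (%s): %d points on [%g, %g], reference %s\n",
              if (is.null(m$kind)) "?" else m$kind, nrow(x), min(x$control),
              max(x$control), format(m$reference)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.energy_curve <- function(x, ...) {
  m <- curve_meta(x)
  helm <- identical(m$kind, "helmholtz")
  graphics::plot(x$control, x$value,
                 xlab = if (helm) "x (A)" else "f (kcal/mol/A)",
                 ylab = sprintf("%s energy difference (kcal/mol)",
                                if (helm) "Helmholtz" else "Gibbs"),
                 type = "l", ...)
  invisible(x)
}

# trapezoid cumulative integral of y over x, from the grid point at x0;
# also propagates per-point standard errors through the trapezoid weights
cumtrapz_ref <- function(xs, ys, ses, x0) {
  i0 <- which(abs(xs - x0) <= 1e-9 * max(1, abs(x0)))
  if (length(i0) != 1)
    stop("reference point must coincide with a grid point")
  n <- length(xs)
  seg <- c(0, cumsum(0.5 * diff(xs) * (ys[-n] + ys[-1])))
  vals <- seg - seg[i0]
  errs <- numeric(n)
  for (j in seq_len(n)) {
    lo <- min(i0, j); hi <- max(i0, j)
    if (lo == hi) { errs[j] <- 0; next }
    idx <- lo:hi
    h <- diff(xs[idx])
    w <- numeric(length(idx))
    w[1] <- h[1] / 2
    w[length(idx)] <- h[length(h)] / 2
    if (length(idx) > 2)
      w[2:(length(idx) - 1)] <- (h[-length(h)] + h[-1]) / 2
    errs[j] <- sqrt(sum(w^2 * ses[idx]^2))
  }
  list(value = vals, err = errs, i0 = i0)
}

#' Thermodynamic integration of force-elongation curves
#'
#' `integrate_isometric` turns a sampled isometric curve (mean force vs
#' end-to-end distance) into Helmholtz energy differences by the composite
#' trapezoid rule, `F(x) - F(x0) = integral of fbar dx`.
#' `integrate_isotensional` turns an isotensional curve (mean extension vs
#' force) into Gibbs energy differences, `G(f) - G(f0) = - integral of xbar
#' df`.  The curve is integrated on its sampled grid without re-fitting;
#' the reported `value_err` propagates the per-point standard errors
#' through the trapezoid weights.  Flagged points (broken bonds) between
#' the reference and any requested point are an error.
#'
#' @param curve a `stretch_curve` of the matching mode.
#' @param x0,f0 reference control value; must equal a grid point (default:
#'   the first).
#' @return an `energy_curve` of kind "helmholtz" or "gibbs".
#' @export
integrate_isometric <- function(curve, x0 = curve$control[1]) {
  m <- curve_meta(curve)
  if (!is.null(m$mode) && !identical(m$mode, "isometric"))
    stop("curve mode is not isometric")
  if (any(curve$flag))
    stop("flagged (broken-bond) grid points at control = ",
         paste(format(curve$control[curve$flag]), collapse = ", "))
  ct <- cumtrapz_ref(curve$control, curve$mean, curve$stderr, x0)
  energy_curve(curve$control, ct$value, ct$err,
               meta = list(kind = "helmholtz", reference = x0,
                           temperature = m$temperature, n_beads = m$n_beads))
}

#' @rdname integrate_isometric
#' @export
integrate_isotensional <- function(curve, f0 = curve$control[1]) {
  m <- curve_meta(curve)
  if (!is.null(m$mode) && !identical(m$mode, "isotensional"))
    stop("curve mode is not isotensional")
  if (any(curve$flag))
    stop("flagged (broken-bond) grid points at control = ",
         paste(format(curve$control[curve$flag]), collapse = ", "))
  ct <- cumtrapz_ref(curve$control, -curve$mean, curve$stderr, f0)
  energy_curve(curve$control, ct$value, ct$err,
               meta = list(kind = "gibbs", reference = f0,
                           temperature = m$temperature, n_beads = m$n_beads))
}

# second derivative on a non-uniform grid, three-point stencil; endpoints
# are dropped (the curve is shortened by one point on each side)
second_diff <- function(xs, ys) {
  n <- length(xs)
  if (n < 3) stop("need at least 3 grid points")
  if (any(diff(xs) == 0)) stop("duplicate grid values")
  i <- 2:(n - 1)
  h1 <- xs[i] - xs[i - 1]
  h2 <- xs[i + 1] - xs[i]
  d2 <- 2 * ((ys[i + 1] - ys[i]) / h2 - (ys[i] - ys[i - 1]) / h1) / (h1 + h2)
  list(x = xs[i], d2 = d2)
}

#' Stretching response functions
#'
#' `response_isometric` differentiates a Helmholtz curve twice:
#' `1/kappa(x) = d2F/dx2 = dfbar/dx`.  In the isometric ensemble this
#' curvature may be negative (non-convex F), which is the signature of
#' ensemble inequivalence.  `response_isotensional` computes
#' `kappa(f) = -d2G/df2`, which for any equilibrium system must be
#' non-negative; values below `-tol` are flagged in the `violation` column.
#' Both use the three-point non-uniform second-difference stencil and drop
#' the two endpoints.
#'
#' @param F,G an `energy_curve` of the matching kind with >= 3 points.
#' @param tol tolerance for flagging negative isotensional response.
#' @return a data.frame with the interior grid, the curvature `inv_kappa`
#'   (isometric) or response `kappa` (isotensional).
#' @export
response_isometric <- function(F) {
  sd2 <- second_diff(F$control, F$value)
  data.frame(control = sd2$x, inv_kappa = sd2$d2, kappa = 1 / sd2$d2)
}

#' @rdname response_isometric
#' @export
response_isotensional <- function(G, tol = 1e-8) {
  sd2 <- second_diff(G$control, G$value)
  kappa <- -sd2$d2
  data.frame(control = sd2$x, kappa = kappa, violation = kappa < -tol)
}

#' Read and write the energy-curve CSV dialect
#'
#' Same dialect as [write_curve()] with columns `control`, `value`,
#' `value_err` and a `# kind=` metadata line.
#'
#' @param ec an `energy_curve`.
#' @param file path.
#' @return `read_energy_curve` returns an `energy_curve`.
#' @export
write_energy_curve <- function(ec, file) {
  write_annotated_csv(as.data.frame(ec), curve_meta(ec), file)
}

#' @rdname write_energy_curve
#' @export
read_energy_curve <- function(file) {
  r <- read_annotated_csv(file)
  energy_curve(r$df$control, r$df$value, r$df$value_err, meta = r$meta)
}
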