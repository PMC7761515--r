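#' Force-elongation curve container
#'
#' A `stretch_curve` is a data.frame with columns `control` (x in Angstrom
#' or f in kcal/mol/A), `mean` (the conjugate observable), `stderr`,
#' `n_samples` and `flag`, plus a `meta` attribute recording temperature,
#' bead count, ensemble mode and base seed.
#'
#' @param df data.frame with at least `control`, `mean`, `stderr`.
#' @param meta named list of metadata.
#' @return object of classes `stretch_curve`, `data.frame`.
#' @export
stretch_curve <- function(df, meta = list()) {
  df <- as.data.frame(df)
  if (!all(c("control", "mean", "stderr") %in% names(df)))
    stop("a stretch_curve needs columns control, mean, stderr")
  if (is.null(df$n_samples)) df$n_samples <- NA_integer_
  if (is.null(df$flag)) df$flag <- FALSE
  if (any(diff(df$control) <= 0)) stop("control grid must be strictly increasing")
  if (any(df$stderr < 0, na.rm = TRUE)) stop("stderr must be >= 0")
  if (nrow(df) != length(df$control)) stop("malformed curve")
  structure(df, meta = meta, class = c("stretch_curve", "data.frame"))
}

curve_meta <- function(curve) attr(curve, "meta", exact = TRUE)

#' @export
print.stretch_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("stretch_curve (%s): %d points, T = %s K, N = %s\n",
              if (is.null(m$mode)) "?" else m$mode, nrow(x),
              format(m$temperature), format(m$n_beads)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.stretch_curve <- function(x, ...) {
  m <- curve_meta(x)
  iso <- identical(m$mode, "isometric")
  graphics::plot(x$control, x$mean,
                 xlab = if (iso) "end-to-end distance x (A)" else "force f (kcal/mol/A)",
                 ylab = if (iso) "mean force (kcal/mol/A)" else "mean extension (A)",
                 type = "b", ...)
  graphics::arrows(x$control, x$mean - x$stderr, x$control, x$mean + x$stderr,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

# shared CSV dialect: '#'-prefixed "key=value" metadata lines, then a comma
# separated table with '.' decimals
write_annotated_csv <- function(df, meta, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    writeLines(sprintf("# %s=%s", k, paste(format(v, digits = 17),
                                           collapse = ",")), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  for (r in seq_len(nrow(df))) {
    cells <- vapply(df[r, , drop = FALSE], function(v) {
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, "")
    writeLines(paste(cells, collapse = ","), con)
  }
  invisible(file)
}

read_annotated_csv <- function(file) {
  lines <- readLines(file)
  metal <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in metal) {
    kv <- sub("^#\\s*", "", l)
    k <- sub("=.*$", "", kv)
    v <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    meta[[k]] <- if (all(is.finite(num))) num else v
  }
  df <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                   header = TRUE, stringsAsFactors = FALSE)
  list(df = df, meta = meta)
}

#' Read and write the curve CSV dialect
#'
#' Curves are stored as comma-separated tables with columns `control`,
#' `mean`, `stderr`, `n_samples`, `flag`, preceded by `#`-prefixed
#' `key=value` metadata header lines (temperature, bead count, mode, seed).
#'
#' @param curve a `stretch_curve`.
#' @param file path.
#' @return `read_curve` returns a `stretch_curve`.
#' @export
write_curve <- function(curve, file) {
  write_annotated_csv(as.data.frame(curve), curve_meta(curve), file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  r <- read_annotated_csv(file)
  r$df$flag <- as.logical(r$df$flag)
  stretch_curve(r$df, meta = r$meta)
}

#' Shape-preserving curve interpolation
#'
#' Monotone (Fritsch-Carlson) piecewise-cubic interpolation of a tabulated
#' curve: exact at the knots, free of overshoot, and monotone wherever the
#' data are monotone -- the behaviour needed when interpolating
#' force-elongation data near kinks.  Works on `stretch_curve` (interpolates
#' `mean`), `energy_curve` (interpolates `value`), or a plain data.frame
#' with an x column first and a y column second.  Queries outside the grid
#' are an error (no extrapolation).
#'
#' @param curve the tabulated curve.
#' @param query numeric vector of control values to interpolate at.
#' @return interpolated values at `query`.
#' @export
interpolate_curve <- function(curve, query) {
  if (inherits(curve, "stretch_curve")) { xs <- curve$control; ys <- curve$mean }
  else if (inherits(curve, "energy_curve")) { xs <- curve$control; ys <- curve$value }
  else { xs <- curve[[1]]; ys <- curve[[2]] }
  if (any(query < min(xs) - 1e-12 | query > max(xs) + 1e-12))
    stop("interpolation query outside the tabulated range [",
         format(min(xs)), ", ", format(max(xs)), "]; no extrapolation")
  query <- pmin(pmax(query, min(xs)), max(xs))
  fn <- splinefun(xs, ys, method = "monoH.FC")
  fn(query)
}
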