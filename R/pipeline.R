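#' Write a Legendre-Fenchel transform result as CSV + kink summary JSON
#'
#' The CSV carries columns `f`, `neg_G`, `argmax_x`, `is_kink` in the same
#' annotated dialect as the curve writers; the kink table goes to a JSON
#' side-car (same path with extension `.kinks.json`).
#'
#' @param result an `lf_transform`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_transform <- function(result, file) {
  is_kink <- rep(FALSE, length(result$f))
  if (nrow(result$kinks)) {
    for (fg in result$kinks$f_grid)
      is_kink[which.min(abs(result$f - fg))] <- TRUE
  }
  df <- data.frame(f = result$f, neg_G = result$neg_G,
                   argmax_x = result$argmax_x, is_kink = is_kink)
  meta <- list(method = result$meta$method, x_min = result$meta$x_min,
               x_max = result$meta$x_max)
  write_annotated_csv(df, meta, file)
  kink_path <- paste0(sub("\\.csv$", "", file), ".kinks.json")
  jsonlite::write_json(list(n_kinks = nrow(result$kinks),
                            kinks = result$kinks),
                       kink_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}

# tiny FNV-1a content hash for provenance (no cryptographic intent)
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), as.integer(b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(out_dir, config, seed, outputs, command = "run_pipeline") {
  manifest <- list(command = command,
                   config_hash = content_hash(config),
                   seed = seed,
                   package_version = as.character(packageVersion("lfstretch")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' End-to-end stretching-ensemble pipeline
#'
#' Runs the full analysis on one chain: sweeps both ensembles, integrates
#' the force-elongation curves into Helmholtz (F) and Gibbs (G) energy
#' differences, transforms F by the pointwise Legendre construction, the
#' Legendre-Fenchel transform and the exact beta-weighted integral
#' transform, and assembles the comparison that diagnoses ensemble
#' inequivalence: all four Gibbs estimates mapped onto a common
#' end-to-end-distance axis through the isotensional force-elongation
#' relation f(x1) and anchored at the first shared point.
#'
#' All randomness derives from `seed`; rerunning with the same inputs
#' reproduces the CSV outputs byte-for-byte (only the manifest timestamp
#' differs).
#'
#' @param ff `force_field`.
#' @param iso_protocol isometric `stretch_protocol`.
#' @param isot_protocol isotensional `stretch_protocol`.
#' @param out_dir output directory (created if missing); `NULL` for none.
#' @param seed base seed overriding the protocols' seeds.
#' @param plots also write simple base-graphics PDF figures.
#' @return (invisibly) a list with the curves, energy curves, transforms,
#'   kink table, and the comparison data.frame with columns `x1`, `f_of_x1`,
#'   `G_ti`, `G_lf`, `G_exact`, `G_legendre` (all anchored differences) and
#'   summary deviations `dev_lf`, `dev_legendre`, `dev_exact`.
#' @export
run_pipeline <- function(ff, iso_protocol, isot_protocol, out_dir = NULL,
                         seed = 1, plots = FALSE) {
  iso_protocol$seed <- as.integer(seed)
  isot_protocol$seed <- as.integer(derive_seed(seed, 7, 7))
  beta <- 1 / (kB_kcal * iso_protocol$temperature)

  curve_iso <- stretch_sweep(ff, iso_protocol)
  curve_isot <- stretch_sweep(ff, isot_protocol)

  Fc <- integrate_isometric(curve_iso)
  Gc <- integrate_isotensional(curve_isot)

  lf <- legendre_fenchel(Fc)
  leg <- legendre(Fc)

  comparison <- ensemble_comparison(Fc, Gc, curve_iso, curve_isot, lf, leg,
                                    beta)

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(iso = "curve_isometric.csv", isot = "curve_isotensional.csv",
               F = "helmholtz.csv", G = "gibbs.csv",
               lf = "legendre_fenchel.csv", cmp = "comparison.csv")
    write_curve(curve_iso, file.path(out_dir, paths["iso"]))
    write_curve(curve_isot, file.path(out_dir, paths["isot"]))
    write_energy_curve(Fc, file.path(out_dir, paths["F"]))
    write_energy_curve(Gc, file.path(out_dir, paths["G"]))
    write_transform(lf, file.path(out_dir, paths["lf"]))
    write_annotated_csv(comparison$table,
                        list(anchor_x1 = comparison$anchor,
                             dev_lf = comparison$dev_lf,
                             dev_legendre = comparison$dev_legendre,
                             dev_exact = comparison$dev_exact),
                        file.path(out_dir, paths["cmp"]))
    outputs <- unname(c(paths, "legendre_fenchel.kinks.json"))
    if (plots) {
      grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 9)
      graphics::par(mfrow = c(3, 1))
      plot(curve_iso, main = "isometric")
      plot(curve_isot, main = "isotensional")
      plot(lf, main = "-G_LF(f)")
      grDevices::dev.off()
      outputs <- c(outputs, "figures.pdf")
    }
    write_manifest(out_dir, list(ff = unclass(ff),
                                 iso = unclass(iso_protocol),
                                 isot = unclass(isot_protocol)),
                   seed, outputs)
  }

  invisible(list(curve_isometric = curve_iso, curve_isotensional = curve_isot,
                 helmholtz = Fc, gibbs = Gc, lf = lf, legendre = leg,
                 kinks = lf$kinks, comparison = comparison))
}

# map the four Gibbs estimates onto a common x1 axis via the isotensional
# force-elongation relation (f(x1) by inverse monotone interpolation) and
# anchor every estimate at the first shared x1
ensemble_comparison <- function(Fc, Gc, curve_iso, curve_isot, lf, leg, beta) {
  # monotone (isotonic) fit of xbar(f), then invert
  ir <- isoreg(curve_isot$control, curve_isot$mean)
  xb <- ir$yf
  f_of_x <- function(x1) approx(xb, curve_isot$control, xout = x1,
                                ties = "ordered", rule = 1)$y
  x1 <- Fc$control
  fx <- f_of_x(x1)
  keep <- is.finite(fx) & fx >= min(Gc$control) & fx <= max(Gc$control) &
    fx > 0
  x1 <- x1[keep]; fx <- fx[keep]
  if (length(x1) < 3) stop("isometric and isotensional ranges barely overlap")

  G_ti <- interpolate_curve(Gc, fx)
  neg_lf <- splinefun(lf$f, lf$neg_G, method = "monoH.FC")
  fx_cl <- pmin(pmax(fx, min(lf$f)), max(lf$f))
  G_lf <- -neg_lf(fx_cl)
  G_exact <- exact_gibbs(Fc, fx, beta)
  # pointwise Legendre construction from the isometric data: F(x1) - fbar(x1) x1
  fbar <- interpolate_curve(curve_iso, x1)
  Fx <- interpolate_curve(Fc, x1)
  G_leg <- Fx - fbar * x1

  anchor <- function(v) v - v[1]
  tab <- data.frame(x1 = x1, f_of_x1 = fx, G_ti = anchor(G_ti),
                    G_lf = anchor(G_lf), G_exact = anchor(G_exact),
                    G_legendre = anchor(G_leg))
  list(table = tab, anchor = x1[1],
       dev_lf = max(abs(tab$G_lf - tab$G_ti)),
       dev_exact = max(abs(tab$G_exact - tab$G_ti)),
       dev_legendre = max(abs(tab$G_legendre - tab$G_ti)))
}
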