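#' Sampling protocol for ensemble sweeps
#'
#' Bundles the control-variable grid and all sampling settings for a sweep
#' in one ensemble.  Defaults are desk-scale: 0.5 fs time step, 100 fs
#' damping time, 2e4 annealing/equilibration steps, 1e5 production steps and
#' 8 independent replicas per grid point.  The default annealing schedule
#' spends half of `n_equil` at 1.5x the target temperature and half at the
#' target.
#'
#' @param mode `"isometric"` (grid of end-to-end distances, Angstrom) or
#'   `"isotensional"` (grid of applied forces, kcal/mol/A).
#' @param grid strictly increasing control values.
#' @param temperature sampling temperature, K.
#' @param timestep integration step, fs.
#' @param damping Langevin damping time, fs (friction gamma = 1/damping).
#' @param n_equil annealing/equilibration steps before production.
#' @param n_prod production steps per replica.
#' @param n_replicas independent replicas per grid point.
#' @param sample_every record the observable every this many steps.
#' @param seed base seed; per-(grid point, replica) seeds are derived from
#'   it with [derive_seed()].
#' @param anneal_schedule list of `c(T, steps)` pairs; `NULL` for default.
#' @return object of class `stretch_protocol`.
#' @export
stretch_protocol <- function(mode = c("isometric", "isotensional"), grid,
                             temperature = 300, timestep = 0.5, damping = 100,
                             n_equil = 20000, n_prod = 100000, n_replicas = 8,
                             sample_every = 10, seed = 1,
                             anneal_schedule = NULL) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  if (length(grid) < 1 || any(diff(grid) <= 0))
    stop("grid must be non-empty and strictly increasing")
  if (timestep <= 0) stop("timestep must be > 0")
  if (damping <= 0) stop("damping must be > 0")
  if (n_prod < 1) stop("n_prod must be >= 1")
  if (is.null(anneal_schedule))
    anneal_schedule <- list(c(1.5 * temperature, floor(n_equil / 2)),
                            c(temperature, ceiling(n_equil / 2)))
  structure(list(mode = mode, grid = grid, temperature = temperature,
                 timestep = timestep, damping = damping,
                 n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 n_replicas = as.integer(n_replicas),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed), anneal_schedule = anneal_schedule),
            class = "stretch_protocol")
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat(sprintf("stretch_protocol: %s, %d grid points in [%g, %g], T = %g K\n",
              x$mode, length(x$grid), min(x$grid), max(x$grid), x$temperature))
  cat(sprintf("  dt = %g fs, damping = %g fs, %d equil + %d prod steps, %d replicas, seed %d\n",
              x$timestep, x$damping, x$n_equil, x$n_prod, x$n_replicas, x$seed))
  invisible(x)
}

#' Read or write a sampling protocol as YAML
#'
#' Same flat key-value dialect as the force-field config: keys `mode`,
#' `grid`, `temperature`, `timestep`, `damping`, `n_equil`, `n_prod`,
#' `n_replicas`, `sample_every`, `seed`, and `anneal_schedule` (a list of
#' `[temperature, steps]` pairs).
#'
#' @param file path to a YAML file.
#' @return `read_protocol` returns a `stretch_protocol`.
#' @export
read_protocol <- function(file) {
  y <- yaml::read_yaml(file)
  sched <- if (is.null(y$anneal_schedule)) NULL else
    lapply(y$anneal_schedule, unlist)
  stretch_protocol(mode = y$mode, grid = unlist(y$grid),
                   temperature = y$temperature %||% 300,
                   timestep = y$timestep %||% 0.5,
                   damping = y$damping %||% 100,
                   n_equil = y$n_equil %||% 20000,
                   n_prod = y$n_prod %||% 100000,
                   n_replicas = y$n_replicas %||% 8,
                   sample_every = y$sample_every %||% 10,
                   seed = y$seed %||% 1,
                   anneal_schedule = sched)
}

#' @param protocol a `stretch_protocol`.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, file) {
  y <- unclass(protocol)
  y$anneal_schedule <- lapply(protocol$anneal_schedule, as.numeric)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Deterministic per-task seed derivation
#'
#' Splits a base seed into reproducible child seeds indexed by grid point
#' and replica, via the LCG-style mixing rule
#' `((base * 69069 + i * 10007 + j * 101) mod 2147483629) + 1`
#' (exact in double precision; result always in 1..2^31-19).  Distinct
#' (i, j) pairs at practical sweep sizes give distinct seeds, and the
#' compiled generator (mt19937-64) decorrelates nearby seeds.
#'
#' @param base base seed (integer).
#' @param i grid-point index.
#' @param j replica index.
#' @return integer-valued child seed.
#' @export
derive_seed <- function(base, i, j) {
  (((base %% 2147483629) * 69069 + i * 10007 + j * 101) %% 2147483629) + 1
}

block_stats <- function(v, n_blocks = 20) {
  n <- length(v)
  if (n == 0) return(list(mean = NA_real_, stderr = NA_real_))
  if (n < n_blocks) return(list(mean = mean(v), stderr = sd(v) / sqrt(n)))
  bl <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks),
                  function(b) mean(v[((b - 1) * bl + 1):(b * bl)]), 0)
  m <- mean(means)
  se <- sd(means) / sqrt(n_blocks)
  if (!is.finite(se)) se <- 0
  list(mean = m, stderr = se)
}

# one replica at one control value; returns mean/stderr/flag
sample_one <- function(ff, control, protocol, seed) {
  p <- protocol
  gamma <- 1 / p$damping
  if (p$mode == "isometric") {
    state <- init_chain(ff, end_to_end = control)
    mode <- "isometric"
    force <- 0
  } else {
    state <- init_chain(ff)
    mode <- "isotensional"
    force <- control
  }
  state <- anneal(state, ff, p$anneal_schedule, dt = p$timestep,
                  gamma = gamma, mode = mode, force = force, seed = seed)
  run <- langevin_run(state, ff, n_steps = p$n_prod,
                      temperature = p$temperature, dt = p$timestep,
                      gamma = gamma, mode = mode, force = force,
                      sample_every = p$sample_every,
                      seed = derive_seed(seed, 1, 0))
  st <- block_stats(run$obs)
  list(mean = st$mean, stderr = st$stderr, broken = run$broken,
       n_samples = length(run$obs))
}

#' Sample one ensemble point
#'
#' `sample_isometric` pins bead 1 at the origin and bead N at (0, 0, x),
#' thermostats the interior beads, and returns the time-averaged axial
#' restraint force (kcal/mol/A), whose mean equals the Helmholtz derivative
#' dF/dx: positive for a chain stretched beyond its preferred length.
#' `sample_isotensional` applies a constant force f along z between the end
#' beads and returns the time-averaged z-projection of `r_N - r_1`
#' (Angstrom).  Standard errors come from block averaging with 20 blocks.
#' A result is flagged `broken` when any bond passed `alpha (r - r0) > 5`
#' (the Morse plateau) during the run.
#'
#' @param ff `force_field`.
#' @param x end-to-end distance, must satisfy `0 < x < (N-1) (r0 + 5/alpha)`.
#' @param f applied force, kcal/mol/A, `f >= 0`.
#' @param protocol `stretch_protocol` (its grid is ignored here).
#' @param seed seed for this point (defaults to the protocol seed).
#' @return list with `mean`, `stderr`, `broken`, `n_samples`.
#' @export
sample_isometric <- function(ff, x, protocol, seed = protocol$seed) {
  if (x <= 0 || x >= (ff$n_beads - 1) * r_break(ff))
    stop("x must lie in (0, (N-1) * (r0 + 5/alpha))")
  p <- protocol
  p$mode <- "isometric"
  sample_one(ff, x, p, seed)
}

#' @rdname sample_isometric
#' @export
sample_isotensional <- function(ff, f, protocol, seed = protocol$seed) {
  if (f < 0) stop("f must be >= 0")
  p <- protocol
  p$mode <- "isotensional"
  sample_one(ff, f, p, seed)
}

#' Sweep a control-variable grid in one ensemble
#'
#' For every grid point and replica, anneals, equilibrates and runs
#' production sampling with a deterministically derived seed
#' (`derive_seed(seed, grid_index, replica_index)`), then aggregates the
#' replicas: the reported mean is the mean of replica means; the standard
#' error is the between-replica standard deviation divided by sqrt(R) when
#' R >= 2, else the single-replica block-averaging error.  Grid points
#' where any replica tripped the bond-break monitor are flagged, not
#' dropped.
#'
#' @param ff `force_field`.
#' @param protocol `stretch_protocol`.
#' @return a `stretch_curve`: a data.frame with columns `control`, `mean`,
#'   `stderr`, `n_samples`, `flag`, and metadata attribute `meta`
#'   (temperature, N, mode, seed).
#' @export
stretch_sweep <- function(ff, protocol) {
  p <- protocol
  R <- p$n_replicas
  out <- data.frame(control = p$grid, mean = NA_real_, stderr = NA_real_,
                    n_samples = 0L, flag = FALSE)
  for (i in seq_along(p$grid)) {
    means <- numeric(R); ses <- numeric(R); brk <- logical(R); ns <- 0L
    for (j in seq_len(R)) {
      s <- sample_one(ff, p$grid[i], p, derive_seed(p$seed, i, j))
      means[j] <- s$mean; ses[j] <- s$stderr; brk[j] <- s$broken
      ns <- ns + s$n_samples
    }
    out$mean[i] <- mean(means)
    out$stderr[i] <- if (R >= 2) {
      se <- sd(means) / sqrt(R)
      if (!is.finite(se) || se == 0) mean(ses) / sqrt(R) else se
    } else ses[1]
    out$n_samples[i] <- ns
    out$flag[i] <- any(brk)
  }
  stretch_curve(out, meta = list(temperature = p$temperature,
                                 n_beads = ff$n_beads, mode = p$mode,
                                 seed = p$seed))
}
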