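#' Langevin dynamics of the chain
#'
#' Integrates the chain with a BAOAB-split underdamped Langevin integrator:
#' velocity half-kick, half-drift, Ornstein-Uhlenbeck friction+noise step,
#' half-drift, half-kick.  With `gamma = 0` the O-step is the identity and
#' the scheme reduces to symplectic velocity Verlet.  Three modes are
#' supported: `"free"` (all beads integrated), `"isometric"` (first and last
#' bead rigidly pinned and excluded from the thermostat; the recorded
#' observable is the axial restraint force estimator
#' \eqn{\frac12 (F_1 - F_N)\cdot\hat z}, whose mean equals dF/dx), and
#' `"isotensional"` (constant force `-f z` on bead 1 and `+f z` on bead N;
#' observable is the z-projection of `r_N - r_1`).
#'
#' The time step must resolve the stiffest bond: for the Morse well the
#' harmonic frequency is `omega = sqrt(2 D alpha^2 * 4.184e-4 / m)` fs^-1
#' and `dt` should stay below about a tenth of `2 pi / omega` (0.5 fs for
#' the default force field, period ~45 fs).
#'
#' All randomness comes from a counter-based generator seeded with `seed`;
#' the same seed gives a bit-identical trajectory.
#'
#' @param state starting `chain_state`.
#' @param ff `force_field`.
#' @param n_steps number of time steps.
#' @param temperature thermostat temperature, K.
#' @param dt time step, fs.
#' @param gamma friction, 1/fs (inverse damping time; 0 disables thermostat).
#' @param mode `"free"`, `"isometric"` or `"isotensional"`.
#' @param force applied axial force for isotensional mode, kcal/mol/A.
#' @param sample_every record the observable every this many steps (0: none).
#' @param seed integer seed for the trajectory noise.
#' @param draw_velocities draw initial free-bead velocities from the
#'   Maxwell distribution at `temperature` before integrating.
#' @return a list with the final `state`, vectors `obs`, `epot`, `ekin`
#'   (kcal/mol) sampled every `sample_every` steps, the number of free beads
#'   `n_free`, the running maximum of `alpha (r - r0)` over all bonds
#'   (`max_stretch`), and `broken` (TRUE if that maximum exceeded 5).
#' @export
langevin_run <- function(state, ff, n_steps, temperature = 300, dt = 0.5,
                         gamma = 1 / 100, mode = c("free", "isometric",
                                                   "isotensional"),
                         force = 0, sample_every = 10, seed = 1,
                         draw_velocities = FALSE) {
  mode <- match.arg(mode)
  check_state_ff(state, ff)
  if (dt <= 0) stop("dt must be > 0")
  if (n_steps < 0) stop("n_steps must be >= 0")
  imode <- match(mode, c("free", "isometric", "isotensional")) - 1L
  vel <- sweep(state$momenta, 1, ff$masses, "/")
  res <- cpp_run(state$positions, vel, ff_as_list(ff), as.integer(n_steps),
                 dt, gamma, temperature, imode, force,
                 as.integer(sample_every), as.double(seed), draw_velocities)
  mom <- sweep(res$vel, 1, ff$masses, "*")
  list(state = chain_state(res$pos, mom), obs = res$obs, epot = res$epot,
       ekin = res$ekin, n_free = res$n_free, max_stretch = res$max_stretch,
       broken = res$max_stretch > 5)
}

#' @rdname langevin_run
#' @export
langevin_step <- function(state, ff, temperature = 300, dt = 0.5,
                          gamma = 1 / 100, mode = "free", force = 0,
                          seed = 1) {
  langevin_run(state, ff, n_steps = 1, temperature = temperature, dt = dt,
               gamma = gamma, mode = mode, force = force, sample_every = 0,
               seed = seed)
}

#' Simulated-annealing equilibration
#'
#' Runs consecutive Langevin segments at the scheduled temperatures, in
#' order, carrying the state from one segment to the next.  Used before
#' production sampling so a stiff multi-well chain starts from a
#' representative configuration rather than the constructed zigzag.
#'
#' @param state starting `chain_state`.
#' @param ff `force_field`.
#' @param schedule a list of `c(T, steps)` pairs, or a 2-column matrix /
#'   data.frame with columns temperature (K) and steps.
#' @param seed base seed; each segment k uses a seed derived from it.
#' @inheritParams langevin_run
#' @return the final `chain_state`.
#' @export
anneal <- function(state, ff, schedule, dt = 0.5, gamma = 1 / 100,
                   mode = "free", force = 0, seed = 1,
                   draw_velocities = TRUE) {
  sched <- as_schedule(schedule)
  if (nrow(sched) == 0) stop("annealing schedule must be non-empty")
  if (any(sched$temperature <= 0)) stop("schedule temperatures must be > 0")
  for (k in seq_len(nrow(sched))) {
    if (sched$steps[k] <= 0) next
    run <- langevin_run(state, ff, n_steps = sched$steps[k],
                        temperature = sched$temperature[k], dt = dt,
                        gamma = gamma, mode = mode, force = force,
                        sample_every = 0, seed = derive_seed(seed, 0, k),
                        draw_velocities = draw_velocities && k == 1)
    state <- run$state
  }
  state
}

as_schedule <- function(schedule) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- do.call(rbind, schedule)
  schedule <- as.data.frame(schedule)
  names(schedule) <- c("temperature", "steps")
  schedule$steps <- as.integer(schedule$steps)
  schedule
}
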