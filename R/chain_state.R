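#' Chain microstate: positions and momenta
#'
#' A minimal container for the instantaneous configuration of an N-bead
#' chain: an N x 3 matrix of positions (Angstrom) and an N x 3 matrix of
#' momenta (g/mol * A/fs).  Internally the dynamics code works with
#' velocities; momenta are stored so the state is self-contained.
#'
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param momenta N x 3 numeric matrix (defaults to zero).
#' @return object of class `chain_state`.
#' @export
chain_state <- function(positions, momenta = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (is.null(momenta)) momenta <- matrix(0, nrow(positions), 3)
  momenta <- as.matrix(momenta)
  if (!all(dim(momenta) == dim(positions)))
    stop("momenta must match positions in shape")
  if (!all(is.finite(positions)) || !all(is.finite(momenta)))
    stop("positions and momenta must be finite")
  structure(list(positions = positions, momenta = momenta),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("chain_state: %d beads, end-to-end %.3f A\n",
              nrow(x$positions),
              sqrt(sum((x$positions[nrow(x$positions), ] - x$positions[1, ])^2))))
  invisible(x)
}

check_state_ff <- function(state, ff) {
  if (nrow(state$positions) != ff$n_beads)
    stop("chain_state has ", nrow(state$positions),
         " beads but force field expects ", ff$n_beads)
  invisible(TRUE)
}

#' Build an initial zigzag chain configuration
#'
#' Places the beads on a planar zigzag in the x-z plane with bond length r0.
#' If `end_to_end` is given, the axial (z) step per bond is set to
#' `end_to_end / (N - 1)`; as long as that step does not exceed r0 the bond
#' length stays at r0 (the transverse amplitude absorbs the rest), otherwise
#' the chain is laid out straight with uniformly stretched bonds.  Bead 1
#' sits at the origin and bead N at (0, 0, end_to_end), which is the
#' geometry the isometric sampler pins.
#'
#' @param ff a `force_field`.
#' @param end_to_end target end-to-end distance along z (Angstrom); default
#'   is the zigzag length with the equilibrium bend angle.
#' @return a `chain_state` with zero momenta.
#' @export
init_chain <- function(ff, end_to_end = NULL) {
  N <- ff$n_beads
  r0 <- ff$bond_r0
  if (is.null(end_to_end)) {
    # equilibrium zigzag: bonds r0, bend angles theta0, axial step
    # d = r0 sin(theta0/2); built directly, no end placement to solve
    d <- r0 * sin(ff$bend_theta0 / 2)
    h <- sqrt(r0^2 - d^2)
  } else {
    if (end_to_end <= 0) stop("end_to_end must be > 0")
    x <- end_to_end
    # axial step d with every bond exactly r0 and |r_N - r_1| = x:
    # odd N: ends are in phase, |v| = (N-1) d;
    # even N: ends differ by the transverse amplitude h = sqrt(r0^2 - d^2),
    #         |v|^2 = (N-1)^2 d^2 + r0^2 - d^2
    feasible <- if (N == 2) FALSE else if (N %% 2 == 1)
      x <= (N - 1) * r0 else (x >= r0 && x <= (N - 1) * r0)
    if (feasible) {
      d <- if (N %% 2 == 1) x / (N - 1) else
        sqrt((x^2 - r0^2) / ((N - 1)^2 - 1))
      h <- sqrt(max(r0^2 - d^2, 0))
    } else {
      d <- x / (N - 1)  # dimer, or stretched straight chain
      h <- 0
    }
  }
  pos <- matrix(0, N, 3)
  pos[, 3] <- (seq_len(N) - 1) * d
  pos[, 1] <- ifelse(seq_len(N) %% 2 == 0, h, 0)
  # rotate in the x-z plane so the end-to-end vector lies along z
  v <- pos[N, ] - pos[1, ]
  th <- atan2(v[1], v[3])
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  pos <- pos %*% R
  pos <- sweep(pos, 2, pos[1, ])
  if (!is.null(end_to_end)) pos[N, ] <- c(0, 0, end_to_end)  # exact placement
  chain_state(pos)
}

#' Read and write XYZ chain snapshots
#'
#' Standard XYZ format: first line the number of beads, second line a
#' comment, then one `element x y z` line per bead (Angstrom).
#'
#' @param state a `chain_state`.
#' @param file path.
#' @param element element label written for every bead.
#' @param comment comment line.
#' @return `read_xyz` returns a `chain_state` with zero momenta.
#' @export
write_xyz <- function(state, file, element = "C", comment = "lfstretch snapshot") {
  p <- state$positions
  lines <- c(sprintf("%d", nrow(p)), comment,
             sprintf("%s %.10f %.10f %.10f", element, p[, 1], p[, 2], p[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  dat <- read.table(text = lines[3:(2 + n)], stringsAsFactors = FALSE)
  chain_state(as.matrix(dat[, 2:4]))
}
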