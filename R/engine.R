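#' @useDynLib dendrisurf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Ewald accuracy parameters from a relative force tolerance: splitting
# parameter from exp(-a^2 rc^2) ~ tol, reciprocal cutoff from the matching
# k-space estimate.
.ewald_params <- function(L, rc, tol) {
  s <- sqrt(-log(tol))
  alpha <- s / rc
  kmax <- ceiling(s^2 * L / (pi * rc))
  list(alpha = alpha, kmax = as.integer(kmax))
}

.coul_code <- c(none = 0L, cutoff = 1L, ewald = 2L)

.engine_params <- function(system, params, coulomb, L, tol = NULL) {
  coulomb <- match.arg(coulomb, names(.coul_code))
  tol <- tol %||% params$coul_tolerance
  ew <- .ewald_params(L, params$rc_coul, tol)
  c(unclass(params),
    list(coul_method = .coul_code[[coulomb]], alpha = ew$alpha, kmax = ew$kmax))
}

#' Forces and potential energy of a configuration
#'
#' Evaluates the full force field (truncated-shifted LJ, FENE bonds,
#' Coulomb) on one frame.  Electrostatics can be switched between Ewald
#' summation (`"ewald"`, accurate to the force tolerance of `params`),
#' shifted-force cutoff truncation (`"cutoff"`), or `"none"`.
#'
#' @param system an `md_system`
#' @param frame an `md_frame`
#' @param params an [force_field()] parameter set
#' @param coulomb electrostatics method
#' @return list with `forces` (n x 3 matrix) and `epot` (total potential
#'   energy in reduced units).
#' @export
compute_forces <- function(system, frame, params = force_field(),
                           coulomb = c("ewald", "cutoff", "none")) {
  coulomb <- match.arg(coulomb)
  p <- .engine_params(system, params, coulomb, frame$box_L)
  cpp_forces(frame$positions, frame$box_L,
             as.integer(system$beads$species == "surfactant-tail"),
             system$beads$charge, as.matrix(system$bonds[, c("i", "j")]), p)
}

#' Long-range electrostatics by Ewald summation
#'
#' Energy (in \eqn{k_B T}) and per-bead forces of a periodic system of point
#' charges, using classical Ewald summation with accuracy set by `tol`.
#' The system must be electroneutral.
#'
#' @param positions `n x 3` coordinate matrix in sigma
#' @param charges per-bead valences
#' @param box_L cubic box edge
#' @param rc real-space cutoff in sigma
#' @param tol relative force accuracy target
#' @param lambda_B_star reduced Bjerrum length prefactor (default 1)
#' @return list with `energy`, `forces`, and `n_kvec` used.
#' @export
ewald_coulomb <- function(positions, charges, box_L, rc = 10, tol = 1e-4,
                          lambda_B_star = 1) {
  if (abs(sum(charges)) > 1e-12) {
    stop("Ewald summation requires an electroneutral system (net charge ",
         sum(charges), ")", call. = FALSE)
  }
  if (rc > box_L / 2) rc <- box_L / 2
  ew <- .ewald_params(box_L, rc, tol)
  cpp_ewald(as.matrix(positions), charges, box_L, ew$alpha, ew$kmax, rc,
            lambda_B_star)
}

#' Neighbour pairs within a cutoff under minimum image
#'
#' All (i, j) pairs with minimum-image distance strictly below `cutoff`.
#' With one coordinate set, unordered pairs i < j within it; with two sets,
#' all cross pairs.
#'
#' @param a `n x 3` coordinate matrix
#' @param b optional second coordinate matrix
#' @param box_L cubic box edge
#' @param cutoff distance threshold in sigma
#' @return tibble with columns `i`, `j`, `dist`.
#' @export
neighbor_pairs <- function(a, b = NULL, box_L, cutoff) {
  df <- cpp_neighbor_pairs(as.matrix(a),
                           if (is.null(b)) NULL else as.matrix(b),
                           box_L, cutoff)
  tibble::as_tibble(df)
}

#' Run Langevin dynamics
#'
#' Integrates the system with a BAOAB splitting of the underdamped Langevin
#' equation at temperature `T_star` and friction `gamma_star`; with
#' `gamma_star = 0` the scheme reduces exactly to velocity Verlet and
#' conserves energy.  Reproducible under `set.seed()`; a run continued from
#' the returned final state reproduces an uninterrupted run bitwise.
#'
#' @inheritParams compute_forces
#' @param n_steps number of time steps
#' @param stride record a frame and log entry every `stride` steps
#' @param velocities optional `n x 3` initial velocities; by default drawn
#'   from the Maxwell-Boltzmann distribution at `T_star`
#' @param seed optional integer seed applied before velocity draw and noise
#' @param noise_state internal thermostat-noise generator state (10 numbers),
#'   used by [continue_langevin()] to resume the exact noise sequence
#' @param limit optional per-step displacement cap in sigma (push-off
#'   relaxation); 0 disables
#' @param step0 step count the trajectory starts at (for continued runs)
#' @return an `md_trajectory`: list with `frames` (list of [md_frame()]),
#'   `log` (tibble: step, pe, ke, temperature), `final` (positions,
#'   velocities, step), `system`, `params`.
#' @export
run_langevin <- function(system, frame, params = force_field(), n_steps,
                         stride = 1000L, velocities = NULL, seed = NULL,
                         coulomb = c("cutoff", "ewald", "none"),
                         limit = 0, step0 = frame$step, noise_state = NULL) {
  coulomb <- match.arg(coulomb)
  if (!is.null(seed)) set.seed(seed)
  n <- system$n_beads
  stopifnot(nrow(frame$positions) == n)
  if (is.null(velocities)) {
    velocities <- matrix(stats::rnorm(3 * n, sd = sqrt(params$T_star / params$mass)), n, 3)
  }
  p <- .engine_params(system, params, coulomb, frame$box_L)
  res <- cpp_run_langevin(frame$positions, velocities, frame$box_L,
                          as.integer(system$beads$species == "surfactant-tail"),
                          system$beads$charge,
                          as.matrix(system$bonds[, c("i", "j")]), p,
                          as.integer(n_steps), as.integer(stride),
                          limit, as.integer(step0), noise_state)
  frames <- purrr::map2(res$frames, res$steps,
                        ~ md_frame(.x, frame$box_L, step = .y))
  structure(
    list(
      frames = frames,
      log = tibble::tibble(step = res$steps, pe = res$pe, ke = res$ke,
                           temperature = res$temperature),
      final = list(positions = res$final_pos, velocities = res$final_vel,
                   step = step0 + n_steps, noise_state = res$rng_state),
      system = system, params = params, box_L = frame$box_L,
      coulomb = coulomb
    ),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames (steps %d..%d), %d beads, box L = %g, coulomb = %s\n",
              length(x$frames), x$log$step[1], x$final$step,
              x$system$n_beads, x$box_L, x$coulomb))
  invisible(x)
}

#' Continue a trajectory from its final state
#'
#' @param traj an `md_trajectory`
#' @param n_steps additional steps
#' @param stride recording stride
#' @return a new `md_trajectory` starting where `traj` ended.  The RNG state
#'   carries over between calls, so splitting a run into segments reproduces
#'   the uninterrupted run exactly.
#' @export
continue_langevin <- function(traj, n_steps, stride = 1000L) {
  # keep the unwrapped coordinates: rewrapping would perturb the floating
  # point state and break bitwise agreement with an uninterrupted run
  fr <- structure(list(positions = traj$final$positions, box_L = traj$box_L,
                       step = traj$final$step), class = "md_frame")
  run_langevin(traj$system, fr, traj$params, n_steps, stride = stride,
               velocities = traj$final$velocities, coulomb = traj$coulomb,
               step0 = traj$final$step, noise_state = traj$final$noise_state)
}

#' Build, place and simulate from a run configuration
#'
#' Thin driver over [assemble_system()] and [run_langevin()]: builds the
#' system described by a [run_config()], applies a short capped-displacement
#' push-off to remove placement strain, then integrates.
#'
#' @param config a [run_config()] list
#' @return an `md_trajectory`.
#' @export
run_simulation <- function(config) {
  cfg <- config
  asm <- assemble_system(cfg$n_d, cfg$n_s, G = cfg$G, S = cfg$S,
                         L = cfg$L_star, seed = cfg$seed)
  ff <- force_field(eps_tt = cfg$eps_tt, T_star = cfg$T_star,
                    gamma_star = cfg$gamma_star, dt_star = cfg$dt_star,
                    rc_coul = cfg$rc_coul, coul_tolerance = cfg$coul_tolerance)
  relax <- run_langevin(asm$system, asm$frame, ff,
                        n_steps = cfg$relax_steps, stride = 0L,
                        coulomb = cfg$coulomb, limit = 0.05)
  fr <- md_frame(relax$final$positions, cfg$L_star, step = 0L)
  run_langevin(asm$system, fr, ff, n_steps = cfg$n_steps,
               stride = cfg$dump_stride, velocities = relax$final$velocities,
               coulomb = cfg$coulomb)
}
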