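#' Truncated and shifted Lennard-Jones pair energy
#'
#' The 12-6 LJ potential cut at `rc` and shifted so that the energy is
#' continuous (zero) at the cutoff:
#' \deqn{U_{ts}(r) = U_{LJ}(r) - U_{LJ}(r_c)\ (r < r_c),\quad 0\ (r \ge r_c)}
#' with \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}.
#' With `rc = 2^(1/6)` the interaction is the purely repulsive WCA form.
#'
#' @param r pair distance in sigma (> 0); vectorised
#' @param eps interaction strength \eqn{\epsilon^*} in energy units
#' @param rc cutoff radius in sigma
#' @param sigma bead diameter (default 1)
#' @return energy in reduced units.
#' @export
lj_ts_energy <- function(r, eps = 1, rc = 2.5, sigma = 1) {
  if (any(r <= 0)) stop("`r` must be positive (LJ diverges at r = 0)", call. = FALSE)
  u <- function(x) 4 * eps * ((sigma / x)^12 - (sigma / x)^6)
  ifelse(r >= rc, 0, u(r) - u(rc))
}

#' FENE bond energy
#'
#' Finitely extensible nonlinear elastic bond potential
#' \deqn{U_{FENE}(r) = -\tfrac{1}{2} k R_0^2 \ln[1 - (r/R_0)^2],}
#' diverging as the bond approaches its maximum extension \eqn{R_0}.
#' Defaults are the Kremer-Grest values \eqn{k^* = 30}, \eqn{R_0^* = 1.5}.
#'
#' @param r bond length in sigma, `0 <= r < R0`; vectorised
#' @param k spring constant in \eqn{\epsilon_u/\sigma^2}
#' @param R0 maximum bond extension in sigma
#' @return energy in reduced units.
#' @export
fene_energy <- function(r, k = 30, R0 = 1.5) {
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  if (any(r >= R0)) {
    stop("FENE bond overstretched: r >= R0 = ", R0, call. = FALSE)
  }
  -0.5 * k * R0^2 * log(1 - (r / R0)^2)
}

#' Coulomb pair energy in thermal units
#'
#' \deqn{U_C(r)/k_BT = \lambda_B^* z_i z_j / r^*.}
#' With the reduced length unit equal to the Bjerrum length,
#' \eqn{\lambda_B^* = 1} and the energy is simply \eqn{z_i z_j/r^*}.
#'
#' @param r pair distance in sigma (> 0); vectorised
#' @param z_i,z_j charge valences (-1, 0, +1)
#' @param lambda_B_star reduced Bjerrum length (default 1)
#' @return energy in \eqn{k_B T}.
#' @export
coulomb_energy <- function(r, z_i, z_j, lambda_B_star = 1) {
  if (any(r <= 0)) stop("`r` must be positive (Coulomb diverges at r = 0)", call. = FALSE)
  lambda_B_star * z_i * z_j / r
}

#' Force-field parameter set
#'
#' Collects every interaction and integrator parameter of the reduced-unit
#' model.  `force_field("paper")` returns the published parameterisation:
#' tail-tail LJ attraction `eps_tt` (1.25 / 1.5 / 1.6) cut at 2.5 sigma, all
#' other pairs WCA-repulsive (eps 1, cutoff 2^(1/6)), FENE bonds with k* = 30
#' and R0* = 1.5, Coulomb with real-space cutoff 10 sigma and force tolerance
#' 1e-4, Langevin damping gamma* = 1 at T* = 1, time step 0.005.
#'
#' @param preset `"paper"` (only preset currently defined)
#' @param eps_tt tail-tail LJ strength; the hydrophobicity dial
#' @param ... overrides for individual fields
#' @return an object of class `ff_params` (a named list).
#' @export
force_field <- function(preset = "paper", eps_tt = 1.5, ...) {
  preset <- match.arg(preset)
  p <- list(
    eps_tt = eps_tt,
    eps_other = 1.0,
    rc_lj_tt = 2.5,
    rc_lj_other = 2^(1 / 6),
    k_fene = 30,
    R0 = 1.5,
    e_star = 9,
    lambda_B_star = 1,
    rc_coul = 10,
    coul_tolerance = 1e-4,
    sigma = 1,
    mass = 1,
    T_star = 1,
    gamma_star = 1,
    dt_star = 0.005
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown force-field fields: ", paste(bad, collapse = ", "), call. = FALSE)
  p[names(dots)] <- dots
  structure(p, class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("<ff_params> reduced-unit force field\n")
  cat(sprintf(
    "  LJ: eps_tt=%.3g (rc %.3g), others eps=%.3g (rc %.4g, WCA)\n",
    x$eps_tt, x$rc_lj_tt, x$eps_other, x$rc_lj_other
  ))
  cat(sprintf("  FENE: k=%.3g R0=%.3g;  Coulomb: rc=%.3g tol=%.1e\n",
              x$k_fene, x$R0, x$rc_coul, x$coul_tolerance))
  cat(sprintf("  Langevin: T*=%.3g gamma*=%.3g dt*=%.3g\n",
              x$T_star, x$gamma_star, x$dt_star))
  invisible(x)
}
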