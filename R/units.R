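#' Bjerrum length of a solvent
#'
#' Distance at which two elementary charges in a dielectric medium have
#' Coulomb energy \eqn{k_B T}:
#' \deqn{\lambda_B(\epsilon_r, T) = e^2 / (4\pi\epsilon_0\,\epsilon_r\,k_B T).}
#' For water at room temperature (\eqn{\epsilon_r \approx 81},
#' \eqn{T \approx 298} K) this is about 7 Angstrom, which serves as the
#' reduced length unit \eqn{\sigma_u} of the model.
#'
#' @param eps_r relative permittivity of the solvent (dimensionless, > 0)
#' @param T_kelvin absolute temperature in kelvin (> 0)
#' @return Bjerrum length in Angstrom.
#' @examples
#' bjerrum_length(81, 298) # ~ 6.9 A, rounds to 7
#' @export
bjerrum_length <- function(eps_r, T_kelvin) {
  if (any(eps_r <= 0) || any(T_kelvin <= 0)) {
    stop("`eps_r` and `T_kelvin` must be positive", call. = FALSE)
  }
  e <- .const$e_charge
  lb_m <- e^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * T_kelvin)
  lb_m * 1e10
}

# CODATA values (SI)
.const <- list(
  e_charge = 1.602176634e-19, # C
  eps0     = 8.8541878128e-12, # F/m
  kB       = 1.380649e-23, # J/K
  NA_      = 6.02214076e23 # 1/mol
)

#' Reduced elementary charge
#'
#' With the reduced length unit set to the Bjerrum length and the reduced
#' temperature to 1, the Coulomb pair energy in thermal units is
#' \eqn{z_i z_j / r^*}. Writing the same energy as
#' \eqn{e^{*2} z_i z_j / (\epsilon_r r^*)} requires
#' \eqn{e^* = \sqrt{\epsilon_r}}; for water (\eqn{\epsilon_r = 81}) this
#' gives \eqn{e^* = 9}.
#'
#' @param eps_r relative permittivity of the solvent (> 0)
#' @return dimensionless reduced elementary charge \eqn{e^*}.
#' @examples
#' reduced_elementary_charge(81) # 9
#' @export
reduced_elementary_charge <- function(eps_r) {
  if (any(eps_r <= 0)) stop("`eps_r` must be positive", call. = FALSE)
  sqrt(eps_r)
}

#' Reduced Lennard-Jones unit system
#'
#' Builds the unit system of the model: energy unit
#' \eqn{\epsilon_u = k_B T_r}, length unit
#' \eqn{\sigma_u = \lambda_B(\epsilon_r, T_r)}, and a real mass unit
#' \eqn{m_u} (default 30 g/mol per bead).  Derived quantities are the LJ
#' time unit \eqn{t_u = \sigma_u \sqrt{m_u/\epsilon_u}} and the reduced
#' elementary charge \eqn{e^* = \sqrt{\epsilon_r}}.
#'
#' @param eps_r relative permittivity of the solvent (default 81, water)
#' @param T_kelvin reference temperature in kelvin (default 298)
#' @param m_u_gmol real mass unit in g/mol per bead (default 30)
#' @return a tibble with one row: `epsilon_u_J`, `sigma_u_A`, `m_u_kg`,
#'   `t_u_ps`, `e_star`, `lambda_B_A`.
#' @examples
#' unit_system() # lambda_B ~ 7 A, e* = 9, t_u ~ 2.4 ps
#' @export
unit_system <- function(eps_r = 81, T_kelvin = 298, m_u_gmol = 30) {
  lb_A <- bjerrum_length(eps_r, T_kelvin)
  eps_u <- .const$kB * T_kelvin # J
  m_kg <- m_u_gmol * 1e-3 / .const$NA_
  t_u_s <- (lb_A * 1e-10) * sqrt(m_kg / eps_u)
  tibble::tibble(
    epsilon_u_J = eps_u,
    sigma_u_A = lb_A,
    m_u_kg = m_kg,
    t_u_ps = t_u_s * 1e12,
    e_star = reduced_elementary_charge(eps_r),
    lambda_B_A = lb_A
  )
}

#' LJ time unit in picoseconds
#'
#' @inheritParams unit_system
#' @return time unit \eqn{t_u} in ps.
#' @export
lj_time_unit <- function(eps_r = 81, T_kelvin = 298, m_u_gmol = 30) {
  unit_system(eps_r, T_kelvin, m_u_gmol)$t_u_ps
}
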