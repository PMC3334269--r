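#' Constitutive parameters of the poroelastic skeleton
#'
#' Parameters of the isotropic exponential strain-energy law for perfused
#' myocardium,
#' \deqn{\Psi^s = a\,[\exp(D_1(\bar I_1(1+\textstyle\sum_i Q_1^i m_i/\rho_f)-3)
#'   + D_2(\bar I_2(1+\sum_i Q_2^i m_i/\rho_f)-3)
#'   + D_3((J-1)^2 + (\sum_i Q_3^i m_i/\rho_f)^2)) - 1],}
#' where \eqn{\bar I_1 = J^{-2/3} I_1} and \eqn{\bar I_2 = J^{-4/3} I_2} are
#' the modified invariants of \eqn{C = F^T F} and \eqn{m_i} is the fluid mass
#' increase of compartment i per reference volume. The energy and its stress
#' vanish in the reference state. Defaults are the manually tuned values used
#' for the left-ventricle simulations; the per-compartment coupling weights
#' `Q1`, `Q2`, `Q3` capture differing vessel compliances.
#'
#' @param a energy scale (kPa).
#' @param D1,D2,D3 dimensionless exponent weights (> 0).
#' @param Q1,Q2,Q3 per-compartment mass-coupling weights, scalars or length-
#'   `n_compartments` vectors.
#' @param rho_f fluid density (g/mm^3); 1.05e-3 is blood.
#' @param mu_f fluid dynamic viscosity (kPa s); 4e-6 is blood.
#' @param n_compartments number of fluid compartments.
#' @return list of class `constitutive_params`.
#' @export
constitutive_params <- function(a = 1.0, D1 = 2.0, D2 = 0.2, D3 = 2.0,
                                Q1 = 1.0, Q2 = 0.5, Q3 = 1.0,
                                rho_f = 1.05e-3, mu_f = 4e-6,
                                n_compartments = 1) {
  stopifnot(a > 0, D1 > 0, D2 > 0, D3 > 0, rho_f > 0, mu_f > 0,
            n_compartments >= 1)
  rep_n <- function(q) if (length(q) == 1) rep(q, n_compartments) else {
    stopifnot(length(q) == n_compartments); q
  }
  structure(list(a = a, D1 = D1, D2 = D2, D3 = D3,
                 Q1 = rep_n(Q1), Q2 = rep_n(Q2), Q3 = rep_n(Q3),
                 rho_f = rho_f, mu_f = mu_f,
                 n_compartments = as.integer(n_compartments)),
            class = "constitutive_params")
}

check_F <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3))) stop("F must be 3 x 3")
  F
}

#' Kinematic quantities of a deformation gradient
#'
#' @param F 3 x 3 deformation gradient.
#' @return list with `F`, `J`, `C`, `E`, `I1`, `I2`, `I1_bar`, `I2_bar`.
#' @export
kinematics_cache <- function(F) {
  F <- check_F(F)
  J <- det(F)
  if (J <= 0) stop("inverted element: J <= 0")
  C <- t(F) %*% F
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  list(F = F, J = J, C = C, E = (C - diag(3)) / 2, I1 = I1, I2 = I2,
       I1_bar = J^(-2 / 3) * I1, I2_bar = J^(-4 / 3) * I2)
}

#' Strain energy of the perfused skeleton
#'
#' @param F 3 x 3 deformation gradient.
#' @param m per-compartment fluid mass increase (g/mm^3 of reference volume).
#' @param params a [constitutive_params()].
#' @return energy density in kPa.
#' @export
strain_energy <- function(F, m, params) {
  m <- as.numeric(m)
  stopifnot(length(m) == params$n_compartments)
  cpp_strain_energy(check_F(F), m, unclass(params))
}

#' Total second Piola--Kirchhoff stress
#'
#' Constitutive part `dPsi/dE` plus the volume-constraint part
#' `lambda J C^{-1}`.
#'
#' @inheritParams strain_energy
#' @param lambda Lagrange multiplier enforcing `J = 1 + sum(m)/rho_f` (kPa).
#' @param constitutive_only if `TRUE`, return only `dPsi/dE`.
#' @return 3 x 3 symmetric stress (kPa).
#' @export
total_second_pk_stress <- function(F, m, lambda, params,
                                   constitutive_only = FALSE) {
  m <- as.numeric(m)
  stopifnot(length(m) == params$n_compartments)
  if (constitutive_only) cpp_pk2_constitutive(check_F(F), m, unclass(params))
  else cpp_pk2(check_F(F), m, lambda, unclass(params))
}

#' Compartment fluid pressures from the constitutive law
#'
#' `p_i = rho_f dPsi/dm_i - lambda`, using the identification
#' `m_i = rho_f (J phi_i - phi0_i)` between pore-volume change and fluid
#' mass increase.
#'
#' @inheritParams total_second_pk_stress
#' @return numeric vector of compartment pressures (kPa).
#' @export
compartment_pressure <- function(F, m, lambda, params) {
  m <- as.numeric(m)
  stopifnot(length(m) == params$n_compartments)
  as.numeric(params$rho_f * cpp_dpsi_dm(check_F(F), m, unclass(params))) -
    lambda
}
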