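#' Initial poroelastic state
#'
#' Zero displacement, multiplier and mass increase at time zero.
#'
#' @param vspace P2 vector [field_space()].
#' @param n_compartments number of fluid compartments.
#' @return object of class `poroelastic_state` with `y` (P2 nodes x 3, mm),
#'   `lambda` (P1, kPa), `m` (P1 nodes x compartments, g/mm^3), `time` (s)
#'   and `flux` (set after converged steps).
#' @export
poroelastic_state <- function(vspace, n_compartments = 1) {
  nv <- nrow(vspace$mesh$nodes)
  structure(list(y = matrix(0, vspace$n_dof, 3), lambda = numeric(nv),
                 m = matrix(0, nv, n_compartments), time = 0,
                 flux = NULL, diagnostics = NULL),
            class = "poroelastic_state")
}

# element-level kinematics from the P2 displacement, with scalars coerced
# to plain vectors
element_kinematics <- function(mesh, vspace, y) {
  kin <- cpp_elem_kinematics(mesh$nodes, mesh$elems, vspace$conn, y)
  list(F = kin$F, J = as.numeric(kin$J), I1b = as.numeric(kin$I1b),
       I2b = as.numeric(kin$I2b))
}

# volume-weighted projection of element kinematic scalars to P1 nodes
nodal_kinematic_scalars <- function(mesh, kin) {
  n <- nrow(mesh$nodes)
  wt <- p1_lumped_volume(mesh)
  proj <- function(v) {
    out <- numeric(n)
    for (a in 1:4)
      out <- out + accumulate_at(v * mesh$volumes / 4, mesh$elems[, a], n)
    out / wt
  }
  list(J = proj(kin$J), I1b = proj(kin$I1b), I2b = proj(kin$I2b))
}

# nodal compartment pressures and their pointwise dp/dm blocks
nodal_pressure_law <- function(mk, m, lambda, params) {
  # mk: list(J, I1b, I2b) nodal; m: n x N
  N <- params$n_compartments
  s1 <- as.numeric(m %*% params$Q1) / params$rho_f
  s2 <- as.numeric(m %*% params$Q2) / params$rho_f
  s3 <- as.numeric(m %*% params$Q3) / params$rho_f
  W <- params$D1 * (mk$I1b * (1 + s1) - 3) +
       params$D2 * (mk$I2b * (1 + s2) - 3) +
       params$D3 * ((mk$J - 1)^2 + s3^2)
  eW <- params$a * exp(W)
  G <- outer(params$D1 * mk$I1b, params$Q1) +
       outer(params$D2 * mk$I2b, params$Q2) +
       outer(2 * params$D3 * s3, params$Q3)   # n x N
  p <- eW * G - lambda
  dp <- vector("list", N)  # dp[[i]][[k]] as n-vectors, via array
  darr <- array(0, c(length(eW), N, N))
  for (i in seq_len(N)) for (k in seq_len(N))
    darr[, i, k] <- eW * (G[, i] * G[, k] +
                          2 * params$D3 * params$Q3[i] * params$Q3[k]) /
      params$rho_f
  list(p = p, dpdm = darr)
}

# implicit (backward Euler) fluid substep: solve for m at t+dt with the
# solid state frozen. Newton on the nodal nonlinear pressure law.
fluid_substep <- function(problem, params, m_prev, m_guess, lambda, dt,
                          kin, mk, tol_scale = 1e-8, max_iter = 30) {
  sys <- darcy_system(problem, kin)
  n <- sys$n; N <- sys$N
  Mbig <- Matrix::kronecker(Matrix::Diagonal(N), sys$ops$M0)
  mprev_v <- as.vector(m_prev)
  resid <- function(mv) {
    mmat <- matrix(mv, n, N)
    law <- nodal_pressure_law(mk, mmat, lambda, params)
    as.numeric(Mbig %*% (mv - mprev_v) +
               dt * (sys$A %*% as.vector(law$p) - sys$rhs))
  }
  jac <- function(mv) {
    mmat <- matrix(mv, n, N)
    law <- nodal_pressure_law(mk, mmat, lambda, params)
    # sparse block map m -> p: rows (i,node), cols (k,node)
    iidx <- jidx <- xval <- vector("list", N * N)
    c_ <- 0L
    for (i in seq_len(N)) for (k in seq_len(N)) {
      c_ <- c_ + 1L
      iidx[[c_]] <- (i - 1) * n + seq_len(n)
      jidx[[c_]] <- (k - 1) * n + seq_len(n)
      xval[[c_]] <- law$dpdm[, i, k]
    }
    Dm <- Matrix::sparseMatrix(i = unlist(iidx), j = unlist(jidx),
                               x = unlist(xval), dims = c(N * n, N * n))
    Mbig + dt * (sys$A %*% Dm)
  }
  # tolerance relative to the natural residual scales (source work, stored
  # mass, and the initial defect), floored at the roundoff noise of the
  # operator application so an already-converged state is accepted
  r0 <- max(abs(resid(as.vector(m_guess))))
  law0 <- nodal_pressure_law(mk, matrix(as.vector(m_guess), n, N), lambda,
                             params)
  noise <- 1e4 * .Machine$double.eps *
    (max(abs(Mbig@x)) * (1 + max(abs(mprev_v))) +
     dt * max(abs(sys$A@x)) * max(abs(law0$p), 1))
  scale <- max(dt * max(abs(sys$rhs)), max(abs(Mbig %*% mprev_v)), r0)
  tol <- max(tol_scale * scale, noise)
  ns <- solve_newton(resid, jac, as.vector(m_guess), tol = tol,
                     max_iter = max_iter)
  if (!ns$converged)
    stop("fluid substep Newton failed (|r| = ", format(ns$residual_norm), ")")
  mmat <- matrix(ns$x, n, N)
  law <- nodal_pressure_law(mk, mmat, lambda, params)
  list(m = mmat, p = law$p)
}

#' One partitioned fluid--solid time step
#'
#' Fixed-point sub-iterations between the nonlinear solid solve (with mass
#' increase frozen) and the backward-Euler fluid mass update (with the
#' deformation frozen), until successive changes of displacement and mass
#' increase fall below `tol_fixed_point`. The Lagrangian flow vectors are
#' recovered only after convergence.
#'
#' @param mesh an [fe_mesh()].
#' @param vspace P2 vector [field_space()].
#' @param problem a [darcy_problem()] describing permeabilities, exchange and
#'   this step's (time-averaged) sources.
#' @param params a [constitutive_params()].
#' @param state current [poroelastic_state()].
#' @param dt time step (s).
#' @param cavity_pressure cavity pressure at the end of the step (kPa).
#' @param bcs a [solid_bcs()].
#' @param cavity_pressure_prev pressure at the start of the step (for load
#'   stepping within the solid solve).
#' @param tol_fixed_point tolerance on the max relative increment of `y` and
#'   `m` between sub-iterations.
#' @param max_subiters maximum sub-iterations.
#' @param solid_tol Newton tolerance of the solid solve.
#' @return updated `poroelastic_state` (with `diagnostics`: sub-iteration
#'   increment norms, constraint residual, solid Newton reports).
#' @export
coupled_step <- function(mesh, vspace, problem, params, state, dt,
                         cavity_pressure, bcs,
                         cavity_pressure_prev = NULL,
                         tol_fixed_point = 1e-6, max_subiters = 25,
                         solid_tol = 1e-9) {
  if (is.null(cavity_pressure_prev)) cavity_pressure_prev <- cavity_pressure
  y <- state$y; lam <- state$lambda; m <- state$m
  m_prev <- state$m
  incr <- numeric(0)
  cres <- NA_real_
  yscale <- NULL; mscale <- NULL
  solid_report <- NULL
  p_from <- cavity_pressure_prev
  for (it in seq_len(max_subiters)) {
    sol <- solve_solid(mesh, vspace, m, params, bcs,
                       cavity_pressure = cavity_pressure,
                       y0 = y, lambda0 = lam, p_prev = p_from,
                       tol = solid_tol)
    p_from <- cavity_pressure  # after first pass, restart from full load
    kin <- element_kinematics(mesh, vspace, sol$y)
    mk <- nodal_kinematic_scalars(mesh, kin)
    fl <- fluid_substep(problem, params, m_prev, m, sol$lambda, dt, kin, mk)
    if (is.null(yscale)) {
      yscale <- max(max(abs(sol$y)), 1e-6)
      mscale <- max(max(abs(fl$m)), params$rho_f * 1e-6)
    }
    dy <- max(abs(sol$y - y)) / yscale
    dm <- max(abs(fl$m - m)) / mscale
    incr <- c(incr, max(dy, dm))
    y <- sol$y; lam <- sol$lambda; m <- fl$m
    cres <- sol$constraint_residual
    solid_report <- sol$newton
    if (max(dy, dm) < tol_fixed_point) {
      flux <- recover_flux(problem, fl$p, kin)
      return(structure(list(y = y, lambda = lam, m = m,
                            time = state$time + dt, flux = flux,
                            p = fl$p,
                            diagnostics = list(subiter_increments = incr,
                                               constraint_residual = cres,
                                               solid_newton = solid_report)),
                       class = "poroelastic_state"))
    }
  }
  stop("fixed-point sub-iterations did not converge in ", max_subiters,
       " iterations; last increments: ",
       paste(format(utils::tail(incr, 3), digits = 3), collapse = ", "))
}

#' Deformed wall volume
#'
#' Integral of the Jacobian `J` over the reference wall.
#'
#' @param mesh an [fe_mesh()].
#' @param vspace P2 vector [field_space()].
#' @param y displacement.
#' @param degree quadrature degree.
#' @return volume in mm^3.
#' @export
wall_volume <- function(mesh, vspace, y, degree = 5) {
  qr <- tet_quadrature(degree)
  cpp_deformed_volume(mesh$nodes, mesh$elems, vspace$conn, y,
                      qr$bary, qr$weights)
}
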