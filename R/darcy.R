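#' Multi-compartment Darcy problem
#'
#' Steady or transient Darcy flow of N interpenetrating fluid compartments
#' on a (possibly deformed) reference mesh:
#' \deqn{\nabla_X\cdot(\rho_f J F^{-1} K_i F^{-T} \nabla_X p_i) + \rho_f q_i
#'  - \sum_k J \beta_{ik} (p_i - p_k) = \frac{d^s m_i}{dt},}
#' with zero normal flux on all exterior/regional boundaries by default,
#' optional fixed-pressure surface patches, and optional distributed
#' reservoir (Robin) couplings that exchange mass with an external pressure
#' in proportion to the local pressure difference (used for distributed
#' arterial inflow and venous drainage).
#'
#' @param mesh an [fe_mesh()].
#' @param model a [compartment_model()] (or one read from file; in that case
#'   `element_region` must be supplied via the model's partition).
#' @param sources list of per-compartment volumetric source terms `q_i`
#'   (1/s): scalars or per-element vectors. Default all zero.
#' @param dirichlet list of `list(label =, compartment =, value =)` fixing
#'   the pressure (kPa) on a labelled surface.
#' @param reservoirs list of `list(compartment =, gamma =, pressure =)`;
#'   `gamma` is a per-element (or scalar) conductance density in
#'   g mm^-3 kPa^-1 s^-1.
#' @param datum compartment whose volume-mean pressure is pinned (with
#'   `value`) when the system otherwise lacks a pressure datum; default pins
#'   the last compartment to 0.
#' @param rho_f fluid density (g/mm^3).
#' @return object of class `darcy_problem`.
#' @export
darcy_problem <- function(mesh, model, sources = NULL, dirichlet = list(),
                          reservoirs = list(),
                          datum = list(compartment = NULL, value = 0),
                          rho_f = model$rho_f) {
  N <- model$n_compartments
  if (is.null(sources)) sources <- rep(list(0), N)
  stopifnot(length(sources) == N)
  if (is.null(datum$compartment)) datum$compartment <- N
  structure(list(mesh = mesh, model = model, sources = sources,
                 dirichlet = dirichlet, reservoirs = reservoirs,
                 datum = datum, rho_f = rho_f, n_compartments = N),
            class = "darcy_problem")
}

# element region indices for a model on a mesh (default: single region)
element_regions <- function(mesh, model) {
  er <- model$partition$element_region
  if (is.null(er)) rep(1L, nrow(mesh$elems)) else er
}

# P1 stiffness matrices with per-element 3x3 coefficient, plus the
# element-consistent mass matrix. kin: list(F = m x 9 (column-major), J).
assemble_darcy_operators <- function(mesh, model, rho_f, kin = NULL) {
  m <- nrow(mesh$elems)
  n <- nrow(mesh$nodes)
  N <- model$n_compartments
  bg <- barycentric_gradients(mesh)
  er <- element_regions(mesh, model)
  ii <- rep(mesh$elems, times = 4)
  jj <- rep(as.vector(mesh$elems), each = 1)
  # build index arrays for 4x4 element blocks
  ia <- matrix(0L, m, 16); ja <- matrix(0L, m, 16)
  for (a in 1:4) for (b in 1:4) {
    k <- (a - 1) * 4 + b
    ia[, k] <- mesh$elems[, a]; ja[, k] <- mesh$elems[, b]
  }
  Fel <- if (is.null(kin)) NULL else kin$F
  Jel <- if (is.null(kin)) rep(1, m) else kin$J
  Kmats <- vector("list", N)
  for (ci in seq_len(N)) {
    xa <- matrix(0, m, 16)
    for (e in seq_len(m)) {
      K <- matrix(model$K[er[e], ci, , ], 3)
      if (!is.null(Fel)) {
        Fm <- matrix(Fel[e, ], 3)
        Fi <- solve(Fm)
        K <- Jel[e] * Fi %*% K %*% t(Fi)
      }
      G <- matrix(bg$grads[e, , ], 4)          # 4 x 3
      xa[e, ] <- as.vector(t(rho_f * mesh$volumes[e] * G %*% K %*% t(G)))
    }
    Kmats[[ci]] <- Matrix::sparseMatrix(i = as.vector(ia), j = as.vector(ja),
                                        x = as.vector(xa), dims = c(n, n))
  }
  # consistent mass on the reference measure (time-derivative and source
  # terms) and its J-weighted counterpart (exchange and reservoir terms)
  mass_tpl <- (diag(4) + 1) / 20
  xm0 <- outer(mesh$volumes, as.vector(t(mass_tpl)))
  M0 <- Matrix::sparseMatrix(i = as.vector(ia), j = as.vector(ja),
                             x = as.vector(xm0), dims = c(n, n))
  xm <- outer(Jel * mesh$volumes, as.vector(t(mass_tpl)))
  Mcons <- Matrix::sparseMatrix(i = as.vector(ia), j = as.vector(ja),
                                x = as.vector(xm), dims = c(n, n))
  # region-resolved masses (for region-wise beta)
  regs <- sort(unique(er))
  Mreg <- lapply(regs, function(r) {
    sel <- er == r
    Matrix::sparseMatrix(i = as.vector(ia[sel, ]), j = as.vector(ja[sel, ]),
                         x = as.vector(xm[sel, ]), dims = c(n, n))
  })
  names(Mreg) <- regs
  list(K = Kmats, M = Mcons, M0 = M0, Mreg = Mreg, regs = regs, er = er,
       vol = mesh$volumes, J = Jel)
}

# full operator on stacked pressures (compartment-major) + rhs pieces
darcy_system <- function(problem, kin = NULL) {
  mesh <- problem$mesh; model <- problem$model
  n <- nrow(mesh$nodes); N <- problem$n_compartments
  ops <- assemble_darcy_operators(mesh, model, problem$rho_f, kin)
  blk <- function(i, k) (list(i = (i - 1) * n, j = (k - 1) * n))
  trips <- list()
  add <- function(i, k, Msp) {
    Tm <- methods::as(methods::as(Msp, "generalMatrix"), "TsparseMatrix")
    trips[[length(trips) + 1L]] <<- cbind(Tm@i + 1 + (i - 1) * n,
                                          Tm@j + 1 + (k - 1) * n, Tm@x)
  }
  for (i in seq_len(N)) add(i, i, ops$K[[i]])
  # exchange, region-wise beta
  for (r in seq_along(ops$regs)) {
    Br <- matrix(model$beta[ops$regs[r], , ], N)
    Mr <- ops$Mreg[[r]]
    for (i in seq_len(N)) for (k in seq_len(N)) {
      if (i == k || Br[i, k] == 0) next
      add(i, i, Br[i, k] * Mr)
      add(i, k, -Br[i, k] * Mr)
    }
  }
  rhs <- numeric(N * n)
  # volumetric sources rho_f q_i (q per element or scalar)
  for (i in seq_len(N)) {
    q <- problem$sources[[i]]
    if (length(q) == 1) q <- rep(q, nrow(mesh$elems))
    if (length(q) != nrow(mesh$elems))
      stop("source must be scalar or per-element")
    w <- problem$rho_f * q * ops$vol / 4
    acc <- numeric(n)
    for (a in 1:4) acc <- acc + accumulate_at(w, mesh$elems[, a], n)
    rhs[(i - 1) * n + seq_len(n)] <- rhs[(i - 1) * n + seq_len(n)] + acc
  }
  # reservoir couplings
  for (rv in problem$reservoirs) {
    i <- rv$compartment
    gam <- rv$gamma
    if (length(gam) == 1) gam <- rep(gam, nrow(mesh$elems))
    w <- gam * ops$J * ops$vol / 4
    Gm <- Matrix::sparseMatrix(i = as.vector(mesh$elems),
                               j = as.vector(mesh$elems),
                               x = rep(w, 4), dims = c(n, n))
    add(i, i, Gm)
    rhs[(i - 1) * n + seq_len(n)] <- rhs[(i - 1) * n + seq_len(n)] +
      rv$pressure * (rep(0, n) + as.numeric(Matrix::rowSums(Gm)))
  }
  tr <- do.call(rbind, trips)
  A <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(N * n, N * n))
  list(A = A, rhs = rhs, ops = ops, n = n, N = N)
}

dirichlet_dofs <- function(problem) {
  mesh <- problem$mesh
  n <- nrow(mesh$nodes)
  idx <- integer(0); val <- numeric(0)
  for (d in problem$dirichlet) {
    lab <- if (is.character(d$label)) surface_labels[[d$label]] else d$label
    nd <- unique(as.vector(mesh$facets[mesh$facet_label == lab, ]))
    if (!length(nd)) stop("no facets with label ", d$label)
    idx <- c(idx, (d$compartment - 1) * n + nd)
    v <- if (is.function(d$value)) d$value(mesh$nodes[nd, , drop = FALSE])
         else rep(d$value, length(nd))
    val <- c(val, v)
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}

#' Solve the steady multi-compartment Darcy problem
#'
#' Static form (`d m/dt = 0`): compartment pressures satisfy the coupled
#' diffusion-exchange balance in weak form. When only flux-type conditions
#' are present, the volume-mean pressure of the datum compartment is pinned
#' via a Lagrange multiplier.
#'
#' @param problem a [darcy_problem()].
#' @param kin optional kinematic state: list with `F` (elements x 9,
#'   column-major deformation gradient) and `J`; identity when omitted.
#' @return object of class `darcy_solution` with `p` (nodes x compartments,
#'   kPa), `flux` (see [recover_flux()]) and `datum_multiplier`.
#' @export
solve_darcy_static <- function(problem, kin = NULL) {
  sys <- darcy_system(problem, kin)
  n <- sys$n; N <- sys$N
  db <- dirichlet_dofs(problem)
  free <- setdiff(seq_len(N * n), db$idx)
  p <- numeric(N * n)
  p[db$idx] <- db$val
  mu <- 0
  need_pin <- length(db$idx) == 0 && length(problem$reservoirs) == 0
  if (need_pin) {
    # pin volume-mean of the datum compartment
    lump <- as.numeric(Matrix::rowSums(sys$ops$M))
    w <- numeric(N * n)
    w[(problem$datum$compartment - 1) * n + seq_len(n)] <- lump / sum(lump)
    A <- rbind(cbind(sys$A, w), c(w, 0))
    rhs <- c(sys$rhs, problem$datum$value)
    sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)), error = function(e)
      stop("singular Darcy system (no pressure datum reachable): ",
           conditionMessage(e), call. = FALSE))
    p <- sol[seq_len(N * n)]
    mu <- sol[N * n + 1]
  } else {
    rhs_f <- sys$rhs[free] - as.numeric(sys$A[free, db$idx, drop = FALSE] %*%
                                        db$val)
    p[free] <- tryCatch(as.numeric(Matrix::solve(sys$A[free, free], rhs_f)),
                        error = function(e)
      stop("singular Darcy system (no pressure datum reachable): ",
           conditionMessage(e), call. = FALSE))
  }
  pm <- matrix(p, n, N)
  structure(list(p = pm, datum_multiplier = mu,
                 flux = recover_flux(problem, pm, kin)),
            class = "darcy_solution")
}

#' Reference-state storage matrix of the constitutive law
#'
#' Pointwise linearisation `dp_i/dm_k` of the compartment-pressure law at
#' the reference state (F = I, m = 0), used as the closure between mass
#' increase and pressure for fluid-only transient runs:
#' `D_ik = a (G_i G_k + 2 D3 Q3_i Q3_k) / rho_f` with
#' `G_i = 3 D1 Q1_i + 3 D2 Q2_i`. Symmetric positive definite.
#'
#' @param params a [constitutive_params()].
#' @return n x n matrix (kPa per (g/mm^3)).
#' @export
storage_matrix <- function(params) {
  G <- 3 * params$D1 * params$Q1 + 3 * params$D2 * params$Q2
  params$a * (outer(G, G) + 2 * params$D3 * outer(params$Q3, params$Q3)) /
    params$rho_f
}

#' One backward-Euler step of the transient multi-compartment Darcy model
#'
#' Advances the fluid mass increase `m_i` with an implicit Euler step of the
#' mass balance, closing pressure as the affine pointwise law
#' `p = p_offset + (m - m_offset) %*% t(D)` (default: the reference-state
#' [storage_matrix()]). With steady sources the iterates approach the static
#' solution as `dt` grows or steps accumulate.
#'
#' @param problem a [darcy_problem()].
#' @param m nodes x compartments matrix of current mass increase (g/mm^3).
#' @param dt time step (s).
#' @param storage n x n storage matrix `dp/dm` (kPa per g/mm^3).
#' @param kin optional kinematics as in [solve_darcy_static()].
#' @return list with `m` (updated), `p` (nodes x compartments).
#' @export
darcy_step_transient <- function(problem, m, dt, storage, kin = NULL) {
  stopifnot(dt > 0)
  sys <- darcy_system(problem, kin)
  n <- sys$n; N <- sys$N
  if (is.vector(m)) m <- matrix(m, n, N)
  Dk <- Matrix::kronecker(Matrix::Matrix(t(storage), sparse = TRUE),
                          Matrix::Diagonal(n))
  Mbig <- Matrix::kronecker(Matrix::Diagonal(N), sys$ops$M0)
  lhs <- Mbig / dt + sys$A %*% Dk
  rhs <- Mbig %*% as.vector(m) / dt + sys$rhs
  mv <- as.numeric(Matrix::solve(lhs, rhs))
  mnew <- matrix(mv, n, N)
  pnew <- mnew %*% t(storage)
  list(m = mnew, p = pnew)
}

#' Recover Lagrangian Darcy flow vectors from pressures
#'
#' `M_i = -rho_f J F^{-1} K_i F^{-T} grad p_i`, evaluated per element and
#' projected to nodes by volume-weighted averaging.
#'
#' @param problem a [darcy_problem()].
#' @param p nodes x compartments pressure matrix.
#' @param kin optional kinematics; identity when omitted.
#' @return list per compartment of `list(element = m x 3, nodal = n x 3)`
#'   in g mm^-2 s^-1.
#' @export
recover_flux <- function(problem, p, kin = NULL) {
  mesh <- problem$mesh; model <- problem$model
  m <- nrow(mesh$elems); n <- nrow(mesh$nodes)
  bg <- barycentric_gradients(mesh)
  er <- element_regions(mesh, model)
  out <- vector("list", problem$n_compartments)
  for (ci in seq_len(problem$n_compartments)) {
    Mel <- matrix(0, m, 3)
    for (e in seq_len(m)) {
      G <- matrix(bg$grads[e, , ], 4)
      gp <- as.numeric(t(G) %*% p[mesh$elems[e, ], ci])
      K <- matrix(model$K[er[e], ci, , ], 3)
      if (!is.null(kin)) {
        Fm <- matrix(kin$F[e, ], 3)
        Fi <- solve(Fm)
        Mel[e, ] <- -problem$rho_f * kin$J[e] * Fi %*% K %*% t(Fi) %*% gp
      } else {
        Mel[e, ] <- -problem$rho_f * K %*% gp
      }
    }
    nodal <- matrix(0, n, 3)
    wt <- numeric(n)
    for (a in 1:4) {
      idx <- mesh$elems[, a]
      for (d in 1:3)
        nodal[, d] <- nodal[, d] +
          accumulate_at(Mel[, d] * mesh$volumes, idx, n)
      wt <- wt + accumulate_at(mesh$volumes, idx, n)
    }
    nodal <- nodal / pmax(wt, 1e-300)
    out[[ci]] <- list(element = Mel, nodal = nodal)
  }
  out
}

# sum vals into bins given by idx (length-n output)
accumulate_at <- function(vals, idx, n) {
  o <- rowsum(vals, idx)
  out <- numeric(n)
  out[as.integer(rownames(o))] <- o
  out
}
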