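#' Displacement boundary conditions for the solid
#'
#' Collects fixed-displacement constraints: whole labelled surfaces (all
#' P2 nodes on the surface, selected components) and explicit pinned nodes.
#'
#' @param vspace the P2 vector [field_space()] of the displacement.
#' @param fixed_surfaces list of `list(label =, comps =)` entries; `comps`
#'   defaults to all three components. Displacement value is zero.
#' @param pinned_dofs optional integer vector of global displacement dof
#'   indices (`3 * (node - 1) + comp`) to pin at zero.
#' @return object of class `solid_bcs` with the fixed dof index set.
#' @export
solid_bcs <- function(vspace, fixed_surfaces = list(list(label = "BASE")),
                      pinned_dofs = integer(0)) {
  idx <- as.integer(pinned_dofs)
  for (fs in fixed_surfaces) {
    nd <- surface_p2_nodes(vspace, fs$label)
    comps <- if (is.null(fs$comps)) 1:3 else fs$comps
    idx <- c(idx, as.vector(outer(3 * (nd - 1L), comps, `+`)))
  }
  structure(list(fixed = sort(unique(idx))), class = "solid_bcs")
}

# P2 node set (vertices + edge nodes) of a labelled surface
surface_p2_nodes <- function(vspace, label) {
  mesh <- vspace$mesh
  lab <- if (is.character(label)) surface_labels[[label]] else label
  fac <- mesh$facets[mesh$facet_label == lab, , drop = FALSE]
  if (!nrow(fac)) stop("no facets with label ", label)
  verts <- unique(as.vector(fac))
  if (vspace$order == 1L) return(verts)
  ed <- vspace$edges
  nv <- nrow(mesh$nodes)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  fe <- rbind(fac[, c(1, 2)], fac[, c(1, 3)], fac[, c(2, 3)])
  fkey <- unique(paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2])))
  enodes <- nv + which(key %in% fkey)
  c(verts, enodes)
}

# facet-level P2 connectivity (6 dofs) for a labelled surface, plus the
# reference coordinates of those dofs (f x 18, row-wise per node xyz)
surface_p2_facets <- function(vspace, label) {
  mesh <- vspace$mesh
  lab <- if (is.character(label)) surface_labels[[label]] else label
  sel <- which(mesh$facet_label == lab)
  fac <- mesh$facets[sel, , drop = FALSE]
  if (!nrow(fac)) stop("no facets with label ", label)
  nv <- nrow(mesh$nodes)
  ed <- vspace$edges
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  edge_dof <- function(a, b) nv + match(paste(pmin(a, b), pmax(a, b)), key)
  fconn <- cbind(fac,
                 edge_dof(fac[, 1], fac[, 2]),
                 edge_dof(fac[, 1], fac[, 3]),
                 edge_dof(fac[, 2], fac[, 3]))
  if (anyNA(fconn)) stop("surface facet references a missing edge node")
  fcoords <- matrix(0, nrow(fconn), 18)
  for (a in 1:6)
    fcoords[, 3 * (a - 1) + 1:3] <- vspace$dof_coords[fconn[, a], ]
  list(conn = fconn, coords = fcoords, facets = fac)
}

#' Solve the finite-strain incompressible poroelastic solid
#'
#' Newton solution of the equilibrium `div(F S) = 0` subject to the volume
#' constraint `J = 1 + sum_i m_i / rho_f` (enforced weakly by a P1 Lagrange
#' multiplier field), with the fluid mass increase fields frozen. Cavity
#' pressure acts as a follower load on the `ENDO` surface. On Newton failure
#' the cavity-pressure increment is bisected recursively (load stepping).
#'
#' @param mesh an [fe_mesh()].
#' @param vspace P2 vector [field_space()] for the displacement.
#' @param m nodes x compartments matrix of fluid mass increases (g/mm^3),
#'   P1 nodal values.
#' @param params a [constitutive_params()].
#' @param bcs a [solid_bcs()].
#' @param cavity_pressure follower pressure on `ENDO` (kPa).
#' @param endo_label surface carrying the pressure load.
#' @param y0,lambda0 initial guesses (default zero).
#' @param p_prev cavity pressure at which `y0` equilibrates (for load
#'   stepping).
#' @param tol Newton tolerance on the max-norm residual.
#' @param max_iter Newton iterations per load level.
#' @param quadrature_degree volume rule degree for the nonlinear terms.
#' @param jac_quadrature_degree (lower) rule degree used when assembling the
#'   finite-difference tangent; the Newton residual always uses the full
#'   rule, so this only affects the iteration path, not the solution.
#' @param max_bisect maximum load-step bisection depth.
#' @return list with `y`, `lambda`, `converged`, `newton`, and
#'   `constraint_residual` (nodal P1-weighted residual of the volume
#'   constraint, max norm).
#' @export
solve_solid <- function(mesh, vspace, m, params, bcs,
                        cavity_pressure = 0, endo_label = "ENDO",
                        y0 = NULL, lambda0 = NULL, p_prev = 0,
                        tol = 1e-9, max_iter = 30, quadrature_degree = 5,
                        jac_quadrature_degree = 3, max_bisect = 5) {
  n2 <- vspace$n_dof
  nv <- nrow(mesh$nodes)
  if (is.null(y0)) y0 <- matrix(0, n2, 3)
  if (is.null(lambda0)) lambda0 <- numeric(nv)
  if (is.vector(m)) m <- matrix(m, nv, params$n_compartments)
  qr <- tet_quadrature(quadrature_degree)
  qrj <- tet_quadrature(jac_quadrature_degree)
  tq <- tri_quadrature(quadrature_degree)
  endo <- if (abs(cavity_pressure) > 0 || TRUE)
    tryCatch(surface_p2_facets(vspace, endo_label), error = function(e) NULL)
  free <- setdiff(seq_len(3 * n2 + nv), bcs$fixed)
  pk <- unclass(params)

  assemble <- function(x, p_cav, want_jac) {
    y <- matrix(0, n2, 3)
    lam <- numeric(nv)
    full <- numeric(3 * n2 + nv)
    full[free] <- x
    y[] <- t(matrix(full[seq_len(3 * n2)], 3))
    lam <- full[3 * n2 + seq_len(nv)]
    qa <- if (want_jac) qrj else qr
    out <- cpp_assemble_solid(mesh$nodes, mesh$elems, vspace$conn, y, lam,
                              m, pk, qa$bary, qa$weights, want_jac)
    res <- out$res
    tri <- if (want_jac) cbind(out$i, out$j, out$x) else NULL
    if (!is.null(endo) && p_cav != 0) {
      fo <- cpp_assemble_follower(endo$coords, endo$conn, y, p_cav,
                                  tq$xi, tq$weights, want_jac, 3 * n2)
      res[seq_len(3 * n2)] <- res[seq_len(3 * n2)] + fo$res
      if (want_jac && length(fo$i))
        tri <- rbind(tri, cbind(fo$i, fo$j, fo$x))
    }
    list(res = res, tri = tri)
  }

  solve_at <- function(p_cav, x_init) {
    rfun <- function(x) assemble(x, p_cav, FALSE)$res[free]
    jfun <- function(x) {
      a <- assemble(x, p_cav, TRUE)
      J <- Matrix::sparseMatrix(i = a$tri[, 1], j = a$tri[, 2],
                                x = a$tri[, 3],
                                dims = rep(3 * n2 + nv, 2))
      J[free, free]
    }
    solve_newton(rfun, jfun, x_init, tol = tol, max_iter = max_iter,
                 reuse_jacobian = TRUE)
  }

  ramp <- function(p_from, p_to, x_init, depth) {
    ns <- solve_at(p_to, x_init)
    if (ns$converged) return(ns)
    if (depth >= max_bisect)
      stop("Newton divergence in solid solve at cavity pressure ",
           format(p_to), " kPa; consider smaller load steps")
    mid <- (p_from + p_to) / 2
    ns_mid <- ramp(p_from, mid, x_init, depth + 1)
    ramp(mid, p_to, ns_mid$x, depth + 1)
  }

  x0 <- c(as.vector(t(y0)), lambda0)[free]
  ns <- ramp(p_prev, cavity_pressure, x0, 0)
  full <- numeric(3 * n2 + nv)
  full[free] <- ns$x
  y <- t(matrix(full[seq_len(3 * n2)], 3))
  lam <- full[3 * n2 + seq_len(nv)]
  # nodal constraint residual: lambda-block of the full residual, scaled by
  # the P1 lumped volume
  res_full <- assemble(ns$x, cavity_pressure, FALSE)$res
  lumped <- p1_lumped_volume(mesh)
  cres <- max(abs(res_full[3 * n2 + seq_len(nv)]) / lumped)
  list(y = y, lambda = lam, converged = ns$converged, newton = ns,
       constraint_residual = cres)
}

# lumped P1 volume weights: integral of each vertex basis function
p1_lumped_volume <- function(mesh) {
  accumulate_at(rep(mesh$volumes / 4, 4), as.vector(mesh$elems),
                nrow(mesh$nodes))
}

#' Cavity volume enclosed by a deformed surface
#'
#' Divergence-theorem volume of the cavity bounded by the (deformed) `ENDO`
#' surface, closed by fanning each open boundary loop to its centroid.
#' Quadratic facets are split into four linear sub-triangles through their
#' midside nodes, so the result is exact for the polyhedral deformed
#' surface.
#'
#' @param mesh an [fe_mesh()].
#' @param vspace P2 vector [field_space()]; may be `NULL` together with `y`
#'   for the undeformed P1 surface.
#' @param y displacement (n_dof x 3) or `NULL` for the reference state.
#' @param label surface label (default `"ENDO"`).
#' @return cavity volume in mm^3.
#' @export
cavity_volume <- function(mesh, vspace = NULL, y = NULL, label = "ENDO") {
  if (is.null(vspace)) {
    lab <- if (is.character(label)) surface_labels[[label]] else label
    fac <- mesh$facets[mesh$facet_label == lab, , drop = FALSE]
    if (!nrow(fac)) stop("no facets with label ", label)
    pts <- mesh$nodes
    tris <- fac
  } else {
    sf <- surface_p2_facets(vspace, label)
    pts <- vspace$dof_coords + if (is.null(y)) 0 else y
    f <- sf$conn
    tris <- rbind(f[, c(1, 4, 5)], f[, c(2, 6, 4)],
                  f[, c(3, 5, 6)], f[, c(4, 6, 5)])
    fac <- sf$facets
  }
  # boundary loops of the patch (coarse facet edges used once)
  ed <- rbind(fac[, c(1, 2)], fac[, c(2, 3)], fac[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  once <- key %in% names(which(table(key) == 1))
  bed <- ed[once, , drop = FALSE]
  cap_tris <- NULL
  cap_pts <- NULL
  if (nrow(bed)) {
    # split directed boundary edges into connected loops
    remaining <- seq_len(nrow(bed))
    while (length(remaining)) {
      loop <- bed[remaining[1], ]
      remaining <- remaining[-1]
      verts <- loop
      repeat {
        nxt <- which(bed[remaining, 1] == verts[length(verts)])
        if (!length(nxt)) break
        verts <- c(verts, bed[remaining[nxt[1]], 2])
        remaining <- remaining[-nxt[1]]
      }
      if (verts[1] != verts[length(verts)])
        stop("open (non-closable) surface patch: boundary loop does not close")
      verts <- verts[-length(verts)]
      cen <- colMeans(pts[verts, , drop = FALSE])
      cid <- nrow(pts) + length(cap_pts) / 3 + 1
      cap_pts <- c(cap_pts, cen)
      vn <- c(verts, verts[1])
      for (k in seq_along(verts)) {
        a <- vn[k]; b <- vn[k + 1]
        if (!is.null(vspace)) {
          # include the midside node of the boundary edge for P2 accuracy
          mid <- surface_edge_mid(vspace, a, b)
          cap_tris <- rbind(cap_tris, c(cid, b, mid), c(cid, mid, a))
        } else cap_tris <- rbind(cap_tris, c(cid, b, a))
      }
    }
  }
  allpts <- rbind(pts, matrix(cap_pts, ncol = 3, byrow = TRUE))
  alltris <- rbind(tris, cap_tris)
  v <- 0
  for (t in seq_len(nrow(alltris))) {
    x1 <- allpts[alltris[t, 1], ]; x2 <- allpts[alltris[t, 2], ]
    x3 <- allpts[alltris[t, 3], ]
    v <- v + det(rbind(x1, x2, x3)) / 6
  }
  abs(v)
}

surface_edge_mid <- function(vspace, a, b) {
  ed <- vspace$edges
  nv <- nrow(vspace$mesh$nodes)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  nv + match(paste(min(a, b), max(a, b)), key)
}
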