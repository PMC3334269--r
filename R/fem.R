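#' Finite-element interpolation space on a tetrahedral mesh
#'
#' Lagrange space of order 1 (vertex nodes) or 2 (vertex + edge-midpoint
#' nodes). Degrees of freedom are enumerated deterministically: vertices in
#' mesh node order, then edges in lexicographic order of their sorted vertex
#' pair. For order 2 the element connectivity lists the 4 vertices followed
#' by the 6 edge nodes in local edge order (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).
#'
#' @param mesh an [fe_mesh()].
#' @param order 1 or 2.
#' @param rank `"scalar"` or `"vector"` (3 components).
#' @return object of class `field_space` with `conn` (element-to-dof),
#'   `dof_coords`, `n_dof` (scalar dof count), `n_comp`.
#' @export
field_space <- function(mesh, order = 1, rank = c("scalar", "vector")) {
  rank <- match.arg(rank)
  stopifnot(order %in% c(1L, 2L))
  nv <- nrow(mesh$nodes)
  edges <- NULL
  if (order == 1L) {
    conn <- mesh$elems
    coords <- mesh$nodes
  } else {
    ed <- mesh_edges(mesh)
    edges <- ed$edges
    conn <- cbind(mesh$elems, nv + ed$elem_edge)
    coords <- rbind(mesh$nodes,
                    (mesh$nodes[ed$edges[, 1], , drop = FALSE] +
                     mesh$nodes[ed$edges[, 2], , drop = FALSE]) / 2)
  }
  structure(list(mesh = mesh, order = as.integer(order), rank = rank,
                 conn = conn, dof_coords = coords, n_dof = nrow(coords),
                 n_comp = if (rank == "vector") 3L else 1L, edges = edges),
            class = "field_space")
}

#' @export
print.field_space <- function(x, ...) {
  cat("field_space: order", x$order, x$rank, "-", x$n_dof, "nodes x",
      x$n_comp, "component(s)\n")
  invisible(x)
}

# Unique mesh edges and the per-element edge-node map (m x 6), local edge
# order (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).
mesh_edges <- function(mesh) {
  le <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  m <- nrow(mesh$elems)
  ea <- mesh$elems[, le[, 1]]  # m x 6
  eb <- mesh$elems[, le[, 2]]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  uk <- sort(unique(key))
  id <- match(key, uk)
  first <- match(uk, key)
  edges <- cbind(lo[first], hi[first])
  list(edges = edges, elem_edge = matrix(id, nrow = m))
}

# Barycentric gradients and 6*volume for all elements.
# Returns list(grads = m x 4 x 3 array, vol = volumes)
barycentric_gradients <- function(mesh) {
  m <- nrow(mesh$elems)
  grads <- array(0, c(m, 4, 3))
  for (e in seq_len(m)) {
    A <- cbind(1, mesh$nodes[mesh$elems[e, ], , drop = FALSE])
    Ci <- solve(A)
    grads[e, , ] <- t(Ci[2:4, ])
  }
  list(grads = grads, vol = mesh$volumes)
}

# Shape function values at barycentric points. bary: q x 4. Returns q x nb.
basis_values <- function(order, bary) {
  if (order == 1L) return(bary)
  L <- bary
  le <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  cbind(L * (2 * L - 1),
        do.call(cbind, lapply(seq_len(6), function(k)
          4 * L[, le[k, 1]] * L[, le[k, 2]])))
}

# dN/dL at barycentric points: list over q of nb x 4 matrices.
basis_dL <- function(order, bary) {
  q <- nrow(bary)
  if (order == 1L) return(lapply(seq_len(q), function(i) diag(4)))
  le <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lapply(seq_len(q), function(i) {
    L <- bary[i, ]
    D <- matrix(0, 10, 4)
    for (a in 1:4) D[a, a] <- 4 * L[a] - 1
    for (k in 1:6) {
      D[4 + k, le[k, 1]] <- 4 * L[le[k, 2]]
      D[4 + k, le[k, 2]] <- 4 * L[le[k, 1]]
    }
    D
  })
}

#' Integrate a scalar field over the mesh
#'
#' Quadrature-exact integration of a nodal field on a `field_space`, with an
#' optional region filter. Exact to machine precision for polynomial fields
#' within the rule degree.
#'
#' @param space a scalar [field_space()].
#' @param values numeric vector of nodal values (length `n_dof`), or a single
#'   number for a constant field.
#' @param region optional integer vector of region labels to include.
#' @param degree quadrature degree.
#' @return the integral (field units times mm^3).
#' @export
integrate_scalar <- function(space, values, region = NULL, degree = 4) {
  mesh <- space$mesh
  if (length(values) == 1L) values <- rep(values, space$n_dof)
  if (length(values) != space$n_dof)
    stop("field length does not match the interpolation space")
  sel <- if (is.null(region)) seq_len(nrow(mesh$elems)) else
    which(mesh$region %in% region)
  qr <- tet_quadrature(degree)
  N <- basis_values(space$order, qr$bary)      # q x nb
  vals <- matrix(values[space$conn[sel, , drop = FALSE]], nrow = length(sel))
  fq <- vals %*% t(N)                          # nsel x q
  sum((fq %*% qr$weights) * 6 * mesh$volumes[sel])
}

#' Damped Newton solver for nonlinear systems
#'
#' Standard Newton iteration with a backtracking (halving) line search on the
#' residual norm. The Jacobian may be dense or any `Matrix` class.
#'
#' @param residual_fn function(x) -> numeric residual vector.
#' @param jacobian_fn function(x) -> square Jacobian (dense or sparse).
#' @param x0 initial guess.
#' @param tol convergence tolerance on `max(abs(residual))`.
#' @param max_iter maximum Newton iterations.
#' @param min_damping smallest line-search step fraction before declaring
#'   failure of the search.
#' @param quiet suppress per-iteration diagnostics.
#' @param reuse_jacobian reuse the factorised Jacobian across iterations
#'   (modified Newton), refreshing it whenever progress stalls or the line
#'   search fails; pays off when factorisation dominates the iteration cost.
#' @return list with `x`, `converged`, `iterations`, `residual_norm`,
#'   `history` (residual norms per iteration).
#' @export
solve_newton <- function(residual_fn, jacobian_fn, x0, tol = 1e-10,
                         max_iter = 30, min_damping = 2^-12, quiet = TRUE,
                         reuse_jacobian = FALSE) {
  x <- x0
  r <- residual_fn(x)
  rn <- max(abs(r))
  hist <- rn
  fact <- NULL
  factorise <- function(x) {
    J <- jacobian_fn(x)
    tryCatch(
      if (methods::is(J, "sparseMatrix")) Matrix::lu(J) else J,
      error = function(e)
        stop("singular Jacobian in Newton solve (", conditionMessage(e), ")",
             call. = FALSE))
  }
  for (it in seq_len(max_iter)) {
    if (rn < tol)
      return(list(x = x, converged = TRUE, iterations = it - 1L,
                  residual_norm = rn, history = hist))
    fresh <- FALSE
    if (is.null(fact)) {
      fact <- factorise(x)
      fresh <- TRUE
    }
    dx <- tryCatch(as.numeric(Matrix::solve(fact, -r)),
                   error = function(e)
                     stop("singular Jacobian in Newton solve (",
                          conditionMessage(e), ")", call. = FALSE))
    alpha <- 1
    ok <- FALSE
    repeat {
      xt <- x + alpha * dx
      rt <- tryCatch(residual_fn(xt), error = function(e) NULL)
      if (!is.null(rt) && all(is.finite(rt)) &&
          max(abs(rt)) < (1 - 1e-4 * alpha) * rn) { ok <- TRUE; break }
      # accept a non-decreasing full step only when already near roundoff
      if (!is.null(rt) && all(is.finite(rt)) && alpha == 1 && rn < 1e3 * tol &&
          max(abs(rt)) <= rn * (1 + 1e-8)) { ok <- TRUE; break }
      alpha <- alpha / 2
      if (alpha < min_damping) break
    }
    if (!ok) {
      if (!fresh && reuse_jacobian) { fact <- NULL; next }  # retry, fresh J
      return(list(x = x, converged = FALSE, iterations = it,
                  residual_norm = rn, history = hist,
                  reason = "line search failed"))
    }
    ratio <- max(abs(rt)) / rn
    x <- xt; r <- rt; rn <- max(abs(r)); hist <- c(hist, rn)
    if (!quiet) message(sprintf("newton it %d  |r|=%.3e  alpha=%.3g",
                                it, rn, alpha))
    if (!reuse_jacobian || ratio > 0.2 || alpha < 1) fact <- NULL
  }
  list(x = x, converged = rn < tol, iterations = max_iter,
       residual_norm = rn, history = hist)
}
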