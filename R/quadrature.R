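#' Gauss--Legendre rule on [0, 1]
#'
#' Nodes and weights integrating polynomials of degree `2n - 1` exactly on
#' the unit interval.
#'
#' @param n number of points.
#' @return list with `nodes` and `weights`, each length `n`.
#' @keywords internal
gauss_legendre_01 <- function(n) {
  gj <- gauss_jacobi_m11(n, alpha = 0, beta = 0)
  list(nodes = (gj$nodes + 1) / 2, weights = gj$weights / 2)
}

#' Gauss--Jacobi rule on [-1, 1] with weight (1-x)^alpha (1+x)^beta
#'
#' Golub--Welsch construction from the three-term recurrence of the Jacobi
#' polynomials; used to build conical-product rules on simplices.
#'
#' @param n number of points.
#' @param alpha,beta weight exponents (> -1).
#' @keywords internal
gauss_jacobi_m11 <- function(n, alpha, beta) {
  stopifnot(n >= 1, alpha > -1, beta > -1)
  ab <- alpha + beta
  k <- seq_len(n) - 1
  # recurrence coefficients of the monic Jacobi polynomials
  a <- ifelse(2 * k + ab == 0 | 2 * k + ab + 2 == 0, 0,
              (beta^2 - alpha^2) / ((2 * k + ab) * (2 * k + ab + 2)))
  if (n >= 2) {
    j <- seq.int(1, n - 1)
    b1 <- ifelse(j == 1 & ab == -1,  # guarded; not hit for alpha,beta >= 0
                 0, 4 * j * (j + alpha) * (j + beta) * (j + ab) /
                   ((2 * j + ab)^2 * (2 * j + ab + 1) * (2 * j + ab - 1)))
    offd <- sqrt(b1)
  } else offd <- numeric(0)
  J <- diag(a, n, n)
  if (n >= 2) {
    J[cbind(1:(n - 1), 2:n)] <- offd
    J[cbind(2:n, 1:(n - 1))] <- offd
  }
  e <- eigen(J, symmetric = TRUE)
  mu0 <- 2^(ab + 1) * beta(alpha + 1, beta + 1)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (mu0 * e$vectors[1, ]^2)[ord])
}

#' Gauss--Jacobi rule on [0, 1] with weight (1-t)^alpha
#' @keywords internal
gauss_jacobi_01 <- function(n, alpha) {
  gj <- gauss_jacobi_m11(n, alpha = alpha, beta = 0)
  list(nodes = (gj$nodes + 1) / 2, weights = gj$weights / 2^(alpha + 1))
}

#' Quadrature rule on the reference tetrahedron
#'
#' Conical-product (Duffy) rule built from one-dimensional Gauss--Jacobi
#' rules. A rule of declared `degree` integrates all polynomials of total
#' degree `<= degree` exactly; weights sum to the reference volume 1/6.
#'
#' @param degree polynomial degree of exactness (>= 1).
#' @return list with `bary` (n x 4 barycentric coordinates) and `weights`.
#' @export
tet_quadrature <- function(degree = 4) {
  n <- ceiling((degree + 1) / 2)
  g2 <- gauss_jacobi_01(n, 2)
  g1 <- gauss_jacobi_01(n, 1)
  g0 <- gauss_legendre_01(n)
  grid <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  t1 <- g2$nodes[grid$i]; t2 <- g1$nodes[grid$j]; t3 <- g0$nodes[grid$k]
  x <- t1
  y <- t2 * (1 - t1)
  z <- t3 * (1 - t1) * (1 - t2)
  w <- g2$weights[grid$i] * g1$weights[grid$j] * g0$weights[grid$k]
  bary <- cbind(1 - x - y - z, x, y, z)
  structure(list(bary = bary, weights = w, degree = 2 * n - 1),
            class = "tet_quadrature")
}

#' Quadrature rule on the reference triangle
#'
#' Conical-product rule on the unit triangle (area 1/2).
#'
#' @param degree polynomial degree of exactness.
#' @return list with `bary` (n x 3), `xi` (n x 2 reference coordinates)
#'   and `weights`.
#' @export
tri_quadrature <- function(degree = 4) {
  n <- ceiling((degree + 1) / 2)
  g1 <- gauss_jacobi_01(n, 1)
  g0 <- gauss_legendre_01(n)
  grid <- expand.grid(i = 1:n, j = 1:n)
  xi <- g1$nodes[grid$i]
  eta <- g0$nodes[grid$j] * (1 - xi)
  w <- g1$weights[grid$i] * g0$weights[grid$j]
  structure(list(bary = cbind(1 - xi - eta, xi, eta),
                 xi = cbind(xi, eta), weights = w, degree = 2 * n - 1),
            class = "tri_quadrature")
}
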