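test_that("simplex quadrature rules integrate monomials exactly", {
  # closed form on the reference tet: int x^a y^b z^c (1-x-y-z)^d
  #   = a! b! c! d! / (a+b+c+d+3)!
  tet_mono <- function(a, b, c, d = 0)
    prod(factorial(c(a, b, c, d))) / factorial(a + b + c + d + 3)
  for (deg in c(1, 3, 5)) {
    q <- tet_quadrature(deg)
    expect_equal(sum(q$weights), 1 / 6, tolerance = 1e-14)
    for (ex in list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0),
                    c(2, 2, 1), c(3, 1, 1))) {
      if (sum(ex) > deg) next
      val <- sum(q$weights * q$bary[, 2]^ex[1] * q$bary[, 3]^ex[2] *
                   q$bary[, 4]^ex[3])
      expect_equal(val, tet_mono(ex[1], ex[2], ex[3]), tolerance = 1e-13,
                   label = paste("tet monomial", paste(ex, collapse = "")))
    }
  }
  q <- tri_quadrature(4)
  expect_equal(sum(q$weights), 1 / 2, tolerance = 1e-14)
  # int over unit triangle of x^2 y = 2! 1! / (2+1+2)! = 1/60
  expect_equal(sum(q$weights * q$xi[, 1]^2 * q$xi[, 2]), 1 / 60,
               tolerance = 1e-14)
})

test_that("integrate_scalar matches closed forms and a per-element oracle", {
  mesh <- unit_cube_mesh(2)
  s1 <- field_space(mesh, 1)
  expect_equal(integrate_scalar(s1, 1), 1, tolerance = 1e-13)
  expect_equal(integrate_scalar(s1, mesh$nodes[, 1]), 0.5, tolerance = 1e-13)
  set.seed(7)
  v <- rnorm(s1$n_dof)
  expect_equal(integrate_scalar(s1, v), p1_exact_integral(mesh, v),
               tolerance = 1e-12)
  # P2 space reproduces quadratics exactly
  s2 <- field_space(mesh, 2)
  f <- s2$dof_coords[, 1]^2 + s2$dof_coords[, 2] * s2$dof_coords[, 3]
  expect_equal(integrate_scalar(s2, f), 1 / 3 + 1 / 4, tolerance = 1e-13)
  expect_error(integrate_scalar(s1, v[-1]), "does not match")
})

test_that("element volumes sum to the integral of one", {
  mesh <- build_annulus_mesh(8, 12, 5, n_r = 1, n_theta = 8, n_z = 1)
  s1 <- field_space(mesh, 1)
  expect_equal(sum(mesh$volumes), integrate_scalar(s1, 1), tolerance = 1e-12)
})

test_that("assembly is deterministic", {
  mesh <- tiny_annulus()
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 1)
  q <- tet_quadrature(3)
  set.seed(11)
  y <- matrix(rnorm(vs$n_dof * 3, 0, 0.01), ncol = 3)
  lam <- rnorm(nrow(mesh$nodes), 0, 0.1)
  m <- matrix(0, nrow(mesh$nodes), 1)
  a1 <- poroperf:::cpp_assemble_solid(mesh$nodes, mesh$elems, vs$conn, y,
                                      lam, m, unclass(par), q$bary,
                                      q$weights, TRUE)
  a2 <- poroperf:::cpp_assemble_solid(mesh$nodes, mesh$elems, vs$conn, y,
                                      lam, m, unclass(par), q$bary,
                                      q$weights, TRUE)
  expect_identical(a1$res, a2$res)
  expect_identical(a1$x, a2$x)
})

test_that("damped Newton solves scalar and linear problems", {
  ns <- solve_newton(function(x) x^2 - 4, function(x) matrix(2 * x), 3,
                     tol = 1e-12)
  expect_true(ns$converged)
  expect_equal(ns$x, 2, tolerance = 1e-10)
  # linear system converges in one iteration
  A <- matrix(c(2, 1, 0, 3), 2)
  b <- c(1, 2)
  ns2 <- solve_newton(function(x) as.numeric(A %*% x - b), function(x) A,
                      c(0, 0), tol = 1e-12)
  expect_true(ns2$converged)
  expect_lte(ns2$iterations, 2)
  expect_equal(ns2$x, solve(A, b), tolerance = 1e-12)
})

test_that("poromechanics element Jacobian is consistent with the residual", {
  mesh <- build_box_mesh(c(1, 1, 1), c(1, 1, 1))
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 2)
  set.seed(3)
  nv <- nrow(mesh$nodes)
  m <- matrix(runif(nv * 2, 0, 0.05) * par$rho_f, nv, 2)
  q <- tet_quadrature(3)
  n2 <- vs$n_dof
  pack <- function(y, lam) c(as.vector(t(y)), lam)
  resid <- function(x) {
    y <- t(matrix(x[seq_len(3 * n2)], 3))
    lam <- x[3 * n2 + seq_len(nv)]
    poroperf:::cpp_assemble_solid(mesh$nodes, mesh$elems, vs$conn, y, lam,
                                  m, unclass(par), q$bary, q$weights,
                                  FALSE)$res
  }
  y0 <- matrix(rnorm(n2 * 3, 0, 0.02), ncol = 3)
  l0 <- rnorm(nv, 0, 0.1)
  x0 <- pack(y0, l0)
  out <- poroperf:::cpp_assemble_solid(mesh$nodes, mesh$elems, vs$conn, y0,
                                       l0, m, unclass(par), q$bary,
                                       q$weights, TRUE)
  J <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                            dims = rep(3 * n2 + nv, 2))
  for (k in 1:4) {
    v <- rnorm(length(x0))
    h <- 1e-6
    fd <- (resid(x0 + h * v) - resid(x0 - h * v)) / (2 * h)
    jv <- as.numeric(J %*% v)
    expect_lt(max(abs(jv - fd)) / max(abs(jv)), 1e-5)
  }
})
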