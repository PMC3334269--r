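test_that("zero loads keep the reference configuration", {
  mesh <- unit_cube_mesh(1)
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 1)
  bcs <- solid_bcs(vs, list(list(label = "ZMIN")))
  sol <- solve_solid(mesh, vs, matrix(0, nrow(mesh$nodes), 1), par, bcs,
                     cavity_pressure = 0, endo_label = "XMIN")
  expect_true(sol$converged)
  expect_lt(max(abs(sol$y)), 1e-10)
  expect_lt(max(abs(sol$lambda)), 1e-10)
})

test_that("uniform fluid mass forces a pure dilation through the constraint", {
  mesh <- unit_cube_mesh(2)
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 1)
  nd <- mesh$nodes
  # 3-2-1 pinning compatible with dilation about the origin corner
  n0 <- which(rowSums(abs(nd)) < 1e-12)
  nx <- which(abs(nd[, 1] - 1) < 1e-12 & nd[, 2] == 0 & nd[, 3] == 0)
  ny <- which(abs(nd[, 2] - 1) < 1e-12 & nd[, 1] == 0 & nd[, 3] == 0)
  pin <- c(3 * (n0 - 1) + 1:3, 3 * (nx - 1) + 2:3, 3 * (ny - 1) + 3)
  bcs <- solid_bcs(vs, fixed_surfaces = list(), pinned_dofs = pin)
  mval <- 0.06 * par$rho_f
  sol <- solve_solid(mesh, vs, matrix(mval, nrow(nd), 1), par, bcs)
  expect_true(sol$converged)
  kin <- poroperf:::element_kinematics(mesh, vs, sol$y)
  expect_equal(range(kin$J), rep(1.06, 2), tolerance = 1e-9)
  expect_equal(wall_volume(mesh, vs, sol$y), 1.06, tolerance = 1e-9)
  expect_lt(sol$constraint_residual, 1e-7)
})

test_that("cavity volume increases monotonically with cavity pressure", {
  mesh <- tiny_annulus()
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 1)
  bcs <- solid_bcs(vs, list(list(label = "BASE")))
  m <- matrix(0, nrow(mesh$nodes), 1)
  vols <- numeric(3)
  sol <- NULL
  ps <- c(0.2, 0.4, 0.6)
  for (k in seq_along(ps)) {
    sol <- solve_solid(mesh, vs, m, par, bcs, cavity_pressure = ps[k],
                       y0 = sol$y, lambda0 = sol$lambda,
                       p_prev = if (k == 1) 0 else ps[k - 1])
    expect_true(sol$converged)
    vols[k] <- cavity_volume(mesh, vs, sol$y)
  }
  expect_gt(vols[1], cavity_volume(mesh, vs, NULL))
  expect_true(all(diff(vols) > 0))
})

test_that("superposed rigid rotation leaves the energy invariant", {
  mesh <- unit_cube_mesh(1)
  vs <- field_space(mesh, 2, "vector")
  par <- constitutive_params(n_compartments = 1)
  set.seed(14)
  y <- matrix(rnorm(vs$n_dof * 3, 0, 0.03), ncol = 3)
  m <- matrix(runif(nrow(mesh$nodes), 0, 0.05) * par$rho_f)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  x_def <- vs$dof_coords + y
  y_rot <- x_def %*% t(R) - vs$dof_coords
  energy <- function(yv) {
    kin <- poroperf:::element_kinematics(mesh, vs, yv)
    sum(vapply(seq_len(nrow(mesh$elems)), function(e)
      strain_energy(matrix(kin$F[e, ], 3),
                    mean(m[mesh$elems[e, ], 1]), par) * mesh$volumes[e],
      numeric(1)))
  }
  expect_equal(energy(y_rot), energy(y), tolerance = 1e-9)
})

test_that("cavity volume closed forms hold for hemisphere and maps", {
  # inner hemisphere of an equator-truncated spherical shell
  mesh <- build_ellipsoid_shell_mesh(rep(6, 3), rep(9, 3), 0,
                                     n_u = 1, n_phi = 10, n_theta = 16)
  vs <- field_space(mesh, 2, "vector")
  v0 <- cavity_volume(mesh, vs, NULL)
  expect_lt(abs(v0 - 2 / 3 * pi * 6^3) / (2 / 3 * pi * 6^3), 0.06)
  # rigid translation leaves the volume unchanged
  ytr <- matrix(rep(c(1.3, -0.4, 2.2), each = vs$n_dof), ncol = 3)
  expect_equal(cavity_volume(mesh, vs, ytr), v0, tolerance = 1e-9)
  # uniform scaling of deformed coordinates scales the volume by alpha^3
  alpha <- 1.17
  ysc <- vs$dof_coords * (alpha - 1)
  expect_equal(cavity_volume(mesh, vs, ysc), alpha^3 * v0,
               tolerance = 1e-9)
})
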