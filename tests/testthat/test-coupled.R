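tiny_coupled_setup <- function(n_comp = 2) {
  mesh <- tiny_annulus()
  vspace <- field_space(mesh, 2, "vector")
  params <- constitutive_params(n_compartments = n_comp)
  model <- poroperf:::uniform_compartment_model(mesh, n_comp, 0.1, 1e-4,
                                                rho_f = params$rho_f)
  bcs <- solid_bcs(vspace, list(list(label = "BASE")))
  list(mesh = mesh, vspace = vspace, params = params, model = model,
       bcs = bcs)
}

test_that("the rest state is a fixed point of the coupled step", {
  s <- tiny_coupled_setup()
  prob <- darcy_problem(s$mesh, s$model, sources = list(0, 0),
                        rho_f = s$params$rho_f)
  st0 <- poroelastic_state(s$vspace, 2)
  st1 <- coupled_step(s$mesh, s$vspace, prob, s$params, st0, dt = 0.2,
                      cavity_pressure = 0, bcs = s$bcs,
                      cavity_pressure_prev = 0)
  expect_lt(max(abs(st1$y)), 1e-10)
  expect_lt(max(abs(st1$m)), 1e-12)
  expect_equal(st1$time, 0.2)
})

test_that("converged steps satisfy the volume constraint consistently", {
  s <- tiny_coupled_setup()
  prob <- darcy_problem(s$mesh, s$model, sources = list(0.05, 0),
                        rho_f = s$params$rho_f)
  st <- poroelastic_state(s$vspace, 2)
  sp1 <- field_space(s$mesh, 1, "scalar")
  for (k in 1:2) {
    st <- coupled_step(s$mesh, s$vspace, prob, s$params, st, dt = 0.25,
                       cavity_pressure = 0.2 * k, bcs = s$bcs,
                       cavity_pressure_prev = 0.2 * (k - 1))
    # integral identity of the weak constraint: int (J - 1) = int sum m/rho
    intJ <- wall_volume(s$mesh, s$vspace, st$y) - mesh_volume(s$mesh)
    intm <- sum(vapply(1:2, function(ci)
      integrate_scalar(sp1, st$m[, ci]), numeric(1))) / s$params$rho_f
    expect_lt(abs(intJ - intm) / abs(intm), 1e-8)
    expect_lt(st$diagnostics$constraint_residual, 1e-6)
  }
  # flow vectors are recovered at convergence
  expect_length(st$flux, 2)
  expect_true(all(is.finite(st$flux[[1]]$nodal)))
})

test_that("global fluid mass tracks the integrated source", {
  s <- tiny_coupled_setup()
  q <- 0.04
  prob <- darcy_problem(s$mesh, s$model, sources = list(q, 0),
                        rho_f = s$params$rho_f)
  st <- poroelastic_state(s$vspace, 2)
  sp1 <- field_space(s$mesh, 1, "scalar")
  dt <- 0.25
  for (k in 1:2)
    st <- coupled_step(s$mesh, s$vspace, prob, s$params, st, dt,
                       cavity_pressure = 0, bcs = s$bcs,
                       cavity_pressure_prev = 0)
  total <- sum(vapply(1:2, function(ci)
    integrate_scalar(sp1, st$m[, ci]), numeric(1)))
  expected <- s$params$rho_f * q * mesh_volume(s$mesh) * 2 * dt
  expect_lt(abs(total - expected) / expected, 1e-7)
})

test_that("the result is stable under more generous sub-iteration budgets", {
  s <- tiny_coupled_setup()
  prob <- darcy_problem(s$mesh, s$model, sources = list(0.05, 0),
                        rho_f = s$params$rho_f)
  st0 <- poroelastic_state(s$vspace, 2)
  a <- coupled_step(s$mesh, s$vspace, prob, s$params, st0, dt = 0.25,
                    cavity_pressure = 0.3, bcs = s$bcs,
                    cavity_pressure_prev = 0, max_subiters = 25)
  b <- coupled_step(s$mesh, s$vspace, prob, s$params, st0, dt = 0.25,
                    cavity_pressure = 0.3, bcs = s$bcs,
                    cavity_pressure_prev = 0, max_subiters = 50)
  expect_equal(a$y, b$y, tolerance = 1e-9)
  expect_equal(a$m, b$m, tolerance = 1e-9)
})

test_that("assembled exchange is mass-neutral for any pressure state", {
  s <- tiny_coupled_setup()
  prob <- darcy_problem(s$mesh, s$model, sources = list(0, 0),
                        rho_f = s$params$rho_f)
  sys <- poroperf:::darcy_system(prob)
  set.seed(31)
  # diffusion columns sum to zero and symmetric beta cancels in the total,
  # so the all-ones vector annihilates the operator from the left
  for (k in 1:5) {
    p <- rnorm(nrow(sys$A))
    expect_lt(abs(sum(sys$A %*% p)), 1e-10 * max(abs(sys$A %*% p), 1))
  }
})
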