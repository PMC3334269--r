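# Shared, lazily computed fixtures (the inflation run is the expensive one;
# it is computed once and reused by several acceptance checks).
.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

unit_cube_mesh <- function(n = 2) build_box_mesh(c(1, 1, 1), rep(n, 3))

# tiny annulus for coupled-solver unit tests
tiny_annulus <- function() with_fixture("tiny_annulus",
  build_annulus_mesh(10, 15, 10, n_r = 1, n_theta = 8, n_z = 1))

acceptance_inflation <- function() with_fixture("inflation",
  run_passive_inflation(inflation_protocol()))

acceptance_comparison <- function() with_fixture("comparison",
  run_network_comparison(comparison_config(seed = 1)))

# exact integral over one tet of a P1 field: volume times vertex mean
p1_exact_integral <- function(mesh, values) {
  sum(mesh$volumes * rowMeans(matrix(values[mesh$elems], nrow(mesh$elems))))
}

random_admissible_state <- function(n_comp, rho_f, magnitude = 0.15) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, magnitude), 3)
    if (det(F) > 0.3) break
  }
  list(F = F, m = runif(n_comp, 0, 0.1) * rho_f, lambda = rnorm(1, 0, 0.5))
}

# finite-difference d(Psi)/dE through Psi as a function of C = 2E + I
fd_dpsi_dE <- function(F, m, params, h = 1e-6) {
  psiC <- function(C) {
    ev <- eigen(C, symmetric = TRUE)
    Fh <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
    strain_energy(Fh, m, params)
  }
  C <- t(F) %*% F
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    Cp <- C; Cm <- C
    if (i == j) {
      Cp[i, i] <- Cp[i, i] + h; Cm[i, i] <- Cm[i, i] - h
    } else {
      Cp[i, j] <- Cp[i, j] + h; Cp[j, i] <- Cp[j, i] + h
      Cm[i, j] <- Cm[i, j] - h; Cm[j, i] <- Cm[j, i] - h
    }
    d <- (psiC(Cp) - psiC(Cm)) / (2 * h)
    S[i, j] <- d; S[j, i] <- d
  }
  diag(S) <- 2 * diag(S)  # S = dPsi/dE = 2 dPsi/dC on the diagonal
  S
}
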