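#' Passive-inflation protocol
#'
#' Configuration of the wall-stiffening experiment: a diastolic cavity
#' pressure ramp applied to an idealised ventricular wall, optionally with a
#' simultaneous linearly ramped distributed fluid source whose integrated
#' mass corresponds to a target overall wall-volume increase (the perfused
#' run). Defaults: coarse annulus wall, 0 to 1.5 kPa in 6 steps over 1 s,
#' 8 percent perfusion target, two fluid compartments with uniform
#' permeability and exchange.
#'
#' @param geometry list describing the wall; `type` is `"annulus"` (fields
#'   `r_inner`, `r_outer`, `height`, `n_r`, `n_theta`, `n_z`) or
#'   `"ellipsoid"` (`semi_axes_inner`, `semi_axes_outer`,
#'   `truncation_height`, `n_u`, `n_phi`, `n_theta`).
#' @param p_start,p_end cavity pressure ramp limits (kPa).
#' @param steps number of equal pressure/time steps (>= 1).
#' @param duration ramp duration (s).
#' @param target_fraction target relative wall-volume increase of the
#'   perfused run (0.08 = 8 percent); 0 disables the source.
#' @param n_compartments fluid compartments in the uniform continuum model.
#' @param permeability isotropic permeability of every compartment
#'   (mm^2 kPa^-1 s^-1).
#' @param beta12 uniform exchange coefficient between adjacent compartments
#'   (g mm^-3 kPa^-1 s^-1).
#' @param params a [constitutive_params()] (rebuilt with the protocol's
#'   compartment count when necessary).
#' @param tol_fixed_point fixed-point tolerance of the partitioned coupling.
#' @return list of class `inflation_protocol`.
#' @export
inflation_protocol <- function(geometry = list(type = "annulus",
                                               r_inner = 10, r_outer = 15,
                                               height = 20, n_r = 2,
                                               n_theta = 10, n_z = 2),
                               p_start = 0, p_end = 1.5, steps = 6,
                               duration = 1, target_fraction = 0.08,
                               n_compartments = 2, permeability = 0.1,
                               beta12 = 1e-4,
                               params = NULL, tol_fixed_point = 1e-6) {
  stopifnot(steps >= 1, target_fraction >= 0, duration > 0)
  if (is.null(params))
    params <- constitutive_params(n_compartments = n_compartments)
  stopifnot(params$n_compartments == n_compartments)
  structure(list(geometry = geometry, p_start = p_start, p_end = p_end,
                 steps = as.integer(steps), duration = duration,
                 target_fraction = target_fraction,
                 n_compartments = as.integer(n_compartments),
                 permeability = permeability, beta12 = beta12,
                 params = params, tol_fixed_point = tol_fixed_point),
            class = "inflation_protocol")
}

protocol_mesh <- function(geometry) {
  g <- geometry
  switch(g$type,
         annulus = build_annulus_mesh(g$r_inner, g$r_outer, g$height,
                                      g$n_r, g$n_theta, g$n_z),
         ellipsoid = build_ellipsoid_shell_mesh(g$semi_axes_inner,
                                                g$semi_axes_outer,
                                                g$truncation_height,
                                                g$n_u, g$n_phi, g$n_theta),
         stop("unknown geometry type: ", g$type))
}

# uniform isotropic compartment model on a single region
uniform_compartment_model <- function(mesh, n_comp, permeability, beta12,
                                      phi = NULL, rho_f = 1.05e-3,
                                      viscosity = 4e-6) {
  if (is.null(phi)) phi <- rep(0.05, n_comp)
  K <- array(0, c(1, n_comp, 3, 3))
  for (ci in seq_len(n_comp)) K[1, ci, , ] <- diag(3) * permeability
  beta <- array(0, c(1, n_comp, n_comp))
  if (n_comp >= 2)
    for (i in seq_len(n_comp - 1)) {
      beta[1, i, i + 1] <- beta12
      beta[1, i + 1, i] <- beta12
    }
  structure(list(n_compartments = n_comp, K = K, phi = matrix(phi, 1),
                 beta = beta,
                 partition = structure(list(
                   element_region = rep(1L, nrow(mesh$elems)),
                   region_subtree = 1L,
                   region_volumes = mesh_volume(mesh)),
                   class = "region_partition"),
                 viscosity = viscosity, rho_f = rho_f, coupling = "full"),
            class = "compartment_model")
}

#' Run the passive-inflation wall-stiffening experiment
#'
#' Inflates the wall over the cavity-pressure ramp twice -- unperfused
#' (no fluid source) and, when `target_fraction > 0`, perfused with a
#' linearly ramped uniform source into compartment 1 whose exact time
#' integral delivers `target_fraction * V_ref * rho_f` of fluid mass.
#' Reports the pressure--volume curve, instantaneous compliance `dV/dp`
#' (central differences, one-sided at the ends), wall volume, constraint
#' and mass-balance diagnostics per step.
#'
#' @param protocol an [inflation_protocol()].
#' @param verbose print per-step progress.
#' @return list of class `inflation_result` with `pv` (data.frame),
#'   `compliance` (data.frame), `states` (final states), `mesh`, `vspace`,
#'   `protocol`.
#' @export
run_passive_inflation <- function(protocol, verbose = FALSE) {
  mesh <- protocol_mesh(protocol$geometry)
  vspace <- field_space(mesh, 2, "vector")
  params <- protocol$params
  N <- protocol$n_compartments
  model <- uniform_compartment_model(mesh, N, protocol$permeability,
                                     protocol$beta12,
                                     rho_f = params$rho_f,
                                     viscosity = params$mu_f)
  bcs <- solid_bcs(vspace, list(list(label = "BASE")))
  V_ref <- mesh_volume(mesh)
  dt <- protocol$duration / protocol$steps
  p_ramp <- seq(protocol$p_start, protocol$p_end,
                length.out = protocol$steps + 1)
  times <- seq(0, protocol$duration, length.out = protocol$steps + 1)
  # linear source ramp: q(t) = q_max * t / T in compartment 1, with
  # integral q_max T / 2 = target_fraction
  q_max <- 2 * protocol$target_fraction / protocol$duration
  runs <- list(unperfused = 0)
  if (protocol$target_fraction > 0) runs <- c(runs, list(perfused = q_max))
  pv <- NULL
  states <- list()
  sp1 <- field_space(mesh, 1, "scalar")
  for (rn in names(runs)) {
    qm <- runs[[rn]]
    state <- poroelastic_state(vspace, N)
    cav0 <- cavity_volume(mesh, vspace, state$y)
    pv <- rbind(pv, data.frame(run = rn, step = 0, time = 0,
                               cavity_pressure = p_ramp[1],
                               cavity_volume = cav0, wall_volume = V_ref,
                               fluid_mass = 0, constraint_residual = 0,
                               exchange_net_mass = 0))
    for (k in seq_len(protocol$steps)) {
      # step-average of the linear ramp (exact integral over the step)
      q_avg <- qm * (times[k] + times[k + 1]) / 2
      sources <- c(list(q_avg), rep(list(0), N - 1))
      problem <- darcy_problem(mesh, model, sources = sources,
                               rho_f = params$rho_f)
      state <- coupled_step(mesh, vspace, problem, params, state, dt,
                            cavity_pressure = p_ramp[k + 1], bcs = bcs,
                            cavity_pressure_prev = p_ramp[k],
                            tol_fixed_point = protocol$tol_fixed_point)
      cav <- cavity_volume(mesh, vspace, state$y)
      wv <- wall_volume(mesh, vspace, state$y)
      fm <- sum(vapply(seq_len(N), function(ci)
        integrate_scalar(sp1, state$m[, ci]), numeric(1)))
      # net mass exchanged between compartments (zero by symmetry of beta)
      exch <- exchange_net_mass(mesh, model, state)
      if (verbose)
        message(sprintf("[%s] step %d: p=%.3f kPa  Vcav=%.1f  Vwall=%.1f",
                        rn, k, p_ramp[k + 1], cav, wv))
      pv <- rbind(pv, data.frame(run = rn, step = k, time = times[k + 1],
                                 cavity_pressure = p_ramp[k + 1],
                                 cavity_volume = cav, wall_volume = wv,
                                 fluid_mass = fm,
                                 constraint_residual =
                                   state$diagnostics$constraint_residual,
                                 exchange_net_mass = exch))
    }
    states[[rn]] <- state
  }
  compliance <- do.call(rbind, lapply(split(pv, pv$run), function(d) {
    d <- d[order(d$step), ]
    data.frame(run = d$run, cavity_pressure = d$cavity_pressure,
               compliance = central_diff(d$cavity_volume,
                                         d$cavity_pressure))
  }))
  rownames(compliance) <- NULL
  structure(list(pv = pv, compliance = compliance, states = states,
                 mesh = mesh, vspace = vspace, protocol = protocol,
                 V_ref = V_ref),
            class = "inflation_result")
}

# pointwise net exchange mass rate summed over compartments: exactly zero
# because beta is symmetric; evaluated from the state's nodal pressures
exchange_net_mass <- function(mesh, model, state) {
  if (is.null(state$p)) return(0)
  N <- ncol(state$p)
  er <- element_regions(mesh, model)
  net <- 0
  for (i in seq_len(N)) for (k in seq_len(N)) {
    if (i == k) next
    bik <- model$beta[cbind(er, i, k)]
    pm <- rowMeans(matrix(state$p[mesh$elems, i] - state$p[mesh$elems, k],
                          nrow(mesh$elems)))
    net <- net + sum(bik * pm * mesh$volumes)
  }
  net
}

central_diff <- function(v, p) {
  n <- length(v)
  if (n < 2) return(rep(NA_real_, n))
  out <- numeric(n)
  out[1] <- (v[2] - v[1]) / (p[2] - p[1])
  out[n] <- (v[n] - v[n - 1]) / (p[n] - p[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    out[i] <- (v[i + 1] - v[i - 1]) / (p[i + 1] - p[i - 1])
  }
  out
}

#' Relative wall-volume increase of an inflation run
#'
#' `100 * (integral of J over the wall / V_ref - 1)` at the final step.
#'
#' @param result an [run_passive_inflation()] result.
#' @param run `"perfused"` or `"unperfused"`.
#' @return percentage.
#' @export
wall_volume_increase <- function(result, run = "perfused") {
  d <- result$pv[result$pv$run == run, ]
  100 * (d$wall_volume[which.max(d$step)] / result$V_ref - 1)
}

#' Configuration of the discrete-versus-continuum comparison
#'
#' A seeded synthetic arterial subtree grown axially through a box of
#' tissue. The discrete Poiseuille solution (inlet pressure at the root,
#' venous pressure at every terminal) is compared with the homogenised
#' three-compartment static Darcy model driven by the same two reservoir
#' pressures: the arterial reservoir couples into compartment 1 through the
#' root segment's conductance (placed in the root's element) and the venous
#' reservoir drains compartment 3 through each terminal segment's
#' conductance (placed at the terminal locations). Both solutions are
#' volume-averaged on `n_slabs` axial slabs, weighted by vessel fluid
#' volume (discrete) and porosity volume (continuum).
#'
#' @param seed RNG seed for the tree.
#' @param box box dimensions (mm).
#' @param mesh_n cells per axis.
#' @param tree a [tree_gen_params()]; default grows one subtree from the
#'   bottom-face centre.
#' @param thresholds compartment radius cutoffs (mm).
#' @param inlet_pressure,terminal_pressure reservoir pressures (kPa).
#' @param viscosity blood viscosity (kPa s).
#' @param rho_f fluid density (g/mm^3).
#' @param n_slabs axial slabs.
#' @return list of class `comparison_config`.
#' @export
comparison_config <- function(seed = 1, box = c(14, 14, 30),
                              mesh_n = c(4, 4, 8), tree = NULL,
                              thresholds = c(0.5, 0.25),
                              inlet_pressure = 10, terminal_pressure = 3,
                              viscosity = 4e-6, rho_f = 1.05e-3,
                              n_slabs = 5) {
  if (is.null(tree))
    tree <- tree_gen_params(domain = list(lower = c(0, 0, 0), upper = box),
                            generations = 18, root_radius = 1, gamma = 3,
                            length_radius_ratio = 6, branch_angle = 45,
                            angle_spread = 8, split_mean = 0.75,
                            asymmetry = 0.08, n_subtrees = 1, r_min = 0.14,
                            root_positions = matrix(c(box[1] / 2,
                                                      box[2] / 2, 0), 1),
                            seed = seed)
  tree$seed <- seed
  structure(list(seed = seed, box = box, mesh_n = mesh_n, tree = tree,
                 thresholds = thresholds, inlet_pressure = inlet_pressure,
                 terminal_pressure = terminal_pressure,
                 viscosity = viscosity, rho_f = rho_f, n_slabs = n_slabs),
            class = "comparison_config")
}

# locate points in elements by nearest centroid (adequate to attribute
# vessel volume to elements for source placement)
nearest_element <- function(mesh, pts) {
  cen <- element_centroids(mesh)
  vapply(seq_len(nrow(pts)), function(i)
    which.min(colSums((t(cen) - pts[i, ])^2)), integer(1))
}

#' Run the discrete-versus-continuum pressure comparison
#'
#' Pipeline: generate the seeded tree, solve Poiseuille flow, homogenise
#' into a three-compartment continuum model, solve the static Darcy model
#' with full and with strictly hierarchical exchange, and volume-average
#' all three pressure fields on axial slabs.
#'
#' @param config a [comparison_config()].
#' @return list of class `comparison_report`: `slabs` (data.frame with
#'   discrete, full and hierarchical slab pressures), `max_rel_err`
#'   (full coupling vs discrete, relative to the discrete slab-pressure
#'   maximum), `max_pressure_full`, `max_pressure_hier`,
#'   `has_direct_13`, plus the network, model and solutions.
#' @export
run_network_comparison <- function(config) {
  cf <- config
  net <- generate_synthetic_tree(cf$tree)
  net <- assign_compartments(net, cf$thresholds)
  mesh <- build_box_mesh(cf$box, cf$mesh_n)
  term <- terminal_nodes(net)
  pbc <- stats::setNames(c(rep(cf$inlet_pressure, length(net$roots)),
                           rep(cf$terminal_pressure, length(term))),
                         c(net$roots, term))
  flow <- poiseuille_solve(net, pbc, viscosity = cf$viscosity)
  model <- compartment_model(mesh, net, viscosity = cf$viscosity,
                             rho_f = cf$rho_f)
  # reservoir couplings from the root and terminal segments
  seg <- net$segments
  lens <- segment_lengths(net)
  g <- segment_conductance(seg$radius, lens, cf$viscosity)
  root_rows <- which(seg$node_a %in% net$roots | seg$node_b %in% net$roots)
  term_rows <- which(seg$node_a %in% term | seg$node_b %in% term)
  node_xyz <- function(ids) as.matrix(net$nodes[match(ids, net$nodes$id),
                                                c("x", "y", "z")])
  # reservoir couplings connect the continuum fields -- which stand for
  # mid-course compartment pressures -- to the external pressures. The
  # arterial inlet couples through the remaining half of the (resolved,
  # low-resistance) root segment; each venous drain couples through half of
  # its terminal corridor: the chain of same-compartment segments from the
  # compartment transition down to the terminal, whose upstream half is
  # already accounted for in the exchange bridges of [estimate_beta()].
  gamma_entries <- function(rows, end_ids, conduct) {
    el <- nearest_element(mesh, node_xyz(end_ids))
    gam <- numeric(nrow(mesh$elems))
    for (j in seq_along(rows))
      gam[el[j]] <- gam[el[j]] + cf$rho_f * conduct[j] / mesh$volumes[el[j]]
    gam
  }
  root_ids <- ifelse(seg$node_a[root_rows] %in% net$roots,
                     seg$node_a[root_rows], seg$node_b[root_rows])
  term_ids <- ifelse(seg$node_a[term_rows] %in% term,
                     seg$node_a[term_rows], seg$node_b[term_rows])
  R_up <- terminal_corridor_resistance(net, g, term_rows, term_ids)
  reservoirs <- list(
    list(compartment = 1,
         gamma = gamma_entries(root_rows, root_ids, 2 * g[root_rows]),
         pressure = cf$inlet_pressure),
    list(compartment = model$n_compartments,
         gamma = gamma_entries(term_rows, term_ids, 2 / R_up),
         pressure = cf$terminal_pressure))
  prob_full <- darcy_problem(mesh, model, reservoirs = reservoirs,
                             rho_f = cf$rho_f)
  sol_full <- solve_darcy_static(prob_full)
  model_h <- make_hierarchical(model)
  prob_h <- darcy_problem(mesh, model_h, reservoirs = reservoirs,
                          rho_f = cf$rho_f)
  sol_h <- solve_darcy_static(prob_h)
  breaks <- seq(0, cf$box[3], length.out = cf$n_slabs + 1)
  disc <- volume_average_discrete_pressure(net, flow, breaks, axis = 3)
  wts <- element_compartment_volumes(mesh, net)
  cont <- function(sol) continuum_slab_pressure(mesh, model, sol, breaks,
                                                element_weights = wts)
  slabs <- data.frame(slab = disc$slab, mid = disc$mid,
                      discrete = disc$pressure,
                      full = cont(sol_full), hierarchical = cont(sol_h))
  ok <- !is.na(slabs$discrete)
  max_rel_err <- max(abs(slabs$full[ok] - slabs$discrete[ok])) /
    max(abs(slabs$discrete[ok]))
  structure(list(slabs = slabs, max_rel_err = max_rel_err,
                 max_pressure_full = max(sol_full$p),
                 max_pressure_hier = max(sol_h$p),
                 has_direct_13 = model$n_compartments >= 3 &&
                   any(model$beta[, 1, 3] > 0),
                 network = net, flow = flow, model = model,
                 sol_full = sol_full, sol_hier = sol_h, mesh = mesh),
            class = "comparison_report")
}

# series resistance of each terminal's same-compartment corridor, walked
# upstream from the terminal until the compartment changes
terminal_corridor_resistance <- function(net, g, term_rows, term_ids) {
  seg <- net$segments
  ids <- c(seg$node_a, seg$node_b)
  srow <- rep(seq_len(nrow(seg)), 2L)
  by_node <- split(srow, ids)
  vapply(seq_along(term_rows), function(j) {
    cur <- term_rows[j]
    nd <- term_ids[j]
    R <- 1 / g[cur]
    repeat {
      nd <- if (seg$node_a[cur] == nd) seg$node_b[cur] else seg$node_a[cur]
      rows <- setdiff(by_node[[as.character(nd)]], cur)
      rows <- rows[seg$compartment_id[rows] == seg$compartment_id[cur]]
      if (!length(rows)) break
      cur <- rows[which.max(g[rows])]
      R <- R + 1 / g[cur]
    }
    R
  }, numeric(1))
}

# fluid-volume-weighted mixture pressure per axial slab. `element_weights`
# (elements x compartments) gives the local fluid volume used to weight the
# continuum pressures -- by default the slab-resolved vessel volumes of the
# underlying network, so the continuum field is sampled where the vessels
# are, exactly mirroring how the discrete solution is averaged. Without
# weights, region porosities times element volume are used.
continuum_slab_pressure <- function(mesh, model, sol, breaks,
                                    element_weights = NULL) {
  er <- element_regions(mesh, model)
  cen <- element_centroids(mesh)
  N <- model$n_compartments
  ns <- length(breaks) - 1
  slab <- pmin(pmax(findInterval(cen[, 3], breaks,
                                 rightmost.closed = TRUE), 1), ns)
  out <- numeric(ns)
  for (s in seq_len(ns)) {
    el <- which(slab == s)
    num <- 0; den <- 0
    for (ci in seq_len(N)) {
      w <- if (!is.null(element_weights)) element_weights[el, ci] else
        model$phi[cbind(er[el], ci)] * mesh$volumes[el]
      pe <- rowMeans(matrix(sol$p[mesh$elems[el, ], ci], length(el)))
      num <- num + sum(w * pe)
      den <- den + sum(w)
    }
    out[s] <- if (den > 0) num / den else NA_real_
  }
  out
}

#' Vessel fluid volume attributed to mesh elements, per compartment
#'
#' Samples each segment at regularly spaced points and accumulates its
#' cylinder volume into the nearest element (by centroid), per compartment.
#' Used to place distributed sources and to weight continuum volume
#' averages consistently with the discrete network.
#'
#' @param mesh an [fe_mesh()].
#' @param network a [vascular_network()] with compartments assigned.
#' @param sample_spacing sampling step along segments (mm).
#' @return elements x compartments matrix (mm^3).
#' @export
element_compartment_volumes <- function(mesh, network, sample_spacing = 1) {
  seg <- network$segments
  if (is.null(seg$compartment_id)) stop("assign compartments first")
  nc <- max(seg$compartment_id)
  a <- as.matrix(network$nodes[match(seg$node_a, network$nodes$id),
                               c("x", "y", "z")])
  b <- as.matrix(network$nodes[match(seg$node_b, network$nodes$id),
                               c("x", "y", "z")])
  lens <- segment_lengths(network)
  out <- matrix(0, nrow(mesh$elems), nc)
  cen <- element_centroids(mesh)
  for (s in seq_len(nrow(seg))) {
    nsamp <- max(2L, ceiling(lens[s] / sample_spacing))
    t <- (seq_len(nsamp) - 0.5) / nsamp
    pts <- outer(1 - t, a[s, ]) + outer(t, b[s, ])
    el <- nearest_element(mesh, pts)
    vol <- pi * seg$radius[s]^2 * lens[s] / nsamp
    for (e in el) out[e, seg$compartment_id[s]] <-
      out[e, seg$compartment_id[s]] + vol
  }
  out
}
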