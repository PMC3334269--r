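make_net <- function(nodes, segs, roots = NULL)
  vascular_network(nodes, segs, roots)

test_that("compartment assignment thresholds by radius", {
  nodes <- data.frame(id = 1:4, x = 0:3, y = 0, z = 0)
  segs <- data.frame(node_a = 1:3, node_b = 2:4,
                     radius = c(1.0, 0.3, 0.05), subtree_id = 1)
  net <- assign_compartments(make_net(nodes, segs), c(0.5, 0.1))
  expect_equal(net$segments$compartment_id, c(1L, 2L, 3L))
  net2 <- assign_compartments(make_net(nodes, segs), 0.5)
  expect_equal(net2$segments$compartment_id, c(1L, 2L, 2L))
  segs$radius <- rep(0.7, 3)
  expect_warning(assign_compartments(make_net(nodes, segs), c(0.5, 0.1)),
                 "empty compartment")
  expect_error(assign_compartments(make_net(nodes, segs), c(0.1, 0.5)),
               "strictly decreasing")
})

test_that("territory partition follows the nearest-subtree metric", {
  mesh <- build_box_mesh(c(10, 1, 1), c(10, 1, 1))
  # two short subtrees near the two ends of the bar
  nodes <- data.frame(id = 1:4, x = c(0.4, 0.6, 9.4, 9.6),
                      y = 0.5, z = 0.5)
  segs <- data.frame(node_a = c(1, 3), node_b = c(2, 4), radius = 0.1,
                     subtree_id = c(1, 2))
  part <- partition_regions(mesh, make_net(nodes, segs))
  cen <- element_centroids(mesh)
  expect_equal(part$element_region, ifelse(cen[, 1] < 5, 1L, 2L))
  expect_equal(sum(part$region_volumes), mesh_volume(mesh), tolerance = 1e-12)
  # idempotent / deterministic
  expect_identical(part, partition_regions(mesh, make_net(nodes, segs)))
  # single subtree takes everything
  one <- partition_regions(mesh, make_net(nodes[1:2, ], segs[1, ]))
  expect_true(all(one$element_region == 1L))
})

test_that("multiple subtrees give contiguous territories covering the mesh", {
  mesh <- build_ellipsoid_shell_mesh(rep(6, 3), rep(9, 3), 0,
                                     n_u = 1, n_phi = 6, n_theta = 12)
  p <- tree_gen_params(domain = list(lower = c(-9, -9, -9),
                                     upper = c(9, 9, 0)),
                       generations = 3, root_radius = 0.6,
                       length_radius_ratio = 4, n_subtrees = 6,
                       root_positions = cbind(6 * cos(1:6), 6 * sin(1:6),
                                              -4),
                       root_direction = c(0, 0, -1), seed = 12)
  net <- generate_synthetic_tree(p)
  part <- partition_regions(mesh, net)
  expect_length(part$region_subtree, 6)
  expect_true(all(tabulate(part$element_region, 6) > 0))
  expect_true(all(regions_contiguous(mesh, part)))
})

test_that("permeability tensor matches the conductance-weighted formula", {
  K <- permeability_from_segments(matrix(c(1, 0, 0), 1), 1, 1, 1)
  expect_equal(K, diag(c(1, 0, 0)), tolerance = 1e-15)
  # three identical orthogonal segments -> isotropic
  K3 <- permeability_from_segments(diag(3), rep(2, 3), rep(0.5, 3), 4)
  expect_equal(K3, diag(3) * 0.5 * 4 / 4, tolerance = 1e-14)
  # PSD for random segment sets
  set.seed(21)
  for (k in 1:10) {
    d <- matrix(rnorm(30), ncol = 3)
    K <- permeability_from_segments(d, runif(10, 0.5, 2), runif(10, 0.1, 5),
                                    3.7)
    expect_true(isSymmetric(K))
    expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-14)
  }
  expect_equal(permeability_from_segments(matrix(0, 0, 3), numeric(0),
                                          numeric(0), 1),
               matrix(0, 3, 3))
})

test_that("permeability is frame-covariant and unit-consistent", {
  set.seed(5)
  d <- matrix(rnorm(15), ncol = 3)
  L <- runif(5, 1, 3); g <- runif(5, 0.5, 2); V <- 11
  K <- permeability_from_segments(d, L, g, V)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Kr <- permeability_from_segments(d %*% t(R), L, g, V)
  expect_equal(Kr, R %*% K %*% t(R), tolerance = 1e-12)
  # mm -> cm: lengths /10, conductance from scaled radii/lengths, volume /1e3
  r <- runif(5, 0.1, 0.5); mu <- 4e-6
  g_mm <- segment_conductance(r, L, mu)
  g_cm <- segment_conductance(r / 10, L / 10, mu)
  K_mm <- permeability_from_segments(d, L, g_mm, V)
  K_cm <- permeability_from_segments(d, L / 10, g_cm, V / 1e3)
  expect_equal(K_cm, K_mm / 100, tolerance = 1e-12)  # cm^2 = 100^-1 mm^2
  phi_mm <- compute_porosity(r, L, V)
  phi_cm <- compute_porosity(r / 10, L / 10, V / 1e3)
  expect_equal(phi_cm, phi_mm, tolerance = 1e-13)    # dimensionless
})

test_that("porosity follows the fluid-volume fraction", {
  expect_equal(compute_porosity(0.1, 10, 100), pi * 0.1 / 100,
               tolerance = 1e-15)
  expect_equal(compute_porosity(numeric(0), numeric(0), 5), 0)
  expect_error(compute_porosity(2, 10, 100), "inconsistent geometry")
})

test_that("exchange matrix is symmetric, zero-diagonal and topology-aware", {
  nodes <- data.frame(id = 1:3, x = c(0, 1, 2), y = 0, z = 0)
  # no bridging: same compartment everywhere
  segs <- data.frame(node_a = 1:2, node_b = 2:3, radius = 0.5,
                     subtree_id = 1, compartment_id = c(1L, 1L))
  net <- make_net(nodes, segs)
  net$segments$compartment_id <- c(1L, 1L)
  b0 <- estimate_beta(net, 3, 10)
  expect_equal(b0, matrix(0, 3, 3))
  # direct 1-3 shortcut produces beta13 > 0, hierarchical projection kills it
  segs$compartment_id <- c(1L, 3L)
  net$segments <- segs
  b <- estimate_beta(net, 3, 10)
  expect_gt(b[1, 3], 0)
  expect_equal(b, t(b))
  expect_equal(diag(b), rep(0, 3))
  bh <- make_hierarchical(b)
  expect_equal(bh[1, 3], 0)
  expect_equal(bh[2, 3], b[2, 3])
  expect_equal(bh, t(bh))
})

test_that("exchange estimate tracks the flow-derived transfer coefficient", {
  # independent oracle: beta implied by the Poiseuille solution,
  # rho_f * (flux crossing i-k junctions) / (V * (mean p_i - mean p_k))
  cfg <- comparison_config(seed = 2)
  net <- generate_synthetic_tree(cfg$tree)
  net <- assign_compartments(net, cfg$thresholds)
  term <- terminal_nodes(net)
  pbc <- stats::setNames(c(rep(10, length(net$roots)),
                           rep(0, length(term))), c(net$roots, term))
  flow <- poiseuille_solve(net, pbc, viscosity = cfg$viscosity)
  seg <- net$segments
  lens <- segment_lengths(net)
  ia <- match(seg$node_a, net$nodes$id); ib <- match(seg$node_b, net$nodes$id)
  pm <- (flow$node_pressure[ia] + flow$node_pressure[ib]) / 2
  vol <- pi * seg$radius^2 * lens
  pbar <- vapply(1:3, function(ci) {
    k <- seg$compartment_id == ci
    sum(pm[k] * vol[k]) / sum(vol[k])
  }, numeric(1))
  ids <- c(seg$node_a, seg$node_b)
  srow <- rep(seq_len(nrow(seg)), 2L)
  Ft <- matrix(0, 3, 3)
  for (nd in unique(ids)) {
    rows <- srow[ids == nd]
    cps <- seg$compartment_id[rows]
    if (length(unique(cps)) < 2) next
    lo <- min(cps)
    for (kk in setdiff(unique(cps), lo)) {
      frows <- rows[cps == kk]
      fx <- sum(ifelse(seg$node_a[frows] == nd, flow$segment_flux[frows],
                       -flow$segment_flux[frows]))
      Ft[lo, kk] <- Ft[lo, kk] + max(fx, 0)
    }
  }
  V <- prod(cfg$box)
  beta_true <- cfg$rho_f * Ft[1, 2] / (V * (pbar[1] - pbar[2]))
  beta_est <- estimate_beta(net, 3, V, cfg$viscosity, cfg$rho_f)
  expect_gt(beta_est[1, 2] / beta_true, 0.5)
  expect_lt(beta_est[1, 2] / beta_true, 2)
})

test_that("compartment model aggregates per region and serialises", {
  cfg <- comparison_config(seed = 3)
  net <- generate_synthetic_tree(cfg$tree)
  net <- assign_compartments(net, cfg$thresholds)
  mesh <- build_box_mesh(cfg$box, c(3, 3, 4))
  model <- compartment_model(mesh, net)
  expect_equal(model$n_compartments, 3)
  expect_true(all(rowSums(model$phi) < 1))
  path <- tempfile(fileext = ".yaml")
  write_compartment_model(model, path)
  back <- read_compartment_model(path)
  expect_equal(back$K, model$K, tolerance = 1e-12)
  expect_equal(back$phi, model$phi, tolerance = 1e-12)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
})

test_that("discrete volume averaging over slabs behaves like a mean", {
  nodes <- data.frame(id = 1:2, x = 0, y = 0, z = c(0, 10))
  segs <- data.frame(node_a = 1, node_b = 2, radius = 0.2, subtree_id = 1)
  net <- make_net(nodes, segs, roots = 1)
  # uniform pressure: every slab average equals it
  fl <- list(node_pressure = c(3, 3))
  out <- volume_average_discrete_pressure(net, fl, c(0, 5, 10))
  expect_equal(out$pressure, c(3, 3))
  # linear pressure along an axial segment: slab averages = mid-slab values
  fl2 <- list(node_pressure = c(10, 0))
  out2 <- volume_average_discrete_pressure(net, fl2, c(0, 5, 10))
  expect_equal(out2$pressure, c(7.5, 2.5), tolerance = 1e-12)
  # empty slab is NA, not zero
  out3 <- volume_average_discrete_pressure(net, fl2, c(0, 10, 20))
  expect_true(is.na(out3$pressure[2]))
})

test_that("global average equals fluid-volume-weighted slab average", {
  cfg <- comparison_config(seed = 4)
  net <- generate_synthetic_tree(cfg$tree)
  net <- assign_compartments(net, cfg$thresholds)
  term <- terminal_nodes(net)
  pbc <- stats::setNames(c(rep(8, length(net$roots)), rep(0, length(term))),
                         c(net$roots, term))
  fl <- poiseuille_solve(net, pbc)
  breaks <- seq(0, cfg$box[3], length.out = 8)
  slabs <- volume_average_discrete_pressure(net, fl, breaks)
  ok <- !is.na(slabs$pressure)
  global_from_slabs <- sum(slabs$pressure[ok] * slabs$fluid_volume[ok]) /
    sum(slabs$fluid_volume[ok])
  whole <- volume_average_discrete_pressure(net, fl,
                                            c(-1e9, 1e9))$pressure[1]
  expect_equal(global_from_slabs, whole, tolerance = 1e-10)
})

test_that("mixture pressure is the porosity-weighted mean", {
  expect_equal(mixture_pressure(c(1, 2, 3), rep(0.1, 3)), 2)
  expect_equal(mixture_pressure(c(9, 4, 1), c(0, 0.3, 0)), 4)
  expect_equal(mixture_pressure(c(10, 4, 1), c(0.1, 0.2, 0.2)), 4)
  pm <- mixture_pressure(rbind(c(1, 3), c(5, 7)), c(0.5, 0.5))
  expect_equal(pm, c(2, 6))
  expect_error(mixture_pressure(c(1, 2), c(0, 0)), "zero total porosity")
})
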