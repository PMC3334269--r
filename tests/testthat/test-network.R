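test_that("synthetic tree generation is structured, seeded and Murray-consistent", {
  p1 <- tree_gen_params(generations = 1, n_subtrees = 1, twig_prob = 0,
                        asymmetry = 0, seed = 4)
  net1 <- generate_synthetic_tree(p1)
  expect_equal(nrow(net1$segments), 3)  # root segment + one bifurcation
  # symmetric split, gamma = 3: child/parent radius ratio 2^(-1/3)
  r <- net1$segments$radius
  expect_equal(sort(unique(r))[1] / max(r), 2^(-1 / 3), tolerance = 1e-12)
  # determinism
  p2 <- tree_gen_params(seed = 5)
  expect_identical(generate_synthetic_tree(p2), generate_synthetic_tree(p2))
  # different seed differs
  p3 <- tree_gen_params(seed = 6)
  expect_false(identical(generate_synthetic_tree(p2),
                         generate_synthetic_tree(p3)))
  # radii stay in the configured range
  net <- generate_synthetic_tree(p2)
  expect_true(all(net$segments$radius >= p2$r_min - 1e-12))
  expect_true(all(net$segments$radius <= p2$r_max + 1e-12))
})

test_that("a too-small domain raises an error reporting achieved depth", {
  p <- tree_gen_params(domain = list(lower = c(0, 0, 0), upper = c(3, 3, 3)),
                       generations = 10, root_radius = 1,
                       length_radius_ratio = 8, seed = 1)
  expect_error(generate_synthetic_tree(p), "achieved depth")
})

test_that("segment conductance follows Poiseuille scaling", {
  expect_equal(segment_conductance(1, 1, 1), pi / 8, tolerance = 1e-15)
  expect_equal(segment_conductance(2, 1, 1) / segment_conductance(1, 1, 1),
               16, tolerance = 1e-12)
  expect_equal(segment_conductance(1, 2, 1) / segment_conductance(1, 1, 1),
               0.5, tolerance = 1e-12)
  expect_error(segment_conductance(-1, 1, 1), "positive")
  expect_error(segment_conductance(1, 0, 1), "positive")
})

test_that("Poiseuille solver reproduces closed forms", {
  # single segment
  nodes <- data.frame(id = 1:2, x = c(0, 2), y = 0, z = 0)
  segs <- data.frame(node_a = 1, node_b = 2, radius = 0.5, subtree_id = 1)
  net <- vascular_network(nodes, segs, roots = 1)
  fl <- poiseuille_solve(net, c("1" = 1, "2" = 0), viscosity = 4e-6)
  g <- segment_conductance(0.5, 2, 4e-6)
  expect_equal(fl$segment_flux, g, tolerance = 1e-12)
  # symmetric Y bifurcation splits flux equally
  nodes <- data.frame(id = 1:4, x = c(0, 0, -1, 1), y = c(0, 1, 2, 2), z = 0)
  segs <- data.frame(node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                     radius = c(1, 0.7, 0.7), subtree_id = 1)
  net <- vascular_network(nodes, segs, roots = 1)
  fl <- poiseuille_solve(net, c("1" = 5, "3" = 0, "4" = 0))
  expect_equal(fl$segment_flux[2], fl$segment_flux[3], tolerance = 1e-12)
  expect_equal(fl$segment_flux[1], fl$segment_flux[2] + fl$segment_flux[3],
               tolerance = 1e-10)
})

test_that("series chain matches harmonic conductance composition", {
  nodes <- data.frame(id = 1:5, x = c(0, 1, 2.5, 3, 4.2), y = 0, z = 0)
  segs <- data.frame(node_a = 1:4, node_b = 2:5,
                     radius = c(0.5, 0.4, 0.35, 0.3), subtree_id = 1)
  net <- vascular_network(nodes, segs, roots = 1)
  dp <- 3.7
  fl <- poiseuille_solve(net, stats::setNames(c(dp, 0), c(1, 5)))
  g_tot <- 1 / sum(1 / fl$conductance)
  expect_equal(fl$segment_flux[1], g_tot * dp,
               tolerance = 1e-12 * g_tot * dp)
})

test_that("flow solution is offset-invariant and linear in the drop", {
  p <- tree_gen_params(generations = 4, seed = 9)
  net <- generate_synthetic_tree(p)
  term <- terminal_nodes(net)
  bc1 <- stats::setNames(c(10, rep(0, length(term))), c(net$roots, term))
  fl1 <- poiseuille_solve(net, bc1)
  fl2 <- poiseuille_solve(net, bc1 + 2.5)           # uniform offset
  expect_equal(fl1$segment_flux, fl2$segment_flux, tolerance = 1e-9)
  fl3 <- poiseuille_solve(net, 2 * bc1)             # double the drop
  expect_equal(2 * fl1$segment_flux, fl3$segment_flux, tolerance = 1e-9)
})

test_that("components without a pressure datum are reported", {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 5, 6), y = 0, z = 0)
  segs <- data.frame(node_a = c(1, 3), node_b = c(2, 4),
                     radius = 0.3, subtree_id = c(1, 2))
  net <- vascular_network(nodes, segs, roots = c(1, 3))
  expect_error(poiseuille_solve(net, c("1" = 1)), "without a pressure datum")
})

test_that("network CSV io round-trips and validates", {
  net <- generate_synthetic_tree(tree_gen_params(generations = 2, seed = 2))
  net <- assign_compartments(net, 0.8)
  stem <- tempfile()
  write_network(net, stem)
  back <- read_network(stem)
  expect_equal(back$nodes, net$nodes, tolerance = 0)
  expect_equal(back$segments, net$segments, tolerance = 0)
  # dangling reference and bad radius are rejected with row numbers
  bad <- net$segments
  bad$node_a[2] <- 99999L
  expect_error(vascular_network(net$nodes, bad), "row\\(s\\): 2")
  bad2 <- net$segments
  bad2$radius[3] <- 0
  expect_error(vascular_network(net$nodes, bad2), "row\\(s\\): 3")
})
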