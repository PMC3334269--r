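#' Discrete vascular network
#'
#' A spatial graph of straight cylindrical vessel segments. Nodes carry 3D
#' coordinates (mm); segments carry a radius (mm), the id of the feeding
#' subtree they belong to, and optionally a compartment id assigned by
#' [assign_compartments()].
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`.
#' @param segments data.frame with columns `node_a`, `node_b`, `radius`,
#'   `subtree_id` and optionally `compartment_id`.
#' @param roots optional integer vector of root (inlet) node ids, one per
#'   subtree.
#' @return object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, roots = NULL) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  need_n <- c("id", "x", "y", "z"); need_s <- c("node_a", "node_b", "radius")
  if (!all(need_n %in% names(nodes))) stop("nodes need columns id,x,y,z")
  if (!all(need_s %in% names(segments)))
    stop("segments need columns node_a,node_b,radius")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (is.null(segments$subtree_id)) segments$subtree_id <- 1L
  bad <- which(!(segments$node_a %in% nodes$id) |
               !(segments$node_b %in% nodes$id))
  if (length(bad))
    stop("segment(s) reference missing nodes at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_r <- which(!(segments$radius > 0))
  if (length(bad_r))
    stop("non-positive radius at segment row(s): ",
         paste(utils::head(bad_r, 5), collapse = ", "))
  if (any(segments$node_a == segments$node_b)) stop("self-loop segment")
  net <- structure(list(nodes = nodes, segments = segments, roots = roots),
                   class = "vascular_network")
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("vascular_network:", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments,", length(unique(x$segments$subtree_id)), "subtree(s)\n")
  cat("  radius range:", format(range(x$segments$radius), digits = 4), "mm\n")
  invisible(x)
}

#' Segment lengths of a network
#' @param network a [vascular_network()].
#' @return numeric vector (mm).
#' @export
segment_lengths <- function(network) {
  a <- network$nodes[match(network$segments$node_a, network$nodes$id),
                     c("x", "y", "z")]
  b <- network$nodes[match(network$segments$node_b, network$nodes$id),
                     c("x", "y", "z")]
  sqrt(rowSums((as.matrix(b) - as.matrix(a))^2))
}

#' Poiseuille conductance of a cylindrical segment
#'
#' `g = pi r^4 / (8 mu L)`: volumetric flux per unit pressure drop of fully
#' developed laminar flow in a straight tube.
#'
#' @param radius radius (mm).
#' @param length length (mm).
#' @param viscosity dynamic viscosity (kPa s); blood is about 4e-6.
#' @return conductance in mm^3 s^-1 kPa^-1.
#' @export
segment_conductance <- function(radius, length, viscosity) {
  if (any(radius <= 0) || any(length <= 0) || any(viscosity <= 0))
    stop("radius, length and viscosity must be positive")
  pi * radius^4 / (8 * viscosity * length)
}

#' Parameters for the synthetic coronary-tree generator
#'
#' The generator emulates the multiscale structure of an imaged coronary
#' tree with a seeded recursive bifurcation scheme: child radii follow a
#' Murray-type law `r_parent^gamma = sum(r_child^gamma)`, segment length is
#' proportional to radius, and several disjoint subtrees feed distinct
#' territories.
#'
#' @param domain list with `lower`, `upper`: bounding box corners (mm).
#' @param generations number of bifurcation levels.
#' @param root_radius radius of each root segment (mm).
#' @param gamma Murray exponent (3 = Murray's law).
#' @param length_radius_ratio segment length / radius.
#' @param branch_angle mean half-angle between children and parent (degrees).
#' @param angle_spread s.d. of the branch-angle jitter (degrees).
#' @param split_mean mean flow split taken by the first child (0.5 =
#'   symmetric bifurcation; larger values produce a dominant trunk that
#'   traverses the territory shedding smaller side branches, as in imaged
#'   coronary trees).
#' @param asymmetry half-width of the uniform flow-split jitter around
#'   `split_mean`.
#' @param twig_prob probability that a bifurcation node also sprouts a
#'   direct small side vessel (radius `twig_radius_ratio` times the parent),
#'   producing the cross-scale connections between non-neighbouring vessel
#'   calibres seen in vascular morphology.
#' @param twig_radius_ratio radius ratio of side twigs.
#' @param n_subtrees number of disjoint rooted trees.
#' @param r_min,r_max admissible radius range (mm); branches stop below
#'   `r_min`.
#' @param root_positions optional n_subtrees x 3 matrix; default: spread
#'   across the z = lower\[3\] face.
#' @param root_direction initial growth direction (default +z).
#' @param seed RNG seed for reproducibility.
#' @return list of class `tree_gen_params`.
#' @export
tree_gen_params <- function(domain = list(lower = c(0, 0, 0),
                                          upper = c(20, 20, 30)),
                            generations = 7, root_radius = 1,
                            gamma = 3, length_radius_ratio = 7,
                            branch_angle = 30, angle_spread = 8,
                            split_mean = 0.5,
                            asymmetry = 0.1, twig_prob = 0.3,
                            twig_radius_ratio = 0.24, n_subtrees = 1,
                            r_min = 0.03, r_max = 2,
                            root_positions = NULL,
                            root_direction = c(0, 0, 1), seed = 1) {
  stopifnot(root_radius > 0, gamma > 0, generations >= 1,
            r_min > 0, r_max >= root_radius, n_subtrees >= 1,
            asymmetry >= 0, asymmetry < 0.5,
            split_mean > 0, split_mean < 1,
            twig_prob >= 0, twig_prob <= 1, twig_radius_ratio > 0,
            twig_radius_ratio < 1)
  structure(as.list(environment()), class = "tree_gen_params")
}

rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Generate a synthetic bifurcating vascular tree
#'
#' Seeded, reproducible stand-in for an imaged coronary tree: `n_subtrees`
#' disjoint rooted binary trees grown inside a bounding box, with Murray-law
#' radii spanning from `root_radius` down to `r_min`. Growth directions that
#' would leave the domain are bent towards the box centre; if a segment
#' cannot be placed even after shrinking, generation stops and an error
#' reports the achieved depth.
#'
#' @param params a [tree_gen_params()].
#' @return a [vascular_network()] with `subtree_id` set and root node ids in
#'   `$roots`.
#' @export
generate_synthetic_tree <- function(params) {
  p <- params
  set.seed(p$seed)
  lower <- p$domain$lower; upper <- p$domain$upper
  if (any(upper <= lower)) stop("empty domain")
  centre <- (lower + upper) / 2
  inside <- function(x) all(x >= lower - 1e-12) && all(x <= upper + 1e-12)
  if (is.null(p$root_positions)) {
    xs <- seq(lower[1], upper[1], length.out = p$n_subtrees + 2)[-c(1, p$n_subtrees + 2)]
    p$root_positions <- cbind(xs, mean(c(lower[2], upper[2])), lower[3])
  }
  nodes_x <- list(); segs <- list(); nid <- 0L
  roots <- integer(p$n_subtrees)
  achieved_depth <- 0L
  new_node <- function(x) {
    nid <<- nid + 1L
    nodes_x[[nid]] <<- x
    nid
  }
  place <- function(pos, dir, len) {
    # bend towards the domain centre until the endpoint fits
    for (bend in seq(0, 1, by = 0.25)) {
      d <- (1 - bend) * dir + bend * (centre - pos) /
        max(sqrt(sum((centre - pos)^2)), 1e-9)
      d <- d / sqrt(sum(d^2))
      for (shrink in c(1, 0.7, 0.5)) {
        x <- pos + d * len * shrink
        if (inside(x)) return(list(x = x, dir = d, len = len * shrink))
      }
    }
    NULL
  }
  for (s in seq_len(p$n_subtrees)) {
    rp <- as.numeric(p$root_positions[s, ])
    if (!inside(rp)) stop("root position outside domain")
    root <- new_node(rp)
    roots[s] <- root
    dir0 <- p$root_direction / sqrt(sum(p$root_direction^2))
    pl <- place(rp, dir0, p$length_radius_ratio * p$root_radius)
    if (is.null(pl))
      stop("domain too small for requested generations; achieved depth 0")
    tip <- new_node(pl$x)
    segs[[length(segs) + 1L]] <- c(root, tip, p$root_radius, s)
    queue <- list(list(node = tip, pos = pl$x, dir = pl$dir,
                       r = p$root_radius, gen = 0L))
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      achieved_depth <- max(achieved_depth, cur$gen)
      if (cur$gen >= p$generations) next
      f <- min(0.95, max(0.05,
             p$split_mean + stats::runif(1, -p$asymmetry, p$asymmetry)))
      rch <- cur$r * c(f, 1 - f)^(1 / p$gamma)
      rch <- pmin(rch, p$r_max)
      # larger child deviates less from the parent course (optimality rule)
      wang <- 2 * rev(rch^2) / sum(rch^2)
      # occasional direct small side vessel off the bifurcation node
      twig_r <- if (stats::runif(1) < p$twig_prob)
        max(cur$r * p$twig_radius_ratio, 0) else 0
      # random plane through the parent direction
      ref <- if (abs(cur$dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- cross3(cur$dir, ref); u <- u / sqrt(sum(u^2))
      phi <- stats::runif(1, 0, 2 * pi)
      u <- rotate_about(u, cur$dir, phi)
      for (ci in 1:3) {
        r <- if (ci <= 2) rch[ci] else twig_r
        if (r < p$r_min) next
        ang <- if (ci <= 2)
          (wang[ci] * p$branch_angle +
           stats::rnorm(1, 0, p$angle_spread)) * pi / 180
        else stats::runif(1, 60, 90) * pi / 180
        d <- rotate_about(cur$dir, u, c(1, -1, 1)[ci] * ang)
        if (ci == 3) d <- rotate_about(d, cur$dir, stats::runif(1, 0, 2 * pi))
        pl <- place(cur$pos, d, p$length_radius_ratio * r)
        if (is.null(pl))
          stop("domain too small for requested generations; achieved depth ",
               achieved_depth)
        child <- new_node(pl$x)
        segs[[length(segs) + 1L]] <- c(cur$node, child, r, s)
        if (ci <= 2)
          queue[[length(queue) + 1L]] <- list(node = child, pos = pl$x,
                                              dir = pl$dir, r = r,
                                              gen = cur$gen + 1L)
      }
    }
  }
  nodes <- do.call(rbind, nodes_x)
  sm <- do.call(rbind, segs)
  vascular_network(
    nodes = data.frame(id = seq_len(nrow(nodes)), x = nodes[, 1],
                       y = nodes[, 2], z = nodes[, 3]),
    segments = data.frame(node_a = as.integer(sm[, 1]),
                          node_b = as.integer(sm[, 2]),
                          radius = sm[, 3], subtree_id = as.integer(sm[, 4])),
    roots = roots)
}

#' Terminal nodes of a network
#'
#' Nodes incident to exactly one segment, excluding declared roots.
#' @param network a [vascular_network()].
#' @return integer vector of node ids.
#' @export
terminal_nodes <- function(network) {
  deg <- table(c(network$segments$node_a, network$segments$node_b))
  term <- as.integer(names(deg)[deg == 1])
  setdiff(term, network$roots)
}

#' Solve Poiseuille flow on a discrete network
#'
#' Kirchhoff nodal conservation with segment conductances
#' `g = pi r^4/(8 mu L)`: interior nodes satisfy
#' `sum_adjacent g (p_node - p_neighbour) = 0`; boundary nodes carry either a
#' fixed pressure or a prescribed inflow flux. Every connected component
#' must contain at least one pressure condition to fix the datum.
#'
#' @param network a [vascular_network()].
#' @param pressure_bc named numeric vector: names are node ids, values kPa.
#' @param flux_bc named numeric vector: names are node ids, values mm^3/s
#'   injected into the node (negative = withdrawal).
#' @param viscosity dynamic viscosity (kPa s).
#' @return object of class `network_flow` with `node_pressure` (kPa, in node
#'   table order), `segment_flux` (mm^3/s, positive from `node_a` to
#'   `node_b`) and `conductance`.
#' @export
poiseuille_solve <- function(network, pressure_bc, flux_bc = NULL,
                             viscosity = 4e-6) {
  nodes <- network$nodes; seg <- network$segments
  n <- nrow(nodes)
  if (length(pressure_bc) == 0) stop("at least one pressure BC is required")
  ia <- match(seg$node_a, nodes$id); ib <- match(seg$node_b, nodes$id)
  g <- segment_conductance(seg$radius, segment_lengths(network), viscosity)
  L <- Matrix::sparseMatrix(i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
                            x = c(g, g, -g, -g), dims = c(n, n))
  rhs <- numeric(n)
  if (!is.null(flux_bc))
    rhs[match(as.integer(names(flux_bc)), nodes$id)] <- flux_bc
  dir_idx <- match(as.integer(names(pressure_bc)), nodes$id)
  if (anyNA(dir_idx)) stop("pressure BC on unknown node id")
  # every connected component needs a pressure datum
  comp <- graph_components(n, ia, ib)
  miss <- setdiff(unique(comp), unique(comp[dir_idx]))
  if (length(miss))
    stop("disconnected component(s) without a pressure datum: component(s) ",
         paste(miss, collapse = ", "), " containing node id(s) ",
         paste(utils::head(nodes$id[comp %in% miss], 8), collapse = ", "))
  p <- numeric(n)
  p[dir_idx] <- pressure_bc
  free <- setdiff(seq_len(n), dir_idx)
  if (length(free)) {
    rhs_f <- rhs[free] - as.numeric(L[free, dir_idx, drop = FALSE] %*%
                                    pressure_bc)
    p[free] <- as.numeric(Matrix::solve(L[free, free], rhs_f))
  }
  structure(list(node_pressure = unname(p),
                 segment_flux = unname(g * (p[ia] - p[ib])),
                 conductance = g, ia = ia, ib = ib),
            class = "network_flow")
}

# connected components by label propagation (no igraph dependency)
graph_components <- function(n, ia, ib) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_along(ia)) {
      v <- min(comp[ia[k]], comp[ib[k]])
      if (comp[ia[k]] > v) { comp[ia[k]] <- v; changed <- TRUE }
      if (comp[ib[k]] > v) { comp[ib[k]] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Nodal flux imbalance of a network flow solution
#'
#' Net volumetric flux into each node; zero at interior nodes of a converged
#' solution, equal to the boundary in/outflow at terminals.
#'
#' @param network a [vascular_network()].
#' @param flow a solution from [poiseuille_solve()].
#' @return numeric vector per node (mm^3/s).
#' @export
node_flux_imbalance <- function(network, flow) {
  n <- nrow(network$nodes)
  imb <- numeric(n)
  for (k in seq_along(flow$segment_flux)) {
    imb[flow$ia[k]] <- imb[flow$ia[k]] - flow$segment_flux[k]
    imb[flow$ib[k]] <- imb[flow$ib[k]] + flow$segment_flux[k]
  }
  imb
}

#' Write / read a vascular network as CSV tables
#'
#' `write_network` writes `<stem>_nodes.csv` (id,x,y,z) and
#' `<stem>_segments.csv` (node_a,node_b,radius,subtree_id\[,compartment_id\]);
#' `read_network` reads them back. The round trip reproduces the network
#' exactly (numbers are written at full precision).
#'
#' @param network a [vascular_network()].
#' @param stem path stem (without suffix).
#' @return `read_network` returns a [vascular_network()]; `write_network`
#'   returns the two paths invisibly.
#' @export
write_network <- function(network, stem) {
  np <- paste0(stem, "_nodes.csv"); sp <- paste0(stem, "_segments.csv")
  nodes <- network$nodes
  nodes$x <- sprintf("%.17g", nodes$x)
  nodes$y <- sprintf("%.17g", nodes$y)
  nodes$z <- sprintf("%.17g", nodes$z)
  utils::write.csv(nodes, np, row.names = FALSE, quote = FALSE)
  seg <- network$segments
  seg$radius <- sprintf("%.17g", seg$radius)
  utils::write.csv(seg, sp, row.names = FALSE, quote = FALSE)
  invisible(c(np, sp))
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  np <- paste0(stem, "_nodes.csv"); sp <- paste0(stem, "_segments.csv")
  if (!file.exists(np) || !file.exists(sp))
    stop("missing network CSV file(s): ", np, " / ", sp)
  vascular_network(utils::read.csv(np), utils::read.csv(sp))
}
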