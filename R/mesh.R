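#' Unstructured tetrahedral mesh
#'
#' Container for a tetrahedral mesh of a reference domain: node coordinates
#' in mm, tetrahedra as 1-based node indices, labelled boundary facets and a
#' per-element integer region label. Element node ordering is normalised so
#' all signed volumes are strictly positive; boundary facets are oriented
#' with outward normals.
#'
#' @param nodes numeric matrix, n x 3 (mm).
#' @param elems integer matrix, m x 4 (1-based node indices).
#' @param region integer vector of length m (defaults to 1).
#' @param facet_labeller optional `function(centroid_matrix, normal_matrix)`
#'   returning an integer label per boundary facet.
#' @param labels named integer vector naming the surface labels in use.
#' @return object of class `fe_mesh` with fields `nodes`, `elems`, `region`,
#'   `facets` (f x 3, outward-oriented), `facet_label`, `facet_elem`,
#'   `labels`, `volumes`.
#' @export
fe_mesh <- function(nodes, elems, region = NULL,
                    facet_labeller = NULL, labels = integer(0)) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(elems) != 4L) stop("elems must be an m x 4 matrix")
  if (min(elems) < 1L || max(elems) > nrow(nodes))
    stop("element indices out of range")
  v <- tet_signed_volumes(nodes, elems)
  neg <- v < 0
  if (any(neg)) {  # swap two nodes to restore positive orientation
    tmp <- elems[neg, 3L]
    elems[neg, 3L] <- elems[neg, 4L]
    elems[neg, 4L] <- tmp
    v[neg] <- -v[neg]
  }
  if (any(v <= .Machine$double.eps))
    stop("degenerate element(s) with non-positive volume: ",
         paste(utils::head(which(v <= .Machine$double.eps), 5), collapse = ", "))
  if (is.null(region)) region <- rep(1L, nrow(elems))
  region <- as.integer(region)
  if (length(region) != nrow(elems))
    stop("region labels must cover all elements")
  bf <- boundary_facets(nodes, elems)
  facet_label <- rep(0L, nrow(bf$facets))
  if (!is.null(facet_labeller) && nrow(bf$facets) > 0) {
    cen <- facet_centroids(nodes, bf$facets)
    facet_label <- as.integer(facet_labeller(cen, bf$normals))
  }
  structure(list(nodes = nodes, elems = elems, region = region,
                 facets = bf$facets, facet_label = facet_label,
                 facet_elem = bf$elem, labels = labels, volumes = v),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("fe_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "tetrahedra,",
      nrow(x$facets), "boundary facets\n")
  cat("  volume:", format(sum(x$volumes)), "mm^3;",
      length(unique(x$region)), "region(s)\n")
  if (length(x$labels))
    cat("  surfaces:", paste(names(x$labels), "=",
                             tabulate(x$facet_label, max(x$labels))[x$labels],
                             collapse = ", "), "\n")
  invisible(x)
}

tet_signed_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 2L], , drop = FALSE] - a
  c_ <- nodes[elems[, 3L], , drop = FALSE] - a
  d <- nodes[elems[, 4L], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Faces of each tet, oriented outward for positively oriented elements.
tet_faces_outward <- function(elems) {
  rbind(elems[, c(1L, 3L, 2L)],
        elems[, c(1L, 2L, 4L)],
        elems[, c(2L, 3L, 4L)],
        elems[, c(1L, 4L, 3L)])
}

boundary_facets <- function(nodes, elems) {
  m <- nrow(elems)
  faces <- tet_faces_outward(elems)
  owner <- rep.int(seq_len(m), 4L)
  key <- apply(faces, 1L, function(r) paste(sort.int(r), collapse = "-"))
  tab <- table(key)
  keep <- key %in% names(tab)[tab == 1L]
  facets <- faces[keep, , drop = FALSE]
  owner <- owner[keep]
  # outward normals (facets inherit outward orientation from the element)
  p1 <- nodes[facets[, 1L], , drop = FALSE]
  e1 <- nodes[facets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[facets[, 3L], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  list(facets = facets, elem = owner, normals = nrm / pmax(len, 1e-300))
}

facet_centroids <- function(nodes, facets) {
  (nodes[facets[, 1L], , drop = FALSE] +
   nodes[facets[, 2L], , drop = FALSE] +
   nodes[facets[, 3L], , drop = FALSE]) / 3
}

#' Total mesh volume
#' @param mesh an `fe_mesh`.
#' @return total volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(mesh$volumes)

#' Element centroids
#' @param mesh an `fe_mesh`.
#' @return m x 3 matrix.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 4L], , drop = FALSE]) / 4
}

# Kuhn subdivision of a structured hexahedral lattice into 6 tets per cell.
# `corners` is an 8-column index matrix ordered c000,c100,c010,c110,c001,
# c101,c011,c111. Conforming across cells because every cell is split along
# the same lattice diagonal. Degenerate (collapsed) cells yield zero-volume
# tets which the caller drops.
kuhn_tets <- function(corners) {
  idx <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
               c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  do.call(rbind, lapply(seq_len(nrow(idx)), function(t)
    corners[, idx[t, ], drop = FALSE]))
}

drop_degenerate <- function(nodes, elems, tol = 1e-12) {
  # remove tets with (near-)zero volume or repeated nodes
  rep_node <- apply(elems, 1L, function(r) anyDuplicated(r) > 0L)
  v <- abs(tet_signed_volumes(nodes, elems))
  scale <- stats::median(v[v > 0])
  elems[!rep_node & v > tol * scale, , drop = FALSE]
}

compact_mesh <- function(nodes, elems) {
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       elems = matrix(remap[elems], ncol = 4L))
}

#' Standard surface labels
#'
#' Named integer codes for the wall surfaces used by the mesh generators:
#' `ENDO` (inner / cavity-facing), `EPI` (outer), `BASE` (top plane),
#' `APEXCAP` (bottom plane of the annulus), and `XMIN..ZMAX` for boxes.
#' @export
surface_labels <- c(ENDO = 1L, EPI = 2L, BASE = 3L, APEXCAP = 4L,
                    XMIN = 11L, XMAX = 12L, YMIN = 13L, YMAX = 14L,
                    ZMIN = 15L, ZMAX = 16L)

#' Structured tetrahedral box mesh
#'
#' Axis-aligned box `[0,Lx] x [0,Ly] x [0,Lz]` split into a structured grid
#' of hexahedra, each subdivided into 6 tetrahedra. Boundary facets carry
#' the labels `XMIN`, `XMAX`, `YMIN`, `YMAX`, `ZMIN`, `ZMAX`.
#'
#' @param lengths numeric length-3, box edge lengths (mm).
#' @param n integer length-3, cells per axis.
#' @return an [fe_mesh()].
#' @export
build_box_mesh <- function(lengths = c(1, 1, 1), n = c(2, 2, 2)) {
  stopifnot(all(lengths > 0), all(n >= 1))
  n <- as.integer(n)
  xs <- seq(0, lengths[1], length.out = n[1] + 1)
  ys <- seq(0, lengths[2], length.out = n[2] + 1)
  zs <- seq(0, lengths[3], length.out = n[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (n[1] + 1L) * (j - 1L) +
    (n[1] + 1L) * (n[2] + 1L) * (k - 1L)
  cells <- expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3])
  corn <- with(cells, cbind(
    idx(i, j, k), idx(i + 1L, j, k), idx(i, j + 1L, k), idx(i + 1L, j + 1L, k),
    idx(i, j, k + 1L), idx(i + 1L, j, k + 1L), idx(i, j + 1L, k + 1L),
    idx(i + 1L, j + 1L, k + 1L)))
  elems <- kuhn_tets(corn)
  tol <- 1e-9 * max(lengths)
  lab <- function(cen, nrm) {
    out <- integer(nrow(cen))
    out[abs(cen[, 1]) < tol] <- surface_labels[["XMIN"]]
    out[abs(cen[, 1] - lengths[1]) < tol] <- surface_labels[["XMAX"]]
    out[abs(cen[, 2]) < tol] <- surface_labels[["YMIN"]]
    out[abs(cen[, 2] - lengths[2]) < tol] <- surface_labels[["YMAX"]]
    out[abs(cen[, 3]) < tol] <- surface_labels[["ZMIN"]]
    out[abs(cen[, 3] - lengths[3]) < tol] <- surface_labels[["ZMAX"]]
    out
  }
  fe_mesh(nodes, elems, facet_labeller = lab,
          labels = surface_labels[c("XMIN", "XMAX", "YMIN", "YMAX",
                                    "ZMIN", "ZMAX")])
}

#' Tetrahedral mesh of a cylindrical annulus wall
#'
#' Desk-scale stand-in for a ventricular wall: a thick-walled cylinder
#' occupying `r_inner <= r <= r_outer`, `0 <= z <= height`. Surfaces are
#' labelled `ENDO` (inner), `EPI` (outer), `BASE` (top, z = height) and
#' `APEXCAP` (bottom, z = 0).
#'
#' @param r_inner,r_outer inner/outer radius (mm), `0 < r_inner < r_outer`.
#' @param height axial extent (mm).
#' @param n_r,n_theta,n_z cells radially, circumferentially, axially.
#' @param resolution optional element-count hint; when given it overrides
#'   `n_r`/`n_theta`/`n_z` with a balanced subdivision of about that many
#'   tetrahedra.
#' @return an [fe_mesh()].
#' @export
build_annulus_mesh <- function(r_inner, r_outer, height,
                               n_r = 2, n_theta = 16, n_z = 4,
                               resolution = NULL) {
  if (!(r_inner > 0 && r_outer > r_inner && height > 0))
    stop("invalid geometry: need 0 < r_inner < r_outer and height > 0")
  if (!is.null(resolution)) {
    # ~6 tets per hex; scale the default proportions to the hint
    s <- max(1, (resolution / 6 / (2 * 16 * 4))^(1 / 3))
    n_r <- max(1L, round(2 * s)); n_theta <- max(8L, round(16 * s))
    n_z <- max(1L, round(4 * s))
  }
  n_r <- as.integer(n_r); n_theta <- as.integer(n_theta); n_z <- as.integer(n_z)
  rs <- seq(r_inner, r_outer, length.out = n_r + 1)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, height, length.out = n_z + 1)
  grid <- expand.grid(ir = 1:(n_r + 1), it = 1:n_theta, iz = 1:(n_z + 1))
  nodes <- cbind(rs[grid$ir] * cos(ths[grid$it]),
                 rs[grid$ir] * sin(ths[grid$it]),
                 zs[grid$iz])
  idx <- function(ir, it, iz) {
    it <- ((it - 1L) %% n_theta) + 1L
    ir + (n_r + 1L) * (it - 1L) + (n_r + 1L) * n_theta * (iz - 1L)
  }
  cells <- expand.grid(ir = 1:n_r, it = 1:n_theta, iz = 1:n_z)
  corn <- with(cells, cbind(
    idx(ir, it, iz), idx(ir + 1L, it, iz),
    idx(ir, it + 1L, iz), idx(ir + 1L, it + 1L, iz),
    idx(ir, it, iz + 1L), idx(ir + 1L, it, iz + 1L),
    idx(ir, it + 1L, iz + 1L), idx(ir + 1L, it + 1L, iz + 1L)))
  elems <- kuhn_tets(corn)
  tolr <- 1e-9 * r_outer; tolz <- 1e-9 * max(height, r_outer)
  lab <- function(cen, nrm) {
    r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
    out <- integer(nrow(cen))
    out[abs(cen[, 3] - height) < tolz] <- surface_labels[["BASE"]]
    out[abs(cen[, 3]) < tolz] <- surface_labels[["APEXCAP"]]
    inner <- out == 0L & r < (r_inner + r_outer) / 2
    out[inner] <- surface_labels[["ENDO"]]
    out[out == 0L] <- surface_labels[["EPI"]]
    out
  }
  fe_mesh(nodes, elems, facet_labeller = lab,
          labels = surface_labels[c("ENDO", "EPI", "BASE", "APEXCAP")])
}

#' Tetrahedral mesh of a truncated-ellipsoid shell
#'
#' Idealised left-ventricle-like wall: the volume between two concentric
#' ellipsoids (apex pointing down the -z axis), truncated by the base plane
#' `z = truncation_height`. With `truncation_height = NULL` the full closed
#' shell is meshed. Surfaces are labelled `ENDO`, `EPI` and (if truncated)
#' `BASE`.
#'
#' @param semi_axes_inner,semi_axes_outer length-3 semi-axes (a, b, c) in mm;
#'   the inner ellipsoid must lie strictly inside the outer one.
#' @param truncation_height z-coordinate of the base plane, in
#'   `(-c_inner, c_outer)`; `NULL` for no truncation.
#' @param n_u,n_phi,n_theta cells through-wall, apex-to-base, and
#'   circumferentially.
#' @return an [fe_mesh()].
#' @export
build_ellipsoid_shell_mesh <- function(semi_axes_inner, semi_axes_outer,
                                       truncation_height = NULL,
                                       n_u = 2, n_phi = 8, n_theta = 12) {
  ai <- as.numeric(semi_axes_inner); ao <- as.numeric(semi_axes_outer)
  if (length(ai) == 1) ai <- rep(ai, 3)
  if (length(ao) == 1) ao <- rep(ao, 3)
  if (!all(ai > 0) || !all(ao > ai))
    stop("invalid geometry: inner ellipsoid must lie strictly inside outer")
  if (!is.null(truncation_height) &&
      (truncation_height <= -ai[3] || truncation_height >= ao[3]))
    stop("invalid geometry: truncation plane misses the shell")
  n_u <- as.integer(n_u); n_phi <- as.integer(n_phi); n_theta <- as.integer(n_theta)
  us <- seq(0, 1, length.out = n_u + 1)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  axes <- function(u) ai + u * (ao - ai)       # per-layer semi-axes
  phimax <- function(u) {
    cc <- axes(u)[3]
    if (is.null(truncation_height)) pi
    else acos(max(-1, min(1, -truncation_height / cc)))
  }
  # node bookkeeping with pole collapse at phi = 0 (and phi = pi, full shell)
  node_list <- list(); node_id <- array(NA_integer_,
                                        c(n_u + 1, n_phi + 1, n_theta))
  cnt <- 0L
  for (iu in 1:(n_u + 1)) {
    ax <- axes(us[iu]); pm <- phimax(us[iu])
    phis <- seq(0, pm, length.out = n_phi + 1)
    for (jp in 1:(n_phi + 1)) {
      ph <- phis[jp]
      collapse <- abs(sin(ph)) < 1e-12
      if (collapse) {
        cnt <- cnt + 1L
        node_list[[cnt]] <- c(0, 0, -ax[3] * cos(ph))
        node_id[iu, jp, ] <- cnt
      } else {
        for (kt in 1:n_theta) {
          cnt <- cnt + 1L
          node_list[[cnt]] <- c(ax[1] * sin(ph) * cos(ths[kt]),
                                ax[2] * sin(ph) * sin(ths[kt]),
                                -ax[3] * cos(ph))
          node_id[iu, jp, kt] <- cnt
        }
      }
    }
  }
  nodes <- do.call(rbind, node_list)
  cells <- expand.grid(iu = 1:n_u, jp = 1:n_phi, kt = 1:n_theta)
  nxt <- function(k) (k %% n_theta) + 1L
  corn <- with(cells, cbind(
    node_id[cbind(iu, jp, kt)],     node_id[cbind(iu + 1L, jp, kt)],
    node_id[cbind(iu, jp, nxt(kt))], node_id[cbind(iu + 1L, jp, nxt(kt))],
    node_id[cbind(iu, jp + 1L, kt)], node_id[cbind(iu + 1L, jp + 1L, kt)],
    node_id[cbind(iu, jp + 1L, nxt(kt))],
    node_id[cbind(iu + 1L, jp + 1L, nxt(kt))]))
  elems <- drop_degenerate(nodes, kuhn_tets(corn))
  cm <- compact_mesh(nodes, elems)
  hb <- if (is.null(truncation_height)) Inf else truncation_height
  tolz <- 1e-6 * ao[3]
  lab <- function(cen, nrm) {
    out <- integer(nrow(cen))
    if (is.finite(hb)) out[abs(cen[, 3] - hb) < tolz] <- surface_labels[["BASE"]]
    rest <- out == 0L
    # classify by implicit mid-ellipsoid value
    am <- (ai + ao) / 2
    val <- (cen[, 1] / am[1])^2 + (cen[, 2] / am[2])^2 + (cen[, 3] / am[3])^2
    out[rest & val < 1] <- surface_labels[["ENDO"]]
    out[rest & val >= 1] <- surface_labels[["EPI"]]
    out
  }
  fe_mesh(cm$nodes, cm$elems, facet_labeller = lab,
          labels = surface_labels[c("ENDO", "EPI", "BASE")])
}
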