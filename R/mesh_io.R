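#' Write a mesh in Gmsh 2.2 ASCII format
#'
#' Tetrahedra are written as element type 4 with the region label as the
#' physical tag; labelled boundary facets as type 2 triangles. Node and
#' element order is the deterministic internal order.
#'
#' @param mesh an [fe_mesh()].
#' @param path output file path.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   format(mesh$nodes[, 1], digits = 17),
                   format(mesh$nodes[, 2], digits = 17),
                   format(mesh$nodes[, 3], digits = 17)), con)
  nt <- nrow(mesh$facets); ne <- nrow(mesh$elems)
  writeLines(c("$EndNodes", "$Elements", as.character(nt + ne)), con)
  if (nt > 0)
    writeLines(paste(seq_len(nt), 2, 2, mesh$facet_label, mesh$facet_label,
                     mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]), con)
  writeLines(paste(nt + seq_len(ne), 4, 2, mesh$region, mesh$region,
                   mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                   mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh 2.2 ASCII mesh
#'
#' Reads tetrahedra (type 4, physical tag as region) and boundary triangles
#' (type 2, physical tag as facet label). Facet labels are re-attached by
#' matching node triples against the mesh's own boundary facets.
#'
#' @param path file path.
#' @return an [fe_mesh()].
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(tag) {
    i0 <- which(lines == paste0("$", tag)); i1 <- which(lines == paste0("$End", tag))
    if (length(i0) != 1 || length(i1) != 1) stop("malformed msh file: ", tag)
    lines[(i0 + 1):(i1 - 1)]
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  nodes <- ntab[order(ntab[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")[-1]
  parsed <- lapply(strsplit(trimws(el), "\\s+"), as.numeric)
  tets <- Filter(function(p) p[2] == 4, parsed)
  tris <- Filter(function(p) p[2] == 2, parsed)
  if (!length(tets)) stop("no tetrahedra in msh file")
  elems <- t(vapply(tets, function(p) p[length(p) - 3:0], numeric(4)))
  region <- vapply(tets, function(p) p[4], numeric(1))
  mesh <- fe_mesh(nodes, elems, region = as.integer(region))
  if (length(tris)) {
    key <- function(f) paste(apply(f, 1, function(r) paste(sort(r), collapse = "-")))
    tf <- t(vapply(tris, function(p) p[length(p) - 2:0], numeric(3)))
    tl <- vapply(tris, function(p) p[4], numeric(1))
    id <- match(key(mesh$facets), key(tf))
    mesh$facet_label[!is.na(id)] <- as.integer(tl[id[!is.na(id)]])
  }
  mesh
}

xml_escape_num <- function(x) format(x, digits = 17, trim = TRUE,
                                     scientific = FALSE)

#' Write mesh and fields to VTK XML unstructured format (.vtu)
#'
#' ASCII VTU writer supporting linear tetrahedra plus optional point and cell
#' data arrays, for visualisation in ParaView. Vector point data must have
#' 3 columns.
#'
#' @param mesh an [fe_mesh()].
#' @param path output path.
#' @param point_data named list of vectors (length n nodes) or n x 3 matrices.
#' @param cell_data named list of vectors (length = number of elements).
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  write_vtu_raw(mesh$nodes, mesh$elems, rep(10L, nrow(mesh$elems)), path,
                point_data = point_data,
                cell_data = c(cell_data, list(region = mesh$region)))
}

#' Write a vascular network to VTU as polylines
#'
#' Each segment becomes a VTK line cell; radius, subtree and compartment ids
#' are written as cell data.
#'
#' @param network a [vascular_network()].
#' @param path output path.
#' @param cell_data extra named list of per-segment vectors.
#' @export
write_network_vtu <- function(network, path, cell_data = list()) {
  seg <- network$segments
  cells <- cbind(match(seg$node_a, network$nodes$id),
                 match(seg$node_b, network$nodes$id))
  cd <- c(list(radius = seg$radius, subtree = seg$subtree_id), cell_data)
  if (!is.null(seg$compartment_id)) cd$compartment <- seg$compartment_id
  write_vtu_raw(as.matrix(network$nodes[, c("x", "y", "z")]), cells,
                rep(3L, nrow(cells)), path, cell_data = cd)
}

write_vtu_raw <- function(points, cells, vtk_types, path,
                          point_data = list(), cell_data = list()) {
  con <- file(path, "w"); on.exit(close(con))
  np <- nrow(points); nc <- nrow(cells)
  w <- function(...) writeLines(paste0(...), con)
  arr <- function(name, x, ncomp = 1)
    c(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp),
      paste(apply(matrix(x, ncol = ncomp), 1, function(r)
        paste(format(r, digits = 12), collapse = " ")), collapse = "\n"),
      "</DataArray>")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc))
  w("<Points>")
  writeLines(arr("Points", as.vector(points), 3), con)
  w("</Points>")
  w("<Cells>")
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(apply(cells - 1L, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w("</DataArray>")
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(cumsum(rep(ncol(cells), nc)), collapse = " "), con)
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(vtk_types, collapse = " "), con)
  w("</DataArray>")
  w("</Cells>")
  if (length(point_data)) {
    w("<PointData>")
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      writeLines(arr(nm, as.vector(as.matrix(x)),
                     if (is.matrix(x)) ncol(x) else 1), con)
    }
    w("</PointData>")
  }
  if (length(cell_data)) {
    w("<CellData>")
    for (nm in names(cell_data)) writeLines(arr(nm, cell_data[[nm]]), con)
    w("</CellData>")
  }
  w("</Piece>")
  w("</UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}
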