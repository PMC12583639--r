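# Tetrahedral mesh container. Units are mm throughout.
#
# nodes:      n x 3 numeric matrix of coordinates
# elements:   m x 4 integer matrix of node indices (positive volume)
# region:     character vector of length m (e.g. bone_left, bone_right, disc)
# node_sets:  named list of integer node-index vectors
# elem_sets:  named list of integer element-index vectors
# facet_sets: named list of f x 3 integer matrices (surface triangles)

#' Construct a tetrahedral finite-element mesh
#'
#' @param nodes n x 3 matrix of node coordinates (mm).
#' @param elements m x 4 integer matrix of tetrahedron connectivity.
#' @param region Character vector of length m tagging each element with a
#'   body/part name.
#' @param node_sets,elem_sets,facet_sets Named lists of node indices, element
#'   indices and surface-triangle matrices.
#' @param fix_orientation Reorder inverted tetrahedra (swap last two nodes)
#'   so all volumes are positive.
#' @return An object of class `fe_mesh`.
#' @export
fe_mesh <- function(nodes, elements, region = rep("body", nrow(elements)),
                    node_sets = list(), elem_sets = list(),
                    facet_sets = list(), fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 4,
            length(region) == nrow(elements))
  if (max(elements) > nrow(nodes) || min(elements) < 1) {
    stop("element connectivity references nodes outside the mesh", call. = FALSE)
  }
  V <- tet_volumes(nodes, elements)
  if (fix_orientation && any(V < 0)) {
    flip <- V < 0
    elements[flip, c(3, 4)] <- elements[flip, c(4, 3)]
    V <- abs(V)
  }
  bad <- which(V <= 1e-12)
  if (length(bad)) {
    stop("degenerate (zero/negative volume) elements: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  for (nm in names(node_sets)) {
    if (length(node_sets[[nm]]) == 0) stop("empty node set: ", nm, call. = FALSE)
    if (max(node_sets[[nm]]) > nrow(nodes)) {
      stop("node set `", nm, "` references missing nodes", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, elements = elements,
                 region = as.character(region),
                 node_sets = node_sets, elem_sets = elem_sets,
                 facet_sets = facet_sets),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d tetrahedra, regions: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(unique(x$region), collapse = ", ")))
  cat(sprintf("  node sets: %s\n  facet sets: %s\n",
              paste(names(x$node_sets), collapse = ", "),
              paste(names(x$facet_sets), collapse = ", ")))
  invisible(x)
}

#' Signed volumes of tetrahedra
#'
#' @param nodes n x 3 coordinate matrix.
#' @param elements m x 4 connectivity matrix.
#' @return Numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  a <- nodes[elements[, 2], , drop = FALSE] - p1
  b <- nodes[elements[, 3], , drop = FALSE] - p1
  c3 <- nodes[elements[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Look up a node set by name (integer vectors pass through).
resolve_node_set <- function(mesh, set) {
  if (is.character(set)) {
    if (is.null(mesh$node_sets[[set]])) {
      stop("unknown node set: ", set, call. = FALSE)
    }
    mesh$node_sets[[set]]
  } else {
    as.integer(set)
  }
}

resolve_facet_set <- function(mesh, set) {
  if (is.character(set)) {
    if (is.null(mesh$facet_sets[[set]])) {
      stop("unknown facet set: ", set, call. = FALSE)
    }
    mesh$facet_sets[[set]]
  } else {
    as.matrix(set)
  }
}

# ---- structured box grid ----------------------------------------------------

# Kuhn 6-tet split of a hexahedron (local vertices 0..7 in the usual VTK
# ordering). All six tets share the main diagonal 0-6, which makes the split
# conforming across a structured grid of identically oriented hexes.
HEX_TO_TETS <- matrix(c(
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7,
  1, 6, 2, 7), ncol = 4, byrow = TRUE)

#' Tetrahedral mesh of a box from grid lines
#'
#' Builds a structured tetrahedral mesh on the grid `xs x ys x zs` by
#' splitting each hexahedral cell into six tetrahedra (conforming split).
#' Mostly used for verification problems (patch tests, beams, glued blocks)
#' and as the building block of the synthetic pelvis.
#'
#' @param xs,ys,zs Strictly increasing numeric vectors of grid coordinates.
#' @param region Region tag applied to all elements.
#' @return An `fe_mesh`.
#' @export
box_grid_mesh <- function(xs, ys, zs, region = "body") {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  stopifnot(nx >= 2, ny >= 2, nz >= 2,
            !is.unsorted(xs, strictly = TRUE),
            !is.unsorted(ys, strictly = TRUE),
            !is.unsorted(zs, strictly = TRUE))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  nid <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  cells <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1),
                       k = seq_len(nz - 1), KEEP.OUT.ATTRS = FALSE)
  # VTK hex vertex order: (i,j,k),(i+1,j,k),(i+1,j+1,k),(i,j+1,k), then k+1
  v <- cbind(nid(cells$i,     cells$j,     cells$k),
             nid(cells$i + 1, cells$j,     cells$k),
             nid(cells$i + 1, cells$j + 1, cells$k),
             nid(cells$i,     cells$j + 1, cells$k),
             nid(cells$i,     cells$j,     cells$k + 1),
             nid(cells$i + 1, cells$j,     cells$k + 1),
             nid(cells$i + 1, cells$j + 1, cells$k + 1),
             nid(cells$i,     cells$j + 1, cells$k + 1))
  elems <- do.call(rbind, lapply(seq_len(nrow(HEX_TO_TETS)), function(t) {
    v[, HEX_TO_TETS[t, ], drop = FALSE]
  }))
  fe_mesh(nodes, elems, region = rep(region, nrow(elems)))
}

# Nodes of a mesh lying on a coordinate plane (within tol).
nodes_on_plane <- function(mesh, axis, value, tol = 1e-8) {
  which(abs(mesh$nodes[, axis] - value) < tol)
}

#' Extract boundary triangles of a tetrahedral mesh
#'
#' Returns the facets that belong to exactly one tetrahedron, optionally
#' restricted to a subset of elements.
#'
#' @param mesh An `fe_mesh`.
#' @param elems Optional integer vector of element indices to restrict to.
#' @return Integer matrix (f x 3) of boundary triangles.
#' @export
boundary_facets <- function(mesh, elems = NULL) {
  el <- mesh$elements
  if (!is.null(elems)) el <- el[elems, , drop = FALSE]
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' Restrict facets to a node set
#'
#' Keeps the triangles whose three nodes all belong to `node_ids`.
#'
#' @param facets Integer f x 3 facet matrix.
#' @param node_ids Integer node ids.
#' @return Filtered facet matrix.
#' @export
facets_within <- function(facets, node_ids) {
  keep <- matrix(facets %in% node_ids, nrow = nrow(facets))
  facets[rowSums(keep) == 3L, , drop = FALSE]
}
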