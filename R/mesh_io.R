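# Plain-text mesh readers/writers: legacy ASCII VTK unstructured grids,
# an Abaqus-INP subset (*NODE, *ELEMENT C3D4, *NSET, *ELSET) and Gmsh MSH 2.2.
# Only what the pipeline needs; no binary variants.

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write a mesh (and optional fields) as legacy ASCII VTK
#'
#' @param mesh An [fe_mesh()].
#' @param path Output file (conventionally `.vtk`).
#' @param point_data Named list of per-node vectors (length n) or n x 3
#'   matrices (written as VECTORS).
#' @param cell_data Named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "symphysim mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
           fmt_num(mesh$nodes[, 3])))
  wl(sprintf("CELLS %d %d", m, 5 * m))
  e0 <- mesh$elements - 1L
  wl(paste(4L, e0[, 1], e0[, 2], e0[, 3], e0[, 4]))
  wl(sprintf("CELL_TYPES %d", m))
  wl(as.character(rep(10L, m)))
  region_id <- as.integer(factor(mesh$region, levels = unique(mesh$region)))
  cell_data <- c(list(region_id = region_id), cell_data)
  if (length(cell_data)) {
    wl(sprintf("CELL_DATA %d", m))
    for (nm in names(cell_data)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(fmt_num(as.numeric(cell_data[[nm]])))
    }
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        wl(sprintf("VECTORS %s double", nm))
        wl(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(fmt_num(as.numeric(v)))
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of tetrahedra
#'
#' @param path VTK file written by [write_vtk()] or compatible (cell type 10).
#' @return An [fe_mesh()] (region restored from the `region_id` cell field if
#'   present).
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)[1]
  n <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  pts <- scan(text = txt[(ip + 1):length(txt)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", txt)[1]
  m <- as.integer(strsplit(txt[ic], "\\s+")[[1]][2])
  cl <- scan(text = txt[(ic + 1):length(txt)], n = 5 * m, quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  if (any(cl[, 1] != 4)) stop("only tetrahedral cells are supported", call. = FALSE)
  elements <- cl[, 2:5] + 1L
  region <- rep("body", m)
  ir <- grep("^SCALARS region_id", txt)
  if (length(ir)) {
    rid <- scan(text = txt[(ir[1] + 2):length(txt)], n = m, quiet = TRUE)
    region <- paste0("region_", as.integer(rid))
  }
  fe_mesh(nodes, elements, region = region, fix_orientation = FALSE)
}

#' Write a mesh as an Abaqus-INP subset
#'
#' Emits `*NODE`, one `*ELEMENT, TYPE=C3D4, ELSET=<region>` block per region,
#' `*NSET` blocks for every node set and `*ELSET` blocks for element sets.
#'
#' @inheritParams write_vtk
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("*HEADING", "symphysim mesh export", "*NODE")
  wl(paste(seq_len(nrow(mesh$nodes)), fmt_num(mesh$nodes[, 1]),
           fmt_num(mesh$nodes[, 2]), fmt_num(mesh$nodes[, 3]), sep = ", "))
  eid <- seq_len(nrow(mesh$elements))
  for (rg in unique(mesh$region)) {
    sel <- mesh$region == rg
    wl(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", rg))
    wl(paste(eid[sel], mesh$elements[sel, 1], mesh$elements[sel, 2],
             mesh$elements[sel, 3], mesh$elements[sel, 4], sep = ", "))
  }
  emit_ids <- function(ids) {
    ids <- as.integer(ids)
    grp <- split(ids, ceiling(seq_along(ids) / 12))
    vapply(grp, function(g) paste(g, collapse = ", "), character(1))
  }
  for (nm in names(mesh$node_sets)) {
    wl(sprintf("*NSET, NSET=%s", nm))
    wl(emit_ids(mesh$node_sets[[nm]]))
  }
  for (nm in names(mesh$elem_sets)) {
    wl(sprintf("*ELSET, ELSET=%s", nm))
    wl(emit_ids(mesh$elem_sets[[nm]]))
  }
  invisible(path)
}

#' Read an Abaqus-INP subset
#'
#' Supports `*NODE`, `*ELEMENT TYPE=C3D4` (ELSET becomes the region tag),
#' `*NSET` and `*ELSET` blocks without GENERATE.
#'
#' @param path INP file.
#' @return An [fe_mesh()].
#' @export
read_inp <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\*\\*", txt)]
  is_kw <- grepl("^\\*", txt)
  blocks <- split(seq_along(txt), cumsum(is_kw))
  nodes <- NULL; elems <- list(); region <- list()
  node_sets <- list(); elem_sets <- list()
  for (b in blocks) {
    kw <- toupper(txt[b[1]])
    body <- txt[b[-1]]
    body <- body[nzchar(trimws(body))]
    if (!length(body) && !grepl("^\\*HEADING", kw)) next
    parse_rows <- function(lines) {
      do.call(rbind, lapply(strsplit(lines, ","), function(x) as.numeric(trimws(x))))
    }
    if (grepl("^\\*NODE", kw)) {
      d <- parse_rows(body)
      nodes <- d[order(d[, 1]), 2:4, drop = FALSE]
    } else if (grepl("^\\*ELEMENT", kw)) {
      if (!grepl("TYPE=C3D4", kw)) stop("only C3D4 elements supported", call. = FALSE)
      rg <- sub(".*ELSET=([^,]+).*", "\\1", kw)
      if (identical(rg, kw)) rg <- "body"
      d <- parse_rows(body)
      elems[[length(elems) + 1]] <- d[, 2:5, drop = FALSE]
      region[[length(region) + 1]] <- rep(tolower(rg), nrow(d))
    } else if (grepl("^\\*NSET", kw)) {
      nm <- sub(".*NSET=([^,]+).*", "\\1", kw)
      node_sets[[tolower(nm)]] <- as.integer(unlist(lapply(
        strsplit(body, ","), function(x) as.integer(trimws(x)))))
    } else if (grepl("^\\*ELSET", kw)) {
      nm <- sub(".*ELSET=([^,]+).*", "\\1", kw)
      elem_sets[[tolower(nm)]] <- as.integer(unlist(lapply(
        strsplit(body, ","), function(x) as.integer(trimws(x)))))
    }
  }
  if (is.null(nodes) || !length(elems)) stop("no *NODE/*ELEMENT data found", call. = FALSE)
  fe_mesh(nodes, do.call(rbind, elems), region = unlist(region),
          node_sets = node_sets, elem_sets = elem_sets,
          fix_orientation = FALSE)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Regions are encoded as physical/geometrical tags (in order of first
#' appearance).
#'
#' @inheritParams write_vtk
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
     as.character(nrow(mesh$nodes)))
  wl(paste(seq_len(nrow(mesh$nodes)), fmt_num(mesh$nodes[, 1]),
           fmt_num(mesh$nodes[, 2]), fmt_num(mesh$nodes[, 3])))
  wl("$EndNodes", "$Elements", as.character(nrow(mesh$elements)))
  rid <- as.integer(factor(mesh$region, levels = unique(mesh$region)))
  wl(paste(seq_len(nrow(mesh$elements)), 4L, 2L, rid, rid,
           mesh$elements[, 1], mesh$elements[, 2], mesh$elements[, 3],
           mesh$elements[, 4]))
  wl("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh (tetrahedra only)
#'
#' @param path MSH file.
#' @return An [fe_mesh()] with regions `region_<tag>`.
#' @export
read_msh <- function(path) {
  txt <- readLines(path)
  i0 <- match("$Nodes", txt)
  nn <- as.integer(txt[i0 + 1])
  nd <- matrix(scan(text = txt[(i0 + 2):(i0 + 1 + nn)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  nodes <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  j0 <- match("$Elements", txt)
  ne <- as.integer(txt[j0 + 1])
  rows <- strsplit(txt[(j0 + 2):(j0 + 1 + ne)], "\\s+")
  tet <- t(vapply(rows, function(r) {
    r <- as.numeric(r)
    ntags <- r[3]
    if (r[2] != 4) return(rep(NA_real_, 5))
    c(r[4], r[(4 + ntags):(7 + ntags)])
  }, numeric(5)))
  tet <- tet[stats::complete.cases(tet), , drop = FALSE]
  if (!nrow(tet)) stop("no tetrahedral elements in MSH file", call. = FALSE)
  fe_mesh(nodes, tet[, 2:5], region = paste0("region_", as.integer(tet[, 1])),
          fix_orientation = FALSE)
}
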