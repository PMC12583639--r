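# Parametric "toy pelvis": two curved bone bars joined anteriorly through a
# soft interpubic-disc block, with named anatomical sets (SIJ patches,
# acetabular patch, symphysis interfaces, 27 muscle attachment sites).
# Stands in for subject CT geometry so the whole pipeline runs on synthetic
# data; it is deliberately schematic, not an anatomical pelvis.

#' Parameters of the synthetic toy pelvis
#'
#' Geometry: each hip bone is a square-section bar of length `arm_length`
#' swept along a circular arc of total angle `arc_angle` in the transverse
#' (x-z) plane, from the pubic end (anterior, near the mid-sagittal plane)
#' to the sacroiliac end (posterior-lateral). The interpubic disc is a
#' slit-like block of dimensions `disc_dims` (width across the midline,
#' height, depth) bridging the two pubic end faces. Mesh edge lengths follow
#' the bone/symphysis refinement idea: `edge_coarse` in the bone, refined
#' toward the symphysis (`edge_fine` within `refine_length` of the pubic
#' end), `disc_edge` in the disc.
#'
#' Densities are calibration-scale (g/cm^3): cortical shell elements (within
#' `shell_thickness` of the bone surface) receive `rho_ct_cortical`, the
#' cancellous core `rho_ct_cancellous`, with zero-truncated Gaussian noise of
#' sd `noise_sd`.
#'
#' @param arm_length Bone bar length (mm).
#' @param cross_section Square cross-section side (mm).
#' @param disc_dims Disc width (x), height (y), depth (z) in mm.
#' @param arc_angle Total sweep angle (rad); 0 gives a straight bar.
#' @param edge_coarse,edge_fine,refine_length,disc_edge Mesh sizing (mm).
#' @param rho_ct_cortical,rho_ct_cancellous Density levels (g/cm^3).
#' @param shell_thickness Cortical shell thickness (mm).
#' @param noise_sd Density noise sd (g/cm^3).
#' @param seed Integer seed for the density noise.
#' @return A list of class `toy_pelvis_params`.
#' @export
toy_pelvis_params <- function(arm_length = 110, cross_section = 24,
                              disc_dims = c(5, 18, 18), arc_angle = 1.92,
                              edge_coarse = 5, edge_fine = 2.5,
                              refine_length = 10, disc_edge = 2,
                              rho_ct_cortical = 1.0,
                              rho_ct_cancellous = 0.3,
                              shell_thickness = 3, noise_sd = 0.03,
                              seed = 42L) {
  p <- list(arm_length = arm_length, cross_section = cross_section,
            disc_dims = disc_dims, arc_angle = arc_angle,
            edge_coarse = edge_coarse, edge_fine = edge_fine,
            refine_length = refine_length, disc_edge = disc_edge,
            rho_ct_cortical = rho_ct_cortical,
            rho_ct_cancellous = rho_ct_cancellous,
            shell_thickness = shell_thickness, noise_sd = noise_sd,
            seed = as.integer(seed))
  stopifnot(arm_length > 0, cross_section > 0, all(disc_dims > 0),
            arc_angle >= 0, edge_fine <= edge_coarse, edge_fine > 0,
            disc_edge > 0, rho_ct_cortical > rho_ct_cancellous,
            shell_thickness > 0, noise_sd >= 0)
  structure(p, class = "toy_pelvis_params")
}

# Muscle attachment layout on the right bone bar: fraction of arc length
# (0 = pubic end, 1 = SIJ end), attachment face and the target-point group
# that defines the default line of action.
MUSCLE_LAYOUT <- data.frame(
  muscle = c("adductor_longus", "gracilis", "adductor_brevis",
             "adductor_magnus_1", "pectineus", "adductor_magnus_2",
             "adductor_magnus_3", "semitendinosus", "biceps_femoris_long",
             "semimembranosus", "quadratus_femoris", "biceps_femoris_short",
             "rectus_femoris", "sartorius", "tensor_fasciae_latae",
             "gluteus_minimus_1", "gluteus_minimus_2", "gluteus_minimus_3",
             "gluteus_medius_1", "gluteus_medius_2", "gluteus_medius_3",
             "gluteus_maximus_1", "gluteus_maximus_2", "gluteus_maximus_3",
             "iliacus", "psoas_major", "piriformis"),
  s_frac = c(0.04, 0.05, 0.07, 0.10, 0.12, 0.14, 0.17,
             0.20, 0.23, 0.26, 0.30, 0.35,
             0.55, 0.42, 0.40,
             0.46, 0.50, 0.54,
             0.55, 0.61, 0.67,
             0.85, 0.90, 0.95,
             0.50, 0.55, 0.90),
  face = c(rep("bottom", 12),
           "bottom", "top", "top",
           rep("lat", 9),
           "med", "med", "med"),
  target = c("femur_medial", "femur_medial", "femur_medial", "femur_medial",
             "femur_medial", "femur_medial", "femur_medial",
             "tibia_posterior", "tibia_posterior", "tibia_posterior",
             "greater_trochanter", "femur_shaft",
             "distal_femur_anterior", "distal_femur_anterior",
             "greater_trochanter",
             rep("greater_trochanter", 6),
             rep("greater_trochanter", 3),
             "lesser_trochanter", "lesser_trochanter", "greater_trochanter"),
  stringsAsFactors = FALSE
)

# graded 1D breaks: step `fine` on [0, refine_len], step `coarse` beyond.
graded_breaks <- function(L, fine, coarse, refine_len) {
  refine_len <- min(refine_len, L)
  s1 <- seq(0, refine_len, by = fine)
  if (max(s1) < refine_len) s1 <- c(s1, refine_len)
  rest <- L - max(s1)
  s2 <- if (rest > 1e-9) {
    max(s1) + seq_len(max(1, round(rest / coarse))) * rest /
      max(1, round(rest / coarse))
  }
  unique(c(s1, s2))
}

# Map bar-local coordinates (s along arc, t in-plane offset, yv vertical) to
# global coordinates for the right bone; pubic end face sits at x = x0.
bar_to_global <- function(s, t, yv, kappa, x0) {
  if (kappa < 1e-12) {
    cbind(x0 + s + 0 * t, yv, t)
  } else {
    cbind(x0 + sin(kappa * s) / kappa + t * sin(kappa * s),
          yv,
          (cos(kappa * s) - 1) / kappa + t * cos(kappa * s))
  }
}

#' Generate the synthetic toy pelvis mesh
#'
#' Builds the two-bone + disc tetrahedral mesh with all named sets:
#' `left_SIJ`, `right_SIJ` (bar end faces), `right_acetabulum` /
#' `left_acetabulum` (inferior patch at mid-arc), `symphysis_interface_left`
#' / `_right` (bone master facets at the pubic end faces),
#' `symphysis_disc_left` / `_right` (disc slave node sets) and one node set
#' per muscle of the packaged muscle table. The geometry is mirror-symmetric
#' about the mid-sagittal plane x = 0 and fully deterministic.
#'
#' @param params A [toy_pelvis_params()].
#' @return An [fe_mesh()] with regions `bone_right`, `bone_left`, `disc`;
#'   attribute `local` stores per-node bar-local coordinates used by
#'   [generate_density()].
#' @export
generate_toy_pelvis <- function(params = toy_pelvis_params()) {
  stopifnot(inherits(params, "toy_pelvis_params"))
  L <- params$arm_length
  cs <- params$cross_section
  hw <- params$disc_dims[1] / 2
  kappa <- if (params$arc_angle > 0) params$arc_angle / L else 0

  s_br <- graded_breaks(L, params$edge_fine, params$edge_coarse,
                        params$refine_length)
  m_cs <- max(2, round(cs / params$edge_coarse))
  c_br <- seq(-cs / 2, cs / 2, length.out = m_cs + 1)

  # build one bar in local coords (s, yv, t) on a box grid, then map
  bar <- box_grid_mesh(s_br, c_br, c_br, region = "bone_right")
  loc <- bar$nodes                       # columns: s, yv, t
  glob_r <- bar_to_global(loc[, 1], loc[, 3], loc[, 2], kappa, hw)
  nb <- nrow(glob_r)

  right <- fe_mesh(glob_r, bar$elements, region = rep("bone_right",
                                                      nrow(bar$elements)))
  left_nodes <- glob_r
  left_nodes[, 1] <- -left_nodes[, 1]
  left <- fe_mesh(left_nodes, bar$elements,
                  region = rep("bone_left", nrow(bar$elements)))

  disc_x <- seq(-hw, hw, length.out = max(2, round(2 * hw / params$disc_edge)) + 1)
  dh <- params$disc_dims[2] / 2; dd <- params$disc_dims[3] / 2
  disc <- box_grid_mesh(disc_x,
                        seq(-dh, dh, length.out = max(2, round(2 * dh / params$disc_edge)) + 1),
                        seq(-dd, dd, length.out = max(2, round(2 * dd / params$disc_edge)) + 1),
                        region = "disc")

  nodes <- rbind(right$nodes, left$nodes, disc$nodes)
  elements <- rbind(right$elements, left$elements + nb,
                    disc$elements + 2L * nb)
  region <- c(right$region, left$region, disc$region)

  tol <- 1e-8
  s_loc <- loc[, 1]; y_loc <- loc[, 2]; t_loc <- loc[, 3]
  end_face_r <- which(abs(s_loc - L) < tol)
  pub_face_r <- which(abs(s_loc) < tol)

  # acetabular patch: inferior face, posterior third of the arc (the hip
  # socket sits close under the sacroiliac joint, not at mid-ring)
  acet_sel <- which(abs(y_loc + cs / 2) < tol &
                    s_loc >= 0.62 * L & s_loc <= 0.80 * L)
  if (!length(acet_sel)) stop("acetabular patch empty; refine the mesh", call. = FALSE)

  node_sets <- list(
    right_SIJ = end_face_r,
    left_SIJ = end_face_r + nb,
    right_acetabulum = acet_sel,
    left_acetabulum = acet_sel + nb
  )

  # muscle attachments on the right bone: nodes of the given face within a
  # fixed radius (in bar-local coordinates) of the target arc position
  att_radius <- max(6, params$edge_coarse * 1.2)
  for (i in seq_len(nrow(MUSCLE_LAYOUT))) {
    mi <- MUSCLE_LAYOUT[i, ]
    s0 <- mi$s_frac * L
    on_face <- switch(mi$face,
      top = abs(y_loc - cs / 2) < tol,
      bottom = abs(y_loc + cs / 2) < tol,
      lat = abs(t_loc - cs / 2) < tol,
      med = abs(t_loc + cs / 2) < tol)
    w_loc <- if (mi$face %in% c("top", "bottom")) t_loc else y_loc
    sel <- which(on_face & abs(s_loc - s0) <= att_radius &
                 abs(w_loc) <= att_radius)
    if (!length(sel)) {
      sel <- which(on_face)[which.min(abs(s_loc[on_face] - s0))]
    }
    node_sets[[mi$muscle]] <- sel
  }

  # disc interface node sets (slave side of the ties)
  nd0 <- 2L * nb
  node_sets$symphysis_disc_right <- nd0 + which(abs(disc$nodes[, 1] - hw) < tol)
  node_sets$symphysis_disc_left <- nd0 + which(abs(disc$nodes[, 1] + hw) < tol)

  mesh <- fe_mesh(nodes, elements, region = region, node_sets = node_sets)

  # master facet sets on the bone pubic end faces (after orientation fixing)
  m_r <- seq_len(nrow(right$elements))
  m_l <- m_r + nrow(right$elements)
  fac_r <- facets_within(boundary_facets(mesh, m_r), pub_face_r)
  fac_l <- facets_within(boundary_facets(mesh, m_l), pub_face_r + nb)
  if (!nrow(fac_r) || !nrow(fac_l)) {
    stop("symphysis interface facets not found", call. = FALSE)
  }
  mesh$facet_sets$symphysis_interface_right <- fac_r
  mesh$facet_sets$symphysis_interface_left <- fac_l
  mesh$elem_sets <- list(
    bone_right = which(mesh$region == "bone_right"),
    bone_left = which(mesh$region == "bone_left"),
    disc = which(mesh$region == "disc"))

  side <- c(rep(1, nb), rep(-1, nb), rep(0, nrow(disc$nodes)))
  attr(mesh, "local") <- list(
    s = c(s_loc, s_loc, rep(NA_real_, nrow(disc$nodes))),
    t = c(t_loc, t_loc, rep(NA_real_, nrow(disc$nodes))),
    y = c(y_loc, y_loc, rep(NA_real_, nrow(disc$nodes))),
    side = side, params = params)
  mesh
}

#' Generate a synthetic per-element CT density field
#'
#' Bone elements whose centroid lies within `shell_thickness` of the bar
#' surface (cross-section boundary or bar ends) receive the cortical density
#' level, interior elements the cancellous level; zero-truncated Gaussian
#' noise is added with the given seed. Disc elements get `NA` (no bone
#' density).
#'
#' @param mesh A [generate_toy_pelvis()] mesh.
#' @param params The [toy_pelvis_params()] used to build it.
#' @param seed Noise seed; defaults to `params$seed`.
#' @return A data.frame `element_id`, `rho_ct` of class `density_field`,
#'   with a `provenance` attribute recording parameters and seed and a
#'   `shell` attribute flagging shell elements.
#' @export
generate_density <- function(mesh, params = attr(mesh, "local")$params,
                             seed = params$seed) {
  local <- attr(mesh, "local")
  if (is.null(local)) stop("mesh lacks bar-local coordinates", call. = FALSE)
  cs <- params$cross_section
  L <- params$arm_length
  if (params$shell_thickness >= cs / 2) {
    warning("shell thickness exceeds half the cross-section: all-cortical bone",
            call. = FALSE)
  }
  m <- nrow(mesh$elements)
  cent_s <- rowMeans(matrix(local$s[mesh$elements], m, 4))
  cent_t <- rowMeans(matrix(local$t[mesh$elements], m, 4))
  cent_y <- rowMeans(matrix(local$y[mesh$elements], m, 4))
  is_bone <- mesh$region != "disc"
  dist_surf <- pmin(cs / 2 - abs(cent_t), cs / 2 - abs(cent_y),
                    cent_s, L - cent_s)
  shell <- is_bone & dist_surf < params$shell_thickness
  rho <- rep(NA_real_, m)
  rho[is_bone] <- ifelse(shell[is_bone], params$rho_ct_cortical,
                         params$rho_ct_cancellous)
  if (params$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    rho[is_bone] <- rho[is_bone] +
      stats::rnorm(sum(is_bone), 0, params$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  rho[is_bone] <- pmax(rho[is_bone], 0)
  out <- data.frame(element_id = seq_len(m), rho_ct = rho)
  attr(out, "provenance") <- list(params = params, seed = seed)
  attr(out, "shell") <- shell
  class(out) <- c("density_field", "data.frame")
  out
}

#' Packaged per-muscle force table
#'
#' The 27 pelvic-region muscle forces active during single-leg stance, as
#' used for the muscle-load case. Cells whose printed source value contained
#' typesetting artifacts carry `ambiguous = TRUE` and a best-reading numeric
#' value; zeros are preserved.
#'
#' @return data.frame with `muscle`, `printed_name`, `printed_force`,
#'   `force_N`, `ambiguous`.
#' @export
table1_muscle_forces <- function() {
  path <- system.file("extdata", "table1_muscle_forces.csv",
                      package = "symphysim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "character",
                                 "numeric", "logical"))
}

# Default muscle target points (mm): schematic femur/tibia landmarks placed
# relative to the acetabular patch centroid of the right bone.
muscle_targets <- function(mesh) {
  ac <- colMeans(mesh$nodes[mesh$node_sets$right_acetabulum, , drop = FALSE])
  list(
    greater_trochanter = ac + c(25, -45, 0),
    lesser_trochanter = ac + c(-5, -55, 10),
    femur_shaft = ac + c(5, -180, 0),
    femur_medial = ac + c(-15, -220, 10),
    distal_femur_anterior = ac + c(0, -350, 40),
    tibia_posterior = ac + c(0, -420, -40)
  )
}

#' Reference load cases for the toy pelvis
#'
#' Two packaged cases mirroring the single-leg-stance analysis:
#' \describe{
#'   \item{`reaction_only`}{the hip-joint reaction force (components
#'     `hip_force`, default `c(852, 2052, -1042)` N mapped to x, y, z)
#'     applied at the right-acetabulum reference point via distributed
#'     coupling;}
#'   \item{`muscles`}{the packaged per-muscle forces applied at their
#'     attachment sets, directed from each attachment centroid toward a
#'     per-muscle target point (schematic femoral/tibial landmarks;
#'     magnitudes are authoritative, directions a modelling choice). The two
#'     loadings are evaluated separately, as in the source analysis; set
#'     `include_hip_reaction = TRUE` to superimpose the hip reaction on the
#'     muscle case.}
#' }
#' Both cases fix the left SIJ and support the right SIJ on springs of total
#' stiffness `k_sij` per axis; load increments are 0.05 (initial) and 0.1
#' (maximum) of the total load.
#'
#' @param mesh A [generate_toy_pelvis()] mesh.
#' @param which `"reaction_only"` or `"muscles"`.
#' @param hip_force Hip reaction components (N) in x, y, z order.
#' @param k_sij Right-SIJ spring stiffness (N/mm).
#' @param targets Named list of target points (see [muscle_targets]
#'   defaults).
#' @param muscle_forces Muscle force table (defaults to
#'   [table1_muscle_forces()]).
#' @param include_hip_reaction Superimpose the hip reaction on the muscle
#'   case (default `FALSE`: the two loadings are separate).
#' @return A [load_case()].
#' @export
reference_load_case <- function(mesh, which = c("reaction_only", "muscles"),
                                hip_force = c(852, 2052, -1042),
                                k_sij = 4285,
                                targets = muscle_targets(mesh),
                                muscle_forces = table1_muscle_forces(),
                                include_hip_reaction = FALSE) {
  which <- match.arg(which)
  ref_pt <- colMeans(mesh$nodes[mesh$node_sets$right_acetabulum, , drop = FALSE])
  pl <- if (which == "reaction_only" || include_hip_reaction) {
    list(list(ref_point = ref_pt, set = "right_acetabulum",
              force = hip_force))
  } else {
    list()
  }
  ml <- list()
  if (which == "muscles") {
    for (i in seq_len(nrow(muscle_forces))) {
      f <- muscle_forces$force_N[i]
      if (f <= 0) next
      nm <- muscle_forces$muscle[i]
      tgt_name <- MUSCLE_LAYOUT$target[MUSCLE_LAYOUT$muscle == nm]
      if (!length(tgt_name) || is.null(mesh$node_sets[[nm]])) next
      ctr <- colMeans(mesh$nodes[mesh$node_sets[[nm]], , drop = FALSE])
      dir <- targets[[tgt_name]] - ctr
      dir <- dir / vnorm(dir)
      ml[[length(ml) + 1]] <- list(set = nm, force = f * dir)
    }
  }
  load_case(point_loads = pl, muscle_loads = ml,
            fixed = list(list(set = "left_SIJ", value = NULL)),
            springs = list(list(set = "right_SIJ", k = k_sij)),
            incr_init = 0.05, incr_max = 0.1, name = which)
}

#' Ties joining the disc to both pubic bones
#'
#' @param mesh A [generate_toy_pelvis()] mesh.
#' @param tol Projection tolerance (mm).
#' @return List of two `tie_map`s (right and left interface).
#' @export
symphysis_ties <- function(mesh, tol = 1e-6) {
  list(
    right = apply_tie(mesh, "symphysis_interface_right",
                      "symphysis_disc_right", tol = tol),
    left = apply_tie(mesh, "symphysis_interface_left",
                     "symphysis_disc_left", tol = tol)
  )
}

#' Write a density field as CSV
#'
#' @param density A [generate_density()] result.
#' @param path File path.
#' @export
write_density_csv <- function(density, path) {
  write_csv_stable(as.data.frame(density), path)
  invisible(path)
}
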