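# FE core: element stiffness, patch test, beam-theory oracle, tie
# constraints, distributed coupling, springs and the incremental solver.

test_that("element stiffness has exactly the six rigid-body modes", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ke <- element_stiffness(coords, E = 1000, nu = 0.3)
  ev <- eigen(ke$K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-6 * max(ev)), 6)
  expect_true(all(ev > -1e-9 * max(ev)))        # positive semi-definite
  # rigid translation produces no force
  u_rigid <- rep(c(1, -2, 3), 4)
  expect_equal(max(abs(ke$K %*% u_rigid)), 0, tolerance = 1e-9 * max(ke$K))
  expect_equal(ke$V, 1 / 6)
  bad <- coords; bad[4, ] <- c(0.5, 0.5, 0)     # coplanar
  expect_error(element_stiffness(bad, 1000, 0.3), "degenerate")
})

test_that("patch test: affine displacement field is reproduced exactly", {
  mesh <- cube_mesh(n = 3, L = 3)
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 2e-4, 8e-4), 3, 3, byrow = TRUE)
  b <- c(1e-3, -2e-3, 5e-4)
  bnd <- unique(as.integer(boundary_facets(mesh)))
  u_bnd <- mesh$nodes[bnd, ] %*% t(A) + matrix(b, length(bnd), 3, byrow = TRUE)
  mesh$node_sets$boundary <- bnd
  lc <- load_case(fixed = list(list(set = "boundary", value = u_bnd)),
                  incr_init = 1, incr_max = 1)
  sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                       2000)), lc)
  eps_exact <- 0.5 * (A + t(A))
  eps_voigt <- c(diag(eps_exact), 2 * eps_exact[1, 2], 2 * eps_exact[2, 3],
                 2 * eps_exact[1, 3])
  for (j in 1:6) {
    expect_equal(sol$strain[, j], rep(eps_voigt[j], nrow(sol$strain)),
                 tolerance = 1e-10)
  }
  # interior node displacements equal the affine map too
  u_exact <- mesh$nodes %*% t(A) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  expect_equal(sol$u, unname(u_exact), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("cantilever tip deflection approaches the beam-theory value", {
  L <- 100; b <- 10; E <- 2000; P <- 10
  mesh <- box_grid_mesh(seq(0, L, length.out = 101),
                        seq(-b / 2, b / 2, length.out = 21),
                        seq(-b / 2, b / 2, length.out = 3))
  mesh$node_sets$root <- which(abs(mesh$nodes[, 1]) < 1e-8)
  tip <- which(abs(mesh$nodes[, 1] - L) < 1e-8)
  mesh$node_sets$tip <- tip
  lc <- load_case(point_loads = list(list(ref_point = c(L, 0, 0),
                                          set = "tip", force = c(0, -P, 0))),
                  fixed = list(list(set = "root", value = NULL)),
                  incr_init = 1, incr_max = 1)
  sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                       E)), lc)
  w_eb <- P * L^3 / (3 * E * b^4 / 12)
  w_fe <- -mean(sol$u[tip, 2])
  expect_lt(abs(w_fe - w_eb) / w_eb, 0.05)
})

test_that("distributed coupling is statically equivalent to the point force", {
  mesh <- cube_mesh(n = 3, L = 6)
  set.seed(3)
  for (rep in 1:4) {
    ids <- which(abs(mesh$nodes[, 3] - 6) < 1e-8)
    ref <- c(stats::runif(2, -3, 9), 8)
    force <- stats::rnorm(3, sd = 500)
    tab <- distributed_coupling(mesh, ref, ids, force)
    expect_equal(colSums(as.matrix(tab[, c("fx", "fy", "fz")])), force,
                 tolerance = 1e-10 * max(1, max(abs(force))),
                 ignore_attr = TRUE)
    # independent moment summation about the reference point
    Msum <- c(0, 0, 0)
    for (i in seq_len(nrow(tab))) {
      r <- mesh$nodes[tab$node[i], ] - ref
      f <- as.numeric(tab[i, c("fx", "fy", "fz")])
      Msum <- Msum + c(r[2] * f[3] - r[3] * f[2],
                       r[3] * f[1] - r[1] * f[3],
                       r[1] * f[2] - r[2] * f[1])
    }
    expect_equal(max(abs(Msum)), 0, tolerance = 1e-8 * max(1, max(abs(force))))
  }
  # symmetric patch, axial force: equal shares
  ring <- which(abs(mesh$nodes[, 3] - 6) < 1e-8)
  ctr <- colMeans(mesh$nodes[ring, ])
  tab <- distributed_coupling(mesh, ctr, ring, c(0, 0, -100))
  expect_equal(tab$fz, rep(-100 / length(ring), length(ring)))
  expect_error(distributed_coupling(mesh, ctr, integer(0), c(1, 0, 0)),
               "empty")
})

test_that("tie constraints glue matching blocks like a merged mesh", {
  nv <- 3
  blkA <- box_grid_mesh(seq(0, 10, length.out = nv),
                        seq(0, 10, length.out = nv),
                        seq(0, 10, length.out = nv))
  blkB <- box_grid_mesh(seq(10, 20, length.out = nv),
                        seq(0, 10, length.out = nv),
                        seq(0, 10, length.out = nv))
  nA <- nrow(blkA$nodes)
  nodes <- rbind(blkA$nodes, blkB$nodes)
  elems <- rbind(blkA$elements, blkB$elements + nA)
  mesh <- fe_mesh(nodes, elems,
                  region = rep("body", nrow(elems)),
                  node_sets = list(
                    left = which(abs(nodes[, 1]) < 1e-8),
                    right = which(abs(nodes[, 1] - 20) < 1e-8),
                    slaveB = nA + which(abs(blkB$nodes[, 1] - 10) < 1e-8),
                    slaveA = which(abs(blkA$nodes[, 1] - 10) < 1e-8)))
  mesh$facet_sets$faceA <- facets_within(
    boundary_facets(mesh, seq_len(nrow(blkA$elements))),
    mesh$node_sets$slaveA)
  mesh$facet_sets$faceB <- facets_within(
    boundary_facets(mesh, nrow(blkA$elements) + seq_len(nrow(blkB$elements))),
    mesh$node_sets$slaveB)
  tie <- apply_tie(mesh, "faceA", "slaveB")
  # coincident grids: weights concentrate on the matching master node
  expect_equal(nrow(tie), length(mesh$node_sets$slaveB))
  expect_equal(unname(rowSums(as.matrix(tie[, c("w1", "w2", "w3")]))),
               rep(1, nrow(tie)))
  wmax <- unname(apply(as.matrix(tie[, c("w1", "w2", "w3")]), 1, max))
  expect_equal(wmax, rep(1, nrow(tie)), tolerance = 1e-8)

  mat <- elastic_bone_table(nrow(elems), 1500)
  lc <- load_case(point_loads = list(list(ref_point = c(20, 5, 5),
                                          set = "right",
                                          force = c(800, 0, 0))),
                  fixed = list(list(set = "left", value = NULL)),
                  incr_init = 1, incr_max = 1)
  sol_tied <- fe_solve(mesh, list(bone = mat), lc, ties = list(tie))
  # oracle: one merged conforming mesh of the union block
  merged <- box_grid_mesh(seq(0, 20, length.out = 2 * nv - 1),
                          seq(0, 10, length.out = nv),
                          seq(0, 10, length.out = nv))
  merged$node_sets$left <- which(abs(merged$nodes[, 1]) < 1e-8)
  merged$node_sets$right <- which(abs(merged$nodes[, 1] - 20) < 1e-8)
  sol_merged <- fe_solve(merged,
                         list(bone = elastic_bone_table(nrow(merged$elements),
                                                        1500)), lc)
  # compare tip-face mean displacement: stress transmitted, no gap
  uA <- colMeans(sol_tied$u[mesh$node_sets$right, ])
  uB <- colMeans(sol_merged$u[merged$node_sets$right, ])
  expect_equal(uA, uB, tolerance = 1e-8)
  # interface continuity: slave nodes follow the master surface
  iA <- mesh$node_sets$slaveA[order(mesh$nodes[mesh$node_sets$slaveA, 2],
                                    mesh$nodes[mesh$node_sets$slaveA, 3])]
  iB <- mesh$node_sets$slaveB[order(mesh$nodes[mesh$node_sets$slaveB, 2],
                                    mesh$nodes[mesh$node_sets$slaveB, 3])]
  expect_equal(sol_tied$u[iA, ], sol_tied$u[iB, ], tolerance = 1e-10)

  # tie symmetry: swapping master and slave barely changes the solution
  tie2 <- apply_tie(mesh, "faceB", "slaveA")
  sol_swap <- fe_solve(mesh, list(bone = mat), lc, ties = list(tie2))
  expect_equal(sol_swap$u, sol_tied$u, tolerance = 1e-8)

  # orphan slave nodes are reported
  expect_error(apply_tie(mesh, "faceA", "right"), "orphan|without a master")
})

test_that("spring supports carry -k u and a unit case recovers Hooke's law", {
  mesh <- cube_mesh(n = 2, L = 10)
  mesh$node_sets$base <- which(abs(mesh$nodes[, 2]) < 1e-8)
  mesh$node_sets$top <- which(abs(mesh$nodes[, 2] - 10) < 1e-8)
  k <- 4285
  lc <- load_case(point_loads = list(list(ref_point = c(5, 10, 5), set = "top",
                                          force = c(0, 1000, 0))),
                  fixed = list(list(set = "base", value = NULL)),
                  springs = list(list(set = "top", k = k)),
                  incr_init = 1, incr_max = 1)
  sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                       500)), lc)
  ids <- mesh$node_sets$top
  k_node <- k / length(ids)
  expect_equal(sol$reactions[ids, ], -k_node * sol$u[ids, ],
               tolerance = 1e-8)
  r <- reaction_at(sol, "top")
  expect_equal(r$magnitude, force_magnitude(r$force))
  # global equilibrium: supports balance the applied load
  tot <- reaction_at(sol, "base")$force + r$force + c(0, 1000, 0)
  expect_lt(force_magnitude(tot), 1e-6 * 1000)
})

test_that("elastic incremental solve equals the one-shot linear solve", {
  mesh <- cube_mesh(n = 2, L = 10)
  mesh$node_sets$base <- which(abs(mesh$nodes[, 2]) < 1e-8)
  mesh$node_sets$top <- which(abs(mesh$nodes[, 2] - 10) < 1e-8)
  mat <- elastic_bone_table(nrow(mesh$elements), 800)
  pl <- list(list(ref_point = c(5, 10, 5), set = "top",
                  force = c(120, -340, 90)))
  fixed <- list(list(set = "base", value = NULL))
  lc_inc <- load_case(point_loads = pl, fixed = fixed,
                      incr_init = 0.05, incr_max = 0.1)
  lc_one <- load_case(point_loads = pl, fixed = fixed,
                      incr_init = 1, incr_max = 1)
  s1 <- fe_solve(mesh, list(bone = mat), lc_inc)
  s2 <- fe_solve(mesh, list(bone = mat), lc_one)
  expect_equal(s1$u, s2$u, tolerance = 1e-8)
  expect_equal(nrow(s1$increments), 11)
  expect_equal(s1$increments$lambda[1], 0.05)
  expect_true(all(diff(s1$increments$lambda) <= 0.1 + 1e-12))
})

test_that("strain energy is non-decreasing under uniform refinement", {
  energy <- function(n) {
    mesh <- cube_mesh(n = n, L = 10)
    mesh$node_sets$base <- which(abs(mesh$nodes[, 2]) < 1e-8)
    mesh$node_sets$top <- which(abs(mesh$nodes[, 2] - 10) < 1e-8)
    lc <- load_case(point_loads = list(list(ref_point = c(5, 10, 5),
                                            set = "top",
                                            force = c(200, -500, 100))),
                    fixed = list(list(set = "base", value = NULL)),
                    incr_init = 1, incr_max = 1)
    sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                         700)), lc)
    0.5 * sum(as.numeric(t(sol$u)) * as.numeric(t(sol$applied)))
  }
  en <- vapply(c(1, 2, 4), energy, numeric(1))
  expect_true(all(diff(en) >= -1e-8 * abs(en[1])))
})

test_that("mirror-symmetric geometry and load give mirror displacements", {
  # a consistently split box grid has asymmetric diagonals, so build the
  # mesh from a half-block and its exact mirror image, sharing the x = 0
  # interface nodes
  half <- box_grid_mesh(seq(0, 6, length.out = 4),
                        seq(0, 4, length.out = 3), seq(0, 4, length.out = 3))
  nh <- nrow(half$nodes)
  on_mid <- abs(half$nodes[, 1]) < 1e-8
  remap <- integer(nh)
  remap[on_mid] <- which(on_mid)
  remap[!on_mid] <- nh + seq_len(sum(!on_mid))
  mir_nodes <- half$nodes[!on_mid, , drop = FALSE]
  mir_nodes[, 1] <- -mir_nodes[, 1]
  nodes <- rbind(half$nodes, mir_nodes)
  elems <- rbind(half$elements,
                 matrix(remap[half$elements], ncol = 4))
  mesh <- fe_mesh(nodes, elems, region = rep("body", nrow(elems)))
  mesh$node_sets$base <- which(abs(mesh$nodes[, 2]) < 1e-8)
  mesh$node_sets$top <- which(abs(mesh$nodes[, 2] - 4) < 1e-8)
  lc <- load_case(point_loads = list(list(ref_point = c(0, 4, 2), set = "top",
                                          force = c(0, -300, 50))),
                  fixed = list(list(set = "base", value = NULL)),
                  incr_init = 1, incr_max = 1)
  sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                       900)), lc)
  # pair nodes with their x-mirror images
  key <- function(M) paste(round(M[, 1], 8), round(M[, 2], 8),
                           round(M[, 3], 8))
  mirrored <- mesh$nodes; mirrored[, 1] <- -mirrored[, 1]
  idx <- match(key(mirrored), key(mesh$nodes))
  expect_false(anyNA(idx))
  expect_equal(sol$u[idx, 1], -sol$u[, 1], tolerance = 1e-6)
  expect_equal(sol$u[idx, 2:3], sol$u[, 2:3], tolerance = 1e-6)
})

test_that("solver rejects unsupported load cases and unknown sets", {
  mesh <- cube_mesh(n = 1, L = 1)
  lc <- load_case(point_loads = list(list(ref_point = c(0, 0, 0),
                                          set = 1:4, force = c(1, 0, 0))),
                  incr_init = 1, incr_max = 1)
  expect_error(fe_solve(mesh, list(bone = elastic_bone_table(6, 100)), lc),
               "fixed support")
  expect_error(apply_tie(mesh, "missing_facets", 1:2), "unknown facet set")
})
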