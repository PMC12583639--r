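# Shared fixtures. Everything is generated in code; the expensive default
# toy-pelvis solves are computed once per session and cached.

# homogeneous elastic "bone" table (yield far beyond reach) for verification
# problems
elastic_bone_table <- function(m, E, nu = 0.3) {
  data.frame(element_id = seq_len(m), rho = 1, tissue = "compact",
             E = E, nu = nu, sigma_y = 1e9, sigma_min = 1e8,
             E_p = -1, eps_ab = 1e9)
}

.toy_cache <- new.env(parent = emptyenv())

# Default-world toy pelvis with both reference load cases solved.
toy_run <- function() {
  if (!is.null(.toy_cache$run)) return(.toy_cache$run)
  params <- toy_pelvis_params()
  mesh <- generate_toy_pelvis(params)
  density <- generate_density(mesh, params)
  ib <- !is.na(density$rho_ct)
  mat <- bone_material_table(density$element_id[ib], density$rho_ct[ib])
  ties <- symphysis_ties(mesh)
  mats <- list(bone = mat, disc = disc_linearized())
  t0 <- proc.time()[["elapsed"]]
  sols <- lapply(c(reaction_only = "reaction_only", muscles = "muscles"),
                 function(case) {
                   fe_solve(mesh, mats, reference_load_case(mesh, case),
                            ties = ties)
                 })
  elapsed <- proc.time()[["elapsed"]] - t0
  .toy_cache$run <- list(params = params, mesh = mesh, density = density,
                         materials = mat, ties = ties, solutions = sols,
                         summaries = lapply(sols, summarize_solution),
                         solve_seconds = elapsed)
  .toy_cache$run
}

# Exhaustive oracle for the 3-muscle, 2-axis static optimization: solutions
# of the moment balance form a line a(t) = a_p + t * nvec; gridding t so each
# activation moves by <= 1e-3 over the feasible segment is an exhaustive
# search of the constraint manifold at that resolution.
grid_oracle_3m2a <- function(A, Q, lb = 0.01, ub = 1) {
  a_p <- as.numeric(t(A) %*% solve(A %*% t(A), Q))  # min-norm particular sol.
  nvec <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
            A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
            A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  nvec <- nvec / sqrt(sum(nvec^2))
  tlo <- -Inf; thi <- Inf
  for (i in 1:3) {
    if (abs(nvec[i]) < 1e-14) next
    r <- sort(c((lb - a_p[i]) / nvec[i], (ub - a_p[i]) / nvec[i]))
    tlo <- max(tlo, r[1]); thi <- min(thi, r[2])
  }
  if (tlo > thi) return(NULL)
  dt <- 1e-3 / max(abs(nvec))
  ts <- seq(tlo, thi, by = dt)
  if (ts[length(ts)] < thi) ts <- c(ts, thi)
  obj <- vapply(ts, function(t) sum((a_p + t * nvec)^2), numeric(1))
  a_p + ts[which.min(obj)] * nvec
}

# small cube meshes for patch/refinement tests
cube_mesh <- function(n = 2, L = 2) {
  s <- seq(0, L, length.out = n + 1)
  box_grid_mesh(s, s, s)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Voigt vector (11,22,33,12,23,13) -> 3x3 symmetric tensor and back
voigt_to_tensor <- function(s) {
  matrix(c(s[1], s[4], s[6],
           s[4], s[2], s[5],
           s[6], s[5], s[3]), 3, 3)
}
tensor_to_voigt <- function(S) {
  c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[1, 3])
}
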