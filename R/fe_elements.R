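# Linear tetrahedron element: constant-strain B operator and stiffness.
# Voigt order (11, 22, 33, 12, 23, 13) with engineering shear strains.

# 6x6 isotropic elasticity matrix for unit Young's modulus.
iso_D_unit <- function(nu) {
  c1 <- 1 / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- 1 / (2 * (1 + nu))
  D
}

# Shape-function gradients of a linear tet: 4x3 matrix G with rows grad(N_a),
# plus the volume. coords is 4x3.
tet_shape_gradients <- function(coords) {
  J <- rbind(coords[2, ] - coords[1, ],
             coords[3, ] - coords[1, ],
             coords[4, ] - coords[1, ])
  detJ <- det(J)
  V <- detJ / 6
  if (V <= 1e-12) {
    stop("degenerate tetrahedron (volume <= 0)", call. = FALSE)
  }
  Jinv <- solve(J)                       # columns: d xi / d x
  G <- rbind(-colSums(t(Jinv)), t(Jinv)) # grad N1 = -(g2+g3+g4)
  list(G = G, V = V)
}

# 6x12 strain-displacement matrix from shape gradients (dofs ordered
# u1x,u1y,u1z,u2x,...).
tet_B <- function(G) {
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    gx <- G[a, 1]; gy <- G[a, 2]; gz <- G[a, 3]
    B[1, c0 + 1] <- gx
    B[2, c0 + 2] <- gy
    B[3, c0 + 3] <- gz
    B[4, c0 + 1] <- gy; B[4, c0 + 2] <- gx
    B[5, c0 + 2] <- gz; B[5, c0 + 3] <- gy
    B[6, c0 + 1] <- gz; B[6, c0 + 3] <- gx
  }
  B
}

#' Stiffness matrix of a linear tetrahedron
#'
#' @param coords 4 x 3 matrix of vertex coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return List with `K` (12 x 12 stiffness, N/mm), `B` (6 x 12
#'   strain-displacement operator) and `V` (volume, mm^3).
#' @export
element_stiffness <- function(coords, E, nu) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4, ncol(coords) == 3)
  sg <- tet_shape_gradients(coords)
  if (sg$V <= 1e-12) {
    stop("degenerate tetrahedron (volume <= 0)", call. = FALSE)
  }
  B <- tet_B(sg$G)
  D <- E * iso_D_unit(nu)
  list(K = sg$V * t(B) %*% D %*% B, B = B, V = sg$V)
}

# Precompute everything assembly needs: per-element unit-modulus stiffness
# values (E factored out; nu fixed per element), triplet indices, a global
# sparse strain operator, volumes and dof maps.
fe_model_prep <- function(mesh, nu_elem) {
  m <- nrow(mesh$elements)
  n <- nrow(mesh$nodes)
  stopifnot(length(nu_elem) == m)
  edof <- matrix(0L, m, 12)
  for (a in 1:4) {
    edof[, 3 * a - 2] <- 3L * (mesh$elements[, a] - 1L) + 1L
    edof[, 3 * a - 1] <- 3L * (mesh$elements[, a] - 1L) + 2L
    edof[, 3 * a]     <- 3L * mesh$elements[, a]
  }
  Dunit <- list(); nu_key <- as.character(round(nu_elem, 10))
  for (k in unique(nu_key)) Dunit[[k]] <- iso_D_unit(as.numeric(k))

  kvals <- matrix(0, m, 144)       # row-wise vec of Ke for E = 1
  Bi <- integer(m * 72); Bj <- integer(m * 72); Bx <- numeric(m * 72)
  # displacement-gradient operator: row 9(e-1) + p + 3(q-1) holds du_p/dx_q
  Gi <- integer(m * 36); Gj <- integer(m * 36); Gx <- numeric(m * 36)
  V <- numeric(m)
  pos <- 0L; gpos <- 0L
  for (e in seq_len(m)) {
    sg <- tryCatch(
      tet_shape_gradients(mesh$nodes[mesh$elements[e, ], , drop = FALSE]),
      error = function(err) {
        stop("degenerate element ", e, ": ", conditionMessage(err),
             call. = FALSE)
      })
    V[e] <- sg$V
    B <- tet_B(sg$G)
    kvals[e, ] <- as.numeric(sg$V * t(B) %*% Dunit[[nu_key[e]]] %*% B)
    idx <- pos + seq_len(72)
    Bi[idx] <- rep(6L * (e - 1L) + 1:6, times = 12)
    Bj[idx] <- rep(edof[e, ], each = 6)
    Bx[idx] <- as.numeric(B)
    pos <- pos + 72L
    for (a in 1:4) {
      for (p in 1:3) {
        gidx <- gpos + seq_len(3)
        Gi[gidx] <- 9L * (e - 1L) + p + 3L * (1:3 - 1L)
        Gj[gidx] <- edof[e, 3L * (a - 1L) + p]
        Gx[gidx] <- sg$G[a, ]
        gpos <- gpos + 3L
      }
    }
  }
  Bglob <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx, dims = c(6 * m, 3 * n))
  Gglob <- Matrix::sparseMatrix(i = Gi, j = Gj, x = Gx, dims = c(9 * m, 3 * n))
  ii <- t(apply(edof, 1, function(d) rep(d, times = 12)))
  jj <- t(apply(edof, 1, function(d) rep(d, each = 12)))
  list(mesh = mesh, ndof = 3L * n, edof = edof, kvals = kvals,
       ki = as.integer(t(ii)), kj = as.integer(t(jj)),
       B = Bglob, Bgrad = Gglob, V = V, nu = nu_elem)
}

# Assemble the global stiffness for per-element moduli E (springs not
# included).
fe_assemble_K <- function(model, E_elem) {
  x <- as.numeric(t(model$kvals * E_elem))
  Matrix::sparseMatrix(i = model$ki, j = model$kj, x = x,
                       dims = c(model$ndof, model$ndof), symmetric = FALSE)
}

# Per-element strain (6-vector rows) from nodal displacements.
fe_strains <- function(model, u) {
  matrix(model$B %*% u, ncol = 6, byrow = TRUE)
}

# Stress rows from strain rows with per-element E, nu.
fe_stresses <- function(model, eps, E_elem) {
  m <- nrow(eps)
  sig <- matrix(0, m, 6)
  nu_key <- as.character(round(model$nu, 10))
  for (k in unique(nu_key)) {
    sel <- nu_key == k
    sig[sel, ] <- (eps[sel, , drop = FALSE] %*% t(iso_D_unit(as.numeric(k)))) *
      E_elem[sel]
  }
  sig
}
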