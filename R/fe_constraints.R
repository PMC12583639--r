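# Boundary conditions and multipoint constraints: surface-to-surface tie
# constraints, distributed (RBE3-style) couplings, fixed and spring supports.

#' Tie a slave surface to a master surface
#'
#' Surface-to-surface tie: every slave node is projected onto the master
#' facets; its degrees of freedom are constrained to the barycentric
#' interpolation of the master facet's nodes, so the interface transmits both
#' tension and compression ("gluing"). Slave nodes farther than `tol` from
#' every master facet are reported as orphans.
#'
#' @param mesh An [fe_mesh()].
#' @param master Facet set (name or f x 3 matrix) acting as master surface.
#' @param slave Node set (name or integer vector) to be tied.
#' @param tol Projection tolerance (mm): max normal distance and barycentric
#'   overshoot allowed.
#' @return A data.frame of class `tie_map` with columns `slave`, `m1..m3`,
#'   `w1..w3` (interpolation weights summing to 1).
#' @export
apply_tie <- function(mesh, master, slave, tol = 1e-6) {
  facets <- resolve_facet_set(mesh, master)
  snodes <- resolve_node_set(mesh, slave)
  X <- mesh$nodes
  nb <- nrow(facets)
  p1 <- X[facets[, 1], , drop = FALSE]
  e1 <- X[facets[, 2], , drop = FALSE] - p1
  e2 <- X[facets[, 3], , drop = FALSE] - p1
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  den <- d11 * d22 - d12^2
  out <- matrix(NA_real_, length(snodes), 6)
  orphans <- integer(0)
  bary_tol <- 1e-6
  for (s in seq_along(snodes)) {
    p <- X[snodes[s], ]
    w <- sweep(p1, 2, p, "-") * -1      # p - p1 per facet
    dp1 <- rowSums(w * e1); dp2 <- rowSums(w * e2)
    b1 <- (d22 * dp1 - d12 * dp2) / den
    b2 <- (d11 * dp2 - d12 * dp1) / den
    # distance from node to the facet plane point at (b1, b2)
    proj <- p1 + e1 * b1 + e2 * b2
    dist <- sqrt(rowSums(sweep(proj, 2, p, "-")^2))
    inside <- b1 >= -bary_tol & b2 >= -bary_tol & (b1 + b2) <= 1 + bary_tol
    cand <- which(inside & dist <= tol)
    if (!length(cand)) {
      orphans <- c(orphans, snodes[s])
      next
    }
    f <- cand[which.min(dist[cand])]
    bw <- c(1 - b1[f] - b2[f], b1[f], b2[f])
    bw <- pmax(bw, 0); bw <- bw / sum(bw)
    out[s, ] <- c(facets[f, ], bw)
  }
  if (length(orphans)) {
    stop("tie: slave nodes without a master facet within tol: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ...", call. = FALSE)
  }
  structure(data.frame(slave = snodes,
                       m1 = as.integer(out[, 1]), m2 = as.integer(out[, 2]),
                       m3 = as.integer(out[, 3]),
                       w1 = out[, 4], w2 = out[, 5], w3 = out[, 6]),
            class = c("tie_map", "data.frame"))
}

#' Distribute a reference-point force over a surface node set
#'
#' RBE3-style distributed coupling: nodal forces with resultant exactly equal
#' to the applied force and zero resultant moment about the reference point.
#' Uniform weights carry the force; the minimum-norm nodal correction field
#' cancels the moment introduced by the offset between the reference point and
#' the patch centroid.
#'
#' @param mesh An [fe_mesh()].
#' @param ref_point Numeric 3-vector (mm), the reference (load application)
#'   point.
#' @param set Node set (name or integer vector) receiving the load.
#' @param force Numeric 3-vector (N).
#' @return A data.frame `node`, `fx`, `fy`, `fz`.
#' @export
distributed_coupling <- function(mesh, ref_point, set, force) {
  ids <- resolve_node_set(mesh, set)
  if (!length(ids)) stop("distributed_coupling: empty node set", call. = FALSE)
  X <- mesh$nodes[ids, , drop = FALSE]
  n <- nrow(X)
  f0 <- matrix(rep(force / n, each = n), n, 3)
  r <- sweep(X, 2, ref_point, "-")
  # moment of the uniform share about the reference point; the correction
  # field c_i must produce the opposite moment with zero resultant:
  #   min sum ||c_i||^2  s.t.  sum c_i = 0,  sum r_i x c_i = M
  M <- -colSums(t(vapply(seq_len(n), function(i) cross3(r[i, ], f0[i, ]),
                         numeric(3))))
  if (vnorm(M) > 1e-12 * max(1, vnorm(force)) * max(1, max(abs(r)))) {
    A <- matrix(0, 6, 6)
    A[1:3, 1:3] <- n * diag(3)
    S <- lapply(seq_len(n), function(i) skew3(r[i, ]))
    Ssum <- Reduce(`+`, S)
    SSt <- Reduce(`+`, lapply(S, function(s) s %*% t(s)))
    A[1:3, 4:6] <- t(Ssum)
    A[4:6, 1:3] <- Ssum
    A[4:6, 4:6] <- SSt
    rhs <- c(0, 0, 0, M)
    lam <- solve(A + diag(1e-12 * max(1, max(abs(A))), 6), rhs)
    corr <- t(vapply(seq_len(n), function(i) {
      lam[1:3] + cross3(lam[4:6], r[i, ])
    }, numeric(3)))
    f0 <- f0 + corr
  }
  data.frame(node = ids, fx = f0[, 1], fy = f0[, 2], fz = f0[, 3])
}

# ---- constraint transformation ---------------------------------------------

# Build u_full = T %*% u_red + g from fixed dofs (value g) and tie maps.
# Slave dofs are eliminated; master and free dofs are retained.
build_transform <- function(ndof, fixed_dofs = integer(0),
                            fixed_vals = numeric(0), ties = NULL) {
  is_slave <- rep(FALSE, ndof)
  if (!is.null(ties) && nrow(ties)) {
    sdof <- as.integer(outer(3L * (ties$slave - 1L), 1:3, `+`))
    is_slave[sdof] <- TRUE
  }
  is_fixed <- rep(FALSE, ndof)
  is_fixed[fixed_dofs] <- TRUE
  if (any(is_fixed & is_slave)) {
    stop("a dof cannot be both fixed and tie-slave", call. = FALSE)
  }
  keep <- which(!is_fixed & !is_slave)
  red_index <- integer(ndof)
  red_index[keep] <- seq_along(keep)

  ti <- keep; tj <- seq_along(keep); tx <- rep(1, length(keep))
  g <- numeric(ndof)
  g[fixed_dofs] <- fixed_vals
  if (!is.null(ties) && nrow(ties)) {
    for (ax in 1:3) {
      sdof <- 3L * (ties$slave - 1L) + ax
      for (mcol in 1:3) {
        mdof <- 3L * (ties[[paste0("m", mcol)]] - 1L) + ax
        w <- ties[[paste0("w", mcol)]]
        mf <- is_fixed[mdof]
        if (any(!mf)) {
          if (any(is_slave[mdof])) {
            stop("tie master node is itself a slave; chained ties unsupported",
                 call. = FALSE)
          }
          ti <- c(ti, sdof[!mf]); tj <- c(tj, red_index[mdof[!mf]])
          tx <- c(tx, w[!mf])
        }
        if (any(mf)) g[sdof[mf]] <- g[sdof[mf]] + w[mf] * g[mdof[mf]]
      }
    }
  }
  Tm <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                             dims = c(ndof, length(keep)))
  list(T = Tm, g = g, keep = keep, is_fixed = is_fixed, is_slave = is_slave)
}

# Spring-support diagonal stiffness vector (length ndof): per-node stiffness
# on all three translations so the patch total per axis equals k_total.
spring_diagonal <- function(mesh, spring_sets) {
  kd <- numeric(3L * nrow(mesh$nodes))
  for (sp in spring_sets) {
    ids <- resolve_node_set(mesh, sp$set)
    if (sp$k <= 0) stop("spring stiffness must be > 0", call. = FALSE)
    k_node <- sp$k / length(ids)
    dofs <- as.integer(outer(3L * (ids - 1L), 1:3, `+`))
    kd[dofs] <- kd[dofs] + k_node
  }
  kd
}
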