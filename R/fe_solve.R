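# Static solver: external load assembly, constraint reduction, and the
# incremental secant-modulus iteration that realizes the elastoplastic
# softening bone law at small strain.

#' Define a load case
#'
#' @param point_loads List of `list(ref_point =, set =, force =)` entries:
#'   a force (N) applied at a reference point and spread over a surface node
#'   set by [distributed_coupling()].
#' @param muscle_loads List of `list(set =, force =)` entries: muscle pulls
#'   distributed over their attachment node set (reference point = patch
#'   centroid).
#' @param fixed List of `list(set =, value =)` entries; `value` is `NULL`
#'   (fully fixed), a 3-vector, or an n x 3 matrix of prescribed
#'   displacements (mm) for the set's nodes.
#' @param springs List of `list(set =, k =)` entries: grounded springs on all
#'   three translations of each node; the patch total per axis equals `k`
#'   (N/mm).
#' @param incr_init,incr_max Initial and maximum load-factor increments of
#'   the incremental scheme, in (0, 1].
#' @param name Optional case label.
#' @return An object of class `load_case`.
#' @export
load_case <- function(point_loads = list(), muscle_loads = list(),
                      fixed = list(), springs = list(),
                      incr_init = 0.05, incr_max = 0.1, name = "case") {
  stopifnot(incr_init > 0, incr_init <= 1, incr_max >= incr_init,
            incr_max <= 1)
  for (sp in springs) {
    if (is.null(sp$k) || sp$k <= 0) stop("spring stiffness must be > 0", call. = FALSE)
  }
  structure(list(point_loads = point_loads, muscle_loads = muscle_loads,
                 fixed = fixed, springs = springs,
                 incr_init = incr_init, incr_max = incr_max, name = name),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf(
    "load_case `%s`: %d point load(s), %d muscle load(s), %d fixed set(s), %d spring set(s)\n",
    x$name, length(x$point_loads), length(x$muscle_loads),
    length(x$fixed), length(x$springs)))
  invisible(x)
}

# External nodal force vector (length 3n) for a load case at full load.
assemble_loads <- function(mesh, lc) {
  f <- numeric(3L * nrow(mesh$nodes))
  add <- function(f, tab) {
    dofs <- 3L * (tab$node - 1L)
    f[dofs + 1L] <- f[dofs + 1L] + tab$fx
    f[dofs + 2L] <- f[dofs + 2L] + tab$fy
    f[dofs + 3L] <- f[dofs + 3L] + tab$fz
    f
  }
  for (pl in lc$point_loads) {
    f <- add(f, distributed_coupling(mesh, pl$ref_point, pl$set, pl$force))
  }
  for (ml in lc$muscle_loads) {
    ids <- resolve_node_set(mesh, ml$set)
    ctr <- colMeans(mesh$nodes[ids, , drop = FALSE])
    f <- add(f, distributed_coupling(mesh, ctr, ml$set, ml$force))
  }
  f
}

# Fixed dof indices and prescribed values from a load case.
fixed_dof_spec <- function(mesh, lc) {
  dofs <- integer(0); vals <- numeric(0)
  for (fx in lc$fixed) {
    ids <- resolve_node_set(mesh, fx$set)
    d <- as.integer(t(outer(3L * (ids - 1L), 1:3, `+`)))
    v <- fx$value
    if (is.null(v)) {
      v <- numeric(length(d))
    } else if (is.matrix(v)) {
      stopifnot(nrow(v) == length(ids), ncol(v) == 3)
      v <- as.numeric(t(v))
    } else {
      v <- rep(as.numeric(v), length(ids))
    }
    dofs <- c(dofs, d); vals <- c(vals, v)
  }
  dup <- duplicated(dofs)
  list(dofs = dofs[!dup], vals = vals[!dup])
}

# Per-element material arrays for the solver.
# materials: list(bone = bone_material_table rows indexed by element_id,
#                 disc = list(E, nu) from disc_linearized())
solver_materials <- function(mesh, materials) {
  m <- nrow(mesh$elements)
  is_disc <- mesh$region == "disc"
  E0 <- numeric(m); nu <- numeric(m)
  sig_y <- rep(Inf, m); sig_min <- rep(Inf, m)
  E_p <- rep(-1, m); eps_ab <- rep(Inf, m)
  if (any(is_disc)) {
    disc <- materials$disc %||% disc_linearized()
    E0[is_disc] <- disc$E
    nu[is_disc] <- disc$nu
  }
  if (any(!is_disc)) {
    bt <- materials$bone
    if (is.null(bt)) stop("materials$bone table is required", call. = FALSE)
    idx <- match(which(!is_disc), bt$element_id)
    if (anyNA(idx)) stop("material table does not cover all bone elements", call. = FALSE)
    rows <- bt[idx, ]
    E0[!is_disc] <- rows$E
    nu[!is_disc] <- rows$nu
    sig_y[!is_disc] <- rows$sigma_y
    # elements with undefined softening behave elastic-perfectly-plastic
    sig_min[!is_disc] <- ifelse(is.na(rows$sigma_min), rows$sigma_y, rows$sigma_min)
    E_p[!is_disc] <- ifelse(is.na(rows$E_p), -1, rows$E_p)
    eps_ab[!is_disc] <- ifelse(is.na(rows$eps_ab), rows$sigma_y / rows$E, rows$eps_ab)
  }
  list(E0 = E0, nu = nu, sigma_y = sig_y, sigma_min = sig_min,
       E_p = E_p, eps_ab = eps_ab, is_bone = !is_disc)
}

von_mises_rows <- function(sig) {
  sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
              (sig[, 3] - sig[, 1])^2) +
       3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
}

#' Solve a static load case on a tetrahedral mesh
#'
#' Incremental static solve with the density-dependent elastoplastic
#' softening bone law. The load is ramped with an initial increment
#' `incr_init` and subsequent increments of at most `incr_max` of the total
#' load. Within each increment, per-element secant moduli are iterated
#' against the uniaxial bone curve evaluated at the von-Mises equivalent
#' strain until the global residual falls below `tol` (purely elastic states
#' converge in one iteration, so the incremental solver then coincides with a
#' one-shot linear solve). Tie constraints are eliminated exactly through a
#' transformation matrix; spring supports add grounded stiffness on each
#' translation.
#'
#' @param mesh An [fe_mesh()].
#' @param materials List with `bone` (a [bone_material_table()], `element_id`
#'   matching mesh element indices) and optionally `disc` (a
#'   [disc_linearized()] list) for elements with region `"disc"`.
#' @param lc A [load_case()].
#' @param ties Optional list of `tie_map`s from [apply_tie()].
#' @param tol Relative residual tolerance.
#' @param max_iter Maximum secant iterations per increment.
#' @param verbose Print per-increment progress.
#' @return An object of class `fe_solution` with nodal displacements `u`
#'   (n x 3, mm), per-element `strain` and `stress` rows (Voigt), per-element
#'   displacement gradients, support reactions (n x 3, N), secant moduli,
#'   convergence flag and increment history.
#' @export
fe_solve <- function(mesh, materials, lc, ties = NULL,
                     tol = 1e-6, max_iter = 60, verbose = FALSE) {
  mat <- solver_materials(mesh, materials)
  model <- fe_model_prep(mesh, mat$nu)
  f_total <- assemble_loads(mesh, lc)
  fd <- fixed_dof_spec(mesh, lc)
  if (!length(fd$dofs)) {
    stop("load case has no fixed support; rigid-body motion unconstrained",
         call. = FALSE)
  }
  tie_tab <- if (!is.null(ties)) do.call(rbind, lapply(ties, as.data.frame))
  tr <- build_transform(model$ndof, fd$dofs, fd$vals, tie_tab)
  kd <- spring_diagonal(mesh, lc$springs)
  Kspring <- Matrix::Diagonal(model$ndof, kd)

  E_cur <- mat$E0
  lam <- lc$incr_init
  history <- list()
  u <- numeric(model$ndof)
  converged_all <- TRUE
  repeat {
    f_lam <- lam * f_total
    ok <- FALSE
    res <- NA_real_
    for (it in seq_len(max_iter)) {
      K <- fe_assemble_K(model, E_cur)
      Ktot <- K + Kspring
      A <- Matrix::forceSymmetric(Matrix::t(tr$T) %*% Ktot %*% tr$T)
      b <- as.numeric(Matrix::t(tr$T) %*% (f_lam - Ktot %*% (lam * tr$g)))
      u_red <- as.numeric(Matrix::solve(A, b))
      u <- as.numeric(tr$T %*% u_red) + lam * tr$g
      eps <- fe_strains(model, u)
      sig <- fe_stresses(model, eps, E_cur)
      svm <- von_mises_rows(sig)
      eps_eff <- ifelse(E_cur > 0, svm / E_cur, 0)
      E_new <- E_cur
      ib <- mat$is_bone & eps_eff > 1e-12
      if (any(ib)) {
        sig_t <- bone_stress_eval(eps_eff[ib], mat$E0[ib], mat$sigma_y[ib],
                                  mat$sigma_min[ib], mat$E_p[ib],
                                  mat$eps_ab[ib])
        E_new[ib] <- pmin(mat$E0[ib],
                          pmax(sig_t / eps_eff[ib], 1e-6 * mat$E0[ib]))
      }
      # residual of the current displacement under the updated moduli,
      # relative to the larger of external and internal force scales (the
      # latter matters for purely displacement-driven cases)
      Knew <- fe_assemble_K(model, E_new) + Kspring
      fint_full <- Knew %*% u
      fint <- as.numeric(Matrix::t(tr$T) %*% fint_full)
      fext <- as.numeric(Matrix::t(tr$T) %*% f_lam)
      res <- vnorm(fint - fext) /
        max(vnorm(fext), vnorm(as.numeric(fint_full)), 1e-12)
      dE <- max(abs(E_new - E_cur) / mat$E0)
      if (res < tol || dE < 1e-12) {
        E_cur <- E_new
        ok <- res < tol
        break
      }
      E_cur <- E_cur + 0.8 * (E_new - E_cur)
    }
    history[[length(history) + 1]] <- data.frame(
      lambda = lam, iterations = it, residual = res, converged = ok)
    if (verbose) {
      message(sprintf("  increment lambda = %.3f: %d iteration(s), residual %.3e",
                      lam, it, res))
    }
    if (!ok) converged_all <- FALSE
    if (lam >= 1 - 1e-12) break
    lam <- min(1, lam + lc$incr_max)
  }
  if (!converged_all) {
    warning(sprintf("fe_solve: secant iteration not fully converged (last residual %.3e)",
                    res), call. = FALSE)
  }

  # final state at lambda = 1: one more solve with the converged secant
  # moduli so the stored displacements satisfy equilibrium to solver
  # precision (material state is already self-consistent)
  K <- fe_assemble_K(model, E_cur)
  Ktot <- K + Kspring
  A <- Matrix::forceSymmetric(Matrix::t(tr$T) %*% Ktot %*% tr$T)
  b <- as.numeric(Matrix::t(tr$T) %*% (f_total - Ktot %*% tr$g))
  u <- as.numeric(tr$T %*% as.numeric(Matrix::solve(A, b))) + tr$g
  eps <- fe_strains(model, u)
  sig <- fe_stresses(model, eps, E_cur)
  grad <- matrix(model$Bgrad %*% u, ncol = 9, byrow = TRUE)
  # support reactions: residual of the bulk stiffness (springs excluded), so
  # spring rows carry -k u and fixed rows the constraint force
  Rvec <- as.numeric(K %*% u) - f_total
  reactions <- matrix(Rvec, ncol = 3, byrow = TRUE)
  structure(list(
    mesh = mesh,
    u = matrix(u, ncol = 3, byrow = TRUE),
    strain = eps, stress = sig, grad = grad,
    E_secant = E_cur,
    reactions = reactions,
    applied = matrix(f_total, ncol = 3, byrow = TRUE),
    spring_diag = kd,
    fixed_dofs = fd$dofs,
    support_sets = unlist(lapply(c(lc$fixed, lc$springs), function(x)
      if (is.character(x$set)) x$set else NULL)),
    converged = converged_all,
    increments = do.call(rbind, history),
    case = lc$name
  ), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(
    "fe_solution `%s`: %d nodes, %d elements, %s (%d increments)\n  max |u| = %.4g mm, max von Mises = %.4g MPa\n",
    x$case, nrow(x$u), nrow(x$strain),
    if (x$converged) "converged" else "NOT converged",
    nrow(x$increments),
    max(sqrt(rowSums(x$u^2))), max(von_mises_rows(x$stress))))
  invisible(x)
}

#' Support reaction over a node set
#'
#' Sums the computed support reactions (constraint forces at fixed nodes,
#' spring forces \eqn{-k u} at spring-supported nodes) over a named node set
#' and reports the resultant and its magnitude
#' \eqn{\sqrt{F_x^2+F_y^2+F_z^2}}.
#'
#' @param solution An [fe_solve()] result.
#' @param set Node set name (or integer node ids).
#' @return List with `force` (3-vector, N) and `magnitude` (N).
#' @export
reaction_at <- function(solution, set) {
  stopifnot(inherits(solution, "fe_solution"))
  ids <- resolve_node_set(solution$mesh, set)
  f <- colSums(solution$reactions[ids, , drop = FALSE])
  list(force = f, magnitude = force_magnitude(f))
}
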