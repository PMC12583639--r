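# Hill-type muscle force evaluation and static optimization of the muscle
# redundancy problem: distribute target joint moments over muscles by
# minimizing the sum of squared activations subject to moment balance and
# activation bounds.

#' Gaussian active force-length relation
#'
#' \eqn{f_L = \exp(-((L/L_{opt} - 1)/0.45)^2)}: unity at optimal fiber length,
#' decaying symmetrically away from it. The width 0.45 is a standard choice
#' for lumped Hill-type models.
#'
#' @param l_norm Normalized fiber length `L / L_opt`.
#' @param width Shape parameter of the Gaussian (dimensionless).
#' @return Force-length factor in (0, 1].
#' @export
fl_gaussian <- function(l_norm, width = 0.45) {
  exp(-((l_norm - 1) / width)^2)
}

#' Saturating hyperbolic force-velocity relation
#'
#' Hill's hyperbola for shortening (`v > 0`), a saturating branch for
#' lengthening (`v < 0`), with \eqn{f_v(0) = 1}. Static analyses evaluate it
#' at `v = 0`, where it is exactly 1.
#'
#' @param v_norm Normalized contraction velocity `v / v_max` (positive =
#'   shortening).
#' @param a_hill Hill shape constant (dimensionless), default 0.25.
#' @param fv_max Eccentric force plateau, default 1.4.
#' @return Force-velocity factor, `>= 0`.
#' @export
fv_hyperbolic <- function(v_norm, a_hill = 0.25, fv_max = 1.4) {
  short <- pmax(0, (1 - v_norm) / (1 + v_norm / a_hill))
  lengthen <- fv_max - (fv_max - 1) / (1 - v_norm / a_hill)
  ifelse(v_norm >= 0, short, lengthen)
}

#' Define a set of muscles
#'
#' Builds the muscle table used by [hill_force()] and [solve_static_opt()].
#' `moment_arms` has one column per joint axis (mm); lengths are in mm,
#' velocities mm/s, forces N, pennation angle `alpha` in radians.
#'
#' @param name Character vector of muscle names.
#' @param F0 Maximum isometric force (N), `> 0`.
#' @param L_opt Optimal fiber length (mm), `> 0`.
#' @param L Current fiber length (mm); defaults to `L_opt`.
#' @param v Contraction velocity (mm/s); defaults to 0 (static).
#' @param alpha Pennation angle (rad), `|alpha| < pi/2`.
#' @param Lslack Tendon slack length (mm); the tendon is treated as rigid.
#' @param attachment Optional n x 3 matrix of attachment coordinates (mm).
#' @param moment_arms n x k matrix of moment arms r_ij (mm), one column per
#'   joint axis.
#' @param v_max Maximum shortening velocity (mm/s); defaults to
#'   `10 * L_opt` per second.
#' @return A data.frame of class `muscle_set` (moment arm columns `r_1..r_k`).
#' @export
muscle_set <- function(name, F0, L_opt, L = L_opt, v = 0, alpha = 0,
                       Lslack = 0, attachment = NULL, moment_arms,
                       v_max = 10 * L_opt) {
  n <- length(name)
  moment_arms <- as.matrix(moment_arms)
  if (nrow(moment_arms) != n) {
    stop("`moment_arms` must have one row per muscle", call. = FALSE)
  }
  stopifnot(all(F0 > 0), all(L_opt > 0), all(abs(alpha) < pi / 2))
  df <- data.frame(name = name, F0 = F0, L_opt = rep_len(L_opt, n),
                   L = rep_len(L, n), v = rep_len(v, n),
                   alpha = rep_len(alpha, n), Lslack = rep_len(Lslack, n),
                   v_max = rep_len(v_max, n), stringsAsFactors = FALSE)
  if (!is.null(attachment)) {
    attachment <- as.matrix(attachment)
    stopifnot(nrow(attachment) == n, ncol(attachment) == 3)
    df$x <- attachment[, 1]; df$y <- attachment[, 2]; df$z <- attachment[, 3]
  }
  colnames(moment_arms) <- paste0("r_", seq_len(ncol(moment_arms)))
  df <- cbind(df, as.data.frame(moment_arms))
  class(df) <- c("muscle_set", "data.frame")
  df
}

moment_arm_matrix <- function(muscles) {
  rcols <- grep("^r_[0-9]+$", names(muscles), value = TRUE)
  if (length(rcols) == 0) stop("muscle set has no moment-arm columns", call. = FALSE)
  as.matrix(muscles[, rcols, drop = FALSE])
}

# activation-independent force capacity: F0 * f_L * f_v * cos(alpha)
muscle_gain <- function(muscles, f_L = fl_gaussian, f_v = fv_hyperbolic) {
  muscles$F0 * f_L(muscles$L / muscles$L_opt) *
    f_v(muscles$v / muscles$v_max) * cos(muscles$alpha)
}

#' Hill-type muscle force
#'
#' \eqn{F = a\,F_0\,f_L(L/L_{opt})\,f_v(v/v_{max})\cos\alpha} with a rigid
#' tendon. The force-length and force-velocity forms default to
#' [fl_gaussian()] and [fv_hyperbolic()] and can be overridden.
#'
#' @param muscles A [muscle_set()] (or one-row subset).
#' @param a Activation per muscle, in `[0, 1]`.
#' @param f_L,f_v Force-length / force-velocity functions of the normalized
#'   argument.
#' @return Muscle force(s) in N.
#' @export
hill_force <- function(muscles, a, f_L = fl_gaussian, f_v = fv_hyperbolic) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]", call. = FALSE)
  a * muscle_gain(muscles, f_L, f_v)
}

#' Define a static-optimization problem
#'
#' @param muscles A [muscle_set()].
#' @param Q Target joint moments (N mm), one per moment-arm axis.
#' @param bounds Activation bounds `c(lower, upper)`, default `c(0.01, 1)`.
#' @param f_L,f_v Hill factor functions (see [hill_force()]).
#' @return An object of class `static_opt_problem`.
#' @export
static_opt_problem <- function(muscles, Q, bounds = c(0.01, 1),
                               f_L = fl_gaussian, f_v = fv_hyperbolic) {
  R <- moment_arm_matrix(muscles)
  if (length(Q) != ncol(R)) {
    stop("length(Q) must equal the number of moment-arm axes", call. = FALSE)
  }
  stopifnot(length(bounds) == 2, bounds[1] >= 0, bounds[2] <= 1,
            bounds[1] <= bounds[2])
  structure(list(muscles = muscles, Q = as.numeric(Q), bounds = bounds,
                 f_L = f_L, f_v = f_v),
            class = "static_opt_problem")
}

#' Solve the static muscle-force optimization
#'
#' Minimizes \eqn{\sum_i a_i^2} subject to moment balance
#' \eqn{\sum_i a_i F_i r_{ij} = Q_j} on every axis j (with
#' \eqn{F_i = F_0 f_L f_v \cos\alpha} evaluated at the fixed static state) and
#' box bounds on the activations. Solved as a strictly convex quadratic
#' program (dual active-set method), so the result is deterministic and
#' satisfies the KKT conditions to solver precision.
#'
#' Activations are non-negative by construction, so the absolute value in the
#' moment-balance sum is dropped after asserting positivity of the gains.
#'
#' If the target moments are unattainable within the bounds, the minimal
#' residual solution of the bounded least-squares problem
#' \eqn{\min \|R^T(F a) - Q\|^2} is returned with `feasible = FALSE`.
#'
#' @param p A [static_opt_problem()].
#' @param tol Feasibility tolerance on the moment residual (relative).
#' @return An `activation_solution`: list with `a`, `forces` (N), `residual`
#'   (moment violation per axis, N mm), `objective` (\eqn{\sum a_i^2}) and
#'   `feasible`.
#' @export
solve_static_opt <- function(p, tol = 1e-6) {
  stopifnot(inherits(p, "static_opt_problem"))
  gains <- muscle_gain(p$muscles, p$f_L, p$f_v)
  if (any(gains < 0)) {
    stop("negative muscle gain encountered; f_L, f_v, cos(alpha) must be >= 0",
         call. = FALSE)
  }
  R <- moment_arm_matrix(p$muscles)
  n <- length(gains)
  k <- ncol(R)
  A <- t(R * gains)                        # k x n: A[j, i] = gain_i * r_ij
  lb <- rep(p$bounds[1], n)
  ub <- rep(p$bounds[2], n)

  sol <- tryCatch(
    qp_box(Dmat = diag(2, n), dvec = rep(0, n),
           Aeq = A, beq = p$Q, lb = lb, ub = ub),
    error = function(e) NULL
  )
  feasible <- !is.null(sol) &&
    all(abs(A %*% sol - p$Q) <= tol * pmax(1, abs(p$Q)))
  if (!feasible) {
    # minimal-residual fallback: min ||A a - Q||^2 within the box
    D <- 2 * (crossprod(A) + diag(1e-10, n))
    d <- 2 * drop(crossprod(A, p$Q))
    sol <- qp_box(Dmat = D, dvec = d, Aeq = NULL, beq = NULL, lb = lb, ub = ub)
  }
  a <- unname(pmin(pmax(drop(sol), lb), ub))   # clip solver roundoff only
  structure(list(
    a = a,
    forces = a * gains,
    residual = unname(drop(A %*% a - p$Q)),
    objective = sum(a^2),
    feasible = feasible,
    gains = gains
  ), class = "activation_solution")
}

# quadprog wrapper: min 1/2 x' D x - d' x  s.t.  Aeq x = beq, lb <= x <= ub.
# The objective is rescaled so quadprog's pivoting tolerances see O(1)
# curvature regardless of force units.
qp_box <- function(Dmat, dvec, Aeq, beq, lb, ub) {
  n <- length(dvec)
  Amat <- cbind(if (!is.null(Aeq)) t(Aeq), diag(n), -diag(n))
  bvec <- c(beq, lb, -ub)
  meq <- if (is.null(Aeq)) 0L else length(beq)
  sc <- max(diag(Dmat))
  drop(quadprog::solve.QP(Dmat / sc, dvec / sc, Amat, bvec, meq = meq)$solution)
}

#' @export
print.activation_solution <- function(x, ...) {
  cat(sprintf(
    "Static optimization: %d muscles, objective sum(a^2) = %.6g, %s\n",
    length(x$a), x$objective,
    if (x$feasible) "feasible" else "INFEASIBLE (minimal-residual solution)"))
  cat("  max |moment residual| =", format(max(abs(x$residual)), digits = 4),
      "N mm\n")
  invisible(x)
}

#' Tabulate muscle forces from an activation solution
#'
#' @param sol An `activation_solution` from [solve_static_opt()].
#' @param muscles The [muscle_set()] the problem was built from.
#' @return A data.frame with columns `muscle`, `activation`, `force_N`,
#'   mirroring the layout of published per-muscle force tables.
#' @export
force_table <- function(sol, muscles) {
  stopifnot(inherits(sol, "activation_solution"),
            nrow(muscles) == length(sol$a))
  data.frame(muscle = muscles$name, activation = sol$a, force_N = sol$forces,
             stringsAsFactors = FALSE)
}

#' Read / write muscle definitions as CSV
#'
#' Columns: `name,F0,L_opt,L,v,alpha,Lslack,x,y,z,r_1..r_k`.
#'
#' @param muscles A [muscle_set()].
#' @param path File path.
#' @export
write_muscle_csv <- function(muscles, path) {
  write_csv_stable(as.data.frame(muscles), path)
  invisible(path)
}

#' @rdname write_muscle_csv
#' @export
read_muscle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcols <- grep("^r_[0-9]+$", names(df), value = TRUE)
  att <- if (all(c("x", "y", "z") %in% names(df))) {
    as.matrix(df[, c("x", "y", "z")])
  }
  muscle_set(name = df$name, F0 = df$F0, L_opt = df$L_opt, L = df$L,
             v = df$v, alpha = df$alpha, Lslack = df$Lslack,
             attachment = att, moment_arms = df[, rcols, drop = FALSE],
             v_max = df$v_max %||% (10 * df$L_opt))
}
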