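# Apparent-density threshold (g/cm^3) separating cancellous from compact bone.
# The two yield power laws intersect close to this density, so a single
# threshold is used consistently for tissue classification and yield branching.
RHO_COMPACT_THRESHOLD <- 0.945

# Lower clip for apparent density to keep element stiffness non-singular.
RHO_FLOOR <- 0.05

#' Calibrate CT density to apparent bone density
#'
#' Converts the calibration-scale density \eqn{\rho_{CT}} (g/cm^3, obtained
#' from CT grey values against a calibration phantom) to apparent bone density
#' \eqn{\rho} via the affine relation \eqn{\rho = 1.54 \rho_{CT} + 0.0784}.
#'
#' @param rho_ct Numeric vector of calibration densities (g/cm^3), `>= 0`.
#' @return Apparent density \eqn{\rho} in g/cm^3.
#' @examples
#' density_from_ct(c(0, 1))
#' @export
density_from_ct <- function(rho_ct) {
  if (!is.numeric(rho_ct) || anyNA(rho_ct)) {
    stop("`rho_ct` must be numeric without NA", call. = FALSE)
  }
  if (any(rho_ct < 0)) {
    stop("`rho_ct` must be >= 0 (calibration densities are non-negative)",
         call. = FALSE)
  }
  1.54 * rho_ct + 0.0784
}

#' Classify bone tissue by apparent density
#'
#' Elements with \eqn{\rho \ge 0.945} g/cm^3 are treated as compact (cortical)
#' bone, lower densities as cancellous, mirroring the branch threshold of
#' [yield_stress()].
#'
#' @param rho Apparent density (g/cm^3), `> 0`.
#' @return Character vector, `"compact"` or `"cancellous"`.
#' @export
classify_tissue <- function(rho) {
  check_rho(rho)
  ifelse(rho >= RHO_COMPACT_THRESHOLD, "compact", "cancellous")
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || anyNA(rho)) {
    stop("`rho` must be numeric without NA", call. = FALSE)
  }
  if (any(rho <= 0)) {
    stop("`rho` must be > 0 (apparent density)", call. = FALSE)
  }
  invisible(rho)
}

check_tissue <- function(tissue, n) {
  tissue <- match.arg(tissue, c("compact", "cancellous"), several.ok = TRUE)
  rep_len(tissue, n)
}

#' Density-dependent elastic modulus of bone
#'
#' Power laws mapping apparent density to Young's modulus:
#' compact bone \eqn{E = 2065\,\rho^{3.09}} MPa, cancellous bone
#' \eqn{E = 1904\,\rho^{1.64}} MPa. Poisson's ratio is 0.3 for both tissues.
#'
#' @param rho Apparent density (g/cm^3), `> 0`.
#' @param tissue `"compact"` or `"cancellous"`; recycled against `rho`.
#' @return Elastic modulus in MPa.
#' @examples
#' elastic_modulus(1, "compact")    # 2065
#' elastic_modulus(1, "cancellous") # 1904
#' @export
elastic_modulus <- function(rho, tissue = classify_tissue(rho)) {
  check_rho(rho)
  tissue <- check_tissue(tissue, length(rho))
  ifelse(tissue == "compact", 2065 * rho^3.09, 1904 * rho^1.64)
}

#' Density-dependent yield stress of bone
#'
#' Branching power law: \eqn{\sigma_y = 57.75\,\rho^{1.73}} MPa for
#' \eqn{\rho \ge 0.945} (compact) and \eqn{\sigma_y = 76.5\,\rho^{6.7}} MPa for
#' \eqn{\rho < 0.945} (cancellous). The two branches intersect near the
#' threshold (both about 52.4 MPa at \eqn{\rho = 0.945}), so the switch is
#' nearly continuous.
#'
#' @inheritParams classify_tissue
#' @return Yield stress in MPa.
#' @export
yield_stress <- function(rho) {
  check_rho(rho)
  ifelse(rho >= RHO_COMPACT_THRESHOLD, 57.75 * rho^1.73, 76.5 * rho^6.7)
}

#' Post-yield softening parameters of bone
#'
#' After the stress plateau at \eqn{\sigma_y}, bone "degrades": stress falls
#' with slope \eqn{E_p} to a residual \eqn{\sigma_{min}}. All quantities are
#' density-dependent:
#' \eqn{\sigma_{min} = 8.5\,\rho^{3.68}} MPa,
#' \eqn{E_p = -244\,\rho^{2.2}} MPa,
#' \eqn{\varepsilon_{ab} = 0.258\,\rho - 0.07} (softening-onset strain), and
#' \eqn{\varepsilon_{bc} = |(\sigma_y - \sigma_{min})/E_p + \varepsilon_{ab}|}.
#'
#' `eps_bc` is evaluated verbatim from that expression and reported for
#' completeness; because the quotient is negative, its printed form yields a
#' value smaller than `eps_ab` for ordinary densities and is therefore not
#' used to construct the softening branch of [bone_curve()] (the terminus is
#' derived from \eqn{(\sigma_y-\sigma_{min})/|E_p|} instead).
#'
#' @inheritParams classify_tissue
#' @return A data.frame with columns `sigma_min`, `E_p`, `eps_ab`, `eps_bc`.
#' @export
softening_params <- function(rho) {
  check_rho(rho)
  eps_ab <- 0.258 * rho - 0.07
  if (any(eps_ab <= 0)) {
    stop("degenerate material: softening undefined for rho <= 0.2713 ",
         "(eps_ab = 0.258*rho - 0.07 must be > 0)", call. = FALSE)
  }
  sig_y <- yield_stress(rho)
  sig_min <- 8.5 * rho^3.68
  E_p <- -244 * rho^2.2
  eps_bc <- abs((sig_y - sig_min) / E_p + eps_ab)
  data.frame(sigma_min = sig_min, E_p = E_p, eps_ab = eps_ab, eps_bc = eps_bc)
}

#' Piecewise stress-strain curve of bone tissue
#'
#' Builds the uniaxial elastoplastic-softening law used for bone: linear
#' elastic rise with slope \eqn{E} up to \eqn{(\sigma_y/E, \sigma_y)}, a
#' perfectly plastic plateau at \eqn{\sigma_y} up to strain
#' \eqn{\varepsilon_{ab}}, linear softening with slope \eqn{E_p} down to the
#' residual stress \eqn{\sigma_{min}}, held constant beyond. If
#' \eqn{\varepsilon_{ab}} falls below the elastic limit strain the plateau is
#' empty and softening starts at yield.
#'
#' @inheritParams elastic_modulus
#' @return An object of class `stress_strain_curve` with fields `rho`,
#'   `tissue`, `E`, `sigma_y`, `sigma_min`, `E_p`, `eps_ab`, `eps_bc` and a
#'   `breakpoints` data.frame of `(strain, stress)` vertices.
#' @seealso [stress_at()] to evaluate the curve.
#' @export
bone_curve <- function(rho, tissue = classify_tissue(rho)) {
  stopifnot(length(rho) == 1L)
  check_rho(rho)
  tissue <- check_tissue(tissue, 1L)
  E <- elastic_modulus(rho, tissue)
  sig_y <- yield_stress(rho)
  sp <- softening_params(rho)
  eps_y <- sig_y / E
  eps_soft <- max(sp$eps_ab, eps_y)         # plateau may be empty
  eps_end <- eps_soft + (sig_y - sp$sigma_min) / abs(sp$E_p)
  bp <- data.frame(
    strain = c(0, eps_y, eps_soft, eps_end),
    stress = c(0, sig_y, sig_y, sp$sigma_min)
  )
  structure(
    list(rho = rho, tissue = tissue, E = E, sigma_y = sig_y,
         sigma_min = sp$sigma_min, E_p = sp$E_p, eps_ab = sp$eps_ab,
         eps_bc = sp$eps_bc, eps_soft_onset = eps_soft,
         eps_soft_end = eps_end, breakpoints = bp),
    class = "stress_strain_curve"
  )
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf(
    "Bone stress-strain curve (%s, rho = %.3f g/cm^3)\n  E = %.1f MPa, sigma_y = %.2f MPa, sigma_min = %.2f MPa, E_p = %.1f MPa\n  plateau [%.4f, %.4f], softening ends at strain %.4f\n",
    x$tissue, x$rho, x$E, x$sigma_y, x$sigma_min, x$E_p,
    x$sigma_y / x$E, x$eps_soft_onset, x$eps_soft_end))
  invisible(x)
}

# Vectorized curve evaluation used both by stress_at() and by the FE secant
# update (which carries the parameters as per-element columns, not objects).
bone_stress_eval <- function(eps, E, sigma_y, sigma_min, E_p, eps_ab) {
  eps_y <- sigma_y / E
  eps_soft <- pmax(eps_ab, eps_y)
  eps_end <- eps_soft + (sigma_y - sigma_min) / abs(E_p)
  sig <- E * eps
  sig <- ifelse(eps > eps_y, sigma_y, sig)
  sig <- ifelse(eps > eps_soft, sigma_y - abs(E_p) * (eps - eps_soft), sig)
  ifelse(eps > eps_end, sigma_min, sig)
}

#' Evaluate a bone stress-strain curve
#'
#' @param curve A [bone_curve()] object.
#' @param eps Numeric vector of (equivalent uniaxial) strains, `>= 0`.
#' @return Stress in MPa at each strain.
#' @export
stress_at <- function(curve, eps) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (any(eps < 0)) stop("`eps` must be >= 0", call. = FALSE)
  bone_stress_eval(eps, curve$E, curve$sigma_y, curve$sigma_min,
                   curve$E_p, curve$eps_ab)
}

#' Per-element bone material table
#'
#' Maps a per-element CT density field to the full set of constitutive
#' parameters used by the solver. Densities are clipped below at
#' 0.05 g/cm^3 to avoid singular elements; elements whose softening strain
#' would be undefined (rho <= 0.2713) keep their elastic and yield values but
#' get `NA` softening parameters and are treated as elastic-perfectly-plastic.
#'
#' @param element_id Integer element ids.
#' @param rho_ct Calibration density per element (g/cm^3).
#' @return A data.frame with columns `element_id`, `rho`, `tissue`, `E`, `nu`,
#'   `sigma_y`, `sigma_min`, `E_p`, `eps_ab`.
#' @export
bone_material_table <- function(element_id, rho_ct) {
  stopifnot(length(element_id) == length(rho_ct))
  rho <- pmax(density_from_ct(rho_ct), RHO_FLOOR)
  tissue <- classify_tissue(rho)
  E <- elastic_modulus(rho, tissue)
  sig_y <- yield_stress(rho)
  eps_ab <- 0.258 * rho - 0.07
  ok <- eps_ab > 0
  sig_min <- ifelse(ok, 8.5 * rho^3.68, NA_real_)
  E_p <- ifelse(ok, -244 * rho^2.2, NA_real_)
  eps_ab[!ok] <- NA_real_
  data.frame(element_id = as.integer(element_id), rho = rho, tissue = tissue,
             E = E, nu = 0.3, sigma_y = sig_y, sigma_min = sig_min,
             E_p = E_p, eps_ab = eps_ab)
}

#' Write / read a material table as CSV
#'
#' @param tab Material table from [bone_material_table()].
#' @param path File path.
#' @return `read_material_table` returns the table; `write_material_table`
#'   returns `path` invisibly.
#' @export
write_material_table <- function(tab, path) {
  write_csv_stable(tab, path)
  invisible(path)
}

#' @rdname write_material_table
#' @export
read_material_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element_id", "rho", "tissue", "E", "nu", "sigma_y",
            "sigma_min", "E_p", "eps_ab")
  if (!all(need %in% names(tab))) {
    stop("material table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab
}

# ---- Mooney-Rivlin interpubic disc -----------------------------------------

#' Mooney-Rivlin parameters for the interpubic disc
#'
#' Three-term incompressible Mooney-Rivlin model
#' \eqn{W = C_{10}(I_1-3) + C_{01}(I_2-3) + C_{11}(I_1-3)(I_2-3)}.
#' Defaults are the fibrocartilage parameters used for the interpubic disc:
#' \eqn{C_{10} = 0.1}, \eqn{C_{01} = 0.45}, \eqn{C_{11} = 0.6} MPa.
#'
#' @param C10,C01,C11 Material constants in MPa.
#' @return An object of class `mooney_rivlin`.
#' @export
mooney_rivlin <- function(C10 = 0.1, C01 = 0.45, C11 = 0.6) {
  p <- list(C10 = C10, C01 = C01, C11 = C11)
  if (2 * (C10 + C01) <= 0) {
    stop("initial shear modulus 2*(C10 + C01) must be positive", call. = FALSE)
  }
  structure(p, class = "mooney_rivlin")
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf(
    "Mooney-Rivlin: C10 = %g, C01 = %g, C11 = %g MPa (mu0 = %g MPa)\n",
    x$C10, x$C01, x$C11, 2 * (x$C10 + x$C01)))
  invisible(x)
}

#' Mooney-Rivlin strain-energy density
#'
#' @param I1,I2 First and second invariants of the deviatoric (isochoric)
#'   stretch tensor; both `>= 3` (equal to 3 in the undeformed state).
#' @param p A [mooney_rivlin()] parameter object.
#' @return Strain-energy density in MPa.
#' @export
mr_energy <- function(I1, I2, p = mooney_rivlin()) {
  stopifnot(inherits(p, "mooney_rivlin"))
  if (any(I1 < 3 - 1e-12) || any(I2 < 3 - 1e-12)) {
    stop("invariants I1, I2 must be >= 3", call. = FALSE)
  }
  p$C10 * (I1 - 3) + p$C01 * (I2 - 3) + p$C11 * (I1 - 3) * (I2 - 3)
}

#' Incompressible uniaxial Cauchy stress of a Mooney-Rivlin solid
#'
#' Closed-form uniaxial response along the incompressible path
#' \eqn{I_1 = \lambda^2 + 2/\lambda}, \eqn{I_2 = 2\lambda + 1/\lambda^2}:
#' \deqn{\sigma = 2(\lambda^2 - 1/\lambda)\left(\frac{\partial W}{\partial I_1}
#'   + \frac{1}{\lambda}\frac{\partial W}{\partial I_2}\right).}
#' Used to verify the disc material against numerical differentiation of
#' [mr_energy()].
#'
#' @param lambda Principal stretch along the loading axis, `> 0`.
#' @inheritParams mr_energy
#' @return Cauchy stress in MPa (negative in compression, `lambda < 1`).
#' @export
mr_uniaxial_stress <- function(lambda, p = mooney_rivlin()) {
  stopifnot(inherits(p, "mooney_rivlin"))
  if (any(lambda <= 0)) stop("`lambda` must be > 0", call. = FALSE)
  I1 <- lambda^2 + 2 / lambda
  I2 <- 2 * lambda + 1 / lambda^2
  dW1 <- p$C10 + p$C11 * (I2 - 3)
  dW2 <- p$C01 + p$C11 * (I1 - 3)
  2 * (lambda^2 - 1 / lambda) * (dW1 + dW2 / lambda)
}

#' Linearized small-strain surrogate for the disc
#'
#' The FE core uses linear kinematics, so the disc's Mooney-Rivlin law is
#' linearized about the undeformed state: initial shear modulus
#' \eqn{\mu_0 = 2(C_{10}+C_{01})} and a near-incompressible Poisson ratio
#' (default 0.475) give \eqn{E = 2\mu_0(1+\nu)}.
#'
#' @inheritParams mr_energy
#' @param nu Poisson ratio of the surrogate, in (0, 0.5).
#' @return List with `E` (MPa) and `nu`.
#' @export
disc_linearized <- function(p = mooney_rivlin(), nu = 0.475) {
  stopifnot(inherits(p, "mooney_rivlin"), nu > 0, nu < 0.5)
  mu0 <- 2 * (p$C10 + p$C01)
  list(E = 2 * mu0 * (1 + nu), nu = nu)
}
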