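# Bone constitutive laws: density calibration, power-law moduli, yield
# branches, softening curve, and the Mooney-Rivlin disc material.

test_that("CT density calibration is the printed affine map", {
  expect_identical(density_from_ct(0), 0.0784)
  expect_equal(density_from_ct(1.0), 1.6184)
  # inverse of the calibration at the tissue-threshold density
  expect_equal(density_from_ct(0.56273), 0.945, tolerance = 1e-4)
  # affine: f(a) + f(b) - f(0) = f(a + b) (up to float associativity)
  a <- c(0.1, 0.7, 1.3); b <- c(0.4, 0.2, 0.9)
  expect_equal(density_from_ct(a) + density_from_ct(b) - density_from_ct(0),
               density_from_ct(a + b))
  expect_error(density_from_ct(-0.1), "rho_ct")
})

test_that("elastic modulus follows the tissue power laws", {
  expect_equal(elastic_modulus(1, "compact"), 2065)
  expect_equal(elastic_modulus(1, "cancellous"), 1904)
  # frozen: 2065 * 0.945^3.09 evaluated independently
  expect_equal(elastic_modulus(0.945, "compact"), 1733.82134123533,
               tolerance = 1e-10)
  expect_error(elastic_modulus(0), "rho")
  # strict monotonicity on (0, 2] for both branches
  rho <- seq(0.05, 2, by = 0.05)
  for (tis in c("compact", "cancellous")) {
    expect_true(all(diff(elastic_modulus(rho, tis)) > 0))
  }
})

test_that("yield stress branches at rho = 0.945 and stays near-continuous", {
  expect_equal(yield_stress(1), 57.75)
  # frozen: 76.5 * 0.5^6.7
  expect_equal(yield_stress(0.5), 0.735801153288173, tolerance = 1e-10)
  # the threshold itself uses the compact branch (>=)
  expect_equal(yield_stress(0.945), 57.75 * 0.945^1.73)
  # branch continuity: both power laws intersect near the threshold
  lo <- 76.5 * 0.945^6.7
  hi <- 57.75 * 0.945^1.73
  expect_lt(abs(hi - lo), 0.1)
  expect_equal(hi, 52.4, tolerance = 0.1)
  rho <- seq(0.05, 2, by = 0.05)
  expect_true(all(diff(76.5 * rho^6.7) > 0))
  expect_true(all(diff(57.75 * rho^1.73) > 0))
})

test_that("softening parameters match the printed formulas", {
  sp <- softening_params(1)
  expect_equal(sp$sigma_min, 8.5)
  expect_equal(sp$E_p, -244)
  expect_equal(sp$eps_ab, 0.188)
  # eps_bc verbatim: |(57.75 - 8.5)/(-244) + 0.188|
  expect_equal(sp$eps_bc, 0.013844262295082, tolerance = 1e-12)
  # the printed expression gives a value below eps_ab (reported, not used
  # for the curve terminus)
  expect_lt(sp$eps_bc, sp$eps_ab)
  expect_error(softening_params(0.2), "degenerate")
})

test_that("bone curve is the elastic / plateau / softening / residual shape", {
  for (rho in c(0.6, 0.945, 1.2)) {
    cv <- bone_curve(rho)
    eps_y <- cv$sigma_y / cv$E
    # elastic branch equals E * eps to high precision
    eps <- seq(1e-6, eps_y, length.out = 7)
    expect_equal(stress_at(cv, eps), cv$E * eps, tolerance = 1e-9)
    expect_equal(stress_at(cv, 0.5 * eps_y), 0.5 * cv$sigma_y)
    # plateau endpoint
    expect_equal(stress_at(cv, cv$eps_ab), cv$sigma_y)
    # beyond the softening terminus the residual stress holds
    eps_end <- cv$eps_soft_onset + (cv$sigma_y - cv$sigma_min) / abs(cv$E_p)
    expect_equal(stress_at(cv, eps_end + 0.05), cv$sigma_min)
    # continuity across all breakpoints
    for (bp in cv$breakpoints$strain[-1]) {
      expect_equal(stress_at(cv, bp - 1e-10), stress_at(cv, bp + 1e-10),
                   tolerance = 1e-6)
    }
    # strictly increasing strain coordinates
    expect_true(all(diff(cv$breakpoints$strain) > 0))
  }
})

test_that("tissue classification mirrors the yield threshold", {
  expect_identical(classify_tissue(c(0.9, 0.945, 1.2)),
                   c("cancellous", "compact", "compact"))
})

test_that("Mooney-Rivlin energy reproduces hand-computed invariant states", {
  p <- mooney_rivlin()   # C10 = 0.1, C01 = 0.45, C11 = 0.6
  expect_equal(mr_energy(3, 3, p), 0)
  expect_equal(mr_energy(4, 3, p), 0.1)
  expect_equal(mr_energy(4, 4, p), 0.1 + 0.45 + 0.6)
  expect_error(mr_energy(2.5, 3, p), "I1")
  expect_error(mooney_rivlin(-1, 0.2, 0), "shear")
})

test_that("uniaxial Mooney-Rivlin stress matches the energy derivative", {
  p <- mooney_rivlin()
  expect_equal(mr_uniaxial_stress(1, p), 0)
  expect_lt(mr_uniaxial_stress(0.9, p), 0)   # compression
  # independent oracle: Cauchy stress = lambda * dW/dlambda along the
  # incompressible uniaxial path, by central differences on mr_energy
  W_of <- function(l) mr_energy(l^2 + 2 / l, 2 * l + 1 / l^2, p)
  h <- 1e-6
  for (l in seq(0.85, 1.25, by = 0.05)) {
    sig_num <- l * (W_of(l + h) - W_of(l - h)) / (2 * h)
    if (abs(l - 1) < 1e-12) next
    expect_equal(mr_uniaxial_stress(l, p), sig_num,
                 tolerance = 1e-6)
  }
})

test_that("disc linearization uses the initial shear modulus", {
  d <- disc_linearized(mooney_rivlin(), nu = 0.475)
  expect_equal(d$E, 2 * 1.1 * 1.475)
  expect_equal(d$nu, 0.475)
})

test_that("material table applies floor, thresholds and CSV round-trip", {
  rho_ct <- c(0, 0.3, 1.0)
  tab <- bone_material_table(1:3, rho_ct)
  expect_equal(tab$rho[2:3], 1.54 * rho_ct[2:3] + 0.0784)
  expect_identical(tab$tissue, c("cancellous", "cancellous", "compact"))
  expect_true(all(tab$nu == 0.3))
  # rho floor keeps the zero-density element usable; its softening is
  # undefined (degenerate) and flagged NA
  expect_equal(tab$rho[1], 0.0784)
  expect_true(is.na(tab$eps_ab[1]))
  expect_false(anyNA(tab$eps_ab[2:3]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_material_table(tab, path)
  back <- read_material_table(path)
  expect_equal(back$E, tab$E, tolerance = 1e-9)
  expect_identical(back$tissue, tab$tissue)
})
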