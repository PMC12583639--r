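# Post-processing reductions: von Mises stress, logarithmic strains,
# summaries and load-case comparisons.

test_that("von Mises stress reproduces canonical stress states", {
  expect_equal(von_mises(c(50, 0, 0, 0, 0, 0)), 50)          # uniaxial
  expect_equal(von_mises(c(0, 0, 0, 12, 0, 0)), sqrt(3) * 12) # pure shear
  expect_equal(von_mises(diag(3) * -75), 0)                   # hydrostatic
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
})

test_that("von Mises stress is invariant under rotations", {
  set.seed(5)
  for (rep in 1:10) {
    S <- voigt_to_tensor(stats::rnorm(6, sd = 40))
    R <- random_rotation()
    expect_equal(von_mises(R %*% S %*% t(R)), von_mises(S),
                 tolerance = 1e-10)
  }
})

test_that("logarithmic principal strains match closed forms", {
  expect_equal(log_principal_strains(matrix(0, 3, 3)),
               c(eps_max = 0, eps_min = 0))
  lam <- 1.17
  g <- diag(c(lam - 1, 0, 0))
  expect_equal(unname(log_principal_strains(g)[1]), log(lam),
               tolerance = 1e-12)
  # a pure rotation carries no strain
  R <- random_rotation()
  ev <- log_principal_strains(R - diag(3))
  expect_equal(unname(ev), c(0, 0), tolerance = 1e-10)
  # inverted element is rejected
  expect_error(log_principal_strains(diag(c(-2.5, 0, 0))), "inverted")
})

test_that("log strains agree with small-strain eigenvalues to second order", {
  set.seed(9)
  for (scale in c(1e-4, 1e-3)) {
    G <- matrix(stats::rnorm(9), 3, 3) * scale
    eps_small <- eigen(0.5 * (G + t(G)), symmetric = TRUE)$values
    ev <- log_principal_strains(G)
    expect_equal(unname(ev[1]), max(eps_small), tolerance = 50 * scale)
    expect_equal(unname(ev[2]), min(eps_small), tolerance = 50 * scale)
  }
})

test_that("single-element uniaxial solve summarizes to analytic values", {
  # stretch a unit cube column axially via prescribed displacements
  mesh <- cube_mesh(n = 1, L = 1)
  u_imp <- 1e-3
  top <- which(abs(mesh$nodes[, 2] - 1) < 1e-8)
  bot <- which(abs(mesh$nodes[, 2]) < 1e-8)
  E <- 1000
  bnd <- unique(as.integer(boundary_facets(mesh)))
  # impose the exact uniaxial-strain affine field on all boundary nodes
  A <- diag(c(0, u_imp, 0))
  ub <- mesh$nodes[bnd, ] %*% t(A)
  mesh$node_sets$bnd <- bnd
  lc <- load_case(fixed = list(list(set = "bnd", value = ub)),
                  incr_init = 1, incr_max = 1)
  sol <- fe_solve(mesh, list(bone = elastic_bone_table(nrow(mesh$elements),
                                                       E, nu = 0.3)), lc)
  s <- summarize_solution(sol, parts = list(column = "body"))
  # constrained uniaxial strain state: sigma_yy from the 1D Hooke matrix
  c1 <- E * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3))
  sig <- c(E * 0.3 / ((1.3) * (0.4)) * u_imp, c1 * u_imp,
           E * 0.3 / ((1.3) * (0.4)) * u_imp, 0, 0, 0)
  expect_equal(s$parts$sigma_red_max, von_mises(sig), tolerance = 1e-8)
  expect_equal(s$parts$eps_max, log(1 + u_imp), tolerance = 1e-6)
  expect_equal(s$parts$u_max, u_imp, tolerance = 1e-10)
  expect_error(summarize_solution(sol, parts = list(ghost = "nothing")),
               "matches no elements")
})

test_that("part-wise maxima dominate member elements and ignore ordering", {
  run <- toy_run()
  sol <- run$solutions$reaction_only
  s <- summarize_solution(sol)
  svm <- apply(sol$stress, 1, von_mises)
  right <- run$mesh$region == "bone_right"
  expect_gte(s$parts$sigma_red_max[s$parts$part == "hip_bones"],
             max(svm[right]))
  expect_gte(s$parts$sigma_red_max[1], s$parts$sigma_red_p99[1])
  expect_true(all(s$parts$eps_min <= s$parts$eps_max))
  # permutation invariance over parts definition order
  s2 <- summarize_solution(sol, parts = list(pubic_symphysis = "disc",
                                             hip_bones = c("bone_right",
                                                           "bone_left")))
  expect_equal(sort(s2$parts$sigma_red_max), sort(s$parts$sigma_red_max))
})

test_that("case comparison reproduces the percent-difference convention", {
  expect_equal(compare_cases(86.50, 73.7, base = "A")$percent_diff,
               14.8, tolerance = 0.05)
  expect_equal(compare_cases(5, 5)$percent_diff, 0)
  expect_equal(compare_cases(10, 5, base = "B")$percent_diff, 100)
  expect_error(compare_cases(1, 0, base = "B"), "zero base")
  # both orientations recompute to the same raw values
  ab <- compare_cases(86.50, 73.7, base = "A")
  ba <- compare_cases(73.7, 86.50, base = "B")
  expect_equal(ab$value_a, ba$value_b)
  expect_equal(ab$percent_diff, -ba$percent_diff)
})

test_that("report table round-trips through CSV", {
  run <- toy_run()
  rep <- table2_report(run$summaries)
  expect_equal(nrow(rep), 4)      # 2 cases x 2 parts
  expect_true(all(is.finite(as.matrix(rep[, -(1:2)]))))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$sigma_red_max, rep$sigma_red_max, tolerance = 1e-9)
  md <- report_markdown(rep)
  expect_equal(length(md), 2 + nrow(rep))
  expect_match(md[1], "sigma_red_max")
})
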