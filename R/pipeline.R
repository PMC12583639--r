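# End-to-end pipeline: generate -> materials -> muscles -> solve -> report,
# with a serialized provenance config, per-stage log and deterministic
# outputs under a fixed seed.

#' Default pipeline configuration
#'
#' @param seed Integer seed (noise in the density generator).
#' @return Nested list: `geometry` ([toy_pelvis_params()] arguments),
#'   `load_cases` (subset of `c("reaction_only", "muscles")`), `solver`
#'   (`tol`, `max_iter`), `hip_force`, `k_sij`, `disc` (Mooney-Rivlin
#'   constants and surrogate `nu`).
#' @export
default_config <- function(seed = 42L) {
  list(
    geometry = list(seed = as.integer(seed)),
    load_cases = c("reaction_only", "muscles"),
    hip_force = c(852, 2052, -1042),
    k_sij = 4285,
    disc = list(C10 = 0.1, C01 = 0.45, C11 = 0.6, nu = 0.475),
    solver = list(tol = 1e-6, max_iter = 60),
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration (JSON or YAML)
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @return Config list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  merge_config(default_config(), cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (!all(cfg$load_cases %in% c("reaction_only", "muscles"))) {
    stop("config: load_cases must be a subset of reaction_only, muscles",
         call. = FALSE)
  }
  if (length(cfg$hip_force) != 3) stop("config: hip_force needs 3 components", call. = FALSE)
  if (cfg$k_sij <= 0) stop("config: k_sij must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Stages: toy-pelvis generation (mesh written as VTK/INP/MSH), synthetic
#' density field (CSV), bone material table (CSV), muscle force table (CSV,
#' only when the muscle load case is requested), one incremental FE solve per
#' load case (solution VTK with displacement, reduced stress and log-strain
#' fields), the per-part results table and load-case comparisons (CSV +
#' markdown), and a structured per-stage log. Outputs are numerically
#' byte-identical under identical config and seed. With `resume = TRUE`,
#' stages whose output files already exist are skipped.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides `config$seed` if given.
#' @param resume Skip stages whose outputs exist.
#' @param verbose Log to console as well as the log file.
#' @return Invisibly, a list with the mesh, solutions, summaries, report and
#'   comparison tables and the output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         resume = FALSE, verbose = TRUE) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$geometry$seed <- as.integer(seed)
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  t_start <- proc.time()[["elapsed"]]
  logmsg <- function(...) {
    line <- sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t_start,
                    sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- stage: generate ---------------------------------------------------
  params <- do.call(toy_pelvis_params, config$geometry)
  mesh_path <- file.path(out_dir, "mesh.vtk")
  logmsg("stage generate: toy pelvis (seed %d)", config$seed)
  mesh <- generate_toy_pelvis(params)
  if (!(resume && file.exists(mesh_path))) {
    write_vtk(mesh, mesh_path)
    write_inp(mesh, file.path(out_dir, "mesh.inp"))
    write_msh(mesh, file.path(out_dir, "mesh.msh"))
  } else logmsg("stage generate: outputs exist, skipped write")
  logmsg("  mesh: %d nodes, %d tets", nrow(mesh$nodes), nrow(mesh$elements))

  # -- stage: density + materials ---------------------------------------
  dens_path <- file.path(out_dir, "density.csv")
  mat_path <- file.path(out_dir, "materials.csv")
  density <- generate_density(mesh, params, seed = config$seed)
  is_bone <- !is.na(density$rho_ct)
  mat_tab <- bone_material_table(density$element_id[is_bone],
                                 density$rho_ct[is_bone])
  if (!(resume && file.exists(dens_path) && file.exists(mat_path))) {
    write_density_csv(density, dens_path)
    write_material_table(mat_tab, mat_path)
  }
  logmsg("stage materials: %d bone elements (%d compact, %d cancellous)",
         nrow(mat_tab), sum(mat_tab$tissue == "compact"),
         sum(mat_tab$tissue == "cancellous"))

  # -- stage: muscles ----------------------------------------------------
  if ("muscles" %in% config$load_cases) {
    mft <- table1_muscle_forces()
    write_csv_stable(mft, file.path(out_dir, "muscle_forces.csv"))
    logmsg("stage muscles: %d muscles, total force %.1f N",
           nrow(mft), sum(mft$force_N))
  }

  # -- stage: solve ------------------------------------------------------
  disc_par <- mooney_rivlin(config$disc$C10, config$disc$C01, config$disc$C11)
  materials <- list(bone = mat_tab,
                    disc = disc_linearized(disc_par, config$disc$nu))
  ties <- symphysis_ties(mesh)
  solutions <- list(); summaries <- list()
  for (case in config$load_cases) {
    logmsg("stage solve: case %s", case)
    lc <- reference_load_case(mesh, case, hip_force = config$hip_force,
                              k_sij = config$k_sij)
    sol <- fe_solve(mesh, materials, lc, ties = ties,
                    tol = config$solver$tol,
                    max_iter = config$solver$max_iter)
    hist <- sol$increments
    logmsg("  %d increments, final residual %.3e, %s",
           nrow(hist), hist$residual[nrow(hist)],
           if (sol$converged) "converged" else "NOT CONVERGED")
    if (!sol$converged) {
      stop("solver non-convergence in case `", case, "` (residual ",
           format(hist$residual[nrow(hist)], digits = 3), ")", call. = FALSE)
    }
    write_solution_vtk(sol, file.path(out_dir, paste0("solution_", case, ".vtk")))
    solutions[[case]] <- sol
    summaries[[case]] <- summarize_solution(sol)
    r <- summaries[[case]]$reactions[["right_SIJ"]]
    logmsg("  right SIJ reaction: (%.1f, %.1f, %.1f) N, |F| = %.1f N",
           r$force[1], r$force[2], r$force[3], r$magnitude)
  }

  # -- stage: report -----------------------------------------------------
  report <- NULL
  if (length(summaries)) {
    report <- table2_report(summaries)
    write_csv_stable(report, file.path(out_dir, "report.csv"))
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  comparison <- NULL
  if (all(c("reaction_only", "muscles") %in% names(summaries))) {
    comparison <- rbind(
      compare_cases(summaries$reaction_only, summaries$muscles,
                    "sigma_red_max", "hip_bones", base = "A"),
      compare_cases(summaries$muscles, summaries$reaction_only,
                    "sigma_red_max", "pubic_symphysis", base = "A"),
      compare_cases(summaries$reaction_only, summaries$muscles,
                    "u_max", "hip_bones", base = "A"),
      compare_cases(summaries$muscles, summaries$reaction_only,
                    "eps_max", "pubic_symphysis", base = "A"))
    write_csv_stable(comparison, file.path(out_dir, "comparison.csv"))
    writeLines(report_markdown(comparison), file.path(out_dir, "comparison.md"))
  }
  logmsg("stage report: done")

  invisible(list(mesh = mesh, density = density, materials = mat_tab,
                 solutions = solutions, summaries = summaries,
                 report = report, comparison = comparison,
                 out_dir = out_dir, config = config))
}
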