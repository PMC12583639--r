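# Reduction of FE solutions to the reported engineering quantities:
# von Mises (reduced) stress, displacement magnitude, logarithmic principal
# strains, support reactions, per-part summaries and load-case comparisons.

#' Von Mises (reduced) equivalent stress
#'
#' \deqn{\sigma_{red} = \sqrt{\tfrac12[(\sigma_{11}-\sigma_{22})^2 +
#' (\sigma_{22}-\sigma_{33})^2 + (\sigma_{33}-\sigma_{11})^2 +
#' 6(\sigma_{12}^2+\sigma_{23}^2+\sigma_{13}^2)]}}
#'
#' @param stress A symmetric 3 x 3 stress tensor (MPa), or a length-6 Voigt
#'   vector (11, 22, 33, 12, 23, 13).
#' @return The equivalent stress (MPa).
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress)) {
    stopifnot(nrow(stress) == 3, ncol(stress) == 3)
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress)))) {
      stop("stress tensor must be symmetric", call. = FALSE)
    }
    s <- c(stress[1, 1], stress[2, 2], stress[3, 3],
           stress[1, 2], stress[2, 3], stress[1, 3])
  } else {
    stopifnot(length(stress) == 6)
    s <- stress
  }
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
       3 * (s[4]^2 + s[5]^2 + s[6]^2))
}

#' Logarithmic principal strains from a displacement gradient
#'
#' Forms \eqn{F = I + \nabla u}, takes the principal values of the
#' logarithmic (Hencky) strain \eqn{\ln\sqrt{F^T F}} and returns the largest
#' and smallest.
#'
#' @param grad_u 3 x 3 displacement gradient (or length-9 column-major
#'   vector).
#' @return Named vector `c(eps_max, eps_min)`.
#' @export
log_principal_strains <- function(grad_u) {
  Fg <- diag(3) + matrix(as.numeric(grad_u), 3, 3)
  if (det(Fg) <= 0) {
    stop("inverted element: deformation gradient has non-positive determinant",
         call. = FALSE)
  }
  ev <- eigen(crossprod(Fg), symmetric = TRUE, only.values = TRUE)$values
  eps <- 0.5 * log(ev)
  c(eps_max = max(eps), eps_min = min(eps))
}

#' Per-part summary of an FE solution
#'
#' Reduces a converged solution to the headline quantities per model part:
#' maximum von Mises stress, maximum displacement magnitude, extreme
#' logarithmic principal strains, plus a 99th-percentile stress as a guard
#' against single-element spikes at constrained nodes, and the support
#' reactions.
#'
#' @param solution An [fe_solve()] result.
#' @param parts Named list mapping part names to region tags, e.g.
#'   `list(hip_bones = c("bone_left", "bone_right"), pubic_symphysis =
#'   "disc")`.
#' @return An object of class `solution_summary`: data.frame `parts` (one
#'   row per part: `sigma_red_max`, `sigma_red_p99`, `u_max`, `eps_max`,
#'   `eps_min`) plus a `reactions` attribute (per support set: force
#'   components and magnitude) and the case name.
#' @export
summarize_solution <- function(solution,
                               parts = list(
                                 hip_bones = c("bone_left", "bone_right"),
                                 pubic_symphysis = "disc")) {
  stopifnot(inherits(solution, "fe_solution"))
  mesh <- solution$mesh
  svm <- von_mises_rows(solution$stress)
  umag <- sqrt(rowSums(solution$u^2))
  rows <- lapply(names(parts), function(p) {
    sel <- mesh$region %in% parts[[p]]
    if (!any(sel)) stop("part `", p, "` matches no elements", call. = FALSE)
    eps <- t(vapply(which(sel), function(e) {
      log_principal_strains(solution$grad[e, ])
    }, numeric(2)))
    nids <- unique(as.integer(mesh$elements[sel, ]))
    data.frame(part = p,
               sigma_red_max = max(svm[sel]),
               sigma_red_p99 = as.numeric(stats::quantile(svm[sel], 0.99,
                                                          names = FALSE)),
               u_max = max(umag[nids]),
               eps_max = max(eps[, 1]),
               eps_min = min(eps[, 2]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  reac <- lapply(solution$support_sets, function(s) reaction_at(solution, s))
  names(reac) <- solution$support_sets
  structure(list(parts = tab, reactions = reac, case = solution$case),
            class = "solution_summary")
}

#' @export
print.solution_summary <- function(x, ...) {
  cat(sprintf("Solution summary, case `%s`:\n", x$case))
  print(x$parts, row.names = FALSE)
  for (nm in names(x$reactions)) {
    r <- x$reactions[[nm]]
    cat(sprintf("  reaction @ %s: (%.1f, %.1f, %.1f) N, |F| = %.1f N\n",
                nm, r$force[1], r$force[2], r$force[3], r$magnitude))
  }
  invisible(x)
}

#' Percent difference between two load cases
#'
#' Computes `100 * (A - B) / base` for one summary quantity, with the base
#' case recorded explicitly so the comparison is recomputable from the
#' reported values.
#'
#' @param summary_a,summary_b `solution_summary` objects (or bare numbers).
#' @param quantity Column of the part table, e.g. `"sigma_red_max"`.
#' @param part Part name the quantity is taken from.
#' @param base `"A"` or `"B"`: which value is the denominator.
#' @return A one-row data.frame of class `case_comparison`: `quantity`,
#'   `part`, `case_a`, `case_b`, `value_a`, `value_b`, `base`,
#'   `percent_diff`.
#' @export
compare_cases <- function(summary_a, summary_b, quantity = "sigma_red_max",
                          part = "hip_bones", base = c("A", "B")) {
  base <- match.arg(base)
  pick <- function(s) {
    if (is.numeric(s)) return(list(v = s, nm = "value"))
    stopifnot(inherits(s, "solution_summary"))
    row <- s$parts[s$parts$part == part, ]
    if (!nrow(row)) stop("part `", part, "` absent from summary", call. = FALSE)
    if (!quantity %in% names(row)) {
      stop("quantity `", quantity, "` absent from summary", call. = FALSE)
    }
    list(v = row[[quantity]], nm = s$case)
  }
  a <- pick(summary_a); b <- pick(summary_b)
  denom <- if (base == "A") a$v else b$v
  if (abs(denom) < .Machine$double.eps) {
    stop("zero base value; percent difference undefined", call. = FALSE)
  }
  structure(data.frame(quantity = quantity, part = part,
                       case_a = a$nm, case_b = b$nm,
                       value_a = a$v, value_b = b$v, base = base,
                       percent_diff = 100 * (a$v - b$v) / denom,
                       stringsAsFactors = FALSE),
            class = c("case_comparison", "data.frame"))
}

#' Tabular report over load cases
#'
#' Builds the per-part, per-case results table (reduced stress, displacement,
#' extreme logarithmic strains) in long form, ready for CSV or markdown.
#'
#' @param summaries List of `solution_summary` objects (one per load case).
#' @return data.frame with columns `case`, `part`, `sigma_red_max`,
#'   `sigma_red_p99`, `u_max`, `eps_max`, `eps_min`.
#' @export
table2_report <- function(summaries) {
  if (inherits(summaries, "solution_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  do.call(rbind, lapply(summaries, function(s) {
    cbind(case = s$case, s$parts, stringsAsFactors = FALSE)
  }))
}

#' Render a report data.frame as markdown
#'
#' @param report Output of [table2_report()] or [compare_cases()].
#' @param digits Significant digits.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report, digits = 4) {
  df <- as.data.frame(report)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Export a solution with result fields to VTK
#'
#' Writes the mesh with nodal displacement vectors and per-element reduced
#' stress and extreme logarithmic strains.
#'
#' @param solution An [fe_solve()] result.
#' @param path Output `.vtk` path.
#' @export
write_solution_vtk <- function(solution, path) {
  m <- nrow(solution$strain)
  eps <- t(vapply(seq_len(m), function(e) {
    log_principal_strains(solution$grad[e, ])
  }, numeric(2)))
  write_vtk(solution$mesh, path,
            point_data = list(u = solution$u),
            cell_data = list(sigma_red = von_mises_rows(solution$stress),
                             eps_log_max = eps[, 1],
                             eps_log_min = eps[, 2]))
}
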