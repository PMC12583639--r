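# Deterministic CSV writer: fixed number formatting so identical inputs give
# byte-identical files across runs and platforms.
write_csv_stable <- function(df, path, digits = 10) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

vnorm <- function(x) sqrt(sum(x^2))

#' Euclidean magnitude of a force vector
#'
#' @param f Numeric 3-vector (N).
#' @return `sqrt(fx^2 + fy^2 + fz^2)`.
#' @examples
#' force_magnitude(c(-381.5, 463.0, -829.6))
#' @export
force_magnitude <- function(f) {
  stopifnot(is.numeric(f))
  sqrt(sum(f^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# skew-symmetric matrix S(a) with S(a) %*% b == a x b
skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}
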