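# Rigid transforms parameterized by unit quaternion + translation.

#' Construct a rigid transform
#'
#' @param q Quaternion `(w, x, y, z)`; normalized on construction.
#' @param t Translation 3-vector (Angstrom).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  q <- as.numeric(q); t <- as.numeric(t)
  stopifnot(length(q) == 4L, length(t) == 3L, all(is.finite(c(q, t))))
  nq <- sqrt(sum(q^2))
  if (nq < 1e-12) stop("degenerate quaternion")
  structure(list(q = q / nq, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform q=(%.4f, %.4f, %.4f, %.4f) t=(%.3f, %.3f, %.3f)>\n",
              x$q[1], x$q[2], x$q[3], x$q[4], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Derivatives of the rotation matrix entries with respect to the (already
# normalized) quaternion components; list of four 3x3 matrices.
quat_matrix_derivs <- function(qh) {
  w <- qh[1]; x <- qh[2]; y <- qh[3]; z <- qh[4]
  list(
    2 * matrix(c(0, -z, y, z, 0, -x, -y, x, 0), 3, 3, byrow = TRUE),
    2 * matrix(c(0, y, z, y, -2 * x, -w, z, w, -2 * x), 3, 3, byrow = TRUE),
    2 * matrix(c(-2 * y, x, w, x, 0, z, -w, z, -2 * y), 3, 3, byrow = TRUE),
    2 * matrix(c(-2 * z, -w, x, w, -2 * z, y, x, y, 0), 3, 3, byrow = TRUE)
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform A [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  R <- quat_to_matrix(transform$q)
  sweep(coords %*% t(R), 2, transform$t, "+")
}

#' Apply a rigid transform to a whole molecule
#'
#' @param mol A [molecule()].
#' @param transform A [rigid_transform()].
#' @return The molecule with every conformer transformed.
#' @export
transform_molecule <- function(mol, transform) {
  mol$conformers <- lapply(mol$conformers, apply_transform,
                           transform = transform)
  mol
}

#' Random rigid transform
#'
#' Uniform random rotation (normalized Gaussian quaternion) and uniform
#' translation in a cube; used by invariance tests.
#'
#' @param max_translation Half-width of the translation cube (Angstrom).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_translation = 5) {
  rigid_transform(q = stats::rnorm(4),
                  t = stats::runif(3, -max_translation, max_translation))
}
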