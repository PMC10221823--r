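#' @name poisson-solvers
#' @title Poisson integration of a gradient field
#'
#' @description
#' Recovers an image from a target divergence by solving the discrete
#' Poisson equation `Laplace(I) = div` on the interior pixels with
#' Dirichlet boundary conditions. [solve_poisson_dst()] is the fast path:
#' the type-I discrete sine transform diagonalises the Dirichlet interior
#' Laplacian exactly, so the solve is two 2-D transforms and a pointwise
#' division by the eigenvalues `2*cos(pi*k/(m+1)) + 2*cos(pi*l/(n+1)) - 4`
#' (all strictly negative, so the division is always safe).
#' [solve_poisson_dense()] assembles the same linear system explicitly
#' and solves it directly; it is deliberately restricted to small grids
#' and serves as the independent oracle for the transform solver.
#'
#' All computation is in double precision; on unit-range images the
#' round-trip `solve(divergence(forward_gradients(I)))` with boundary
#' pinned to `I` reproduces `I` to around 1e-13 max abs error.
#'
#' @param div numeric matrix of target divergence values (only the
#'   interior entries are used).
#' @param boundary `NULL` for a zero Dirichlet boundary, or a matrix of
#'   the same shape as `div` whose outer ring supplies the boundary
#'   values.
#' @return numeric matrix of the same shape as `div`: the solved interior
#'   framed by the boundary ring.
NULL

# type-I DST of each column of A, via the odd-extension FFT identity
dst1_cols <- function(A) {
  m <- nrow(A)
  ext <- rbind(0, A, 0, -A[m:1, , drop = FALSE])
  F <- stats::mvfft(ext)
  -Im(F[2:(m + 1), , drop = FALSE]) / 2
}

dst1_2d <- function(A) t(dst1_cols(t(dst1_cols(A))))

#' @rdname poisson-solvers
#' @export
solve_poisson_dst <- function(div, boundary = NULL) {
  check_poisson_args(div, boundary)
  M <- nrow(div); N <- ncol(div)
  if (is.null(boundary)) boundary <- matrix(0, M, N)
  m <- M - 2; n <- N - 2
  rhs <- div[2:(M - 1), 2:(N - 1), drop = FALSE]
  rhs[1, ] <- rhs[1, ] - boundary[1, 2:(N - 1)]
  rhs[m, ] <- rhs[m, ] - boundary[M, 2:(N - 1)]
  rhs[, 1] <- rhs[, 1] - boundary[2:(M - 1), 1]
  rhs[, n] <- rhs[, n] - boundary[2:(M - 1), N]
  eig <- outer(2 * cos(pi * seq_len(m) / (m + 1)) - 2,
               2 * cos(pi * seq_len(n) / (n + 1)) - 2, `+`)
  stopifnot(all(eig < 0))
  Uhat <- dst1_2d(rhs) / eig
  u <- dst1_2d(Uhat) * (2 / (m + 1)) * (2 / (n + 1))
  out <- boundary
  out[2:(M - 1), 2:(N - 1)] <- u
  out
}

#' @rdname poisson-solvers
#' @export
solve_poisson_dense <- function(div, boundary = NULL) {
  check_poisson_args(div, boundary)
  M <- nrow(div); N <- ncol(div)
  if (M > 64 || N > 64)
    stop("dense solver is an oracle for grids <= 64 x 64")
  if (is.null(boundary)) boundary <- matrix(0, M, N)
  m <- M - 2; n <- N - 2
  idx <- matrix(seq_len(m * n), m, n)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(r, c, v) {
    rows <<- c(rows, r); cols <<- c(cols, c); vals <<- c(vals, v)
  }
  rhs <- as.vector(div[2:(M - 1), 2:(N - 1), drop = FALSE])
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      p <- idx[i, j]
      add(p, p, -4)
      # neighbours: interior -> matrix entry, ring -> move to rhs
      if (i > 1) add(p, idx[i - 1, j], 1)
      else rhs[p] <- rhs[p] - boundary[1, j + 1]
      if (i < m) add(p, idx[i + 1, j], 1)
      else rhs[p] <- rhs[p] - boundary[M, j + 1]
      if (j > 1) add(p, idx[i, j - 1], 1)
      else rhs[p] <- rhs[p] - boundary[i + 1, 1]
      if (j < n) add(p, idx[i, j + 1], 1)
      else rhs[p] <- rhs[p] - boundary[i + 1, N]
    }
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(m * n, m * n))
  u <- as.numeric(Matrix::solve(A, rhs))
  out <- boundary
  out[2:(M - 1), 2:(N - 1)] <- matrix(u, m, n)
  out
}

check_poisson_args <- function(div, boundary) {
  if (length(dim(div)) != 2) stop("div must be a 2-D matrix")
  if (nrow(div) < 3 || ncol(div) < 3)
    stop("grid must be at least 3 x 3 (one interior pixel)")
  if (!all(is.finite(div))) stop("div must be finite")
  if (!is.null(boundary) && !identical(dim(boundary), dim(div)))
    stop("boundary image must match div's shape")
  invisible(TRUE)
}
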