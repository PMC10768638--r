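#' Takagi-Autonne decomposition of a complex symmetric matrix
#'
#' Factorizes a complex symmetric matrix as `B = U diag(lambda) t(U)` with `U`
#' unitary and `lambda >= 0` sorted in descending order. For a Gaussian boson
#' sampler this is the step that turns a (rescaled) graph Laplacian into the
#' interferometer unitary and the per-mode squeezing values `tanh(r_i)`.
#'
#' The decomposition is computed through the real symmetric embedding
#' `M = rbind(cbind(X, Y), cbind(Y, -X))` of `B = X + iY`: eigenvectors of `M`
#' with eigenvalue `+lambda` give Takagi vectors `u = a + ib` satisfying
#' `B Conj(u) = lambda u`. Eigenpairs of `M` come in `(+lambda, -lambda)`
#' partners, so taking an orthonormal real eigenbasis of the positive part
#' yields complex-orthonormal Takagi columns even for degenerate `lambda`.
#' Exact-zero values are handled by completing `U` to a unitary on the null
#' space (any unitary completion is valid there).
#'
#' Column normalization: each column with `lambda > 0` is sign-flipped (the
#' only phase freedom that keeps `lambda` real positive) so that its first
#' significant entry has non-negative real part (positive imaginary part on a
#' tie).
#'
#' @param B complex (or numeric) symmetric matrix.
#' @param tol symmetry tolerance on the input.
#' @param zero_tol relative threshold below which a Takagi value is treated as
#'   exactly zero.
#' @return list with components `U` (unitary matrix) and `lambda`
#'   (non-negative, descending).
#' @export
takagi_decompose <- function(B, tol = 1e-10, zero_tol = 1e-12) {
  B <- as.matrix(B)
  N <- nrow(B)
  if (N != ncol(B)) stop("takagi_decompose: matrix must be square")
  if (N == 0L) return(list(U = matrix(0 + 0i, 0, 0), lambda = numeric(0)))
  if (max(abs(B - t(B))) > tol) {
    stop("takagi_decompose: matrix is not symmetric within tolerance ", tol)
  }
  X <- Re(B)
  Y <- Im(B)
  M <- rbind(cbind(X, Y), cbind(Y, -X))
  e <- eigen(M, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  thresh <- zero_tol * scale
  pos <- which(e$values > thresh)
  # eigen() returns descending eigenvalues, so `pos` is already sorted.
  lam <- e$values[pos]
  U <- matrix(0 + 0i, N, N)
  if (length(pos) > 0L) {
    V <- e$vectors[, pos, drop = FALSE]
    U[, seq_along(pos)] <- (V[seq_len(N), , drop = FALSE] +
                              1i * V[N + seq_len(N), , drop = FALSE])
  }
  nzero <- N - length(pos)
  if (nzero > 0L) {
    # Complete to a unitary on the (numerical) null space of B.
    if (length(pos) > 0L) {
      basis <- qr.Q(qr(cbind(U[, seq_along(pos), drop = FALSE],
                             diag(1 + 0i, N))))
      U[, length(pos) + seq_len(nzero)] <- basis[, length(pos) + seq_len(nzero),
                                                 drop = FALSE]
    } else {
      U <- diag(1 + 0i, N)
    }
    lam <- c(lam, rep(0, nzero))
  }
  # Sign normalization (columns with lambda > 0 admit only a +/-1 flip).
  for (j in seq_len(N)) {
    col <- U[, j]
    i0 <- which(abs(col) > 1e-8 * max(abs(col)))[1L]
    v <- col[i0]
    if (Re(v) < 0 || (abs(Re(v)) < 1e-14 && Im(v) < 0)) {
      U[, j] <- -col
    }
  }
  list(U = U, lambda = lam)
}

#' Squeezing parameters from Takagi values
#'
#' Inverts `lambda_i = tanh(r_i)`. Values at or above 1 are rejected: a unit
#' Takagi value would require an infinitely bright squeezer, which is the
#' signature of a graph that was not rescaled into the admissible spectrum.
#'
#' @param lambda numeric vector, each value in `[0, 1)`.
#' @return numeric vector of squeezing parameters `r_i = atanh(lambda_i)`.
#' @export
squeezing_from_takagi <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (any(!is.finite(lambda))) stop("squeezing_from_takagi: non-finite value")
  if (any(lambda < 0)) {
    stop("squeezing_from_takagi: negative Takagi value ",
         format(min(lambda)), " (spectrum error)")
  }
  if (any(lambda >= 1)) {
    stop("squeezing_from_takagi: Takagi value ", format(max(lambda)),
         " >= 1; the graph scaling failed to bring the spectrum into [0, 1)")
  }
  atanh(lambda)
}

# Check unitarity of a matrix to a given max-abs tolerance.
is_unitary <- function(U, tol = 1e-10) {
  U <- as.matrix(U)
  if (nrow(U) != ncol(U)) return(FALSE)
  max(abs(Conj(t(U)) %*% U - diag(1, nrow(U)))) <= tol
}
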